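#' EMS-mutagenize an individual
#'
#' Adds `n_variants` heterozygous point mutations (on haplotype 1): exactly
#' one causal suppressor variant placed in the CDS of `causal_gene` with
#' the requested truth effect class, plus `n_variants - 1` passengers at
#' random genome positions. EMS chemistry is modelled as a substitution
#' spectrum: with probability `transition_fraction` a variant is a G:C->A:T
#' transition (the dominant EMS signature); otherwise ref and alt are drawn
#' uniformly from the remaining substitution types. Variant positions never
#' collide with marker positions or with each other.
#'
#' Reference bases at previously unmaterialized (N) genome positions are
#' assigned and patched into the genome so that downstream ref checks
#' against the FASTA always agree.
#'
#' @param ind Individual to mutagenize (typically the A-strain parent).
#' @param n_variants Total new variants including the causal one (>= 1).
#' @param transition_fraction Fraction of G:C->A:T transitions in `[0, 1]`.
#' @param gene_models `gene_models` (for causal placement and truth labels).
#' @param genome Genome `DNAStringSet`.
#' @param map A `marker_map`.
#' @param variants Existing screen-wide variant table.
#' @param causal_gene Gene id in `gene_models` to host the causal variant.
#' @param causal_effect Truth effect class for the causal variant
#'   (default `"missense"`).
#' @return `list(individual, variants, genome, causal_id)`.
#' @export
mutagenize <- function(ind, n_variants, transition_fraction = 0.87,
                       gene_models, genome, map, variants,
                       causal_gene, causal_effect = "missense") {
  if (!is.numeric(n_variants) || n_variants < 1)
    fail("`n_variants` must be >= 1 (one causal variant plus passengers)")
  check_number(transition_fraction, "transition_fraction", 0, 1)
  if (!causal_gene %in% gene_models$genes$gene_id)
    fail("causal locus %s is not in the supplied gene models", causal_gene)

  taken <- paste(variants$chrom, variants$pos)
  marker_keys <- paste(map$markers$chrom, map$markers$pos)
  is_free <- function(ch, p) {
    k <- paste(ch, p)
    !(k %in% taken) && !(k %in% marker_keys)
  }

  g <- gene_models$genes[gene_models$genes$gene_id == causal_gene, ]
  ex <- gene_exons(gene_models, causal_gene)
  cds_pos_pool <- unlist(lapply(seq_len(nrow(ex)),
                                function(i) ex$start[i]:ex$end[i]))

  # --- causal variant: search CDS positions until the effect class matches
  causal <- NULL
  for (try in seq_len(2000L)) {
    p <- sample(cds_pos_pool, 1L)
    if (!is_free(g$chrom, p)) next
    ref <- genome_base(genome, g$chrom, p)
    alt <- if (ref == "G") "A" else if (ref == "C") "T" else
      sample(other_bases(ref), 1L)
    eff <- classify_effect(g$chrom, p, ref, alt, gene_models, genome)
    if (eff == causal_effect) {
      causal <- list(chrom = g$chrom, pos = p, ref = ref, alt = alt,
                     effect = eff)
      break
    }
  }
  if (is.null(causal))
    fail("could not place a %s causal variant in %s", causal_effect,
         causal_gene)
  taken <- c(taken, paste(causal$chrom, causal$pos))

  # --- passengers
  n_pass <- n_variants - 1L
  chroms <- names(map$chrom_lengths)
  lens <- as.numeric(map$chrom_lengths)
  pchrom <- character(n_pass); ppos <- integer(n_pass)
  pref <- character(n_pass); palt <- character(n_pass)
  patch_pos <- list(); patch_base <- list()
  for (i in seq_len(n_pass)) {
    transition <- stats::runif(1L) < transition_fraction
    repeat {
      ch <- sample(chroms, 1L, prob = lens)
      p <- sample.int(map$chrom_lengths[[ch]], 1L)
      if (!is_free(ch, p)) next
      ref <- genome_base(genome, ch, p)
      if (transition) {
        if (ref == "N") ref <- sample(c("G", "C"), 1L)
        if (!ref %in% c("G", "C")) next  # redraw: transitions need G/C refs
        alt <- if (ref == "G") "A" else "T"
      } else {
        if (ref == "N") ref <- sample(DNA4, 1L)
        excl <- switch(ref, G = "A", C = "T", NULL)
        alt <- sample(setdiff(other_bases(ref), excl), 1L)
      }
      break
    }
    if (genome_base(genome, ch, p) == "N") {
      patch_pos[[length(patch_pos) + 1L]] <- c(ch, p)
      patch_base[[length(patch_base) + 1L]] <- ref
    }
    pchrom[i] <- ch; ppos[i] <- p; pref[i] <- ref; palt[i] <- alt
    taken <- c(taken, paste(ch, p))
  }
  # batch-patch assigned reference bases, one replaceAt per chromosome
  if (length(patch_pos)) {
    pm <- do.call(rbind, patch_pos)
    for (ch in unique(pm[, 1L])) {
      sel <- pm[, 1L] == ch
      genome <- patch_genome_bases(genome, ch,
                                   as.integer(pm[sel, 2L]),
                                   unlist(patch_base)[sel])
    }
  }

  pass_eff <- if (n_pass > 0)
    vapply(seq_len(n_pass), function(i)
      classify_effect(pchrom[i], ppos[i], pref[i], palt[i],
                      gene_models, genome), "") else character()

  variants <- add_variant_rows(variants, causal$chrom, causal$pos,
                               causal$ref, causal$alt, "causal",
                               causal$effect)
  causal_id <- variants$id[nrow(variants)]
  if (n_pass > 0)
    variants <- add_variant_rows(variants, pchrom, ppos, pref, palt,
                                 "passenger", pass_eff)

  new_ids <- variants$id[variants$role %in% c("causal", "passenger") &
                           variants$id >= causal_id]
  for (id in new_ids) ind <- carry_variant(ind, variants, id, 1L)
  list(individual = ind, variants = variants, genome = genome,
       causal_id = causal_id)
}
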