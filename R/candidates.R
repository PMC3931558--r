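#' Candidate-filtering policy
#'
#' Encodes the published candidate rules: unique variants at more than 85%
#' pool allele frequency for recessive suppressors or more than 67% for
#' semi-dominant ones (strict inequalities), restricted to missense,
#' nonsense or splice-site changes; variants shared by at least
#' `background_min_strains` sequenced strains are background.
#'
#' @param recessive_min_freq Strict lower frequency bound, recessive mode
#'   (default 0.85).
#' @param semidominant_min_freq Same for semi-dominant/dominant mode
#'   (default 0.67).
#' @param allowed_effects Effect classes that qualify.
#' @param background_min_strains Strains (including the focal pool) a
#'   variant must appear in to count as background (default 2).
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(recessive_min_freq = 0.85,
                          semidominant_min_freq = 0.67,
                          allowed_effects = c("missense", "nonsense",
                                              "splice_site"),
                          background_min_strains = 2) {
  if (!(semidominant_min_freq > 0 &&
          semidominant_min_freq < recessive_min_freq &&
          recessive_min_freq <= 1))
    fail("need 0 < semidominant_min_freq < recessive_min_freq <= 1")
  check_number(background_min_strains, "background_min_strains", lower = 1)
  structure(list(recessive_min_freq = recessive_min_freq,
                 semidominant_min_freq = semidominant_min_freq,
                 allowed_effects = allowed_effects,
                 background_min_strains = background_min_strains),
            class = "filter_policy")
}

policy_threshold <- function(mode, policy) {
  switch(mode,
         recessive = policy$recessive_min_freq,
         dominant = ,
         semidominant = policy$semidominant_min_freq,
         fail("unknown mode %s", mode))
}

#' Remove variants present in the parental strain
#'
#' Drops every pool variant whose (chromosome, position, alt) key appears
#' in the parental variant set — the original lethal allele and any
#' pre-existing strain variants the parental library detected.
#'
#' @param pool_variants,parental_variants Data frames keyed by `chrom`,
#'   `pos`, `alt`.
#' @return The filtered pool variants.
#' @export
subtract_parental <- function(pool_variants, parental_variants) {
  if (!nrow(pool_variants) || !nrow(parental_variants))
    return(pool_variants)
  keep <- !(variant_key(pool_variants) %in% variant_key(parental_variants))
  out <- pool_variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove cross-strain background variants
#'
#' Non-polymorphic-strain variants common to multiple sequenced strains
#' are background (shared ancestry or systematic artifacts), not
#' EMS-induced candidates: a variant found in at least `min_strains`
#' pools in total (the focal pool plus the others) is removed.
#'
#' @param variants Focal pool variants (`chrom`, `pos`, `alt`).
#' @param other_pool_variant_sets List of variant data frames from other
#'   sequenced strains.
#' @param min_strains Occurrence threshold (default 2).
#' @return The filtered variants (pass-through with a warning when no
#'   other pools are provided).
#' @export
remove_background <- function(variants, other_pool_variant_sets,
                              min_strains = 2) {
  if (!length(other_pool_variant_sets)) {
    warning("no other pools provided: background removal skipped",
            call. = FALSE)
    return(variants)
  }
  if (!nrow(variants)) return(variants)
  keys <- variant_key(variants)
  n_strains <- 1L + Reduce(`+`, lapply(other_pool_variant_sets, function(s)
    as.integer(keys %in% variant_key(s))))
  out <- variants[n_strains < min_strains, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# CDS coordinate (1-based, mRNA orientation) of a genomic position inside
# an exon of `gene`; NA when the position is not exonic
cds_coord <- function(pos, gene, exons) {
  widths <- exons$end - exons$start + 1L
  i <- which(pos >= exons$start & pos <= exons$end)
  if (!length(i)) return(NA_integer_)
  if (gene$strand == "+") {
    before <- if (i > 1L) sum(widths[seq_len(i - 1L)]) else 0L
    before + (pos - exons$start[i] + 1L)
  } else {
    after <- if (i < nrow(exons)) sum(widths[(i + 1L):nrow(exons)]) else 0L
    after + (exons$end[i] - pos + 1L)
  }
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Classify the coding effect of a point variant
#'
#' Coding substitutions are translated through the standard genetic code
#' on the coding strand: stop gain is `nonsense`, an amino-acid change is
#' `missense`, a silent change `synonymous` (loss of the natural stop is
#' grouped with missense). Positions in the first or last two bases of an
#' intron are `splice_site` (the standard donor/acceptor definition);
#' everything else — intron interior, intergenic — is `noncoding`. The
#' variant's ref allele is checked against the genome and a mismatch is a
#' hard error reporting the coordinates.
#'
#' @param chrom,pos,ref,alt The variant.
#' @param gene_models A `gene_models` object.
#' @param genome Genome `DNAStringSet` covering the variant position.
#' @return One of `"missense"`, `"nonsense"`, `"splice_site"`,
#'   `"synonymous"`, `"noncoding"`.
#' @export
classify_effect <- function(chrom, pos, ref, alt, gene_models, genome) {
  if (ref == alt) fail("ref and alt are identical at %s:%d", chrom, pos)
  gbase <- genome_base(genome, chrom, pos)
  if (gbase != "N" && gbase != ref)
    fail("variant ref %s disagrees with genome base %s at %s:%d",
         ref, gbase, chrom, pos)
  g <- gene_models$genes
  hit <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
  if (!length(hit)) return("noncoding")
  gene <- g[hit[1L], ]
  exons <- gene_exons(gene_models, gene$gene_id)
  cpos <- cds_coord(pos, gene, exons)
  if (is.na(cpos)) {
    # intronic: within 2 bases of an exon boundary?
    for (i in seq_len(nrow(exons) - 1L)) {
      intron <- c(exons$end[i] + 1L, exons$start[i + 1L] - 1L)
      if (pos < intron[1L] || pos > intron[2L]) next
      if (pos - intron[1L] <= 1L || intron[2L] - pos <= 1L)
        return("splice_site")
    }
    return("noncoding")
  }
  cds <- gene_cds_seq(gene_models, gene$gene_id, genome)
  ref_tx <- if (gene$strand == "+") ref else complement_base(ref)
  alt_tx <- if (gene$strand == "+") alt else complement_base(alt)
  if (substr(cds, cpos, cpos) != ref_tx)
    fail("CDS base disagrees with variant ref at %s:%d", chrom, pos)
  codon_i <- (cpos - 1L) %/% 3L
  off <- (cpos - 1L) %% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, off + 1L, off + 1L) <- alt_tx
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Classify effects for a table of variants
#'
#' Vectorized wrapper around [classify_effect()].
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models,genome See [classify_effect()].
#' @return The input with `effect` and `gene_id` columns appended.
#' @export
classify_effects <- function(variants, gene_models, genome) {
  n <- nrow(variants)
  eff <- character(n); gid <- rep(NA_character_, n)
  g <- gene_models$genes
  for (i in seq_len(n)) {
    eff[i] <- classify_effect(variants$chrom[i], variants$pos[i],
                              variants$ref[i], variants$alt[i],
                              gene_models, genome)
    hit <- which(g$chrom == variants$chrom[i] & g$start <= variants$pos[i] &
                   g$end >= variants$pos[i])
    if (length(hit)) gid[i] <- g$gene_id[hit[1L]]
  }
  variants$effect <- eff
  variants$gene_id <- gid
  variants
}

#' Filter candidate suppressor mutations inside a mapped interval
#'
#' Keeps variants strictly inside the interval, of an allowed effect
#' class, with pool allele frequency strictly above the mode's threshold,
#' sorted by position.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`, `freq`,
#'   `effect` (and optionally `gene_id`).
#' @param interval One interval row (`chrom`, `start`, `end`).
#' @param mode `"recessive"`, `"semidominant"` or `"dominant"`.
#' @param policy A [filter_policy()].
#' @return The qualifying candidates with `inside_interval = TRUE`.
#' @export
filter_candidates <- function(variants, interval, mode,
                              policy = filter_policy()) {
  thr <- policy_threshold(mode, policy)
  keep <- variants$chrom == interval$chrom &
    variants$pos > interval$start & variants$pos < interval$end &
    variants$effect %in% policy$allowed_effects &
    !is.na(variants$freq) & variants$freq > thr
  out <- variants[keep, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  if (nrow(out)) out$inside_interval <- TRUE
  rownames(out) <- NULL
  out
}

#' Detect intragenic (linked) suppressor candidates in the target gene
#'
#' Even without any unique extragenic interval, a new qualifying variant
#' inside the target gene itself — a second-site intragenic suppressor —
#' is reported. The original lethal allele never appears here because
#' parental subtraction runs upstream.
#'
#' @param variants Candidate variants after parental/background filtering,
#'   with `freq` and `effect` columns.
#' @param target_gene_region `list(chrom =, start =, end =)` or a one-row
#'   data frame for the target gene.
#' @param mode Dominance mode (sets the frequency threshold).
#' @param policy A [filter_policy()].
#' @return Qualifying intragenic candidates.
#' @export
detect_intragenic <- function(variants, target_gene_region, mode,
                              policy = filter_policy()) {
  thr <- policy_threshold(mode, policy)
  keep <- variants$chrom == target_gene_region$chrom &
    variants$pos >= target_gene_region$start &
    variants$pos <= target_gene_region$end &
    variants$effect %in% policy$allowed_effects &
    !is.na(variants$freq) & variants$freq > thr
  out <- variants[keep, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the candidate report
#'
#' Mirrors the published result-table surface: mapping interval, candidate
#' gene, mutation frequency and effect per candidate, plus the mapping
#' outcome and run metadata. When a truth record is supplied the report
#' adds a truth comparison: whether the candidate list contains the causal
#' variant, and the candidate count.
#'
#' @param candidates Candidate data frame (possibly empty).
#' @param outcome Outcome list from [classify_outcome()].
#' @param run_metadata Named list recorded verbatim.
#' @param truth Optional truth record (with `chrom`, `pos`, `alt`).
#' @return A `candidate_report` list with elements `candidates`,
#'   `outcome`, `metadata`, `truth_comparison`.
#' @export
report_table <- function(candidates, outcome, run_metadata = list(),
                         truth = NULL) {
  cols <- c("chrom", "pos", "ref", "alt", "freq", "gene_id", "effect")
  if (nrow(candidates) == 0L)
    candidates <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             freq = numeric(), gene_id = character(),
                             effect = character(), stringsAsFactors = FALSE)
  candidates <- candidates[, intersect(c(cols, "inside_interval"),
                                       names(candidates)), drop = FALSE]
  tc <- NULL
  if (!is.null(truth)) {
    key <- variant_key(list(chrom = truth$chrom, pos = truth$pos,
                            alt = truth$alt))
    tc <- list(causal_in_candidates =
                 nrow(candidates) > 0 && key %in% variant_key(candidates),
               candidate_count = nrow(candidates))
  }
  structure(list(candidates = candidates, outcome = outcome$outcome,
                 unique_intervals = outcome$unique_intervals,
                 metadata = run_metadata, truth_comparison = tc),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> outcome=%s, %d candidate(s)\n",
              x$outcome, nrow(x$candidates)))
  if (nrow(x$candidates)) print(x$candidates)
  if (!is.null(x$truth_comparison))
    cat(sprintf("  causal in candidates: %s\n",
                x$truth_comparison$causal_in_candidates))
  invisible(x)
}
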