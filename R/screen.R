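#' Configuration of a simulated suppressor screen
#'
#' Defaults encode the study conditions of the screen being emulated:
#' six chromosomes with LG I = 15 Mb and LG IV = 17.5 Mb; a marker density
#' of 20/Mb (about 2,000 strain-diagnostic SNPs genome-wide, a desk-scale
#' thinning of the real catalogue); 300 EMS passengers at 87% G:C->A:T
#' transitions; four backcross rounds of the suppressor line and six
#' introgression rounds of the mapping strain; 250 F2 recombinants (the
#' stated range is 160-300) selfed en masse for two further generations;
#' and introgression gaps on LG I (1.5-12.8 Mb) and LG IV (0-15.8 Mb).
#' The paternal-effect incompatibility locus defaults to 2.3 Mb on LG I,
#' inside the LG I gap, and is disabled by default because the gap already
#' masks it in mapping runs.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param marker_density Markers per Mb.
#' @param n_passenger_ems EMS passenger count before backcrossing.
#' @param ems_transition_fraction G:C->A:T fraction of EMS variants.
#' @param backcross_rounds Backcrosses of the mutagenized line.
#' @param f2_pool_size Number of F2 recombinants pooled (> 0); also the
#'   per-generation size of the en-masse culture.
#' @param extra_selfing_generations Selfing generations after F2 selection.
#' @param introgression_gaps Data frame `chrom`, `start`, `end` (1-based
#'   inclusive) retained as A-origin in the mapping strain.
#' @param mode Suppression mode; see [selection_model()].
#' @param het_survival,het_brood Optional overrides of the heterozygote's
#'   survival probability and brood multiplier.
#' @param target_gene,causal_gene `list(gene_id =, chrom =, pos =)` anchors
#'   for the target (lethal-allele) gene and the suppressor gene.
#' @param causal_effect Truth effect class of the causal variant.
#' @param n_decoy_genes_per_chrom Decoy genes per chromosome.
#' @param n_background_variants Strain-A background SNVs shared by all
#'   suppressor lines.
#' @param incompatibility Enable the paternal-effect locus.
#' @param incompatibility_locus `list(chrom =, pos =)`.
#' @param crossover_model `"obligate"` or `"poisson"`.
#' @param preselect Preselect homozygous F2s before pooling.
#' @param preselect_n_f2 F2s screened singly when preselecting.
#' @param preselect_keep Homozygotes pooled after preselection.
#' @param survivor_threshold Brood-survival cutoff of the preselection.
#' @param progeny_per_f2 Brood size scored per preselected F2.
#' @param preselect_before_selection Draw the screened F2s from the raw F2
#'   population (`TRUE`) or from viability-selected survivors (`FALSE`).
#' @param n_lines Independent suppressor lines to simulate.
#' @param seed Integer seed governing the entire simulation.
#' @return A `screen_config` object (a validated list).
#' @export
screen_config <- function(
    chrom_lengths = c(I = 15e6, II = 15e6, III = 14e6,
                      IV = 17.5e6, V = 21e6, X = 18e6),
    marker_density = 20,
    n_passenger_ems = 300,
    ems_transition_fraction = 0.87,
    backcross_rounds = 4,
    f2_pool_size = 250,
    extra_selfing_generations = 2,
    introgression_gaps = data.frame(
      chrom = c("I", "IV"), start = c(1.5e6, 1), end = c(12.8e6, 15.8e6),
      stringsAsFactors = FALSE),
    mode = "recessive",
    het_survival = NULL,
    het_brood = NULL,
    target_gene = list(gene_id = "tgt-1", chrom = "IV", pos = 8e6),
    causal_gene = list(gene_id = "sup-1", chrom = "II", pos = 6.5e6),
    causal_effect = "missense",
    n_decoy_genes_per_chrom = 3,
    n_background_variants = 50,
    incompatibility = FALSE,
    incompatibility_locus = list(chrom = "I", pos = 2.3e6),
    crossover_model = "obligate",
    preselect = FALSE,
    preselect_n_f2 = 120,
    preselect_keep = 26,
    survivor_threshold = 0.6,
    progeny_per_f2 = 100,
    preselect_before_selection = TRUE,
    n_lines = 1,
    seed = 1) {
  cfg <- structure(as.list(environment()), class = "screen_config")
  validate_screen_config(cfg)
}

#' Validate a screen configuration
#'
#' Checks chromosome lengths, pool size, gap bounds and gene anchors;
#' called by [screen_config()] and after programmatic edits.
#'
#' @param cfg A `screen_config`.
#' @return The configuration, invisibly, or an error.
#' @export
validate_screen_config <- function(cfg) {
  if (any(cfg$chrom_lengths <= 0)) fail("chromosome lengths must be positive")
  check_number(cfg$f2_pool_size, "f2_pool_size", lower = 1)
  check_number(cfg$marker_density, "marker_density", lower = 1e-12)
  check_number(cfg$ems_transition_fraction, "ems_transition_fraction", 0, 1)
  check_number(cfg$extra_selfing_generations, "extra_selfing_generations",
               lower = 0)
  check_number(cfg$n_lines, "n_lines", lower = 1)
  g <- cfg$introgression_gaps
  if (!is.null(g) && nrow(g)) {
    if (!all(g$chrom %in% names(cfg$chrom_lengths)))
      fail("introgression gap on unknown chromosome")
    if (any(g$start < 1 | g$end > cfg$chrom_lengths[g$chrom] |
              g$start > g$end))
      fail("introgression gap outside chromosome bounds")
  }
  for (gene in list(cfg$target_gene, cfg$causal_gene)) {
    if (!gene$chrom %in% names(cfg$chrom_lengths))
      fail("gene %s placed on unknown chromosome %s", gene$gene_id,
           gene$chrom)
    if (gene$pos < 1 || gene$pos > cfg$chrom_lengths[[gene$chrom]])
      fail("gene %s placed outside chromosome %s", gene$gene_id, gene$chrom)
  }
  invisible(cfg)
}

config_selection_model <- function(cfg) {
  viability <- NULL; brood <- NULL
  if (!is.null(cfg$het_survival))
    viability <- c("sup/+" = cfg$het_survival)
  if (!is.null(cfg$het_brood)) brood <- c("sup/+" = cfg$het_brood)
  selection_model(cfg$mode, viability = viability, brood = brood,
                  incompatibility_enabled = isTRUE(cfg$incompatibility))
}

# align marker allele_a with materialized genome sequence: markers inside
# gene bodies adopt the gene's base; elsewhere the marker base is patched
# into the genome.
reconcile_markers_genome <- function(map, genome) {
  for (ch in names(map$by_chrom)) {
    m <- map$by_chrom[[ch]]
    if (!nrow(m)) next
    base <- genome_base(genome, ch, m$pos)
    inside <- base != "N"
    if (any(inside)) {
      m$allele_a[inside] <- base[inside]
      clash <- inside & m$allele_a == m$allele_b
      if (any(clash))
        m$allele_b[clash] <- vapply(m$allele_a[clash],
                                    function(b) sample(other_bases(b), 1L),
                                    "")
    }
    if (any(!inside))
      genome <- patch_genome_bases(genome, ch, m$pos[!inside],
                                   m$allele_a[!inside])
    map$by_chrom[[ch]] <- m
  }
  markers <- do.call(rbind, map$by_chrom)
  rownames(markers) <- NULL
  list(map = new_marker_map(map$chrom_lengths, markers), genome = genome)
}

#' Simulate a complete suppressor screen and mapping cross
#'
#' Runs the whole scheme: build the marker map and sparse genome with gene
#' models; create the A-strain parent carrying the target-gene lethal
#' allele and shared background variants; introgress the lethal allele
#' into the polymorphic strain (with the configured introgression gaps);
#' for each suppressor line, EMS-mutagenize, fix the suppressor, backcross
#' to the unmutagenized parent, cross to the introgressed mapping strain,
#' self the F1 into `f2_pool_size` F2 recombinants, select (or preselect
#' homozygotes), and propagate en masse for the configured number of
#' further generations. Deterministic given `config$seed`.
#'
#' @param config A [screen_config()].
#' @return A `screen_truth` bundle: `config`, `map`, `genome`,
#'   `gene_models`, `variants`, `parental` (the unmutagenized A-strain
#'   individual and its variant ids), `pools` (one final
#'   `population_pool` per line) and `truth` (per line: causal
#'   chromosome/position/alleles/effect class, mode, seed, and the causal
#'   variant's true frequency in the final pool).
#' @export
simulate_screen <- function(config) {
  validate_screen_config(config)
  set.seed(config$seed)
  model <- config_selection_model(config)
  incomp <- if (isTRUE(config$incompatibility))
    config$incompatibility_locus else NULL

  map <- build_marker_map(config$chrom_lengths, config$marker_density)
  genome <- new_genome(config$chrom_lengths)
  intragenic_causal <-
    config$causal_gene$gene_id == config$target_gene$gene_id
  gm <- make_gene_models(genome, config$target_gene,
                         if (intragenic_causal) NULL else config$causal_gene,
                         config$n_decoy_genes_per_chrom)
  genome <- gm$genome
  models <- gm$models
  rec <- reconcile_markers_genome(map, genome)
  map <- rec$map; genome <- rec$genome

  variants <- empty_variant_table()

  # target-gene lethal allele: a missense variant both strains carry
  tgt <- models$genes[models$genes$role == "target", ]
  tgt_ex <- gene_exons(models, tgt$gene_id)
  lethal <- NULL
  for (try in 1:2000) {
    p <- sample(unlist(Map(seq, tgt_ex$start, tgt_ex$end)), 1L)
    ref <- genome_base(genome, tgt$chrom, p)
    alt <- sample(other_bases(ref), 1L)
    if (paste(tgt$chrom, p) %in% paste(map$markers$chrom, map$markers$pos))
      next
    if (classify_effect(tgt$chrom, p, ref, alt, models, genome) ==
          "missense") {
      lethal <- list(chrom = tgt$chrom, pos = p, ref = ref, alt = alt)
      break
    }
  }
  variants <- add_variant_rows(variants, lethal$chrom, lethal$pos,
                               lethal$ref, lethal$alt, "parental_lethal",
                               "missense")
  lethal_id <- variants$id[nrow(variants)]

  # shared strain-A background variants at random non-marker positions
  nbg <- config$n_background_variants
  if (nbg > 0) {
    chroms <- names(config$chrom_lengths)
    taken <- c(paste(map$markers$chrom, map$markers$pos),
               paste(variants$chrom, variants$pos))
    bchrom <- character(nbg); bpos <- integer(nbg)
    bref <- character(nbg); balt <- character(nbg)
    for (i in seq_len(nbg)) {
      repeat {
        ch <- sample(chroms, 1L, prob = as.numeric(config$chrom_lengths))
        p <- sample.int(config$chrom_lengths[[ch]], 1L)
        if (paste(ch, p) %in% taken) next
        ref <- genome_base(genome, ch, p)
        if (ref == "N") ref <- sample(DNA4, 1L)
        bchrom[i] <- ch; bpos[i] <- p; bref[i] <- ref
        balt[i] <- sample(other_bases(ref), 1L)
        taken <- c(taken, paste(ch, p))
        break
      }
    }
    for (ch in unique(bchrom)) {   # batch-patch assigned reference bases
      sel <- which(bchrom == ch)[genome_base(genome, ch,
                                             bpos[bchrom == ch]) == "N"]
      if (length(sel))
        genome <- patch_genome_bases(genome, ch, bpos[sel], bref[sel])
    }
    beff <- vapply(seq_len(nbg), function(i)
      classify_effect(bchrom[i], bpos[i], bref[i], balt[i], models, genome),
      "")
    variants <- add_variant_rows(variants, bchrom, bpos, bref, balt,
                                 "background", beff)
  }
  parental_ids <- variants$id

  strain_a <- strain_individual(map, 0L)
  for (id in parental_ids)
    strain_a <- carry_variant(strain_a, variants, id, 1:2)

  # The introgressed mapping strain is constructed directly from its
  # measured description: polymorphic (B) origin everywhere except the
  # configured introgression gaps, which stay A-type, carrying the
  # target-gene lethal allele homozygous. Building it this way keeps the
  # gap annotation written to disk exactly equal to the strain's true
  # A-type regions — the situation of an introgressed strain whose gaps
  # have been mapped by sequencing before use. (Simulating the
  # introgression cross itself is available via backcross_series(); its
  # linkage drag extends A-type regions stochastically beyond any fixed
  # annotation, which is precisely why the measured description is used
  # here.)
  mapping_strain <- strain_individual(map, 1L, sex = "male")
  g <- config$introgression_gaps
  if (!is.null(g) && nrow(g)) {
    for (i in seq_len(nrow(g))) {
      ch <- g$chrom[i]
      mpos <- map$by_chrom[[ch]]$pos
      sel <- mpos >= g$start[i] & mpos <= g$end[i]
      for (h in 1:2) mapping_strain$haps[[ch]][[h]]$origin[sel] <- 0L
    }
  }
  in_gap <- function(ch, p) {
    if (is.null(g) || !nrow(g)) return(FALSE)
    any(g$chrom == ch & g$start <= p & g$end >= p)
  }
  mapping_strain <- carry_variant(mapping_strain, variants, lethal_id, 1:2)
  for (id in setdiff(parental_ids, lethal_id))
    if (in_gap(variants$chrom[id], variants$pos[id]))
      mapping_strain <- carry_variant(mapping_strain, variants, id, 1:2)

  pools <- list(); truth <- list()
  for (line_i in seq_len(config$n_lines)) {
    mut <- mutagenize(strain_a, config$n_passenger_ems + 1L,
                      config$ems_transition_fraction, models, genome, map,
                      variants, causal_gene = config$causal_gene$gene_id,
                      causal_effect = config$causal_effect)
    variants <- mut$variants; genome <- mut$genome
    causal_id <- mut$causal_id
    # isolate a stable homozygous suppressor line, then clean its
    # background by backcrossing to the unmutagenized parent
    line <- backcross_series(mut$individual, strain_a,
                             config$backcross_rounds, map, variants,
                             keep_id = causal_id, homozygose = TRUE,
                             crossover = config$crossover_model)
    f1 <- cross(line, mapping_strain, 1L, map, variants,
                incompatibility = incomp,
                crossover = config$crossover_model)[[1L]]
    f2 <- self_cross(f1, config$f2_pool_size, map, variants,
                     incompatibility = incomp,
                     crossover = config$crossover_model)
    if (isTRUE(config$preselect)) {
      source_f2 <- f2
      if (!isTRUE(config$preselect_before_selection)) {
        sel <- apply_selection(f2, model, map, variants, causal_id)
        source_f2 <- sel$individuals
      }
      screened <- utils::head(source_f2, config$preselect_n_f2)
      kept <- preselect_homozygotes(screened, model,
                                    config$survivor_threshold,
                                    config$progeny_per_f2, map, variants,
                                    causal_id,
                                    crossover = config$crossover_model)
      kept <- utils::head(kept, config$preselect_keep)
      pool0 <- population_pool(kept, "F2", map, variants, causal_id)
      if (!length(kept)) {
        warning("preselection kept no F2s", call. = FALSE)
        attr(pool0, "extinct") <- TRUE
      }
    } else {
      pool0 <- apply_selection(f2, model, map, variants, causal_id)
    }
    # en-masse growth refills the plate each generation: the propagated
    # pool holds f2_pool_size animals regardless of how many founders
    # survived selection
    final <- if (pool_size(pool0) > 0)
      propagate_pool(pool0, config$extra_selfing_generations, model,
                     n = config$f2_pool_size, incompatibility = incomp,
                     crossover = config$crossover_model)
    else pool0
    line_name <- sprintf("line%d", line_i)
    pools[[line_name]] <- final
    cv <- variants[variants$id == causal_id, ]
    freq <- if (pool_size(final) > 0)
      pool_variant_freqs(final)$true_freq[causal_id] else NA_real_
    truth[[line_name]] <- list(
      line = line_name, causal_id = causal_id, chrom = cv$chrom,
      pos = cv$pos, ref = cv$ref, alt = cv$alt,
      effect = cv$effect_truth, mode = config$mode, seed = config$seed,
      causal_true_freq = freq,
      target_gene = config$target_gene$gene_id,
      causal_gene = config$causal_gene$gene_id)
  }
  # pools share the final variant table (ids are stable across lines)
  for (nm in names(pools)) pools[[nm]]$variants <- variants

  structure(list(config = config, map = map, genome = genome,
                 gene_models = models, variants = variants,
                 parental = list(individual = strain_a,
                                 variant_ids = parental_ids),
                 mapping_strain = mapping_strain,
                 pools = pools, truth = truth),
            class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf("<screen_truth> %d line(s), mode=%s, seed=%d\n",
              length(x$pools), x$config$mode, x$config$seed))
  for (nm in names(x$truth)) {
    t <- x$truth[[nm]]
    cat(sprintf("  %s: causal %s:%d %s>%s (%s), true freq %.3f\n",
                nm, t$chrom, t$pos, t$ref, t$alt, t$effect,
                t$causal_true_freq))
  }
  invisible(x)
}
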