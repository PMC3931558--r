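# shared fixtures, built in code at test time

# desk-scale screen configuration: 2 chromosomes x 2 Mb, 40 markers
tiny_config <- function(seed = 1, ...) {
  defaults <- list(
    chrom_lengths = c(I = 2e6, II = 2e6),
    marker_density = 20,
    n_passenger_ems = 40,
    f2_pool_size = 60,
    introgression_gaps = data.frame(chrom = "I", start = 2e5, end = 9e5,
                                    stringsAsFactors = FALSE),
    target_gene = list(gene_id = "tgt-1", chrom = "I", pos = 5e5),
    causal_gene = list(gene_id = "sup-1", chrom = "II", pos = 1e6),
    n_decoy_genes_per_chrom = 1,
    n_background_variants = 10,
    backcross_rounds = 2,
    seed = seed)
  do.call(screen_config, utils::modifyList(defaults, list(...)))
}

# mapping parameters scaled to the 2 Mb tiny fixture (10x smaller windows
# and spans than the full-genome defaults, same thresholds)
tiny_mapping_params <- function(...)
  mapping_params(window_size = 1e5, min_markers_per_window = 2,
                 min_interval_span = 2e5, ...)

# one-chromosome map with markers at given positions (alleles A/G)
simple_map <- function(positions, len = 1e6, chrom = "I") {
  marker_map(stats::setNames(len, chrom),
             data.frame(chrom = chrom, pos = as.integer(positions),
                        allele_a = "A", allele_b = "G",
                        stringsAsFactors = FALSE))
}

# individual with explicit per-haplotype origin vectors on a one-chrom map
individual_with_origins <- function(map, o1, o2, var1 = integer(),
                                    var2 = integer()) {
  ch <- names(map$chrom_lengths)[1L]
  g1 <- stats::setNames(list(list(origin = as.integer(o1), var = var1)), ch)
  g2 <- stats::setNames(list(list(origin = as.integer(o2), var = var2)), ch)
  fuse_gametes(g1, g2)
}

# F1 hybrid: A-strain haplotype carrying the causal variant, B-strain
# haplotype without it; heterozygous everywhere
make_f1 <- function(map, variants, causal_id) {
  a <- strain_individual(map, 0L)
  a <- carry_variant(a, variants, causal_id, 1:2)
  b <- strain_individual(map, 1L)
  fuse_gametes(meiosis(a, map, variants), meiosis(b, map, variants))
}

# genotype-labelled F2-like individuals on a simple map: returns a list
# with `dose` copies of the causal variant each
f2_with_dose <- function(map, variants, causal_id, dose, n) {
  base <- strain_individual(map, 0L)
  ind <- base
  if (dose >= 1) ind <- carry_variant(ind, variants, causal_id, 1L)
  if (dose >= 2) ind <- carry_variant(ind, variants, causal_id, 2L)
  replicate(n, ind, simplify = FALSE)
}

one_variant_table <- function(chrom = "I", pos = 5e5)
  variant_table(chrom, pos, "G", "A", role = "causal",
                effect_truth = "missense")

# run the analysis half of the pipeline in memory on a simulated bundle:
# pooled read sampling, frequency track, interval calling, gap
# subtraction and the candidate scan for the first line
map_and_scan_screen <- function(b, map_mode = b$config$mode,
                                sparams = seq_params(),
                                mparams = mapping_params(),
                                policy = filter_policy()) {
  pool <- b$pools$line1
  sites <- sample_site_counts(pool_site_table(pool), sparams)
  track <- marker_frequencies(sites, b$map, mparams$min_depth)
  w <- window_stats(track, mparams, b$map$chrom_lengths)
  iv <- call_intervals(w, map_mode, mparams, track)
  g <- b$config$introgression_gaps
  bed <- data.frame(chrom = g$chrom, start = g$start - 1, end = g$end)
  iv <- subtract_known_gaps(iv, bed, track = track)
  uniq <- iv[!is.na(iv$unique) & iv$unique, , drop = FALSE]
  vars <- sites[!sites$is_marker & sites$alt_count > 0, , drop = FALSE]
  vars$freq <- vars$alt_count / (vars$ref_count + vars$alt_count)
  parental <- b$variants[b$variants$role %in%
                           c("parental_lethal", "background"), ]
  vars <- subtract_parental(vars, parental)
  vars <- classify_effects(vars, b$gene_models, b$genome)
  cands <- if (nrow(uniq))
    unique(do.call(rbind, lapply(seq_len(nrow(uniq)), function(i)
      filter_candidates(vars, uniq[i, ], map_mode, policy))))
  else vars[0, , drop = FALSE]
  truth <- b$truth$line1
  contains <- nrow(uniq) > 0 &&
    any(uniq$chrom == truth$chrom & uniq$start <= truth$pos &
          uniq$end >= truth$pos)
  truth_key <- paste(truth$chrom, truth$pos, truth$alt, sep = ":")
  cand_keys <- if (nrow(cands))
    paste(cands$chrom, cands$pos, cands$alt, sep = ":") else character()
  list(track = track, intervals = iv, uniq = uniq, candidates = cands,
       truth = truth, contains_truth = contains,
       causal_in_candidates = truth_key %in% cand_keys,
       truth_span = if (contains)
         uniq$span[uniq$chrom == truth$chrom][1] else NA_real_)
}

# deterministic two-gene toy genome (one gene per strand) for effect tests
toy_gene_genome <- function(seed = 42) {
  set.seed(seed)
  genome <- new_genome(c(A = 2e4, B = 2e4))
  gm <- make_gene_models(genome,
                         target = list(gene_id = "gA", chrom = "A",
                                       pos = 5000),
                         causal = list(gene_id = "gB", chrom = "B",
                                       pos = 5000),
                         n_decoys_per_chrom = 0)
  gm
}
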