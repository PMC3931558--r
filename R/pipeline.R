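#' Serialize / restore a screen configuration
#'
#' Round-trips a [screen_config()] through JSON so a run is reproducible
#' from its written configuration alone.
#'
#' @param config A `screen_config`.
#' @param path JSON path.
#' @return `path` (writer); a `screen_config` (reader).
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$chrom_lengths <- unlist(raw$chrom_lengths)
  if (!is.null(raw$introgression_gaps))
    raw$introgression_gaps <- as.data.frame(raw$introgression_gaps)
  do.call(screen_config, raw)
}

# internal: 1-based inclusive gap table -> BED-convention half-open
gaps_to_bed <- function(gaps) {
  if (is.null(gaps) || !nrow(gaps))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(chrom = gaps$chrom, start = as.integer(gaps$start) - 1L,
             end = as.integer(gaps$end), stringsAsFactors = FALSE)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    fail("output directory %s exists and is not empty (use force = TRUE)",
         out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

#' Simulate a screen and write the truth bundle to disk
#'
#' Writes genome FASTA, gene models GFF3, marker TSV, gaps BED, the
#' serialized configuration, a truth JSON, the parental-strain VCF and one
#' pooled VCF per suppressor line. Byte-identical across reruns with the
#' same configuration (all randomness flows from `config$seed`).
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @param sparams [seq_params()] for the pooled read sampling.
#' @return Invisibly, `list(bundle, files)`.
#' @export
run_simulate <- function(config, out_dir, force = FALSE,
                         sparams = seq_params()) {
  prepare_out_dir(out_dir, force)
  bundle <- simulate_screen(config)
  f <- function(...) file.path(out_dir, ...)
  files <- list(genome = f("genome.fa"), gff = f("genes.gff3"),
                markers = f("markers.tsv"), gaps = f("gaps.bed"),
                config = f("config.json"), truth = f("truth.json"),
                parental = f("parental.vcf"))
  write_genome_fasta(bundle$genome, files$genome)
  write_gff3(bundle$gene_models, files$gff, config$chrom_lengths)
  write_marker_tsv(bundle$map, files$markers)
  write_gaps_bed(config$introgression_gaps, files$gaps)
  write_run_config(config, files$config)

  tgt <- bundle$gene_models$genes[bundle$gene_models$genes$role == "target", ]
  truth_out <- list(lines = bundle$truth,
                    target_gene_region = list(gene_id = tgt$gene_id,
                                              chrom = tgt$chrom,
                                              start = tgt$start,
                                              end = tgt$end),
                    seq_params = unclass(sparams))
  jsonlite::write_json(truth_out, files$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  par_sites <- individual_site_table(bundle$parental$individual, bundle$map,
                                     bundle$variants)
  par_counts <- sample_site_counts(par_sites, sparams)
  emit_pool_vcf(par_counts[, setdiff(names(par_counts), "true_freq")],
                files$parental, sample_name = "parental",
                contigs = config$chrom_lengths)
  for (nm in names(bundle$pools)) {
    pool <- bundle$pools[[nm]]
    path <- f(sprintf("pool_%s.vcf", nm))
    files[[paste0("pool_", nm)]] <- path
    if (pool_size(pool) == 0L) {
      empty <- sample_site_counts(
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), true_freq = numeric(),
                   is_marker = logical(), stringsAsFactors = FALSE), sparams)
      emit_pool_vcf(empty, path, sample_name = nm,
                    contigs = config$chrom_lengths)
      next
    }
    counts <- sample_site_counts(pool_site_table(pool), sparams)
    emit_pool_vcf(counts[, setdiff(names(counts), "true_freq")], path,
                  sample_name = nm, contigs = config$chrom_lengths)
  }
  invisible(list(bundle = bundle, files = files))
}

#' Map a pooled VCF to candidate intervals
#'
#' Reads the pool VCF, marker TSV and gaps BED, computes the marker
#' frequency track, window statistics and interval calls, subtracts the
#' known introgression gaps and classifies the outcome. Writes
#' `track.tsv`, `plot_data.tsv` (the display-filtered view), `windows.tsv`,
#' `intervals.tsv`, `intervals.bed` and `outcome.json`; every parameter
#' used is recorded in the outcome metadata.
#'
#' @param vcf Pool VCF path.
#' @param markers Marker TSV path.
#' @param gaps Gaps BED path (or `NULL` for none).
#' @param mode `"recessive"`, `"semidominant"` or `"dominant"`.
#' @param params A [mapping_params()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @param intragenic_hits Optional qualifying target-gene hits, consulted
#'   when no unique interval remains.
#' @return Invisibly, `list(track, windows, intervals, outcome)`.
#' @export
run_map <- function(vcf, markers, gaps, mode, params = mapping_params(),
                    out_dir, force = FALSE, intragenic_hits = NULL) {
  prepare_out_dir(out_dir, force)
  sites <- read_pool_vcf(vcf)
  map <- read_marker_tsv(markers)
  gap_df <- if (!is.null(gaps) && file.exists(gaps)) read_gaps_bed(gaps)
  else data.frame(chrom = character(), start = integer(), end = integer())
  track <- marker_frequencies(sites, map, params$min_depth)
  windows <- window_stats(track, params, map$chrom_lengths)
  intervals <- call_intervals(windows, mode, params, track)
  intervals <- subtract_known_gaps(intervals, gap_df, track = track)
  outcome <- classify_outcome(intervals, intragenic_hits)

  f <- function(...) file.path(out_dir, ...)
  write_tsv(track, f("track.tsv"))
  write_tsv(display_filter(track, params$display_min_freq),
            f("plot_data.tsv"))
  write_tsv(windows, f("windows.tsv"))
  write_tsv(intervals, f("intervals.tsv"))
  if (nrow(intervals)) {
    bed <- data.frame(chrom = intervals$chrom,
                      start = intervals$start - 1L, end = intervals$end,
                      name = sprintf("%s_%s", intervals$mode,
                                     ifelse(intervals$unique, "unique",
                                            "gap")))
    utils::write.table(bed, f("intervals.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else file.create(f("intervals.bed"))
  jsonlite::write_json(
    list(outcome = outcome$outcome,
         unique_intervals = outcome$unique_intervals,
         coverage = attr(track, "coverage"),
         params = unclass(params), mode = mode),
    f("outcome.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(track = track, windows = windows, intervals = intervals,
                 outcome = outcome))
}

# variant sites (non-marker, any alt evidence) of a site-count table,
# with observed frequencies
observed_variants <- function(sites) {
  v <- sites[!sites$is_marker & sites$alt_count > 0, , drop = FALSE]
  v$freq <- site_freq(v)
  rownames(v) <- NULL
  v
}

#' Scan mapped intervals for candidate suppressor mutations
#'
#' Pipeline order: parental subtraction, cross-strain background removal,
#' effect classification, then interval restriction and the mode's
#' frequency/effect filter; an intragenic target-gene scan covers the
#' linked-suppressor case. Stage-wise variant counts are logged and
#' recorded in the report metadata.
#'
#' @param vcf Focal pool VCF path.
#' @param parental Parental-strain VCF path.
#' @param background Character vector of other pools' VCF paths (possibly
#'   empty).
#' @param intervals Interval table from [run_map()] (data frame) or the
#'   written `intervals.tsv` path.
#' @param gff Gene models GFF3 path.
#' @param fasta Genome FASTA path.
#' @param mode `"recessive"`, `"semidominant"` or `"dominant"`.
#' @param policy A [filter_policy()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @param target_gene_id Target gene id for the intragenic scan (or `NULL`).
#' @param truth Optional truth record for the report's truth comparison.
#' @return Invisibly, the `candidate_report`.
#' @export
run_candidates <- function(vcf, parental, background = character(),
                           intervals, gff, fasta, mode,
                           policy = filter_policy(), out_dir, force = FALSE,
                           target_gene_id = NULL, truth = NULL) {
  prepare_out_dir(out_dir, force)
  pool_sites <- read_pool_vcf(vcf)
  vars <- observed_variants(pool_sites)
  parental_vars <- observed_variants(read_pool_vcf(parental))
  other_sets <- lapply(background, function(p)
    observed_variants(read_pool_vcf(p)))
  if (is.character(intervals)) intervals <- read_tsv(intervals)
  models <- read_gff3(gff)
  genome <- read_genome_fasta(fasta)

  counts <- c(pool = nrow(vars))
  vars <- subtract_parental(vars, parental_vars)
  counts["after_parental"] <- nrow(vars)
  if (length(other_sets)) {
    vars <- remove_background(vars, other_sets,
                              policy$background_min_strains)
  }
  counts["after_background"] <- nrow(vars)
  vars <- classify_effects(vars, models, genome)

  uniq <- if (nrow(intervals))
    intervals[!is.na(intervals$unique) & intervals$unique, , drop = FALSE]
  else intervals
  cands <- list()
  for (i in seq_len(nrow(uniq)))
    cands[[i]] <- filter_candidates(vars, uniq[i, ], mode, policy)
  candidates <- if (length(cands)) unique(do.call(rbind, cands)) else
    vars[0, , drop = FALSE]
  counts["candidates"] <- nrow(candidates)

  hits <- NULL
  if (!is.null(target_gene_id) &&
        target_gene_id %in% models$genes$gene_id) {
    tg <- models$genes[models$genes$gene_id == target_gene_id, ]
    hits <- detect_intragenic(vars, list(chrom = tg$chrom, start = tg$start,
                                         end = tg$end), mode, policy)
  }
  outcome <- classify_outcome(intervals, hits)
  if (outcome$outcome == "linked_to_target") candidates <- hits
  message(paste(sprintf("%s=%d", names(counts), counts), collapse = "  "))

  report <- report_table(candidates, outcome,
                         run_metadata = list(mode = mode,
                                             policy = unclass(policy),
                                             stage_counts = as.list(counts)),
                         truth = truth)
  f <- function(...) file.path(out_dir, ...)
  write_tsv(report$candidates, f("candidates.tsv"))
  jsonlite::write_json(
    list(outcome = report$outcome, candidates = report$candidates,
         metadata = report$metadata,
         truth_comparison = report$truth_comparison),
    f("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the whole pipeline: simulate, map, identify candidates
#'
#' Convenience wrapper chaining [run_simulate()], [run_map()] and
#' [run_candidates()] per simulated line, then comparing the candidate
#' list against the simulation truth. Everything is recomputed from the
#' files the simulation stage wrote, so the run also exercises every
#' reader/writer pair.
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @param sparams,mparams,policy Stage parameter objects.
#' @return Invisibly, a per-line list of
#'   `list(map, report, truth, causal_recovered)`.
#' @export
run_e2e <- function(config, out_dir, force = FALSE,
                    sparams = seq_params(), mparams = mapping_params(),
                    policy = filter_policy()) {
  sim <- run_simulate(config, out_dir, force, sparams)
  files <- sim$files
  truth_all <- jsonlite::fromJSON(files$truth, simplifyVector = FALSE)
  results <- list()
  line_names <- names(sim$bundle$pools)
  for (nm in line_names) {
    vcf <- files[[paste0("pool_", nm)]]
    others <- unlist(files[paste0("pool_", setdiff(line_names, nm))],
                     use.names = FALSE)
    mapped <- run_map(vcf, files$markers, files$gaps, config$mode, mparams,
                      out_dir = file.path(out_dir, paste0(nm, "_map")),
                      force = force)
    truth <- truth_all$lines[[nm]]
    report <- run_candidates(
      vcf, files$parental, others, mapped$intervals, files$gff,
      files$genome, config$mode, policy,
      out_dir = file.path(out_dir, paste0(nm, "_candidates")),
      force = force, target_gene_id = config$target_gene$gene_id,
      truth = truth)
    results[[nm]] <- list(map = mapped, report = report, truth = truth,
                          causal_recovered =
                            isTRUE(report$truth_comparison$causal_in_candidates))
  }
  jsonlite::write_json(
    lapply(results, function(r) list(outcome = r$report$outcome,
                                     causal_recovered = r$causal_recovered,
                                     n_candidates = nrow(r$report$candidates))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
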