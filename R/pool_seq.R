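#' Fold coverage of a sequencing library
#'
#' `n_reads * read_length / genome_size`; e.g. 36 million 50-nt reads over
#' a 100 Mb genome give 18-fold coverage.
#'
#' @param n_reads Number of reads (>= 0).
#' @param read_length Read length in nucleotides (> 0).
#' @param genome_size Genome size in base pairs (> 0).
#' @return Fold coverage (dimensionless).
#' @export
fold_coverage <- function(n_reads, read_length, genome_size) {
  if (!is.numeric(n_reads) || any(n_reads < 0))
    fail("`n_reads` must be >= 0")
  if (!is.numeric(read_length) || any(read_length <= 0))
    fail("`read_length` must be > 0")
  if (!is.numeric(genome_size) || any(genome_size <= 0))
    fail("`genome_size` must be > 0 (zero genome size is not defined)")
  n_reads * read_length / genome_size
}

#' Pooled-sequencing sampling parameters
#'
#' @param mean_depth Mean reads per site (default 18, the screen's
#'   per-library fold coverage).
#' @param base_error Per-read miscall probability (default 0.001), folded
#'   over strand/mapping error with uniform erroneous-base choice.
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @return A `seq_params` object.
#' @export
seq_params <- function(mean_depth = 18, base_error = 0.001,
                       depth_model = c("poisson", "fixed")) {
  check_number(mean_depth, "mean_depth", lower = 1e-9)
  check_number(base_error, "base_error", 0, 0.25)
  depth_model <- match.arg(depth_model)
  structure(list(mean_depth = mean_depth, base_error = base_error,
                 depth_model = depth_model), class = "seq_params")
}

#' Sample pooled read counts at sites of known true frequency
#'
#' Depth is drawn per site from the depth model; the alt read count is
#' `Binomial(depth, f')` with `f' = f(1-e) + (1-f)e/3`, where `f` is the
#' true pool frequency and `e` the per-read miscall probability. Sites may
#' come back with depth 0 (frequency undefined there).
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `true_freq` and optionally `is_marker`.
#' @param params A [seq_params()].
#' @return The input with `ref_count`, `alt_count` columns appended
#'   (`true_freq` retained for truth comparison; drop before writing VCF).
#' @export
sample_site_counts <- function(sites, params = seq_params()) {
  if (any(sites$true_freq < 0 | sites$true_freq > 1, na.rm = TRUE))
    fail("true frequencies must lie in [0, 1]")
  n <- nrow(sites)
  depth <- switch(params$depth_model,
                  poisson = stats::rpois(n, params$mean_depth),
                  fixed = rep(as.integer(round(params$mean_depth)), n))
  e <- params$base_error
  f2 <- sites$true_freq * (1 - e) + (1 - sites$true_freq) * e / 3
  alt <- stats::rbinom(n, depth, f2)
  sites$ref_count <- depth - alt
  sites$alt_count <- alt
  if (is.null(sites$is_marker)) sites$is_marker <- FALSE
  sites
}

site_depth <- function(sites) sites$ref_count + sites$alt_count

site_freq <- function(sites) {
  d <- site_depth(sites)
  ifelse(d > 0, sites$alt_count / d, NA_real_)
}

#' Build the site table of a pool for sequencing
#'
#' One row per known marker (B-allele = alt) plus one row per variant
#' segregating in the pool (true frequency > 0), sorted by chromosome and
#' position. Markers are flagged with `is_marker` so the same file serves
#' both the mapping scan and the candidate-mutation scan.
#'
#' @param pool A `population_pool`.
#' @return Data frame ready for [sample_site_counts()].
#' @export
pool_site_table <- function(pool) {
  mk <- pool_marker_freqs(pool)
  m <- pool$map$markers
  marker_sites <- data.frame(chrom = m$chrom, pos = m$pos,
                             ref = m$allele_a, alt = m$allele_b,
                             true_freq = mk$true_freq, is_marker = TRUE,
                             stringsAsFactors = FALSE)
  v <- pool_variant_freqs(pool)
  v <- v[v$true_freq > 0, , drop = FALSE]
  var_sites <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                          alt = v$alt, true_freq = v$true_freq,
                          is_marker = FALSE, stringsAsFactors = FALSE)
  out <- rbind(marker_sites, var_sites)
  out <- order_sites(out, names(pool$map$chrom_lengths))
  rownames(out) <- NULL
  out
}

# site table of a single (clonal) individual, e.g. the parental strain
individual_site_table <- function(ind, map, variants) {
  pool <- population_pool(list(ind), "P0", map, variants)
  v <- pool_variant_freqs(pool)
  v <- v[v$true_freq > 0, , drop = FALSE]
  out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    true_freq = v$true_freq, is_marker = FALSE,
                    stringsAsFactors = FALSE)
  out <- order_sites(out, names(map$chrom_lengths))
  rownames(out) <- NULL
  out
}

#' Write pooled site counts as VCF 4.2
#'
#' One record per site with per-sample allelic depths (`AD` = ref,alt) and
#' total depth (`DP`); known strain-diagnostic markers carry the `MARKER`
#' INFO flag. Input must be sorted by (chromosome, position) in contig
#' order with no duplicate (chrom, pos, alt); zero-depth sites are
#' retained with `AD=0,0`.
#'
#' @param sites Data frame from [sample_site_counts()].
#' @param path Output path.
#' @param sample_name Sample column name (default `"pool"`).
#' @param contigs Named chromosome lengths for `##contig` lines.
#' @return `path`, invisibly.
#' @export
emit_pool_vcf <- function(sites, path, sample_name = "pool", contigs) {
  key <- paste(sites$chrom, sites$pos, sites$alt)
  if (anyDuplicated(key))
    fail("duplicate (chrom, pos, alt) records: %s",
         key[duplicated(key)][1L])
  ord <- order(factor(sites$chrom, levels = names(contigs)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    fail("sites must be sorted by (chromosome, position)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=supmapr",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    paste0("##INFO=<ID=MARKER,Number=0,Type=Flag,",
           "Description=\"Known strain-diagnostic marker site\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(sites)) {
    info <- ifelse(sites$is_marker, "MARKER", ".")
    dp <- site_depth(sites)
    writeLines(paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                     ".", ".", info, "AD:DP",
                     sprintf("%d,%d:%d", sites$ref_count, sites$alt_count,
                             dp),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a pooled VCF back into a site-count table
#'
#' Parses with `vcfR` and extracts the `AD`/`DP` per-sample fields and the
#' `MARKER` INFO flag; the reader/writer pair is a round-trip identity on
#' site counts.
#'
#' @param path VCF path.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `is_marker`, with the sample name in attribute
#'   `"sample"`.
#' @export
read_pool_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(v@gt) == 0 && nrow(fix) > 0)
    fail("VCF %s has no genotype columns", path)
  fmt <- if (nrow(v@gt)) v@gt[, 1L] else character()
  if (length(fmt) && !all(grepl("AD", fmt)))
    fail("VCF %s lacks the AD (allelic depth) FORMAT field", path)
  n <- nrow(fix)
  if (n == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer(),
                      is_marker = logical(), stringsAsFactors = FALSE)
    attr(out, "sample") <- colnames(v@gt)[2L]
    return(out)
  }
  ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_count <- vapply(parts, function(p) as.integer(p[1L]), 0L)
  alt_count <- vapply(parts, function(p) as.integer(p[2L]), 0L)
  info <- fix[, "INFO"]
  info[is.na(info)] <- "."
  out <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    ref_count = ref_count, alt_count = alt_count,
    is_marker = grepl("(^|;)MARKER(;|$)", info),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sample") <- colnames(v@gt)[2L]
  out
}
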