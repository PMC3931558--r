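#' Parameters of the SNP-frequency mapping scan
#'
#' The published interval definition was visual ("absence" of polymorphic
#' SNPs for recessive suppressors, "reduction" for dominant ones); this
#' windowed threshold-run algorithm is the package's codification of it,
#' with every constant exposed here and recorded in output metadata. The
#' dominant-mode reduction cutoff is this package's default, not a
#' published value.
#'
#' @param window_size Tiling window size in bp (default 500 kb).
#' @param min_markers_per_window Markers needed for a window to be
#'   informative (default 5).
#' @param absence_threshold Window-mean B frequency at or below which a
#'   window qualifies in recessive (absence) mode (default 0.10).
#' @param reduction_threshold Same for dominant/semi-dominant (reduction)
#'   mode (default 0.30).
#' @param display_min_freq Plotting filter: only frequencies strictly
#'   above this are displayed (default 0.20).
#' @param min_depth Minimum read depth for a marker to enter the frequency
#'   track (default 4).
#' @param merge_gap Qualifying runs separated by at most this many
#'   non-qualifying windows are merged (default 1).
#' @param min_interval_span Minimum interval span in bp (default 500 kb).
#' @return A `mapping_params` object.
#' @export
mapping_params <- function(window_size = 5e5, min_markers_per_window = 5,
                           absence_threshold = 0.10,
                           reduction_threshold = 0.30,
                           display_min_freq = 0.20, min_depth = 4,
                           merge_gap = 1, min_interval_span = 5e5) {
  check_number(window_size, "window_size", lower = 1)
  check_number(absence_threshold, "absence_threshold", 0, 1)
  check_number(reduction_threshold, "reduction_threshold", 0, 1)
  if (!(absence_threshold < reduction_threshold &&
          reduction_threshold < 0.5))
    fail("need 0 <= absence_threshold < reduction_threshold < 0.5")
  check_number(min_depth, "min_depth", lower = 0)
  check_number(merge_gap, "merge_gap", lower = 0)
  structure(list(window_size = window_size,
                 min_markers_per_window = min_markers_per_window,
                 absence_threshold = absence_threshold,
                 reduction_threshold = reduction_threshold,
                 display_min_freq = display_min_freq,
                 min_depth = min_depth, merge_gap = merge_gap,
                 min_interval_span = min_interval_span),
            class = "mapping_params")
}

mode_threshold <- function(mode, params) {
  switch(mode,
         recessive = params$absence_threshold,
         dominant = ,
         semidominant = params$reduction_threshold,
         fail("unknown mapping mode %s", mode))
}

#' Observed B-allele frequency track at known marker sites
#'
#' For every marker in the map found in the pooled site counts with depth
#' at or above `min_depth`, the observed polymorphic-strain (B/alt) allele
#' frequency is `alt_count / depth`. Non-marker sites are ignored; markers
#' missing from the pool file are treated as depth 0 and dropped. A
#' coverage report (total / missing / low-depth marker counts) is attached
#' as attribute `"coverage"`.
#'
#' @param sites Site counts (from [read_pool_vcf()] or
#'   [sample_site_counts()]).
#' @param map A `marker_map`.
#' @param min_depth Minimum depth (default 4).
#' @return Data frame `chrom`, `pos`, `freq`, `depth` sorted by
#'   (chromosome, position).
#' @export
marker_frequencies <- function(sites, map, min_depth = 4) {
  m <- map$markers
  key_m <- paste(m$chrom, m$pos)
  s <- sites[sites$is_marker | paste(sites$chrom, sites$pos) %in% key_m, ,
             drop = FALSE]
  idx <- match(key_m, paste(s$chrom, s$pos))
  depth <- ifelse(is.na(idx), 0L, site_depth(s)[idx])
  alt <- ifelse(is.na(idx), 0L, s$alt_count[idx])
  keep <- depth >= min_depth
  track <- data.frame(chrom = m$chrom[keep], pos = m$pos[keep],
                      freq = alt[keep] / depth[keep],
                      depth = depth[keep], stringsAsFactors = FALSE)
  track <- order_sites(track, names(map$chrom_lengths))
  rownames(track) <- NULL
  attr(track, "coverage") <- list(n_markers = nrow(m),
                                  n_missing = sum(is.na(idx)),
                                  n_low_depth = sum(!keep & !is.na(idx)))
  track
}

#' Display filter for frequency plots
#'
#' Returns the plotting view of a track: only markers with frequency
#' strictly above `display_min_freq` are displayed. Never used for
#' interval calling.
#'
#' @param track A frequency track.
#' @param display_min_freq Threshold (default 0.20).
#' @return The filtered track.
#' @export
display_filter <- function(track, display_min_freq = 0.20) {
  out <- track[track$freq > display_min_freq, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window summary of a frequency track
#'
#' Tiles every chromosome with windows of `window_size` starting at base
#' 1 and reports the unweighted mean marker frequency (each marker one
#' vote, matching the dot-per-SNP presentation of the original frequency
#' plots) and marker count per window. Windows with fewer than
#' `min_markers_per_window` markers are flagged uninformative.
#'
#' @param track A frequency track from [marker_frequencies()].
#' @param params A [mapping_params()].
#' @param chrom_lengths Named chromosome lengths.
#' @return Data frame `chrom`, `start`, `end`, `n_markers`, `mean_freq`,
#'   `informative`, one row per tiling window.
#' @export
window_stats <- function(track, params, chrom_lengths) {
  w <- params$window_size
  rows <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n_win <- ceiling(L / w)
    start <- (seq_len(n_win) - 1L) * w + 1
    end <- pmin(start + w - 1, L)
    t <- track[track$chrom == ch, , drop = FALSE]
    idx <- if (nrow(t)) (t$pos - 1) %/% w + 1L else integer()
    cnt <- tabulate(idx, nbins = n_win)
    sums <- numeric(n_win)
    if (nrow(t)) {
      agg <- tapply(t$freq, idx, sum)
      sums[as.integer(names(agg))] <- agg
    }
    data.frame(chrom = ch, start = start, end = end, n_markers = cnt,
               mean_freq = ifelse(cnt > 0, sums / cnt, NA_real_),
               informative = cnt >= params$min_markers_per_window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call candidate mapping intervals from window statistics
#'
#' A window qualifies when it is informative and its mean B frequency is
#' at or below the mode's threshold (absence threshold for recessive
#' suppressors, reduction threshold for dominant/semi-dominant ones).
#' Maximal runs of qualifying windows — merging across at most
#' `merge_gap` intervening non-qualifying windows — become intervals.
#' Interval bounds snap to the outermost sub-threshold marker positions:
#' starting from the sub-threshold markers inside the run, the bounds are
#' extended outward along the track while consecutive flanking markers
#' remain at or below the threshold (so a depleted marker stranded in an
#' adjacent marker-sparse window still bounds the interval). Intervals
#' spanning less than `min_interval_span` are discarded.
#'
#' @param windows Window table from [window_stats()].
#' @param mode `"recessive"`, `"dominant"` or `"semidominant"`.
#' @param params A [mapping_params()].
#' @param track The frequency track the windows were computed from.
#' @return Data frame `chrom`, `start`, `end`, `span`, `mean_freq`,
#'   `n_markers`, `mode`, `threshold`, `unique` (NA until gap
#'   subtraction). Attribute `"params"` records the parameters used.
#' @export
call_intervals <- function(windows, mode, params, track) {
  thr <- mode_threshold(mode, params)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), span = integer(),
                      mean_freq = numeric(), n_markers = integer(),
                      mode = character(), threshold = numeric(),
                      unique = logical(), stringsAsFactors = FALSE)
  attr(empty, "params") <- params
  if (!any(windows$informative)) {
    warning("no informative windows: interval calling is impossible",
            call. = FALSE)
    return(empty)
  }
  out <- list()
  for (ch in unique(windows$chrom)) {
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    tch <- track[track$chrom == ch, , drop = FALSE]
    qual <- which(wch$informative & !is.na(wch$mean_freq) &
                    wch$mean_freq <= thr)
    if (!length(qual)) next
    run_id <- cumsum(c(1L, diff(qual) > params$merge_gap + 1L))
    for (r in unique(run_id)) {
      win <- qual[run_id == r]
      span_start <- wch$start[min(win)]
      span_end <- wch$end[max(win)]
      inside <- which(tch$pos >= span_start & tch$pos <= span_end &
                        tch$freq <= thr)
      if (!length(inside)) next
      # extend outward while flanking markers stay sub-threshold
      lo <- min(inside); hi <- max(inside)
      while (lo > 1L && tch$freq[lo - 1L] <= thr) lo <- lo - 1L
      while (hi < nrow(tch) && tch$freq[hi + 1L] <= thr) hi <- hi + 1L
      start <- tch$pos[lo]; end <- tch$pos[hi]
      if (end - start < params$min_interval_span) next
      span_markers <- tch[lo:hi, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end, span = end - start,
        mean_freq = mean(span_markers$freq), n_markers = nrow(span_markers),
        mode = mode, threshold = thr, unique = NA,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "params") <- params
  res
}

#' Subtract known introgression gaps from called intervals
#'
#' Intervals of low polymorphic-SNP frequency that merely recapitulate the
#' mapping strain's introgression gaps are not evidence of linkage: an
#' interval fully contained in the gap set is marked non-unique; a
#' partially overlapping interval is trimmed to its residual outside the
#' gaps and kept (flagged `trimmed`) only if the residual spans at least
#' `min_residual_span`.
#'
#' @param intervals Interval calls from [call_intervals()].
#' @param gaps Data frame `chrom`, `start`, `end`. Following BED
#'   conventions these are 0-based half-open; use [read_gaps_bed()] for
#'   files written by this package.
#' @param min_residual_span Minimum residual span (default: the calling
#'   parameters' `min_interval_span` when available, else 5e5).
#' @param track Optional frequency track to recompute marker statistics of
#'   trimmed residuals.
#' @return The interval table with `unique` filled in (and possibly
#'   trimmed rows).
#' @export
subtract_known_gaps <- function(intervals, gaps, min_residual_span = NULL,
                                track = NULL) {
  p <- attr(intervals, "params")
  min_residual_span <- min_residual_span %||%
    (if (!is.null(p)) p$min_interval_span else 5e5)
  if (!nrow(intervals)) return(intervals)
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    g <- gaps[gaps$chrom == iv$chrom, , drop = FALSE]
    if (!nrow(g)) {
      iv$unique <- TRUE
      out[[length(out) + 1L]] <- iv
      next
    }
    ir <- IRanges::IRanges(iv$start, iv$end)
    gr <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    resid <- IRanges::setdiff(ir, gr)
    if (sum(IRanges::width(resid)) == 0L) {
      iv$unique <- FALSE
      out[[length(out) + 1L]] <- iv
      next
    }
    if (identical(as.integer(IRanges::start(resid)), as.integer(iv$start)) &&
        identical(as.integer(IRanges::end(resid)), as.integer(iv$end))) {
      iv$unique <- TRUE
      out[[length(out) + 1L]] <- iv
      next
    }
    for (j in seq_along(resid)) {
      s <- IRanges::start(resid)[j]; e <- IRanges::end(resid)[j]
      if (e - s < min_residual_span) next
      piece <- iv
      piece$start <- s; piece$end <- e; piece$span <- e - s
      piece$unique <- TRUE
      piece$trimmed <- TRUE
      if (!is.null(track)) {
        tm <- track[track$chrom == iv$chrom & track$pos >= s &
                      track$pos <= e, , drop = FALSE]
        piece$mean_freq <- if (nrow(tm)) mean(tm$freq) else NA_real_
        piece$n_markers <- nrow(tm)
      } else {
        piece$mean_freq <- NA_real_
        piece$n_markers <- NA_integer_
      }
      out[[length(out) + 1L]] <- piece
    }
  }
  for (k in seq_along(out))
    if (is.null(out[[k]]$trimmed)) out[[k]]$trimmed <- FALSE
  res <- if (length(out)) do.call(rbind, out) else {
    e <- intervals[0, , drop = FALSE]
    e$trimmed <- logical()
    e
  }
  rownames(res) <- NULL
  attr(res, "params") <- p
  res
}

#' Classify the mapping outcome of a screen
#'
#' Exactly one unique extragenic interval means the suppressor mapped
#' (`extragenic_mapped`). No unique interval but a qualifying new variant
#' inside the target gene means a linked, intragenic suppressor
#' (`linked_to_target`) — the signature of second-site mutations in the
#' target gene itself, which hide inside the introgression gap. Neither
#' means `unmapped`. More than one unique interval is reported as
#' `ambiguous` with all intervals listed rather than silently resolved.
#'
#' @param intervals Interval table after [subtract_known_gaps()].
#' @param intragenic_hits Optional data frame of qualifying target-gene
#'   candidate variants (see [detect_intragenic()]).
#' @return `list(outcome =, unique_intervals =, intragenic_hits =)` with
#'   `outcome` one of `"extragenic_mapped"`, `"linked_to_target"`,
#'   `"unmapped"`, `"ambiguous"`.
#' @export
classify_outcome <- function(intervals, intragenic_hits = NULL) {
  uniq <- if (nrow(intervals))
    intervals[!is.na(intervals$unique) & intervals$unique, , drop = FALSE]
  else intervals
  n_hits <- if (is.null(intragenic_hits)) 0L else nrow(intragenic_hits)
  outcome <- if (nrow(uniq) == 1L) "extragenic_mapped"
  else if (nrow(uniq) > 1L) "ambiguous"
  else if (n_hits > 0L) "linked_to_target"
  else "unmapped"
  list(outcome = outcome, unique_intervals = uniq,
       intragenic_hits = intragenic_hits)
}

#' Write / read a gaps BED file (0-based half-open)
#'
#' @param gaps Data frame `chrom`, `start`, `end` in 1-based inclusive
#'   coordinates (as used internally).
#' @param path File path.
#' @return `path` (writer) / a data frame in 0-based half-open BED
#'   coordinates ready for [subtract_known_gaps()] (reader).
#' @export
write_gaps_bed <- function(gaps, path) {
  bed <- data.frame(chrom = gaps$chrom,
                    start = as.integer(gaps$start) - 1L,
                    end = as.integer(gaps$end))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gaps_bed
#' @export
read_gaps_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
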