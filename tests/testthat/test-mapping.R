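# hand-built track/window fixtures

track_df <- function(chrom, pos, freq, depth = 18L)
  data.frame(chrom = chrom, pos = as.integer(pos), freq = freq,
             depth = depth, stringsAsFactors = FALSE)

# random window fixture: `n_win` windows of 100 kb with marker counts and
# frequencies controlled by `freq_fun`
random_track <- function(n_win, freq_fun, min_markers = 3) {
  pos <- integer(); freq <- numeric()
  for (w in seq_len(n_win)) {
    k <- stats::rpois(1, 6)
    if (k == 0) next
    p <- sort(sample(((w - 1) * 1e5 + 1):(w * 1e5), k))
    pos <- c(pos, p)
    freq <- c(freq, freq_fun(w, k))
  }
  track_df("I", pos, freq)
}

test_that("marker frequencies come from allele depths with depth and
           coverage accounting", {
  map <- marker_map(c(I = 1e6),
                    data.frame(chrom = "I", pos = c(1e5, 2e5, 3e5),
                               allele_a = "A", allele_b = "G",
                               stringsAsFactors = FALSE))
  sites <- data.frame(chrom = c("I", "I"), pos = c(1e5, 2e5),
                      ref = "A", alt = "G",
                      ref_count = c(9L, 2L), alt_count = c(9L, 1L),
                      is_marker = TRUE, stringsAsFactors = FALSE)
  track <- marker_frequencies(sites, map, min_depth = 4)
  expect_equal(track$freq, 0.5)          # (9,9) -> 0.5
  expect_equal(track$pos, 1e5)           # depth 3 dropped, missing dropped
  cov <- attr(track, "coverage")
  expect_equal(cov$n_markers, 3L)
  expect_equal(cov$n_missing, 1L)
  expect_equal(cov$n_low_depth, 1L)
})

test_that("display filter keeps only frequencies strictly above the
           threshold and never alters calling input", {
  t <- track_df("I", c(1, 2, 3) * 1e5, c(0.05, 0.21, 0.5))
  expect_equal(display_filter(t, 0.20)$freq, c(0.21, 0.5))
  expect_equal(nrow(display_filter(t[0, ], 0.20)), 0L)
  all5 <- track_df("I", c(1, 2) * 1e5, c(0.5, 0.5))
  expect_equal(display_filter(all5, 0.20), all5)
})

test_that("window statistics equal direct per-window averaging", {
  p <- mapping_params(window_size = 1e5, min_markers_per_window = 3)
  set.seed(91)
  t <- random_track(3, function(w, k) stats::runif(k))
  w <- window_stats(t, p, c(I = 3e5))
  expect_equal(nrow(w), 3L)
  for (i in 1:3) {
    sel <- t$pos > (i - 1) * 1e5 & t$pos <= i * 1e5
    if (any(sel)) expect_equal(w$mean_freq[i], mean(t$freq[sel]))
    expect_equal(w$n_markers[i], sum(sel))
  }
  # sparse window flagged uninformative
  t2 <- track_df("I", c(1e4, 2e4), c(0.5, 0.5))
  w2 <- window_stats(t2, mapping_params(window_size = 1e5,
                                        min_markers_per_window = 5),
                     c(I = 1e5))
  expect_false(w2$informative)
})

test_that("interval calling follows the windowed threshold-run rules", {
  p <- mapping_params(window_size = 1e5, min_markers_per_window = 3,
                      min_interval_span = 5e4)
  mk_track <- function(means) {
    pos <- integer(); freq <- numeric()
    for (w in seq_along(means)) {
      pp <- (w - 1) * 1e5 + c(1e4, 5e4, 9e4)
      pos <- c(pos, pp); freq <- c(freq, rep(means[w], 3))
    }
    track_df("I", pos, freq)
  }
  L <- c(I = 5e5)
  t <- mk_track(c(0.5, 0.5, 0.05, 0.02, 0.5))
  w <- window_stats(t, p, L)
  iv <- call_intervals(w, "recessive", p, t)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 2e5 + 1e4)   # outermost sub-threshold markers
  expect_equal(iv$end, 3e5 + 9e4)

  flat <- mk_track(c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(nrow(call_intervals(window_stats(flat, p, L), "recessive",
                                   p, flat)), 0L)

  # reduction vs absence mode
  t2 <- mk_track(c(0.5, 0.25, 0.22, 0.5))
  w2 <- window_stats(t2, p, c(I = 4e5))
  expect_equal(nrow(call_intervals(w2, "dominant", p, t2)), 1L)
  expect_equal(nrow(call_intervals(w2, "recessive", p, t2)), 0L)

  # no informative windows at all
  empty <- track_df("I", 1e4, 0.5)
  we <- window_stats(empty, p, c(I = 1e5))
  expect_warning(iv0 <- call_intervals(we, "recessive", p, empty),
                 "no informative")
  expect_equal(nrow(iv0), 0L)
})

test_that("interval caller agrees with the exhaustive-scan oracle on
           random tracks of up to 50 windows", {
  set.seed(101)
  for (case in 1:40) {
    n_win <- sample(5:50, 1)
    base <- stats::runif(1, 0.3, 0.6)
    t <- random_track(n_win, function(w, k)
      pmin(1, pmax(0, stats::rnorm(k, if (stats::runif(1) < 0.3) 0.05
                                   else base, 0.05))))
    mg <- sample(0:2, 1)
    p <- mapping_params(window_size = 1e5, min_markers_per_window = 3,
                        merge_gap = mg,
                        min_interval_span = sample(c(5e4, 15e4), 1))
    w <- window_stats(t, p, c(I = n_win * 1e5))
    for (mode in c("recessive", "dominant")) {
      thr <- if (mode == "recessive") p$absence_threshold else
        p$reduction_threshold
      got <- suppressWarnings(call_intervals(w, mode, p, t))
      want <- oracle_call_intervals(w, t, thr, p$merge_gap,
                                    p$min_interval_span)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  }
})

test_that("lowering the absence threshold never enlarges an interval", {
  set.seed(111)
  for (case in 1:15) {
    t <- random_track(30, function(w, k)
      pmin(1, pmax(0, stats::rnorm(k, sample(c(0.04, 0.12, 0.5), 1), 0.04))))
    p_hi <- mapping_params(window_size = 1e5, min_markers_per_window = 3,
                           absence_threshold = 0.15,
                           min_interval_span = 5e4)
    p_lo <- mapping_params(window_size = 1e5, min_markers_per_window = 3,
                           absence_threshold = 0.08,
                           min_interval_span = 5e4)
    w <- window_stats(t, p_hi, c(I = 3e6))
    iv_hi <- suppressWarnings(call_intervals(w, "recessive", p_hi, t))
    iv_lo <- suppressWarnings(call_intervals(w, "recessive", p_lo, t))
    if (!nrow(iv_lo)) succeed()
    for (i in seq_len(nrow(iv_lo))) {
      inside <- iv_hi$start <= iv_lo$start[i] & iv_hi$end >= iv_lo$end[i]
      expect_true(any(inside))
    }
  }
})

test_that("known introgression gaps are subtracted by interval
           arithmetic", {
  p <- mapping_params()
  iv <- data.frame(chrom = c("I", "II", "IV"),
                   start = c(2e6, 5.4e6, 14e6),
                   end = c(10e6, 7.0e6, 17e6),
                   span = c(8e6, 1.6e6, 3e6),
                   mean_freq = 0.02, n_markers = 50L, mode = "recessive",
                   threshold = 0.1, unique = NA,
                   stringsAsFactors = FALSE)
  attr(iv, "params") <- p
  gaps <- data.frame(chrom = c("I", "IV"), start = c(1.5e6, 0),
                     end = c(12.8e6, 15.8e6))   # 0-based half-open
  out <- subtract_known_gaps(iv, gaps)
  i1 <- out[out$chrom == "I", ]
  expect_false(i1$unique)                     # fully inside the LG I gap
  i2 <- out[out$chrom == "II", ]
  expect_true(i2$unique)                      # no gap on LG II
  i4 <- out[out$chrom == "IV", ]
  expect_true(i4$unique)                      # trimmed to the residual
  expect_equal(i4$start, 15.8e6 + 1)
  expect_equal(i4$end, 17e6)
  expect_true(i4$trimmed)
  # residual below the minimum span is dropped entirely
  out2 <- subtract_known_gaps(iv[3, ], gaps, min_residual_span = 2e6)
  expect_equal(nrow(out2), 0L)
})

test_that("mapping outcomes are classified per the published logic", {
  one <- data.frame(chrom = "II", start = 5e6, end = 7e6, unique = TRUE)
  none <- one[0, ]
  two <- rbind(one, data.frame(chrom = "III", start = 1e6, end = 3e6,
                               unique = TRUE))
  hit <- data.frame(chrom = "IV", pos = 8e6, freq = 0.95,
                    effect = "missense")
  expect_equal(classify_outcome(one)$outcome, "extragenic_mapped")
  expect_equal(classify_outcome(none, hit)$outcome, "linked_to_target")
  expect_equal(classify_outcome(none)$outcome, "unmapped")
  expect_equal(classify_outcome(two)$outcome, "ambiguous")
  expect_equal(nrow(classify_outcome(two)$unique_intervals), 2L)
  # a qualifying unique interval takes precedence over target-gene hits
  expect_equal(classify_outcome(one, hit)$outcome, "extragenic_mapped")
})

test_that("gaps BED round-trips through the 0-based half-open
           convention", {
  gaps <- data.frame(chrom = c("I", "IV"), start = c(1.5e6, 1),
                     end = c(12.8e6, 15.8e6))
  path <- withr::local_tempfile(fileext = ".bed")
  write_gaps_bed(gaps, path)
  back <- read_gaps_bed(path)
  expect_equal(back$start, gaps$start - 1)
  expect_equal(back$end, gaps$end)
})
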