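test_that("fold coverage arithmetic", {
  expect_equal(fold_coverage(36e6, 50, 100e6), 18)
  expect_equal(fold_coverage(0, 50, 100e6), 0)
  expect_equal(fold_coverage(1e6, 100, 100e6), 1)
  expect_error(fold_coverage(1e6, 50, 0), "> 0")
})

test_that("seq params validate their bounds", {
  expect_error(seq_params(mean_depth = 0), "mean_depth")
  expect_error(seq_params(base_error = 0.3), "base_error")
  expect_equal(seq_params()$mean_depth, 18)
})

test_that("read counts conserve depth and follow the binomial model", {
  set.seed(5)
  sites <- data.frame(chrom = "I", pos = 1:200 * 100L, ref = "A", alt = "G",
                      true_freq = 0.5, stringsAsFactors = FALSE)
  counts <- sample_site_counts(sites, seq_params(mean_depth = 1000,
                                                 base_error = 0,
                                                 depth_model = "fixed"))
  expect_true(all(counts$ref_count + counts$alt_count == 1000L))
  obs <- counts$alt_count / 1000
  expect_lt(abs(mean(obs) - 0.5), 0.01)

  # error-free fixed counts at frequency 1 are saturated
  s1 <- data.frame(chrom = "I", pos = 1e4L, ref = "A", alt = "G",
                   true_freq = 1)
  c1 <- sample_site_counts(s1, seq_params(base_error = 0,
                                          depth_model = "fixed"))
  expect_equal(c1$alt_count, 18L)
  expect_equal(c1$ref_count, 0L)

  expect_error(sample_site_counts(data.frame(chrom = "I", pos = 1L,
                                             ref = "A", alt = "G",
                                             true_freq = 1.2)),
               "\\[0, 1\\]")
})

test_that("observed frequency converges to truth at high depth without
           error", {
  set.seed(6)
  f <- rep(seq(0, 1, by = 0.1), each = 10)  # 10 replicate sites per level
  sites <- data.frame(chrom = "I", pos = seq_along(f) * 1000L, ref = "A",
                      alt = "G", true_freq = f)
  counts <- sample_site_counts(sites, seq_params(mean_depth = 10000,
                                                 base_error = 0,
                                                 depth_model = "fixed"))
  obs <- counts$alt_count / (counts$ref_count + counts$alt_count)
  per_level <- tapply(obs - f, f, mean)  # binomial sd 5e-4 at n = 1e5
  expect_true(all(abs(per_level) <= 0.01))
})

test_that("zero-depth sites survive the VCF round trip with undefined
           frequency", {
  sites <- data.frame(chrom = c("I", "I", "II"),
                      pos = c(100L, 200L, 50L),
                      ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                      ref_count = c(9L, 0L, 3L),
                      alt_count = c(9L, 0L, 15L),
                      is_marker = c(TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  emit_pool_vcf(sites, path, sample_name = "poolX",
                contigs = c(I = 1000, II = 1000))
  back <- read_pool_vcf(path)
  expect_equal(back, sites, ignore_attr = TRUE)
  expect_equal(attr(back, "sample"), "poolX")
  sf <- supmapr:::site_freq(back)
  expect_equal(sf, c(0.5, NA, 15 / 18))
})

test_that("unsorted or duplicated records are rejected by the writer", {
  bad <- data.frame(chrom = c("I", "I"), pos = c(200L, 100L),
                    ref = "A", alt = "G", ref_count = 1L, alt_count = 1L,
                    is_marker = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  expect_error(emit_pool_vcf(bad, path, contigs = c(I = 1000)), "sorted")
  dup <- data.frame(chrom = "I", pos = c(100L, 100L), ref = "A",
                    alt = c("G", "G"), ref_count = 1L, alt_count = 1L,
                    is_marker = FALSE)
  expect_error(emit_pool_vcf(dup, path, contigs = c(I = 1000)), "duplicate")
})

test_that("pool site tables merge markers and segregating variants in
           sorted order", {
  map <- simple_map(c(2e5, 8e5))
  vt <- one_variant_table()
  f1 <- make_f1(map, vt, 1L)
  pool <- population_pool(list(f1), "F1", map, vt, 1L)
  sites <- pool_site_table(pool)
  expect_equal(sites$pos, c(2e5, 5e5, 8e5))
  expect_equal(sites$is_marker, c(TRUE, FALSE, TRUE))
  expect_equal(sites$true_freq, c(0.5, 0.5, 0.5))
})
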