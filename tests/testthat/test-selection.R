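make_counted_pool <- function(map, vt, n_ss, n_het, n_wt, generation = "F2") {
  inds <- c(f2_with_dose(map, vt, 1L, 2, n_ss),
            f2_with_dose(map, vt, 1L, 1, n_het),
            f2_with_dose(map, vt, 1L, 0, n_wt))
  population_pool(inds, generation, map, vt, 1L)
}

test_that("selection model construction enforces its invariants", {
  m <- selection_model("recessive")
  expect_equal(unname(m$viability), c(1, 0, 0))
  expect_error(selection_model("recessive",
                               viability = c("sup/+" = 0.5)),
               "recessive")
  expect_error(selection_model("dominant", viability = c("sup/sup" = 1.2)),
               "\\[0, 1\\]")
  expect_error(selection_model("dominant", brood = c("+/+" = -1)), ">= 0")
})

test_that("viability maps act deterministically on genotype classes", {
  map <- simple_map(5e5)
  vt <- one_variant_table()
  pool <- make_counted_pool(map, vt, 25, 50, 25)
  rec <- apply_selection(pool, selection_model("recessive"))
  geno <- vapply(rec$individuals, sup_genotype, "", variants = vt,
                 causal_id = 1L)
  expect_equal(unname(table(factor(geno, c("sup/sup", "sup/+", "+/+")))),
               c(25L, 0L, 0L), ignore_attr = TRUE)
  semi <- apply_selection(pool, selection_model("semidominant"))
  geno <- vapply(semi$individuals, sup_genotype, "", variants = vt,
                 causal_id = 1L)
  expect_equal(sum(geno == "sup/sup"), 25L)
  expect_equal(sum(geno == "sup/+"), 50L)
  expect_equal(sum(geno == "+/+"), 0L)
  perm <- apply_selection(pool, selection_model("recessive"),
                          temperature = "permissive")
  expect_equal(pool_size(perm), 100L)
})

test_that("an all-inviable population returns a flagged empty pool", {
  map <- simple_map(5e5)
  vt <- one_variant_table()
  pool <- make_counted_pool(map, vt, 0, 0, 30)
  expect_warning(out <- apply_selection(pool, selection_model("recessive")),
                 "extinct")
  expect_equal(pool_size(out), 0L)
  expect_true(isTRUE(attr(out, "extinct")))
})

test_that("recessive propagation fixes the causal allele", {
  map <- simple_map(c(2e5, 8e5))
  vt <- one_variant_table()
  f1 <- make_f1(map, vt, 1L)
  set.seed(21)
  f2 <- self_cross(f1, 80, map, vt)
  pool <- apply_selection(f2, selection_model("recessive"), map, vt, 1L)
  final <- propagate_pool(pool, 2, selection_model("recessive"))
  expect_equal(final$generation, "F4")
  expect_equal(pool_variant_freqs(final)$true_freq[1L], 1.0)
})

test_that("semidominant propagation with equal broods matches the exact
           genotype-frequency recursion", {
  # oracle: F2-selected (1/3, 2/3, 0); allele frequency 2/3 at F2 and
  # 23/27 after two more generations
  model <- selection_model("semidominant", brood = c("sup/+" = 1))
  p2 <- oracle_selfing_recursion(c(0.25, 0.5, 0.25) * c(1, 1, 0),
                                 model$viability, model$brood, 0)
  expect_equal(oracle_allele_freq(p2), 2 / 3)
  p4 <- oracle_selfing_recursion(p2, model$viability, model$brood, 2)
  expect_equal(oracle_allele_freq(p4), 23 / 27)

  map <- simple_map(c(2e5, 8e5))
  vt <- one_variant_table()
  set.seed(31)
  freqs <- vapply(1:3, function(i) {
    f1 <- make_f1(map, vt, 1L)
    f2 <- self_cross(f1, 250, map, vt)
    pool <- apply_selection(f2, model, map, vt, 1L)
    final <- propagate_pool(pool, 2, model)
    pool_variant_freqs(final)$true_freq[1L]
  }, 0)
  expect_lt(abs(mean(freqs) - 23 / 27), 0.05)
})

test_that("causal-allele frequency is non-decreasing across generations in
           expectation", {
  map <- simple_map(c(2e5, 8e5))
  vt <- one_variant_table()
  model <- selection_model("semidominant", brood = c("sup/+" = 1))
  set.seed(41)
  steps <- t(vapply(1:8, function(i) {
    f1 <- make_f1(map, vt, 1L)
    f2 <- self_cross(f1, 120, map, vt)
    pool <- apply_selection(f2, model, map, vt, 1L)
    f3 <- propagate_pool(pool, 1, model)
    f4 <- propagate_pool(f3, 1, model)
    c(pool_variant_freqs(pool)$true_freq[1L],
      pool_variant_freqs(f3)$true_freq[1L],
      pool_variant_freqs(f4)$true_freq[1L])
  }, numeric(3)))
  means <- colMeans(steps)
  expect_true(all(diff(means) > -0.02))
})

test_that("backcrossing halves unlinked passenger retention per round and
           preserves forced-A regions", {
  # causal on I; 300 unlinked passengers spread over six other
  # chromosomes (within-chromosome retention is correlated through shared
  # crossovers, so independence comes from the chromosome count)
  set.seed(51)
  lens <- c(I = 1e6, II = 1e6, III = 1e6, IV = 1e6, V = 1e6, VI = 1e6,
            VII = 1e6)
  map <- build_marker_map(lens, density = 10, seed = 52)
  pass_chrom <- rep(names(lens)[-1], each = 50)
  pass_pos <- unlist(lapply(names(lens)[-1], function(ch)
    sort(sample(setdiff(1:1e6, map$markers$pos), 50))))
  vt <- variant_table(c("I", pass_chrom), c(5e5, pass_pos),
                      rep("G", 301), rep("A", 301),
                      role = c("causal", rep("passenger", 300)))
  recurrent <- strain_individual(map, 0L)
  line0 <- strain_individual(map, 0L)
  for (id in 1:301) line0 <- carry_variant(line0, vt, id, 1L)

  expect_identical(backcross_series(line0, recurrent, 0, map, vt), line0)

  retained <- vapply(1:60, function(i) {
    bc <- backcross_series(line0, recurrent, 4, map, vt, keep_id = 1L)
    n_kept <- sum(vapply(names(lens)[-1], function(ch)
      length(bc$haps[[ch]][[1]]$var), 0L))
    n_kept / 300
  }, 0)
  expect_lt(abs(mean(retained) - 1 / 16), 0.02)

  # introgression direction: A-strain line into B-strain recurrent parent,
  # with a forced gap that must stay A-type
  gap <- data.frame(chrom = "I", start = 2e5, end = 6e5)
  hw <- strain_individual(map, 1L)
  intro <- backcross_series(line0, hw, 5, map, vt, keep_id = 1L,
                            force_a_regions = gap, homozygose = TRUE)
  mpos <- map$by_chrom$I$pos
  inside <- mpos >= 2e5 & mpos <= 6e5
  expect_true(all(intro$haps$I[[1]]$origin[inside] == 0L))
  expect_true(all(intro$haps$I[[2]]$origin[inside] == 0L))
  expect_equal(variant_dose(intro, vt, 1L), 2L)
})

test_that("preselection keeps suppressor homozygotes and drops
           non-carriers", {
  map <- simple_map(c(2e5, 8e5))
  vt <- one_variant_table()
  model <- selection_model("semidominant", viability = c("sup/+" = 0.5))
  ss <- f2_with_dose(map, vt, 1L, 2, 1)[[1]]
  wt <- f2_with_dose(map, vt, 1L, 0, 1)[[1]]
  set.seed(61)
  kept <- preselect_homozygotes(list(ss, wt), model, 0.6, 50, map, vt, 1L)
  expect_length(kept, 1L)
  expect_equal(sup_genotype(kept[[1]], vt, 1L), "sup/sup")
  expect_error(preselect_homozygotes(list(ss), model, 0.6, 0, map, vt, 1L),
               ">= 1")
})

test_that("preselection of an unselected F2 population enriches the
           homozygous quarter", {
  # 120 F2s at exact 1:2:1 (30:60:30); het offspring survival 0.5 makes a
  # het brood average 0.25*1 + 0.5*0.5 = 0.5 < 0.6, so mostly the 30
  # homozygotes pass the >60% brood-survival screen (hets leak through
  # with P[Bin(60, .5) > 36] ~ 0.03)
  map <- simple_map(c(2e5, 8e5))
  vt <- one_variant_table()
  model <- selection_model("semidominant", viability = c("sup/+" = 0.5))
  f2s <- c(f2_with_dose(map, vt, 1L, 2, 30),
           f2_with_dose(map, vt, 1L, 1, 60),
           f2_with_dose(map, vt, 1L, 0, 30))
  set.seed(71)
  n_kept <- vapply(1:10, function(i) {
    kept <- preselect_homozygotes(f2s, model, 0.6, 60, map, vt, 1L)
    length(kept)
  }, 0L)
  expect_lt(abs(mean(n_kept) - 30), 6)
})
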