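vdf <- function(chrom, pos, ref = "G", alt = "A", freq = 1,
                effect = "missense")
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             freq = freq, effect = effect, stringsAsFactors = FALSE)

test_that("parental subtraction removes exactly the parental keys", {
  pool <- vdf(c("I", "I", "II"), c(100, 200, 300))
  parental <- vdf("I", 100)
  out <- subtract_parental(pool, parental)
  expect_equal(out$pos, c(200L, 300L))
  expect_equal(subtract_parental(pool, pool[0, ]), pool)
  # same position, different alt survives
  par2 <- vdf("I", 200, alt = "T")
  expect_equal(nrow(subtract_parental(pool, par2)), 3L)
})

test_that("background removal counts strains including the focal pool", {
  focal <- vdf(c("I", "I", "I"), c(100, 200, 300))
  other1 <- vdf("I", 100)
  other5 <- replicate(5, vdf("I", 300), simplify = FALSE)
  out <- remove_background(focal, list(other1), min_strains = 2)
  expect_equal(out$pos, c(200L, 300L))          # shared by 2 -> removed
  out2 <- remove_background(focal, other5[1], min_strains = 3)
  expect_equal(nrow(out2), 3L)                  # focal + 1 of 5 < 3 -> kept
  expect_warning(out3 <- remove_background(focal, list()), "skipped")
  expect_equal(out3, focal)
})

test_that("parental subtraction and background removal commute", {
  set.seed(121)
  for (i in 1:10) {
    pool <- vdf("I", sample(1e4, 30))
    parental <- vdf("I", sample(1e4, 20))
    others <- list(vdf("I", sample(1e4, 20)), vdf("I", sample(1e4, 20)))
    a <- suppressWarnings(
      remove_background(subtract_parental(pool, parental), others, 2))
    b <- suppressWarnings(
      subtract_parental(remove_background(pool, others, 2), parental))
    expect_equal(a[order(a$pos), ], b[order(b$pos), ], ignore_attr = TRUE)
  }
})

test_that("effect classification handles the canonical codon cases", {
  # hand-built plus-strand gene: two exons, CDS split 6 + 9,
  # codons ATG GAA | TGC GCT TAA with a 60 bp intron between
  cds <- "ATGGAATGCGCTTAA"
  exon1 <- substr(cds, 1, 6); exon2 <- substr(cds, 7, 15)
  intron <- paste(rep("C", 60), collapse = "")
  intron <- paste0("GT", substr(intron, 3, 58), "AG")
  seq_a <- paste0(strrep("T", 100), exon1, intron, exon2, strrep("T", 100))
  genome <- Biostrings::DNAStringSet(c(A = seq_a))
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "A", strand = "+", start = 101L,
               end = 101L + 6L + 60L + 9L - 1L, role = "target"),
    data.frame(gene_id = "g1", rank = 1:2,
               start = c(101L, 167L), end = c(106L, 175L)))
  # codon 2 GAA -> TAA (G at cds position 4 = genomic 104)
  expect_equal(classify_effect("A", 104L, "G", "T", gm, genome), "nonsense")
  # codon 4 GCT -> GTT missense (cds 11 = genomic 171)
  expect_equal(classify_effect("A", 171L, "C", "T", gm, genome), "missense")
  # codon 4 GCT -> GCC synonymous (cds 12 = genomic 172)
  expect_equal(classify_effect("A", 172L, "T", "C", gm, genome),
               "synonymous")
  # intron donor +1 (genomic 107) and acceptor -1 (genomic 166)
  expect_equal(classify_effect("A", 107L, "G", "A", gm, genome),
               "splice_site")
  expect_equal(classify_effect("A", 166L, "G", "C", gm, genome),
               "splice_site")
  # intron interior and intergenic are noncoding
  expect_equal(classify_effect("A", 140L, "C", "A", gm, genome),
               "noncoding")
  expect_equal(classify_effect("A", 50L, "T", "C", gm, genome),
               "noncoding")
  # ref mismatch is a hard error naming the position
  expect_error(classify_effect("A", 104L, "C", "T", gm, genome),
               "A:104")
})

test_that("classifier equals the brute-force translation oracle on a
           two-gene toy genome", {
  gm <- toy_gene_genome()
  models <- gm$models
  genome <- gm$genome
  expect_setequal(models$genes$strand, c("+", "-"))  # both strands covered
  set.seed(131)
  for (g in seq_len(nrow(models$genes))) {
    gene <- models$genes[g, ]
    pos_pool <- seq(gene$start - 10L, gene$end + 10L)
    pos_sample <- sample(pos_pool, 150)
    for (pos in pos_sample) {
      ref <- genome_base(genome, gene$chrom, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- classify_effect(gene$chrom, pos, ref, alt, models, genome)
        want <- oracle_classify_effect(gene$chrom, pos, ref, alt, models,
                                       genome)
        if (got != want)
          fail(sprintf("mismatch at %s:%d %s>%s: %s vs %s",
                       gene$chrom, pos, ref, alt, got, want))
      }
    }
  }
  succeed()
})

test_that("frequency and effect filters follow the strict published
           thresholds", {
  iv <- data.frame(chrom = "II", start = 5e6, end = 8e6)
  pol <- filter_policy()
  v <- vdf(rep("II", 4), c(6e6, 6.5e6, 7e6, 7.5e6),
           freq = c(0.90, 0.80, 0.95, 0.85),
           effect = c("missense", "missense", "synonymous", "missense"))
  rec <- filter_candidates(v, iv, "recessive", pol)
  expect_equal(rec$pos, 6e6)            # 0.80 and exactly-0.85 excluded
  semi <- filter_candidates(v, iv, "semidominant", pol)
  expect_equal(semi$pos, c(6e6, 6.5e6, 7.5e6))  # synonymous still dropped
  # strictly inside the interval
  edge <- vdf("II", 5e6, freq = 0.99)
  expect_equal(nrow(filter_candidates(edge, iv, "recessive", pol)), 0L)
  # outside chromosome
  off <- vdf("III", 6e6, freq = 0.99)
  expect_equal(nrow(filter_candidates(off, iv, "recessive", pol)), 0L)
})

test_that("policy construction rejects inconsistent thresholds", {
  expect_error(filter_policy(recessive_min_freq = 0.5,
                             semidominant_min_freq = 0.6), "recessive")
})

test_that("intragenic detection reports qualifying target-gene variants
           only", {
  region <- list(chrom = "IV", start = 8e6, end = 8.01e6)
  v <- vdf(rep("IV", 3), c(8.002e6, 8.005e6, 8.2e6),
           freq = c(0.95, 0.95, 0.95),
           effect = c("missense", "synonymous", "missense"))
  hits <- detect_intragenic(v, region, "recessive")
  expect_equal(hits$pos, 8.002e6)
})

test_that("reports preserve outcome, tolerate empty candidate lists and
           compare against truth", {
  oc <- classify_outcome(data.frame(chrom = character(), unique = logical(),
                                    start = integer(), end = integer()))
  rep0 <- report_table(vdf("I", 1)[0, ], oc, list(mode = "recessive"))
  expect_equal(rep0$outcome, "unmapped")
  expect_equal(nrow(rep0$candidates), 0L)

  truth <- list(chrom = "II", pos = 6e6, alt = "A")
  cands <- vdf("II", c(6e6, 7e6))
  cands$gene_id <- c("sup-1", NA)
  oc2 <- classify_outcome(data.frame(chrom = "II", start = 5e6, end = 8e6,
                                     unique = TRUE))
  rep2 <- report_table(cands, oc2, list(), truth = truth)
  expect_true(rep2$truth_comparison$causal_in_candidates)
  expect_equal(rep2$truth_comparison$candidate_count, 2L)
})
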