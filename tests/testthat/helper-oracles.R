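# independent oracles, deliberately implemented along different routes
# than the code paths they check

# Exact genotype-frequency recursion for selfing under selection with
# per-parent brood compensation (each surviving parent contributes equal
# surviving offspring, weighted by its brood multiplier). States:
# (sup/sup, sup/+, +/+).
oracle_selfing_recursion <- function(p0, viability, brood, generations) {
  offspring <- list("sup/sup" = c(1, 0, 0),
                    "sup/+"   = c(0.25, 0.5, 0.25),
                    "+/+"     = c(0, 0, 1))
  p <- p0 / sum(p0)
  for (g in seq_len(generations)) {
    contrib <- matrix(0, 3, 3)
    w <- numeric(3)
    for (i in 1:3) {
      surv <- offspring[[i]] * viability          # surviving offspring mix
      if (sum(surv) == 0 || brood[i] == 0) next   # sterile lineage
      contrib[i, ] <- surv / sum(surv)            # compensated brood
      w[i] <- p[i] * brood[i]
    }
    if (sum(w) == 0) return(rep(NA_real_, 3))
    p <- colSums(contrib * (w / sum(w)))
  }
  p
}

oracle_allele_freq <- function(p) unname(p[1] + p[2] / 2)

# Exhaustive-scan interval oracle: qualifying windows linked whenever the
# index gap between consecutive qualifying windows is <= merge_gap + 1,
# closed under transitivity by fixed-point merging of index sets (a
# different mechanism than the caller's single linear scan).
oracle_call_intervals <- function(windows, track, threshold, merge_gap,
                                  min_span) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    qual <- which(wch$informative & !is.na(wch$mean_freq) &
                    wch$mean_freq <= threshold)
    if (!length(qual)) next
    groups <- as.list(qual)
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        if (merged) break
        for (j in seq_along(groups)) {
          if (i >= j) next
          a <- groups[[i]]; b <- groups[[j]]
          # linked if some qualifying window pair across the two groups
          # has no more than merge_gap windows strictly between them
          if (min(abs(outer(a, b, "-"))) <= merge_gap + 1) {
            groups[[i]] <- sort(c(a, b))
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    tch <- track[track$chrom == ch, , drop = FALSE]
    tch <- tch[order(tch$pos), , drop = FALSE]
    for (g in groups) {
      lo <- wch$start[min(g)]; hi <- wch$end[max(g)]
      sub <- tch$pos >= lo & tch$pos <= hi & tch$freq <= threshold
      if (!any(sub)) next
      # marker-level bound extension, recomputed by set logic: the bound
      # markers are the ends of the maximal all-sub-threshold index run
      # containing the in-span sub-threshold markers
      ok <- tch$freq <= threshold
      run <- cumsum(c(TRUE, diff(ok) != 0))
      members <- which(ok & run == run[which(sub)[1L]])
      s <- tch$pos[min(members)]; e <- tch$pos[max(members)]
      # the run containing the last in-span marker may differ
      members2 <- which(ok & run == run[rev(which(sub))[1L]])
      e <- max(e, tch$pos[max(members2)])
      s <- min(s, tch$pos[min(members2)])
      if (e - s < min_span) next
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Brute-force effect oracle: rebuild the mutant CDS from a patched genome
# copy, translate ref and alt proteins in full with Biostrings, and
# compare; splice sites from explicit intron enumeration.
oracle_classify_effect <- function(chrom, pos, ref, alt, models, genome) {
  g <- models$genes
  hit <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
  if (!length(hit)) return("noncoding")
  gene <- g[hit[1L], ]
  ex <- models$exons[models$exons$gene_id == gene$gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  exonic <- any(pos >= ex$start & pos <= ex$end)
  if (!exonic) {
    splice <- FALSE
    for (i in seq_len(nrow(ex) - 1L)) {
      d <- c(ex$end[i] + 1L, ex$end[i] + 2L)               # donor side
      a <- c(ex$start[i + 1L] - 2L, ex$start[i + 1L] - 1L)  # acceptor side
      if (pos %in% c(d, a)) splice <- TRUE
    }
    return(if (splice) "splice_site" else "noncoding")
  }
  mut <- genome
  mut[[chrom]] <- Biostrings::replaceAt(mut[[chrom]],
                                        IRanges::IRanges(pos, pos), alt)
  get_cds <- function(gen) {
    parts <- vapply(seq_len(nrow(ex)), function(i)
      as.character(Biostrings::subseq(gen[[chrom]], ex$start[i],
                                      ex$end[i])), "")
    s <- Biostrings::DNAString(paste(parts, collapse = ""))
    if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
    s
  }
  # no.init.codon: plain genetic code, no initiator special-casing (a
  # start-codon change is a coding change, not a silent one)
  p_ref <- as.character(Biostrings::translate(get_cds(genome),
                                              no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(get_cds(mut),
                                              no.init.codon = TRUE))
  if (p_ref == p_alt) return("synonymous")
  # first difference decides: stop gain is nonsense, else missense
  cmp <- cbind(strsplit(p_ref, "")[[1]], strsplit(p_alt, "")[[1]])
  diff <- which(cmp[, 1] != cmp[, 2])[1]
  if (cmp[diff, 2] == "*") "nonsense" else "missense"
}
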