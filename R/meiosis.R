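#' Generate one gamete by meiosis
#'
#' Per chromosome the default model performs exactly one obligate crossover
#' at a position uniform on (0, length) between the two parental
#' haplotypes, then returns one of the two reciprocal products at random.
#' This matches the near-complete crossover interference of holocentric
#' nematode chromosomes (~50 cM each). A `"poisson"` model (Poisson(1)
#' crossover count, positions uniform) is available as an alternative.
#'
#' Every gamete allele at every marker equals one of the two parental
#' alleles at that marker (conservation), and carried variants segregate
#' with the haplotype segment they sit on.
#'
#' @param ind Parent `individual`.
#' @param map A `marker_map`.
#' @param variants Screen-wide variant table (for variant positions).
#' @param crossover `"obligate"` (default) or `"poisson"`.
#' @return A gamete: named per-chromosome list of `list(origin, var)`.
#' @export
meiosis <- function(ind, map, variants, crossover = "obligate") {
  out <- vector("list", length(ind$haps))
  names(out) <- names(ind$haps)
  for (ch in names(ind$haps)) {
    L <- map$chrom_lengths[[ch]]
    cx <- switch(crossover,
                 obligate = stats::runif(1L, 0, L),
                 poisson = sort(stats::runif(stats::rpois(1L, 1), 0, L)),
                 fail("unknown crossover model %s", crossover))
    h1 <- ind$haps[[ch]][[1L]]
    h2 <- ind$haps[[ch]][[2L]]
    start1 <- sample.int(2L, 1L) == 1L  # strand carried in segment 0
    pick1 <- function(pos)
      ((findInterval(pos, cx) %% 2L) == 0L) == start1
    mpos <- map$by_chrom[[ch]]$pos
    origin <- h2$origin
    if (length(mpos)) {
      p1 <- pick1(mpos)
      origin[p1] <- h1$origin[p1]
    }
    var <- c(h1$var[pick1(variants$pos[h1$var])],
             h2$var[!pick1(variants$pos[h2$var])])
    out[[ch]] <- list(origin = origin, var = sort(unique(var)))
  }
  out
}

#' Fuse two gametes into an individual
#'
#' @param g1,g2 Gametes from [meiosis()].
#' @param sex Sex of the offspring.
#' @return An `individual`.
#' @export
fuse_gametes <- function(g1, g2, sex = "hermaphrodite") {
  haps <- lapply(names(g1), function(ch) list(g1[[ch]], g2[[ch]]))
  names(haps) <- names(g1)
  new_individual(haps, sex)
}

# does a diploid carry B/B at `pos` and is the sperm parent heterozygous?
incompatibility_kills <- function(child, sperm_parent, map, locus) {
  child_o <- origin_at(child, map, locus$chrom, locus$pos)
  if (any(is.na(child_o)) || sum(child_o) != 2L) return(FALSE)
  parent_o <- origin_at(sperm_parent, map, locus$chrom, locus$pos)
  sum(parent_o) == 1L
}

#' Cross two parents
#'
#' Each offspring is formed from one independent gamete per parent. When an
#' incompatibility locus is supplied, offspring homozygous for the B
#' (polymorphic-strain) origin at that locus and sired by a heterozygous
#' sperm parent die (paternal-effect zygotic lethality, as at the
#' peel-1/zeel-1 locus), so fewer than `n_offspring` may be returned.
#'
#' @param hermaphrodite,male Parent `individual`s (the male provides sperm).
#' @param n_offspring Number of zygotes to form (>= 0).
#' @param map A `marker_map`.
#' @param variants Screen-wide variant table.
#' @param incompatibility `NULL`, or `list(chrom =, pos =)`.
#' @param crossover Crossover model, see [meiosis()].
#' @return List of surviving offspring `individual`s.
#' @export
cross <- function(hermaphrodite, male, n_offspring, map, variants,
                  incompatibility = NULL, crossover = "obligate") {
  if (!is.numeric(n_offspring) || n_offspring < 0)
    fail("`n_offspring` must be >= 0")
  out <- vector("list", n_offspring)
  kept <- 0L
  for (i in seq_len(n_offspring)) {
    child <- fuse_gametes(meiosis(hermaphrodite, map, variants, crossover),
                          meiosis(male, map, variants, crossover))
    if (!is.null(incompatibility) &&
        incompatibility_kills(child, male, map, incompatibility)) next
    kept <- kept + 1L
    out[[kept]] <- child
  }
  out[seq_len(kept)]
}

#' @rdname cross
#' @param individual Selfing parent (provides both gametes, including sperm).
#' @export
self_cross <- function(individual, n_offspring, map, variants,
                       incompatibility = NULL, crossover = "obligate") {
  cross(individual, individual, n_offspring, map, variants,
        incompatibility, crossover)
}
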