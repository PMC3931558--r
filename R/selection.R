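GENOTYPES <- c("sup/sup", "sup/+", "+/+")

#' Genotype-to-fitness rules for a suppressor screen
#'
#' Encodes how the suppressor genotype maps to survival of an animal's
#' lineage at the nonpermissive temperature, and to its relative brood
#' size. In the recessive mode only suppressor homozygotes propagate
#' (heterozygous survival is 0 by definition of recessivity here). In the
#' semi-dominant mode heterozygotes survive but, by default, contribute
#' smaller broods; in the dominant mode heterozygotes are fully fit.
#' At the permissive temperature everything survives (see
#' [apply_selection()]).
#'
#' @param mode `"recessive"`, `"semidominant"` or `"dominant"`.
#' @param viability Optional named survival-probability override,
#'   `c("sup/sup" = , "sup/+" = , "+/+" = )`, each in `[0, 1]`.
#' @param brood Optional named relative brood-size override (>= 0).
#' @param incompatibility_enabled Enable the paternal-effect
#'   incompatibility locus in crosses driven by this model.
#' @return A `selection_model` object.
#' @export
selection_model <- function(mode = c("recessive", "semidominant", "dominant"),
                            viability = NULL, brood = NULL,
                            incompatibility_enabled = FALSE) {
  mode <- match.arg(mode)
  viab <- switch(mode,
                 recessive    = c(1, 0, 0),
                 semidominant = c(1, 1, 0),
                 dominant     = c(1, 1, 0))
  names(viab) <- GENOTYPES
  br <- switch(mode,
               recessive    = c(1, 1, 1),
               semidominant = c(1, 0.5, 1),
               dominant     = c(1, 1, 1))
  names(br) <- GENOTYPES
  if (!is.null(viability)) viab[names(viability)] <- viability
  if (!is.null(brood)) br[names(brood)] <- brood
  if (any(viab < 0 | viab > 1)) fail("survival probabilities must be in [0, 1]")
  if (any(br < 0)) fail("brood multipliers must be >= 0")
  if (mode == "recessive" && viab[["sup/+"]] != 0)
    fail("recessive mode requires sup/+ survival 0")
  check_flag(incompatibility_enabled, "incompatibility_enabled")
  structure(list(mode = mode, viability = viab, brood = br,
                 incompatibility_enabled = incompatibility_enabled),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> mode=%s\n", x$mode))
  cat("  survival:", paste(sprintf("%s=%g", GENOTYPES, x$viability),
                           collapse = "  "), "\n")
  cat("  brood:   ", paste(sprintf("%s=%g", GENOTYPES, x$brood),
                           collapse = "  "), "\n")
  invisible(x)
}

#' A truth-annotated population pool
#'
#' Container for a set of individuals plus the bookkeeping needed to
#' compute true per-site allele frequencies (frequency = carrying
#' haplotypes / 2N).
#'
#' @param individuals List of `individual`s.
#' @param generation Generation label, e.g. `"F2"`.
#' @param map The `marker_map`.
#' @param variants Screen-wide variant table.
#' @param causal_id Causal variant row id (or `NA`).
#' @return A `population_pool`.
#' @export
population_pool <- function(individuals, generation, map, variants,
                            causal_id = NA_integer_) {
  structure(list(individuals = individuals, generation = generation,
                 map = map, variants = variants, causal_id = causal_id),
            class = "population_pool")
}

#' @export
print.population_pool <- function(x, ...) {
  cat(sprintf("<population_pool> %s, %d individuals\n",
              x$generation, length(x$individuals)))
  invisible(x)
}

#' Number of individuals in a pool
#' @param pool A `population_pool`.
#' @return Integer count.
#' @export
pool_size <- function(pool) length(pool$individuals)

#' True per-marker B-allele frequencies of a pool
#'
#' @param pool A `population_pool`.
#' @return Data frame `chrom`, `pos`, `true_freq` over all markers.
#' @export
pool_marker_freqs <- function(pool) {
  map <- pool$map
  n2 <- 2L * pool_size(pool)
  rows <- lapply(names(map$chrom_lengths), function(ch) {
    nm <- n_markers(map, ch)
    if (nm == 0L) return(NULL)
    acc <- numeric(nm)
    for (ind in pool$individuals)
      acc <- acc + ind$haps[[ch]][[1L]]$origin + ind$haps[[ch]][[2L]]$origin
    data.frame(chrom = ch, pos = map$by_chrom[[ch]]$pos,
               true_freq = if (n2 > 0) acc / n2 else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), true_freq = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' True variant allele frequencies of a pool
#'
#' @param pool A `population_pool`.
#' @return The variant table with a `true_freq` column appended.
#' @export
pool_variant_freqs <- function(pool) {
  variants <- pool$variants
  n2 <- 2L * pool_size(pool)
  counts <- integer(nrow(variants))
  all_ids <- unlist(lapply(pool$individuals, function(ind)
    unlist(lapply(ind$haps, function(h) c(h[[1L]]$var, h[[2L]]$var)))),
    use.names = FALSE)
  if (length(all_ids))
    counts <- tabulate(all_ids, nbins = nrow(variants))
  variants$true_freq <- if (n2 > 0) counts / n2 else NA_real_
  variants
}

#' Apply genotype-dependent viability selection to a set of individuals
#'
#' Each individual survives with the probability its suppressor genotype
#' maps to in the model; at the permissive temperature everything survives.
#' An empty survivor set is returned (with a warning and attribute
#' `extinct = TRUE`), modelling screens in which no survivors were
#' recovered after the mapping cross.
#'
#' @param individuals List of `individual`s or a `population_pool`.
#' @param model A `selection_model`.
#' @param map,variants,causal_id Bookkeeping (taken from the pool when a
#'   pool is supplied).
#' @param temperature `"nonpermissive"` (selective) or `"permissive"`.
#' @param generation Label for the returned pool.
#' @return A `population_pool` of survivors.
#' @export
apply_selection <- function(individuals, model, map = NULL, variants = NULL,
                            causal_id = NULL,
                            temperature = c("nonpermissive", "permissive"),
                            generation = "F2") {
  temperature <- match.arg(temperature)
  if (inherits(individuals, "population_pool")) {
    pool <- individuals
    map <- pool$map; variants <- pool$variants; causal_id <- pool$causal_id
    generation <- pool$generation
    individuals <- pool$individuals
  }
  if (!length(individuals)) fail("empty input population")
  keep <- vapply(individuals, function(ind) {
    if (temperature == "permissive") return(TRUE)
    p <- model$viability[[sup_genotype(ind, variants, causal_id)]]
    stats::runif(1L) < p
  }, TRUE)
  survivors <- individuals[keep]
  out <- population_pool(survivors, generation, map, variants, causal_id)
  if (!length(survivors)) {
    warning("no survivors after selection: pool is extinct", call. = FALSE)
    attr(out, "extinct") <- TRUE
  }
  out
}

# probability that a selfed offspring of `g` is viable, and the offspring
# genotype distribution (sup/sup, sup/+, +/+)
offspring_genotype_dist <- function(genotype) {
  switch(genotype,
         "sup/sup" = c(1, 0, 0),
         "sup/+"   = c(0.25, 0.5, 0.25),
         "+/+"     = c(0, 0, 1))
}

#' Propagate a selected pool by en-masse selfing
#'
#' Each generation the pool is replaced by `pool_size` viable selfed
#' offspring. A parent is drawn with probability proportional to its brood
#' multiplier (among parents able to produce any viable offspring), and a
#' viable offspring of that parent is then formed by rejection sampling:
#' offspring dying under the viability map (or the incompatibility rule)
#' are discarded and the same hermaphrodite is resampled. Dead embryos
#' therefore do not reduce a parent's representation — hermaphrodites lay
#' far more embryos than a food-limited plate propagates, so surviving
#' parents contribute equally up to their brood weight. Under this model
#' the heterozygote fraction of a semi-dominant pool shrinks by 2/3 each
#' generation (the closed-form recursion used as a test oracle).
#'
#' @param pool A `population_pool` (e.g. selected F2s).
#' @param generations Number of further selfing generations (>= 0).
#' @param model A `selection_model`.
#' @param n Pool size per generation; default keeps the current size.
#' @param incompatibility Optional `list(chrom =, pos =)` locus (applied
#'   only when the model enables it).
#' @param crossover Crossover model, see [meiosis()].
#' @param max_tries Rejection-sampling cap per slot.
#' @return The final `population_pool` (empty, flagged `extinct`, if the
#'   population dies out).
#' @export
propagate_pool <- function(pool, generations, model, n = NULL,
                           incompatibility = NULL, crossover = "obligate",
                           max_tries = 1000L) {
  if (!is.numeric(generations) || generations < 0)
    fail("`generations` must be >= 0")
  n <- n %||% pool_size(pool)
  map <- pool$map; variants <- pool$variants; causal_id <- pool$causal_id
  gen_num <- suppressWarnings(as.integer(sub("^F", "", pool$generation)))
  incomp <- if (model$incompatibility_enabled) incompatibility else NULL
  current <- pool$individuals
  for (g in seq_len(generations)) {
    if (!length(current)) break
    geno <- vapply(current, sup_genotype, "", variants = variants,
                   causal_id = causal_id)
    viable_prob <- vapply(geno, function(gt)
      sum(offspring_genotype_dist(gt) * model$viability), 0)
    w <- model$brood[geno] * (viable_prob > 0)
    if (all(w == 0)) { current <- list(); break }
    nxt <- vector("list", n)
    for (slot in seq_len(n)) {
      repeat {
        p <- current[[sample.int(length(current), 1L, prob = w)]]
        child <- NULL
        for (try in seq_len(max_tries)) {
          cand <- fuse_gametes(meiosis(p, map, variants, crossover),
                               meiosis(p, map, variants, crossover))
          if (!is.null(incomp) &&
              incompatibility_kills(cand, p, map, incomp)) next
          surv <- model$viability[[sup_genotype(cand, variants, causal_id)]]
          if (stats::runif(1L) < surv) { child <- cand; break }
        }
        if (!is.null(child)) break
      }
      nxt[[slot]] <- child
    }
    current <- nxt
  }
  label <- if (is.na(gen_num)) pool$generation else
    sprintf("F%d", gen_num + generations)
  out <- population_pool(current, label, map, variants, causal_id)
  if (!length(current)) {
    warning("population went extinct during propagation", call. = FALSE)
    attr(out, "extinct") <- TRUE
  }
  out
}

#' Preselect F2 recombinants homozygous for the suppressor
#'
#' Emulates plating F2s singly and keeping those whose selfed brood shows
#' more than `survivor_threshold` survivors: each F2's brood of
#' `progeny_per_f2` selfed offspring is simulated and scored under the
#' model's viability map. For semi-dominant models whose heterozygous
#' broods fall below the threshold this enriches suppressor homozygotes,
#' the manoeuvre that sharpened the hardest-to-map suppressor's interval.
#'
#' @param f2_individuals List of F2 `individual`s.
#' @param model A `selection_model`.
#' @param survivor_threshold Keep F2s with survival fraction strictly above
#'   this (default 0.6).
#' @param progeny_per_f2 Brood size scored per F2 (>= 1).
#' @param map,variants,causal_id Bookkeeping.
#' @param crossover Crossover model.
#' @return The kept subset of `f2_individuals`.
#' @export
preselect_homozygotes <- function(f2_individuals, model,
                                  survivor_threshold = 0.6,
                                  progeny_per_f2 = 100L,
                                  map, variants, causal_id,
                                  crossover = "obligate") {
  if (!is.numeric(progeny_per_f2) || progeny_per_f2 < 1)
    fail("`progeny_per_f2` must be >= 1")
  check_number(survivor_threshold, "survivor_threshold", 1e-9, 1 - 1e-9)
  keep <- vapply(f2_individuals, function(f2) {
    brood <- self_cross(f2, progeny_per_f2, map, variants,
                        crossover = crossover)
    surv <- vapply(brood, function(ch) {
      p <- model$viability[[sup_genotype(ch, variants, causal_id)]]
      stats::runif(1L) < p
    }, TRUE)
    mean(surv) > survivor_threshold
  }, TRUE)
  f2_individuals[keep]
}

#' Backcross a line to a recurrent parent
#'
#' Each round one gamete is taken from the current line (conditioned to
#' carry `keep_id` when given, modelling selection for the suppressor or
#' target allele) and fused with a gamete from the recurrent parent.
#' Unlinked heterozygous passenger variants are transmitted with
#' probability 1/2 per round, so their expected retention halves each
#' round. Marker origins inside `force_a_regions` are reset to A-origin
#' after every round, reproducing the empirical introgression gaps of the
#' mapping strain (regions that resist introgression, e.g. around the
#' incompatibility locus and the target gene). With `homozygose = TRUE`
#' the final line is selfed until homozygous for `keep_id`.
#'
#' @param line Starting `individual`.
#' @param recurrent_parent Recurrent parent `individual`.
#' @param rounds Number of backcross rounds (>= 0).
#' @param map,variants Bookkeeping.
#' @param keep_id Variant row id whose transmission is enforced, or `NULL`.
#' @param force_a_regions Optional data frame `chrom`, `start`, `end`
#'   (1-based inclusive) kept A-origin.
#' @param homozygose Self the product until `keep_id` is homozygous.
#' @param crossover Crossover model.
#' @param max_tries Sampling cap.
#' @return The backcrossed `individual`.
#' @export
backcross_series <- function(line, recurrent_parent, rounds, map, variants,
                             keep_id = NULL, force_a_regions = NULL,
                             homozygose = FALSE, crossover = "obligate",
                             max_tries = 1000L) {
  if (!is.numeric(rounds) || rounds < 0) fail("`rounds` must be >= 0")
  force_a <- function(ind) {
    if (is.null(force_a_regions)) return(ind)
    for (i in seq_len(nrow(force_a_regions))) {
      ch <- force_a_regions$chrom[i]
      if (!ch %in% names(map$by_chrom)) next
      mpos <- map$by_chrom[[ch]]$pos
      sel <- mpos >= force_a_regions$start[i] & mpos <= force_a_regions$end[i]
      for (h in 1:2) ind$haps[[ch]][[h]]$origin[sel] <- 0L
    }
    ind
  }
  gamete_with <- function(ind, id) {
    for (try in seq_len(max_tries)) {
      g <- meiosis(ind, map, variants, crossover)
      if (is.null(id)) return(g)
      ch <- variants$chrom[id]
      if (id %in% g[[ch]]$var) return(g)
    }
    fail("could not draw a gamete carrying the kept variant")
  }
  for (r in seq_len(rounds)) {
    line <- fuse_gametes(gamete_with(line, keep_id),
                         meiosis(recurrent_parent, map, variants, crossover))
    line <- force_a(line)
  }
  if (homozygose && !is.null(keep_id)) {
    for (try in seq_len(max_tries)) {
      cand <- fuse_gametes(gamete_with(line, keep_id),
                           gamete_with(line, keep_id))
      if (variant_dose(cand, variants, keep_id) == 2L) {
        line <- force_a(cand)
        break
      }
    }
    if (variant_dose(line, variants, keep_id) != 2L)
      fail("failed to homozygose the kept variant")
  }
  line
}
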