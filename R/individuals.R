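#' Construct a homozygous strain individual
#'
#' An individual is a diploid: per chromosome, two haplotypes, each holding
#' a per-marker origin indicator (0 = A/reference-strain origin, 1 =
#' B/polymorphic-strain origin) plus the set of point variants the
#' haplotype carries (row ids into a screen-wide variant table).
#'
#' @param map A `marker_map`.
#' @param origin 0 (A-strain) or 1 (B-strain) at every marker.
#' @param sex `"hermaphrodite"` or `"male"`.
#' @return An `individual` object.
#' @export
strain_individual <- function(map, origin = 0L, sex = "hermaphrodite") {
  origin <- as.integer(origin)
  if (!origin %in% c(0L, 1L)) fail("origin must be 0 or 1")
  haps <- lapply(names(map$chrom_lengths), function(ch) {
    n <- n_markers(map, ch)
    list(list(origin = rep(origin, n), var = integer()),
         list(origin = rep(origin, n), var = integer()))
  })
  names(haps) <- names(map$chrom_lengths)
  new_individual(haps, sex)
}

new_individual <- function(haps, sex = "hermaphrodite") {
  structure(list(haps = haps, sex = sex), class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  nv <- sum(vapply(x$haps, function(h)
    length(h[[1L]]$var) + length(h[[2L]]$var), 0L))
  cat(sprintf("<individual> %s, %d chromosomes, %d carried variants\n",
              x$sex, length(x$haps), nv))
  invisible(x)
}

#' Construct a variant table
#'
#' Builds the screen-wide table of point variants that individuals'
#' haplotypes reference by row id. Positions must not collide with marker
#' positions of the map in use.
#'
#' @param chrom,pos,ref,alt Vectors describing the variants.
#' @param role `"causal"`, `"passenger"`, `"parental_lethal"` or
#'   `"background"`.
#' @param effect_truth Truth effect class per variant.
#' @return A variant table data frame with an `id` column.
#' @export
variant_table <- function(chrom, pos, ref, alt, role = "causal",
                          effect_truth = "missense") {
  if (any(ref == alt)) fail("variant with alt equal to ref")
  add_variant_rows(empty_variant_table(), chrom, pos, ref, alt,
                   rep_len(role, length(pos)),
                   rep_len(effect_truth, length(pos)))
}

#' Add a variant to an individual's haplotype(s)
#'
#' @param ind An `individual`.
#' @param variants The variant table.
#' @param id Variant row id.
#' @param haplotypes `1`, `2` or `1:2`.
#' @return The modified individual.
#' @export
carry_variant <- function(ind, variants, id, haplotypes = 1L) {
  ch <- variants$chrom[id]
  for (h in haplotypes) {
    v <- ind$haps[[ch]][[h]]$var
    ind$haps[[ch]][[h]]$var <- sort(unique(c(v, id)))
  }
  ind
}

#' Number of haplotypes (0, 1 or 2) of an individual carrying a variant
#'
#' @inheritParams carry_variant
#' @return Integer dose.
#' @export
variant_dose <- function(ind, variants, id) {
  ch <- variants$chrom[id]
  sum(id %in% ind$haps[[ch]][[1L]]$var,
      id %in% ind$haps[[ch]][[2L]]$var)
}

#' Suppressor-locus genotype of an individual
#'
#' @param ind An `individual`.
#' @param variants The screen-wide variant table.
#' @param causal_id Row id of the causal suppressor variant.
#' @return One of `"sup/sup"`, `"sup/+"`, `"+/+"`.
#' @export
sup_genotype <- function(ind, variants, causal_id) {
  c("+/+", "sup/+", "sup/sup")[variant_dose(ind, variants, causal_id) + 1L]
}

# marker-origin pair of an individual at an arbitrary genomic position
# (origin of the nearest marker at or left of `pos`; first marker if none)
origin_at <- function(ind, map, chrom, pos) {
  mpos <- map$by_chrom[[chrom]]$pos
  if (!length(mpos)) return(c(NA_integer_, NA_integer_))
  i <- max(1L, findInterval(pos, mpos))
  c(ind$haps[[chrom]][[1L]]$origin[i], ind$haps[[chrom]][[2L]]$origin[i])
}

# empty variant table with the canonical columns
empty_variant_table <- function() {
  data.frame(id = integer(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), role = character(),
             effect_truth = character(), stringsAsFactors = FALSE)
}

add_variant_rows <- function(variants, chrom, pos, ref, alt, role,
                             effect_truth) {
  new <- data.frame(id = nrow(variants) + seq_along(pos), chrom = chrom,
                    pos = as.integer(pos), ref = ref, alt = alt, role = role,
                    effect_truth = effect_truth, stringsAsFactors = FALSE)
  rbind(variants, new)
}
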