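#' Build a strain-diagnostic marker map
#'
#' Places biallelic markers along each chromosome at a target density.
#' Markers stand in for the catalogue of SNPs distinguishing the reference
#' (N2-like, "A") strain from the polymorphic mapping (Hawaiian-like, "B")
#' strain; in a mapping cross the per-marker B-allele frequency of a selected
#' pool is the mapping signal.
#'
#' The number of markers per chromosome is `round(density * length / 1e6)`,
#' placed at uniform-random unique positions. Each marker carries two
#' distinct alleles, `allele_a` (reference strain) and `allele_b`
#' (polymorphic strain).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs. All lengths must be positive.
#' @param density Markers per megabase (default 20).
#' @param seed Optional integer seed. When `NULL` the current RNG state is
#'   used (so callers embedding this in a larger seeded simulation get
#'   reproducibility from their own seed).
#' @return A `marker_map` object: a list with `chrom_lengths`, a `markers`
#'   data frame (`chrom`, `pos`, `allele_a`, `allele_b`) sorted by position
#'   within chromosome, and a per-chromosome split `by_chrom`.
#' @examples
#' map <- build_marker_map(c(I = 1e6), density = 10, seed = 1)
#' nrow(map$markers)
#' @export
build_marker_map <- function(chrom_lengths, density = 20, seed = NULL) {
  if (length(chrom_lengths) == 0L || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths))))
    fail("`chrom_lengths` must be a non-empty named vector")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    fail("zero-length chromosome: all chromosome lengths must be positive")
  check_number(density, "density", lower = 1e-12)
  if (!is.null(seed)) set.seed(seed)

  rows <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n <- as.integer(round(density * L / 1e6))
    if (n == 0L) return(NULL)
    if (n > L) fail("density places more than one marker per base on %s", ch)
    pos <- sort(sample.int(L, n))
    a <- random_bases(n)
    b <- vapply(a, function(x) sample(other_bases(x), 1L), "",
                USE.NAMES = FALSE)
    data.frame(chrom = ch, pos = pos, allele_a = a, allele_b = b,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  markers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(),
               allele_a = character(), allele_b = character(),
               stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  new_marker_map(chrom_lengths, markers)
}

#' Construct a marker map from explicit markers
#'
#' Low-level constructor for hand-built maps (tests, custom scenarios);
#' [build_marker_map()] is the random generator.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param markers Data frame `chrom`, `pos`, `allele_a`, `allele_b`,
#'   sorted by position within chromosome.
#' @return A validated `marker_map`.
#' @export
marker_map <- function(chrom_lengths, markers) {
  new_marker_map(chrom_lengths, markers)
}

new_marker_map <- function(chrom_lengths, markers) {
  map <- structure(
    list(chrom_lengths = chrom_lengths,
         markers = markers,
         by_chrom = split(markers,
                          factor(markers$chrom,
                                 levels = names(chrom_lengths)))),
    class = "marker_map")
  validate_marker_map(map)
}

#' Validate marker map invariants
#'
#' Checks that positions are strictly increasing within each chromosome,
#' alleles differ at every marker, and no marker lies beyond its
#' chromosome's end.
#'
#' @param map A `marker_map`.
#' @return The map, invisibly, or an error.
#' @export
validate_marker_map <- function(map) {
  m <- map$markers
  if (!all(m$chrom %in% names(map$chrom_lengths)))
    fail("marker on unknown chromosome")
  for (ch in names(map$by_chrom)) {
    p <- map$by_chrom[[ch]]$pos
    if (length(p) > 1L && any(diff(p) <= 0))
      fail("marker positions not strictly increasing on %s", ch)
    if (length(p) && (p[1L] < 1L || p[length(p)] > map$chrom_lengths[[ch]]))
      fail("marker position outside chromosome %s", ch)
  }
  if (any(m$allele_a == m$allele_b))
    fail("marker with identical alleles")
  invisible(map)
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("<marker_map> %d chromosomes, %d markers\n",
              length(x$chrom_lengths), nrow(x$markers)))
  for (ch in names(x$chrom_lengths))
    cat(sprintf("  %-4s %8.2f Mb  %5d markers\n", ch,
                x$chrom_lengths[[ch]] / 1e6, nrow(x$by_chrom[[ch]])))
  invisible(x)
}

n_markers <- function(map, chrom = NULL) {
  if (is.null(chrom)) nrow(map$markers) else nrow(map$by_chrom[[chrom]])
}

#' Write / read a marker map as TSV
#'
#' The TSV has columns `chrom`, `pos`, `allele_a`, `allele_b`; chromosome
#' lengths are stored in `#length` header comment lines so the file
#' round-trips to an identical `marker_map`.
#'
#' @param map A `marker_map`.
#' @param path Output file path.
#' @return `path` (write) or a `marker_map` (read), invisibly for the writer.
#' @export
write_marker_tsv <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(map$chrom_lengths))
    writeLines(sprintf("#length\t%s\t%d", ch,
                       as.integer(map$chrom_lengths[[ch]])), con)
  utils::write.table(map$markers, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  lines <- readLines(path)
  lens <- lines[startsWith(lines, "#length")]
  if (!length(lens)) fail("marker TSV lacks #length header lines: %s", path)
  parts <- strsplit(lens, "\t", fixed = TRUE)
  chrom_lengths <- stats::setNames(
    vapply(parts, function(p) as.numeric(p[3L]), 0),
    vapply(parts, function(p) p[2L], ""))
  body <- lines[!startsWith(lines, "#")]
  markers <- utils::read.table(text = body, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  new_marker_map(chrom_lengths, markers)
}
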