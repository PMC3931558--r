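# internal helpers shared across modules

fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    fail("`%s` must be a single number", name)
  if (x < lower || x > upper)
    fail("`%s` must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    fail("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

# order a site-like data frame by (chromosome in the given order, position)
order_sites <- function(df, chrom_levels) {
  df[order(factor(df$chrom, levels = chrom_levels), df$pos), , drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

DNA4 <- c("A", "C", "G", "T")

random_bases <- function(n) sample(DNA4, n, replace = TRUE)

other_bases <- function(base) DNA4[DNA4 != base]

# key uniquely identifying a SNV (positions formatted as integers so
# numeric input never falls into scientific notation)
variant_key <- function(df)
  paste(df$chrom, format(df$pos, scientific = FALSE, trim = TRUE),
        df$alt, sep = ":")
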