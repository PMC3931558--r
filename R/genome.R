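#' Create an empty synthetic genome
#'
#' Chromosomes are held as `Biostrings::DNAStringSet` records filled with
#' `N`. Real sequence is patched in only where the simulation needs it
#' (gene bodies, marker sites, variant sites): a sparse synthetic
#' reference that keeps full-length chromosome coordinates at desk-scale
#' memory cost.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return A `DNAStringSet`, one record per chromosome.
#' @export
new_genome <- function(chrom_lengths) {
  if (any(chrom_lengths <= 0)) fail("chromosome lengths must be positive")
  seqs <- vapply(chrom_lengths, function(L) strrep("N", as.integer(L)), "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_lengths)))
}

# patch single bases (positions `pos`, bases `base`) into one chromosome
patch_genome_bases <- function(genome, chrom, pos, base) {
  if (!length(pos)) return(genome)
  o <- order(pos)
  genome[[chrom]] <- Biostrings::replaceAt(
    genome[[chrom]], IRanges::IRanges(pos[o], pos[o]), base[o])
  genome
}

# patch one contiguous segment [start, start+nchar(seq)-1]
patch_genome_segment <- function(genome, chrom, start, seq) {
  genome[[chrom]] <- Biostrings::replaceAt(
    genome[[chrom]],
    IRanges::IRanges(start, start + nchar(seq) - 1L), seq)
  genome
}

#' Look up reference bases
#'
#' @param genome A `DNAStringSet` genome.
#' @param chrom Chromosome name.
#' @param pos Positions (1-based).
#' @return Character vector of bases (`"N"` where unmaterialized).
#' @export
genome_base <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) fail("unknown chromosome %s", chrom)
  L <- length(genome[[chrom]])
  if (any(pos < 1L | pos > L)) fail("position outside chromosome %s", chrom)
  as.character(Biostrings::extractAt(genome[[chrom]],
                                     IRanges::IRanges(pos, pos)))
}

genome_segment <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  all_codons <- as.character(Biostrings::mkAllStrings(DNA4, 3L))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Build one gene: exon structure, CDS written into the genome on `strand`.
# All exons are coding (single transcript, CDS == exons).
random_gene_structure <- function(n_exons = NULL) {
  n_exons <- n_exons %||% sample(2:4, 1L)
  exon_lens <- sample(seq(120L, 480L, by = 3L), n_exons, replace = TRUE)
  intron_lens <- if (n_exons > 1L)
    sample(60:300, n_exons - 1L, replace = TRUE) else integer()
  list(exon_lens = exon_lens, intron_lens = intron_lens,
       span = sum(exon_lens) + sum(intron_lens))
}

build_gene <- function(gene_id, chrom, start, strand, struct, role) {
  k <- length(struct$exon_lens)
  exon_start <- integer(k); exon_end <- integer(k)
  at <- start
  for (i in seq_len(k)) {
    exon_start[i] <- at
    exon_end[i] <- at + struct$exon_lens[i] - 1L
    at <- exon_end[i] + 1L
    if (i < k) at <- at + struct$intron_lens[i]
  }
  cds <- random_cds(sum(struct$exon_lens) %/% 3L)
  # distribute CDS over exons in transcription order
  tx_lens <- if (strand == "+") struct$exon_lens else rev(struct$exon_lens)
  ends <- cumsum(tx_lens)
  chunks <- substring(cds, c(1L, utils::head(ends, -1L) + 1L), ends)
  exon_seq <- if (strand == "+") chunks else
    rev(vapply(chunks, revcomp, "", USE.NAMES = FALSE))
  # assemble the genomic region: exons interleaved with random introns
  pieces <- character(2L * k - 1L)
  pieces[seq(1L, by = 2L, length.out = k)] <- exon_seq
  if (k > 1L)
    pieces[seq(2L, by = 2L, length.out = k - 1L)] <-
      vapply(struct$intron_lens,
             function(n) paste(random_bases(n), collapse = ""), "")
  list(gene = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = start, end = at - 1L, role = role,
                         stringsAsFactors = FALSE),
       exons = data.frame(gene_id = gene_id, rank = seq_len(k),
                          start = exon_start, end = exon_end,
                          stringsAsFactors = FALSE),
       region_seq = paste(pieces, collapse = ""))
}

#' Generate toy gene models and write their sequence into the genome
#'
#' Creates one target gene (the locus carrying the original
#' temperature-sensitive lethal allele), one suppressor gene (where the
#' causal suppressor variant will be placed), and a configurable number of
#' decoy genes per chromosome at random non-overlapping positions. Every
#' gene has a single transcript whose exons are all coding; the CDS starts
#' with ATG, ends with a stop codon, and contains no internal stop.
#'
#' @param genome A genome from [new_genome()].
#' @param target `list(gene_id=, chrom=, pos=)` anchor for the target gene.
#' @param causal Same, for the suppressor gene; `NULL` when the suppressor
#'   is intragenic (the target gene hosts the causal variant).
#' @param n_decoys_per_chrom Decoy genes per chromosome (default 3).
#' @return `list(models =, genome =)` with the patched genome and a
#'   `gene_models` object (`genes` and `exons` data frames).
#' @export
make_gene_models <- function(genome, target, causal, n_decoys_per_chrom = 3) {
  genes <- list(); exons <- list()
  occupied <- lapply(names(genome), function(ch) cbind(start = integer(),
                                                       end = integer()))
  names(occupied) <- names(genome)
  place <- function(gene_id, chrom, anchor, role) {
    L <- length(genome[[chrom]])
    struct <- random_gene_structure()
    for (try in 1:200) {
      start <- if (!is.null(anchor)) as.integer(anchor) else
        sample.int(max(1L, L - struct$span - 1L), 1L)
      start <- max(1L, min(start, L - struct$span))
      end <- start + struct$span - 1L
      occ <- occupied[[chrom]]
      clash <- any(start <= occ[, "end"] & end >= occ[, "start"])
      if (!clash) {
        occupied[[chrom]] <<- rbind(occ, c(start, end))
        strand <- sample(c("+", "-"), 1L)
        g <- build_gene(gene_id, chrom, start, strand, struct, role)
        genes[[length(genes) + 1L]] <<- g$gene
        exons[[length(exons) + 1L]] <<- g$exons
        genome <<- patch_genome_segment(genome, chrom, start, g$region_seq)
        return(invisible(TRUE))
      }
      anchor <- NULL  # decoys retry elsewhere; anchored genes must fit
    }
    fail("could not place gene %s on %s", gene_id, chrom)
  }
  place(target$gene_id, target$chrom, target$pos, "target")
  if (!is.null(causal))
    place(causal$gene_id, causal$chrom, causal$pos, "causal")
  if (n_decoys_per_chrom > 0)
    for (ch in names(genome))
      for (i in seq_len(n_decoys_per_chrom))
        place(sprintf("dcy-%s-%d", ch, i), ch, NULL, "decoy")
  models <- new_gene_models(do.call(rbind, genes), do.call(rbind, exons))
  list(models = models, genome = genome)
}

#' Construct gene models from explicit tables
#'
#' Low-level constructor for hand-built toy genes (tests, worked
#' examples); [make_gene_models()] is the random generator.
#'
#' @param genes Data frame `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (and optionally `role`).
#' @param exons Data frame `gene_id`, `rank`, `start`, `end` (1-based
#'   inclusive; all exons coding).
#' @return A validated `gene_models` object.
#' @export
gene_models <- function(genes, exons) {
  if (is.null(genes$role)) genes$role <- "decoy"
  new_gene_models(genes, exons)
}

new_gene_models <- function(genes, exons) {
  rownames(genes) <- NULL; rownames(exons) <- NULL
  gm <- structure(list(genes = genes, exons = exons), class = "gene_models")
  validate_gene_models(gm)
}

#' Validate gene model invariants
#'
#' Exons must be non-overlapping and ordered within each gene, total CDS
#' length divisible by 3, and every exon inside its gene's span.
#'
#' @param models A `gene_models` object.
#' @return The models, invisibly, or an error.
#' @export
validate_gene_models <- function(models) {
  for (gid in models$genes$gene_id) {
    ex <- gene_exons(models, gid)
    if (any(diff(ex$start) <= 0) || any(ex$start > ex$end))
      fail("exons of %s not ordered", gid)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      fail("overlapping exons in %s", gid)
    if (sum(ex$end - ex$start + 1L) %% 3L != 0L)
      fail("CDS length of %s not divisible by 3", gid)
    g <- models$genes[models$genes$gene_id == gid, ]
    if (ex$start[1L] != g$start || ex$end[nrow(ex)] != g$end)
      fail("exons of %s do not span the gene", gid)
  }
  invisible(models)
}

gene_exons <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  ex[order(ex$start), , drop = FALSE]
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

# spliced CDS in mRNA orientation
gene_cds_seq <- function(models, gene_id, genome) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  ex <- gene_exons(models, gene_id)
  parts <- vapply(seq_len(nrow(ex)), function(i)
    genome_segment(genome, g$chrom, ex$start[i], ex$end[i]), "")
  s <- paste(parts, collapse = "")
  if (g$strand == "-") revcomp(s) else s
}

#' Write genome FASTA
#'
#' @param genome A `DNAStringSet` genome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read genome FASTA
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features (1-based inclusive,
#' single transcript per gene, CDS identical to exons, phase from
#' cumulative CDS length). The generator-side `role` is carried in a
#' `locus_role` attribute.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for `##sequence-region`.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(chrom_lengths))
    for (ch in names(chrom_lengths))
      writeLines(sprintf("##sequence-region %s 1 %d", ch,
                         as.integer(chrom_lengths[[ch]])), con)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    ex <- gene_exons(models, g$gene_id)
    mrna_id <- paste0(g$gene_id, ".t1")
    row <- function(type, start, end, phase, attrs)
      writeLines(paste(g$chrom, "supmapr", type, start, end, ".", g$strand,
                       phase, attrs, sep = "\t"), con)
    row("gene", g$start, g$end, ".",
        sprintf("ID=%s;locus_role=%s", g$gene_id, g$role))
    row("mRNA", g$start, g$end, ".",
        sprintf("ID=%s;Parent=%s", mrna_id, g$gene_id))
    # phase: bases to skip at the start of each CDS piece, 5' -> 3'
    widths <- ex$end - ex$start + 1L
    tx_w <- if (g$strand == "+") widths else rev(widths)
    phase_tx <- c(0L, (3L - cumsum(tx_w)[-length(tx_w)] %% 3L) %% 3L)
    phases <- if (g$strand == "+") phase_tx else rev(phase_tx)
    for (j in seq_len(nrow(ex))) {
      row("exon", ex$start[j], ex$end[j], ".",
          sprintf("ID=%s.e%d;Parent=%s", g$gene_id, j, mrna_id))
      row("CDS", ex$start[j], ex$end[j], phases[j],
          sprintf("ID=%s.c%d;Parent=%s", g$gene_id, j, mrna_id))
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses `rtracklayer::import` and reconstructs the single-transcript
#' `gene_models` container from `gene` and `exon` features.
#'
#' @param path GFF3 path.
#' @return A `gene_models` object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- as.character(gr$type) == "gene"
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    role = if (!is.null(gr$locus_role))
      as.character(gr$locus_role[is_gene]) else NA_character_,
    stringsAsFactors = FALSE)
  is_exon <- as.character(gr$type) == "exon"
  parent <- vapply(gr$Parent[is_exon], function(p) as.character(p)[1L], "")
  gene_of <- sub("\\.t1$", "", parent)
  exons <- data.frame(gene_id = gene_of,
                      start = GenomicRanges::start(gr)[is_exon],
                      end = GenomicRanges::end(gr)[is_exon],
                      stringsAsFactors = FALSE)
  exons <- exons[order(factor(exons$gene_id, levels = genes$gene_id),
                       exons$start), ]
  exons$rank <- stats::ave(exons$start, exons$gene_id,
                           FUN = seq_along)
  new_gene_models(genes, exons[, c("gene_id", "rank", "start", "end")])
}
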