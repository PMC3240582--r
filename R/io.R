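#' Write a synthetic world to standard flat files
#'
#' Emits `genome.fa` (FASTA), `genes.gff3` (gene/mRNA/exon features,
#' 1-based closed per GFF3), `transposons.bed` (BED6, 0-based half-open,
#' name = family), `expression.tsv`, and `truth_classes.tsv` into `dir`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    bed = file.path(dir, "transposons.bed"),
    expr = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth_classes.tsv"))
  Biostrings::writeXStringSet(world$genome, paths["fasta"])

  g <- world$genes
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  ex <- g %>%
    select("gene_id", "chrom", "strand", "exon_starts", "exon_ends") %>%
    tidyr::unnest(c("exon_starts", "exon_ends"))
  exon_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$exon_starts + 1L, ex$exon_ends),
    strand = ex$strand, type = "exon", Parent = ex$gene_id)
  rtracklayer::export(c(gene_gr, exon_gr), paths["gff3"], format = "gff3")

  tx <- world$transposons
  if (nrow(tx) > 0) {
    bed_gr <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end), strand = tx$strand,
      name = tx$family, score = 0L)
    rtracklayer::export(bed_gr, paths["bed"], format = "bed")
  }
  utils::write.table(world$expression, paths["expr"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$truth$classes, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write simulated reads as FASTQ
#'
#' Constant 'I' quality (Phred 40) per base.
#'
#' @param reads Named DNAStringSet.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read/write tag tables as TSV
#'
#' One row per mapped site: `read_id`, `chrom`, `pos` (0-based 5'
#' position), `strand`, `mismatches`, `k`.
#'
#' @param tags Tag tibble.
#' @param path TSV path.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a bin track as a WIG file
#'
#' Fixed-span wiggle output (span = bin width, 1-based starts) via
#' rtracklayer. All bins are emitted with the full span; the final bin of
#' a chromosome may overhang its end by up to bin - 1 bp.
#'
#' @param track A `bin_track`.
#' @param path Output WIG path.
#' @export
write_wig <- function(track, path) {
  bin <- track$bin
  df <- tidy(track)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$start + bin),
    score = df$score)
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Read a WIG file into a bin track
#'
#' @param path WIG path.
#' @param layout Named chromosome lengths (bp).
#' @param bin Bin width (default 50).
#' @param mark,mode,tag_total Track metadata to attach.
#' @export
read_wig <- function(path, layout, bin = 50L, mark = "mark", mode = "U+M",
                     tag_total = NA_integer_) {
  gr <- rtracklayer::import(path, format = "wig")
  nb <- ceiling(layout / bin)
  scores <- lapply(nb, numeric)
  df <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               score = gr$score)
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, ]
    scores[[chrom]][d$start %/% bin + 1L] <- d$score
  }
  new_bin_track(scores, bin, tag_total, mode, mark,
                depth_normalized = TRUE)
}

#' Write reported enrichment regions as BED
#'
#' @param x An `fdr_track` (or a regions tibble from [call_regions()]).
#' @param path Output BED path.
#' @export
write_bed_regions <- function(x, path) {
  regions <- if (inherits(x, "fdr_track")) call_regions(x) else x
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
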