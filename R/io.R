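#' Read transcript exon records from a GTF/GFF file
#'
#' Thin wrapper over `rtracklayer::import()` converting exon records to
#' the 0-based half-open table [build_gene_models()] accepts. A gene is
#' marked coding when the annotation carries any CDS record for it.
#'
#' @param path GTF or GFF3 file.
#' @return Exon record data.frame (`gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`, `coding`).
#' @export
read_gtf_exons <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  coding_genes <- unique(gr$gene_id[type == "CDS"])
  ex <- gr[type == "exon"]
  data.frame(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(ex)),
             start = GenomicRanges::start(ex) - 1L,
             end = GenomicRanges::end(ex),
             strand = as.character(GenomicRanges::strand(ex)),
             coding = ex$gene_id %in% coding_genes, row.names = NULL)
}

#' Write gene models as a GTF file
#'
#' One representative transcript per merged gene model, exon records
#' only, written deterministically (stable ordering) so repeated runs on
#' the same models produce identical files.
#'
#' @param gene_models List of `gene_model` objects.
#' @param path Output file.
#' @export
write_gtf <- function(gene_models, path) {
  ex <- gene_models_to_exons(gene_models)
  ex <- ex[order(ex$chrom, ex$start), , drop = FALSE]
  lines <- sprintf(
    paste0("%s\trnalifecycle\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s\";"),
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
    ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write features as BED6+
#'
#' @param features Feature data.frame from [enumerate_features()];
#'   features without genomic coordinates (SPL) are skipped.
#' @param path Output file.
#' @export
write_features_bed <- function(features, path) {
  f <- features[!is.na(features$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s:%s:%d\t0\t%s", f$chrom,
                   as.integer(f$start), as.integer(f$end), f$gene_id,
                   f$class, f$ordinal, f$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read an alignment table
#'
#' Reads the simple tab-delimited alignment format (`chrom`, `start`
#' 0-based, `length`, `strand`; no header), or a BAM file via Rsamtools
#' when `path` ends in `.bam` (uniquely mapped approximated by a mapping
#' quality threshold).
#'
#' @param path TSV or BAM file.
#' @param mapq Minimum mapping quality for BAM input.
#' @return Read data.frame as consumed by [assign_reads()].
#' @export
read_reads <- function(path, mapq = 10L) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package")
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "strand", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    keep <- !is.na(b$mapq) & b$mapq >= mapq
    return(data.frame(chrom = as.character(b$rname)[keep],
                      start = b$pos[keep] - 1L, length = b$qwidth[keep],
                      strand = as.character(b$strand)[keep]))
  }
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "length", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character"))
}

#' Write an alignment table
#'
#' @param reads Read data.frame (`chrom`, `start`, `length`, `strand`).
#' @param path Output file.
#' @export
write_reads <- function(reads, path) {
  utils::write.table(reads[, c("chrom", "start", "length", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
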