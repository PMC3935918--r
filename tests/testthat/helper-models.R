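# fixture builders used across the suite

# exon records for one plus-strand gene laid out from `offset` with the
# given exon/intron lengths (transcription order)
exon_records <- function(gene_id, exon_lengths, intron_lengths,
                         offset = 10000, chrom = "chr1", strand = "+") {
  stopifnot(length(exon_lengths) == length(intron_lengths) + 1L)
  w <- as.vector(rbind(exon_lengths, c(intron_lengths, NA)))
  w <- w[!is.na(w)]
  ends <- offset + cumsum(w)
  starts <- c(offset, ends[-length(ends)])
  keep <- seq(1, length(w), by = 2)
  data.frame(gene_id = gene_id, chrom = chrom, start = starts[keep],
             end = ends[keep], strand = strand)
}

# a cohort of n genes with identical geometry, spaced along chr1
uniform_cohort <- function(n, exon_lengths, intron_lengths,
                           spacing = 2e5) {
  ex <- do.call(rbind, lapply(seq_len(n), function(i)
    exon_records(sprintf("g%04d", i), exon_lengths, intron_lengths,
                 offset = 1e4 + (i - 1) * spacing)))
  build_gene_models(ex)
}

# parameter table with fixed times and given c0S values
fixed_params <- function(gene_models, c0S, T5 = 90, T3 = 45, Tgamma = 25,
                         Tmu = 7200, Talpha = 1 / 60) {
  ids <- vapply(gene_models, `[[`, character(1), "gene_id")
  out <- data.frame(gene_id = ids, c0S = rep_len(c0S, length(ids)),
                    T5 = T5, T3 = T3, Tgamma = Tgamma, Tmu = Tmu)
  attr(out, "Talpha") <- Talpha
  out
}
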