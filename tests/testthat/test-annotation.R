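test_that("isoform merging applies the exon-priority rule", {
  # isoform A: 3 exons; isoform B retains intron 1 -> that region is EXN
  ex <- rbind(
    data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
               start = c(100, 500, 900), end = c(200, 600, 1000)),
    data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
               start = 100, end = 600))
  g <- build_gene_models(ex)[["gA"]]
  expect_identical(g$n_introns, 1L)
  expect_equal(unname(g$exons[1, ]), c(100, 600))   # intron 1 absorbed
  expect_equal(unname(g$introns[1, ]), c(600, 900))

  # identity merge for a single-transcript 3-exon gene
  g2 <- build_gene_models(exon_records("gB", c(100, 100, 100),
                                       c(300, 400)))[["gB"]]
  expect_identical(g2$n_introns, 2L)
  expect_equal(g2$intron_lengths, c(300, 400))
  expect_equal(g2$tss, 10000)
})

test_that("minus-strand ordinals follow transcription direction", {
  ex <- exon_records("gM", c(100, 200, 300), c(1000, 2000), strand = "-")
  g <- build_gene_models(ex)[["gM"]]
  # exon ordinal 1 has the largest genomic coordinate
  expect_true(g$exons[1, "start"] > g$exons[3, "start"])
  expect_equal(g$exon_lengths, c(300, 200, 100))
  expect_equal(g$intron_lengths, c(2000, 1000))
  expect_equal(g$tss, max(ex$end))
})

test_that("malformed records are rejected and rebuild is idempotent", {
  ex <- exon_records("gC", c(100, 100), 5000)
  bad <- rbind(ex, data.frame(gene_id = "gC", chrom = "chr1",
                              start = 99, end = 50, strand = "+"))
  expect_warning(m1 <- build_gene_models(bad), "malformed")
  m2 <- build_gene_models(gene_models_to_exons(m1))
  expect_equal(m2[["gC"]][c("exons", "introns", "tss", "strand")],
               m1[["gC"]][c("exons", "introns", "tss", "strand")])

  expect_warning(
    expect_error(build_gene_models(data.frame(gene_id = "x", chrom = "c",
                                              start = 5, end = 5,
                                              strand = "+"))),
    "malformed")
})

test_that("feature enumeration has the right counts and geometry", {
  g <- build_gene_models(exon_records("gD", c(200, 300, 250, 150),
                                      c(6000, 4000, 12000)))
  fs <- enumerate_features(g, r = 35)
  f <- fs$features
  # all exon pairs: choose(N+1, 2) splice junctions
  expect_equal(sum(f$class == "SPL"), choose(4, 2))
  expect_equal(nrow(fs$splice_library), choose(4, 2))
  # every junction window has effective length r - 1
  expect_true(all(f$length[f$class %in% c("JXN5", "JXN3")] == 34))
  expect_identical(sum(f$class == "JXN5"), 3L)
  # 3' window: whole intron when < 10 kb, else 10 kb
  i3 <- f[f$class == "INT3", ]
  expect_equal(i3$length[i3$ordinal == 2], 4000)
  expect_equal(i3$length[i3$ordinal == 3], 10000)
  # EXN and INT tile the gene span without overlap
  span <- f[f$class %in% c("EXN", "INT"), ]
  span <- span[order(span$start), ]
  expect_equal(span$start[-1], span$end[-nrow(span)])
  expect_equal(min(span$start), unname(g[[1]]$exons[1, "start"]))
  expect_equal(sum(span$end - span$start),
               sum(g[[1]]$exon_lengths) + sum(g[[1]]$intron_lengths))
})

test_that("single-exon genes get no intron or junction features", {
  g <- build_gene_models(data.frame(gene_id = "gS", chrom = "chr1",
                                    start = 100, end = 2000,
                                    strand = "+"))
  fs <- enumerate_features(g, r = 35)
  expect_identical(unique(fs$features$class), "EXN")
  expect_null(fs$splice_library)
})

test_that("overlapping same-strand genes mask each other's introns", {
  # gene E's exon sits inside gene F's intron
  ex <- rbind(exon_records("gF", c(100, 100), 8000, offset = 0),
              data.frame(gene_id = "gE", chrom = "chr1", strand = "+",
                         start = 3000, end = 3500))
  fs <- enumerate_features(build_gene_models(ex), r = 35)
  int_f <- fs$features[fs$features$gene_id == "gF" &
                         fs$features$class == "INT", ]
  expect_identical(nrow(int_f), 2L)          # intron split into two blocks
  expect_true(all(int_f$ordinal == 1))
  expect_equal(sum(int_f$end - int_f$start), 8000 - 500)
  # opposite strands are independent
  ex2 <- rbind(exon_records("gF", c(100, 100), 8000, offset = 0),
               data.frame(gene_id = "gE", chrom = "chr1", strand = "-",
                          start = 3000, end = 3500))
  fs2 <- enumerate_features(build_gene_models(ex2), r = 35)
  int_f2 <- fs2$features[fs2$features$gene_id == "gF" &
                           fs2$features$class == "INT", ]
  expect_identical(nrow(int_f2), 1L)
})

test_that("intron bins are equal-length, ordered 5' to 3'", {
  g <- build_gene_models(exon_records("gG", c(100, 100), 5000,
                                      strand = "-"))
  fs <- enumerate_features(g, r = 35, n_bins = 100)
  b <- fs$features[fs$features$class == "INTBIN", ]
  expect_identical(nrow(b), 100L)
  expect_equal(sum(b$end - b$start), 5000)
  expect_equal(unique(b$end - b$start), 50)
  # minus strand: bin 1 (5' end) is at the highest genomic coordinate
  expect_true(b$start[b$ordinal2 == 1] > b$start[b$ordinal2 == 100])
})

test_that("mappability is computed by exact k-mer uniqueness", {
  r <- 10L
  set.seed(21)
  # unique random sequence: everything mappable
  alphabet <- c("A", "C", "G", "T")
  uniq <- paste(sample(alphabet, 3000, replace = TRUE), collapse = "")
  g <- build_gene_models(exon_records("gH", c(200, 200), 1000,
                                      offset = 100, chrom = "chrU"))
  fs <- enumerate_features(g, r = r)
  genome <- Biostrings::DNAStringSet(c(chrU = uniq))
  mp <- compute_mappability(fs$features, genome, r = r)
  expect_true(all(mp$mappability[mp$class == "INT"] == 1))

  # duplicate a 100-bp block inside the intron (two copies in the genome)
  s <- substring(uniq, 401, 500)
  dup <- paste0(substring(uniq, 1, 700), s, substring(uniq, 801, 3000))
  genome2 <- Biostrings::DNAStringSet(c(chrU = dup))
  mp2 <- compute_mappability(fs$features, genome2, r = r)
  int_frac <- mp2$mappability[mp2$class == "INT"]
  expect_lt(int_frac, 1)

  # brute-force oracle: scan every window over the intron independently
  seqs <- as.character(genome2)
  all_k <- unlist(lapply(c(seqs, as.character(
    Biostrings::reverseComplement(genome2))), function(x)
      substring(x, 1:(nchar(x) - r + 1), r:nchar(x))))
  tab <- table(all_k)
  intron <- g[[1]]$introns[1, ]
  base_ok <- logical(intron["end"] - intron["start"])
  for (p0 in seq(intron["start"] - r + 1, intron["end"] - 1)) {
    km <- substring(seqs, p0 + 1, p0 + r)
    if (nchar(km) == r && tab[km] == 1) {
      cov <- pmax(p0, intron["start"]):pmin(p0 + r - 1, intron["end"] - 1)
      base_ok[cov - intron["start"] + 1] <- TRUE
    }
  }
  expect_equal(int_frac, mean(base_ok))

  # no genome: default index of ones
  mp0 <- compute_mappability(fs$features, NULL, r = r)
  expect_true(all(mp0$mappability == 1))
  # missing chromosome falls back to 1 with a warning
  expect_warning(
    mpz <- compute_mappability(fs$features,
                               Biostrings::DNAStringSet(c(other = uniq)),
                               r = r),
    "no genome sequence")
  expect_true(all(mpz$mappability == 1))
})

test_that("a feature inside an exact long repeat is unmappable", {
  r <- 10L
  set.seed(22)
  alphabet <- c("A", "C", "G", "T")
  block <- paste(sample(alphabet, 400, replace = TRUE), collapse = "")
  pad <- function(n) paste(sample(alphabet, n, replace = TRUE),
                           collapse = "")
  # two exact copies of a 400-bp block; the feature sits inside copy 1
  genome <- Biostrings::DNAStringSet(c(chrR = paste0(
    pad(50), block, pad(300), block, pad(50))))
  g <- build_gene_models(data.frame(gene_id = "gR", chrom = "chrR",
                                    start = 100, end = 300, strand = "+"))
  fs <- enumerate_features(g, r = r)
  mp <- compute_mappability(fs$features, genome, r = r)
  expect_equal(mp$mappability[mp$class == "EXN"], 0)
})
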