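# a 3-exon gene used throughout: exons 1000 bp, introns 6000/4000 bp
.q_models <- function()
  build_gene_models(exon_records("gQ", c(1000, 1000, 1000), c(6000, 4000),
                                 offset = 0))

test_that("reads land in the features that contain them", {
  models <- .q_models()
  fs <- enumerate_features(models, r = 35)
  # exon1: 0-1000, intron1: 1000-7000, exon2: 7000-8000,
  # intron2: 8000-12000, exon3: 12000-13000
  reads <- data.frame(
    chrom = "chr1",
    start = c(9000,    # fully inside intron 2
              985,     # straddles the exon1/intron1 boundary
              500),    # fully inside exon 1
    length = 35, strand = "+")
  counts <- assign_reads(reads, fs$features, fs$splice_library)
  f <- counts$features
  rd <- function(cls, ord) sum(f$rdbp[f$class == cls & f$ordinal == ord])
  expect_equal(rd("INT", 2), 35)
  # boundary-crossing read: all 35 bases inside the JXN5 window
  expect_equal(rd("JXN5", 1), 35)
  expect_equal(rd("JXN3", 1), 0)
  # its bases split 15/20 between exon 1 and intron 1
  expect_equal(rd("EXN", 1), 35 + 15)
  expect_equal(rd("INT", 1), 20)
  expect_equal(counts$total_read_bases, 105)
  expect_equal(counts$intergenic_read_bases, 0)

  # conservation: EXN + INT bases account for every aligned base
  expect_equal(sum(f$rdbp[f$class %in% c("EXN", "INT")]), 105)

  # a read outside any gene goes to the intergenic bucket
  counts2 <- assign_reads(rbind(reads,
                                data.frame(chrom = "chr1", start = 50000,
                                           length = 35, strand = "+")),
                          fs$features, fs$splice_library)
  expect_equal(counts2$intergenic_read_bases, 35)
  # strand-specific: an antisense read counts nowhere
  counts3 <- assign_reads(data.frame(chrom = "chr1", start = 9000,
                                     length = 35, strand = "-"),
                          fs$features, fs$splice_library)
  expect_equal(sum(counts3$features$rdbp), 0)
})

test_that("splice-library reads feed SPL features", {
  models <- .q_models()
  fs <- enumerate_features(models, r = 35)
  reads <- data.frame(chrom = c("SPL|gQ|1|3", "SPL|gQ|1|2", "SPL|gQ|1|2"),
                      start = 0, length = 35, strand = "+")
  counts <- assign_reads(reads, fs$features, fs$splice_library)
  spl <- counts$splice
  expect_equal(spl$n_reads[spl$exon_a == 1 & spl$exon_b == 3], 1)
  expect_equal(spl$rdbp[spl$exon_a == 1 & spl$exon_b == 3], 35)
  expect_false(spl$consecutive[spl$exon_a == 1 & spl$exon_b == 3])
  expect_equal(spl$n_reads[spl$exon_a == 1 & spl$exon_b == 2], 2)
})

test_that("density normalization follows the 10M x 35 bp convention", {
  # 1000-bp feature holding 100 contained 35-bp reads
  models <- build_gene_models(exon_records("gN", c(1000, 50), 2000,
                                           offset = 0))
  fs <- enumerate_features(models, r = 35)
  f <- fs$features
  f$rdbp <- ifelse(f$class == "EXN" & f$ordinal == 1, 3500, 0)
  counts <- structure(list(features = f, splice = fs$splice_library,
                           total_read_bases = 1e7 * 35,
                           intergenic_read_bases = 0),
                      class = "feature_counts")
  dens <- normalize_densities(counts)
  d1 <- dens$features$density[dens$features$class == "EXN" &
                                dens$features$ordinal == 1]
  expect_equal(d1, 3.5)
  # doubling the library halves the density
  dens2 <- normalize_densities(counts, total_read_bases = 2e7 * 35)
  expect_equal(dens2$features$density[dens2$features$class == "EXN" &
                                        dens2$features$ordinal == 1], 1.75)
  # normalizing an already-standard library is the identity
  expect_equal(dens$features$density,
               dens$features$rdbp / (dens$features$length), tolerance = 1e-12)

  # density / RPKM = 0.35 regardless of length, count, library size
  for (case in list(c(bp = 1000, n = 100, reads = 1e7),
                    c(bp = 250, n = 7, reads = 3.2e7),
                    c(bp = 54321, n = 1234, reads = 5e6))) {
    D <- (case[["n"]] * 35 / case[["bp"]]) * (1e7 * 35) /
      (case[["reads"]] * 35)
    rpkm <- case[["n"]] / ((case[["bp"]] / 1000) * (case[["reads"]] / 1e6))
    expect_equal(D / rpkm, 0.35)
  }
})

test_that("zero-mappability features are excluded with a flag", {
  models <- .q_models()
  fs <- enumerate_features(models, r = 35)
  f <- compute_mappability(fs$features, NULL, r = 35)
  f$mappability[f$class == "INT" & f$ordinal == 1] <- 0
  f$rdbp <- 1
  counts <- structure(list(features = f, splice = NULL,
                           total_read_bases = 3.5e8),
                      class = "feature_counts")
  dens <- normalize_densities(counts)
  bad <- dens$features$class == "INT" & dens$features$ordinal == 1
  expect_true(all(is.na(dens$features$density[bad])))
  expect_true(all(dens$features$excluded[bad]))
})

test_that("consecutive splice fraction applies the two-read rule", {
  models <- .q_models()
  fs <- enumerate_features(models, r = 35)
  mk <- function(n12, n23, n13) {
    keys <- c(rep("SPL|gQ|1|2", n12), rep("SPL|gQ|2|3", n23),
              rep("SPL|gQ|1|3", n13))
    reads <- data.frame(chrom = keys,
                        start = rep(0L, length(keys)),
                        length = rep(35L, length(keys)),
                        strand = rep("+", length(keys)))
    assign_reads(reads, fs$features, fs$splice_library)
  }
  expect_equal(consecutive_splice_fraction(mk(50, 45, 5))$fraction, 0.95)
  expect_equal(consecutive_splice_fraction(mk(10, 10, 0))$fraction, 1)
  # a single-read non-consecutive junction is excluded from the tally
  expect_equal(consecutive_splice_fraction(mk(50, 49, 1))$fraction, 1)
  # no splice reads at all: fraction undefined
  expect_true(is.na(consecutive_splice_fraction(mk(0, 0, 0))$fraction))
  # detectably-skipped exon 2: 5 skip reads vs 95 inclusion reads
  spe <- consecutive_splice_fraction(mk(50, 45, 5))$skipped_per_exon
  expect_equal(spe$skipped_fraction[spe$exon == 2], 0.05)
})

test_that("retained introns are flagged from splice-site densities", {
  models <- .q_models()
  fs <- enumerate_features(models, r = 35)
  f <- fs$features
  scale_d <- function(cls, ord, d) {
    sel <- f$class == cls & f$ordinal == ord
    f$rdbp[sel] <<- d * f$length[sel]
  }
  # gene-level: exon density 10, intron density 0.2
  for (e in 1:3) scale_d("EXN", e, 10)
  for (i in 1:2) scale_d("INT", i, 0.2)
  # intron 1 retained: its splice sites sit at the exonic level;
  # intron 2 normal: splice sites at the intronic level
  scale_d("JXN5", 1, 10); scale_d("JXN3", 1, 10)
  scale_d("JXN5", 2, 0.2); scale_d("JXN3", 2, 0.25)
  counts <- structure(list(features = f, splice = NULL,
                           total_read_bases = 3.5e8),
                      class = "feature_counts")
  flags <- retained_intron_filter(normalize_densities(counts))
  expect_true(flags$flagged[flags$ordinal == 1])
  expect_false(flags$flagged[flags$ordinal == 2])
})

test_that("simulated retained introns are flagged at depth 10M", {
  models <- uniform_cohort(40, rep(300, 4), rep(8000, 3))
  pars <- fixed_params(models, c0S = 2e-3)   # a well-expressed gene
  set.seed(31)
  ds <- simulate_dataset(models, pars, depth_reads = 1e7, seed = 31)
  f <- ds$features
  # emit intron 2's splice sites with the exon lifetime (retention):
  # their densities jump from the intronic to the exonic level
  tr <- ds$truth
  for (gid in tr$gene_id) {
    d_exn <- with(tr[tr$gene_id == gid, ],
                  c0S * (Tt_EXN + T5 + T3 + Tmu))
    sel <- f$gene_id == gid & f$class %in% c("JXN5", "JXN3") &
      f$ordinal == 2
    f$rdbp[sel] <- rpois(sum(sel), d_exn * f$length[sel] / 35) * 35
  }
  ds$features <- f
  flags <- retained_intron_filter(normalize_densities(ds))
  expect_gt(mean(flags$flagged[flags$ordinal == 2]), 0.95)
  expect_lt(mean(flags$flagged[flags$ordinal != 2]), 0.2)
})
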