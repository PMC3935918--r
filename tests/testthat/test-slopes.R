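test_that("intron slope fitting matches an independent OLS oracle", {
  set.seed(12)
  y <- pmax(0.01, 0.5 - 5e-5 * (1:100) * 50 + rnorm(100, 0, 0.02))
  fit <- fit_intron_slope(y, bin_bp = 50)
  x <- (1:100) * 50 - 25
  olm <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$slope, olm[2, 1])
  expect_equal(fit$se, olm[2, 2])
  expect_equal(fit$tdr, 1 - pnorm(fit$slope / fit$se))
  expect_identical(fit$n_bins_used, 100L)
})

test_that("TDR follows the one-tailed null probability", {
  # slope/SE = -2 gives TDR = 0.9772 (standard normal CDF); the residual
  # pattern (+1,-1,-1,+1) is orthogonal to the line, so slope and RSS are
  # known exactly and the true slope can be placed at exactly -2 SE
  n <- 60; w <- 10
  x <- (1:n) * w - w / 2
  pat <- rep(c(1, -1, -1, 1), n / 4) * 0.1
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(pat^2) / (n - 2) / sxx)
  y <- 5 - (2 * se) * x + pat
  f <- fit_intron_slope(y, bin_bp = w)
  expect_equal(f$slope / f$se, -2, tolerance = 1e-10)
  expect_equal(f$tdr, pnorm(2), tolerance = 1e-10)
  expect_equal(f$tdr, 0.9772, tolerance = 1e-4)
  # constant density: slope 0 with zero SE, TDR 1/2
  fc <- fit_intron_slope(rep(2, 100), bin_bp = 50)
  expect_equal(fc$slope, 0)
  expect_equal(fc$tdr, 0.5)
  # TDR strictly decreases as the slope increases at fixed SE
  z <- seq(-3, 3, by = 0.5)
  tdr <- 1 - pnorm(z)
  expect_true(all(diff(tdr) < 0))
})

test_that("noiseless linear profiles give the exact synthesis slope", {
  p <- lifecycle_params(c0S = 0.01 / 60, T5 = 90, T3 = 45, Tgamma = 25,
                        Tmu = 7200)
  L <- 24000
  # per-bin (100 bins) and per-base fits agree: binning invariance
  for (nb in c(100L, 500L)) {
    w <- L / nb
    mids <- (seq_len(nb) - 0.5) * w
    y <- predict_intron_profile(p, L, mids)
    f <- fit_intron_slope(y, bin_bp = w)
    expect_equal(f$slope, -p$c0S * p$Talpha, tolerance = 1e-12)
    expect_equal(f$slope, -2.778e-6, tolerance = 1e-3)
    expect_identical(f$tdr, 1)            # zero residual, negative slope
  }
})

test_that("spike bins are dropped and sparse profiles refused", {
  p <- lifecycle_params(1e-4, 90, 45, 25, 7200)
  y <- predict_intron_profile(p, 10000, (1:100 - 0.5) * 100)
  ys <- y; ys[40] <- 100 * median(y)
  f <- fit_intron_slope(ys, bin_bp = 100)
  expect_true(f$usable)
  expect_identical(f$n_bins_used, 99L)     # spike bin excluded
  expect_equal(f$slope, -p$c0S * p$Talpha, tolerance = 1e-10)
  ys6 <- y; ys6[seq(5, 55, by = 10)] <- 100 * median(y)
  expect_false(fit_intron_slope(ys6, bin_bp = 100)$usable)
  # fewer than 20 nonzero bins
  yz <- y; yz[20:100] <- 0
  f2 <- fit_intron_slope(yz, bin_bp = 100)
  expect_false(f2$usable)
  expect_match(f2$reason, "min_bins")
  expect_false(fit_intron_slope(rep(0, 100), bin_bp = 100)$usable)
})

test_that("gene-level aggregation uses quadrature error propagation", {
  mkfit <- function(slope, se, tdr = NULL) {
    if (is.null(tdr)) tdr <- 1 - pnorm(slope / se)
    list(slope = slope, se = se, tdr = tdr, n_bins_used = 100L,
         usable = TRUE, reason = NA_character_)
  }
  # single intron: pass-through
  a <- aggregate_gene_slope(list(mkfit(-2e-6, 1e-7)), 8000)
  expect_equal(a$slope, -2e-6)
  expect_equal(a$se, 1e-7)
  # equal weights: arithmetic mean of slopes
  b <- aggregate_gene_slope(list(mkfit(-2e-6, 1e-7, 1),
                                 mkfit(-4e-6, 1e-7, 1)),
                            c(5000, 5000))
  expect_equal(b$slope, -3e-6)
  # equal slopes, SEs, weights: propagated SE is se / sqrt(2)
  cc <- aggregate_gene_slope(list(mkfit(-2e-6, 1e-7, 1),
                                  mkfit(-2e-6, 1e-7, 1)),
                             c(5000, 5000))
  expect_equal(cc$se, 1e-7 / sqrt(2))
  expect_equal(cc$tdr, 1 - pnorm(-2e-6 / cc$se))
  # length * TDR^2 weighting: a long confident intron dominates the SE
  d <- aggregate_gene_slope(list(mkfit(-2e-6, 1e-8, 1),
                                 mkfit(-2e-6, 1e-5, 0.5)),
                            c(50000, 5000))
  w <- c(50000 * 1, 5000 * 0.25)
  expect_equal(d$se, sqrt(sum(w^2 * c(1e-8, 1e-5)^2)) / sum(w))
  expect_null(aggregate_gene_slope(list(list(usable = FALSE)), 5000))
})

test_that("gene filters apply the documented thresholds inclusively", {
  models <- uniform_cohort(4, rep(200, 3), rep(8000, 2))
  slopes <- data.frame(gene_id = sprintf("g%04d", 1:4),
                       slope = -2e-6, se = 1e-7,
                       tdr = c(0.89, 0.90, 0.99, 0.99),
                       n_introns_used = 2L)
  dens <- structure(list(genes = data.frame(
    gene_id = sprintf("g%04d", 1:4),
    D_EXN = c(10, 50, 50.5, 10), D_INT = c(0.5, 1.00, 0.5, 1.01),
    D_5SS = 1, D_3SS = 1, D_SPL = 1)), class = "density_table")
  flt <- filter_genes_for_model(slopes, dens, models)
  # g1 fails TDR (0.89 < 0.90); g2 sits exactly on both inclusive bounds;
  # g3 fails D_EXN; g4 fails D_INT
  expect_identical(flt$eligible, "g0002")
  expect_equal(unname(flt$diagnostics["fail_tdr"]), 1)
  expect_equal(unname(flt$diagnostics["fail_d_exn"]), 1)
  expect_equal(unname(flt$diagnostics["fail_d_int"]), 1)
  # empty result aborts with per-filter diagnostics
  slopes$tdr <- 0.1
  expect_error(filter_genes_for_model(slopes, dens, models),
               "no genes pass")
})

test_that("usability gates: length, TSS distance, and slope sign", {
  # gene with one 3-kb and one 8-kb intron; only the 8-kb one is usable,
  # and only when the TSS-distance gate is relaxed (it starts at 3.2 kb)
  models <- build_gene_models(exon_records("gT", c(100, 100, 100),
                                           c(3000, 8000)))
  pars <- fixed_params(models, c0S = 5e-4)
  ds <- simulate_dataset(models, pars, noise = "none")
  dens <- normalize_densities(ds)
  sl0 <- gene_slopes(dens, models, min_tss_dist = 0)
  expect_identical(sl0$n_introns_used, 1L)
  expect_equal(sl0$slope, -5e-4 / 60, tolerance = 1e-10)
  # the 8-kb intron starts 3.2 kb from the TSS: excluded by the 5-kb rule
  expect_null(gene_slopes(dens, models))
  # positive-slope genes are retained but fail the TDR gate downstream
  models2 <- uniform_cohort(20, rep(150, 3), rep(8000, 2))
  pars2 <- fixed_params(models2, c0S = 2e-3)
  ds2 <- simulate_dataset(models2, pars2, depth_reads = 1e7, seed = 41)
  f <- ds2$features
  flip <- f$gene_id %in% sprintf("g%04d", 1:5) & f$class == "INTBIN"
  # reverse the first five genes' bin profiles: rising density
  for (gid in sprintf("g%04d", 1:5)) for (o in 1:2) {
    sel <- which(f$gene_id == gid & f$class == "INTBIN" & f$ordinal == o)
    f$rdbp[sel] <- rev(f$rdbp[sel])
  }
  ds2$features <- f
  sl2 <- gene_slopes(normalize_densities(ds2), models2, min_tss_dist = 0)
  bad <- sl2$gene_id %in% sprintf("g%04d", 1:5)
  expect_true(all(sl2$tdr[bad] < 0.9))          # positive slopes fail
  expect_gt(median(sl2$tdr[!bad]), median(sl2$tdr[bad]))
})

test_that("3'-intron density matches the closed form and pools per gene", {
  # noiseless intron of 20 kb: window mean = c0S * (Tp + Talpha*10000/2)
  models <- build_gene_models(exon_records("gW", c(500, 500), 20000))
  pars <- fixed_params(models, c0S = 1.667e-4, T5 = 90, T3 = 45,
                       Tgamma = 25)
  ds <- simulate_dataset(models, pars, noise = "none")
  d3 <- compute_d3int(normalize_densities(ds))
  expect_equal(d3$per_gene$d3int, 1.667e-4 * (160 + 10000 / 120),
               tolerance = 1e-10)
  expect_equal(d3$per_gene$d3int, 0.0406, tolerance = 2e-3)
  expect_equal(d3$per_gene$d3int_se, 0)
  # intron shorter than the window: whole-intron mean
  models2 <- build_gene_models(exon_records("gV", c(500, 500), 4000))
  ds2 <- simulate_dataset(models2, fixed_params(models2, 1.667e-4),
                          noise = "none")
  d32 <- compute_d3int(normalize_densities(ds2))
  expect_equal(d32$per_gene$d3int, 1.667e-4 * (160 + 4000 / 120),
               tolerance = 1e-10)
  # identical introns: within-gene SE is zero
  models3 <- uniform_cohort(1, rep(200, 4), rep(15000, 3))
  ds3 <- simulate_dataset(models3, fixed_params(models3, 2e-4),
                          noise = "none")
  d33 <- compute_d3int(normalize_densities(ds3))
  expect_equal(d33$per_gene$d3int_se, 0)
  expect_identical(d33$per_gene$n_introns, 3L)
})

test_that("slope and 3'-intron density are proportional readouts", {
  models <- uniform_cohort(12, rep(200, 4), rep(15000, 3))
  set.seed(17)
  pars <- fixed_params(models, c0S = rlnorm(12, log(2e-4), 1))
  ds <- simulate_dataset(models, pars, noise = "none")
  dens <- normalize_densities(ds)
  sl <- gene_slopes(dens, models, min_tss_dist = 0)
  d3 <- compute_d3int(dens)$per_gene
  pc <- proxy_consistency(sl, d3)
  expect_equal(pc$slope, 1, tolerance = 1e-10)
  expect_identical(pc$n_genes, 12L)
  expect_error(proxy_consistency(sl[1:5, ], d3), "at least 10")
})
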