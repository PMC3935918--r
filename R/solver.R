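#' Solve the linear lifecycle system for one (aggregated) sample
#'
#' Inverts the four-equation density model for the processing times given
#' the synthesis rate. The coefficient matrix over `(T5, T3, Tgamma, Tmu)`
#' is lower-triangular zeros and ones, so the solution is sequential:
#' \deqn{T_5 = D_{5'SS}/c_0S - T_{t,5'SS}}
#' \deqn{T_3 = D_{3'SS}/c_0S - T_5}
#' \deqn{T_\gamma = D_{INT}/c_0S - T_{t,INT} - T_5 - T_3}
#' \deqn{T_\mu = D_{EXN}/c_0S - T_{t,EXN} - T_5 - T_3}
#' No positivity is enforced here; the Monte Carlo layer discards samples
#' with any negative time.
#'
#' @param D Named numeric with `D_5SS`, `D_3SS`, `D_INT`, `D_EXN` (all
#'   must be positive), e.g. from [predict_densities()].
#' @param wt A [waiting_times()] object (or list with `Tt_5SS`, `Tt_INT`,
#'   `Tt_EXN`).
#' @param c0S Fused synthesis rate (density per second), > 0.
#' @return Named numeric `(T5, T3, Tgamma, Tmu)` in seconds.
#' @export
solve_sample <- function(D, wt, c0S) {
  if (c0S <= 0) stop("c0S must be positive")
  d <- D[c("D_5SS", "D_3SS", "D_INT", "D_EXN")]
  if (any(is.na(d)) || any(d <= 0))
    stop("all four feature densities must be positive to solve")
  T5 <- unname(d["D_5SS"]) / c0S - wt$Tt_5SS
  T3 <- unname(d["D_3SS"]) / c0S - T5
  Tg <- unname(d["D_INT"]) / c0S - wt$Tt_INT - T5 - T3
  Tm <- unname(d["D_EXN"]) / c0S - wt$Tt_EXN - T5 - T3
  c(T5 = T5, T3 = T3, Tgamma = Tg, Tmu = Tm)
}

# geometric mean over rows of a matrix, NA entries ignored
.row_gm <- function(m) exp(rowMeans(log(m), na.rm = TRUE))

#' Monte Carlo inversion over random gene samples
#'
#' Repeatedly draws `sample_size` genes without replacement, perturbs each
#' gene's slope with Gaussian noise of its own standard error, aggregates
#' the sample, solves the linear system, and keeps solutions with all four
#' processing times positive. Aggregation is by geometric mean: the fused
#' synthesis rate is the geometric mean of the slope magnitudes divided by
#' `Talpha`; each feature density is the geometric mean of the sample's
#' nonzero values (a sample with all-zero densities for some feature type
#' is discarded); transcription waiting times are aggregated the same way
#' by default, which preserves the exact forward-inverse round trip on
#' homogeneous cohorts. A perturbed slope that lands at or above zero is
#' redrawn for that gene (up to 20 times) before the sample is abandoned.
#'
#' @param genes Data.frame with one row per eligible gene and columns
#'   `slope`, `se`, `D_5SS`, `D_3SS`, `D_INT`, `D_EXN`, `Tt_5SS`,
#'   `Tt_INT`, `Tt_EXN`.
#' @param sample_size Genes per sample (default 5).
#' @param max_samples Cap on samples drawn (default 200000).
#' @param min_valid Stop once this many all-positive solutions are
#'   accumulated (default 2000).
#' @param Talpha Transcription time constant, s/bp.
#' @param tt_aggregate `"geometric"` (default) or `"arithmetic"` waiting
#'   time aggregation; geometric falls back to arithmetic for a component
#'   whose sample contains non-positive values.
#' @param seed Optional RNG seed for bit-reproducible runs.
#' @return List of class `mc_solution`: `times` (matrix of valid
#'   solutions, columns `T5`, `T3`, `Tgamma`, `Tmu`, seconds),
#'   `samples_drawn`, `n_valid`, `n_discarded_zero_density`,
#'   `n_slope_redraw_failures`, `config`. Warns when `max_samples` is
#'   reached before `min_valid`.
#' @export
monte_carlo_solve <- function(genes, sample_size = 5L, max_samples = 200000L,
                              min_valid = 2000L, Talpha = 1 / 60,
                              tt_aggregate = c("geometric", "arithmetic"),
                              seed = NULL) {
  tt_aggregate <- match.arg(tt_aggregate)
  max_samples <- as.integer(max_samples)
  min_valid <- as.integer(min_valid)
  stopifnot(sample_size >= 1L, min_valid <= max_samples)
  need <- c("slope", "se", "D_5SS", "D_3SS", "D_INT", "D_EXN",
            "Tt_5SS", "Tt_INT", "Tt_EXN")
  if (!all(need %in% names(genes)))
    stop("genes table must have columns: ", paste(need, collapse = ", "))
  n <- nrow(genes)
  if (n < sample_size) stop("fewer genes (", n, ") than sample_size")
  if (!is.null(seed)) set.seed(seed)

  k <- sample_size
  pick <- function(m) vapply(seq_len(m), function(i) sample.int(n, k),
                             integer(k))
  agg_tt <- function(m) {
    if (tt_aggregate == "geometric") {
      ok <- rowSums(m <= 0) == 0
      out <- numeric(nrow(m))
      out[ok] <- exp(rowMeans(log(m[ok, , drop = FALSE])))
      out[!ok] <- rowMeans(m[!ok, , drop = FALSE])
      out
    } else rowMeans(m)
  }

  acc <- list()
  drawn <- 0L; n_valid <- 0L; n_zero <- 0L; n_redraw_fail <- 0L
  chunk <- 4096L
  while (n_valid < min_valid && drawn < max_samples) {
    m <- min(chunk, max_samples - drawn)
    idx <- t(pick(m))                               # m x k gene indices
    sl <- matrix(genes$slope[idx], m, k) +
      matrix(stats::rnorm(m * k), m, k) * matrix(genes$se[idx], m, k)
    for (try in seq_len(20L)) {                     # redraw nonneg slopes
      bad <- sl >= 0
      if (!any(bad)) break
      sl[bad] <- genes$slope[idx][bad] +
        stats::rnorm(sum(bad)) * genes$se[idx][bad]
    }
    sample_ok <- rowSums(sl >= 0) == 0
    n_redraw_fail <- n_redraw_fail + sum(!sample_ok)
    c0S <- .row_gm(abs(sl)) / Talpha   # invalid rows dropped via sample_ok

    dens <- lapply(c("D_5SS", "D_3SS", "D_INT", "D_EXN"), function(col) {
      dm <- matrix(genes[[col]][idx], m, k)
      dm[dm <= 0] <- NA
      .row_gm(dm)
    })
    all_zero <- Reduce(`|`, lapply(dens, function(v) is.nan(v) | is.na(v)))
    n_zero <- n_zero + sum(all_zero & sample_ok)
    sample_ok <- sample_ok & !all_zero

    tt5 <- agg_tt(matrix(genes$Tt_5SS[idx], m, k))
    tti <- agg_tt(matrix(genes$Tt_INT[idx], m, k))
    tte <- agg_tt(matrix(genes$Tt_EXN[idx], m, k))

    T5 <- dens[[1]] / c0S - tt5
    T3 <- dens[[2]] / c0S - T5
    Tg <- dens[[3]] / c0S - tti - T5 - T3
    Tm <- dens[[4]] / c0S - tte - T5 - T3
    valid <- sample_ok & T5 > 0 & T3 > 0 & Tg > 0 & Tm > 0
    if (any(valid))
      acc[[length(acc) + 1L]] <- cbind(T5 = T5[valid], T3 = T3[valid],
                                       Tgamma = Tg[valid], Tmu = Tm[valid])
    n_valid <- n_valid + sum(valid)
    drawn <- drawn + m
  }
  times <- if (length(acc)) do.call(rbind, acc) else
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("T5", "T3", "Tgamma",
                                                     "Tmu")))
  if (n_valid > min_valid) times <- times[seq_len(min_valid), , drop = FALSE]
  if (n_valid < min_valid)
    warning("only ", n_valid, " valid solutions after ", drawn,
            " samples (requested ", min_valid, "); returning partial result")
  structure(list(times = times, samples_drawn = drawn,
                 n_valid = nrow(times),
                 n_discarded_zero_density = n_zero,
                 n_slope_redraw_failures = n_redraw_fail,
                 config = list(sample_size = sample_size,
                               max_samples = max_samples,
                               min_valid = min_valid, Talpha = Talpha,
                               tt_aggregate = tt_aggregate, seed = seed)),
            class = "mc_solution")
}

#' Fit the mRNA lifecycle model to a quantified RNA-seq snapshot
#'
#' The top-level estimator. Filters genes with
#' [filter_genes_for_model()], attaches each eligible gene's transcription
#' waiting times, and runs the Monte Carlo inversion
#' ([monte_carlo_solve()]) to obtain distributions of the four processing
#' times. Accepted-time distributions tend to be log-normal, so point
#' estimates are geometric means and intervals are quantile-based.
#'
#' @param density A `density_table` from [normalize_densities()].
#' @param slopes Gene slopes from [gene_slopes()].
#' @param gene_models Gene models from [build_gene_models()] (or the
#'   simulator).
#' @param Talpha Transcription time constant, s/bp.
#' @param tdr_min,max_d_int,max_d_exn,coding_only Gene filters, see
#'   [filter_genes_for_model()].
#' @param sample_size,max_samples,min_valid,tt_aggregate,seed Monte Carlo
#'   controls, see [monte_carlo_solve()].
#' @return Object of class `snapshot_fit`; see [summary.snapshot_fit()],
#'   [coef.snapshot_fit()], [confint.snapshot_fit()],
#'   [plot.snapshot_fit()].
#' @export
snapshot_fit <- function(density, slopes, gene_models, Talpha = 1 / 60,
                         tdr_min = 0.90, max_d_int = 1.00, max_d_exn = 50,
                         coding_only = TRUE, sample_size = 5L,
                         max_samples = 200000L, min_valid = 2000L,
                         tt_aggregate = "geometric", seed = NULL) {
  flt <- filter_genes_for_model(slopes, density, gene_models,
                                tdr_min = tdr_min, max_d_int = max_d_int,
                                max_d_exn = max_d_exn,
                                coding_only = coding_only)
  by_id <- stats::setNames(gene_models,
                           vapply(gene_models, `[[`, character(1),
                                  "gene_id"))
  tab <- merge(slopes[slopes$gene_id %in% flt$eligible, , drop = FALSE],
               density$genes, by = "gene_id")
  wts <- t(vapply(tab$gene_id, function(id) {
    wt <- waiting_times(by_id[[id]], Talpha = Talpha)
    c(wt$Tt_5SS, wt$Tt_INT, wt$Tt_EXN)
  }, numeric(3)))
  tab$Tt_5SS <- wts[, 1]; tab$Tt_INT <- wts[, 2]; tab$Tt_EXN <- wts[, 3]

  mc <- monte_carlo_solve(tab, sample_size = sample_size,
                          max_samples = max_samples, min_valid = min_valid,
                          Talpha = Talpha, tt_aggregate = tt_aggregate,
                          seed = seed)
  structure(list(times = mc$times, mc = mc, eligible = flt$eligible,
                 filter_diagnostics = flt$diagnostics, genes = tab,
                 call = match.call()),
            class = "snapshot_fit")
}

#' Synthesis-rate proxy and stability ratio per gene
#'
#' The 3'-intron density is a relative pre-mRNA synthesis rate, and the
#' ratio of exon density to it is a relative mRNA stability (proportional
#' to the mRNA lifetime when intron processing times are comparable
#' across genes). Absolute lifetimes require the full model fit.
#'
#' @param density A `density_table`.
#' @param d3int `per_gene` element of [compute_d3int()]; computed from
#'   `density` when omitted.
#' @return Data.frame: `gene_id`, `synthesis_proxy` (= `d3int`), `D_EXN`,
#'   `stability` (`D_EXN / d3int`, `NA` when the proxy is zero).
#' @export
stability_and_lifetime <- function(density, d3int = NULL) {
  if (is.null(d3int)) d3int <- compute_d3int(density)$per_gene
  m <- merge(d3int, density$genes[, c("gene_id", "D_EXN")], by = "gene_id")
  m$stability <- ifelse(m$d3int > 0, m$D_EXN / m$d3int, NA_real_)
  data.frame(gene_id = m$gene_id, synthesis_proxy = m$d3int,
             D_EXN = m$D_EXN, stability = m$stability)
}
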