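#' @export
print.snapshot_fit <- function(x, ...) {
  cat("Steady-state mRNA lifecycle fit (Monte Carlo inversion)\n")
  cat(sprintf("  eligible genes: %d   samples drawn: %d   valid solutions: %d\n",
              length(x$eligible), x$mc$samples_drawn, x$mc$n_valid))
  if (nrow(x$times)) {
    gm <- exp(colMeans(log(x$times)))
    cat("  geometric-mean times (s): ",
        paste(sprintf("%s = %.3g", names(gm), gm), collapse = "  "), "\n")
  } else {
    cat("  no valid solutions\n")
  }
  invisible(x)
}

#' Summarize a lifecycle model fit
#'
#' @param object A `snapshot_fit`.
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return Data.frame, one row per processing time, with geometric mean,
#'   median, and quantile interval bounds (seconds), plus sample counts as
#'   attributes.
#' @export
summary.snapshot_fit <- function(object, level = 0.95, ...) {
  t <- object$times
  if (!nrow(t)) stop("no valid solutions to summarize")
  a <- (1 - level) / 2
  out <- data.frame(
    time = colnames(t),
    geometric_mean = exp(colMeans(log(t))),
    median = apply(t, 2, stats::median),
    lower = apply(t, 2, stats::quantile, probs = a),
    upper = apply(t, 2, stats::quantile, probs = 1 - a),
    row.names = NULL)
  attr(out, "n_valid") <- object$mc$n_valid
  attr(out, "samples_drawn") <- object$mc$samples_drawn
  attr(out, "level") <- level
  class(out) <- c("summary.snapshot_fit", "data.frame")
  out
}

#' @export
print.summary.snapshot_fit <- function(x, ...) {
  cat(sprintf("Processing-time distributions over %d valid Monte Carlo solutions\n",
              attr(x, "n_valid")))
  cat(sprintf("(%d samples drawn; %.0f%% quantile intervals; seconds)\n",
              attr(x, "samples_drawn"), 100 * attr(x, "level")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.snapshot_fit <- function(object, ...) {
  if (!nrow(object$times)) stop("no valid solutions")
  exp(colMeans(log(object$times)))
}

#' @export
confint.snapshot_fit <- function(object, parm, level = 0.95, ...) {
  t <- object$times
  if (missing(parm)) parm <- colnames(t)
  a <- (1 - level) / 2
  ci <- t(apply(t[, parm, drop = FALSE], 2, stats::quantile,
                probs = c(a, 1 - a)))
  colnames(ci) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  ci
}

#' Plot accepted processing-time distributions
#'
#' Histograms of the log10 accepted Monte Carlo solutions for each of the
#' four processing times; the distributions are roughly log-normal.
#'
#' @param x A `snapshot_fit`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.snapshot_fit <- function(x, ...) {
  t <- x$times
  if (!nrow(t)) stop("no valid solutions to plot")
  labs <- c(T5 = "lariat formation T5", T3 = "exon ligation T3",
            Tgamma = "intron degradation Tgamma", Tmu = "mRNA lifetime Tmu")
  old <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(old))
  for (nm in colnames(t)) {
    graphics::hist(log10(t[, nm]), main = labs[[nm]],
                   xlab = "log10 time (s)", col = "grey80", border = NA,
                   ...)
    graphics::abline(v = log10(exp(mean(log(t[, nm])))), col = 2, lwd = 2)
  }
  invisible(x)
}
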