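#' Meta-intron profile and guillotine blade/base heights
#'
#' Aggregates long introns, aligned at their 3' ends, into one average
#' profile per intron ordinal. Under the model the profile over the last
#' `window` bp is a line: its intercept at the 3' terminus (the "base")
#' is `c0S * Tp`, set by the intron processing time, while the drop across
#' the window (the "blade") is `c0S * Talpha * window`, set by synthesis
#' alone. Both are estimated from a straight-line fit to the aggregated
#' profile, which is exact on noiseless model data and noise-robust
#' otherwise. Only introns longer than `min_intron_bp` from genes with at
#' least `min_introns` introns contribute; ordinals above 10 are not
#' aggregated.
#'
#' @param density A `density_table` whose features include `INTBIN` rows.
#' @param gene_models The gene models.
#' @param window 3'-anchored window, bp (default 50 kb).
#' @param min_introns Minimum introns per contributing gene.
#' @param min_intron_bp Minimum contributing intron length, bp.
#' @param grid_bins Positions across the window at which profiles are
#'   aggregated.
#' @param stat `"mean"` (default) or `"median"` across introns per
#'   position.
#' @return Object of class `meta_intron_profile`: list with `profiles`
#'   (data.frame `ordinal`, `position` = bp from the 3' end, `density`,
#'   `n_introns`) and `blade_base` (data.frame `ordinal`, `base`, `blade`,
#'   `n_introns`). Empty (with a warning) when no intron qualifies.
#' @export
meta_intron_profile <- function(density, gene_models, window = 50000,
                                min_introns = 10L, min_intron_bp = 50000,
                                grid_bins = 100L,
                                stat = c("mean", "median")) {
  stopifnot(inherits(density, "density_table"))
  stat_fn <- switch(match.arg(stat), mean = mean, median = stats::median)
  f <- density$features
  bins <- f[f$class == "INTBIN", , drop = FALSE]
  bins_by_gene <- split(bins, bins$gene_id)
  grid <- (seq_len(grid_bins) - 0.5) * window / grid_bins  # bp from 3' end

  rows <- list()
  for (g in gene_models) {
    if (g$n_introns < min_introns) next
    gb <- bins_by_gene[[g$gene_id]]
    if (is.null(gb)) next
    for (i in which(g$intron_lengths > min_intron_bp)) {
      if (i > 10L) next
      L <- g$intron_lengths[i]
      bi <- gb[gb$ordinal == i, , drop = FALSE]
      if (!nrow(bi)) next
      bi <- bi[order(bi$ordinal2), , drop = FALSE]
      edges5 <- cumsum(bi$length)                  # bin ends, bp from 5'
      pos5 <- L - grid                             # grid in 5' coordinates
      bin_of <- findInterval(pos5, c(0, edges5), rightmost.closed = TRUE)
      bin_of <- pmin(pmax(bin_of, 1L), nrow(bi))
      rows[[length(rows) + 1L]] <-
        data.frame(ordinal = i, position = grid,
                   density = bi$density[bin_of])
    }
  }
  if (!length(rows)) {
    warning("no introns qualify for the meta-intron profile")
    empty <- data.frame(ordinal = integer(0), position = numeric(0),
                        density = numeric(0), n_introns = integer(0))
    return(structure(list(profiles = empty,
                          blade_base = data.frame(ordinal = integer(0),
                                                  base = numeric(0),
                                                  blade = numeric(0),
                                                  n_introns = integer(0))),
                     class = "meta_intron_profile"))
  }
  all <- do.call(rbind, rows)
  prof <- do.call(rbind, lapply(split(all, all$ordinal), function(a) {
    agg <- tapply(a$density, a$position, stat_fn)
    data.frame(ordinal = a$ordinal[1], position = as.numeric(names(agg)),
               density = as.numeric(agg),
               n_introns = sum(a$position == a$position[1]))
  }))
  rownames(prof) <- NULL
  bb <- do.call(rbind, lapply(split(prof, prof$ordinal), function(pr) {
    fit <- stats::lm(density ~ position, data = pr)
    data.frame(ordinal = pr$ordinal[1],
               base = max(0, unname(stats::coef(fit)[1])),
               blade = abs(unname(stats::coef(fit)[2])) * window,
               n_introns = pr$n_introns[1])
  }))
  rownames(bb) <- NULL
  structure(list(profiles = prof, blade_base = bb),
            class = "meta_intron_profile")
}

#' @export
print.meta_intron_profile <- function(x, ...) {
  cat("Meta-intron profile (3'-anchored):\n")
  print.data.frame(x$blade_base, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compare two conditions' feature densities and intron profiles
#'
#' For detecting global splicing perturbations: computes per-class fold
#' changes of the fraction of aligned read-bases (library-size effects
#' cancel), and per-ordinal fold changes of the meta-intron base and
#' blade heights with paired two-tailed t-tests over ordinals 2-10.
#' A slowed splicing step raises the base (proportional to the intron
#' processing time) while leaving the blade (proportional to synthesis)
#' unchanged.
#'
#' @param density_a,density_b `density_table`s for the two conditions,
#'   quantified on the same feature set.
#' @param blade_base_a,blade_base_b `blade_base` data.frames from
#'   [meta_intron_profile()] for the two conditions.
#' @return List: `class_fold` (per-class read-fraction fold B/A),
#'   `base_fold`, `blade_fold` (mean over shared ordinals 2-10),
#'   `base_p`, `blade_p` (paired t-tests), `per_ordinal`.
#' @export
condition_compare <- function(density_a, density_b, blade_base_a,
                              blade_base_b) {
  fa <- density_a$features; fb <- density_b$features
  if (nrow(fa) != nrow(fb) || !all(fa$class == fb$class) ||
        !all(fa$gene_id == fb$gene_id))
    stop("the two conditions were not quantified on the same feature set")
  frac <- function(f) {
    cls <- c("JXN5", "JXN3", "INT", "EXN")
    tot <- sum(f$rdbp[f$class %in% cls])
    vapply(cls, function(cl) sum(f$rdbp[f$class == cl]) / tot, numeric(1))
  }
  class_fold <- frac(fb) / frac(fa)
  names(class_fold) <- c("D_5SS", "D_3SS", "D_INT", "D_EXN")

  m <- merge(blade_base_a, blade_base_b, by = "ordinal",
             suffixes = c("_a", "_b"))
  m <- m[m$ordinal >= 2 & m$ordinal <= 10, , drop = FALSE]
  if (nrow(m) < 2) stop("need blade/base values for at least 2 of ",
                        "ordinals 2-10 in both conditions")
  paired_p <- function(x, y) {
    # degenerate noiseless profiles: identical -> 1, constant shift -> 0
    if (stats::sd(x - y) < .Machine$double.eps^0.5 * max(abs(x), 1))
      return(if (isTRUE(all.equal(x, y))) 1 else 0)
    tryCatch(stats::t.test(x, y, paired = TRUE)$p.value,
             error = function(e) NA_real_)
  }
  base_p <- paired_p(m$base_b, m$base_a)
  blade_p <- paired_p(m$blade_b, m$blade_a)
  list(class_fold = class_fold,
       base_fold = mean(m$base_b) / mean(m$base_a),
       blade_fold = mean(m$blade_b) / mean(m$blade_a),
       base_p = base_p, blade_p = blade_p, per_ordinal = m)
}

#' Trend of 3'-intron density along genes (sawtooth diagnostic)
#'
#' Under co-transcriptional splicing the density at the 3' end of each
#' intron does not vary systematically with intron ordinal along a gene
#' (the profile resets at every exon - the sawtooth); obligate
#' post-transcriptional splicing or uniform premature termination would
#' instead produce a monotone decline. Fits a per-gene regression of
#' log 3'-intron density on ordinal and tests the cohort mean slope
#' against zero.
#'
#' @param d3int_per_intron `per_intron` element of [compute_d3int()].
#' @param min_introns Minimum introns (with positive density) per gene.
#' @return List: `per_gene` (`gene_id`, `slope` in log-density per
#'   ordinal, `n_introns`), `mean_slope`, `p_value` (two-sided one-sample
#'   t-test), `n_genes`. Genes with fewer usable introns are skipped.
#' @export
sawtooth_trend <- function(d3int_per_intron, min_introns = 3L) {
  d <- d3int_per_intron[d3int_per_intron$d3int > 0, , drop = FALSE]
  per_gene <- do.call(rbind, lapply(split(d, d$gene_id), function(s) {
    if (nrow(s) < min_introns) return(NULL)
    fit <- stats::lm(log(d3int) ~ ordinal, data = s)
    data.frame(gene_id = s$gene_id[1],
               slope = unname(stats::coef(fit)[2]), n_introns = nrow(s))
  }))
  if (is.null(per_gene) || !nrow(per_gene))
    return(list(per_gene = data.frame(gene_id = character(0),
                                      slope = numeric(0),
                                      n_introns = integer(0)),
                mean_slope = NA_real_, p_value = NA_real_, n_genes = 0L))
  rownames(per_gene) <- NULL
  p <- if (stats::sd(per_gene$slope) == 0 || nrow(per_gene) < 2) {
    if (isTRUE(all.equal(mean(per_gene$slope), 0))) 1 else 0
  } else {
    stats::t.test(per_gene$slope, mu = 0)$p.value
  }
  list(per_gene = per_gene, mean_slope = mean(per_gene$slope),
       p_value = p, n_genes = nrow(per_gene))
}
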