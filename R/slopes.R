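# true-discovery rate of a slope: 1 minus the one-tailed null probability
# of a slope at least this negative given its SE
.tdr <- function(slope, se) {
  ifelse(se > 0, stats::pnorm(slope / se, lower.tail = FALSE),
         ifelse(slope < 0, 1, ifelse(slope == 0, 0.5, 0)))
}

#' Fit a straight line to an intron's binned density profile
#'
#' Ordinary least squares of per-bin density against bin midpoint position
#' (bp from the intron's 5' end, transcription direction), restricted to
#' bins with nonzero density. Spike bins - density above `spike_factor`
#' times the median nonzero density, typically embedded non-coding RNAs or
#' repeats - are dropped; the intron is refused when more than
#' `max_spike_bins` bins are spikes or fewer than `min_bins` clean nonzero
#' bins remain. The goodness-of-fit statistic is the true-discovery rate
#' `TDR = 1 - pnorm(slope / SE)`: the probability that random data would
#' not produce a slope this negative. A zero-SE (noiseless) fit has TDR 1
#' for a negative slope and 0.5 for a flat one.
#'
#' @param density Per-bin densities, 5' to 3' in transcription direction.
#' @param bin_bp Bin widths in bp (scalar or per bin).
#' @param positions Optional bin midpoints (bp from the 5' end); computed
#'   from `bin_bp` when omitted.
#' @param min_bins Minimum nonzero bins for a usable fit.
#' @param spike_factor,max_spike_bins Spike-removal rule.
#' @return List: `slope` (density per bp), `se`, `tdr`, `n_bins_used`,
#'   `usable`, `reason`.
#' @export
fit_intron_slope <- function(density, bin_bp, positions = NULL,
                             min_bins = 20L, spike_factor = 10,
                             max_spike_bins = 5L) {
  n <- length(density)
  if (length(bin_bp) == 1L) bin_bp <- rep(bin_bp, n)
  if (is.null(positions)) positions <- cumsum(bin_bp) - bin_bp / 2
  refuse <- function(reason)
    list(slope = NA_real_, se = NA_real_, tdr = NA_real_, n_bins_used = 0L,
         usable = FALSE, reason = reason)
  nz <- density > 0
  if (!any(nz)) return(refuse("all bins empty"))
  spike <- density > spike_factor * stats::median(density[nz])
  if (sum(spike) > max_spike_bins) return(refuse("too many spike bins"))
  use <- nz & !spike
  m <- sum(use)
  if (m < min_bins) return(refuse("fewer than min_bins nonzero bins"))
  x <- positions[use]; y <- density[use]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  resid <- y - mean(y) - slope * xc
  se <- if (m > 2) sqrt(sum(resid^2) / (m - 2) / sxx) else 0
  list(slope = slope, se = se, tdr = unname(.tdr(slope, se)),
       n_bins_used = m, usable = TRUE, reason = NA_character_)
}

#' Aggregate intron slope fits to a gene-level slope
#'
#' The gene slope is the arithmetic mean of its usable introns' slopes.
#' The propagated standard error combines the introns' SEs in quadrature
#' with weights proportional to intron length times squared TDR:
#' `se_g = sqrt(sum(w^2 * se^2)) / sum(w)`, `w = L * TDR^2` (or equal
#' weights). The gene TDR is recomputed from the z-score `slope_g / se_g`.
#'
#' @param fits List of fits from [fit_intron_slope()] (unusable ones are
#'   ignored).
#' @param intron_lengths Lengths (bp) matching `fits`.
#' @param weights `"length_tdr2"` (default) or `"equal"`.
#' @return List: `slope`, `se`, `tdr`, `n_introns_used`; `NULL` when no
#'   usable introns.
#' @export
aggregate_gene_slope <- function(fits, intron_lengths,
                                 weights = c("length_tdr2", "equal")) {
  weights <- match.arg(weights)
  ok <- vapply(fits, function(f) isTRUE(f$usable), logical(1))
  if (!any(ok)) return(NULL)
  sl <- vapply(fits[ok], `[[`, numeric(1), "slope")
  se <- vapply(fits[ok], `[[`, numeric(1), "se")
  td <- vapply(fits[ok], `[[`, numeric(1), "tdr")
  L <- intron_lengths[ok]
  w <- if (weights == "length_tdr2") L * td^2 else rep(1, length(L))
  if (sum(w) == 0) w <- rep(1, length(L))
  slope_g <- mean(sl)
  se_g <- sqrt(sum(w^2 * se^2)) / sum(w)
  list(slope = slope_g, se = se_g, tdr = unname(.tdr(slope_g, se_g)),
       n_introns_used = sum(ok))
}

# distance (bp, transcription coordinates) from the TSS to the 5' end of
# each intron
.intron_tss_distance <- function(gene_model) {
  g <- gene_model
  if (g$n_introns == 0L) return(numeric(0))
  cumsum(g$exon_lengths)[seq_len(g$n_introns)] +
    c(0, cumsum(g$intron_lengths))[seq_len(g$n_introns)]
}

#' Per-gene intron slopes from a density table
#'
#' Runs [fit_intron_slope()] on every usable intron (length at least
#' `min_intron_bp`; starting more than `min_tss_dist` from the TSS, where
#' promoter-proximal polymerase pausing would distort the profile) and
#' aggregates with [aggregate_gene_slope()].
#'
#' @param density A `density_table` whose features include `INTBIN` rows.
#' @param gene_models The gene models the features came from.
#' @param min_intron_bp Minimum usable intron length (bp).
#' @param min_tss_dist Minimum distance of the intron start from the TSS
#'   (bp); set to 0 to disable.
#' @param min_bins,spike_factor,max_spike_bins Passed to
#'   [fit_intron_slope()].
#' @param weights Passed to [aggregate_gene_slope()].
#' @return Data.frame: `gene_id`, `slope`, `se`, `tdr`, `n_introns_used`.
#'   Genes with no usable intron are omitted.
#' @export
gene_slopes <- function(density, gene_models, min_intron_bp = 5000,
                        min_tss_dist = 5000, min_bins = 20L,
                        spike_factor = 10, max_spike_bins = 5L,
                        weights = "length_tdr2") {
  stopifnot(inherits(density, "density_table"))
  f <- density$features
  bins <- f[f$class == "INTBIN", , drop = FALSE]
  if (!nrow(bins)) stop("density table has no INTBIN features; enumerate ",
                        "features with n_bins > 0")
  bins_by_gene <- split(bins, bins$gene_id)
  out <- lapply(gene_models, function(g) {
    gb <- bins_by_gene[[g$gene_id]]
    if (is.null(gb) || !nrow(gb)) return(NULL)
    tssd <- .intron_tss_distance(g)
    usable_i <- which(g$intron_lengths >= min_intron_bp &
                        (min_tss_dist <= 0 | tssd > min_tss_dist))
    if (!length(usable_i)) return(NULL)
    fits <- lapply(usable_i, function(i) {
      bi <- gb[gb$ordinal == i, , drop = FALSE]
      bi <- bi[order(bi$ordinal2), , drop = FALSE]
      fit_intron_slope(bi$density, bin_bp = bi$length, min_bins = min_bins,
                       spike_factor = spike_factor,
                       max_spike_bins = max_spike_bins)
    })
    agg <- aggregate_gene_slope(fits, g$intron_lengths[usable_i],
                                weights = weights)
    if (is.null(agg)) return(NULL)
    data.frame(gene_id = g$gene_id, slope = agg$slope, se = agg$se,
               tdr = agg$tdr, n_introns_used = agg$n_introns_used)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select genes eligible for solving the lifecycle model
#'
#' Applies the gene-level gates: consensus slope quality `TDR >= tdr_min`,
#' mean intron density at most `max_d_int` (removes genes with density
#' spikes), mean exon density at most `max_d_exn` (avoids dominance of a
#' few very highly expressed genes), and coding genes only.
#'
#' @param slopes Output of [gene_slopes()].
#' @param density A `density_table` (for the gene-class densities).
#' @param gene_models Gene models (for the coding flag).
#' @param tdr_min,max_d_int,max_d_exn Filter thresholds (inclusive bounds
#'   on the density gates).
#' @param coding_only Restrict to coding genes.
#' @return List with `eligible` (gene ids) and `diagnostics` (genes
#'   removed per filter). Aborts when no gene survives.
#' @export
filter_genes_for_model <- function(slopes, density, gene_models,
                                   tdr_min = 0.90, max_d_int = 1.00,
                                   max_d_exn = 50, coding_only = TRUE) {
  g <- density$genes
  m <- merge(slopes, g, by = "gene_id")
  coding <- vapply(gene_models, function(x) x$coding, logical(1))
  names(coding) <- vapply(gene_models, function(x) x$gene_id, character(1))
  pass_tdr <- m$tdr >= tdr_min
  pass_dint <- !is.na(m$D_INT) & m$D_INT <= max_d_int
  pass_dexn <- !is.na(m$D_EXN) & m$D_EXN <= max_d_exn
  pass_coding <- !coding_only | coding[m$gene_id]
  keep <- pass_tdr & pass_dint & pass_dexn & pass_coding
  diagnostics <- c(with_slope = nrow(m), fail_tdr = sum(!pass_tdr),
                   fail_d_int = sum(!pass_dint),
                   fail_d_exn = sum(!pass_dexn),
                   fail_coding = sum(!pass_coding), eligible = sum(keep))
  if (!any(keep))
    stop("no genes pass the model filters; removed per filter: ",
         paste(names(diagnostics), diagnostics, sep = "=", collapse = ", "))
  list(eligible = m$gene_id[keep], diagnostics = diagnostics)
}

#' Mean density over the 3'-most window of each intron
#'
#' The density of the last 10 kb of an intron is dominated by the intron
#' processing time rather than the transcription time, so its per-gene
#' mean is a relative pre-mRNA synthesis-rate proxy that is nearly free of
#' intron-length bias.
#'
#' @param density A `density_table` whose features include `INT3` windows.
#' @return List with `per_gene` (`gene_id`, `d3int` = mean over introns,
#'   `d3int_se` = within-gene standard error, `n_introns`) and
#'   `per_intron` (`gene_id`, `ordinal`, `d3int`).
#' @export
compute_d3int <- function(density) {
  stopifnot(inherits(density, "density_table"))
  f <- density$features
  w <- f[f$class == "INT3" & !is.na(f$density), , drop = FALSE]
  if (!nrow(w)) stop("density table has no INT3 features")
  per_intron <- data.frame(gene_id = w$gene_id, ordinal = w$ordinal,
                           d3int = w$density)
  per_gene <- do.call(rbind, lapply(split(per_intron$d3int,
                                          per_intron$gene_id),
                                    function(v)
    data.frame(d3int = mean(v),
               d3int_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                          else 0,
               n_introns = length(v))))
  per_gene <- data.frame(gene_id = rownames(per_gene), per_gene,
                         row.names = NULL)
  list(per_gene = per_gene, per_intron = per_intron)
}

#' Consistency of the two synthesis-rate readouts
#'
#' Both the magnitude of the gene slope and the 3'-intron density are
#' proportional to the synthesis rate, so a log-log regression of
#' `|slope|` on `d3int` across genes should have slope near 1 when the
#' processing-time spread is modest.
#'
#' @param slopes Output of [gene_slopes()].
#' @param d3int `per_gene` element of [compute_d3int()] output.
#' @param min_genes Minimum genes with usable (negative slope, positive
#'   density) pairs.
#' @return List: `slope`, `intercept`, `n_genes`.
#' @export
proxy_consistency <- function(slopes, d3int, min_genes = 10L) {
  m <- merge(slopes, d3int, by = "gene_id")
  m <- m[m$slope < 0 & m$d3int > 0, , drop = FALSE]
  if (nrow(m) < min_genes)
    stop("need at least ", min_genes, " genes with negative slope and ",
         "positive 3'-intron density; got ", nrow(m))
  fit <- stats::lm(log(-slope) ~ log(d3int), data = m)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n_genes = nrow(m))
}
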