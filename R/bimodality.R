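#' Classify genes into off/low/high expression modes
#'
#' Genes at or below the detection floor are "off"; the remaining log10
#' densities are fit with a two-component Gaussian mixture (unequal
#' variances) and split into "low" and "high" at posterior 0.5. Metazoan
#' expression (and, under the lifecycle model, synthesis rate) is
#' bimodal, roughly separating genes below and above about one mRNA per
#' cell; the mixture boundary operationalizes that cut without knowing
#' the density-per-transcript constant. A fit whose components are not
#' separated (or that does not beat a single Gaussian by BIC) is flagged
#' unimodal and no low/high split is reported.
#'
#' @param density Per-gene densities (e.g. exon density or the 3'-intron
#'   synthesis proxy).
#' @param gene_ids Optional gene identifiers (defaults to names or
#'   indices).
#' @param floor Detection floor; densities `<= floor` are "off"
#'   (default 0: only zero-density genes).
#' @param min_genes Minimum number of genes required.
#' @param min_separation Minimum distance between component means, in
#'   units of the larger component standard deviation, for the fit to
#'   count as bimodal.
#' @param min_bic_gain Minimum BIC advantage of two components over one.
#' @return Object of class `mode_assignment`: list with `assignments`
#'   (data.frame `gene_id`, `density`, `mode`, `posterior_high`),
#'   `mixture` (means, sds, weights on log10 scale, per-component
#'   full width at half maximum), `bimodal` (logical), `valley_ratio`
#'   (smoothed density at the valley between the component means over the
#'   smaller mode peak), `floor`.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_modes <- function(density, gene_ids = NULL, floor = 0,
                           min_genes = 100L, min_separation = 2,
                           min_bic_gain = 10) {
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(names(density))) names(density)
                else as.character(seq_along(density))
  stopifnot(length(gene_ids) == length(density))
  if (length(density) < min_genes)
    stop("need at least ", min_genes, " genes")
  off <- is.na(density) | density <= floor
  x <- log10(density[!off])

  fit <- tryCatch(Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE),
                  error = function(e) NULL)
  bic1 <- if (!is.null(fit)) fit$BIC["1", "V"] else NA
  bic2 <- if (!is.null(fit)) fit$BIC["2", "V"] else NA
  mode <- rep("off", length(density))
  post_high <- rep(NA_real_, length(density))
  bimodal <- FALSE
  mixture <- NULL
  valley_ratio <- NA_real_

  if (!is.na(bic2) && fit$G == 2) {
    mu <- fit$parameters$mean
    sd <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd) == 1L) sd <- rep(sd, 2)
    w <- fit$parameters$pro
    hi <- which.max(mu); lo <- which.min(mu)
    sep <- abs(diff(mu)) / max(sd)
    gain <- bic2 - ifelse(is.na(bic1), -Inf, bic1)
    dens_est <- stats::density(x)
    in_between <- dens_est$x > min(mu) & dens_est$x < max(mu)
    peak <- function(m) dens_est$y[which.min(abs(dens_est$x - m))]
    valley_ratio <- if (any(in_between))
      min(dens_est$y[in_between]) / min(peak(mu[1]), peak(mu[2]))
    else NA_real_
    bimodal <- sep >= min_separation && gain >= min_bic_gain
    mixture <- list(mean = unname(mu[c(lo, hi)]), sd = sd[c(lo, hi)],
                    weight = unname(w[c(lo, hi)]),
                    fwhm = 2 * sqrt(2 * log(2)) * sd[c(lo, hi)])
    if (bimodal) {
      ph <- fit$z[, hi]
      mode[!off] <- ifelse(ph >= 0.5, "high", "low")
      post_high[!off] <- ph
    }
  }
  if (!bimodal) {
    mode[!off] <- "expressed"
    if (is.null(mixture))
      mixture <- list(mean = mean(x), sd = stats::sd(x), weight = 1,
                      fwhm = 2 * sqrt(2 * log(2)) * stats::sd(x))
  }
  structure(list(assignments = data.frame(gene_id = gene_ids,
                                          density = density, mode = mode,
                                          posterior_high = post_high,
                                          row.names = NULL),
                 mixture = mixture, bimodal = bimodal,
                 valley_ratio = valley_ratio, floor = floor),
            class = "mode_assignment")
}

#' @export
print.mode_assignment <- function(x, ...) {
  tab <- table(x$assignments$mode)
  cat("Expression mode assignment (",
      if (x$bimodal) "bimodal" else "unimodal", "):\n", sep = "")
  print(tab)
  invisible(x)
}

# TSS table from gene models
.tss_table <- function(gene_models) {
  data.frame(gene_id = vapply(gene_models, `[[`, character(1), "gene_id"),
             chrom = vapply(gene_models, `[[`, character(1), "chromosome"),
             strand = vapply(gene_models, `[[`, character(1), "strand"),
             tss = vapply(gene_models, function(g) as.numeric(g$tss),
                          numeric(1)),
             row.names = NULL)
}

#' Distance from each gene to the nearest high-mode gene
#'
#' TSS-to-TSS distances within chromosomes, self excluded, plus
#' two-sample Kolmogorov-Smirnov tests comparing the distance
#' distributions of low and high genes against off genes. Genes on
#' chromosomes without any high-mode gene are excluded (count reported).
#'
#' @param modes A `mode_assignment` (or its `assignments` data.frame).
#' @param gene_models Gene models supplying chromosome and TSS.
#' @return List: `distances` (data.frame `gene_id`, `mode`, `distance`),
#'   `ks_low_vs_off`, `ks_high_vs_off` (p-values), `n_excluded`.
#' @export
nearest_high_distance <- function(modes, gene_models) {
  a <- if (inherits(modes, "mode_assignment")) modes$assignments else modes
  tss <- .tss_table(gene_models)
  m <- merge(a[, c("gene_id", "mode")], tss, by = "gene_id")
  out <- list(); excluded <- 0L
  for (ch in unique(m$chrom)) {
    s <- m[m$chrom == ch, , drop = FALSE]
    hi <- which(s$mode == "high")
    if (!length(hi)) { excluded <- excluded + nrow(s); next }
    d <- vapply(seq_len(nrow(s)), function(i) {
      others <- setdiff(hi, i)
      if (!length(others)) return(NA_real_)
      min(abs(s$tss[others] - s$tss[i]))
    }, numeric(1))
    out[[ch]] <- data.frame(gene_id = s$gene_id, mode = s$mode,
                            distance = d)
  }
  if (!length(out)) stop("no chromosome has a high-mode gene")
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d <- d[!is.na(d$distance), , drop = FALSE]
  ks <- function(m1, m2) {
    x <- d$distance[d$mode == m1]; y <- d$distance[d$mode == m2]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(stats::ks.test(x, y)$p.value)
  }
  list(distances = d, ks_low_vs_off = ks("low", "off"),
       ks_high_vs_off = ks("high", "off"), n_excluded = excluded)
}

# adjacency edges (consecutive genes in TSS order per chromosome) with
# orientation class of the pair
.adjacency_edges <- function(gene_models) {
  tss <- .tss_table(gene_models)
  edges <- do.call(rbind, lapply(split(tss, tss$chrom), function(s) {
    s <- s[order(s$tss), , drop = FALSE]
    if (nrow(s) < 2) return(NULL)
    i <- seq_len(nrow(s) - 1L)
    ori <- ifelse(s$strand[i] == s$strand[i + 1L], "head_to_tail",
                  ifelse(s$strand[i] == "+", "tail_to_tail",
                         "head_to_head"))
    data.frame(a = s$gene_id[i], b = s$gene_id[i + 1L], orientation = ori)
  }))
  rownames(edges) <- NULL
  edges
}

#' Permutation test for low-mode enrichment next to high expressors
#'
#' Tests whether genes adjacent to high-mode genes are disproportionately
#' low rather than off. The statistic is the fraction of low genes among
#' the non-high genes adjacent (nearest genomic neighbor on either side)
#' to at least one high gene, overall and stratified by the orientation
#' of the gene pair (head-to-tail = same strand, tail-to-tail =
#' convergent, head-to-head = divergent). The null permutes the mode
#' labels across genes; the empirical p-value uses the +1 correction,
#' `p = (1 + #{null >= observed}) / (1 + iterations)`.
#'
#' @param modes A `mode_assignment` (or its `assignments` data.frame).
#' @param gene_models Gene models (chromosome/TSS/strand).
#' @param iterations Number of label permutations (>= 1).
#' @param seed Optional RNG seed.
#' @return Data.frame, one row per stratum (`overall`, `head_to_tail`,
#'   `tail_to_tail`, `head_to_head`): `observed` (low fraction),
#'   `null_mean`, `p_value`, `n_adjacent`.
#' @export
neighbor_permutation <- function(modes, gene_models, iterations = 1e6,
                                 seed = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a <- if (inherits(modes, "mode_assignment")) modes$assignments else modes
  edges <- .adjacency_edges(gene_models)
  ids <- unique(c(edges$a, edges$b))
  lab0 <- a$mode[match(ids, a$gene_id)]
  ea <- match(edges$a, ids); eb <- match(edges$b, ids)
  strata <- list(overall = seq_len(nrow(edges)))
  for (o in c("head_to_tail", "tail_to_tail", "head_to_head"))
    strata[[o]] <- which(edges$orientation == o)

  stat <- function(lab, sel) {
    is_high <- lab == "high"
    adj <- logical(length(ids))
    adj[ea[sel][is_high[eb[sel]]]] <- TRUE
    adj[eb[sel][is_high[ea[sel]]]] <- TRUE
    cand <- adj & !is_high & lab %in% c("low", "off")
    if (!any(cand)) return(c(NA_real_, 0))
    c(sum(lab[cand] == "low") / sum(cand), sum(cand))
  }
  obs <- lapply(strata, function(sel) stat(lab0, sel))
  null_ge <- numeric(length(strata)); null_sum <- numeric(length(strata))
  null_n <- numeric(length(strata))
  for (it in seq_len(iterations)) {
    lab <- sample(lab0)
    for (j in seq_along(strata)) {
      v <- stat(lab, strata[[j]])[1]
      if (!is.na(v)) {
        null_sum[j] <- null_sum[j] + v
        null_n[j] <- null_n[j] + 1
        if (!is.na(obs[[j]][1]) && v >= obs[[j]][1])
          null_ge[j] <- null_ge[j] + 1
      }
    }
  }
  data.frame(stratum = names(strata),
             observed = vapply(obs, `[`, numeric(1), 1),
             null_mean = ifelse(null_n > 0, null_sum / null_n, NA),
             p_value = (1 + null_ge) / (1 + iterations),
             n_adjacent = vapply(obs, `[`, numeric(1), 2),
             row.names = NULL)
}

#' Do genes that switch off move away from high expressors?
#'
#' Among genes that are low in condition A and off in condition B,
#' computes the fraction whose distance to the nearest high expressor
#' increased, against a randomized control in which the roles of the two
#' conditions are flipped per gene with probability 1/2; a chi-square
#' test compares the two 2x2 counts. An excess over the control indicates
#' that part of low-mode expression is driven by proximity to a high
#' expressor present in that condition.
#'
#' @param modes_a,modes_b `mode_assignment`s for the two conditions on a
#'   shared annotation.
#' @param gene_models Gene models.
#' @param seed Optional RNG seed for the control flips.
#' @return List: `n_transitions`, `observed_fraction`,
#'   `control_fraction`, `p_value`, `table`. `NULL` fractions (with
#'   message) when no low-to-off transition exists.
#' @export
transition_analysis <- function(modes_a, modes_b, gene_models,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  da <- nearest_high_distance(modes_a, gene_models)$distances
  db <- nearest_high_distance(modes_b, gene_models)$distances
  m <- merge(da, db, by = "gene_id", suffixes = c("_a", "_b"))
  tr <- m[m$mode_a == "low" & m$mode_b == "off", , drop = FALSE]
  if (!nrow(tr)) {
    message("no low-to-off transitions between the two conditions")
    return(list(n_transitions = 0L, observed_fraction = NA_real_,
                control_fraction = NA_real_, p_value = NA_real_,
                table = NULL))
  }
  inc_obs <- tr$distance_b > tr$distance_a
  flip <- stats::runif(nrow(tr)) < 0.5
  inc_ctl <- ifelse(flip, tr$distance_a > tr$distance_b,
                    tr$distance_b > tr$distance_a)
  tab <- rbind(observed = c(increased = sum(inc_obs),
                            not = sum(!inc_obs)),
               control = c(increased = sum(inc_ctl), not = sum(!inc_ctl)))
  p <- tryCatch(stats::chisq.test(tab)$p.value, error = function(e) NA)
  list(n_transitions = nrow(tr), observed_fraction = mean(inc_obs),
       control_fraction = mean(inc_ctl), p_value = p, table = tab)
}
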