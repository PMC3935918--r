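#' Simulate a gene annotation on linear chromosomes
#'
#' Draws gene structures (exon/intron counts and log-normal lengths) and
#' places the genes sequentially along chromosomes with log-normal
#' intergenic gaps and random orientations. Optionally plants a
#' neighborhood structure for the expression-bimodality analyses: genes
#' are pre-assigned off/low/high modes and, with probability
#' `couple_prob`, each low gene is placed immediately downstream of a high
#' gene with a short (1-5 kb) gap, so that coupled low genes are genomic
#' neighbors of high genes.
#'
#' @param n_genes Number of genes.
#' @param n_chrom Number of chromosomes (genes split evenly).
#' @param n_introns_fn Function of `n` returning intron counts per gene
#'   (default `3 + rpois(n, 4)`, a human-like median of ~7).
#' @param exon_meanlog,exon_sdlog Log-normal exon lengths, bp (default
#'   median 150 bp).
#' @param intron_meanlog,intron_sdlog Log-normal intron lengths, bp
#'   (default median 5 kb).
#' @param gap_meanlog,gap_sdlog Log-normal intergenic gaps, bp.
#' @param layout Optional planted neighborhood: list with `modes` (named
#'   proportions for `off`, `low`, `high`), `couple_prob` (probability a
#'   low gene is planted next to a high gene).
#' @param seed Optional RNG seed.
#' @return List with `gene_models` (named list of `gene_model`) and
#'   `modes` (data.frame `gene_id`/`mode`, or `NULL` without `layout`).
#' @export
simulate_annotation <- function(n_genes = 2000L, n_chrom = 4L,
                                n_introns_fn = function(n)
                                  3L + stats::rpois(n, 4),
                                exon_meanlog = log(150), exon_sdlog = 0.5,
                                intron_meanlog = log(5000),
                                intron_sdlog = 0.9,
                                gap_meanlog = log(30000), gap_sdlog = 0.8,
                                layout = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_int <- pmax(1L, n_introns_fn(n_genes))
  ids <- sprintf("g%05d", seq_len(n_genes))

  modes <- NULL
  order_idx <- seq_len(n_genes)
  couple_after <- rep(NA_integer_, n_genes)     # index gene must follow
  if (!is.null(layout)) {
    pr <- layout$modes[c("off", "low", "high")]
    mode <- sample(names(pr), n_genes, replace = TRUE, prob = pr)
    modes <- data.frame(gene_id = ids, mode = mode)
    high_idx <- which(mode == "high")
    low_idx <- which(mode == "low")
    if (length(high_idx)) {
      coupled <- low_idx[stats::runif(length(low_idx)) <=
                           layout$couple_prob]
      couple_after[coupled] <- sample(high_idx, length(coupled),
                                      replace = TRUE)
    }
    # placement order: free genes shuffled, coupled genes right after host
    free <- setdiff(seq_len(n_genes), which(!is.na(couple_after)))
    seq0 <- sample(free)
    order_idx <- integer(0)
    for (i in seq0) {
      order_idx <- c(order_idx, i, which(couple_after == i))
    }
  }

  # contiguous blocks per chromosome so placement order = genomic order
  chrom_of <- ceiling(seq_along(order_idx) /
                        ceiling(length(order_idx) / n_chrom))
  pos <- rep(0, n_chrom)
  models <- vector("list", n_genes)
  for (j in seq_along(order_idx)) {
    i <- order_idx[j]
    ni <- n_int[i]
    Lam <- pmax(20, round(stats::rlnorm(ni + 1L, exon_meanlog, exon_sdlog)))
    L <- pmax(60, round(stats::rlnorm(ni, intron_meanlog, intron_sdlog)))
    ch <- chrom_of[j]
    gap <- if (!is.na(couple_after[i]))
      round(stats::runif(1, 1000, 5000))
    else round(stats::rlnorm(1, gap_meanlog, gap_sdlog))
    start <- pos[ch] + gap
    widths <- as.vector(rbind(Lam, c(L, NA)))
    widths <- widths[!is.na(widths)]            # exon,intron,...,exon
    ends <- start + cumsum(widths)
    starts <- c(start, ends[-length(ends)])
    ex_rows <- seq(1, length(widths), by = 2)
    strand <- sample(c("+", "-"), 1)
    ex <- cbind(start = starts[ex_rows], end = ends[ex_rows])
    intr <- if (ni > 0)
      cbind(start = starts[-ex_rows], end = ends[-ex_rows])
    else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    if (strand == "-") {
      ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
      if (nrow(intr)) intr <- intr[rev(seq_len(nrow(intr))), , drop = FALSE]
      Lam <- rev(Lam); L <- rev(L)
    }
    models[[i]] <- structure(
      list(gene_id = ids[i], chromosome = paste0("chr", ch),
           strand = strand,
           tss = unname(if (strand == "+") ex[1, "start"] else ex[1, "end"]),
           exons = ex, introns = intr, exon_lengths = as.numeric(Lam),
           intron_lengths = as.numeric(L), n_introns = ni, coding = TRUE),
      class = "gene_model")
    pos[ch] <- max(ends)
  }
  names(models) <- ids
  list(gene_models = models, modes = modes)
}

#' Draw per-gene ground-truth lifecycle parameters
#'
#' Processing times are shared across genes (optionally with a log-normal
#' per-gene spread) while the fused synthesis rate `c0S` is log-normal,
#' optionally a two-component (bimodal) mixture. Defaults reflect
#' realistic bulk transcriptomes: `c0S` centered at 0.01 density units per
#' minute with a spread of several orders of magnitude, lariat formation
#' 90 s, exon ligation 45 s, excised-intron persistence 25 s, and an mRNA
#' lifetime of 2 h.
#'
#' @param gene_models Gene models (list).
#' @param T5,T3,Tgamma,Tmu Central processing times, seconds.
#' @param time_sdlog Log-normal per-gene spread applied to each time
#'   (0 = identical in every gene).
#' @param c0S_meanlog,c0S_sdlog Log-normal `c0S` (density per second).
#' @param c0S_bimodal Optional mixture: list with `meanlog` (length 2,
#'   low/high component), `sdlog` (length 2), `weight` (probability of the
#'   high component).
#' @param modes Optional mode table from [simulate_annotation()]: `off`
#'   genes get `c0S = 0`, `low`/`high` genes draw from the corresponding
#'   mixture component (requires `c0S_bimodal`).
#' @param Talpha Transcription time constant, s/bp.
#' @param seed Optional RNG seed.
#' @return Data.frame `gene_id`, `c0S`, `T5`, `T3`, `Tgamma`, `Tmu` with
#'   `Talpha` as an attribute.
#' @export
simulate_params <- function(gene_models, T5 = 90, T3 = 45, Tgamma = 25,
                            Tmu = 7200, time_sdlog = 0,
                            c0S_meanlog = log(0.01 / 60), c0S_sdlog = 2,
                            c0S_bimodal = NULL, modes = NULL,
                            Talpha = 1 / 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(gene_models, `[[`, character(1), "gene_id")
  n <- length(ids)
  draw_c0S <- function(m) {
    if (is.null(c0S_bimodal))
      return(stats::rlnorm(m, c0S_meanlog, c0S_sdlog))
    hi <- stats::runif(m) <= c0S_bimodal$weight
    comp <- ifelse(hi, 2L, 1L)
    stats::rlnorm(m, c0S_bimodal$meanlog[comp], c0S_bimodal$sdlog[comp])
  }
  if (is.null(modes)) {
    c0S <- draw_c0S(n)
  } else {
    if (is.null(c0S_bimodal))
      stop("mode-driven synthesis rates require c0S_bimodal")
    mode <- modes$mode[match(ids, modes$gene_id)]
    c0S <- numeric(n)
    c0S[mode == "low"] <- stats::rlnorm(sum(mode == "low"),
                                        c0S_bimodal$meanlog[1],
                                        c0S_bimodal$sdlog[1])
    c0S[mode == "high"] <- stats::rlnorm(sum(mode == "high"),
                                         c0S_bimodal$meanlog[2],
                                         c0S_bimodal$sdlog[2])
  }
  spread <- function(center) {
    if (time_sdlog > 0) stats::rlnorm(n, log(center), time_sdlog)
    else rep(center, n)
  }
  out <- data.frame(gene_id = ids, c0S = c0S, T5 = spread(T5),
                    T3 = spread(T3), Tgamma = spread(Tgamma),
                    Tmu = spread(Tmu), row.names = NULL)
  attr(out, "Talpha") <- Talpha
  out
}

# expected densities for every feature row of one gene
.expected_feature_densities <- function(feat, g, p, Talpha) {
  Lam <- g$exon_lengths
  L <- g$intron_lengths
  N <- g$n_introns
  Tp <- p$T5 + p$T3 + p$Tgamma
  d <- numeric(nrow(feat))
  waits_ex <- if (N > 0) .per_exon_waits(Lam, L, Talpha) else Talpha * Lam / 2
  waits_jx <- if (N > 0) .per_jxn_waits(Lam, L, Talpha) else numeric(0)
  cls <- feat$class
  i <- feat$ordinal
  sel <- cls == "EXN"
  d[sel] <- p$c0S * (waits_ex[i[sel]] +
                       (if (N > 0) p$T5 + p$T3 else 0) + p$Tmu)
  sel <- cls %in% c("INT", "INTBIN")     # mean over block via its midpoint
  if (any(sel)) {
    mid <- (feat$start[sel] + feat$end[sel]) / 2
    off <- if (g$strand == "+") mid - g$introns[i[sel], "start"]
           else g$introns[i[sel], "end"] - mid
    d[sel] <- p$c0S * (Talpha * (L[i[sel]] - off) + Tp)
  }
  sel <- cls == "INT3"
  d[sel] <- p$c0S * (Talpha * (feat$end[sel] - feat$start[sel]) / 2 + Tp)
  sel <- cls == "JXN5"
  d[sel] <- p$c0S * (Talpha * L[i[sel]] + p$T5)
  sel <- cls == "JXN3"
  d[sel] <- p$c0S * (p$T5 + p$T3)
  sel <- cls == "SPL" & feat$ordinal2 == i + 1L
  d[sel] <- p$c0S * (waits_jx[i[sel]] + p$Tmu)
  d
}

#' Simulate an RNA-seq snapshot from the forward model
#'
#' Computes every feature's expected density from the steady-state model
#' and draws per-feature read counts as Poisson variables with mean
#' `density * feature_bp * depth_factor / read_length`, where the depth
#' factor rescales the standard 10M x 35 bp library to the requested
#' depth. The whole-intron count is the sum of its bin counts (one
#' consistent realization); other feature classes are independent Poisson
#' views. In `noise = "none"` mode counts equal their expectations
#' exactly, which makes the full pipeline an exact round trip.
#'
#' @param gene_models Gene models (list), e.g. from
#'   [simulate_annotation()].
#' @param params Per-gene truth from [simulate_params()], or a single
#'   [lifecycle_params()] shared by all genes.
#' @param depth_reads,read_length Library size. Density normalization in
#'   [normalize_densities()] assumes the simulated genes sit inside a
#'   library of exactly this size.
#' @param n_bins Intron bins for slope fitting (default 100).
#' @param noise `"poisson"` or `"none"`.
#' @param emit_reads Also generate an alignment table (`chrom`, `start`,
#'   `length`, `strand`; splice reads carry the library key as `chrom`)
#'   with read positions drawn within each feature, for end-to-end tests
#'   of the read-assignment path.
#' @param d3_window 3'-intron window, bp.
#' @param seed Optional RNG seed.
#' @return Object of classes `synthetic_dataset` and `feature_counts`,
#'   directly consumable by [normalize_densities()]: `features` (with
#'   `rdbp`), `splice`, `gene_models`, `truth` (params plus per-gene
#'   waiting times and expected densities), `total_read_bases`, `reads`
#'   (if requested), `config`.
#' @export
simulate_dataset <- function(gene_models, params, depth_reads = 1e7,
                             read_length = 35L, n_bins = 100L,
                             noise = c("poisson", "none"),
                             emit_reads = FALSE, d3_window = 10000L,
                             seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "lifecycle_params")) {
    Talpha <- params$Talpha
    ids <- vapply(gene_models, `[[`, character(1), "gene_id")
    params <- data.frame(gene_id = ids, c0S = params$c0S, T5 = params$T5,
                         T3 = params$T3, Tgamma = params$Tgamma,
                         Tmu = params$Tmu)
    attr(params, "Talpha") <- Talpha
  }
  Talpha <- attr(params, "Talpha")
  if (is.null(Talpha)) Talpha <- 1 / 60
  fs <- enumerate_features(gene_models, r = read_length, n_bins = n_bins,
                           d3_window = d3_window)
  feat <- fs$features
  by_id <- stats::setNames(gene_models,
                           vapply(gene_models, `[[`, character(1),
                                  "gene_id"))
  dens <- numeric(nrow(feat))
  truth_rows <- vector("list", length(gene_models))
  split_idx <- split(seq_len(nrow(feat)), feat$gene_id)
  pidx <- match(vapply(gene_models, `[[`, character(1), "gene_id"),
                params$gene_id)
  for (gi in seq_along(gene_models)) {
    g <- gene_models[[gi]]
    idx <- split_idx[[g$gene_id]]
    p <- params[pidx[gi], , drop = FALSE]
    dens[idx] <- .expected_feature_densities(feat[idx, , drop = FALSE], g,
                                             p, Talpha)
    wt <- waiting_times(g, Talpha = Talpha)
    truth_rows[[gi]] <- data.frame(
      p, Tt_5SS = wt$Tt_5SS, Tt_INT = wt$Tt_INT, Tt_EXN = wt$Tt_EXN,
      slope = -p$c0S * Talpha, row.names = NULL)
  }
  depth_factor <- depth_reads * read_length / (1e7 * 35)
  lambda <- dens * feat$length * depth_factor / read_length

  feat$expected_density <- dens
  non_bin <- feat$class != "INT"
  feat$rdbp <- 0
  if (noise == "poisson") {
    feat$rdbp[non_bin] <- stats::rpois(sum(non_bin), lambda[non_bin]) *
      read_length
  } else {
    feat$rdbp[non_bin] <- lambda[non_bin] * read_length
  }
  # whole-intron counts: one realization shared with the bins
  int_rows <- which(feat$class == "INT")
  if (length(int_rows)) {
    if (n_bins > 0L) {
      binsum <- tapply(feat$rdbp[feat$class == "INTBIN"],
                       paste(feat$gene_id[feat$class == "INTBIN"],
                             feat$ordinal[feat$class == "INTBIN"]),
                       sum)
      key <- paste(feat$gene_id[int_rows], feat$ordinal[int_rows])
      feat$rdbp[int_rows] <- as.numeric(binsum[key])
    } else if (noise == "poisson") {
      feat$rdbp[int_rows] <- stats::rpois(length(int_rows),
                                          lambda[int_rows]) * read_length
    } else {
      feat$rdbp[int_rows] <- lambda[int_rows] * read_length
    }
  }

  spl <- fs$splice_library
  if (!is.null(spl)) {
    srow <- match(paste(spl$gene_id, spl$exon_a, spl$exon_b),
                  paste(feat$gene_id[feat$class == "SPL"],
                        feat$ordinal[feat$class == "SPL"],
                        feat$ordinal2[feat$class == "SPL"]))
    spl$rdbp <- feat$rdbp[feat$class == "SPL"][srow]
    spl$n_reads <- spl$rdbp / read_length
  }

  reads <- NULL
  if (emit_reads) {
    src <- feat[feat$class %in% c("EXN", "JXN5", "JXN3",
                                  if (n_bins > 0L) "INTBIN" else "INT") &
                  feat$rdbp > 0, , drop = FALSE]
    rows <- rep(seq_len(nrow(src)), src$rdbp / read_length)
    lo <- src$start[rows]
    hi <- pmax(lo, src$end[rows] - read_length)
    jx <- src$class[rows] %in% c("JXN5", "JXN3")
    lo[jx] <- src$boundary[rows][jx] - read_length + 1L
    hi[jx] <- src$boundary[rows][jx] - 1L
    starts <- lo + floor(stats::runif(length(rows)) * (hi - lo + 1))
    reads <- data.frame(chrom = src$chrom[rows], start = starts,
                        length = read_length, strand = src$strand[rows])
    if (!is.null(spl) && any(spl$n_reads > 0)) {
      sr <- rep(seq_len(nrow(spl)), spl$n_reads)
      reads <- rbind(reads, data.frame(chrom = spl$key[sr], start = 0L,
                                       length = read_length,
                                       strand = "+"))
    }
  }

  structure(list(features = feat, splice = spl, gene_models = gene_models,
                 truth = do.call(rbind, truth_rows),
                 total_read_bases = depth_reads * read_length,
                 reads = reads,
                 config = list(depth_reads = depth_reads,
                               read_length = read_length, n_bins = n_bins,
                               noise = noise, Talpha = Talpha,
                               d3_window = d3_window)),
            class = c("synthetic_dataset", "feature_counts"))
}

#' Counting-noise error experiment
#'
#' Quantifies, by Monte Carlo over single synthetic two-exon genes, the
#' relative error of the measured intron density, exon density, intron
#' slope, and solved processing times as a function of intron length,
#' total intron processing time, and sequencing depth. The slope here is
#' fit to all bins (no usability gates) so that every replicate yields an
#' estimate; errors are summarized as medians of `|estimate/truth - 1|`
#' per grid cell.
#'
#' @param L_grid Intron lengths, bp.
#' @param Tp_grid Total intron processing times, seconds (split among
#'   lariat formation, exon ligation, and intron degradation in the
#'   canonical 90:45:25 proportion).
#' @param depth_grid Library sizes, reads; the default brackets a deeply
#'   sequenced bulk library.
#' @param n_reps Replicates per grid cell.
#' @param c0S,Tmu,Talpha Shared lifecycle parameters; the default `c0S`
#'   is a robustly measured gene from the upper-middle of the usable
#'   slope range, so mid-grid cells land in the ~25% relative-error
#'   regime rather than at zero counts.
#' @param read_length,n_bins,exon_length Geometry of the synthetic gene.
#' @param seed Optional RNG seed.
#' @return Data.frame of class `noise_error_table`: one row per grid cell
#'   with `L`, `Tp`, `depth` and median relative errors `err_d_int`,
#'   `err_d_exn`, `err_slope`, `err_times` (mean over the three splicing
#'   times; `NA` when no replicate was solvable).
#' @export
noise_error_experiment <- function(L_grid = c(100, 1000, 10000),
                                   Tp_grid = c(6, 60, 600),
                                   depth_grid = c(1e7, 1e8, 1e9),
                                   n_reps = 50L, c0S = 6e-4,
                                   Tmu = 7200, Talpha = 1 / 60,
                                   read_length = 35L, n_bins = 100L,
                                   exon_length = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(L = L_grid, Tp = Tp_grid, depth = depth_grid)
  res <- lapply(seq_len(nrow(grid)), function(row) {
    L <- grid$L[row]; Tp <- grid$Tp[row]; depth <- grid$depth[row]
    fr <- Tp / 160
    p <- lifecycle_params(c0S, 90 * fr, 45 * fr, 25 * fr, Tmu, Talpha)
    wt <- waiting_times(c(exon_length, exon_length), L, Talpha)
    D <- predict_densities(p, wt)
    df <- depth * read_length / (1e7 * 35)
    nb <- max(3L, min(n_bins, floor(L / 2)))
    w <- L / nb
    mids <- (seq_len(nb) - 0.5) * w
    d_bin <- predict_intron_profile(p, L, mids)
    e_int <- e_exn <- e_slope <- e_times <- rep(NA_real_, n_reps)
    for (rep in seq_len(n_reps)) {
      n_bin <- stats::rpois(nb, d_bin * w * df / read_length)
      d_int_hat <- sum(n_bin) * read_length / (L * df)
      e_int[rep] <- abs(d_int_hat / D[["D_INT"]] - 1)
      n_exn <- stats::rpois(1, D[["D_EXN"]] * 2 * exon_length * df /
                              read_length)
      d_exn_hat <- n_exn * read_length / (2 * exon_length * df)
      e_exn[rep] <- abs(d_exn_hat / D[["D_EXN"]] - 1)
      y <- n_bin * read_length / (w * df)
      xc <- mids - mean(mids)
      slope_hat <- sum(xc * y) / sum(xc^2)
      e_slope[rep] <- abs(slope_hat / (-c0S * Talpha) - 1)
      sigma <- read_length - 1L
      n5 <- stats::rpois(1, D[["D_5SS"]] * sigma * df / read_length)
      n3 <- stats::rpois(1, D[["D_3SS"]] * sigma * df / read_length)
      d5 <- n5 * read_length / (sigma * df)
      d3 <- n3 * read_length / (sigma * df)
      if (slope_hat < 0 && d5 > 0 && d3 > 0 && d_int_hat > 0 &&
            d_exn_hat > 0) {
        tt <- solve_sample(c(D_5SS = d5, D_3SS = d3, D_INT = d_int_hat,
                             D_EXN = d_exn_hat), wt, -slope_hat / Talpha)
        e_times[rep] <- mean(abs(tt[c("T5", "T3", "Tgamma")] /
                                   c(p$T5, p$T3, p$Tgamma) - 1))
      }
    }
    data.frame(L = L, Tp = Tp, depth = depth,
               err_d_int = stats::median(e_int, na.rm = TRUE),
               err_d_exn = stats::median(e_exn, na.rm = TRUE),
               err_slope = stats::median(e_slope, na.rm = TRUE),
               err_times = stats::median(e_times, na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  class(out) <- c("noise_error_table", "data.frame")
  out
}
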