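#' Lifecycle parameter set
#'
#' Bundles the kinetic parameters of the steady-state mRNA lifecycle model.
#' All times are in seconds. The synthesis rate enters only as the fused
#' product `c0S` (normalized read density accumulated per second of feature
#' lifetime): the per-cell initiation rate `S` and the sample constant `c0`
#' are not separately identifiable from a single RNA-seq library.
#'
#' @param c0S Fused synthesis rate (density per second), >= 0.
#' @param T5 Lariat-formation time (cleavage of the 5' splice site after the
#'   intron is fully transcribed), seconds.
#' @param T3 Exon-ligation time (second catalytic step after lariat
#'   formation), seconds.
#' @param Tgamma Excised-intron (lariat) persistence time after excision,
#'   seconds.
#' @param Tmu Mature-mRNA lifetime after the final splice, seconds.
#' @param Talpha Transcription time constant, seconds per bp. The default
#'   1/60 corresponds to an elongation rate of 3.6 kb per minute.
#' @return An object of class `lifecycle_params`; `$Tp` holds the total
#'   intron processing time `T5 + T3 + Tgamma`.
#' @examples
#' p <- lifecycle_params(c0S = 1.667e-4, T5 = 90, T3 = 45, Tgamma = 25,
#'                       Tmu = 7200)
#' p$Tp  # 160 s
#' @export
lifecycle_params <- function(c0S, T5, T3, Tgamma, Tmu, Talpha = 1 / 60) {
  vals <- c(c0S = c0S, T5 = T5, T3 = T3, Tgamma = Tgamma, Tmu = Tmu,
            Talpha = Talpha)
  if (any(!is.finite(vals))) stop("lifecycle parameters must be finite")
  if (any(vals < 0)) stop("lifecycle parameters must be non-negative")
  structure(list(c0S = c0S, T5 = T5, T3 = T3, Tgamma = Tgamma, Tmu = Tmu,
                 Talpha = Talpha, Tp = T5 + T3 + Tgamma),
            class = "lifecycle_params")
}

#' @export
print.lifecycle_params <- function(x, ...) {
  cat("mRNA lifecycle parameters (seconds):\n")
  cat(sprintf("  c0S = %.4g /s   Talpha = %.4g s/bp (%.3g kb/min)\n",
              x$c0S, x$Talpha, 60 / x$Talpha / 1000))
  cat(sprintf("  T5 = %.4g  T3 = %.4g  Tgamma = %.4g  Tmu = %.4g  (Tp = %.4g)\n",
              x$T5, x$T3, x$Tgamma, x$Tmu, x$Tp))
  invisible(x)
}

# mean transcription waiting time of each exon (transcription order).
# Exon e <= N waits for the rest of itself (Lam/2 on average), downstream
# exons except the last, and downstream introns; the last exon carries a
# negative lag of half its own length. Cumulative tail sums keep it O(N).
.per_exon_waits <- function(Lam, L, Talpha) {
  N <- length(L)
  tail_ex <- rev(cumsum(rev(Lam)))            # sum(Lam[e:(N+1)])
  tail_in <- c(rev(cumsum(rev(L))), 0)        # sum(L[e:N]), 0 for e = N+1
  e <- seq_len(N)
  c(Talpha * (Lam[e] / 2 + (tail_ex[e + 1L] - Lam[N + 1L]) + tail_in[e]),
    -Talpha * Lam[N + 1L] / 2)
}

# mean waiting time of exon-exon junction s (joins exons s and s+1):
# transcription of exons/introns s+1 .. N; the last junction waits 0
.per_jxn_waits <- function(Lam, L, Talpha) {
  N <- length(L)
  tail_ex <- rev(cumsum(rev(Lam)))
  tail_in <- c(rev(cumsum(rev(L))), 0)
  s <- seq_len(N)
  Talpha * ((tail_ex[s + 1L] - Lam[N + 1L]) + (tail_in[s] - L[s]))
}

#' Transcription waiting times for the features of a gene
#'
#' Computes the mean "transcription waiting time" of each feature class:
#' the average time a base (or junction) of that class spends as part of a
#' nascent transcript before the event that starts its own processing clock.
#' Intervals are length-weighted exactly as densities are (total read-bases
#' over total bases), so squared lengths appear for introns and exons.
#'
#' For a gene with exon lengths `Lambda[e]` (e = 1..N+1, transcription
#' order) and intron lengths `L[i]` (i = 1..N):
#' * introns: `Tt_INT = Talpha * sum(L^2) / (2 * sum(L))`
#' * 5' splice sites: mean over introns of `Talpha * L[i]` (all splice-site
#'   features share the same effective length, read length minus one)
#' * 3' splice sites: 0 by construction
#' * exons: length-weighted mean of per-exon waits; exon e <= N waits for
#'   the rest of itself (half its length on average), all downstream exons
#'   except the last, and all downstream introns. The last exon instead
#'   carries a negative lag of half its own length: its bases are born
#'   after the last 3' splice site, so on average they wait that much
#'   *less* than the full `T5 + T3 + Tmu`.
#' * exon-exon junctions: equal-weight mean of per-junction waits, junction
#'   s waiting for exons and introns `s+1 .. N`; the last junction waits 0.
#'
#' @param exon_lengths Exon lengths in bp, transcription order; or a
#'   `gene_model` object, in which case `intron_lengths` is ignored.
#' @param intron_lengths Intron lengths in bp, transcription order.
#' @param Talpha Transcription time constant, seconds per bp.
#' @return An object of class `waiting_times`: list with `Tt_5SS`, `Tt_3SS`
#'   (always 0), `Tt_INT`, `Tt_EXN`, `Tt_EXNJXN`, `n_introns`.
#' @examples
#' wt <- waiting_times(exon_lengths = c(1000, 1000), intron_lengths = 6000)
#' wt$Tt_EXN  # 50 s: mean of 108.33 s (exon 1) and -8.33 s (last exon)
#' @export
waiting_times <- function(exon_lengths, intron_lengths = NULL,
                          Talpha = 1 / 60) {
  if (inherits(exon_lengths, "gene_model")) {
    g <- exon_lengths
    exon_lengths <- g$exon_lengths
    intron_lengths <- g$intron_lengths
  }
  Lam <- as.numeric(exon_lengths)
  L <- as.numeric(intron_lengths)
  n_ex <- length(Lam)
  N <- length(L)
  if (n_ex != N + 1L)
    stop("need one more exon than introns (got ", n_ex, " exons, ", N,
         " introns)")
  if (any(Lam < 1) || (N > 0 && any(L < 1)))
    stop("all feature lengths must be >= 1 bp")

  if (N == 0L) {
    # singleton exon: D_EXN = c0S * (Talpha*Lambda/2 + Tmu); no other features
    return(structure(list(Tt_5SS = NA_real_, Tt_3SS = 0, Tt_INT = NA_real_,
                          Tt_EXN = Talpha * Lam / 2, Tt_EXNJXN = NA_real_,
                          n_introns = 0L),
                     class = "waiting_times"))
  }

  Tt_INT <- Talpha * sum(L^2) / (2 * sum(L))
  Tt_5SS <- Talpha * mean(L)
  Tt_EXN <- sum(Lam * .per_exon_waits(Lam, L, Talpha)) / sum(Lam)
  Tt_EXNJXN <- mean(.per_jxn_waits(Lam, L, Talpha))

  structure(list(Tt_5SS = Tt_5SS, Tt_3SS = 0, Tt_INT = Tt_INT,
                 Tt_EXN = Tt_EXN, Tt_EXNJXN = Tt_EXNJXN, n_introns = N),
            class = "waiting_times")
}

#' @export
print.waiting_times <- function(x, ...) {
  cat("Transcription waiting times (s):\n")
  cat(sprintf("  5'SS %.4g | 3'SS %.4g | INT %.4g | EXN %.4g | EXN-JXN %.4g (N = %d)\n",
              x$Tt_5SS, x$Tt_3SS, x$Tt_INT, x$Tt_EXN, x$Tt_EXNJXN,
              x$n_introns))
  invisible(x)
}

#' Predict steady-state feature densities for a gene
#'
#' The forward model: every feature's normalized read density equals `c0S`
#' times its mean lifetime, the sum of its transcription waiting time and
#' the processing times it survives through:
#' \deqn{Slope_{INT} = -c_0 S\, T_\alpha}
#' \deqn{D_{5'SS} = c_0 S (T_{t,5'SS} + T_5)}
#' \deqn{D_{3'SS} = c_0 S (T_5 + T_3)}
#' \deqn{D_{INT} = c_0 S (T_{t,INT} + T_5 + T_3 + T_\gamma)}
#' \deqn{D_{EXN} = c_0 S (T_{t,EXN} + T_5 + T_3 + T_\mu)}
#' \deqn{D_{EXNJXN} = c_0 S (T_{t,EXNJXN} + T_\mu)}
#' The exon-junction density is computed as a consistency check but is not
#' used by the inversion ([solve_sample()]): with mRNA lifetimes of an hour
#' or more it carries almost the same information as the exon density.
#'
#' @param params A [lifecycle_params()] object.
#' @param wt A [waiting_times()] object for the gene.
#' @return Named numeric vector with elements `Slope_INT`, `D_5SS`, `D_3SS`,
#'   `D_INT`, `D_EXN`, `D_EXNJXN`.
#' @export
predict_densities <- function(params, wt) {
  stopifnot(inherits(params, "lifecycle_params"),
            inherits(wt, "waiting_times"))
  p <- params
  if (wt$n_introns == 0L) {
    return(c(Slope_INT = NA_real_, D_5SS = 0, D_3SS = 0, D_INT = 0,
             D_EXN = p$c0S * (wt$Tt_EXN + p$Tmu), D_EXNJXN = 0))
  }
  c(Slope_INT = -p$c0S * p$Talpha,
    D_5SS = p$c0S * (wt$Tt_5SS + p$T5),
    D_3SS = p$c0S * (p$T5 + p$T3),
    D_INT = p$c0S * (wt$Tt_INT + p$T5 + p$T3 + p$Tgamma),
    D_EXN = p$c0S * (wt$Tt_EXN + p$T5 + p$T3 + p$Tmu),
    D_EXNJXN = p$c0S * (wt$Tt_EXNJXN + p$Tmu))
}

#' Per-base intron density profile
#'
#' A base at distance `x` from the 5' end of an intron of length `L` is
#' part of nascent transcripts for `Talpha * (L - x)` and then survives the
#' whole intron processing time `Tp`, so its density is
#' `D(x) = c0S * (Talpha * (L - x) + Tp)`: a line falling from 5' to 3'.
#' The drop across the intron (the "guillotine blade") reads out synthesis
#' only; the 3'-terminal level (the "base") reads out `c0S * Tp`.
#'
#' @param params A [lifecycle_params()] object.
#' @param L Intron length, bp.
#' @param x Distances from the intron 5' end, bp; must satisfy
#'   `0 <= x < L`.
#' @return Densities at `x` (same length as `x`).
#' @export
predict_intron_profile <- function(params, L, x) {
  stopifnot(inherits(params, "lifecycle_params"), L >= 1)
  if (any(x < 0 | x >= L)) stop("positions must satisfy 0 <= x < L")
  params$c0S * (params$Talpha * (L - x) + params$Tp)
}

#' Intron-end and splice-site density differences, with lariat-degradation
#' variants
#'
#' Under the default model the excised lariat persists intact for `Tgamma`
#' and then vanishes, so the density drop between the intron's 5' and 3'
#' ends is `c0S * Talpha * L`, while the drop between the 5' and 3' splice
#' sites is `c0S * (Talpha * L - T3)`; the latter changes sign at
#' `L = T3 / Talpha`. Comparing the two drops empirically tests whether
#' exonucleolytic degradation of the excised lariat shapes the intron
#' profile, because degradation can alter intron-end abundances but never
#' the splice-site features (those are destroyed by the catalytic steps
#' themselves).
#'
#' The `model` argument selects how the excised lariat is degraded and
#' modifies the per-base profile accordingly. Writing `delta(x)` for the
#' post-excision survival of the base at distance `x` from the 5' end
#' (degradation sweeps at speed `v` bp/s):
#' * `"I"`   3'->5' exonuclease at the polymerase speed, `delta = (L-x)*Talpha`
#' * `"IIa"` 3'->5' at 10x polymerase speed, `delta = (L-x)*Talpha/10`
#' * `"IIb"` effectively instantaneous degradation after a delay `Tgamma`
#'   (the default model; no positional effect)
#' * `"IIc"` 5'->3' at 10x polymerase speed, `delta = x*Talpha/10`
#' * `"III"` 5'->3' at the polymerase speed, `delta = x*Talpha`
#'
#' The modified profile is `c0S * (Talpha*(L-x) + T5 + T3 + delta(x))` and
#' the model-specific intron-end drop is its value at `x = 0` minus its
#' value at `x = L`. The splice-site drop is identical for every variant.
#'
#' @param params A [lifecycle_params()] object.
#' @param L Intron length(s), bp.
#' @param model One of `"I"`, `"IIa"`, `"IIb"`, `"IIc"`, `"III"`.
#' @return List with `model`, `delta_D_ends` (per `L`), `delta_D_ss`
#'   (per `L`), and `profile`, a `function(x, L)` giving the modified
#'   per-base density.
#' @export
lariat_model_predictions <- function(params, L, model = c("IIb", "I", "IIa",
                                                          "IIc", "III")) {
  stopifnot(inherits(params, "lifecycle_params"))
  model <- match.arg(model)
  p <- params
  delta <- switch(model,
    I   = function(x, L) (L - x) * p$Talpha,
    IIa = function(x, L) (L - x) * p$Talpha / 10,
    IIb = function(x, L) rep(p$Tgamma, length(x)),
    IIc = function(x, L) x * p$Talpha / 10,
    III = function(x, L) x * p$Talpha)
  profile <- function(x, L) {
    if (any(x < 0 | x > L)) stop("positions must satisfy 0 <= x <= L")
    p$c0S * (p$Talpha * (L - x) + p$T5 + p$T3 + delta(x, L))
  }
  dd_ends <- vapply(L, function(l) profile(0, l) - profile(l, l), numeric(1))
  dd_ss <- p$c0S * (p$Talpha * L - p$T3)
  list(model = model, delta_D_ends = dd_ends, delta_D_ss = dd_ss,
       profile = profile)
}
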