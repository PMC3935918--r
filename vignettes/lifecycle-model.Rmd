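---
title: "The steady-state mRNA lifecycle model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The steady-state mRNA lifecycle model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnalifecycle)
```

## The model and its assumptions

The package treats a total RNA-seq library as a steady-state snapshot:
every RNA species is present in proportion to its mean lifetime, so
genomic features that live through different stages of the mRNA
lifecycle acquire different read densities. The assumptions are:

* a gene is N+1 exons separated by N introns; transcription initiates
  at a constant per-gene rate S and elongates uniformly at
  1/T~α~ = 60 bp/s (3.6 kb/min), with no locus-specific pausing;
* each intron is spliced independently and in two steps: the 5' splice
  site is cleaved (lariat formation) a time T~5~ after the intron is
  fully transcribed, and the 3' splice site a time T~3~ later (exon
  ligation);
* the excised intron persists a further time T~γ~ and then disappears;
  by default its degradation does not reshape the intronic profile
  (variants with directional exonucleases are available, see below);
* the mature mRNA survives a time T~μ~ after the final ligation;
* densities are proportional to lifetime through a sample constant c~0~
  that is not separately identifiable: only the product c~0~S enters
  anywhere.

Under these assumptions the per-base intron density is the falling line
`c0S (Tα (L - x) + Tp)` with `Tp = T5 + T3 + Tγ`, and class-averaged
densities are linear in the four processing times with known
geometry-dependent transcription waiting times (length-weighted, which
is why squared lengths appear: both a feature's mean waiting time and
its base count grow with its length). The exon–exon junction equation
is computed by the forward model but deliberately excluded from the
inversion: with mRNA lifetimes of an hour or more it is numerically
almost identical to the exon equation and adds no information, so it is
exposed as a consistency check only.

The model is strictly a steady-state description; induction transients
and promoter-proximal pausing are out of scope, which is why intron
slopes are only fit to introns at least 5 kb long that start more than
5 kb from the transcription start site.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `Talpha` | transcription time constant | s/bp | 1/60 |
| `c0S` | fused synthesis rate | density/s | estimated per gene |
| `T5`, `T3`, `Tgamma`, `Tmu` | processing times | s | estimated |
| `r` | read length | bp | 35 |
| library standard | density normalization | read-bases | 10⁷ × 35 |
| `n_bins` | bins per intron for slope fits | – | 100 |
| `min_bins` | nonzero bins required per fit | – | 20 |
| `min_intron_bp`, `min_tss_dist` | intron usability | bp | 5000, 5000 |
| `tdr_min`, `max_d_int`, `max_d_exn` | gene gates | – | 0.90, 1.00, 50 |
| `sample_size`, `max_samples`, `min_valid` | Monte Carlo | – | 5, 2·10⁵, 2000 |

Densities divide by 0.35 to give RPKM. All times are seconds
internally; summaries print seconds.

## The estimation pipeline

1. **Gene models**: all transcripts of a gene are merged by exon union,
   so any base exonic in any isoform is exonic (this resolves
   retained-intron ambiguity in favor of exons before counting).
   Introns are the gaps; ordinals follow transcription direction.
2. **Quantification**: uniquely-mapped strand-specific reads are
   counted into exons, introns, 100 equal intron bins, the 3'-most
   10 kb of each intron, boundary-crossing windows of r−1 bp for the 5'
   and 3' splice sites, and a splice-junction library of all exon
   pairs. Densities are read-bases per mappable base, renormalized to a
   10M × 35 bp library.
3. **Slopes**: per-intron OLS on nonzero bins, spike removal, and the
   true-discovery rate TDR = 1 − Φ(slope/SE); gene slopes are the
   arithmetic mean of usable intron slopes with quadrature-propagated
   SE (weights L·TDR², configurable to equal weights).
4. **Inversion**: random samples of five eligible genes; per sample the
   slope magnitudes are geometrically averaged into c~0~S (after adding
   Gaussian noise with each gene's slope SE), nonzero densities are
   geometrically averaged per feature class, the triangular system is
   solved in closed form, and only all-positive solutions are kept,
   until 2,000 are accumulated or 200,000 samples are drawn.

## What the simulator emulates — and what it does not

`simulate_annotation()` and `simulate_dataset()` generate the study
conditions used throughout the tests: log-normal exon (median 150 bp)
and intron (median 5 kb, sdlog 0.9) lengths, 3+Pois(4) introns per
gene, genes laid head-to-tail on linear chromosomes with log-normal
gaps and random orientations, per-gene constant synthesis with c~0~S
log-normal centered at 0.01 per minute and spread over roughly three to
four orders of magnitude (optionally a bimodal mixture, optionally a
planted low-near-high neighborhood structure), linearly declining
intronic coverage, splice-site densities proportional to feature
lifetimes, and Poisson counting noise at a configurable depth
normalized to 10M 35-bp reads. Counts are drawn per feature as Poisson
read numbers; the whole-intron count is the sum of its bin counts so
slope and density estimates see one consistent realization, while other
classes are independent views. A read-level emission mode (`emit_reads`)
exercises the read-assignment path end to end.

The simulator does **not** model sequence-level library biases (GC,
hexamer priming), mappability gaps, alternative splicing, paired-end
fragments, or multimapping. Passing tests therefore demonstrate the
estimator's behavior under counting noise and the model's own
assumptions, not robustness to the library-preparation biases that
dominate real data; on real libraries the same pipeline inherits those
biases (the model's authorship of c~0~ makes absolute synthesis rates
unrecoverable regardless).

Simulation problem sizes in the tests were chosen to keep each
experiment's Monte Carlo error well below the tolerance it is checked
against: 2,000 genes at 10M reads for recovery, 40 ten-intron genes
with ~60 kb introns for meta-intron profiles, a 3×3×3 grid with 50
replicates for the counting-noise experiment, and 10⁴ permutations for
neighborhood enrichment.

## Numerical choices and degenerate inputs

* **Zero-SE fits** (noiseless data): TDR is defined as 1 for a negative
  slope, 0.5 for a flat one, 0 for a positive one — the limits of
  1 − Φ(z).
* **Spike bins**: a bin whose density exceeds 10× the median nonzero
  bin density is dropped; an intron with more than 5 spike bins is
  refused. The threshold is configurable; embedded non-coding RNAs are
  the typical cause.
* **Retained/shortened introns**: an intron is flagged when both its
  splice-site densities are closer on the log scale to the gene's exon
  density than to its own intron density, with a half-read pseudocount
  so zero counts stay finite. The log-midpoint rule is symmetric and
  scale-free.
* **Waiting-time aggregation** across a sample's genes uses the
  geometric mean, mirroring the density aggregation; this preserves the
  exact forward–inverse round trip on geometry-homogeneous cohorts. An
  arithmetic option exists, and the geometric path falls back to
  arithmetic for a component with non-positive values (possible for the
  exon waiting time of short last-exon genes).
* **Noisy slopes that land non-negative** are redrawn (up to 20 times)
  rather than discarding the whole sample; a sample that still contains
  a non-negative slope is dropped and counted.
* **Zero densities** are ignored in the per-sample geometric mean; a
  sample with a feature class entirely zero is discarded, as is any
  solution with a non-positive time.
* **Degenerate mixtures** in the bimodality analysis (components closer
  than two standard deviations, or no BIC advantage over one
  component) are flagged unimodal and produce no low/high split.
* **Permutation p-values** use the +1 correction,
  (1 + #{null ≥ observed})/(1 + iterations), so they are never zero and
  remain valid under exchangeability.
* **Overlapping same-strand genes** keep separate models; shared exonic
  bases are excised from the other gene's intron features so no base is
  counted as both exonic and intronic. Opposite strands are independent
  (the data are strand-specific).

## Lariat-degradation variants

Intron-end density differences (`c0S·Tα·L`) and splice-site differences
(`c0S·(Tα·L − T3)`, zero at L = T3/Tα) separate transcription from
processing. Because splicing destroys the splice-site features, no
lariat-degradation mechanism can alter the splice-site difference — but
directional exonucleolytic degradation would reshape the intron-end
difference. Five variants are implemented as closed-form per-base
survival terms (3'→5' or 5'→3' sweeps at 1× or 10× the polymerase
speed, or delayed instantaneous decay) and validated against a
discrete-event simulation of the molecular timeline in the test suite.

## Known limitations

Two systematic biases of the published estimation protocol are visible
in the recovery harness and are reported honestly rather than patched:

* **Sparse junction counts.** At 10M reads a typical eligible gene's
  splice-site features carry on the order of one read. The prescribed
  aggregation ignores zero densities, and the mean of a Poisson count
  conditional on being nonzero exceeds its unconditional mean, so
  splice-site densities — and with them T~5~, T~3~, and T~μ~ — are
  biased upward at this depth (recovered medians are high by roughly
  30–70% in the acceptance run). The bias disappears at higher depth
  (at 10⁸ reads junction densities are nearly unbiased), which matches
  the observation that splice-site quantification is counting-noise
  limited.
* **Heterogeneous-geometry aggregation.** Geometric-mean aggregation of
  densities and waiting times across genes with different geometries
  satisfies gm(T~t~ + T~p~) − gm(T~t~) > T~p~, inflating T~γ~ by
  roughly a quarter even on noiseless data. On geometry-homogeneous
  cohorts the round trip is exact to machine precision, which is the
  regression test that separates this structural property from
  implementation error.

The per-sample positivity filter partially compensates for both, and
the qualitative structure — the ordering T~5~ > T~3~ > T~γ~, fold
changes between paired conditions, and all relative (per-gene proxy)
quantities — is robust to them.
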