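# rnalifecycle

Inference of mRNA lifecycle kinetics — pre-mRNA synthesis rates and the
timescales of lariat formation, exon ligation, excised-intron
degradation, and mRNA decay — from a **single strand-specific total
RNA-seq experiment**, with no metabolic labeling, transcription
inhibition, or time course.

It is written for transcriptomics researchers who have ordinary bulk
total RNA-seq (rRNA-depleted, not poly-A selected) and want genome-wide
estimates of how fast transcripts are made, spliced, and degraded, plus
the diagnostics that go with them: meta-intron profiles for detecting
splicing perturbations, intron-density proxies for synthesis rate, and
analyses of the bimodal structure of gene expression.

## The model

At steady state, every RNA species is present in proportion to its mean
lifetime. A base at distance *x* from the 5' end of an intron of length
*L* is part of nascent transcripts for the transcription waiting time
*T*<sub>α</sub>(*L* − *x*) (with *T*<sub>α</sub> = 1/60 s/bp, an
elongation rate of 3.6 kb/min) and then survives the intron processing
time *T*<sub>p</sub> = *T*<sub>5</sub> + *T*<sub>3</sub> +
*T*<sub>γ</sub>, so its normalized read density is a falling line:

    D(x) = c0·S · [ Tα(L − x) + Tp ]

The slope reads out synthesis alone (Slope = −c0·S·Tα; as a rule of
thumb 3600·|Slope| is c0·S per minute), while the 3'-terminal level
reads out c0·S·Tp — the "blade" and "base" of the intronic profile.
Averaging each feature class of a gene, with length-weighted
transcription waiting times **T**<sub>t</sub> computed from the gene's
exon/intron geometry:

    Slope_INT = −c0S·Tα
    D_5'SS    = c0S·(T_t,5'SS + T5)
    D_3'SS    = c0S·(T5 + T3)
    D_INT     = c0S·(T_t,INT + T5 + T3 + Tγ)
    D_EXN     = c0S·(T_t,EXN + T5 + T3 + Tμ)
    D_EXNJXN  = c0S·(T_t,EXNJXN + Tμ)      (consistency check only)

Given c0·S from the intron slope, the remaining system is triangular in
(*T*<sub>5</sub>, *T*<sub>3</sub>, *T*<sub>γ</sub>, *T*<sub>μ</sub>)
and is solved in closed form. Because single-gene densities are noisy,
estimation aggregates random samples of five genes (geometric means of
slopes and nonzero densities, Gaussian slope-noise injection, and a
positivity filter on the solved times), yielding Monte Carlo
distributions for the four timescales.

## Worked example

Simulate a 500-gene snapshot at 10M 35-bp reads with the default truth
(T5 = 90 s, T3 = 45 s, Tγ = 25 s, Tμ = 7200 s, log-normal synthesis
rates), quantify it, and fit the model:

```r
library(rnalifecycle)
ann  <- simulate_annotation(n_genes = 500, seed = 42)
pars <- simulate_params(ann$gene_models, seed = 43)
ds   <- simulate_dataset(ann$gene_models, pars, depth_reads = 1e7, seed = 44)
dens <- normalize_densities(ds)
sl   <- gene_slopes(dens, ann$gene_models)
fit  <- snapshot_fit(dens, sl, ann$gene_models, min_valid = 500, seed = 45)
summary(fit)
```

```
Processing-time distributions over 500 valid Monte Carlo solutions
(28672 samples drawn; 95% quantile intervals; seconds)
   time geometric_mean  median    lower   upper
     T5         150.23  151.41   55.838   349.2
     T3          29.51   36.84    1.866   142.1
 Tgamma         19.78   24.38    1.034   103.5
    Tmu        9056.00 9045.41 5724.870 15215.9
```

Lariat formation comes out slowest, exon ligation faster, intron
degradation fastest, and the mRNA lifetime is around 2.5 hours — the
expected ordering, with medians within a factor ~1.7 of the simulated
truth at this depth (splice-site features carry roughly one read per
gene at 10M reads, which biases the small-sample aggregation upward;
see the methods vignette). Per-gene relative synthesis and stability
come from the 3'-intron proxy:

```r
d3 <- compute_d3int(dens)$per_gene
head(stability_and_lifetime(dens, d3), 3)
#>   gene_id synthesis_proxy     D_EXN stability
#> 1  g00001     0.019356230 0.8705357  44.97445
#> 2  g00002     0.001221671 0.0000000   0.00000
#> 3  g00003     0.014020291 0.3564815  25.42611
```

A thin command-line front end over the same functions is installed at
`inst/cli/snapshot.R` (subcommands `simulate`, `quantify`, `slopes`,
`solve`).

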