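# agesplit

Separating **primary aging** from inflammation- and inactivity-driven
("secondary") gene-expression changes in a three-group multi-omics design.

## The problem

Age-related expression change in human tissue mixes two signals: intrinsic,
time-dependent ("primary") aging, and the footprint of chronic disease and
physical inactivity that accumulates with age.  A three-arm design separates
them: young healthy controls (**YH**), young patients with advanced
osteoarthritis (**YP** — inflammation/inactivity without age) and older
patients (**OP**).  Effects shared by YP and OP relative to YH are
pathology-driven; effects separating OP from *both* young groups, in the
same direction in OP vs YP and OP vs YH, are candidates for primary aging.

`agesplit` is a tested, reusable implementation of the computational core of
that workflow, for transcriptomics/proteomics analysts who want each stage
as an inspectable, recalibratable function rather than a black box:

* **Synthetic data with planted truth** — NB counts with pathology/primary
  effect classes, a TMT-style protein layer with transcriptional /
  post-transcriptional-only / buffered regulation modes and two kit batches,
  and promoter sequences with planted motifs. Every downstream stage has a
  recovery test.
* **Differential expression** — TPM, median-of-ratios size factors,
  method-of-moments NB dispersion with trend shrinkage, per-gene NB Wald
  tests (vectorized IRLS), BH correction, and DEG gates
  `padj < 0.01`, `|FC| >= 1.25`, `TPM > 1`; plus a simulation-based
  power/sample-size study.
* **Proteome statistics** — cross-kit batch normalization (batch means made
  equal to machine precision), strict >70% presence filter, one-way ANOVA on
  log2 reporter intensities with BH q-values, Tukey–Kramer post-hoc pairwise
  calls (`q < 0.05` and Tukey `p < 0.05`).
* **Integration** — protein–mRNA concordance classes
  ("protein UP–mRNA NS", ...), primary-aging gene selection
  (unidirectional change in both OP comparisons, with detected-but-flat
  proteins vetoing mRNA-only evidence), YH→YP→OP trajectory z-scores,
  hypergeometric gene-set overlap, PCA QC.
* **TFBS enrichment** — TRANSFAC PWM parsing, both-strand log-odds scanning
  with a background-calibrated threshold (site frequency ≤ 1 per 2000 bp),
  adjusted fold enrichment **FE_adj** (the 99% CI lower bound of the odds
  ratio, Woolf SE, Haldane–Anscombe correction) in site-frequency and
  promoter-count variants, one-sided binomial/Fisher tests, BH FDR, per-TF
  collapse, expressed-TF (OP TPM > 1) filter.

The core statistics in notation: counts are modelled
`K_gs ~ NB(mu_gs, alpha_g)` with `mu_gs = s_s * q_g * 2^(x_s * beta_g)`,
`Var = mu + alpha mu^2`; the Wald statistic is `beta_g / SE(beta_g)`.
Enrichment of a PWM with `k_fg` sites in `n_fg` scanned foreground bp vs
`k_bg`/`n_bg` background is summarized by
`FE_adj = exp(ln OR − z_0.995 · SE_lnOR)`, `OR` the 2×2 odds ratio.

## Worked example

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `06_power.R`).  A condensed session:

```r
library(agesplit)

design <- study_design(seed = 42)          # 10,000 genes; groups 15/8/37
sim  <- simulate_counts(design)            # counts + planted truth
ps   <- simulate_proteome(design, sim$counts)

prot <- anova_tukey(filter_proteins(batch_normalize(ps$proteins)))
de_op_yp <- run_de(sim$counts, c("OP", "YP"))
de_op_yh <- run_de(sim$counts, c("OP", "YH"))

sel <- select_primary_aging(de_op_yp, de_op_yh, prot)
nrow(sel)                                  # 140 genes (71 up, 69 down)
```

Scoring the selection against the planted truth (`analysis/04_integrate.R`
prints exactly this):

```
Primary-aging set: 140 genes (71 up, 69 down; 31 protein evidence)
Sensitivity 0.927, precision 0.993, pathology specificity 0.997
```

i.e. 92.7% of the 150 planted primary-aging genes are recovered, 99.3% of
selected genes are truly primary-aging, and 99.7% of the 300 planted
pathology genes (shared YP/OP effects) are correctly excluded.  The
power/sample-size study (`analysis/06_power.R`):

```
  n  power    fdr
  3 0.5832 0.0175
  5 0.9100 0.0158
  8 0.9929 0.0176
 12 0.9996 0.0159
```

showing the DEG gates pass power 0.8 between n = 3 and n = 5 per group and
reach ≈ 0.99 at n = 8 under the strong-effect regime (10% DE at fold change
2, dispersion 0.05).  The TFBS stage (`analysis/05_tfbs.R`) plants one motif
in the promoters of down-regulated primary-aging genes and recovers it at
rank 1 of 21 PWMs with FDR 2e-15; no decoy reaches significance.

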