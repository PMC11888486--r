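# cytocsf

Immune-cell profiling of pediatric cerebrospinal fluid (CSF) by flow
cytometry, as an end-to-end, testable R pipeline. The package is aimed at
cytometrists and neuroimmunology analysts who want to work with the
population definitions, composite scores and classifier evaluations used to
distinguish pediatric-onset multiple sclerosis (MS) from myelin
oligodendrocyte glycoprotein antibody-associated disease (MOGAD) and other
acquired demyelinating syndromes (ADS) — including when no patient-level
event data can be shared: a seeded synthetic cohort generator reproduces the
statistical structure of seven diagnosis groups (NIND, PIND, AIE, IDWM,
otherADS, MOGAD, MS) so every downstream stage runs without any download.

## What it computes

* **Synthetic cohorts** — per-donor event matrices over a 17-channel panel
  (16 markers + side scatter), with diagnosis-specific leukocyte
  compositions, a three-state Gaussian marker-expression model, donor-level
  Dirichlet composition jitter, lognormal CSF cell concentrations, an
  age-dependent naive-CD8 fraction, and zero-inflated antibody-secreting-cell
  (ASC) presence in MOGAD/otherADS.
* **Hierarchical gating** — a declarative gate tree (CD45+ leukocytes →
  PMN / CD14+ myeloid / T / B / NK / DC; CD4/CD8/DN/DP; CD27 × CD45RA
  naive/CM/EM/TEMRA; CXCR3 × CCR6 Th states; CD38+HLA-DR+ activation;
  CD25+CD127lo Treg; CD27hi CD38hi ASC) applied with fixed or
  mixture-estimated thresholds.
* **Population metrics** — frequencies under the parent / leukocyte /
  lymphocyte / T-cell denominators and absolute counts,
  `cells/mL = freq% / 100 × cells/µL × 1000`.
* **Diagnostic scores** — per donor:
  * AMR, the ASC to CD14+ myeloid frequency ratio;
  * coNCS, the CSF-only neuroinflammatory composite score
    `(cells/µL + 1) × B% × 100 / (CD14% × NKT%)` with its zero rules
    (any zero numerator or denominator factor ⇒ score 0);
  * the full NCS, which adds the blood CD56dim NK frequency to the
    denominator when available;
  * a PMN flag (frequency > 2 × the NIND mean), which is associated with
    MOGAD/otherADS and argues against MS.
* **Group statistics** — Wilcoxon rank-sum comparisons (exact for small
  tie-free samples), log10 fold-changes of medians, Spearman age trends.
* **ROC classification** — empirical ROC curves and trapezoidal AUCs for
  the AMR and coNCS classifiers over the MS-vs-MOGAD, MS-vs-otherADS and
  MS-vs-MOGAD/otherADS contrasts, with an independent Mann-Whitney AUC
  oracle.

## Worked example

```r
library(cytocsf)

cfg    <- build_default_config(c("NIND", "MS", "MOGAD"), master_seed = 1)
cohort <- simulate_cohort(cfg)
counts <- lapply(names(cohort$events), function(id) {
  th <- estimate_thresholds(cohort$events[[id]], "midpoint-mixture")
  apply_gate_tree(cohort$events[[id]], thresholds = th, donor_id = id)
})
names(counts) <- names(cohort$events)
tab <- population_table(counts, cohort$metadata)

cohort_summary(tab, "pct_leukocytes", "T", "NIND")
#>   group population measure            n median   min   max
#> 1 NIND  T          pct_leukocytes    33   66.7  58.8  75.6
```

The simulated non-inflammatory (NIND) cohort median of 66.7% CD3+ T cells
among leukocytes recovers the 67.3% the generator is parameterized with —
the whole simulate → threshold → gate → summarize chain is exercised, so
the agreement is a pipeline property, not an identity.

```r
scores <- compute_score_table(tab, cohort$metadata)
roc_summary(scores)$summary
#>   contrast             score   auc n_pos n_neg
#> 1 MS-vs-MOGAD          amr   1        15    10
#> 2 MS-vs-MOGAD          concs 0.987    15    10
#> 3 MS-vs-MOGAD/otherADS amr   1        15    10
#> 4 MS-vs-MOGAD/otherADS concs 0.987    15    10
```

Both classifiers separate simulated MS from MOGAD essentially perfectly
under the default effect sizes (elevated ASC and depressed CD14+ myeloid
frequencies in MS). A Wilcoxon comparison of ASC frequencies:

```r
compare_groups(extract_feature(tab, "ASC", "pct_leukocytes"),
               "ASC:pct_leukocytes", list(c("MS", "MOGAD")))
#>   feature            group_a group_b n_a n_b median_a median_b log10_fc   U        p stars
#> 1 ASC:pct_leukocytes MS      MOGAD    15  10     1.33        0      Inf 150  2.9e-05  ****
```

(The infinite fold-change flag records that the MOGAD median ASC frequency
is exactly zero — ASCs are absent in half the simulated MOGAD donors by
construction.)

A command-line front-end wraps the same functions
(`Rscript inst/cli/cytocsf.R run-all --seed 1 --out-dir out/`), with
subcommands `defaults`, `simulate`, `gate` (CSV or FCS 3.0/3.1 input),
`summarize`, `score`, `compare`, `roc` and `run-all`.

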