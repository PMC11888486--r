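---
title: "Methods: simulated pediatric CSF immune profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated pediatric CSF immune profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocsf)
```

## Scope and rationale

Pediatric CSF immunophenotyping cohorts are small and their event-level
cytometry data are rarely shareable. `cytocsf` therefore couples the
analysis proper — hierarchical gating, frequency/count summaries, the AMR
and neuroinflammatory composite scores, nonparametric group comparisons and
ROC evaluation — to a seeded generator whose *defaults are the study
conditions*: the non-inflammatory (NIND) group is parameterized directly by
published cohort medians, and the disease groups by direction-constrained
values (inflammatory groups more cellular than NIND; strong B-cell
enrichment in demyelinating disease; MS with elevated antibody-secreting
cells, depressed CD14+ myeloid cells and near-absent granulocytes relative
to MOGAD/otherADS). Every downstream claim the test-suite makes is a
*recovery* statement about this generative model, not about patients.

## The generative model

Each donor in group $g$ is drawn as:

* **age** $\sim U(a_g^{lo}, a_g^{hi})$ (years, per-group ranges; NIND
  2.6–19.4);
* **concentration** $c \sim \mathrm{Lognormal}(\log m_g, s_g)$ in
  cells/µL. $m_g$ is the *median* (NIND 0.63; PIND 0.8; AIE 1.2; IDWM 0.7;
  otherADS 4.0; MOGAD 5.0; MS 3.0). $s_g = 0.9$ for NIND — chosen so 33
  draws span roughly 0.2–6 cells/µL — and 0.6 elsewhere (a ~10-fold 95%
  inter-donor range, matching the wide count ranges described for
  inflammatory CSF);
* **events** $n = \mathrm{round}(c \times V \times 1000)$ with simulated
  volume $V = 3$ mL, clamped to $[200, 50000]$, so a typical NIND donor
  yields ~1.9k events and inflammatory donors proportionally more;
* **composition**: a donor-level Dirichlet draw around the group's
  leukocyte composition over {T, CD14 myeloid, NK, DC, B, PMN, unassigned}
  with total concentration 200. Because the anchoring values are cohort
  *medians* (and concentration is median-parameterized), the Dirichlet is
  **median-centered**: component $k$ uses gamma shape
  $200\,p_k + \tfrac13$, exploiting the $\mathrm{median}[\Gamma(a)] \approx
  a - \tfrac13$ approximation so that the marginal median sits at $p_k$.
  Mean-centering instead biases the recovered medians of rare, right-skewed
  components (PMN, DC, B) well below their configured values;
* **lineage sub-structure** (all groups): CD4/CD8/DN/DP of T =
  67.2/23.6/8.4/0.7 (renormalized); memory fraction of CD4 = 0.978,
  age-independent; CM/EM/TEMRA = 0.80/0.18/0.02 of memory CD4 and
  0.55/0.35/0.10 of memory CD8 (CM-dominant); CXCR3×CCR6 states of memory
  CD4 = 0.60/0.15/0.10/0.15 (Th1-dominant); activated (CD38+HLA-DR+)
  fractions 0.02 / 0.05 of memory CD4 / CD8; Treg 0.05 of CD4; CD56+
  (NKT) overlay on 5% of T cells. The NKT fraction is this package's
  addition: the coNCS denominator contains the NKT frequency and its zero
  rule would otherwise null the score for every donor;
* **naive CD8 fraction**: $\mathrm{clamp}(0.74 - 0.0467\,\mathrm{age},
  0.02, 0.95)$ — a linear-with-clamp stand-in for the observed age trend,
  calibrated so a cohort of median age ~11 y recovers a memory-CD8 median
  near 77%. Chosen over smoother forms for testability (closed form,
  monotone, hand-checkable);
* **ASC zero-inflation**: with probability 0.5 a MOGAD/otherADS donor has
  *no* ASC among its B cells (ASC otherwise 10% of B; 12% in MS with no
  inflation; 2–3% in controls), reproducing the absent-in-half pattern that
  drives the AMR's discrimination;
* **intensities**: each channel draws from a three-state Gaussian in
  already-transformed (arcsinh-like) units — negative mean 0, positive 4,
  high 6, shared SD 0.5; side scatter low 0 / high 6, SD 0.5. The ≥6σ gap
  between negative and positive states makes hard threshold gating
  essentially error-free at the 4σ midpoint; the positive/high boundary is
  only a 2σ split each side, so ~2% of ASC events fall on the wrong side of
  a `hi` threshold per channel — immaterial at ASC abundances but worth
  knowing when reusing the `hi` machinery.

Donor seeds are `master_seed + donor_index` (donors indexed consecutively
across groups in configuration order, NIND first), so a NIND-only run and
the NIND donors of a full-cohort run coincide, and identical inputs are
bit-identical.

## Gating conventions

Gating is hard and binary: an event belongs to a node iff it satisfies the
node's predicates and all ancestors'; values exactly at a threshold count
as positive. Three decisions fill gaps that gate listings usually leave
implicit:

* **ASC** = CD19+ CD27hi CD38hi (the plasmablast/plasma-cell convention);
* **Treg** = CD4+ CD25+ CD127lo, the only plausible encoding on this panel;
* **lymphocytes** (a coNCS denominator) = T ∪ B ∪ NK within
  CD45+/CD14−/SSClo, excluding DCs — the conventional definition;
* the DC gate sits inside the SSC-low non-myeloid parent, and NKT
  (CD3+CD56+) is an *overlay* on T cells rather than part of the
  CD4/CD8/DN/DP partition.

`memory` nodes are unions of the CM/EM/TEMRA quadrants and `non_ASC` is
the complement of ASC within B, so the partition-conservation invariants
(quadrants summing exactly to their parent) hold by construction.

Thresholds: the defaults are 2.0 (primary) for every fluorescence channel,
5.0 (high) for CD27/CD38, and 3.0 for the side-scatter low/high split —
the midpoints of the expression model's states. `midpoint-mixture`
estimation instead fits, per channel, a two-component equal-variance
Gaussian mixture (`mclust`, model "E") and takes the midpoint of the two
component means; high thresholds are re-derived at primary + 3. Numerical
choices: fits use at most 2000 evenly spaced events (the hierarchical
initialisation is quadratic in $n$); a fit whose component means are
separated by less than three common SDs is treated as degenerate and falls
back to the channel's fixed default with a warning — on channels where
fewer than ~2% of events are positive, a two-component fit reliably splits
the majority mode instead of finding the rare population, and the fallback
is what keeps rare-population gating sane.

## Scores and statistics

The coNCS is computed as $((c + 1) \cdot B\% \cdot 100) / (CD14\% \cdot
NKT\%)$ — numerator multiplied out before the division — with B% and NKT%
as percent of lymphocytes and CD14% as percent of CSF cells; any zero
factor in numerator or denominator forces the score to exactly 0. The full
NCS divides additionally by the blood CD56dim NK frequency and is *absent*
(not zero) when that value is missing. The AMR uses ASC and CD14+
frequencies under a common denominator (% of leukocytes here; the ratio is
denominator-invariant), returns 0 when ASC = 0, and returns a flagged
infinite sentinel when ASC > 0 with CD14 = 0 — ranked above every finite
value in ROC construction, preserving the classifier's ordering semantics
instead of erroring.

Wilcoxon comparisons use the exact rank-sum distribution for tie-free
samples with $n_A n_B \le 400$ and the tie-corrected normal approximation
(continuity-corrected) otherwise; a fully tied pooled sample reports
$p = 1$. No multiplicity correction is applied by default (matching how
such panels of comparisons are usually presented); Benjamini–Hochberg is
available behind a flag. The age trend uses Spearman correlation — no
particular functional form is assumed, only monotonicity. ROC curves place
thresholds at every distinct score value; the trapezoidal AUC is checked
against an independently coded Mann–Whitney pair fraction (ties one half)
to $10^{-9}$ in the test-suite.

## What the generator does and does not emulate

It emulates compositional structure, inter-donor spread, an age trend, and
score-relevant zero patterns. It does **not** simulate raw fluorescence,
spillover/compensation, doublets, debris, acquisition drift, non-Gaussian
expression (and with 6σ state separation, threshold placement is far more
forgiving than on real data), correlations between lineage fractions
beyond the Dirichlet's, or paired whole blood beyond a scalar CD56dim NK
column. Passing recovery tests therefore demonstrates the *pipeline's*
correctness and the *internal consistency* of the configured effect sizes;
it does not validate the biology of real cohorts.

## Sampling noise at cohort scale

The default cohort sizes are deliberately small (33 NIND, 15 MS, 10 + 10
MOGAD/otherADS, 7/6/4 controls). At these sizes some recovered cohort
medians have substantial seed-to-seed spread, quantified here because the
test-suite pins a fixed seed:

* the NIND **NK** median (4.3% population, 33 donors) has SD ≈ 0.3 pp, so
  a ±0.5 pp recovery band is a ~1.7σ band and fails for roughly one seed
  in seven;
* the NIND **memory-CD8** median inherits the cohort's median-age noise
  (SD ≈ 1.1 y → ≈ 5 pp), so a ±5 pp band is a ~1σ band;
* the ADS-vs-AIE B-cell enrichment fold-change compares against an
  $n = 6$ arm with lognormal concentrations; its expectation under the
  defaults is ~12 but values below 10 are common.

These are properties of the configured study conditions, not bugs; the
recovery tests report them honestly at their fixed seed, and
`scripts/acceptance.R` recomputes everything at any chosen seed.

## Problem sizes

The standard runs used throughout the tests and the acceptance script are
the 85-donor default cohort (~0.2–15k events per donor, ~300k events
total), gated per donor with per-channel mixture fits — a few seconds on a
single core — and property suites on thousands of small randomized
instances.
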