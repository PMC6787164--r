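---
title: "Methods: multi-cohort signature discovery, scoring and clinical validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort signature discovery, scoring and clinical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk expression cohorts of solid tumors — hepatocellular carcinoma being the
motivating case — are typically scattered over many small datasets measured
on different platforms, each with its own location and scale per gene.
`metasig` implements a workflow for asking, across such heterogeneous
cohorts: *which gene programs are consistently suppressed in tumors relative
to adjacent normal tissue, and does their suppression track disease severity
and survival?*

The workflow has five stages, each usable on its own:

1. **Within-dataset Z-score normalization and pooling.** Every gene is
   standardized across all samples of one dataset (tumor and normal
   together) using the sample SD (denominator $n-1$); the standardized
   matrices are then column-concatenated over the genes shared by all
   datasets. Standardizing within each dataset removes per-platform
   location/scale differences while preserving the tumor-vs-normal contrast
   as a mean shift in Z-units.
2. **Pooled differential testing.** Each gene is compared between tumor and
   normal samples of the pooled matrix with a classical two-tailed
   equal-variance (Student) *t*-test, Bonferroni-corrected with multiplier
   equal to the number of genes actually tested. Directional top lists
   (default $n = 1000$, adjusted $p < 0.05$) feed the later stages.
3. **Signature construction.** The top downregulated list is intersected
   with pathway gene sets, then filtered by an enzyme-role annotation
   (catabolic / anabolic / non-enzymatic / unknown) to produce a signature
   such as a catabolic gene signature, with per-gene provenance. Sub-
   signatures are split out per metabolic process, and survival-associated
   genes shared by three or more processes can be short-listed as candidate
   functional targets.
4. **Scoring and enrichment.** The *patient score* of a sample for a gene
   set is the sum of the sample's Z-scores over the member genes. Given a
   two-group split (normal vs tumor, or low vs high score), the *pathway
   score* is
   $$\mathrm{score} = s \cdot \log_{10}\lvert \bar{G_0} - \bar{G_1}\rvert,$$
   where $\bar{G_0},\bar{G_1}$ are the group means of patient scores and
   the sign $s$ is $-1$ if the set is higher in $G_0$, $+1$ if higher in
   $G_1$, and $0$ whenever the two-tailed equal-variance *t*-test comparing
   the groups has $p \ge \alpha$ (default $\alpha = 0.05$). Composite
   activity scores (e.g. an HDAC1 activity score) are arithmetic means of
   several sets' patient scores. A hypergeometric over-representation test
   stands in for web-service pathway enrichment.
5. **Clinical association.** Kaplan–Meier curves and the two-group log-rank
   (Mantel–Cox) test compare survival between median-split score groups;
   ordinal covariates (stage, grade, prognosis, vascular invasion) are
   compared by two-group *t*-tests between extreme levels; Pearson
   correlation relates regulator activity scores to target-gene expression.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.05 | probability | significance cutoff everywhere: Bonferroni-adjusted p in the differential stage, raw p in the sign rule, survival flags and covariate tests |
| `top_n` | 1000 | genes | length of each directional candidate list |
| `zdiff_threshold` | 1.96 | Z-units | two-sided 5% normal quantile for the single-pair rule; the inequality is strict, so a value exactly at the threshold is not flagged |
| `split_rule` | median | — | low/high grouping; ties at the median go to the low group (G0), deterministically |
| `floor` (pathway score) | 1e-12 | Z-units | lower clamp on the absolute group difference before `log10`, so an exact tie cannot produce `-Inf` |

The low/high cutoff for score splits is not a settled convention in this
kind of analysis; the median is the package default because it is
assumption-free and keeps groups balanced, and a tertile rule (bottom vs top
third) plus externally supplied labels are available alternatives. Group
splits are recorded in outputs so the rule in force is always auditable.

# The single-pair Z-difference rule

When a contrast offers only one profile per condition (e.g. one treated and
one control sample), no *t*-test is possible. Each profile is standardized
across genes *within the sample*, and a gene is called differential when
$\lvert Z_{\mathrm{treated}} - Z_{\mathrm{control}}\rvert > 1.96$. This is a
heuristic, not a calibrated test: it flags genes whose relative rank within
the sample changed strongly, and is provided for parity with single-sample
contrasts in public datasets.

# What the synthetic cohort generator emulates

`generate_cohorts()` produces the study conditions that the analysis
assumes, with full ground truth for recovery testing:

* **Multiple heterogeneous cohorts.** Each dataset applies a per-gene
  additive offset $\mathcal{N}(0, \sigma_{\mathrm{off}})$ and multiplicative
  scale $\mathrm{Unif}(0.5, 2)$ to a shared signal, so pooling raw values
  would be dominated by platform effects — within-dataset Z-scoring is
  *necessary*, exactly as when pooling public microarray series.
* **Planted differential modules.** A configurable number of genes is
  shifted down (and another set up) in tumors by `effect_size_sd`
  within-dataset SD units (default 1.5, a strong but realistic bulk
  expression effect; the default module size of 100 genes mirrors a
  ~hundred-gene catabolic signature).
* **A regulator program.** `regulator_set_size` genes (default 20) share a
  latent factor with loading 0.7 and are additionally up-shifted in tumors,
  emulating a hyperactive signaling program; two designated target genes
  (members of the planted-down module, as a suppressed-target pair would
  be) load on the same factor with opposite sign, scaled so the Pearson
  correlation between the summed regulator score and each target is the
  configured `regulator_target_corr` (default −0.6, the magnitude typical
  of reported score–expression correlations).
* **Severity-linked clinical labels.** Stage, grade, prognosis and vascular
  invasion are drawn by thresholding independent noisy copies
  ($\sigma = 0.5$) of the *negated* standardized planted-signature score
  into tertiles, so the signature decreases stochastically with severity
  without asserting any specific clinical model.
* **Score-linked survival.** Event times are exponential with
  $\log h = \log h_0 + \beta z$, where $z$ is the standardized planted
  score and $\beta$ = `log_hazard_per_score_sd` (default −0.8: high
  signature score, longer survival). Censoring is independent with
  probability `censoring_rate` (default 0.3), observed at a uniform
  fraction of the latent event time.

All randomness flows from the single integer `seed`; identical config and
seed give bit-identical output.

**What it does not emulate** — and hence what passing recovery tests do
*not* establish about real data: probe-level artifacts and probe-to-gene
collapsing, correlated gene–gene background structure beyond the planted
factor, patient-level pairing of tumor/normal tissue, non-exponential
hazards, informative censoring, and missing-not-at-random clinical fields.
Effect sizes are a single shared constant rather than a fitted
distribution, because the real per-gene effect distribution of a suppressed
module is not identifiable from published summaries.

# Numerical and design choices

* **Z-scores over all samples of a dataset**, not per condition: pooling
  both conditions preserves the tumor/normal contrast as a mean shift;
  standardizing within condition would erase it. This choice is the
  package's documented convention (the alternative can be composed manually
  from the same primitives).
* **Zero-variance genes** become all-zero Z rows rather than being dropped,
  keeping gene universes aligned across datasets; they are reported in a
  `zero_variance` attribute and never reach significance.
* **Equal-variance Student *t*-test** rather than Welch, matching the
  classical "Student's t-test" convention of this analysis style; after
  Z-normalization group variances are near 1 anyway, making the distinction
  marginal.
* **Bonferroni multiplier** = genes actually tested in the pooled matrix
  (not the platform probe count): only tested hypotheses are corrected.
* **Top-list ranking key**: adjusted p ascending, ties broken by
  $\lvert\text{mean difference}\rvert$ descending, then gene id — fully
  deterministic.
* **Pathway-score magnitude** is applied literally: absolute group
  differences in $(0,1)$ give negative magnitudes. The formula targets
  patient scores summed over many genes, where the group difference is
  typically far above 1; the floor of $10^{-12}$ only guards the
  pathological exact tie (which cannot co-occur with a significant p).
* **Degenerate two-group tests**: identical constant groups give $t = 0$,
  $p = 1$; zero pooled spread with unequal means gives $p = 0$. Both
  conventions are continuous limits of the ordinary cases.
* **Log-rank ties** use the standard aggregated-table (hypergeometric
  variance) formulation; the implementation is cross-checked against the
  `survival` package to $10^{-8}$ in the test suite.
* **Survival-flag direction** is read from the two groups' KM curves at the
  median follow-up time — a single, deterministic comparison point.
* **Covariate pairwise tests are uncorrected by default** (extreme-pair
  comparisons reported as raw p, as conventional for per-panel clinical
  contrasts); any `p.adjust` method can be switched on.
* **Enzyme roles come from a user-supplied annotation table**, because
  role assignment in the motivating analyses is a literature-curation step
  that cannot be recomputed; genes annotated `unknown` are conservatively
  excluded from role-filtered signatures. `example_cascade()` builds an
  in-code fixture shaped like a real discovery run (159 pathway genes, of
  which 119 enzymes: 110 catabolic + 9 anabolic) for demonstrations and
  tests.

# Problem sizes used in validation

The package validates itself on simulation scales chosen to be informative
yet quick: recovery of a 100-gene planted module uses 4 datasets × 10,000
genes × (40 tumor + 40 normal); type-I control uses 2 × 2,000 genes ×
(25 + 25); the null enrichment matrix uses 20 replicate studies of 2 × 300
genes with five random 20-gene sets; the end-to-end chain runs the default
configuration (4 × 5,000 genes, 50 + 50 per dataset). These sizes put
standard errors well inside the asserted bounds while keeping a full run in
tens of seconds.

# Known limitations

* The pathway score's log-magnitude is scale-dependent (it inherits the
  gene-set size through the patient-score sum), so scores are comparable
  across cohorts for the *same* set, not across sets of very different
  size.
* Bonferroni control is deliberately conservative; with few samples per
  cohort true effects of modest size will be missed rather than
  false-discovered.
* The log-rank implementation covers the two-group, 1-df case only; no Cox
  modeling, stratification or trend tests.
* Survival flagging tests each gene marginally at a median split; it is a
  screening device, not a multivariable prognostic model.
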