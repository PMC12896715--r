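---
title: "Methods: deriving and auditing a prognostic EMT signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and auditing a prognostic EMT signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtsig)
```

## The problem

Epithelial-to-mesenchymal transition (EMT) in breast cancer is not a
binary switch: most tumours co-express epithelial markers (E-cadherin,
cytokeratins) and mesenchymal markers (Vimentin, α-SMA), occupying hybrid
states associated with plasticity and stemness.  `emtsig` implements two
complementary analyses around this observation:

1. **Signature derivation** — starting from independent EMT gene surveys,
   retain genes reported repeatedly (consensus filter), screen them for
   tumour-versus-normal differential expression (Welch test) and for
   prognostic value across three survival endpoints (optimal-cutpoint
   log-rank screen), and intersect the two screens requiring *direction
   concordance*: up-regulated genes whose high expression worsens
   prognosis, and down-regulated genes whose high expression improves it.
2. **Proteomic phenotype analysis** — normalise Western-blot densitometry
   to a housekeeping channel, correlate marker intensities (Pearson), and
   classify patients as epithelial, hybrid or mesenchymal from the
   Vimentin/E-cadherin ratio.

Both analyses are fully testable offline: synthetic generators produce
inputs with exactly the statistical structure each stage assumes.

## The statistical machinery

### Differential screen

For each gene the tumour and normal samples are compared by Welch's
unequal-variance t-test on `log2(TPM + 1)`:

$$t = \frac{\bar x_T - \bar x_N}{\sqrt{s_T^2/n_T + s_N^2/n_N}},$$

with Welch–Satterthwaite degrees of freedom and a two-sided p-value.  The
log transform stabilises the variance of TPM-like values and makes the
direction call (sign of the log-mean difference) a fold-change statement.
Significance is nominal at `alpha_de = 0.05` — the criterion used by the
public expression portals this screen mirrors — with an optional
Benjamini–Hochberg mode (`adjust = "BH"`).  Genes with zero variance in
both groups are reported as untestable rather than silently dropped.

### Optimal-cutpoint survival screen

For a gene and endpoint, every distinct observed expression value within
the interquartile range `[Q1, Q3]` is a candidate cutoff.  Each candidate
splits patients into low (`<= c`) and high (`> c`); the two arms are
compared by the standard log-rank test, and the cutoff minimising the
p-value is retained.  Numerical conventions, all pinned for
reproducibility:

* quartiles by R's default type-7 linear interpolation;
* split rule `low <= c < high`, so only distinct observed values yield
  distinct splits;
* ties in the minimum p resolved toward the smaller cutoff;
* candidates leaving fewer than 5 patients in either arm are skipped
  (degenerate splits carry essentially no information);
* a zero log-rank variance (e.g. all events concentrated in one tied
  block exhausting the risk set) returns `p = 1` with a degeneracy flag.

The hazard ratio of high versus low is the Pike O/E estimator
$\mathrm{HR} = (O_H/E_H)/(O_L/E_L)$ with confidence interval
$\exp(\log \mathrm{HR} \pm 1.96\sqrt{1/E_H + 1/E_L})$, computed from the
same hypergeometric tables as the log-rank test — deliberately
self-contained, with no proportional-hazards model fit.

**Minimum-p adjustment.**  A minimum over dozens of candidate splits is
anti-conservative: under the null its rejection rate at 0.05 is well
above 0.05 (the acceptance suite demonstrates this empirically).  The
source screens state that a multiplicity correction is applied but not
which one, so the package makes its own choice: a permutation adjustment,
which is assumption-free and directly testable.  Expression values are
shuffled against the fixed (time, event) pairs `B` times
(`n_permutations`, default 1000, minimum 100), the full scan is repeated
on each shuffle, and

$$p_{adj} = \frac{1 + \#\{\min p^{(b)} \le \min p_{obs}\}}{B + 1}.$$

The candidate set depends only on the multiset of expression values and
is therefore identical across permutations; the comparison is carried out
on the equivalent maximum chi-square scale.  The permutation scan is
implemented in C++ with an incremental histogram formulation (each
patient leaves the high group exactly once along the ascending candidate
sequence), keeping a 500-patient, 1000-permutation scan under a second.
Across-gene false-discovery control, when wanted, is an orthogonal second
step: apply `stats::p.adjust(..., "BH")` to the adjusted p-values.

### Three-endpoint coherence

A gene is called prognostic only when *all three* endpoints — distant
metastasis-free (DMFS), overall (OS) and relapse-free (RFS) survival —
are significant at `alpha_surv = 0.05` (on the adjusted p when
permutations are enabled) *and* the hazard-ratio directions agree.  Any
disagreement yields direction `none`.  This conjunction is deliberately
conservative: requiring coherent significance on three partially
dependent endpoints suppresses endpoint-specific flukes.

### Concordance intersection

The final signature intersects the significant diagnostic calls with the
coherent prognostic calls by exact gene symbol (no alias resolution — the
published tables print bare symbols, and silent synonym mapping would
manufacture or destroy overlaps).  Concordant classes are `up_worse` and
`down_better`; discordant overlaps (e.g. down-regulated yet hazardous)
are *retained and flagged* rather than discarded, because the audit trail
of a signature matters as much as its members.  On the packaged tables:

```{r}
sig <- derive_signature(read_diagnostic_table(emt_fixture("table1")),
                        read_prognostic_table(emt_fixture("table2")))
table(sig$class)
```

### Phenotype classification

Band intensities are normalised per patient by the β-actin (ACTB)
channel, cancelling gel-loading scale.  The Vimentin/E-cadherin ratio
partitions patients with a *closed* hybrid interval: ratio `< 1`
epithelial, `[1, 10]` hybrid, `> 10` mesenchymal — the closed middle
interval is the only reading consistent with the three published
boundary statements.  ND ("not detected") is missing, not zero; the
ratio conventions follow from the limit semantics: detected Vimentin over
undetected E-cadherin is unbounded above (mesenchymal side), the reverse
is 0 (epithelial side), both-ND is unclassifiable.  Multi-band markers
(Vimentin 50/40 kDa, E-cadherin 110/90 kDa) are summed per marker by
default; `mode = "dominant"` uses the strongest band, since it is not
stated whether the published ratios summed isoform bands.

## The synthetic generators

The generators define the study conditions under which the pipeline is
validated; they are first-class, tested code.

* **Expression**: per-gene log-normal values, `2^N(5, 1)` baseline on the
  log2 scale, tumour mean shifted by the gene's effect size.  Planted
  effects use ±2 log2 units at 200 tumour/200 normal samples.
* **Survival**: exponential event times under proportional hazards,
  `h_i = h_0 exp(Σ_g β_g z_{ig})` with `h_0 = 0.1` per unit time and
  standardized expression `z`; planted effects use `|β| = ln 2` per SD at
  500 patients per endpoint.  Censoring: with probability `censor_rate`
  (default 0.3) a patient draws a uniform administrative censoring time
  on `[0, max_follow_up]` (default 10), otherwise follow-up is capped at
  `max_follow_up`; `censor_rate = 0` with infinite follow-up yields pure
  event data.  The exponential law is the simplest satisfying
  proportional hazards; no competing risks, no time-varying effects.
* **Densitometry**: a three-component latent mixture with proportions
  (0.14, 0.63, 0.23) — the published cohort composition of 13/95
  epithelial, 60/95 hybrid, 22/95 mesenchymal patients — with log-normal
  marker intensities around class means separated on the log10 ratio
  scale (−0.6, +0.5, +1.6 for VIM−CDH1).  Both channels' class means
  co-increase across classes and the within-class noise carries a
  VIM–CDH1 correlation of 0.6, so marker intensities correlate
  positively across the cohort — the hybrid marker-coexistence finding
  the phenotype analysis rests on — while the ratio still separates the
  classes.  Per-patient
  loading noise cancelled by normalisation, and ND insertion at a
  configurable rate.
* **Study lists**: each gene is placed in exactly its specified number of
  the 14 studies, randomising only the assignment — the consensus filter
  must recover `{g : recurrence >= min_studies}` exactly.

What the generators do *not* emulate: real TCGA marginal distributions,
batch effects, probe-level artefacts, dependence between endpoints
measured on overlapping patients, or spatial/stromal contamination of
bulk densitometry.  Passing tests therefore certify the *machinery*
(calibration, recovery, bookkeeping), not the biology of any particular
cohort; the published database-derived counts are reproduced from the
packaged tables, not re-derived from public portals.

## Problem sizes and seeds

The validation suite uses: exhaustive brute-force comparison of the
cutoff scan on 200 random cohorts of up to 12 patients; 1000 null
simulations for log-rank type-I error; 300 null scans (B = 199) for the
minimum-p inflation/adjustment contrast; 20 independent end-to-end
replicates at the planted-effect sizes above (B = 1000); and 40
simulated 95-patient panels for the phenotype classifier.  These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands
while keeping a full run in a few minutes on one core.  All randomness
is seeded; generators restore the caller's RNG state.

## Known limitations

* The permutation adjustment is the package's own documented choice, not
  a reconstruction of the unspecified correction used by the public
  survival portal; adjusted p-values are therefore not comparable to that
  portal's printed values.
* The O/E hazard ratio at the *selected* cutoff inherits selection bias
  (it overestimates the per-SD effect); it is reported as the screen's
  effect summary, not as an unbiased estimate.
* Whether the published tables' p-values are nominal or corrected is not
  stated; the fixtures treat them as given.
* The printed worse-prognosis panel has 33 rows while the accompanying
  text counts 32 (CKMT1A/CKMT1B share identical statistics but are
  separate rows); the fixture reproduces the table verbatim and the
  package surfaces, rather than resolves, the discrepancy.
* Gene identity is the exact printed symbol; no nomenclature service is
  consulted.
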