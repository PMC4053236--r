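---
title: "Identifying molecular apocrine breast tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying molecular apocrine breast tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apocrineR)
```

## The problem

Estrogen-receptor-negative (ER−) breast cancers are heterogeneous. Within
them, *molecular apocrine* (MA) tumors form a subtype defined
transcriptionally by androgen-receptor (AR) pathway activation — AR and
FOXA1 overexpression together with AR-target genes — while *basal-like*
(BL) tumors express basal cytokeratins (CK5/6, CK17) and EGFR and lack the
AR program. Distinguishing the two matters clinically: MA tumors are
candidates for AR-directed therapy, and AR immunohistochemistry alone is an
insensitive surrogate (only about half of MA tumors stain for AR protein
despite uniformly high *AR* mRNA).

apocrineR implements the full identification pipeline: qRT-PCR ratio
quantification, data-driven positivity cutoffs from a two-component
Gaussian mixture, the multi-gene MA signature call, evaluation of composite
immunohistochemical (IHC) diagnostic rules with exact statistics, CART-style
rule discovery, Kaplan–Meier survival summaries, and a calibrated synthetic
cohort generator so that every stage is testable without patient-level
data.

## Expression quantification

Expression is measured as a normalized ratio against the TATA-box binding
protein (TBP) reference gene,

$$ r = s \cdot E^{\,Ct_{\mathrm{ref}} - Ct_{\mathrm{target}}}, $$

with amplification efficiency $E \in (1, 2]$ (default 2, a perfect
doubling per cycle) and scale $s$ (default 1000). The scale is a reporting
convention: all downstream logic is equivariant in $s$, and the default
puts ratios on the order of the conventional positivity cutoffs (ER 20,
HER2 7, AR/FOXA1 100). Neither the efficiency correction nor the scale
convention affects any conclusion, because cutoffs are derived on the same
scale as the data.

## Mixture-model cutoffs

Per-gene positivity cutoffs are estimated from the cohort itself. Ratios
span zero to several thousand, so the mixture is fitted on
$x = \log_{10}(r + 1)$; the pseudocount keeps zero ratios finite and is
negligible at the cutoff magnitudes involved. A two-component Gaussian
mixture

$$ f(x) = w_1\,\phi(x; \mu_1, \sigma_1) + w_2\,\phi(x; \mu_2, \sigma_2) $$

is fitted by EM (median-split moment initialization, tolerance $10^{-8}$
on the log-likelihood, at most 500 iterations, variance floor $10^{-4}$
with one re-initialization on collapse). The positivity cutoff is the
intersection of the two weighted component densities, solved in closed
form — a quadratic in $x$, degenerating to a linear equation when the
variances are equal; the root strictly between the means is taken and
back-transformed to the ratio scale. This is the point where a tumor
becomes more likely to originate from the high-expression component.

A fitted cutoff is only trusted when the sample is genuinely bimodal:
fits that do not converge, collapse, or whose separation
$(\mu_2 - \mu_1)/\max(\sigma_1, \sigma_2)$ is below 2 fall back to the
documented defaults (ESR1 20, ERBB2 7, AR/FOXA1 100, and 100 for the five
AR-related genes by the same relative-ratio convention) with a warning.
Without this guard, EM on a unimodal gene such as ESR1 in an all-ER−
cohort happily splits the single mode in two and produces a cutoff in the
middle of the negative population.

## The subtype calls

A tumor is called **MA** when all of the following hold on its expression
panel: ESR1 at or below its cutoff (ER−), AR above its cutoff, FOXA1 above
its cutoff, and at least 3 of the 5 AR-related genes (AGR2, ALCAM, SPDEF,
TFF3, UGT2B28A) above theirs. Missing AR-related values count against
positivity, never toward it. Two deliberate readings of the definition:
"three of five" is implemented as *at least* three, and the gene usually
listed as "TTF3" in signature descriptions is encoded under its HGNC
symbol TFF3 (trefoil factor 3), which is what the assay targets.

A tumor failing the MA criteria is a **BL candidate** when it lacks ESR1,
FOXA1 *and* ERBB2 expression; AR is deliberately not required to be
negative, because a minority (about 2/13) of basal-like tumors express AR
mRNA. Everything else is **unclassified**. By construction a panel can
never satisfy both rules (MA requires FOXA1 positivity, the BL rule its
absence).

The composite IHC signature in the ER− setting is **HER2(3+) OR
GCDFP15(+)**. Only an ASCO score of 3+ counts on the HER2 side:
ISH-amplified 2+ cases are HER2-positive for descriptive tables
(`call_her2()`), but the combined rule is defined on the 3+ score and the
package keeps those two notions distinct. A missing component is treated
as negative within the OR; a tumor missing both raises an error.

## Diagnostic statistics

Group comparisons use the exact two-sided Fisher test, computed by full
enumeration of the hypergeometric support with the point-probability rule
(tables no more probable than the observed one, with a $10^{-7}$ relative
tolerance for floating-point ties). Confidence intervals for sensitivity
and specificity are exact Clopper–Pearson intervals by beta inversion —
this choice reproduces the published intervals exactly, e.g. (85 to 99)
for 51/54. For a binary rule the ROC curve has a single interior vertex,
so AUC = (sensitivity + specificity)/2. One published value is not
reproducible by any exact interval: a specificity of 13/13 printed as
"100% (75 to 99)" — the exact upper bound is 100%, and the package reports
it as computed. No multiple-testing correction is applied, matching the
descriptive use of the tables.

Multiple correspondence analysis of the marker panel uses the standard
indicator-matrix decomposition: each binary marker contributes a
positive and a negative column, and the SVD of the standardized residual
matrix yields principal coordinates; rows with missing markers are
dropped listwise.

## Rule discovery by classification tree

`grow_tree()` implements CART-style recursive binary partitioning on
categorical markers with deviance splitting (misclassification optional),
stopping at pure nodes, nodes below twice the minimum leaf size
(default 5), or when no split reduces the risk. Ties between equally good
splits break lexicographically by marker name and then by level order, so
the tree is fully deterministic. Missing values follow the training
majority branch. `prune_tree()` computes the weakest-link cost-complexity
path and selects the penalty by stratified 10-fold cross-validation
scored with Laplace-smoothed held-out deviance (the smoothing keeps empty
leaf/label combinations finite); ties prefer the smaller tree. On the
packaged ER− cohort replica the tree recovers the composite rule: the
root split is HER2(3+) and the next split GCDFP15.

## Survival

`kaplan_meier()` is the product-limit estimator with Greenwood variance;
censorings tied with events are handled after the events. Curves are
evaluated as right-continuous step functions; two-group comparison uses
the one-degree-of-freedom log-rank statistic; median follow-up uses the
reverse Kaplan–Meier. Individual follow-up data for the study cohort are
not published, so the reported 5-year figures serve only as calibration
targets for the generator (below), never as exact assertions.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the pipeline assumes,
with defaults set to the published study conditions: 58 MA and 13 BL
tumors; log10-ratio components per gene and subtype (the BL AR component
centered on ratio 45, the MA component on 1500, giving a population
density intersection near the conventional AR cutoff of 100); IHC
positivity probabilities equal to the observed frequencies; and within
ER− MA tumors a jointly constrained HER2(3+)/GCDFP15 distribution whose
union probability is 51/54 (cells 21/54 both, 18/54 HER2-only, 12/54
GCDFP15-only). Infeasible joint settings — a union below a marginal or
above the marginal sum — are rejected with an explanatory error. BL AR
mRNA exceeds the cutoff with probability 2/13, matching the observed
AR-positive BL fraction. TP53 is nonfunctional in 50% of MA and all BL
tumors; PIK3CA carries a hotspot mutation in 11/58 of MA (1 E542K, 10
H1047R) and no BL tumors.

Survival is exponential per endpoint and arm with rate
$\lambda = -\ln S_5 / 60$, so the analytic five-year survival equals the
target exactly (DFS 66%/79%, OS 77%/73% for MA/BL), under independent
uniform administrative censoring on (0, 180) months, whose median (~90
months) approximates the reported 94-month median follow-up.

What the generator does *not* model — and hence what passing tests do not
demonstrate about real data: correlations between markers beyond the
HER2/GCDFP15 union constraint (the study publishes no joint
distribution); correlation between mRNA and IHC positivity for the same
gene; dependence between DFS and OS; Ct-level technical noise beyond the
lognormal ratio model; and clinical covariates. Ki67 is kept continuous
(truncated normal around the reported medians) with no positivity call,
since only medians are published.

`generate_fixture_replica()` is different in kind: a deterministic
reconstruction of the study's marker tables in which every printed
marginal and combined count is reproduced exactly (58/13 groups, ER− 54,
HER2(3+) 39 with five 2+ cases of which four ISH-amplified, GCDFP15+ 33,
AR+ 33/57 assessable, and within the 67 ER− tumors the 51/54 combined-rule
positives and 31/53 AR-positives). Cell-level assignments that the
publication does not fix are a documented reconstruction, and its stain
percentages are representative constants, not measurements. One ER−
HER2(3+) MA tumor carries the single missing AR/EGFR/CK5-6/CK17 value,
which is the only missing-data layout consistent with the printed
57-tumor denominators and the published Fisher p-values.

## Numerical choices and problem sizes

Key tolerances: EM log-likelihood tolerance $10^{-8}$; variance floor
$10^{-4}$; cutoff acceptance requires component separation at least 2 sd;
tie tolerance $10^{-7}$ (relative) in the Fisher rule; tree split
acceptance requires a deviance reduction above $10^{-9}$, with pruning
ties resolved toward smaller trees. Validation exercises use cohorts of
500 tumors (scaled 408/92) for cutoff-recovery and end-to-end
classification checks, 20 seeds for recovery medians, 50 seeds for
noise-pruning rates, 200 seeds for marker-frequency calibration, and 5000
tumors for pinning the survival calibration; at the study's own size
(58/13) classification accuracy is necessarily noisier than the ~99.4%
observed at n = 500.

## Known limitations

* The signature thresholds assume the ratio scale described above; data
  normalized differently must either supply their own cutoffs or rely on
  `derive_cutoffs()`, which needs a genuinely bimodal cohort (at least 10
  values per gene, and in practice far more).
* The BL-candidate rule is a screening rule, not a validated basal-like
  classifier; tumors can remain unclassified.
* The tree module handles categorical markers only (no surrogate splits,
  no continuous features); this matches its role of rediscovering
  marker-combination rules.
* The fixture replica is a reconstruction for verification, not patient
  data; analyses that depend on joint marker patterns beyond the
  published counts reflect the reconstruction choices documented above.
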