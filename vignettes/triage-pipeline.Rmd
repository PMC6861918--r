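---
title: "Methods: multi-criteria triage of repurposing candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria triage of repurposing candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbitriage)
```

## The problem

Connectivity-mapping screens nominate compounds whose induced expression
signatures match (or invert) a disease signature, but a concordance score
alone cannot say whether a compound will help or harm. This package
implements a staged triage that turns heterogeneous evidence — transcriptomic
concordance, pharmacokinetic feasibility, co-culture biomarker assays, and
qPCR target engagement — into a single weighted go/no-go score per compound,
and then evaluates in vivo monitoring biomarkers (longitudinal plasma
cytokines) with a nested cross-validated classifier. The worked case is drug
repurposing for traumatic brain injury (TBI) in a rat lateral
fluid-percussion model, with neuron–BV2-microglia co-cultures as the in vitro
stage, but every stage is configuration-driven and reusable.

## Signature construction

A differential-expression table (gene, log2 fold change, Benjamini–Hochberg
FDR) is filtered to a directioned signature: a gene enters iff
$|\log_2 \mathrm{FC}| > \log_2(1.5)$ **and** FDR $< 0.05$, both strict.
Genes whose FDR is absent (undetected expression) are excluded. The default
thresholds are the conventional fold-change-plus-FDR rule used to define the
acute (32 h) and chronic (3 month) cortical injury signatures; both are
arguments to `build_signature()`.

Identifier translation (`translate_ids()`) applies a user-supplied mapping
table (e.g. rat array IDs to human NCBI IDs). Unmapped genes are dropped and
counted; one-to-many mappings expand to all targets with the source's
direction. For many-to-one collisions we keep the entry with the largest
|log2FC| (deterministic tie-break by source identifier): the signature type
deliberately carries only gene, direction and effect size, so effect
magnitude is the only quantitative key available at translation time.
Collisions with conflicting directions are an error rather than silently
resolved — a signature must not assert both directions for one gene.

Percent-of-control conversion is $2^{\mathrm{log_2FC}} \times 100$, with
half-up rounding when integer output is requested, matching the convention
of printed effect sizes (a log2FC of 2.860 is 726% of control).

## Concordance banding

Compounds are ranked by the *absolute* concordance between their
perturbagen signature and the injury signature; percentile = rank/N with
rank 1 the strongest, and ties share the worst percentile of their block
(the conservative choice: a tie cannot lift a compound into a better band).
Bands award 5/4/3/2/1 points at percentiles ≤ 0.10/0.20/0.30/0.40/0.50 and
0 beyond; an absent score is 0. Two published ambiguities are resolved as
follows:

* the banded scale lists "> top 60%" for 0 points but defines no 50–60%
  band; we treat everything beyond the top 50% as 0, following the stated
  10%-per-point progression;
* ranking by absolute value would let a strongly *negative* concordance
  score points, yet the published scorecard gave a strong negative chronic
  concordance 0 points. `score_concordance()` therefore exposes
  `negative_scores_eligible` (default `FALSE`) so the published behaviour is
  the default while the footnote's literal reading remains available.

Ranking happens within the supplied table. The original screen banded
candidates against a full perturbagen library; reproducing those percentile
positions requires supplying the library-wide table, not just the
candidates.

## Co-culture assays

`percent_of_control()` is the ratio of treated to control well means × 100,
pooling wells across duplicate experiments (quadruplicates × 2 runs = 8
wells per cell). Significance against untreated control wells uses a
two-sided Mann–Whitney U test. For combined samples of ≤ 16 wells the
p-value is exact: the null distribution of the rank sum is built by dynamic
programming over doubled midranks (equivalent to enumerating all
$\binom{n_1+n_2}{n_1}$ assignments, and valid under ties, which the
classical exact tables are not). Larger samples use the normal
approximation with tie-corrected variance and continuity correction.
Completely tied data return p = 1: no separation is evidence of nothing,
not an error.

Banded points: for inhibition readouts (TNFα, nitrite) a significant
reduction earns 1–5 points as percent of control falls through
90/70/50/30/10, a significant *increase* above 100% earns −5, and 90–100%
earns 0; for viability a significant increase earns 1–5 through
115/150/200/250/300 and a significant decrease below 100% earns −5. Band
edges are inclusive on the favourable side (70% of control earns the
"< 70%" band's 2 points), which is what makes a 30% maximal reduction
reproduce its printed 0.3 weighted contribution. The published band table
prints a scrambled no-effect column for the neurotoxicity and viability
rows (200% / "> 115, > 100" in the 0/1 columns); we read the viability
no-credit zone as 100–115% with the first credit band above 115%,
consistent with a 135–147% viability gain earning exactly 1 point.
Per compound and analyte, the point value is banded at the strongest
significant concentration (minimum percent for inhibition, maximum for
viability), since the scorecard assigns one value per compound across
concentrations. Dose dependence (`dose_dependence()`) requires both a
stronger mean effect at the higher concentration and Mann–Whitney p < 0.05.

## Target engagement

Relative expression follows the ΔCt method,
$2^{-(Ct_\mathrm{gene} - Ct_\mathrm{Gapdh})}$. Treatment effects are
estimated on the $-\Delta Ct$ scale — log2 expression relative to the
reference — so the coefficient of the treatment indicator in
`lm(-dCt ~ treatment + batch)` *is* the log2 fold change; batch enters as
fixed-effect indicators absorbing constant between-run shifts (the
duplicated 16-h experiment gives two batches). We chose the regression on
$-\Delta Ct$ rather than a test on $2^{-\Delta Ct}$ values because the
log scale is where qPCR noise is approximately additive and because it
makes "log2FC" a direct model coefficient. A design in which every batch
contains only one treatment arm is rejected as inestimable rather than
silently dropping the batch term. Calls are two-sided at α = 0.05 with no
multiplicity correction across the 4 genes × 2 conditions (raw p-values
are reported, matching how such panels are conventionally read);
significant up/down-regulation maps to +1/−1 points, anything else to 0.
A target that fails to amplify is treated as absent data, not as an
extreme fold change.

## Composite score

The default scheme weights: acute and chronic concordance 10% each,
blood–brain-barrier penetration and water solubility 10% each (+5 yes, 0
unknown, −5 no), TNFα and nitrite 15% each, viability 20%, and eight
target-engagement slots (4 genes × 2 conditions) at 1.25% each. Weights sum
to 100%; each component's contribution is points × weight; subtotals are
*running* sums from the top of the column, and the total is the final
cumulative value. The achievable range is −3.6 to +4.6 (concordance cannot
go negative; pharmacokinetic and assay components bottom out at −5,
engagement at −1). Components missing from a compound's evidence contribute
0 with a warning — unassayed is not penalised. Ranking is by total, then
co-culture cumulative subtotal, then name, with sort keys rounded to 9
decimals so accumulated floating-point error cannot break a genuine tie
between weighted sums of the same points.

One published scorecard column (ionomycin) is internally inconsistent: its
printed component contributions sum to 0.1, not the printed −0.2 subtotal
(and the printed 0.2625 total follows the subtotals, not the components).
Recomputation reproduces the other columns exactly; the package makes no
attempt to "fix" the inconsistent column.

## Cytokine classifier

Longitudinal panels (12 plasma cytokines at days 7/14/28; 15 vehicle and 11
treated animals, the sizes of the in vivo trial) are turned into feature
matrices by `build_features()`: raw values per requested day, and — for
multi-day sets with `augment = TRUE` — successive differences and the
least-squares slope of value on actual day (units per day; actual days, not
visit index, so unequal spacing is respected). Single-day sets are raw
12-feature panels with no augmentation and no feature selection.

`nested_cv_evaluate()` implements leave-one-out on the outer level and
stratified 10-fold grid search on the inner level. Per outer fold: features
are standardized with the outer-training mean/SD only; the grid (gradient-
boosted-tree depth {2, 3}, learning rate {0.05, 0.1}, trees {50, 200},
crossed with the feature-selection hyperparameter) is scored by the AUC of
the pooled inner-validation predictions; the winner is refit on the full
outer-training set and the held-out animal is scored with its class-1
probability. Feature selection — top-percentile by one-way F statistic,
above-average-importance features of an extremely-randomized-tree ensemble,
or PCA by retained variance — is fitted strictly inside the inner loop.
Pooled held-out scores give one AUC per repeat; repeats (default 10) differ
in inner-fold randomization; the advancement gate is mean AUC > 0.75.
"Radial gradient boosted trees" in the source methods has no standard
meaning; we read it as ordinary gradient-boosted decision trees (xgboost),
behind a small fit/score wrapper so the classifier is replaceable.
Degenerate stratified splits (a class missing from an inner training fold)
are re-drawn. With a single-row grid the inner loop is skipped entirely —
there is nothing to search — which makes permutation calibration studies
affordable.

Permutation significance repeats the full nested evaluation on
label-permuted data; p = (1 + #{permuted AUC ≥ observed}) / (1 + N), the
finite-sample correction that cannot return 0. Note that with N
permutations the smallest attainable p is 1/(N+1), so at least 39
permutations are needed before p < 0.05 is reachable.

Two numerical behaviours of this design are worth knowing. First, pooled
leave-one-out AUC is *pessimistic* under the null (each held-out animal is
scored by a model trained with its own class underrepresented), so null
means sit slightly below 0.5 — the suite checks the mean over null panels
against the band [0.4, 0.6] rather than expecting 0.5 exactly. Second,
xgboost places split thresholds at observed feature values rather than
midpoints between classes, so a held-out animal lying exactly on its
class's boundary can fall on the wrong side of a perfectly separating
feature; perfect separation is only guaranteed to survive leave-one-out
when the separating feature has no within-class spread.

## Synthetic data

The generators exist so the full pipeline runs and is tested without any
wet-lab input; they emulate the statistical structure the analyses assume,
not the biology. Assay and cytokine values are log-normal (non-negative,
right-skewed, the standard shape of concentration data); qPCR noise is
Gaussian on the Ct scale. Defaults mirror the study design: quadruplicate
wells in duplicate experiments, two qPCR batches, 15 + 11 animals at days
7/14/28, vehicle cytokines declining towards day 28 with the treated-group
shift planted at day 28. Where the study fixes no value we chose plausible
scales once — well noise CV 0.1, Ct noise SD 0.3, animal intercept SD 0.3,
residual log SD 0.2 — and the recipes expose them. Each generator draws
from a per-stage substream of the master seed, so adding one generator
never perturbs another's output and regeneration is byte-identical.

What passing synthetic tests does *not* show: real plasma cytokines are
correlated across analytes and days beyond a shared animal intercept, real
plates have spatial effects, and real qPCR has amplification-efficiency
differences. The published real-data AUCs are not reproducible here because
the underlying animal-level measurements are not public; the ML tests are
therefore property-based (null calibration, planted-signal recovery) rather
than value-matching.

## Problem sizes

The test suite and drivers run, by choice, at: 1000 random small-sample
Mann–Whitney cases against a full-enumeration oracle; 12 null panels and
one planted panel (2 pooled-SD shift on 3 cytokines) at n = 15 + 11 with
the default grid and 10 repeats; 60 null calibration runs at 39
permutations each with a single-combination grid; and 100 paired
strong-vs-null end-to-end seeds.

## Known limitations

* Pharmacokinetic points are user-supplied judgments; nothing validates
  them.
* The concordance stage ingests scores; it does not submit signatures to a
  connectivity service.
* The ΔCt model assumes equal amplification efficiency between target and
  reference.
* Weights and band edges are configurable, but the default scheme encodes
  one group's priorities; the bounds (−3.6, 4.6) are properties of that
  default only.
* One compound's published 12–26% TNFα reduction implies 1 band point under
  any consistent reading of the band table, while its printed weighted
  contribution corresponds to 2 points; when fed printed points the engine
  reproduces the printed scorecard, but the raw-percent route cannot
  reconcile that one entry.
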