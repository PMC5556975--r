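---
title: "Detecting response shift with regression trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting response shift with regression trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proshift)
library(dplyr)
```

## The problem

Longitudinal patient-reported outcome (PRO) measures assume that respondents
use a stable internal yardstick. In practice the meaning of a self-evaluation
can change between assessments — *response shift* — through **recalibration**
(a changed internal standard), **reprioritization** (changed relative values
of life domains) or reconceptualization (a redefined construct). When this
happens, observed change scores mix true health change with shift, and
treatment effects can be masked or inflated.

proshift implements a tree-based route to detecting recalibration and
reprioritization in two-timepoint PRO data, developed here around the Dentine
Hypersensitivity Experience Questionnaire (DHEQ): 34 items on a 7-point
Likert scale, five subscales (restrictions, coping, social, emotional,
identity), totals in $[34, 238]$, higher = worse quality of life. The same
machinery applies to any instrument with a scale total, domain subscores and
an external clinical anchor.

## The regression-tree engine

The core is a least-squares CART-style engine written for this package,
because the analysis depends on details (surrogate splits, node-level
reporting, importance accounting over surrogate roles) that have to be
inspectable and testable:

* **Splitting.** Impurity is within-node SSE. The split of a node maximises
  $\Delta = \mathrm{SSE}(t) - \mathrm{SSE}(t_L) - \mathrm{SSE}(t_R)$ over all
  predictors; numeric candidate thresholds are midpoints of consecutive
  distinct observed values (cases $\le$ threshold go left), and categorical
  predictors use the exact least-squares shortcut (levels ordered by outcome
  mean, $k-1$ ordered cuts). Ties go to the predictor supplied earlier, then
  to the smaller threshold, making fits reproducible.
* **Stopping.** A node is splittable when it holds at least
  $\lceil 0.10\,N \rceil$ cases; children must keep at least
  $\lceil 0.05\,N \rceil$, with $N$ the root sample size. These are the usual
  CRT settings for small QoL trials; both fractions are controls.
* **Missing data.** Each internal node stores surrogate splits ranked by
  Breiman's predictive association
  $\lambda = \frac{\min(p_L,p_R) - (1 - \text{agreement})}{\min(p_L,p_R)}$;
  a case missing the primary splitter is routed by the first observed
  surrogate, and by the larger child when all surrogates are missing too, so
  every case reaches exactly one terminal. Surrogates with $\lambda \le 0$
  (no better than the majority guess) are discarded. Both orientations of a
  candidate surrogate are considered, so a mirrored copy of the primary
  splitter is still a perfect surrogate.
* **Validation.** Ten-fold cross-validation with seeded random folds
  estimates the risk (mean squared prediction error); an option balances
  folds across outcome quantiles, but plain random folds are the default
  reading of "roughly equal parts". All randomness flows from the single
  seed in `tree_controls()`, so repeated fits are bit-identical.
* **Pruning.** Cost-complexity (weakest-link) pruning with the 1-SE rule is
  available but **off by default**: the package reports the full tree, since
  in small samples pruning collapses exactly the small clusters with subtle
  shifts that the analysis is after. When on, subtrees are matched across
  folds through geometric means of consecutive complexity parameters, as is
  standard.
* **Model fit.** The root variance is the population (divide-by-$n$)
  variance, so a root-only tree has risk equal to the root variance and
  $S^2_x = 1 - \mathrm{risk}/S^2_y$ is an explained-variance proportion in
  $[0,1]$.

One deliberate behaviour: when predictor values are missing, a candidate
split's improvement is computed (unweighted) on the cases observed for that
predictor. This is the simplest contract consistent with surrogate routing,
and it is what the oracle tests pin down.

## Operationalising response shift

With week-8 clinical status as the anchor (DH+ requires at least two
non-adjacent sensitive teeth, where sensitive means tactile threshold
$\le 20$ g *and* Schiff score $\ge 2$; adjacency is same-quadrant consecutive
FDI numbers), recalibration is read off discordance with the total change
score $\Delta = \text{week8} - \text{screening}$:

| status  | $\Delta < 0$ | $\Delta > 0$ |
|---------|--------------|--------------|
| DH+     | **downward shift** | consistent (worse) |
| DH−     | consistent (improved) | **upward shift** |

$\Delta = 0$ is classified as no shift: there is no evidence in either
direction, and the operational table covers only strict changes. The
minimally important difference (MID, 22 DHEQ points) is reported as a
separate `rs_important` flag rather than folded into the direction rule —
the upward cluster in the motivating analysis averaged +17.6 points, below
the MID, and was still read as upward recalibration, so both conventions
must remain expressible.

Reprioritization is read from changes in variable-importance *ranks* between
trees anchored at the two time points. Importance sums each predictor's SSE
improvement over its primary-splitter roles **and** its surrogate roles (the
surrogate's own improvement on the node's cases, the SPSS/CART convention),
scaled to 100 for the best performer. Because the published screening-time
model specification is not fully determined, `reprioritization_report()`
deliberately takes two fitted importance tables rather than hard-coding the
two designs; rank ties share the smaller rank, since the report compares
ranks.

The design-based companions — then-test (`'then' − 'pre'`) and ideals
(`'ideal follow-up' − 'ideal baseline'`) — are complete-case per contrast
(the two completer subsets genuinely differ), summarised by a one-sample
t-test with the sample SD. Note that published subscale-level then-test t
values are not exactly recomputable from rounded means and SDs; the package
works from the raw difference scores.

## The anchored first split

In the motivating analysis the sample is *first* classified by clinical
status, and the tree is read from that partition downwards. This cannot be
left to the split competition: the five subscale change scores sum to the
total change score by construction, so the dominant subscale always offers a
larger SSE improvement than the binary status indicator, whose group means
differ by only a few points once recalibration works against the treatment
effect. `grow_tree(root_split = )` therefore anchors the root on a
designated predictor (the pipeline default anchors on `dh_week8`), with all
deeper splits fully data-driven. Setting `root_split = NULL` gives the
unanchored tree.

## What the synthetic generator emulates

`simulate_trial()` exists so the whole pipeline is testable without the
original trial data. Its defaults *are* the study conditions: $n = 75$,
baseline total 129.9 (SD 36.5), change $-14.1$, 49.3% persistent DH at week
8, 36% downward / 14.7% upward recalibrators, 43 then-test and 31 ideals
completers.

* Baseline subscale totals follow a one-factor model (a single latent
  severity plus subscale noise), calibrated to the published subscale means
  and SDs; the published subscale means sum to 131.9 against a printed total
  of 129.9, so they are used as *relative* shares of the configured total.
  Scores are rounded to the item grid and clipped to each subscale's range;
  the location of each subscale is analytically adjusted so the
  rounded-and-clipped mean still hits its target (ceiling effects on the
  emotional subscale would otherwise bias the total by a few tenths of a
  point).
* Items per subscale default to 5/14/5/6/4
  (restrictions/coping/social/emotional/identity), a calibration choice
  matching the subscale mean magnitudes, not a claim about the instrument;
  it is overridable. Emitted item scores are a deterministic disaggregation
  of each subscale total (floor plus spread remainder), so they always lie
  in 1..7 and sum back exactly.
* Change is a four-class mixture: persisters with/without a downward shift
  and resolvers with/without an upward shift. Downward shifts occur only
  among persisters and upward only among resolvers (infeasible probability
  combinations are rejected, naming the binding constraint). The
  resolver-class location is solved so the mixture mean equals the
  configured target, including an analytic correction for instrument-range
  clipping. Downward recalibrators average about $-26$ (beyond the MID);
  upward ones about $+17$.
* The class-conditional change SDs are proportional to the configured
  `change_total_sd`. The proportionality constants were fixed once so that
  change directions stay class-consistent (this is what lets large-sample
  recovery of the injected fractions succeed within a few percentage
  points); a consequence is that the realised SD of the observed total
  change is about 27 rather than the configured 31.9 — the price of keeping
  the injected classes identifiable.
* Per-tooth evidence is constructed to be consistent with the DH+ rule
  (persisters get a guaranteed non-adjacent sensitive pair; resolvers get
  zero, one, or an adjacent-only pair — the last deliberately exercising the
  adjacency clause). Tests verify the emitted evidence reclassifies to the
  assigned status for every participant.
* Ground-truth labels (`true_class`, `true_shift`) live in a separate
  `truth` element and a separate sidecar file on disk; analysis functions
  never receive them.

What the generator does **not** emulate: item-level psychometrics
(reliability, item-total structure), per-tooth longitudinal pain
trajectories, correlation between baseline severity and change, arm-level
treatment differences (arms are exchangeable labels), and reconceptualization.
Passing tests therefore show that the *method* recovers what was injected
under these conditions, not that real cohorts behave this simply.

## Problem sizes used in the checks

The split search is verified against exhaustive enumeration on 500 random
tables of up to 50 rows and 4 mixed-type predictors (with missingness);
generator calibration uses 200 replicates of the default $n = 75$ cohort
with Monte-Carlo 99% confidence intervals; recovery of the injected
recalibration fractions uses a single $n = 5000$ cohort, where both
fractions come back within 5 percentage points through the full
tree-plus-node-summary pipeline. These sizes give stable checks in seconds
on one core.

## A worked run

```{r pipeline}
bundle <- run_pipeline(pipeline_config(seed = 1))
glance(bundle$tree)
bundle$fit
bundle$importance
bundle$design_tests |> select(contrast, n, mean_diff, sd_diff, t, p_two_tailed)
```

Reprioritization, read from trees anchored at the two time points (baseline
structure vs change structure):

```{r reprio}
cohort <- bundle$cohort
t1_fit <- grow_tree(cohort, "total_screening",
                    paste0(dheq_subscales, "_screening"), cv = FALSE)
t2_fit <- grow_tree(cohort, "total_change",
                    paste0(dheq_subscales, "_change"), cv = FALSE)
reprioritization_report(variable_importance(t1_fit),
                        variable_importance(t2_fit))
```

## Known limitations

* Trees are high-variance: small data perturbations can change the fitted
  structure, and importance ranks are strictly relative to a given tree.
  The reprioritization report is therefore descriptive, not inferential.
* The recalibration table is a *screen*: discordance can also reflect
  measurement error or genuine but sub-clinical change. The MID flag and
  the node-level summaries are provided so users can demand both
  discordance and importance.
* With predictors that sum to the outcome (subscale changes vs the total),
  explained variance is optimistic; the anchored first split keeps the
  clinically interpretable partition on top but does not remove that
  arithmetic coupling.
* The generator's realised change SD is below its configured value (see
  above); treat `change_total_sd` as a scale knob, not a guaranteed moment.
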