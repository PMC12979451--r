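---
title: "Rich-club analysis of structural connectomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richclubr)
library(dplyr)
```

## The problem

Diffusion tractography summarises a brain's white-matter wiring as a
weighted network: nodes are parcellation regions (here 90 cortical and
subcortical regions), edge weights are streamline counts. A recurring
finding in such networks is *rich-club organization*: the highest-degree
nodes (hubs) are more densely interconnected than their degrees alone would
predict. Because hub–hub ("rich") connections carry much of the network's
integrative traffic, their selective disruption is a candidate mechanism in
depression, and childhood maltreatment — a major environmental risk factor
— may be one of its drivers. richclubr implements the full analysis chain
used to ask such questions: network thresholding, rich-club quantification
against degree-preserving null models, hub and edge-class decomposition,
permutation-based group inference with FDR control, and covariate-adjusted
brain–behaviour correlation — together with a synthetic cohort generator
that makes every stage testable without access to subject data.

## The model and its assumptions

**Edge existence.** A connection is accepted when supported by at least
`min_streamlines` streamlines (default 3, the conventional rule for
deterministic tractography); weaker entries are treated as noise and
zeroed, surviving entries keep their raw counts. The choice to retain
counts (rather than binarize) is forced by the downstream strength
definitions, which sum weights.

**Degree and the rich-club coefficient.** Degree is binary — the number of
edges at a node. For each degree level $k$ from the minimum non-isolated
degree to the maximum degree, nodes with degree $< k$ are removed and

$$\Phi(k) = \frac{E_{>k}}{S(S-1)/2},$$

the density of the subgraph induced by the $S$ survivors. With fewer than
two survivors $\Phi$ is undefined and carried as `NA` (never an error). The
default survivor rule keeps degree $\ge k$; the strict variant
(`rule = "gt"`), common in the classic literature, is a flag because the
two conventions differ by one sweep position and users comparing against
other toolboxes need both.

**Normalization.** $\Phi(k)$ rises mechanically with $k$ even in random
graphs, so it is normalized by $\Phi_{random}(k)$, the mean coefficient
over `n_random` degree-preserving random networks (default 1000) obtained
by Maslov–Sneppen pairwise edge swaps (10 attempted swaps per edge). Edge
swaps conserve every node's degree exactly, so the null ensemble shares the
observed network's degree sequence — the confound $\Phi$ must be corrected
for — and its $k$ sweep. $\Phi_{norm}(k) = \Phi(k)/\Phi_{random}(k) > 1$
over a contiguous range of high $k$ is the rich-club signature. At each
$k$ the null mean averages only nulls where $\Phi$ is defined; if none is,
$\Phi_{norm}$ is undefined there (this avoids 0/0).

**Hubs and edge classes.** Hubs are defined on a *group-averaged* binary
network keeping edges present in at least 60% of the group's subjects:
the `round(0.12 × N)` highest-degree nodes (round half up — on 90 nodes
exactly 11 regions). Ties at the cut-off degree are broken by ascending
label order and reported, making the selection deterministic and
permutation-invariant up to the documented tie-break. Every edge of a
subject's network then falls in exactly one class by endpoint membership:
*rich* (hub–hub), *feeder* (hub–non-hub), *local* (non-hub–non-hub).
Class-wise **connectivity strength** is the sum of the subject's edge
weights in the class; **connectivity density** is that sum divided by
whole-network strength, so the three densities add to one. Note the
deliberate mixing of levels: $\Phi$ and hubs live on binary topology,
strengths on subject-level weights.

**Inference.** Group contrasts use two-sample permutation tests on the
absolute difference of group means (10,000 label shuffles by default),
with the add-one estimator $p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) /
(n_{perm}+1)$ so p values are never zero and never below
$1/(n_{perm}+1)$. The FDR family is all pairwise group contrasts × all six
class metrics corrected together — the widest choice; the definition of the
family is a genuine analysis degree of freedom, so
`permute_group_contrasts()` exposes the metric set. Brain–behaviour associations are partial
correlations: each variable is residualized on an intercept plus age, sex
(0/1) and education by least squares, the residuals correlated, and the p
value taken from a t distribution on $n - 2 - q$ degrees of freedom.
Constant covariate columns duplicate the intercept and are dropped;
genuinely collinear columns are an error naming the offending column.

**Summary-table reconstruction.** Published demographic tables print group
means, SDs and sizes but not raw data. `anova_from_summary()`,
`two_sample_t_from_summary()`, `tukey_hsd_from_summary()` and
`chi_squared_independence()` recompute the F, t, studentized-range and
χ² statistics exactly from those summaries (between-group sums of squares
from the means, within-group from the SDs), which both validates the
bundled cohort table and gives users a way to audit any published table of
this shape. The bundled table reconstructs all eleven statistics within
~1% of their printed values; residual discrepancy is the rounding of the
printed means and SDs.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `min_streamlines` | 3 | streamline count an edge needs to exist |
| `prevalence` | 0.60 | fraction of subjects an edge needs for the group network (inclusive) |
| `hub_fraction` | 0.12 | fraction of nodes taken as hubs (11 of 90) |
| `survivor_rule` | `"ge"` | keep degree ≥ k; `"gt"` for the strict variant |
| `n_random` | 1000 | null networks per profile |
| `n_swap_per_edge` | 10 | attempted Maslov–Sneppen swaps per edge |
| `n_perm` | 10000 | label permutations per contrast |
| `fdr_alpha` | 0.05 | significance level on BH-adjusted p values |

The defaults reproduce the conventional parameterization of this analysis;
all are exposed as arguments of `run_richclub_analysis()`.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws a four-group cohort (84 / 46 / 32 / 90 subjects:
patients and controls, each split by maltreatment exposure) of 90-node
integer-weighted connectomes plus phenotypes:

* **Topology** — a planted-core stochastic block template: within a
  designated 11-node block, connection probability `base_density +
  hub_density_boost` (defaults 0.15 + 0.5); elsewhere `base_density`.
  This guarantees rich-club organization by construction (with zero boost
  the model collapses to Erdős–Rényi and $\Phi_{norm}$ concentrates at 1).
  Each subject's topology is a noisy redraw around the template
  (`topology_noise` = 0.1 mixing weight), so group-averaged networks are
  close to the template and all four groups identify essentially the same
  hub set — the cross-group stability the analysis relies on.
* **Weights** — gamma–Poisson (negative binomial) integer counts with
  class-specific means (60 / 35 / 20 for rich / feeder / local, dispersion
  4), floored at 1 on present edges: overdispersed nonnegative integers,
  the qualitative shape of streamline counts, and a floor low enough that
  the 3-streamline existence rule still has work to do.
* **Effect classes** — one deliberate design choice: group effects are
  keyed to the hub set that the top-12%-degree rule identifies *on the
  template itself*, not to the raw planted block. At the default densities
  the block's expected degree advantage is comparable to realization-level
  degree noise, so the two sets only partially overlap; planting effects on
  the degree-identified set makes the classes the pipeline recovers
  coincide with the classes the effects act on, which is exactly the
  stability the shared-template design is meant to provide.
* **Group effects** — multiplicative on class mean weights:
  patients-with-maltreatment 0.7 / 0.8 / 0.9 (rich / feeder / local),
  patients-without and controls-with 1 / 0.8 / 1, controls-without
  1 / 1 / 1 (the reference). These magnitudes were fixed by pilot power
  runs so that the planted directions are recovered in ≥ 90% of cohorts at
  the study's group sizes; they are generator parameters, not empirical
  estimates.
* **Scores** — CTQ subscales drawn per group from the bundled summary
  table, truncated to their 5–25 range and rejection-sampled until the
  published cut-off rule (emotional abuse ≥ 13, physical abuse ≥ 10,
  sexual abuse ≥ 8, emotional neglect ≥ 15, physical neglect ≥ 10; any one
  suffices) reproduces the subject's group label, so group sizes are hit
  exactly and classification is internally consistent. Symptom scales and
  covariates follow the same per-group summaries.
* **Brain–behaviour coupling** — each subject's feeder-edge mean is scaled
  by $1 + \beta z$, where $z$ is the CTQ total standardized *within the
  subject's group* and $\beta$ = +0.25 for patients, −0.25 for controls.
  Standardizing within group keeps the coupling from shifting the group
  means that the effect multipliers control.

**What passing tests do not show.** The generator makes no attempt at
spatial geometry, distance-dependent connection probabilities, modular
cortical organization, or realistic effect magnitudes. Because the planted
group effects and the coupling both align CTQ with feeder density, the
pooled within-diagnosis correlations come out around |r| ≈ 0.8 — far
stronger than the modest associations typical of real cohorts (|r| ≈ 0.2).
Recovery rates near 100% on this synthetic regime therefore demonstrate
that the pipeline's machinery is correct and well calibrated, not that
comparable effects would be detectable in real data.

## Numerical choices and degenerate inputs

* Symmetry of input matrices is validated with exact equality — streamline
  counts are integers, and any asymmetry indicates a broken upstream step,
  not floating-point noise.
* $\Phi$ undefined (fewer than two survivors) is a legal `NA` return;
  curves keep undefined rows so profiles over a shared degree sequence
  align row for row.
* Rewiring a network with fewer than two edges returns it unchanged with a
  warning; `n_swap_per_edge = 0` is the identity, which gives the
  self-ensemble sanity check $\Phi_{norm} \equiv 1$.
* Hub-count rounding is half-up (base R `round()` is round-half-even,
  which would make the count depend on floating parity).
* All randomness flows from single master seeds: per-null and per-test
  seeds are derived by counter, callers' RNG state is never touched
  (`withr::with_seed`), and rerunning any entry point with the same seed
  is byte-identical.
* A subject with total strength zero yields `NA` densities rather than a
  division error.

## Problem sizes used by the test-suite

The packaged tests scale simulation sizes to what a laptop runs in minutes
while keeping every scientific claim intact: oracle equivalence on 200
random graphs of up to 30 nodes; rewiring invariants over 100 seeds; null
ensembles of 100–200 random networks; type-I calibration over 1000
replicates at 199 permutations; and recovery of planted effects over 20
full-size cohorts (252 subjects, 90 nodes) at 1000 permutations per
contrast. The defaults users see (`n_random = 1000`, `n_perm = 10000`)
remain the conventional sizes.

## Known limitations

* The weighted rich-club coefficient and other topological summaries
  (efficiency, small-worldness, path length) are out of scope.
* The FDR family definition is a convention, not a theorem; users whose
  field corrects within metric type should pass the narrower metric set.
* Tukey HSD from summaries assumes the within-group variances pooled in
  the published table are meaningful (i.e., near-homoscedastic groups), as
  the original ANOVA does.
* The generator's rejection sampler assumes the per-group score
  distributions are broadly consistent with their group's classification;
  wildly inconsistent configurations (e.g., an exposed group whose scores
  almost never cross a cut-off) would slow it down and are capped by a
  forcing fallback.
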