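---
title: "Methods: longitudinal connectome analysis with sparse partial correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal connectome analysis with sparse partial correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
```

## The scientific problem

Focal neurosurgical interventions — here the motivating case is unilateral
focused-ultrasound thalamotomy for essential tremor — change not only the
lesioned structure but the whole functional network it is embedded in.
Resting-state fMRI scanned repeatedly around the intervention (a
pre-operative baseline, an acute post-operative scan, and later follow-ups)
can in principle separate two kinds of network change:

* **persistent** reorganisation: couplings inside the lesioned subnetwork
  that drop after surgery and stay down;
* **transient** diaschisis: remote couplings that are perturbed acutely and
  return to baseline at follow-up.

The statistical difficulty is the scale of such studies: around eight
patients, three or four sessions, ordinal clinical scores, and connectivity
matrices with hundreds of edges estimated from roughly 160 usable volumes
per session. `longconn` implements the full chain — synthetic ground truth,
temporal preprocessing, connectivity estimation, graph metrics, and the
longitudinal statistics — so that every inferential step can be validated
against a known generative model before it is trusted on real data.

## The generative model

A cohort is defined by a **Gaussian graphical model**: a sparse symmetric
positive-definite precision matrix $\Omega$ whose zero pattern encodes
conditional independence between regions. `make_modular_precision()` draws
such a matrix with modular structure (denser support within a module, e.g.
"motor", than between modules) and, optionally, exact hemispheric mirror
symmetry: the right-hemisphere block equals the left-hemisphere block
entrywise under the homotopic node pairing, and the between-hemisphere
block is symmetric in paired coordinates. Because the subsequent
positive-definiteness repair (a ridge on the diagonal) and the rescaling to
a unit-diagonal covariance are both equivariant under the hemisphere swap,
the final partial-correlation matrix is mirror-symmetric by construction —
which gives the inter-hemispheric similarity metric an exact ground truth
of 1.

```{r truth}
mods <- rep(c(rep("motor", 3), rep("other", 2)), 2)
gt <- make_modular_precision(10, mods, symmetry = TRUE, seed = 1)
gt
```

**Lesion trajectory.** `lesion_trajectory()` scales the off-diagonal
precision entries of the motor module by `persistent_scale` from the first
post-operative session onward, and a designated set of non-motor edges by
`transient_scale` at the acute session only; the transient edges revert
*bitwise* to their baseline values afterwards, so tests can assert exact
recovery. Positive-definiteness is re-checked after every application.
Perturbing the precision matrix (rather than the correlations) is the
scientifically meaningful choice: it models a change in direct coupling,
whose marginal-correlation footprint then spreads through the matrix
inverse — exactly the confound that motivates partial-correlation
connectivity.

**Time series.** Each session draws a stationary AR(1) process
$x_t = \phi x_{t-1} + e_t$ with $e_t \sim N(0, (1-\phi^2)\Sigma)$, so the
cross-sectional covariance equals $\Sigma = \Omega^{-1}$ for any $\phi$.
On top of the signal the generator adds low-frequency drift (sinusoids
below 0.009 Hz), leakage of the simulated motion and tissue nuisance
regressors, and white observation noise. Subjects differ by a log-normal
jitter (sd 0.1 on the log scale) of the nonzero precision entries, which
preserves the support.

**Clinical scores.** Ordinal 0–4 action and posture scores are generated
from a latent severity linear in the standardised motor-network partial
correlation strength, rounded and clipped — so stronger motor coupling
means worse tremor, and the lesion-induced attenuation produces the
improvement pattern the longitudinal statistics should detect.

**Realism and limits.** The generator reproduces the study's design
constants (8 subjects, 4 sessions, 165 volumes at TR = 2 s, 5 discarded
volumes) and the qualitative structure of BOLD contamination, but it is
deliberately idealised: Gaussian signals, exact AR(1) dynamics, nuisance
leakage that is exactly linear in the saved regressors, and no spatial
preprocessing at all (the package starts from region-level series; slice
timing, realignment and normalisation are out of scope). Conclusions about
*calibration* transfer to real data only to the extent that these
idealisations hold.

## Preprocessing

`preprocess_session()` applies the canonical temporal pipeline: discard the
first 5 equilibration volumes; build one design matrix containing an
intercept, orthogonal linear and quadratic trends, the six motion
parameters, their backward-difference derivatives, three tissue components,
and discrete sine/cosine pairs at every frequency $f_k = k/(T\,\mathrm{TR})
\le 0.009$ Hz; and remove everything in a **single** least-squares
projection. A single projection (rather than sequential regressions) makes
the result order-invariant and leaves residuals exactly orthogonal to every
regressor — the property the unit tests assert. Exactly collinear design
columns are dropped with a warning rather than silently regularised.
`extract_eigenvariate()` provides the standard first-principal-component
summary for going from voxel blocks to region series.

## Connectivity: FC and sparse pFC

Functional connectivity is Pearson correlation passed through the Fisher
transform ($z = \operatorname{atanh} r$), tested one-sidedly for positive
coupling with the normal approximation $z\sqrt{T_\mathrm{eff}-3}$ and
thresholded by Benjamini–Hochberg FDR at $q = 0.05$; surviving z-values are
the edge weights.

Partial-correlation connectivity estimates $\Omega$ by the **graphical
lasso**, maximising $\log\det\Omega - \operatorname{tr}(S\Omega) -
\lambda\sum_{i\ne j}|\Omega_{ij}|$ with the diagonal unpenalised. The
solver (`src/glasso.cpp`) is block coordinate descent over columns with an
inner soft-thresholding lasso; no CRAN solver was available in the build
environment, so correctness is enforced by oracle tests instead: at
$\lambda = 0$ the estimate matches `solve(S)` to 1e-6, and at convergence
the KKT conditions hold ($|W - S| \le \lambda$ off-diagonal, with equality
on the active set).

**Penalty selection** uses StARS: 50 row-subsamples of size
$\lfloor 10\sqrt{T}\rfloor$, per-edge selection frequencies $\theta$,
instability $2\theta(1-\theta)$ averaged over edges into $D(\lambda)$, and
the smallest $\lambda$ whose monotonised instability stays below
$\beta = 0.05$. One numerical choice deserves emphasis: the textbook
monotonisation takes a running maximum of $D$ from the sparsest end of the
grid. At atlas sizes of 10–20 nodes and $T \approx 160$ that rule is
fragile — one or two high-variance edges flicker in and out at penalties
near the support-vanishing boundary, push $D$ above $\beta$ there, and the
running maximum then hides the genuinely stable valley, collapsing the
selection to an empty graph. `stars_select_lambda()` therefore anchors the
running maximum at the most stable point of the *sparse regime* (mean
selection frequency $\le 0.5$) and leaves sparser grid points
unmonotonised. When the sparse end is clean — the usual situation on
larger problems — this reduces exactly to the canonical rule; the
restriction to the sparse regime preserves the original safeguard against
walking into the trivially stable dense end on null data.

After support selection, `refit_constrained_mle()` removes the L1 bias by
**covariance selection**: the Gaussian MLE constrained to zeros off the
selected support, computed by the same block sweep with an unpenalised
linear solve per column. At convergence the implied covariance matches $S$
exactly (to 1e-6) on the support and diagonal, and off-support precision
entries are exact zeros. Partial correlations
$\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$ are thresholded at
$\rho > 10^{-5}$, just above the solver's exact zeros.

## Graph metrics

All metrics operate on the thresholded weighted graph with edge length
$1/w$: node degree and strength, nodal path length (mean shortest-path
distance to *reachable* nodes, `NA` for isolated nodes), and global
efficiency (mean inverse distance, zero contribution from unreachable
pairs, so a complete unit-weight graph scores exactly 1). Shortest paths
are delegated to igraph's Dijkstra implementation; the test suite checks
it against an exhaustive enumeration of all simple paths on graphs of up
to six nodes, which is the one regime where brute force is an independent
oracle. Inter-hemispheric similarity is the Pearson correlation between
the within-left and within-right edge vectors under the homotopic
ordering.

## Longitudinal statistics

`rm_anova_oneway()` computes the subjects-as-blocks decomposition directly
(cross-checked against `aov(y ~ session + Error(subject/session))` in the
tests) because the Greenhouse–Geisser and Huynh–Feldt epsilons and Tukey's
within-subject `MS_error` need the intermediate sums of squares. Both
sphericity corrections are reported: published tables in this literature
mix the two, and with $k = 3$ sessions and $n = 8$ subjects the choice
visibly changes the fractional degrees of freedom. Post hoc session
contrasts use the studentized-range distribution (`ptukey`) with the
within-subject error term; edge- or node-wise families are corrected by
Benjamini–Hochberg. Relationships between network properties and clinical
scores use a random-intercept linear mixed model (`lmerTest`, REML,
Satterthwaite degrees of freedom) with session order as a numeric time
covariate.

At this sample size, calibration cannot be assumed — it is tested: the
acceptance suite verifies the RM-ANOVA type-I error at $n=8, k=3$ over
2,000 null simulations, the realised false-discovery proportion of the BH
step on null connectivity, and the bias and confidence-interval coverage
of the mixed-model slope over hundreds of simulated cohorts.

## Classifying persistent versus transient edge change

The scientific endpoint is the classification of longitudinal profiles.
Two estimators are provided. `classify_edge_trajectories()` labels single
edges by comparing acute ($|x_2 - x_1|$) and late
($|\bar x_{3:k} - x_1|$) deviations of the group-mean matrices against a
threshold. On eight subjects this is honest but underpowered, and it is
kept for larger-cohort use.

The powered analysis is set-level. `classify_set_trajectory()` takes
per-subject partial-correlation matrices (from `sample_partial_corr()`,
the unregularised inverse — unbiased per edge, which matters more here
than sparsity), averages $|\rho|$ over a programmed edge set per subject
and session, forms *paired within-subject* contrasts against baseline
(removing stable between-subject differences in overall coupling
strength), and summarises each contrast as a one-sample t statistic. The
decision rule is shape-based: a set is persistent when the late deviation
is significant *and* its magnitude is at least half the acute magnitude;
transient when the acute deviation is significant but the late effect has
collapsed; stable otherwise. The magnitude comparison is essential at this
scale: a truly transient set can retain a small but statistically
detectable late residual through estimation coupling with the persistent
changes elsewhere in the network, and the trajectory *shape* — not the
bare significance of the late contrast — is what distinguishes the two
regimes. On 20 independent synthetic cohorts at the default study size the
rule recovers the programmed persistent and transient sets in every
cohort.

## Problem sizes and costs

The package is designed for desk-scale problems: atlases of 10–90 regions,
cohorts of 5–20 subjects, 3–6 sessions, 100–500 volumes per session. The
expensive stage is StARS (subsamples × grid × graphical-lasso fits, warm
started along the path): about a second per session at 20 nodes and under
a minute at 90 nodes. Everything else — preprocessing, FC, metrics,
ANOVA/Tukey/LMM — is effectively instantaneous at these sizes. The
end-to-end pipeline over a default synthetic cohort (8 subjects × 4
sessions, 20 nodes, with pFC) runs in a few minutes on one CPU.

## A worked run

```{r pipeline, eval = FALSE}
cohort_dir <- file.path(tempdir(), "cohort")
out_dir <- file.path(tempdir(), "results")
co <- generate_cohort(cohort_config(random_seed = 42), seed = 42,
                      out_dir = cohort_dir)
motor <- co$atlas$node_labels[co$atlas$module_id == "motor"]
cfg <- pipeline_config(cohort_dir, out_dir,
                       subnetworks = list(motor = motor), seed = 42)
res <- run_pipeline(cfg)
subset(res$stats$network_table, metric == "global_efficiency")
```

The same run is available from a shell via the wrapper installed at
`system.file("scripts", "run_pipeline.R", package = "longconn")`.
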