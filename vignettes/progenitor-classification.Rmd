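---
title: "Classifying hippocampal neural progenitor cells from patch-clamp biophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hippocampal neural progenitor cells from patch-clamp biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgzephys)
```

## The problem

Neural progenitor cells in the sub-granular zone (SGZ) of the dentate gyrus
pass through distinct stages: quiescent radial glia-like stem cells
("type 1", Sox2+), transit-amplifying progenitors ("type 2a", Sox2+/Tbr2+),
and lineage-restricted neuroblast-like progenitors ("type 2b", Tbr2+).
Identifying the stage of a patch-clamped cell normally requires post-hoc
immunostaining, which fails for the majority of recorded cells. The stages,
however, differ systematically in three passive membrane properties that
every whole-cell recording yields for free:

* **Vm** — resting membrane potential (mV). Type 1 cells are strongly
  hyperpolarized; type 2b cells sit more depolarized, and type 2b cells
  lacking the Kv1.1 potassium channel are further depolarized still.
* **Rm** — input resistance (MΩ). Low in type 1 cells (immense passive
  conductance and gap-junction coupling), high in electrically isolated
  type 2b cells.
* **Cm** — membrane capacitance (pF). High in gap-junction-coupled type 1
  networks, low in single type 2b cells.

This package classifies cells from these three numbers, and surrounds the
classifier with the supporting analyses such a study needs: voltage-step
I-V analysis with leak subtraction and sodium-transient detection,
fixed-radius clone calling from lineage-tracing coordinates, and the
group-level statistics.

## The model

For cell-type label $C \in \{0, 1, 2\}$ (type 1, 2a, 2b) and feature vector
$x = (x_1, x_2, x_3)$ — the centred and scaled $(\log C_m, \log R_m, V_m)$ —
the classifier is a three-class multinomial logistic regression with type 1
as the reference class:

$$\frac{P(C = c \mid X = x)}{P(C = 0 \mid X = x)} =
  \exp(\beta_{c,0} + x_1\beta_{c,1} + x_2\beta_{c,2} + x_3\beta_{c,3}),
  \qquad c = 1, 2.$$

Separate models are fitted for wild-type and Kv1.1-knockout cells, because
the knockout shifts the type 2b voltage distribution and there is no reason
to force shared coefficients. Each cell is assigned to the class of highest
posterior probability; exact ties (within $10^{-12}$) are broken toward the
reference class and flagged.

Fitting is plain maximum likelihood: `fit_mlr()` runs Newton-Raphson with
the analytic gradient and Hessian, started at the zero matrix. The
log-likelihood is concave, so when no class separation exists the optimum is
unique and reached in a handful of iterations; the gradient max-norm
tolerance is $10^{-8}$. Log-sum-exp stabilization keeps the likelihood
finite for logits up to several hundred. Two situations are reported rather
than silently "solved": if any coefficient magnitude exceeds 50 during
iteration the fit stops and flags probable separation (the MLE does not
exist), and non-convergence within the iteration cap raises a warning with
the fit metadata preserved. No regularization is applied by default,
matching the plain-MLE setting the model is meant to reproduce.

### Standardization choices

The features are standardized *within genotype*, over all QC-passing cells
of that genotype, so each genotype's model is self-contained. Two
conventions are genuinely open — whether the scale uses the $n-1$ or $n$
denominator, and which cells enter the means — so both denominator variants
are first-class (`sd_denom`), and `reproduce_published_fit()` reports both.
Natural logs are used; the choice is immaterial, since any log base or unit
change is an affine map absorbed by the centring and scaling. The test
suite asserts this invariance end to end: rescaling all capacitances by
1000, all resistances by any positive constant, or shifting all potentials
by a constant leaves every classification identical to $10^{-12}$.

The published coefficient vectors for both genotypes ship as fixtures
(`published_model()`). They come without standardization parameters —
the source prints only the coefficients — so the package refuses to apply
them to raw records until means and scales are attached explicitly.

## The synthetic cohort

The raw recordings behind the original analysis are not available, so the
`generate_cells()` module simulates cohorts with the structure the analysis
assumes: per type-by-genotype archetype, Vm is normal and Rm, Cm are
log-normal. The default archetypes are invented plausible values, not
measurements:

| type | Vm (mV) | Rm (MΩ, median) | Cm (pF, median) |
|------|---------|-----------------|-----------------|
| type 1 | −85 ± 3 | 50 | 50 |
| type 2a | −80 ± 4 | 500 | 20 |
| type 2b (WT) | −75 ± 5 | 2000 | 10 |
| type 2b (KO) | −60 ± 8 | 2000 | 10 |

with log-scale sds of 0.4 (Rm) and 0.35 (Cm), a class mixture of
(0.60, 0.25, 0.15), and 30% of cells carrying a marker label (emulating the
minority of recordings whose immunostaining succeeds). The knockout shift
appears only in type 2b, which is the hypothesis the downstream statistics
should be able to detect. QC fields are drawn so that a few percent of
cells fail the series-resistance or holding-current criteria.

Two consequences of these defaults are worth stating plainly. First, the
archetypes are far better separated than real recordings: the labeled
training subsets are typically *linearly separable*, so the fitted
coefficients run to the separation cap and resubstitution accuracy is 1.0.
Passing tests on this cohort therefore demonstrate the pipeline's
mechanics, not a realistic error rate — real cohorts with ~80% accuracy
live in the overlapping regime, which the parameter-recovery and
oracle-equivalence tests cover instead by simulating directly from the
published coefficient vectors (`generate_cells_from_model()`, labels drawn
from the model's own posteriors at standard-normal features). Second,
nothing downstream asserts the archetype numbers against any published
value; they are study conditions for testing, fixed once.

## Electrophysiology

`step_protocol()` defaults to steps from −120 to +40 mV in 10 mV
increments from a holding potential of −80 mV, sampled at 5 kHz, with a
100 ms step epoch. Three trace archetypes are generated: passive (ohmic
leak plus capacitive transient), rectifier (adds a Boltzmann-activated
outward conductance, $V_{1/2} = -30$ mV, slope 10 mV, 5 ms activation), and
rectifier-with-sodium (adds a brief inactivating inward current at steps
above −30 mV).

* **Steady state** is measured over the last 10% of the step epoch by
  default — late enough that the capacitive transient (τ ≈ 2 ms at default
  parameters) and the 5 ms rectifier activation have settled. The window is
  validated against the epoch.
* **Leak subtraction** fits a least-squares line over the hyperpolarized
  limb (−120 to −70 mV by default, where voltage-gated conductances are
  closed) and subtracts its extrapolation; slope and intercept are kept on
  the curve, and double subtraction is an error. A P/N-style protocol is
  not offered for I-V curves; the linear fit is deterministic and exactly
  removes any ohmic component (asserted to $10^{-6}$ in tests).
* **Transient inward detection** first removes each trace's passive
  component using a scaled template from the most hyperpolarized step (the
  classic P/N idea), then looks for a dip below −threshold (default 50 pA)
  within 10 ms of onset that recovers to ≥ 50% of its peak before the
  window ends. The recovery rule is this package's operationalization of
  "transient"; threshold and window are exposed. Only steps more positive
  than −30 mV are searched, and the detector is invariant to constant
  offsets.
* **Condition subtraction** (`subtract_conditions()`) is the
  blocker-sensitive current: control minus treated on identical voltage
  grids, used for Kv1 isolation by dendrotoxin-K-style experiments.

## Clone calling

The membership rule — a clone is all labeled cells within a 100 µm radius
of the clone center — does not by itself say how centers are found. The
package's rule is greedy maximum coverage: repeatedly seed a clone at the
unassigned cell whose radius-ball contains the most unassigned cells (ties
broken toward the lexicographically smallest cell id) and assign that
ball's cells to it. This is deterministic, parameter-free beyond the
radius, yields a true partition, and provably recovers ground truth when clone
centers are separated by more than the calling radius plus twice the
scatter bound. The synthetic generator scatters members uniformly within a
hard ball (radius `scatter_um`) rather than with an unbounded Gaussian,
precisely so that these geometric guarantees hold and are testable. Distances are 3D Euclidean (whole-mount imaging is 3D); a
2D projection mode exists. Clone-size distributions are compared by the
two-sample KS statistic (asymptotic p; sizes are heavily tied, so no exact
p is attempted) together with a t-test — Welch by default, pooled
available, since the original report does not state its variant.

## Statistics

* `two_way_anova()` uses type II (model-comparison) sums of squares, which
  coincide with the classical decomposition on balanced designs and do not
  depend on factor order when unbalanced; type III is deliberately not
  offered. Every design cell must be non-empty. When all responses are
  identical the convention F = 0, p = 1 is reported, with floating-point
  dust snapped to exact zero at relative 1e−12.
* `sidak_adjust()` implements $1-(1-p)^m$; post-hoc comparisons are
  Sidak-adjusted pairwise Welch tests (`pairwise_sidak()`). Studentized-
  range (Tukey) post-hocs are out of scope; for the package's synthetic
  demonstrations the Sidak-adjusted pairwise tests fill the same role.
* `mann_whitney_u()` computes U from midranks. The exact two-sided p is
  by full enumeration of all $\binom{n_A+n_B}{n_A}$ rank assignments, with
  the symmetric-tail definition $P(|U - n_An_B/2| \ge |u - n_An_B/2|)$ —
  on tie-free data this equals the usual doubled-tail value, and under ties
  it remains well defined. Enumeration is used automatically up to a
  combined n of 14 (3432 arrangements); beyond that the normal
  approximation with tie and continuity corrections takes over, and the two
  agree to better than 0.02 around the crossover in tests.
* `normalize_phospho()` is the per-cell intensity normalization
  $F_1 / (F_2 \cdot \text{area})$.

## Problem sizes and determinism

All simulation-based checks run at sizes chosen to make the statistical
assertions sharp but cheap: 5000 cells for parameter recovery (coefficients
recovered within 3 standard errors of the generating values for both
genotypes), 20 datasets of 60 cells for the optimizer cross-check
(agreement with an independent BFGS run to $10^{-4}$), cohorts of 200 cells
per genotype for the pipeline, and clone fields of 10–25 clones. Every
generator is a pure function of its (config, seed); the pipeline report is
byte-identical across reruns of the same configuration.

## Known limitations

* The synthetic cohort does not emulate recording artifacts (seal quality
  drift, series-resistance error, gap-junction network dynamics), and its
  class separation is optimistic, as discussed above.
* The published coefficients cannot be applied to new raw data without
  reconstructing the original feature means and scales, which were not
  printed; any such use requires refitting the standardization on a
  comparable cohort and saying so.
* Clone calling assumes partition semantics; overlapping-clone
  interpretations of the fixed-radius rule are not implemented.
* The detector for transient inward currents needs a hyperpolarized step
  (away from holding) in the protocol to build its passive template; with
  none available it falls back to baseline subtraction only and becomes
  conservative on strongly rectifying cells.
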