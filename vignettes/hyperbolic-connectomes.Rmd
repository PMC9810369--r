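---
title: "Hyperbolic disc embedding of functional connectivity networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic disc embedding of functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercon)
```

## Overview

`hypercon` implements a complete analysis chain for functional connectivity
networks built from interregional time-series correlation:

1. **connectivity** — Pearson correlation matrices, absolute-value
   thresholding into binary graphs, largest-component retention, and
   threshold selection by a scale-free + retention window;
2. **manifold benchmarking** — embedding binary graphs into
   constant-curvature spaces (Euclidean, hyperbolic, spherical) by
   Riemannian stochastic gradient descent, scored by average distortion and
   mean average precision;
3. **S1/H2 embedding** — maximum-likelihood inference of the
   popularity-similarity geometry (hidden degrees, inverse temperature,
   angular coordinates) and the change of variables to a hyperbolic disc;
4. **anomaly detection** — reproducibility quantification via the
   coefficient of variation of a distance analog over repeated embeddings,
   and edge-level comparison of an individual against a control cohort;
5. **synthetic cohorts** — generators that emulate the statistical
   structure the analysis assumes, used as the test bed for everything
   above.

## The S1/H2 model

Each node carries a hidden degree $\kappa_i > 0$ (popularity) and an angle
$\theta_i \in [0, 2\pi)$ on a circle of radius $R = N / 2\pi$ (similarity).
An unordered pair connects independently with probability

$$p_{ij} = \frac{1}{1 + \chi_{ij}^{\beta}}, \qquad
  \chi_{ij} = \frac{R\,\Delta\theta_{ij}}{\mu\,\kappa_i \kappa_j},$$

where $\beta > 1$ (inverse temperature) controls clustering strength and
$\mu$ sets the mean degree. The equivalent hyperbolic representation places
node $i$ at radius $r_i = R_{\mathrm{disc}} - 2\ln(\kappa_i/\kappa_{\min})$,
so that with distances

$$d_{ij} \approx r_i + r_j + 2\ln\frac{\Delta\theta_{ij}}{2}$$

the connection probability becomes the Fermi-Dirac form
$p_{ij} = 1/(1 + e^{(\beta/2)(d_{ij} - \hat R)})$, with $\hat R$ the
outermost radial coordinate. At $d = \hat R$ the probability is exactly
$1/2$; the distance analog $D_{ij} = e^{(d_{ij} - \hat R)/2}$ equals 1
there.

### Normalization conventions

The source text for this model leaves the $\mu$ normalization to a
supplement that is not part of our inputs. We adopt the standard
convention from the S1 literature:
$\mu = \beta \sin(\pi/\beta) / (2\pi \langle k \rangle)$, with hidden
degrees rescaled so their sample mean equals the target mean degree. Under
this choice the mean-field expected degree of node $i$ is $\kappa_i$; our
Monte-Carlo checks (20 seeds at $N = 500$, $\gamma = 2.7$,
$\langle k\rangle = 10$, $\beta = 2.5$) find the realized mean degree
within 10% of the target, the residual shortfall being the usual
finite-size truncation of the angular integral.

Hidden degrees are drawn from a Pareto distribution with exponent
$\gamma$, truncated at $\kappa_{\max} = N^{1/(\gamma-1)}$ to avoid
condensation of the degree sequence in finite samples.

## Threshold selection

Correlation matrices are binarized by $|\rho_{ij}| > \tau$ (strict
inequality; anticorrelated pairs count as connected). For each $\tau$ on a
grid (default 0.15 to 0.65 in steps of 0.01, i.e. 51 thresholds) we record

* the fraction of nodes retained in the largest connected component
  (default requirement: at least 95%, which for a 274-node parcellation
  means at least 261 nodes), and
* whether the degree sequence passes a scale-free check.

The admissible window is the longest contiguous run satisfying both; a
group-level threshold is the grid value covered by the most subject
windows, ties resolved towards the larger (sparser) threshold.

**Operationalizing "follows a power law".** The source analysis judged
degree distributions by eye. We replace this with a maximum-likelihood
discrete power-law fit (Clauset-style exponent and lower cutoff, via
`igraph::fit_power_law`) plus a semi-parametric bootstrap of the
Kolmogorov-Smirnov statistic; a sequence passes at bootstrap $p \ge 0.1$.
Because a power law fitted to a vanishing tail of a peaked distribution is
not meaningful scale-freeness, we additionally require the fitted tail to
cover at least 10% of the nonzero degrees and the fitted exponent to lie in
a plausible scale-free range (default `[1.5, 6]`): peaked degree
distributions pass the pure goodness-of-fit test surprisingly often, but
only with absurd exponents of 8-40 fitted to a handful of extreme values.
All three cutoffs are arguments of `scale_free_check()`. This is a declared substitute for a visual judgment,
not a reconstruction of it; calibration tests show the check accepts its
own generative model in over 90% of seeds and rejects binomial (peaked)
degree sequences in over 90% of seeds.

## RSGD benchmarking

`rsgd_embed()` minimizes
$L = \sum_{i<j} \left( (d_V(x_i, x_j) / (s\, d_U(i,j)))^2 - 1 \right)^2$
over coordinates on the unit-curvature model space; the global scale $s$
is re-optimized in closed form every epoch and absorbs curvature
magnitude, so only the curvature sign and dimension of the target space
matter. The exact auxiliary loss used by the work this package follows is
not reproduced in our inputs; this distortion-style squared-ratio loss is
our declared choice. Gradients are computed in the ambient space,
corrected to Riemannian gradients (Minkowski metric correction on the
hyperboloid), projected to the tangent space, and retracted with the
exponential map; the hyperboloid model is used internally for hyperbolic
space because its gradients are numerically stabler than the Poincaré
ball's. Coordinates start as unit-scale tangent noise around the
pole/origin (not a near-zero cloud): because the loss optimizes a global
scale jointly, a near-zero start confines the whole optimization to the
flat small-distance regime where curvature never engages. Steps are
normalized by the configuration's current characteristic distance (the
loss is nearly scale-free, so raw gradients blow up as the layout shrinks)
and decay exponentially to 1% of the initial rate. Convergence is declared when the relative loss change over the
last 10 epochs falls below $10^{-4}$ (epoch cap 3000); the source reports
convergence counts without stating its rule, so this bookkeeping is a
package choice.

Reported `d_avg` is the distortion minimized over a global rescaling of
the embedded distances (a weighted-median problem, solved exactly), which
makes the benchmark insensitive to the arbitrary overall size of the
layout. `map_score` is the mean average precision; exact distance ties are
broken by a deterministic jitter of $10^{-9}$ times the node index, since
the rank-based definition is otherwise undefined under ties.

## Maximum-likelihood disc embedding

`embed_s1h2()` composes four stages:

1. **`infer_beta`** — bisection on $\beta \in (1.05, 25]$ matching the
   observed mean local clustering coefficient against synthetic S1 draws
   at the current hidden-degree estimates with uniform angles (4 draws per
   candidate, seeded, so the estimate is deterministic given the seed).
   Graphs with near-zero clustering pin at the lower boundary with a
   warning.
2. **`infer_kappa`** — damped fixed-point iteration
   $\kappa_i \leftarrow \max(\kappa_i + \eta (k_i - \mathbb E[k_i \mid
   \kappa, \beta]), \varepsilon)$ with mean-field expected degrees
   computed from the angular integral of the connection kernel (analytic
   tail approximation, Simpson quadrature when the integration limit is
   small).
3. **`infer_angles`** — multi-start spectral initialization followed by
   likelihood sweeps. Three starts come from the leading nontrivial
   eigenpair of the normalized adjacency with hub-hub edges discounted as
   $w_{ij} = a_{ij}/(k_i k_j)^{\alpha}$, $\alpha \in \{0, 0.5, 1\}$:
   hub-hub edges carry little similarity information, but the appropriate
   discount depends on the realized hub structure, so all three are tried.
   Each start is refined by a few burn-in sweeps (the first in decreasing
   degree order — hub placement anchors the rest — the others in seeded
   random order); the best is selected by Bernoulli log-likelihood and
   refined until a full sweep improves the log-likelihood by less than
   $10^{-4}$. A node update evaluates 72 equispaced candidate angles and
   polishes the best by golden-section search, holding all other angles
   fixed, so accepted moves never decrease the likelihood.
4. **`to_disc`** — the radial change of variables above, anchored at the
   observed minimum hidden degree. $\hat R$ used by the connection
   probability and the distance analog is the realized outermost radius,
   not the theoretical disc radius.

Known limitation: the likelihood at moderate size and mean degree
($N \approx 300$, $\langle k \rangle \approx 10$) is nearly flat with
respect to smooth warpings of the angular density. The optimizer recovers
the circular *ordering* of nodes almost perfectly (order agreement
$\approx 0.98$ in our recovery experiments), but the circular correlation
of raw angles against the generating truth fluctuates more between
realizations because the inferred density may be locally stretched or
compressed without likelihood cost. Distance-based statistics (Spearman
correlation of pairwise hyperbolic distances with ground truth, typically
0.85-0.9) are the more stable recovery measure, and all downstream
analyses consume distances, not raw angles.

The default distance kernel combines the logarithmic approximation
$a = r_i + r_j + 2\ln(\Delta\theta/2)$ with its coincident-angle floor
$b = |r_i - r_j|$ *smoothly*, as $\ln(e^a + e^b)$. This is the genuine
asymptotic form of the hyperbolic law of cosines — for well-separated radii
$\cosh d \approx \cosh(r_i - r_j) + \sinh r_i \sinh r_j
(1 - \cos\Delta\theta)$ splits into exactly these two exponentials — and
the often-quoted hard maximum $\max(a, b)$ is its zero-temperature limit.
We initially implemented the hard maximum and found it violates the
package's own kernel-consistency requirement (agreement with the exact
kernel within 1% whenever $a > 10$ and $\Delta\theta \le 0.2$): near the
crossover $a \approx b + 2$ its relative error peaks at about 1.3%. The
smooth form meets the requirement everywhere in that regime, equals
$|r_i - r_j|$ exactly at $\Delta\theta = 0$, and differs from the hard
maximum by at most $\ln 2$. The law-of-cosines kernel remains available
with `exact = TRUE`.

Reflection of the disc is a likelihood symmetry and is never resolved at
inference time; `align_disc()` resolves rotation (and optionally
reflection) only for comparison or display, by rotating the circular mean
of a reference node set to zero. All pairwise distances are invariant
under both operations.

## Reproducibility and anomaly detection

`repeat_embed_cv()` embeds the same graph with consecutive seeds and
computes, for every graph edge, the coefficient of variation of the
distance analog across repetitions, plus each node's mean over incident
edges (the default 100 repetitions matches the reference analysis; tests
use fewer and say so). Failed repetitions are recorded and excluded, with
at least 80% required to succeed.

`build_control()` stores per-edge control samples and empirical cut points
computed with inclusive order statistics and linear interpolation
(`quantile type 6`). At a cohort size of 134 this estimator makes the
expected exceedance probability of the $1-t$ cut essentially the nominal
$t$, which is what the null-calibration acceptance test checks. The
Shapiro-Wilk normality p-value per edge is retained as QC metadata only:
our inputs do not state whether the reference cuts were parametric or
empirical, so we default to the assumption-light empirical cuts and keep
the normality test as diagnostics (a parametric option would be a
one-line change on top of the stored means and SDs). Flags use strict
inequalities, so a test value exactly at a cut is never flagged; no
multiple-comparison correction is applied by default (`bh_filter()` is
available but off), matching the reference procedure.

In correlation mode the same machinery runs on per-edge correlation
values; `long` then means anomalously *high* correlation (which
corresponds to *short* hyperbolic distance — the mode label records which
scale was used).

## What the synthetic generators do and do not emulate

`gen_block_timeseries()` draws zero-mean multivariate normal series with a
block-structured correlation target (within-block and between-block
levels). This reproduces the two features the pipeline relies on —
modular correlation structure and heavy-tailed degree sequences after
absolute-value thresholding — but deliberately omits hemodynamic
autocorrelation, scanner noise spectra, and acquisition artifacts. A green
test therefore establishes correctness of the *procedure* on data
satisfying its statistical assumptions, not robustness to fMRI-specific
noise.

`gen_s1_network()` draws graphs from the S1 model with known ground truth,
which is the only way to test parameter recovery; `gen_control_cohort()`
adds independent edge flips as measurement noise; `inject_anomaly()`
perturbs topology only (disconnecting pairs and decoupling their
neighborhoods, or connecting them), so injected anomalies are visible to
the entire pipeline rather than to a single stage. Default generator
settings (power-law exponent 2.7, inverse temperature 2.5, mean degree 10,
cohort sizes up to 134) mirror the regimes stated for the reference
analysis; where the reference states no value we chose once (e.g. 5%
edge-flip noise in cohort tests) and did not revisit.

## Numerical choices

* Strict inequality everywhere a value meets a threshold or cut
  (edges, flags), for determinism at ties.
* Largest-component ties break towards the component containing the
  smallest node index.
* Connection probabilities are clamped away from 0 and 1 before entering
  logarithms; the logistic is evaluated in its overflow-safe form.
* One integer seed per operation; internal child seeds are derived with a
  fixed 32-bit linear map, so every artifact is bit-reproducible from the
  run log.
* Scale of simulations in the shipped tests is reduced relative to the
  reference analysis (e.g. 3 recovery seeds instead of 5 for the
  end-to-end anomaly experiment, whose cohorts of 30 embedded controls
  dominate the runtime) to fit a single-CPU test budget; the acceptance
  tests state this where it applies.

## Known limitations

* Angular-density warping (above) limits raw-angle recovery at moderate
  mean degree; distances are the reliable currency.
* `infer_beta` estimates carry a sampling scatter of roughly ±0.2 at
  $N = 300$; downstream distances are only mildly sensitive to this.
* The RSGD benchmark and the ML disc embedding are different procedures
  with different objectives; their fidelity numbers are not comparable
  across modules.
* Weighted graphs, partial correlation, and dynamic connectivity are out
  of scope.
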