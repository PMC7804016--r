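---
title: "Density estimation in fenced reserves: models, masks and the permeability experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density estimation in fenced reserves: models, masks and the permeability experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Camera-trap surveys of large carnivores in fenced reserves face a modelling
decision with outsized consequences: is the fence a hard boundary for the
study species, or do animals move through it? Spatial capture-recapture
(SCR) integrates each animal's latent activity centre over a discretized
*state space* (the habitat mask). If the fence is assumed impermeable, the
mask is clipped to the fence polygon; if permeable, the mask extends in a
wide buffer beyond the detectors. Both choices are common in practice, and
for species such as the brown hyaena — which digs under and exploits holes
in fences — the clipped choice can inflate density estimates roughly
tenfold in small reserves. `fencescr` implements the full pipeline needed
to quantify this effect: capture-history construction, both mask
constructions, multi-session maximum-likelihood SCR, AICc selection,
derived quantities, and a simulation module with an explicit
fence-permeability parameter.

## The observation model

Detections are binary per individual $i$, occasion $s$ and proximity
detector $k$: $\omega_{isk} \in \{0, 1\}$, with paired cameras at a station
collapsed to a single detector (the pairing exists to photograph both
flanks, not to duplicate effort). Conditional on an activity centre $x$,

$$\Pr(\omega_{isk} = 1 \mid x) = g\!\left(d(x, k)\right),$$

where $g$ is one of three distance-decay detection functions with baseline
$g_0$ (detection probability at distance zero) and spatial scale $\sigma$
(km):

* half-normal: $g(d) = g_0 \exp(-d^2 / 2\sigma^2)$;
* hazard rate: $g(d) = g_0 (1 - \exp(-(d/\sigma)^{-z}))$, shape $z$;
* negative exponential: $g(d) = g_0 \exp(-d/\sigma)$.

Activity centres follow a homogeneous Poisson process with intensity
$D_r$ within each session (reserve) $r$. Over a mask of cells $x$ with
cell area $a$, the probability an animal centred at $x$ is ever detected is
$p_\cdot(x) = 1 - \prod_{s,k \text{ used}} (1 - g(d(x,k)))$, and the full
multi-session log-likelihood is

$$\ell = \sum_r \Big[ \sum_i \log\big(a \textstyle\sum_x D_r(x)
\Pr(\omega_i \mid x)\big) - a \sum_x D_r(x)\, p_\cdot(x) - \log n_r! \Big].$$

The $\log n_r!$ constant is retained so printed log-likelihoods are
comparable across density structures. A conditional (density-free) variant,
$\ell_c = \sum_r \sum_i \log( \sum_x \Pr(\omega_i|x) / \sum_x p_\cdot(x))$,
is provided for detection-only models; with homogeneous density the full
likelihood profiles to it, so the two modes share detection MLEs (a fact
the test suite exploits).

Model structures follow the conventions of multi-session SCR software:
density and $g_0$ may be constant, session-specific, or log-/logit-linear
in one z-scored session covariate; $g_0$ may instead carry a *learned
response* `b` — a permanent, global logit offset applied to an animal's
$g_0$ on occasions after its first capture. Terms for never-detected
animals ($p_\cdot$, the Poisson integral) always use the pre-response
$g_0$. $\sigma$ and $z$ are shared across sessions, matching the parameter
counts such models report (e.g. 15 densities + 15 $g_0$ + $\sigma$ + $z$ =
32 for a 15-session site-structured hazard-rate model).

### Links, optimisation and variances

Parameters are estimated on link scales — log for density (stored per
100 km²), $\sigma$ and $z$; logit for $g_0$; the learned response is an
additive logit offset. The likelihood is maximised by quasi-Newton search
(`nlminb`) with a relative tolerance of 1e-10; start values come from raw
detection rates ($g_0$), the bias-adjusted pooled RPSV ($\sigma$; squared
deviations of detection locations about each animal's centroid divided by
$2(\sum_i m_i - n)$ degrees of freedom), and detected individuals per mask
area ($D$). The covariance is the inverse of a central-difference Hessian
(relative step 1e-4 on the link scale); non-convergence and boundary
estimates ($|\mathrm{logit}\, g_0| > 8$) are flagged, never silent.

## Capture-history rules

* **Occasions** are 24-h windows from 12:00 to 11:59 the next day, so a
  nocturnal animal photographed either side of midnight yields one
  occasion, not two.
* **Flank selection**: both-flank records are always kept; single-flank
  records are kept only for the most frequently photographed flank at each
  site, with ties broken deterministically in favour of left (logged).
* **Binarisation**: repeated records of an animal at one detector within
  an occasion collapse to a single 1; usage matrices track station active
  windows, and records at inactive detectors are an error naming the rows.
* **RAI** (relative abundance index) is filtered captures per 100
  trap-days. The 30-minute independence filter chains sequentially — each
  retained capture opens a new window — which we chose over fixed bins
  because it is the common field convention; the window is an argument, so
  the alternative reading is one parameter away.
* **z-scores** use the sample (n−1) standard deviation by default, with a
  population-SD option.

## Habitat masks

Masks are square lattices (default spacing 0.5 km, the home-range-centre
spacing used throughout) anchored on an absolute grid: the bounding-box
lower-left is snapped down to a whole number of spacings and centres sit
half a spacing inwards. Anchoring on an absolute grid means clipped and
buffered masks of the same reserve share a lattice, so containment and
cell-matching are exact. Membership is by centre-point test; exclusion
polygons (areas uninhabitable to the species) are removed from both mask
types.

The buffered mask measures its width $W$ from the detectors, not the fence,
because the state space must cover the centres of all detectable animals;
this is the standard convention and the one we document for reproducing a
published buffer. `suggest_buffer()` supplies $W$ from a pilot RPSV
$\hat\sigma$ by inverting the detection tail in closed form
($g(W)/g_0 \le \tau$, default $\tau = 10^{-4}$), rounded up to a whole
number of cells. The tail-threshold heuristic was chosen over the
bias-projection algorithm of other software because it is closed-form and
directly testable; any published buffer (such as the 31 km used with
heavy-tailed hazard-rate fits at the original sites) can be passed
verbatim.

## Derived quantities

* `derived_density()`: Horvitz–Thompson, $\hat D_r = n_r / \hat a_r$ with
  $\hat a_r = a \sum_x p_\cdot(x; \hat\theta)$; the CV combines Poisson
  variance of $n_r$ with delta-method propagation of $\hat\theta$, and the
  95% interval is lognormal, $\hat D \exp(\pm 1.96 \sqrt{\log(1 + CV^2)})$
  — chosen for positivity, as the interval form was not otherwise pinned
  down.
* `region_n()`: expected $N = a\sum_x \hat D(x)$ and realized
  $N = n + a \sum_x \hat D(x)(1 - p_\cdot(x))$ over any sub-region of the
  fitted lattice.
* `fx_total()`: the combined activity-centre surface — per-animal centre
  posteriors plus the intensity of undetected centres — whose integral
  equals realized $N$ (asserted numerically in the tests).
* `aicc()` / `rank_models()`: AICc with $n$ = total individuals across
  sessions (the convention of the reference software; models within
  $\Delta\mathrm{AICc} < 2$ are flagged as retained).

## The permeability experiment

`run_dual_mask()` feeds *identical* capture histories to two fits that
differ only in the mask, returning paired per-session densities; the
per-session ratio $R = D_\mathrm{impermeable} / D_\mathrm{permeable}$ and
its unweighted mean are the headline quantities. The relationship of $R$
to reserve size $A$ is modelled by `fit_ratio_glm()` /
`compare_families()`: inverse-Gaussian, gamma and gaussian GLMs of
`ratio ~ reserve_size`, plus an intercept-only inverse-Gaussian null. We
use log links for the two positive families (the canonical $1/\mu^2$ and
$1/\mu$ links are numerically fragile on small, skewed ratio sets; the
link is an argument), identity for gaussian; degrees of freedom count the
dispersion, so the null model has df 2 and every slope model df 3.

## The simulator and what it does (not) emulate

`sim_config()` holds the true state: density (per 100 km²), detection
function and parameters, occasions, the generation margin, and the
permeability $\rho \in [0,1]$. Centres follow a homogeneous Poisson
process over the fence dilated by the margin (default $4\sigma$, covering
essentially all detectable centres), realised exactly by Poisson-thinning
a bounding-box proposal. Detection of an animal centred outside the fence
is scaled by $\rho$: $\rho = 1$ is a fully permeable fence (the fence is
invisible to movement), $\rho = 0$ fully impermeable. This one-parameter
bridge is the simplest formalisation of the two extremes studied at real
reserves, where per-site fence quality could not be quantified; $\rho$
values are scenario choices, not estimates of any real fence. Undetected
animals are dropped from the returned history but kept in a truth record
for recovery tests.

Defaults are the reference validation conditions: half-normal detection,
$D = 5$ per 100 km², $g_0 = 0.2$, $\sigma = 1$ km, 40 occasions, a
36-station array at 2 km spacing in a 400 km² reserve. The permeability
experiment instead uses reserves of 100–800 km² sharing one 25-station,
2-km array (a 5×5 block; holding the array fixed isolates the
reserve-size effect, and 36 stations cannot fit a 10 × 10 km reserve at
2 km spacing), $\sigma = 3$ km — realistic for a species whose home ranges
span tens to hundreds of km² — with $g_0 = 0.15$, $D = 8$ per 100 km², 30
occasions and $\rho = 1$. Problem sizes in the validation runs (200
recovery replicates at 1-km mask spacing; six replicates per reserve size;
20 GLM replicates of 60 sites) were chosen once as the smallest designs
that give stable Monte-Carlo summaries.

The simulator is deliberately simpler than reality: centres are static and
uniform (no habitat preference, no social structure), detection is
independent across occasions and stations given the centre, and
permeability is spatially uniform rather than concentrated at holes.
Passing tests therefore demonstrate that the estimation machinery is
correct and that the state-space mechanism alone reproduces the
qualitative inflation law — they do not certify any particular real-world
density, where movement behaviour, heterogeneous detection and fence
geometry all intrude.

## Numerical choices and degenerate inputs

* Log-sum-exp is used across mask cells; detection probabilities are
  floored at 1e-300 before logging (cells that far out carry zero counts).
* Likelihood oracle equivalence is enforced to 1e-10 against brute-force
  loop implementations on tiny instances (≤ 6 cells, ≤ 3 detectors, ≤ 3
  occasions), including the learned-response split at first capture.
* Halving the mask spacing changes $\hat D$ by < 2% on a reference
  simulated survey; 1-km spacing is used for simulation studies on that
  basis, 0.5 km remains the analysis default.
* Empty record sets, all-zero histories, zero-effort sessions, non-positive
  ratios under positive-only GLM families, masks smaller than one cell,
  and AICc with $n \le K + 1$ are all explicit errors, not warnings.

## Known limitations

Density surfaces are session-homogeneous (site-level covariates only);
non-Euclidean distance through fence holes, habitat-quality-weighted
masks, open populations, Bayesian fitting and sex-structured models are
out of scope. The learned response is the global permanent variant only.
Coordinates are planar kilometres from a user-supplied projection; the
package performs no geodesy.
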