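---
title: "Multi-model RBE-weighted fluence optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model RBE-weighted fluence optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionplan)
```

## The problem

Carbon-ion centers prescribe and evaluate dose in *RBE-weighted* units,
Gy(RBE): the photon dose that would produce the same biological effect as
the delivered ion dose. Different clinics use different radiobiological
models to perform that conversion — a local-effect-model (LEM-I-style)
tradition in Europe, microdosimetric-kinetic-model (mMKM / NIRS-MKM-style)
variants in Japan — and the models disagree systematically: the LEM-style
model predicts a higher RBE in the entrance / low-LET region, while
MKM-style models predict relatively more effect at high LET. A plan that is
numerically perfect in one model can therefore violate coverage or
constraint goals when recalculated in the other, which is a real obstacle
for transferring prescriptions and organ-at-risk (OAR) constraints between
centers.

`ionplan` implements the planning-side answer to this problem: a fluence
optimizer whose cost function can mix terms expressed in *several* RBE
models at once, assigning the most appropriate model per region of interest
(ROI), or duplicating target objectives in two models simultaneously. Three
scenarios structure its use:

* **A (single-model)** — all objectives and constraints in one model;
* **B (mixed-RBE)** — target objectives in a second model, OAR constraints
  kept in the first;
* **C (multi-RBE)** — target objectives duplicated in both models (equal
  priority by default), OAR constraints in the first.

Everything upstream of the optimizer — transport, per-voxel spectra — is
replaced by an analytic pencil-beam fixture on synthetic water phantoms, so
the whole chain is deterministic, fast, and testable on a laptop.

## Mixed-field linear-quadratic biology

Cell survival after a dose $d$ of radiation with LQ coefficients
$(\alpha, \beta)$ is $-\ln S = \alpha d + \beta d^2$. For a scanned plan,
voxel $i$ receives contributions $d_{ij} = $ (dose per unit fluence weight)
from many beamlets $j$, each arriving with its own LET and hence its own
table-derived $(\alpha_{ij}, \beta_{ij})$. The package uses the standard
mixed-field theorem (dose-weighted $\alpha$, dose-weighted $\sqrt\beta$):

$$D_i = \sum_j w_j d_{ij}, \qquad
  A_i = \sum_j w_j\,\alpha_{ij} d_{ij}, \qquad
  B_i = \sum_j w_j \sqrt{\beta_{ij}}\, d_{ij},$$

with per-fraction biological effect $E_i = A_i + B_i^2$ and mixed
coefficients $\alpha_{\text{mix}} = A_i / D_i$,
$\sqrt{\beta}_{\text{mix}} = B_i / D_i$. The RBE-weighted dose inverts the
photon reference curve $\alpha_x D + \beta_x D^2 = E$:

$$D_{\text{RBE},i} =
  \frac{\sqrt{\alpha_x^2 + 4 \beta_x E_i} - \alpha_x}{2\beta_x},$$

with the linear limit $E_i/\alpha_x$ for $\beta_x = 0$. Effects are
computed per fraction (the LQ model is fraction-wise) and totals scale
linearly with the fraction count; a model may additionally carry a clinical
scaling factor applied after the inversion (the NIRS-style "clinical dose"
convention). Prescriptions convert between unit systems by a median-dose
factor; the packaged pelvic case uses the published 1.153 value:
$1.153 \times 3.60 = 4.15$ Gy(RBE) per fraction, $66.4$ vs $57.6$ Gy(RBE)
in 16 fractions.

An `influence_set` stores $d_{ij}$ once (sparse, beamlet-major) together
with precomputed $a_{ij} = \alpha_m(\text{LET}_{ij}) d_{ij}$ and
$b_{ij} = \sqrt{\beta_m(\text{LET}_{ij})}\, d_{ij}$ blocks for *every*
registered model on the shared sparsity pattern — this is what lets one
optimization evaluate several models' doses cheaply. Each beamlet carries
its own LET at a voxel (per-field table lookup); cross-beam mixing happens
through the $a/b$ summation.

## The analytic beam fixture

The pencil-beam kernel is depth-dose × lateral Gaussian:

* **Depth-dose** (per unit weight, peak value exactly 1): a Bragg-peak
  Gaussian of width `peak_sigma` (3 mm default) on an entrance plateau.
  The plateau starts at `entrance_ratio` (0.35) of the peak and rises 15%
  between the surface and $R - 2\sigma_p$; beyond the peak a fragmentation
  tail of relative amplitude `tail_fraction` (0.05) decays exponentially
  over `tail_length` (20 mm). The normalization makes the stated
  entrance-to-peak ratio exact, which the tests rely on.
* **Dose-averaged LET**: rises from `let_entrance` (13 keV/µm) to
  `let_peak` (80 keV/µm) as $(z/R)^q$ with $q = 3$ (carbon-like convexity),
  then relaxes linearly back to the entrance value over the tail.
* **Lateral spread**: $\sigma(z) = \sigma_0 (1 + 0.5\, z/R)$; the 2-D
  Gaussian is normalized so its plane integral is the fluence weight, and
  entries are cut at the larger of $3\sigma$ and the $10^{-4}$
  relative-dose radius ($\approx 4.29\sigma$), bounding the truncated mass
  at $10^{-4}$.

Beams are axis-aligned (the multi-beam case uses three orthogonal beams in
place of non-coplanar gantry angles); water-equivalent depth equals
geometric depth on the uniform phantom; spot lattices are centered on the
target footprint midpoint so mirror-symmetric problems stay exactly
symmetric; energy layers step at `layer_spacing` across the target depth
extent plus margin. Phantoms, spot placement and kernels are fully
deterministic.

What the fixture does **not** emulate: nuclear fragmentation spectra,
tissue heterogeneity, ripple filters, and genuinely non-coplanar geometry.
Passing tests therefore demonstrate the *optimization and evaluation
machinery* and the qualitative inter-model physics, not agreement with any
patient dataset.

## Fixture RBE tables and their calibration

The packaged tables are declared fixture values shaped to reproduce the
clinically observed divergence pattern at desk scale:

* `LEMlike`: $\alpha(L) = 0.10 + 0.26\,(1 - e^{-L/18})$ — steep low-LET
  rise, early saturation, so its RBE dominates in the entrance region;
* `MKMlike`: $\alpha(L) = 0.10 + 0.18\,(1 - e^{-L/95})
  + 0.34/(1 + e^{-(L-61)/6})$ — well below the LEM-like curve at low LET,
  overtaking it near the mixed-field LET of a mid-depth SOBP;
* `NIRSlike`: the MKM tables with clinical scale 0.8794;
* $\beta(L) = \beta_x = 0.05$ Gy⁻² for all three;
  $\alpha_x = 0.1$ Gy⁻¹, i.e. $(\alpha/\beta)_x = 2$ Gy.

Two properties were calibrated once, then frozen. First, the crossover of
the two $\alpha$ curves is centered on the median mixed-field LET
(~54–61 keV/µm) of the packaged targets, so the LEM-like and MKM-like
doses disagree in *opposite directions* on the low-LET and high-LET
portions of a target — the mechanism behind the scenario phenomenology.
Second, the NIRS clinical scale is the measured median LEM/MKM dose ratio
on the two-beam target divided by 1.153, so that the LEM-like dose is
1.153 × the NIRS-like clinical dose on the SOBP plateau, matching the
published prescription-conversion convention.

A note on geometry: with **two opposite beams**, every target voxel mixes
a proximal contribution of one beam with the distal contribution of the
other, and the per-voxel mixed LET becomes almost uniform (the measured
LEM/MKM ratio spread is ~±1.3%). Model disagreement is then a nearly
uniform scale factor — which is why the pelvic-like two-beam case passes
coverage in every scenario and is used to study the median-dose scaling
factor. With **three orthogonal beams** the proximal-for-all and
distal-for-all corners of the target see genuinely different LET mixtures
(~3× the spread), and the single-model scenarios fail the other model's
coverage goal — this is the packaged case that exhibits the
coverage-failure pattern.

## Optimizer

The objective is a weighted sum of quadratic penalties on the total
RBE-weighted dose of each term's ROI in each term's model:

$$F(w) = \sum_t \frac{p_t}{|R_t|} \sum_{i \in R_t}
  \mathrm{pen}_t\!\left(D^{m_t}_i\right),$$

with `uniform` $(D-P)^2$, `max_dose` $\max(0, D-L)^2$, `min_dose`
$\max(0, L-D)^2$, and `dvh_max` applying the overdose penalty only to
voxels exceeding the level beyond the allowed volume (the allowed hottest
voxels are exempt, recomputed each iteration, ties broken by voxel index).
The gradient is exact via the chain rule through the LQ inversion:
$\partial D_i / \partial w_j = s\,(a_{ij} + 2 B_i b_{ij}) /
\sqrt{\alpha_x^2 + 4\beta_x E_i}$, with $s$ the fraction count times the
clinical scale.

The solver is projected-gradient descent on $w \ge 0$ with
Barzilai–Borwein step lengths and Armijo backtracking (sufficient-decrease
constant $10^{-4}$, at most 40 halvings); it stops when the projected
gradient's infinity norm falls below `grad_tol` (relative to its initial
value) or at `max_iter`. The objective trace is monotone over accepted
steps and the run is deterministic: initialization is uniform weights
scaled so the mean target physical dose times a nominal RBE of 2 matches
the first target prescription. Tests check analytic gradients against
central differences, the closed-form single-voxel optimum, a nonnegative
least-squares active-set oracle, and `optim`'s L-BFGS-B as an independent
cross-check.

Scenario construction turns a `scenario_config` into cost terms: per
target model a `uniform` term at that model's prescription plus a
`min_dose` term at the same level with twice the priority (the usual
clinical emphasis on coverage — without it the symmetric uniform penalty
lets the abutting-OAR pull drag the 95%-coverage statistic just below its
goal), and per OAR constraint a `max_dose`/`dvh_max` term in the OAR
model. OAR constraints are soft penalties; a goal checker reports
violations afterwards, mirroring clinical-objective workflows.

## Evaluation conventions

DVH statistics use the discrete descending-sort convention with ceiling
indexing and no interpolation: $D_{x\%}$ is the $\lceil xn/100 \rceil$-th
hottest voxel's dose; $D_{v\,\mathrm{cc}}$ converts volume to
$\lceil v / v_{\text{voxel}} \rceil$ voxels; $V_D$ counts voxels at or
above the level; ties include all tied voxels. The homogeneity index is
$\mathrm{HI}\,[\%] = 100\,(D_{2\%} - D_{98\%})/D_{50\%}$ (≲17% is the
usual acceptability bound), invariant under dose scaling. $F_{\text{scal}}$
is the ratio of CTV median doses between two models' reconstructions of
the same plan. Goal comparisons are inclusive (achieving exactly the
threshold passes). Ratio maps are flagged undefined below 1% of the
reference maximum rather than dividing by near-zero dose. Mean dose is the
arithmetic voxel mean (the grids are uniform). All operators are tested
against exhaustive sort-and-count oracles.

## Packaged study conditions

* `two_beam` — pelvic-like: 48 × 48 × 28 grid at 2.5 mm (~65k voxels),
  40 × 40 × 30 mm box CTV (~48 cc) with an abutting OAR, two opposite
  beams, ~1400 beamlets, 16 fractions, prescriptions 66.4 / 57.6 Gy(RBE)
  (LEM-like / NIRS-like), coverage goals V ≥ 95% at 63.08 / 54.72.
* `three_beam` — head-and-neck-like: 40³ grid at 2.5 mm, 16 mm-radius
  spherical CTV with an abutting OAR, three orthogonal beams (~1000
  beamlets), 20 fractions, equal 60 / 60 Gy(RBE) prescriptions (LEM-like /
  MKM-like share the photon endpoint), coverage goal V₅₇ ≥ 95% in both.
* `mini` — a small two-beam variant for examples and fast tests.

Problem sizes were chosen so a full scenario solves in well under a minute
on one CPU while retaining several-voxel penumbra and a multi-layer SOBP;
beam parameters (6 mm spots, 5 mm layers, σ₀ = 4 mm) are typical scanned
carbon values. Solver budgets are 200 iterations (300 for `mini`) at
`grad_tol` 1e-5, which the descent diagnostics show is past the point
where the clinical metrics move.

## Numerical choices and degenerate inputs

Interpolation of the α/β tables is linear with end-value clamping outside
the grid. Sparse kernels drop entries below 1e-7 of the kernel maximum.
Zero-dose voxels contribute zero gradient; `dvh_max` ties break by voxel
index so runs are reproducible across platforms. Degenerate inputs error
eagerly: zero-volume ROIs, CTVs outside the grid, non-axis-aligned beams,
beamlet ranges beyond the grid, negative weights, empty α/β tables,
non-increasing LET grids, zero median dose in HI, ROIs smaller than a
requested absolute volume.

## Known limitations

The fixture's LET model is a single effective curve per beamlet, not a
spectrum; fragmentation, heterogeneity and setup/range uncertainty are out
of scope; OAR constraints are soft; DVH percentiles are non-interpolated
(a half-voxel bias at small ROI sizes); and the fixture tables are
calibrated caricatures of the clinical model families — adequate for
demonstrating the optimization framework's behaviour, not for quantitative
clinical claims. Plans in this package are per-fraction-weight scaled by
fraction count; intra-course re-optimization is not modelled.
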