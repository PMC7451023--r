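---
title: "Surface plasticity of conformational ensembles: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface plasticity of conformational ensembles: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfplast)
```

## The problem

Antibody paratopes and antigen epitopes are not static shapes: the binding
interface of a protein explores an ensemble of conformations in solution,
and where — and how much — the molecular *surface* fluctuates carries
mechanistic information. Experimentally suggested epitopes tend to be the
most rigid patches of an antigen surface, paratopes tend to be floppy
before binding and rigidify afterwards, and the binding-competent shape is
typically already present in the free ensemble (conformational selection).
`surfplast` quantifies these effects from conformational ensembles
(multi-model PDB files, e.g. frames of a gaMD trajectory) with a
density-based *surface plasticity* field, together with the companion
analyses one needs around it: superposition and RMSF, Cartesian principal
component analysis, Boltzmann reweighting of boosted (gaMD) samples, and
binding-competent-state occupancy statistics.

## The plasticity model

For every frame $t$ a smooth density is built by placing a unit-amplitude
Gaussian on each atom center:

$$\rho_t(\mathbf{x}) = \sum_{i=1}^{N}
  \exp\!\left(-\frac{\lVert\mathbf{x}-\mathbf{r}_i(t)\rVert^2}
  {2\sigma^2}\right)$$

on a regular grid. Across frames the per-voxel temporal mean
$\bar\rho(\mathbf{x})$ and population standard deviation
$s(\mathbf{x})$ are accumulated (Welford's streaming update, so a million
frames cost no extra memory). An isovalue of the mean field draws a
typical protein surface; the SD field is the *plasticity*: it is large
exactly where space is sometimes protein-occupied and sometimes solvent.
A further Gaussian smoothing of the SD grid suppresses voxel noise and
emphasizes contiguous flexible regions. Finally the smoothed SD field is
sampled (trilinearly) at each atom's time-averaged position and averaged
per residue, giving the localized plasticity values that can be written
into the B-factor column for surface coloring.

Frames are superposed (Kabsch, iterated-mean reference, C$\alpha$ fit,
reflections excluded) before gridding, otherwise global tumbling would be
indistinguishable from internal plasticity; `align = FALSE` is available
for pre-aligned input.

### Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `kernel_sigma` | 1.5 | Å | per-atom Gaussian width; heavy-atom scale |
| `spacing` | 0.5 | Å | grid voxel edge |
| `padding` | 6 | Å | margin around the bounding box ($= 4\sigma$) |
| `cutoff_sigmas` | 4 | – | kernel truncation (per-axis box) |
| `smooth_sigma` | 1.5 | Å | SD-field smoothing width |

Plasticity magnitudes depend on `kernel_sigma` and `smooth_sigma`; they
are therefore echoed into every result object and into the pipeline
manifest, and systems meant to be compared are always computed on one
shared grid geometry and should be displayed on one color scale
(`run_pipeline()` enforces the shared geometry automatically when given
several labeled ensembles). The unit kernel amplitude — rather than a
normalized density — keeps a given isovalue meaningful independently of
atom count. The kernel truncation is implemented as a per-axis box of
half-width $4\sigma$, a superset of the spherical cutoff: with the default
padding the frame density integral conserves the analytic Gaussian mass
$N(2\pi\sigma^2)^{3/2}$ to well under 0.5%.

## RMSF

`compute_rmsf()` uses the standard definition
$\mathrm{RMSF}_i = \sqrt{\tfrac1T\sum_t \lVert \mathbf r_i(t) -
\langle\mathbf r_i\rangle\rVert^2}$ with population ($1/T$) normalization,
the common trajectory-analysis convention; per-residue values are the
arithmetic means over each residue's atoms. RMSF and plasticity are
complementary: large side-chain RMSF need not change the surface shape,
which is why the density-based field is the primary statistic and RMSF
the familiar cross-check.

## Cartesian PCA, gaMD reweighting and free-energy surfaces

`fit_pca()` eigendecomposes the $3N \times 3N$ covariance of the
(aligned) C$\alpha$ Cartesian coordinates, via SVD of the centered
$T\times3N$ matrix, again with population normalization. Free-energy
surfaces over one or two PCs are weighted histograms,
$F = -\ln p$ in $k_BT$ units, shifted so the occupied minimum is zero;
empty bins are *flagged*, never assigned an arbitrary constant, which
keeps local-minima counting well defined.

Ensembles generated with Gaussian-accelerated MD are biased by a per-frame
boost energy $\Delta V_t \ge 0$. The canonical weight
$e^{\beta\Delta V_t}$ is notoriously noisy, so the package uses the
standard Maclaurin-series approximation
$w_t = \sum_{k=0}^{K} (\beta\Delta V_t)^k / k!$ with default order
$K = 10$ (the exact exponential is available with `order = Inf` for
validation), normalized to mean 1. Weights are non-decreasing in $K$ and
bounded by the exponential, properties the test suite asserts.

When free and bound ensembles are compared, both are projected onto a
PCA basis fit to the *concatenated* aligned ensemble and binned on shared
edges — the symmetric choice when no single system is privileged — and
`population_shift()` reports, per PC, the ratio of occupied range (bins
with $F \le 3\,k_BT$ by default) and the difference in the number of
strict local minima (8-neighborhood in 2-D; plateaus are not minima;
empty bins act as infinitely high neighbors). Minima candidates are
restricted to the occupied region $F \le F_{\mathrm{cut}}$: without that
restriction, isolated single-count histogram bins in the far tails would
register as spurious conformational states.

`binding_competence()` Kabsch-fits every free-ensemble frame to a
reference conformation (e.g. the bound one) and reports the fraction of
frames within an RMSD cutoff. No universal cutoff exists — it depends on
system size and the question asked — so the cutoff is a required argument
and is always echoed in the report.

## The synthetic-ensemble generators

Real inputs are microsecond trajectories that cannot ship with a package,
so validation rests on generators whose statistics are known exactly:

* `sample_harmonic_ensemble()` draws i.i.d. frames
  $\mathbf r_i(t) = \mathbf r_i^0 + \sigma_{\mathrm{region}(i)}
  \boldsymbol\eta + \sum_m c_m(t)\,\mathbf d_{m,i}$ with
  $\boldsymbol\eta$ standard normal and $c_m \sim N(0, a_m^2)$: regions of
  prescribed flexibility plus optional collective (loop-like) modes. Its
  per-atom covariance is $\sigma^2 I + \sum_m a_m^2\,\mathbf d_m
  \mathbf d_m^{\top}$ exactly, the RMSF expectation is $\sigma\sqrt3$, and
  a planted mode is the exact PC1 — all recovered by the suite.
* `sample_toy_gamd()` runs a random-walk Metropolis chain on a 1-D
  boosted potential $V + \Delta V$, with the gaMD harmonic rule
  $\Delta V(x) = \tfrac12 k (E - V(x))^2$ below the threshold $E$. The
  defaults realize the double well $V(x) = (x^2-1)^2$ kcal/mol at 300 K
  with $E = 1$ kcal/mol (the barrier top, so wells are raised and the
  barrier untouched) and $k = 1/(E - V_{\min}) = 1$; proposal s.d.
  0.5 Å, 10% burn-in, no step adaptation — reproducibility over
  efficiency. The 1-D analytic Boltzmann integral provides an exact
  reference FES for the reweighting.

What the generators deliberately omit: kinetics (frames are independent —
every statistic computed here is time-order invariant), anharmonicity
beyond the collective modes, side chains, and solvent. Passing tests
therefore demonstrate the *estimators* are correct, not that any
particular biological system behaves harmonically.

Synthetic amplitudes are free parameters of the experiment designs: the
three-segment peptide (0.2 / 1.0 / 0.2 Å) contrasts rigid flanks with a
flexible loop at a five-fold amplitude ratio, and the free-vs-bound
"binding" experiment reduces interface amplitudes (0.9 → 0.3 Å, mode
1.2 → 0.4 Å) while keeping the scaffold at 0.3 Å — ratios of the order
seen between flexible loops and structured cores.

## Numerical choices and degenerate inputs

* Kabsch uses the sign-corrected SVD; configurations that are collinear
  (rank < 2 after centering) or have fewer than 3 atoms are geometry
  errors rather than silent garbage. Alignment to the iterated mean
  starts from the ensemble's current mean structure (falling back to
  frame 1 only if that mean is degenerate) and iterates until the mean
  moves < $10^{-10}$ Å (at most 50 rounds); starting from the mean rather
  than a frame-1 pre-fit makes re-aligning an already aligned ensemble a
  no-op to $\sim 10^{-9}$ Å (idempotence), which a looser stopping rule
  cannot guarantee.
* Grid statistics use Welford's one-pass update; a static ensemble yields
  an *exactly* zero SD field, and duplicated frames leave mean and SD
  unchanged to machine precision.
* Smoothing uses a discretely normalized separable kernel with zero
  padding: interior constants are preserved, total mass never increases.
* Isosurfaces use marching tetrahedra (six tetrahedra per voxel sharing
  the main diagonal), which needs no case table and produces meshes whose
  vertices lie within one voxel of the true level set — for a unit
  Gaussian atom the 0.5-isovalue vertices sit at
  $\sigma\sqrt{2\ln 2} \approx 1.177$ Å.
* `reweighted_fes()` histograms on explicitly shareable ranges so two
  surfaces can be compared bin-by-bin; weights must be strictly positive;
  min-shift normalization is a projection (idempotent).
* Single-frame SD grids and sub-minimal inputs (T < 2 for RMSF/PCA,
  < 3 fit atoms, empty selections, mismatched boost lengths) raise typed
  errors at the point of use.

## Problem sizes used in the shipped validation

The suite recovers ground truth at sizes chosen to make sampling error
small relative to the asserted tolerances: $10^4$ frames for the RMSF
closed form (2%), 100 seeds × 2000 frames for the plasticity
localization contrast, $2\times10^5$ Metropolis samples for the
reweighted barrier (0.5 $k_BT$ of the analytic value), $10^6$ draws for
the independent RMSD-distribution oracle behind the competent-fraction
check, and 800-frame free/bound pairs for the interface-rigidification
contrast. `scripts/acceptance.R` re-runs the same experiments end to end
from a single seed.

## Known limitations

* Plasticity magnitudes are kernel-dependent; only values computed with
  identical parameters on a shared geometry are comparable.
* The localized value samples the smoothed SD at the *mean* atom
  position; for very large excursions a per-frame sampling average would
  differ (the mean-position convention matches the surface-coloring use
  case).
* Multi-model PDB is the only built-in trajectory format; binary formats
  would enter through the same `structure_ensemble` contract.
* The toy gaMD system is 1-D; the reweighting arithmetic is
  dimension-agnostic, but multi-dimensional boost statistics (e.g.
  anisotropic noise in $\Delta V$) are not emulated.
* No mass weighting, no solvent, no per-element kernel radii by default
  (an element-scaled kernel can be emulated by calling
  `frame_density_grid()` per element class).
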