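---
title: "A mechanochemical wave model of calvarial bone expansion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical wave model of calvarial bone expansion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteowave)
```

## The biological problem

During skull morphogenesis the flat calvarial bones expand toward the
midline through intramembranous ossification: undifferentiated mesenchymal
progenitors convert to osteoblasts at the osteogenic front, the leading
edge of the bone. Live imaging of reporter-labelled explants shows three
things that any mechanistic account has to reproduce at once:

* the front advances steadily (of order 15 µm per 6 h ex vivo) while the
  cells tracked at the front advance distinctly less — new osteoblasts are
  added at the edge by differentiation rather than carried there;
* cell motility is position-dependent: near-ballistic at the front,
  diffusive deep in the collagen-rich, stiffer, more densely packed bone
  center;
* tissue stiffness is graded (bone center > front > mesenchyme), and
  perturbing that gradient changes bone size in a specific direction:
  excising the stiff center halts expansion, while chemically blocking
  collagen crosslinking — softening the front and steepening the gradient —
  *enlarges* the bone and flattens the reporter-intensity profile at the
  front.

`osteowave` implements a one-dimensional two-population continuum model
that couples these observations through a single mechanochemical feedback
loop, together with the complete quantification toolbox used on the
imaging-derived data, synthetic-data generators for every input modality,
and the one-parameter fit.

## The model

The tissue is a viscous two-component fluid on the medial–lateral axis
(+x = medial, the direction of expansion; the bone occupies small x). State
fields: mesenchyme density $\rho_m(x,t)$, osteoblast density $\rho_o(x,t)$,
net division rate $k(x,t)$, velocity $v(x,t)$; derived fields: total
density $\rho = \rho_m + \rho_o$, osteoblast fraction
$\phi = \rho_o/\rho$ (defined as 0 where $\rho = 0$).

$$
\partial_t \rho_m + \partial_x(\rho_m v) = D\,\partial_x^2 \rho_m
  + k\rho_m - \lambda(E)\,\rho_m
$$
$$
\partial_t \rho_o + \partial_x(\rho_o v) = D\,\partial_x^2 \rho_o
  + k\rho_o + \lambda(E)\,\rho_m
$$
$$
\partial_t k + v\,\partial_x k = -\bigl(k - \alpha(1 - \rho/\rho_0(\phi))\bigr)/\tau,
\qquad
\eta\,v'' - \xi v = \partial_x P .
$$

Differentiation converts mesenchyme to osteoblasts and therefore conserves
cell number; only the growth term $k\rho$ changes it. The force balance
pits pressure gradients against viscosity $\eta$ and friction $\xi$ with
the surrounding tissue layers (no inertia at these scales), with no-slip
walls $v = 0$ at both domain ends and no-flux boundaries for the densities.

### Closures

The mechanochemical loop is closed by four constitutive choices, each
isolated behind its own exported function so alternatives can be swapped:

* **Stiffness mixing** (`stiffness_of_phi`): osteoblasts deposit fibrillar
  collagen, so local stiffness interpolates linearly between the mesenchyme
  and bone values, $E(\phi) = E_m + (E_o - E_m)\phi$.
* **Differentiation rate** (`differentiation_rate`): mechanosensitive
  conversion increasing with stiffness,
  $\lambda(E) = \beta\,\mathrm{clamp}((E - E_m)/(E_o - E_m), 0, 1)$ — zero
  in soft mesenchyme, saturating at $\beta$, the model's single fitted
  parameter.
* **Homeostatic density** (`homeostatic_density`): linear in composition,
  $\rho_0(\phi) = \rho_{0,m} + (\rho_{0,o} - \rho_{0,m})\phi$; the bone
  center is more densely packed than mesenchyme.
* **Pressure** (`tissue_pressure`): a crowding term plus a matrix swelling
  term,
  $$P = E(\phi)\,\frac{\rho - \rho_0(\phi)}{\rho_0(\phi)}
      + c_s\,(E(\phi) - E_m)\,\frac{\rho}{\rho_0(\phi)} .$$

The swelling term deserves comment because it is what makes the mechanics
load-bearing. The crowding term alone relaxes to zero wherever growth has
restored homeostasis, so a tissue at rest exerts no net push regardless of
its composition; the differentiation wave then degenerates into a pure
reaction–diffusion (pulled, KPP-type) front in $\phi$ whose speed ignores
the stiffness field entirely — excising the bone center or rescaling the
stiffnesses leaves the front speed essentially unchanged, contradicting
both perturbation experiments. Physically, the collagen-rich matrix that
differentiated cells deposit is a hydrated, space-filling material: tissue
that is stiffer because of its matrix also carries a standing compressive
(swelling) stress. We model that stress as proportional to the local
stiffness excess over bare mesenchyme, weighted by the relative packing
$\rho/\rho_0(\phi)$ so that diluted tissue exerts proportionally less
push (and an excised, draining band loses its push as it thins). The
dimensionless coefficient $c_s$ is the swelling strain scale. With this
term the osteoblast domain is a pressure reservoir: the pressure ladder
across the front drives a medially directed flow that peaks at the front,
carries the tracked cells at a fraction of the front speed, and responds
in the experimentally observed direction to both perturbations.

### Default parameters

Defaults live in the versioned file `inst/extdata/default_params.yaml`, not
in code. No reference parameter table was available, so values are the
package's own calibration under three constraints taken from the
measurements the model is meant to reproduce: a stiffness ratio
$E_o/E_m \approx 3$, a packing ratio $\rho_{0,o}/\rho_{0,m} \approx 1.5$,
and a front advance of roughly 15 µm per 6 h.

| parameter | default | units | rationale |
|---|---|---|---|
| `E_m`, `E_o` | 1, 3 | kPa | embryonic-tissue scale; ratio 3 across the gradient |
| `rho0_m`, `rho0_o` | 1, 1.5 | cells/µm | denser packing in bone |
| `eta` | 2.5 | kPa·h | with `xi` sets the hydrodynamic length $\sqrt{\eta/\xi} = 10$ µm, localizing the velocity peak at the front |
| `xi` | 0.025 | kPa·h/µm² | sets flow magnitude ~1–2 µm/h near the front |
| `D` | 1 | µm²/h | effective nuclear diffusivity; matches the diffusive MSD scale of bone-center cells |
| `tau` | 5 | h | division-rate relaxation, cell-cycle scale |
| `alpha` | 0.15 | 1/h | maximal net growth rate (attained only far from homeostasis) |
| `beta` | 0.3 | 1/h | the fitted coupling; calibrated to the front rate |
| `c_swell` | 1.5 | — | swelling strain; sets the push so tracked cells move at ~2/3 of the front speed |

With these defaults the wave advances ≈ 14 µm per 6 h with a speed CV
below 1%, the co-moving $\phi$ profile collapses to a fixed shape, the
velocity profile peaks within a few µm of the $\phi = 1/2$ front, and the
front outruns the mean tracked cell by a factor ≈ 1.5 — each of these is
recomputed by the test suite and `scripts/acceptance.R`, never asserted
from this text.

## Numerics

Uniform node-centred grid (default 1 µm spacing over 1000 µm — fine enough
to resolve the ~4 µm reaction–diffusion front width, which a coarser grid
distorts), explicit Euler in time. Advection uses van Leer flux-limited
upwind fluxes by default: first-order upwind adds numerical diffusion
$|v|\Delta x/2$ comparable to $D$ itself at feasible resolutions and biases
the front speed by several percent between grid refinements; the limiter
restores second-order accuracy in smooth regions while preserving
positivity (`advection = "upwind"` remains available). Diffusion is
centred, in flux form, so that with growth off the total cell number is
conserved to round-off. The time step is capped at
$0.4\,\min(\Delta x^2/2D,\ 1/(\alpha + \beta + 1/\tau))$ and the advective
CFL number is asserted against the realized flow at every step; negative or
non-finite densities abort with the offending field named. The force
balance is a symmetric tridiagonal system solved by a sparse Cholesky
factorization computed once per run; a dense solve of the identical
discretization serves as the test oracle. The simulation asserts that the
detected front stays > 100 µm from both boundaries. Front detection scans
from the bone side and linearly interpolates the medial-most level
crossing; a profile sitting exactly at the level over a flat stretch
returns that stretch's medial end, and profiles that never cross raise a
"front not in domain" error rather than guessing.

Lagrangian tracers (the model's tracked nuclei) follow Euler–Maruyama
updates with bilinear interpolation of the saved velocity history and
reflecting boundaries, reproducible by seed; they are the only stochastic
element of the simulation stage.

## Quantification procedures

These mirror the measurement definitions used on the imaging data:

* **MSD** uses the from-origin definition
  $\mathrm{MSD}(T) = \langle|x_i(T) - x_i(0)|^2\rangle_i$ averaged over
  tracks only — not time-lag averaged — and refuses to interpolate
  mismatched time bases. Scaling exponents are log–log least-squares
  slopes on a stated window.
* **Velocity correlations** use centred finite-difference velocities
  (one-sided at track ends), normalized to unit vectors, with pairs binned
  by transverse distance; zero-velocity cells are excluded.
* **Division angles** are treated as plain circular data (90° = division
  parallel to the expansion axis), with mean angle, resultant length $R$,
  Rayleigh $z = nR^2$ and its standard p-value approximation; an axial
  option (angle doubling) is available behind a flag. The von Mises
  generator uses Best–Fisher rejection sampling and is checked against the
  Bessel-ratio $I_1(\kappa)/I_0(\kappa)$ oracle.
* **Daughter displacement** projects both daughter centroids onto the
  expansion axis relative to the metaphase-plate centroid; the daughter
  with the larger signed projection is "medial", and the paired magnitude
  difference is returned for a downstream paired test. Coincident
  centroids are zeroed and flagged.
* **Profile alignment** determines, per sample, a baseline as the mean
  over the annotated mesenchyme region and the alignment point as the
  first position exceeding 1.1× baseline, scanning from the mesenchyme
  toward the bone (the direction that makes "first exceeds"
  well-defined); distances into the bone are binned at 1 µm within
  sample, then averaged across samples. The front slope is the
  least-squares slope over 0–100 µm. The raw first-exceedance rule is
  exact for noiseless steps and shift-invariant, but it assumes the
  profile noise stays below the 10% threshold — appropriate because the
  profiles are transverse averages; per-point noise at or above ~5% makes
  the scan fire on baseline fluctuations, which is why the generators
  default to 1–2% noise.
* **Bone areas** threshold at a common intensity and keep the largest
  8-connected component (8- rather than 4-connectivity so diagonal
  junctions do not split the bone); the labelling is built on an
  8-neighbour pixel graph. Sub-threshold pixel values are provably
  irrelevant (tested by permutation).
* **Regional proliferation** counts mitosis-positive fractions in 100 µm
  windows ahead of, behind, and at the center of the bone; empty regions
  yield flagged NAs, never silent zeros.

## Synthetic data: what it does and does not emulate

The generators produce every input modality with the statistical structure
the analyses assume, so the whole pipeline runs and is tested without any
external data: persistent random walks with region-dependent persistence
(ballistic at the front, diffusive in the center), translating sigmoidal
intensity wavefronts with per-sample offset jitter and multiplicative
log-normal noise, von Mises division angles with biased paired daughter
displacements, and blob images with known ground-truth areas. Each
generator is a pure function of its specification and seed.

They deliberately do **not** emulate: inter-cell velocity coupling (tracks
are independent, so the spatial velocity correlation of synthetic data is
zero — collective motion enters only through the continuum model), nucleus
detection and tracking from raw movies, image stitching, 2D/3D tissue
geometry, or photorealistic microscopy noise. Passing tests on synthetic
data therefore validate the *procedures* (and parameter recovery under the
stated noise models), not the biology of any particular dataset.

The simulation-to-reporter map (`simulate_gfp_profiles`) models reporter
intensity as a saturating function of osteoblast age — the time since the
front passed — with a 60 h maturation scale, so intensity keeps rising
across the 0–100 µm analysis window and the front slope is proportional to
the inverse wave speed. That is the mechanism by which a faster
(crosslink-blocked) wave produces a shallower intensity slope.

## Perturbation protocols

*Excision* mirrors the explant surgery: a wave is first established, then
all tissue lateral of (front − 10 µm) is removed and both arms are observed
for 6 h, the imaging-session scale. The 10 µm retained band is the width of
the partially differentiated front zone in this model; retaining more keeps
mature, matrix-bearing bone whose swelling push persists, and keeping the
full bone reproduces the control exactly (a tested limit). *Gradient
steepening* multiplies $E_m$ by 0.5 and $E_o$ by 1.1 for the whole run,
emulating chronic crosslink inhibition during development; both arms are
compared on front trajectories, final osteoblast-domain size
($\phi \ge 0.5$), and aligned reporter-intensity slopes across seeded
replicates.

## Fitting

`fit_beta` minimizes the equally weighted summed squared residual between
simulated and observed normalized displacement curves of the front and the
mean tracked cell — the quantities the imaging analysis produces — over a
bracketing grid followed by golden-section refinement. The simulated cell
curve uses the deterministic mean tracer path ($D = 0$), making the
objective deterministic and smooth in $\beta$. The weighting is exposed
because the original objective is not fully specified; curves (rather than
endpoint speeds) are the default residual style. Recovery is verified on
synthetic truth: sub-percent error noiseless and a few percent under 5%
multiplicative observation noise. Fitting runs use a reduced scale (600 µm
domain, 24 h horizon) chosen so one fit costs ~35 simulations of ~0.5 s;
the recovered coupling is scale-independent because the wave is already
established at that size.

## Problem sizes

Defaults used throughout the tests and the acceptance script: a 1001-point
grid over 1000 µm for 48 h (about 1200 steps), one 4001-point refinement
run, 200-tracer ensembles, 800–2000 synthetic tracks, 500 division angles,
20-replicate slope comparisons, and 11 fits at the reduced fitting scale.
These sizes make every claim recomputable in minutes on one CPU while
keeping all stochastic checks comfortably inside their tolerance bands.

## Known limitations

* The model is 1D: transverse front roughness enters only through the
  `front_fluctuations` summary (RMS interface width and its log–log growth
  slope — a stand-in statistic, as the original fluctuation analysis is
  not fully specified), not through the dynamics.
* Collagen is not an explicit field; its mechanics are folded into
  $E(\phi)$ and the swelling term. Mineralization, osteocyte maturation
  stages, and fiber anisotropy are out of scope.
* The homeostatic bone state carries a residual swelling pressure
  $c_s(E_o - E_m)$; pressures are therefore defined up to the convention
  that *mesenchyme* at homeostasis is the zero reference.
* Explicit time stepping bounds `dt` by the diffusion number; a stiffer
  (implicit) scheme would be needed for much larger `D` or much finer
  grids than the defaults.
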