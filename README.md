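# osteowave

Mechanochemical waves of osteoblast differentiation in calvarial bone
expansion: a 1D continuum model, its analysis toolbox, and an end-to-end
synthetic-data pipeline.

During skull development the flat calvarial bones expand toward the midline
as mesenchymal progenitors differentiate into osteoblasts at the osteogenic
front. Live imaging shows a puzzle: the front advances faster than the
cells tracked at it, cell motility degrades from ballistic at the front to
diffusive in the stiff, dense bone center, and perturbing the tissue
stiffness gradient changes bone size — removal of the stiff center halts
expansion while softening the front (by blocking collagen crosslinking)
*enlarges* the bone. `osteowave` is for quantitative developmental
biologists and biophysicists who want to simulate, fit, and interrogate the
mechanochemical feedback that reconciles these observations, and to run the
corresponding image-derived quantifications on their own (or synthetic)
data.

## The model

Two cell populations on the medial–lateral axis (+x = medial), mesenchyme
ρ_m and osteoblasts ρ_o, advected by a tissue flow v and coupled by
stiffness-dependent differentiation:

    ∂t ρ_m + ∂x(ρ_m v) = D ∂x² ρ_m + k ρ_m − λ(E) ρ_m
    ∂t ρ_o + ∂x(ρ_o v) = D ∂x² ρ_o + k ρ_o + λ(E) ρ_m
    ∂t k   + v ∂x k    = −(k − α(1 − ρ/ρ0(φ)))/τ
    η v″ − ξ v         = ∂x P

with φ = ρ_o/ρ, linear stiffness mixing E(φ) = E_m + (E_o − E_m)φ,
differentiation rate λ(E) = β·clamp((E − E_m)/(E_o − E_m), 0, 1) (β is the
single fitted parameter), and an equation of state combining crowding and
matrix swelling:

    P = E(φ)(ρ − ρ0(φ))/ρ0(φ) + c_s (E(φ) − E_m) ρ/ρ0(φ).

Differentiation raises local stiffness (collagen deposition), higher
stiffness raises the differentiation rate, and the swelling stress of the
deposited matrix pushes tissue medially: the loop self-propagates as a
traveling wave whose front outruns the cells it carries. The methods
vignette (`vignettes/osteowave-methods.Rmd`) derives every closure and
documents all defaults.

## Worked example

```r
library(osteowave)

params <- sim_params()            # defaults from inst/extdata/default_params.yaml
sim    <- simulate_wave(params)   # deterministic PDE integration, 48 h
traj   <- front_trajectory(sim)   # phi = 1/2 front position vs time
front_speed(traj)$speed * 6
#> [1] 14.19790
obs <- displacement_observables(sim, t0 = 24, duration = 6,
                                n_tracers = 200, seed = 7)
obs$speed_ratio
#> [1] 1.569066
```

The wave advances 14.2 µm per 6 h and outruns its tracked cells by a
factor 1.57 — differentiation adds new osteoblasts at the edge, so the
front is not a material surface. Fitting the coupling back from these
curves recovers it to a fraction of a percent:

```r
fp    <- sim_params(domain_length = 600, n_grid = 601, t_end = 24,
                    x_front0 = 250, save_every = 1)
truth <- displacement_observables(simulate_wave(fp), n_tracers = 1, D = 0)$curves
fit_beta(truth, fp)
#> <beta_fit> beta_hat = 0.3000 1/h (objective 1.51e-08, 36 simulations, converged)
```

The in-silico perturbations reproduce the experimental directions:

```r
scenario_excision(sim_params(t_end = 24))$displacement_ratio
#> [1] -0.03639728      # excised explant: the front stalls (−4% of control)
gs <- scenario_gradient_steepening(sim_params())   # softer front, stiffer center
c(gs$domain_control, gs$domain_treated)
#> [1] 564 592           # crosslink block enlarges the osteoblast domain
```

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | default-configuration wave, front trajectory, collapse and speed diagnostics |
| `02_track_statistics.R` | synthetic track MSD per region, velocity correlations, model tracers vs front |
| `03_divisions_and_profiles.R` | division-angle circular statistics, daughter displacement, profile alignment and slope, bone-area segmentation, regional proliferation |
| `04_fit_beta.R` | single-parameter fit with objective curve and post-fit predictions |
| `05_perturbations.R` | bone-center excision and stiffness-gradient steepening scenarios |

Run any of them as `Rscript analysis/01_simulate.R` from the repository
root. `run_pipeline()` offers the same stages as a single call with a
digest-carrying run manifest.

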