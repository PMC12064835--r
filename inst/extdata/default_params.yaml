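# Default model configuration (versioned; see the methods vignette for the
# rationale behind every value).
#
# Mechanics and cell biology
E_m: 1.0        # stiffness of undifferentiated mesenchyme (kPa)
E_o: 3.0        # stiffness of osteoblast tissue (kPa); E_o/E_m = 3
rho0_m: 1.0     # homeostatic mesenchyme density (cells/um, 1D-projected)
rho0_o: 1.5     # homeostatic osteoblast density (cells/um); 1.5x denser bone
eta: 2.5        # tissue viscosity (kPa h); hydrodynamic length sqrt(eta/xi) = 10 um
xi: 0.025       # friction with surrounding layers (kPa h / um^2)
D: 1.0          # effective cell diffusivity (um^2/h)
c_swell: 1.5    # matrix swelling strain scale (dimensionless)
tau: 5.0        # relaxation time of the net division rate (h)
alpha: 0.15     # maximal net growth rate (1/h)
beta: 0.3       # differentiation-stiffness coupling (1/h); the fitted parameter
#
# Numerics and run control
domain_length: 1000.0   # um
n_grid: 1001            # grid nodes (1 um spacing)
dt: 0.04                # h (capped further by the stability bound at run time)
t_end: 48.0             # h
x_front0: 450.0         # initial osteogenic front position (um)
save_every: 2.0         # h between saved states
advection: vanleer      # advection scheme: vanleer | upwind
seed: 1
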