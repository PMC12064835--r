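#!/usr/bin/env Rscript
# Simulate the osteoblast differentiation wave under the default
# configuration and record its basic wave observables. The run demonstrates
# that stiffness-differentiation feedback plus matrix swelling produces a
# constant-speed traveling front whose shape is invariant in the co-moving
# frame.

suppressPackageStartupMessages(library(osteowave))
dir.create("results", showWarnings = FALSE)

params <- sim_params()
print(params)

sim <- simulate_wave(params)
write_states(sim, "results/states")

traj <- front_trajectory(sim)
sp <- front_speed(traj)
col <- profile_collapse_rms(sim)
cat(sprintf("\nFront speed: %.2f um/h (%.1f um per 6 h), CV %.2f%%\n",
            sp$speed, 6 * sp$speed, 100 * front_speed_cv(traj)))
cat(sprintf("Co-moving profile collapse RMS: %.2e\n", col$rms))

last <- length(sim$times)
f <- detect_front(sim$x, sim_phi(sim)[last, ])
cat(sprintf("Velocity peak %.1f um from the front (max %.2f um/h)\n",
            sim$x[which.max(sim$v[last, ])] - f, max(sim$v[last, ])))

utils::write.csv(traj, "results/front_trajectory.csv", row.names = FALSE)
jsonlite::write_json(
  list(front_speed_um_per_h = sp$speed,
       front_advance_um_per_6h = 6 * sp$speed,
       front_speed_cv = front_speed_cv(traj),
       collapse_rms = col$rms,
       v_peak_offset_um = sim$x[which.max(sim$v[last, ])] - f),
  "results/wave_summary.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/states/, results/front_trajectory.csv, results/wave_summary.json\n")
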