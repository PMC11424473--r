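#!/usr/bin/env Rscript
# Calibration script: re-derives the package's default parameters from their
# documented goals. Running it prints the sweeps behind the shipped defaults
# and verifies the goals with marginflow::calibrate_defaults(). Expect a few
# minutes of runtime.
#
# Goals (in order):
#   1. 1D: supercritical mechanical feedback -- beta * zeta * sech(alpha)^2 > 1.
#   2. 1D: steady contracting fraction 0.37 +/- 0.02 (control embryos), with
#      fronts sharp enough that the fraction is invariant (±5%) across margin
#      lengths L0, L0/2, L0/4 and insensitive to grid refinement.
#   3. 2D: anterior inhibition -- no ectopic focus in intact runs over >= 10 h.
#   4. 2D: half-obstacle marginality -- an ectopic focus forms at the default
#      tension-propagation range and is suppressed by a <= 20% range increase.

suppressPackageStartupMessages(library(marginflow))

cat("== 1D calibration ==\n")
cat("Fixed choices: zeta = 0.75, beta = 6 (comfortably supercritical),\n")
cat("D = 0.00125 (front width sqrt(D*tau) ~ 0.035, sharp enough for the\n")
cat("length-scaling invariance), n_grid = 1024 (>= 5 points per front).\n")
cat("Sweep alpha for a steady contracting fraction of 0.37:\n")
for (alpha in seq(-1.3, -1.1, by = 0.05)) {
  sim <- simulate_1d(params_1d(alpha = alpha), "posterior_bias",
                     t_end = 160, save_every = 2000)
  fr <- domain_fraction(sim$states[[length(sim$states)]])
  cat(sprintf("  alpha = %5.2f -> fraction %.3f%s\n", alpha, fr,
              if (abs(fr - 0.37) <= 0.02) "  <- within goal" else ""))
}
cat("Shipped default: alpha = -1.2.\n\n")

cat("== 2D calibration ==\n")
cat("Fixed choices (see the methods vignette for rationale): delta_c = 0.5\n")
cat("and lam = 0.5 so the low-contractility margin can transmit tension\n")
cat("without yielding prematurely; Ts = 3 so margin-line transmission\n")
cat("dominates the bulk; beta = 4.5, just above the quiescent instability\n")
cat("threshold so interrupted tension propagation ignites a focus within\n")
cat("hours while stretched regions stay quiescent.\n")
cat("friction0 is the marginality knob base: sweep the half-obstacle\n")
cat("scenario over the range knob (screening length multiplier):\n")
site_foci <- function(range_scale) {
  tr <- simulate_scenario(scenario_spec("obstacle", obstacle = "half",
                                        t_end = 12),
                          params_2d(range_scale = range_scale),
                          record_every = 3, tracer_spacing = NA,
                          flow_snapshots = 1L)
  f <- contraction_foci(tr$margin[[length(tr$margin)]])
  nrow(f[f$ectopic & abs(f$theta_mid) > 100, ])
}
for (rs in c(0.9, 1.0, 1.05, 1.1, 1.2)) {
  cat(sprintf("  range x %.2f -> ectopic foci %d\n", rs, site_foci(rs)))
}
cat("Shipped default friction0 = 0.0166 places the defaults just inside\n")
cat("the focus-forming regime; a ~10% range increase suppresses it.\n\n")

cat("== Goal verification (calibrate_defaults) ==\n")
res <- calibrate_defaults("all")
print(res$report, row.names = FALSE)
if (!all(res$report$satisfied)) {
  cat("NOT all goals satisfied -- defaults need recalibration.\n")
  quit(status = 1)
}
cat("All goals satisfied.\n")
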