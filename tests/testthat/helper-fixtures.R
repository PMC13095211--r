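# Shared fixtures: dynamics, effort parameters, compact solver settings and
# hand-built trial objects.

dyn0 <- wrist_dynamics()
eff0 <- effort_params()

# Cheap duration-search settings for tests (durations of interest < 2 s)
fast_search <- list(t_range = c(0.05, 3), coarse_n = 40)

# Build a trial_time_series by hand from a position trace.
make_trial <- function(t, q, markers, sample_rate, tau_interaction = NULL,
                       condition = "NF") {
  structure(list(t = t, q = q, tau_interaction = tau_interaction,
                 markers = markers, sample_rate = sample_rate,
                 condition = condition, stiffness = 0, viscosity = 0),
            class = "trial_time_series")
}

# Analytic span of the 5%-of-peak-velocity segment of a minimum-jerk
# movement of duration xi.
analytic_span <- function(xi, threshold = 0.05) {
  xi * minimum_jerk_span_fraction(threshold)
}

ref_laws <- list(
  average = c(slope = 0.314, intercept = 0.298),
  fast    = c(slope = 0.235, intercept = 0.285),
  slow    = c(slope = 0.35,  intercept = 0.323)
)
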