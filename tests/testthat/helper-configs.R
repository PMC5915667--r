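# A fully deterministic cohort: noise-free archetype chains, zero trajectory
# noise, fixed visit grid (six in-window CVPAs), no funnel violations.
noise_free_config <- function(n, patterns = c("self-contained", "shared",
                                              "participatory"), seed = 1) {
  tp <- trajectory_defaults()
  tp[["compensated"]]$sd <- 0
  simulation_config(
    n_patients = n,
    pattern_mix = stats::setNames(rep(1 / length(patterns), length(patterns)),
                                  patterns),
    transition_matrices = pattern_archetypes("noise_free"),
    segment_mix = c("compensated" = 1),
    trajectory_params = tp,
    visit_interval_days = 61, visit_jitter_days = 0, test_jitter_months = 0,
    adherence_violation_rate = 0, comorbidity_rate = 0, single_test_rate = 0,
    seed = seed
  )
}
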