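test_that("configuration invariants are enforced by field", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(pattern_mix = c("shared" = 0.5)), "pattern_mix")
  bad_tm <- pattern_archetypes()
  bad_tm[["shared"]]$transition[1, ] <- c(0.5, 0.4, 0.2)
  expect_error(simulation_config(transition_matrices = bad_tm),
               "row-stochastic")
  expect_error(simulation_config(adherence_violation_rate = 1.2),
               "adherence_violation_rate")
  expect_error(simulation_config(horizon_months = 6), "horizon_months")
  expect_error(
    simulation_config(pattern_mix = c(foo = 1)),
    "transition_matrices missing"
  )
})

test_that("a degenerate physician chain yields an all-physician sequence", {
  cfg <- noise_free_config(1, patterns = "self-contained")
  coh <- generate_cohort(cfg)
  expect_true(all(coh$encounters$discipline == "P"))
  expect_gt(nrow(coh$encounters), 1)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- simulation_config(n_patients = 25, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$encounters, b$encounters)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(simulation_config(n_patients = 25, seed = 100))
  expect_false(identical(a$measurements, c$measurements))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(generate_cohort(simulation_config(n_patients = 5, seed = 1)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("empirical transition frequencies match the configured chains", {
  cfg <- simulation_config(n_patients = 500, seed = 1,
                           visit_interval_days = 20, visit_jitter_days = 5,
                           adherence_violation_rate = 0, comorbidity_rate = 0,
                           single_test_rate = 0)
  coh <- generate_cohort(cfg)
  truth <- stats::setNames(coh$truth$pattern, coh$truth$patient_id)
  trans <- list()
  for (id in unique(coh$encounters$patient_id)) {
    s <- coh$encounters$discipline[coh$encounters$patient_id == id]
    if (length(s) < 2) next
    trans[[truth[[id]]]] <- rbind(
      trans[[truth[[id]]]],
      cbind(s[-length(s)], s[-1])
    )
  }
  for (pattern in names(trans)) {
    tm <- cfg$transition_matrices[[pattern]]$transition
    emp <- table(factor(trans[[pattern]][, 1], levels = c("P", "N", "D")),
                 factor(trans[[pattern]][, 2], levels = c("P", "N", "D")))
    for (from in c("P", "N", "D")) {
      n_from <- sum(emp[from, ])
      if (n_from < 300) next  # too few visits from this state to compare
      expect_true(all(abs(emp[from, ] / n_from - tm[from, ]) <= 0.05),
                  label = paste("transition row", from, "of", pattern))
    }
  }
})

test_that("trajectories realise their planted segment at zero noise", {
  with_seed(5, {
    tr <- generate_trajectory("compensated",
                              list(baseline = 6.2, slope = 0, sd = 0), 26)
    expect_true(all(tr$value == 6.2))
    expect_equal(classify_segment(tr$time, tr$value)$label, "compensated")

    tr <- generate_trajectory("improved",
                              list(baseline = 9.5, slope = -0.2, sd = 0), 18)
    expect_lt(tr$value[nrow(tr)], 7)
    expect_lt(series_slope(tr$time, tr$value), 0)
    expect_equal(classify_segment(tr$time, tr$value)$label, "improved")

    tr <- generate_trajectory("highly decompensated",
                              list(baseline = 10, slope = 0, sd = 0), 26)
    expect_true(all(tr$value > 9))
    expect_equal(classify_segment(tr$time, tr$value)$label,
                 "highly decompensated")

    tr <- generate_trajectory("moderately decompensated",
                              list(baseline = 8, slope = 0, sd = 0), 26)
    expect_equal(classify_segment(tr$time, tr$value)$label,
                 "moderately decompensated")
  })
  expect_error(generate_trajectory("cured", window_months = 26), "segment")
  expect_error(generate_trajectory("improved", window_months = 6), "window")
})

test_that("planted adherence violations are detected at the planted rate", {
  cfg <- simulation_config(n_patients = 1000, seed = 4,
                           adherence_violation_rate = 0.3,
                           comorbidity_rate = 0, single_test_rate = 0)
  coh <- generate_cohort(cfg)
  f <- run_funnel(coh$patients, coh$measurements)
  removed <- 1 - f$counts[["adherent"]] / f$counts[["no_comorbidity"]]
  expect_lt(abs(removed - 0.3), 0.05)
  # the removed patients are exactly the planted violators
  removed_ids <- setdiff(coh$truth$patient_id, f$eligible)
  flagged <- coh$truth$patient_id[coh$truth$adherence_violator]
  expect_true(all(flagged %in% removed_ids))
})

test_that("cohorts are internally consistent", {
  coh <- generate_cohort(simulation_config(n_patients = 40, seed = 2))
  expect_setequal(coh$truth$patient_id, coh$patients$patient_id)
  expect_true(all(coh$encounters$patient_id %in% coh$patients$patient_id))
  expect_true(all(coh$measurements$patient_id %in% coh$patients$patient_id))
  expect_true(all(coh$measurements$value >= 4 & coh$measurements$value <= 20))
  expect_true(all(coh$encounters$discipline %in% c("P", "N", "D")))
  # comorbidity flags follow the configured rate direction
  comorb <- coh$patients$dcsi_count > 0 | coh$patients$cic_count > 0
  expect_gt(mean(comorb), 0.5)  # default rate is 0.796
})
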