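#' Discipline-transition archetypes of the seven collaboration patterns
#'
#' Each archetype is a first-order Markov chain over the disciplines: an
#' initial-discipline distribution and a 3 x 3 row-stochastic transition
#' matrix. Two sets are available:
#'
#' * `"reference"` -- stochastic chains whose stationary behaviour reproduces
#'   the index profile of each pattern (used to exercise the pattern
#'   classifier on pooled per-pattern networks);
#' * `"noise_free"` -- fully deterministic chains. A first-order chain over
#'   three states admits exactly three deterministic behaviours (a constant,
#'   a two-cycle and a three-cycle), realising the self-contained, shared and
#'   participatory patterns; these are the patterns a noise-free cohort can
#'   plant, and recovery experiments on them are exact.
#'
#' @param type `"reference"` or `"noise_free"`.
#' @return named list of archetypes, each a list with `init` (length-3
#'   probability vector) and `transition` (3 x 3 row-stochastic matrix), both
#'   over `c("P", "N", "D")`.
#' @export
pattern_archetypes <- function(type = c("reference", "noise_free")) {
  type <- match.arg(type)
  mk <- function(init, rows) {
    tr <- matrix(rows, 3, 3, byrow = TRUE,
                 dimnames = list(DISCIPLINES, DISCIPLINES))
    list(init = setNames(init, DISCIPLINES), transition = tr)
  }
  if (type == "noise_free") {
    return(list(
      "self-contained" = mk(c(1, 0, 0), c(1, 0, 0,  1, 0, 0,  1, 0, 0)),
      "shared"         = mk(c(1, 0, 0), c(0, 1, 0,  1, 0, 0,  1, 0, 0)),
      "participatory"  = mk(c(1, 0, 0), c(0, 1, 0,  0, 0, 1,  1, 0, 0))
    ))
  }
  list(
    "self-contained" = mk(c(1, 0, 0),
                          c(1, 0, 0,  1, 0, 0,  1, 0, 0)),
    "tacit leader" = mk(c(0.7, 0.3, 0),
                        c(0.6, 0.4, 0,  0.9, 0.1, 0,  1, 0, 0)),
    "shared" = mk(c(0.5, 0.5, 0),
                  c(0.3, 0.7, 0,  0.7, 0.3, 0,  1, 0, 0)),
    "participatory" = mk(c(1, 1, 1) / 3,
                         c(1, 1, 1,  1, 1, 1,  1, 1, 1) / 3),
    "equitably centered" = mk(c(1, 0, 0),
                              c(0.5, 0.25, 0.25,  0.5, 0, 0.5,  0.5, 0.5, 0)),
    "hierarchically centered" = mk(c(1, 0, 0),
                                   c(0.5, 0.35, 0.15,  0.6, 0.4, 0,  1, 0, 0)),
    "self-referred leader" = mk(c(1, 0, 0),
                                c(0.8, 0.02, 0.18,  1, 0, 0,  0.95, 0, 0.05))
  )
}

#' Per-segment HbA1c trajectory parameters
#'
#' Baseline (percent), slope (percent per month) and Gaussian noise standard
#' deviation (percent) of the linear trajectory model used for each planted
#' outcome segment. The defaults realise the four segments robustly: a stable
#' compensated patient (6.2%), a decompensated patient returning to goal
#' (9.5% falling 0.2%/month), a stable moderately decompensated patient
#' (8.0%) and a stable highly decompensated patient (10.0%), each with 0.15%
#' measurement-to-measurement noise.
#'
#' @return named list of lists with `baseline`, `slope`, `sd`.
#' @export
trajectory_defaults <- function() {
  list(
    "compensated" = list(baseline = 6.2, slope = 0, sd = 0.15),
    "improved" = list(baseline = 9.5, slope = -0.2, sd = 0.15),
    "moderately decompensated" = list(baseline = 8.0, slope = 0, sd = 0.15),
    "highly decompensated" = list(baseline = 10.0, slope = 0, sd = 0.15)
  )
}

check_mix <- function(mix, field) {
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    stop(field, " must be a named probability vector")
  }
  if (any(mix < 0 | mix > 1)) stop(field, " has probabilities outside [0, 1]")
  if (abs(sum(mix) - 1) > 1e-9) stop(field, " must sum to 1")
  invisible(mix)
}

#' Configuration of the synthetic ECR generator
#'
#' Defaults emulate the reference primary-care cohort: 231 analysed patients,
#' pattern and segment mixes matching the reference cohort's distribution,
#' roughly 4.8 CVPAs per patient over an 18-month window (114-day mean visit
#' interval), and funnel-stage attrition rates matching the reference
#' selection funnel (15.6% of patients with a single test, 79.6% with
#' comorbidity flags, 44.9% adherence violators among the remainder).
#'
#' @param n_patients number of patients to generate.
#' @param pattern_mix named probabilities over collaboration patterns
#'   (must have matching entries in `transition_matrices`).
#' @param transition_matrices named list of archetypes
#'   (see [pattern_archetypes()]).
#' @param segment_mix named probabilities over the four outcome segments.
#' @param trajectory_params per-segment trajectory parameters
#'   (see [trajectory_defaults()]).
#' @param visit_interval_days mean gap between CVPAs.
#' @param visit_jitter_days uniform jitter applied to each visit gap.
#' @param test_jitter_months uniform jitter applied to each protocol test gap.
#' @param adherence_violation_rate probability that a patient's test schedule
#'   contains a gap exceeding the allowed protocol window plus tolerance.
#' @param comorbidity_rate probability of positive comorbidity flags.
#' @param single_test_rate probability that a patient has only one HbA1c test.
#' @param horizon_months simulated follow-up length (>= 10).
#' @param seed integer seed; generation is fully deterministic given the seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 231,
                              pattern_mix = NULL,
                              transition_matrices = pattern_archetypes(),
                              segment_mix = NULL,
                              trajectory_params = trajectory_defaults(),
                              visit_interval_days = 114,
                              visit_jitter_days = 21,
                              test_jitter_months = 0.25,
                              adherence_violation_rate = 0.449,
                              comorbidity_rate = 0.796,
                              single_test_rate = 0.156,
                              horizon_months = 26,
                              seed = 1L) {
  if (is.null(pattern_mix)) {
    pattern_mix <- setNames(c(41, 61, 24, 35, 21, 14, 17) / 213, PATTERN_LEVELS)
  }
  if (is.null(segment_mix)) {
    segment_mix <- setNames(c(114, 37, 43, 37) / 231, SEGMENT_LEVELS)
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("n_patients must be a single integer >= 1")
  }
  check_mix(pattern_mix, "pattern_mix")
  check_mix(segment_mix, "segment_mix")
  missing_tm <- setdiff(names(pattern_mix)[pattern_mix > 0],
                        names(transition_matrices))
  if (length(missing_tm)) {
    stop("transition_matrices missing pattern(s): ",
         paste(missing_tm, collapse = ", "))
  }
  for (nm in names(transition_matrices)) {
    a <- transition_matrices[[nm]]
    if (any(a$transition < 0) || any(a$transition > 1) ||
        any(abs(rowSums(a$transition) - 1) > 1e-9)) {
      stop("transition_matrices[['", nm, "']] is not row-stochastic")
    }
    if (any(a$init < 0) || abs(sum(a$init) - 1) > 1e-9) {
      stop("transition_matrices[['", nm, "']] has an invalid initial distribution")
    }
  }
  missing_tp <- setdiff(names(segment_mix)[segment_mix > 0],
                        names(trajectory_params))
  if (length(missing_tp)) {
    stop("trajectory_params missing segment(s): ",
         paste(missing_tp, collapse = ", "))
  }
  rates <- c(adherence_violation_rate = adherence_violation_rate,
             comorbidity_rate = comorbidity_rate,
             single_test_rate = single_test_rate)
  for (nm in names(rates)) {
    if (rates[[nm]] < 0 || rates[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (horizon_months < 10) stop("horizon_months must be at least 10")
  if (visit_interval_days <= 0) stop("visit_interval_days must be positive")
  if (visit_jitter_days < 0 || visit_jitter_days >= visit_interval_days) {
    stop("visit_jitter_days must be in [0, visit_interval_days)")
  }
  structure(list(
    n_patients = as.integer(n_patients), pattern_mix = pattern_mix,
    transition_matrices = transition_matrices, segment_mix = segment_mix,
    trajectory_params = trajectory_params,
    visit_interval_days = visit_interval_days,
    visit_jitter_days = visit_jitter_days,
    test_jitter_months = test_jitter_months,
    adherence_violation_rate = adherence_violation_rate,
    comorbidity_rate = comorbidity_rate, single_test_rate = single_test_rate,
    horizon_months = horizon_months, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate one patient's HbA1c trajectory
#'
#' Linear-plus-noise model: HbA1c(t) = baseline + slope * t + N(0, sd),
#' truncated to \[4, 20\]%. Test times follow the follow-up protocol: after a
#' compensated value the next test is 12 months later, after a moderately
#' decompensated value 6 months, after a highly decompensated value 3 months
#' (optionally jittered). Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param segment one of the four outcome segment labels.
#' @param params list with `baseline`, `slope`, `sd`; defaults to the
#'   segment's entry in [trajectory_defaults()].
#' @param window_months follow-up length in months (>= 10).
#' @param jitter_months uniform jitter on each protocol gap (default 0).
#' @return data frame with columns `time` (months) and `value` (percent).
#' @export
generate_trajectory <- function(segment, params = NULL, window_months = 26,
                                jitter_months = 0) {
  if (!segment %in% SEGMENT_LEVELS) {
    stop("unknown segment label: ", segment)
  }
  if (window_months < 10) stop("window_months must be at least 10")
  params <- params %||% trajectory_defaults()[[segment]]
  t <- 0
  time <- numeric(0)
  value <- numeric(0)
  repeat {
    v <- params$baseline + params$slope * t +
      (if (params$sd > 0) rnorm(1, 0, params$sd) else 0)
    # round to reporting precision first so the protocol band, the stored
    # record and downstream classification all see the same value
    v <- round(min(max(v, 4), 20), 1)
    time <- c(time, t)
    value <- c(value, v)
    gap <- if (v < 7) 12 else if (v <= 9) 6 else 3
    if (jitter_months > 0) gap <- gap + runif(1, -jitter_months, jitter_months)
    t <- t + gap
    if (t > window_months) break
  }
  data.frame(time = time, value = value)
}

sample_markov_sequence <- function(archetype, n_visits) {
  s <- integer(n_visits)
  s[1] <- sample.int(3, 1, prob = archetype$init)
  if (n_visits > 1) {
    for (i in seq_len(n_visits - 1)) {
      s[i + 1] <- sample.int(3, 1, prob = archetype$transition[s[i], ])
    }
  }
  DISCIPLINES[s]
}

#' Generate a synthetic ECR cohort
#'
#' For each patient a collaboration pattern, an outcome segment, a
#' comorbidity flag, a single-test flag and an adherence-violator flag are
#' drawn from the configured mixes. The patient's CVPA discipline sequence is
#' a realisation of the planted pattern's Markov chain; the HbA1c series
#' follows the planted segment's linear trajectory model on a
#' protocol-driven test schedule. Violators get one inter-test gap inflated
#' to the allowed window plus 2 months, guaranteeing detection by the
#' adherence filter. Generation is deterministic for a fixed seed and leaves
#' the caller's RNG state untouched.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: list with data frames
#'   `encounters` (`patient_id`, `date`, `discipline`), `measurements`
#'   (`patient_id`, `date`, `value`), `patients` (demographics and
#'   comorbidity counts) and `truth` (`patient_id`, `pattern`, `segment`,
#'   `adherence_violator`), plus the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("p%05d", seq_len(n))
    patterns <- sample(names(config$pattern_mix), n, replace = TRUE,
                       prob = config$pattern_mix)
    segments <- sample(names(config$segment_mix), n, replace = TRUE,
                       prob = config$segment_mix)
    violator <- runif(n) < config$adherence_violation_rate
    comorbid <- runif(n) < config$comorbidity_rate
    single <- runif(n) < config$single_test_rate
    violator[single] <- FALSE  # a single test has no gap to violate
    origin <- as.Date("2013-01-01") + sample.int(365, n, replace = TRUE) - 1

    enc <- list()
    meas <- list()
    horizon_days <- config$horizon_months * MONTH_DAYS
    for (i in seq_len(n)) {
      traj <- generate_trajectory(segments[i],
                                  config$trajectory_params[[segments[i]]],
                                  config$horizon_months,
                                  config$test_jitter_months)
      if (violator[i] && nrow(traj) >= 2) {
        allowed <- allowed_test_gap(traj$value[1])
        shift <- (allowed + 2) - (traj$time[2] - traj$time[1])
        traj$time[-1] <- traj$time[-1] + shift
      }
      if (single[i]) traj <- traj[1, , drop = FALSE]
      meas[[i]] <- data.frame(
        patient_id = ids[i],
        date = origin[i] + round(traj$time * MONTH_DAYS),
        value = traj$value
      )
      t <- 0
      times <- numeric(0)
      while (t <= horizon_days) {
        times <- c(times, t)
        gap <- config$visit_interval_days +
          (if (config$visit_jitter_days > 0)
             runif(1, -config$visit_jitter_days, config$visit_jitter_days)
           else 0)
        t <- t + gap
      }
      arch <- config$transition_matrices[[patterns[i]]]
      enc[[i]] <- data.frame(
        patient_id = ids[i],
        date = origin[i] + round(times),
        discipline = sample_markov_sequence(arch, length(times))
      )
    }
    age <- pmin(pmax(round(rnorm(n, 59.7, 12.6)), 20), 89)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.576, 0.424))
    years <- round(pmin(pmax(rnorm(n, 4.6, 3.8), 0), 30), 1)
    dcsi <- ifelse(comorbid, sample.int(3, n, replace = TRUE), 0L)
    cic <- ifelse(comorbid, sample.int(3, n, replace = TRUE) - 1L, 0L)
    patients <- data.frame(patient_id = ids, age = age, sex = sex,
                           years_with_t2dm = years, dcsi_count = dcsi,
                           cic_count = cic)
    truth <- data.frame(patient_id = ids, pattern = patterns,
                        segment = segments, adherence_violator = violator)
    structure(list(
      encounters = do.call(rbind, c(enc, make.row.names = FALSE)),
      measurements = do.call(rbind, c(meas, make.row.names = FALSE)),
      patients = patients, truth = truth, config = config
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ECR cohort:", nrow(x$patients), "patients,",
      nrow(x$encounters), "CVPAs,", nrow(x$measurements), "HbA1c tests\n")
  invisible(x)
}
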