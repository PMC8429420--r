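# Synthetic cohort generator: determinism, calibration, mechanisms.

test_that("simulation is deterministic given the seed", {
  cfg <- generator_config(n_subjects = 400, seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$visits, b$visits)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c2 <- simulate_cohort(cfg, seed = 4)
  expect_false(identical(a$subjects$pe, c2$subjects$pe))
})

test_that("incidence converges to the configured target", {
  ch <- simulate_cohort(generator_config(n_subjects = 10000, seed = 1))
  n_pe <- sum(ch$subjects$pe)
  # central 99% binomial interval at p = 0.044
  expect_gte(n_pe, qbinom(0.005, 10000, 0.044))
  expect_lte(n_pe, qbinom(0.995, 10000, 0.044))
})

test_that("visit schedules look like antenatal care", {
  cfg <- generator_config(n_subjects = 10, seed = 1)
  s <- base_subject("A", ga_delivery_days = 280)
  counts <- firsts <- numeric(1000)
  for (i in seq_len(1000)) {
    sch <- simulate_visit_schedule(s, cfg, seed = i)
    expect_true(all(diff(sch) > 0))
    expect_true(all(sch < 280))
    counts[i] <- length(sch)
    firsts[i] <- sch[1]
  }
  expect_true(all(firsts >= 49 & firsts <= 112))
  expect_true(median(counts) >= 9 && median(counts) <= 14)

  # very preterm delivery still gets at least one visit, all before it
  sch <- simulate_visit_schedule(base_subject("B", ga_delivery_days = 161),
                                 cfg, seed = 1)
  expect_gte(length(sch), 1)
  expect_true(all(sch < 161))

  # same subject, same stream state: identical schedule
  expect_identical(simulate_visit_schedule(s, cfg, seed = 77),
                   simulate_visit_schedule(s, cfg, seed = 77))
})

test_that("marker series reduce to the mean curve without noise", {
  cfg <- generator_config(
    n_subjects = 10, seed = 1,
    markers = list(sbp = list(resid_sd = 0, round = 0, measure_prob = 1)))
  sch <- c(70, 120, 180, 240)
  val <- simulate_marker_series(base_subject("A"), sch, "sbp", cfg,
                                seed = 1, random_effects = c(intercept = 0,
                                                             slope = 0))
  expect_equal(val, marker_mean(cfg, "sbp", sch), tolerance = 1e-12)
  expect_error(simulate_marker_series(base_subject("A"), sch, "pulse", cfg),
               "unknown marker")
})

test_that("blood pressure rounding to the nearest 5 is exact", {
  ch <- simulate_cohort(generator_config(n_subjects = 200, seed = 2,
                                         bp_rounding = "nearest5"))
  sbp <- ch$visits$sbp[!is.na(ch$visits$sbp)]
  dbp <- ch$visits$dbp[!is.na(ch$visits$dbp)]
  expect_true(all(sbp %% 5 == 0))
  expect_true(all(dbp %% 5 == 0))
  expect_true(all(sbp > dbp))
})

test_that("symphysis-fundal height never appears before week 24", {
  v <- small_cohort()$visits
  expect_true(all(is.na(v$sf_height[v$ga_days < 168])))
  expect_true(any(!is.na(v$sf_height[v$ga_days >= 168])))
})

test_that("pre-diagnosis curvature ramp is detectable woman by woman", {
  # equal case/control arms isolate the trajectory mechanism; the ramp
  # carries only its default curvature component
  mags <- lapply(generator_config()$pe_departure$magnitudes,
                 function(m) c(level = 0, trend = 0, curvature = 0))
  mags$sbp["curvature"] <-
    generator_config()$pe_departure$magnitudes$sbp[["curvature"]]
  cfg <- generator_config(n_subjects = 1000, seed = 6,
                          target_incidence = 0.5,
                          pe_departure = list(magnitudes = mags))
  ch <- simulate_cohort(cfg)
  v <- ch$visits[!is.na(ch$visits$sbp), ]
  v$residual <- v$sbp - marker_mean(cfg, "sbp", v$ga_days)
  curv <- vapply(split(v, v$subject_id), function(d)
    raw_trajectory_coefficients(d$ga_days, d$residual)[["curvature"]],
    numeric(1))
  pe <- ch$subjects$pe[match(names(curv), ch$subjects$subject_id)]
  cutoff <- quantile(abs(curv[!pe]), 0.975)
  expect_gt(mean(abs(curv[pe]) > cutoff), 0.5)
})

test_that("categorical rates and placement follow the configuration", {
  cfg <- generator_config(n_subjects = 4000, seed = 8, target_incidence = 0.5)
  ch <- simulate_cohort(cfg)
  tr <- attr(ch, "truth")
  n_case <- sum(tr$pe)
  hits <- sum(tr$glucose_high_ever[tr$pe])
  expect_gte(hits, qbinom(0.005, n_case, 0.053))
  expect_lte(hits, qbinom(0.995, n_case, 0.053))
  # ever-high women really show a >= 9 mmol/L reading and vice versa
  v <- ch$visits
  obs_high <- tapply(!is.na(v$glucose) & v$glucose >= 9, v$subject_id, any)
  expect_identical(as.vector(obs_high[tr$subject_id]), tr$glucose_high_ever)
  # case dipstick elevations sit at/after the departure onset
  el <- v[!is.na(v$proteinuria) & v$proteinuria != "0", ]
  el_t0 <- tr$departure_onset[match(el$subject_id, tr$subject_id)]
  el_pe <- tr$pe[match(el$subject_id, tr$subject_id)]
  expect_true(all(el$ga_days[el_pe] >= el_t0[el_pe]))

  off <- generator_config(n_subjects = 300, seed = 8,
                          proteinuria_rates = list(
                            control = c(p1 = 0, p2 = 0),
                            case = c(p1 = 0, p2 = 0)))
  ch0 <- simulate_cohort(off)
  expect_true(all(ch0$visits$proteinuria[!is.na(ch0$visits$proteinuria)] == "0"))
})

test_that("with noise and random effects off, case residuals equal the configured ramp", {
  mk <- function() list(re_sd = c(intercept = 0, slope = 0), resid_sd = 0,
                        round = 0)
  cfg <- generator_config(n_subjects = 400, seed = 13, target_incidence = 0.3,
                          markers = list(sbp = mk(), dbp = mk(), weight = mk(),
                                         hb = mk(), sf_height = mk()))
  ch <- simulate_cohort(cfg)
  tr <- attr(ch, "truth")
  cases <- ch$subjects[ch$subjects$pe, ]
  v <- ch$visits[ch$visits$subject_id %in% cases$subject_id &
                   !is.na(ch$visits$sbp), ]
  dx <- cases$ga_diagnosis_days[match(v$subject_id, cases$subject_id)]
  expected <- ifelse(
    v$ga_days > dx - cfg$pe_departure$lead_time,
    departure_ramp(v$ga_days, dx, cfg$pe_departure$lead_time,
                   cfg$pe_departure$magnitudes$sbp), 0)
  observed <- v$sbp - marker_mean(cfg, "sbp", v$ga_days)
  # sbp is floored at dbp + 2; restrict to un-floored rows
  keep <- v$sbp > v$dbp + 2
  expect_equal(observed[keep], expected[keep], tolerance = 1e-10)
})

test_that("with all group differences switched off the landmark AUC is null", {
  beta0 <- default_outcome_coefficients() * 0
  cfg <- generator_config(
    n_subjects = 3000, seed = 21,
    outcome_coefficients = beta0,
    pe_departure = list(magnitudes = lapply(
      generator_config()$pe_departure$magnitudes, function(m) m * 0)),
    glucose = list(high_rate = c(control = 0.033, case = 0.033)),
    proteinuria_rates = list(control = c(p1 = 0.105, p2 = 0.0132),
                             case = c(p1 = 0.105, p2 = 0.0132)))
  ch <- simulate_cohort(cfg)
  # held-out evaluation: in-sample AUC would be optimistic by design
  fit <- pe_landmark(ch, landmarks = 32, outcomes = "any_pe",
                     holdout = TRUE, n_boot = 0, seed = 2)
  a <- fit$evaluation$auc[1]
  n1 <- fit$evaluation$n_cases[1]; n0 <- fit$evaluation$n_controls[1]
  se_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * se_null)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(target_incidence = 1.5), "probabilities")
  expect_error(generator_config(pe_departure = list(lead_time = -1)),
               "lead_time")
  expect_error(generator_config(bp_rounding = "nearest10"), "bp_rounding")
  expect_error(generator_config(nonsense = 1), "unknown generator config")
})
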