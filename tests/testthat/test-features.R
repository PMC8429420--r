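# u-score features: raw coefficients, scales, categorical features,
# landmark windowing.

test_that("raw coefficients equal the brute-force least-squares oracle", {
  withr::with_seed(101, {
    for (rep in seq_len(200)) {
      n <- sample(3:10, 1)
      ga <- sort(sample(50:250, n))
      y <- rnorm(n, sd = 5)
      ours <- raw_trajectory_coefficients(ga, y)
      oracle <- oracle_raw_coefficients(ga, y)
      expect_equal(unname(ours[1:3]), unname(oracle), tolerance = 1e-10)
    }
  })
  # worked example: rising residuals accelerate, so curvature > 0
  ours <- raw_trajectory_coefficients(c(140, 168, 196), c(1, 2, 4))
  oracle <- oracle_raw_coefficients(c(140, 168, 196), c(1, 2, 4))
  expect_equal(unname(ours[1:3]), unname(oracle), tolerance = 1e-12)
  expect_gt(ours[["curvature"]], 0)
})

test_that("degenerate observation counts shrink to the population mean", {
  expect_equal(raw_trajectory_coefficients(numeric(0), numeric(0)),
               c(level = 0, trend = 0, curvature = 0, n_obs = 0))
  expect_equal(raw_trajectory_coefficients(120, 3.5),
               c(level = 3.5, trend = 0, curvature = 0, n_obs = 1))
  two <- raw_trajectory_coefficients(c(100, 142), c(1, 7))
  expect_equal(two[["curvature"]], 0)
  expect_equal(two[["level"]], 4)
  expect_equal(two[["trend"]], 6 / 6)       # 6 units over 6 weeks
  # exactly linear residuals: zero curvature, slope recovered
  ga <- c(80, 120, 170, 230)
  lin <- raw_trajectory_coefficients(ga, 2 + 0.5 * (ga / 7))
  expect_equal(lin[["curvature"]], 0, tolerance = 1e-12)
  expect_equal(lin[["trend"]], 0.5, tolerance = 1e-12)
  # residuals identically zero
  expect_equal(unname(raw_trajectory_coefficients(ga, rep(0, 4))[1:3]),
               c(0, 0, 0))
  # duplicated times cannot support trend or curvature
  dup <- raw_trajectory_coefficients(c(100, 100, 100), c(1, 2, 3))
  expect_equal(dup[["trend"]], 0)
  expect_equal(dup[["curvature"]], 0)
})

test_that("u-score scales standardize their own sample to mean 0, sd 1", {
  withr::with_seed(7, {
    raw <- data.frame(subject_id = sprintf("R%04d", 1:1000),
                      level = rnorm(1000), trend = rnorm(1000),
                      curvature = rnorm(1000), n_obs = 5L)
  })
  sc <- fit_uscore_scale(raw, "sbp", 28)
  # standard-normal coefficients by construction
  expect_lt(max(abs(sc$center)), 3 / sqrt(1000))
  expect_true(all(abs(sc$sd - 1) < 3 / sqrt(2 * 1000) + 0.01))
  u <- compute_uscores(raw, sc)
  expect_equal(mean(u$u_level), 0, tolerance = 1e-12)
  expect_equal(sd(u$u_curvature), 1, tolerance = 1e-12)
})

test_that("degenerate or thin scales are refused or disabled per feature", {
  raw <- data.frame(subject_id = sprintf("R%02d", 1:40), level = 1,
                    trend = 1, curvature = 1, n_obs = 5L)
  expect_error(fit_uscore_scale(raw, "sbp", 28), "degenerate")
  expect_error(fit_uscore_scale(raw[1:10, ], "sbp", 28), "unreliable")
  # curvature contributors below the floor: feature disabled, not fatal
  withr::with_seed(8, {
    raw2 <- data.frame(subject_id = sprintf("R%04d", 1:200),
                       level = rnorm(200), trend = rnorm(200),
                       curvature = rnorm(200),
                       n_obs = rep(c(2L, 5L), c(180, 20)))
  })
  sc2 <- fit_uscore_scale(raw2, "sbp", 24)
  expect_true(is.na(sc2$center[["curvature"]]))
  expect_false(is.na(sc2$center[["level"]]))
  u2 <- compute_uscores(raw2, sc2)
  expect_true(all(u2$u_curvature == 0))
  expect_identical(attr(u2, "inactive"), "u_curvature")
  # single-visit women: raw 0 standardized through the scale
  one <- data.frame(subject_id = "X", level = 0, trend = 0, curvature = 0,
                    n_obs = 1L)
  u1 <- compute_uscores(one, sc2)
  expect_equal(u1$u_trend,
               (0 - sc2$center[["trend"]]) / sc2$sd[["trend"]])
})

test_that("categorical features respect thresholds and the landmark window", {
  v <- rbind(
    base_visit("A", 80, glucose = 5.1),
    base_visit("A", 120, glucose = 9.0),          # boundary inclusive
    base_visit("B", 90, glucose = 8.9),
    base_visit("B", 250, proteinuria = "2"),      # after week-24 window
    base_visit("B", 130, proteinuria = "1"),
    base_visit("C", 100))                          # nothing measured
  f24 <- compute_categorical_features(v, 24)
  f24 <- f24[order(f24$subject_id), ]
  expect_equal(f24$glucose_high_ever, c(TRUE, FALSE, FALSE))
  expect_equal(f24$proteinuria_max, c(0L, 1L, 0L))
  f36 <- compute_categorical_features(v, 36)
  f36 <- f36[order(f36$subject_id), ]
  expect_equal(f36$proteinuria_max[2], 2L)
  # the window is strictly before the end of the completed week
  vb <- rbind(base_visit("A", 7 * 25 - 1, glucose = 9.5),
              base_visit("A", 7 * 25, glucose = 9.5))
  expect_true(compute_categorical_features(vb, 24)$glucose_high_ever)
  vb2 <- base_visit("A", 7 * 25, glucose = 9.5)
  expect_false(compute_categorical_features(vb2, 24)$glucose_high_ever)
})

test_that("no feature at a landmark uses post-landmark measurements", {
  ch <- small_cohort()
  ctrl <- ch$subjects[!ch$subjects$pe, ]
  vctrl <- ch$visits[ch$visits$subject_id %in% ctrl$subject_id, ]
  traj <- list(sbp = fit_population_trajectory(vctrl, ctrl, "sbp"))
  ds <- assemble_design(ch, traj, 28)

  tampered <- ch
  late <- tampered$visits$ga_days >= 7 * 29
  tampered$visits$sbp[late] <- tampered$visits$sbp[late] + 50
  tampered$visits$glucose[late] <- 12
  tampered$visits$proteinuria[late] <- "2"
  ds2 <- assemble_design(tampered, traj, 28)
  expect_identical(ds$X, ds2$X)
})

test_that("curvature u-scores separate imminent cases from controls", {
  # women whose diagnosis is approaching (preterm cases still at risk
  # at week 32) carry the departure signal inside the landmark window
  run_sep <- function(mags) {
    cfg <- generator_config(n_subjects = 2000, seed = 61,
                            target_incidence = 0.5,
                            pe_departure = list(magnitudes = mags))
    ch <- simulate_cohort(cfg)
    ctrl <- ch$subjects[!ch$subjects$pe, ]
    vctrl <- ch$visits[ch$visits$subject_id %in% ctrl$subject_id, ]
    traj <- list(sbp = fit_population_trajectory(vctrl, ctrl, "sbp"))
    ds <- assemble_design(ch, traj, 32)
    y <- ds$labels$preterm_pe
    list(X = ds$X, y = y,
         sep = function(col) {
           u <- ds$X[, col]
           (mean(u[y]) - mean(u[!y])) /
             sqrt(var(u) * (1 / sum(y) + 1 / sum(!y)))
         })
  }
  # under the default departure the curvature u-score separates clearly
  r <- run_sep(generator_config()$pe_departure$magnitudes)
  expect_gt(r$sep("u_sbp_curvature"), 2)

  # a curvature-only ramp shows up in curvature, not in level
  mags0 <- lapply(generator_config()$pe_departure$magnitudes,
                  function(m) c(level = 0, trend = 0, curvature = 0))
  mags0$sbp["curvature"] <-
    generator_config()$pe_departure$magnitudes$sbp[["curvature"]]
  r0 <- run_sep(mags0)
  z_curv <- r0$sep("u_sbp_curvature")
  expect_gt(z_curv, 2)
  expect_gt(z_curv, r0$sep("u_sbp_level"))
})
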