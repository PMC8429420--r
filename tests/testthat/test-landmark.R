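# Outcome labels, risk sets, design assembly and risk models.

test_that("outcome definitions follow the 37-week boundaries", {
  s <- rbind(
    base_subject("preterm", pe = TRUE, ga_diagnosis_days = 245,
                 ga_delivery_days = 252),
    base_subject("dx_early_term_deliv", pe = TRUE, ga_diagnosis_days = 250,
                 ga_delivery_days = 262),
    base_subject("term", pe = TRUE, ga_diagnosis_days = 265,
                 ga_delivery_days = 270),
    base_subject("none"))
  lab <- classify_outcomes(s)
  expect_equal(lab$preterm_pe, c(TRUE, FALSE, FALSE, FALSE))
  # diagnosis before 37 weeks but delivery at term: term preeclampsia
  # by delivery, early diagnosis by timing
  expect_equal(lab$term_pe, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(lab$dx_before_37, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lab$dx_from_37, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(!lab$preterm_pe | lab$any_pe))
  expect_true(all(!(lab$preterm_pe & lab$term_pe)))
  expect_true(all(unlist(lab[4, -1]) == FALSE))
  s_bad <- base_subject("x", pe = TRUE, ga_diagnosis_days = NA_real_,
                        ga_delivery_days = 260)
  expect_error(classify_outcomes(s_bad), "without diagnosis")
})

test_that("risk sets drop affected, delivered and optionally aspirin women", {
  s <- rbind(
    base_subject("dx160", pe = TRUE, ga_diagnosis_days = 160,
                 ga_delivery_days = 240),
    base_subject("dx250", pe = TRUE, ga_diagnosis_days = 250,
                 ga_delivery_days = 255),
    base_subject("delivered", ga_delivery_days = 170),
    base_subject("asp", aspirin_use = TRUE),
    base_subject("plain"))
  rs <- build_riskset(s, 24)
  expect_false("dx160" %in% rs)            # 160 < 175, already affected
  expect_true("dx250" %in% rs)
  expect_false("delivered" %in% rs)
  expect_true("asp" %in% rs)
  expect_false("asp" %in% build_riskset(s, 24, exclude_aspirin = TRUE))
  expect_error(build_riskset(s[s$subject_id == "dx160", ], 24), "empty")

  # monotone: later risk sets are subsets of earlier ones
  ch <- small_cohort()
  rs24 <- build_riskset(ch$subjects, 24)
  rs36 <- build_riskset(ch$subjects, 36)
  expect_true(all(rs36 %in% rs24))
  expect_lt(length(rs36), length(rs24))

  # aspirin exclusion removes about the configured fraction
  n_asp <- sum(ch$subjects$aspirin_use[ch$subjects$subject_id %in% rs24])
  rs24a <- build_riskset(ch$subjects, 24, exclude_aspirin = TRUE)
  expect_equal(length(rs24) - length(rs24a), n_asp)
})

test_that("the landmark design has the documented fixed schema", {
  ch <- small_cohort()
  ctrl <- ch$subjects[!ch$subjects$pe, ]
  vctrl <- ch$visits[ch$visits$subject_id %in% ctrl$subject_id, ]
  traj <- lapply(setNames(c("sbp", "dbp", "weight", "hb", "sf_height"),
                          c("sbp", "dbp", "weight", "hb", "sf_height")),
                 function(m) fit_population_trajectory(vctrl, ctrl, m))
  ds <- assemble_design(ch, traj, 28)
  # 38 baseline columns + 15 u-scores + glucose + 2 proteinuria dummies
  expect_equal(ncol(ds$X), 56)
  expect_equal(sum(grepl("^u_", colnames(ds$X))), 15)
  expect_true(all(c("glucose_high", "proteinuria_1", "proteinuria_2")
                  %in% colnames(ds$X)))
  # never-seen covariate (thrombosis) is constant and flagged inactive
  expect_true("thrombosis_history" %in% ds$meta$inactive)

  # early landmark: symphysis-fundal trend/curvature scales cannot be
  # estimated yet, columns stay but are flagged
  ds24 <- assemble_design(ch, traj, 24)
  expect_true(all(c("u_sf_height_trend", "u_sf_height_curvature")
                  %in% ds24$meta$inactive))

  # row order of the inputs is irrelevant
  perm <- ch
  withr::with_seed(1, {
    perm$subjects <- perm$subjects[sample(nrow(perm$subjects)), ]
    perm$visits <- perm$visits[sample(nrow(perm$visits)), ]
  })
  ds_p <- assemble_design(perm, traj, 28)
  expect_identical(colnames(ds_p$X), colnames(ds$X))
  expect_equal(ds_p$X[ds$subject_id, ], ds$X, tolerance = 1e-12)
})

test_that("risk model fitting matches glm and guards its preconditions", {
  ch <- small_cohort()
  ctrl <- ch$subjects[!ch$subjects$pe, ]
  vctrl <- ch$visits[ch$visits$subject_id %in% ctrl$subject_id, ]
  traj <- list(sbp = fit_population_trajectory(vctrl, ctrl, "sbp"),
               dbp = fit_population_trajectory(vctrl, ctrl, "dbp"))
  ds <- assemble_design(ch, traj, 28)
  m <- fit_risk_model(ds, "any_pe")
  p <- predict_risk(m, ds)
  expect_true(all(p > 0 & p < 1))

  if (!m$regularized) {
    # an independent glm() call reproduces coefficients and fitted values
    active <- setdiff(colnames(ds$X), ds$meta$inactive)
    df <- data.frame(y = as.numeric(ds$labels$any_pe), ds$X[, active])
    g <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    expect_equal(unname(coef(g)), unname(m$coefficients), tolerance = 1e-6)
    expect_equal(unname(p), unname(fitted(g)), tolerance = 1e-8)
  }

  # monotonicity in a positively weighted column
  cf <- m$coefficients[-1]
  up <- names(which.max(cf))
  ds_up <- ds
  ds_up$X[, up] <- ds_up$X[, up] + 1
  expect_true(all(predict_risk(m, ds_up) >= p - 1e-12))

  expect_error(fit_risk_model(ds, "weird"), "unknown outcome")
  tiny <- ds
  keep <- c(which(ds$labels$any_pe)[1:5], which(!ds$labels$any_pe)[1:200])
  tiny$X <- tiny$X[keep, ]; tiny$labels <- tiny$labels[keep, ]
  tiny$subject_id <- tiny$subject_id[keep]
  expect_error(fit_risk_model(tiny, "any_pe"), "only 5 cases")

  dup <- ds
  dup$X <- cbind(dup$X, maternal_age_copy = dup$X[, "maternal_age"])
  dup$meta$columns <- colnames(dup$X)
  expect_error(fit_risk_model(dup, "any_pe"), "collinear")
})

test_that("separation triggers the documented weak-ridge fallback", {
  withr::with_seed(5, {
    n <- 300
    X <- cbind(sep = c(rep(0, 150), rep(1, 150)), noise = rnorm(n))
    y <- c(rep(0, 150), rbinom(150, 1, 0.2))
    y[X[, "sep"] == 0] <- 0               # perfectly separated column
  })
  ds <- structure(list(landmark_week = 28, X = X,
                       labels = data.frame(any_pe = y == 1),
                       subject_id = as.character(seq_len(n)),
                       scales = list(),
                       meta = list(columns = colnames(X), centers = NULL,
                                   reference_levels = NULL,
                                   inactive = character(0))),
                  class = "pe_landmark_dataset")
  m <- fit_risk_model(ds, "any_pe")
  expect_true(m$regularized)
  expect_true(all(is.finite(m$coefficients)))
  expect_match(m$regularization, "1e-04|0.0001")
  p <- predict_risk(m, ds)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("null models keep their advertised type-I error", {
  # outcome independent of 4 predictors: per-coefficient Wald tests
  # should reject at about the nominal 5% rate
  rejections <- 0; total <- 0
  withr::with_seed(303, {
    for (r in seq_len(200)) {
      n <- 400
      X <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("x", 1:4)))
      y <- rbinom(n, 1, 0.3)
      ds <- structure(list(landmark_week = 28, X = X,
                           labels = data.frame(any_pe = y == 1),
                           subject_id = as.character(seq_len(n)),
                           scales = list(),
                           meta = list(columns = colnames(X),
                                       centers = NULL,
                                       reference_levels = NULL,
                                       inactive = character(0))),
                      class = "pe_landmark_dataset")
      m <- fit_risk_model(ds, "any_pe")
      z <- (m$coefficients / m$se)[-1]
      rejections <- rejections + sum(abs(z) > qnorm(0.975))
      total <- total + length(z)
    }
  })
  rate <- rejections / total
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("risk models survive JSON serialization", {
  ch <- small_cohort()
  ctrl <- ch$subjects[!ch$subjects$pe, ]
  vctrl <- ch$visits[ch$visits$subject_id %in% ctrl$subject_id, ]
  traj <- list(sbp = fit_population_trajectory(vctrl, ctrl, "sbp"))
  ds <- assemble_design(ch, traj, 28)
  m <- fit_risk_model(ds, "any_pe")
  p <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, p)
  m2 <- read_risk_model(p)
  expect_equal(predict_risk(m2, ds), predict_risk(m, ds), tolerance = 1e-12)
})
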