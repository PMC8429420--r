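# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure the landmark analysis consumes:
# baseline covariate marginals and a logistic outcome model with the
# intercept solved so the marginal incidence hits its target; visit
# schedules with a median of 11 visits in unaffected and 12 in affected
# women; five continuous markers as population mean curve + per-woman
# random intercept/slope + noise, with a smooth pre-diagnosis departure
# ramp in affected pregnancies; and categorical glucose/proteinuria
# excesses among cases.

#' Generator configuration
#'
#' Builds the full configuration for [simulate_cohort()]. Defaults are
#' calibrated to the published cohort descriptives of the study
#' population the generator stands in for: 4.4% preeclampsia incidence,
#' 1.1% aspirin use, median 11/12 antenatal visits (unaffected /
#' affected), maternal age 29.3 (SD 5.0) years, second-trimester dips
#' in blood pressure and hemoglobin, and case excesses of high capillary
#' glucose and dipstick proteinuria. Any element can be overridden via
#' `...` (nested lists are merged with [utils::modifyList()]).
#'
#' @param n_subjects number of pregnancies to simulate.
#' @param seed default integer seed used by [simulate_cohort()].
#' @param ... named overrides of any top-level config element.
#' @return an object of class `pe_generator_config` (a nested list).
#' @export
generator_config <- function(n_subjects = 1000, seed = 1, ...) {
  cfg <- list(
    n_subjects = n_subjects,
    seed = seed,
    target_incidence = 0.044,
    aspirin_rate = 0.0106,
    baseline_marginals = list(
      maternal_age = c(mean = 29.3, sd = 5.0),
      height_cm = c(mean = 166.6, sd = 6.5),
      region_of_birth = c(Sweden = 0.7412, Nordic_other = 0.0158,
                          Europe_other = 0.0749, Africa = 0.0315,
                          North_America = 0.0069, South_America = 0.0168,
                          Asia = 0.0985, Oceania = 0.0009, missing = 0.0135),
      family_situation = c(with_partner = 0.9191, single = 0.0209,
                           other = 0.0536, missing = 0.0064),
      smoking_pre = c(none = 0.8347, lt10 = 0.0865, ge10 = 0.0726,
                      missing = 0.0062),
      smoking_early = c(none = 0.9535, lt10 = 0.0348, ge10 = 0.0060,
                        missing = 0.0057),
      prev_miscarriage = 0.176,
      infertility_duration = c(none = 0.836, y1_2 = 0.110, gt2 = 0.054),
      infertility_treatment = c(none = 0.920, ovarian_stimulation = 0.014,
                                ivf = 0.066),
      fam_hist_preeclampsia = 0.0025,
      fam_hist_hypertension = 0.166,
      cardiovascular_disease = 0.013,
      endocrine_disease = 0.049,
      preexisting_diabetes = 0.0044,
      thrombosis_history = 0,
      sle = 0.0011,
      chronic_hypertension = 0.0044,
      ibd = 0.0085,
      chronic_kidney_disease = 0.0044,
      blood_group = c(O = 0.3516, A = 0.3977, AB = 0.0508, B = 0.1227,
                      missing = 0.0772)
    ),
    outcome_coefficients = default_outcome_coefficients(),
    preterm_fraction_among_pe = 0.25,
    diagnosis_ga = list(preterm = c(mean = 235, sd = 15, lo = 148, hi = 258),
                        term = c(mean = 272, sd = 9, lo = 259, hi = 300)),
    diagnosis_to_delivery_days = c(shape = 1.6, scale = 5),
    nonpe_delivery = list(early_frac = 0.05,
                          early = c(mean = 250, sd = 18),
                          main = c(mean = 281, sd = 8),
                          range = c(154, 310)),
    visit_schedule = list(
      first_mean = 70, first_sd = 10, first_range = c(49, 112),
      # inter-visit gap means (days) by gestational-age bracket
      gap_breaks = c(168, 231, 259),
      gap_mu = c(31, 20, 11, 7),
      gap_cv = 0.25, min_gap = 4,
      case_gap_mult = 0.70, max_visits = 40
    ),
    markers = list(
      sbp = list(mean = list(center_week = 20,
                             coef = c(113, 0.06, 0.025, 0.0004)),
                 re_sd = c(intercept = 7, slope = 0.12),
                 resid_sd = 5.5, measure_prob = 1, round = 1),
      dbp = list(mean = list(center_week = 20,
                             coef = c(67, 0.05, 0.020, 0.0003)),
                 re_sd = c(intercept = 5.5, slope = 0.10),
                 resid_sd = 4.5, measure_prob = 1, round = 1),
      weight = list(mean = list(center_week = 10,
                                coef = c(65.5, 0.30, 0.0045, 0)),
                    re_sd = c(intercept = 11, slope = 0.22),
                    resid_sd = 0.9, measure_prob = 0.95, round = 0.1),
      hb = list(mean = list(center_week = 25,
                            coef = c(117, -0.05, 0.032, 0)),
                re_sd = c(intercept = 6.5, slope = 0.10),
                resid_sd = 4.5, measure_prob = 0.45, round = 1),
      sf_height = list(mean = list(center_week = 24,
                                   coef = c(23, 0.95, 0, 0)),
                       re_sd = c(intercept = 1.3, slope = 0.06),
                       resid_sd = 1.4, measure_prob = 1, round = 0.5)
    ),
    pe_departure = list(
      lead_time = 35,
      # per-marker departure reached at diagnosis, split into a
      # saturating level component, a linear trend and a quadratic
      # curvature component (curvature dominates, as observed)
      magnitudes = list(
        sbp = c(level = 2, trend = 3, curvature = 20),
        dbp = c(level = 1.5, trend = 2.5, curvature = 15),
        weight = c(level = 0.3, trend = 0.6, curvature = 3),
        hb = c(level = 1, trend = 1.5, curvature = 6),
        sf_height = c(level = 0, trend = -0.5, curvature = -3)
      )
    ),
    glucose = list(high_rate = c(control = 0.033, case = 0.053),
                   measure_prob = 0.55,
                   normal = c(mean = 5.2, sd = 0.8, lo = 3.2, hi = 8.8),
                   high = c(base = 9, rate = 1.25, hi = 13)),
    proteinuria_rates = list(control = c(p1 = 0.105, p2 = 0.0132),
                             case = c(p1 = 0.260, p2 = 0.444)),
    bp_rounding = "none"
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0)
      stop_pe("unknown generator config element(s): %s",
              paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  validate_generator_config(cfg)
  structure(cfg, class = "pe_generator_config")
}

default_outcome_coefficients <- function() {
  c(maternal_age = 0.024, height_cm = -0.012,
    region_of_birth_Nordic_other = 0, region_of_birth_Europe_other = -0.28,
    region_of_birth_Africa = 0.22, region_of_birth_North_America = -0.3,
    region_of_birth_South_America = -0.25, region_of_birth_Asia = -0.40,
    region_of_birth_Oceania = 0, region_of_birth_missing = 0,
    family_situation_single = 0.2, family_situation_other = 0,
    family_situation_missing = 0,
    smoking_pre_lt10 = 0, smoking_pre_ge10 = -0.10, smoking_pre_missing = 0,
    smoking_early_lt10 = -0.26, smoking_early_ge10 = 0.29,
    smoking_early_missing = 0,
    prev_miscarriage = 0.08,
    infertility_duration_y1_2 = 0.05, infertility_duration_gt2 = 0.37,
    infertility_treatment_ovarian_stimulation = 0.2,
    infertility_treatment_ivf = 0.19,
    fam_hist_preeclampsia = 1.1, fam_hist_hypertension = 0.40,
    cardiovascular_disease = 0.33, endocrine_disease = 0.27,
    preexisting_diabetes = 1.78, thrombosis_history = 0, sle = 0,
    chronic_hypertension = 1.41, ibd = -0.13, chronic_kidney_disease = 0.93,
    blood_group_A = 0.05, blood_group_AB = -0.08, blood_group_B = 0.09,
    blood_group_missing = 0)
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1)
    stop_pe("n_subjects must be >= 1")
  probs <- c(cfg$target_incidence, cfg$aspirin_rate,
             cfg$preterm_fraction_among_pe,
             unlist(cfg$glucose$high_rate),
             unlist(cfg$proteinuria_rates),
             unlist(cfg$baseline_marginals[
               !(names(cfg$baseline_marginals) %in%
                   c("maternal_age", "height_cm"))]))
  if (any(probs < 0 | probs > 1))
    stop_pe("all configured probabilities must lie in [0, 1]")
  if (cfg$pe_departure$lead_time <= 0)
    stop_pe("pe_departure lead_time must be > 0")
  for (nm in c("control", "case")) {
    p <- cfg$proteinuria_rates[[nm]]
    if (sum(p) > 1) stop_pe("proteinuria rates for %s exceed 1", nm)
  }
  if (!cfg$bp_rounding %in% c("none", "nearest5"))
    stop_pe("bp_rounding must be 'none' or 'nearest5'")
  invisible(TRUE)
}

#' Population mean curve of a marker
#'
#' Evaluates the configured control-population mean curve (a cubic
#' polynomial in gestational weeks centered at a marker-specific week)
#' at given gestational ages.
#'
#' @param config a `pe_generator_config`.
#' @param marker one of `"sbp"`, `"dbp"`, `"weight"`, `"hb"`,
#'   `"sf_height"`.
#' @param ga_days gestational age(s) in days.
#' @return numeric vector of mean marker values.
#' @export
marker_mean <- function(config, marker, ga_days) {
  m <- config$markers[[marker]]
  if (is.null(m)) stop_pe("unknown marker '%s'", marker)
  d <- ga_days / 7 - m$mean$center_week
  cf <- m$mean$coef
  cf[1] + cf[2] * d + cf[3] * d^2 + cf[4] * d^3
}

#' Pre-diagnosis trajectory departure ramp
#'
#' The smooth departure added to an affected woman's marker values,
#' starting `lead_time` days before diagnosis: with
#' `h = max(0, ga - (dx - lead_time)) / lead_time`, the departure is
#' `level * (1 - (1 - min(h,1))^2) + trend * h + curvature * h^2`, so
#' the curvature magnitude is independently controllable and dominates
#' under the defaults.
#'
#' @param ga_days gestational age(s) in days.
#' @param ga_diagnosis_days diagnosis gestational age in days.
#' @param lead_time ramp onset lead time in days before diagnosis.
#' @param magnitudes named numeric `c(level=, trend=, curvature=)`,
#'   units of the marker, reached at `h = 1` (the diagnosis day).
#' @return numeric vector of departures (0 before ramp onset).
#' @export
departure_ramp <- function(ga_days, ga_diagnosis_days, lead_time, magnitudes) {
  h <- pmax(0, ga_days - (ga_diagnosis_days - lead_time)) / lead_time
  sat <- 1 - (1 - pmin(h, 1))^2
  magnitudes[["level"]] * sat + magnitudes[["trend"]] * h +
    magnitudes[["curvature"]] * h^2
}

round_to <- function(x, unit) {
  if (unit <= 0) return(x)     # unit 0 disables recording precision
  round(x / unit) * unit
}

# ---- subject-level simulation -------------------------------------------

sim_baseline <- function(cfg) {
  n <- cfg$n_subjects
  bm <- cfg$baseline_marginals
  draw_cat <- function(nm) {
    p <- bm[[nm]]
    sample(names(p), n, replace = TRUE, prob = p)
  }
  s <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    maternal_age = pmin(pmax(round(rnorm(n, bm$maternal_age["mean"],
                                         bm$maternal_age["sd"]), 1), 16), 52),
    height_cm = pmin(pmax(round(rnorm(n, bm$height_cm["mean"],
                                      bm$height_cm["sd"]), 1), 140), 200),
    region_of_birth = draw_cat("region_of_birth"),
    family_situation = draw_cat("family_situation"),
    smoking_pre = draw_cat("smoking_pre"),
    smoking_early = draw_cat("smoking_early"),
    prev_miscarriage = runif(n) < bm$prev_miscarriage,
    infertility_duration = draw_cat("infertility_duration"),
    infertility_treatment = draw_cat("infertility_treatment"),
    fam_hist_preeclampsia = runif(n) < bm$fam_hist_preeclampsia,
    fam_hist_hypertension = runif(n) < bm$fam_hist_hypertension,
    cardiovascular_disease = runif(n) < bm$cardiovascular_disease,
    endocrine_disease = runif(n) < bm$endocrine_disease,
    preexisting_diabetes = runif(n) < bm$preexisting_diabetes,
    thrombosis_history = runif(n) < bm$thrombosis_history,
    sle = runif(n) < bm$sle,
    chronic_hypertension = runif(n) < bm$chronic_hypertension,
    ibd = runif(n) < bm$ibd,
    chronic_kidney_disease = runif(n) < bm$chronic_kidney_disease,
    blood_group = draw_cat("blood_group"),
    aspirin_use = runif(n) < cfg$aspirin_rate,
    stringsAsFactors = FALSE
  )
  s
}

sim_outcome <- function(s, cfg) {
  enc <- encode_baseline(s, centers = c(
    maternal_age = unname(cfg$baseline_marginals$maternal_age["mean"]),
    height_cm = unname(cfg$baseline_marginals$height_cm["mean"])))
  beta <- cfg$outcome_coefficients
  miss <- setdiff(colnames(enc$X), names(beta))
  if (length(miss) > 0)
    stop_pe("outcome_coefficients missing entries: %s",
            paste(miss, collapse = ", "))
  lp <- drop(enc$X %*% beta[colnames(enc$X)])
  a <- uniroot(function(a) mean(plogis(a + lp)) - cfg$target_incidence,
               c(-30, 10), tol = 1e-10)$root
  p <- plogis(a + lp)
  pe <- runif(nrow(s)) < p
  list(pe = pe, lp = lp, p = p, intercept = a)
}

sim_gestational_ages <- function(pe, cfg) {
  n <- length(pe)
  dgc <- cfg$diagnosis_ga
  is_pre <- runif(n) < cfg$preterm_fraction_among_pe
  dx_pre <- pmin(pmax(rnorm(n, dgc$preterm["mean"], dgc$preterm["sd"]),
                      dgc$preterm["lo"]), dgc$preterm["hi"])
  dx_trm <- pmin(pmax(rnorm(n, dgc$term["mean"], dgc$term["sd"]),
                      dgc$term["lo"]), dgc$term["hi"])
  dx <- round(ifelse(is_pre, dx_pre, dx_trm))
  gap <- round(rgamma(n, shape = cfg$diagnosis_to_delivery_days["shape"],
                      scale = cfg$diagnosis_to_delivery_days["scale"]))
  deliv_pe <- pmin(pmax(dx + gap, 154), 310)
  npd <- cfg$nonpe_delivery
  early <- runif(n) < npd$early_frac
  d_np <- round(ifelse(early, rnorm(n, npd$early["mean"], npd$early["sd"]),
                       rnorm(n, npd$main["mean"], npd$main["sd"])))
  d_np <- pmin(pmax(d_np, npd$range[1]), npd$range[2])
  list(ga_diagnosis_days = ifelse(pe, dx, NA_real_),
       ga_delivery_days = ifelse(pe, deliv_pe, d_np))
}

# Vectorized visit schedules for n subjects; returns a long data.table
# (subject row index, visit_idx, ga_days), visits strictly before
# delivery and strictly increasing within woman.
sim_schedules <- function(delivery, pe, t0, cfg) {
  vs <- cfg$visit_schedule
  n <- length(delivery)
  t <- pmin(pmax(round(rnorm(n, vs$first_mean, vs$first_sd)),
                 vs$first_range[1]), vs$first_range[2])
  cols <- vector("list", vs$max_visits)
  cols[[1]] <- t
  breaks <- c(-Inf, vs$gap_breaks, Inf)
  for (k in 2:vs$max_visits) {
    t_work <- ifelse(is.na(t), 280, t)
    mu <- vs$gap_mu[findInterval(t_work, breaks, left.open = TRUE)]
    mult <- ifelse(pe & !is.na(t0) & t_work >= t0, vs$case_gap_mult, 1)
    gap <- pmax(round(rnorm(n, mu * mult, vs$gap_cv * mu * mult)), vs$min_gap)
    t <- t + gap
    t[!is.na(t) & t >= delivery] <- NA
    cols[[k]] <- t
    if (all(is.na(t))) break
  }
  mat <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
  keep <- !is.na(mat)
  data.table::data.table(
    subj = rep(seq_len(n), times = rowSums(keep)),
    ga_days = as.vector(t(mat))[as.vector(t(keep))]
  )[, visit_idx := seq_len(.N), by = subj]
}

# ---- full cohort ---------------------------------------------------------

#' Simulate a synthetic antenatal cohort
#'
#' Generates subjects, visit schedules, continuous marker series and
#' categorical glucose/proteinuria observations according to `config`.
#' Deterministic given the seed (single documented RNG: R's
#' Mersenne-Twister via [set.seed()]); the caller's RNG state is left
#' untouched. Affected women's marker trajectories depart from the
#' control mean along [departure_ramp()] starting `lead_time` days
#' before diagnosis, and their visits continue until delivery —
#' removal of diagnosed women is the risk-set logic's job, not the
#' generator's.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a [pe_cohort()] whose `"truth"` attribute holds the latent
#'   linear predictor, outcome probability, departure onset, per-marker
#'   random effects and categorical assignments per subject.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pe_generator_config"))
  validate_generator_config(config)
  seed <- seed %||% config$seed
  with_seed(seed, {
    s <- sim_baseline(config)
    out <- sim_outcome(s, config)
    s$pe <- out$pe
    ga <- sim_gestational_ages(s$pe, config)
    s$ga_diagnosis_days <- ga$ga_diagnosis_days
    s$ga_delivery_days <- ga$ga_delivery_days
    lead <- config$pe_departure$lead_time
    t0 <- ifelse(s$pe, s$ga_diagnosis_days - lead, NA_real_)

    sched <- sim_schedules(s$ga_delivery_days, s$pe, t0, config)
    vis <- data.frame(subject_id = s$subject_id[sched$subj],
                      ga_days = sched$ga_days,
                      stringsAsFactors = FALSE)
    nv <- nrow(vis)
    subj <- sched$subj
    row_pe <- s$pe[subj]
    row_t0 <- t0[subj]

    # continuous markers: draws are taken for every row and every
    # subject in a fixed order, so configs differing only in departure
    # magnitudes share identical control data under the same seed
    truth_re <- list()
    vals <- list()
    for (m in .pe_markers) {
      mc <- config$markers[[m]]
      b0 <- rnorm(config$n_subjects, 0, mc$re_sd[["intercept"]])
      b1 <- rnorm(config$n_subjects, 0, mc$re_sd[["slope"]])
      noise <- rnorm(nv, 0, mc$resid_sd)
      u_meas <- runif(nv)
      val <- marker_mean(config, m, vis$ga_days) +
        b0[subj] + b1[subj] * (vis$ga_days - 140) / 7 + noise
      ramp_rows <- which(row_pe & vis$ga_days > row_t0)
      if (length(ramp_rows) > 0) {
        val[ramp_rows] <- val[ramp_rows] + departure_ramp(
          vis$ga_days[ramp_rows], row_t0[ramp_rows] + lead, lead,
          config$pe_departure$magnitudes[[m]])
      }
      measured <- u_meas < mc$measure_prob
      if (m == "sf_height") measured <- measured & vis$ga_days >= 168
      val[!measured] <- NA
      vals[[m]] <- val
      truth_re[[paste0("b0_", m)]] <- b0
      truth_re[[paste0("b1_", m)]] <- b1
    }
    # blood pressure: measured as a pair, pulse pressure floored
    bp_meas <- !is.na(vals$sbp) | !is.na(vals$dbp)
    vals$sbp[!bp_meas] <- NA; vals$dbp[!bp_meas] <- NA
    for (m in .pe_markers) {
      unit <- if (m %in% c("sbp", "dbp") && config$bp_rounding == "nearest5")
        5 else config$markers[[m]]$round
      vals[[m]] <- round_to(vals[[m]], unit)
    }
    floor_pp <- if (config$bp_rounding == "nearest5") 5 else 2
    vals$sbp <- pmax(vals$sbp, vals$dbp + floor_pp)

    cat_res <- sim_categoricals_rows(s, subj, vis$ga_days, sched$visit_idx,
                                     row_t0, config)
    vis$sbp <- vals$sbp; vis$dbp <- vals$dbp; vis$weight <- vals$weight
    vis$hb <- vals$hb; vis$sf_height <- vals$sf_height
    vis$glucose <- cat_res$glucose
    vis$proteinuria <- cat_res$proteinuria

    truth <- data.frame(subject_id = s$subject_id, lp = out$lp,
                        p_pe = out$p, pe = s$pe,
                        departure_onset = t0,
                        glucose_high_ever = cat_res$ever_high,
                        proteinuria_max = cat_res$prot_max,
                        stringsAsFactors = FALSE)
    for (nm in names(truth_re)) truth[[nm]] <- truth_re[[nm]]
    attr(truth, "outcome_intercept") <- out$intercept

    cohort <- pe_cohort(s, vis, truth = truth)
    attr(cohort, "config") <- config
    attr(cohort, "seed") <- seed
    cohort
  })
}

# Per-row categorical simulation shared by the cohort path and the
# single-subject wrapper. `subj` indexes rows into subjects.
sim_categoricals_rows <- function(s, subj, ga_days, visit_idx, row_t0, cfg) {
  n <- nrow(s)
  nv_by_subj <- tabulate(subj, nbins = n)
  is_case <- s$pe

  # --- glucose ------------------------------------------------------------
  gl <- cfg$glucose
  rate <- ifelse(is_case, gl$high_rate[["case"]], gl$high_rate[["control"]])
  ever_high <- runif(n) < rate & nv_by_subj > 0
  des_idx <- pmin(ceiling(runif(n) * pmax(nv_by_subj, 1)), nv_by_subj)
  normal_val <- pmin(pmax(rnorm(length(subj), gl$normal[["mean"]],
                                gl$normal[["sd"]]),
                          gl$normal[["lo"]]), gl$normal[["hi"]])
  high_val <- pmin(gl$high[["base"]] + rexp(length(subj),
                                            gl$high[["rate"]]),
                   gl$high[["hi"]])
  u_meas <- runif(length(subj))
  high_row <- ever_high[subj] & visit_idx == des_idx[subj]
  measured <- (u_meas < gl$measure_prob) | high_row
  glucose <- round(ifelse(high_row, high_val, normal_val), 1)
  glucose[!measured] <- NA

  # --- proteinuria ---------------------------------------------------------
  pr <- cfg$proteinuria_rates
  u <- runif(n)
  p2 <- ifelse(is_case, pr$case[["p2"]], pr$control[["p2"]])
  p1 <- ifelse(is_case, pr$case[["p1"]], pr$control[["p1"]])
  M <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
  M[nv_by_subj == 0] <- 0L

  # choose where the elevation starts: cases at/after departure onset
  # (gestational proteinuria precedes the diagnosis), controls anywhere
  u_start <- runif(n)
  extra_len <- 1L + (runif(n) < 0.3)
  dt <- data.table::data.table(subj = subj, visit_idx = visit_idx,
                               ga_days = ga_days)
  dt[, elig := TRUE]
  case_row <- is_case[subj]
  dt[case_row, elig := ga_days >= row_t0[case_row]]
  # fall back to the last visit when no visit reaches the onset window
  first_elig <- dt[, {
    w <- which(elig)
    list(fe = if (length(w)) visit_idx[w[1]] else .N, ne = max(length(w), 1L))
  }, by = subj]
  fe <- ne <- rep(1L, n)
  fe[first_elig$subj] <- first_elig$fe
  ne[first_elig$subj] <- first_elig$ne
  start <- fe + pmin(floor(u_start * ne), ne - 1L)

  prot <- rep(0L, length(subj))
  m_row <- M[subj]
  st_row <- start[subj]
  if (any(M > 0)) {
    ca <- case_row & m_row > 0L
    prot[ca & visit_idx >= st_row] <- m_row[ca & visit_idx >= st_row]
    # escalation: the first elevated reading of a >=2+ woman is 1+
    esc <- ca & visit_idx == st_row & m_row == 2L &
      visit_idx < nv_by_subj[subj]
    prot[esc] <- 1L
    co <- !case_row & m_row > 0L
    in_run <- co & visit_idx >= st_row &
      visit_idx < st_row + extra_len[subj]
    prot[in_run] <- m_row[in_run]
  }
  list(glucose = glucose, proteinuria = as.character(prot),
       ever_high = ever_high,
       prot_max = as.integer(tapply(prot, factor(subj, levels = seq_len(n)),
                                    function(x) max(c(0L, x)))))
}

# ---- single-subject wrappers (spec operation surface) --------------------

one_subject_frame <- function(subject) {
  if (inherits(subject, "pe_cohort")) subject <- subject$subjects
  s <- as.data.frame(subject, stringsAsFactors = FALSE)
  stopifnot(nrow(s) == 1)
  s
}

#' Simulate one woman's visit schedule
#'
#' Visits start near gestational week 10, recur at trimester-dependent
#' intervals, densify close to diagnosis for affected women, and stop
#' strictly before delivery.
#'
#' @param subject one-row subject data.frame (needs `ga_delivery_days`,
#'   `pe` and, if affected, `ga_diagnosis_days`).
#' @param config a [generator_config()].
#' @param seed integer seed for this draw.
#' @return increasing integer vector of visit gestational ages (days).
#' @export
simulate_visit_schedule <- function(subject, config, seed = 1) {
  s <- one_subject_frame(subject)
  t0 <- if (isTRUE(s$pe)) s$ga_diagnosis_days - config$pe_departure$lead_time
        else NA_real_
  with_seed(seed,
    sim_schedules(s$ga_delivery_days, isTRUE(s$pe), t0, config)$ga_days)
}

#' Simulate one woman's continuous marker series
#'
#' @param subject one-row subject data.frame.
#' @param schedule visit gestational ages in days.
#' @param marker one of the five continuous markers.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param random_effects optional named `c(intercept=, slope=)`
#'   overriding the drawn per-woman effects (used in exactness tests).
#' @return numeric vector of marker values aligned to `schedule` (`NA`
#'   when unmeasured; symphysis-fundal height absent before 168 days).
#' @export
simulate_marker_series <- function(subject, schedule, marker, config,
                                   seed = 1, random_effects = NULL) {
  if (!marker %in% .pe_markers) stop_pe("unknown marker '%s'", marker)
  s <- one_subject_frame(subject)
  mc <- config$markers[[marker]]
  lead <- config$pe_departure$lead_time
  with_seed(seed, {
    re <- random_effects %||%
      c(intercept = rnorm(1, 0, mc$re_sd[["intercept"]]),
        slope = rnorm(1, 0, mc$re_sd[["slope"]]))
    noise <- rnorm(length(schedule), 0, mc$resid_sd)
    u_meas <- runif(length(schedule))
    val <- marker_mean(config, marker, schedule) + re[["intercept"]] +
      re[["slope"]] * (schedule - 140) / 7 + noise
    if (isTRUE(s$pe)) {
      t0 <- s$ga_diagnosis_days - lead
      on <- schedule > t0
      val[on] <- val[on] + departure_ramp(schedule[on], s$ga_diagnosis_days,
                                          lead,
                                          config$pe_departure$magnitudes[[marker]])
    }
    measured <- u_meas < mc$measure_prob
    if (marker == "sf_height") measured <- measured & schedule >= 168
    val[!measured] <- NA
    unit <- if (marker %in% c("sbp", "dbp") && config$bp_rounding == "nearest5")
      5 else mc$round
    round_to(val, unit)
  })
}

#' Simulate one woman's categorical visit measurements
#'
#' @inheritParams simulate_marker_series
#' @return list with `glucose` (numeric, `NA` when not sampled) and
#'   `proteinuria` (character categories "0"/"1"/"2") aligned to
#'   `schedule`.
#' @export
simulate_categoricals <- function(subject, schedule, config, seed = 1) {
  s <- one_subject_frame(subject)
  t0 <- if (isTRUE(s$pe)) s$ga_diagnosis_days - config$pe_departure$lead_time
        else NA_real_
  with_seed(seed, {
    res <- sim_categoricals_rows(s, rep(1L, length(schedule)), schedule,
                                 seq_along(schedule), rep(t0, length(schedule)),
                                 config)
    list(glucose = res$glucose, proteinuria = res$proteinuria)
  })
}

#' @export
simulate.pe_generator_config <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% object$seed
  if (nsim == 1) return(simulate_cohort(object, seed))
  lapply(seq_len(nsim),
         function(k) simulate_cohort(object, derive_seed(seed, paste0("sim", k))))
}

#' @export
print.pe_generator_config <- function(x, ...) {
  cat(sprintf(paste0("pe_generator_config: n_subjects=%d, incidence=%.3f, ",
                     "aspirin=%.4f, preterm fraction among PE=%.2f\n"),
              x$n_subjects, x$target_incidence, x$aspirin_rate,
              x$preterm_fraction_among_pe))
  invisible(x)
}
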