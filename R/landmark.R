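# Outcome labels, landmark risk sets, design assembly and the
# per-outcome logistic risk models.

#' Outcome labels per woman
#'
#' Five preeclampsia outcome definitions (259 days = 37 completed
#' weeks): preterm preeclampsia is diagnosis and delivery before 37
#' weeks; term preeclampsia is any diagnosis with delivery at or after
#' 37 weeks; the two secondary outcomes classify by diagnosis timing
#' irrespective of delivery.
#'
#' @param subjects subject data.frame.
#' @return data.frame `subject_id`, `any_pe`, `preterm_pe`, `term_pe`,
#'   `dx_before_37`, `dx_from_37`.
#' @export
classify_outcomes <- function(subjects) {
  s <- subjects
  bad <- s$pe & is.na(s$ga_diagnosis_days)
  if (any(bad))
    stop_pe("preeclamptic subject without diagnosis gestational age: %s",
            s$subject_id[which(bad)[1]])
  data.frame(
    subject_id = s$subject_id,
    any_pe = s$pe,
    preterm_pe = s$pe & s$ga_delivery_days < 259,
    term_pe = s$pe & s$ga_delivery_days >= 259,
    dx_before_37 = s$pe & !is.na(s$ga_diagnosis_days) & s$ga_diagnosis_days < 259,
    dx_from_37 = s$pe & !is.na(s$ga_diagnosis_days) & s$ga_diagnosis_days >= 259,
    stringsAsFactors = FALSE
  )
}

#' Landmark risk set
#'
#' Women predictable at a landmark: those not yet affected by
#' preeclampsia (diagnosis not before the end of the completed landmark
#' week) and not yet delivered by then; optionally, aspirin users are
#' excluded (the sensitivity analysis).
#'
#' @param subjects subject data.frame.
#' @param landmark_week completed gestational week.
#' @param exclude_aspirin drop `aspirin_use = TRUE` women.
#' @return character vector of subject ids.
#' @export
build_riskset <- function(subjects, landmark_week, exclude_aspirin = FALSE) {
  end <- landmark_end_day(landmark_week)
  keep <- !(subjects$pe & !is.na(subjects$ga_diagnosis_days) &
              subjects$ga_diagnosis_days < end) &
    subjects$ga_delivery_days >= end
  if (exclude_aspirin) keep <- keep & !subjects$aspirin_use
  ids <- subjects$subject_id[keep]
  if (length(ids) == 0)
    stop_pe("empty risk set at landmark week %d", landmark_week)
  ids
}

# ---- baseline encoding ---------------------------------------------------

baseline_factor_vars <- function() {
  c("region_of_birth", "family_situation", "smoking_pre", "smoking_early",
    "infertility_duration", "infertility_treatment", "blood_group")
}

baseline_bool_vars <- function() {
  c("prev_miscarriage", "fam_hist_preeclampsia", "fam_hist_hypertension",
    "cardiovascular_disease", "endocrine_disease", "preexisting_diabetes",
    "thrombosis_history", "sle", "chronic_hypertension", "ibd",
    "chronic_kidney_disease")
}

#' Encode baseline covariates as a numeric design block
#'
#' Dummy encoding against declared reference levels (the largest
#' printed category of each covariate: Sweden, living with partner,
#' non-smoking, no infertility, blood group O); explicit `missing`
#' dummies, never imputation. Continuous age and height are centered;
#' the centers default to the sample means and are returned so they can
#' be reused verbatim on new data.
#'
#' @param subjects subject data.frame.
#' @param centers optional named `c(maternal_age=, height_cm=)`.
#' @return list with `X` (matrix, deterministic 38-column order),
#'   `centers`, and `reference_levels`.
#' @export
encode_baseline <- function(subjects, centers = NULL) {
  s <- subjects
  centers <- centers %||% c(maternal_age = mean(s$maternal_age),
                            height_cm = mean(s$height_cm))
  cols <- list(
    maternal_age = s$maternal_age - centers[["maternal_age"]],
    height_cm = s$height_cm - centers[["height_cm"]]
  )
  order_vars <- c("region_of_birth", "family_situation", "smoking_pre",
                  "smoking_early", "prev_miscarriage",
                  "infertility_duration", "infertility_treatment",
                  "fam_hist_preeclampsia", "fam_hist_hypertension",
                  "cardiovascular_disease", "endocrine_disease",
                  "preexisting_diabetes", "thrombosis_history", "sle",
                  "chronic_hypertension", "ibd", "chronic_kidney_disease",
                  "blood_group")
  refs <- vapply(baseline_factor_vars(), function(v) .pe_levels[[v]][1],
                 character(1))
  for (v in order_vars) {
    if (v %in% baseline_factor_vars()) {
      lev <- .pe_levels[[v]]
      for (l in lev[-1]) cols[[paste0(v, "_", l)]] <- as.numeric(s[[v]] == l)
    } else {
      cols[[v]] <- as.numeric(s[[v]])
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- s$subject_id
  list(X = X, centers = centers, reference_levels = refs)
}

# ---- design assembly -----------------------------------------------------

#' Assemble the landmark design matrix
#'
#' Builds the modelling dataset for one landmark: encoded baseline
#' covariates, the 15 u-scores (5 markers x level/trend/curvature,
#' standardized against the non-preeclamptic at-risk women of this
#' landmark), the ever-high-glucose flag and the two dipstick dummies.
#' Column order is deterministic. Columns that carry no information —
#' u-score features whose scale is unavailable (e.g. symphysis-fundal
#' curvature at week 24) and constant baseline dummies — are kept at
#' their place but flagged inactive in the metadata so the fitter can
#' skip them; symphysis-fundal height contributes only from landmark
#' 24.
#'
#' When `template` (the metadata of a previously assembled dataset) is
#' given, its scales, centers and inactive set are reused, so new
#' subjects are encoded exactly as the training data were.
#'
#' @param cohort a `pe_cohort`.
#' @param trajectories named list of `pe_trajectory` models (one per
#'   marker); alternatively precomputed residuals via `residuals_list`.
#' @param landmark_week completed gestational week.
#' @param riskset subject ids (default [build_riskset()]).
#' @param exclude_aspirin passed to [build_riskset()] when `riskset`
#'   is `NULL`.
#' @param template metadata list of a training dataset, for scoring new
#'   data.
#' @param residuals_list optional named list of precomputed residual
#'   data.frames (from [trajectory_residuals()]), to avoid recomputing
#'   across landmarks.
#' @return a `pe_landmark_dataset`: list with `landmark_week`, `X`
#'   (design matrix), `labels` (outcome data.frame aligned to rows),
#'   `subject_id`, `scales`, and `meta` (column names, centers,
#'   reference levels, inactive columns).
#' @export
assemble_design <- function(cohort, trajectories, landmark_week,
                            riskset = NULL, exclude_aspirin = FALSE,
                            template = NULL, residuals_list = NULL) {
  stopifnot(inherits(cohort, "pe_cohort"))
  s <- cohort$subjects
  labels <- classify_outcomes(s)
  riskset <- riskset %||% build_riskset(s, landmark_week, exclude_aspirin)
  srs <- s[match(riskset, s$subject_id), , drop = FALSE]
  if (anyNA(srs$subject_id))
    stop_pe("risk set contains unknown subject ids")

  enc <- encode_baseline(srs, centers = template$centers)
  inactive <- character(0)

  markers <- names(trajectories) %||% names(residuals_list)
  u_cols <- list()
  scales <- if (is.null(template)) list() else template$scales
  non_pe_ids <- srs$subject_id[!srs$pe]
  for (m in markers) {
    res <- if (!is.null(residuals_list)) residuals_list[[m]]
           else trajectory_residuals(trajectories[[m]], cohort$visits)
    res <- res[res$subject_id %in% riskset, , drop = FALSE]
    sf_blocked <- (m == "sf_height" && landmark_week < 24)
    raw <- raw_coefficients_all(res, landmark_week, srs$subject_id)
    if (sf_blocked) {
      u <- data.frame(subject_id = srs$subject_id, u_level = 0, u_trend = 0,
                      u_curvature = 0, n_obs = 0L, stringsAsFactors = FALSE)
      attr(u, "inactive") <- c("u_level", "u_trend", "u_curvature")
      scales[[m]] <- NULL
    } else if (is.null(template)) {
      sc <- tryCatch(
        fit_uscore_scale(raw[raw$subject_id %in% non_pe_ids, , drop = FALSE],
                         m, landmark_week),
        error = function(e) NULL)
      scales[[m]] <- sc
      u <- if (is.null(sc)) {
        z <- data.frame(subject_id = srs$subject_id, u_level = 0, u_trend = 0,
                        u_curvature = 0, n_obs = raw$n_obs,
                        stringsAsFactors = FALSE)
        attr(z, "inactive") <- c("u_level", "u_trend", "u_curvature")
        z
      } else compute_uscores(raw, sc)
    } else {
      sc <- scales[[m]]
      if (is.null(sc) && !sf_blocked) {
        u <- data.frame(subject_id = srs$subject_id, u_level = 0, u_trend = 0,
                        u_curvature = 0, n_obs = raw$n_obs,
                        stringsAsFactors = FALSE)
        attr(u, "inactive") <- c("u_level", "u_trend", "u_curvature")
      } else if (!is.null(sc)) {
        u <- compute_uscores(raw, sc)
      }
    }
    for (f in c("u_level", "u_trend", "u_curvature")) {
      col <- sub("^u_", paste0("u_", m, "_"), f)
      u_cols[[col]] <- u[[f]]
      if (f %in% (attr(u, "inactive") %||% character(0)))
        inactive <- c(inactive, col)
    }
  }

  cats <- compute_categorical_features(cohort$visits, landmark_week,
                                       subject_ids = srs$subject_id)
  Xu <- if (length(u_cols)) do.call(cbind, u_cols) else NULL
  Xc <- cbind(glucose_high = as.numeric(cats$glucose_high_ever),
              proteinuria_1 = as.numeric(cats$proteinuria_max == 1L),
              proteinuria_2 = as.numeric(cats$proteinuria_max == 2L))
  X <- cbind(enc$X, Xu, Xc)

  if (is.null(template)) {
    const <- colnames(X)[apply(X, 2, function(x) max(x) - min(x) == 0)]
    inactive <- union(inactive, const)
  } else {
    if (!identical(colnames(X), template$columns))
      stop_pe("design columns do not match the training template")
    inactive <- template$inactive
  }

  structure(list(
    landmark_week = landmark_week,
    X = X,
    labels = labels[match(srs$subject_id, labels$subject_id), , drop = FALSE],
    subject_id = srs$subject_id,
    scales = scales,
    meta = list(columns = colnames(X), centers = enc$centers,
                reference_levels = enc$reference_levels,
                inactive = inactive, markers = markers,
                exclude_aspirin = exclude_aspirin)
  ), class = "pe_landmark_dataset")
}

#' @export
print.pe_landmark_dataset <- function(x, ...) {
  cat(sprintf(paste0("pe_landmark_dataset[week %d]: %d women, %d columns ",
                     "(%d inactive), %d preeclampsia cases pending\n"),
              x$landmark_week, nrow(x$X), ncol(x$X),
              length(x$meta$inactive), sum(x$labels$any_pe)))
  invisible(x)
}

# ---- risk model ----------------------------------------------------------

#' Fit the landmark logistic risk model for one outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the active
#' design columns. Detected separation or non-convergence triggers a
#' refit with a weak L2 penalty (1e-4 on standardized columns,
#' intercept unpenalized), recorded in the diagnostics; fewer than
#' `min_cases` cases or a rank-deficient active design is an error (the
#' collinear columns are named).
#'
#' @param dataset a [assemble_design()] result.
#' @param outcome one of the label columns (`"any_pe"`, `"preterm_pe"`,
#'   `"term_pe"`, `"dx_before_37"`, `"dx_from_37"`).
#' @param min_cases minimum outcome cases (default 10).
#' @param ridge penalty used by the fallback.
#' @return a `pe_risk_model`.
#' @export
fit_risk_model <- function(dataset, outcome, min_cases = 10, ridge = 1e-4) {
  stopifnot(inherits(dataset, "pe_landmark_dataset"))
  if (!outcome %in% names(dataset$labels))
    stop_pe("unknown outcome '%s'", outcome)
  y <- as.numeric(dataset$labels[[outcome]])
  if (sum(y) < min_cases)
    stop_pe("only %d cases of %s at landmark %d (need >= %d)",
            sum(y), outcome, dataset$landmark_week, min_cases)
  active <- setdiff(colnames(dataset$X), dataset$meta$inactive)
  X <- dataset$X[, active, drop = FALSE]

  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- c("(Intercept)", colnames(X))[qrX$pivot[-seq_len(qrX$rank)]]
    stop_pe("rank-deficient design at landmark %d; collinear column(s): %s",
            dataset$landmark_week, paste(dropped, collapse = ", "))
  }

  regularized <- FALSE
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial(),
            control = glm.control(maxit = 100)))
  separated <- !fit$converged || anyNA(fit$coefficients) ||
    any(abs(fit$coefficients) > 15)
  if (separated) {
    cf <- ridge_logistic(X, y, lambda = ridge)
    regularized <- TRUE
    eta <- drop(cbind(1, X) %*% cf)
    ll <- sum(y * eta - log1p(exp(eta)))
    converged <- TRUE
  } else {
    cf <- fit$coefficients
    eta <- drop(cbind(1, X) %*% cf)
    ll <- sum(y * eta - log1p(exp(eta)))
    converged <- fit$converged
  }
  se <- tryCatch({
    p <- plogis(eta); w <- p * (1 - p)
    XtWX <- crossprod(cbind(1, X) * sqrt(w))
    sqrt(diag(solve(XtWX)))
  }, error = function(e) rep(NA_real_, length(cf)))
  names(cf) <- names(se) <- c("(Intercept)", colnames(X))

  structure(list(outcome = outcome, landmark_week = dataset$landmark_week,
                 coefficients = cf, se = se,
                 regularization = if (regularized)
                   sprintf("L2 penalty %g on standardized columns", ridge)
                 else "none",
                 converged = converged, regularized = regularized,
                 log_likelihood = ll,
                 n = length(y), n_cases = sum(y),
                 meta = dataset$meta),
            class = "pe_risk_model")
}

# Weak-ridge logistic regression by Newton iterations with
# step-halving on the penalized deviance; penalty applies on
# standardized columns, intercept unpenalized. Returns coefficients on
# the original scale.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 200, tol = 1e-10) {
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, sd)
  sd_x[sd_x == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, mu_x), 2, sd_x, "/"))
  pen <- c(0, rep(lambda, ncol(X)))
  obj <- function(beta) {
    eta <- drop(Z %*% beta)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * beta^2) / 2
  }
  beta <- c(qlogis(max(min(mean(y), 1 - 1e-8), 1e-8)), rep(0, ncol(X)))
  f <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- -drop(crossprod(Z, y - p)) + pen * beta
    H <- crossprod(Z * sqrt(w)) + diag(pen)
    step <- drop(solve(H, grad))
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      fc <- obj(cand)
      if (is.finite(fc) && fc <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { cand <- beta; fc <- f; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand; f <- fc
    if (moved < tol) break
  }
  b <- beta[-1] / sd_x
  c(beta[1] - sum(b * mu_x), b)
}

#' Predicted risk from a landmark model
#'
#' Inverse-logit of the linear predictor; errors if the dataset's
#' column schema differs from the model's.
#'
#' @param model a `pe_risk_model`.
#' @param dataset a `pe_landmark_dataset` assembled with the model's
#'   template metadata.
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, dataset) {
  stopifnot(inherits(model, "pe_risk_model"),
            inherits(dataset, "pe_landmark_dataset"))
  if (!identical(dataset$meta$columns, model$meta$columns))
    stop_pe("dataset columns do not match the model's encoding metadata")
  active <- setdiff(model$meta$columns, model$meta$inactive)
  X <- dataset$X[, active, drop = FALSE]
  p <- plogis(drop(cbind(1, X) %*% model$coefficients))
  names(p) <- dataset$subject_id
  p
}

#' @export
print.pe_risk_model <- function(x, ...) {
  cat(sprintf(paste0("pe_risk_model[%s, week %d]: %d coefficients, %d/%d ",
                     "cases, logLik %.1f%s\n"),
              x$outcome, x$landmark_week, length(x$coefficients),
              x$n_cases, x$n, x$log_likelihood,
              if (x$regularized) sprintf(" (ridge: %s)", x$regularization)
              else ""))
  invisible(x)
}

#' @export
coef.pe_risk_model <- function(object, ...) object$coefficients

#' Serialize / restore a risk model as JSON
#'
#' @param model a `pe_risk_model`.
#' @param path output file.
#' @export
write_risk_model <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)
  obj$se <- as.list(obj$se)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$se <- unlist(obj$se)
  obj$meta$columns <- as.character(unlist(obj$meta$columns))
  obj$meta$inactive <- as.character(unlist(obj$meta$inactive))
  obj$meta$markers <- as.character(unlist(obj$meta$markers))
  obj$meta$centers <- unlist(obj$meta$centers)
  structure(obj, class = "pe_risk_model")
}
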