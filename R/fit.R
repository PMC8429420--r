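# The central model object: population trajectories -> u-scores ->
# per-landmark logistic risk models -> ROC evaluation, as one fit.

#' Fit the sequential landmark preeclampsia prediction model
#'
#' Runs the three modelling steps on a cohort: (1) non-preeclamptic
#' population mean trajectories per continuous marker (mixed-effects
#' model), (2) per-woman level/trend/curvature u-scores of the
#' departures from those curves at each landmark, using only
#' measurements strictly before the end of the completed landmark
#' week, and (3) a logistic risk model per outcome and landmark on the
#' baseline covariates, the u-scores and the categorical
#' glucose/proteinuria features, fitted among women not yet affected
#' (nor delivered) at the landmark. Evaluation is apparent (in-sample)
#' by default; `holdout = TRUE` fits on a seeded half of the women and
#' evaluates on the other half.
#'
#' @param cohort a [pe_cohort()].
#' @param landmarks completed gestational weeks (default 24, 28, 32,
#'   34, 36).
#' @param outcomes outcome labels to model (subset of `any_pe`,
#'   `preterm_pe`, `term_pe`, `dx_before_37`, `dx_from_37`).
#' @param markers continuous markers to use.
#' @param exclude_aspirin drop aspirin users from the risk sets,
#'   trajectory training and model fitting (the sensitivity analysis).
#' @param holdout evaluate on a held-out half instead of in-sample.
#' @param engine trajectory engine, see [fit_population_trajectory()].
#' @param n_boot bootstrap resamples for sensitivity CIs (0 to skip).
#' @param seed master seed (bootstrap and holdout split).
#' @param keep_data keep the per-landmark datasets and residuals in the
#'   returned object (needed by [residuals.pe_landmark()] and
#'   in-sample [predict.pe_landmark()] shortcuts).
#' @return an object of class `pe_landmark` with elements
#'   `trajectories`, `models`, `datasets`, `evaluation`, `landmarks`,
#'   `outcomes` and bookkeeping; see [predict.pe_landmark()],
#'   [summary.pe_landmark()], [plot.pe_landmark()].
#' @export
pe_landmark <- function(cohort,
                        landmarks = c(24, 28, 32, 34, 36),
                        outcomes = c("any_pe", "preterm_pe", "term_pe"),
                        markers = .pe_markers,
                        exclude_aspirin = FALSE,
                        holdout = FALSE,
                        engine = c("reml", "moment"),
                        n_boot = 2000,
                        seed = 1,
                        keep_data = TRUE) {
  stopifnot(inherits(cohort, "pe_cohort"))
  engine <- match.arg(engine)
  cl <- match.call()
  all_outcomes <- c("any_pe", "preterm_pe", "term_pe", "dx_before_37",
                    "dx_from_37")
  stopifnot(all(outcomes %in% all_outcomes))

  train <- cohort; test <- NULL
  if (holdout) {
    ids <- cohort$subjects$subject_id
    half <- with_seed(derive_seed(seed, "holdout"),
                      sample(ids, floor(length(ids) / 2)))
    train <- subset_cohort(cohort, half)
    test <- subset_cohort(cohort, setdiff(ids, half))
  }
  if (exclude_aspirin) {
    keep <- train$subjects$subject_id[!train$subjects$aspirin_use]
    train <- subset_cohort(train, keep)
    if (!is.null(test))
      test <- subset_cohort(test,
                            test$subjects$subject_id[!test$subjects$aspirin_use])
  }

  # step 1: population curves on unaffected women only
  ctrl_ids <- train$subjects$subject_id[!train$subjects$pe]
  ctrl <- subset_cohort(train, ctrl_ids)
  trajectories <- lapply(setNames(markers, markers), function(m)
    fit_population_trajectory(ctrl$visits, ctrl$subjects, m, engine = engine))

  # residuals once per marker, reused across landmarks
  res_train <- lapply(trajectories, trajectory_residuals,
                      visits = train$visits)
  res_test <- if (!is.null(test))
    lapply(trajectories, trajectory_residuals, visits = test$visits)

  datasets <- list(); eval_sets <- list(); models <- list()
  for (w in landmarks) {
    key <- as.character(w)
    ds <- assemble_design(train, trajectories, w,
                          residuals_list = res_train)
    datasets[[key]] <- ds
    eval_sets[[key]] <- if (is.null(test)) ds else
      assemble_design(test, trajectories, w, template = ds$meta,
                      residuals_list = res_test)
    for (oc in outcomes) {
      fit <- tryCatch(fit_risk_model(ds, oc), error = function(e) e)
      if (inherits(fit, "error")) {
        models[[oc]][key] <- list(NULL)
        attr(models, "absent") <- rbind(
          attr(models, "absent"),
          data.frame(outcome = oc, landmark_week = w,
                     reason = conditionMessage(fit),
                     stringsAsFactors = FALSE))
      } else {
        models[[oc]][[key]] <- fit
      }
    }
  }

  evaluation <- evaluate_all(models, eval_sets, outcomes = outcomes,
                             landmarks = landmarks, n_boot = n_boot,
                             seed = seed, keep_roc = TRUE)

  structure(list(call = cl,
                 landmarks = landmarks, outcomes = outcomes,
                 markers = markers,
                 exclude_aspirin = exclude_aspirin, holdout = holdout,
                 trajectories = trajectories,
                 models = models,
                 datasets = if (keep_data) datasets else NULL,
                 eval_datasets = if (keep_data && holdout) eval_sets else NULL,
                 residuals = if (keep_data) res_train else NULL,
                 evaluation = evaluation,
                 absent = attr(models, "absent"),
                 n_subjects = nrow(cohort$subjects),
                 seed = seed),
            class = "pe_landmark")
}

# restrict a cohort (and its truth attribute) to a set of women
subset_cohort <- function(cohort, ids) {
  out <- structure(list(
    subjects = cohort$subjects[cohort$subjects$subject_id %in% ids, ,
                               drop = FALSE],
    visits = cohort$visits[cohort$visits$subject_id %in% ids, ,
                           drop = FALSE]), class = "pe_cohort")
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) attr(out, "truth") <- tr[tr$subject_id %in% ids, ,
                                             drop = FALSE]
  out
}

#' @export
print.pe_landmark <- function(x, ...) {
  cat("Sequential landmark preeclampsia prediction model\n")
  cat(sprintf("  %d subjects; landmarks (completed weeks): %s\n",
              x$n_subjects, paste(x$landmarks, collapse = ", ")))
  cat(sprintf("  outcomes: %s\n", paste(x$outcomes, collapse = ", ")))
  cat(sprintf("  markers: %s\n", paste(x$markers, collapse = ", ")))
  cat(sprintf("  evaluation: %s%s\n",
              if (x$holdout) "holdout" else "apparent (in-sample)",
              if (x$exclude_aspirin) ", aspirin users excluded" else ""))
  n_fit <- sum(vapply(x$models, function(l)
    sum(!vapply(l, is.null, logical(1))), numeric(1)))
  cat(sprintf("  %d fitted risk models", n_fit))
  if (!is.null(x$absent))
    cat(sprintf(" (%d outcome x landmark cells absent)", nrow(x$absent)))
  cat("\n")
  invisible(x)
}

#' @export
summary.pe_landmark <- function(object, ...) {
  structure(list(fit = object), class = "summary.pe_landmark")
}

#' @export
print.summary.pe_landmark <- function(x, ...) {
  print(x$fit)
  cat("\nPopulation trajectories:\n")
  for (tr in x$fit$trajectories) print(tr)
  cat("\n")
  print(x$fit$evaluation)
  if (!is.null(x$fit$absent)) {
    cat("\nAbsent cells:\n")
    print(x$fit$absent, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.pe_landmark <- function(object, outcome = NULL, landmark = NULL, ...) {
  outcome <- outcome %||% object$outcomes[1]
  landmark <- landmark %||% object$landmarks
  out <- lapply(setNames(as.character(landmark), paste0("week", landmark)),
                function(k) {
                  m <- object$models[[outcome]][[k]]
                  if (is.null(m)) NULL else m$coefficients
                })
  if (length(out) == 1) out[[1]] else out
}

#' Predict landmark-specific preeclampsia risk
#'
#' Scores a cohort with the fitted models. New women are run through
#' the full feature pipeline (residuals against the stored population
#' curves, u-scores with the stored training scales, training encoding
#' template), so no quantity is re-estimated on the new data.
#'
#' @param object a `pe_landmark` fit.
#' @param newdata a `pe_cohort`; omit for training-set predictions.
#' @param landmark completed week(s); default all fitted.
#' @param outcome outcome label(s); default all fitted.
#' @return data.frame `subject_id`, `landmark_week`, `outcome`, `risk`.
#' @export
predict.pe_landmark <- function(object, newdata = NULL, landmark = NULL,
                                outcome = NULL, ...) {
  landmark <- landmark %||% object$landmarks
  outcome <- outcome %||% object$outcomes
  rows <- list()
  for (w in landmark) {
    key <- as.character(w)
    ds_train <- object$datasets[[key]]
    if (is.null(ds_train))
      stop_pe("no dataset stored for landmark %s (refit with keep_data=TRUE)",
              key)
    ds <- if (is.null(newdata)) ds_train else
      assemble_design(newdata, object$trajectories, w,
                      template = ds_train$meta)
    for (oc in outcome) {
      m <- object$models[[oc]][[key]]
      if (is.null(m)) next
      p <- predict_risk(m, ds)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ds$subject_id, landmark_week = w, outcome = oc,
        risk = unname(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
residuals.pe_landmark <- function(object, marker = NULL, ...) {
  if (is.null(object$residuals))
    stop_pe("residuals were not kept (refit with keep_data=TRUE)")
  marker <- marker %||% object$markers[1]
  object$residuals[[marker]]
}

#' Plot a landmark fit
#'
#' `type = "roc"` draws the ROC curves of one outcome across landmarks;
#' `type = "trajectory"` draws the fitted population mean curves.
#'
#' @param x a `pe_landmark`.
#' @param type `"roc"` or `"trajectory"`.
#' @param outcome outcome for ROC curves.
#' @param ... unused.
#' @export
plot.pe_landmark <- function(x, type = c("roc", "trajectory"),
                             outcome = NULL, ...) {
  type <- match.arg(type)
  if (type == "roc") {
    outcome <- outcome %||% x$outcomes[1]
    rocs <- attr(x$evaluation, "roc")
    keys <- paste0(outcome, "_w", x$landmarks)
    keys <- keys[keys %in% names(rocs)]
    if (length(keys) == 0) stop_pe("no ROC curves stored for %s", outcome)
    plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
         xlab = "False positive rate", ylab = "Sensitivity",
         main = sprintf("ROC by landmark: %s", outcome))
    cols <- seq_along(keys) + 1
    for (i in seq_along(keys))
      lines(rocs[[keys[i]]]$fpr, rocs[[keys[i]]]$tpr, col = cols[i])
    legend("bottomright", legend = sub(paste0(outcome, "_w"), "week ", keys),
           col = cols, lty = 1, bty = "n")
  } else {
    old <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    on.exit(par(old))
    for (m in x$markers) {
      tr <- x$trajectories[[m]]
      ga <- seq(tr$ga_support[1], tr$ga_support[2], by = 1)
      plot(ga / 7, predict_mean(tr, ga), type = "l",
           xlab = "Gestational week", ylab = m,
           main = sprintf("%s population mean", m))
    }
  }
  invisible(x)
}
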