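# Population mean trajectories of the continuous markers, fitted on
# the non-preeclamptic population with a linear mixed model (fixed
# spline basis in gestational age, random intercept per woman).

#' Basis specification for a trajectory model
#'
#' @param type `"bspline"` (cubic B-spline with fixed knots) or
#'   `"linear"`.
#' @param degree spline degree (bspline only).
#' @param boundary boundary knots in gestational days.
#' @param interior interior knots in gestational days.
#' @return a `pe_basis_spec` list.
#' @export
basis_spec <- function(type = c("bspline", "linear"), degree = 3,
                       boundary = c(42, 310), interior = c(112, 168, 224)) {
  type <- match.arg(type)
  structure(list(type = type, degree = degree, boundary = boundary,
                 interior = if (type == "bspline") interior else numeric(0)),
            class = "pe_basis_spec")
}

#' Default basis per marker
#'
#' Cubic B-splines with interior knots at weeks 16/24/32 reproduce the
#' non-monotone shapes (second-trimester dip in blood pressure and
#' hemoglobin); symphysis-fundal height, measured only from week 24,
#' gets a linear basis on `[168, 310]`.
#'
#' @param marker marker name.
#' @return a [basis_spec()].
#' @export
default_basis <- function(marker) {
  if (marker == "sf_height")
    basis_spec("linear", boundary = c(168, 310))
  else
    basis_spec("bspline")
}

build_basis <- function(spec, ga_days) {
  if (spec$type == "bspline") {
    # extrapolation beyond the boundary knots is flagged by
    # predict_mean; bs() would warn redundantly
    B <- suppressWarnings(
      splines::bs(ga_days, knots = spec$interior, degree = spec$degree,
                  Boundary.knots = spec$boundary, intercept = FALSE))
    B <- unclass(B)[, , drop = FALSE]
    colnames(B) <- paste0("b", seq_len(ncol(B)))
  } else {
    B <- matrix((ga_days - spec$boundary[1]) / 7, ncol = 1,
                dimnames = list(NULL, "b1"))
  }
  B
}

#' Fit the non-preeclamptic population mean trajectory of a marker
#'
#' Linear mixed model `marker ~ basis(ga) + (1 | woman)` fitted by REML
#' on the visits of women without preeclampsia only (the guard refuses
#' training data containing an affected woman). A degenerate fit with
#' essentially zero residual variance (e.g. noise-free synthetic data)
#' falls back to ordinary least squares, which is exact in that limit.
#'
#' @param visits visit data.frame (rows with `NA` marker are dropped;
#'   symphysis-fundal height observations before 168 days are refused).
#' @param subjects subject data.frame covering the visits' women; every
#'   one must have `pe = FALSE`.
#' @param marker one of `"sbp"`, `"dbp"`, `"weight"`, `"hb"`,
#'   `"sf_height"`.
#' @param basis a [basis_spec()]; default [default_basis()].
#' @param random_slope also include a random slope in gestational age.
#' @param engine `"reml"` (lme4) or `"moment"` (ordinary least squares
#'   for the fixed curve plus method-of-moments variance components;
#'   useful at large scale where the two agree).
#' @return a `pe_trajectory` object.
#' @export
fit_population_trajectory <- function(visits, subjects, marker,
                                      basis = NULL, random_slope = FALSE,
                                      engine = c("reml", "moment")) {
  engine <- match.arg(engine)
  if (!marker %in% .pe_markers) stop_pe("unknown marker '%s'", marker)
  basis <- basis %||% default_basis(marker)
  keep <- !is.na(visits[[marker]])
  d <- data.frame(subject_id = visits$subject_id[keep],
                  ga_days = visits$ga_days[keep],
                  y = visits[[marker]][keep], stringsAsFactors = FALSE)
  pe_flag <- subjects$pe[match(unique(d$subject_id), subjects$subject_id)]
  if (anyNA(pe_flag))
    stop_pe("training visits reference subjects missing from the subject table")
  if (any(pe_flag))
    stop_pe("training set for the population trajectory must contain only women without preeclampsia")
  if (marker == "sf_height" && any(d$ga_days < 168))
    stop_pe("symphysis-fundal height observations before 168 days are not admissible")
  if (length(unique(d$subject_id)) < 2 || nrow(d) < 4)
    stop_pe("insufficient data: need >= 2 observations from >= 2 subjects")

  B <- build_basis(basis, d$ga_days)
  X <- cbind(`(Intercept)` = 1, B)
  fit <- NULL
  notes <- character(0)

  ols <- lm.fit(X, d$y)
  ols_resid_var <- sum(ols$residuals^2) / max(1, nrow(d) - ncol(X))

  if (engine == "reml" && ols_resid_var > 1e-16) {
    dd <- cbind(d, as.data.frame(B))
    form <- as.formula(paste(
      "y ~", paste(colnames(B), collapse = " + "),
      if (random_slope) "+ (1 + I(ga_days/7) | subject_id)"
      else "+ (1 | subject_id)"))
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(form, data = dd, REML = TRUE,
                          control = lme4::lmerControl(calc.derivs = FALSE)),
               error = function(e) {
                 stop_pe("trajectory model for %s did not converge: %s",
                         marker, conditionMessage(e))
               }),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        notes <<- c(notes, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
  }

  if (!is.null(fit)) {
    cf <- lme4::fixef(fit)
    fixed_se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri <- vc$sdcor[vc$grp == "subject_id" & vc$var1 == "(Intercept)" &
                     is.na(vc$var2)][1]
    rs <- if (random_slope)
      vc$sdcor[vc$grp == "subject_id" & !is.na(vc$var1) &
                 vc$var1 != "(Intercept)" & is.na(vc$var2)][1] else 0
    sig <- vc$sdcor[vc$grp == "Residual"][1]
  } else {
    # noise-free limit or explicit moment engine
    cf <- ols$coefficients
    e <- ols$residuals
    ebar <- tapply(e, d$subject_id, mean)
    nsub <- tapply(e, d$subject_id, length)
    within <- e - ebar[d$subject_id]
    sig2 <- sum(within^2) / max(1, nrow(d) - length(ebar))
    ri2 <- max(0, var(ebar) - sig2 * mean(1 / nsub))
    ri <- sqrt(ri2); rs <- 0; sig <- sqrt(sig2)
    xtx_inv <- chol2inv(chol(crossprod(X)))
    fixed_se <- sqrt(pmax(diag(xtx_inv), 0) * (sig^2 + ri^2))
    if (engine == "reml") notes <- c(notes, "zero-residual OLS fallback")
  }
  names(cf) <- names(fixed_se) <- colnames(X)

  structure(list(marker = marker, basis = basis,
                 fixed_coefficients = cf,
                 fixed_se = fixed_se,
                 random_intercept_sd = unname(ri),
                 random_slope_sd = unname(rs),
                 residual_sd = unname(sig),
                 fit_n_subjects = length(unique(d$subject_id)),
                 fit_n_obs = nrow(d),
                 ga_support = range(d$ga_days),
                 engine = if (is.null(fit)) "ols" else engine,
                 notes = notes),
            class = "pe_trajectory")
}

#' Evaluate the fitted population mean curve
#'
#' Deterministic evaluation of the fixed-effect curve at arbitrary
#' gestational ages. Points outside the training support are evaluated
#' but flagged: the result carries an `"extrapolated"` logical
#' attribute and a warning is raised.
#'
#' @param model a `pe_trajectory`.
#' @param ga_days gestational ages in days.
#' @return numeric vector of mean marker values.
#' @export
predict_mean <- function(model, ga_days) {
  stopifnot(inherits(model, "pe_trajectory"))
  B <- build_basis(model$basis, ga_days)
  out <- drop(cbind(1, B) %*% model$fixed_coefficients)
  extra <- ga_days < model$ga_support[1] | ga_days > model$ga_support[2]
  if (any(extra)) {
    warning(sprintf("%d of %d evaluation points lie outside the %s support [%g, %g]",
                    sum(extra), length(ga_days), model$marker,
                    model$ga_support[1], model$ga_support[2]), call. = FALSE)
    attr(out, "extrapolated") <- extra
  }
  out
}

#' @export
predict.pe_trajectory <- function(object, ga_days, ...) {
  predict_mean(object, ga_days)
}

#' Departures of observed visits from the population mean curve
#'
#' One residual (observed minus predicted mean) per non-missing
#' measurement of the model's marker, input order preserved.
#'
#' @param model a `pe_trajectory`.
#' @param visits visit data.frame (any subset of women).
#' @return data.frame with `subject_id`, `ga_days`, `residual`.
#' @export
trajectory_residuals <- function(model, visits) {
  stopifnot(inherits(model, "pe_trajectory"))
  keep <- !is.na(visits[[model$marker]])
  ga <- visits$ga_days[keep]
  pred <- suppressWarnings(predict_mean(model, ga))
  data.frame(subject_id = visits$subject_id[keep], ga_days = ga,
             residual = visits[[model$marker]][keep] - as.numeric(pred),
             stringsAsFactors = FALSE)
}

#' @export
residuals.pe_trajectory <- function(object, visits, ...) {
  trajectory_residuals(object, visits)
}

#' @export
print.pe_trajectory <- function(x, ...) {
  cat(sprintf(paste0("pe_trajectory[%s]: %s basis, %d coefficients; ",
                     "random intercept SD %.3f, residual SD %.3f; ",
                     "fitted on %d obs from %d women, support [%g, %g] days\n"),
              x$marker, x$basis$type, length(x$fixed_coefficients),
              x$random_intercept_sd, x$residual_sd, x$fit_n_obs,
              x$fit_n_subjects, x$ga_support[1], x$ga_support[2]))
  invisible(x)
}

#' Serialize / restore a trajectory model as JSON
#'
#' @param model a `pe_trajectory`.
#' @param path output file.
#' @return `write_trajectory` the path, invisibly; `read_trajectory`
#'   the restored `pe_trajectory`.
#' @export
write_trajectory <- function(model, path) {
  stopifnot(inherits(model, "pe_trajectory"))
  obj <- unclass(model)
  obj$basis <- unclass(obj$basis)
  obj$fixed_coefficients <- as.list(obj$fixed_coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$fixed_coefficients <- unlist(obj$fixed_coefficients)
  obj$fixed_se <- unlist(obj$fixed_se)
  obj$basis <- structure(as.list(obj$basis), class = "pe_basis_spec")
  obj$ga_support <- as.numeric(obj$ga_support)
  structure(obj, class = "pe_trajectory")
}
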