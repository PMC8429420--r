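# Per-woman trajectory features at a landmark: level / trend /
# curvature coefficients of the residual curve, standardized into
# u-scores against the non-preeclamptic at-risk population, plus the
# two categorical time-varying features.
#
# The landmark window is strictly before the end of completed week w:
# only measurements with ga_days < 7 * (w + 1) enter any feature.

#' Raw level/trend/curvature coefficients of one woman's residuals
#'
#' Least-squares fit of the residuals on an orthogonal quadratic
#' polynomial in centered gestational age (centered at the woman's mean
#' observed ga within the window, measured in weeks; the basis is
#' orthogonalized on her own observation times, so the intercept is the
#' mean departure, the linear coefficient the trend per week and the
#' quadratic coefficient the curvature per week squared, and the three
#' are mutually uncorrelated). Degenerate inputs shrink to the
#' population mean: two observations give an exact line with zero
#' curvature, one observation gives its residual as the level, none
#' gives all zeros.
#'
#' @param ga_days observation gestational ages (days), already
#'   truncated to the landmark window.
#' @param residuals departures from the population mean curve, aligned
#'   to `ga_days`.
#' @return named numeric `c(level, trend, curvature, n_obs)`.
#' @export
raw_trajectory_coefficients <- function(ga_days, residuals) {
  stopifnot(length(ga_days) == length(residuals))
  n <- length(ga_days)
  if (n == 0) return(c(level = 0, trend = 0, curvature = 0, n_obs = 0))
  t <- (ga_days - mean(ga_days)) / 7
  y <- residuals
  s2 <- sum(t^2); s3 <- sum(t^3); s4 <- sum(t^4)
  level <- mean(y)
  trend <- if (s2 > 1e-10) sum(t * y) / s2 else 0
  curv <- 0
  if (s2 > 1e-10) {
    p2ss <- s4 - s3^2 / s2 - s2^2 / n
    if (p2ss > 1e-10)
      curv <- (sum(t^2 * y) - (s3 / s2) * sum(t * y) - (s2 / n) * sum(y)) / p2ss
  }
  c(level = level, trend = trend, curvature = curv, n_obs = n)
}

# Vectorized raw coefficients for many women at once (same algebra as
# raw_trajectory_coefficients, via per-group sufficient statistics).
raw_coefficients_all <- function(res_df, landmark_week, subject_ids) {
  dt <- data.table::as.data.table(res_df)
  dt <- dt[ga_days < landmark_end_day(landmark_week)]
  if (nrow(dt) > 0) {
    dt[, t_c := (ga_days - mean(ga_days)) / 7, by = subject_id]
    agg <- dt[, {
      n <- .N
      s2 <- sum(t_c^2); s3 <- sum(t_c^3); s4 <- sum(t_c^4)
      sy <- sum(residual); sty <- sum(t_c * residual)
      st2y <- sum(t_c^2 * residual)
      level <- sy / n
      trend <- if (s2 > 1e-10) sty / s2 else 0
      curv <- 0
      if (s2 > 1e-10) {
        p2ss <- s4 - s3^2 / s2 - s2^2 / n
        if (p2ss > 1e-10) curv <- (st2y - (s3 / s2) * sty - (s2 / n) * sy) / p2ss
      }
      list(level = level, trend = trend, curvature = curv, n_obs = n)
    }, by = subject_id]
  } else {
    agg <- data.table::data.table(subject_id = character(0), level = numeric(0),
                                  trend = numeric(0), curvature = numeric(0),
                                  n_obs = integer(0))
  }
  out <- data.table::data.table(subject_id = subject_ids)
  out <- agg[out, on = "subject_id"]
  for (cl in c("level", "trend", "curvature")) # women with no obs: shrink to 0
    data.table::set(out, which(is.na(out[[cl]])), cl, 0)
  data.table::set(out, which(is.na(out$n_obs)), "n_obs", 0L)
  as.data.frame(out)
}

#' Standardization scale of raw coefficients at a landmark
#'
#' Centers and dispersions of the raw level/trend/curvature
#' coefficients among women without preeclampsia still at risk at the
#' landmark; a woman contributes to the level scale with >= 1
#' observation, to trend with >= 2 and to curvature with >= 3. A
#' feature with fewer than `min_contributors` contributing women is
#' marked unavailable (`NA` center/sd) — its u-scores are zeroed and
#' flagged downstream; fewer than `min_contributors` level contributors
#' makes the whole scale unreliable and is an error, as is a
#' dispersion at the degeneracy floor.
#'
#' @param raw data.frame from [raw_trajectory_coefficients()] /
#'   `raw_coefficients_all` restricted to non-preeclamptic at-risk
#'   women (columns `level`, `trend`, `curvature`, `n_obs`).
#' @param marker marker name (metadata only).
#' @param landmark_week completed gestational week of the landmark.
#' @param min_contributors minimum women per feature (default 30).
#' @param sd_floor degeneracy guard on the dispersions (default 1e-8).
#' @return a `pe_uscore_scale` object.
#' @export
fit_uscore_scale <- function(raw, marker, landmark_week,
                             min_contributors = 30, sd_floor = 1e-8) {
  need <- c(level = 1L, trend = 2L, curvature = 3L)
  center <- sds <- setNames(rep(NA_real_, 3), names(need))
  n_contrib <- setNames(integer(3), names(need))
  for (f in names(need)) {
    x <- raw[[f]][raw$n_obs >= need[[f]]]
    n_contrib[[f]] <- length(x)
    if (length(x) >= min_contributors) {
      center[[f]] <- mean(x)
      sds[[f]] <- sd(x)
      if (sds[[f]] < sd_floor)
        stop_pe("degenerate %s %s dispersion at landmark %d (below the %g floor)",
                marker, f, landmark_week, sd_floor)
    }
  }
  if (is.na(center[["level"]]))
    stop_pe("unreliable u-score scale for %s at landmark %d: only %d contributing women (need %d)",
            marker, landmark_week, n_contrib[["level"]], min_contributors)
  structure(list(marker = marker, landmark_week = landmark_week,
                 center = center, sd = sds, n_contributors = n_contrib),
            class = "pe_uscore_scale")
}

#' @export
print.pe_uscore_scale <- function(x, ...) {
  cat(sprintf("pe_uscore_scale[%s, week %d]\n", x$marker, x$landmark_week))
  for (f in names(x$center))
    cat(sprintf("  %-9s center %8.4g  sd %8.4g  (n=%d)\n", f,
                x$center[[f]], x$sd[[f]], x$n_contributors[[f]]))
  invisible(x)
}

#' Standardize raw coefficients into u-scores
#'
#' `u = (raw - center) / sd` per feature; features whose scale is
#' unavailable yield 0 and are listed in the `"inactive"` attribute.
#'
#' @param raw data.frame of raw coefficients (any set of women).
#' @param scale a [fit_uscore_scale()] result for the same marker and
#'   landmark.
#' @return data.frame `subject_id`, `u_level`, `u_trend`,
#'   `u_curvature`, `n_obs`.
#' @export
compute_uscores <- function(raw, scale) {
  stopifnot(inherits(scale, "pe_uscore_scale"))
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  inactive <- character(0)
  for (f in c("level", "trend", "curvature")) {
    u_col <- paste0("u_", f)
    if (is.na(scale$center[[f]])) {
      out[[u_col]] <- 0
      inactive <- c(inactive, u_col)
    } else {
      out[[u_col]] <- (raw[[f]] - scale$center[[f]]) / scale$sd[[f]]
    }
  }
  out$n_obs <- raw$n_obs
  attr(out, "inactive") <- inactive
  out
}

#' Categorical time-varying features at a landmark
#'
#' Ever-high capillary glucose (>= 9 mmol/L at any visit strictly
#' before the end of the landmark week, boundary inclusive) and the
#' maximum dipstick proteinuria category observed in the same window
#' (0 when never measured).
#'
#' @param visits visit data.frame.
#' @param landmark_week completed gestational week.
#' @param subject_ids women to report (default: all in `visits`).
#' @return data.frame `subject_id`, `glucose_high_ever`,
#'   `proteinuria_max`.
#' @export
compute_categorical_features <- function(visits, landmark_week,
                                         subject_ids = NULL) {
  subject_ids <- subject_ids %||% unique(visits$subject_id)
  dt <- data.table::as.data.table(
    visits[, c("subject_id", "ga_days", "glucose", "proteinuria")])
  dt <- dt[ga_days < landmark_end_day(landmark_week)]
  agg <- dt[, list(
    glucose_high_ever = any(!is.na(glucose) & glucose >= 9.0),
    proteinuria_max = {
      p <- suppressWarnings(as.integer(proteinuria))
      as.integer(max(c(0L, p[!is.na(p)])))
    }), by = subject_id]
  out <- data.table::data.table(subject_id = subject_ids)
  out <- agg[out, on = "subject_id"]
  data.table::set(out, which(is.na(out$glucose_high_ever)),
                  "glucose_high_ever", FALSE)
  data.table::set(out, which(is.na(out$proteinuria_max)),
                  "proteinuria_max", 0L)
  as.data.frame(out)
}
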