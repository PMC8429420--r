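# Cohort container, CSV readers/writers and invariant validation.

#' Construct a cohort object
#'
#' Bundles a one-row-per-woman subject table and a long visit table into
#' a `pe_cohort` object, coercing column types against the declared
#' schemas. Category columns are stored as character vectors restricted
#' to their documented level sets; booleans as logicals; blank/absent
#' optional measurements as `NA`.
#'
#' @param subjects data.frame with the subject columns (see
#'   [load_cohort()] for the schema).
#' @param visits data.frame with the visit columns.
#' @param truth optional data.frame of generator ground truth.
#' @return an object of class `pe_cohort`: a list with elements
#'   `subjects` and `visits` (both data.frames).
#' @export
pe_cohort <- function(subjects, visits, truth = NULL) {
  subjects <- coerce_table(subjects, .subject_schema, "subjects")
  visits <- coerce_table(visits, .visit_schema, "visits")
  unknown <- setdiff(visits$subject_id, subjects$subject_id)
  if (length(unknown) > 0)
    stop_pe("visits reference unknown subject_id(s): %s",
            paste(head(unknown, 5), collapse = ", "))
  out <- structure(list(subjects = subjects, visits = visits),
                   class = "pe_cohort")
  if (!is.null(truth)) attr(out, "truth") <- truth
  out
}

coerce_table <- function(df, schema, what) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), names(schema))
  if (length(extra) > 0)
    stop_pe("unknown column(s) in %s: %s", what, paste(extra, collapse = ", "))
  miss <- setdiff(names(schema), names(df))
  if (length(miss) > 0)
    stop_pe("missing column(s) in %s: %s", what, paste(miss, collapse = ", "))
  df <- df[names(schema)]
  for (col in names(schema)) {
    df[[col]] <- coerce_column(df[[col]], schema[[col]], col, what)
  }
  df
}

coerce_column <- function(x, type, col, what) {
  if (type == "character") return(as.character(x))
  if (type == "numeric") {
    if (is.character(x)) x[x == ""] <- NA
    xn <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(xn))
    if (length(bad) > 0)
      stop_pe("unparseable number in %s$%s at row %d: '%s'",
              what, col, bad[1], as.character(x[bad[1]]))
    return(xn)
  }
  if (type == "logical") {
    if (is.logical(x)) return(x)
    xc <- as.character(x)
    xc[xc == ""] <- NA
    ok <- is.na(xc) | xc %in% c("0", "1", "TRUE", "FALSE")
    if (!all(ok))
      stop_pe("non-boolean value in %s$%s at row %d: '%s'",
              what, col, which(!ok)[1], xc[which(!ok)[1]])
    return(xc %in% c("1", "TRUE") & !is.na(xc))
  }
  if (type == "category") {
    levels <- .pe_levels[[col]]
    xc <- as.character(x)
    if (col == "proteinuria") {
      xc[!is.na(xc) & xc == ""] <- NA       # dipstick not taken
    } else if ("missing" %in% levels) {
      xc[is.na(xc) | xc == ""] <- "missing"
    } else {
      # covariates recorded as tick boxes: absent means none
      xc[is.na(xc) | xc == ""] <- "none"
    }
    bad <- which(!is.na(xc) & !(xc %in% levels))
    if (length(bad) > 0)
      stop_pe("unknown %s level in %s at row %d: '%s' (allowed: %s)",
              col, what, bad[1], xc[bad[1]], paste(levels, collapse = "/"))
    return(xc)
  }
  stop_pe("unhandled schema type '%s'", type)
}

#' Read a cohort from CSV files
#'
#' Reads `subjects.csv` and `visits.csv` written by [write_cohort()] (or
#' prepared externally with the same headers). Booleans are encoded
#' 0/1, missing values as empty cells; hemoglobin is in g/L, blood
#' pressure in mmHg, weight in kg, gestational ages in days.
#'
#' @param subjects_path path to the subject CSV.
#' @param visits_path path to the visit CSV.
#' @return a [pe_cohort()] object.
#' @export
load_cohort <- function(subjects_path, visits_path) {
  if (!file.exists(subjects_path)) stop_pe("no such file: %s", subjects_path)
  if (!file.exists(visits_path)) stop_pe("no such file: %s", visits_path)
  s <- data.table::fread(subjects_path, colClasses = "character",
                         na.strings = NULL, data.table = FALSE)
  v <- data.table::fread(visits_path, colClasses = "character",
                         na.strings = NULL, data.table = FALSE)
  if (nrow(s) == 0) s <- empty_frame(.subject_schema)
  if (nrow(v) == 0) v <- empty_frame(.visit_schema)
  pe_cohort(s, v)
}

empty_frame <- function(schema) {
  out <- lapply(schema, function(t) switch(t,
    character = character(0), numeric = numeric(0),
    logical = logical(0), category = character(0)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a cohort to CSV files
#'
#' Inverse of [load_cohort()]: `load_cohort` on the written files
#' reproduces the cohort field-for-field (generated measurements are
#' rounded to clinical precision at simulation time, so the numeric
#' round trip is exact).
#'
#' @param cohort a `pe_cohort`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector with the two file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "pe_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(out_dir, "subjects.csv"),
             visits = file.path(out_dir, "visits.csv"))
  data.table::fwrite(cohort$subjects, paths[["subjects"]], na = "",
                     logical01 = TRUE)
  data.table::fwrite(cohort$visits, paths[["visits"]], na = "",
                     logical01 = TRUE)
  invisible(paths)
}

#' Validate cohort invariants
#'
#' Checks every domain invariant and returns all violations (violations
#' are data, not exceptions): delivery from gestational week 22
#' (>= 154 days); preeclampsia diagnosis after 20 weeks (> 140 days)
#' and not after delivery; visit gestational ages within `[0,
#' delivery]`; symphysis-fundal height only from week 24 (>= 168 days);
#' systolic pressure accompanied by, and exceeding, diastolic.
#'
#' @param cohort a `pe_cohort`.
#' @return a `pe_validation` object: list with `n_subjects`, `n_visits`
#'   and a data.frame `violations` (rule_id, subject_id, message).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pe_cohort"))
  s <- cohort$subjects
  v <- cohort$visits
  viol <- list()
  add <- function(rule, ids, msg) {
    if (length(ids) > 0)
      viol[[length(viol) + 1]] <<- data.frame(
        rule_id = rule, subject_id = ids, message = msg,
        stringsAsFactors = FALSE)
  }

  add("delivery_week22_floor",
      s$subject_id[!is.na(s$ga_delivery_days) & s$ga_delivery_days < 154],
      "ga_delivery_days below 154 (births included from week 22)")
  add("delivery_present", s$subject_id[is.na(s$ga_delivery_days)],
      "ga_delivery_days missing")
  add("diagnosis_iff_pe",
      s$subject_id[(s$pe & is.na(s$ga_diagnosis_days)) |
                   (!s$pe & !is.na(s$ga_diagnosis_days))],
      "ga_diagnosis_days must be present exactly for preeclamptic women")
  pe_dx <- s$pe & !is.na(s$ga_diagnosis_days)
  add("diagnosis_after_week20",
      s$subject_id[pe_dx & s$ga_diagnosis_days <= 140],
      "preeclampsia diagnosis at or before 140 days (20 weeks)")
  add("diagnosis_before_delivery",
      s$subject_id[pe_dx & !is.na(s$ga_delivery_days) &
                   s$ga_diagnosis_days > s$ga_delivery_days],
      "diagnosis after delivery")

  deliv <- s$ga_delivery_days[match(v$subject_id, s$subject_id)]
  add("visit_ga_range",
      unique(v$subject_id[is.na(v$ga_days) | v$ga_days < 0 |
                          (!is.na(deliv) & v$ga_days > deliv)]),
      "visit ga_days outside [0, ga_delivery_days]")
  add("sf_height_from_week24",
      unique(v$subject_id[!is.na(v$sf_height) & v$ga_days < 168]),
      "symphysis-fundal height recorded before 168 days (week 24)")
  add("bp_pair",
      unique(v$subject_id[(!is.na(v$sbp) & is.na(v$dbp)) |
                          (!is.na(v$sbp) & !is.na(v$dbp) & v$sbp <= v$dbp)]),
      "sbp requires dbp present and sbp > dbp")

  violations <- if (length(viol) > 0) do.call(rbind, viol) else
    data.frame(rule_id = character(0), subject_id = character(0),
               message = character(0), stringsAsFactors = FALSE)
  structure(list(n_subjects = nrow(s), n_visits = nrow(v),
                 violations = violations),
            class = "pe_validation")
}

#' @export
print.pe_validation <- function(x, ...) {
  cat(sprintf("Cohort validation: %d subjects, %d visits\n",
              x$n_subjects, x$n_visits))
  if (nrow(x$violations) == 0) {
    cat("No violations.\n")
  } else {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    tab <- table(x$violations$rule_id)
    for (r in names(tab)) cat(sprintf("  %-28s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' @export
print.pe_cohort <- function(x, ...) {
  n_pe <- sum(x$subjects$pe)
  cat(sprintf("pe_cohort: %d subjects (%d with preeclampsia, %.1f%%), %d visits\n",
              nrow(x$subjects), n_pe,
              if (nrow(x$subjects)) 100 * n_pe / nrow(x$subjects) else 0,
              nrow(x$visits)))
  invisible(x)
}
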