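# Shared constants and small helpers.

# Category level sets; the first level is the modelling reference
# (largest printed group for each covariate).
.pe_levels <- list(
  region_of_birth = c("Sweden", "Nordic_other", "Europe_other", "Africa",
                      "North_America", "South_America", "Asia", "Oceania",
                      "missing"),
  family_situation = c("with_partner", "single", "other", "missing"),
  smoking_pre = c("none", "lt10", "ge10", "missing"),
  smoking_early = c("none", "lt10", "ge10", "missing"),
  infertility_duration = c("none", "y1_2", "gt2"),
  infertility_treatment = c("none", "ovarian_stimulation", "ivf"),
  blood_group = c("O", "A", "AB", "B", "missing"),
  proteinuria = c("0", "1", "2")
)

# Subject table schema in declared CSV column order.
.subject_schema <- c(
  subject_id = "character",
  maternal_age = "numeric",
  height_cm = "numeric",
  region_of_birth = "category",
  family_situation = "category",
  smoking_pre = "category",
  smoking_early = "category",
  prev_miscarriage = "logical",
  infertility_duration = "category",
  infertility_treatment = "category",
  fam_hist_preeclampsia = "logical",
  fam_hist_hypertension = "logical",
  cardiovascular_disease = "logical",
  endocrine_disease = "logical",
  preexisting_diabetes = "logical",
  thrombosis_history = "logical",
  sle = "logical",
  chronic_hypertension = "logical",
  ibd = "logical",
  chronic_kidney_disease = "logical",
  blood_group = "category",
  aspirin_use = "logical",
  pe = "logical",
  ga_diagnosis_days = "numeric",
  ga_delivery_days = "numeric"
)

.visit_schema <- c(
  subject_id = "character",
  ga_days = "numeric",
  sbp = "numeric",
  dbp = "numeric",
  weight = "numeric",
  hb = "numeric",
  sf_height = "numeric",
  glucose = "numeric",
  proteinuria = "category"
)

.pe_markers <- c("sbp", "dbp", "weight", "hb", "sf_height")

# Day before which a measurement counts for "completed week w":
# the window is ga_days < 7 * (w + 1).
landmark_end_day <- function(landmark_week) 7 * (landmark_week + 1)

#' Derive a reproducible sub-seed from a master seed
#'
#' Stable fan-out of one integer seed into per-stage substreams, so that
#' e.g. changing the landmark list of a pipeline run never perturbs
#' cohort generation. Pure integer arithmetic below 2^31.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed in `[1, 2147483628]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483629
  as.integer(((seed %% 2147483629) * 48271 + h) %% 2147483629 + 1)
}

# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pe <- function(...) stop(sprintf(...), call. = FALSE)
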