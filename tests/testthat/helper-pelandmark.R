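# Shared fixtures and independent oracles, all built in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a mid-sized default cohort reused across test files
small_cohort <- function() {
  cached("small_cohort",
         function() simulate_cohort(generator_config(n_subjects = 3000,
                                                     seed = 42)))
}

# minimal hand-built subject/visit rows for invariant tests
base_subject <- function(subject_id = "S1", pe = FALSE,
                         ga_diagnosis_days = NA_real_,
                         ga_delivery_days = 280, aspirin_use = FALSE, ...) {
  out <- data.frame(
    subject_id = subject_id, maternal_age = 30, height_cm = 166,
    region_of_birth = "Sweden", family_situation = "with_partner",
    smoking_pre = "none", smoking_early = "none", prev_miscarriage = FALSE,
    infertility_duration = "none", infertility_treatment = "none",
    fam_hist_preeclampsia = FALSE, fam_hist_hypertension = FALSE,
    cardiovascular_disease = FALSE, endocrine_disease = FALSE,
    preexisting_diabetes = FALSE, thrombosis_history = FALSE, sle = FALSE,
    chronic_hypertension = FALSE, ibd = FALSE,
    chronic_kidney_disease = FALSE, blood_group = "O",
    aspirin_use = aspirin_use, pe = pe,
    ga_diagnosis_days = ga_diagnosis_days,
    ga_delivery_days = ga_delivery_days, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

base_visit <- function(subject_id = "S1", ga_days = 100, sbp = NA_real_,
                       dbp = NA_real_, weight = NA_real_, hb = NA_real_,
                       sf_height = NA_real_, glucose = NA_real_,
                       proteinuria = NA_character_) {
  data.frame(subject_id = subject_id, ga_days = ga_days, sbp = sbp,
             dbp = dbp, weight = weight, hb = hb, sf_height = sf_height,
             glucose = glucose, proteinuria = proteinuria,
             stringsAsFactors = FALSE)
}

# --- independent oracles --------------------------------------------------

# brute-force normal-equations least squares on the explicitly
# orthogonalized quadratic basis (independent of the package's
# closed-form sufficient-statistics path)
oracle_raw_coefficients <- function(ga_days, residuals) {
  t <- (ga_days - mean(ga_days)) / 7
  p0 <- rep(1, length(t))
  p1 <- t - sum(t * p0) / sum(p0 * p0) * p0
  t2 <- t^2
  p2 <- t2 - sum(t2 * p0) / sum(p0 * p0) * p0 -
    sum(t2 * p1) / sum(p1 * p1) * p1
  B <- cbind(p0, p1, p2)
  cf <- solve(crossprod(B), crossprod(B, residuals))
  c(level = cf[1], trend = cf[2], curvature = cf[3])
}

# AUC by exhaustive enumeration of case-control pairs, ties one half
oracle_auc_paircount <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}
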