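ENDPOINTS <- c("total_cancer", "breast", "colorectal", "lung",
               "total_death", "cancer_death")
SITE_ENDPOINTS <- c("breast", "colorectal", "lung")

#' Solve the first-stage calibration of 25OHD on the genetic score
#'
#' Chooses the per-allele 25OHD effect, intercept and residual SD so that the
#' generated biomarker has population mean `ohd_mean`, total SD `ohd_sd`, and
#' an unweighted allele-count score explaining `target_r2` of its variance.
#'
#' With a common per-allele effect `b` across the panel, the genetic variance
#' of the score model is `b^2 * sum(2 p (1 - p))` (Hardy-Weinberg, no LD), so
#' `b = sqrt(target_r2 * ohd_sd^2 / sum(2 p (1 - p)))`. When the panel already
#' carries per-allele effects, those are honoured and the implied R-squared is
#' reported instead; the residual SD is then `sqrt(ohd_sd^2 - genetic var)`,
#' which must be non-negative.
#'
#' @param snps List of 5 [snp_definition()] objects.
#' @param target_r2 Fraction of 25OHD variance the score should explain,
#'   in `[0, 1)`. Ignored when the panel supplies its own effects.
#' @param ohd_mean,ohd_sd Target population mean and SD of 25OHD (nmol/L).
#' @return A list with `per_allele_effects` (length 5), `intercept` (nmol/L),
#'   `sigma_resid` (nmol/L), `r2` (the calibrated or implied value),
#'   `grs_mean` and `grs_var` (moments of the allele-count score).
#' @export
calibrate_first_stage <- function(snps = default_snp_panel(),
                                  target_r2 = 0.026,
                                  ohd_mean = 67.8, ohd_sd = 26.1) {
  freqs <- panel_counted_freqs(snps)
  eff   <- panel_field(snps, "per_allele_effect")
  if (ohd_sd <= 0) stop("ohd_sd must be positive", call. = FALSE)
  grs_var  <- sum(2 * freqs * (1 - freqs))
  grs_mean <- sum(2 * freqs)

  if (all(is.na(eff))) {
    if (target_r2 < 0 || target_r2 >= 1) {
      stop("target_r2 must lie in [0, 1)", call. = FALSE)
    }
    b   <- sqrt(target_r2 * ohd_sd^2 / grs_var)
    eff <- rep(b, 5L)
    r2  <- target_r2
  } else if (anyNA(eff)) {
    stop("per-allele effects must be all supplied or all NA", call. = FALSE)
  } else {
    r2 <- sum(eff^2 * 2 * freqs * (1 - freqs)) / ohd_sd^2
  }
  gvar <- sum(eff^2 * 2 * freqs * (1 - freqs))
  resid_var <- ohd_sd^2 - gvar
  if (resid_var < 0) {
    stop("per-allele effects imply more genetic variance (",
         format(gvar), ") than ohd_sd^2 (", format(ohd_sd^2),
         "): residual variance would be negative", call. = FALSE)
  }
  list(per_allele_effects = eff,
       intercept   = ohd_mean - sum(eff * 2 * freqs),
       sigma_resid = sqrt(resid_var),
       r2 = r2, grs_mean = grs_mean, grs_var = grs_var)
}

#' Exponential baseline hazard reproducing a target event count
#'
#' Under a constant event rate `lambda` and administrative censoring at
#' `followup` years (no competing events, no covariate effects), the expected
#' fraction of subjects with an event is `1 - exp(-lambda * followup)`.
#' Inverting gives `lambda = -log(1 - target_events / n) / followup`.
#'
#' @param target_events Expected number of events to reproduce.
#' @param n Cohort size.
#' @param followup Follow-up horizon in years.
#' @return Hazard rate per year.
#' @examples
#' calibrate_incidence(3985, 23294, 20)  # ~0.00938 / yr
#' @export
calibrate_incidence <- function(target_events, n, followup) {
  stopifnot(length(target_events) == 1L, length(n) == 1L)
  if (followup <= 0) stop("followup must be positive", call. = FALSE)
  if (target_events <= 0 || target_events >= n) {
    stop("target_events must satisfy 0 < target_events < n", call. = FALSE)
  }
  -log(1 - target_events / n) / followup
}

#' Incidence hazard compensated for competing death censoring
#'
#' When incidence endpoints are censored at an independent exponential death
#' time with rate `death_hazard`, the expected number of *observed* events is
#' `n * lambda / (lambda + mu) * (1 - exp(-(lambda + mu) * followup))`.
#' This solves that identity for `lambda` so that the simulated, death-censored
#' event count matches `target_events` in expectation.
#'
#' @inheritParams calibrate_incidence
#' @param death_hazard Competing death rate per year (`mu` above).
#' @return Cause-specific hazard rate per year.
#' @export
calibrate_incidence_competing <- function(target_events, n, followup,
                                          death_hazard) {
  if (death_hazard < 0) stop("death_hazard must be >= 0", call. = FALSE)
  lam0 <- calibrate_incidence(target_events, n, followup)
  if (death_hazard == 0) return(lam0)
  p <- target_events / n
  expected <- function(l) {
    tot <- l + death_hazard
    l / tot * (1 - exp(-tot * followup)) - p
  }
  # observed fraction is increasing in l; naive lam0 undershoots, so bracket up
  upper <- lam0
  while (expected(upper) < 0) upper <- upper * 2
  stats::uniroot(expected, c(lam0 / 2, upper), tol = 1e-12)$root
}

# cause-specific cancer-death hazard inside a fixed total-death rate:
# expected cancer deaths = n * (lam_cd / lam_td) * (1 - exp(-lam_td * T))
calibrate_cancer_death <- function(target_events, n, followup,
                                   total_death_hazard) {
  p <- target_events / n
  lam <- p * total_death_hazard /
    (1 - exp(-total_death_hazard * followup))
  if (lam > total_death_hazard) {
    stop("cancer-death target exceeds what the total-death rate allows",
         call. = FALSE)
  }
  lam
}

#' Build a synthetic-cohort generator configuration
#'
#' Collects every simulation truth in one object: cohort and biomarker
#' subcohort sizes, the SNP panel and its first-stage calibration, age and BMI
#' distributions, follow-up horizon, per-endpoint exponential baseline
#' hazards, and per-endpoint causal effects of latent 25OHD on the hazard.
#'
#' Defaults emulate a cohort of 23,294 women aged 45+ followed ~20 years, a
#' measured-25OHD subcohort of 1782, 25OHD mean (SD) 67.8 (26.1) nmol/L with
#' the 5-SNP score explaining 2.6% of its variance, and endpoint counts of
#' 3985 total cancers (1560 breast, 329 colorectal, 330 lung), 2973 total
#' deaths and 770 cancer deaths. Baseline hazards are calibrated in closed
#' form; incidence and cancer-death hazards are additionally compensated for
#' competing death censoring so that *observed* event counts hit the targets
#' in expectation (see [calibrate_incidence_competing()]).
#'
#' @param n_cohort,n_subcohort Cohort size and number of subjects with a
#'   measured 25OHD value (`n_subcohort <= n_cohort`).
#' @param snps SNP panel, a list of 5 [snp_definition()].
#' @param ohd_mean,ohd_sd Population mean and SD of 25OHD (nmol/L).
#' @param target_r2 Fraction of 25OHD variance explained by the score.
#' @param age_mean,age_sd,age_min Age distribution (years), Normal truncated
#'   below at `age_min`.
#' @param bmi_mean,bmi_sd,bmi_min BMI distribution (kg/m^2), truncated below.
#' @param followup_years Administrative censoring horizon (years).
#' @param target_events Named vector of expected event counts per endpoint
#'   (`total_cancer`, `breast`, `colorectal`, `lung`, `total_death`,
#'   `cancer_death`).
#' @param causal_log_hr_per_nmol Named per-endpoint log hazard ratio per
#'   1 nmol/L latent 25OHD (0 under the null). Site-specific cancers inherit
#'   the `total_cancer` value because they are realised as a type label on the
#'   first cancer event.
#' @param age_log_hr Named per-endpoint log hazard ratio per year of age
#'   (centered); default 0 so the closed-form calibration is exact.
#' @param noise_sd SD of Gaussian imputation noise added to dosages of
#'   imputed SNPs (dosage units).
#' @param reference_n Cohort size at which `target_events` are expressed;
#'   hazards preserve the implied cumulative incidence when `n_cohort`
#'   differs (e.g. scaled-down replicates).
#' @param seed Integer seed making every draw reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cohort = 23294L,
                             n_subcohort = 1782L,
                             snps = default_snp_panel(),
                             ohd_mean = 67.8, ohd_sd = 26.1,
                             target_r2 = 0.026,
                             age_mean = 54.7, age_sd = 7.1, age_min = 45,
                             bmi_mean = 25.9, bmi_sd = 5.0, bmi_min = 15,
                             followup_years = 20,
                             target_events = c(total_cancer = 3985,
                                               breast = 1560,
                                               colorectal = 329,
                                               lung = 330,
                                               total_death = 2973,
                                               cancer_death = 770),
                             causal_log_hr_per_nmol = c(total_cancer = 0,
                                                        breast = 0,
                                                        colorectal = 0,
                                                        lung = 0,
                                                        total_death = 0,
                                                        cancer_death = 0),
                             age_log_hr = c(total_cancer = 0, breast = 0,
                                            colorectal = 0, lung = 0,
                                            total_death = 0, cancer_death = 0),
                             noise_sd = 0.05,
                             reference_n = 23294L,
                             seed = 1L) {
  n_cohort <- as.integer(n_cohort); n_subcohort <- as.integer(n_subcohort)
  if (n_cohort < 1L) stop("n_cohort must be >= 1", call. = FALSE)
  if (n_subcohort > n_cohort) {
    stop("n_subcohort must not exceed n_cohort", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  target_events <- target_events[ENDPOINTS]
  if (anyNA(target_events)) {
    stop("target_events must name all endpoints: ",
         paste(ENDPOINTS, collapse = ", "), call. = FALSE)
  }
  fill <- function(x) {
    out <- stats::setNames(numeric(length(ENDPOINTS)), ENDPOINTS)
    out[names(x)] <- x
    out
  }
  causal_log_hr_per_nmol <- fill(causal_log_hr_per_nmol)
  age_log_hr <- fill(age_log_hr)

  first_stage <- calibrate_first_stage(snps, target_r2, ohd_mean, ohd_sd)

  # event targets are expectations for a cohort of size reference_n; hazards
  # preserve the implied cumulative incidence whatever n_cohort is simulated
  lam_td <- calibrate_incidence(target_events["total_death"], reference_n,
                                followup_years)
  lam_cd <- calibrate_cancer_death(target_events["cancer_death"], reference_n,
                                   followup_years, lam_td)
  lam_tc <- calibrate_incidence_competing(target_events["total_cancer"],
                                          reference_n, followup_years, lam_td)
  site_probs <- target_events[SITE_ENDPOINTS] /
    target_events["total_cancer"]
  if (sum(site_probs) > 1) {
    stop("site-specific cancer targets exceed the total-cancer target",
         call. = FALSE)
  }
  baseline_hazards <- c(
    total_cancer = unname(lam_tc),
    stats::setNames(unname(site_probs * lam_tc), SITE_ENDPOINTS),
    total_death  = unname(lam_td),
    cancer_death = unname(lam_cd)
  )[ENDPOINTS]

  structure(
    list(n_cohort = n_cohort, n_subcohort = n_subcohort, snps = snps,
         ohd_mean = ohd_mean, ohd_sd = ohd_sd, target_r2 = target_r2,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_min = bmi_min,
         followup_years = followup_years,
         target_events = target_events,
         baseline_hazards = baseline_hazards,
         site_probs = site_probs,
         causal_log_hr_per_nmol = causal_log_hr_per_nmol,
         age_log_hr = age_log_hr,
         noise_sd = noise_sd,
         reference_n = as.integer(reference_n),
         first_stage = first_stage,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  cohort n = %d, 25OHD subcohort n = %d, follow-up %.0f y\n",
              x$n_cohort, x$n_subcohort, x$followup_years))
  cat(sprintf("  25OHD mean (SD) = %.1f (%.1f) nmol/L, score R2 target %.3f\n",
              x$ohd_mean, x$ohd_sd, x$target_r2))
  cat(sprintf("  per-allele effect = %.3f nmol/L, residual SD = %.2f\n",
              x$first_stage$per_allele_effects[1], x$first_stage$sigma_resid))
  cat("  baseline hazards (/yr):\n")
  for (e in ENDPOINTS) {
    cat(sprintf("    %-12s %.6f  (target %g events)\n",
                e, x$baseline_hazards[[e]], x$target_events[[e]]))
  }
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
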