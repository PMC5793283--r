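#' Draw Hardy-Weinberg genotypes for a SNP panel
#'
#' Each SNP column is an independent Binomial(2, f) count of the higher-25OHD
#' allele, where f is that allele's frequency (`maf` when the counted allele
#' is minor, `1 - maf` otherwise) — random mating, no linkage disequilibrium
#' between panel members. The five default variants sit in three genes; pairs
#' sharing a gene are still simulated independently because the downstream
#' score is a plain sum.
#'
#' @param n Number of subjects (>= 1).
#' @param snps List of 5 [snp_definition()] objects.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @return Integer matrix `n x 5` with entries in `{0, 1, 2}`; columns named
#'   by rsid.
#' @export
draw_genotypes <- function(n, snps = default_snp_panel(), seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  freqs <- panel_counted_freqs(snps)  # validates the panel, incl. maf range
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n))
  counts <- matrix(as.integer(counts), nrow = n, ncol = length(freqs),
                   dimnames = list(NULL, panel_rsids(snps)))
  counts
}

#' Add imputation noise to hard allele counts
#'
#' Emulates imputed dosages: for SNPs flagged `imputed`, the dosage is the
#' true allele count plus Gaussian noise, clamped to `[0, 2]`; hard-called
#' SNPs keep their exact integer count.
#'
#' @param allele_counts Integer matrix from [draw_genotypes()].
#' @param snps The SNP panel (supplies the `imputed` flags).
#' @param noise_sd Noise SD in dosage units (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric dosage matrix, same shape, entries in `[0, 2]`.
#' @export
add_imputation_noise <- function(allele_counts, snps = default_snp_panel(),
                                 noise_sd = 0.05, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  imputed <- panel_field(snps, "imputed")
  stopifnot(ncol(allele_counts) == length(imputed))
  dos <- allele_counts * 1.0
  if (noise_sd > 0 && any(imputed)) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(dos)
    for (j in which(imputed)) {
      dos[, j] <- pmin(pmax(dos[, j] + stats::rnorm(n, 0, noise_sd), 0), 2)
    }
  }
  dos
}

#' Draw circulating 25OHD from the calibrated first-stage model
#'
#' `ohd_i = intercept + sum_s effect_s * count_is + N(0, sigma_resid)`, with
#' the intercept and residual SD from [calibrate_first_stage()] so the
#' population mean and total SD hit the configured targets. Negative draws
#' are clamped at 0; the clamping fraction is attached as attribute
#' `"truncation_fraction"` (negligible at the default calibration, where 0 is
#' 2.6 SDs below the mean).
#'
#' @param allele_counts Integer matrix from [draw_genotypes()].
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of 25OHD values (nmol/L) with the truncation
#'   fraction attribute.
#' @export
draw_25ohd <- function(allele_counts, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  fs <- config$first_stage
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(allele_counts)
  mu <- fs$intercept + drop(allele_counts %*% fs$per_allele_effects)
  ohd <- mu + stats::rnorm(n, 0, fs$sigma_resid)
  trunc_frac <- mean(ohd < 0)
  ohd[ohd < 0] <- 0
  attr(ohd, "truncation_fraction") <- trunc_frac
  ohd
}

# truncated-normal draw by inverse CDF on the upper tail (vectorised)
rnorm_trunc_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Attach exponential event times for every endpoint
#'
#' Each subject's hazard for endpoint *e* is
#' `lambda_e * exp(age_log_hr_e * (age - age_mean) +
#'   causal_log_hr_per_nmol_e * (ohd_latent - ohd_mean))`,
#' with the event time exponential at that rate and administrative censoring
#' at `followup_years`. Centering latent 25OHD at its population mean leaves
#' every hazard *ratio* unchanged and keeps `lambda_e` interpretable as the
#' rate for an average subject. The latent (pre-truncation, fully observed)
#' 25OHD drives the causal mechanism even for subjects whose measured value
#' is missing.
#'
#' Structure across endpoints: total death is the first of a cancer-death and
#' an other-death exponential, so `cancer_death` implies `total_death` at the
#' same time. The first incident cancer gets a site label (breast /
#' colorectal / lung / other) drawn with the configured split, so any site
#' event coincides with the `total_cancer` event. Incidence endpoints are
#' additionally censored at the death time (cause-specific convention, no
#' formal competing-risks model).
#'
#' @param cohort Data frame with at least `age` and `ohd_latent` columns.
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return The cohort with `event_<endpoint>` and `time_<endpoint>` columns
#'   appended for the six endpoints.
#' @export
draw_survival <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"),
            all(c("age", "ohd_latent") %in% names(cohort)))
  if (any(config$baseline_hazards < 0)) {
    stop("baseline hazards must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n  <- nrow(cohort)
  fu <- config$followup_years
  lp <- function(endpoint) {
    config$age_log_hr[[endpoint]] * (cohort$age - config$age_mean) +
      config$causal_log_hr_per_nmol[[endpoint]] *
        (cohort$ohd_latent - config$ohd_mean)
  }
  draw_time <- function(rate) {
    # rate 0 -> no event within any horizon
    t <- rep(Inf, n)
    pos <- rate > 0
    if (any(pos)) t[pos] <- stats::rexp(sum(pos), rate[pos])
    t
  }

  # mortality: total death = min(cancer death, other-cause death)
  lam_cd <- config$baseline_hazards[["cancer_death"]]
  lam_td <- config$baseline_hazards[["total_death"]]
  if (lam_cd > lam_td) stop("cancer_death hazard exceeds total_death hazard",
                            call. = FALSE)
  t_cd    <- draw_time(lam_cd * exp(lp("cancer_death")))
  t_other <- draw_time((lam_td - lam_cd) * exp(lp("total_death")))
  t_death <- pmin(t_cd, t_other)

  # incidence: one first-cancer time, then a site label
  t_tc <- draw_time(config$baseline_hazards[["total_cancer"]] *
                      exp(lp("total_cancer")))
  site_p <- c(config$site_probs, other = 1 - sum(config$site_probs))
  site <- sample(names(site_p), n, replace = TRUE, prob = site_p)

  out <- cohort
  # observed death endpoints: administrative censoring only
  death_cens <- pmin(t_death, fu)
  out$event_total_death <- as.integer(t_death <= fu)
  out$time_total_death  <- death_cens
  out$event_cancer_death <- as.integer(t_cd <= fu & t_cd <= t_other)
  out$time_cancer_death  <- death_cens

  # incidence endpoints: censored at death and administratively
  inc_cens <- pmin(t_death, fu)
  tc_event <- t_tc <= inc_cens
  out$event_total_cancer <- as.integer(tc_event)
  out$time_total_cancer  <- pmin(t_tc, inc_cens)
  for (s in SITE_ENDPOINTS) {
    ev <- tc_event & site == s
    out[[paste0("event_", s)]] <- as.integer(ev)
    out[[paste0("time_", s)]]  <- ifelse(ev, pmin(t_tc, inc_cens), inc_cens)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generator under one seed: genotypes, imputed dosages,
#' latent and measured 25OHD, age and BMI, and all six survival endpoints.
#' Identical `config` (including its seed) gives a bit-identical table.
#'
#' @param config A [generator_config()]; its `seed` drives all randomness.
#' @return A `data.frame` (class `cohort_table`) with one row per subject:
#'   `id`, five allele-count columns (rsid names), five dosage columns
#'   (`<rsid>_ds`), `age`, `bmi`, `ohd_latent`, `ohd` (NA outside the
#'   measured subcohort), `in_subcohort`, and `event_*` / `time_*` per
#'   endpoint. The 25OHD truncation fraction is attached as an attribute.
#' @examples
#' cfg <- generator_config(n_cohort = 500, n_subcohort = 100, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' mean(cohort$ohd, na.rm = TRUE)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_cohort

  counts <- draw_genotypes(n, config$snps)
  dosages <- add_imputation_noise(counts, config$snps, config$noise_sd)
  ohd_latent <- draw_25ohd(counts, config)
  age <- rnorm_trunc_lower(n, config$age_mean, config$age_sd, config$age_min)
  bmi <- rnorm_trunc_lower(n, config$bmi_mean, config$bmi_sd, config$bmi_min)

  cohort <- data.frame(id = sprintf("S%06d", seq_len(n)),
                       counts, age = age, bmi = bmi,
                       ohd_latent = as.numeric(ohd_latent),
                       check.names = FALSE,
                       stringsAsFactors = FALSE)
  ds <- as.data.frame(dosages)
  names(ds) <- paste0(colnames(counts), "_ds")
  cohort <- cbind(cohort, ds)

  sub <- sample.int(n, config$n_subcohort)
  cohort$in_subcohort <- FALSE
  cohort$in_subcohort[sub] <- TRUE
  cohort$ohd <- ifelse(cohort$in_subcohort, cohort$ohd_latent, NA_real_)

  cohort <- draw_survival(cohort, config)
  attr(cohort, "truncation_fraction") <-
    attr(ohd_latent, "truncation_fraction")
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
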