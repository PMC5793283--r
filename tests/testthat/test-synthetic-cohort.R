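test_that("genotype draws respect Hardy-Weinberg at every configured frequency", {
  n <- 1e5
  g <- draw_genotypes(n, default_snp_panel(), seed = 101)
  freqs <- ifelse(vapply(default_snp_panel(), `[[`, logical(1),
                         "risk_allele_is_minor"),
                  vapply(default_snp_panel(), `[[`, numeric(1), "maf"),
                  1 - vapply(default_snp_panel(), `[[`, numeric(1), "maf"))
  for (j in seq_len(ncol(g))) {
    p <- freqs[j]
    obs <- tabulate(g[, j] + 1L, nbins = 3L)
    expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi <- sum((obs - expected)^2 / expected)
    expect_gt(stats::pchisq(chi, df = 2, lower.tail = FALSE), 0.001)
  }
  expect_true(all(g %in% 0:2))
})

test_that("allele-count moments match binomial expectations", {
  # a panel where the counted allele IS the minor allele at maf 0.25
  panel <- default_snp_panel()
  panel <- lapply(panel, function(s) {
    snp_definition(s$rsid, s$gene, 0.25, imputed = s$imputed,
                   risk_allele_is_minor = TRUE)
  })
  n <- 1e5
  g <- draw_genotypes(n, panel, seed = 5)
  se <- sqrt(2 * 0.25 * 0.75 / n)
  expect_lt(abs(mean(g[, 1]) - 0.5), 3 * se)

  # heterozygote fraction at maf 0.44: 2 * 0.44 * 0.56
  panel44 <- lapply(panel, function(s) {
    snp_definition(s$rsid, s$gene, 0.44, imputed = s$imputed,
                   risk_allele_is_minor = TRUE)
  })
  g44 <- draw_genotypes(n, panel44, seed = 6)
  het <- mean(g44[, 1] == 1L)
  p_het <- 2 * 0.44 * 0.56
  expect_lt(abs(het - p_het), 3 * sqrt(p_het * (1 - p_het) / n))
})

test_that("degenerate allele frequencies are handled, invalid ones rejected", {
  panel <- lapply(default_snp_panel(), function(s) {
    snp_definition(s$rsid, s$gene, 1e-6, imputed = s$imputed,
                   risk_allele_is_minor = TRUE)
  })
  g <- draw_genotypes(100, panel, seed = 2)
  expect_true(all(g == 0L))

  expect_error(snp_definition("rs1", "GC", 0.6), "0.5")
  expect_error(snp_definition("rs1", "GC", 0), "0.5")
  expect_error(draw_genotypes(0, default_snp_panel()), "positive")
})

test_that("imputation noise is clamped, identity at zero, folded-normal in size", {
  panel <- default_snp_panel()
  g <- draw_genotypes(2e4, panel, seed = 31)

  expect_equal(add_imputation_noise(g, panel, noise_sd = 0), g * 1.0,
               ignore_attr = TRUE)
  expect_error(add_imputation_noise(g, panel, noise_sd = -1), ">= 0")

  # hard-called SNPs never change; imputed ones stay inside [0, 2]
  d <- add_imputation_noise(g, panel, noise_sd = 5, seed = 7)
  imputed <- vapply(panel, `[[`, logical(1), "imputed")
  expect_equal(d[, !imputed], g[, !imputed] * 1.0)
  expect_true(all(d >= 0 & d <= 2))

  # mean |dosage - count| for interior genotypes = folded-normal mean
  sd0 <- 0.1
  d2 <- add_imputation_noise(g, panel, noise_sd = sd0, seed = 8)
  j <- which(imputed)[1]
  het <- g[, j] == 1L  # clamping unreachable at 10 SDs from both bounds
  dev <- abs(d2[het, j] - 1)
  fold_mean <- sd0 * sqrt(2 / pi)
  fold_sd <- sd0 * sqrt(1 - 2 / pi)
  expect_lt(abs(mean(dev) - fold_mean), 3 * fold_sd / sqrt(sum(het)))
})

test_that("25OHD calibration hits its mean, SD and variance-identity targets", {
  cfg <- generator_config(seed = 1)
  fs <- cfg$first_stage

  # beta^2 * Var(GRS) = r2 * sd^2 (exact algebra of the calibration)
  expect_equal(fs$per_allele_effects[1]^2 * fs$grs_var,
               0.026 * 26.1^2, tolerance = 1e-12)
  expect_equal(fs$per_allele_effects, rep(2.8547, 5), tolerance = 1e-3)

  n <- 1e5
  g <- draw_genotypes(n, cfg$snps, seed = 21)
  ohd <- draw_25ohd(g, cfg, seed = 22)
  expect_lt(abs(mean(ohd) - 67.8), 3 * 26.1 / sqrt(n))
  expect_lt(abs(sd(ohd) - 26.1), 3 * 26.1 / sqrt(2 * n))
  expect_lt(attr(ohd, "truncation_fraction"), 0.01)

  # null panel: no genetic signal, R2 ~ 0
  null_panel <- lapply(cfg$snps, function(s) {
    snp_definition(s$rsid, s$gene, s$maf, per_allele_effect = 0,
                   imputed = s$imputed)
  })
  cfg0 <- generator_config(snps = null_panel, seed = 3)
  ohd0 <- draw_25ohd(g, cfg0, seed = 23)
  r2 <- summary(lm(ohd0 ~ rowSums(g)))$r.squared
  expect_lt(r2, 5 / n * 3 + 1e-4)
  expect_lt(abs(mean(ohd0) - 67.8), 3 * 26.1 / sqrt(n))
})

test_that("inconsistent first-stage calibration is rejected", {
  big_effect <- lapply(default_snp_panel(), function(s) {
    snp_definition(s$rsid, s$gene, s$maf, per_allele_effect = 30,
                   imputed = s$imputed)
  })
  expect_error(calibrate_first_stage(big_effect, ohd_sd = 26.1),
               "residual variance")
})

test_that("incidence calibration matches the exponential closed form", {
  expect_equal(calibrate_incidence(3985, 23294, 20), 0.0093812,
               tolerance = 1e-4)
  expect_equal(calibrate_incidence(770, 23294, 20),
               -log(1 - 770 / 23294) / 20, tolerance = 1e-12)
  expect_equal(calibrate_incidence(770, 23294, 20), 0.0016808,
               tolerance = 1e-4)
  # rare-event limit: lambda ~ e / (n * followup)
  expect_equal(calibrate_incidence(5, 1e6, 10), 5 / (1e6 * 10),
               tolerance = 1e-3)
  expect_error(calibrate_incidence(100, 100, 20), "target_events")
  expect_error(calibrate_incidence(0, 100, 20), "target_events")

  # competing compensation: plugging the solved rate back into the
  # death-censored expectation recovers the target exactly
  mu <- calibrate_incidence(2973, 23294, 20)
  lam <- calibrate_incidence_competing(3985, 23294, 20, mu)
  expect_gt(lam, calibrate_incidence(3985, 23294, 20))
  expected <- 23294 * lam / (lam + mu) * (1 - exp(-(lam + mu) * 20))
  expect_equal(expected, 3985, tolerance = 1e-6)
  expect_equal(calibrate_incidence_competing(3985, 23294, 20, 0),
               calibrate_incidence(3985, 23294, 20))
})

test_that("zero hazards produce no events and full follow-up", {
  cfg <- small_config(seed = 4, n = 300, n_sub = 100)
  cfg$baseline_hazards[] <- 0
  cohort <- data.frame(age = rnorm(300, 54.7, 7.1),
                       ohd_latent = rnorm(300, 67.8, 26.1))
  out <- draw_survival(cohort, cfg, seed = 9)
  for (e in c("total_cancer", "breast", "colorectal", "lung",
              "total_death", "cancer_death")) {
    expect_identical(sum(out[[paste0("event_", e)]]), 0L)
    expect_true(all(out[[paste0("time_", e)]] == cfg$followup_years))
  }
})

test_that("a 20 nmol/L 25OHD difference yields the configured hazard ratio", {
  causal <- log(1.30) / 20
  cfg <- generator_config(
    n_cohort = 20000, n_subcohort = 1000,
    causal_log_hr_per_nmol = c(total_death = causal, cancer_death = causal),
    seed = 77)
  cohort <- simulate_cohort(cfg)
  # regress on latent 25OHD in 20 nmol/L units: coef should recover log(1.3)
  f <- fit_cox(cohort$time_total_death, cohort$event_total_death,
               cohort$ohd_latent / 20)
  expect_lt(abs(f$coef - log(1.30)), 3 * f$coef_se)
})

test_that("cohort structure invariants hold and the draw is deterministic", {
  cfg <- small_config(seed = 12)
  cohort <- simulate_cohort(cfg)

  expect_identical(nrow(cohort), cfg$n_cohort)
  expect_identical(sum(cohort$in_subcohort), cfg$n_subcohort)
  expect_true(all(is.na(cohort$ohd) != cohort$in_subcohort))
  expect_true(all(cohort$age >= cfg$age_min))
  expect_true(all(cohort$bmi >= cfg$bmi_min))

  fu <- cfg$followup_years
  for (e in c("total_cancer", "breast", "colorectal", "lung",
              "total_death", "cancer_death")) {
    expect_true(all(cohort[[paste0("time_", e)]] <= fu + 1e-12))
    expect_true(all(cohort[[paste0("time_", e)]] > 0))
  }
  # site cancers imply a total-cancer event at the same time
  for (s in c("breast", "colorectal", "lung")) {
    ev <- cohort[[paste0("event_", s)]] == 1L
    expect_true(all(cohort$event_total_cancer[ev] == 1L))
    expect_equal(cohort$time_total_cancer[ev],
                 cohort[[paste0("time_", s)]][ev])
  }
  # cancer death implies total death at the same time
  cd <- cohort$event_cancer_death == 1L
  expect_true(all(cohort$event_total_death[cd] == 1L))
  expect_equal(cohort$time_total_death[cd], cohort$time_cancer_death[cd])

  # full determinism: identical config => bit-identical table
  expect_identical(simulate_cohort(cfg), simulate_cohort(small_config(seed = 12)))
})
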