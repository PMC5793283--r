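#' Trend test of 25OHD across score quintiles
#'
#' OLS regression of the biomarker on the quintile index (1-5), returning
#' the Wald p-value for a zero slope. Requires at least two non-empty
#' quintiles.
#'
#' @param ohd Numeric 25OHD values (missing allowed, dropped listwise).
#' @param quintile Integer quintile labels from [assign_quintiles()].
#' @return List with `slope`, `se`, `p`, `n`.
#' @export
trend_test_across_quintiles <- function(ohd, quintile) {
  keep <- !(is.na(ohd) | is.na(quintile))
  ohd <- ohd[keep]; quintile <- as.numeric(quintile[keep])
  if (length(unique(quintile)) < 2L) {
    stop("need at least two non-empty quintiles for a trend test",
         call. = FALSE)
  }
  fit <- stats::lm(ohd ~ quintile)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["quintile", "Estimate"]),
       se = unname(sm["quintile", "Std. Error"]),
       p = unname(sm["quintile", "Pr(>|t|)"]),
       n = length(ohd))
}

# one endpoint's rows of the report table: continuous + category fits,
# rates per 1000 person-years by category
endpoint_report <- function(cohort, grs, endpoint, adjust_bmi = FALSE) {
  times <- cohort[[paste0("time_", endpoint)]]
  events <- cohort[[paste0("event_", endpoint)]]
  covs <- data.frame(age = cohort$age)
  if (adjust_bmi) covs$bmi <- cohort$bmi

  fit_cont <- fit_cox(times, events, grs$score, covs)
  fit_cat  <- fit_cox(times, events, grs$category, covs)

  cat_rows <- lapply(levels(grs$category), function(lv) {
    in_cat <- grs$category == lv
    data.frame(group = lv,
               cases = sum(events[in_cat]),
               n = sum(in_cat),
               person_years = sum(times[in_cat]))
  })
  cat_rows <- do.call(rbind, cat_rows)
  rates <- rate_table(cat_rows$group, cat_rows$cases, cat_rows$n,
                      cat_rows$person_years)

  # align category coefficients with levels (a sparse cohort may drop one)
  others <- levels(grs$category)[-1]
  pull <- function(values, default) {
    out <- stats::setNames(rep(default, length(others)), others)
    hit <- intersect(fit_cat$term, others)
    out[hit] <- values[match(hit, fit_cat$term)]
    out
  }
  rows <- data.frame(
    endpoint = endpoint,
    exposure = c("continuous",
                 paste0("category ", levels(grs$category))),
    cases = c(sum(events), rates$cases),
    n = c(nrow(cohort), rates$n),
    rate_per_1000 = c(NA_real_, rates$rate_per_1000),
    coef = c(fit_cont$coef, 0, pull(fit_cat$coef, NA_real_)),
    se = c(fit_cont$coef_se, NA, pull(fit_cat$coef_se, NA_real_)),
    hr = c(fit_cont$hr, 1, pull(fit_cat$hr, NA_real_)),
    lo = c(fit_cont$ci95[, "lo"], NA, pull(fit_cat$ci95[, "lo"], NA_real_)),
    hi = c(fit_cont$ci95[, "hi"], NA, pull(fit_cat$ci95[, "hi"], NA_real_)),
    p = c(fit_cont$p, NA, pull(fit_cat$p, NA_real_))
  )
  list(rows = rows, fit_continuous = fit_cont, fit_categorical = fit_cat)
}

#' Run the full simulate - score - associate - MR pipeline
#'
#' Orchestrates one reproducible analysis of a (synthetic or supplied)
#' cohort:
#' \enumerate{
#'   \item score construction (dosages rounded to hard calls, score,
#'     categories, no-GC variant, quintiles);
#'   \item first-stage linear fit of measured 25OHD on the score (and on the
#'     no-GC score) in the biomarker subcohort;
#'   \item age-adjusted Cox models per endpoint: continuous score, score
#'     categories, and per-SNP allele counts;
#'   \item quintile mean-25OHD table with a trend test;
#'   \item Wald-ratio IV estimates per endpoint at the configured 25OHD
#'     scale for both score variants, with delta-method SEs and
#'     weak-instrument flags.
#' }
#'
#' When `out_dir` is given, tab-delimited tables, a full-precision JSON
#' mirror and a run manifest (config snapshot, seed, content digests,
#' row/event counts, warnings) are written; reruns with an identical config
#' produce byte-identical files.
#'
#' @param config A [generator_config()]; its seed drives all randomness.
#' @param cohort Optional pre-built cohort table (e.g. read from external
#'   files); defaults to `simulate_cohort(config)`.
#' @param scale 25OHD increment for IV estimates (nmol/L, default 20).
#' @param adjust_bmi Also adjust Cox models for BMI (default FALSE, matching
#'   the primary age-adjusted analysis).
#' @param out_dir Optional output directory.
#' @return An object of class `vitdmr_report`: list with `table2`
#'   (endpoint x exposure association rows), `per_snp`, `quintiles` (+
#'   trend test), `first_stage`, `first_stage_no_gc`, `iv` (per endpoint x
#'   score variant), `manifest`, and the underlying cohort and score table.
#' @export
run_full_analysis <- function(config, cohort = NULL, scale = 20,
                              adjust_bmi = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  if (is.null(cohort)) cohort <- simulate_cohort(config)
  trunc_frac <- attr(cohort, "truncation_fraction")
  if (!is.null(trunc_frac) && trunc_frac > 0.01) {
    note("25OHD truncation fraction %.3f exceeds 1%%", trunc_frac)
  }

  rsids <- panel_rsids(config$snps)
  dosage_cols <- paste0(rsids, "_ds")
  geno <- if (all(dosage_cols %in% names(cohort))) {
    m <- as.matrix(cohort[, dosage_cols]); colnames(m) <- rsids; m
  } else {
    as.matrix(cohort[, rsids])
  }
  grs <- grs_table(geno, config$snps, id = cohort$id)

  # first stage in the measured-25OHD subcohort
  sub <- !is.na(cohort$ohd)
  first_stage <- fit_linear(cohort$ohd[sub], grs$score[sub])
  first_stage_no_gc <- fit_linear(cohort$ohd[sub], grs$score_no_gc[sub])
  if (first_stage$f_stat < 10) {
    note("first-stage F = %.1f < 10 (weak instrument)", first_stage$f_stat)
  }

  hard_counts <- geno
  for (j in seq_len(ncol(hard_counts))) {
    hard_counts[, j] <- round_dosage(hard_counts[, j])
  }

  table2 <- list(); iv_rows <- list(); per_snp <- list()
  fits_cont <- list()
  for (e in ENDPOINTS) {
    rep_e <- endpoint_report(cohort, grs, e, adjust_bmi)
    table2[[e]] <- rep_e$rows
    fits_cont[[e]] <- rep_e$fit_continuous
    if (!rep_e$fit_continuous$converged) {
      note("continuous Cox fit for %s flagged non-converged", e)
    }

    times <- cohort[[paste0("time_", e)]]
    events <- cohort[[paste0("event_", e)]]
    covs <- data.frame(age = cohort$age)
    if (adjust_bmi) covs$bmi <- cohort$bmi
    for (rs in rsids) {
      f <- fit_cox(times, events, hard_counts[, rs], covs)
      per_snp[[paste(e, rs)]] <- data.frame(
        endpoint = e, rsid = rs, coef = f$coef, se = f$coef_se,
        hr = f$hr, lo = f$ci95[, "lo"], hi = f$ci95[, "hi"], p = f$p,
        cases = f$n_events, n = f$n)
    }

    for (variant in c("grs", "grs_no_gc")) {
      fs <- if (variant == "grs") first_stage else first_stage_no_gc
      fc <- if (variant == "grs") {
        rep_e$fit_continuous
      } else {
        fit_cox(times, events, grs$score_no_gc, covs)
      }
      iv <- withCallingHandlers(
        wald_iv(fc$coef, fc$coef_se, fs$slope, fs$slope_se,
                scale = scale, f_stat = fs$f_stat),
        warning = function(w) {
          note("%s/%s: %s", e, variant, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      iv_rows[[paste(e, variant)]] <- data.frame(
        endpoint = e, score = variant, method = iv$method,
        scale = iv$scale, beta = iv$beta_iv, se = iv$se_iv,
        estimate = iv$or_, lo = iv$ci95[["lo"]], hi = iv$ci95[["hi"]],
        p = iv$p, weak_instrument = iv$weak_instrument)
    }
  }
  table2 <- do.call(rbind, c(table2, make.row.names = FALSE))
  per_snp <- do.call(rbind, c(per_snp, make.row.names = FALSE))
  iv_tab <- do.call(rbind, c(iv_rows, make.row.names = FALSE))

  q_ohd <- tapply(cohort$ohd[sub], grs$quintile[sub], mean)
  q_sd  <- tapply(cohort$ohd[sub], grs$quintile[sub], stats::sd)
  q_n   <- tapply(cohort$ohd[sub], grs$quintile[sub], length)
  quintiles <- data.frame(quintile = as.integer(names(q_ohd)),
                          n = as.integer(q_n),
                          ohd_mean = as.numeric(q_ohd),
                          ohd_sd = as.numeric(q_sd))
  trend <- trend_test_across_quintiles(cohort$ohd[sub], grs$quintile[sub])

  manifest <- list(
    package_version = as.character(utils::packageVersion("vitdmr")),
    seed = config$seed,
    n_cohort = config$n_cohort,
    n_subcohort_measured = sum(sub),
    truncation_fraction = trunc_frac,
    events = stats::setNames(
      lapply(ENDPOINTS, function(e) sum(cohort[[paste0("event_", e)]])),
      ENDPOINTS),
    warnings = warnings_log
  )

  report <- structure(list(
    table2 = table2, per_snp = per_snp,
    quintiles = quintiles, trend = trend,
    first_stage = first_stage, first_stage_no_gc = first_stage_no_gc,
    iv = iv_tab,
    fits_continuous = fits_cont,
    cohort = cohort, grs = grs,
    config = config, manifest = manifest
  ), class = "vitdmr_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' Tab-delimited tables (association rows with display rounding to 2
#' decimals for rates/HRs, full precision elsewhere), a JSON mirror at full
#' precision, and `manifest.json` listing every output with its md5 digest.
#'
#' @param report A `vitdmr_report` from [run_full_analysis()].
#' @param out_dir Directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)

  t2 <- report$table2
  for (col in c("rate_per_1000", "hr", "lo", "hi")) {
    t2[[col]] <- round(t2[[col]], 2)
  }
  wt <- function(x, f) {
    utils::write.table(x, fp(f), sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
    f
  }
  files <- c(
    wt(t2, "association_table.tsv"),
    wt(report$per_snp, "per_snp_table.tsv"),
    wt(cbind(report$quintiles,
             trend_p = c(report$trend$p, rep(NA, nrow(report$quintiles) - 1))),
       "quintile_table.tsv"),
    wt(report$iv, "iv_table.tsv"),
    wt(report$grs, "grs_table.tsv")
  )
  json <- list(
    first_stage = unclass(report$first_stage),
    first_stage_no_gc = unclass(report$first_stage_no_gc),
    association = report$table2,
    per_snp = report$per_snp,
    quintiles = report$quintiles,
    trend = report$trend,
    iv = report$iv
  )
  jsonlite::write_json(json, fp("results.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  files <- c(files, "results.json")

  manifest <- report$manifest
  manifest$files <- lapply(stats::setNames(files, files), function(f) {
    unname(tools::md5sum(fp(f)))
  })
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' @export
print.vitdmr_report <- function(x, ...) {
  cat("<vitdmr_report>\n")
  cat(sprintf("  cohort n = %d, measured 25OHD n = %d\n",
              nrow(x$cohort), x$first_stage$n))
  cat(sprintf("  first stage: slope %.3f nmol/L per score unit, R2 %.4f, F %.1f\n",
              x$first_stage$slope, x$first_stage$r2, x$first_stage$f_stat))
  cat(sprintf("  trend across quintiles: p = %.3g\n", x$trend$p))
  cat("  IV estimates (delta method):\n")
  iv <- x$iv[x$iv$score == "grs", ]
  for (i in seq_len(nrow(iv))) {
    cat(sprintf("    %-12s ratio %.2f (%.2f-%.2f) per %g nmol/L, p = %.2g\n",
                iv$endpoint[i], iv$estimate[i], iv$lo[i], iv$hi[i],
                iv$scale[i], iv$p[i]))
  }
  if (length(x$manifest$warnings)) {
    cat("  warnings:\n")
    for (w in x$manifest$warnings) cat("    -", w, "\n")
  }
  invisible(x)
}
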