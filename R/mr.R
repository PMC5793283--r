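Z975 <- 1.959964

#' Wald-ratio instrumental-variable estimate with delta-method SE
#'
#' The one-sample Mendelian randomization estimator: the ratio of the
#' instrument-outcome log hazard ratio (`beta1`, per score unit) to the
#' instrument-exposure slope (`beta2`, nmol/L per score unit), rescaled to a
#' chosen 25OHD increment (default 20 nmol/L):
#' \deqn{\hat\beta_{IV} = s \,\beta_1/\beta_2.}
#' The first-order delta-method variance, treating the two stage estimates
#' as independent, is
#' \deqn{SE_{IV}^2 = (s/\beta_2)^2 SE_1^2 + (s\beta_1/\beta_2^2)^2 SE_2^2.}
#' The ratio estimate is exponentiated to an odds/hazard-ratio scale with a
#' 95% Wald CI and two-sided normal p-value.
#'
#' A weak-instrument warning (attribute `weak_instrument`, plus an R
#' warning) is attached when the first-stage `|beta2| / se2 < 2` or, if
#' `f_stat` is supplied, when `f_stat < 10`; weak instruments bias ratio
#' estimates and the warning is never escalated to an error.
#'
#' @param beta1 Outcome-model coefficient, log hazard (or odds) per score
#'   unit.
#' @param se1 Standard error of `beta1`.
#' @param beta2 First-stage slope, nmol/L per score unit; must be non-zero.
#' @param se2 Standard error of `beta2`.
#' @param scale 25OHD increment the estimate is expressed per (nmol/L,
#'   default 20).
#' @param f_stat Optional first-stage F statistic for the weak-instrument
#'   check.
#' @return Object of class `iv_estimate`: `beta_iv`, `se_iv`, `or_`,
#'   `ci95 = c(lo, hi)`, `p`, `scale`, `method = "delta"`,
#'   `weak_instrument`.
#' @examples
#' wald_iv(beta1 = 0.1, se1 = 0.05, beta2 = 2, se2 = 0.1, scale = 20)
#' @export
wald_iv <- function(beta1, se1, beta2, se2, scale = 20, f_stat = NULL) {
  check_iv_inputs(beta2, se1, se2, scale)
  beta_iv <- scale * beta1 / beta2
  se_iv <- sqrt((scale / beta2)^2 * se1^2 +
                  (scale * beta1 / beta2^2)^2 * se2^2)
  weak <- is_weak_instrument(beta2, se2, f_stat)
  new_iv_estimate(beta_iv, se_iv, scale, "delta", weak)
}

#' Simple rescaling of an outcome coefficient to a 25OHD increment
#'
#' Multiplies the outcome beta and its SE by `target / slope`, treating the
#' first-stage slope as known: no second-stage variance enters, so the SE is
#' never larger than the delta-method SE (equal only when the slope is
#' noise-free or the outcome beta is zero).
#'
#' @param beta,se Outcome coefficient (log hazard per score unit) and SE.
#' @param slope First-stage slope, nmol/L per score unit; non-zero.
#' @param target 25OHD increment (nmol/L, default 20).
#' @param f_stat Optional first-stage F for the weak-instrument check.
#' @return Object of class `iv_estimate` with `method = "simple"`.
#' @export
rescale_simple <- function(beta, se, slope, target = 20, f_stat = NULL) {
  check_iv_inputs(slope, se, 0, target)
  k <- target / slope
  new_iv_estimate(beta * k, abs(k) * se, target, "simple",
                  is_weak_instrument(slope, NA_real_, f_stat))
}

check_iv_inputs <- function(beta2, se1, se2, scale) {
  if (!is.numeric(beta2) || beta2 == 0) {
    stop("first-stage slope is zero: the Wald ratio is undefined",
         call. = FALSE)
  }
  if (se1 < 0 || se2 < 0) stop("standard errors must be >= 0", call. = FALSE)
  if (scale <= 0) stop("scale must be positive (nmol/L)", call. = FALSE)
  invisible(TRUE)
}

is_weak_instrument <- function(beta2, se2, f_stat) {
  weak <- FALSE
  if (!is.null(f_stat) && is.finite(f_stat) && f_stat < 10) weak <- TRUE
  if (is.finite(se2) && se2 > 0 && abs(beta2) / se2 < 2) weak <- TRUE
  if (weak) {
    warning("weak instrument: first-stage signal is small; ",
            "ratio estimate may be unstable", call. = FALSE)
  }
  weak
}

new_iv_estimate <- function(beta_iv, se_iv, scale, method, weak) {
  structure(list(
    beta_iv = beta_iv,
    se_iv = se_iv,
    or_ = exp(beta_iv),
    ci95 = c(lo = exp(beta_iv - Z975 * se_iv),
             hi = exp(beta_iv + Z975 * se_iv)),
    p = 2 * stats::pnorm(-abs(beta_iv) / se_iv),
    scale = scale,
    method = method,
    weak_instrument = weak
  ), class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf(
    "<iv_estimate> %s method, per %g nmol/L 25OHD\n", x$method, x$scale))
  cat(sprintf("  ratio %.3f (95%% CI %.3f-%.3f), beta %.4f (SE %.4f), p = %.3g\n",
              x$or_, x$ci95[["lo"]], x$ci95[["hi"]],
              x$beta_iv, x$se_iv, x$p))
  if (x$weak_instrument) cat("  WARNING: weak instrument\n")
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` tests. For the 5 SNPs plus the score, `0.05 / 6 =
#' 0.008333`; note this is a plain arithmetic quotient — reports that quote a
#' different printed cut-off should surface both numbers rather than choose.
#'
#' @param alpha Family-wise level in `(0, 1)` (default 0.05).
#' @param m Number of tests (>= 1).
#' @return The per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / m
}

#' Flag p-values at a Bonferroni threshold
#'
#' @param p Numeric vector of p-values.
#' @param alpha Family-wise level.
#' @param m Number of tests (defaults to `length(p)`).
#' @return Data frame `p`, `threshold`, `significant`.
#' @export
bonferroni_flag <- function(p, alpha = 0.05, m = length(p)) {
  thr <- bonferroni_threshold(alpha, m)
  data.frame(p = p, threshold = thr, significant = p < thr)
}
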