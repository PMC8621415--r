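#' Log-likelihood of occurrence data, prevalence estimated separately
#'
#' Concentration of a hazard in a food is modelled log-normally: the log
#' concentration is normal with mean `mu` and standard deviation `sigma`.
#' Under the separate-prevalence option every reported measurement -- even a
#' non-detect -- is taken to be a true positive, and the prevalence `q` is
#' informed only by a binomial sample of positives. Exact values contribute
#' the normal density of their log, interval-censored values the probability
#' mass between log LOD and log LOQ, non-detects the mass below log LOD, and
#' the prevalence sample a binomial likelihood.
#'
#' @param params List with elements `mu`, `sigma` (> 0) and, if a prevalence
#'   sample is supplied, `q` in \[0, 1\].
#' @param records Occurrence tibble for one hazard--food pair (columns
#'   `value`, `censor`, `lod`, `loq`).
#' @param prevalence Optional one-row prevalence tibble (`positive`, `total`).
#' @return The scalar log-likelihood; `-Inf` (never `NaN`) whenever the
#'   parameters give any data point zero probability, including `sigma <= 0`.
#' @export
loglik_occurrence_separate <- function(params, records, prevalence = NULL) {
  mu <- params$mu; sigma <- params$sigma
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) return(-Inf)
  ll <- 0
  exact <- records$censor == "exact"
  if (any(exact)) {
    ll <- ll + sum(stats::dnorm(log(records$value[exact]), mu, sigma, log = TRUE))
  }
  int <- records$censor == "interval"
  if (any(int)) {
    ll <- ll + sum(log_pnorm_diff(log(records$lod[int]), log(records$loq[int]),
                                  mu, sigma))
  }
  nd <- records$censor == "nd"
  if (any(nd)) {
    ll <- ll + sum(stats::pnorm(log(records$lod[nd]), mu, sigma, log.p = TRUE))
  }
  if (!is.null(prevalence) && nrow(prevalence)) {
    q <- params$q
    if (is.null(q) || !is.finite(q) || q < 0 || q > 1) return(-Inf)
    ll <- ll + sum(stats::dbinom(prevalence$positive, prevalence$total, q,
                                 log = TRUE))
  }
  if (is.nan(ll)) -Inf else ll
}

#' Log-likelihood of occurrence data, zero-inflated option
#'
#' Under the zero-inflated option a unit of food is contaminated with
#' probability `q` and, if contaminated, carries a log-normal concentration.
#' A non-detect then either is a true zero or a positive below LOD:
#' its likelihood is `1 - q * (1 - F(log LOD))`. A detected interval-censored
#' value contributes `q * (F(log LOQ) - F(log LOD))` and an exact value
#' `q * f(log c)` -- the truncation of the detected-value density cancels
#' against the detection probability, so no truncated density is needed.
#'
#' @inheritParams loglik_occurrence_separate
#' @param params List with `mu`, `sigma` (> 0), `q` in \[0, 1\].
#' @return Scalar log-likelihood, `-Inf` outside the parameter support.
#' @export
loglik_occurrence_zero_inflated <- function(params, records) {
  mu <- params$mu; sigma <- params$sigma; q <- params$q
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) return(-Inf)
  if (is.null(q) || !is.finite(q) || q < 0 || q > 1) return(-Inf)
  ll <- 0
  nd <- records$censor == "nd"
  if (any(nd)) {
    f_lod <- stats::pnorm(log(records$lod[nd]), mu, sigma)
    p_nodetect <- 1 - q * (1 - f_lod)
    if (any(p_nodetect <= 0)) return(-Inf)
    ll <- ll + sum(log(p_nodetect))
  }
  int <- records$censor == "interval"
  if (any(int)) {
    if (q == 0) return(-Inf)
    ll <- ll + sum(log(q) + log_pnorm_diff(log(records$lod[int]),
                                           log(records$loq[int]), mu, sigma))
  }
  exact <- records$censor == "exact"
  if (any(exact)) {
    if (q == 0) return(-Inf)
    ll <- ll + sum(log(q) +
                     stats::dnorm(log(records$value[exact]), mu, sigma, log = TRUE))
  }
  if (is.nan(ll)) -Inf else ll
}

#' Data-driven upper bound for the concentration log-sd prior
#'
#' The uniform prior on the log-scale standard deviation needs a finite upper
#' bound to stay proper without allowing absurd spread. The bound is an
#' empirical heuristic: take the observed exact log concentrations, append
#' two pseudo-extreme values -- `min - R` and `max + R` with
#' `R = max(range, range_floor)` -- and return `k` times the standard
#' deviation of the augmented vector. The augmentation guarantees a strictly
#' positive bound even for a single observation, and the bound is invariant
#' under shifting all values (change of measurement unit on the log scale).
#'
#' @param log_values Numeric vector of observed exact log concentrations.
#' @param k Multiplier applied to the augmented standard deviation
#'   (default 5).
#' @param range_floor Minimum spread used for the pseudo-extremes (default 1
#'   log unit), which is what keeps the bound positive for degenerate data.
#' @return A single positive number.
#' @export
#' @examples
#' sigma_upper_bound(log(c(2, 5, 9)))
sigma_upper_bound <- function(log_values, k = 5, range_floor = 1) {
  log_values <- log_values[is.finite(log_values)]
  if (!length(log_values)) stop("no finite log values", call. = FALSE)
  r <- max(diff(range(log_values)), range_floor)
  augmented <- c(log_values, min(log_values) - r, max(log_values) + r)
  k * stats::sd(augmented)
}

#' Log prior density of occurrence parameters
#'
#' The mean log concentration gets a near-flat wide normal prior
#' (sd 1000 on the log scale -- effectively flat but proper), the prevalence
#' a Beta(1, 1), and the log-sd either a uniform on `(0, U)` or a gamma prior
#' on the inverse variance (with the Jacobian of the precision-to-sd change
#' of variables included).
#'
#' @param params List with `mu`, `sigma` and optionally `q`.
#' @param prior List with elements `sigma_prior` (`"uniform"` or `"gamma"`),
#'   `sigma_upper` (U for the uniform case), `gamma_a`, `gamma_b`, and
#'   `mu_sd` (default 1000).
#' @return Scalar log prior density, `-Inf` outside the support.
#' @export
log_prior_occurrence <- function(params, prior) {
  mu <- params$mu; sigma <- params$sigma
  mu_sd <- prior$mu_sd %||% 1000
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  lp <- stats::dnorm(mu, 0, mu_sd, log = TRUE)
  if ((prior$sigma_prior %||% "uniform") == "uniform") {
    u <- prior$sigma_upper
    if (sigma >= u) return(-Inf)
    lp <- lp - log(u)
  } else {
    a <- prior$gamma_a %||% 0.01
    b <- prior$gamma_b %||% 0.01
    tau <- 1 / sigma^2
    # density of sigma when 1/sigma^2 ~ Gamma(a, b): |d tau / d sigma| = 2 / sigma^3
    lp <- lp + stats::dgamma(tau, a, rate = b, log = TRUE) + log(2) - 3 * log(sigma)
  }
  if (!is.null(params$q)) {
    if (params$q < 0 || params$q > 1) return(-Inf)
    lp <- lp + stats::dbeta(params$q, 1, 1, log = TRUE)
  }
  lp
}
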