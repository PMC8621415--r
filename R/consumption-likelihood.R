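#' Log-likelihood of body weights
#'
#' Body weights are modelled log-normally: each log weight contributes a
#' normal density with mean `mu_w` and sd `sigma_w`.
#'
#' @param params List with `mu_w`, `sigma_w` (> 0).
#' @param weights Numeric vector of body weights (kg, > 0), or a tibble with
#'   a `weight` column.
#' @return Scalar log-likelihood, `-Inf` for `sigma_w <= 0`.
#' @export
loglik_bodyweight <- function(params, weights) {
  if (is.data.frame(weights)) weights <- weights$weight
  if (!is.finite(params$sigma_w) || params$sigma_w <= 0) return(-Inf)
  if (any(weights <= 0)) return(-Inf)
  sum(stats::dnorm(log(weights), params$mu_w, params$sigma_w, log = TRUE))
}

#' Log-likelihood of positive consumption amounts
#'
#' Daily consumed amounts per body weight are log multivariate normal around
#' a consumer-specific mean vector with within-consumer (day-to-day)
#' covariance `C_s`; the consumer mean vectors are themselves multivariate
#' normal around the population mean `mu0` with between-consumer covariance
#' `C_mu`. Zero amounts are treated as missing: a day contributes the
#' marginal multivariate normal density of its observed (positive)
#' coordinates only -- the mean and covariance sub-blocks of the consuming
#' foods -- and an all-zero day contributes nothing, since not consuming says
#' nothing about how much would have been consumed.
#'
#' @param params List with `mu0` (length-nf vector), `C_s`, `C_mu` (nf x nf
#'   covariance matrices) and `mu_r` (nr x nf matrix of consumer means, rows
#'   named by respondent).
#' @param diary Wide diary tibble (see [read_consumption()]).
#' @param weights Body-weight tibble (`respondent`, `weight`); raw amounts
#'   are divided by the respondent's weight before taking logs.
#' @return Scalar log-likelihood: the sum of per-day marginal densities plus
#'   the hierarchical density of each consumer mean. `-Inf` if either
#'   covariance is not positive definite.
#' @export
loglik_amounts <- function(params, diary, weights) {
  foods <- names(params$mu0) %||% setdiff(names(diary), c("respondent", "day"))
  nf <- length(foods)
  amounts <- as.matrix(diary[foods])
  w <- weights$weight[match(diary$respondent, weights$respondent)]
  y <- log(amounts / w)  # -Inf where amount is zero (masked below)
  mu_r <- params$mu_r
  if (is.null(rownames(mu_r))) stop("mu_r must have respondent rownames")
  ridx <- match(diary$respondent, rownames(mu_r))

  if (inherits(tryCatch(chol(params$C_s), error = function(e) e, "error"), "error") ||
      inherits(tryCatch(chol(params$C_mu), error = function(e) e, "error"), "error")) {
    return(-Inf)
  }

  ll <- 0
  obs <- amounts > 0
  pattern <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  for (pat in unique(pattern)) {
    sel <- which(obs[match(pat, pattern), ])
    if (!length(sel)) next
    rows <- which(pattern == pat)
    yo <- y[rows, sel, drop = FALSE]
    mo <- mu_r[ridx[rows], sel, drop = FALSE]
    ll <- ll + sum(dmvnorm_log(yo - mo, rep(0, length(sel)),
                               params$C_s[sel, sel, drop = FALSE]))
  }
  ll <- ll + sum(dmvnorm_log(mu_r, params$mu0, params$C_mu))
  if (is.nan(ll)) -Inf else ll
}

#' Log-likelihood of consumption indicators, independent-day option
#'
#' Each respondent-day-food consumption indicator is Bernoulli with the
#' respondent's food-specific frequency; the logit-frequencies of a
#' respondent are multivariate normal around the population logit
#' frequencies with covariance `C_p`, capturing between-food frequency
#' correlation.
#'
#' @param params List with `p0` (population frequencies, length nf), `C_p`
#'   (nf x nf), `p_r` (nr x nf matrix of per-consumer frequencies, rows named
#'   by respondent).
#' @param indicators Matrix (or data frame) of 0/1 consumption indicators,
#'   one row per respondent-day, plus a `respondent` vector aligning rows to
#'   consumers: supply as a list `list(u = matrix, respondent = chr)` or a
#'   diary tibble from which indicators are taken as `amount > 0`.
#' @return Scalar log-likelihood, `-Inf` when an observed consumption has
#'   frequency 0 (or non-consumption frequency 1), or `C_p` is not positive
#'   definite.
#' @export
loglik_frequency_independent <- function(params, indicators) {
  if (is.data.frame(indicators)) {
    foods <- setdiff(names(indicators), c("respondent", "day"))
    u <- as.matrix(indicators[foods]) > 0
    resp <- indicators$respondent
  } else {
    u <- indicators$u > 0
    resp <- indicators$respondent
  }
  p_r <- params$p_r
  ridx <- match(resp, rownames(p_r))
  p <- p_r[ridx, , drop = FALSE]
  if (any(p[u] == 0) || any(p[!u] == 1)) return(-Inf)
  ll <- sum(log(p[u])) + sum(log1p(-p[!u]))
  eta <- apply(p_r, 2L, logit)
  ll <- ll + sum(dmvnorm_log(eta, logit(params$p0), params$C_p))
  if (is.nan(ll)) -Inf else ll
}

#' Count day-to-day consumption transitions for one respondent
#'
#' For a consecutive-day diary, tabulates the adjacent-day transitions of the
#' consumption indicator of one food: `x01` transitions 0 to 1 out of `n0`
#' days preceded by non-consumption, and `x11` transitions 1 to 1 out of `n1`
#' days preceded by consumption. `n0 + n1` equals the number of day pairs.
#'
#' @param u Integer/logical vector of daily consumption indicators in day
#'   order (days must be consecutive).
#' @return A one-row tibble with columns `x01`, `n0`, `x11`, `n1`.
#' @export
#' @examples
#' count_transitions(c(0, 1, 1, 0))
count_transitions <- function(u) {
  u <- as.integer(u > 0)
  if (length(u) < 2L) {
    return(tibble::tibble(x01 = 0L, n0 = 0L, x11 = 0L, n1 = 0L))
  }
  from <- u[-length(u)]
  to <- u[-1L]
  tibble::tibble(
    x01 = sum(from == 0L & to == 1L), n0 = sum(from == 0L),
    x11 = sum(from == 1L & to == 1L), n1 = sum(from == 1L)
  )
}

#' Pooled transition counts per food from a diary
#'
#' Applies [count_transitions()] within each respondent (sorted by day) and
#' sums the counts, per food. Respondents with a single day contribute no
#' pairs. Transition probabilities are population-level parameters, so the
#' counts pool over respondents.
#'
#' @param diary Wide diary tibble with consecutive day indices.
#' @return A tibble with one row per food: `food`, `x01`, `n0`, `x11`, `n1`.
#' @export
transition_counts <- function(diary) {
  foods <- setdiff(names(diary), c("respondent", "day"))
  diary <- diary[order(diary$respondent, diary$day), ]
  purrr::map_dfr(foods, function(f) {
    per_r <- lapply(split(diary[[f]], diary$respondent), count_transitions)
    counts <- dplyr::summarise(dplyr::bind_rows(per_r),
                               dplyr::across(dplyr::everything(), sum))
    dplyr::bind_cols(tibble::tibble(food = f), counts)
  })
}

#' Log-likelihood of Markov consumption transitions
#'
#' The two-state day-to-day Markov chain contributes, per food, a product of
#' two binomial kernels: `p01^x01 (1-p01)^(n0-x01)` for days preceded by
#' non-consumption and `p11^x11 (1-p11)^(n1-x11)` for days preceded by
#' consumption. Both transition probabilities carry uniform priors, so their
#' posteriors are Beta with the observed counts plus one.
#'
#' @param params List with vectors `p01`, `p11` aligned to the rows of
#'   `counts`.
#' @param counts Tibble from [transition_counts()].
#' @return Scalar log-likelihood, `-Inf` outside \[0, 1\] or when an observed
#'   transition has probability 0.
#' @export
loglik_frequency_markov <- function(params, counts) {
  p01 <- params$p01; p11 <- params$p11
  if (any(!is.finite(p01)) || any(!is.finite(p11)) ||
      any(p01 < 0 | p01 > 1) || any(p11 < 0 | p11 > 1)) {
    return(-Inf)
  }
  ll <- sum(stats::dbinom(counts$x01, counts$n0, p01, log = TRUE)) +
    sum(stats::dbinom(counts$x11, counts$n1, p11, log = TRUE)) -
    sum(lchoose(counts$n0, counts$x01)) - sum(lchoose(counts$n1, counts$x11))
  if (is.nan(ll)) -Inf else ll
}

#' Stationary daily consumption probability of the Markov option
#'
#' The long-run probability of consuming a food on an arbitrary day implied
#' by the transition probabilities: `p = p01 / (p01 + p10)` with
#' `p10 = 1 - p11`.
#'
#' @param p01 Probability of consuming given no consumption the previous day.
#' @param p11 Probability of consuming given consumption the previous day.
#' @return Stationary consumption probability (vectorised).
#' @export
#' @examples
#' markov_stationary(0.2, 0.7)  # 0.4
markov_stationary <- function(p01, p11) {
  p10 <- 1 - p11
  if (any(p01 + p10 <= 0)) {
    stop("stationary probability undefined: p01 + p10 = 0 (chain never moves)",
         call. = FALSE)
  }
  p01 / (p01 + p10)
}
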