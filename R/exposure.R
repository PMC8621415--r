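# Exposure assessment from posterior draws.
#
# Every function here maps the posterior sample of model parameters into
# exposure quantities, keeping uncertainty (across draws) separate from
# variability (across consumers/days/servings within a draw).

#' Adjustment (processing) factor table
#'
#' Constant multipliers translating measured occurrence to the point of
#' consumption: `conc_factor` (> 0) multiplies concentrations (equivalently,
#' adds its log to the log-concentration mean everywhere it appears), and
#' `prev_factor` (in \[0, 1\]) multiplies prevalence, with the product
#' clipped to \[0, 1\]. Defaults are 1 and pairs not listed are unadjusted;
#' the factors carry no uncertainty distribution.
#'
#' @param hazard,food Character vectors (recycled) naming the pairs.
#' @param conc_factor,prev_factor Numeric factors as described.
#' @return A validated tibble usable as the `factors` argument of the
#'   exposure functions.
#' @export
adjustment_factors <- function(hazard, food, conc_factor = 1,
                               prev_factor = 1) {
  out <- tibble::tibble(hazard = hazard, food = food,
                        conc_factor = conc_factor,
                        prev_factor = prev_factor)
  if (any(out$conc_factor <= 0)) stop("conc_factor must be > 0", call. = FALSE)
  if (any(out$prev_factor < 0 | out$prev_factor > 1)) {
    stop("prev_factor must lie in [0, 1]", call. = FALSE)
  }
  out
}

get_factors <- function(factors, hazard, food) {
  if (is.null(factors)) return(c(conc = 1, prev = 1))
  row <- factors[factors$hazard == hazard & factors$food == food, ]
  if (!nrow(row)) return(c(conc = 1, prev = 1))
  c(conc = row$conc_factor[1L], prev = row$prev_factor[1L])
}

# Extract all population parameters of one posterior draw as matrices/vectors.
draw_params <- function(fit, row) {
  d <- fit$draws[row, ]
  foods <- fit$foods
  par <- list()
  if (!is.null(foods)) {
    par$mu0 <- stats::setNames(
      as.numeric(d[sprintf("mu0[%s]", foods)]), foods)
    par$C_s <- vec_to_cov(d, "Cs", foods)
    par$C_mu <- vec_to_cov(d, "Cmu", foods)
    if (fit$spec$frequency_option == "independent") {
      par$p0 <- stats::setNames(as.numeric(d[sprintf("p0[%s]", foods)]), foods)
      par$C_p <- vec_to_cov(d, "Cp", foods)
    } else {
      par$p01 <- stats::setNames(as.numeric(d[sprintf("p01[%s]", foods)]), foods)
      par$p11 <- stats::setNames(as.numeric(d[sprintf("p11[%s]", foods)]), foods)
    }
  }
  if ("bw_mu" %in% names(d)) {
    par$bw <- list(mu_w = d$bw_mu, sigma_w = d$bw_sigma)
  }
  if (!is.null(fit$pairs)) {
    par$occ <- purrr::pmap(fit$pairs, function(hazard, food) {
      key <- sprintf("[%s,%s]", hazard, food)
      list(mu = d[[paste0("occ_mu", key)]],
           sigma = d[[paste0("occ_sigma", key)]],
           q = d[[paste0("q", key)]] %||% 1)
    })
    names(par$occ) <- paste(fit$pairs$hazard, fit$pairs$food, sep = "\r")
  }
  par
}

# Population daily consumption probability per food for one draw: the
# population-median frequency under the independent-day option, or the
# stationary Markov probability (common to all consumers) under the Markov
# option.
population_freq <- function(par, foods) {
  if (!is.null(par[["p0"]])) {
    par[["p0"]][foods]
  } else {
    markov_stationary(par$p01[foods], par$p11[foods])
  }
}

pair_cols <- function(fit, hazard, food) {
  key <- sprintf("[%s,%s]", hazard, food)
  list(mu = fit$draws[[paste0("occ_mu", key)]],
       sigma = fit$draws[[paste0("occ_sigma", key)]],
       q = fit$draws[[paste0("q", key)]] %||%
         rep(1, nrow(fit$draws)))
}

#' Acute single-pair exposure distribution (closed form)
#'
#' For a microbiological hazard in a single food, the positive acute exposure
#' of a random consumer on a consumption day -- amount times concentration
#' times body weight -- is log-normal with log-mean
#' `mu0_j + mu_h + mu_w` and log-variance
#' `Cs[j,j] + Cmu[j,j] + sigma_h^2 + sigma_w^2`, because amounts,
#' concentration and body weight are independent log-normals with a
#' hierarchical two-component consumption variance. Evaluating the
#' parameters at every posterior draw yields the uncertainty distribution of
#' the variability distribution; the exposure mean
#' `exp(ln_mu + ln_var / 2)` and median `exp(ln_mu)` per draw give the
#' uncertainty of those summaries.
#'
#' @param fit A `bde_fit` containing occurrence, consumption and body-weight
#'   blocks.
#' @param hazard,food Pair selection (the hazard must be microbiological).
#' @param factors Optional [adjustment_factors()]; the concentration factor
#'   enters as `+ log(conc_factor)` in `ln_mu` and the prevalence factor
#'   multiplies `q` (clipped to \[0, 1\]).
#' @return A tibble with one row per posterior draw: `ln_mu`, `ln_var`,
#'   `mean`, `median`, `exposure_freq` (probability that a random day is a
#'   consumption day of contaminated food: population consumption frequency
#'   times prevalence).
#' @export
acute_pair <- function(fit, hazard, food, factors = NULL) {
  check_hazard_type(fit, hazard, "microbiological")
  fac <- get_factors(factors, hazard, food)
  occ <- pair_cols(fit, hazard, food)
  d <- fit$draws
  j <- food
  ln_mu <- d[[sprintf("mu0[%s]", j)]] + occ$mu + log(fac["conc"]) + d$bw_mu
  ln_var <- d[[sprintf("Cs[%s,%s]", j, j)]] + d[[sprintf("Cmu[%s,%s]", j, j)]] +
    occ$sigma^2 + d$bw_sigma^2
  q_adj <- pmin(pmax(occ$q * fac["prev"], 0), 1)
  p_j <- freq_column(fit, j)
  tibble::tibble(
    ln_mu = ln_mu, ln_var = ln_var,
    mean = exp(ln_mu + 0.5 * ln_var), median = exp(ln_mu),
    exposure_freq = p_j * q_adj
  )
}

#' Chronic single-pair exposure distribution (closed form)
#'
#' For a chemical hazard in a single food, concentration variability is
#' replaced by the mean concentration `E(c) = exp(mu_h + sigma_h^2 / 2)`,
#' and the long-run mean exposure per body weight of a random consumer on
#' consumption days is log-normal with log-mean
#' `mu0_j + Cs[j,j] / 2 + log E(c)` and log-variance `Cmu[j,j]`: the only
#' remaining variability is between consumer means.
#'
#' @inheritParams acute_pair
#' @return A tibble with one row per posterior draw: `ln_mu`, `ln_var`,
#'   `mean`, `median`, `exposure_freq`.
#' @export
chronic_pair <- function(fit, hazard, food, factors = NULL) {
  check_hazard_type(fit, hazard, "chemical")
  fac <- get_factors(factors, hazard, food)
  occ <- pair_cols(fit, hazard, food)
  d <- fit$draws
  j <- food
  log_ec <- occ$mu + log(fac["conc"]) + 0.5 * occ$sigma^2
  ln_mu <- d[[sprintf("mu0[%s]", j)]] + 0.5 * d[[sprintf("Cs[%s,%s]", j, j)]] +
    log_ec
  ln_var <- d[[sprintf("Cmu[%s,%s]", j, j)]]
  q_adj <- pmin(pmax(occ$q * fac["prev"], 0), 1)
  tibble::tibble(
    ln_mu = ln_mu, ln_var = ln_var,
    mean = exp(ln_mu + 0.5 * ln_var), median = exp(ln_mu),
    exposure_freq = freq_column(fit, j) * q_adj
  )
}

freq_column <- function(fit, food) {
  d <- fit$draws
  if (fit$spec$frequency_option == "independent") {
    d[[sprintf("p0[%s]", food)]]
  } else {
    markov_stationary(d[[sprintf("p01[%s]", food)]],
                      d[[sprintf("p11[%s]", food)]])
  }
}

#' Probability of exposure on a random day
#'
#' The proportion of days on which a contaminated unit of the food is
#' consumed: population consumption frequency (stationary probability under
#' the Markov option) times prevalence, per posterior draw.
#'
#' @inheritParams acute_pair
#' @return Numeric vector, one value per posterior draw.
#' @export
exposure_frequency <- function(fit, hazard, food, factors = NULL) {
  fac <- get_factors(factors, hazard, food)
  occ <- pair_cols(fit, hazard, food)
  q_adj <- pmin(pmax(occ$q * fac["prev"], 0), 1)
  freq_column(fit, food) * q_adj
}

check_hazard_type <- function(fit, hazard, expected) {
  ht <- fit$hazard_type
  if (!is.null(names(ht)) && hazard %in% names(ht)) ht <- ht[[hazard]]
  if (!identical(unname(ht[1L]), expected)) {
    stop(sprintf("hazard '%s' is not %s: %s exposure is not produced for it",
                 hazard, expected,
                 if (expected == "microbiological") "acute" else "chronic"),
         call. = FALSE)
  }
  invisible(TRUE)
}

## ---- conditional-sequence simulation ---------------------------------------

# One draw's variability simulation shared by acute and chronic totals:
# consumer frequencies, consumption indicators, consumer means, day amounts,
# body weights, concentrations and contamination indicators, composed
# multiplicatively per food and summed over the selected subset.
simulate_consumers <- function(par, fit, hazard, foods_sel, n, factors,
                               chronic = FALSE) {
  nf <- length(foods_sel)
  # consumer frequencies
  if (!is.null(par[["p0"]])) {
    eta <- rmvnorm_chol(n, logit(par[["p0"]][foods_sel]),
                        par$C_p[foods_sel, foods_sel, drop = FALSE])
    p_r <- inv_logit(eta)
  } else {
    p_r <- matrix(rep(markov_stationary(par$p01[foods_sel],
                                        par$p11[foods_sel]), each = n), n, nf)
  }
  mu_r <- rmvnorm_chol(n, par$mu0[foods_sel],
                       par$C_mu[foods_sel, foods_sel, drop = FALSE])
  per_food <- matrix(0, n, nf, dimnames = list(NULL, foods_sel))
  for (k in seq_len(nf)) {
    j <- foods_sel[k]
    occ <- par$occ[[paste(hazard, j, sep = "\r")]]
    if (is.null(occ)) stop("no occurrence draws for pair ", hazard, "/", j)
    fac <- get_factors(factors, hazard, j)
    q_adj <- min(max(occ$q * fac["prev"], 0), 1)
    if (chronic) {
      e_pos <- exp(mu_r[, k] + 0.5 * par$C_s[j, j] +
                     occ$mu + log(fac["conc"]) + 0.5 * occ$sigma^2)
      per_food[, k] <- q_adj * p_r[, k] * e_pos
    } else {
      u <- stats::runif(n) < p_r[, k]
      y <- mu_r[, k] + stats::rnorm(n, 0, sqrt(par$C_s[j, j]))
      w <- exp(stats::rnorm(n, par$bw$mu_w, par$bw$sigma_w))
      conc <- exp(stats::rnorm(n, occ$mu + log(fac["conc"]), occ$sigma))
      contaminated <- stats::runif(n) < q_adj
      per_food[, k] <- contaminated * u * exp(y) * conc * w
    }
  }
  per_food
}

# day amounts must share the consumer's full covariance across foods; redo
# with joint day draw (the per-food loop above draws day amounts food by
# food, which would lose the day-level correlation for the acute sum)
simulate_consumers_acute_joint <- function(par, fit, hazard, foods_sel, n,
                                           factors) {
  nf <- length(foods_sel)
  if (!is.null(par[["p0"]])) {
    eta <- rmvnorm_chol(n, logit(par[["p0"]][foods_sel]),
                        par$C_p[foods_sel, foods_sel, drop = FALSE])
    p_r <- inv_logit(eta)
  } else {
    p_r <- matrix(rep(markov_stationary(par$p01[foods_sel],
                                        par$p11[foods_sel]), each = n), n, nf)
  }
  u <- matrix(stats::runif(n * nf), n, nf) < p_r
  mu_r <- rmvnorm_chol(n, par$mu0[foods_sel],
                       par$C_mu[foods_sel, foods_sel, drop = FALSE])
  y <- mu_r + rmvnorm_chol(n, rep(0, nf),
                           par$C_s[foods_sel, foods_sel, drop = FALSE])
  w <- exp(stats::rnorm(n, par$bw$mu_w, par$bw$sigma_w))
  per_food <- matrix(0, n, nf, dimnames = list(NULL, foods_sel))
  for (k in seq_len(nf)) {
    j <- foods_sel[k]
    occ <- par$occ[[paste(hazard, j, sep = "\r")]]
    fac <- get_factors(factors, hazard, j)
    q_adj <- min(max(occ$q * fac["prev"], 0), 1)
    conc <- exp(stats::rnorm(n, occ$mu + log(fac["conc"]), occ$sigma))
    contaminated <- stats::runif(n) < q_adj
    per_food[, k] <- contaminated * u[, k] * exp(y[, k]) * conc * w
  }
  per_food
}

#' Simulate acute total exposure for one posterior draw
#'
#' Runs the conditional sampling sequence for `n_consumers` simulated
#' consumers under the parameters of one posterior draw: consumer
#' logit-frequencies (or the stationary Markov probability), Bernoulli
#' consumption indicators, consumer mean amounts, day amounts (with the full
#' between-food covariance), body weight, concentrations and Bernoulli
#' contamination indicators; the per-food exposures are summed over the
#' selected foods and a Poisson draw turns the expected microbial count into
#' a realised dose. The model must have been fitted with the full food set;
#' the subset only restricts the summation.
#'
#' @param fit A `bde_fit`.
#' @param hazard A microbiological hazard id.
#' @param foods Food subset to sum over (default: all foods).
#' @param n_consumers Number of simulated consumers.
#' @param draw Row index of the posterior draw to condition on (default 1).
#' @param factors Optional [adjustment_factors()].
#' @return A tibble with `total` (expected count per serving day, zeros
#'   included) and `dose` (Poisson realised count) per simulated consumer,
#'   plus per-food exposure columns `e_<food>`.
#' @export
simulate_acute_total <- function(fit, hazard, foods = fit$foods,
                                 n_consumers = 10000L, draw = 1L,
                                 factors = NULL) {
  stopifnot(length(foods) >= 1L)
  check_hazard_type(fit, hazard, "microbiological")
  par <- draw_params(fit, draw)
  per_food <- simulate_consumers_acute_joint(par, fit, hazard, foods,
                                             n_consumers, factors)
  total <- rowSums(per_food)
  out <- tibble::tibble(total = total,
                        dose = stats::rpois(n_consumers, total))
  out[paste0("e_", foods)] <- tibble::as_tibble(per_food)
  out
}

#' Simulate chronic total exposure for one posterior draw
#'
#' As [simulate_acute_total()] but for a chemical hazard: per consumer, the
#' long-run mean exposure per body weight of each food
#' (`q * p_r * E(positive exposure)`), summed over the subset. There is no
#' Poisson step -- chronic chemical exposure is a mean, not a count.
#'
#' @inheritParams simulate_acute_total
#' @param hazard A chemical hazard id.
#' @return A tibble with `total` plus per-food columns `e_<food>`.
#' @export
simulate_chronic_total <- function(fit, hazard, foods = fit$foods,
                                   n_consumers = 10000L, draw = 1L,
                                   factors = NULL) {
  stopifnot(length(foods) >= 1L)
  check_hazard_type(fit, hazard, "chemical")
  par <- draw_params(fit, draw)
  per_food <- simulate_consumers(par, fit, hazard, foods, n_consumers,
                                 factors, chronic = TRUE)
  out <- tibble::tibble(total = rowSums(per_food))
  out[paste0("e_", foods)] <- tibble::as_tibble(per_food)
  out
}

#' Per-consumer chronic exposure including zero exposures, one food
#'
#' Variability sampler for the chronic exposure of food `food` including
#' zero-exposure days: `q * p_r * E(e+)` with `p_r` drawn logit-normal (or
#' the stationary Markov constant) and the positive part log-normal.
#' Equivalent to [simulate_chronic_total()] with a single-food subset.
#'
#' @inheritParams simulate_chronic_total
#' @param food Single food id.
#' @return Numeric vector of per-consumer chronic exposures.
#' @export
chronic_including_zeros <- function(fit, hazard, food, n_consumers = 10000L,
                                    draw = 1L, factors = NULL) {
  simulate_chronic_total(fit, hazard, foods = food,
                         n_consumers = n_consumers, draw = draw,
                         factors = factors)$total
}

#' Posterior predictive exposure sample
#'
#' Integrates uncertainty and variability into a single distribution by
#' simulating exactly one consumer from the variability distribution of each
#' retained posterior draw. For acute (microbiological) exposure the result
#' includes the Poisson-realised dose; for chronic (chemical) exposure the
#' long-run mean per body weight.
#'
#' @param fit A `bde_fit`.
#' @param hazard Hazard id.
#' @param foods Food subset summed over (default all).
#' @param type `"acute"` or `"chronic"`; defaults to the hazard's type.
#' @param factors Optional [adjustment_factors()].
#' @return A tibble with one row per posterior draw: `total` and, for acute,
#'   `dose`.
#' @export
predictive_exposure <- function(fit, hazard, foods = fit$foods, type = NULL,
                                factors = NULL) {
  type <- type %||% unname(
    if (!is.null(names(fit$hazard_type))) fit$hazard_type[[hazard]]
    else fit$hazard_type[1L])
  type <- switch(type, microbiological = , acute = "acute",
                 chemical = , chronic = "chronic",
                 stop("unknown exposure type", call. = FALSE))
  n_draws <- nrow(fit$draws)
  totals <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    par <- draw_params(fit, i)
    per_food <- if (type == "acute") {
      simulate_consumers_acute_joint(par, fit, hazard, foods, 1L, factors)
    } else {
      simulate_consumers(par, fit, hazard, foods, 1L, factors, chronic = TRUE)
    }
    totals[i] <- sum(per_food)
  }
  out <- tibble::tibble(total = totals)
  if (type == "acute") out$dose <- stats::rpois(n_draws, totals)
  out
}

#' Posterior predictive quantile table
#'
#' Summarises a predictive (or any) exposure sample by the seven standard
#' quantiles 1, 5, 10, 50, 90, 95 and 99 percent. Quantiles of a sample are
#' non-decreasing by construction, and for a degenerate (constant) sample
#' all seven equal the constant.
#'
#' @param x Numeric vector of exposure samples, or a tibble with a `total`
#'   column (e.g. from [predictive_exposure()]).
#' @param probs Quantile levels (default the seven above).
#' @return A tibble with columns `quantile` (in percent) and `value`.
#' @export
predictive_quantiles <- function(x, probs = c(1, 5, 10, 50, 90, 95, 99) / 100) {
  if (is.data.frame(x)) x <- x$total
  tibble::tibble(
    quantile = 100 * probs,
    value = unname(stats::quantile(x, probs, type = 7, names = FALSE))
  )
}

#' Uncertainty distribution of a variability quantile (2D summary)
#'
#' Separates uncertainty from variability for a chosen variability quantile
#' `gamma`: per posterior draw, the gamma-quantile of that draw's
#' variability distribution is computed -- in closed form
#' `exp(ln_mu + z_gamma * sqrt(ln_var))` for a single log-normal hazard-food
#' pair (at `gamma` = 0.95 this is the familiar `exp(mu + 1.64 sigma)`), or
#' as the empirical quantile of `n_inner` simulated consumers for multi-food
#' totals. The spread of those per-draw quantiles is the uncertainty of the
#' variability quantile, summarised by central 90% bounds.
#'
#' @param fit A `bde_fit`.
#' @param hazard Hazard id.
#' @param foods Single food (closed form) or a food subset (inner
#'   simulation).
#' @param gamma Variability quantile level (default 0.95).
#' @param type `"acute"` or `"chronic"` (defaults to the hazard's type).
#' @param n_inner Inner simulation size per draw for multi-food totals
#'   (default 10000).
#' @param n_outer Number of posterior draws used: all draws in the
#'   closed-form case; a subsample (default up to 200) when each draw needs
#'   an inner simulation. Monte Carlo error of the inner empirical quantile
#'   shrinks as `1/sqrt(n_inner)`.
#' @param positives_only For the simulated route, condition on positive
#'   exposure (consumption of contaminated food) before taking the quantile.
#' @param factors Optional [adjustment_factors()].
#' @return A tibble with one row per used draw (`draw`, `quantile_value`);
#'   attribute `"bounds"` holds the 5% and 95% uncertainty bounds.
#' @export
two_dim_summary <- function(fit, hazard, foods, gamma = 0.95, type = NULL,
                            n_inner = 10000L, n_outer = NULL,
                            positives_only = TRUE, factors = NULL) {
  type <- type %||% unname(
    if (!is.null(names(fit$hazard_type))) fit$hazard_type[[hazard]]
    else fit$hazard_type[1L])
  type <- if (type %in% c("microbiological", "acute")) "acute" else "chronic"
  n_draws <- nrow(fit$draws)
  if (length(foods) == 1L) {
    pair_fun <- if (type == "acute") acute_pair else chronic_pair
    pd <- pair_fun(fit, hazard, foods, factors)
    qv <- exp(pd$ln_mu + stats::qnorm(gamma) * sqrt(pd$ln_var))
    out <- tibble::tibble(draw = seq_len(n_draws), quantile_value = qv)
  } else {
    n_outer <- n_outer %||% min(200L, n_draws)
    rows <- round(seq(1L, n_draws, length.out = n_outer))
    qv <- vapply(rows, function(i) {
      sim <- if (type == "acute") {
        simulate_acute_total(fit, hazard, foods, n_inner, draw = i,
                             factors = factors)$total
      } else {
        simulate_chronic_total(fit, hazard, foods, n_inner, draw = i,
                               factors = factors)$total
      }
      if (positives_only) sim <- sim[sim > 0]
      if (!length(sim)) return(0)
      stats::quantile(sim, gamma, names = FALSE)
    }, numeric(1L))
    out <- tibble::tibble(draw = rows, quantile_value = qv)
  }
  attr(out, "bounds") <- stats::quantile(out$quantile_value, c(0.05, 0.95))
  out
}
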