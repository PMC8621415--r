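# Posterior sampling.
#
# The joint posterior factorises exactly into an occurrence block, a
# body-weight block, an amounts block and a frequency block: the blocks share
# no parameters, so each is sampled from its own sub-posterior with its own
# seeded RNG stream (which also makes the draws of one block bit-identical
# whether or not the others are co-sampled). Within blocks the model is
# conditionally conjugate once censored concentrations, latent contamination
# states and zero (missing) consumption coordinates are data-augmented, so
# almost every update is an exact Gibbs draw; only the per-consumer
# logit-frequencies need an adaptive random-walk Metropolis step.

#' Moment-based initial parameter values
#'
#' Builds a starting point for the sampler from simple moment estimates:
#' concentration mean/sd from the observed log values with censored records
#' substituted at the midpoint of their censoring interval (for
#' initialisation only -- estimation always uses the integrated likelihood),
#' prevalence from the naive positive fraction clamped inside (0, 1),
#' consumption covariances from diagonal sample variances, and frequencies
#' from observed day fractions clamped to (0.01, 0.99).
#'
#' @param data A [bde_data()] bundle.
#' @param spec A [model_spec()].
#' @return A nested list of initial values per model block.
#' @export
init_params <- function(data, spec) {
  out <- list()
  if (!is.null(data$occurrence) || !is.null(data$prevalence)) {
    pairs <- occurrence_pairs(data)
    out$occurrence <- purrr::pmap(pairs, function(hazard, food) {
      recs <- pair_records(data$occurrence, hazard, food)
      prev <- pair_records(data$prevalence, hazard, food)
      init <- list()
      if (!is.null(recs) && nrow(recs)) {
        y <- log(recs$value[recs$censor == "exact"])
        int <- recs$censor == "interval"
        # midpoint (raw scale) of the censoring interval, init only
        y <- c(y, log((recs$lod[int] + recs$loq[int]) / 2),
               log(recs$lod[recs$censor == "nd"] / 2))
        y <- y[is.finite(y)]
        init$mu <- mean(y)
        init$sigma <- max(stats::sd(y), 0.1)
        if (is.na(init$sigma)) init$sigma <- 0.5
        pos_frac <- mean(recs$censor != "nd")
        init$q <- min(max(pos_frac, 0.01), 0.99)
      }
      if (!is.null(prev) && nrow(prev)) {
        init$q <- min(max(sum(prev$positive) / sum(prev$total), 0.01), 0.99)
      }
      init
    })
    names(out$occurrence) <- paste(pairs$hazard, pairs$food, sep = "\r")
  }
  if (!is.null(data$weights)) {
    lw <- log(data$weights$weight)
    out$bw <- list(mu_w = mean(lw), sigma_w = max(stats::sd(lw), 0.05))
  }
  if (!is.null(data$diary)) {
    foods <- data$foods
    amounts <- as.matrix(data$diary[foods])
    w <- data$weights$weight[match(data$diary$respondent,
                                   data$weights$respondent)]
    y <- log(amounts / w)
    y[amounts == 0] <- NA
    mu0 <- apply(y, 2L, function(v) {
      m <- mean(v, na.rm = TRUE); if (is.finite(m)) m else 0
    })
    pooled <- apply(y, 2L, function(v) {
      s <- stats::var(v, na.rm = TRUE)
      if (is.finite(s) && s > 0) s else 0.5
    })
    out$amounts <- list(mu0 = mu0,
                        C_s = diag(pooled, length(foods)),
                        C_mu = diag(pmax(pooled / 2, 0.1), length(foods)))
    u <- amounts > 0
    p_hat <- colSums(u) / nrow(u)
    out$frequency <- list(p0 = pmin(pmax(p_hat, 0.01), 0.99),
                          C_p = diag(0.5, length(foods)))
  }
  out
}

#' Sample the joint posterior of all active model blocks
#'
#' Runs the block-wise MCMC described in the package vignette: exact
#' conjugate Gibbs updates with data augmentation for censored
#' concentrations, latent contamination indicators (zero-inflated option),
#' and zero-as-missing consumption coordinates; Beta draws for prevalence
#' and Markov transition probabilities; inverse-Wishart draws for the three
#' covariance matrices; and an adaptive random-walk Metropolis step for the
#' per-consumer logit frequencies (independent-day option). Each chain and
#' block gets its own RNG stream derived from the spec seed, so runs are
#' fully reproducible and block draws do not depend on which other blocks
#' are present.
#'
#' @param data A [bde_data()] bundle.
#' @param spec A [model_spec()].
#' @param fixed Optional named list pinning selected parameters at fixed
#'   values instead of sampling them (supported: `C_s`, `C_mu`, `C_p`), a
#'   sensitivity-analysis device.
#' @return A `bde_fit` object: `$draws` is a tibble with `.chain`, `.iter`
#'   and one column per scalar parameter (population-level parameters only;
#'   consumer-level parameters are re-simulated from the hierarchy during
#'   exposure assessment).
#' @seealso [diagnostics()], [tidy.bde_fit()], [acute_pair()],
#'   [predictive_exposure()]
#' @export
#' @examples
#' truth <- default_truth("micro-like")
#' truth$counts <- list(nr = 40L, nd = 2L, n_occ = 60L, n_prev = 0L)
#' d <- generate_dataset(truth, seed = 1)
#' spec <- model_spec(d, occurrence_option = "zero_inflated",
#'                    frequency_option = "markov",
#'                    hazard_type = "microbiological",
#'                    chains = 2, iter = 200, burnin = 100, seed = 1)
#' fit <- sample_posterior(d, spec)
#' fit
sample_posterior <- function(data, spec, fixed = NULL) {
  stopifnot(inherits(data, "bde_data"), inherits(spec, "bde_spec"))
  inits <- init_params(data, spec)
  chains <- spec$chains
  per_chain <- vector("list", chains)

  for (ch in seq_len(chains)) {
    mats <- list()
    if (!is.null(inits$occurrence)) {
      set.seed(block_seed(spec$seed, 1L, ch))
      mats$occ <- sample_occurrence_block(data, spec, inits$occurrence, ch)
    }
    if (!is.null(inits$bw)) {
      set.seed(block_seed(spec$seed, 2L, ch))
      mats$bw <- sample_bodyweight_block(data, spec, inits$bw, ch)
    }
    if (!is.null(inits$amounts)) {
      set.seed(block_seed(spec$seed, 3L, ch))
      mats$amounts <- sample_amounts_block(data, spec, inits$amounts, ch, fixed)
    }
    if (!is.null(inits$frequency)) {
      set.seed(block_seed(spec$seed, 4L, ch))
      mats$freq <- sample_frequency_block(data, spec, inits$frequency, ch, fixed)
    }
    stopifnot(length(mats) > 0)
    m <- do.call(cbind, unname(mats))
    per_chain[[ch]] <- dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iter = seq_len(nrow(m))),
      tibble::as_tibble(m)
    )
  }

  structure(
    list(draws = dplyr::bind_rows(per_chain), spec = spec, data = data,
         foods = data$foods, pairs = occurrence_pairs(data),
         hazard_type = spec$hazard_type, seed = spec$seed),
    class = "bde_fit"
  )
}

#' @export
print.bde_fit <- function(x, ...) {
  cat("<bde_fit>\n")
  cat("  ", max(x$draws$.chain), "chain(s) x",
      max(x$draws$.iter), "retained draws,",
      ncol(x$draws) - 2L, "parameters\n")
  cat("  components:", paste(x$spec$active, collapse = " "), "\n")
  invisible(x)
}

block_seed <- function(seed, block, chain) {
  ((seed %% 100000L) * 8192L + block * 64L + chain) %% 2147483647L
}

occurrence_pairs <- function(data) {
  p1 <- if (!is.null(data$occurrence)) unique(data$occurrence[c("hazard", "food")])
  p2 <- if (!is.null(data$prevalence)) unique(data$prevalence[c("hazard", "food")])
  out <- dplyr::distinct(dplyr::bind_rows(p1, p2))
  if (!nrow(out)) NULL else out
}

pair_records <- function(tbl, hazard, food) {
  if (is.null(tbl)) return(NULL)
  tbl[tbl$hazard == hazard & tbl$food == food, ]
}

# chain-specific jitter applied to initial values
jitter_init <- function(x, ch, scale = 0.1) {
  if (ch == 1L) x else x + stats::rnorm(length(x), 0, scale)
}

## ---- occurrence block -------------------------------------------------------

sample_occurrence_block <- function(data, spec, inits, ch) {
  pairs <- occurrence_pairs(data)
  cols <- list()
  for (i in seq_len(nrow(pairs))) {
    h <- pairs$hazard[i]; f <- pairs$food[i]
    recs <- pair_records(data$occurrence, h, f)
    prev <- pair_records(data$prevalence, h, f)
    init <- inits[[paste(h, f, sep = "\r")]]
    m <- sample_occurrence_pair(recs, prev, spec, init, ch)
    colnames(m) <- sprintf("%s[%s,%s]", colnames(m), h, f)
    cols[[i]] <- m
  }
  do.call(cbind, cols)
}

sample_occurrence_pair <- function(recs, prev, spec, init, ch) {
  n_keep <- spec$iter; burnin <- spec$burnin
  total <- n_keep + burnin
  has_conc <- !is.null(recs) && nrow(recs) > 0
  has_prev <- !is.null(prev) && nrow(prev) > 0
  zero_inflated <- spec$occurrence_option == "zero_inflated"

  # prevalence-only sub-model: exact i.i.d. conjugate draws
  if (!has_conc) {
    x <- sum(prev$positive); n <- sum(prev$total)
    q <- stats::rbeta(total, x + 1, n - x + 1)[(burnin + 1):total]
    return(matrix(q, ncol = 1, dimnames = list(NULL, "q")))
  }

  y_exact <- log(recs$value[recs$censor == "exact"])
  int <- recs$censor == "interval"
  lo_int <- log(recs$lod[int]); hi_int <- log(recs$loq[int])
  nd <- recs$censor == "nd"
  lod_nd <- log(recs$lod[nd])
  n_int <- sum(int); n_nd <- sum(nd); n_ex <- length(y_exact)

  u_sigma <- sigma_upper_bound(y_exact)
  mu <- jitter_init(init$mu, ch)
  sigma <- min(init$sigma * exp(jitter_init(0, ch, 0.2)), u_sigma * 0.9)
  q <- init$q %||% 0.5
  track_q <- has_prev || zero_inflated

  keep <- matrix(NA_real_, n_keep, 2L + track_q)
  colnames(keep) <- c("occ_mu", "occ_sigma", if (track_q) "q")
  x_prev <- if (has_prev) sum(prev$positive) else 0L
  n_prev <- if (has_prev) sum(prev$total) else 0L

  for (it in seq_len(total)) {
    # -- data augmentation of censored log concentrations
    y_int <- if (n_int) rtruncnorm(n_int, mu, sigma, lo_int, hi_int)
    if (zero_inflated) {
      if (n_nd) {
        f_lod <- stats::pnorm((lod_nd - mu) / sigma)
        pz <- q * f_lod / (1 - q * (1 - f_lod))
        z <- stats::runif(n_nd) < pz
        y_nd <- rtruncnorm(sum(z), mu, sigma, -Inf, lod_nd[z])
      } else {
        z <- logical(0); y_nd <- numeric(0)
      }
      a_q <- 1 + n_ex + n_int + sum(z) + x_prev
      b_q <- 1 + sum(!z) + (n_prev - x_prev)
      q <- stats::rbeta(1, a_q, b_q)
    } else {
      y_nd <- if (n_nd) rtruncnorm(n_nd, mu, sigma, -Inf, lod_nd)
      if (has_prev) q <- stats::rbeta(1, x_prev + 1, n_prev - x_prev + 1)
    }
    y <- c(y_exact, y_int, y_nd)
    n <- length(y)

    # -- conjugate normal update for mu (wide normal prior, sd 1000)
    prec <- n / sigma^2 + 1e-6
    mu <- stats::rnorm(1, sum(y) / sigma^2 / prec, sqrt(1 / prec))

    # -- sigma update under the chosen prior
    ss <- sum((y - mu)^2)
    sigma <- draw_sigma(n, ss, spec, u_sigma)

    if (it > burnin) {
      keep[it - burnin, 1:2] <- c(mu, sigma)
      if (track_q) keep[it - burnin, 3L] <- q
    }
  }
  keep
}

# sigma | complete data. Uniform(0, U) prior on sigma gives a truncated
# inverse-gamma for sigma^2, drawn exactly by inverse-CDF on the precision;
# the gamma option is plainly conjugate for the precision.
draw_sigma <- function(n, ss, spec, u_sigma) {
  if (spec$sigma_prior == "uniform") {
    a <- (n - 1) / 2; b <- ss / 2
    if (a <= 0) {  # single observation: sample sigma from its flat prior slice
      return(stats::runif(1, 1e-3, u_sigma))
    }
    lo <- stats::pgamma(1 / u_sigma^2, a, rate = b)
    tau <- stats::qgamma(stats::runif(1, min(lo, 1 - 1e-12), 1), a, rate = b)
  } else {
    tau <- stats::rgamma(1, spec$gamma_a + n / 2, rate = spec$gamma_b + ss / 2)
  }
  1 / sqrt(max(tau, 1e-12))
}

## ---- body-weight block ------------------------------------------------------

sample_bodyweight_block <- function(data, spec, init, ch) {
  n_keep <- spec$iter; burnin <- spec$burnin
  total <- n_keep + burnin
  lw <- log(data$weights$weight)
  n <- length(lw)
  u_sigma <- sigma_upper_bound(lw)
  mu <- jitter_init(init$mu_w, ch, 0.05)
  sigma <- init$sigma_w
  keep <- matrix(NA_real_, n_keep, 2L,
                 dimnames = list(NULL, c("bw_mu", "bw_sigma")))
  for (it in seq_len(total)) {
    prec <- n / sigma^2 + 1e-6
    mu <- stats::rnorm(1, sum(lw) / sigma^2 / prec, sqrt(1 / prec))
    sigma <- draw_sigma(n, sum((lw - mu)^2), spec, u_sigma)
    if (it > burnin) keep[it - burnin, ] <- c(mu, sigma)
  }
  keep
}

## ---- amounts block ----------------------------------------------------------

sample_amounts_block <- function(data, spec, init, ch, fixed = NULL) {
  n_keep <- spec$iter; burnin <- spec$burnin
  total <- n_keep + burnin
  foods <- data$foods; nf <- length(foods)
  nu0 <- nf + 1          # inverse-Wishart df giving uniform marginal correlations
  s0 <- diag(nf)

  amounts <- as.matrix(data$diary[foods])
  w <- data$weights$weight[match(data$diary$respondent,
                                 data$weights$respondent)]
  obs <- amounts > 0
  keep_day <- rowSums(obs) > 0           # all-zero days carry no amount information
  y <- log(amounts / w)
  y <- y[keep_day, , drop = FALSE]
  obs <- obs[keep_day, , drop = FALSE]
  resp <- unique(data$diary$respondent)
  nr <- length(resp)
  ridx <- match(data$diary$respondent[keep_day], resp)
  nday <- nrow(y)

  # group day rows by missingness pattern for vectorised conditional imputation
  pattern <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  pat_groups <- split(seq_len(nday), pattern)
  pat_obs <- lapply(pat_groups, function(rows) which(obs[rows[1L], ]))

  kd <- tabulate(ridx, nbins = nr)       # informative days per respondent
  kd_groups <- split(seq_len(nr), kd)

  mu0 <- jitter_init(init$mu0, ch, 0.1)
  C_s <- fixed$C_s %||% init$C_s
  C_mu <- fixed$C_mu %||% init$C_mu
  mu_r <- matrix(rep(mu0, each = nr), nr, nf)
  y[!obs] <- mu_r[ridx, ][!obs]

  keep <- matrix(NA_real_, n_keep, nf + nf * (nf + 1L))
  colnames(keep) <- c(sprintf("mu0[%s]", foods),
                      cov_param_names("Cs", foods),
                      cov_param_names("Cmu", foods))

  for (it in seq_len(total)) {
    cs_inv <- chol2inv(chol(C_s))
    cmu_inv <- chol2inv(chol(C_mu))

    # -- impute zero (missing) coordinates from their conditional MVN
    for (g in seq_along(pat_groups)) {
      o <- pat_obs[[g]]
      m <- setdiff(seq_len(nf), o)
      if (!length(m)) next
      rows <- pat_groups[[g]]
      b <- C_s[m, o, drop = FALSE] %*% solve(C_s[o, o, drop = FALSE])
      cond <- C_s[m, m, drop = FALSE] - b %*% C_s[o, m, drop = FALSE]
      mean_m <- mu_r[ridx[rows], m, drop = FALSE] +
        (y[rows, o, drop = FALSE] - mu_r[ridx[rows], o, drop = FALSE]) %*% t(b)
      y[rows, m] <- mean_m +
        matrix(stats::rnorm(length(rows) * length(m)), ncol = length(m)) %*%
          chol(cond)
    }

    # -- consumer means, grouped by number of informative days
    sum_y <- matrix(0, nr, nf)
    rs <- rowsum(y, ridx)
    sum_y[as.integer(rownames(rs)), ] <- rs
    for (kg in seq_along(kd_groups)) {
      k <- as.integer(names(kd_groups)[kg])
      rows <- kd_groups[[kg]]
      if (k == 0L) {
        mu_r[rows, ] <- rmvnorm_chol(length(rows), mu0, C_mu)
        next
      }
      prec <- k * cs_inv + cmu_inv
      cov_k <- chol2inv(chol(prec))
      bmat <- sum_y[rows, , drop = FALSE] %*% cs_inv +
        matrix(rep(as.numeric(cmu_inv %*% mu0), each = length(rows)),
               nrow = length(rows))
      mu_r[rows, ] <- bmat %*% cov_k +
        matrix(stats::rnorm(length(rows) * nf), ncol = nf) %*% chol(cov_k)
    }

    # -- population mean (wide normal prior)
    prec0 <- nr * cmu_inv + diag(1e-6, nf)
    cov0 <- chol2inv(chol(prec0))
    mean0 <- cov0 %*% (cmu_inv %*% colSums(mu_r))
    mu0 <- as.numeric(mean0 + t(chol(cov0)) %*% stats::rnorm(nf))

    # -- covariances (inverse-Wishart, conjugate)
    if (is.null(fixed$C_mu)) {
      sc <- crossprod(sweep(mu_r, 2L, mu0))
      C_mu <- riwish(nu0 + nr, s0 + sc)
    }
    if (is.null(fixed$C_s)) {
      sc <- crossprod(y - mu_r[ridx, , drop = FALSE])
      C_s <- riwish(nu0 + nday, s0 + sc)
    }

    if (it > burnin) {
      keep[it - burnin, ] <- c(mu0, cov_to_vec(C_s, "Cs", foods),
                               cov_to_vec(C_mu, "Cmu", foods))
    }
  }
  keep
}

## ---- frequency block --------------------------------------------------------

sample_frequency_block <- function(data, spec, init, ch, fixed = NULL) {
  if (spec$frequency_option == "markov") {
    sample_frequency_markov(data, spec)
  } else {
    sample_frequency_independent(data, spec, init, ch, fixed)
  }
}

# conjugate: both transition probabilities are Beta draws given the pooled
# transition counts, i.i.d. across iterations
sample_frequency_markov <- function(data, spec) {
  n_keep <- spec$iter
  counts <- transition_counts(data$diary)
  total <- n_keep + spec$burnin
  cols <- purrr::pmap(counts, function(food, x01, n0, x11, n1) {
    m <- cbind(stats::rbeta(total, x01 + 1, n0 - x01 + 1),
               stats::rbeta(total, x11 + 1, n1 - x11 + 1))[
                 (spec$burnin + 1):total, , drop = FALSE]
    colnames(m) <- sprintf(c("p01[%s]", "p11[%s]"), food)
    m
  })
  do.call(cbind, cols)
}

sample_frequency_independent <- function(data, spec, init, ch, fixed = NULL) {
  n_keep <- spec$iter; burnin <- spec$burnin
  total <- n_keep + burnin
  foods <- data$foods; nf <- length(foods)
  nu0 <- nf + 1; s0 <- diag(nf)

  u <- as.matrix(data$diary[foods]) > 0
  resp <- unique(data$diary$respondent)
  nr <- length(resp)
  ridx <- match(data$diary$respondent, resp)
  k_cons <- matrix(0, nr, nf)
  rs <- rowsum(u + 0, ridx)
  k_cons[as.integer(rownames(rs)), ] <- rs
  nd_r <- tabulate(ridx, nbins = nr)

  eta0 <- jitter_init(logit(init$p0), ch, 0.1)
  C_p <- fixed$C_p %||% init$C_p
  # start consumer logits at the observed fraction, clamped
  eta <- logit(pmin(pmax(sweep(k_cons, 1L, pmax(nd_r, 1L), `/`), 0.05), 0.95))
  step <- 0.8

  keep <- matrix(NA_real_, n_keep, nf + nf * (nf + 1L) / 2L)
  colnames(keep) <- c(sprintf("p0[%s]", foods), cov_param_names("Cp", foods))

  bern_ll <- function(e) {
    rowSums(k_cons * stats::plogis(e, log.p = TRUE) +
              (nd_r - k_cons) * stats::plogis(-e, log.p = TRUE))
  }
  for (it in seq_len(total)) {
    cp_chol <- chol(C_p)
    quad <- function(e) {
      z <- backsolve(cp_chol, t(sweep(e, 2L, eta0)), transpose = TRUE)
      0.5 * colSums(z^2)
    }
    # -- random-walk Metropolis on consumer logits, vectorised by consumer;
    # several sweeps per scan since the binary data give the logits little
    # likelihood information and the hierarchy updates lean on them
    for (sweep in 1:3) {
      prop <- eta + matrix(stats::rnorm(nr * nf, 0, step), nr, nf)
      log_ratio <- bern_ll(prop) - bern_ll(eta) - quad(prop) + quad(eta)
      acc <- log(stats::runif(nr)) < log_ratio
      eta[acc, ] <- prop[acc, ]
      if (it <= burnin) step <- step * exp(0.05 * (mean(acc) - 0.35))
    }

    # -- population logit mean and covariance
    cp_inv <- chol2inv(cp_chol)
    prec0 <- nr * cp_inv + diag(1e-6, nf)
    cov0 <- chol2inv(chol(prec0))
    mean0 <- cov0 %*% (cp_inv %*% colSums(eta))
    eta0 <- as.numeric(mean0 + t(chol(cov0)) %*% stats::rnorm(nf))
    if (is.null(fixed$C_p)) {
      sc <- crossprod(sweep(eta, 2L, eta0))
      C_p <- riwish(nu0 + nr, s0 + sc)
    }
    if (it > burnin) {
      keep[it - burnin, ] <- c(inv_logit(eta0), cov_to_vec(C_p, "Cp", foods))
    }
  }
  keep
}
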