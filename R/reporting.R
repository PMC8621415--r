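# Model-versus-data validation summaries and plots.

#' Lower- and upper-bound empirical CDFs of censored concentrations
#'
#' With censored records the empirical distribution of the data is only
#' known up to bounds. The lower-bound substitution puts non-detects at a
#' configurable floor (default `lod / floor_divisor`, since zero cannot be
#' plotted on a log axis) and interval-censored records at their LOD; the
#' upper-bound substitution puts non-detects at the LOD and
#' interval-censored records at their LOQ. The two step functions bracket
#' every ECDF compatible with the censoring: at any concentration the
#' lower-substitution ECDF is at least the upper-substitution ECDF.
#'
#' @param records Occurrence tibble for one hazard--food pair.
#' @param floor_divisor Non-detects are placed at `lod / floor_divisor`
#'   under lower-bound substitution (default 100).
#' @return A tibble with columns `bound` (`"lower"`/`"upper"`) and `value`
#'   (the substituted concentrations); attribute `"ecdf"` holds the two step
#'   functions.
#' @export
empirical_cdf_bounds <- function(records, floor_divisor = 100) {
  sub_lower <- dplyr::case_when(
    records$censor == "exact" ~ records$value,
    records$censor == "interval" ~ records$lod,
    TRUE ~ records$lod / floor_divisor
  )
  sub_upper <- dplyr::case_when(
    records$censor == "exact" ~ records$value,
    records$censor == "interval" ~ records$loq,
    TRUE ~ records$lod
  )
  out <- dplyr::bind_rows(
    tibble::tibble(bound = "lower", value = sub_lower),
    tibble::tibble(bound = "upper", value = sub_upper)
  )
  attr(out, "ecdf") <- list(lower = stats::ecdf(sub_lower),
                            upper = stats::ecdf(sub_upper))
  out
}

#' Bootstrapped pseudo-empirical exposure distributions
#'
#' Occurrence and consumption are two unrelated data sources, so no observed
#' exposures exist to validate against. A non-parametric stand-in is built
#' by resampling each data set with replacement, pairing random
#' concentration and consumption values independently, and multiplying;
#' repeating over bootstrap replicates visualises the sampling uncertainty
#' of this pseudo-empirical exposure distribution. Censored concentrations
#' enter by lower- or upper-bound substitution.
#'
#' @param records Occurrence tibble for one hazard--food pair.
#' @param diary,weights Consumption tables; only positive amounts of `food`
#'   are used.
#' @param food Food column of the diary to pair with.
#' @param b Number of bootstrap replicates.
#' @param bound `"lower"` or `"upper"` substitution for censored records.
#' @param per_bw Divide amounts by body weight (chemical convention,
#'   default `TRUE`); otherwise absolute amounts (microbiological).
#' @param n_products Random products drawn per replicate (default: size of
#'   the smaller data set).
#' @return A tibble with columns `replicate` and `exposure`.
#' @export
bootstrap_pseudo_exposure <- function(records, diary, weights, food, b = 20L,
                                      bound = c("lower", "upper"),
                                      per_bw = TRUE, n_products = NULL) {
  bound <- match.arg(bound)
  subs <- empirical_cdf_bounds(records)
  conc <- subs$value[subs$bound == bound]
  amounts <- diary[[food]]
  pos <- amounts > 0
  amounts <- amounts[pos]
  if (per_bw) {
    w <- weights$weight[match(diary$respondent, weights$respondent)][pos]
    amounts <- amounts / w
  }
  if (!length(amounts)) stop("no positive consumption of ", food, call. = FALSE)
  n_products <- n_products %||% min(length(conc), length(amounts))
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  purrr::map_dfr(seq_len(b), function(i) {
    cb <- resample(conc, length(conc))
    ab <- resample(amounts, length(amounts))
    tibble::tibble(
      replicate = i,
      exposure = resample(cb, n_products) * resample(ab, n_products)
    )
  })
}

## ---- plots ------------------------------------------------------------------

#' Overlay plot of posterior concentration distributions against data
#'
#' Cumulative distribution functions of the positive concentration
#' distribution for a sample of posterior draws (visualising uncertainty of
#' the variability distribution), together with the lower/upper-bound
#' empirical CDFs of the data and a prevalence estimate in the subtitle.
#'
#' @param fit A `bde_fit` with occurrence data attached.
#' @param hazard,food Pair selection.
#' @param n_curves Number of posterior draws to overlay (default 20).
#' @param log_scale Plot the log10 axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_concentration_fit <- function(fit, hazard, food, n_curves = 20L,
                                   log_scale = TRUE) {
  occ <- pair_cols(fit, hazard, food)
  n_draws <- length(occ$mu)
  rows <- round(seq(1L, n_draws, length.out = min(n_curves, n_draws)))
  grid_q <- seq(0.005, 0.995, length.out = 200L)
  curves <- purrr::map_dfr(rows, function(i) {
    tibble::tibble(draw = i, p = grid_q,
                   value = exp(stats::qnorm(grid_q, occ$mu[i], occ$sigma[i])))
  })
  gg <- ggplot2::ggplot(curves,
                        ggplot2::aes(x = .data$value, y = .data$p,
                                     group = .data$draw)) +
    ggplot2::geom_line(alpha = 0.3, colour = "magenta3") +
    ggplot2::labs(
      x = paste0("concentration", unit_label(fit, hazard, food)),
      y = "cumulative probability",
      title = paste("Positive concentration:", hazard, "in", food),
      subtitle = sprintf("posterior mean prevalence %.2f", mean(occ$q))
    )
  if (!is.null(fit$data) && !is.null(fit$data$occurrence)) {
    recs <- pair_records(fit$data$occurrence, hazard, food)
    if (nrow(recs)) {
      subs <- empirical_cdf_bounds(recs)
      gg <- gg + ggplot2::stat_ecdf(
        data = subs,
        ggplot2::aes(x = .data$value, colour = .data$bound, group = .data$bound),
        inherit.aes = FALSE
      )
    }
  }
  if (log_scale) gg <- gg + ggplot2::scale_x_log10()
  gg
}

unit_label <- function(fit, hazard, food) {
  if (is.null(fit$data) || is.null(fit$data$occurrence)) return("")
  u <- unique(pair_records(fit$data$occurrence, hazard, food)$unit)
  if (length(u) == 1L) paste0(" [", u, "]") else ""
}

#' Overlay plot of exposure CDFs with mean/median uncertainty
#'
#' Positive-exposure cumulative distributions for a sample of posterior
#' draws of a single hazard--food pair (closed-form log-normal), with the
#' uncertainty distributions of the exposure mean and median drawn as rug
#' marks, and the estimated exposure frequency in the subtitle. Zeros are
#' excluded from the plotted support (distributions are for positives
#' only); the zero-inclusive exposure frequency is reported numerically.
#'
#' @param fit A `bde_fit`.
#' @param hazard,food Pair selection.
#' @param type `"acute"` or `"chronic"` (defaults to the hazard's type).
#' @param n_curves Number of overlaid posterior draws (default 20).
#' @param factors Optional [adjustment_factors()].
#' @return A ggplot object.
#' @export
plot_exposure_cdf <- function(fit, hazard, food, type = NULL, n_curves = 20L,
                              factors = NULL) {
  type <- type %||% unname(
    if (!is.null(names(fit$hazard_type))) fit$hazard_type[[hazard]]
    else fit$hazard_type[1L])
  pair_fun <- if (type %in% c("microbiological", "acute")) acute_pair else chronic_pair
  pd <- pair_fun(fit, hazard, food, factors)
  rows <- round(seq(1L, nrow(pd), length.out = min(n_curves, nrow(pd))))
  grid_q <- seq(0.005, 0.995, length.out = 200L)
  curves <- purrr::map_dfr(rows, function(i) {
    tibble::tibble(draw = i, p = grid_q,
                   value = exp(stats::qnorm(grid_q, pd$ln_mu[i],
                                            sqrt(pd$ln_var[i]))))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value, y = .data$p,
                                       group = .data$draw)) +
    ggplot2::geom_line(alpha = 0.3, colour = "magenta3") +
    ggplot2::geom_rug(data = tibble::tibble(value = pd$mean),
                      ggplot2::aes(x = .data$value), inherit.aes = FALSE,
                      colour = "grey40", alpha = 0.3, sides = "b") +
    ggplot2::geom_rug(data = tibble::tibble(value = pd$median),
                      ggplot2::aes(x = .data$value), inherit.aes = FALSE,
                      colour = "black", alpha = 0.3, sides = "t") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "positive exposure", y = "cumulative probability",
      title = paste0(ifelse(type %in% c("microbiological", "acute"),
                            "Acute", "Chronic"),
                     " exposure: ", hazard, " via ", food),
      subtitle = sprintf("estimated exposure frequency %.3f (mean of p*q)",
                         mean(pd$exposure_freq))
    )
}

#' Scatter plot of observed versus simulated consumption pairs
#'
#' Pairwise log consumption amounts on jointly positive days: observed diary
#' points against points simulated from the fitted consumption model, to
#' judge whether the between-food correlation is captured.
#'
#' @param fit A `bde_fit` with consumption data attached.
#' @param food_x,food_y The two foods.
#' @param n_sim Number of simulated days (default 500).
#' @return A ggplot object.
#' @export
plot_consumption_pairs <- function(fit, food_x, food_y, n_sim = 500L) {
  stopifnot(!is.null(fit$data))
  diary <- fit$data$diary
  w <- fit$data$weights$weight[match(diary$respondent,
                                     fit$data$weights$respondent)]
  pos <- diary[[food_x]] > 0 & diary[[food_y]] > 0
  obs <- tibble::tibble(source = "data",
                        x = log(diary[[food_x]][pos] / w[pos]),
                        y = log(diary[[food_y]][pos] / w[pos]))
  rows <- round(seq(1L, nrow(fit$draws), length.out = n_sim))
  sel <- c(food_x, food_y)
  sim <- purrr::map_dfr(rows, function(i) {
    par <- draw_params(fit, i)
    mu_r <- rmvnorm_chol(1L, par$mu0[sel], par$C_mu[sel, sel])
    y <- mu_r + rmvnorm_chol(1L, c(0, 0), par$C_s[sel, sel])
    tibble::tibble(source = "model", x = y[1L], y = y[2L])
  })
  ggplot2::ggplot(dplyr::bind_rows(obs, sim),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$source)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(data = "blue", model = "magenta3")) +
    ggplot2::labs(x = paste("log", food_x, "per bw"),
                  y = paste("log", food_y, "per bw"),
                  title = "Consumption amounts on jointly positive days")
}

#' @rdname plot_exposure_cdf
#' @param object,... `autoplot` method arguments: a `bde_fit` plus the
#'   arguments of [plot_exposure_cdf()].
#' @method autoplot bde_fit
#' @export
autoplot.bde_fit <- function(object, hazard, food, ...) {
  plot_exposure_cdf(object, hazard, food, ...)
}
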