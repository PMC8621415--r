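#' Tidy a fitted exposure model
#'
#' One row per scalar parameter with posterior mean, sd, median, central 95%
#' credible interval and convergence diagnostics.
#'
#' @param x A `bde_fit` from [sample_posterior()].
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate` (posterior mean),
#'   `std.error` (posterior sd), `median`, `conf.low`, `conf.high`, `rhat`,
#'   `ess`.
#' @method tidy bde_fit
#' @export
tidy.bde_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  diag_tbl <- suppressMessages(diagnostics(x))
  draws <- x$draws
  ci <- purrr::map_dfr(diag_tbl$parameter, function(p) {
    qs <- stats::quantile(draws[[p]], c(a, 0.5, 1 - a), names = FALSE)
    tibble::tibble(median = qs[2L], conf.low = qs[1L], conf.high = qs[3L])
  })
  tibble::tibble(
    parameter = diag_tbl$parameter,
    estimate = diag_tbl$mean, std.error = diag_tbl$sd,
    median = ci$median, conf.low = ci$conf.low, conf.high = ci$conf.high,
    rhat = diag_tbl$rhat, ess = diag_tbl$ess
  )
}

#' Glance at a fitted exposure model
#'
#' @param x A `bde_fit`.
#' @param ... Unused.
#' @return A one-row tibble: chains, retained iterations, parameter count,
#'   worst R-hat, smallest effective sample size, seed.
#' @method glance bde_fit
#' @export
glance.bde_fit <- function(x, ...) {
  d <- suppressMessages(diagnostics(x))
  tibble::tibble(
    n_chains = max(x$draws$.chain),
    n_iter = max(x$draws$.iter),
    n_parameters = nrow(d),
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_ess = min(d$ess, na.rm = TRUE),
    seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
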