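#' Convergence diagnostics for a posterior sample
#'
#' Computes the split-R-hat statistic and an effective sample size for every
#' scalar parameter (each chain is split in half, so R-hat is informative
#' even for a single chain), and flags parameters with R-hat above a
#' threshold. Diagnostics never stop or truncate a run -- they only report;
#' with weakly identified regimes (for instance heavily censored
#' zero-inflated occurrence data, which can produce bimodal posteriors)
#' re-running with different lengths and comparing is the recommended
#' practice.
#'
#' @param fit A `bde_fit` from [sample_posterior()].
#' @param rhat_warn Threshold above which a parameter is flagged
#'   (default 1.05).
#' @return A tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `rhat`, `ess`, `flagged`. The flagged subset is also attached as
#'   attribute `"warnings"` and printed as a message when non-empty.
#' @export
diagnostics <- function(fit, rhat_warn = 1.05) {
  draws <- fit$draws
  params <- setdiff(names(draws), c(".chain", ".iter"))
  out <- purrr::map_dfr(params, function(p) {
    m <- matrix(draws[[p]], ncol = max(draws$.chain))
    tibble::tibble(
      parameter = p,
      mean = mean(m), sd = stats::sd(m),
      rhat = split_rhat(m), ess = ess_basic(m)
    )
  })
  out$flagged <- !is.na(out$rhat) & out$rhat > rhat_warn
  if (any(out$flagged)) {
    message("possible non-convergence (R-hat > ", rhat_warn, ") for: ",
            paste(out$parameter[out$flagged], collapse = ", "),
            " -- consider longer or repeated runs")
  }
  attr(out, "warnings") <- out$parameter[out$flagged]
  out
}

# split-R-hat: halve each chain, compare between- and within-half variances
split_rhat <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[(n - half + 1):n, , drop = FALSE])
  w <- mean(apply(sub, 2L, stats::var))
  b <- half * stats::var(colMeans(sub))
  if (!is.finite(w) || w == 0) {
    # degenerate within-chain variance: identical constants across chains are
    # converged; different constants are maximally divergent
    return(if (isTRUE(all.equal(max(sub), min(sub)))) 1 else Inf)
  }
  sqrt(((half - 1) / half * w + b / half) / w)
}

# effective sample size via chain-averaged autocorrelations with Geyer-style
# truncation at the first negative paired sum
ess_basic <- function(m) {
  n <- nrow(m); nch <- ncol(m)
  if (n < 4L) return(NA_real_)
  v <- apply(m, 2L, stats::var)
  if (all(v == 0)) return(NA_real_)
  max_lag <- min(n - 2L, 200L)
  rho <- rowMeans(vapply(seq_len(nch), function(ch) {
    a <- stats::acf(m[, ch], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
    as.numeric(a)
  }, numeric(max_lag)))
  s <- 0
  for (k in seq(1L, max_lag - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  min(n * nch, n * nch / (1 + 2 * s))
}

#' Write posterior draws to a columnar text file
#'
#' One row per retained draw, columns `.chain`, `.iter` and every scalar
#' parameter; a JSON sidecar (`<path>.meta.json`) stores the model options
#' needed to rebuild a `bde_fit`, so exposure assessment and reporting can
#' run later without refitting.
#'
#' @param fit A `bde_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  readr::write_csv(fit$draws, path)
  meta <- list(
    foods = fit$foods,
    hazard_type = as.list(fit$spec$hazard_type),
    occurrence_option = fit$spec$occurrence_option,
    frequency_option = fit$spec$frequency_option,
    active = fit$spec$active,
    chains = fit$spec$chains, iter = fit$spec$iter,
    burnin = fit$spec$burnin, seed = fit$spec$seed
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' Rebuild a fit object from saved draws
#'
#' @param path CSV path written by [write_draws()].
#' @return A `bde_fit` (without the original data tables).
#' @export
read_draws <- function(path) {
  draws <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  spec <- structure(
    list(occurrence_option = meta$occurrence_option,
         frequency_option = meta$frequency_option,
         active = meta$active,
         hazard_type = unlist(meta$hazard_type),
         chains = meta$chains, iter = meta$iter, burnin = meta$burnin,
         seed = meta$seed, sigma_prior = "uniform"),
    class = "bde_spec"
  )
  pairs <- parse_pair_columns(names(draws))
  structure(
    list(draws = draws, spec = spec, data = NULL, foods = meta$foods,
         pairs = pairs, hazard_type = spec$hazard_type, seed = meta$seed),
    class = "bde_fit"
  )
}

parse_pair_columns <- function(nms) {
  m <- regmatches(nms, regexec("^occ_mu\\[([^,]+),(.+)\\]$", nms))
  hits <- purrr::keep(m, ~ length(.x) == 3L)
  if (!length(hits)) {
    m <- regmatches(nms, regexec("^q\\[([^,]+),(.+)\\]$", nms))
    hits <- purrr::keep(m, ~ length(.x) == 3L)
  }
  if (!length(hits)) return(NULL)
  tibble::tibble(hazard = purrr::map_chr(hits, 2L),
                 food = purrr::map_chr(hits, 3L))
}
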