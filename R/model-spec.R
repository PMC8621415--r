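#' Build a model specification from the data features
#'
#' The model fitted by [sample_posterior()] is assembled automatically from
#' the data: every likelihood component with at least one matching data
#' instance is switched on, and nothing else. Exact concentration values
#' activate the exact-value term, interval-censored rows the interval term,
#' non-detects the below-LOD term, a prevalence sample the binomial term, and
#' the consumption tables the body-weight, amount and frequency terms. The
#' same inputs always produce the same specification.
#'
#' @param data A [bde_data()] bundle.
#' @param occurrence_option `"separate"`: all reported measurements are taken
#'   as true positives and prevalence is estimated from a separate binomial
#'   sample (components L1--L4). `"zero_inflated"`: non-detects may be true
#'   zeros, prevalence and concentration parameters are estimated jointly
#'   from the censored records (components L5--L7).
#' @param frequency_option `"independent"`: consumption events on different
#'   diary days are independent Bernoulli draws with correlated logit-normal
#'   per-consumer frequencies. `"markov"`: consumption on a day depends on
#'   the previous (consecutive) day through a common transition matrix per
#'   food; requires consecutive integer day indices per respondent.
#' @param hazard_type Named character vector mapping each hazard id to
#'   `"chemical"` or `"microbiological"`; a single unnamed value recycles to
#'   all hazards. Chemical hazards get chronic exposure, microbiological get
#'   acute.
#' @param chains,iter,burnin MCMC settings: number of chains, retained
#'   iterations per chain after discarding `burnin`.
#' @param seed Integer seed making the whole run reproducible.
#' @param sigma_prior `"uniform"` (default): uniform prior on the
#'   concentration log-sd with a data-derived upper bound (see
#'   [sigma_upper_bound()]); `"gamma"`: Gamma(`gamma_a`, `gamma_b`) prior on
#'   the inverse variance.
#' @param gamma_a,gamma_b Hyperparameters of the gamma precision prior.
#' @param factors Optional adjustment-factor table, see
#'   [adjustment_factors()].
#' @return An object of class `bde_spec` with the set of active likelihood
#'   components in `$active`.
#' @export
#' @examples
#' d <- generate_dataset(default_truth("chemical-like"), seed = 1)
#' model_spec(d, occurrence_option = "separate")$active
model_spec <- function(data,
                       occurrence_option = c("separate", "zero_inflated"),
                       frequency_option = c("independent", "markov"),
                       hazard_type = "chemical",
                       chains = 2L, iter = 2000L, burnin = 1000L,
                       seed = 1L,
                       sigma_prior = c("uniform", "gamma"),
                       gamma_a = 0.01, gamma_b = 0.01,
                       factors = NULL) {
  stopifnot(inherits(data, "bde_data"))
  occurrence_option <- match.arg(occurrence_option)
  frequency_option <- match.arg(frequency_option)
  sigma_prior <- match.arg(sigma_prior)

  active <- character(0)
  occ <- data$occurrence
  if (!is.null(occ)) {
    has <- table(factor(occ$censor, levels = c("exact", "interval", "nd"))) > 0
    if (occurrence_option == "separate") {
      if (is.null(data$prevalence)) {
        stop("occurrence_option = 'separate' needs a prevalence sample per ",
             "hazard-food pair; none supplied. Use 'zero_inflated' or ",
             "provide prevalence data.", call. = FALSE)
      }
      active <- c(active,
                  if (has[["exact"]]) "L1",
                  if (has[["interval"]]) "L2",
                  if (has[["nd"]]) "L3")
    } else {
      active <- c(active,
                  if (has[["nd"]]) "L5",
                  if (has[["interval"]]) "L6",
                  if (has[["exact"]]) "L7")
    }
    pairs <- unique(occ[c("hazard", "food")])
    if (occurrence_option == "separate") {
      merged <- dplyr::inner_join(pairs, data$prevalence,
                                  by = c("hazard", "food"))
      if (nrow(merged) < nrow(pairs)) {
        stop("occurrence_option = 'separate' requires a prevalence sample ",
             "for every hazard-food pair", call. = FALSE)
      }
    }
  }
  if (!is.null(data$prevalence)) active <- c(active, "L4")
  if (!is.null(data$weights)) active <- c(active, "Lw")
  if (!is.null(data$diary)) {
    active <- c(active, "Lr",
                if (frequency_option == "independent") "Ljr" else "Lj")
    if (frequency_option == "markov") {
      check_consecutive_days(data$diary)
    }
  }

  hazards <- if (!is.null(occ)) unique(occ$hazard) else character(0)
  hazard_type <- resolve_hazard_type(hazard_type, hazards)

  structure(
    list(
      occurrence_option = occurrence_option,
      frequency_option = frequency_option,
      active = active,
      hazard_type = hazard_type,
      chains = as.integer(chains), iter = as.integer(iter),
      burnin = as.integer(burnin), seed = as.integer(seed),
      sigma_prior = sigma_prior, gamma_a = gamma_a, gamma_b = gamma_b,
      factors = factors
    ),
    class = "bde_spec"
  )
}

resolve_hazard_type <- function(hazard_type, hazards) {
  hazard_type <- tolower(hazard_type)
  if (!all(hazard_type %in% c("chemical", "microbiological"))) {
    stop("hazard_type must be 'chemical' or 'microbiological'", call. = FALSE)
  }
  if (!length(hazards)) return(hazard_type)
  if (is.null(names(hazard_type))) {
    if (length(hazard_type) != 1L) {
      stop("unnamed hazard_type must be a single value", call. = FALSE)
    }
    return(stats::setNames(rep(hazard_type, length(hazards)), hazards))
  }
  missing_h <- setdiff(hazards, names(hazard_type))
  if (length(missing_h)) {
    stop("hazard_type missing for: ", paste(missing_h, collapse = ", "),
         call. = FALSE)
  }
  hazard_type[hazards]
}

check_consecutive_days <- function(diary) {
  ok <- tapply(diary$day, diary$respondent, function(d) {
    d <- sort(d)
    length(d) < 2L || all(diff(d) == 1L)
  })
  if (!all(ok)) {
    stop("frequency_option = 'markov' requires consecutive day indices per ",
         "respondent; offending respondent(s): ",
         paste(utils::head(names(ok)[!ok], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.bde_spec <- function(x, ...) {
  cat("<bde_spec>\n")
  cat("  occurrence:", x$occurrence_option,
      "| frequency:", x$frequency_option, "\n")
  cat("  active likelihood components:",
      paste(x$active, collapse = " "), "\n")
  cat("  mcmc:", x$chains, "chain(s) x", x$iter, "retained after",
      x$burnin, "burn-in, seed", x$seed, "\n")
  invisible(x)
}
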