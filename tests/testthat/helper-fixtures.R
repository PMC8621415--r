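# Small fixtures built in code, shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

occ_row <- function(hazard = "haz", food = "food", value = NA_real_,
                    censor = "nd", lod = 0.5, loq = 1, unit = "mg/kg") {
  tibble::tibble(hazard = hazard, food = food, value = value,
                 censor = censor, lod = lod, loq = loq, unit = unit)
}

# three-record table: one exact, one interval, one non-detect
small_occurrence <- function() {
  dplyr::bind_rows(
    occ_row(value = 5, censor = "exact"),
    occ_row(censor = "interval"),
    occ_row(censor = "nd")
  )
}

small_diary <- function() {
  tibble::tibble(
    respondent = rep(c("a", "b"), each = 2L),
    day = rep(1:2, 2L),
    bread = c(120, 0, 80, 95),
    milk = c(200, 180, 0, 0)
  )
}

small_weights <- function() {
  tibble::tibble(respondent = c("a", "b"), weight = c(70, 82))
}

# a reduced truth for fast end-to-end fits in tests
small_truth <- function(preset = "chemical-like", nr = 60L, n_occ = 80L,
                        n_prev = 60L) {
  truth <- default_truth(preset)
  truth$counts$nr <- as.integer(nr)
  truth$counts$n_occ <- as.integer(n_occ)
  if (truth$counts$n_prev > 0) truth$counts$n_prev <- as.integer(n_prev)
  truth
}

fast_fit <- function(preset = "chemical-like", seed = 11, iter = 400L,
                     burnin = 200L, chains = 2L, nr = 60L, ...) {
  truth <- small_truth(preset, nr = nr)
  d <- generate_dataset(truth, seed = seed)
  is_chem <- preset == "chemical-like"
  spec <- model_spec(
    d,
    occurrence_option = if (is_chem) "separate" else "zero_inflated",
    frequency_option = if (is_chem) "independent" else "markov",
    hazard_type = if (is_chem) "chemical" else "microbiological",
    chains = chains, iter = iter, burnin = burnin, seed = seed, ...
  )
  sample_posterior(d, spec)
}
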