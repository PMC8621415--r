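test_that("moment-based initialisation is sane on standard and edge data", {
  d <- generate_dataset(small_truth(), seed = 8)
  spec <- model_spec(d, "separate", hazard_type = "chemical", seed = 8)
  init <- init_params(d, spec)
  # all-exact pair: init mu is the mean of observed logs
  occ_exact <- dplyr::bind_rows(occ_row(value = 5, censor = "exact"),
                                occ_row(value = 9, censor = "exact"))
  d2 <- bde_data(occurrence = occ_exact)
  init2 <- init_params(d2, model_spec(d2, "zero_inflated"))
  expect_equal(init2$occurrence[[1]]$mu, mean(log(c(5, 9))))

  # saturated prevalence sample: q init clamped below 1
  prev <- tibble::tibble(hazard = "haz", food = "food",
                         positive = 10L, total = 10L)
  d3 <- bde_data(occurrence = occ_exact, prevalence = prev)
  init3 <- init_params(d3, model_spec(d3, "separate"))
  expect_lt(init3$occurrence[[1]]$q, 1)

  # consumption init: diagonal covariances from sample variances
  expect_true(all(diag(init$amounts$C_s) > 0))
  expect_true(all(init$frequency$p0 > 0 & init$frequency$p0 < 1))
})

test_that("prevalence-only posterior is exactly the conjugate Beta", {
  prev <- tibble::tibble(hazard = "h", food = "f", positive = 7L, total = 25L)
  d <- bde_data(prevalence = prev)
  spec <- model_spec(d, "separate", chains = 1, iter = 5000, burnin = 200,
                     seed = 31)
  fit <- sample_posterior(d, spec)
  q <- fit$draws[["q[h,f]"]]
  set.seed(99)
  ref <- rbeta(5000, 7 + 1, 25 - 7 + 1)
  ks <- suppressWarnings(ks.test(q, ref))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(q > 0 & q < 1))
})

test_that("markov transition posteriors are the conjugate Betas", {
  truth <- small_truth("micro-like", nr = 80L)
  cons <- generate_consumption(truth, seed = 12)
  d <- bde_data(diary = cons$diary, weights = cons$weights)
  spec <- model_spec(d, frequency_option = "markov", chains = 1, iter = 5000,
                     burnin = 100, seed = 13)
  fit <- sample_posterior(d, spec)
  counts <- transition_counts(cons$diary)
  for (i in seq_len(nrow(counts))) {
    f <- counts$food[i]
    set.seed(1000 + i)
    ref <- rbeta(5000, counts$x01[i] + 1, counts$n0[i] - counts$x01[i] + 1)
    ks <- suppressWarnings(ks.test(fit$draws[[sprintf("p01[%s]", f)]], ref))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("fixed seed reproduces draws bit-identically", {
  f1 <- fast_fit(seed = 21, iter = 50L, burnin = 30L, nr = 30L)
  f2 <- fast_fit(seed = 21, iter = 50L, burnin = 30L, nr = 30L)
  expect_identical(f1$draws, f2$draws)
  f3 <- fast_fit(seed = 22, iter = 50L, burnin = 30L, nr = 30L)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("occurrence draws are identical with or without co-sampled consumption", {
  truth <- small_truth()
  occ <- generate_occurrence(truth, "separate", seed = 14)
  cons <- generate_consumption(truth, seed = 14)
  d_occ <- bde_data(occurrence = occ$occurrence, prevalence = occ$prevalence)
  d_all <- bde_data(occurrence = occ$occurrence, prevalence = occ$prevalence,
                    diary = cons$diary, weights = cons$weights)
  s_occ <- model_spec(d_occ, "separate", chains = 1, iter = 200, burnin = 100,
                      seed = 5)
  s_all <- model_spec(d_all, "separate", chains = 1, iter = 200, burnin = 100,
                      seed = 5)
  f_occ <- sample_posterior(d_occ, s_occ)
  f_all <- sample_posterior(d_all, s_all)
  occ_cols <- grep("^(occ_|q\\[)", names(f_occ$draws), value = TRUE)
  expect_identical(f_occ$draws[occ_cols], f_all$draws[occ_cols])
})

test_that("hierarchy collapses to the pooled closed form when Cmu is pinned near zero", {
  # with the between-consumer covariance fixed at ~0 and the day covariance
  # fixed, consumer means coincide with the population mean, whose posterior
  # is N(pooled mean, Cs / N) under a flat prior
  truth <- small_truth(nr = 80L)
  truth$frequency$p0[] <- 0.999   # essentially no zeros
  truth$C_mu <- matrix(c(1e-8, 0, 0, 1e-8), 2, dimnames = dimnames(truth$C_mu))
  cons <- generate_consumption(truth, seed = 30)
  d <- bde_data(diary = cons$diary, weights = cons$weights)
  spec <- model_spec(d, chains = 1, iter = 3000, burnin = 200, seed = 30)
  fixed <- list(C_mu = diag(1e-8, 2), C_s = truth$C_s)
  fit <- sample_posterior(d, spec, fixed = fixed)

  amounts <- as.matrix(cons$diary[truth$foods])
  w <- cons$weights$weight[match(cons$diary$respondent,
                                 cons$weights$respondent)]
  y <- log(amounts / w)
  y[amounts == 0] <- NA
  keep <- rowSums(!is.na(y)) == 2L  # jointly positive days (p0 ~ 1: almost all)
  y <- y[keep, ]
  n <- nrow(y)
  for (j in 1:2) {
    mu_draws <- fit$draws[[sprintf("mu0[%s]", truth$foods[j])]]
    expect_equal(mean(mu_draws), mean(y[, j]), tolerance = 0.02)
    expect_equal(sd(mu_draws), sqrt(truth$C_s[j, j] / n), tolerance = 0.15)
  }
})

test_that("population frequency is recovered within posterior uncertainty", {
  truth <- small_truth(nr = 200L)
  truth$frequency$C_p <- matrix(c(0.5, 0, 0, 0.5), 2, dimnames = dimnames(truth$frequency$C_p))
  cons <- generate_consumption(truth, seed = 44)
  d <- bde_data(diary = cons$diary, weights = cons$weights)
  spec <- model_spec(d, chains = 2, iter = 800, burnin = 400, seed = 44)
  fit <- sample_posterior(d, spec)
  for (f in truth$foods) {
    draws <- fit$draws[[sprintf("p0[%s]", f)]]
    expect_lt(abs(mean(draws) - truth$frequency$p0[[f]]), 3 * sd(draws))
  }
})

test_that("inverse-Wishart prior with df = nf + 1 gives uniform correlations", {
  set.seed(77)
  nf <- 2
  rho <- replicate(2000, {
    S <- dietex:::riwish(nf + 1, diag(nf))
    S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  })
  ks <- suppressWarnings(ks.test(rho, punif, -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("heavily censored zero-inflated data run without crashing and report disagreement", {
  # ~85% non-detects: (q, mu) may be bimodal; the run must complete and the
  # diagnostics must be computable and allowed to flag chain disagreement
  set.seed(55)
  n <- 60
  conc <- exp(rnorm(n, 0, 1))
  lod <- quantile(conc, 0.9)
  loq <- lod * 1.2
  occ <- tibble::tibble(
    hazard = "h", food = "f",
    value = ifelse(conc > loq, conc, NA_real_),
    censor = ifelse(conc <= lod, "nd", ifelse(conc <= loq, "interval", "exact")),
    lod = lod, loq = loq, unit = "u"
  )
  d <- bde_data(occurrence = occ)
  spec <- model_spec(d, "zero_inflated", chains = 2, iter = 300, burnin = 150,
                     seed = 56)
  fit <- sample_posterior(d, spec)
  expect_true(all(is.finite(as.matrix(fit$draws))))
  diag_tbl <- suppressMessages(diagnostics(fit))
  expect_true(all(is.finite(diag_tbl$rhat)))
  expect_type(attr(diag_tbl, "warnings"), "character")
})

test_that("diagnostics behave on known inputs", {
  # i.i.d. pseudo-draws: rhat ~ 1
  set.seed(9)
  fake <- structure(list(draws = tibble::tibble(
    .chain = rep(1:2, each = 1000), .iter = rep(1:1000, 2),
    theta = rnorm(2000)
  )), class = "bde_fit")
  d1 <- diagnostics(fake)
  expect_true(d1$rhat > 0.99 && d1$rhat < 1.02)
  expect_lte(d1$ess, 2000)

  # two chains stuck at different constants are flagged
  fake2 <- structure(list(draws = tibble::tibble(
    .chain = rep(1:2, each = 100), .iter = rep(1:100, 2),
    theta = rep(c(0, 1), each = 100)
  )), class = "bde_fit")
  expect_message(d2 <- diagnostics(fake2), "non-convergence")
  expect_gt(d2$rhat, 1.05)
})

test_that("draws round-trip through the columnar store", {
  fit <- fast_fit(seed = 61, iter = 60L, burnin = 40L, nr = 25L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(as.data.frame(back$draws), as.data.frame(fit$draws),
               tolerance = 1e-12)
  expect_equal(back$foods, fit$foods)
  expect_equal(back$spec$frequency_option, fit$spec$frequency_option)
  expect_equal(back$pairs, fit$pairs)
})
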