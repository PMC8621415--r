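# Internal numerical helpers shared across modules.

# Probabilities are clamped away from {0, 1} (and positives away from 0)
# before logit/log transforms; 1e-12 keeps the transforms finite without
# visibly distorting any plausible estimate.
.clamp_eps <- 1e-12

logit <- function(p) {
  p <- pmin(pmax(p, .clamp_eps), 1 - .clamp_eps)
  log(p) - log1p(-p)
}

inv_logit <- function(x) stats::plogis(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# log(Phi(b) - Phi(a)) for a normal(mu, sigma), evaluated in whichever tail
# keeps the difference well conditioned. a may be -Inf.
log_pnorm_diff <- function(a, b, mu = 0, sigma = 1) {
  stopifnot(length(sigma) == 1L || length(sigma) == length(a))
  za <- (a - mu) / sigma
  zb <- (b - mu) / sigma
  out <- numeric(length(zb))
  # use the lower tail when the interval sits left of the mode, upper otherwise
  lower <- is.infinite(za) | (za + zb < 0)
  if (any(lower)) {
    la <- stats::pnorm(za[lower], log.p = TRUE)
    lb <- stats::pnorm(zb[lower], log.p = TRUE)
    out[lower] <- lb + log1p(-exp(pmin(la - lb, 0)))
  }
  if (any(!lower)) {
    la <- stats::pnorm(za[!lower], lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(zb[!lower], lower.tail = FALSE, log.p = TRUE)
    out[!lower] <- la + log1p(-exp(pmin(lb - la, 0)))
  }
  out[za >= zb] <- -Inf
  out
}

# Truncated normal draws by inverse-CDF; bounds may be +-Inf.
rtruncnorm <- function(n, mu, sigma, lower = -Inf, upper = Inf) {
  a <- stats::pnorm((lower - mu) / sigma)
  b <- stats::pnorm((upper - mu) / sigma)
  # guard against both bounds collapsing in one tail
  b <- pmax(b, a + 1e-15)
  u <- stats::runif(n, a, b)
  q <- stats::qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15))
  mu + sigma * q
}

# Multivariate normal log-density given a covariance matrix; returns -Inf for
# a non-positive-definite covariance rather than erroring (sampler-safe).
dmvnorm_log <- function(x, mean, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(-Inf, nrow(x)))
  p <- ncol(x)
  centred <- sweep(x, 2L, mean)
  z <- backsolve(ch, t(centred), transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# Draws from MVN(mean, sigma); mean may be a matrix (one row per draw).
# Positive semi-definite covariances (degenerate components) are handled via
# an eigendecomposition square root.
rmvnorm_chol <- function(n, mean, sigma) {
  p <- ncol(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen(sigma, symmetric = TRUE)
    ch <- diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  }
  z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  if (is.matrix(mean)) z + mean else sweep(z, 2L, mean, `+`)
}

# Inverse-Wishart draw: sigma ~ IW(df, scale)  <=>  sigma^-1 ~ Wishart(df, scale^-1)
riwish <- function(df, scale) {
  prec <- stats::rWishart(1L, df, solve(scale))[, , 1L]
  solve(prec)
}

# Named matrix column for a symmetric covariance: upper triangle incl. diagonal.
cov_param_names <- function(prefix, foods) {
  nf <- length(foods)
  idx <- which(upper.tri(diag(nf), diag = TRUE), arr.ind = TRUE)
  sprintf("%s[%s,%s]", prefix, foods[idx[, 1L]], foods[idx[, 2L]])
}

cov_to_vec <- function(C, prefix, foods) {
  idx <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  stats::setNames(C[idx], cov_param_names(prefix, foods))
}

vec_to_cov <- function(v, prefix, foods) {
  if (is.data.frame(v)) v <- unlist(v[1L, ])
  nf <- length(foods)
  C <- matrix(0, nf, nf, dimnames = list(foods, foods))
  idx <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  C[idx] <- as.numeric(v[cov_param_names(prefix, foods)])
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  C
}
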