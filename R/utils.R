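# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_spd <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  # tolerance relative to the largest eigenvalue only, so legitimately tiny
  # (but strictly positive definite) covariances are accepted
  all(ev > tol * max(abs(ev)))
}

assert_spd <- function(m, name = deparse(substitute(m))) {
  if (!is_spd(m)) {
    stop(sprintf("`%s` must be a symmetric positive-definite matrix", name),
         call. = FALSE)
  }
  invisible(m)
}

# n draws from N_d(mean, sigma); returns n x d matrix
rmvnorm2 <- function(n, mean, sigma) {
  d <- length(mean)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2, mean, `+`)
}

# n draws from a multivariate Student-t with df degrees of freedom,
# location `mu` and scale matrix `scale` (not the covariance).
rmvt2 <- function(n, df, mu, scale) {
  z <- rmvnorm2(n, rep(0, length(mu)), scale)
  w <- stats::rchisq(n, df) / df
  sweep(z / sqrt(w), 2, mu, `+`)
}

# Inverse-Wishart draw: X ~ IW(df, S)  <=>  X^-1 ~ Wishart(df, S^-1)
rinvwishart <- function(df, S) {
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

# Dirichlet draw via gamma normalization; alpha may contain zeros
# (zero components stay exactly 0).
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Univariate slice sampler for a log-density, one update from x0.
slice_sample1 <- function(x0, logf, w = 1, lower = 1e-12, upper = Inf,
                          max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  l <- max(lower, x0 - stats::runif(1) * w)
  r <- min(upper, l + w)
  steps <- max_steps
  while (steps > 0 && l > lower && logf(l) > y) {
    l <- max(lower, l - w); steps <- steps - 1
  }
  steps <- max_steps
  while (steps > 0 && r < upper && logf(r) > y) {
    r <- min(upper, r + w); steps <- steps - 1
  }
  repeat {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
    if (r - l < 1e-14) return(x0)
  }
}

# Uniform draw from an inclusive integer range (safe when lo == hi)
sample_range <- function(lo, hi) {
  v <- seq.int(lo, hi)
  v[sample.int(length(v), 1L)]
}

# Empirical 95% interval
ci95 <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                    na.rm = TRUE)

# Derive a reproducible child seed from a base seed and a stream index.
child_seed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k) * 7919L) %% 2147483L
}
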