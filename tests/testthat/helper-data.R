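# Fixtures built in code.

# Small fixed dataset, d = 1.
toy_data <- function() {
  mr_summary_data(
    beta_exposure = c(0.2, 0.1, 0.25),
    se_exposure = c(0.02, 0.015, 0.03),
    beta_outcome = c(0.4, -0.2, 0.5),
    se_outcome = c(0.1, 0.2, 0.3),
    variant_ids = c("rs1", "rs2", "rs3"))
}

# Summary-level draws from the asymptotic two-sample model: strong
# instruments, known SEs, optional planted pleiotropic shifts. This is the
# fast null/planted-outlier oracle used by unit and property tests.
summary_sim <- function(n = 100, d = 1, theta = if (d == 3) c(0, 1, -0.5) else 1,
                        sx = 0.05, sy = 0.05, shift = numeric(0),
                        shift_idx = integer(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bx_true <- matrix(runif(n * d, 0.5, 1.5), n, d)
  by_true <- drop(bx_true %*% theta)
  if (length(shift_idx)) by_true[shift_idx] <- by_true[shift_idx] + shift
  bx <- bx_true + matrix(rnorm(n * d, 0, sx), n, d)
  by <- by_true + rnorm(n, 0, sy)
  mr_summary_data(beta_exposure = bx,
                  se_exposure = matrix(sx, n, d),
                  beta_outcome = by, se_outcome = rep(sy, n))
}

# Independent brute-force origin-constrained WLS oracle: explicit loops over
# the normal equations, no shared code with the implementation.
wls_oracle <- function(X, y, omega) {
  X <- as.matrix(X)
  d <- ncol(X)
  A <- matrix(0, d, d)
  b <- numeric(d)
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(d)) {
      b[j] <- b[j] + X[i, j] * y[i] / omega[i]
      for (k in seq_len(d)) {
        A[j, k] <- A[j, k] + X[i, j] * X[i, k] / omega[i]
      }
    }
  }
  list(theta = drop(solve(A, b)), se = sqrt(diag(solve(A))))
}

# Brute-force weighted-median oracle via the weight CDF over sorted ratios.
weighted_median_oracle <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  p <- w[ord] / sum(w)
  S <- cumsum(p) - p / 2
  if (0.5 <= S[1]) return(r[1])
  if (0.5 >= S[length(S)]) return(r[length(r)])
  k <- max(which(S < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - S[k]) / (S[k + 1] - S[k])
}
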