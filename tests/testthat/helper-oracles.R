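# Independent oracles and tiny fixture builders shared across test files.

# Exhaustive-enumeration oracle for the shared-regulator hypergeometric test:
# draw N_i of N labelled miRNAs uniformly; the category is {1..N_j}; return
# P[overlap >= N_ij] by enumerating every draw.
hypergeom_enum_oracle <- function(N, N_i, N_j, N_ij) {
  subsets <- combn(N, N_i)
  ov <- colSums(subsets <= N_j)
  mean(ov >= N_ij)
}

# Naive O(m^2) step-up BH oracle: adj p(i) = min_{j: p_j >= p_i} m * p_j / rank_j.
bh_naive_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * sorted[j] / j, numeric(1))
    r[i] <- min(1, min(cand))
  }
  r[order(o)]
}

# Partial correlation via the inverse-correlation-matrix route (independent of
# the package's residual-regression implementation).
pcor_invmat_oracle <- function(x, y, Z) {
  omega <- solve(cor(cbind(x, y, Z)))
  -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
}

# First-order recursion for |Z| = 1.
pcor_recursion_oracle <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Mean-zero vectors with exact sample correlation structure, built from an
# orthonormal mean-zero basis (for pinning closed-form partial correlations).
exact_corr_triplet <- function(n = 20, rxy = 0.8, rxz = 0.6, ryz = 0.6) {
  raw <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  e <- sqrt(n - 1) * raw  # columns: mean 0, sd 1, mutually orthogonal
  z <- e[, 1]
  x <- rxz * e[, 1] + sqrt(1 - rxz^2) * e[, 2]
  a <- (rxy - rxz * ryz) / sqrt(1 - rxz^2)
  y <- ryz * e[, 1] + a * e[, 2] + sqrt(1 - ryz^2 - a^2) * e[, 3]
  list(x = x, y = y, z = z)
}

# Small z-scored ExpressionMatrix from a plain matrix.
zmat <- function(m, kind = "mixed") {
  sdv <- apply(m, 1, sd)
  z <- (m - rowMeans(m)) / sdv
  expression_matrix(z, kind, "zscore",
                    setNames(rep("tumor", ncol(m)), colnames(m)))
}

named_mat <- function(data, rids, sids) {
  matrix(data, length(rids), length(sids), dimnames = list(rids, sids))
}

# Reduced-cost LASSO config used across tests: 50 runs / threshold 37 keeps
# the 75% selection fraction; 200 bootstraps (scaled_down per the stated
# acceptance allowance).
test_lasso_config <- function(seed, n_runs = 50, n_bootstrap = 200)
  lasso_config(n_runs = n_runs, freq_threshold = 0.75 * n_runs,
               n_bootstrap = n_bootstrap, seed = seed)
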