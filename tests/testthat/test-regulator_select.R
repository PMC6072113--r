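make_design <- function(n = 200, p = 5, beta = c(-0.8, rep(0, 4)),
                        noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("m", seq_len(p))
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  regression_design(y, X, rep("miRNA", p))
}

test_that("one-SE LASSO: planted signal, KKT boundary, OLS limit", {
  # planted covariate dominates; pure-noise covariates are zeroed
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(200 * 6), 200)
    colnames(X) <- paste0("m", 1:6)
    y <- X[, 1]  # exact copy
    d <- regression_design(y, X, rep("miRNA", 6))
    f <- fit_lasso_one_se(d, fold_seed = s)
    expect_equal(which.max(abs(f$coefficients)), c(m1 = 1L))
    expect_true(all(f$coefficients[-1] == 0))
  }

  d <- make_design(seed = 3)
  grid <- lasso_lambda_grid(d$X, d$y)
  at_max <- cernet:::cpp_lasso_path(d$X, d$y, grid[1])$beta
  expect_true(all(at_max == 0))

  # lambda -> 0 approaches the closed-form least-squares solution
  set.seed(4)
  X <- matrix(rnorm(150 * 3), 150); colnames(X) <- c("a", "b", "c")
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(150)
  path <- cernet:::cpp_lasso_path(X, y, c(lasso_lambda_grid(X, y), 1e-10))
  Xc <- cbind(1, X)
  ols <- solve(crossprod(Xc), crossprod(Xc, y))[-1]
  expect_lt(max(abs(path$beta[, 101] - ols)), 1e-4)

  expect_error(fit_lasso_one_se(make_design(n = 5), cfg = lasso_config()),
               "folds")
})

test_that("stability selection counts strong and noise covariates correctly", {
  cfg <- lasso_config(n_runs = 100, seed = 99)
  for (s in 1:5) {
    d <- make_design(beta = c(-0.8, rep(0, 4)), seed = 100 + s)
    st <- stability_select(d, cfg)
    expect_equal(st$selection_count[1], 100L)
    expect_true(st$frequently_selected[1])
    expect_lt(st$median_coefficient[1], 0)
  }
  # pure-noise covariates rarely reach the 75% threshold
  noise_ok <- sapply(1:20, function(s) {
    d <- make_design(beta = rep(0, 5), seed = 200 + s)
    all(stability_select(d, cfg)$selection_count < 75)
  })
  expect_gte(mean(noise_ok), 0.95)
  # identical seed implies bitwise identical counts
  d <- make_design(seed = 5)
  expect_identical(stability_select(d, cfg), stability_select(d, cfg))
})

test_that("bootstrap CI filter keeps planted negatives and applies the rules", {
  for (s in 1:5) {
    d <- make_design(beta = c(-0.8, rep(0, 4)), seed = 300 + s)
    cfg <- test_lasso_config(seed = 300 + s)
    sel <- bootstrap_ci_filter(d, stability_select(d, cfg), cfg)
    expect_true(sel$kept[1])
    expect_lt(sel$ci_hi[1], 0)
    expect_true(all(!sel$kept[-1]))
  }
  # rule checks on a constructed selection table: CI straddling zero, and a
  # median outside its own CI, are both dropped even when frequent
  d <- make_design(seed = 9)
  cfg <- test_lasso_config(seed = 9)
  sel <- bootstrap_ci_filter(d, stability_select(d, cfg), cfg)
  fake <- sel
  fake$frequently_selected <- TRUE
  fake$ci_lo <- -0.5; fake$ci_hi <- 0.5; fake$median_coefficient <- -0.2
  expect_false(with(fake[1, ], frequently_selected & ci_lo <= median_coefficient &
                      median_coefficient <= ci_hi & !(ci_lo <= 0 & ci_hi >= 0)))
  fake$ci_lo <- -0.5; fake$ci_hi <- -0.3; fake$median_coefficient <- -0.9
  expect_false(with(fake[1, ], ci_lo <= median_coefficient & median_coefficient <= ci_hi))
})

test_that("keep_negative_mirnas applies sign and kind rules", {
  sel <- data.frame(covariate = c("mA", "mB", "TF1", "CNA"),
                    kind = c("miRNA", "miRNA", "TF", "CNA"),
                    selection_count = c(90L, 90L, 90L, 90L),
                    median_coefficient = c(-0.5, 0.3, -0.4, 0.8),
                    frequently_selected = rep(TRUE, 4),
                    ci_lo = c(-0.7, 0.1, -0.6, 0.5),
                    ci_hi = c(-0.3, 0.5, -0.2, 1.1),
                    kept = rep(TRUE, 4), stringsAsFactors = FALSE)
  class(sel) <- c("RegulatorSelection", "data.frame")
  res <- keep_negative_mirnas(sel, rna_id = "g1")
  expect_equal(res$interactions$regulator, "mA")  # mB positive, TF/CNA not miRNA
  expect_setequal(res$regulator_summary$covariate, c("mA", "mB", "TF1", "CNA"))
  summ <- regulator_kind_summary(res$regulator_summary)
  expect_equal(summ$percent_of_targets[summ$kind == "CNA"], 100)
})

test_that("ols_select matches the normal equations and applies the sign rule", {
  set.seed(21)
  X <- matrix(rnorm(120 * 3), 120)
  colnames(X) <- c("m1", "m2", "tf")
  y <- -0.9 * X[, 1] + 0.8 * X[, 3] + rnorm(120)
  d <- regression_design(y, X, c("miRNA", "miRNA", "TF"), standardize = FALSE)
  res <- ols_select(d)
  Xc <- cbind(1, X)
  oracle <- drop(solve(crossprod(Xc), crossprod(Xc, y)))[-1]
  expect_lt(max(abs(res$coefficient - oracle)), 1e-8)
  expect_true(res$kept[res$covariate == "m1"])
  # positive significant miRNA and non-miRNA covariates are never kept
  expect_false(res$kept[res$covariate == "tf"])
  # rank-deficient design errors
  X2 <- cbind(X, m1b = X[, 1])
  d2 <- regression_design(y, X2, c("miRNA", "miRNA", "TF", "miRNA"),
                          standardize = FALSE)
  expect_error(ols_select(d2), "rank")
})

test_that("null designs keep almost nothing (false-positive control)", {
  cfg0 <- test_lasso_config(seed = 0, n_runs = 50, n_bootstrap = 100)
  kept_counts <- sapply(1:50, function(s) {
    d <- make_design(n = 100, p = 4, beta = rep(0, 4), seed = 400 + s)
    cfg <- cfg0; cfg$seed <- 400 + s
    sum(bootstrap_ci_filter(d, stability_select(d, cfg), cfg)$kept)
  })
  expect_lte(mean(kept_counts), 0.1)
})

test_that("the selection step is a pure function of design and seed", {
  d <- make_design(seed = 31)
  cfg <- test_lasso_config(seed = 31, n_runs = 20, n_bootstrap = 40)
  r1 <- bootstrap_ci_filter(d, stability_select(d, cfg), cfg)
  r2 <- bootstrap_ci_filter(d, stability_select(d, cfg), cfg)
  expect_identical(r1, r2)
  # kept implies frequently_selected; both subsets of the candidate set
  expect_true(all(!r1$kept | r1$frequently_selected))
})
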