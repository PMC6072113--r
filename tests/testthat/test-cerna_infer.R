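test_that("candidate_pairs enumerates shared-regulator pairs and matches brute force", {
  net <- interaction_table(c("m", "m", "m", "x"), c("a", "b", "c", "d"),
                           "miRNA", "t")
  pairs <- candidate_pairs(net, n_de_mirnas = 10)
  expect_equal(nrow(pairs), 3)  # (a,b), (a,c), (b,c); d shares nothing
  expect_true(all(pairs$rna_i < pairs$rna_j))
  expect_true(all(pairs$N == 10 & pairs$N_ij >= 1))
  expect_true(all(pairs$N_ij <= pmin(pairs$N_i, pairs$N_j)))

  set.seed(17)
  big <- interaction_table(sample(paste0("m", 1:12), 80, TRUE),
                           sample(paste0("r", sprintf("%02d", 1:30)), 80, TRUE),
                           "miRNA", "t")
  got <- candidate_pairs(big)
  regs <- split(big$regulator, big$target)
  rn <- sort(names(regs))
  oracle <- 0
  for (i in seq_along(rn)) for (j in seq_along(rn)) if (i < j) {
    sh <- length(intersect(regs[[rn[i]]], regs[[rn[j]]]))
    if (sh > 0) {
      oracle <- oracle + 1
      row <- got[got$rna_i == rn[i] & got$rna_j == rn[j], ]
      expect_equal(row$N_ij, sh)
    }
  }
  expect_equal(nrow(got), oracle)
})

test_that("pearson_filter applies the r and p thresholds exactly", {
  sids <- paste0("s", 1:30)
  set.seed(2)
  base <- rnorm(30)
  vals <- rbind(a = base, b = base,            # r = 1
                c = rnorm(30), d = rnorm(30))
  colnames(vals) <- sids
  expr <- zmat(vals)
  pairs <- data.frame(rna_i = c("a", "c"), rna_j = c("b", "d"),
                      shared_mirnas = "m", N = 5, N_i = 1, N_j = 1, N_ij = 1,
                      stringsAsFactors = FALSE)
  res <- pearson_filter(pairs, expr)
  expect_equal(res$pearson_r[1], 1)
  expect_true(res$pass_pearson[1])
  # r below min_corr is dropped regardless of p
  cfg <- cerna_config(min_corr = 0.5)
  fake <- res; fake$pearson_r[2] <- 0.49; fake$pearson_p[2] <- 1e-10
  expect_false(fake$pearson_r[2] >= cfg$min_corr)
  # r matches the definitional sum-formula oracle
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(25); y <- rnorm(25)
    rdef <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(cor(x, y) - rdef), 1e-12)
  }
  expect_error(pearson_filter(pairs, zmat(vals[, 1:2])), "3 samples")
})

test_that("hypergeometric kernel reproduces enumeration-derived values", {
  expect_equal(hypergeom_shared_pvalue(10, 3, 3, 3), 1 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_shared_pvalue(5, 5, 2, 2), 1.0)
  expect_equal(hypergeom_shared_pvalue(10, 1, 1, 1), 0.1, tolerance = 1e-12)
  expect_error(hypergeom_shared_pvalue(10, 3, 3, 4), "invalid")
})

test_that("hypergeom_filter adjusts within the tested family", {
  one <- data.frame(rna_i = "a", rna_j = "b", N = 20, N_i = 4, N_j = 4,
                    N_ij = 2, stringsAsFactors = FALSE)
  r1 <- hypergeom_filter(one)
  expect_equal(r1$hyper_p_adj, r1$hyper_p)
  # uniform ties: BH leaves equal p-values unchanged
  many <- one[rep(1, 100), ]
  r100 <- hypergeom_filter(many)
  expect_true(all(abs(r100$hyper_p_adj - r100$hyper_p) < 1e-12))
  expect_equal(bh_adjust(r100$hyper_p), r100$hyper_p_adj)
})

test_that("partial correlation: limits, closed form, and annihilation", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partial_correlation(x, y)$pc, cor(x, y))

  tri <- exact_corr_triplet(n = 30, rxy = 0.8, rxz = 0.6, ryz = 0.6)
  pc <- partial_correlation(tri$x, tri$y, cbind(z = tri$z))$pc
  expect_equal(pc, (0.8 - 0.36) / sqrt(0.64 * 0.64), tolerance = 1e-10)

  # x a deterministic function of z: any partial correlation vanishes
  z <- rnorm(50); x2 <- 2 * z + 1
  expect_lt(abs(partial_correlation(x2, rnorm(50), cbind(z))$pc), 1e-8)

  # rank-deficient conditioning set errors naming columns
  Z <- cbind(z1 = z, z2 = 2 * z)
  expect_error(partial_correlation(rnorm(50), rnorm(50), Z), "collinear")
  expect_error(partial_correlation(x[1:4], y[1:4], cbind(z[1:4], rnorm(4))),
               "n >")
})

test_that("sensitivity correlation identity and null behavior", {
  expect_equal(sensitivity_correlation(0.8, 0.6875), 0.1125)
  # shared miRNAs independent of both RNAs: SC concentrates near 0
  scs <- sapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(200); y <- rnorm(200); Z <- matrix(rnorm(600), 200)
    corr <- cor(x, y)
    corr - partial_correlation(x, y, Z)$pc
  })
  expect_lt(mean(abs(scs)), 0.05)
  # both RNAs equal to the same miRNA plus tiny noise: pc ~ 0, sc -> corr
  set.seed(33)
  m <- rnorm(200)
  x <- m + rnorm(200, sd = 0.01); y <- m + rnorm(200, sd = 0.01)
  corr <- cor(x, y)
  pc <- partial_correlation(x, y, cbind(m))$pc
  expect_lt(abs(pc), 0.2)
  expect_gt(corr - pc, 0.7)
})

test_that("empirical SC p-value: determinism, degenerate pool, planted signal", {
  sids <- paste0("s", 1:100)
  set.seed(12)
  mir <- zmat(named_mat(rnorm(8 * 100), paste0("m", 1:8), sids), "miRNA")
  x <- rnorm(100); y <- rnorm(100)
  cfg <- cerna_config(sc_resamples = 200, seed = 42)
  p1 <- empirical_sc_pvalue(x, y, cor(x, y), 0.1, 2, mir, paste0("m", 1:8), cfg)
  p2 <- empirical_sc_pvalue(x, y, cor(x, y), 0.1, 2, mir, paste0("m", 1:8), cfg)
  expect_identical(p1, p2)

  # pool equal to the shared set: every sampled SC equals the original, and
  # the strict ">" rule gives p = 0 (with a warning)
  sc0 <- cor(x, y) -
    partial_correlation(x, y, t(mir$values[c("m1", "m2"), ]))$pc
  expect_warning(
    p0 <- empirical_sc_pvalue(x, y, cor(x, y), sc0, 2, mir, c("m1", "m2"), cfg),
    "degenerate")
  expect_equal(p0, 0)

  # planted pair: its shared miRNAs are the only real regulators in the pool
  hits <- sapply(1:20, function(s) {
    set.seed(500 + s)
    M <- named_mat(rnorm(30 * 150), paste0("m", 1:30), paste0("s", 1:150))
    x <- -0.7 * M["m1", ] - 0.6 * M["m2", ] + rnorm(150)
    y <- -0.8 * M["m1", ] - 0.7 * M["m2", ] + rnorm(150)
    mirm <- zmat(M, "miRNA")
    sc <- cor(x, y) - partial_correlation(x, y, t(M[c("m1", "m2"), ]))$pc
    cfg <- cerna_config(sc_resamples = 200, seed = 500 + s)
    empirical_sc_pvalue(x, y, cor(x, y), sc, 2, mirm, paste0("m", 1:30),
                        cfg) < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("sc_filter applies all three conditions and the deactivated variant", {
  pairs <- data.frame(rna_i = letters[1:4], rna_j = LETTERS[1:4],
                      sc = c(-0.1, 0.2, 0.2, 0.2),
                      pc_p = c(0.01, 0.01, 0.5, 0.01),
                      sc_empirical_p = c(0.01, 0.01, 0.01, 0.5),
                      stringsAsFactors = FALSE)
  res <- sc_filter(pairs, cerna_config())
  expect_equal(res$pass_sc, c(FALSE, TRUE, FALSE, FALSE))
  off <- sc_filter(pairs, cerna_config(sc_filter_enabled = FALSE))
  expect_true(all(off$pass_sc))
  expect_gte(sum(off$pass_sc), sum(res$pass_sc))
})

test_that("pair statistics are symmetric in the two RNAs", {
  set.seed(91)
  sids <- paste0("s", 1:80)
  M <- named_mat(rnorm(5 * 80), paste0("m", 1:5), sids)
  x <- -0.7 * M["m1", ] + rnorm(80); y <- -0.7 * M["m1", ] + rnorm(80)
  Z <- t(M["m1", , drop = FALSE])
  a <- partial_correlation(x, y, Z); b <- partial_correlation(y, x, Z)
  expect_equal(a$pc, b$pc)
  expect_equal(a$pc_p, b$pc_p)
  expect_equal(cor(x, y), cor(y, x))
  expect_equal(hypergeom_shared_pvalue(10, 4, 6, 2),
               hypergeom_shared_pvalue(10, 6, 4, 2), tolerance = 1e-12)
})

test_that("correlation baseline prunes positive miRNA edges and null data", {
  sids <- paste0("s", 1:100)
  set.seed(55)
  m <- rnorm(100)
  # gneg repressed by m; gpos positively correlated with m
  vals <- rbind(gneg1 = -0.9 * m + rnorm(100, sd = .3),
                gneg2 = -0.9 * m + rnorm(100, sd = .3),
                gpos = 0.9 * m + rnorm(100, sd = .3))
  colnames(vals) <- sids
  rna <- zmat(vals)
  mir <- zmat(named_mat(m, "m1", sids), "miRNA")
  put <- interaction_table(rep("m1", 3), rownames(vals), "miRNA", "t")
  res <- correlation_baseline(rna, mir, put)
  expect_setequal(res$mirna_edges$target, c("gneg1", "gneg2"))
  expect_equal(nrow(res$pairs), 1)  # gneg1-gneg2, strongly positive

  # planted-null data: near-empty output
  frac <- sapply(1:10, function(s) {
    set.seed(600 + s)
    vals <- named_mat(rnorm(12 * 60), paste0("g", 1:12), paste0("s", 1:60))
    mirv <- named_mat(rnorm(3 * 60), paste0("m", 1:3), paste0("s", 1:60))
    put <- interaction_table(sample(paste0("m", 1:3), 24, TRUE),
                             sample(paste0("g", 1:12), 24, TRUE), "miRNA", "t")
    res <- correlation_baseline(zmat(vals), zmat(mirv, "miRNA"), put)
    cand <- candidate_pairs(put)
    if (!nrow(cand)) return(0)
    nrow(res$pairs) / nrow(cand)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("the filter cascade is monotone and the driver fills sc exactly", {
  set.seed(77)
  sids <- paste0("s", 1:120)
  M <- named_mat(rnorm(6 * 120), paste0("m", 1:6), sids)
  u <- rnorm(120)
  g <- rbind(a = -0.8 * M["m1", ] - 0.7 * M["m2", ] + 0.5 * u + rnorm(120),
             b = -0.7 * M["m1", ] - 0.8 * M["m2", ] + 0.5 * u + rnorm(120),
             c = rnorm(120))
  colnames(g) <- sids
  net <- interaction_table(c("m1", "m2", "m1", "m2", "m3"),
                           c("a", "a", "b", "b", "c"), "miRNA", "t")
  res <- infer_cerna(net, zmat(g), zmat(M, "miRNA"),
                     cerna_config(sc_resamples = 200, seed = 7))
  expect_true(all(res$final$pass_pearson & res$final$pass_hyper &
                    res$final$pass_sc))
  expect_true(nrow(res$final) <= nrow(res$pairs))
  done <- !is.na(res$pairs$sc)
  expect_identical(res$pairs$sc[done],
                   res$pairs$corr[done] - res$pairs$pc[done])
})
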