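test_that("counts_to_cpm normalizes columns to one million", {
  m <- expression_matrix(named_mat(c(10, 990, 5, 5), c("g1", "g2"),
                                   c("s1", "s2")), "mRNA", "raw_count")
  cpm <- counts_to_cpm(m)
  expect_equal(cpm$values[, "s1"], c(g1 = 1e4, g2 = 9.9e5))
  expect_equal(unname(colSums(cpm$values)), c(1e6, 1e6))
  z <- expression_matrix(named_mat(c(0, 0, 1, 1), c("g1", "g2"),
                                   c("s1", "s2")), "mRNA", "raw_count")
  expect_error(counts_to_cpm(z), "s1")
})

test_that("cpm_filter applies the strict more-than-t rule", {
  # 3 normal + 5 tumor samples -> t = 5
  sids <- paste0("s", 1:8)
  groups <- setNames(c(rep("normal", 3), rep("tumor", 5)), sids)
  # library sizes equal, so CPM < 1 iff count == 0 (given large other rows)
  low6 <- c(rep(0, 6), rep(100, 2))    # low in 6 > 5 -> dropped
  low5 <- c(rep(0, 5), rep(100, 3))    # low in exactly 5 -> kept
  high <- rep(100, 8)
  vals <- rbind(low6 = low6, low5 = low5, high = high)
  colnames(vals) <- sids
  m <- expression_matrix(vals, "mRNA", "raw_count", groups)
  kept <- cpm_filter(m, groups)
  expect_setequal(kept, c("low5", "high"))
  # invariant to sample order and common library scaling
  perm <- sample(sids)
  m2 <- expression_matrix(m$values[, perm] * 4, "mRNA", "raw_count", groups)
  expect_setequal(cpm_filter(m2, groups), kept)
  expect_error(cpm_filter(m, setNames(rep("tumor", 8), sids)), "non-empty")
})

test_that("simple_de_test labels planted shifts and controls the null", {
  sids <- paste0("s", 1:40)
  groups <- setNames(rep(c("normal", "tumor"), each = 20), sids)
  # planted 3-sd shift at n = 20/20 is detected essentially always
  detect <- sapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(40); x[21:40] <- x[21:40] + 3
    m <- expression_matrix(named_mat(rbind(x), "g1", sids), "mRNA",
                           "arbitrary", groups)
    c(w = simple_de_test(m, groups, "wilcoxon")$is_DE,
      t = simple_de_test(m, groups, "welch_t")$is_DE)
  })
  expect_gte(sum(detect["w", ]), 99)
  expect_gte(sum(detect["t", ]), 99)

  # type-I control on null data: DE fraction <= 2 * alpha over 50 seeds
  frac <- sapply(1:50, function(s) {
    set.seed(1000 + s)
    m <- expression_matrix(named_mat(rnorm(40 * 20), paste0("g", 1:20), sids),
                           "mRNA", "arbitrary", groups)
    mean(simple_de_test(m, groups, "welch_t")$is_DE)
  })
  expect_lte(mean(frac), 0.01 * 2)

  # constant feature: warning and p = 1, never DE
  m <- expression_matrix(named_mat(rep(1, 40), "flat", sids), "mRNA",
                         "arbitrary", groups)
  expect_warning(res <- simple_de_test(m, groups, "wilcoxon"), "constant")
  expect_false(res$is_DE)
})

test_that("log_and_znormalize restricts, transforms and scales", {
  sids <- paste0("s", 1:5)
  vals <- rbind(g0 = c(0, 2, 4, 7, 11),
                flat = c(1, 1, 1, 1, 3),  # constant over the tumor subset
                g2 = c(1, 3, 5, 9, 13),
                g3 = c(1, 1, 2, 5, 1))
  colnames(vals) <- sids
  m <- expression_matrix(vals, "mRNA", "rpkm")
  expect_warning(z <- log_and_znormalize(m, sids[1:4]), "zero-variance")
  expect_false("flat" %in% rownames(z$values))
  expect_identical(colnames(z$values), sids[1:4])
  expect_lt(max(abs(rowMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-10)
  # an RPKM of 0 maps to log2(0.001) before scaling
  expect_equal(log2(0 + 0.001), -9.965784, tolerance = 1e-6)
})

test_that("promoter_methylation respects window bounds and strand", {
  sids <- c("s1", "s2")
  beta <- expression_matrix(
    named_mat(c(0.2, 0.3, 0.4, 0.5, 0.9, 0.8, 0.6, 0.7),
              c("pA", "pB", "pC", "pD"), sids), "mRNA", "beta")
  # "+" gene with tss 10000: window [8500, 9800] inclusive
  # "-" gene with tss 20000: window [20200, 21500] inclusive
  genes <- gene_annotation(c("gp", "gm"), c("chr1", "chr1"),
                           c(10000, 19000), c(15000, 20000), c("+", "-"))
  probes <- probe_annotation(
    c("pA", "pB", "pC", "pD"), rep("chr1", 4),
    c(9000, 9800,    # gp: in-window (pB exactly at tss-200 -> included)
      20300, 19700)) # gm: pC at tss+300 included, pD at tss-300 excluded
  res <- promoter_methylation(beta, probes, genes)
  expect_equal(res$values["gp", ], colMeans(beta$values[c("pA", "pB"), ]))
  expect_equal(res$values["gm", ], beta$values["pC", ])
  expect_true(all(res$values >= 0 & res$values <= 1))
})

test_that("segments_to_gene_cna weights by overlap length", {
  genes <- gene_annotation(c("inside", "split", "nohit"), rep("chr1", 3),
                           c(100, 950, 5000), c(200, 1049, 6000),
                           rep("+", 3))
  seg <- segment_table(rep("s1", 2), rep("chr1", 2), c(1, 1000),
                       c(999, 2000), c(0.0, 1.0))
  expect_message(res <- segments_to_gene_cna(seg, genes), "nohit")
  expect_equal(unname(res$values["inside", "s1"]), 0.0)
  # split gene: 50 bp in each segment -> 0.5
  expect_equal(unname(res$values["split", "s1"]), 0.5)
  # all segments sharing one value give every covered gene that value
  seg2 <- segment_table(rep("s1", 2), rep("chr1", 2), c(1, 1000),
                        c(999, 2000), c(0.7, 0.7))
  res2 <- suppressMessages(segments_to_gene_cna(seg2, genes))
  expect_true(all(abs(res2$values - 0.7) < 1e-12))
})

test_that("bh_adjust matches the textbook example and the naive oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(7)
  for (i in 1:1000) {
    p <- runif(sample(1:200, 1))
    expect_lt(max(abs(bh_adjust(p) - bh_naive_oracle(p))), 1e-12)
  }
  # properties: monotone in rank, adjusted >= raw, capped at 1
  p <- runif(50)
  a <- bh_adjust(p)
  expect_true(all(a >= p))
  expect_true(all(a <= 1))
  expect_true(all(diff(a[order(p)]) >= -1e-15))
  # bonferroni alternative
  expect_equal(bh_adjust(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
})
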