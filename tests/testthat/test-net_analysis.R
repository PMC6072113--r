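two_clique_bridge <- function(k = 6) {
  cliq <- function(ids) {
    cmb <- t(combn(ids, 2))
    data.frame(rna_i = cmb[, 1], rna_j = cmb[, 2], stringsAsFactors = FALSE)
  }
  rbind(cliq(sprintf("a%02d", 1:k)), cliq(sprintf("b%02d", 1:k)),
        data.frame(rna_i = "a01", rna_j = "b01", stringsAsFactors = FALSE))
}

test_that("power-law fit recovers analytic slopes and rejects degenerates", {
  k <- 1:20
  pk <- k^-2 / sum(k^-2)
  names(pk) <- k
  fit <- powerlaw_loglog_fit(pk)
  expect_equal(fit$slope, -2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # regular graph: a single observed degree is degenerate
  ring <- data.frame(rna_i = paste0("n", 1:5),
                     rna_j = paste0("n", c(2:5, 1)))
  expect_error(powerlaw_loglog_fit(cerna_network(ring)), "3 distinct")

  # slope invariant under node relabeling (star plus chain: degrees 1, 2, 5)
  sp <- data.frame(rna_i = c(rep("hub", 5), "leaf1"),
                   rna_j = c(paste0("leaf", 1:5), "leaf2"),
                   stringsAsFactors = FALSE)
  relab <- sp
  relab$rna_i <- toupper(sp$rna_i); relab$rna_j <- toupper(sp$rna_j)
  expect_equal(powerlaw_loglog_fit(cerna_network(sp))$slope,
               powerlaw_loglog_fit(cerna_network(relab))$slope)
})

test_that("module detection splits the two-clique bridge optimally", {
  net <- cerna_network(two_clique_bridge())
  mod <- detect_modules(net, seed = 1)
  expect_equal(length(mod), 12)
  expect_equal(length(unique(mod)), 2)
  a_mods <- unique(mod[grep("^a", names(mod))])
  b_mods <- unique(mod[grep("^b", names(mod))])
  expect_equal(length(a_mods), 1)
  expect_equal(length(b_mods), 1)
  expect_false(a_mods == b_mods)

  # exhaustive 2-partition enumeration: the clique split maximizes modularity
  best <- -Inf
  nodes <- names(mod)
  for (mask in 0:(2^11 - 1)) {
    side <- c(0L, as.integer(intToBits(mask))[1:11]) + 1L
    q <- network_modularity(net, setNames(side, nodes))
    if (q > best) best <- q
  }
  expect_equal(network_modularity(net, mod), best, tolerance = 1e-12)

  # single clique stays one module
  one <- cerna_network(two_clique_bridge()[1:15, ])
  expect_equal(length(unique(detect_modules(one, seed = 1))), 1)

  # planted 2-block graphs yield positive modularity
  qs <- sapply(1:5, function(s) {
    set.seed(s)
    block <- rep(1:2, each = 30)
    edges <- NULL
    for (i in 1:59) for (j in (i + 1):60) {
      p <- if (block[i] == block[j]) 0.3 else 0.01
      if (runif(1) < p) edges <- rbind(edges, c(paste0("v", i), paste0("v", j)))
    }
    df <- data.frame(rna_i = edges[, 1], rna_j = edges[, 2],
                     stringsAsFactors = FALSE)
    g <- cerna_network(df)
    network_modularity(g, detect_modules(g, seed = s))
  })
  expect_true(all(qs > 0))
})

test_that("module enrichment uses the shared hypergeometric kernel", {
  universe <- sprintf("g%03d", 1:100)
  assignment <- setNames(rep(1L, 10), universe[1:10])
  sets <- structure(list(hit = list(description = "d", genes = universe[1:10]),
                         nohit = list(description = "d", genes = universe[90:99])),
                    class = "GeneSetCollection")
  res <- enrich_modules(assignment, sets, universe, min_module_size = 10)
  expect_equal(res$p[res$set_name == "hit"], 1 / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(res$p[res$set_name == "nohit"], 1)
  # same kernel as the pair test
  expect_equal(res$p[res$set_name == "hit"],
               hypergeom_shared_pvalue(100, 10, 10, 10), tolerance = 1e-15)
  # small modules skipped
  tiny <- setNames(rep(2L, 3), universe[11:13])
  res2 <- enrich_modules(c(assignment, tiny), sets, universe)
  expect_false(2L %in% res2$module_id)
  expect_error(enrich_modules(setNames(1L, "zz"), sets, universe), "universe")
})

test_that("gene_set_hypergeom handles edge cases and symmetry", {
  u <- paste0("g", 1:10)
  expect_equal(gene_set_hypergeom(u, u, u), 1)
  expect_equal(gene_set_hypergeom(u[1:3], u[1:3], u), 1 / 120,
               tolerance = 1e-12)
  expect_equal(gene_set_hypergeom(u[1:4], u[3:8], u),
               gene_set_hypergeom(u[3:8], u[1:4], u), tolerance = 1e-12)
  expect_error(gene_set_hypergeom(c("zz"), u[1:2], u), "subsets")
})

test_that("hub calling by degree quantile", {
  star <- data.frame(rna_i = "hub", rna_j = paste0("leaf", 1:10),
                     stringsAsFactors = FALSE)
  net <- cerna_network(star)
  expect_equal(call_hubs(net, 0.90), "hub")
  # all-equal degrees: everyone is at the threshold, all are hubs
  ring <- cerna_network(data.frame(rna_i = paste0("n", 1:5),
                                   rna_j = paste0("n", c(2:5, 1))))
  expect_equal(length(call_hubs(ring, 0.90)), 5)
  # monotone non-increasing in the quantile
  sizes <- sapply(c(0.5, 0.7, 0.9, 0.99),
                  function(q) length(call_hubs(net, q)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("overlap counting matches a brute-force lookup", {
  net <- cerna_network(two_clique_bridge())
  none <- data.frame(regulator = "x1", target = "x2")
  expect_equal(overlap_with_interactions(net, none),
               list(count = 0, fraction = 0))
  all_edges <- net$edges[, c("rna_j", "rna_i")]  # reversed order still counts
  full <- overlap_with_interactions(net, all_edges)
  expect_equal(full$fraction, 1.0)
  set.seed(9)
  some <- net$edges[sample(nrow(net$edges), 10), ]
  brute <- sum(paste(pmin(net$edges$rna_i, net$edges$rna_j),
                     pmax(net$edges$rna_i, net$edges$rna_j)) %in%
                 paste(pmin(some$rna_i, some$rna_j),
                       pmax(some$rna_i, some$rna_j)))
  expect_equal(overlap_with_interactions(net, some)$count, brute)
})
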