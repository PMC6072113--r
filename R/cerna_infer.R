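# Step 3: candidate ceRNA pairs from shared miRNA regulators, filtered by
# Pearson correlation, a hypergeometric shared-regulator test and the
# sensitivity-correlation (SC) criterion with an empirical resampling null.

#' ceRNA inference configuration
#'
#' Defaults follow the published thresholds: pair correlation >= 0.5 with raw
#' p < 0.05; BH-adjusted hypergeometric p < 0.05; SC > 0 with partial
#' correlation p < 0.05 and empirical SC p < 0.05 from 1000 resamples.
#'
#' @param min_corr minimum Pearson correlation.
#' @param corr_p raw Pearson p-value threshold.
#' @param hyper_alpha BH-adjusted hypergeometric threshold.
#' @param sc_resamples resampling iterations for the empirical SC p-value.
#' @param sc_alpha empirical SC p threshold.
#' @param pc_p_alpha partial-correlation p threshold.
#' @param sc_filter_enabled when FALSE the SC stage passes all pairs through
#'   (the "SC filter deactivated" variant).
#' @param seed integer seed for the resampling stream.
#' @return a `CeRNAConfig` list.
#' @export
cerna_config <- function(min_corr = 0.5, corr_p = 0.05, hyper_alpha = 0.05,
                         sc_resamples = 1000, sc_alpha = 0.05,
                         pc_p_alpha = 0.05, sc_filter_enabled = TRUE,
                         seed = 1L) {
  stopifnot(min_corr >= -1, min_corr <= 1, corr_p > 0, corr_p < 1,
            hyper_alpha > 0, hyper_alpha < 1, sc_resamples > 0,
            sc_alpha > 0, sc_alpha < 1, pc_p_alpha > 0, pc_p_alpha < 1)
  structure(list(min_corr = min_corr, corr_p = corr_p,
                 hyper_alpha = hyper_alpha,
                 sc_resamples = as.integer(sc_resamples), sc_alpha = sc_alpha,
                 pc_p_alpha = pc_p_alpha,
                 sc_filter_enabled = isTRUE(sc_filter_enabled),
                 seed = as.integer(seed)),
            class = "CeRNAConfig")
}

#' Candidate ceRNA pairs from shared miRNA regulators
#'
#' All unordered RNA pairs whose members share at least one miRNA regulator
#' in the selected network. `N` is the total number of DE miRNAs in the
#' analysis universe (not only those surviving selection); `N_i`/`N_j` count
#' each member's regulators and `N_ij` the shared ones. Pairs are ordered
#' lexicographically with `rna_i < rna_j`.
#'
#' @param net a miRNA->RNA `InteractionTable` (selected network).
#' @param n_de_mirnas total DE miRNAs in the universe; defaults to the number
#'   of distinct regulators in `net`.
#' @return data.frame of pair skeletons with `shared_mirnas`
#'   (";"-joined), `N`, `N_i`, `N_j`, `N_ij`.
#' @export
candidate_pairs <- function(net, n_de_mirnas = NULL) {
  regs <- split(net$regulator, net$target)
  regs <- lapply(regs, unique)
  if (is.null(n_de_mirnas)) n_de_mirnas <- length(unique(net$regulator))
  rnas <- sort(names(regs))
  out <- list()
  if (length(rnas) >= 2) {
    for (a in seq_len(length(rnas) - 1)) {
      for (b in seq(a + 1, length(rnas))) {
        shared <- intersect(regs[[rnas[a]]], regs[[rnas[b]]])
        if (!length(shared)) next
        out[[length(out) + 1L]] <- data.frame(
          rna_i = rnas[a], rna_j = rnas[b],
          shared_mirnas = paste(sort(shared), collapse = ";"),
          N = n_de_mirnas,
          N_i = length(regs[[rnas[a]]]), N_j = length(regs[[rnas[b]]]),
          N_ij = length(shared), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(rna_i = character(0), rna_j = character(0),
                      shared_mirnas = character(0), N = integer(0),
                      N_i = integer(0), N_j = integer(0), N_ij = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

pearson_test <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

#' Pearson correlation filter for candidate pairs
#'
#' Fills `pearson_r` and its exact two-sided t-distribution p-value (n-2 df)
#' for every pair; a pair passes iff its correlation is at least `min_corr`
#' and `p < corr_p` (the threshold applies to r itself, not |r|).
#'
#' @param pairs candidate pair data.frame ([candidate_pairs()]).
#' @param expr z-scored tumor `ExpressionMatrix` covering all pair members.
#' @param cfg a [cerna_config()].
#' @return `pairs` with `pearson_r`, `pearson_p`, `pass_pearson`.
#' @export
pearson_filter <- function(pairs, expr, cfg = cerna_config()) {
  if (ncol(expr$values) < 3) stop("need at least 3 samples for correlation")
  miss <- setdiff(unique(c(pairs$rna_i, pairs$rna_j)), rownames(expr$values))
  if (length(miss))
    stop("expression missing for pair member(s): ",
         paste(head(miss, 5), collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i)
    pearson_test(expr$values[pairs$rna_i[i], ], expr$values[pairs$rna_j[i], ]))
  pairs$pearson_r <- vapply(res, `[[`, numeric(1), "r")
  pairs$pearson_p <- vapply(res, `[[`, numeric(1), "p")
  pairs$pass_pearson <- pairs$pearson_r >= cfg$min_corr &
    pairs$pearson_p < cfg$corr_p
  pairs
}

#' Hypergeometric shared-regulator p-value
#'
#' Probability of observing at least `N_ij` shared regulators when `N_i` and
#' `N_j` regulators are drawn independently from a universe of `N` DE miRNAs:
#' `p = 1 - sum_{k=0}^{N_ij-1} C(N_j,k) C(N-N_j, N_i-k) / C(N, N_i)`,
#' accumulated in log space for stability.
#'
#' @param N universe size; `N_i`,`N_j` per-RNA regulator counts; `N_ij`
#'   shared count.
#' @param N_i,N_j,N_ij see above.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_shared_pvalue <- function(N, N_i, N_j, N_ij) {
  if (N_ij < 1 || N_ij > min(N_i, N_j) || N_i > N || N_j > N)
    stop("invalid counts: need 1 <= N_ij <= min(N_i, N_j) <= N")
  k <- 0:(N_ij - 1)
  logterm <- lchoose(N_j, k) + lchoose(N - N_j, N_i - k) - lchoose(N, N_i)
  p <- 1 - sum(exp(logterm))
  min(max(p, 0), 1)
}

#' Hypergeometric filter with BH adjustment over the tested pairs
#'
#' BH adjustment is applied across exactly the pairs reaching this stage; a
#' pair passes iff its adjusted p is below `hyper_alpha`.
#'
#' @param pairs pair data.frame with counts filled; only rows with
#'   `pass_pearson` (if present) are tested.
#' @param cfg a [cerna_config()].
#' @return `pairs` with `hyper_p`, `hyper_p_adj`, `pass_hyper`.
#' @export
hypergeom_filter <- function(pairs, cfg = cerna_config()) {
  test <- if ("pass_pearson" %in% names(pairs)) pairs$pass_pearson
  else rep(TRUE, nrow(pairs))
  pairs$hyper_p <- NA_real_
  pairs$hyper_p_adj <- NA_real_
  if (any(test)) {
    p <- vapply(which(test), function(i)
      hypergeom_shared_pvalue(pairs$N[i], pairs$N_i[i], pairs$N_j[i],
                              pairs$N_ij[i]), numeric(1))
    pairs$hyper_p[test] <- p
    pairs$hyper_p_adj[test] <- bh_adjust(p)
  }
  pairs$pass_hyper <- !is.na(pairs$hyper_p_adj) &
    pairs$hyper_p_adj < cfg$hyper_alpha
  pairs
}

#' Partial correlation via residual regression
#'
#' Correlation of the residuals of `x` and `y` after each is linearly
#' regressed (with intercept) on the conditioning set `Z`. The p-value uses
#' the t statistic `pc * sqrt((n-2-|Z|)/(1-pc^2))` on `n-2-|Z|` degrees of
#' freedom, two-sided. With `Z = NULL` this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param Z numeric matrix of conditioning vectors (columns), or NULL.
#' @return list with `pc` and `pc_p`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(as.matrix(Z))
  if (n <= k + 2) stop("need n > |Z| + 2")
  if (k == 0) {
    pc <- cor(x, y)
  } else {
    Z <- as.matrix(Z)
    Q <- qr(cbind(1, Z))
    if (Q$rank < ncol(Z) + 1) {
      drop <- setdiff(seq_len(ncol(Z) + 1), Q$pivot[seq_len(Q$rank)]) - 1
      stop("rank-deficient conditioning set; collinear column(s): ",
           paste(if (is.null(colnames(Z))) drop else colnames(Z)[drop],
                 collapse = ", "))
    }
    rx <- qr.resid(Q, x); ry <- qr.resid(Q, y)
    # a variable fully explained by Z has a numerically-zero residual; its
    # partial correlation with anything is 0 by convention, not cor() noise
    if (sd(rx) <= 1e-10 * sd(x) || sd(ry) <= 1e-10 * sd(y))
      return(list(pc = 0, pc_p = 1))
    pc <- cor(rx, ry)
  }
  if (abs(pc) >= 1) return(list(pc = pc, pc_p = 0))
  df <- n - 2 - k
  tstat <- pc * sqrt(df / (1 - pc^2))
  list(pc = pc, pc_p = 2 * pt(-abs(tstat), df))
}

#' Sensitivity correlation of a pair
#'
#' `SC = Corr - PC`: the share of the pair's co-expression attributable to
#' the conditioning miRNAs. The identity holds exactly by construction.
#'
#' @param corr Pearson correlation of the pair.
#' @param pc partial correlation conditioned on the shared miRNAs.
#' @return `corr - pc`.
#' @export
sensitivity_correlation <- function(corr, pc) corr - pc

#' Empirical p-value for the sensitivity correlation
#'
#' Resamples `N_ij` miRNAs uniformly without replacement from `mirna_pool`,
#' recomputes the sampled SC each time, and returns the fraction of
#' iterations in which the sampled SC strictly exceeds the original SC.
#' No pseudo-count smoothing is applied (p = 0 is attainable).
#'
#' @param x,y pair expression vectors.
#' @param corr their Pearson correlation.
#' @param sc the pair's original SC.
#' @param n_shared number of shared miRNAs (`N_ij`).
#' @param mirna_expr z-scored miRNA `ExpressionMatrix` over the same samples.
#' @param mirna_pool ids of eligible miRNAs (the resampling pool).
#' @param cfg a [cerna_config()]; `sc_resamples` and `seed` are used.
#' @return empirical p-value.
#' @export
empirical_sc_pvalue <- function(x, y, corr, sc, n_shared, mirna_expr,
                                mirna_pool, cfg = cerna_config()) {
  pool <- intersect(mirna_pool, rownames(mirna_expr$values))
  if (length(pool) < n_shared)
    stop("resampling pool smaller than the shared miRNA set")
  if (length(pool) == n_shared)
    warning("resampling pool equals the shared set size; empirical p is degenerate")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)
  exceed <- 0L
  for (i in seq_len(cfg$sc_resamples)) {
    z <- sample(pool, n_shared)
    pc_s <- partial_correlation(x, y, t(mirna_expr$values[z, , drop = FALSE]))$pc
    if (corr - pc_s > sc) exceed <- exceed + 1L
  }
  exceed / cfg$sc_resamples
}

#' Sensitivity-correlation filter
#'
#' A pair passes iff `SC > 0`, its partial-correlation p-value is below
#' `pc_p_alpha`, and its empirical SC p-value is below `sc_alpha`. With
#' `sc_filter_enabled = FALSE` the stage passes every incoming pair through
#' unchanged (the deactivated-SC variant).
#'
#' @param pairs data.frame with `sc`, `pc_p`, `sc_empirical_p` filled for
#'   rows reaching this stage.
#' @param cfg a [cerna_config()].
#' @return `pairs` with `pass_sc`.
#' @export
sc_filter <- function(pairs, cfg = cerna_config()) {
  upstream <- if ("pass_hyper" %in% names(pairs)) pairs$pass_hyper
  else rep(TRUE, nrow(pairs))
  if (!cfg$sc_filter_enabled) {
    pairs$pass_sc <- upstream
    return(pairs)
  }
  pairs$pass_sc <- upstream & !is.na(pairs$sc) & pairs$sc > 0 &
    !is.na(pairs$pc_p) & pairs$pc_p < cfg$pc_p_alpha &
    !is.na(pairs$sc_empirical_p) & pairs$sc_empirical_p < cfg$sc_alpha
  pairs
}

#' Infer the ceRNA network (step 3 driver)
#'
#' Runs the full filter cascade: candidate pairs from shared regulators,
#' Pearson filter, hypergeometric + BH filter, then SC/partial-correlation/
#' empirical-SC filter. Every statistic and per-stage flag is retained for
#' all candidate pairs. The resampling pool for the empirical SC p-value is
#' the set of DE miRNAs with expression available.
#'
#' @param net selected miRNA->RNA `InteractionTable` (step 2 output).
#' @param rna_expr z-scored tumor RNA `ExpressionMatrix`.
#' @param mirna_expr z-scored tumor miRNA `ExpressionMatrix`.
#' @param cfg a [cerna_config()].
#' @param n_de_mirnas DE-miRNA universe size for the hypergeometric `N`;
#'   defaults to `nrow(mirna_expr)`.
#' @return list with `pairs` (all candidates, all statistics and flags) and
#'   `final` (pairs passing every stage).
#' @export
infer_cerna <- function(net, rna_expr, mirna_expr, cfg = cerna_config(),
                        n_de_mirnas = nrow(mirna_expr$values)) {
  common <- intersect(colnames(rna_expr$values), colnames(mirna_expr$values))
  if (length(common) < 4) stop("too few shared tumor samples")
  rexp <- rna_expr; rexp$values <- rna_expr$values[, common, drop = FALSE]
  mexp <- mirna_expr; mexp$values <- mirna_expr$values[, common, drop = FALSE]
  pairs <- candidate_pairs(net, n_de_mirnas)
  pairs <- pairs[pairs$rna_i %in% rownames(rexp$values) &
                   pairs$rna_j %in% rownames(rexp$values), , drop = FALSE]
  if (!nrow(pairs)) {
    pairs$pass_pearson <- logical(0); pairs$pass_hyper <- logical(0)
    pairs$pass_sc <- logical(0)
    return(list(pairs = pairs, final = pairs))
  }
  pairs <- pearson_filter(pairs, rexp, cfg)
  pairs <- hypergeom_filter(pairs, cfg)
  pairs$corr <- pairs$pearson_r
  pairs$pc <- NA_real_; pairs$pc_p <- NA_real_
  pairs$sc <- NA_real_; pairs$sc_empirical_p <- NA_real_
  pool <- rownames(mexp$values)
  for (i in which(pairs$pass_hyper)) {
    shared <- strsplit(pairs$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    shared <- intersect(shared, rownames(mexp$values))
    if (!length(shared)) next
    x <- rexp$values[pairs$rna_i[i], ]
    y <- rexp$values[pairs$rna_j[i], ]
    pcres <- partial_correlation(x, y, t(mexp$values[shared, , drop = FALSE]))
    pairs$pc[i] <- pcres$pc
    pairs$pc_p[i] <- pcres$pc_p
    pairs$sc[i] <- sensitivity_correlation(pairs$corr[i], pcres$pc)
    if (cfg$sc_filter_enabled) {
      pcfg <- cfg
      pcfg$seed <- derive_seed(cfg$seed,
                               paste(pairs$rna_i[i], pairs$rna_j[i], sep = "|"))
      pairs$sc_empirical_p[i] <- empirical_sc_pvalue(
        x, y, pairs$corr[i], pairs$sc[i], length(shared), mexp, pool, pcfg)
    }
  }
  pairs <- sc_filter(pairs, cfg)
  list(pairs = pairs, final = pairs[pairs$pass_sc, , drop = FALSE])
}

#' Correlation-based baseline inference
#'
#' The pairwise-correlation method used as comparison: a putative miRNA->RNA
#' edge is kept iff the miRNA and the RNA are negatively correlated
#' (r < 0, p < 0.05); RNA pairs sharing at least one surviving miRNA are
#' reported iff their mutual correlation passes `min_corr`/`corr_p`. No
#' hypergeometric or SC stages, no multi-omics covariates.
#'
#' @param rna_expr,mirna_expr z-scored tumor `ExpressionMatrix` objects.
#' @param putative `PutativeNetwork` or miRNA `InteractionTable` (step 1).
#' @param cfg a [cerna_config()].
#' @return list with `mirna_edges` (surviving negative-correlation edges) and
#'   `pairs` (final baseline ceRNA pairs).
#' @export
correlation_baseline <- function(rna_expr, mirna_expr, putative,
                                 cfg = cerna_config()) {
  interactions <- if (inherits(putative, "PutativeNetwork"))
    putative$interactions else putative
  common <- intersect(colnames(rna_expr$values), colnames(mirna_expr$values))
  keep <- logical(nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    mi <- interactions$regulator[i]; tg <- interactions$target[i]
    if (!(mi %in% rownames(mirna_expr$values)) ||
        !(tg %in% rownames(rna_expr$values))) next
    ct <- pearson_test(mirna_expr$values[mi, common], rna_expr$values[tg, common])
    keep[i] <- ct$r < 0 && ct$p < 0.05
  }
  edges <- interactions[keep, , drop = FALSE]
  class(edges) <- c("InteractionTable", "data.frame")
  pairs <- candidate_pairs(edges)
  if (nrow(pairs)) {
    rexp <- rna_expr; rexp$values <- rna_expr$values[, common, drop = FALSE]
    pairs <- pearson_filter(pairs, rexp, cfg)
    pairs <- pairs[pairs$pass_pearson, , drop = FALSE]
  }
  list(mirna_edges = edges, pairs = pairs)
}
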