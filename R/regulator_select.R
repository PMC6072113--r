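# Step 2: per-RNA LASSO-based selection of regulators among candidate miRNAs
# plus CNA, promoter methylation and TF covariates, with stability-selection
# and bootstrap confidence-interval filters.

#' LASSO selection configuration
#'
#' Defaults follow the published procedure: 100 LASSO runs with re-randomized
#' 10-fold CV assignments, covariates kept when selected in more than 75 runs,
#' 500 bootstrap refits for the 95% percentile confidence interval, and a
#' 100-point log-spaced lambda grid from lambda_max down to 1e-3*lambda_max.
#'
#' @param n_runs number of stability-selection runs.
#' @param freq_threshold strict selection-count threshold (kept if
#'   `selection_count > freq_threshold`).
#' @param n_bootstrap number of bootstrap refits.
#' @param ci_level confidence level of the percentile interval.
#' @param n_folds CV folds for the one-SE rule.
#' @param lambda_grid_size points on the lambda grid.
#' @param lambda_min_ratio smallest grid lambda as a fraction of lambda_max.
#' @param seed integer seed; the whole step is a pure function of
#'   (design, seed).
#' @return a `LassoConfig` list.
#' @export
lasso_config <- function(n_runs = 100, freq_threshold = 75, n_bootstrap = 500,
                         ci_level = 0.95, n_folds = 10, lambda_grid_size = 100,
                         lambda_min_ratio = 1e-3, seed = 1L) {
  stopifnot(n_runs > 0, freq_threshold > 0, n_bootstrap > 0,
            ci_level > 0, ci_level < 1, n_folds > 1, lambda_grid_size > 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(n_runs = as.integer(n_runs),
                 freq_threshold = freq_threshold,
                 n_bootstrap = as.integer(n_bootstrap),
                 ci_level = ci_level, n_folds = as.integer(n_folds),
                 lambda_grid_size = as.integer(lambda_grid_size),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "LassoConfig")
}

#' Regression design for one RNA
#'
#' Response is the z-scored tumor expression of one RNA; covariates are its
#' candidate miRNA expressions and, for mRNAs, its own copy number, promoter
#' methylation and candidate TF expressions. Covariates are z-scored here so
#' that a single penalty applies comparably to all of them; constant columns
#' are rejected.
#'
#' @param y numeric response vector.
#' @param X numeric covariate matrix (samples x covariates, named columns).
#' @param covariate_kind character vector (`"miRNA"`, `"CNA"`, `"DNAm"`,
#'   `"TF"`) parallel to the columns of `X`.
#' @param rna_id identifier of the response RNA.
#' @param standardize z-score covariate columns (default TRUE).
#' @return a `RegressionDesign` list.
#' @export
regression_design <- function(y, X, covariate_kind, rna_id = "RNA",
                              standardize = TRUE) {
  if (!is.matrix(X) || is.null(colnames(X))) stop("X must be a named matrix")
  if (length(y) != nrow(X)) stop("response and covariates must share samples")
  if (length(covariate_kind) != ncol(X))
    stop("covariate_kind must have one entry per column of X")
  if (!all(covariate_kind %in% c("miRNA", "CNA", "DNAm", "TF")))
    stop("covariate_kind entries must be miRNA/CNA/DNAm/TF")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (standardize) X <- scale(X)[, , drop = FALSE]
  structure(list(y = as.numeric(y), X = X,
                 covariate_kind = covariate_kind, rna_id = rna_id),
            class = "RegressionDesign")
}

#' Lambda grid for a design
#'
#' `lambda_max = max_j |<x_j, y>| / n` on the centered data (the smallest
#' penalty whose solution is all-zero, given the unpenalized intercept); the
#' grid is `size` log-spaced values
#' from lambda_max down to `lambda_max * min_ratio`, in decreasing order (ties
#' in the one-SE rule thereby break toward the larger lambda, i.e. the
#' simpler model).
#'
#' @param X covariate matrix, `y` response, `size` grid length,
#'   `min_ratio` lower-end ratio.
#' @param y,size,min_ratio see above.
#' @return decreasing numeric vector of lambdas.
#' @export
lasso_lambda_grid <- function(X, y, size = 100, min_ratio = 1e-3) {
  Xc <- sweep(X, 2, colMeans(X))
  lmax <- max(abs(crossprod(Xc, y - mean(y))) / nrow(X))
  if (lmax <= 0) lmax <- 1e-12
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = size))
}

make_folds <- function(n, nfolds) {
  if (n < nfolds) stop("fewer samples (", n, ") than folds (", nfolds, ")")
  sample(rep_len(seq_len(nfolds), n))
}

#' Fit the LASSO at the one-standard-error lambda
#'
#' 10-fold cross validation selects the largest lambda on the grid whose mean
#' CV error is within one standard error of the minimum; the returned
#' coefficients are the full-data coordinate-descent solution at that lambda.
#' The intercept is unpenalized (handled by centering).
#'
#' @param design a [regression_design()].
#' @param fold_seed integer seed for the fold assignment.
#' @param cfg a [lasso_config()].
#' @return list with `coefficients` (named), `intercept`, `lambda`,
#'   `lambda_index`, and the `grid`.
#' @export
fit_lasso_one_se <- function(design, fold_seed = 1L, cfg = lasso_config()) {
  stopifnot(inherits(design, "RegressionDesign"))
  n <- nrow(design$X)
  if (ncol(design$X) < 1) stop("need at least one covariate")
  grid <- lasso_lambda_grid(design$X, design$y, cfg$lambda_grid_size,
                            cfg$lambda_min_ratio)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(fold_seed)
  foldid <- make_folds(n, cfg$n_folds)
  mse <- cpp_cv_mse(design$X, design$y, foldid, grid)
  cvm <- rowMeans(mse)
  imin <- which.min(cvm)
  se <- sd(mse[imin, ]) / sqrt(ncol(mse))
  idx <- which(cvm <= cvm[imin] + se)[1]
  fit <- cpp_lasso_path(design$X, design$y, grid[seq_len(idx)])
  beta <- fit$beta[, idx]
  names(beta) <- colnames(design$X)
  list(coefficients = beta, intercept = fit$intercept[idx],
       lambda = grid[idx], lambda_index = idx, grid = grid)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Stability selection over repeated LASSO fits
#'
#' Runs `n_runs` one-SE LASSO fits that differ only in the (seeded) CV fold
#' assignment, counts how often each covariate has a non-zero coefficient,
#' and records the median coefficient over all runs (zeros included).
#' `frequently_selected` applies the strict `> freq_threshold` rule.
#'
#' @param design a [regression_design()].
#' @param cfg a [lasso_config()].
#' @return data.frame with one row per covariate: `covariate`, `kind`,
#'   `selection_count`, `median_coefficient`, `frequently_selected`.
#' @export
stability_select <- function(design, cfg = lasso_config()) {
  stopifnot(inherits(design, "RegressionDesign"))
  n <- nrow(design$X)
  grid <- lasso_lambda_grid(design$X, design$y, cfg$lambda_grid_size,
                            cfg$lambda_min_ratio)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)
  foldmat <- vapply(seq_len(cfg$n_runs), function(i) make_folds(n, cfg$n_folds),
                    integer(n))
  res <- cpp_stability(design$X, design$y, foldmat, grid)
  counts <- rowSums(res$coefficients != 0)
  med <- apply(res$coefficients, 1, median)
  data.frame(covariate = colnames(design$X), kind = design$covariate_kind,
             selection_count = as.integer(counts), median_coefficient = med,
             frequently_selected = counts > cfg$freq_threshold,
             stringsAsFactors = FALSE)
}

#' Bootstrap confidence-interval filter
#'
#' Refits the full one-SE LASSO procedure on `n_bootstrap` resamples of the
#' samples (with replacement, size n; resamples with a constant response are
#' redrawn and logged). The covariate's percentile interval (2.5%, 97.5% at
#' the default level) over bootstrap coefficients must contain its median
#' stability coefficient and must exclude zero for the covariate to be kept.
#'
#' @param design a [regression_design()].
#' @param stability result of [stability_select()] on the same design.
#' @param cfg a [lasso_config()].
#' @return a `RegulatorSelection` data.frame: the stability columns plus
#'   `ci_lo`, `ci_hi` and `kept`.
#' @export
bootstrap_ci_filter <- function(design, stability, cfg = lasso_config()) {
  stopifnot(inherits(design, "RegressionDesign"))
  n <- nrow(design$X)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  draw_idx <- function() {
    for (tries in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(design$y[idx]) > 0) return(idx)
      message("degenerate bootstrap resample (constant response); redrawn")
    }
    stop("could not draw a non-degenerate bootstrap resample")
  }
  idxmat <- vapply(seq_len(cfg$n_bootstrap), function(i) draw_idx(), integer(n))
  foldmat <- vapply(seq_len(cfg$n_bootstrap), function(i) make_folds(n, cfg$n_folds),
                    integer(n))
  coefs <- cpp_bootstrap(design$X, design$y, idxmat, foldmat,
                         nlambda = cfg$lambda_grid_size,
                         min_ratio = cfg$lambda_min_ratio)
  alpha <- (1 - cfg$ci_level) / 2
  ci <- t(apply(coefs, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  out <- stability
  out$ci_lo <- ci[, 1]
  out$ci_hi <- ci[, 2]
  out$kept <- out$frequently_selected &
    out$ci_lo <= out$median_coefficient &
    out$median_coefficient <= out$ci_hi &
    !(out$ci_lo <= 0 & out$ci_hi >= 0)
  class(out) <- c("RegulatorSelection", "data.frame")
  out
}

#' Directed miRNA edges from a completed regulator selection
#'
#' Of the kept covariates, only miRNAs with negative median coefficients
#' become miRNA->RNA interactions (miRNAs are repressors); kept CNA, DNAm and
#' TF covariates are summarized separately and never become miRNA edges.
#'
#' @param selections named list of `RegulatorSelection` tables, one per RNA
#'   (names are RNA ids), or a single table plus `rna_id`.
#' @param rna_id RNA id when a single table is passed.
#' @return list with `interactions` (an `InteractionTable`) and
#'   `regulator_summary` (kept covariates of every kind, per RNA).
#' @export
keep_negative_mirnas <- function(selections, rna_id = NULL) {
  if (inherits(selections, "RegulatorSelection")) {
    stopifnot(!is.null(rna_id))
    selections <- setNames(list(selections), rna_id)
  }
  rows <- lapply(names(selections), function(rna) {
    s <- selections[[rna]]
    k <- s[s$kept, , drop = FALSE]
    if (!nrow(k)) return(NULL)
    cbind(rna = rna, as.data.frame(k), stringsAsFactors = FALSE)
  })
  summary_df <- do.call(rbind, rows)
  if (is.null(summary_df))
    summary_df <- data.frame(rna = character(0), covariate = character(0),
                             kind = character(0), selection_count = integer(0),
                             median_coefficient = numeric(0),
                             frequently_selected = logical(0),
                             ci_lo = numeric(0), ci_hi = numeric(0),
                             kept = logical(0), stringsAsFactors = FALSE)
  mir <- summary_df[summary_df$kind == "miRNA" &
                      summary_df$median_coefficient < 0, , drop = FALSE]
  interactions <- interaction_table(mir$covariate, mir$rna, "miRNA",
                                    "lasso_selection")
  if (!nrow(mir))
    interactions <- interaction_table(character(0), character(0), "miRNA",
                                      "lasso_selection")
  list(interactions = interactions, regulator_summary = summary_df)
}

#' Kept-regulator percentages by kind (multi-omics summary)
#'
#' For RNAs with at least one kept miRNA regulator, the percentage that are
#' also under kept CNA, DNAm or TF regulation.
#'
#' @param regulator_summary the `regulator_summary` from
#'   [keep_negative_mirnas()].
#' @return data.frame with `kind` and `percent_of_targets`.
#' @export
regulator_kind_summary <- function(regulator_summary) {
  mir_rnas <- unique(regulator_summary$rna[regulator_summary$kind == "miRNA"])
  if (!length(mir_rnas))
    return(data.frame(kind = c("CNA", "DNAm", "TF"),
                      percent_of_targets = rep(NA_real_, 3)))
  pct <- vapply(c("CNA", "DNAm", "TF"), function(k) {
    with_k <- unique(regulator_summary$rna[regulator_summary$kind == k])
    100 * mean(mir_rnas %in% with_k)
  }, numeric(1))
  data.frame(kind = names(pct), percent_of_targets = unname(pct),
             stringsAsFactors = FALSE)
}

#' Ordinary-least-squares selection variant
#'
#' Multiple linear regression of the response on all covariates; a miRNA
#' covariate is kept iff its coefficient is negative and its t-test p-value
#' is below `alpha`. Rank-deficient designs are an error.
#'
#' @param design a [regression_design()].
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame per covariate: `covariate`, `kind`, `coefficient`, `p`,
#'   `kept` (miRNA sign-and-significance rule).
#' @export
ols_select <- function(design, alpha = 0.05) {
  stopifnot(inherits(design, "RegressionDesign"))
  n <- nrow(design$X); p <- ncol(design$X)
  if (n <= p + 1) stop("need n > #covariates + 1 for OLS")
  fit <- lm(design$y ~ design$X)
  if (fit$rank < p + 1) stop("rank-deficient design")
  sm <- summary(fit)$coefficients[-1, , drop = FALSE]
  data.frame(covariate = colnames(design$X), kind = design$covariate_kind,
             coefficient = sm[, 1], p = sm[, 4],
             kept = design$covariate_kind == "miRNA" & sm[, 1] < 0 & sm[, 4] < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Deterministic per-RNA seed stream: adding/removing an RNA does not perturb
# another RNA's randomness.
derive_seed <- function(seed, id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (x in utf8ToInt(as.character(id))) h <- (h * 31 + x) %% m
  as.integer(h)
}

#' Select regulators for every RNA in a putative network (step 2 driver)
#'
#' For each target RNA with expression available, builds the regression
#' design (candidate miRNAs; plus own CNA, own promoter methylation and
#' candidate TF expressions for mRNAs), runs stability selection and the
#' bootstrap CI filter, and assembles the selected miRNA->RNA network.
#' Randomness is keyed per RNA id from the global config seed.
#'
#' @param rna_expr z-scored tumor `ExpressionMatrix` of candidate ceRNAs.
#' @param mirna_expr z-scored tumor `ExpressionMatrix` of DE miRNAs.
#' @param putative `PutativeNetwork` or miRNA `InteractionTable` (step 1).
#' @param cna,dnam optional gene-level `ExpressionMatrix` objects (CNA and
#'   promoter methylation); matched to mRNA targets by feature id.
#' @param tf_net optional TF `InteractionTable`; `tf_expr` the TF expression
#'   matrix.
#' @param tf_expr optional TF `ExpressionMatrix`.
#' @param cfg a [lasso_config()].
#' @param method `"lasso"` (stability + bootstrap) or `"ols"`.
#' @param only_mirna when TRUE, drop CNA/DNAm/TF covariates from every design
#'   (the only_miRNA ablation variant).
#' @return list with `interactions` (selected miRNA->RNA `InteractionTable`),
#'   `selections` (per-RNA tables), `regulator_summary`.
#' @export
select_regulators <- function(rna_expr, mirna_expr, putative, cna = NULL,
                              dnam = NULL, tf_net = NULL, tf_expr = NULL,
                              cfg = lasso_config(),
                              method = c("lasso", "ols"),
                              only_mirna = FALSE) {
  method <- match.arg(method)
  interactions <- if (inherits(putative, "PutativeNetwork"))
    putative$interactions else putative
  targets <- split(interactions$regulator, interactions$target)
  common <- intersect(colnames(rna_expr$values), colnames(mirna_expr$values))
  if (length(common) < 3) stop("too few shared samples")
  selections <- list()
  for (rna in intersect(names(targets), rownames(rna_expr$values))) {
    cand <- intersect(targets[[rna]], rownames(mirna_expr$values))
    if (!length(cand)) next
    Xm <- t(mirna_expr$values[cand, common, drop = FALSE])
    kinds <- rep("miRNA", length(cand))
    X <- Xm
    if (!only_mirna) {
      if (!is.null(cna) && rna %in% rownames(cna$values)) {
        X <- cbind(X, CNA = cna$values[rna, common])
        kinds <- c(kinds, "CNA")
      }
      if (!is.null(dnam) && rna %in% rownames(dnam$values)) {
        X <- cbind(X, DNAm = dnam$values[rna, common])
        kinds <- c(kinds, "DNAm")
      }
      if (!is.null(tf_net) && !is.null(tf_expr)) {
        tfs <- intersect(tf_net$regulator[tf_net$target == rna],
                         rownames(tf_expr$values))
        if (length(tfs)) {
          X <- cbind(X, t(tf_expr$values[tfs, common, drop = FALSE]))
          kinds <- c(kinds, rep("TF", length(tfs)))
        }
      }
    }
    ok <- apply(X, 2, sd) > 0
    X <- X[, ok, drop = FALSE]; kinds <- kinds[ok]
    if (!ncol(X)) next
    y <- rna_expr$values[rna, common]
    if (sd(y) == 0) next
    design <- regression_design(y, X, kinds, rna_id = rna)
    if (method == "ols") {
      sel <- ols_select(design)
      sel$median_coefficient <- sel$coefficient
      selections[[rna]] <- sel
    } else {
      rcfg <- cfg
      rcfg$seed <- derive_seed(cfg$seed, rna)
      stab <- stability_select(design, rcfg)
      selections[[rna]] <- bootstrap_ci_filter(design, stab, rcfg)
    }
  }
  if (!length(selections))
    stop("no RNA produced a valid design; check inputs")
  net <- keep_negative_mirnas(selections)
  c(net, list(selections = selections))
}
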