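# Multi-omics synthetic data with planted regulatory and ceRNA structure.
# The generator emits post-preprocessing (z-scored, tumor-only) matrices by
# default, plus a raw-count mode to exercise the preprocessing path.

#' Synthetic scenario configuration
#'
#' Scenario presets encode the stated testing worlds:
#' * `recovery` - 30 miRNAs, 100 mRNAs, n = 200 tumor samples, planted
#'   negative miRNA effects with |beta| in \[0.4, 0.8\], CNA/DNAm/TF
#'   confounders active, noise sd 1, 3x decoy putative edges.
#' * `cerna` - groups of 3 RNAs sharing `k_true = 3` strong miRNAs
#'   (|beta| in \[0.6, 0.8\]) plus a within-group coupling term
#'   (sequestration-driven co-expression), background RNAs with private
#'   regulators.
#' * `null` - putative network with shared structure but zero planted
#'   effects (pure noise expression).
#' * `perturb` - the `cerna` world, intended to be paired with
#'   [generate_perturbations()].
#'
#' @param scenario one of `"recovery"`, `"cerna"`, `"null"`, `"perturb"`.
#' @param n_mirna,n_mrna,n_lncrna,n_tf feature counts.
#' @param n_samples tumor sample count.
#' @param effect_range magnitude range of planted miRNA effects (applied with
#'   negative sign).
#' @param noise_sd residual standard deviation.
#' @param k_true shared miRNAs per planted ceRNA group.
#' @param group_size RNAs per planted ceRNA group.
#' @param n_groups number of planted ceRNA groups (cerna/perturb).
#' @param coupling within-group coupling coefficient (cerna/perturb).
#' @param decoy_ratio decoy putative edges per planted edge.
#' @param confounders plant CNA/DNAm/TF effects on mRNAs.
#' @param raw_counts also emit Poisson raw-count matrices.
#' @param seed integer seed.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(scenario = c("recovery", "cerna", "null", "perturb"),
                         n_mirna = 30, n_mrna = NULL, n_lncrna = NULL,
                         n_tf = 5, n_samples = 200,
                         effect_range = NULL, noise_sd = 1,
                         k_true = 3, group_size = 3, n_groups = 8,
                         coupling = 0.5, decoy_ratio = 3,
                         confounders = TRUE, raw_counts = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(n_mrna)) n_mrna <- switch(scenario, recovery = 100, null = 40, 40)
  if (is.null(n_lncrna)) n_lncrna <- switch(scenario, recovery = 0, null = 8, 8)
  if (is.null(effect_range))
    effect_range <- if (scenario %in% c("cerna", "perturb")) c(0.6, 0.8) else c(0.4, 0.8)
  stopifnot(n_mirna >= 1, n_mrna >= 1, n_samples >= 10,
            all(effect_range > 0), noise_sd >= 0, k_true >= 1,
            decoy_ratio >= 0)
  structure(list(scenario = scenario, n_mirna = n_mirna, n_mrna = n_mrna,
                 n_lncrna = n_lncrna, n_tf = n_tf, n_samples = n_samples,
                 effect_range = sort(effect_range), noise_sd = noise_sd,
                 k_true = k_true, group_size = group_size, n_groups = n_groups,
                 coupling = coupling, decoy_ratio = decoy_ratio,
                 confounders = isTRUE(confounders),
                 raw_counts = isTRUE(raw_counts), seed = as.integer(seed)),
            class = "SynthConfig")
}

zscore_rows <- function(m) {
  sdv <- apply(m, 1, sd)
  if (any(sdv == 0))
    stop("cannot z-score constant row(s): ",
         paste(head(rownames(m)[sdv == 0], 5), collapse = ", "))
  (m - rowMeans(m)) / sdv
}

#' Generate a synthetic multi-omics dataset with planted structure
#'
#' miRNA, TF and CNA values are standard normal; promoter methylation is a
#' logistic transform of a standard normal (so beta lies in (0, 1)). Each
#' RNA's expression is the sum of its planted effects (negative miRNA
#' coefficients; additive CNA/DNAm/TF terms for mRNAs; within-group coupling
#' for ceRNA scenarios) plus Gaussian noise, then row z-scored. The putative
#' interaction table contains all planted miRNA edges plus decoys; DE labels
#' are all true by construction (the generator emulates post-DE data).
#'
#' @param cfg a [synth_config()].
#' @return list with `ExpressionMatrix` objects (`rna_expr`, `mirna_expr`,
#'   `tf_expr`, `cna`, `dnam`; optionally `rna_counts`/`mirna_counts`),
#'   interaction tables (`putative`, `tf_net`), DE label tables, `node_kind`
#'   and the `truth` record.
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  mir_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("gene%03d", seq_len(cfg$n_mrna))
  lnc_ids <- if (cfg$n_lncrna) sprintf("lnc%03d", seq_len(cfg$n_lncrna)) else character(0)
  tf_ids <- if (cfg$n_tf) sprintf("TF%02d", seq_len(cfg$n_tf)) else character(0)
  rna_ids <- c(mrna_ids, lnc_ids)
  samp <- sprintf("tumor%03d", seq_len(n))

  M <- matrix(rnorm(cfg$n_mirna * n), cfg$n_mirna, n,
              dimnames = list(mir_ids, samp))
  TFm <- if (cfg$n_tf) matrix(rnorm(cfg$n_tf * n), cfg$n_tf, n,
                              dimnames = list(tf_ids, samp)) else NULL

  null_world <- cfg$scenario == "null"
  grouped <- cfg$scenario %in% c("cerna", "perturb")

  # planted miRNA regulator sets per RNA
  reg <- setNames(vector("list", length(rna_ids)), rna_ids)
  eff <- setNames(vector("list", length(rna_ids)), rna_ids)
  groups <- list()
  if (!null_world) {
    if (grouped) {
      pool <- mir_ids
      for (g in seq_len(cfg$n_groups)) {
        members <- rna_ids[((g - 1) * cfg$group_size + 1):(g * cfg$group_size)]
        members <- members[!is.na(members)]
        shared <- if (length(pool) >= cfg$k_true) {
          s <- pool[seq_len(cfg$k_true)]; pool <- setdiff(pool, s); s
        } else sample(mir_ids, cfg$k_true)
        groups[[g]] <- list(members = members, shared = shared)
        for (r in members) {
          reg[[r]] <- shared
          eff[[r]] <- -runif(cfg$k_true, cfg$effect_range[1], cfg$effect_range[2])
        }
      }
      planted_members <- unlist(lapply(groups, `[[`, "members"))
      for (r in setdiff(rna_ids, planted_members)) {
        k <- sample(1:2, 1)
        reg[[r]] <- sample(mir_ids, k)
        eff[[r]] <- -runif(k, cfg$effect_range[1], cfg$effect_range[2])
      }
    } else {
      for (r in rna_ids) {
        k <- sample(2:4, 1)
        reg[[r]] <- sample(mir_ids, k)
        eff[[r]] <- -runif(k, cfg$effect_range[1], cfg$effect_range[2])
      }
    }
  }

  # mRNA confounders: prevalences mirror observed multi-omics regulator
  # percentages (CNA ~76%, DNAm ~30%, TF ~54% of targets)
  cna_vals <- matrix(rnorm(cfg$n_mrna * n), cfg$n_mrna, n,
                     dimnames = list(mrna_ids, samp))
  dnam_raw <- matrix(rnorm(cfg$n_mrna * n), cfg$n_mrna, n,
                     dimnames = list(mrna_ids, samp))
  dnam_beta <- 1 / (1 + exp(-dnam_raw))
  cna_eff <- setNames(numeric(cfg$n_mrna), mrna_ids)
  dnam_eff <- setNames(numeric(cfg$n_mrna), mrna_ids)
  tf_assign <- setNames(rep(NA_character_, cfg$n_mrna), mrna_ids)
  tf_eff <- setNames(numeric(cfg$n_mrna), mrna_ids)
  if (cfg$confounders && !null_world) {
    # planted ceRNA group members are driven by their shared miRNAs plus the
    # coupling term only: a detectable ceRNA pair requires miRNA-mediated
    # variance to dominate, so confounders act on background RNAs
    group_members <- unlist(lapply(groups, `[[`, "members"))
    eligible <- !(mrna_ids %in% group_members)
    has_cna <- runif(cfg$n_mrna) < 0.8 & eligible
    cna_eff[has_cna] <- runif(sum(has_cna), 0.5, 1.5)
    has_dnam <- runif(cfg$n_mrna) < 0.3 & eligible
    dnam_eff[has_dnam] <- -runif(sum(has_dnam), 0.2, 0.8)
    if (cfg$n_tf) {
      has_tf <- runif(cfg$n_mrna) < 0.54 & eligible
      tf_assign[has_tf] <- sample(tf_ids, sum(has_tf), replace = TRUE)
      tf_eff[has_tf] <- runif(sum(has_tf), 0.3, 0.9)
    }
  }

  coupling_u <- lapply(groups, function(g) rnorm(n))

  linpred <- matrix(0, length(rna_ids), n, dimnames = list(rna_ids, samp))
  dnam_z <- zscore_rows(dnam_beta)
  for (r in rna_ids) {
    lin <- rep(0, n)
    if (length(reg[[r]]))
      lin <- lin + as.vector(crossprod(M[reg[[r]], , drop = FALSE], eff[[r]]))
    if (r %in% mrna_ids) {
      lin <- lin + cna_eff[r] * cna_vals[r, ] + dnam_eff[r] * dnam_z[r, ]
      if (!is.na(tf_assign[r])) lin <- lin + tf_eff[r] * TFm[tf_assign[r], ]
    }
    if (grouped) {
      for (g in seq_along(groups)) {
        if (r %in% groups[[g]]$members)
          lin <- lin + cfg$coupling * coupling_u[[g]]
      }
    }
    linpred[r, ] <- lin
  }
  expr <- linpred + if (cfg$noise_sd > 0)
    matrix(rnorm(length(linpred), sd = cfg$noise_sd), nrow(linpred)) else 0

  planted <- do.call(rbind, lapply(rna_ids, function(r) {
    if (!length(reg[[r]])) return(NULL)
    data.frame(mirna = reg[[r]], rna = r, coefficient = eff[[r]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(planted))
    planted <- data.frame(mirna = character(0), rna = character(0),
                          coefficient = numeric(0), stringsAsFactors = FALSE)

  # putative network: planted edges plus decoys (database false positives)
  all_pairs <- expand.grid(mirna = mir_ids, rna = rna_ids,
                           stringsAsFactors = FALSE)
  pkey <- paste(planted$mirna, planted$rna)
  free <- all_pairs[!(paste(all_pairs$mirna, all_pairs$rna) %in% pkey), ]
  n_decoy <- min(nrow(free), ceiling(cfg$decoy_ratio * max(nrow(planted), 40)))
  decoys <- free[sample.int(nrow(free), n_decoy), , drop = FALSE]
  putative <- interaction_table(c(planted$mirna, decoys$mirna),
                                c(planted$rna, decoys$rna),
                                "miRNA",
                                c(rep("planted", nrow(planted)),
                                  rep("decoy", nrow(decoys))))

  tf_net <- NULL
  if (cfg$n_tf) {
    tf_rows <- !is.na(tf_assign)
    extra <- data.frame(regulator = sample(tf_ids, cfg$n_mrna %/% 4, replace = TRUE),
                        target = sample(mrna_ids, cfg$n_mrna %/% 4, replace = TRUE),
                        stringsAsFactors = FALSE)
    tf_net <- interaction_table(c(tf_assign[tf_rows], extra$regulator),
                                c(mrna_ids[tf_rows], extra$target),
                                "TF", "synthetic")
  }

  # planted ceRNA pairs: RNA pairs sharing >= k_true planted miRNAs
  cerna_pairs <- if (length(groups)) {
    do.call(rbind, lapply(groups, function(g) {
      cmb <- t(combn(sort(g$members), 2))
      data.frame(rna_i = cmb[, 1], rna_j = cmb[, 2],
                 n_shared = length(g$shared), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(rna_i = character(0), rna_j = character(0),
               n_shared = integer(0), stringsAsFactors = FALSE)
  }

  node_kind <- setNames(c(rep("mRNA", length(mrna_ids)),
                          rep("lncRNA", length(lnc_ids))), rna_ids)

  de_all <- function(ids) de_label_table(ids, rep(1, length(ids)),
                                         rep(0, length(ids)))
  out <- list(
    rna_expr = expression_matrix(zscore_rows(expr), "mixed", "zscore",
                                 setNames(rep("tumor", n), samp)),
    mirna_expr = expression_matrix(zscore_rows(M), "miRNA", "zscore",
                                   setNames(rep("tumor", n), samp)),
    tf_expr = if (cfg$n_tf) expression_matrix(TFm, "mRNA", "arbitrary") else NULL,
    cna = expression_matrix(cna_vals, "mRNA", "cna"),
    dnam = expression_matrix(dnam_beta, "mRNA", "beta"),
    putative = putative, tf_net = tf_net,
    de_mirnas = de_all(mir_ids), de_rnas = de_all(rna_ids),
    node_kind = node_kind,
    truth = structure(list(mirna_effects = planted,
                           cna_effects = cna_eff, dnam_effects = dnam_eff,
                           tf_assign = tf_assign, tf_effects = tf_eff,
                           cerna_pairs = cerna_pairs, groups = groups,
                           regulators = reg, linear_predictor = linpred,
                           noise_sd = cfg$noise_sd, n_samples = n,
                           seed = cfg$seed, config = cfg),
                      class = "SyntheticTruth"))
  if (cfg$raw_counts) {
    lam <- exp(pmin(linpred / 2 + 5, 20))
    cnt <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                  dimnames = dimnames(lam))
    out$rna_counts <- expression_matrix(cnt, "mixed", "raw_count",
                                        setNames(rep("tumor", n), samp))
  }
  out
}

#' Network of planted ceRNA pairs
#' @param truth a `SyntheticTruth`.
#' @return a `CeRNANetwork` of the planted pairs.
#' @export
truth_network <- function(truth) {
  if (!nrow(truth$cerna_pairs)) stop("truth contains no planted ceRNA pairs")
  cerna_network(truth$cerna_pairs, NULL)
}

#' Generate knockdown perturbations consistent with the planted model
#'
#' A fraction of RNAs is knocked down; for each knockdown, every other RNA
#' is profiled as a downstream gene. Downstream partners (RNAs sharing
#' planted miRNA regulators with the knocked-down RNA) receive a fold change
#' below 1 with magnitude proportional to the shared effect strength (miRNA
#' reallocation); non-partners receive FC = 1. Multiplicative log-normal
#' noise with sd `fc_noise_sd` is applied to all fold changes (`0` gives the
#' noise-free limit).
#'
#' @param truth a `SyntheticTruth`.
#' @param knockdown_fraction fraction of RNAs knocked down (default 0.3).
#' @param fc_noise_sd sd of the multiplicative log-normal noise (default 0).
#' @param timepoints timepoint tags to emit (same model per timepoint,
#'   independent noise).
#' @param seed integer seed.
#' @return a `PerturbationTable`.
#' @export
generate_perturbations <- function(truth, knockdown_fraction = 0.3,
                                   fc_noise_sd = 0,
                                   timepoints = "96h", seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  reg <- truth$regulators
  rnas <- names(reg)
  n_kd <- max(2L, ceiling(knockdown_fraction * length(rnas)))
  kd <- sample(rnas, n_kd)
  rows <- list()
  for (tp in timepoints) {
    for (up in kd) {
      for (down in setdiff(rnas, up)) {
        shared <- intersect(reg[[up]], reg[[down]])
        fc <- if (length(shared)) {
          e_up <- truth$mirna_effects
          strength <- sum(abs(e_up$coefficient[e_up$rna == up &
                                                 e_up$mirna %in% shared])) +
            sum(abs(e_up$coefficient[e_up$rna == down &
                                       e_up$mirna %in% shared]))
          exp(-0.5 * strength)
        } else 1
        if (fc_noise_sd > 0) fc <- fc * exp(rnorm(1, sd = fc_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          upstream = up, downstream = down, fold_change = fc,
          timepoint = tp, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  perturbation_table(df$upstream, df$downstream, df$fold_change, df$timepoint)
}

#' Write a generated scenario to disk in the package's exchange formats
#' @param sim output of [synth_generate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$rna_expr, file.path(dir, "rna_expr.tsv"))
  write_matrix(sim$mirna_expr, file.path(dir, "mirna_expr.tsv"))
  if (!is.null(sim$tf_expr)) write_matrix(sim$tf_expr, file.path(dir, "tf_expr.tsv"))
  write_matrix(sim$cna, file.path(dir, "cna.tsv"))
  write_matrix(sim$dnam, file.path(dir, "dnam.tsv"))
  write_interactions(sim$putative, file.path(dir, "putative.tsv"))
  if (!is.null(sim$tf_net)) write_interactions(sim$tf_net, file.path(dir, "tf_net.tsv"))
  write.table(sim$truth$mirna_effects, file.path(dir, "truth_mirna_effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
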