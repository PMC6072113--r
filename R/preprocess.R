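# Expression filtering, normalization, DE labeling, and gene-centric
# aggregation of methylation and copy number.

#' Preprocessing configuration
#'
#' @param cpm_threshold CPM value below which a feature counts as unexpressed
#'   in a sample (default 1).
#' @param de_alpha adjusted-p cutoff for calling differential expression
#'   (default 0.01).
#' @param log_offset offset added before log2 transform (default 0.001, so an
#'   abundance of 0 maps to log2(0.001) ~ -9.97).
#' @param promoter_min_upstream,promoter_max_upstream promoter window bounds in
#'   base pairs upstream of the TSS (defaults 200 and 1500, both inclusive).
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(cpm_threshold = 1, de_alpha = 0.01,
                              log_offset = 0.001,
                              promoter_min_upstream = 200,
                              promoter_max_upstream = 1500) {
  stopifnot(cpm_threshold > 0, de_alpha > 0, log_offset > 0,
            promoter_min_upstream > 0,
            promoter_max_upstream > promoter_min_upstream)
  structure(list(cpm_threshold = cpm_threshold, de_alpha = de_alpha,
                 log_offset = log_offset,
                 promoter_min_upstream = promoter_min_upstream,
                 promoter_max_upstream = promoter_max_upstream),
            class = "PreprocessConfig")
}

#' Convert raw counts to counts-per-million
#'
#' Each entry is divided by its sample's library size (column sum) and scaled
#' by 1e6, so every output column sums to 1e6.
#'
#' @param m an `ExpressionMatrix` with unit `raw_count`.
#' @return an `ExpressionMatrix` with unit `cpm`.
#' @export
counts_to_cpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "raw_count") stop("counts_to_cpm expects unit 'raw_count'")
  libs <- colSums(m$values)
  zero <- libs == 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(colnames(m$values)[zero], collapse = ", "))
  cpm <- sweep(m$values, 2, libs, "/") * 1e6
  expression_matrix(cpm, m$feature_kind, "cpm", m$sample_groups)
}

#' Low-expression filter on the CPM scale
#'
#' A feature is dropped if its CPM is below `cpm_threshold` in *more than*
#' t samples, where t is the larger of the tumor and normal group sizes.
#' Exactly t low samples keeps the feature (the sample-side rule is strict).
#'
#' @param m an `ExpressionMatrix` with unit `raw_count`.
#' @param groups named vector mapping every sample to `"normal"`/`"tumor"`;
#'   defaults to the matrix's own `sample_groups`.
#' @param cfg a [preprocess_config()].
#' @return character vector of kept feature ids.
#' @export
cpm_filter <- function(m, groups = m$sample_groups, cfg = preprocess_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(groups)) stop("groups are required")
  groups <- groups[colnames(m$values)]
  if (anyNA(groups)) stop("groups must cover every sample")
  n_norm <- sum(groups == "normal"); n_tum <- sum(groups == "tumor")
  if (n_norm == 0 || n_tum == 0)
    stop("both groups must be non-empty (normal: ", n_norm, ", tumor: ", n_tum, ")")
  t_thr <- max(n_norm, n_tum)
  cpm <- counts_to_cpm(m)$values
  n_low <- rowSums(cpm < cfg$cpm_threshold)
  rownames(m$values)[n_low <= t_thr]
}

#' Simple two-group differential-expression surrogate
#'
#' A pluggable surrogate for count-model DE callers: per-feature Wilcoxon
#' rank-sum or Welch t test between tumor and normal samples, BH-adjusted.
#' The log fold change is mean(tumor) - mean(normal) computed on
#' log2(x + log_offset) when the input is on a raw abundance scale, or on the
#' values as-is for already-log/z-scored input.
#'
#' @param m an `ExpressionMatrix`.
#' @param groups named normal/tumor vector (defaults to the matrix's).
#' @param method `"wilcoxon"` (default) or `"welch_t"`.
#' @param cfg a [preprocess_config()].
#' @return a `DELabelTable` data.frame with columns `feature_id`,
#'   `log_fold_change`, `adjusted_p`, `is_DE`.
#' @export
simple_de_test <- function(m, groups = m$sample_groups,
                           method = c("wilcoxon", "welch_t"),
                           cfg = preprocess_config()) {
  method <- match.arg(method)
  stopifnot(inherits(m, "ExpressionMatrix"))
  groups <- groups[colnames(m$values)]
  if (anyNA(groups)) stop("groups must cover every sample")
  tum <- groups == "tumor"; nor <- groups == "normal"
  if (sum(tum) < 2 || sum(nor) < 2) stop("need >= 2 samples per group")
  logv <- if (m$unit %in% c("raw_count", "cpm", "rpkm"))
    log2(m$values + cfg$log_offset) else m$values
  p <- apply(m$values, 1, function(x) {
    if (var(x) == 0) {
      warning("constant feature; p set to 1")
      return(1)
    }
    if (method == "wilcoxon")
      suppressWarnings(wilcox.test(x[tum], x[nor], exact = FALSE)$p.value)
    else
      t.test(x[tum], x[nor])$p.value
  })
  adj <- bh_adjust(p)
  df <- data.frame(feature_id = rownames(m$values),
                   log_fold_change = rowMeans(logv[, tum, drop = FALSE]) -
                     rowMeans(logv[, nor, drop = FALSE]),
                   adjusted_p = adj,
                   is_DE = adj < cfg$de_alpha,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("DELabelTable", "data.frame")
  df
}

#' Build a DE label table from externally computed results
#'
#' DE labels are a first-class pipeline input (count-model DE callers are out
#' of scope); this constructor enforces the label/threshold invariant.
#'
#' @param feature_id,log_fold_change,adjusted_p per-feature results.
#' @param de_alpha cutoff defining `is_DE` (default 0.01).
#' @return a `DELabelTable`.
#' @export
de_label_table <- function(feature_id, log_fold_change, adjusted_p,
                           de_alpha = 0.01) {
  if (any(adjusted_p < 0 | adjusted_p > 1)) stop("adjusted_p must lie in [0,1]")
  df <- data.frame(feature_id = as.character(feature_id),
                   log_fold_change = as.numeric(log_fold_change),
                   adjusted_p = as.numeric(adjusted_p),
                   is_DE = adjusted_p < de_alpha, stringsAsFactors = FALSE)
  class(df) <- c("DELabelTable", "data.frame")
  df
}

#' Log-transform and z-normalize over tumor samples
#'
#' Restricts the matrix to tumor samples, applies log2(x + log_offset), and
#' centers/scales each feature row to mean 0, sd 1 over those samples.
#' Zero-variance rows after the log transform are dropped with a warning.
#'
#' @param m an `ExpressionMatrix` on an abundance scale (e.g. `rpkm`).
#' @param tumor_sample_ids subset of the matrix's sample ids.
#' @param cfg a [preprocess_config()].
#' @return an `ExpressionMatrix` with unit `zscore` over the tumor samples.
#' @export
log_and_znormalize <- function(m, tumor_sample_ids, cfg = preprocess_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!all(tumor_sample_ids %in% colnames(m$values)))
    stop("tumor_sample_ids must be a subset of the matrix sample ids")
  x <- log2(m$values[, tumor_sample_ids, drop = FALSE] + cfg$log_offset)
  sdv <- apply(x, 1, sd)
  drop <- sdv == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance feature(s): ",
            paste(head(rownames(x)[drop], 5), collapse = ", "))
    x <- x[!drop, , drop = FALSE]
    sdv <- sdv[!drop]
  }
  z <- (x - rowMeans(x)) / sdv
  groups <- m$sample_groups
  if (!is.null(groups)) groups <- groups[tumor_sample_ids]
  expression_matrix(z, m$feature_kind, "zscore", groups)
}

#' Gene-level promoter methylation
#'
#' A gene's methylation level is the arithmetic mean of beta values over the
#' probes lying in its promoter window: positions in
#' \[tss - max_up, tss - min_up\] on the `+` strand, mirrored to
#' \[tss + min_up, tss + max_up\] on the `-` strand, both ends inclusive
#' (coordinates 1-based). Genes with no probe in the window are absent from
#' the output; genes missing from the annotation are skipped with a warning.
#'
#' @param beta probe-by-sample `ExpressionMatrix` with unit `beta`.
#' @param probes a [probe_annotation()].
#' @param genes a [gene_annotation()].
#' @param cfg a [preprocess_config()] (window bounds).
#' @return gene-by-sample `ExpressionMatrix` with unit `beta`.
#' @export
promoter_methylation <- function(beta, probes, genes, cfg = preprocess_config()) {
  stopifnot(inherits(beta, "ExpressionMatrix"), beta$unit == "beta")
  probes <- probes[probes$probe_id %in% rownames(beta$values), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      lo <- g$tss - cfg$promoter_max_upstream; hi <- g$tss - cfg$promoter_min_upstream
    } else {
      lo <- g$tss + cfg$promoter_min_upstream; hi <- g$tss + cfg$promoter_max_upstream
    }
    sel <- probes$chromosome == g$chromosome & probes$position >= lo &
      probes$position <= hi
    if (!any(sel)) next
    out[[g$gene_id]] <- colMeans(beta$values[probes$probe_id[sel], , drop = FALSE])
  }
  if (!length(out)) stop("no gene has a probe in its promoter window")
  vals <- do.call(rbind, out)
  expression_matrix(vals, "mRNA", "beta", beta$sample_groups)
}

#' Gene-level copy number from segmented data
#'
#' Each gene/sample value is the overlap-length-weighted mean of the segment
#' means of all segments intersecting the gene body. Genes with no overlapping
#' segment in at least one sample are dropped (logged via message).
#'
#' @param seg a [segment_table()].
#' @param genes a [gene_annotation()].
#' @return gene-by-sample `ExpressionMatrix` with unit `cna`.
#' @export
segments_to_gene_cna <- function(seg, genes) {
  samples <- unique(seg$sample_id)
  vals <- matrix(NA_real_, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    sub <- seg[seg$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      hit <- sub$chromosome == g$chromosome & sub$start <= g$end & sub$end >= g$start
      if (!any(hit)) next
      ov <- pmin(sub$end[hit], g$end) - pmax(sub$start[hit], g$start) + 1
      vals[i, s] <- sum(sub$segment_mean[hit] * ov) / sum(ov)
    }
  }
  keep <- complete.cases(vals)
  if (!all(keep))
    message("segments_to_gene_cna: dropping ", sum(!keep),
            " gene(s) with missing coverage: ",
            paste(head(rownames(vals)[!keep], 5), collapse = ", "))
  if (!any(keep)) stop("no gene covered by segments in every sample")
  expression_matrix(vals[keep, , drop = FALSE], "mRNA", "cna", NULL)
}

#' Multiple-testing adjustment (Benjamini-Hochberg step-up by default)
#'
#' Step-up adjusted values `adj p(i) = min_{j >= i} m * p(j) / j` over ranks,
#' monotone and capped at 1. `method = "bonferroni"` is available as the
#' conservative alternative.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1) || anyNA(p)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (method == "bonferroni") return(pmin(1, p * m))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
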