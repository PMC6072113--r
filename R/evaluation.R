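# Knockdown-based validation: ratio fold change of downstream ceRNAs and
# network accuracy.

#' Perturbation (knockdown) table
#'
#' Rows record the expression fold change of a downstream gene after shRNA
#' knockdown of an upstream gene at a given timepoint. Fold changes are on
#' the linear scale and must be positive; log-scale input must be
#' exponentiated by the caller.
#'
#' @param upstream,downstream gene ids.
#' @param fold_change positive fold change of the downstream gene.
#' @param timepoint timepoint tag (e.g. `"96h"`).
#' @return a `PerturbationTable` data.frame.
#' @export
perturbation_table <- function(upstream, downstream, fold_change, timepoint) {
  if (any(fold_change <= 0)) stop("fold_change must be > 0")
  df <- data.frame(upstream = as.character(upstream),
                   downstream = as.character(downstream),
                   fold_change = as.numeric(fold_change),
                   timepoint = as.character(timepoint),
                   stringsAsFactors = FALSE)
  key <- paste(df$upstream, df$downstream, df$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (upstream, downstream, timepoint) rows")
  class(df) <- c("PerturbationTable", "data.frame")
  df
}

#' Read a perturbation table from tab-delimited text
#' @param path file with header columns upstream, downstream, fold_change,
#'   timepoint.
#' @return a `PerturbationTable`.
#' @export
read_perturbations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  perturbation_table(df$upstream, df$downstream, df$fold_change, df$timepoint)
}

cerna_partners <- function(network, node) {
  e <- network$edges
  unique(c(e$rna_j[e$rna_i == node], e$rna_i[e$rna_j == node]))
}

#' Ratio fold change of one downstream ceRNA
#'
#' Mean fold change over knockdowns of the downstream gene's ceRNA partners
#' divided by the mean fold change over knockdowns of upstream genes that are
#' not its partners (arithmetic mean by default; `"geometric"` available).
#' An RFC below 1 supports the predicted interactions (partners' knockdown
#' frees shared miRNAs, which repress the downstream ceRNA).
#'
#' @param downstream downstream gene id.
#' @param network a `CeRNANetwork`.
#' @param perturb a `PerturbationTable`.
#' @param timepoint timepoint to evaluate.
#' @param aggregate `"arithmetic"` (default) or `"geometric"` mean.
#' @return the RFC, or NA (with a message) when the gene has no partner or
#'   no non-partner knockdown at the timepoint.
#' @export
ratio_fold_change <- function(downstream, network, perturb, timepoint,
                              aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  sub <- perturb[perturb$timepoint == timepoint &
                   perturb$downstream == downstream, , drop = FALSE]
  partners <- cerna_partners(network, downstream)
  fc_part <- sub$fold_change[sub$upstream %in% partners]
  fc_non <- sub$fold_change[!(sub$upstream %in% partners)]
  if (!length(fc_part) || !length(fc_non)) {
    message("downstream '", downstream,
            "' lacks partner or non-partner knockdowns; excluded")
    return(NA_real_)
  }
  agg <- if (aggregate == "arithmetic") mean else function(v) exp(mean(log(v)))
  agg(fc_part) / agg(fc_non)
}

#' Accuracy of a ceRNA network against knockdown data
#'
#' The percentage of evaluable downstream ceRNAs (network nodes profiled as
#' downstream genes with both partner and non-partner knockdowns at the
#' timepoint) whose RFC is below 1.
#'
#' @param network a `CeRNANetwork`.
#' @param perturb a `PerturbationTable`.
#' @param timepoint timepoint to evaluate.
#' @param aggregate passed to [ratio_fold_change()].
#' @return list with `accuracy` (percent), `n_evaluable`, and the per-gene
#'   `rfc` vector.
#' @export
network_accuracy <- function(network, perturb, timepoint,
                             aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  nodes <- igraph::V(network$graph)$name
  down <- intersect(nodes, unique(perturb$downstream[perturb$timepoint == timepoint]))
  rfc <- vapply(down, function(d)
    suppressMessages(ratio_fold_change(d, network, perturb, timepoint, aggregate)),
    numeric(1))
  rfc <- rfc[!is.na(rfc)]
  if (!length(rfc)) stop("no evaluable downstream ceRNA at timepoint ", timepoint)
  list(accuracy = 100 * mean(rfc < 1), n_evaluable = length(rfc), rfc = rfc)
}
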