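#' @useDynLib cernet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm median pnorm pt quantile rbinom rnorm runif rpois sd setNames var wilcox.test t.test p.adjust complete.cases coef
#' @importFrom utils combn read.delim write.table head
NULL

EXPR_UNITS <- c("raw_count", "cpm", "rpkm", "log2", "zscore", "beta", "cna", "arbitrary")
FEATURE_KINDS <- c("miRNA", "mRNA", "lncRNA", "mixed")

#' Feature-by-sample expression matrix with typed unit and sample groups
#'
#' The central data container of the pipeline: a numeric matrix (features in
#' rows, samples in columns) tagged with the kind of feature it holds, the unit
#' its entries are expressed in, and an optional normal/tumor group label per
#' sample. Unit-specific invariants are enforced at construction: raw counts
#' must be non-negative, methylation beta values must lie in \[0, 1\], and
#' z-scored rows must have mean ~0 and sd ~1 (tolerance 1e-8).
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids); no missing values.
#' @param feature_kind one of `"miRNA"`, `"mRNA"`, `"lncRNA"`, `"mixed"`.
#' @param unit one of `"raw_count"`, `"cpm"`, `"rpkm"`, `"log2"`, `"zscore"`,
#'   `"beta"`, `"cna"`, `"arbitrary"`.
#' @param sample_groups optional named character vector mapping every sample id
#'   to `"normal"` or `"tumor"`.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, feature_kind, unit, sample_groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have rownames (feature ids) and colnames (sample ids)")
  feature_kind <- match.arg(feature_kind, FEATURE_KINDS)
  unit <- match.arg(unit, EXPR_UNITS)
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(values)) stop("missing values are not allowed in an ExpressionMatrix")
  if (unit == "raw_count" && any(values < 0))
    stop("raw_count entries must be non-negative")
  if (unit == "beta" && (any(values < 0) || any(values > 1)))
    stop("beta entries must lie in [0, 1]")
  if (unit == "zscore" && nrow(values) > 0 && ncol(values) > 1) {
    mu <- rowMeans(values)
    sdv <- apply(values, 1, sd)
    bad <- abs(mu) > 1e-8 | abs(sdv - 1) > 1e-8
    if (any(bad))
      stop("zscore rows must have mean 0 and sd 1 (tolerance 1e-8); offenders: ",
           paste(head(rownames(values)[bad], 5), collapse = ", "))
  }
  if (!is.null(sample_groups)) {
    if (is.null(names(sample_groups)) ||
        !all(colnames(values) %in% names(sample_groups)))
      stop("sample_groups must be named and cover every sample id")
    sample_groups <- sample_groups[colnames(values)]
    if (!all(sample_groups %in% c("normal", "tumor")))
      stop("sample_groups values must be 'normal' or 'tumor'")
  }
  structure(list(values = values, feature_kind = feature_kind, unit = unit,
                 sample_groups = sample_groups),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s feature(s) x %d sample(s) [unit: %s]\n",
              nrow(x$values), x$feature_kind, ncol(x$values), x$unit))
  if (!is.null(x$sample_groups))
    cat("  groups:", paste(names(table(x$sample_groups)),
                           table(x$sample_groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample ids of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of ids.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(m$values)

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a delimited feature-by-sample matrix
#'
#' First column holds feature ids, the header row holds sample ids. The
#' delimiter is auto-detected between tab and comma. Non-numeric or missing
#' cells are rejected with their row/column location; duplicated ids are
#' rejected naming the offenders.
#'
#' @param path file path.
#' @param unit,feature_kind declared unit and feature kind
#'   (see [expression_matrix()]).
#' @param sample_groups optional named group vector, passed through.
#' @return an `ExpressionMatrix`.
#' @export
read_matrix <- function(path, unit, feature_kind, sample_groups = NULL) {
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file must have a feature-id column and >= 1 sample column")
  fid <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) , arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing cell at feature '%s', sample '%s'",
                 fid[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  }
  dimnames(num) <- list(fid, colnames(raw))
  expression_matrix(num, feature_kind = feature_kind, unit = unit,
                    sample_groups = sample_groups)
}

#' Write an ExpressionMatrix as tab-delimited text
#'
#' Output is always tab-delimited with a `feature_id` first column; values are
#' printed at full precision so that read/write round-trips are lossless.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$values),
                   format(m$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(m$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Directed regulator-target interaction table
#'
#' Rows are (regulator, target) pairs of a single regulator kind with a
#' provenance tag. Duplicate (regulator, target, kind) triples are collapsed,
#' joining their provenance tags with `";"`.
#'
#' @param regulator,target character vectors of equal length.
#' @param regulator_kind `"miRNA"` or `"TF"` (scalar or vector).
#' @param source_tag provenance string (scalar or vector).
#' @return an `InteractionTable` (a `data.frame` subclass).
#' @export
interaction_table <- function(regulator, target, regulator_kind = "miRNA",
                              source_tag = "unspecified") {
  if (length(regulator) != length(target))
    stop("regulator and target must have equal length")
  if (!all(regulator_kind %in% c("miRNA", "TF")))
    stop("regulator_kind must be 'miRNA' or 'TF'")
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   regulator_kind = rep_len(as.character(regulator_kind), length(regulator)),
                   source_tag = rep_len(as.character(source_tag), length(regulator)),
                   stringsAsFactors = FALSE)
  key <- paste(df$regulator, df$target, df$regulator_kind, sep = "\r")
  if (anyDuplicated(key)) {
    tags <- split(df$source_tag, key)
    df <- df[!duplicated(key), , drop = FALSE]
    df$source_tag <- vapply(paste(df$regulator, df$target, df$regulator_kind, sep = "\r"),
                            function(k) paste(sort(unique(unlist(strsplit(tags[[k]], ";", fixed = TRUE)))),
                                              collapse = ";"),
                            character(1), USE.NAMES = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("InteractionTable", "data.frame")
  df
}

#' Read a two-column regulator-target interaction list
#'
#' Headerless two-column delimited text (regulator, target); tab or comma
#' delimiter auto-detected. The result is deduplicated.
#'
#' @param path file path.
#' @param regulator_kind `"miRNA"` or `"TF"`.
#' @param source_tag provenance tag stored with every row.
#' @return an `InteractionTable`.
#' @export
read_interactions <- function(path, regulator_kind = "miRNA",
                              source_tag = basename(path)) {
  if (!file.size(path)) stop("empty interaction file: ", path)
  delim <- detect_delim(path)
  first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  has_header <- identical(tolower(first[1:2]), c("regulator", "target"))
  df <- read.delim(path, sep = delim, header = has_header,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty interaction file: ", path)
  if (ncol(df) < 2) stop("interaction file must have two columns")
  interaction_table(df[[1]], df[[2]], regulator_kind, source_tag)
}

#' Union of interaction tables
#'
#' Aggregates tables from several sources; a pair present in more than one
#' source keeps all source tags (joined with `";"`).
#'
#' @param ... `InteractionTable` objects.
#' @return an `InteractionTable`.
#' @export
merge_interactions <- function(...) {
  tabs <- list(...)
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  interaction_table(df$regulator, df$target, df$regulator_kind, df$source_tag)
}

#' Write an InteractionTable as tab-delimited text
#' @param x an `InteractionTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation with strand-aware transcription start site
#'
#' Coordinates are 1-based inclusive (GENCODE GTF convention). The TSS is the
#' `start` coordinate for `+`-strand genes and the `end` coordinate for
#' `-`-strand genes.
#'
#' @param gene_id,chromosome character vectors.
#' @param start,end 1-based inclusive integer positions, `start <= end`.
#' @param strand `"+"` or `"-"` per gene.
#' @return a `GeneAnnotation` data.frame with a `tss` column.
#' @export
gene_annotation <- function(gene_id, chromosome, start, end, strand) {
  if (any(start > end)) stop("start must be <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   tss = ifelse(strand == "+", as.integer(start), as.integer(end)),
                   stringsAsFactors = FALSE)
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Methylation probe annotation
#' @param probe_id unique probe identifiers.
#' @param chromosome chromosome per probe.
#' @param position 1-based probe position.
#' @return a `ProbeAnnotation` data.frame.
#' @export
probe_annotation <- function(probe_id, chromosome, position) {
  if (anyDuplicated(probe_id)) stop("duplicate probe ids")
  df <- data.frame(probe_id = as.character(probe_id),
                   chromosome = as.character(chromosome),
                   position = as.integer(position), stringsAsFactors = FALSE)
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Copy-number segment table
#'
#' Segments within a sample must not overlap on the same chromosome; a
#' violation is an error (it indicates malformed segmentation output).
#'
#' @param sample_id,chromosome character vectors.
#' @param start,end 1-based inclusive segment bounds.
#' @param segment_mean estimated mean copy number of each segment.
#' @return a `SegmentTable` data.frame.
#' @export
segment_table <- function(sample_id, chromosome, start, end, segment_mean) {
  if (any(start > end)) stop("segment start must be <= end")
  df <- data.frame(sample_id = as.character(sample_id),
                   chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   segment_mean = as.numeric(segment_mean),
                   stringsAsFactors = FALSE)
  for (grp in split(df, paste(df$sample_id, df$chromosome, sep = "\r"))) {
    if (nrow(grp) < 2) next
    o <- order(grp$start)
    if (any(grp$start[o][-1] <= grp$end[o][-nrow(grp)]))
      stop("overlapping segments for sample ", grp$sample_id[1],
           " on chromosome ", grp$chromosome[1])
  }
  class(df) <- c("SegmentTable", "data.frame")
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT lines: set name, description, then one or more member gene
#' ids, tab-separated. Lines with fewer than three fields are an error.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`: named list with `description` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, members)")
    sets[[f[1]]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a GeneSetCollection as GMT
#' @param sets a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
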