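# End-to-end orchestration: config, staged pipeline runs with provenance,
# and run summaries. Variants (only_mirna, ols, no_sc_filter,
# correlation_baseline) are first-class.

PIPELINE_VARIANTS <- c("cancerin", "only_mirna", "ols", "no_sc_filter",
                       "correlation_baseline")

#' Pipeline configuration
#'
#' @param seed global integer seed; per-stage and per-RNA streams are derived
#'   from it (keyed by feature id, so adding an RNA does not perturb another
#'   RNA's randomness).
#' @param variant one of `"cancerin"` (full pipeline), `"only_mirna"`
#'   (no CNA/DNAm/TF covariates), `"ols"` (OLS selection in step 2),
#'   `"no_sc_filter"` (SC stage passes everything), or
#'   `"correlation_baseline"`.
#' @param scenario synthetic scenario name (`"recovery"`, `"cerna"`,
#'   `"null"`, `"perturb"`) when no input paths are given.
#' @param inputs optional named list of file paths (`rna_expr`,
#'   `mirna_expr`, `putative`, and optionally `cna`, `dnam`, `tf_net`,
#'   `tf_expr`).
#' @param lasso,cerna named lists of overrides for [lasso_config()] /
#'   [cerna_config()].
#' @param synth named list of overrides for [synth_config()].
#' @param hub_quantile hub degree quantile.
#' @param min_module_size smallest module used in enrichment.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 1L, variant = "cancerin",
                            scenario = "cerna", inputs = NULL,
                            lasso = list(), cerna = list(), synth = list(),
                            hub_quantile = 0.90, min_module_size = 10) {
  variant <- match.arg(variant, PIPELINE_VARIANTS)
  structure(list(seed = as.integer(seed), variant = variant,
                 scenario = scenario, inputs = inputs, lasso = lasso,
                 cerna = cerna, synth = synth, hub_quantile = hub_quantile,
                 min_module_size = min_module_size),
            class = "PipelineConfig")
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    groups_t <- NULL
    rna <- read_matrix(inp$rna_expr, "zscore", "mixed")
    mir <- read_matrix(inp$mirna_expr, "zscore", "miRNA")
    list(rna_expr = rna, mirna_expr = mir,
         putative = read_interactions(inp$putative, "miRNA", "input"),
         cna = if (!is.null(inp$cna)) read_matrix(inp$cna, "cna", "mRNA"),
         dnam = if (!is.null(inp$dnam)) read_matrix(inp$dnam, "beta", "mRNA"),
         tf_net = if (!is.null(inp$tf_net))
           read_interactions(inp$tf_net, "TF", "input"),
         tf_expr = if (!is.null(inp$tf_expr))
           read_matrix(inp$tf_expr, "arbitrary", "mRNA"),
         de_mirnas = NULL, de_rnas = NULL, node_kind = NULL, truth = NULL)
  } else {
    scfg <- do.call(synth_config,
                    c(list(scenario = config$scenario, seed = config$seed),
                      config$synth))
    synth_generate(scfg)
  }
}

#' Run the full inference pipeline
#'
#' Executes step 1 (DE restriction of the putative network), step 2
#' (regulator selection, per variant), step 3 (ceRNA filtering, per variant)
#' and the network characterization, writing every stage output plus a
#' provenance record into `outdir`. Outputs carry no timestamps, so a rerun
#' with the same config and seed is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @return the run directory, invisibly; side effect: stage TSV/JSON files.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dat <- load_pipeline_inputs(config)

  # step 1: DE restriction (synthetic data is post-DE by construction)
  step1 <- if (!is.null(dat$de_mirnas))
    restrict_to_de(dat$putative, dat$de_mirnas, dat$de_rnas)
  else dat$putative
  step1_tab <- if (inherits(step1, "PutativeNetwork")) step1$interactions else step1
  write_interactions(step1_tab, file.path(outdir, "step1_interactions.tsv"))

  lcfg <- do.call(lasso_config, c(list(seed = config$seed), config$lasso))
  ccfg <- do.call(cerna_config,
                  c(list(seed = config$seed,
                         sc_filter_enabled = config$variant != "no_sc_filter"),
                    config$cerna))

  counts <- list(step1_interactions = nrow(step1_tab))

  if (config$variant == "correlation_baseline") {
    base <- correlation_baseline(dat$rna_expr, dat$mirna_expr, step1, ccfg)
    sel_net <- base$mirna_edges
    pairs_all <- base$pairs
    final <- if (nrow(pairs_all)) pairs_all else pairs_all
    write_interactions(sel_net, file.path(outdir, "selected_interactions.tsv"))
  } else {
    sel <- select_regulators(
      dat$rna_expr, dat$mirna_expr, step1,
      cna = dat$cna, dnam = dat$dnam,
      tf_net = dat$tf_net, tf_expr = dat$tf_expr, cfg = lcfg,
      method = if (config$variant == "ols") "ols" else "lasso",
      only_mirna = config$variant == "only_mirna")
    sel_net <- sel$interactions
    write_interactions(sel_net, file.path(outdir, "selected_interactions.tsv"))
    write.table(sel$regulator_summary,
                file.path(outdir, "regulator_selection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res3 <- infer_cerna(sel_net, dat$rna_expr, dat$mirna_expr, ccfg,
                        n_de_mirnas = nrow(dat$mirna_expr$values))
    pairs_all <- res3$pairs
    final <- res3$final
  }
  counts$selected_interactions <- nrow(sel_net)
  counts$candidate_pairs <- nrow(pairs_all)
  counts$final_pairs <- nrow(final)

  write.table(pairs_all, file.path(outdir, "cerna_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(final, file.path(outdir, "cerna_final.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (nrow(final)) {
    net <- cerna_network(final, dat$node_kind)
    modules <- detect_modules(net, seed = config$seed)
    hubs <- call_hubs(net, config$hub_quantile)
    nodes <- data.frame(node = names(net$degree),
                        degree = as.integer(net$degree),
                        module = as.integer(modules[names(net$degree)]),
                        hub = names(net$degree) %in% hubs,
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$node), , drop = FALSE]
    write.table(nodes, file.path(outdir, "nodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$nodes <- nrow(nodes)
    counts$modules <- length(unique(nodes$module))
    counts$hubs <- sum(nodes$hub)
    pl <- tryCatch(powerlaw_loglog_fit(net), error = function(e) NULL)
    if (!is.null(pl)) counts$powerlaw_slope <- pl$slope
    if (!is.null(dat$node_kind))
      counts$pair_types <- as.list(pair_type_summary(net))
  } else {
    counts$nodes <- 0; counts$modules <- 0; counts$hubs <- 0
  }

  prov <- list(package_version = as.character(utils::packageVersion("cernet")),
               seed = config$seed, variant = config$variant,
               scenario = if (is.null(config$inputs)) config$scenario else NULL,
               lasso = config$lasso, cerna = config$cerna,
               counts = counts)
  json_write(prov, file.path(outdir, "provenance.json"))
  invisible(outdir)
}

#' Summarize a completed pipeline run
#'
#' Recomputes interaction/pair/node counts from the stage files and writes a
#' deterministic `report.json`. Missing stage artifacts are an error listing
#' them.
#'
#' @param outdir a completed run directory.
#' @return the report list, invisibly; side effect: `report.json`.
#' @export
summarize_run <- function(outdir) {
  need <- c("step1_interactions.tsv", "selected_interactions.tsv",
            "cerna_pairs.tsv", "cerna_final.tsv", "provenance.json")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing))
    stop("incomplete run; missing: ", paste(missing, collapse = ", "))
  cnt_rows <- function(f) {
    df <- tryCatch(read.delim(file.path(outdir, f)), error = function(e) NULL)
    if (is.null(df)) 0L else nrow(df)
  }
  final <- tryCatch(read.delim(file.path(outdir, "cerna_final.tsv")),
                    error = function(e) data.frame())
  report <- list(
    step1_interactions = cnt_rows("step1_interactions.tsv"),
    selected_interactions = cnt_rows("selected_interactions.tsv"),
    candidate_pairs = cnt_rows("cerna_pairs.tsv"),
    final_pairs = if (nrow(final)) nrow(final) else 0L,
    cernas = if (nrow(final)) length(unique(c(final$rna_i, final$rna_j))) else 0L)
  json_write(report, file.path(outdir, "report.json"))
  invisible(report)
}

#' Parse a plain key-value pipeline config file
#'
#' Lines of the form `key: value`; dotted keys populate the nested stage
#' configs (e.g. `lasso.n_runs: 50`, `cerna.min_corr: 0.5`). Unknown keys
#' are an error.
#'
#' @param path config file path.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  cfg <- list(lasso = list(), cerna = list(), synth = list())
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("unparseable config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
    else if (val %in% c("true", "false", "TRUE", "FALSE"))
      as.logical(toupper(val)) else val
    if (grepl("\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (!parts[1] %in% c("lasso", "cerna", "synth"))
        stop("unknown config section: ", parts[1])
      cfg[[parts[1]]][[parts[2]]] <- parsed
    } else {
      if (!key %in% c("seed", "variant", "scenario", "hub_quantile",
                      "min_module_size"))
        stop("unknown config key: ", key)
      cfg[[key]] <- parsed
    }
  }
  do.call(pipeline_config, cfg)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all`, `summarize`. Used by the
#' `inst/cli/cernet` script; exposed as a function so it is testable.
#'
#' @param args character vector of CLI arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cernet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cernet <subcommand> [options]",
    "  simulate  --scenario <name> --seed <int> --out <dir>",
    "  run-all   [--config <file>] [--scenario <name>] [--variant <name>]",
    "            [--seed <int>] --out <dir>",
    "  summarize --out <dir>", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  opt <- list(scenario = "cerna", seed = 1L, out = NULL, variant = "cancerin",
              config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$out)) stop("--out is required")
  opt$seed <- as.integer(opt$seed)
  if (sub == "simulate") {
    sim <- synth_generate(synth_config(opt$scenario, seed = opt$seed))
    write_synth_scenario(sim, opt$out)
  } else if (sub == "run-all") {
    config <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
    else pipeline_config(seed = opt$seed, variant = opt$variant,
                         scenario = opt$scenario)
    run_pipeline(config, opt$out)
    summarize_run(opt$out)
  } else if (sub == "summarize") {
    summarize_run(opt$out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
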