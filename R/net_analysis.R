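# Characterization of the inferred ceRNA network: degree/power-law
# statistics, multilevel modularity clustering, module gene-set enrichment,
# hub calling and overlap counting against external interaction sets.

#' Build a ceRNA network object from final pairs
#'
#' @param pairs data.frame with `rna_i`, `rna_j` columns (final ceRNA pairs).
#' @param node_kind optional named vector mapping node id to `"mRNA"` or
#'   `"lncRNA"` (used for the pair-type summary).
#' @return a `CeRNANetwork`: list with the `igraph` graph, `edges`, and
#'   per-node `degree`.
#' @export
cerna_network <- function(pairs, node_kind = NULL) {
  if (!nrow(pairs)) stop("empty pair set")
  g <- igraph::graph_from_data_frame(pairs[, c("rna_i", "rna_j")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  structure(list(graph = g,
                 edges = data.frame(rna_i = pairs$rna_i, rna_j = pairs$rna_j,
                                    stringsAsFactors = FALSE),
                 degree = igraph::degree(g),
                 node_kind = node_kind),
            class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  cat(sprintf("CeRNANetwork: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Pair-type counts (mRNA-mRNA / mRNA-lncRNA / lncRNA-lncRNA)
#' @param network a `CeRNANetwork` with `node_kind` set.
#' @return named integer vector of edge counts by pair type.
#' @export
pair_type_summary <- function(network) {
  if (is.null(network$node_kind)) stop("node_kind is required")
  k1 <- network$node_kind[network$edges$rna_i]
  k2 <- network$node_kind[network$edges$rna_j]
  typ <- ifelse(k1 == "mRNA" & k2 == "mRNA", "mRNA-mRNA",
                ifelse(k1 == "lncRNA" & k2 == "lncRNA", "lncRNA-lncRNA",
                       "mRNA-lncRNA"))
  c("mRNA-mRNA" = sum(typ == "mRNA-mRNA"),
    "mRNA-lncRNA" = sum(typ == "mRNA-lncRNA"),
    "lncRNA-lncRNA" = sum(typ == "lncRNA-lncRNA"))
}

#' Log-log power-law fit of the degree distribution
#'
#' Least-squares line through (log k, log p(k)) over observed degrees, where
#' p(k) is the fraction of nodes with degree k (natural log). Accepts either
#' a `CeRNANetwork` or a named numeric vector of degree probabilities (names
#' are the degrees), which permits analytic inputs.
#'
#' @param x a `CeRNANetwork` or a named degree-probability vector.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
powerlaw_loglog_fit <- function(x) {
  if (inherits(x, "CeRNANetwork")) {
    deg <- x$degree
    tab <- table(deg[deg > 0])
    pk <- as.numeric(tab) / length(deg)
    k <- as.numeric(names(tab))
  } else {
    k <- as.numeric(names(x))
    pk <- as.numeric(x)
  }
  if (length(k) < 3) stop("need >= 3 distinct positive degrees")
  fit <- lm(log(pk) ~ log(k))
  rss <- sum(fit$residuals^2)
  tss <- sum((log(pk) - mean(log(pk)))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - rss / tss)
}

#' Multilevel (Louvain) module detection
#'
#' Greedy modularity maximization via the multilevel algorithm; deterministic
#' under a fixed seed. The result's modularity is checked to be at least that
#' of the all-singletons partition.
#'
#' @param network a `CeRNANetwork`.
#' @param seed integer seed.
#' @return named integer vector: module id per node.
#' @export
detect_modules <- function(network, seed = 1L) {
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  memb <- igraph::membership(cl)
  singletons <- seq_len(igraph::vcount(g))
  if (igraph::modularity(g, memb) <
      igraph::modularity(g, singletons) - 1e-12)
    stop("modularity below the singleton partition; clustering failed")
  out <- as.integer(memb)
  names(out) <- igraph::V(g)$name
  out
}

#' Modularity of a partition of a CeRNANetwork
#' @param network a `CeRNANetwork`.
#' @param membership named or ordered module ids per node.
#' @return modularity value.
#' @export
network_modularity <- function(network, membership) {
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(network$graph)$name]
  igraph::modularity(network$graph, as.integer(factor(membership)))
}

#' Gene-set over-representation p-value (shared hypergeometric kernel)
#'
#' One-sided over-representation probability of observing at least
#' `length(intersect(hits, category))` category members among the hits, via
#' the same kernel as the shared-regulator test.
#'
#' @param hits,category,universe character vectors; `hits` and `category`
#'   must be subsets of `universe`.
#' @return p-value.
#' @export
gene_set_hypergeom <- function(hits, category, universe) {
  hits <- unique(hits); category <- unique(category); universe <- unique(universe)
  if (!all(hits %in% universe) || !all(category %in% universe))
    stop("hits and category must be subsets of the universe")
  ov <- length(intersect(hits, category))
  if (ov == 0) return(1)
  hypergeom_shared_pvalue(length(universe), length(hits), length(category), ov)
}

#' Gene-set enrichment of network modules
#'
#' One-sided hypergeometric over-representation test of every (module, set)
#' combination, BH-adjusted across all tests jointly. Modules below
#' `min_module_size` are skipped; sets disjoint from the universe are skipped
#' with a warning.
#'
#' @param assignment named module-id vector ([detect_modules()]).
#' @param sets a `GeneSetCollection`.
#' @param universe background gene ids (must cover all module members).
#' @param min_module_size smallest module tested (default 10).
#' @param alpha significance threshold recorded in `enriched`.
#' @return an `EnrichmentResult` data.frame.
#' @export
enrich_modules <- function(assignment, sets, universe, min_module_size = 10,
                           alpha = 0.05) {
  if (!all(names(assignment) %in% universe))
    stop("universe must contain every module member")
  universe <- unique(universe)
  rows <- list()
  for (mod in sort(unique(assignment))) {
    members <- names(assignment)[assignment == mod]
    if (length(members) < min_module_size) next
    for (nm in names(sets)) {
      genes <- intersect(sets[[nm]]$genes, universe)
      if (!length(genes)) {
        warning("gene set '", nm, "' is disjoint from the universe; skipped")
        next
      }
      ov <- length(intersect(members, genes))
      p <- if (ov == 0) 1 else
        hypergeom_shared_pvalue(length(universe), length(members),
                                length(genes), ov)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mod, set_name = nm, overlap_count = ov,
        module_size = length(members), set_size = length(genes),
        universe_size = length(universe), p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(module_id = integer(0), set_name = character(0),
                      overlap_count = integer(0), module_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      p = numeric(0), p_adj = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$enriched <- out$p_adj < alpha
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Hub calling by degree quantile
#'
#' Hubs are nodes whose degree is at least the `quantile` quantile of the
#' degree distribution. The quantile uses the Weibull plotting position
#' (`type = 6`): in a star graph only the center clears the 90th percentile,
#' while with all-equal degrees every node sits at the threshold and all are
#' hubs (>= comparison).
#'
#' @param network a `CeRNANetwork`.
#' @param quantile degree quantile threshold (default 0.90).
#' @return character vector of hub node ids.
#' @export
call_hubs <- function(network, quantile = 0.90) {
  deg <- network$degree
  if (!length(deg)) stop("empty network")
  thr <- stats::quantile(deg, quantile, names = FALSE, type = 6)
  names(deg)[deg >= thr]
}

#' Overlap of network edges with an external interaction set
#'
#' Counts network edges present (as unordered pairs) in `other` and the
#' fraction of network edges they represent.
#'
#' @param network a `CeRNANetwork`.
#' @param other an `InteractionTable` or a data.frame with two id columns.
#' @return list with `count` and `fraction`.
#' @export
overlap_with_interactions <- function(network, other) {
  a <- as.character(other[[1]]); b <- as.character(other[[2]])
  if ("regulator" %in% names(other)) { a <- other$regulator; b <- other$target }
  okey <- unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
  ekey <- paste(pmin(network$edges$rna_i, network$edges$rna_j),
                pmax(network$edges$rna_i, network$edges$rna_j), sep = "\r")
  cnt <- sum(ekey %in% okey)
  list(count = cnt,
       fraction = if (length(ekey)) cnt / length(ekey) else 0)
}
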