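# Step 1: putative DE-miRNA -> DE-RNA interaction network from aggregated
# interaction tables; sequence-based edges are an input contract (databases),
# with a minimal seed-complementarity scanner for synthetic fixtures only.

#' Restrict an interaction table to differentially expressed features
#'
#' Keeps only interactions whose miRNA regulator and RNA target are both
#' labeled DE; targets left without any candidate miRNA disappear from the
#' network. The operation is idempotent.
#'
#' @param interactions an `InteractionTable` of miRNA regulators.
#' @param de_mirnas,de_rnas `DELabelTable`s for regulators and targets.
#' @return a `PutativeNetwork`: list with the filtered `interactions` table,
#'   `de_mirna_ids`, `de_rna_ids`, and `targets` (per-target candidate miRNA
#'   list).
#' @export
restrict_to_de <- function(interactions, de_mirnas, de_rnas) {
  stopifnot(inherits(interactions, "InteractionTable"))
  if (!nrow(interactions) || !nrow(de_mirnas) || !nrow(de_rnas))
    stop("interaction and DE tables must be non-empty")
  mir_ok <- de_mirnas$feature_id[de_mirnas$is_DE]
  rna_ok <- de_rnas$feature_id[de_rnas$is_DE]
  keep <- interactions$regulator_kind == "miRNA" &
    interactions$regulator %in% mir_ok & interactions$target %in% rna_ok
  out <- interactions[keep, , drop = FALSE]
  if (!nrow(out))
    stop("no interaction survives DE restriction; review DE thresholds")
  rownames(out) <- NULL
  class(out) <- c("InteractionTable", "data.frame")
  structure(list(interactions = out,
                 de_mirna_ids = sort(unique(out$regulator)),
                 de_rna_ids = sort(unique(out$target)),
                 targets = split(out$regulator, out$target)),
            class = "PutativeNetwork")
}

#' @export
print.PutativeNetwork <- function(x, ...) {
  cat(sprintf("PutativeNetwork: %d interactions, %d DE miRNAs, %d DE RNAs\n",
              nrow(x$interactions), length(x$de_mirna_ids), length(x$de_rna_ids)))
  invisible(x)
}

reverse_complement_dna <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Minimal miRNA seed-match scanner (fixture generator)
#'
#' Reports a (miRNA, RNA) pair when the reverse complement of the miRNA seed
#' occurs in the target's 3'UTR. Site definitions: 6mer = seed positions 2-7;
#' 7mer-m8 = positions 2-8; 7mer-A1 = positions 2-7 with an `A` opposite
#' position 1; 8mer = positions 2-8 with the opposite `A`. U and T are
#' treated as equivalent. This is a stand-in for external target-prediction
#' databases when building synthetic fixtures; it performs no thermodynamic
#' or conservation scoring.
#'
#' @param mirna_seqs named character vector of mature miRNA sequences (5'->3').
#' @param utr_seqs named character vector of 3'UTR sequences (5'->3').
#' @param site_types subset of `c("6mer", "7mer-m8", "7mer-A1", "8mer")`.
#' @return an `InteractionTable` with source tag `seed_match`.
#' @export
seed_match_scan <- function(mirna_seqs, utr_seqs,
                            site_types = c("6mer", "7mer-m8", "7mer-A1", "8mer")) {
  site_types <- match.arg(site_types, several.ok = TRUE)
  norm <- function(s) chartr("Uu", "TT", toupper(s))
  mirna_seqs <- vapply(mirna_seqs, norm, character(1))
  utr_seqs <- vapply(utr_seqs, norm, character(1))
  ok <- function(s) grepl("^[ACGT]+$", s)
  if (!all(ok(mirna_seqs)) || !all(ok(utr_seqs)))
    stop("sequences must be over {A,C,G,U/T}")
  reg <- character(0); tgt <- character(0)
  for (mi in names(mirna_seqs)) {
    ms <- mirna_seqs[[mi]]
    if (nchar(ms) < 8) next
    seed27 <- substr(ms, 2, 7)
    seed28 <- substr(ms, 2, 8)
    pats <- character(0)
    if ("6mer" %in% site_types) pats <- c(pats, reverse_complement_dna(seed27))
    if ("7mer-m8" %in% site_types) pats <- c(pats, reverse_complement_dna(seed28))
    if ("7mer-A1" %in% site_types) pats <- c(pats, paste0(reverse_complement_dna(seed27), "A"))
    if ("8mer" %in% site_types) pats <- c(pats, paste0(reverse_complement_dna(seed28), "A"))
    for (u in names(utr_seqs)) {
      if (any(vapply(pats, function(p) grepl(p, utr_seqs[[u]], fixed = TRUE), logical(1)))) {
        reg <- c(reg, mi); tgt <- c(tgt, u)
      }
    }
  }
  if (!length(reg))
    return(interaction_table(character(0), character(0), "miRNA", "seed_match"))
  interaction_table(reg, tgt, "miRNA", "seed_match")
}
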