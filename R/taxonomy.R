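#' @name taxonomy
#' @title Majority-rule and LCA taxonomic affiliation
#'
#' @description Lineages are ordered rank vectors (e.g. order, family, genus
#' for viruses; the seven canonical ranks for hosts), either as character
#' vectors or semicolon-delimited strings. `UNASSIGNED` marks an empty rank;
#' no assigned rank may sit below an unassigned one.
NULL

UNASSIGNED <- "UNASSIGNED"

#' Split semicolon-delimited lineages into a rank matrix
#'
#' @param lineages character vector of `;`-delimited lineages (ragged ends
#'   padded with `UNASSIGNED`).
#' @return character matrix, one row per lineage, one column per rank.
#' @export
lineage_matrix <- function(lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  nr <- max(lengths(parts))
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == "" | is.na(p)] <- UNASSIGNED
    c(p, rep(UNASSIGNED, nr - length(p)))
  }, character(nr)))
  mat
}

#' Affiliate a group from its members' lineages by a strict majority rule
#'
#' At each rank from the highest down, the group is affiliated to the label
#' carried by strictly more than `q` of ALL members (members unassigned at
#' the rank count in the denominator); affiliation stops at the first rank
#' where no label clears the threshold.
#'
#' @param lineages character vector of `;`-delimited member lineages.
#' @param q majority threshold (default 0.75; strictly greater than).
#' @return single `;`-delimited lineage string.
#' @export
affiliate_members <- function(lineages, q = 0.75) {
  if (!length(lineages)) stop("no member lineages supplied")
  mat <- lineage_matrix(lineages)
  out <- rep(UNASSIGNED, ncol(mat))
  for (r in seq_len(ncol(mat))) {
    labs <- mat[, r]
    tab <- table(labs[labs != UNASSIGNED])
    if (!length(tab)) break
    frac <- tab / length(lineages)
    top <- which.max(frac)
    if (frac[top] > q) out[r] <- names(tab)[top] else break
  }
  paste(out, collapse = ";")
}

#' Lowest common ancestor of a set of lineages
#'
#' Deepest rank at which all lineages agree on an assigned label; deeper
#' ranks are `UNASSIGNED`.
#'
#' @param lineages character vector of `;`-delimited lineages.
#' @return single `;`-delimited lineage string.
#' @export
lineage_lca <- function(lineages) {
  if (!length(lineages)) stop("no lineages supplied")
  mat <- lineage_matrix(lineages)
  out <- rep(UNASSIGNED, ncol(mat))
  for (r in seq_len(ncol(mat))) {
    labs <- unique(mat[, r])
    if (length(labs) == 1L && labs != UNASSIGNED) out[r] <- labs else break
  }
  paste(out, collapse = ";")
}

#' Affiliate a sequence from its genes' best reference hits
#'
#' The relevant hit set is the absolute best hit across all genes plus, for
#' every other gene, its best hit when that hit's score exceeds 75% of the
#' absolute best score. The sequence is affiliated to the lowest common
#' ancestor of the relevant hits' lineages. A sequence is thus affiliated
#' only when its best hits are consistent. Ties at a gene's best score are
#' resolved by lexicographic target id.
#'
#' @param hits data.frame with columns `gene_id`, `target`, `score`,
#'   `lineage` (`;`-delimited); may be empty.
#' @param score_fraction relevant-hit threshold relative to the absolute
#'   best score (default 0.75, strictly greater than).
#' @return list with `lineage` (`;`-delimited) and `n_relevant` (number of
#'   relevant hits used).
#' @export
affiliate_sequence <- function(hits, score_fraction = 0.75) {
  if (is.null(hits) || !nrow(hits))
    return(list(lineage = UNASSIGNED, n_relevant = 0L))
  stopifnot(all(c("gene_id", "target", "score", "lineage") %in% names(hits)))
  best_per_gene <- do.call(rbind, lapply(split(hits, hits$gene_id),
                                         function(h) {
    h <- h[h$score >= max(h$score) - 1e-12, , drop = FALSE]
    h[order(h$target), ][1, , drop = FALSE]
  }))
  s_max <- max(best_per_gene$score)
  relevant <- best_per_gene[best_per_gene$score >= s_max - 1e-12 |
                              best_per_gene$score > score_fraction * s_max, ,
                            drop = FALSE]
  list(lineage = lineage_lca(relevant$lineage),
       n_relevant = nrow(relevant))
}

#' Affiliate a virus cluster from its members' affiliations
#'
#' Same strict >75% rank-wise rule as [affiliate_members()]; a VC whose
#' members disagree already at the first rank is `unclassified`.
#'
#' @param lineages member lineages (`;`-delimited).
#' @param q majority threshold (default 0.75).
#' @return list with `lineage` and `status` (`affiliated`/`unclassified`).
#' @export
affiliate_vc <- function(lineages, q = 0.75) {
  if (!length(lineages)) stop("VC has no members")
  lin <- affiliate_members(lineages, q = q)
  first <- strsplit(lin, ";", fixed = TRUE)[[1]][1]
  list(lineage = lin,
       status = if (first == UNASSIGNED) "unclassified" else "affiliated")
}
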