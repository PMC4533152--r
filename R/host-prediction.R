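#' Predict a virus's host from tetranucleotide frequency distance
#'
#' The predicted host is the eligible genome with the lowest MAE between
#' tetranucleotide frequency vectors; ties are broken lexicographically by
#' genome id. Eligibility depends on the exclusion mode: `none` uses the full
#' library, `host_species` removes every genome of the true host's species,
#' `host_genus` removes every genome of the true host's genus. Correctness at
#' order/family/genus compares the predicted genome's lineage to the true
#' host's. Distances fall into the bins `d < 4e-4`, `4e-4 <= d < 1e-3`,
#' `d >= 1e-3` (closed on the left, open on the right).
#'
#' @param virus_tnf named numeric vector (a k = 4 [kmer_frequencies()]).
#' @param library named list or matrix of host TNF vectors (genome id ->
#'   vector).
#' @param host_taxonomy data.frame with `genome_id`, `order`, `family`,
#'   `genus`, `species`.
#' @param true_host genome id of the actual host.
#' @param exclusion one of `"none"`, `"host_species"`, `"host_genus"`.
#' @return one-row data.frame: `predicted_genome`, `distance`, `bin`,
#'   `correct_order`, `correct_family`, `correct_genus`.
#' @export
predict_host <- function(virus_tnf, library, host_taxonomy, true_host,
                         exclusion = c("none", "host_species", "host_genus")) {
  exclusion <- match.arg(exclusion)
  tax <- host_taxonomy
  truth <- tax[tax$genome_id == true_host, ]
  if (nrow(truth) != 1) stop("true host ", true_host, " not in taxonomy")
  ids <- if (is.matrix(library)) rownames(library) else names(library)
  eligible <- switch(exclusion,
    none = ids,
    host_species = ids[!ids %in%
                         tax$genome_id[tax$species == truth$species]],
    host_genus = ids[!ids %in% tax$genome_id[tax$genus == truth$genus]])
  if (!length(eligible))
    stop("exclusion mode '", exclusion, "' leaves no eligible genome")
  d <- vapply(eligible, function(g) {
    v <- if (is.matrix(library)) library[g, ] else library[[g]]
    mae_distance(virus_tnf, v)
  }, numeric(1))
  ord <- order(d, eligible)
  pred <- eligible[ord[1]]
  dist <- d[ord[1]]
  plin <- tax[tax$genome_id == pred, ]
  data.frame(
    predicted_genome = pred, distance = unname(dist),
    bin = distance_bin(dist),
    correct_order = plin$order == truth$order,
    correct_family = plin$family == truth$family,
    correct_genus = plin$genus == truth$genus,
    stringsAsFactors = FALSE)
}

#' Distance bin labels used in the evaluation table
#'
#' @param d numeric distances.
#' @return factor with levels `d<4e-04`, `4e-04<=d<1e-03`, `d>=1e-03`.
#' @export
distance_bin <- function(d) {
  cut(d, breaks = c(-Inf, 4e-4, 1e-3, Inf),
      labels = c("d<4e-04", "4e-04<=d<1e-03", "d>=1e-03"),
      right = FALSE)
}

#' Predict hosts for every virus in a world
#'
#' @param world a `synthetic_world`.
#' @param exclusion exclusion mode, see [predict_host()].
#' @param library optional precomputed TNF library
#'   ([host_composition_library()] at k = 4); computed when NULL.
#' @return data.frame with one row per virus: `virus_id`, `true_host`, and
#'   the [predict_host()] columns.
#' @export
predict_hosts <- function(world, exclusion = "none", library = NULL) {
  stopifnot(nrow(world$viruses) > 0)
  if (is.null(library)) {
    lib4 <- host_composition_library(world, ks = 4)
    library <- lapply(lib4, `[[`, 4)
  }
  tax <- world$hosts[, c("genome_id", "order", "family", "genus", "species")]
  out <- lapply(seq_len(nrow(world$viruses)), function(i) {
    v <- world$viruses[i, ]
    cbind(data.frame(virus_id = v$sequence_id, true_host = v$genome_id,
                     stringsAsFactors = FALSE),
          predict_host(kmer_frequencies(v$sequence, 4), library, tax,
                       v$genome_id, exclusion))
  })
  do.call(rbind, out)
}

#' Evaluate host predictions per exclusion mode, distance bin and rank
#'
#' @param predictions named list of [predict_hosts()] outputs, one per
#'   exclusion mode (names used as the `mode` column).
#' @return data.frame: `mode`, `bin`, `rank`, `n`, `n_correct`, `ratio_pct`.
#' @export
evaluate_predictions <- function(predictions) {
  rows <- list(); k <- 0L
  bins <- levels(distance_bin(0))
  for (mode in names(predictions)) {
    p <- predictions[[mode]]
    for (b in bins) {
      sub <- p[as.character(p$bin) == b, , drop = FALSE]
      for (rank in c("order", "family", "genus")) {
        ok <- sub[[paste0("correct_", rank)]]
        k <- k + 1L
        rows[[k]] <- data.frame(
          mode = mode, bin = b, rank = rank, n = nrow(sub),
          n_correct = sum(ok),
          ratio_pct = if (nrow(sub)) 100 * mean(ok) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
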