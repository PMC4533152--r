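#' Detect co-infections with the terminase large-subunit safeguard
#'
#' A genome project carrying two or more distinct curated viral sequences is
#' a candidate co-infection. Because several contigs of one mis-assembled
#' Caudovirales genome can mimic a co-infection, a candidate whose sequences
#' are all Caudovirales-affiliated is only counted when the summed terminase
#' large-subunit (terL) copies across its sequences reach 2 (terL is single
#' copy in Caudovirales). Candidates mixing families are counted regardless
#' under the default policy; `terl_gate = "always"` applies the terL rule to
#' every candidate.
#'
#' @param sequences data.frame with one row per curated viral sequence:
#'   `sequence_id`, `genome_id`, `family` (family-level affiliation; the
#'   label `Caudovirales` or any of its family names counts as Caudovirales,
#'   see `caudo_families`), `terL_count`.
#' @param terl_gate `"caudo_only"` (default) or `"always"`.
#' @param caudo_families labels treated as Caudovirales-affiliated.
#' @return list with `records` (per-genome data.frame: `genome_id`,
#'   `n_viral_sequences`, `terL_total`, `all_caudo`, `counted`), `histogram`
#'   (table of viruses-per-genome over genomes with >= 1 virus), and `pairs`
#'   (data.frame of unordered family-pair counts over counted genomes).
#' @export
detect_coinfections <- function(sequences,
                                terl_gate = c("caudo_only", "always"),
                                caudo_families = c("Caudovirales",
                                                   "Siphoviridae",
                                                   "Myoviridae",
                                                   "Podoviridae")) {
  terl_gate <- match.arg(terl_gate)
  req <- c("sequence_id", "genome_id", "family", "terL_count")
  stopifnot(all(req %in% names(sequences)))
  if (any(is.na(sequences$genome_id) | sequences$genome_id == ""))
    stop("sequence without genome id: ",
         sequences$sequence_id[which(is.na(sequences$genome_id) |
                                       sequences$genome_id == "")[1]])
  by_g <- split(sequences, sequences$genome_id)
  records <- do.call(rbind, lapply(by_g, function(s) {
    all_caudo <- all(s$family %in% caudo_families)
    candidate <- nrow(s) >= 2
    gated <- if (terl_gate == "always") TRUE else all_caudo
    counted <- candidate && (!gated || sum(s$terL_count) >= 2)
    data.frame(genome_id = s$genome_id[1], n_viral_sequences = nrow(s),
               terL_total = sum(s$terL_count), all_caudo = all_caudo,
               counted = counted, stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL
  histogram <- table(records$n_viral_sequences)
  pair_rows <- lapply(by_g[records$genome_id[records$counted]], function(s) {
    cmb <- utils::combn(sort(s$family), 2)
    data.frame(family1 = cmb[1, ], family2 = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(pair_rows)) {
    p <- do.call(rbind, pair_rows)
    agg <- stats::aggregate(list(n = seq_len(nrow(p))),
                            by = list(family1 = p$family1,
                                      family2 = p$family2), FUN = length)
    agg[order(-agg$n), ]
  } else data.frame(family1 = character(0), family2 = character(0),
                    n = integer(0))
  rownames(pairs) <- NULL
  list(records = records, histogram = histogram, pairs = pairs)
}
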