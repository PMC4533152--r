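#' Curate viral prediction tables
#'
#' Applies the post-detection filters to a table of viral predictions, in a
#' fixed order, logging for every dropped row the first rule it violates:
#' \enumerate{
#'   \item rows labelled as the PhiX174 Illumina sequencing control;
#'   \item category-3 predictions (gene enrichment only, no hallmark);
#'   \item prophage predictions without any viral hallmark gene;
#'   \item linear sequences shorter than 10 kb, except predictions carrying
#'     the non-Caudovirales detection tag, for which the threshold is 5 kb;
#'   \item circular sequences shorter than 3 kb (likely short repeat
#'     regions);
#'   \item sequence ids on the manual exclusion list.
#' }
#' Retained plasmid-labelled rows are kept but flagged `ambiguous_plasmid`.
#'
#' @param predictions data.frame with at least `sequence_id`, `category`,
#'   `detection_tag` (one of `hallmark`, `refseq`, `noncaudo`, `vdb`),
#'   `circular`, `prophage`, `length_bp`, `hallmark_count`, `label`.
#' @param exclusions optional character vector of sequence ids removed by
#'   manual curation (an input list, never recomputed).
#' @return list with `retained` (the surviving rows, plus an
#'   `ambiguous_plasmid` flag) and `rejected` (data.frame `sequence_id`,
#'   `rule` naming the first violated rule).
#' @export
apply_curation_filters <- function(predictions, exclusions = NULL) {
  req <- c("sequence_id", "category", "detection_tag", "circular",
           "prophage", "length_bp", "hallmark_count", "label")
  miss <- setdiff(req, names(predictions))
  if (length(miss)) stop("predictions table lacks columns: ",
                         paste(miss, collapse = ", "))
  known <- c("hallmark", "refseq", "noncaudo", "vdb")
  bad <- !predictions$detection_tag %in% known
  if (any(bad))
    stop("unknown detection_tag '", predictions$detection_tag[which(bad)[1]],
         "' in row for sequence ", predictions$sequence_id[which(bad)[1]])

  p <- predictions
  circ <- as.logical(p$circular)
  proph <- as.logical(p$prophage)
  rule <- rep(NA_character_, nrow(p))
  hit <- function(cond, name) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(rule) & cond, name, rule)
  }
  rule <- hit(grepl("phix", p$label, ignore.case = TRUE), "phix_control")
  rule <- hit(p$category == 3, "category_3")
  rule <- hit(proph & p$hallmark_count == 0, "prophage_no_hallmark")
  rule <- hit(!circ & p$detection_tag != "noncaudo" & p$length_bp < 10000,
              "linear_lt_10kb")
  rule <- hit(!circ & p$detection_tag == "noncaudo" & p$length_bp < 5000,
              "noncaudo_linear_lt_5kb")
  rule <- hit(circ & p$length_bp < 3000, "circular_lt_3kb")
  if (!is.null(exclusions))
    rule <- hit(p$sequence_id %in% exclusions, "manual_exclusion")

  retained <- p[is.na(rule), , drop = FALSE]
  retained$ambiguous_plasmid <- grepl("plasmid", retained$label,
                                      ignore.case = TRUE) &
    retained$hallmark_count == 0
  if (any(retained$ambiguous_plasmid))
    warning(sum(retained$ambiguous_plasmid),
            " plasmid-labelled sequence(s) without hallmark genes retained ",
            "with an ambiguity flag")
  rejected <- data.frame(sequence_id = p$sequence_id[!is.na(rule)],
                         rule = rule[!is.na(rule)],
                         stringsAsFactors = FALSE)
  rownames(retained) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Classify curated sequences by replication mode
#'
#' Prophage predictions are `integrated`. Sequences without microbial genes
#' are `extrachromosomal` when circular or longer than `size_threshold_bp`
#' (complete genomes assembled outside the chromosome), otherwise
#' `undetermined` (short linear fragments that may come from either an
#' integrated prophage or an extrachromosomal genome).
#'
#' @param records data.frame of retained predictions with columns `prophage`,
#'   `circular`, `length_bp`, `has_microbial_genes`.
#' @param size_threshold_bp length above which a linear sequence free of
#'   microbial genes is considered a complete extrachromosomal genome
#'   (default 30 kb).
#' @return `records` with a `replication_mode` column added.
#' @export
classify_replication_mode <- function(records, size_threshold_bp = 30000) {
  stopifnot(all(c("prophage", "circular", "length_bp",
                  "has_microbial_genes") %in% names(records)))
  proph <- as.logical(records$prophage)
  circ <- as.logical(records$circular)
  micro <- as.logical(records$has_microbial_genes)
  bad <- proph & !micro
  if (any(bad))
    stop("inconsistent annotation for sequence ",
         records$sequence_id[which(bad)[1]],
         ": prophage flag set but no microbial genes")
  records$replication_mode <- ifelse(
    proph, "integrated",
    ifelse(!micro & (circ | records$length_bp > size_threshold_bp),
           "extrachromosomal",
           "undetermined"))
  records
}

#' Exact one-sided test for marker enrichment between two sequence groups
#'
#' Tests whether a marker (e.g. the plasmid partition genes ParA/ParB) occurs
#' at a higher per-sequence rate in group 1 than in group 2. Conditional on
#' the total marker count, the group-1 count is binomial with success
#' probability `n1 / (n1 + n2)` under the null of equal rates; the returned
#' p-value is the exact upper tail `P(X >= k1)`. This is the classical exact
#' two-sample Poisson rate-ratio test.
#'
#' @param k1,n1 marker-positive count and size of group 1.
#' @param k2,n2 marker-positive count and size of group 2.
#' @return one-sided p-value in `[0, 1]`; 1 when no marker is observed.
#' @export
marker_enrichment_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 + n2 > 0)
  total <- k1 + k2
  if (total == 0) return(1.0)
  if (k1 == 0) return(1.0)
  stats::pbinom(k1 - 1, size = total, prob = n1 / (n1 + n2),
                lower.tail = FALSE)
}

#' Classify a genome project as draft or complete
#'
#' Genome projects with more than 5 different sequences are considered draft
#' assemblies; 5 or fewer sequences allows for genomes split into several
#' chromosomes or carrying plasmids.
#'
#' @param n_sequences sequence count(s) per genome project (>= 1).
#' @return character vector, `"draft"` or `"complete"`.
#' @export
classify_genome_status <- function(n_sequences) {
  stopifnot(all(n_sequences >= 1))
  ifelse(n_sequences > 5, "draft", "complete")
}
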