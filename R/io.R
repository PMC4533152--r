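#' Read a BLAST tabular (outfmt 6) similarity table
#'
#' @param path TSV with the 12 standard columns (no header).
#' @return data.frame with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`.
#' @export
read_blast_outfmt6 <- function(path) {
  utils::read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "mismatch", "gapopen", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore"),
                    stringsAsFactors = FALSE)
}

#' Read a prediction table TSV
#'
#' @param path tab-separated prediction table with header (the dialect
#'   written by [write_world()]).
#' @return data.frame of prediction records.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# write a TSV with optional '# key: value' header comments
.write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_gff3 <- function(genes, prophages, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    attrs <- sprintf(
      "ID=%s;protein_id=%s;origin=%s;hallmark=%d;terminase_LSU=%d;parA=%d;parB=%d;func_cat=%s;trna=%d",
      genes$gene_id, genes$protein_id, genes$origin,
      as.integer(genes$hallmark), as.integer(genes$terL),
      as.integer(genes$parA), as.integer(genes$parB), genes$func_cat,
      genes$trna)
    writeLines(paste(genes$parent_id, "provirome", "CDS", genes$start,
                     genes$end, ".", genes$strand, "0", attrs, sep = "\t"),
               con)
  }
  if (!is.null(prophages) && nrow(prophages)) {
    writeLines(paste(prophages$genome_id, "provirome", "prophage_region",
                     prophages$prophage_start, prophages$prophage_end, ".",
                     "+", ".", sprintf("ID=%s", prophages$sequence_id),
                     sep = "\t"), con)
  }
}

#' Write a synthetic world to disk in standard formats
#'
#' Emits host and viral genome FASTA, protein FASTA (translated CDS), a GFF3
#' of gene calls (1-based inclusive coordinates) with hallmark/terL/ParA/ParB
#' attribute flags plus prophage regions, the BLAST-style similarity table,
#' the prediction TSV, the host lineage TSV
#' (`genome_id<TAB>domain;...;species`), and the truth tables.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  hseq <- Biostrings::DNAStringSet(
    stats::setNames(world$hosts$sequence, world$hosts$genome_id))
  Biostrings::writeXStringSet(hseq, f("hosts.fna"))
  if (nrow(world$viruses)) {
    vseq <- Biostrings::DNAStringSet(
      stats::setNames(world$viruses$sequence, world$viruses$sequence_id))
    Biostrings::writeXStringSet(vseq, f("viruses.fna"))
    cds <- Biostrings::DNAStringSet(
      stats::setNames(world$viral_genes$cds, world$viral_genes$protein_id))
    Biostrings::writeXStringSet(Biostrings::translate(cds),
                                f("proteins.faa"))
  }
  gcols <- setdiff(names(world$host_genes), "cds")
  genes <- world$host_genes[, gcols]
  if (nrow(world$viruses)) genes <- rbind(genes, world$viral_genes[, gcols])
  pro <- world$viruses[world$viruses$prophage %in% TRUE,
                       c("genome_id", "sequence_id", "prophage_start",
                         "prophage_end")]
  .write_gff3(genes, pro, f("genes.gff3"))
  utils::write.table(world$similarity, f("similarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  .write_tsv(world$predictions, f("predictions.tsv"),
             comments = sprintf("seed: %d", world$config$seed))
  .write_tsv(data.frame(genome_id = world$hosts$genome_id,
                        lineage = world$hosts$lineage), f("lineages.tsv"))
  tr <- world$truth
  .write_tsv(data.frame(virus = names(tr$virus2host), host = tr$virus2host,
                        cluster = tr$virus2cluster[names(tr$virus2host)]),
             f("truth_viruses.tsv"))
  .write_tsv(data.frame(protein = names(tr$protein2family),
                        family = tr$protein2family), f("truth_proteins.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}

#' Write an incidence matrix as TSV (rows = VCs, header = host classes)
#'
#' @param A binary matrix from [build_incidence()].
#' @param path output path.
#' @export
write_incidence <- function(A, path) {
  df <- data.frame(vc_id = rownames(A), as.data.frame(unclass(A)),
                   check.names = FALSE)
  .write_tsv(df, path)
}
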