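#' Pipeline configuration
#'
#' Collects stage toggles and parameters for [run_all()]. Analysis parameters
#' default to the study values: bit score 50 and e-value 0.001 for protein
#' hits, significance threshold 1 and inflation 4 for genome clustering,
#' protein-level inflation 2, 99 permutations for the modularity null, and
#' host-prediction distance bins at 4e-4 and 1e-3. `min_vc_size` defaults to
#' 5 in the pipeline (the incidence-matrix builder itself defaults to the
#' study's "more than 10 sequences"): at the bundled synthetic scale of ~8
#' sequences per virus cluster the larger cutoff would empty the matrix.
#'
#' @param synthetic a [sim_config()] describing the world to generate.
#' @param seed master seed; each stage derives its own substream.
#' @param out_dir optional output directory for stage TSVs and the summary
#'   JSON; no files are written when NULL.
#' @param stages named logical vector toggling stages `curation`,
#'   `clustering`, `taxonomy`, `host_network`, `composition`,
#'   `host_prediction`, `coinfection`.
#' @param min_score,max_evalue RBH thresholds.
#' @param protein_inflation,genome_inflation MCL inflations.
#' @param sig_threshold genome-network significance threshold.
#' @param min_vc_size incidence-matrix VC size cutoff (strictly greater
#'   than).
#' @param n_perm modularity permutations.
#' @param n_picks non-host picks per category in the adaptation experiment.
#' @param metrics composition metrics.
#' @param exclusions optional manual exclusion id list for curation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = sim_config(), seed = 1,
                            out_dir = NULL,
                            stages = c(curation = TRUE, clustering = TRUE,
                                       taxonomy = TRUE, host_network = TRUE,
                                       composition = TRUE,
                                       host_prediction = TRUE,
                                       coinfection = TRUE),
                            min_score = 50, max_evalue = 0.001,
                            protein_inflation = 2, genome_inflation = 4,
                            sig_threshold = 1, min_vc_size = 5,
                            n_perm = 99, n_picks = 10,
                            metrics = c("k4", "cai"), exclusions = NULL) {
  def <- c(curation = TRUE, clustering = TRUE, taxonomy = TRUE,
           host_network = TRUE, composition = TRUE, host_prediction = TRUE,
           coinfection = TRUE)
  def[names(stages)] <- stages
  structure(list(synthetic = synthetic, seed = as.integer(seed),
                 out_dir = out_dir, stages = def, min_score = min_score,
                 max_evalue = max_evalue,
                 protein_inflation = protein_inflation,
                 genome_inflation = genome_inflation,
                 sig_threshold = sig_threshold, min_vc_size = min_vc_size,
                 n_perm = n_perm, n_picks = n_picks, metrics = metrics,
                 exclusions = exclusions),
            class = "pipeline_config")
}

.stage_seed <- function(master, stage) {
  offsets <- c(simulate = 0L, curation = 101L, clustering = 211L,
               taxonomy = 307L, host_network = 401L, composition = 503L,
               host_prediction = 601L, coinfection = 701L)
  (master * 1009L + offsets[[stage]]) %% 2147483647L
}

.need <- function(x, stage, upstream) {
  if (is.null(x))
    stop("stage '", stage, "' requires output of stage '", upstream,
         "', which is toggled off")
  x
}

#' Run the full pipeline on a synthetic world
#'
#' Stages run in order: simulate, curation, clustering, taxonomy, host
#' network, composition, host prediction, co-infection; each stage's tables
#' are written (when `out_dir` is set) before the next starts. The bundle is
#' a pure function of the config, including its seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with one element per stage plus `summary`
#'   (the flat summary also serialised to `summary.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(); s <- config$stages
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name, comments = NULL) {
    if (!is.null(dir)) .write_tsv(x, file.path(dir, name), comments)
  }
  world_cfg <- config$synthetic
  world_cfg$seed <- .stage_seed(config$seed, "simulate")
  world <- generate_world(world_cfg)
  out$world <- world
  if (!is.null(dir)) write_world(world, file.path(dir, "world"))
  summary <- list(seed = config$seed, n_hosts = nrow(world$hosts),
                  n_viruses = nrow(world$viruses),
                  n_predictions = nrow(world$predictions))

  curated <- NULL
  if (s[["curation"]]) {
    cur <- apply_curation_filters(world$predictions,
                                  exclusions = config$exclusions)
    curated <- classify_replication_mode(cur$retained)
    ext <- curated$replication_mode == "extrachromosomal"
    marked <- as.logical(curated$parA) | as.logical(curated$parB)
    enrich <- marker_enrichment_test(sum(marked & ext), sum(ext),
                                     sum(marked & !ext), sum(!ext))
    out$curation <- list(retained = curated, rejected = cur$rejected,
                         parab_p = enrich)
    emit(curated, "curated.tsv")
    emit(cur$rejected, "rejected.tsv")
    summary$n_retained <- nrow(curated)
    summary$n_rejected <- nrow(cur$rejected)
    summary$parab_p <- enrich
    stopifnot(nrow(curated) + nrow(cur$rejected) == nrow(world$predictions))
  }

  clusters <- NULL
  if (s[["clustering"]]) {
    .need(curated, "clustering", "curation")
    g <- build_rbh_graph(world$similarity, config$min_score,
                         config$max_evalue)
    pcs <- mcl(g, inflation = config$protein_inflation)
    p2g <- stats::setNames(world$viral_genes$parent_id,
                           world$viral_genes$protein_id)
    keep <- names(p2g)[p2g[names(p2g)] %in% curated$sequence_id]
    prof <- genome_profiles(pcs[names(pcs) %in% keep], p2g)
    net <- build_genome_network(prof, config$sig_threshold)
    clusters <- cluster_genomes(net, inflation = config$genome_inflation)
    md <- data.frame(sequence_id = curated$sequence_id,
                     circular = as.logical(curated$circular),
                     complete = as.logical(curated$circular),
                     length_bp = curated$length_bp, reference = FALSE)
    vcs <- classify_vcs(clusters$membership, md)
    out$clustering <- list(pc_membership = pcs, profiles = prof,
                           network = net, membership = clusters$membership,
                           unclustered = clusters$unclustered, vcs = vcs)
    emit(data.frame(protein_id = names(pcs), pc = as.integer(pcs)),
         "protein_clusters.tsv")
    emit(data.frame(sequence_id = names(clusters$membership),
                    vc = as.integer(clusters$membership)), "vcs.tsv")
    el <- igraph::as_data_frame(net, what = "edges")
    names(el) <- c("source", "target", "significance")
    emit(el, "genome_network.tsv")
    summary$n_pcs <- length(unique(pcs))
    summary$n_vcs <- length(unique(clusters$membership))
    summary$n_unclustered <- length(clusters$unclustered)
    summary$n_new_genera <- unname(vcs$counts["n_new"])
    stopifnot(length(clusters$membership) + length(clusters$unclustered) ==
                igraph::vcount(net))
  }

  affiliations <- NULL
  if (s[["taxonomy"]]) {
    .need(clusters, "taxonomy", "clustering")
    vlin <- stats::setNames(
      paste(world$viruses$order_v, world$viruses$family_v,
            world$viruses$genus_v, sep = ";"),
      world$viruses$sequence_id)
    affiliations <- do.call(rbind, lapply(
      split(names(clusters$membership), as.character(clusters$membership)),
      function(members) {
        af <- affiliate_vc(vlin[members])
        data.frame(n_members = length(members), lineage = af$lineage,
                   status = af$status, stringsAsFactors = FALSE)
      }))
    affiliations <- cbind(vc = rownames(affiliations), affiliations)
    rownames(affiliations) <- NULL
    out$taxonomy <- affiliations
    emit(affiliations, "vc_affiliations.tsv")
    summary$n_vc_affiliated <- sum(affiliations$status == "affiliated")
  }

  if (s[["host_network"]]) {
    .need(clusters, "host_network", "clustering")
    v2c <- stats::setNames(world$hosts$class[
      match(world$truth$virus2host[names(clusters$membership)],
            world$hosts$genome_id)], names(clusters$membership))
    A <- build_incidence(clusters$membership, v2c,
                         min_vc_size = config$min_vc_size)
    null <- permutation_null(A, n_perm = config$n_perm,
                             seed = .stage_seed(config$seed, "host_network"))
    out$host_network <- c(list(incidence = A), null)
    if (!is.null(dir)) write_incidence(A, file.path(dir, "incidence.tsv"))
    summary$q_obs <- null$q_obs
    summary$q_perm_mean <- unname(null$summary["mean"])
    summary$q_perm_max <- unname(null$summary["max"])
    summary$modularity_p <- null$p
  }

  if (s[["composition"]]) {
    adapt <- adaptation_experiment(
      world, metrics = config$metrics, n_picks = config$n_picks,
      strata = stats::setNames(world$viruses$family_v,
                               world$viruses$sequence_id),
      seed = .stage_seed(config$seed, "composition"))
    out$composition <- adapt
    emit(adapt$report, "adaptation_report.tsv")
    k4 <- adapt$report[adapt$report$metric == "k4" &
                         adapt$report$category == "different_order", ]
    summary$ks_k4_different_order <- round(
      sum(k4$d * k4$n_virus) / sum(k4$n_virus), 4)
  }

  if (s[["host_prediction"]]) {
    lib4 <- host_composition_library(world, ks = 4)
    lib <- lapply(lib4, `[[`, 4)
    preds <- lapply(c(none = "none", host_species = "host_species",
                      host_genus = "host_genus"), function(m)
      predict_hosts(world, exclusion = m, library = lib))
    ev <- evaluate_predictions(preds)
    out$host_prediction <- list(predictions = preds, evaluation = ev)
    emit(preds$none, "host_predictions.tsv")
    emit(ev, "host_prediction_evaluation.tsv")
    full <- preds$none
    summary$genus_accuracy_full_pct <- 100 * mean(full$correct_genus)
  }

  if (s[["coinfection"]]) {
    .need(curated, "coinfection", "curation")
    real <- curated[curated$sequence_id %in% world$viruses$sequence_id, ]
    fam <- stats::setNames(world$viruses$family_v,
                           world$viruses$sequence_id)
    co <- detect_coinfections(data.frame(
      sequence_id = real$sequence_id, genome_id = real$genome_id,
      family = unname(fam[real$sequence_id]),
      terL_count = real$terL_count, stringsAsFactors = FALSE))
    out$coinfection <- co
    emit(co$records, "coinfection_records.tsv")
    emit(co$pairs, "coinfection_pairs.tsv")
    summary$n_coinfections <- sum(co$records$counted)
  }

  out$summary <- summary
  if (!is.null(dir))
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out)
}
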