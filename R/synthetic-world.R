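#' Simulation configuration for a synthetic virus-host world
#'
#' Bundles and validates the parameters of [generate_world()]. The defaults
#' describe the package's reference study conditions: 8 viral genera, 4 host
#' genomes per genus, 2 viruses per host (about 60 viral genomes), 100 kb
#' hosts, and a host-mixing weight of 0.9 so that viral genome composition is
#' dominated by, but not identical to, the host signature.
#'
#' @param n_genera number of viral genera (= host genome groups).
#' @param hosts_per_genus host genome projects per genus group.
#' @param viruses_per_host viral sequences generated per host genome.
#' @param genome_length_bp approximate host genome length in bp.
#' @param viral_length_range_bp length-2 vector, min/max viral genome length
#'   in bp; the minimum must be at least 1 kb.
#' @param alpha_host_mixing weight in `[0,1]` of the host codon-usage
#'   signature in viral genome composition; the remainder is a global
#'   background signature shared by all viruses.
#' @param family_pool_size protein families in the pool of a typical
#'   (Caudovirales-sized) viral genus; small-genome genera get pools scaled to
#'   their gene counts.
#' @param genes_per_virus gene count of a 30 kb viral genome; actual counts
#'   scale linearly with genome length.
#' @param decoy_rate fraction of prediction-table rows that are decoys, each
#'   violating exactly one curation rule.
#' @param prophage_fraction fraction of Caudovirales-like viruses integrated
#'   into their host chromosome as prophages.
#' @param seed integer seed; the world is a pure function of the config.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genera = 8, hosts_per_genus = 4, viruses_per_host = 2,
                       genome_length_bp = 100000,
                       viral_length_range_bp = c(4000, 50000),
                       alpha_host_mixing = 0.9, family_pool_size = 40,
                       genes_per_virus = 25, decoy_rate = 0.1,
                       prophage_fraction = 0.4, seed = 1) {
  cfg <- list(n_genera = n_genera, hosts_per_genus = hosts_per_genus,
              viruses_per_host = viruses_per_host,
              genome_length_bp = genome_length_bp,
              viral_length_range_bp = viral_length_range_bp,
              alpha_host_mixing = alpha_host_mixing,
              family_pool_size = family_pool_size,
              genes_per_virus = genes_per_virus, decoy_rate = decoy_rate,
              prophage_fraction = prophage_fraction, seed = as.integer(seed))
  counts <- c("n_genera", "hosts_per_genus", "genome_length_bp",
              "family_pool_size", "genes_per_virus")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("'", f, "' must be a positive count")
  }
  if (viruses_per_host < 0) stop("'viruses_per_host' must be >= 0")
  for (f in c("alpha_host_mixing", "decoy_rate", "prophage_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0,1]")
  }
  if (length(viral_length_range_bp) != 2L ||
      viral_length_range_bp[1] > viral_length_range_bp[2])
    stop("'viral_length_range_bp' must be an increasing pair")
  if (viral_length_range_bp[1] < 1000)
    stop("minimum viral length must be at least 1 kb")
  if (viral_length_range_bp[2] > genome_length_bp)
    stop("viral length range exceeds 'genome_length_bp'")
  structure(cfg, class = "sim_config")
}

# --- composition machinery ---------------------------------------------------

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# list: amino acid -> codons (sense codons only)
.codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

.gc_count <- function(codons) {
  vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
         numeric(1))
}

# A composition signature combines amino-acid usage, within-family codon
# preference, and a GC skew; GC content and amino-acid usage dominate k-mer
# divergence between real genomes, while the within-family codon bias carries
# the codon-adaptation signal. The signature collapses to one global codon
# sampling distribution.
.compose_pi <- function(sig) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(sig$fam_freq)
  pi <- sig$u_aa[unname(gc[sense])] * sig$fam_freq *
    exp(sig$beta_gc * .gc_count(sense))
  pi <- pi / sum(pi)
  names(pi) <- sense
  pi
}

# group (host-class) level: strong codon bias, moderate amino-acid usage
# variation, GC skew spanning roughly 40-60% genomic GC
.draw_group_signature <- function() {
  fams <- .codon_families()
  u_aa <- stats::setNames(.rdirichlet(rep(8, length(fams))), names(fams))
  fam_freq <- numeric(0)
  for (cods in fams)
    fam_freq[cods] <- if (length(cods) == 1L) 1 else
      .rdirichlet(rep(1.2, length(cods)))
  sig <- list(u_aa = u_aa, fam_freq = fam_freq[.sense_codons()],
              beta_gc = stats::runif(1, -0.45, 0.45))
  sig$pi <- .compose_pi(sig)
  sig
}

# genus level, nested in a group: mild perturbation of the group signature
.draw_genus_signature <- function(group, fam_conc = 60, aa_conc = 400,
                                  beta_jitter = 0.04) {
  fams <- .codon_families()
  u_aa <- stats::setNames(.rdirichlet(aa_conc * group$u_aa), names(fams))
  fam_freq <- numeric(0)
  for (cods in fams)
    fam_freq[cods] <- if (length(cods) == 1L) 1 else
      .rdirichlet(fam_conc * length(cods) * group$fam_freq[cods])
  sig <- list(u_aa = u_aa, fam_freq = fam_freq[.sense_codons()],
              beta_gc = group$beta_gc +
                stats::runif(1, -beta_jitter, beta_jitter))
  sig$pi <- .compose_pi(sig)
  sig
}

# neutral background shared by all viruses (the non-host composition source)
.background_signature <- function() {
  fams <- .codon_families()
  u_aa <- stats::setNames(rep(1 / length(fams), length(fams)), names(fams))
  fam_freq <- numeric(0)
  for (cods in fams) fam_freq[cods] <- 1 / length(cods)
  sig <- list(u_aa = u_aa, fam_freq = fam_freq[.sense_codons()],
              beta_gc = 0)
  sig$pi <- .compose_pi(sig)
  sig
}

# mononucleotide marginal implied by a per-family codon frequency vector
.mono_from_codon <- function(freq) {
  cods <- names(freq)
  base <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(cods)) {
    for (nt in strsplit(cods[i], "")[[1]]) base[nt] <- base[nt] + freq[i]
  }
  base / sum(base)
}

.coding_seq <- function(n_codons, freq) {
  paste0(sample(names(freq), n_codons, replace = TRUE, prob = freq),
         collapse = "")
}

.intergenic_seq <- function(n, mono) {
  if (n <= 0) return("")
  paste0(sample(names(mono), n, replace = TRUE, prob = mono), collapse = "")
}

# --- world generation --------------------------------------------------------

#' Generate a seeded synthetic virus-host world
#'
#' Builds host genomes with per-genus codon-usage signatures, viral genomes
#' whose composition is an `alpha`-weighted mixture of the host signature and
#' a global background, viral gene repertoires drawn mostly from genus-level
#' protein-family pools, prophage insertions, a reciprocal similarity table
#' consistent with true family membership, and a prediction table that
#' includes single-violation decoy rows for the curation filters. All truth
#' labels (virus to host, virus to genus, protein to family) are returned.
#'
#' Genus groups are assigned viral families round-robin from Siphoviridae,
#' Myoviridae, Podoviridae (Caudovirales, 15-50 kb linear genomes, one
#' terminase large subunit each) and Inoviridae, Microviridae (ssDNA, 4-8 kb
#' mostly circular genomes, detection tag `noncaudo`). ssDNA genera get a
#' reduced host-mixing weight (0.6 alpha), reflecting the weaker
#' composition adaptation of ssDNA viruses.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_world`: a list with elements
#'   `config`, `hosts`, `host_genes`, `viruses`, `viral_genes`, `similarity`,
#'   `predictions`, and `truth` (list of named vectors `virus2host`,
#'   `virus2cluster`, `protein2family`).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genera
  fam_cycle <- c("Siphoviridae", "Myoviridae", "Podoviridae",
                 "Inoviridae", "Microviridae")
  ord_cycle <- c("Caudovirales", "Caudovirales", "Caudovirales",
                 "Tubulavirales", "Petitvirales")
  v_family <- rep_len(fam_cycle, G)
  v_order  <- rep_len(ord_cycle, G)
  is_ssdna <- v_order != "Caudovirales"

  background <- .background_signature()

  # per-group (host class) composition signature; two host genera nest
  # inside each group with a mild within-group perturbation
  group_sig <- lapply(seq_len(G), function(g) .draw_group_signature())

  hosts <- list(); host_genes <- list()
  n_host_genera <- if (config$hosts_per_genus >= 2) 2L else 1L
  host_freqs <- list()
  hid <- 0L
  for (g in seq_len(G)) {
    genus_sigs <- lapply(seq_len(n_host_genera), function(i)
      .draw_genus_signature(group_sig[[g]]))
    for (h in seq_len(config$hosts_per_genus)) {
      hid <- hid + 1L
      genus_idx <- ((h - 1L) %% n_host_genera) + 1L
      freq <- genus_sigs[[genus_idx]]$pi
      genome_id <- sprintf("HOST_%03d", hid)
      host_freqs[[genome_id]] <- freq
      mono <- .mono_from_codon(freq)
      L <- config$genome_length_bp
      parts <- character(0); genes <- list(); pos <- 0L; gi <- 0L
      repeat {
        ig <- sample(50:150, 1)
        n_cod <- max(100L, min(600L, round(stats::rnorm(1, 300, 40))))
        glen <- 3L * n_cod
        if (pos + ig + glen > L) break
        parts <- c(parts, .intergenic_seq(ig, mono))
        cds <- .coding_seq(n_cod, freq)
        parts <- c(parts, cds)
        gi <- gi + 1L
        genes[[gi]] <- data.frame(
          parent_id = genome_id, gene_id = sprintf("%s_g%03d", genome_id, gi),
          start = pos + ig + 1L, end = pos + ig + glen, strand = "+",
          protein_id = sprintf("%s_p%03d", genome_id, gi), origin = "host",
          hallmark = FALSE, terL = FALSE, parA = FALSE, parB = FALSE,
          func_cat = "cellular", trna = 0L, cds = cds,
          stringsAsFactors = FALSE)
        pos <- pos + ig + glen
      }
      parts <- c(parts, .intergenic_seq(L - pos, mono))
      hosts[[hid]] <- data.frame(
        genome_id = genome_id, group = g,
        domain = "Bacteria", phylum = sprintf("Phylum_%02d", ceiling(g / 2)),
        class = sprintf("Class_%02d", g), order = sprintf("Order_%02d", g),
        family = sprintf("Family_%02d", g),
        genus = sprintf("Genus_%02d_%d", g, genus_idx),
        species = sprintf("Species_%02d_%d_%d", g, genus_idx, h),
        length_bp = L, sequence = paste0(parts, collapse = ""),
        stringsAsFactors = FALSE)
      host_genes[[hid]] <- do.call(rbind, genes)
    }
  }
  hosts <- do.call(rbind, hosts)
  hosts$lineage <- apply(hosts[, c("domain", "phylum", "class", "order",
                                   "family", "genus", "species")], 1,
                         paste, collapse = ";")
  host_genes <- do.call(rbind, host_genes)

  # --- genus protein-family pools -------------------------------------------
  pool_sizes <- pmax(8L, round(config$family_pool_size *
                                 ifelse(is_ssdna, 6000, 32000) / 30000))
  pools <- lapply(seq_len(G), function(g)
    sprintf("VG%02d_F%03d", g, seq_len(pool_sizes[g])))
  n_bg_fam <- 60L
  bg_pool <- sprintf("BGF_%03d", seq_len(n_bg_fam))

  # genus members share a typical genome length (+/- 15%), as real genera do
  rng <- config$viral_length_range_bp
  genus_len <- vapply(seq_len(G), function(g) {
    if (is_ssdna[g]) {
      lo <- max(4500, rng[1]); hi <- min(7000, rng[2])
    } else {
      lo <- max(15000, rng[1]); hi <- rng[2]
    }
    if (hi < lo) { lo <- rng[1]; hi <- rng[2] }
    stats::runif(1, lo, hi)
  }, numeric(1))

  # --- viruses ---------------------------------------------------------------
  viruses <- list(); viral_genes <- list()
  vid <- 0L
  if (config$viruses_per_host > 0) {
    for (i in seq_len(nrow(hosts))) {
      g <- hosts$group[i]
      alpha_eff <- config$alpha_host_mixing * if (is_ssdna[g]) 0.6 else 1
      vfreq <- alpha_eff * host_freqs[[hosts$genome_id[i]]] +
        (1 - alpha_eff) * background$pi
      mono <- .mono_from_codon(vfreq)
      for (v in seq_len(config$viruses_per_host)) {
        vid <- vid + 1L
        seq_id <- sprintf("VIRUS_%04d", vid)
        len <- round(genus_len[g] * stats::runif(1, 0.85, 1.15))
        len <- max(rng[1], min(rng[2], len))
        prophage <- !is_ssdna[g] &&
          stats::runif(1) < config$prophage_fraction
        circular <- if (prophage) FALSE else if (is_ssdna[g]) {
          stats::runif(1) < 0.8
        } else stats::runif(1) < 0.5

        # gene density: ~1 gene/1.2 kb for Caudovirales (genes_per_virus per
        # 30 kb), ~1 gene/550 bp for the compact ssDNA genomes
        n_genes <- if (is_ssdna[g]) max(6L, round(len / 550)) else
          max(4L, round(config$genes_per_virus * len / 30000))
        k_own <- max(2L, min(pool_sizes[g], round(0.88 * n_genes)))
        # core/accessory structure: every genus member carries a prefix of
        # the pool (shared core, incl. capsid and terL families), plus
        # accessory families sampled from the rest of the pool
        k_core <- max(2L, ceiling(0.7 * k_own))
        acc_pool <- pools[[g]][-seq_len(k_core)]
        own <- c(pools[[g]][seq_len(k_core)],
                 if (k_own > k_core) sample(acc_pool,
                                            min(length(acc_pool),
                                                k_own - k_core)))
        k_bg <- min(n_bg_fam, n_genes - length(own))
        fams <- c(own, sample(bg_pool, max(0L, k_bg)))
        n_genes <- length(fams)
        glen_nt <- 3L * max(60L, floor(len * 0.85 / n_genes / 3))
        parts <- character(0); pos <- 0L; genes <- list()
        # plasmid partition genes enrich in bona fide extrachromosomal
        # genomes (circular or >30 kb), not in prophages or short fragments
        extrachrom <- !prophage && (circular || len > 30000)
        parA <- stats::runif(1) < (if (extrachrom) 0.13 else 0.01)
        for (k in seq_len(n_genes)) {
          ig <- sample(20:80, 1)
          if (pos + ig + glen_nt > len) break
          parts <- c(parts, .intergenic_seq(ig, mono))
          cds <- .coding_seq(glen_nt %/% 3L, vfreq)
          parts <- c(parts, cds)
          is_capsid <- fams[k] == pools[[g]][1]
          is_terl <- !is_ssdna[g] && fams[k] == pools[[g]][2]
          genes[[k]] <- data.frame(
            parent_id = seq_id, gene_id = sprintf("%s_g%03d", seq_id, k),
            start = pos + ig + 1L, end = pos + ig + glen_nt, strand = "+",
            protein_id = sprintf("%s_p%03d", seq_id, k), origin = "viral",
            hallmark = is_capsid || is_terl, terL = is_terl,
            parA = parA && k == n_genes, parB = parA && k == n_genes,
            func_cat = if (is_capsid || is_terl) "structure" else
              sample(c("replication", "lysis", "other"), 1),
            trna = 0L, cds = cds, family = fams[k],
            stringsAsFactors = FALSE)
          pos <- pos + ig + glen_nt
        }
        genes <- do.call(rbind, genes)
        parts <- c(parts, .intergenic_seq(len - pos, mono))
        vseq <- paste0(parts, collapse = "")

        viruses[[vid]] <- data.frame(
          sequence_id = seq_id, genome_id = hosts$genome_id[i], group = g,
          order_v = v_order[g], family_v = v_family[g],
          genus_v = sprintf("VG_%02d", g),
          length_bp = nchar(vseq), circular = circular, prophage = prophage,
          prophage_start = NA_integer_, prophage_end = NA_integer_,
          detection_tag = if (is_ssdna[g]) "noncaudo" else
            sample(c("hallmark", "refseq"), 1),
          hallmark_count = sum(genes$hallmark),
          terL_count = sum(genes$terL),
          parA = any(genes$parA), parB = any(genes$parB),
          trna = if (is_ssdna[g]) 0L else stats::rpois(1, 2),
          alpha_eff = alpha_eff, sequence = vseq,
          stringsAsFactors = FALSE)
        viral_genes[[vid]] <- genes
      }
    }
  }
  viruses <- if (vid > 0) do.call(rbind, viruses) else
    data.frame(sequence_id = character(0))
  viral_genes <- if (vid > 0) do.call(rbind, viral_genes) else
    data.frame(protein_id = character(0))

  # --- prophage insertion ----------------------------------------------------
  if (vid > 0) {
    for (i in which(viruses$prophage)) {
      gid <- viruses$genome_id[i]
      hrow <- which(hosts$genome_id == gid)
      hg_idx <- which(host_genes$parent_id == gid)
      # insert after the end of a random host gene
      anchor <- sample(host_genes$end[hg_idx], 1) + sample(10:40, 1)
      hseq <- hosts$sequence[hrow]
      vlen <- viruses$length_bp[i]
      hosts$sequence[hrow] <- paste0(substr(hseq, 1, anchor),
                                     viruses$sequence[i],
                                     substr(hseq, anchor + 1, nchar(hseq)))
      hosts$length_bp[hrow] <- nchar(hosts$sequence[hrow])
      viruses$prophage_start[i] <- anchor + 1L
      viruses$prophage_end[i] <- anchor + vlen
      shift <- host_genes$parent_id == gid & host_genes$start > anchor
      host_genes$start[shift] <- host_genes$start[shift] + vlen
      host_genes$end[shift] <- host_genes$end[shift] + vlen
      # shift previously placed prophages downstream of the insertion point
      prev <- viruses$genome_id == gid & !is.na(viruses$prophage_start) &
        viruses$prophage_start > anchor &
        viruses$sequence_id != viruses$sequence_id[i]
      viruses$prophage_start[prev] <- viruses$prophage_start[prev] + vlen
      viruses$prophage_end[prev] <- viruses$prophage_end[prev] + vlen
    }
  }

  # --- similarity table (one conserved score per true family) ---------------
  similarity <- .family_similarity_table(viral_genes)

  # --- prediction table ------------------------------------------------------
  predictions <- .prediction_table(viruses, hosts, config)

  truth <- list(
    virus2host = if (vid > 0)
      stats::setNames(viruses$genome_id, viruses$sequence_id) else
        stats::setNames(character(0), character(0)),
    virus2cluster = if (vid > 0)
      stats::setNames(viruses$genus_v, viruses$sequence_id) else
        stats::setNames(character(0), character(0)),
    protein2family = if (vid > 0)
      stats::setNames(viral_genes$family, viral_genes$protein_id) else
        stats::setNames(character(0), character(0)))

  structure(list(config = config, hosts = hosts, host_genes = host_genes,
                 viruses = viruses, viral_genes = viral_genes,
                 similarity = similarity, predictions = predictions,
                 truth = truth),
            class = "synthetic_world")
}

.family_similarity_table <- function(viral_genes) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!nrow(viral_genes)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- cols
    return(out)
  }
  fams <- split(viral_genes$protein_id, viral_genes$family)
  fams <- fams[lengths(fams) >= 2]
  rows <- lapply(names(fams), function(f) {
    ids <- fams[[f]]
    score <- round(stats::runif(1, 60, 300), 1)
    pairs <- expand.grid(q = ids, s = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$q != pairs$s, ]
    data.frame(qseqid = pairs$q, sseqid = pairs$s,
               pident = round(stats::runif(nrow(pairs), 60, 95), 1),
               length = 250L, mismatch = 30L, gapopen = 2L,
               qstart = 1L, qend = 250L, sstart = 1L, send = 250L,
               evalue = 1e-20, bitscore = score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.prediction_table <- function(viruses, hosts, config) {
  real <- if (nrow(viruses) && "genome_id" %in% names(viruses)) data.frame(
    sequence_id = viruses$sequence_id, genome_id = viruses$genome_id,
    category = sample(1:2, nrow(viruses), replace = TRUE),
    detection_tag = viruses$detection_tag,
    circular = as.integer(viruses$circular),
    length_bp = viruses$length_bp,
    prophage = as.integer(viruses$prophage),
    hallmark_count = viruses$hallmark_count,
    terL_count = viruses$terL_count,
    parA = as.integer(viruses$parA), parB = as.integer(viruses$parB),
    label = "", has_microbial_genes = viruses$prophage,
    stringsAsFactors = FALSE) else NULL
  n_real <- if (is.null(real)) 0L else nrow(real)
  n_decoy <- if (config$decoy_rate > 0 && n_real > 0)
    round(config$decoy_rate * n_real / (1 - config$decoy_rate)) else 0L
  decoys <- NULL
  if (n_decoy > 0) {
    type <- rep_len(1:6, n_decoy)
    decoys <- data.frame(
      sequence_id = sprintf("DECOY_%03d", seq_len(n_decoy)),
      genome_id = sample(hosts$genome_id, n_decoy, replace = TRUE),
      category = ifelse(type == 2, 3L, 1L),
      detection_tag = ifelse(type == 6, "noncaudo", "hallmark"),
      circular = as.integer(type %in% c(1, 5)),
      length_bp = c(5386L, 20000L, 20000L, 7000L, 2500L, 4000L)[type],
      prophage = as.integer(type == 3),
      hallmark_count = ifelse(type == 3, 0L, 1L),
      terL_count = 0L, parA = 0L, parB = 0L,
      label = ifelse(type == 1, "Enterobacteria phage PhiX174", ""),
      has_microbial_genes = type == 3,
      stringsAsFactors = FALSE)
  }
  out <- rbind(real, decoys)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(0), genome_id = character(0),
                      category = integer(0), detection_tag = character(0),
                      circular = integer(0), length_bp = integer(0),
                      prophage = integer(0), hallmark_count = integer(0),
                      terL_count = integer(0), parA = integer(0),
                      parB = integer(0), label = character(0),
                      has_microbial_genes = logical(0))
  } else {
    out <- out[sample(nrow(out)), ]
    rownames(out) <- NULL
  }
  out
}

#' Fragment host genomes into draft-like contigs
#'
#' Splits each host genome at random breakpoints into contigs of roughly
#' `target_contig_len_bp`, retaining per-contig gene counts and
#' prophage-vs-host provenance. A prophage fully contained in a contig with no
#' host genes is the misclassification case the curation filters must guard
#' against (an integrated prophage that looks extrachromosomal).
#'
#' @param world a `synthetic_world`.
#' @param target_contig_len_bp target contig length (>= 1 kb).
#' @param seed integer seed.
#' @param breakpoints optional named list (genome_id -> integer vector of
#'   breakpoint positions) overriding the random breakpoints, for constructing
#'   exact fragmentation cases.
#' @return data.frame of contigs: `contig_id`, `genome_id`, `start`, `end`,
#'   `length_bp`, `n_host_genes`, `prophage_overlap_bp`, `fully_viral`
#'   (overlaps a prophage and contains no host gene), `provenance`
#'   (`host`, `prophage`, or `mixed`).
#' @export
fragment_genomes <- function(world, target_contig_len_bp, seed = 1,
                             breakpoints = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (target_contig_len_bp < 1000)
    stop("'target_contig_len_bp' must be at least 1 kb")
  set.seed(seed)
  out <- list(); n <- 0L
  pro <- world$viruses[world$viruses$prophage %in% TRUE, , drop = FALSE]
  for (i in seq_len(nrow(world$hosts))) {
    gid <- world$hosts$genome_id[i]
    L <- world$hosts$length_bp[i]
    bp <- if (!is.null(breakpoints) && gid %in% names(breakpoints)) {
      sort(unique(breakpoints[[gid]]))
    } else {
      k <- max(0L, round(L / target_contig_len_bp) - 1L)
      if (k > 0) sort(sample(L - 1L, k)) else integer(0)
    }
    bounds <- cbind(start = c(1L, bp + 1L), end = c(bp, L))
    hg <- world$host_genes[world$host_genes$parent_id == gid, , drop = FALSE]
    pg <- pro[pro$genome_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(bounds))) {
      n <- n + 1L
      s <- bounds[j, "start"]; e <- bounds[j, "end"]
      nh <- sum(hg$start >= s & hg$end <= e)
      ov <- 0L
      if (nrow(pg)) {
        ov <- sum(pmax(0L, pmin(e, pg$prophage_end) -
                         pmax(s, pg$prophage_start) + 1L))
      }
      fully_viral <- ov > 0 && nh == 0
      out[[n]] <- data.frame(
        contig_id = sprintf("%s_c%03d", gid, j), genome_id = gid,
        start = s, end = e, length_bp = e - s + 1L, n_host_genes = nh,
        prophage_overlap_bp = ov, fully_viral = fully_viral,
        provenance = if (ov == 0) "host" else if (nh == 0) "prophage" else
          "mixed",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Misclassification rate of integrated prophages under a size threshold
#'
#' Among contigs derived from integrated prophages (any prophage overlap),
#' the fraction that carry no host gene and exceed `size_threshold_bp`, i.e.
#' that the replication-mode rule would call extrachromosomal.
#'
#' @param contigs output of [fragment_genomes()].
#' @param size_threshold_bp length above which a fully viral linear contig is
#'   classified extrachromosomal.
#' @return a fraction in `[0,1]` (NaN when no prophage-derived contig exists).
#' @export
prophage_misclassification_rate <- function(contigs, size_threshold_bp) {
  der <- contigs[contigs$prophage_overlap_bp > 0, , drop = FALSE]
  if (!nrow(der)) return(NaN)
  mean(der$fully_viral & der$length_bp > size_threshold_bp)
}
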