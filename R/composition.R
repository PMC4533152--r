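#' k-mer relative frequencies of a nucleotide sequence
#'
#' Counts overlapping k-mers on the given strand (windows containing non-ACGT
#' characters match nothing and are effectively skipped) and normalises to
#' relative frequencies. With `canonical = TRUE`, a k-mer and its reverse
#' complement are collapsed onto the lexicographically smaller of the two.
#'
#' @param sequence character string or [Biostrings::DNAString].
#' @param k word size, 1 to 4 supported (any k >= 1 accepted).
#' @param canonical collapse reverse complements (default FALSE: the counts
#'   are single-strand).
#' @return named numeric vector of 4^k frequencies summing to 1 (or, when
#'   canonical, one entry per canonical k-mer).
#' @export
kmer_frequencies <- function(sequence, k, canonical = FALSE) {
  stopifnot(k >= 1)
  s <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(as.character(sequence))
  if (length(s) < k) stop("sequence shorter than k")
  counts <- Biostrings::oligonucleotideFrequency(s, width = k)
  if (sum(counts) == 0)
    stop("no valid ACGT window of width ", k, " in sequence")
  if (canonical) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(counts))))
    canon <- pmin(names(counts), rc)
    counts <- tapply(counts, canon, sum)
    counts <- counts[sort(names(counts))]
  }
  counts / sum(counts)
}

#' Mean absolute error distance between two frequency vectors
#'
#' @param v1,v2 equal-length k-mer frequency vectors (same k).
#' @return mean of absolute differences; symmetric, zero iff identical.
#' @export
mae_distance <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("frequency vectors have different k (lengths ", length(v1), " vs ",
         length(v2), ")")
  mean(abs(v1 - v2))
}

#' Codon usage table with relative adaptiveness
#'
#' Counts codons over a set of coding sequences (standard genetic code),
#' computes each codon's frequency within its synonymous family and its
#' relative adaptiveness `w = f / max(f among synonyms)`. Codons never
#' observed in a family that was itself observed get `w` floored at
#' `floor_w` so the geometric mean in [cai()] stays positive; in a family
#' with no observations all members get `w = 1` (uninformative).
#'
#' @param cds character vector of coding sequences, each of length divisible
#'   by 3 (names used in error messages).
#' @param floor_w floor for unseen codons (default 1e-3).
#' @return list with `freq` (within-family frequency) and `w` (relative
#'   adaptiveness), both named by codon (sense codons only).
#' @export
codon_usage_table <- function(cds, floor_w = 1e-3) {
  stopifnot(length(cds) >= 1)
  bad <- nchar(cds) %% 3 != 0
  if (any(bad)) {
    nm <- names(cds)[which(bad)[1]]
    stop("CDS ", if (!is.null(nm) && nzchar(nm)) nm else which(bad)[1],
         " has length not divisible by 3")
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(cds), width = 3, step = 3))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  counts <- counts[sense]
  fams <- split(sense, unname(gc[sense]))
  freq <- w <- stats::setNames(numeric(length(sense)), sense)
  for (cods in fams) {
    tot <- sum(counts[cods])
    if (tot == 0) { freq[cods] <- NA_real_; w[cods] <- 1; next }
    freq[cods] <- counts[cods] / tot
    w[cods] <- pmax(freq[cods] / max(freq[cods]), floor_w)
  }
  list(freq = freq, w = w)
}

#' Codon adaptation index of a gene against a usage table
#'
#' Geometric mean of the relative adaptiveness `w` over the gene's codons,
#' excluding stop codons and single-codon families (Met, Trp), which carry no
#' usage information.
#'
#' @param cds a coding sequence (length divisible by 3).
#' @param usage a [codon_usage_table()].
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(cds, usage) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                      seq(3, nchar(cds), by = 3))
  gc <- Biostrings::GENETIC_CODE
  fam_size <- table(unname(gc[gc != "*"]))
  aa <- gc[codons]
  keep <- !is.na(aa) & aa != "*" & fam_size[aa] > 1
  codons <- codons[keep]
  if (!length(codons))
    stop("gene contains only stop codons and single-codon families")
  exp(mean(log(usage$w[codons])))
}

#' Mean CAI of a set of genes
#'
#' @param cds_set character vector of coding sequences.
#' @param usage a [codon_usage_table()].
#' @return mean gene-level CAI.
#' @export
sequence_cai <- function(cds_set, usage) {
  mean(vapply(cds_set, cai, numeric(1), usage = usage))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum of the absolute difference between the two empirical CDFs.
#'
#' @param sample1,sample2 non-empty numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(sample1, sample2) {
  if (!length(sample1) || !length(sample2)) stop("empty sample")
  unname(suppressWarnings(
    stats::ks.test(sample1, sample2, exact = FALSE)$statistic))
}

# distances from one virus to a set of host genomes under one metric
.virus_distances <- function(vkmer, vcai_genes, host_kmers, host_tables,
                             metric, genome_ids) {
  if (metric == "cai") {
    vapply(genome_ids, function(g)
      1 - sequence_cai(vcai_genes, host_tables[[g]]), numeric(1))
  } else {
    k <- as.integer(sub("k", "", metric))
    vapply(genome_ids, function(g)
      mae_distance(vkmer[[k]], host_kmers[[g]][[k]]), numeric(1))
  }
}

#' Genome-composition adaptation experiment
#'
#' For every virus and every metric (k-mer MAE for k = 1..4 and 1 - CAI),
#' computes the distance to its host and to 10 randomly selected genomes from
#' each comparison category: same genus as the host, same family, and a
#' different order. Per category (and optionally per stratum of viruses) the
#' Kolmogorov-Smirnov distance D between the virus-host distance distribution
#' and the pooled virus-non-host distribution is reported. A category with
#' fewer candidates than `n_picks` is sampled with replacement; a category
#' with no candidate is skipped with a warning.
#'
#' @param world a `synthetic_world` (or a list with the same `hosts`,
#'   `host_genes`, `viruses`, `viral_genes` tables).
#' @param metrics subset of `c("k1","k2","k3","k4","cai")`.
#' @param n_picks random picks per category (default 10).
#' @param strata optional named vector (virus id -> stratum label) splitting
#'   the report, e.g. by family, tRNA-count bin, or replication mode.
#' @param seed integer seed.
#' @return list with `report` (data.frame `stratum`, `metric`, `category`,
#'   `d`, `n_virus`) and `distances` (long data.frame of all computed
#'   distances).
#' @export
adaptation_experiment <- function(world,
                                  metrics = c("k1", "k2", "k3", "k4", "cai"),
                                  n_picks = 10, strata = NULL, seed = 1) {
  stopifnot(nrow(world$viruses) > 0)
  set.seed(seed)
  hosts <- world$hosts
  host_kmers <- host_composition_library(world, ks = 1:4)
  host_tables <- if ("cai" %in% metrics) host_usage_tables(world) else NULL
  vs <- world$viruses
  rows <- list(); nr <- 0L
  for (i in seq_len(nrow(vs))) {
    hid <- vs$genome_id[i]
    h <- hosts[hosts$genome_id == hid, ]
    cats <- list(
      host = hid,
      same_genus = hosts$genome_id[hosts$genus == h$genus &
                                     hosts$genome_id != hid],
      same_family = hosts$genome_id[hosts$family == h$family &
                                      hosts$genome_id != hid],
      different_order = hosts$genome_id[hosts$order != h$order])
    vkmer <- lapply(1:4, function(k) kmer_frequencies(vs$sequence[i], k))
    vgenes <- world$viral_genes$cds[
      world$viral_genes$parent_id == vs$sequence_id[i]]
    for (cat in names(cats)) {
      pool <- cats[[cat]]
      if (!length(pool)) {
        warning("no candidate genome for category '", cat, "' (virus ",
                vs$sequence_id[i], "); skipped")
        next
      }
      picks <- if (cat == "host") pool else
        sample(pool, n_picks, replace = length(pool) < n_picks)
      for (metric in metrics) {
        d <- .virus_distances(vkmer, vgenes, host_kmers, host_tables,
                              metric, picks)
        nr <- nr + 1L
        rows[[nr]] <- data.frame(virus = vs$sequence_id[i], category = cat,
                                 metric = metric, genome = picks,
                                 distance = unname(d),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  distances <- do.call(rbind, rows)
  strat <- if (is.null(strata))
    stats::setNames(rep("all", nrow(vs)), vs$sequence_id) else strata
  distances$stratum <- strat[distances$virus]
  rep_rows <- list(); k <- 0L
  for (st in unique(distances$stratum)) {
    dst <- distances[distances$stratum %in% st, ]
    for (metric in unique(dst$metric)) {
      dm <- dst[dst$metric == metric, ]
      hostd <- dm$distance[dm$category == "host"]
      for (cat in setdiff(unique(dm$category), "host")) {
        k <- k + 1L
        rep_rows[[k]] <- data.frame(
          stratum = st, metric = metric, category = cat,
          d = ks_statistic(hostd, dm$distance[dm$category == cat]),
          n_virus = length(unique(dm$virus)), stringsAsFactors = FALSE)
      }
    }
  }
  list(report = do.call(rbind, rep_rows), distances = distances)
}

#' Host k-mer composition library
#'
#' @param world a `synthetic_world`.
#' @param ks k values (default 4 only).
#' @param mask_prophages remove integrated prophage regions from host genomes
#'   before counting (default TRUE).
#' @return named list: genome id -> list indexed by k of frequency vectors.
#' @export
host_composition_library <- function(world, ks = 4, mask_prophages = TRUE) {
  seqs <- stats::setNames(world$hosts$sequence, world$hosts$genome_id)
  if (mask_prophages && nrow(world$viruses)) {
    pro <- world$viruses[world$viruses$prophage %in% TRUE, , drop = FALSE]
    for (g in unique(pro$genome_id)) {
      s <- seqs[[g]]
      regs <- pro[pro$genome_id == g, c("prophage_start", "prophage_end")]
      regs <- regs[order(-regs$prophage_start), ]
      for (r in seq_len(nrow(regs))) {
        s <- paste0(substr(s, 1, regs$prophage_start[r] - 1),
                    substr(s, regs$prophage_end[r] + 1, nchar(s)))
      }
      seqs[[g]] <- s
    }
  }
  lapply(seqs, function(s) {
    out <- vector("list", max(ks))
    for (k in ks) out[[k]] <- kmer_frequencies(s, k)
    out
  })
}

#' Codon usage tables for every host genome
#'
#' @param world a `synthetic_world`.
#' @return named list: genome id -> [codon_usage_table()].
#' @export
host_usage_tables <- function(world) {
  lapply(split(world$host_genes$cds, world$host_genes$parent_id),
         codon_usage_table)
}

#' Fragment-size subsampling experiment
#'
#' Draws `n` viruses (with replacement when fewer are available), cuts from
#' each a contiguous fragment at every size in `sizes`, and computes the
#' k-mer MAE distance from the fragment to the virus's host and to one random
#' different-order genome. Reports, per k and size, the mean host and
#' non-host distances and the least-squares slope of distance versus size.
#'
#' @param world a `synthetic_world`.
#' @param sizes fragment sizes in bp (default 2000 to 20000 by 2000).
#' @param n fragments per size (default 1000).
#' @param ks k values (default 1:4).
#' @param seed integer seed.
#' @return data.frame `k`, `size`, `mean_host`, `mean_nonhost`, plus an
#'   attribute `slopes` (data.frame `k`, `slope_host`, `slope_nonhost`).
#' @export
subsample_experiment <- function(world, sizes = seq(2000, 20000, by = 2000),
                                 n = 1000, ks = 1:4, seed = 1) {
  stopifnot(nrow(world$viruses) > 0)
  set.seed(seed)
  host_kmers <- host_composition_library(world, ks = ks)
  hosts <- world$hosts
  vs <- world$viruses
  sizes <- sort(sizes)
  usable <- vs$length_bp >= min(sizes)
  vs <- vs[usable, , drop = FALSE]
  idx <- sample(nrow(vs), n, replace = TRUE)
  rows <- list(); r <- 0L
  for (sz in sizes) {
    ok <- which(vs$length_bp[idx] >= sz)
    if (!length(ok)) {
      warning("fragment size ", sz, " exceeds every sampled genome; skipped")
      next
    }
    for (ii in ok) {
      i <- idx[ii]
      start <- sample(vs$length_bp[i] - sz + 1L, 1)
      frag <- substr(vs$sequence[i], start, start + sz - 1L)
      hid <- vs$genome_id[i]
      h <- hosts[hosts$genome_id == hid, ]
      nonpool <- hosts$genome_id[hosts$order != h$order]
      nh <- if (length(nonpool)) sample(nonpool, 1) else NA_character_
      for (k in ks) {
        fk <- kmer_frequencies(frag, k)
        r <- r + 1L
        rows[[r]] <- data.frame(
          k = k, size = sz,
          host = mae_distance(fk, host_kmers[[hid]][[k]]),
          nonhost = if (is.na(nh)) NA_real_ else
            mae_distance(fk, host_kmers[[nh]][[k]]))
      }
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(host, nonhost) ~ k + size, data = long,
                          FUN = mean)
  names(agg)[3:4] <- c("mean_host", "mean_nonhost")
  slopes <- do.call(rbind, lapply(split(long, long$k), function(d) {
    data.frame(k = d$k[1],
               slope_host = stats::coef(stats::lm(host ~ size, d))[2],
               slope_nonhost = stats::coef(stats::lm(nonhost ~ size, d))[2])
  }))
  rownames(slopes) <- NULL
  attr(agg, "slopes") <- slopes
  agg
}

#' Compare gene-level CAI between functional categories
#'
#' Reporting utility: for each functional category, a Wilcoxon signed-rank
#' comparison of member genes' CAI against genes of the reference category
#' (default `"other"`), paired by rank via a two-sample Wilcoxon when group
#' sizes differ.
#'
#' @param gene_cai numeric vector of gene CAI values.
#' @param categories character vector of functional categories (same
#'   length).
#' @param reference reference category label (default `"other"`).
#' @return data.frame `category`, `n`, `median_cai`, `p_value`.
#' @export
cai_by_category <- function(gene_cai, categories, reference = "other") {
  stopifnot(length(gene_cai) == length(categories))
  ref <- gene_cai[categories == reference]
  cats <- setdiff(unique(categories), reference)
  out <- lapply(cats, function(cc) {
    x <- gene_cai[categories == cc]
    p <- if (length(x) && length(ref))
      suppressWarnings(stats::wilcox.test(x, ref)$p.value) else NA_real_
    data.frame(category = cc, n = length(x), median_cai = stats::median(x),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
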