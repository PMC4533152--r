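#' Build the reciprocal-best-hit protein graph
#'
#' Filters an all-vs-all protein similarity table (BLAST tabular columns) at
#' `min_score` / `max_evalue`, then draws an undirected edge between two
#' proteins when each is among the other's best-scoring passing hits (ties at
#' the maximal score are all considered best hits). Edge weight is the mean of
#' the two directed bit scores. Self hits are ignored.
#'
#' @param hits data.frame with columns `qseqid`, `sseqid`, `bitscore`,
#'   `evalue` (extra columns ignored).
#' @param min_score minimum bit score (default 50).
#' @param max_evalue maximum e-value (default 0.001).
#' @return an undirected weighted [igraph::graph] whose vertices are the
#'   proteins appearing in passing hits.
#' @export
build_rbh_graph <- function(hits, min_score = 50, max_evalue = 0.001) {
  stopifnot(all(c("qseqid", "sseqid", "bitscore", "evalue") %in% names(hits)))
  h <- hits[hits$bitscore >= min_score & hits$evalue <= max_evalue &
              hits$qseqid != hits$sseqid, , drop = FALSE]
  if (!nrow(h))
    return(igraph::make_empty_graph(directed = FALSE))
  # keep best score per directed pair, then best (with ties) per query
  key <- paste(h$qseqid, h$sseqid, sep = "\r")
  best_pair <- tapply(h$bitscore, key, max)
  qs <- sub("\r.*", "", names(best_pair))
  ss <- sub(".*\r", "", names(best_pair))
  sc <- as.numeric(best_pair)
  qmax <- tapply(sc, qs, max)
  is_best <- sc >= qmax[qs] - 1e-9
  dir_best <- stats::setNames(sc, paste(qs, ss, sep = "\r"))[is_best]
  fwd <- names(dir_best)
  rev <- paste(sub(".*\r", "", fwd), sub("\r.*", "", fwd), sep = "\r")
  mutual <- fwd[rev %in% fwd]
  if (!length(mutual)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, length(unique(c(qs, ss))),
                              name = unique(c(qs, ss)))
    return(g)
  }
  q2 <- sub("\r.*", "", mutual)
  s2 <- sub(".*\r", "", mutual)
  w <- (dir_best[mutual] +
          dir_best[paste(s2, q2, sep = "\r")]) / 2
  keep <- q2 < s2
  edges <- data.frame(from = q2[keep], to = s2[keep],
                      weight = as.numeric(w[keep]),
                      stringsAsFactors = FALSE)
  verts <- unique(c(qs, ss))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Column-normalises the adjacency matrix (with unit self loops), then
#' iterates expansion (matrix squaring) and inflation (element-wise power
#' followed by column renormalisation), pruning entries below `prune` after
#' each inflation, until the matrix changes by less than `tol` (max absolute
#' difference) or `max_iter` iterations. Attractor rows of the limit matrix
#' define the clusters; a node attracted by several attractors is assigned to
#' the first.
#'
#' @param graph an undirected [igraph::graph] with non-negative `weight`
#'   attribute (unweighted graphs get unit weights).
#' @param inflation inflation exponent (> 1).
#' @param add_self_loops add unit self loops before normalisation (default).
#' @param prune threshold below which entries are zeroed (default 1e-6).
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return named integer vector: cluster id per vertex (a partition).
#' @export
mcl <- function(graph, inflation, add_self_loops = TRUE, prune = 1e-6,
                tol = 1e-8, max_iter = 100) {
  stopifnot(inflation > 1)
  n <- igraph::vcount(graph)
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (igraph::ecount(graph) > 0 &&
      !is.null(igraph::E(graph)$weight) &&
      any(igraph::E(graph)$weight <= 0))
    stop("MCL requires positive edge weights")
  A <- igraph::as_adjacency_matrix(
    graph, attr = if (!is.null(igraph::E(graph)$weight) &&
                      igraph::ecount(graph) > 0) "weight" else NULL,
    sparse = TRUE)
  A <- methods::as(A, "generalMatrix")
  if (add_self_loops) Matrix::diag(A) <- pmax(Matrix::diag(A), 1)
  norm_cols <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- norm_cols(A)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2@x <- M2@x ^ inflation           # inflation
    M2 <- norm_cols(M2)
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- norm_cols(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  M <- methods::as(methods::as(M, "CsparseMatrix"), "TsparseMatrix")
  attractors <- which(Matrix::diag(M) > prune)
  membership <- rep(NA_integer_, n)
  cid <- 0L
  for (a in sort(attractors)) {
    members <- unique(c(a, M@j[M@i == a - 1L] + 1L))
    new <- members[is.na(membership[members])]
    if (a %in% new || is.na(membership[a])) {
      cid <- cid + 1L
      membership[new] <- cid
    } else {
      membership[new] <- membership[a]
    }
  }
  # nodes never reached (numerically zero rows): singleton clusters
  for (i in which(is.na(membership))) {
    cid <- cid + 1L
    membership[i] <- cid
  }
  stats::setNames(membership, nm)
}

#' Hypergeometric significance of shared gene content between two genomes
#'
#' Given two genomes carrying `a` and `b` distinct protein clusters (PCs) out
#' of a universe of `n` PCs, the probability of sharing `c` or more PCs by
#' chance is the hypergeometric upper tail
#' \deqn{P = \sum_{i=c}^{\min(a,b)} \binom{a}{i}\binom{n-a}{b-i} /
#'   \binom{n}{b}.}
#' The significance is `S = max(0, -log10(P * n_pairs))`, a Bonferroni-style
#' correction by the number of genome pairs tested. The tail sum is evaluated
#' in log space so that very small probabilities survive.
#'
#' @param a,b PC counts of the two genomes.
#' @param c shared PC count (presence/absence, not copy number).
#' @param n total number of PCs in the data set.
#' @param n_pairs number of genome pairs tested (correction factor).
#' @return list with `p` (tail probability) and `s` (significance).
#' @export
pair_significance <- function(a, b, c, n, n_pairs = 1) {
  if (a > n || b > n) stop("'a' and 'b' cannot exceed the universe size 'n'")
  stopifnot(c >= 0, c <= min(a, b), n_pairs >= 1)
  if (c == 0) return(list(p = 1, s = 0))
  i <- c:min(a, b)
  logterms <- lchoose(a, i) + lchoose(n - a, b - i) - lchoose(n, b)
  m <- max(logterms)
  logp <- m + log(sum(exp(logterms - m)))
  logp <- min(logp, 0)
  log10p <- logp / log(10)
  s <- max(0, -(log10p + log10(n_pairs)))
  list(p = exp(logp), s = s)
}

#' Genome gene-content profiles from protein clusters
#'
#' @param pc_membership named vector (protein id -> PC id), e.g. from [mcl()]
#'   on the RBH graph.
#' @param protein2genome named vector (protein id -> genome/sequence id).
#' @return list with `profiles` (named list: genome -> character vector of PC
#'   ids) and `n_pcs` (universe size). Proteins without a PC (singletons never
#'   clustered) do not contribute.
#' @export
genome_profiles <- function(pc_membership, protein2genome) {
  prot <- names(pc_membership)
  gen <- protein2genome[prot]
  keep <- !is.na(gen)
  profiles <- lapply(split(as.character(pc_membership[keep]), gen[keep]),
                     unique)
  list(profiles = profiles, n_pcs = length(unique(pc_membership)))
}

#' Build the genome-genome shared-gene-content network
#'
#' Computes the hypergeometric significance [pair_significance()] for every
#' genome pair and draws an edge when `S >= sig_threshold`, weighted by `S`.
#'
#' @param profiles output of [genome_profiles()].
#' @param sig_threshold minimum significance to draw an edge (default 1).
#' @return an undirected weighted [igraph::graph] over all profiled genomes
#'   (isolated genomes included as vertices).
#' @export
build_genome_network <- function(profiles, sig_threshold = 1) {
  prof <- profiles$profiles
  if (length(prof) < 2) stop("at least two genome profiles required")
  sig <- pairwise_significance(profiles)
  keep <- sig$s >= sig_threshold
  edges <- data.frame(from = sig$g1[keep], to = sig$g2[keep],
                      weight = sig$s[keep], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = names(prof)))
}

#' All-pairs shared-gene-content significance
#'
#' @param profiles output of [genome_profiles()].
#' @return data.frame `g1`, `g2`, `shared`, `p`, `s` for every genome pair.
#' @export
pairwise_significance <- function(profiles) {
  prof <- profiles$profiles
  ids <- names(prof)
  n <- profiles$n_pcs
  np <- choose(length(ids), 2)
  out <- vector("list", np)
  k <- 0L
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      k <- k + 1L
      cc <- length(intersect(prof[[i]], prof[[j]]))
      ps <- pair_significance(length(prof[[i]]), length(prof[[j]]), cc, n,
                              n_pairs = np)
      out[[k]] <- data.frame(g1 = ids[i], g2 = ids[j], shared = cc,
                             p = ps$p, s = ps$s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cluster genomes into virus clusters (VCs)
#'
#' Runs [mcl()] on the significance-weighted genome network. Genomes with no
#' edge are reported separately as unclustered rather than forced into
#' singleton VCs.
#'
#' @param network genome network from [build_genome_network()].
#' @param inflation MCL inflation (default 4).
#' @return list with `membership` (named vector, genome -> VC id, clustered
#'   genomes only) and `unclustered` (character vector of isolated genomes).
#' @export
cluster_genomes <- function(network, inflation = 4) {
  deg <- igraph::degree(network)
  isolated <- names(deg)[deg == 0]
  sub <- igraph::delete_vertices(network, isolated)
  membership <- if (igraph::vcount(sub) > 0) mcl(sub, inflation) else
    stats::setNames(integer(0), character(0))
  list(membership = membership, unclustered = isolated)
}

#' Intra-cluster clustering coefficient (ICCC)
#'
#' Cluster homogeneity: for each node of degree >= 1, the fraction of its
#' neighbours sharing its cluster; ICCC is the mean over those nodes.
#' Degree-0 nodes are excluded.
#'
#' @param network an [igraph::graph].
#' @param membership named vector (vertex name -> cluster) covering at least
#'   all vertices of degree >= 1.
#' @return a value in `[0, 1]`.
#' @export
iccc <- function(network, membership) {
  deg <- igraph::degree(network)
  nodes <- names(deg)[deg > 0]
  if (!length(nodes)) stop("ICCC undefined: all nodes have degree 0")
  fr <- vapply(nodes, function(v) {
    nb <- igraph::neighbors(network, v)$name
    mean(membership[nb] == membership[v], na.rm = FALSE)
  }, numeric(1))
  mean(fr)
}

#' Sweep significance threshold and MCL inflation, scored by ICCC
#'
#' Evaluates the full grid, recomputing pairwise significances once. The
#' argmax by ICCC breaks ties by lower threshold, then lower inflation.
#'
#' @param profiles output of [genome_profiles()].
#' @param inflations inflation grid (default 1.5 to 5 by 0.25).
#' @param thresholds significance threshold grid (default `c(1, 5, 10, 20,
#'   50)`).
#' @return list with `grid` (data.frame `threshold`, `inflation`, `iccc`,
#'   `n_clusters`, `n_unclustered`) and `best` (the argmax row).
#' @export
sweep_parameters <- function(profiles,
                             inflations = seq(1.5, 5, by = 0.25),
                             thresholds = c(1, 5, 10, 20, 50)) {
  if (!length(inflations) || !length(thresholds))
    stop("empty parameter grid")
  sig <- pairwise_significance(profiles)
  ids <- names(profiles$profiles)
  rows <- list(); k <- 0L
  for (th in sort(thresholds)) {
    keep <- sig$s >= th
    net <- igraph::graph_from_data_frame(
      data.frame(from = sig$g1[keep], to = sig$g2[keep],
                 weight = sig$s[keep]),
      directed = FALSE, vertices = data.frame(name = ids))
    for (inf in sort(inflations)) {
      cl <- cluster_genomes(net, inflation = inf)
      ic <- if (any(igraph::degree(net) > 0))
        iccc(net, cl$membership) else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(threshold = th, inflation = inf, iccc = ic,
                              n_clusters = length(unique(cl$membership)),
                              n_unclustered = length(cl$unclustered))
    }
  }
  grid <- do.call(rbind, rows)
  ok <- which(!is.na(grid$iccc))
  best <- if (length(ok)) {
    o <- ok[order(-grid$iccc[ok], grid$threshold[ok], grid$inflation[ok])]
    grid[o[1], ]
  } else grid[1, ]
  list(grid = grid, best = best)
}

#' Annotate virus clusters and call putative new genera
#'
#' A VC is a putative genus when at least one member is circular, a known
#' complete genome, or longer than 30 kb (avoiding genome fragments being
#' called new genera); it is `putative_genus_new` when additionally no member
#' is a reference genome, `putative_genus_known` when a reference is present,
#' and `fragment_only` otherwise.
#'
#' @param membership named vector (sequence id -> VC id).
#' @param metadata data.frame with `sequence_id`, `circular`, `complete`,
#'   `length_bp`, `reference` covering every clustered sequence.
#' @return list with `vcs` (data.frame `vc_id`, `n_members`,
#'   `contains_reference`, `has_large_or_complete`, `status`) and `counts`
#'   (`n_putative_genera`, `n_new`).
#' @export
classify_vcs <- function(membership, metadata) {
  miss <- setdiff(names(membership), metadata$sequence_id)
  if (length(miss))
    stop("metadata missing for sequence ", miss[1])
  md <- metadata[match(names(membership), metadata$sequence_id), ]
  vcs <- lapply(split(seq_along(membership), as.character(membership)),
                function(idx) {
    ref <- any(as.logical(md$reference[idx]))
    large <- any(as.logical(md$circular[idx]) |
                   as.logical(md$complete[idx]) | md$length_bp[idx] > 30000)
    data.frame(n_members = length(idx), contains_reference = ref,
               has_large_or_complete = large,
               status = if (!large) "fragment_only" else
                 if (ref) "putative_genus_known" else "putative_genus_new",
               stringsAsFactors = FALSE)
  })
  vcs <- cbind(vc_id = names(vcs), do.call(rbind, vcs))
  rownames(vcs) <- NULL
  list(vcs = vcs,
       counts = c(n_putative_genera = sum(vcs$status != "fragment_only"),
                  n_new = sum(vcs$status == "putative_genus_new")))
}
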