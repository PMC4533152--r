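# Worlds are expensive to generate; cache them per test session.
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(name, config) {
  if (!exists(name, envir = .world_cache))
    assign(name, generate_world(config), envir = .world_cache)
  get(name, envir = .world_cache)
}

default_world <- function() cached_world("default", sim_config(seed = 101))

adapted_world <- function() {
  cached_world("adapted", sim_config(alpha_host_mixing = 0.95, seed = 102))
}

tiny_world <- function() {
  cached_world("tiny", sim_config(n_genera = 4, hosts_per_genus = 2,
                                  viruses_per_host = 2,
                                  genome_length_bp = 40000,
                                  viral_length_range_bp = c(4000, 20000),
                                  seed = 103))
}

# clustering results on the default world, cached alongside it
default_clustering <- function() {
  if (!exists("default_cl", envir = .world_cache)) {
    w <- default_world()
    g <- build_rbh_graph(w$similarity)
    pcs <- mcl(g, inflation = 2)
    p2g <- stats::setNames(w$viral_genes$parent_id,
                           w$viral_genes$protein_id)
    prof <- genome_profiles(pcs, p2g)
    net <- build_genome_network(prof, sig_threshold = 1)
    cl <- cluster_genomes(net, inflation = 4)
    assign("default_cl",
           list(pcs = pcs, profiles = prof, network = net, clusters = cl),
           envir = .world_cache)
  }
  get("default_cl", envir = .world_cache)
}

# all partitions of the set 1..n (Bell(5) = 52), for exhaustive modularity
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    p[[length(p) + 1L]] <- n
    out[[length(out) + 1L]] <- p
  }
  out
}

# exhaustive optimum of Barber's Q: enumerate row partitions; given row
# modules, each column independently takes its best module (or none)
exhaustive_bipartite_q <- function(A) {
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  best <- -Inf
  for (p in set_partitions(nrow(A))) {
    tot <- 0
    for (j in seq_len(ncol(A))) {
      contrib <- vapply(p, function(rows) sum(B[rows, j]), numeric(1))
      tot <- tot + max(0, max(contrib))
    }
    best <- max(best, tot / m)
  }
  best
}
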