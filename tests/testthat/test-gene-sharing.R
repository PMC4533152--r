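hit_row <- function(q, s, score, evalue = 1e-30) {
  data.frame(qseqid = q, sseqid = s, bitscore = score, evalue = evalue,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits need mutual best scores above thresholds", {
  h <- rbind(hit_row("p", "q", 200), hit_row("q", "p", 200))
  g <- build_rbh_graph(h)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 200)

  # p's best is q but q's best is r: no p-q edge
  h2 <- rbind(hit_row("p", "q", 150), hit_row("q", "p", 150),
              hit_row("q", "r", 180), hit_row("r", "q", 180))
  g2 <- build_rbh_graph(h2)
  el <- igraph::as_data_frame(g2)
  expect_equal(nrow(el), 1)
  expect_setequal(unlist(el[, c("from", "to")]), c("q", "r"))

  # sub-threshold scores are excluded before best-hit selection
  h3 <- rbind(hit_row("p", "q", 40), hit_row("q", "p", 40))
  expect_equal(igraph::ecount(build_rbh_graph(h3)), 0)
  h4 <- rbind(hit_row("p", "q", 200, evalue = 0.1),
              hit_row("q", "p", 200, evalue = 0.1))
  expect_equal(igraph::ecount(build_rbh_graph(h4)), 0)
  expect_equal(igraph::vcount(build_rbh_graph(h3[0, ])), 0)
})

test_that("MCL recovers hand-checked cluster structures", {
  # single isolated node
  g1 <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(1, name = "a")
  expect_equal(unname(mcl(g1, 2)), 1L)

  # two triangles joined by one weak edge split at inflation 2
  el <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
              c("d", "e"), c("e", "f"), c("d", "f"), c("c", "d"))
  w <- c(1, 1, 1, 1, 1, 1, 0.1)
  g2 <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g2)$weight <- w
  cl <- mcl(g2, 2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[c("a", "b", "c")])), 1)
  expect_equal(length(unique(cl[c("d", "e", "f")])), 1)

  # complete graph stays one cluster
  g3 <- igraph::make_full_graph(4)
  igraph::V(g3)$name <- letters[1:4]
  expect_equal(length(unique(mcl(g3, 3))), 1)

  g_neg <- igraph::graph_from_edgelist(rbind(c("a", "b")), directed = FALSE)
  igraph::E(g_neg)$weight <- -1
  expect_error(mcl(g_neg, 2), "positive")
  expect_error(mcl(g3, 1), "inflation > 1")
})

test_that("hypergeometric significance matches enumeration and is monotone", {
  ps <- pair_significance(4, 3, 2, 10, n_pairs = 1)
  expect_equal(ps$p, 40 / 120, tolerance = 1e-12)
  expect_equal(ps$s, -log10(1 / 3), tolerance = 1e-6)
  expect_equal(pair_significance(4, 3, 0, 10)$p, 1)
  expect_equal(pair_significance(4, 3, 0, 10)$s, 0)
  expect_error(pair_significance(12, 3, 1, 10), "universe")

  # P decreases as c grows, others fixed
  p_seq <- vapply(0:5, function(cc) pair_significance(6, 5, cc, 20)$p,
                  numeric(1))
  expect_true(all(diff(p_seq) < 0))

  # correction: S is clipped at zero
  expect_equal(pair_significance(4, 3, 1, 10, n_pairs = 100)$s, 0)
})

test_that("genome network edges obey the significance threshold", {
  prof <- list(profiles = list(A = c("p1", "p2", "p3", "p4"),
                               B = c("p1", "p2", "p3", "p4", "p5"),
                               C = c("p8", "p9")),
               n_pcs = 12)
  # A-B: P = C(8,1)/C(12,5) = 8/792, S = -log10(3P) ~ 1.52 >= 1
  net1 <- build_genome_network(prof, sig_threshold = 1)
  el <- igraph::as_data_frame(net1)
  # only A-B share content; C shares nothing
  expect_equal(nrow(el), 1)
  expect_setequal(unlist(el[, c("from", "to")]), c("A", "B"))
  # a pair whose significance falls below the threshold draws no edge
  s_ab <- pairwise_significance(prof)
  s_ab <- s_ab$s[s_ab$g1 == "A" & s_ab$g2 == "B"]
  expect_equal(igraph::ecount(build_genome_network(prof, s_ab + 0.1)), 0)
  # raising the threshold never adds edges
  for (th in c(2, 5, 20))
    expect_lte(igraph::ecount(build_genome_network(prof, th)),
               igraph::ecount(net1))
  expect_error(build_genome_network(list(profiles = list(A = "p1"),
                                         n_pcs = 1), 1), "at least two")
})

test_that("ICCC measures cluster homogeneity", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                   directed = FALSE)
  all_one <- stats::setNames(c(1, 1, 1), c("a", "b", "c"))
  expect_equal(iccc(g, all_one), 1.0)
  split2 <- stats::setNames(c(1, 1, 2), c("a", "b", "c"))
  # a: 1/1, b: 1/2, c: 0/1 -> mean 0.5
  expect_equal(iccc(g, split2), 0.5)
  singletons <- stats::setNames(1:3, c("a", "b", "c"))
  expect_equal(iccc(g, singletons), 0.0)
  g0 <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(2, name = c("x", "y"))
  expect_error(iccc(g0, stats::setNames(1:2, c("x", "y"))), "degree 0")
})

test_that("parameter sweep reports the full grid with deterministic ties", {
  prof <- default_clustering()$profiles
  sw <- sweep_parameters(prof, inflations = 2, thresholds = 1)
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$best$threshold, 1)

  sw2 <- sweep_parameters(prof, inflations = c(2, 4),
                          thresholds = c(1, 5, 10))
  expect_equal(nrow(sw2$grid), 6)
  # VC count is non-decreasing in inflation at fixed threshold
  for (th in c(1, 5, 10)) {
    sub <- sw2$grid[sw2$grid$threshold == th, ]
    sub <- sub[order(sub$inflation), ]
    expect_true(all(diff(sub$n_clusters) >= 0))
  }
  expect_error(sweep_parameters(prof, inflations = numeric(0)), "empty")
})

test_that("VC status distinguishes new genera from fragments", {
  membership <- stats::setNames(c(1, 1, 2, 2, 3, 3, 3), paste0("s", 1:7))
  md <- data.frame(
    sequence_id = paste0("s", 1:7),
    circular = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    complete = FALSE,
    length_bp = c(8000, 12000, 45000, 20000, 15000, 15000, 15000),
    reference = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  out <- classify_vcs(membership, md)
  st <- stats::setNames(out$vcs$status, out$vcs$vc_id)
  expect_identical(unname(st[c("1", "2", "3")]),
                   c("putative_genus_new", "putative_genus_known",
                     "fragment_only"))
  expect_equal(unname(out$counts), c(2, 1))
  expect_error(classify_vcs(membership, md[-1, ]), "s1")
})

test_that("clustering recovers true families and genera on a known world", {
  w <- default_world()
  res <- default_clustering()
  expect_gte(adjusted_rand_index(res$pcs, w$truth$protein2family), 0.9)
  expect_gte(adjusted_rand_index(res$clusters$membership,
                                 w$truth$virus2cluster), 0.9)
  total <- length(res$clusters$membership) +
    length(res$clusters$unclustered)
  expect_lte(length(res$clusters$unclustered) / total, 0.05)
  # cross-check the ARI implementation against an independent one
  if (requireNamespace("mclust", quietly = TRUE)) {
    common <- intersect(names(res$pcs), names(w$truth$protein2family))
    expect_equal(
      adjusted_rand_index(res$pcs, w$truth$protein2family),
      mclust::adjustedRandIndex(res$pcs[common],
                                w$truth$protein2family[common]),
      tolerance = 1e-12)
  }
})
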