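test_that("k-mer frequencies skip invalid windows and normalise", {
  f1 <- kmer_frequencies("AAAA", 1)
  expect_equal(unname(f1["A"]), 1)
  expect_equal(sum(f1), 1)

  f2 <- kmer_frequencies("ACGT", 2)
  expect_equal(unname(f2[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(f2), 1)

  expect_error(kmer_frequencies("ANG", 2), "no valid")
  expect_error(kmer_frequencies("AC", 4), "shorter")

  fc <- kmer_frequencies("ACGTACGA", 2, canonical = TRUE)
  expect_equal(sum(fc), 1)
  expect_false("GT" %in% names(fc))  # collapsed onto AC
})

test_that("MAE distance matches hand arithmetic and metric properties", {
  v <- c(0.5, 0.5, 0, 0)
  u <- rep(0.25, 4)
  expect_equal(mae_distance(v, u), 0.25)
  expect_equal(mae_distance(v, v), 0)
  expect_equal(mae_distance(v, u), mae_distance(u, v))
  expect_error(mae_distance(v, rep(0.25, 16)), "different k")
  set.seed(2)
  for (i in 1:25) {
    x <- stats::runif(16); y <- stats::runif(16); z <- stats::runif(16)
    expect_lte(mae_distance(x, z), mae_distance(x, y) + mae_distance(y, z))
  }
})

test_that("codon usage tables and CAI match hand computations", {
  tab <- codon_usage_table("AAAAAG")
  expect_equal(unname(tab$freq[c("AAA", "AAG")]), c(0.5, 0.5))
  expect_equal(unname(tab$w[c("AAA", "AAG")]), c(1, 1))
  expect_equal(unname(tab$w["ATG"]), 1)  # single-codon family

  # usage 0.8 / 0.2 -> w(AAG) = 0.25
  tab2 <- codon_usage_table(paste0(strrep("AAA", 4), "AAG"))
  expect_equal(unname(tab2$w["AAG"]), 0.25)
  expect_error(codon_usage_table(c(ok = "AAAAAG", bad = "AAAA")), "bad")

  # CAI: geometric mean sqrt(1 * 0.25) = 0.5
  expect_equal(cai("AAAAAG", tab2), 0.5, tolerance = 1e-12)
  # gene of only most frequent codons scores 1
  expect_equal(cai("AAAAAA", tab2), 1.0)
  # appending a w = 1 codon never decreases CAI
  expect_gte(cai("AAAAAGAAA", tab2), cai("AAAAAG", tab2))
  # gene of only excluded codons (Met, Trp, stop) errors
  expect_error(cai("ATGTGGTAA", tab2), "only stop")
  expect_error(cai("AAAA", tab2), "divisible")
})

test_that("K-S statistic equals the brute-force ECDF sup difference", {
  expect_equal(ks_statistic(c(1, 2), c(3, 4)), 1.0)
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(ks_statistic(numeric(0), 1), "empty")

  brute_ks <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
  }
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:40, 1))
    y <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1))
    expect_equal(ks_statistic(x, y), brute_ks(x, y), tolerance = 1e-12)
  }
})

test_that("a genome's own genes are better adapted than shuffled ones", {
  w <- tiny_world()
  gid <- w$hosts$genome_id[1]
  genes <- w$host_genes$cds[w$host_genes$parent_id == gid][1:10]
  tab <- codon_usage_table(w$host_genes$cds[w$host_genes$parent_id == gid])
  own <- sequence_cai(genes, tab)
  set.seed(7)
  shuffled <- vapply(genes, function(g) {
    paste0(sample(strsplit(g, "")[[1]]), collapse = "")
  }, character(1))
  expect_gte(own, sequence_cai(shuffled, tab))
})

test_that("adaptation distances order by taxonomic distance from the host", {
  w <- default_world()
  ad <- adaptation_experiment(w, metrics = c("k2", "k4", "cai"), seed = 5)
  r <- ad$report
  for (m in unique(r$metric)) {
    d <- stats::setNames(r$d[r$metric == m], r$category[r$metric == m])
    expect_gte(d[["different_order"]], d[["same_family"]])
    expect_gte(d[["same_family"]], d[["same_genus"]])
  }
  # distances to the true host are stochastically smaller than to
  # different-order genomes (one-sided Mann-Whitney)
  k4 <- ad$distances[ad$distances$metric == "k4", ]
  mw <- stats::wilcox.test(k4$distance[k4$category == "host"],
                           k4$distance[k4$category == "different_order"],
                           alternative = "less")
  expect_lt(mw$p.value, 1e-6)

  # determinism
  ad2 <- adaptation_experiment(w, metrics = "k4", seed = 5)
  ad3 <- adaptation_experiment(w, metrics = "k4", seed = 5)
  expect_identical(ad2$report, ad3$report)
})

test_that("an unadapted world shows no detectable host signal", {
  w0 <- cached_world("alpha0",
                     sim_config(n_genera = 4, hosts_per_genus = 4,
                                viruses_per_host = 2,
                                genome_length_bp = 50000,
                                alpha_host_mixing = 0, seed = 17))
  ad <- adaptation_experiment(w0, metrics = "k4", seed = 2)
  d <- ad$report$d[ad$report$category == "different_order"]
  n1 <- sum(ad$distances$category == "host" & ad$distances$metric == "k4")
  n2 <- sum(ad$distances$category == "different_order" &
              ad$distances$metric == "k4")
  crit <- 1.358 * sqrt((n1 + n2) / (n1 * n2))  # K-S critical value, p = 0.05
  expect_lt(d, crit)
})

test_that("subsampling keeps host separation at small fragment sizes", {
  w <- default_world()
  sub <- subsample_experiment(w, sizes = c(5000, 10000), n = 40, ks = 1:2,
                              seed = 9)
  for (k in 1:2) {
    at5 <- sub[sub$k == k & sub$size == 5000, ]
    expect_lt(at5$mean_host, at5$mean_nonhost)
  }
  sub2 <- subsample_experiment(w, sizes = c(5000, 10000), n = 40, ks = 1:2,
                               seed = 9)
  expect_identical(sub, sub2)

  # a fragment of the full genome length reproduces the whole-genome distance
  v <- w$viruses[1, ]
  lib <- lapply(host_composition_library(w, ks = 4), `[[`, 4)
  d_full <- mae_distance(kmer_frequencies(v$sequence, 4),
                         lib[[v$genome_id]])
  start <- 1
  frag <- substr(v$sequence, start, start + v$length_bp - 1)
  expect_equal(mae_distance(kmer_frequencies(frag, 4), lib[[v$genome_id]]),
               d_full)
})
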