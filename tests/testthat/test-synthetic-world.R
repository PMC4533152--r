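test_that("world generation is deterministic and validates its config", {
  cfg <- sim_config(n_genera = 2, hosts_per_genus = 2, viruses_per_host = 1,
                    genome_length_bp = 20000,
                    viral_length_range_bp = c(4000, 15000), seed = 9)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$hosts$sequence, w2$hosts$sequence)
  expect_identical(w1$viruses, w2$viruses)
  expect_identical(w1$similarity, w2$similarity)
  expect_identical(w1$predictions, w2$predictions)

  expect_error(sim_config(viral_length_range_bp = c(500, 5000)),
               "at least 1 kb")
  expect_error(sim_config(genome_length_bp = 10000,
                          viral_length_range_bp = c(4000, 50000)),
               "exceeds")
  expect_error(sim_config(alpha_host_mixing = 1.2), "\\[0,1\\]")
})

test_that("a world without viruses has hosts only and empty truth", {
  w <- generate_world(sim_config(n_genera = 2, hosts_per_genus = 2,
                                 viruses_per_host = 0,
                                 genome_length_bp = 20000,
                                 viral_length_range_bp = c(4000, 15000),
                                 seed = 4))
  expect_equal(nrow(w$hosts), 4)
  expect_equal(nrow(w$viruses), 0)
  expect_length(w$truth$virus2host, 0)
  expect_equal(nrow(w$predictions), 0)
})

test_that("world invariants hold: coordinates, truth mappings, symmetry", {
  w <- tiny_world()
  # every virus maps to exactly one existing host
  expect_true(all(w$truth$virus2host %in% w$hosts$genome_id))
  expect_false(any(duplicated(names(w$truth$virus2host))))
  # prophage coordinates lie within the host contig
  pro <- w$viruses[w$viruses$prophage, ]
  hlen <- stats::setNames(w$hosts$length_bp, w$hosts$genome_id)
  expect_true(all(pro$prophage_start >= 1))
  expect_true(all(pro$prophage_end <= hlen[pro$genome_id]))
  # the inserted region is the viral sequence itself
  for (i in seq_len(min(3, nrow(pro)))) {
    hseq <- w$hosts$sequence[w$hosts$genome_id == pro$genome_id[i]]
    expect_identical(substr(hseq, pro$prophage_start[i], pro$prophage_end[i]),
                     pro$sequence[i])
  }
  # gene coordinates lie within their sequence
  vlen <- stats::setNames(w$viruses$length_bp, w$viruses$sequence_id)
  expect_true(all(w$viral_genes$end <= vlen[w$viral_genes$parent_id]))
  expect_true(all(w$viral_genes$start >= 1))
  # similarity table is symmetric pair-wise
  key <- paste(w$similarity$qseqid, w$similarity$sseqid)
  rkey <- paste(w$similarity$sseqid, w$similarity$qseqid)
  expect_true(all(rkey %in% key))
  # k-mer frequencies of emitted sequences sum to 1
  for (k in 1:4)
    expect_equal(sum(kmer_frequencies(w$viruses$sequence[1], k)), 1,
                 tolerance = 1e-9)
})

test_that("viral composition tracks the host at alpha = 0.9", {
  w <- cached_world("mix09",
                    sim_config(n_genera = 4, hosts_per_genus = 5,
                               viruses_per_host = 1, seed = 31))
  lib <- lapply(host_composition_library(w, ks = 4), `[[`, 4)
  hit <- vapply(seq_len(nrow(w$viruses)), function(i) {
    v <- kmer_frequencies(w$viruses$sequence[i], 4)
    hid <- w$viruses$genome_id[i]
    h <- w$hosts[w$hosts$genome_id == hid, ]
    d_host <- mae_distance(v, lib[[hid]])
    others <- w$hosts$genome_id[w$hosts$order != h$order]
    d_host < stats::median(vapply(others, function(g)
      mae_distance(v, lib[[g]]), numeric(1)))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("fragmentation preserves provenance and honours breakpoints", {
  w <- tiny_world()
  expect_error(fragment_genomes(w, 500), "1 kb")

  # target = genome length: single unchanged contig per genome
  whole <- fragment_genomes(w, max(w$hosts$length_bp))
  expect_equal(nrow(whole), nrow(w$hosts))
  expect_equal(whole$length_bp, w$hosts$length_bp[
    match(whole$genome_id, w$hosts$genome_id)])

  # breakpoints exactly flanking a prophage isolate it: a fully viral contig
  pro <- w$viruses[w$viruses$prophage, ][1, ]
  bp <- list(c(pro$prophage_start - 1L, pro$prophage_end))
  names(bp) <- pro$genome_id
  frag <- fragment_genomes(w, 10000, breakpoints = bp)
  target <- frag[frag$genome_id == pro$genome_id &
                   frag$start == pro$prophage_start, ]
  expect_equal(target$length_bp, pro$length_bp)
  expect_equal(target$n_host_genes, 0)
  expect_identical(target$provenance, "prophage")

  # determinism of the misclassification fraction across runs
  r1 <- vapply(1:10, function(s)
    prophage_misclassification_rate(fragment_genomes(w, 15000, seed = s),
                                    30000), numeric(1))
  r2 <- vapply(1:10, function(s)
    prophage_misclassification_rate(fragment_genomes(w, 15000, seed = s),
                                    30000), numeric(1))
  expect_identical(r1, r2)
})
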