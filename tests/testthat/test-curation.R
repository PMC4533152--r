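make_pred <- function(sequence_id = "S1", category = 1,
                      detection_tag = "hallmark", circular = 0,
                      length_bp = 20000, prophage = 0, hallmark_count = 1,
                      label = "", has_microbial_genes = prophage > 0) {
  data.frame(sequence_id = sequence_id, genome_id = "G1",
             category = category, detection_tag = detection_tag,
             circular = circular, length_bp = length_bp,
             prophage = prophage, hallmark_count = hallmark_count,
             terL_count = 0, parA = 0, parB = 0, label = label,
             has_microbial_genes = has_microbial_genes,
             stringsAsFactors = FALSE)
}

test_that("curation rules fire in order with one logged rule per drop", {
  preds <- rbind(
    make_pred("circ_small", circular = 1, length_bp = 2500),
    make_pred("nc_ok", category = 2, detection_tag = "noncaudo",
              length_bp = 6000),
    make_pred("nc_small", detection_tag = "noncaudo", length_bp = 4500),
    make_pred("lin_small", length_bp = 9000),
    make_pred("phix_also_cat3", category = 3,
              label = "Enterobacteria phage PhiX174"),
    make_pred("pro_nohm", prophage = 1, hallmark_count = 0,
              has_microbial_genes = TRUE),
    make_pred("ok_big", length_bp = 35000))
  res <- apply_curation_filters(preds)
  expect_setequal(res$retained$sequence_id, c("nc_ok", "ok_big"))
  rules <- stats::setNames(res$rejected$rule, res$rejected$sequence_id)
  expect_identical(rules[["circ_small"]], "circular_lt_3kb")
  expect_identical(rules[["nc_small"]], "noncaudo_linear_lt_5kb")
  expect_identical(rules[["lin_small"]], "linear_lt_10kb")
  # PhiX removal precedes the category-3 rule
  expect_identical(rules[["phix_also_cat3"]], "phix_control")
  expect_identical(rules[["pro_nohm"]], "prophage_no_hallmark")
  # every dropped row appears exactly once in the log
  expect_equal(nrow(res$rejected) + nrow(res$retained), nrow(preds))
  expect_false(any(duplicated(res$rejected$sequence_id)))

  # idempotence
  again <- apply_curation_filters(res$retained)
  expect_equal(nrow(again$rejected), 0)
  expect_setequal(again$retained$sequence_id, res$retained$sequence_id)

  # exclusion list and unknown tag
  res2 <- apply_curation_filters(preds, exclusions = "ok_big")
  expect_false("ok_big" %in% res2$retained$sequence_id)
  expect_identical(
    res2$rejected$rule[res2$rejected$sequence_id == "ok_big"],
    "manual_exclusion")
  bad <- make_pred("x", detection_tag = "mystery")
  expect_error(apply_curation_filters(bad), "mystery")
})

test_that("replication mode follows the prophage / circular / 30 kb rules", {
  rows <- rbind(
    make_pred("pro", prophage = 1, length_bp = 45000,
              has_microbial_genes = TRUE),
    make_pred("circ", circular = 1, length_bp = 8000),
    make_pred("short_lin", length_bp = 12000),
    make_pred("long_lin", length_bp = 42000))
  out <- classify_replication_mode(rows)
  modes <- stats::setNames(out$replication_mode, out$sequence_id)
  expect_identical(unname(modes[c("pro", "circ", "short_lin", "long_lin")]),
                   c("integrated", "extrachromosomal", "undetermined",
                     "extrachromosomal"))
  bad <- make_pred("inc", prophage = 1, has_microbial_genes = FALSE)
  expect_error(classify_replication_mode(bad), "inconsistent")
})

test_that("marker enrichment test is exact, monotone and bounded", {
  # P(X >= 2), X ~ Binom(2, 1/2), by enumeration = 1/4
  expect_equal(marker_enrichment_test(2, 2, 0, 2), 0.25)
  expect_equal(marker_enrichment_test(0, 50, 0, 10), 1.0)
  expect_equal(marker_enrichment_test(0, 5, 3, 10), 1.0)

  # brute-force binomial tail oracle
  tail_sum <- function(k1, n1, k2, n2) {
    tot <- k1 + k2; pr <- n1 / (n1 + n2)
    sum(choose(tot, k1:tot) * pr^(k1:tot) * (1 - pr)^(tot - (k1:tot)))
  }
  expect_equal(marker_enrichment_test(13, 100, 10, 1000),
               tail_sum(13, 100, 10, 1000), tolerance = 1e-12)
  expect_equal(marker_enrichment_test(5, 40, 7, 60),
               tail_sum(5, 40, 7, 60), tolerance = 1e-12)

  p <- vapply(0:15, function(k) marker_enrichment_test(k, 100, 15 - k, 1000),
              numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("genome status uses the more-than-5-sequences draft rule", {
  expect_identical(classify_genome_status(c(1, 5, 6, 12)),
                   c("complete", "complete", "draft", "draft"))
  expect_error(classify_genome_status(0))
})

test_that("the packaged 25-row fixture yields exactly 10 retained rows", {
  path <- system.file("extdata", "curation_fixture.tsv",
                      package = "provirome")
  preds <- read_predictions(path)
  expect_equal(nrow(preds), 25)
  res <- apply_curation_filters(preds)
  expect_equal(nrow(res$retained), 10)
  expect_equal(nrow(res$rejected), 15)
  expected_rule <- c(PHIX = "phix_control", CAT3 = "category_3",
                     PRO = "prophage_no_hallmark", LIN = "linear_lt_10kb",
                     NC5 = "noncaudo_linear_lt_5kb",
                     CIRC = "circular_lt_3kb")
  kind <- sub("^DECOY_([A-Z0-9]+)_.*$", "\\1", res$rejected$sequence_id)
  expect_identical(res$rejected$rule, unname(expected_rule[kind]))
})
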