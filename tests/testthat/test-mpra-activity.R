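test_that("directional clustering applies the count inequality at Hamming distance 1", {
  res <- cluster_barcodes(c(ACGT = 100L, ACGA = 10L))
  expect_equal(unname(res$map["ACGA"]), "ACGT") # 100 >= 2*10 - 1
  expect_equal(unname(res$counts["ACGT"]), 110L)

  res <- cluster_barcodes(c(ACGT = 100L, ACGA = 60L))
  expect_equal(unname(res$map["ACGA"]), "ACGA") # 100 < 119: kept separate

  res <- cluster_barcodes(c(ACGT = 100L, ACAA = 10L)) # Hamming distance 2
  expect_equal(unname(res$map["ACAA"]), "ACAA")

  expect_error(cluster_barcodes(c(ACGT = 5L, ACGTA = 2L)), "length")
})

test_that("clustering is order-independent and matches the brute-force oracle", {
  set.seed(17)
  for (rep in 1:100) {
    counts <- random_barcode_counts(sample(2:8, 1))
    res <- cluster_barcodes(counts)
    perm <- sample(length(counts))
    res_perm <- cluster_barcodes(counts[perm])
    expect_equal(res$map[names(counts)], res_perm$map[names(counts)])
    expect_identical(unname(res$map[names(counts)]),
                     unname(cluster_oracle(counts)[names(counts)]))
    # counts are conserved
    expect_equal(sum(res$counts), sum(counts))
  }
})

test_that("barcodes-per-million normalization scales columns to one million", {
  expect_equal(normalize_bpm(c(1, 3)), c(250000, 750000))
  expect_equal(normalize_bpm(rep(7, 10)), rep(1e5, 10))
  m <- matrix(c(1, 3, 2, 2), 2, 2)
  expect_equal(colSums(normalize_bpm(m)), c(1e6, 1e6))
  expect_equal(normalize_bpm(c(2, 6) * 17), normalize_bpm(c(2, 6)))
  expect_error(normalize_bpm(c(0, 0)), "zero")
})

test_that("log-ratio computation drops incomplete barcodes and uses BPM columns", {
  rec <- data.frame(
    barcode = c("AAAA", "CCCC", "GGGG"),
    sequence_id = "s1",
    plasmid = c(100L, 0L, 100L),
    cdna_1 = c(200L, 50L, 100L),
    cdna_2 = c(200L, 50L, 0L))
  lr <- barcode_log_ratios(rec)
  # zero plasmid and a zero cDNA replicate are dropped before ratios
  expect_equal(lr$barcode, "AAAA")
  expect_equal(attr(lr, "n_dropped"), 2L)
  # expected value from explicit BPM arithmetic
  exp_rep1 <- log2((200 / 350 * 1e6) / (100 / 200 * 1e6))
  expect_equal(lr$log2_rep1, exp_rep1)
  expect_equal(lr$pooled, mean(c(lr$log2_rep1, lr$log2_rep2)))

  # equal cDNA and plasmid composition gives ratio 0 for all barcodes
  rec2 <- data.frame(barcode = c("AAAA", "CCCC"), sequence_id = "s1",
                     plasmid = c(100L, 300L), cdna_1 = c(200L, 600L))
  expect_equal(barcode_log_ratios(rec2)$log2_rep1, c(0, 0))
})

ratio_frame <- function(values, ids) {
  data.frame(barcode = sprintf("bc%03d", seq_along(values)),
             sequence_id = ids, pooled = values, stringsAsFactors = FALSE)
}

test_that("activity calls separate shifted sequences from a null reference", {
  set.seed(41)
  ref_vals <- rnorm(200, 0, 0.3)
  ratios <- rbind(
    ratio_frame(c(2.1, 1.9, 2.3, 2.0, 2.2), "hot"),
    ratio_frame(ref_vals, rep(sprintf("ref%02d", 1:40), each = 5)))
  calls <- call_activity(ratios)
  expect_equal(calls$status[calls$sequence_id == "hot"], "active")
  # null sequences stay mostly inactive at 5% FDR
  expect_lt(mean(calls$status[calls$sequence_id != "hot"] == "active"), 0.1)
  # fewer than the minimum barcode count is untestable, not inactive
  ratios2 <- rbind(ratio_frame(c(5, 5), "tiny"), ratio_frame(ref_vals, "ref"))
  calls2 <- call_activity(ratios2)
  expect_equal(calls2$status[calls2$sequence_id == "tiny"], "untestable")
})

test_that("rank-sum p-values agree with an exact enumeration oracle on small sets", {
  set.seed(12)
  x <- rnorm(6, 1)
  y <- rnorm(8, 0)
  p_impl <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                         correct = TRUE)$p.value)
  p_oracle <- ranksum_exact_oracle(x, y)
  expect_equal(p_impl, p_oracle, tolerance = 0.05)
})

test_that("element activity is the any-probe-active rule", {
  calls <- data.frame(sequence_id = c("p1", "p2", "p3", "p4"),
                      status = c("active", "inactive", "inactive", "untestable"))
  seq_map <- data.frame(element_id = c("E1", "E1", "E2", "E3"),
                        sequence_id = c("p1", "p2", "p3", "p4"))
  ea <- element_activity(seq_map, calls)
  expect_equal(ea$status[ea$element_id == "E1"], "active")
  expect_equal(ea$status[ea$element_id == "E2"], "inactive")
  expect_equal(ea$status[ea$element_id == "E3"], "untested")
})

test_that("variant effects require both an activity gate and a significant shift", {
  set.seed(8)
  mk <- function(id, mu) ratio_frame(rnorm(10, mu, 0.1), id)
  ratios <- rbind(mk("act_w", 2.5), mk("act_o", 1.0),
                  mk("flat_w", 2.0), mk("flat_o", 2.0),
                  mk("dead_w", -1.5), mk("dead_o", 0),
                  ratio_frame(rnorm(300, 0, 0.3), rep(sprintf("r%02d", 1:60), each = 5)))
  calls <- call_activity(ratios)
  pairs <- data.frame(variant_id = c("v_mod", "v_flat", "v_dead"),
                      seq_with = c("act_w", "flat_w", "dead_w"),
                      seq_without = c("act_o", "flat_o", "dead_o"))
  ve <- variant_effect(pairs, ratios, calls)
  expect_equal(ve$call[ve$variant_id == "v_mod"], "modulating")
  expect_equal(ve$direction[ve$variant_id == "v_mod"], "increase")
  # identical distributions: active but no shift
  expect_equal(ve$call[ve$variant_id == "v_flat"], "not_modulating")
  # neither sequence active: never modulating regardless of the difference
  expect_equal(ve$call[ve$variant_id == "v_dead"], "not_modulating")

  ve2 <- variant_effect(data.frame(variant_id = "vx", seq_with = "act_w",
                                   seq_without = "absent"), ratios, calls)
  expect_equal(ve2$call, "untestable")
})

test_that("mutagenesis classification excludes flank-only records and calls direction", {
  set.seed(15)
  assoc <- data.frame(
    barcode = sprintf("b%02d", 1:12),
    probe_id = "probe1",
    variant_ids = c(rep("vUp", 4), rep("vFlank", 4), rep("vUp,vOther", 4)),
    flank_only = c(rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 4)))
  mutant <- data.frame(barcode = sprintf("b%02d", 1:12),
                       pooled = c(rnorm(4, 2, 0.1), rnorm(4, 0, 0.1),
                                  rnorm(4, 2, 0.1)))
  wt <- data.frame(probe_id = "probe1", pooled = rnorm(12, 0, 0.1))
  res <- mutagenesis_classify(assoc, mutant, wt)
  expect_false("vFlank" %in% res$variant_id)
  expect_equal(res$call[res$variant_id == "vUp"], "increase")
  # single-variant restriction drops the multi-variant barcodes
  res1 <- mutagenesis_classify(assoc, mutant, wt, single_variant_only = TRUE)
  expect_equal(res1$n_barcodes[res1$variant_id == "vUp"], 4L)
  expect_false("vOther" %in% res1$variant_id)
})
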