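test_that("overlap merging joins overlapping but not abutting intervals", {
  el <- data.frame(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L),
                   element_id = c("a", "b"), element_class = "HAR")
  m <- merge_overlapping(el)
  expect_equal(m$start, 10L)
  expect_equal(m$end, 30L)
  expect_equal(m$element_id, "a+b")

  # half-open coordinates: [10,20) and [20,30) abut, they do not overlap
  ab <- data.frame(chrom = "chr1", start = c(10L, 20L), end = c(20L, 30L),
                   element_id = c("a", "b"))
  expect_equal(nrow(merge_overlapping(ab)), 2L)

  dis <- data.frame(chrom = "chr1", start = c(100L, 10L), end = c(120L, 30L),
                    element_id = c("b", "a"))
  m <- merge_overlapping(dis)
  expect_equal(m$start, c(10L, 100L)) # returned sorted, otherwise unchanged
  expect_equal(nrow(merge_overlapping(dis[0, ])), 0L)
})

test_that("merging is idempotent and preserves base coverage (bitmap oracle)", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    start <- sample.int(9000L, n)
    el <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = start, end = start + sample.int(800L, n),
                     element_id = sprintf("e%d", seq_len(n)))
    m <- merge_overlapping(el)
    expect_identical(merge_overlapping(m)[, c("chrom", "start", "end")],
                     m[, c("chrom", "start", "end")])
    for (ch in unique(el$chrom)) {
      expect_identical(coverage_bitmap(m[m$chrom == ch, ]),
                       coverage_bitmap(el[el$chrom == ch, ]))
    }
    # disjointness
    for (ch in unique(m$chrom)) {
      sub <- m[m$chrom == ch, ]
      if (nrow(sub) > 1L) expect_true(all(diff(sub$start) > 0) &&
                                        all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
})

test_that("element subdivision extracts runs and merges across small gaps", {
  ve <- data.frame(chrom = "chr5", start = 1000L, end = 1200L,
                   element_id = "VE1")
  sc <- rep(0, 200)
  sc[11:60] <- 0.9   # run [10,60) in element-local 0-based coords
  sc[101:140] <- 0.8 # run [100,140): gap of 40 bases
  seg <- subdivide_ve(ve, sc)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 1000L + 10L)
  expect_equal(seg$end, 1000L + 140L)

  sc2 <- rep(0, 200)
  sc2[11:60] <- 0.9
  sc2[112:140] <- 0.8 # gap of 51 bases: not merged
  seg2 <- subdivide_ve(ve, sc2)
  expect_equal(nrow(seg2), 2L)

  sc3 <- rep(0, 200)
  sc3[11:60] <- 0.9
  sc3[111:140] <- 0.8 # gap of exactly 50: merged ("50 bp or closer")
  expect_equal(nrow(subdivide_ve(ve, sc3)), 1L)

  expect_equal(nrow(subdivide_ve(ve, rep(0.57, 200))), 0L) # strict threshold
  expect_error(subdivide_ve(ve, rep(1, 10)), "length")
})

test_that("subdivision agrees with a brute-force run-merging oracle", {
  set.seed(21)
  for (rep in 1:30) {
    len <- sample(50:400, 1)
    sc <- stats::runif(len)
    gap <- sample(0:60, 1)
    ve <- data.frame(chrom = "chr1", start = 0L, end = len, element_id = "v")
    seg <- subdivide_ve(ve, sc, threshold = 0.5, merge_gap = gap)
    orc <- runs_oracle(sc, 0.5, gap)
    expect_equal(nrow(seg), nrow(orc))
    if (nrow(seg)) {
      expect_equal(seg$start, orc[, 1] - 1L)
      expect_equal(seg$end, orc[, 2])
      # segments stay within the parent and cover every qualifying base
      expect_true(all(seg$start >= 0 & seg$end <= len))
      qual <- which(sc > 0.5) - 1L
      covered <- unlist(Map(function(s, e) s:(e - 1L), seg$start, seg$end))
      expect_true(all(qual %in% covered))
    }
  }
})

cne_fixture <- function() {
  list(
    conserved = data.frame(
      chrom = "chr1", start = c(100L, 300L, 500L, 700L, 900L),
      end = c(200L, 400L, 600L, 800L, 1000L),
      element_id = sprintf("c%d", 1:5),
      log_odds = c(450, 399.9, 450, 450, 450)),
    states = data.frame(chrom = "chr1", start = c(100L, 300L, 500L, 900L),
                        end = c(250L, 450L, 650L, 1000L),
                        element_id = sprintf("s%d", 1:4),
                        score = c("Enh", "EnhG", "Enh", "Enh"),
                        tissue = c("fetal_brain", "adult_brain",
                                   "neurospheres", "fetal_brain")),
    exons = data.frame(chrom = "chr1", start = 920L, end = 950L,
                       element_id = "x1"))
}

test_that("CNE selection applies all four filters", {
  fx <- cne_fixture()
  # c1: 1 variant base / 100 bp = 1% -> accepted
  vars <- data.frame(chrom = "chr1", pos0 = c(150L, 550L, 551L, 552L))
  res <- define_cne(fx$conserved, fx$states, fx$exons, vars)
  # c1 accepted; c2 fails log-odds (399.9 not > 400); c4 no chromatin state;
  # c5 exonic; c3 has 3% variant bases -> rejected
  expect_equal(res$cne$element_id, "c1")
  expect_equal(res$rejections[["log_odds"]], 1L)
  expect_equal(res$rejections[["exonic"]], 1L)
  expect_equal(res$rejections[["variant_density"]], 1L)
  # boundary: log-odds exactly 400 is not accepted (strict inequality)
  fx$conserved$log_odds[2] <- 400
  res2 <- define_cne(fx$conserved, fx$states, fx$exons, vars)
  expect_false("c2" %in% res2$cne$element_id)
  # 2% exactly is allowed ("no more than 2%")
  vars2 <- data.frame(chrom = "chr1", pos0 = c(550L, 551L))
  res3 <- define_cne(fx$conserved, fx$states, fx$exons, vars2)
  expect_true("c3" %in% res3$cne$element_id)
})

test_that("CNE filters commute: the output is the intersection of single filters", {
  fx <- cne_fixture()
  vars <- data.frame(chrom = "chr1", pos0 = c(150L, 550L, 551L, 552L))
  res <- define_cne(fx$conserved, fx$states, fx$exons, vars)
  no_exon <- fx$exons[0, ]
  no_var <- vars[0, ]
  all_state <- data.frame(chrom = "chr1", start = 0L, end = 2000L,
                          element_id = "all", score = "Enh",
                          tissue = "fetal_brain")
  pass_lod <- define_cne(fx$conserved, all_state, no_exon, no_var)$cne$element_id
  pass_enh <- define_cne(fx$conserved, fx$states, no_exon, no_var,
                         min_log_odds = -Inf)$cne$element_id
  pass_exon <- define_cne(fx$conserved, all_state, fx$exons, no_var,
                          min_log_odds = -Inf)$cne$element_id
  pass_var <- define_cne(fx$conserved, all_state, no_exon, vars,
                         min_log_odds = -Inf)$cne$element_id
  expect_setequal(res$cne$element_id,
                  Reduce(intersect, list(pass_lod, pass_enh, pass_exon, pass_var)))
  expect_true(all(res$cne$element_id %in% fx$conserved$element_id))
})

test_that("gene-model context labels follow exon > intron > intergenic precedence", {
  el <- data.frame(chrom = "chr1", start = c(10L, 200L, 5000L), end = c(50L, 260L, 5100L),
                   element_id = c("inGene", "onExon", "outside"))
  exons <- data.frame(chrom = "chr1", start = 250L, end = 300L, element_id = "ex1")
  genes <- data.frame(chrom = "chr1", start = 0L, end = 1000L, element_id = "g1")
  ctx <- annotate_context(el, exons, genes)
  expect_equal(ctx$context, c("intronic", "genic-overlap", "intergenic"))
})
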