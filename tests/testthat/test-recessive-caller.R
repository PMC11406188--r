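# Build a single-element trio variant set and run the caller.
trio_events <- function(child, father, mother, chrom = "chr1",
                        child_sex = "male") {
  n <- length(child)
  sites <- data.frame(chrom = rep(chrom, n), pos = 1000L + seq_len(n) * 10L,
                      ref = "A", alt = "G", af = 0.001, filter = "PASS",
                      class = "damaging_conserved", stringsAsFactors = FALSE)
  gt <- cbind(C1 = child, FA = father, MO = mother)
  vs <- make_variant_set(sites, gt)
  el <- data.frame(chrom = chrom, start = 1000L, end = 1000L + n * 10L + 1L,
                   element_id = "E1")
  ped <- data.frame(family_id = "F1",
                    individual_id = c("C1", "FA", "MO"),
                    father_id = c("FA", NA, NA), mother_id = c("MO", NA, NA),
                    sex = c(child_sex, "male", "female"),
                    affected = c("case", "unknown", "unknown"),
                    stringsAsFactors = FALSE)
  call_recessive_events(vs, el, ped, af_cutoff = 0.005)
}

GT_CODES <- c("homref", "het", "homalt", "hemi_ref", "hemi_alt", "missing")

test_that("transmission phasing matches the exhaustive single-site oracle", {
  combos <- expand.grid(child = GT_CODES, father = GT_CODES, mother = GT_CODES,
                        stringsAsFactors = FALSE)
  got <- phase_by_transmission(combos$child, combos$father, combos$mother)
  want <- mapply(phase_oracle_single, combos$child, combos$father, combos$mother)
  expect_identical(as.character(got), unname(want))
  # Mendelian impossibility is flagged
  o <- phase_by_transmission("homalt", "homref", "het")
  expect_true(attr(o, "mendelian_violation"))
  expect_equal(as.character(o), "ambiguous")
})

test_that("canonical trio configurations phase as expected", {
  expect_equal(as.character(phase_by_transmission("het", "het", "homref")),
               "paternal")
  expect_equal(as.character(phase_by_transmission("het", "het", "het")),
               "ambiguous")
  expect_equal(as.character(phase_by_transmission("het", "missing", "homref")),
               "ambiguous")
})

test_that("compound-het detection is exhaustive over per-site origin patterns", {
  # every origin vector over {paternal, maternal, ambiguous} for up to 6
  # sites, realised as concrete trio genotypes; together with the
  # exhaustive per-site phasing check this covers all trio configurations
  parent_for <- list(paternal = c("het", "homref"),
                     maternal = c("homref", "het"),
                     ambiguous = c("het", "het"))
  for (n in 2:6) {
    pats <- expand.grid(rep(list(names(parent_for)), n),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pats))) {
      orig <- unlist(pats[i, ])
      father <- vapply(orig, function(o) parent_for[[o]][1], "")
      mother <- vapply(orig, function(o) parent_for[[o]][2], "")
      child <- rep("het", n)
      ev <- trio_events(child, father, mother)
      called <- any(ev$kind == "compound_het")
      expect_identical(called, comphet_oracle(child, father, mother),
                       info = paste(orig, collapse = ","))
      # and the direct predicate: needs one certain paternal + one maternal
      expect_identical(called,
                       any(orig == "paternal") && any(orig == "maternal"))
    }
  }
})

test_that("compound-het calling matches the brute-force oracle on random full trios", {
  set.seed(99)
  diploid <- c("homref", "het", "homalt", "missing")
  for (rep in 1:150) {
    n <- sample(4:6, 1)
    child <- sample(diploid, n, replace = TRUE)
    father <- sample(diploid, n, replace = TRUE)
    mother <- sample(diploid, n, replace = TRUE)
    ev <- trio_events(child, father, mother)
    expect_identical(any(ev$kind == "compound_het"),
                     comphet_oracle(child, father, mother),
                     info = paste(child, father, mother, collapse = "|"))
  }
})

test_that("in-cis pairs and ambiguous phases never produce an event", {
  ev <- trio_events(c("het", "het"), c("het", "het"), c("homref", "homref"))
  expect_false(any(ev$kind == "compound_het"))
  # two logged exclusions: the child's in-cis pair and the father's own
  # unphaseable het pair (founders have no parents to phase against)
  expect_equal(attr(ev, "n_ambiguous_pairs"), 2L)
  # missing parent genotype blocks phasing
  ev <- trio_events(c("het", "het"), c("het", "missing"), c("homref", "het"))
  expect_false(any(ev$kind == "compound_het"))
})

test_that("homozygous and hemizygous events follow the autosome/X conventions", {
  # male hemizygous chrX inside an element
  ev <- trio_events("hemi_alt", "hemi_ref", "het", chrom = "chrX")
  expect_equal(ev$kind, "hemizygous")
  expect_equal(ev$chrom_class, "chrX")
  ped <- data.frame(family_id = "F1", individual_id = c("C1", "FA", "MO"),
                    father_id = c("FA", NA, NA), mother_id = c("MO", NA, NA),
                    sex = c("male", "male", "female"),
                    affected = c("case", "control", "control"),
                    stringsAsFactors = FALSE)
  # excluded from combined-sex (autosomal) analysis, included for males
  tab_both <- carrier_table(ev, ped, "both")
  expect_equal(tab_both[["a"]], 0L)
  tab_male <- carrier_table(ev, ped, "male")
  expect_equal(tab_male[["a"]], 1L)

  # autosomal homozygote counts in the combined analysis
  ev2 <- trio_events("homalt", "het", "het")
  expect_equal(ev2$kind[ev2$individual_id == "C1"], "homozygous")
  expect_equal(carrier_table(ev2, ped, "both")[["a"]], 1L)
})

test_that("carrier tables partition eligible individuals and count carriers once", {
  ped <- rbind(
    make_ped(sprintf("case%02d", 1:10), affected = "case", sex = "female"),
    make_ped(sprintf("ctrl%02d", 1:20), affected = "control", sex = "female"),
    make_ped("nn1", affected = "unknown"))
  ev <- data.frame(
    individual_id = c("case01", "case02", "case02", "ctrl05", "nn1"),
    element_id = c("E1", "E1", "E2", "E1", "E1"),
    kind = "homozygous", chrom_class = "autosome",
    variants = "chr1:1:A>G", origins = "biparental", stringsAsFactors = FALSE)
  tab <- carrier_table(ev, ped, "both")
  expect_equal(as.integer(tab), c(2L, 8L, 1L, 19L)) # case02 counted once
  expect_equal(tab[["a"]] + tab[["b"]], 10L)
  expect_equal(tab[["c"]] + tab[["d"]], 20L)
  expect_equal(attr(tab, "n_unknown_affection"), 1L)
})

test_that("all planted recessive events in a simulated cohort are recovered", {
  cfg <- cohort_sim_config(
    n_families = c(consanguineous = 60, multiplex = 0, simplex = 0),
    seed = 202)
  sim <- simulate_cohort(cfg)
  vs <- classify_variant_set(sim$vcf, sim$scores)
  ev <- call_recessive_events(vs, sim$elements, sim$ped,
                              af_cutoff = cfg$af_cutoff)
  truth <- sim$truth_events[sim$truth_events$site_class == "damaging_conserved", ]
  truth_keys <- paste(truth$individual_id, truth$element_id, truth$kind)
  called_keys <- paste(ev$individual_id, ev$element_id, ev$kind)
  expect_true(all(truth_keys %in% called_keys)) # 100% recall of planted events
})
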