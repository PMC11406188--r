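# Synthetic cohort and MPRA library generators with known ground truth.
# All randomness flows from the single config seed.

#' Cohort simulation configuration
#'
#' Defaults emulate a consanguineous case-control cohort of quad families
#' (two parents, two children): first-cousin-offspring inbreeding
#' (F = 0.0625), rare allele frequencies (beta-distributed, mass below
#' 0.01), three element classes with a mixture of damaging-conserved and
#' neutral sites, a small X-linked element fraction, and a retrospective
#' logistic penetrance on damaging-recessive carrier status calibrated so
#' the expected case:control carrier odds ratio equals
#' `planted_carrier_or`. An additional uniform `consanguinity_inflation`
#' multiplies the probability of affection independently of carrier status
#' strata when emulating endogamy-driven rate inflation at both neutral and
#' damaging sites is required (see [simulate_carrier_cohort()] for the
#' carrier-level analogue used in large replicate studies).
#'
#' @param n_families Named counts per structure
#'   (`consanguineous`, `multiplex`, `simplex`).
#' @param children_per_family Children per family (default 2).
#' @param inbreeding_f Inbreeding coefficient F in \[0, 0.25\] for
#'   consanguineous families.
#' @param n_elements Named counts per element class.
#' @param element_length_range Min/max element length in bp.
#' @param sites_per_element_mean Mean sites per element (Poisson, >= 1).
#' @param af_shape1,af_shape2 Beta parameters of the per-site allele
#'   frequency distribution.
#' @param fraction_conserved Fraction of sites that are damaging at
#'   conserved bases (the rest are neutral).
#' @param planted_carrier_or Target case:control carrier odds ratio at
#'   damaging recessive events (>= 1 at damaging sites; always 1 at
#'   neutral sites).
#' @param baseline_case_prob Affection probability for non-carriers.
#' @param x_linked_fraction Fraction of elements placed on chrX.
#' @param sex_ratio Probability a child is male.
#' @param af_cutoff Rarity cutoff defining qualifying sites for the
#'   penetrance model and truth events.
#' @param dp_mean,gq_value Genotype QC field generators (Poisson depth,
#'   constant GQ).
#' @param qc_fail_rate Fraction of genotypes given failing QC fields
#'   (default 0: clean fields, so planted truth is recoverable).
#' @param seed Mandatory integer seed.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_families = c(consanguineous = 100, multiplex = 0,
                                             simplex = 0),
                              children_per_family = 2L,
                              inbreeding_f = 0.0625,
                              n_elements = c(HAR = 60, VE = 40, CNE = 40),
                              element_length_range = c(150L, 600L),
                              sites_per_element_mean = 6,
                              af_shape1 = 3, af_shape2 = 700,
                              fraction_conserved = 0.4,
                              planted_carrier_or = 1,
                              baseline_case_prob = 1 / 3,
                              x_linked_fraction = 0.05,
                              sex_ratio = 0.5,
                              af_cutoff = 0.005,
                              dp_mean = 40, gq_value = 99L,
                              qc_fail_rate = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inbreeding_f >= 0, inbreeding_f <= 0.25,
            planted_carrier_or >= 0, sex_ratio >= 0, sex_ratio <= 1)
  structure(as.list(environment()), class = "cohort_sim_config")
}

random_chrom <- function(n, x_fraction) {
  ifelse(stats::runif(n) < x_fraction, "chrX",
         paste0("chr", sample(1:22, n, replace = TRUE)))
}

#' Simulate a family cohort with planted recessive ground truth
#'
#' Generates element sets, rare variant sites with per-base annotations,
#' founder haplotypes drawn per site allele frequency, Mendelian
#' transmission to children (haploid X in males), consanguinity modelled by
#' identical-by-descent founder-allele sharing at rate 4F (yielding
#' offspring autozygosity F), affection assigned retrospectively by a
#' logistic penetrance on damaging-recessive carrier status, and QC fields.
#' Children are the study subjects (cases/controls by affection); parents
#' are genotyped for phasing and carry unknown affection status.
#'
#' @param config A [cohort_sim_config()].
#' @param out_dir Optional directory; when given, VCF/PED/BED/score/truth
#'   files are written there.
#' @return List with `vcf` (a `variant_set`), `ped`, `elements`, `scores`,
#'   `truth_events` (planted recessive events with kinds and origins),
#'   `truth_sites`, and, when `out_dir` is given, the file `paths`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  cf <- config

  # --- elements ------------------------------------------------------------
  classes <- rep(names(cf$n_elements), cf$n_elements)
  n_el <- length(classes)
  len <- sample(cf$element_length_range[1L]:cf$element_length_range[2L],
                n_el, replace = TRUE)
  chrom <- random_chrom(n_el, cf$x_linked_fraction)
  start <- sort(sample.int(5e7, n_el)) # spread out; overlap never matters across chroms
  elements <- data.frame(chrom = chrom, start = start, end = start + len,
                         element_id = sprintf("%s%04d", classes, seq_len(n_el)),
                         element_class = classes, stringsAsFactors = FALSE)

  # --- sites ---------------------------------------------------------------
  n_sites_el <- pmax(1L, stats::rpois(n_el, cf$sites_per_element_mean))
  site_el <- rep(seq_len(n_el), n_sites_el)
  n_sites <- length(site_el)
  offset <- unlist(lapply(seq_len(n_el), function(i) {
    sort(sample.int(len[i], n_sites_el[i]))
  }))
  sites <- data.frame(
    chrom = elements$chrom[site_el],
    pos = elements$start[site_el] + offset, # 1-based inside [start+1, end]
    ref = sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
    element_id = elements$element_id[site_el],
    af = stats::rbeta(n_sites, cf$af_shape1, cf$af_shape2),
    stringsAsFactors = FALSE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  sites$class <- ifelse(stats::runif(n_sites) < cf$fraction_conserved,
                        "damaging_conserved", "neutral")
  if (cf$planted_carrier_or != 1 &&
      !any(sites$class == "damaging_conserved" & sites$af < cf$af_cutoff)) {
    stop("infeasible config: planted carrier odds ratio requires rare damaging sites")
  }

  # per-base annotation rows consistent with each site's class
  scores <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    gerp = ifelse(sites$class == "damaging_conserved",
                  stats::runif(n_sites, 2.5, 6), stats::runif(n_sites, -2, 1.5)),
    cadd = ifelse(sites$class == "damaging_conserved",
                  stats::runif(n_sites, 16, 35), stats::runif(n_sites, 0, 10)),
    dann = ifelse(sites$class == "damaging_conserved",
                  stats::runif(n_sites, 0.86, 1), stats::runif(n_sites, 0, 0.5)),
    fathmmnc = ifelse(sites$class == "damaging_conserved",
                      stats::runif(n_sites, 0.86, 1), stats::runif(n_sites, 0, 0.5)),
    in_exon = FALSE, in_utr = FALSE,
    in_promoter_or_1kb_tss = sites$class == "neutral" & stats::runif(n_sites) < 0.5,
    in_phastcons_element = sites$class == "damaging_conserved",
    stringsAsFactors = FALSE)

  # --- families ------------------------------------------------------------
  structures <- rep(names(cf$n_families), cf$n_families)
  n_fam <- length(structures)
  fam_id <- sprintf("F%04d", seq_len(n_fam))
  n_child <- cf$children_per_family
  is_x <- is_chrx(sites$chrom)

  ids <- character(0); fams <- character(0); fathers <- character(0)
  mothers <- character(0); sexes <- character(0); roles <- character(0)
  for (f in seq_len(n_fam)) {
    fid <- fam_id[f]
    pids <- paste0(fid, c("_FA", "_MO"))
    cids <- paste0(fid, "_C", seq_len(n_child))
    ids <- c(ids, pids, cids)
    fams <- c(fams, rep(fid, 2 + n_child))
    fathers <- c(fathers, NA, NA, rep(pids[1L], n_child))
    mothers <- c(mothers, NA, NA, rep(pids[2L], n_child))
    sexes <- c(sexes, "male", "female",
               ifelse(stats::runif(n_child) < cf$sex_ratio, "male", "female"))
    roles <- c(roles, "father", "mother", rep("child", n_child))
  }
  n_ind <- length(ids)

  # --- haplotypes ----------------------------------------------------------
  # father alleles (fa1, fa2; fa2 unused on X), mother alleles (mo1, mo2)
  draw <- function() matrix(stats::rbinom(n_sites * n_fam, 1L,
                                          rep(sites$af, n_fam)),
                            nrow = n_sites)
  fa1 <- draw(); fa2 <- draw(); mo1 <- draw(); mo2 <- draw()
  # consanguinity: mother's first allele IBD with father's first allele
  ibd_rate <- 4 * cf$inbreeding_f
  ibd <- matrix(FALSE, n_sites, n_fam)
  consang <- structures == "consanguineous"
  if (any(consang) && ibd_rate > 0) {
    ibd[, consang] <- stats::runif(n_sites * sum(consang)) < ibd_rate
    mo1[ibd] <- fa1[ibd]
  }

  gt_num <- matrix(0L, n_sites, n_ind, dimnames = list(NULL, ids))
  from_father <- matrix(FALSE, n_sites, n_ind, dimnames = list(NULL, ids))
  from_mother <- matrix(FALSE, n_sites, n_ind, dimnames = list(NULL, ids))
  autozygous <- matrix(FALSE, n_sites, n_ind, dimnames = list(NULL, ids))
  is_male <- sexes == "male"

  fam_of <- match(fams, fam_id)
  for (i in seq_len(n_ind)) {
    f <- fam_of[i]
    if (roles[i] == "father") {
      gt_num[, i] <- ifelse(is_x, fa1[, f], fa1[, f] + fa2[, f])
    } else if (roles[i] == "mother") {
      gt_num[, i] <- mo1[, f] + mo2[, f]
    } else {
      pick_f <- stats::runif(n_sites) < 0.5 # TRUE -> fa1
      pick_m <- stats::runif(n_sites) < 0.5 # TRUE -> mo1
      pat <- ifelse(pick_f, fa1[, f], fa2[, f])
      on_x_pat <- fa1[, f] # X: father transmits his single X to daughters
      mat <- ifelse(pick_m, mo1[, f], mo2[, f])
      if (is_male[i]) {
        gt_num[, i] <- ifelse(is_x, mat, pat + mat)
        from_father[, i] <- !is_x & pat == 1L
      } else {
        gt_num[, i] <- ifelse(is_x, on_x_pat + mat, pat + mat)
        from_father[, i] <- ifelse(is_x, on_x_pat == 1L, pat == 1L)
      }
      from_mother[, i] <- mat == 1L
      autozygous[, i] <- ibd[, f] & pick_m &
        (ifelse(is_x & !is_male[i], TRUE, pick_f)) &
        (!is_x | !is_male[i])
    }
  }

  # --- truth events (children only) ---------------------------------------
  rare_dam <- sites$class == "damaging_conserved" & sites$af < cf$af_cutoff
  rare_neu <- sites$class == "neutral" & sites$af < cf$af_cutoff
  truth_events <- list()
  carrier_aut <- setNames(rep(FALSE, n_ind), ids)
  for (i in which(roles == "child")) {
    for (rare_set in list(c("damaging_conserved", "rare_dam"),
                          c("neutral", "rare_neu"))) {
      rs <- if (rare_set[2L] == "rare_dam") rare_dam else rare_neu
      g <- gt_num[, i]
      hom <- which(rs & !is_x & g == 2L)
      hemi <- which(rs & is_x & is_male[i] & g == 1L)
      homx <- which(rs & is_x & !is_male[i] & g == 2L)
      het <- which(rs & !is_x & g == 1L)
      ev <- data.frame(individual_id = character(), element_id = character(),
                       kind = character(), chrom_class = character(),
                       site_class = character(), stringsAsFactors = FALSE)
      add <- function(idx, kind, xc) {
        if (length(idx)) {
          ev <<- rbind(ev, data.frame(
            individual_id = ids[i], element_id = sites$element_id[idx],
            kind = kind, chrom_class = xc, site_class = rare_set[1L],
            stringsAsFactors = FALSE))
        }
      }
      add(hom, "homozygous", "autosome")
      add(hemi, "hemizygous", "chrX")
      add(homx, "homozygous", "chrX")
      if (length(het) >= 2L) {
        for (el in unique(sites$element_id[het])) {
          hs <- het[sites$element_id[het] == el]
          pat <- from_father[hs, i] & !from_mother[hs, i]
          mat <- from_mother[hs, i] & !from_father[hs, i]
          if (any(pat) && any(mat)) {
            add(hs[which(pat)[1L]], "compound_het", "autosome")
          }
        }
      }
      ev <- ev[!duplicated(ev[, c("element_id", "kind")]), , drop = FALSE]
      if (nrow(ev)) truth_events[[length(truth_events) + 1L]] <- ev
      if (rare_set[1L] == "damaging_conserved" &&
          any(ev$chrom_class == "autosome")) {
        carrier_aut[i] <- TRUE
      }
    }
  }
  truth_events <- if (length(truth_events)) do.call(rbind, truth_events) else
    data.frame(individual_id = character(), element_id = character(),
               kind = character(), chrom_class = character(),
               site_class = character(), stringsAsFactors = FALSE)

  # --- affection: retrospective penetrance ---------------------------------
  p0 <- cf$baseline_case_prob
  odds1 <- cf$planted_carrier_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  affected <- rep("unknown", n_ind)
  child <- roles == "child"
  p_case <- ifelse(carrier_aut[child], p1, p0)
  affected[child] <- ifelse(stats::runif(sum(child)) < p_case, "case", "control")

  ped <- data.frame(family_id = fams, individual_id = ids,
                    father_id = fathers, mother_id = mothers,
                    sex = sexes, affected = affected, stringsAsFactors = FALSE)

  # --- QC fields and variant_set container ---------------------------------
  dp <- matrix(stats::rpois(n_sites * n_ind, cf$dp_mean) + 1L, n_sites, n_ind,
               dimnames = list(NULL, ids))
  gq <- matrix(cf$gq_value, n_sites, n_ind, dimnames = list(NULL, ids))
  if (cf$qc_fail_rate > 0) {
    fail <- matrix(stats::runif(n_sites * n_ind) < cf$qc_fail_rate, n_sites, n_ind)
    dp[fail] <- sample(0:5, sum(fail), replace = TRUE)
    gq[fail] <- sample(0:19, sum(fail), replace = TRUE)
  }
  x_ind <- matrix(is_x, n_sites, n_ind)
  male_mat <- matrix(rep(is_male, each = n_sites), n_sites, n_ind)
  gt_chr <- matrix("homref", n_sites, n_ind, dimnames = list(NULL, ids))
  gt_chr[gt_num == 1L] <- "het"
  gt_chr[gt_num == 2L] <- "homalt"
  hemi_mask <- x_ind & male_mat
  gt_chr[hemi_mask & gt_num == 0L] <- "hemi_ref"
  gt_chr[hemi_mask & gt_num == 1L] <- "hemi_alt"
  n_copies <- ifelse(hemi_mask, 1L, 2L)
  ad_alt <- matrix(0L, n_sites, n_ind, dimnames = list(NULL, ids))
  alt_frac <- gt_num / n_copies
  carrier <- gt_num > 0L
  ad_alt[carrier] <- stats::rbinom(sum(carrier), dp[carrier],
                                   pmin(1, alt_frac[carrier]))
  ad_alt[carrier] <- pmin(dp[carrier], pmax(ad_alt[carrier], 5L)) # plausible alt support, <= DP

  site_tab <- data.frame(chrom = sites$chrom, pos = sites$pos,
                         ref = sites$ref, alt = sites$alt, af = sites$af,
                         filter = "PASS", stringsAsFactors = FALSE)
  site_tab$pos0 <- site_tab$pos - 1L
  ord <- order(site_tab$chrom, site_tab$pos)
  vs <- structure(list(sites = site_tab[ord, ], gt = gt_chr[ord, , drop = FALSE],
                       ad_alt = ad_alt[ord, , drop = FALSE],
                       dp = dp[ord, , drop = FALSE], gq = gq[ord, , drop = FALSE],
                       samples = ids), class = "variant_set")
  truth_sites <- data.frame(sites[ord, c("chrom", "pos", "element_id", "af")],
                            class = sites$class[ord], stringsAsFactors = FALSE)
  out <- list(vcf = vs, ped = ped, elements = elements, scores = scores[ord, ],
              truth_events = truth_events, truth_sites = truth_sites,
              autozygosity = autozygous[ord, child, drop = FALSE],
              config = cf)
  if (!is.null(out_dir)) out$paths <- write_cohort(out, out_dir)
  out
}

# Write the simulated cohort to standard files (VCF/PED/BED/TSV).
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- sim$vcf
  vcf_path <- file.path(out_dir, "cohort.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", vs$samples), collapse = "\t"))
  gt_str <- c(homref = "0/0", het = "0/1", homalt = "1/1",
              hemi_ref = "0", hemi_alt = "1", missing = "./.")
  body <- vapply(seq_len(nrow(vs$sites)), function(i) {
    s <- vs$sites[i, ]
    fmt <- sprintf("%s:%d,%d:%d:%d", gt_str[vs$gt[i, ]],
                   vs$dp[i, ] - vs$ad_alt[i, ], vs$ad_alt[i, ],
                   vs$dp[i, ], vs$gq[i, ])
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, "100", s$filter,
            sprintf("AF=%.8f", s$af), "GT:AD:DP:GQ", fmt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), vcf_path)

  ped_path <- file.path(out_dir, "cohort.ped")
  pd <- sim$ped
  utils::write.table(
    data.frame(pd$family_id, pd$individual_id,
               ifelse(is.na(pd$father_id), "0", pd$father_id),
               ifelse(is.na(pd$mother_id), "0", pd$mother_id),
               c(male = 1L, female = 2L, unknown = 0L)[pd$sex],
               c(case = 2L, control = 1L, unknown = 0L)[pd$affected]),
    ped_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  bed_paths <- vapply(unique(sim$elements$element_class), function(cl) {
    p <- file.path(out_dir, paste0("elements_", cl, ".bed"))
    write_bed(sim$elements[sim$elements$element_class == cl, ], p)
    p
  }, "")
  scores_path <- file.path(out_dir, "scores.tsv")
  write_table(sim$scores, scores_path)
  truth_path <- file.path(out_dir, "truth_events.tsv")
  write_table(sim$truth_events, truth_path)
  list(vcf = vcf_path, ped = ped_path, beds = bed_paths,
       scores = scores_path, truth = truth_path)
}

#' Carrier-level cohort simulation
#'
#' Draws per-individual carrier status directly from the retrospective
#' penetrance model used by [simulate_cohort()] (carrier probability per
#' group implied by the control carrier rate and the target odds ratio),
#' skipping genotype materialisation. Suitable for large replicate studies
#' of the burden statistic, which depends on genotypes only through the
#' 2x2 carrier table. Optionally simulates a parallel neutral stratum with
#' a uniform case-rate inflation applied to both strata (emulating
#' consanguinity-driven excess, for correction studies).
#'
#' @param n_rep Number of replicate cohorts.
#' @param n_cases,n_controls Group sizes.
#' @param control_rate Control carrier rate at damaging sites.
#' @param carrier_or Target case:control carrier odds ratio.
#' @param neutral_control_rate Optional control carrier rate at neutral
#'   sites (adds `a_neut`/`c_neut` columns).
#' @param inflation Uniform multiplicative inflation of case carrier rates
#'   (applied to damaging and neutral strata alike).
#' @param seed Integer seed.
#' @return Data frame with one row per replicate: `a`, `b`, `c`, `d` and,
#'   when a neutral stratum is simulated, `a_neut`, `c_neut`.
#' @export
simulate_carrier_cohort <- function(n_rep, n_cases = 200L, n_controls = 400L,
                                    control_rate = 0.128, carrier_or = 1,
                                    neutral_control_rate = NULL,
                                    inflation = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  odds <- carrier_or * control_rate / (1 - control_rate)
  case_rate <- min(1, odds / (1 + odds) * 1) # odds -> probability
  case_rate <- min(1, case_rate * inflation)
  a <- stats::rbinom(n_rep, n_cases, case_rate)
  c <- stats::rbinom(n_rep, n_controls, control_rate)
  out <- data.frame(a = a, b = n_cases - a, c = c, d = n_controls - c)
  if (!is.null(neutral_control_rate)) {
    neut_case <- min(1, neutral_control_rate * inflation)
    out$a_neut <- stats::rbinom(n_rep, n_cases, neut_case)
    out$c_neut <- stats::rbinom(n_rep, n_controls, neutral_control_rate)
  }
  out
}

#' MPRA simulation configuration
#'
#' Defaults emulate a synthesized-oligo library: each sequence represented
#' by 10 distinct barcodes, 6 cDNA replicates, negative-binomially
#' dispersed counts, 20% active sequences with a log2 effect of 1.5.
#'
#' @param n_sequences Number of sequences in the library.
#' @param barcodes_per_sequence Barcodes per sequence (default 10).
#' @param fraction_active Fraction of active sequences.
#' @param effect_log2 log2 activity shift of active sequences.
#' @param nb_mean,nb_dispersion Negative-binomial mean and size.
#' @param n_replicates Number of cDNA replicates (default 6).
#' @param barcode_length Barcode length in nt (default 12).
#' @param n_variant_pairs Number of with/without-variant sequence pairs to
#'   append; half the pairs receive an activity-modulating `effect_log2`
#'   shift in the with-variant sequence.
#' @param seed Mandatory integer seed.
#' @return List of class `mpra_sim_config`.
#' @export
mpra_sim_config <- function(n_sequences = 100L, barcodes_per_sequence = 10L,
                            fraction_active = 0.2, effect_log2 = 1.5,
                            nb_mean = 200, nb_dispersion = 10,
                            n_replicates = 6L, barcode_length = 12L,
                            n_variant_pairs = 0L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nb_dispersion > 0, fraction_active >= 0, fraction_active <= 1)
  structure(as.list(environment()), class = "mpra_sim_config")
}

random_barcodes <- function(n, len) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate an MPRA barcode count table with known truth
#'
#' Plasmid counts are negative binomial; cDNA counts per replicate are
#' negative binomial with mean scaled by `2^effect` for active sequences.
#' When `n_variant_pairs > 0`, matched with/without-variant sequence pairs
#' are appended (both sides active at baseline) with half the pairs
#' carrying a variant effect, for variant-effect call validation.
#'
#' @param config An [mpra_sim_config()].
#' @param out_dir Optional output directory for TSV files.
#' @return List with `counts` (barcode records), `truth` (per-sequence
#'   `active` flag and `effect`), and `pairs` (variant design, possibly
#'   empty).
#' @export
simulate_mpra <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "mpra_sim_config"))
  set.seed(config$seed)
  cf <- config
  n_base <- cf$n_sequences
  seq_ids <- sprintf("seq%04d", seq_len(n_base))
  active <- stats::runif(n_base) < cf$fraction_active
  effect <- ifelse(active, cf$effect_log2, 0)
  variant_id <- rep(NA_character_, n_base)
  pairs <- data.frame(variant_id = character(), seq_with = character(),
                      seq_without = character(), modulating = logical(),
                      stringsAsFactors = FALSE)
  if (cf$n_variant_pairs > 0L) {
    vid <- sprintf("var%03d", seq_len(cf$n_variant_pairs))
    s_wo <- sprintf("pair%03d_ref", seq_len(cf$n_variant_pairs))
    s_wi <- sprintf("pair%03d_alt", seq_len(cf$n_variant_pairs))
    modul <- seq_len(cf$n_variant_pairs) <= ceiling(cf$n_variant_pairs / 2)
    seq_ids <- c(seq_ids, s_wo, s_wi)
    active <- c(active, rep(TRUE, 2L * cf$n_variant_pairs))
    effect <- c(effect, rep(cf$effect_log2, cf$n_variant_pairs),
                cf$effect_log2 + ifelse(modul, cf$effect_log2, 0))
    variant_id <- c(variant_id, rep(vid, 2L))
    pairs <- data.frame(variant_id = vid, seq_with = s_wi, seq_without = s_wo,
                        modulating = modul, stringsAsFactors = FALSE)
  }
  n_seq <- length(seq_ids)
  n_bc <- n_seq * cf$barcodes_per_sequence
  counts <- data.frame(
    barcode = random_barcodes(n_bc, cf$barcode_length),
    sequence_id = rep(seq_ids, each = cf$barcodes_per_sequence),
    variant_id = rep(variant_id, each = cf$barcodes_per_sequence),
    plasmid = stats::rnbinom(n_bc, mu = cf$nb_mean, size = cf$nb_dispersion),
    stringsAsFactors = FALSE)
  eff_bc <- rep(effect, each = cf$barcodes_per_sequence)
  for (r in seq_len(cf$n_replicates)) {
    counts[[paste0("cdna_", r)]] <-
      stats::rnbinom(n_bc, mu = cf$nb_mean * 2^eff_bc, size = cf$nb_dispersion)
  }
  truth <- data.frame(sequence_id = seq_ids, active = active, effect = effect,
                      stringsAsFactors = FALSE)
  out <- list(counts = counts, truth = truth, pairs = pairs, config = cf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(counts, file.path(out_dir, "mpra_counts.tsv"))
    write_table(truth, file.path(out_dir, "mpra_truth.tsv"))
    out$paths <- list(counts = file.path(out_dir, "mpra_counts.tsv"),
                      truth = file.path(out_dir, "mpra_truth.tsv"))
  }
  out
}
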