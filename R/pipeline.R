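# Pipeline orchestration: reproducible burden / MPRA / simulation runs with
# config validation, logging, and a fixed output layout.

require_keys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss)) {
    stop(sprintf("config validation error: missing key '%s'", miss[1L]))
  }
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a run configuration from YAML
#'
#' @param path Path to a YAML config file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# subset a variant_set to a logical/integer row selection
subset_sites <- function(vs, sel) {
  vs$sites <- vs$sites[sel, , drop = FALSE]
  vs$gt <- vs$gt[sel, , drop = FALSE]
  vs$ad_alt <- vs$ad_alt[sel, , drop = FALSE]
  vs$dp <- vs$dp[sel, , drop = FALSE]
  vs$gq <- vs$gq[sel, , drop = FALSE]
  vs
}

# counts of damaging variant sites carried by >= 1 case / control, per sex
# and AF grid point (input to the AF-cutoff rule)
damaging_counts_by_af <- function(vs, ped, grid) {
  idx <- match(colnames(vs$gt), ped$individual_id)
  alt <- vs$gt %in% c("het", "homalt", "hemi_alt")
  dim(alt) <- dim(vs$gt)
  dam <- vs$sites$class == "damaging_conserved"
  rows <- list()
  for (s in c("male", "female")) {
    for (g in grid) {
      in_af <- dam & !is.na(vs$sites$af) & vs$sites$af < g
      sel_case <- ped$affected[idx] == "case" & ped$sex[idx] == s
      sel_ctrl <- ped$affected[idx] == "control" & ped$sex[idx] == s
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, af_cutoff = g,
        n_case_variants = sum(in_af & rowSums(alt[, sel_case, drop = FALSE]) > 0),
        n_control_variants = sum(in_af & rowSums(alt[, sel_ctrl, drop = FALSE]) > 0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the recessive burden pipeline
#'
#' Orchestrates: input parsing, genotype QC, ensemble classification,
#' AF-cutoff selection, recessive event calling per element class, carrier
#' tables and odds-ratio statistics per sex filter, the neutral-rate
#' harmonization check with optional (or automatic) consanguinity
#' correction, BH adjustment across the element-class x sex family, an
#' AF-scan table, and per-element tallies. Deterministic given config and
#' inputs; every output file carries the config hash and seed in a comment
#' header, and all filter in/out counts are logged.
#'
#' @param config Named list (or YAML via [read_config()]) with keys:
#'   `cohort`, `vcf`, `ped`, `elements` (named list class -> BED path),
#'   `scores`, `qc_profile`, `seed`; optional `af_grid`, `sex_filters`,
#'   `fdr_level`, `correction` (`"on"`/`"off"`/`"auto"`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `results`, `tally`, `af_scan` data frames
#'   and the chosen cutoffs.
#' @export
run_burden <- function(config, out_dir) {
  require_keys(config, c("cohort", "vcf", "ped", "elements", "scores",
                         "qc_profile", "seed"))
  af_grid <- config$af_grid %||% c(0.01, 0.005, 0.001, 5e-04)
  sex_filters <- config$sex_filters %||% c("both", "male", "female")
  fdr_level <- config$fdr_level %||% 0.05
  correction <- config$correction %||% "auto"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  hash <- config_hash(config)
  hdr <- c(sprintf("config_hash: %s", hash), sprintf("seed: %s", config$seed))
  set.seed(config$seed)

  ped <- read_ped(config$ped)
  vs <- read_vcf(config$vcf, ped = ped)
  log("loaded %d sites x %d samples", nrow(vs$sites), length(vs$samples))
  prof <- qc_profile(config$qc_profile)
  n_called_pre <- sum(vs$gt != "missing")
  vs <- apply_genotype_qc(vs, prof)
  log("genotype QC (%s): %d -> %d called genotypes", prof$name,
      n_called_pre, sum(vs$gt != "missing"))
  scores <- read_scores(config$scores)
  vs <- classify_variant_set(vs, scores)
  for (lb in unique(vs$sites$class)) {
    log("class %s: %d sites", lb, sum(vs$sites$class == lb))
  }
  element_sets <- lapply(config$elements, function(p) read_bed(p))

  counts <- damaging_counts_by_af(vs, ped, af_grid)
  cutoffs <- suppressWarnings(select_af_cutoff(counts, af_grid))
  af_cutoff <- max(cutoffs) # one cohort-level cutoff: the laxer of the sexes
  log("chosen AF cutoffs: male %g, female %g -> cohort %g",
      cutoffs[["male"]], cutoffs[["female"]], af_cutoff)

  neut_sel <- neutral_set(vs$sites, scores, scope = "promoter_nonconserved")
  vs_neut <- subset_sites(vs, neut_sel)
  vs_neut$sites$class <- rep_len("neutral", nrow(vs_neut$sites))

  results <- list()
  tallies <- list()
  scans <- list()
  for (cl in names(element_sets)) {
    el <- element_sets[[cl]]
    ev <- call_recessive_events(vs, el, ped, af_cutoff = af_cutoff)
    ev_neut <- call_recessive_events(vs_neut, el, ped, af_cutoff = af_cutoff,
                                     class_filter = "neutral")
    log("%s: %d damaging events, %d neutral events, %d ambiguous pairs dropped",
        cl, nrow(ev), nrow(ev_neut), attr(ev, "n_ambiguous_pairs"))
    for (sx in sex_filters) {
      tab <- carrier_table(ev, ped, sex_filter = sx, samples = vs$samples)
      ntab <- carrier_table(ev_neut, ped, sex_filter = sx, samples = vs$samples)
      n_case <- tab[["a"]] + tab[["b"]]
      n_ctrl <- tab[["c"]] + tab[["d"]]
      neut_case <- if (n_case > 0) ntab[["a"]] / n_case else NA_real_
      neut_ctrl <- if (n_ctrl > 0) ntab[["c"]] / n_ctrl else NA_real_
      harm <- if (!is.na(neut_case) && !is.na(neut_ctrl)) {
        harmonization_check(neut_case, neut_ctrl, n_case, n_ctrl)
      } else list(flag = "undefined")
      apply_corr <- switch(correction,
                           on = TRUE,
                           off = FALSE,
                           auto = identical(harm$flag, "elevated"))
      apply_corr <- apply_corr && !is.na(neut_case) && neut_case > 0
      res <- burden_result(tab, element_class = cl, cohort = config$cohort,
                           sex_filter = sx, af_cutoff = af_cutoff,
                           correct = apply_corr,
                           neutral_case_rate = neut_case,
                           neutral_control_rate = neut_ctrl)
      res$neutral_flag <- harm$flag
      results[[length(results) + 1L]] <- res
    }
    tl <- per_element_tally(ev, ped)
    if (nrow(tl)) tl <- cbind(element_class = cl, tl)
    tallies[[length(tallies) + 1L]] <- tl
    scan <- af_scan(vs, el, ped, grid = af_grid, sex_filter = "both",
                    element_class = cl, cohort = config$cohort)
    scans[[length(scans) + 1L]] <- scan
  }
  results <- do.call(rbind, results)
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  results$significant <- !is.na(results$p_adj) & results$p_adj <= fdr_level
  tally <- do.call(rbind, tallies)
  scan <- do.call(rbind, scans)

  write_table(results, file.path(out_dir, "burden_results.tsv"), comment = hdr)
  write_table(tally, file.path(out_dir, "per_element_tally.tsv"), comment = hdr)
  write_table(scan, file.path(out_dir, "af_scan.tsv"), comment = hdr)
  writeLines(c(paste0("# ", hdr), log_lines), file.path(out_dir, "run.log"))
  invisible(list(results = results, tally = tally, af_scan = scan,
                 af_cutoffs = cutoffs))
}

#' Run the MPRA analysis pipeline
#'
#' Computes barcode log-ratios, per-sequence activity calls, optional
#' element-level activity and variant-effect calls, and writes result TSVs.
#'
#' @param config Named list with keys `counts` (TSV path or data frame) and
#'   `seed`; optional `design` (variant pair TSV/data frame with
#'   `variant_id`, `seq_with`, `seq_without`), `element_map` (TSV/data
#'   frame with `element_id`, `sequence_id`), `min_barcodes`, `fdr_level`.
#' @param out_dir Output directory.
#' @return Invisibly, list with `ratios`, `activity`, `elements`,
#'   `variant_effects`.
#' @export
run_mpra <- function(config, out_dir) {
  require_keys(config, c("counts", "seed"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[!vapply(config, is.data.frame, NA)])
  hdr <- c(sprintf("config_hash: %s", hash), sprintf("seed: %s", config$seed))
  set.seed(config$seed)
  counts <- if (is.character(config$counts)) read_table_tsv(config$counts)
            else config$counts
  if (nrow(counts) == 0L) {
    message("nothing to test: empty count table")
    return(invisible(list(ratios = NULL, activity = NULL,
                          elements = NULL, variant_effects = NULL)))
  }
  ratios <- barcode_log_ratios(counts)
  message(sprintf("%d barcodes dropped (absent from plasmid or a cDNA replicate)",
                  attr(ratios, "n_dropped")))
  activity <- call_activity(ratios,
                            min_barcodes = config$min_barcodes %||% 3L,
                            fdr_level = config$fdr_level %||% 0.05)
  write_table(activity, file.path(out_dir, "activity.tsv"), comment = hdr)
  elements <- NULL
  if (!is.null(config$element_map)) {
    em <- if (is.character(config$element_map)) read_table_tsv(config$element_map)
          else config$element_map
    elements <- element_activity(em, activity)
    write_table(elements, file.path(out_dir, "element_activity.tsv"),
                comment = hdr)
  }
  veff <- NULL
  if (!is.null(config$design)) {
    des <- if (is.character(config$design)) read_table_tsv(config$design)
           else config$design
    veff <- variant_effect(des, ratios, activity,
                           fdr_level = config$fdr_level %||% 0.05)
    write_table(veff, file.path(out_dir, "variant_effects.tsv"), comment = hdr)
  }
  invisible(list(ratios = ratios, activity = activity, elements = elements,
                 variant_effects = veff))
}

#' Generate a synthetic cohort dataset directory
#'
#' @param config Named list of [cohort_sim_config()] arguments (must
#'   include `seed`).
#' @param out_dir Output directory.
#' @return Invisibly, the simulation object (see [simulate_cohort()]).
#' @export
run_simulate <- function(config, out_dir) {
  require_keys(config, "seed")
  cfg <- do.call(cohort_sim_config, config)
  invisible(simulate_cohort(cfg, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
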