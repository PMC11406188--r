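# Case-control burden statistics: Woolf odds ratio with SE/CI/z, BH-FDR,
# consanguinity correction, contribution estimates, AF scans, per-element
# tallies.

#' Odds ratio with Woolf standard error, CI, z and p
#'
#' For the 2x2 carrier table (`a` cases with events, `b` cases without,
#' `c` controls with, `d` controls without):
#' `OR = (a/b)/(c/d)`, `SE(ln OR) = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `95% CI = exp(ln OR +/- 1.96 SE)`, `z = ln(OR)/SE`, and a two-sided
#' normal-tail p-value. When any cell is zero the Haldane-Anscombe 0.5
#' continuity correction is applied to all four cells. An all-zero margin
#' (no cases or no carriers at all) is undefined and returned as `NA` with
#' `undefined = TRUE`.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `se_ln_or`, `ci_low`, `ci_high`, `z`, `p`,
#'   `undefined`.
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(or = NA_real_, se_ln_or = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, z = NA_real_, p = NA_real_,
                undefined = TRUE))
  }
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(or) / se
  list(or = or, se_ln_or = se,
       ci_low = exp(log(or) - zq * se), ci_high = exp(log(or) + zq * se),
       z = z, p = 2 * stats::pnorm(-abs(z)), undefined = FALSE)
}

#' Odds ratio implied by two carrier proportions
#'
#' `((p1/(1-p1)) / (p0/(1-p0)))` -- the odds ratio reconstructed from
#' printed case and control carrier rates.
#'
#' @param case_rate,control_rate Carrier proportions in (0, 1).
#' @return The odds ratio.
#' @export
rate_odds_ratio <- function(case_rate, control_rate) {
  (case_rate / (1 - case_rate)) / (control_rate / (1 - control_rate))
}

#' Contribution of an element class to case risk
#'
#' The difference between case and control carrier rates, in percent:
#' `100 * (case_rate - control_rate)`, read as the fraction of cases
#' attributable to recessive events in the element class. Negative
#' differences are floored at 0 with a warning.
#'
#' @param case_rate,control_rate Carrier proportions in \[0, 1\].
#' @return Contribution in percent.
#' @export
contribution <- function(case_rate, control_rate) {
  stopifnot(case_rate >= 0, case_rate <= 1, control_rate >= 0, control_rate <= 1)
  d <- 100 * (case_rate - control_rate)
  if (d < 0) {
    warning("case rate below control rate; contribution floored at 0")
    d <- 0
  }
  d
}

#' Consanguinity correction of the case carrier rate
#'
#' Reduces the damaging-event case rate proportionally to the excess
#' observed at likely-neutral (non-conserved promoter) sites, where rates
#' should be equal between cases and controls absent consanguinity:
#' `corrected = damaging_case_rate * neutral_control_rate / neutral_case_rate`.
#'
#' @param damaging_case_rate Case carrier rate at damaging conserved sites.
#' @param neutral_case_rate,neutral_control_rate Carrier rates at neutral
#'   sites; `neutral_case_rate` must be positive.
#' @return The corrected case carrier rate.
#' @export
consanguinity_correction <- function(damaging_case_rate, neutral_case_rate,
                                     neutral_control_rate) {
  if (neutral_case_rate <= 0) {
    stop("consanguinity correction inapplicable: neutral case rate is zero")
  }
  if (neutral_control_rate > neutral_case_rate) {
    warning("neutral control rate exceeds neutral case rate; corrected case rate increases")
  }
  damaging_case_rate * (neutral_control_rate / neutral_case_rate)
}

#' Benjamini-Hochberg adjusted p-values with a significance flag
#'
#' Standard step-up adjustment (monotone) with significance assessed at the
#' given FDR level.
#'
#' @param p Numeric vector of p-values.
#' @param fdr_level FDR level (default 0.05).
#' @return Data frame with `p`, `p_adj`, `significant`.
#' @export
bh_fdr <- function(p, fdr_level = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adj = adj, significant = !is.na(adj) & adj <= fdr_level)
}

#' Assemble a burden result row from a carrier table
#'
#' Computes rates, odds ratio statistics and the contribution; when neutral
#' case/control rates are supplied and `correct = TRUE`, the case rate is
#' consanguinity-corrected, the corrected carrier count
#' `a' = round(corrected_rate * (a + b))` replaces `a`, and OR and
#' contribution are recomputed from the corrected table.
#'
#' @param tab Named vector `c(a, b, c, d)` from [carrier_table()].
#' @param element_class,cohort,sex_filter,af_cutoff Metadata columns.
#' @param correct Apply the consanguinity correction?
#' @param neutral_case_rate,neutral_control_rate Neutral carrier rates used
#'   by the correction.
#' @return One-row data frame with all burden-result fields.
#' @export
burden_result <- function(tab, element_class = NA, cohort = NA,
                          sex_filter = NA, af_cutoff = NA,
                          correct = FALSE, neutral_case_rate = NULL,
                          neutral_control_rate = NULL) {
  a <- tab[["a"]]; b <- tab[["b"]]; c <- tab[["c"]]; d <- tab[["d"]]
  case_rate <- if ((a + b) > 0) a / (a + b) else NA_real_
  control_rate <- if ((c + d) > 0) c / (c + d) else NA_real_
  corrected_case_rate <- NA_real_
  if (correct) {
    corrected_case_rate <- consanguinity_correction(
      case_rate, neutral_case_rate, neutral_control_rate)
    a <- round(corrected_case_rate * (a + b))
    b <- (tab[["a"]] + tab[["b"]]) - a
  }
  st <- odds_ratio(a, b, c, d)
  eff_case_rate <- if (correct) corrected_case_rate else case_rate
  contrib <- if (!is.na(eff_case_rate) && !is.na(control_rate)) {
    suppressWarnings(contribution(eff_case_rate, control_rate))
  } else NA_real_
  data.frame(
    element_class = element_class, cohort = cohort, sex_filter = sex_filter,
    af_cutoff = af_cutoff,
    a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
    case_rate = case_rate, control_rate = control_rate,
    or_value = st$or, se_ln_or = st$se_ln_or,
    ci_low = st$ci_low, ci_high = st$ci_high, z = st$z, p = st$p,
    p_adj = NA_real_, corrected = correct,
    corrected_case_rate = corrected_case_rate,
    contribution_pct = contrib,
    stringsAsFactors = FALSE)
}

#' Burden results across an allele-frequency grid
#'
#' Recomputes the carrier table and burden statistics at each cutoff in the
#' grid, demonstrating robustness of the signal to the AF cutoff. Cutoffs
#' at which no variant survives yield an undefined (`NA`) result row.
#'
#' @param vs Classified `variant_set`.
#' @param elements Element data frame.
#' @param ped Pedigree data frame.
#' @param grid Numeric vector of AF cutoffs.
#' @param sex_filter Passed to [carrier_table()].
#' @param class_filter Site class used for events.
#' @param ... Metadata passed to [burden_result()].
#' @return Data frame with one row per grid point.
#' @export
af_scan <- function(vs, elements, ped, grid, sex_filter = "both",
                    class_filter = "damaging_conserved", ...) {
  rows <- lapply(grid, function(g) {
    ev <- call_recessive_events(vs, elements, ped, af_cutoff = g,
                                class_filter = class_filter)
    tab <- carrier_table(ev, ped, sex_filter = sex_filter,
                         samples = vs$samples)
    burden_result(tab, af_cutoff = g, sex_filter = sex_filter, ...)
  })
  do.call(rbind, rows)
}

#' Per-element case/control carrier tallies
#'
#' Counts case and control carriers per element, flags elements with a
#' numerical excess of case carriers, and lists "patient variants": variants
#' in excess-flagged elements seen in cases, excluding any variant also
#' observed in a control. Output is sorted by (excess, case carriers)
#' descending.
#'
#' @param events Event data frame from [call_recessive_events()].
#' @param ped Pedigree data frame.
#' @return Data frame with `element_id`, `n_case_carriers`,
#'   `n_control_carriers`, `excess`, `patient_variants`, `variants`.
#' @export
per_element_tally <- function(events, ped) {
  aff <- setNames(ped$affected, ped$individual_id)
  events$affected <- aff[events$individual_id]
  split_vars <- function(v) unique(unlist(strsplit(v, ",", fixed = TRUE)))
  rows <- lapply(split(events, events$element_id), function(ev) {
    case_ev <- ev[ev$affected == "case", , drop = FALSE]
    ctrl_ev <- ev[ev$affected == "control", , drop = FALSE]
    n_case <- length(unique(case_ev$individual_id))
    n_ctrl <- length(unique(ctrl_ev$individual_id))
    excess <- n_case > n_ctrl
    case_vars <- split_vars(case_ev$variants)
    ctrl_vars <- split_vars(ctrl_ev$variants)
    pv <- if (excess) setdiff(case_vars, ctrl_vars) else character()
    data.frame(element_id = ev$element_id[1L],
               n_case_carriers = n_case, n_control_carriers = n_ctrl,
               excess = excess,
               patient_variants = paste(pv, collapse = ","),
               variants = paste(union(case_vars, ctrl_vars), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(element_id = character(), n_case_carriers = integer(),
                      n_control_carriers = integer(), excess = logical(),
                      patient_variants = character(), variants = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$excess, -out$n_case_carriers), , drop = FALSE]
  rownames(out) <- NULL
  out
}
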