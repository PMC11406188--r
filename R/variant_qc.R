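# Per-cohort genotype-level QC, allele-frequency cutoff selection, and the
# neutral-rate harmonization check.

#' Built-in cohort QC profiles
#'
#' Thresholds follow each cohort's published filter wording exactly:
#' the consanguineous WGS cohort (HMCA) keeps genotypes with AD > 2,
#' DP > 10 and GQ > 20; the targeted-sequencing cohort (NIMH) requires a
#' minimum of 10x coverage (DP >= 10), GQ > 20 and AD > 4; the simplex WGS
#' cohort (SSC) keeps AD >= 3, DP >= 5, GQ >= 20 and PASS records only.
#'
#' @param name One of `"HMCA"`, `"NIMH"`, `"SSC"` or `"custom"`.
#' @param ... For `"custom"`: fields overriding the defaults
#'   (`min_ad`, `ad_inclusive`, `min_dp`, `dp_inclusive`, `min_gq`,
#'   `gq_inclusive`, `require_pass`, `af_cutoff`).
#' @return A list of class `qc_profile`.
#' @export
qc_profile <- function(name = c("HMCA", "NIMH", "SSC", "custom"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    HMCA = list(min_ad = 2, ad_inclusive = FALSE, min_dp = 10, dp_inclusive = FALSE,
                min_gq = 20, gq_inclusive = FALSE, require_pass = FALSE,
                af_cutoff = 0.005),
    NIMH = list(min_ad = 4, ad_inclusive = FALSE, min_dp = 10, dp_inclusive = TRUE,
                min_gq = 20, gq_inclusive = FALSE, require_pass = FALSE,
                af_cutoff = 0.001),
    SSC  = list(min_ad = 3, ad_inclusive = TRUE, min_dp = 5, dp_inclusive = TRUE,
                min_gq = 20, gq_inclusive = TRUE, require_pass = TRUE,
                af_cutoff = 0.005),
    custom = list(min_ad = 0, ad_inclusive = TRUE, min_dp = 0, dp_inclusive = TRUE,
                  min_gq = 0, gq_inclusive = TRUE, require_pass = FALSE,
                  af_cutoff = 0.005))
  over <- list(...)
  base[names(over)] <- over
  base$name <- name
  structure(base, class = "qc_profile")
}

#' Apply genotype-level QC to a variant set
#'
#' Genotypes failing the profile's AD/DP/GQ thresholds are set to
#' `"missing"`. QC is per genotype, never per site: a failing sample never
#' removes other samples' calls. Reference-homozygous (and hemizygous
#' reference) genotypes are exempt from the alt-depth (AD) test.
#' Missing AD/DP/GQ values fail any threshold that tests them
#' (conservative exclusion). When the profile requires PASS, every genotype
#' of a non-PASS record is set missing.
#'
#' @param vs A `variant_set` (see [read_vcf()]).
#' @param profile A [qc_profile()].
#' @return The `variant_set` with failing genotypes set to `"missing"`.
#' @export
apply_genotype_qc <- function(vs, profile) {
  stopifnot(inherits(profile, "qc_profile"))
  cmp <- function(x, thr, inclusive) {
    ok <- if (inclusive) x >= thr else x > thr
    ok & !is.na(x)
  }
  alt_carrying <- vs$gt %in% c("het", "homalt", "hemi_alt")
  dim(alt_carrying) <- dim(vs$gt)
  pass <- matrix(TRUE, nrow(vs$gt), ncol(vs$gt))
  if (profile$min_dp > 0) pass <- pass & cmp(vs$dp, profile$min_dp, profile$dp_inclusive)
  if (profile$min_gq > 0) pass <- pass & cmp(vs$gq, profile$min_gq, profile$gq_inclusive)
  if (profile$min_ad > 0) {
    ad_ok <- cmp(vs$ad_alt, profile$min_ad, profile$ad_inclusive)
    pass <- pass & (ad_ok | !alt_carrying)
  }
  if (isTRUE(profile$require_pass)) {
    pass <- pass & matrix(vs$sites$filter == "PASS",
                          nrow(vs$gt), ncol(vs$gt))
  }
  vs$gt[!pass & vs$gt != "missing"] <- "missing"
  vs
}

#' Select the allele-frequency cutoff per sex
#'
#' Chooses, per sex, the smallest cutoff in a descending grid at which the
#' number of predicted damaging variants exceeds 5 in cases and in controls.
#' If no grid point qualifies, the largest grid value is returned with a
#' warning.
#'
#' @param counts Data frame with columns `sex`, `af_cutoff`,
#'   `n_case_variants`, `n_control_variants` (one row per sex x grid point).
#' @param grid Numeric vector of cutoffs, sorted descending.
#' @param min_variants Minimum count that must be exceeded (default 5).
#' @return Named numeric vector: chosen cutoff per sex.
#' @export
select_af_cutoff <- function(counts, grid, min_variants = 5L) {
  if (length(grid) == 0L) stop("empty allele-frequency grid")
  stopifnot(all(diff(grid) < 0))
  sexes <- unique(counts$sex)
  vapply(setNames(sexes, sexes), function(s) {
    sub <- counts[counts$sex == s, , drop = FALSE]
    ok <- vapply(grid, function(g) {
      row <- sub[sub$af_cutoff == g, , drop = FALSE]
      nrow(row) == 1L && row$n_case_variants > min_variants &&
        row$n_control_variants > min_variants
    }, NA)
    if (!any(ok)) {
      warning(sprintf("no cutoff with > %d damaging variants in both groups for sex %s; using %g",
                      min_variants, s, grid[1L]))
      return(grid[1L])
    }
    min(grid[ok])
  }, 1)
}

#' Compare likely-neutral variant rates between cases and controls
#'
#' Data-harmonization check: rates of likely neutral variants (rare variants
#' at non-conserved sites) should be comparable between cases and controls;
#' an elevated case rate signals residual consanguinity/endogamy and that
#' the consanguinity correction should be applied. Equality is tested with
#' a two-proportion test at the 0.05 level.
#'
#' @param case_rate,control_rate Carrier fractions in \[0, 1\].
#' @param n_cases,n_controls Group sizes.
#' @param alpha Significance level (default 0.05).
#' @return List with `ratio` (case/control, `NA` when the control rate is
#'   zero), `p`, and `flag` (`"elevated"`, `"comparable"`, or `"undefined"`).
#' @export
harmonization_check <- function(case_rate, control_rate, n_cases, n_controls,
                                alpha = 0.05) {
  stopifnot(case_rate >= 0, case_rate <= 1, control_rate >= 0, control_rate <= 1)
  if (control_rate == 0) {
    return(list(ratio = NA_real_, p = NA_real_, flag = "undefined"))
  }
  x <- round(c(case_rate * n_cases, control_rate * n_controls))
  n <- c(n_cases, n_controls)
  p <- suppressWarnings(stats::prop.test(x, n, correct = FALSE)$p.value)
  list(ratio = case_rate / control_rate, p = p,
       flag = if (!is.na(p) && p < alpha && case_rate > control_rate)
         "elevated" else "comparable")
}
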