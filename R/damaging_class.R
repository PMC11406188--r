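# Ensemble damaging/neutral classifier over conservation-based variant
# effect predictors (GERP, CADD, DANN, FATHMM-nc) plus region context.

#' Classify variants as damaging-at-conserved-base, neutral, or excluded
#'
#' Applies: (1) variants in exonic regions of protein-coding genes are
#' `excluded_exonic`; (2) variants passing the ensemble rule (GERP > 2 and
#' (CADD > 15 or DANN > 0.85 or FATHMM-nc > 0.85)) are `damaging_conserved`,
#' except that in a UTR or within 1 kb of a transcription start site /
#' predicted promoter they must additionally overlap a phastCons conserved
#' element, else `excluded_context`; (3) variants failing every predictor
#' threshold simultaneously (GERP <= 2 and CADD <= 15 and DANN <= 0.85 and
#' FATHMM-nc <= 0.85) are `neutral` -- the likely benign class that backs
#' the harmonization check and, restricted to promoters, the consanguinity
#' correction; (4) everything else is `other` (e.g. a high CADD score at a
#' non-conserved base). All inequalities are strict, and the labels
#' partition the input.
#'
#' @param sites Data frame with `chrom`, `pos`.
#' @param scores Annotation table from [read_scores()] with columns `gerp`,
#'   `cadd`, `dann`, `fathmmnc`, `in_exon`, `in_utr`,
#'   `in_promoter_or_1kb_tss`, `in_phastcons_element`.
#' @param thresholds Named list of predictor thresholds.
#' @return Character vector of labels, one per site. Positions absent from
#'   `scores` are an error naming the first missing position.
#' @export
classify_variants <- function(sites, scores,
                              thresholds = list(gerp = 2, cadd = 15,
                                                dann = 0.85, fathmmnc = 0.85)) {
  idx <- match(paste(sites$chrom, sites$pos), paste(scores$chrom, scores$pos))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    stop(sprintf("no annotation for position %s:%d",
                 sites$chrom[miss], sites$pos[miss]))
  }
  ann <- scores[idx, , drop = FALSE]
  damaging <- ann$gerp > thresholds$gerp &
    (ann$cadd > thresholds$cadd | ann$dann > thresholds$dann |
       ann$fathmmnc > thresholds$fathmmnc)
  neutral <- ann$gerp <= thresholds$gerp & ann$cadd <= thresholds$cadd &
    ann$dann <= thresholds$dann & ann$fathmmnc <= thresholds$fathmmnc
  needs_conserved_element <- (ann$in_utr | ann$in_promoter_or_1kb_tss) &
    !ann$in_phastcons_element
  label <- ifelse(ann$in_exon, "excluded_exonic",
           ifelse(damaging & needs_conserved_element, "excluded_context",
           ifelse(damaging, "damaging_conserved",
           ifelse(neutral, "neutral", "other"))))
  label
}

#' Classify the sites of a variant set in place
#'
#' @param vs A `variant_set`.
#' @param scores Annotation table from [read_scores()].
#' @param ... Passed to [classify_variants()].
#' @return The `variant_set` with a `class` column added to `$sites`.
#' @export
classify_variant_set <- function(vs, scores, ...) {
  vs$sites$class <- classify_variants(vs$sites, scores, ...)
  vs
}

#' Select the likely-neutral variant subset
#'
#' `scope = "all_nonconserved"` returns every neutral-labelled variant
#' (used for the harmonization check); `"promoter_nonconserved"`
#' additionally requires the variant to lie within a gene promoter /
#' 1 kb of a TSS (the set used for the consanguinity correction, where
#' absence of selection bias is assumed).
#'
#' @param sites Classified site table (with `class` column).
#' @param scores Annotation table (for the promoter flag).
#' @param scope `"all_nonconserved"` or `"promoter_nonconserved"`.
#' @return Logical vector marking the selected sites.
#' @export
neutral_set <- function(sites, scores,
                        scope = c("all_nonconserved", "promoter_nonconserved")) {
  scope <- match.arg(scope)
  sel <- sites$class == "neutral"
  if (scope == "promoter_nonconserved") {
    idx <- match(paste(sites$chrom, sites$pos), paste(scores$chrom, scores$pos))
    sel <- sel & !is.na(idx) & scores$in_promoter_or_1kb_tss[idx]
  }
  sel
}
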