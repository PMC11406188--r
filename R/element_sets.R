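# Element-set construction: HAR merging, VE subdivision into conserved
# cores, CNE selection by conservation + chromatin state + constraint.

#' Merge overlapping intervals
#'
#' Returns the minimal set of disjoint intervals covering the union of the
#' input, sorted by (chrom, start). Under half-open coordinates abutting
#' intervals (`end == start`) do not overlap and are not merged. Ids of
#' merged intervals are concatenated with `"+"` in input order.
#'
#' @param elements Data frame of intervals (`chrom`, `start`, `end`,
#'   `element_id`, optional `element_class`).
#' @return Data frame of disjoint merged intervals.
#' @export
merge_overlapping <- function(elements) {
  if (nrow(elements) == 0L) return(elements)
  gr <- elements_granges(elements)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, red))
  ids <- vapply(seq_along(red), function(i) {
    paste(elements$element_id[S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == i]], collapse = "+")
  }, "")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    element_id = ids,
    element_class = if ("element_class" %in% names(elements))
      rep_len(elements$element_class[1L], length(red)) else NA_character_,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subdivide a long element into conserved cores
#'
#' Extracts maximal runs of bases whose per-base conservation score is
#' strictly greater than `threshold`, then merges runs separated by
#' `merge_gap` or fewer intervening bases into single elements. Used to
#' reduce long VISTA enhancers to their species-conserved cores.
#'
#' @param ve One-row data frame (or list) with `chrom`, `start`, `end`,
#'   `element_id` for the parent element (0-based half-open).
#' @param per_base_score Numeric vector of per-base scores covering the
#'   element, length `end - start`.
#' @param threshold Score threshold; bases with score strictly above it
#'   qualify (default 0.57, the mild species-conservation cutoff).
#' @param merge_gap Maximum number of intervening non-qualifying bases for
#'   two runs to be merged (default 50, inclusive: "50 bp or closer").
#' @return Data frame of conserved-core intervals (possibly zero rows), ids
#'   `"<parent>_core<k>"`.
#' @export
subdivide_ve <- function(ve, per_base_score, threshold = 0.57, merge_gap = 50L) {
  len <- ve$end - ve$start
  if (length(per_base_score) != len) {
    stop(sprintf("score vector length %d does not match element length %d",
                 length(per_base_score), len))
  }
  qual <- per_base_score > threshold
  if (!any(qual)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      element_id = character(), stringsAsFactors = FALSE))
  }
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs whose gap (bases strictly between them) is <= merge_gap
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  data.frame(
    chrom = ve$chrom,
    start = ve$start + merged$start - 1L,
    end = ve$start + merged$end,
    element_id = sprintf("%s_core%d", ve$element_id, seq_len(nrow(merged))),
    stringsAsFactors = FALSE)
}

#' Select conserved neural enhancer (CNE) candidates
#'
#' A candidate conserved segment is accepted as a CNE when it satisfies all
#' of: phastCons Viterbi log-odds strictly greater than `min_log_odds`;
#' at least 1 bp overlap with an enhancer-associated chromatin state
#' (`EnhG`, `Enh`, `EnhBiv`) in any accepted tissue; zero overlap with
#' exon/splice intervals; and a fraction of bases carrying a population
#' variant no greater than `max_variant_fraction` (multiple variants at one
#' base count once, denominator is the segment length).
#'
#' @param conserved Data frame of candidate segments with `chrom`, `start`,
#'   `end`, `element_id`, `log_odds`.
#' @param enhancer_states Data frame of chromatin-state intervals with a
#'   `score` column holding the state label and a `tissue` column.
#' @param exons Data frame of exon/splice intervals.
#' @param variant_positions Data frame with `chrom`, `pos0` (0-based) of
#'   population variants.
#' @param min_log_odds Log-odds threshold (default 400, strict).
#' @param enhancer_labels Accepted state labels.
#' @param tissues Accepted tissue tags.
#' @param max_variant_fraction Maximum variant-base fraction (default 0.02).
#' @return List with `cne` (accepted segments) and `rejections` (named
#'   counts per filter).
#' @export
define_cne <- function(conserved, enhancer_states, exons, variant_positions,
                       min_log_odds = 400,
                       enhancer_labels = c("EnhG", "Enh", "EnhBiv"),
                       tissues = c("neurospheres", "fetal_brain", "adult_brain"),
                       max_variant_fraction = 0.02) {
  if (nrow(conserved) == 0L) {
    return(list(cne = conserved, rejections = c(log_odds = 0L, chromatin = 0L,
                                                exonic = 0L, variant_density = 0L)))
  }
  gr <- elements_granges(conserved)
  pass_lod <- conserved$log_odds > min_log_odds

  enh <- enhancer_states[enhancer_states$score %in% enhancer_labels &
                           enhancer_states$tissue %in% tissues, , drop = FALSE]
  pass_enh <- if (nrow(enh)) {
    suppressWarnings(GenomicRanges::countOverlaps(
      gr, elements_granges(enh), minoverlap = 1L)) > 0L
  } else rep(FALSE, nrow(conserved))

  pass_exon <- if (nrow(exons)) {
    suppressWarnings(GenomicRanges::countOverlaps(gr, elements_granges(exons))) == 0L
  } else rep(TRUE, nrow(conserved))

  pass_var <- vapply(seq_len(nrow(conserved)), function(i) {
    el <- conserved[i, ]
    hit <- variant_positions$chrom == el$chrom &
      variant_positions$pos0 >= el$start & variant_positions$pos0 < el$end
    n_bases <- length(unique(variant_positions$pos0[hit]))
    n_bases / (el$end - el$start) <= max_variant_fraction
  }, NA)

  keep <- pass_lod & pass_enh & pass_exon & pass_var
  list(
    cne = conserved[keep, , drop = FALSE],
    rejections = c(log_odds = sum(!pass_lod),
                   chromatin = sum(!pass_enh),
                   exonic = sum(!pass_exon),
                   variant_density = sum(!pass_var)))
}

#' Label elements by gene-model context
#'
#' Elements overlapping any exon are labelled `"genic-overlap"`; elements
#' overlapping a gene span without exon overlap are `"intronic"`; all others
#' are `"intergenic"`.
#'
#' @param elements Data frame of elements.
#' @param exons Data frame of exon intervals.
#' @param gene_spans Data frame of gene-span intervals.
#' @return `elements` with an added `context` column.
#' @export
annotate_context <- function(elements, exons, gene_spans) {
  gr <- elements_granges(elements)
  in_exon <- if (nrow(exons)) {
    suppressWarnings(GenomicRanges::countOverlaps(gr, elements_granges(exons))) > 0L
  } else rep(FALSE, nrow(elements))
  in_gene <- if (nrow(gene_spans)) {
    suppressWarnings(GenomicRanges::countOverlaps(gr, elements_granges(gene_spans))) > 0L
  } else rep(FALSE, nrow(elements))
  elements$context <- ifelse(in_exon, "genic-overlap",
                             ifelse(in_gene, "intronic", "intergenic"))
  elements
}
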