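# MPRA barcode-count analysis: directional barcode error correction,
# barcodes-per-million normalization, log2(cDNA/plasmid) ratios, activity
# calls, variant-effect calls, and mutagenesis variant classification.

hamming1 <- function(a, b) {
  # both same length; TRUE when exactly one position differs
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  sum(av != bv) == 1L
}

#' Directional barcode error-correction clustering
#'
#' Implements the directional network method used for UMI error correction:
#' barcode `B` can be absorbed by barcode `A` when they differ at exactly
#' one position and `count(A) >= 2 * count(B) - 1`. Clusters are formed
#' greedily from the highest-count unassigned barcode (ties broken
#' lexicographically), following directed absorption edges transitively
#' (chains of sequencing errors collapse into one representative). Counts
#' of absorbed barcodes are added to their representative.
#'
#' @param counts Named integer vector (names are barcodes over A/C/G/T, one
#'   common length).
#' @return List with `map` (named character: barcode -> representative) and
#'   `counts` (named integer: corrected counts per representative).
#' @export
cluster_barcodes <- function(counts) {
  bcs <- names(counts)
  if (length(unique(nchar(bcs))) > 1L) stop("mixed barcode lengths")
  n <- length(bcs)
  ord <- order(-counts, bcs)
  rep_of <- setNames(rep(NA_character_, n), bcs)
  if (n == 0L) return(list(map = rep_of, counts = counts))
  # precompute Hamming-1 adjacency
  mat <- do.call(rbind, strsplit(bcs, ""))
  adj <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      i != j && sum(mat[i, ] != mat[j, ]) == 1L
    }, NA))
  })
  for (i in ord) {
    if (!is.na(rep_of[i])) next
    root <- bcs[i]
    queue <- i
    rep_of[i] <- root
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (is.na(rep_of[v]) && counts[u] >= 2L * counts[v] - 1L) {
          rep_of[v] <- root
          queue <- c(queue, v)
        }
      }
    }
  }
  corrected <- tapply(as.numeric(counts), rep_of[bcs], sum)
  list(map = rep_of, counts = setNames(as.integer(corrected), names(corrected)))
}

#' Barcodes-per-million normalization
#'
#' Scales each count column to sum to one million, removing sequencing
#' coverage bias. Scaling the input by any constant leaves the output
#' unchanged.
#'
#' @param x Numeric vector or matrix (columns are sequencing pools).
#' @return The scaled vector/matrix.
#' @export
normalize_bpm <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    totals <- colSums(x)
    if (any(totals == 0)) stop("zero column total in count table")
    sweep(x, 2L, totals, "/") * 1e6
  } else {
    total <- sum(x)
    if (total == 0) stop("zero total count")
    x / total * 1e6
  }
}

#' Per-barcode log2(cDNA/plasmid) ratios
#'
#' Normalizes the plasmid and cDNA count columns to barcodes-per-million,
#' drops barcodes absent from the plasmid pool or from any cDNA replicate
#' pool, and computes one log2(cDNA_bpm / plasmid_bpm) per barcode and
#' replicate, plus the per-barcode mean across replicates (`pooled`).
#'
#' @param records Data frame with columns `barcode`, `sequence_id`,
#'   optionally `variant_id`, `plasmid`, and cDNA replicate columns
#'   `cdna_1` .. `cdna_k`.
#' @return Data frame (`barcode`, `sequence_id`, `variant_id` if present,
#'   `log2_rep1..k`, `pooled`) with attribute `n_dropped`.
#' @export
barcode_log_ratios <- function(records) {
  cdna_cols <- grep("^cdna_", names(records), value = TRUE)
  stopifnot(length(cdna_cols) >= 1L, "plasmid" %in% names(records))
  counts <- as.matrix(records[, c("plasmid", cdna_cols)])
  bpm <- normalize_bpm(counts)
  keep <- records$plasmid > 0 & apply(records[, cdna_cols, drop = FALSE] > 0, 1L, all)
  n_dropped <- sum(!keep)
  lr <- log2(bpm[keep, cdna_cols, drop = FALSE] / bpm[keep, "plasmid"])
  colnames(lr) <- sub("^cdna_", "log2_rep", cdna_cols)
  out <- data.frame(barcode = records$barcode[keep],
                    sequence_id = records$sequence_id[keep],
                    stringsAsFactors = FALSE)
  if ("variant_id" %in% names(records)) out$variant_id <- records$variant_id[keep]
  out <- cbind(out, lr)
  out$pooled <- rowMeans(lr)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Call per-sequence enhancer activity
#'
#' Tests each sequence's per-barcode pooled log-ratios against a reference
#' distribution (by default all other sequences' barcodes in the library;
#' optionally a provided negative-control set) with the Wilcoxon rank-sum
#' test, adjusts across sequences by Benjamini-Hochberg, and flags a
#' sequence active when its adjusted p-value passes the FDR level and its
#' median exceeds the reference median. `fold_active_2x` additionally
#' requires the median to sit at least one log2 unit (2-fold) above the
#' reference median. Sequences with fewer than `min_barcodes` testable
#' barcodes are `"untestable"`.
#'
#' @param ratios Data frame from [barcode_log_ratios()].
#' @param min_barcodes Minimum barcodes per testable sequence (default 3).
#' @param reference Optional numeric vector of negative-control pooled
#'   log-ratios; default uses all other sequences' barcodes.
#' @param fdr_level FDR level (default 0.05).
#' @return Data frame with `sequence_id`, `n_barcodes`, `median_log2`,
#'   `p`, `p_adj`, `status` (`active`/`inactive`/`untestable`),
#'   `fold_active_2x`.
#' @export
call_activity <- function(ratios, min_barcodes = 3L, reference = NULL,
                          fdr_level = 0.05) {
  seqs <- unique(ratios$sequence_id)
  res <- lapply(seqs, function(sid) {
    own <- ratios$pooled[ratios$sequence_id == sid]
    ref <- if (is.null(reference)) {
      ratios$pooled[ratios$sequence_id != sid]
    } else reference
    if (length(own) < min_barcodes || length(ref) < min_barcodes) {
      return(data.frame(sequence_id = sid, n_barcodes = length(own),
                        median_log2 = stats::median(own), ref_median = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(own, ref, exact = FALSE,
                                             correct = TRUE)$p.value)
    data.frame(sequence_id = sid, n_barcodes = length(own),
               median_log2 = stats::median(own),
               ref_median = stats::median(ref), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$status <- ifelse(is.na(res$p), "untestable",
                ifelse(res$p_adj <= fdr_level & res$median_log2 > res$ref_median,
                       "active", "inactive"))
  res$fold_active_2x <- res$status == "active" &
    !is.na(res$ref_median) & (res$median_log2 - res$ref_median) >= 1
  res
}

#' Element-level activity from per-sequence calls
#'
#' An element is active if at least one of its sequences (probes) is
#' active; inactive if all testable sequences are inactive; `"untested"`
#' when it has no testable sequence.
#'
#' @param seq_map Data frame with `element_id`, `sequence_id` (each sequence
#'   maps to at most one element).
#' @param calls Data frame from [call_activity()].
#' @return Data frame with `element_id`, `status`.
#' @export
element_activity <- function(seq_map, calls) {
  st <- setNames(calls$status, calls$sequence_id)
  rows <- lapply(split(seq_map$sequence_id, seq_map$element_id), function(sids) {
    s <- st[intersect(sids, names(st))]
    if (length(s) == 0L || all(s == "untestable")) "untested"
    else if (any(s == "active")) "active"
    else "inactive"
  })
  data.frame(element_id = names(rows), status = unlist(rows),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variant-effect calls from matched with/without-variant sequences
#'
#' A variant modulates enhancer activity when the sequence containing the
#' variant site (with or without the variant) has significant enhancer
#' activity AND the rank-sum comparison between the with- and
#' without-variant barcode log-ratio sets passes the FDR level after
#' Benjamini-Hochberg adjustment across variants. Direction is the sign of
#' the median difference (with minus without). Pairs with an untestable
#' side are `"untestable"`.
#'
#' @param pairs Data frame with `variant_id`, `seq_with`, `seq_without`.
#' @param ratios Data frame from [barcode_log_ratios()].
#' @param calls Data frame from [call_activity()].
#' @param fdr_level FDR level (default 0.05).
#' @return Data frame with `variant_id`, `call` (`modulating`,
#'   `not_modulating`, `untestable`), `direction` (`increase`/`decrease`/
#'   `none`), `log2_fold_change`, `p`, `p_adj`.
#' @export
variant_effect <- function(pairs, ratios, calls, fdr_level = 0.05) {
  st <- setNames(calls$status, calls$sequence_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    vw <- ratios$pooled[ratios$sequence_id == pairs$seq_with[i]]
    vo <- ratios$pooled[ratios$sequence_id == pairs$seq_without[i]]
    s_w <- st[pairs$seq_with[i]]
    s_o <- st[pairs$seq_without[i]]
    untestable <- is.na(s_w) || is.na(s_o) ||
      s_w == "untestable" || s_o == "untestable"
    p <- if (untestable) NA_real_ else {
      suppressWarnings(stats::wilcox.test(vw, vo, exact = FALSE)$p.value)
    }
    data.frame(variant_id = pairs$variant_id[i],
               either_active = !untestable && (s_w == "active" || s_o == "active"),
               untestable = untestable,
               log2_fold_change = stats::median(vw) - stats::median(vo),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$call <- ifelse(res$untestable, "untestable",
              ifelse(res$either_active & !is.na(res$p_adj) &
                       res$p_adj <= fdr_level, "modulating", "not_modulating"))
  res$direction <- ifelse(res$call == "modulating",
                          ifelse(res$log2_fold_change > 0, "increase", "decrease"),
                          "none")
  res[, c("variant_id", "call", "direction", "log2_fold_change", "p", "p_adj")]
}

#' Classify random-mutagenesis variants by activity effect
#'
#' For capture-based mutagenesis libraries: barcodes whose introduced
#' variants all fall in the flanking sequence are excluded; per variant,
#' the mutant barcode log-ratios are compared to the probe's wild-type
#' barcode log-ratios by rank-sum, adjusted by Benjamini-Hochberg, with
#' direction by median difference. Optionally restricted to barcodes
#' carrying a single introduced variant.
#'
#' @param assoc Association table: `barcode`, `probe_id`, `variant_ids`
#'   (comma-separated), `flank_only` (logical).
#' @param mutant_ratios Data frame (`barcode`, `pooled`) of mutant barcode
#'   log-ratios.
#' @param wt_ratios Data frame (`probe_id`, `pooled`) of wild-type barcode
#'   log-ratios per probe.
#' @param single_variant_only Keep only single-variant barcodes?
#' @param fdr_level FDR level (default 0.05).
#' @return Data frame with `variant_id`, `probe_id`, `n_barcodes`, `call`
#'   (`increase`/`decrease`/`no_change`/`untestable`), `p`, `p_adj`.
#' @export
mutagenesis_classify <- function(assoc, mutant_ratios, wt_ratios,
                                 single_variant_only = FALSE,
                                 fdr_level = 0.05) {
  assoc <- assoc[!assoc$flank_only, , drop = FALSE]
  vl <- strsplit(assoc$variant_ids, ",", fixed = TRUE)
  if (single_variant_only) {
    keep <- lengths(vl) == 1L
    assoc <- assoc[keep, , drop = FALSE]
    vl <- vl[keep]
  }
  long <- data.frame(barcode = rep(assoc$barcode, lengths(vl)),
                     probe_id = rep(assoc$probe_id, lengths(vl)),
                     variant_id = unlist(vl), stringsAsFactors = FALSE)
  mr <- setNames(mutant_ratios$pooled, mutant_ratios$barcode)
  rows <- lapply(split(long, long$variant_id), function(g) {
    mut <- mr[g$barcode]
    mut <- mut[!is.na(mut)]
    wt <- wt_ratios$pooled[wt_ratios$probe_id == g$probe_id[1L]]
    if (length(mut) == 0L || length(wt) == 0L) {
      return(data.frame(variant_id = g$variant_id[1L], probe_id = g$probe_id[1L],
                        n_barcodes = length(mut), delta = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(mut, wt, exact = FALSE)$p.value)
    data.frame(variant_id = g$variant_id[1L], probe_id = g$probe_id[1L],
               n_barcodes = length(mut),
               delta = stats::median(mut) - stats::median(wt), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$call <- ifelse(is.na(res$p), "untestable",
              ifelse(res$p_adj <= fdr_level,
                     ifelse(res$delta > 0, "increase", "decrease"),
                     "no_change"))
  rownames(res) <- NULL
  res[, c("variant_id", "probe_id", "n_barcodes", "call", "delta", "p", "p_adj")]
}
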