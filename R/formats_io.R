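# Internal coordinate convention: 0-based half-open everywhere. BED is read
# as-is; VCF and score tables (1-based) are converted at parse time.

#' Read a BED file of genomic elements
#'
#' Reads a 3+ column BED file into a data frame of elements with BED's
#' 0-based half-open coordinates preserved. The optional 4th column becomes
#' the element id; for 3-column lines an id of the form `"chrom:start-end"`
#' is synthesized. A 5th column, when present, is kept as `score`/state
#' payload and a 6th as `tissue` (used for ChromHMM state tracks).
#'
#' @param path Path to a BED file.
#' @param element_class Optional class label recycled across all intervals
#'   (e.g. `"HAR"`, `"VE"`, `"CNE"`).
#' @return A data frame with columns `chrom`, `start`, `end`, `element_id`,
#'   `element_class`, and any extra payload columns.
#' @export
read_bed <- function(path, element_class = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      element_id = character(),
                      element_class = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3L)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns", bad[1L]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates", bad[1L]))
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end or negative start",
                 bad[1L]))
  }
  id <- ifelse(n_col >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               sprintf("%s:%d-%d", chrom, start, end))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    element_id = id,
                    element_class = rep_len(element_class, length(chrom)),
                    stringsAsFactors = FALSE)
  if (any(n_col >= 5L)) {
    out$score <- ifelse(n_col >= 5L,
                        vapply(fields, function(f) if (length(f) >= 5L) f[5L] else NA_character_, ""),
                        NA_character_)
  }
  if (any(n_col >= 6L)) {
    out$tissue <- ifelse(n_col >= 6L,
                         vapply(fields, function(f) if (length(f) >= 6L) f[6L] else NA_character_, ""),
                         NA_character_)
  }
  out
}

#' Write elements back to BED
#'
#' @param elements Data frame as returned by [read_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(elements, path) {
  df <- elements[, c("chrom", "start", "end", "element_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Map one VCF GT string (possibly haploid) to the internal genotype code.
gt_code <- function(gt, allele_index, haploid_male_x = FALSE) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return("missing")
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a)) return("missing")
  n_alt <- sum(a == allele_index)
  if (length(a) == 1L) {
    # haploid call (male X)
    if (n_alt == 1L) return("hemi_alt")
    return("hemi_ref")
  }
  if (n_alt == 2L) return("homalt")
  if (n_alt == 1L) return("het")
  "homref"
}

#' Read a VCF into a variant-set container
#'
#' Parses a VCF 4.x file (via the \pkg{vcfR} parser) into a `variant_set`:
#' a site table plus per-sample genotype, alt-supporting depth (AD), total
#' depth (DP), and genotype quality (GQ) matrices. Multiallelic records are
#' decomposed into one site per alt allele with per-allele AD; genotypes
#' carrying a different alt allele count as reference-carrying for the
#' decomposed site. Haploid genotypes (male chrX) map to
#' `hemi_ref`/`hemi_alt`. The site allele frequency is taken from INFO/AF
#' when present, otherwise estimated from founder genotypes (all samples if
#' no pedigree is supplied).
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param sample_subset Optional character vector of sample ids to keep.
#' @param ped Optional pedigree data frame (see [read_ped()]); founders
#'   (individuals without recorded parents) back the AF estimate.
#' @return An object of class `variant_set`: a list with `sites` (data frame
#'   with `chrom`, `pos`, `pos0`, `ref`, `alt`, `af`, `filter`), `gt`, `ad_alt`,
#'   `dp`, `gq` (sites x samples matrices), and `samples`.
#' @export
read_vcf <- function(path, sample_subset = NULL, ped = NULL) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fmt_ids <- unique(unlist(strsplit(unname(v@gt[, "FORMAT"]), ":", fixed = TRUE)))
  if (!"GT" %in% fmt_ids) stop("VCF format error: no GT field")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- if ("AD" %in% fmt_ids) vcfR::extract.gt(v, element = "AD") else NULL
  dp_raw <- if ("DP" %in% fmt_ids) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE) else NULL
  gq_raw <- if ("GQ" %in% fmt_ids) vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE) else NULL
  samples <- colnames(gt_raw)
  if (!is.null(sample_subset)) {
    keep <- samples %in% sample_subset
    gt_raw <- gt_raw[, keep, drop = FALSE]
    if (!is.null(ad_raw)) ad_raw <- ad_raw[, keep, drop = FALSE]
    if (!is.null(dp_raw)) dp_raw <- dp_raw[, keep, drop = FALSE]
    if (!is.null(gq_raw)) gq_raw <- gq_raw[, keep, drop = FALSE]
    samples <- samples[keep]
  }
  info_af <- vcfR::extract.info(v, element = "AF")

  founders <- samples
  if (!is.null(ped)) {
    f <- ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
    if (length(intersect(f, samples)) > 0L) founders <- intersect(f, samples)
  }

  n_rec <- nrow(fix)
  site_rows <- list()
  gt_rows <- list()
  ad_rows <- list()
  dp_rows <- list()
  gq_rows <- list()
  k <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    ad_i <- if (!is.null(ad_raw)) {
      lapply(strsplit(ad_raw[i, ], ",", fixed = TRUE),
             function(x) suppressWarnings(as.integer(x)))
    } else NULL
    af_i <- if (!is.na(info_af[i])) {
      suppressWarnings(as.numeric(strsplit(info_af[i], ",", fixed = TRUE)[[1L]]))
    } else NULL
    for (j in seq_along(alts)) {
      k <- k + 1L
      gts <- vapply(gt_raw[i, ], gt_code, "", allele_index = j)
      ad_alt <- if (!is.null(ad_i)) {
        vapply(ad_i, function(x) {
          if (length(x) >= j + 1L && !is.na(x[j + 1L])) x[j + 1L] else NA_integer_
        }, 1L)
      } else rep(NA_integer_, length(gts))
      af <- if (!is.null(af_i) && length(af_i) >= j && !is.na(af_i[j])) {
        af_i[j]
      } else {
        founder_af(gts[founders])
      }
      site_rows[[k]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[j], af = af,
        filter = ifelse(is.na(fix[i, "FILTER"]), "PASS", fix[i, "FILTER"]),
        stringsAsFactors = FALSE)
      gt_rows[[k]] <- gts
      ad_rows[[k]] <- ad_alt
      dp_rows[[k]] <- if (!is.null(dp_raw)) as.integer(dp_raw[i, ]) else rep(NA_integer_, length(gts))
      gq_rows[[k]] <- if (!is.null(gq_raw)) as.integer(gq_raw[i, ]) else rep(NA_integer_, length(gts))
    }
  }
  sites <- do.call(rbind, site_rows)
  sites$pos0 <- sites$pos - 1L
  vs <- list(
    sites = sites,
    gt = do.call(rbind, gt_rows),
    ad_alt = do.call(rbind, ad_rows),
    dp = do.call(rbind, dp_rows),
    gq = do.call(rbind, gq_rows),
    samples = samples)
  dimnames(vs$gt) <- list(NULL, samples)
  dimnames(vs$ad_alt) <- dimnames(vs$dp) <- dimnames(vs$gq) <- dimnames(vs$gt)
  class(vs) <- "variant_set"
  vs
}

# Allele frequency from founder genotype codes (alt alleles / called alleles).
founder_af <- function(gts) {
  n_alt <- sum(c(homalt = 2, het = 1, hemi_alt = 1)[gts], na.rm = TRUE)
  n_all <- sum(c(homref = 2, het = 2, homalt = 2, hemi_ref = 1, hemi_alt = 1)[gts],
               na.rm = TRUE)
  if (n_all == 0L) return(NA_real_)
  n_alt / n_all
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited columns: family, individual, father, mother,
#' sex (1 = male, 2 = female, else unknown), phenotype (2 = case,
#' 1 = control, else unknown). `"0"` parent entries become `NA`.
#'
#' @param path Path to a PED file.
#' @return Data frame with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`/`"female"`/`"unknown"`), `affected`
#'   (`"case"`/`"control"`/`"unknown"`).
#' @export
read_ped <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family_id", "individual_id",
                                        "father_id", "mother_id", "sex", "phenotype"),
                          colClasses = "character")
  if (anyDuplicated(df$individual_id)) {
    stop("pedigree error: duplicate individual id")
  }
  df$father_id[df$father_id == "0"] <- NA_character_
  df$mother_id[df$mother_id == "0"] <- NA_character_
  orphan <- setdiff(stats::na.omit(c(df$father_id, df$mother_id)), df$individual_id)
  if (length(orphan)) {
    stop(sprintf("pedigree error: parent '%s' not present in pedigree", orphan[1L]))
  }
  df$sex <- c(`1` = "male", `2` = "female")[df$sex]
  df$sex[is.na(df$sex)] <- "unknown"
  df$affected <- c(`2` = "case", `1` = "control")[df$phenotype]
  df$affected[is.na(df$affected)] <- "unknown"
  df$phenotype <- NULL
  df
}

#' Read a per-base annotation/score table
#'
#' Headered TSV keyed by `chrom`, `pos` (1-based) with predictor scores
#' (`gerp`, `cadd`, `dann`, `fathmmnc`) and region-context flags (`in_exon`,
#' `in_utr`, `in_promoter_or_1kb_tss`, `in_phastcons_element`).
#'
#' @param path Path to the TSV.
#' @return Data frame with one row per position and an added `pos0` column;
#'   duplicate `(chrom, pos)` keys are an error.
#' @export
read_scores <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    stop(sprintf("score table error: duplicate position %s",
                 key[duplicated(key)][1L]))
  }
  df$pos0 <- df$pos - 1L
  flag_cols <- intersect(c("in_exon", "in_utr", "in_promoter_or_1kb_tss",
                           "in_phastcons_element"), names(df))
  for (cn in flag_cols) df[[cn]] <- as.logical(df[[cn]])
  df
}

#' Write a result table as deterministic TSV
#'
#' Emits a headered, tab-delimited, newline-terminated file with the column
#' order of the input data frame. An optional comment header (e.g. config
#' hash and seed) is prepended as `#`-prefixed lines.
#'
#' @param rows Data frame to write.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (without `#`).
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, comment = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

# elements data frame -> GRanges (0-based half-open -> 1-based closed)
elements_granges <- function(elements) {
  GenomicRanges::GRanges(
    seqnames = elements$chrom,
    ranges = IRanges::IRanges(start = elements$start + 1L, end = elements$end),
    element_id = elements$element_id)
}

# site positions -> GRanges of width 1 (pos is 1-based VCF convention)
sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
}
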