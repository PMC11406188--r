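# Recessive event detection: homozygous, transmission-phased compound
# heterozygous, and male-X hemizygous genotypes, with the autosome/X
# conventions (X events enter only sex-stratified analyses).

CARRIER_GT <- c("het", "homalt", "hemi_alt")
NONCARRIER_GT <- c("homref", "hemi_ref")

#' Phase heterozygous child genotypes by transmission
#'
#' Deterministic pedigree-based phasing: a heterozygous child variant is
#' assigned a parental origin when exactly one parent carries the alternate
#' allele. Double-carrier parents, apparent de novo configurations (neither
#' parent carries), and missing parent genotypes are `"ambiguous"`.
#' Non-heterozygous child genotypes are `"untransmitted"` (no single-parent
#' origin to assign), except that a Mendelian impossibility (child
#' homozygous-alt with a homozygous-reference parent) is flagged and
#' returned as `"ambiguous"`.
#'
#' @param child,father,mother Genotype codes (vectors of equal length) in
#'   `homref`, `het`, `homalt`, `hemi_ref`, `hemi_alt`, `missing`.
#' @return Character vector of origins (`paternal`, `maternal`, `ambiguous`,
#'   `untransmitted`) with a logical attribute `mendelian_violation`.
#' @export
phase_by_transmission <- function(child, father, mother) {
  n <- length(child)
  stopifnot(length(father) == n, length(mother) == n)
  f_car <- father %in% CARRIER_GT
  m_car <- mother %in% CARRIER_GT
  f_non <- father %in% NONCARRIER_GT
  m_non <- mother %in% NONCARRIER_GT
  viol <- child == "homalt" & (father == "homref" | mother == "homref")
  origin <- rep("untransmitted", n)
  origin[viol] <- "ambiguous"
  is_het <- child == "het"
  origin[is_het] <- "ambiguous"
  origin[is_het & f_car & m_non] <- "paternal"
  origin[is_het & m_car & f_non] <- "maternal"
  attr(origin, "mendelian_violation") <- viol
  origin
}

is_chrx <- function(chrom) chrom %in% c("chrX", "X")

#' Call qualifying recessive events per individual per element
#'
#' Detects, among QC'd, classified sites below the allele-frequency cutoff:
#' (1) homozygous-alt genotypes (`homozygous`); (2) male-X hemizygous-alt
#' genotypes (`hemizygous`); (3) compound-heterozygous pairs: two or more
#' heterozygous sites in the same element with at least one paternal and one
#' maternal transmission-phased origin yield one `compound_het` event (the
#' first in-trans pair by position); in-cis or ambiguous-phase pairs yield
#' no event. One event per individual, element and kind. Each event carries
#' `chrom_class` (`autosome`/`chrX`) so downstream tables can apply the
#' combined-sex autosome-only convention.
#'
#' @param vs A classified `variant_set` (see [classify_variant_set()]).
#' @param elements Element data frame (`chrom`, `start`, `end`, `element_id`).
#' @param ped Pedigree from [read_ped()].
#' @param af_cutoff Allele-frequency cutoff; sites with `af < af_cutoff` keep.
#' @param class_filter Site class to use (`"damaging_conserved"` or
#'   `"neutral"`).
#' @return Data frame of events (`individual_id`, `element_id`, `kind`,
#'   `chrom_class`, `variants`, `origins`) with attribute
#'   `n_ambiguous_pairs`, the count of multi-het individuals x elements
#'   dropped for lacking an in-trans phase.
#' @export
call_recessive_events <- function(vs, elements, ped, af_cutoff,
                                  class_filter = "damaging_conserved") {
  stopifnot(!is.null(vs$sites$class))
  keep <- vs$sites$class == class_filter & !is.na(vs$sites$af) &
    vs$sites$af < af_cutoff
  sites <- vs$sites[keep, , drop = FALSE]
  empty <- data.frame(individual_id = character(), element_id = character(),
                      kind = character(), chrom_class = character(),
                      variants = character(), origins = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) {
    attr(empty, "n_ambiguous_pairs") <- 0L
    return(empty)
  }
  gt <- vs$gt[keep, , drop = FALSE]
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sites_granges(sites),
                                elements_granges(elements)))
  site_idx <- S4Vectors::queryHits(hits)
  elem_id <- elements$element_id[S4Vectors::subjectHits(hits)]
  ped_idx <- match(colnames(gt), ped$individual_id)
  sex <- ped$sex[ped_idx]
  father <- ped$father_id[ped_idx]
  mother <- ped$mother_id[ped_idx]
  xcls_site <- ifelse(is_chrx(sites$chrom), "chrX", "autosome")
  vlab_site <- sprintf("%s:%d:%s>%s", sites$chrom, sites$pos,
                       sites$ref, sites$alt)

  # expand one row per (site-in-element, sample) for a given genotype code
  events_for <- function(code) {
    w <- which(gt == code, arr.ind = TRUE)
    if (nrow(w) == 0L) return(NULL)
    hit_rows <- lapply(w[, "row"], function(r) which(site_idx == r))
    rep_n <- lengths(hit_rows)
    df <- data.frame(site = rep(w[, "row"], rep_n),
                     sample = rep(w[, "col"], rep_n),
                     element_id = elem_id[unlist(hit_rows)],
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L) NULL else df
  }

  out <- list()
  hom <- events_for("homalt")
  if (!is.null(hom)) {
    hom <- hom[order(sites$chrom[hom$site], sites$pos[hom$site]), ]
    hom <- hom[!duplicated(hom[, c("sample", "element_id")]), ]
    out[[length(out) + 1L]] <- data.frame(
      individual_id = colnames(gt)[hom$sample], element_id = hom$element_id,
      kind = "homozygous", chrom_class = xcls_site[hom$site],
      variants = vlab_site[hom$site], origins = "biparental",
      stringsAsFactors = FALSE)
  }
  hemi <- events_for("hemi_alt")
  if (!is.null(hemi)) {
    hemi <- hemi[xcls_site[hemi$site] == "chrX" &
                   !is.na(sex[hemi$sample]) & sex[hemi$sample] == "male", ,
                 drop = FALSE]
    hemi <- hemi[order(sites$pos[hemi$site]), , drop = FALSE]
    hemi <- hemi[!duplicated(hemi[, c("sample", "element_id")]), , drop = FALSE]
    if (nrow(hemi)) {
      out[[length(out) + 1L]] <- data.frame(
        individual_id = colnames(gt)[hemi$sample], element_id = hemi$element_id,
        kind = "hemizygous", chrom_class = "chrX",
        variants = vlab_site[hemi$site], origins = "maternal",
        stringsAsFactors = FALSE)
    }
  }
  n_ambig <- 0L
  het <- events_for("het")
  if (!is.null(het)) {
    key <- paste(het$sample, het$element_id)
    multi <- names(which(table(key) >= 2L))
    for (k in multi) {
      grp <- het[key == k, , drop = FALSE]
      s <- grp$sample[1L]
      si <- grp$site[order(sites$chrom[grp$site], sites$pos[grp$site])]
      has_parents <- !is.na(father[s]) && !is.na(mother[s]) &&
        father[s] %in% colnames(gt) && mother[s] %in% colnames(gt)
      if (!has_parents) {
        n_ambig <- n_ambig + 1L
        next
      }
      orig <- phase_by_transmission(gt[si, s], gt[si, father[s]],
                                    gt[si, mother[s]])
      pat <- which(orig == "paternal")
      mat <- which(orig == "maternal")
      if (length(pat) && length(mat)) {
        pair <- sort(c(si[pat[1L]], si[mat[1L]]))
        out[[length(out) + 1L]] <- data.frame(
          individual_id = colnames(gt)[s], element_id = grp$element_id[1L],
          kind = "compound_het", chrom_class = xcls_site[pair[1L]],
          variants = paste(vlab_site[pair], collapse = ","),
          origins = paste(orig[match(pair, si)], collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        n_ambig <- n_ambig + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "n_ambiguous_pairs") <- n_ambig
  res
}

#' Build the 2x2 carrier table
#'
#' Counts individuals carrying at least one qualifying recessive event:
#' `a` = cases with events, `b` = cases without, `c` = controls with,
#' `d` = controls without. Each individual is counted once regardless of
#' event multiplicity. With `sex_filter = "both"` only autosomal events
#' qualify; `"male"`/`"female"` restrict to that sex and additionally admit
#' chrX events (male hemizygous, female homozygous). Individuals with
#' unknown affection status are excluded (count reported as an attribute).
#'
#' @param events Event data frame from [call_recessive_events()].
#' @param ped Pedigree data frame.
#' @param sex_filter `"both"`, `"male"` or `"female"`.
#' @param samples Optional vector restricting eligibility to genotyped
#'   individuals.
#' @return Named integer vector `c(a, b, c, d)` with attribute
#'   `n_unknown_affection`.
#' @export
carrier_table <- function(events, ped, sex_filter = c("both", "male", "female"),
                          samples = NULL) {
  sex_filter <- match.arg(sex_filter)
  eligible <- ped
  if (!is.null(samples)) eligible <- eligible[eligible$individual_id %in% samples, ]
  n_unknown <- sum(eligible$affected == "unknown")
  eligible <- eligible[eligible$affected %in% c("case", "control"), , drop = FALSE]
  if (sex_filter != "both") {
    eligible <- eligible[eligible$sex == sex_filter, , drop = FALSE]
  }
  ev <- events
  if (sex_filter == "both") {
    ev <- ev[ev$chrom_class == "autosome", , drop = FALSE]
  }
  carriers <- unique(ev$individual_id)
  is_case <- eligible$affected == "case"
  has_ev <- eligible$individual_id %in% carriers
  out <- c(a = sum(is_case & has_ev), b = sum(is_case & !has_ev),
           c = sum(!is_case & has_ev), d = sum(!is_case & !has_ev))
  attr(out, "n_unknown_affection") <- n_unknown
  out
}
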