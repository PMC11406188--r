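# In-code fixtures and independent oracles shared across test files.

# Minimal variant_set builder: sites is a data.frame with chrom/pos/ref/alt/af
# (+ optional class); gt is a sites x samples character matrix. QC fields
# default to passing values.
make_variant_set <- function(sites, gt, ad_alt = NULL, dp = NULL, gq = NULL,
                             filter = "PASS") {
  n <- nrow(sites)
  m <- ncol(gt)
  if (is.null(sites$filter)) sites$filter <- filter
  sites$pos0 <- sites$pos - 1L
  alt_carrying <- matrix(gt %in% c("het", "homalt", "hemi_alt"), n, m)
  structure(list(
    sites = sites,
    gt = gt,
    ad_alt = if (is.null(ad_alt)) matrix(ifelse(alt_carrying, 15L, 0L), n, m,
                                         dimnames = dimnames(gt)) else ad_alt,
    dp = if (is.null(dp)) matrix(30L, n, m, dimnames = dimnames(gt)) else dp,
    gq = if (is.null(gq)) matrix(99L, n, m, dimnames = dimnames(gt)) else gq,
    samples = colnames(gt)), class = "variant_set")
}

make_ped <- function(ids, father = NA, mother = NA, sex = "male",
                     affected = "control", family = "F1") {
  data.frame(family_id = rep_len(family, length(ids)), individual_id = ids,
             father_id = rep_len(father, length(ids)),
             mother_id = rep_len(mother, length(ids)),
             sex = rep_len(sex, length(ids)),
             affected = rep_len(affected, length(ids)),
             stringsAsFactors = FALSE)
}

# ---- independent oracles ---------------------------------------------------

# per-base bitmap union of intervals on one chromosome (merge oracle)
coverage_bitmap <- function(intervals, max_bp = 10000L) {
  bm <- logical(max_bp)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$end[i] > intervals$start[i]) {
      bm[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
    }
  }
  bm
}

# brute-force run extraction + gap merging (subdivide oracle)
runs_oracle <- function(scores, threshold, merge_gap) {
  qual <- which(scores > threshold)
  if (length(qual) == 0L) return(matrix(numeric(), ncol = 2L))
  segs <- list(c(qual[1L], qual[1L]))
  for (q in qual[-1L]) {
    last <- segs[[length(segs)]]
    if (q - last[2L] - 1L <= merge_gap) {
      segs[[length(segs)]][2L] <- q
    } else {
      segs[[length(segs) + 1L]] <- c(q, q)
    }
  }
  do.call(rbind, segs)
}

# exhaustive trio transmission oracle for a single heterozygous child site
phase_oracle_single <- function(child, father, mother) {
  carries <- function(g) g %in% c("het", "homalt", "hemi_alt")
  absent <- function(g) g %in% c("homref", "hemi_ref")
  if (child != "het") {
    if (child == "homalt" && (father == "homref" || mother == "homref")) {
      return("ambiguous")
    }
    return("untransmitted")
  }
  if (carries(father) && absent(mother)) return("paternal")
  if (carries(mother) && absent(father)) return("maternal")
  "ambiguous"
}

# brute-force compound-het oracle over full trio configurations:
# per site, the set of possible origins of the child's alt allele is derived
# from parental carrier status (sites with no consistent origin are dropped);
# an event is real iff every selection from the per-site origin sets contains
# both a paternal and a maternal origin.
comphet_oracle <- function(child, father, mother) {
  carries <- function(g) g %in% c("het", "homalt", "hemi_alt")
  missing_g <- function(g) g == "missing"
  origin_sets <- list()
  for (i in seq_along(child)) {
    if (child[i] != "het") next
    if (missing_g(father[i]) || missing_g(mother[i])) {
      # missing-data contract: an ungenotyped parent leaves the origin open
      origin_sets[[length(origin_sets) + 1L]] <- c("P", "M")
      next
    }
    s <- character()
    if (carries(father[i])) s <- c(s, "P")
    if (carries(mother[i])) s <- c(s, "M")
    if (length(s) == 0L) next # apparent de novo: uninformative
    origin_sets[[length(origin_sets) + 1L]] <- s
  }
  if (length(origin_sets) < 2L) return(FALSE)
  combos <- expand.grid(origin_sets, stringsAsFactors = FALSE)
  all(apply(combos, 1L, function(sel) "P" %in% sel && "M" %in% sel))
}

# brute-force directional clustering oracle (independent recursive BFS over
# an explicit Hamming-distance matrix; for small barcode sets)
cluster_oracle <- function(counts) {
  bcs <- names(counts)
  n <- length(bcs)
  hd <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    sum(strsplit(bcs[i], "")[[1L]] != strsplit(bcs[j], "")[[1L]])
  }))
  assigned <- rep(NA_character_, n)
  # order: by decreasing count, ties lexicographic
  ord <- seq_len(n)[order(-counts, bcs)]
  for (i in ord) {
    if (!is.na(assigned[i])) next
    assigned[i] <- bcs[i]
    frontier <- i
    repeat {
      nxt <- integer()
      for (u in frontier) {
        for (v in seq_len(n)) {
          if (is.na(assigned[v]) && hd[u, v] == 1L &&
              counts[u] >= 2L * counts[v] - 1L) {
            assigned[v] <- bcs[i]
            nxt <- c(nxt, v)
          }
        }
      }
      if (length(nxt) == 0L) break
      frontier <- nxt
    }
  }
  stats::setNames(assigned, bcs)
}

# exact rank-sum p-value by enumeration of all group assignments (small n)
ranksum_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  ws <- apply(combos, 2L, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mu <- n * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

random_barcode_counts <- function(n, len = 4L, max_count = 120L) {
  bcs <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")))
  stats::setNames(sample.int(max_count, length(bcs), replace = TRUE), bcs)
}
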