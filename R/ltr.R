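#' Deduplicate LTRs to one anchor per integration
#'
#' Per genomic integration: when both the 5' and 3' LTR are present only the
#' 5' LTR is represented; single-LTR integrations and orphan LTRs are kept
#' as-is. The anchor position is the strand-aware 5' boundary of the kept
#' LTR: its start on the plus strand, its end on the minus strand (0-based
#' coordinates).
#'
#' @param annotation a [RepeatAnnotation-class].
#' @param families optional character; restrict to these families.
#' @return data.frame with one row per anchor: `chrom`, `position` (0-based
#'   strand-aware 5' boundary), `strand`, `family`, `integration_id`, and the
#'   kept LTR interval `start`, `end` (0-based half-open).
#' @export
dedupLtrs <- function(annotation, families = NULL) {
  stopifnot(is(annotation, "RepeatAnnotation"))
  gr <- annotationRanges(annotation)
  mc <- mcols(gr)
  is_ltr <- mc$role %in% c("LTR5", "LTR3", "orphanLTR")
  gr <- gr[is_ltr]
  mc <- mcols(gr)
  if (!is.null(families)) {
    keep <- mc$family %in% families
    gr <- gr[keep]; mc <- mcols(gr)
  }
  if (length(gr) == 0L) {
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(), family = character(),
                      integration_id = character(),
                      start = integer(), end = integer()))
  }
  idx_by_int <- split(seq_along(gr), mc$integration_id)
  kept <- vapply(idx_by_int, function(ii) {
    roles <- mc$role[ii]
    if (sum(roles == "LTR5") > 1L) {
      stopf("integration '%s' carries two 5' LTR records",
            mc$integration_id[ii[1L]])
    }
    if (any(roles == "LTR5")) ii[which(roles == "LTR5")[1L]] else ii[1L]
  }, integer(1))
  kept <- sort(unname(kept))
  g <- gr[kept]
  st0 <- start(g) - 1L                    # 0-based start
  en0 <- end(g)                           # 0-based half-open end
  pos <- ifelse(as.character(strand(g)) == "-", en0, st0)
  data.frame(chrom = as.character(seqnames(g)), position = pos,
             strand = as.character(strand(g)),
             family = mcols(g)$family,
             integration_id = mcols(g)$integration_id,
             start = st0, end = en0)
}

# Per-base coverage is a named list (one numeric vector per chromosome);
# element p of a vector is the signal on 0-based base p-1.
assertCoverage <- function(coverage, chroms) {
  miss <- setdiff(chroms, names(coverage))
  if (length(miss)) {
    stopf("coverage lacks chromosome(s): %s", paste(miss, collapse = ", "))
  }
}

#' Build an LTR-anchored coverage profile matrix
#'
#' For each anchor, averages per-base coverage in fixed-width bins across the
#' window `[-window_up, +window_down)` in strand orientation (minus-strand
#' windows are reflected so "upstream" is biological upstream). Bins reaching
#' past a chromosome end are masked as `NA`, never zero-filled. Rows are
#' ordered by descending row mean.
#'
#' @param coverage named list of per-base numeric vectors, one per chromosome.
#' @param anchors data.frame from [dedupLtrs()].
#' @param window_up,window_down window extent in bp (defaults 1500/8000).
#' @param bin_size bin width in bp; must divide the window span.
#' @param sort_rows order rows by descending mean (default) or keep anchor
#'   order.
#' @return a [ProfileMatrix-class].
#' @export
buildProfileMatrix <- function(coverage, anchors, window_up = 1500L,
                               window_down = 8000L, bin_size = 50L,
                               sort_rows = TRUE) {
  if (window_up <= 0 || window_down <= 0 || bin_size <= 0) {
    stopf("window_up, window_down and bin_size must be positive")
  }
  span <- window_up + window_down
  if (span %% bin_size != 0) {
    stopf("window span %d not divisible by bin_size %d", span, bin_size)
  }
  assertCoverage(coverage, unique(anchors$chrom))
  n_bins <- span %/% bin_size
  offsets <- seq.int(-window_up, window_down - 1L)   # biological coords
  binof <- rep(seq_len(n_bins), each = bin_size)
  vals <- matrix(NA_real_, nrow(anchors), n_bins)
  for (i in seq_len(nrow(anchors))) {
    cov <- coverage[[anchors$chrom[i]]]
    # anchor base: first biological base of the LTR
    a0 <- if (anchors$strand[i] == "-") anchors$position[i] - 1L
          else anchors$position[i]
    g <- if (anchors$strand[i] == "-") a0 - offsets else a0 + offsets
    per_base <- rep(NA_real_, span)
    inside <- g >= 0L & g < length(cov)
    per_base[inside] <- cov[g[inside] + 1L]
    vals[i, ] <- tapply(per_base, binof, function(v) {
      if (anyNA(v)) NA_real_ else mean(v)
    })
  }
  ord <- seq_len(nrow(anchors))
  if (sort_rows && nrow(anchors) > 1L) {
    ord <- order(rowMeans(vals, na.rm = TRUE), decreasing = TRUE)
  }
  new("ProfileMatrix", values = vals[ord, , drop = FALSE],
      anchors = anchors[ord, , drop = FALSE],
      windowUp = as.integer(window_up), windowDown = as.integer(window_down),
      binSize = as.integer(bin_size))
}

#' Average profile across anchors
#'
#' Column means over unmasked cells with the standard error of the mean;
#' fully masked columns come back `NA` with `n = 0`.
#'
#' @param pm a [ProfileMatrix-class].
#' @return data.frame with columns `bin_start` (bp relative to the anchor),
#'   `mean`, `sem`, `n`.
#' @export
averageProfile <- function(pm) {
  stopifnot(is(pm, "ProfileMatrix"))
  v <- profileValues(pm)
  n <- colSums(!is.na(v))
  mu <- ifelse(n > 0, colMeans(v, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_len(ncol(v)), function(j) {
    if (n[j] > 1) stats::sd(v[, j], na.rm = TRUE) / sqrt(n[j]) else NA_real_
  }, numeric(1))
  data.frame(bin_start = seq.int(-pm@windowUp, pm@windowDown - 1L, pm@binSize),
             mean = mu, sem = sem, n = n)
}

#' Count fragments within deduplicated LTR intervals
#'
#' Each fragment is counted once toward every LTR interval it overlaps by at
#' least 1 bp.
#'
#' @param anchors data.frame from [dedupLtrs()].
#' @param fragments a `GRanges` of sequenced fragments.
#' @return integer counts, one per anchor row.
#' @export
countInLtrs <- function(anchors, fragments) {
  stopifnot(is(fragments, "GRanges"))
  ltr <- GRanges(anchors$chrom,
                 IRanges(start = anchors$start + 1L, end = anchors$end))
  GenomicRanges::countOverlaps(ltr, fragments, ignore.strand = TRUE)
}

#' Per-family differential accessibility test at LTRs
#'
#' Two-sided Wilcoxon rank-sum test per family between per-anchor counts of
#' the two conditions (independent samples; exact null when the combined n is
#' <= 25 and tie-free, normal approximation with continuity and tie
#' correction otherwise), followed by Benjamini-Hochberg adjustment across
#' the families tested in this invocation.
#'
#' @param countsA,countsB per-anchor counts for conditions A and B.
#' @param family family label per anchor; either one vector (same anchors in
#'   both conditions) or a list of two vectors aligned with countsA/countsB.
#' @return data.frame: `family`, `n_A`, `n_B`, `W`, `p`, `p_adj`.
#' @export
ltrDifferentialTest <- function(countsA, countsB, family) {
  if (is.list(family)) {
    famA <- family[[1L]]; famB <- family[[2L]]
  } else {
    famA <- famB <- family
  }
  if (length(famA) != length(countsA) || length(famB) != length(countsB)) {
    stopf("family labels must align with the count vectors")
  }
  fams <- sort(unique(c(as.character(famA), as.character(famB))))
  rows <- lapply(fams, function(f) {
    a <- countsA[famA == f]
    b <- countsB[famB == f]
    if (length(a) == 0L || length(b) == 0L) {
      stopf("family '%s' has no anchors in one condition", f)
    }
    exact <- (length(a) + length(b)) <= 25L &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    data.frame(family = f, n_A = length(a), n_B = length(b),
               W = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
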