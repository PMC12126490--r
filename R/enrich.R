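#' Counts per million
#'
#' Depth normalization: `count / library_total * 1e6`. ChIP and input tracks
#' each use their own library total.
#'
#' @param count non-negative count (vectorized).
#' @param library_total positive library size.
#' @return CPM value(s).
#' @export
computeCPM <- function(count, library_total) {
  if (any(library_total <= 0)) stopf("library_total must be > 0")
  if (any(count < 0)) stopf("counts must be non-negative")
  count / library_total * 1e6
}

#' Remove low-coverage loci
#'
#' Drops every (locus, dataset) row with less than 1 input read; removal
#' counts are attached per family when the annotation is supplied. The filter
#' is the pipeline's only guard against division by zero in fold enrichment
#' (no pseudocount is used downstream).
#'
#' @param counts a [LocusCounts-class].
#' @param annotation optional [RepeatAnnotation-class] used to log removals
#'   per family.
#' @return a filtered [LocusCounts-class] with attribute `removed_per_family`.
#' @export
filterLowCoverage <- function(counts, annotation = NULL) {
  stopifnot(is(counts, "LocusCounts"))
  cc <- countTable(counts)
  keep <- cc$input_count >= 1
  removed <- cc[!keep, , drop = FALSE]
  out <- LocusCounts(cc[keep, , drop = FALSE], libraryTotals(counts))
  if (!is.null(annotation)) {
    fam <- mcols(annotationRanges(annotation))$family
    names(fam) <- mcols(annotationRanges(annotation))$locus_id
    attr(out, "removed_per_family") <-
      table(factor(fam[removed$locus_id], levels = sort(unique(fam))))
  } else {
    attr(out, "removed_per_family") <- table(removed$locus_id)
  }
  if (nrow(countTable(out)) == 0L) {
    warnf("no locus survived the input-coverage filter")
  }
  out
}

#' Per-locus fold enrichment
#'
#' Depth-normalized ChIP over depth-normalized input. The input CPM must be
#' positive: callers are expected to have applied [filterLowCoverage()].
#'
#' @param chip_cpm,input_cpm CPM values (vectorized).
#' @return fold enrichment value(s).
#' @export
locusFoldEnrichment <- function(chip_cpm, input_cpm) {
  if (any(input_cpm <= 0)) {
    stopf("input CPM must be positive; apply the input-coverage filter first")
  }
  chip_cpm / input_cpm
}

#' Family median fold enrichment
#'
#' The family summary statistic: a standard median (mean of the two central
#' order statistics at even n), robust to a minority of outlier loci.
#'
#' @param fe_values numeric fold enrichments for one family.
#' @param family family label, used in error messages.
#' @return the median.
#' @export
familyMedian <- function(fe_values, family = "<unnamed>") {
  if (length(fe_values) == 0L) {
    stopf("family '%s' has no loci after filtering", family)
  }
  stats::median(fe_values)
}

#' Z-score transform of family medians for one dataset
#'
#' Standardizes each dataset to itself: `z = (m - mean(m)) / sd(m)` with the
#' sample (n-1) standard deviation, so each dataset column has mean 0 and
#' sample sd 1.
#'
#' @param medians numeric vector of per-family medians (length >= 2).
#' @param dataset label for error messages.
#' @return z-scores, same names as `medians`.
#' @export
zscoreTransform <- function(medians, dataset = "<unnamed>") {
  if (length(medians) < 2L) {
    stopf("dataset '%s': need >= 2 families to z-score", dataset)
  }
  s <- stats::sd(medians)
  if (!is.finite(s) || s == 0) {
    stopf("dataset '%s': zero variance across family medians, z-score undefined",
          dataset)
  }
  (medians - mean(medians)) / s
}

# Spearman-rank dissimilarity: d(u, v) = 1 - rho(u, v), midrank ties.
spearmanDist <- function(m) {
  rho <- stats::cor(t(m), method = "spearman")
  stats::as.dist(1 - rho)
}

#' Hierarchical Spearman-rank clustering of the enrichment matrix
#'
#' Agglomerative clustering with distance `1 - Spearman rho` between rows of
#' the chosen axis and average linkage. Rows are ordered lexicographically by
#' label before clustering so leaf order is deterministic under ties.
#'
#' @param fe a [FamilyEnrichment-class] (or plain numeric matrix).
#' @param axis `"families"` (rows) or `"datasets"` (columns).
#' @return an `hclust` object; leaf labels give the ordering.
#' @export
clusterMatrix <- function(fe, axis = c("families", "datasets")) {
  axis <- match.arg(axis)
  m <- if (is(fe, "FamilyEnrichment")) zscores(fe) else fe
  if (axis == "datasets") m <- t(m)
  if (nrow(m) < 2L) stopf("need >= 2 %s to cluster", axis)
  m <- m[order(rownames(m)), , drop = FALSE]
  cst <- apply(m, 1L, function(r) stats::sd(r) == 0 || anyNA(r))
  if (any(cst)) {
    stopf("constant or incomplete row(s) make Spearman undefined: %s",
          paste(rownames(m)[cst], collapse = ", "))
  }
  stats::hclust(spearmanDist(m), method = "average")
}

#' Run the full repeat-family enrichment pipeline
#'
#' Fixed stage order: CPM normalization, input-coverage filter, per-locus
#' fold enrichment, per-family median, per-dataset z-score, Spearman-rank
#' clustering. Families left without surviving loci in any dataset are
#' dropped (with a warning) so every z-score column stays well defined.
#'
#' @param annotation a [RepeatAnnotation-class].
#' @param counts a [LocusCounts-class] covering every dataset of interest.
#' @param cluster logical; also compute row/column dendrograms (needs >= 2
#'   families and >= 2 datasets for the respective axis).
#' @return a [FamilyEnrichment-class].
#' @export
runEnrichmentPipeline <- function(annotation, counts, cluster = TRUE) {
  stopifnot(is(annotation, "RepeatAnnotation"), is(counts, "LocusCounts"))
  gr <- annotationRanges(annotation)
  fam_of <- stats::setNames(as.character(mcols(gr)$family), mcols(gr)$locus_id)
  families <- sort(unique(unname(fam_of)))
  lt <- libraryTotals(counts)
  datasets <- lt$dataset

  filtered <- filterLowCoverage(counts, annotation)
  cc <- countTable(filtered)
  unknown <- setdiff(cc$locus_id, names(fam_of))
  if (length(unknown)) {
    stopf("stage fold-enrichment: %d count rows reference loci absent from the annotation",
          length(unknown))
  }
  cc$family <- fam_of[cc$locus_id]

  raw <- matrix(NA_real_, length(families), length(datasets),
                dimnames = list(families, datasets))
  nus <- matrix(0L, length(families), length(datasets),
                dimnames = list(families, datasets))
  for (ds in datasets) {
    sub <- cc[cc$dataset == ds, , drop = FALSE]
    row <- lt[lt$dataset == ds, ]
    fe <- locusFoldEnrichment(computeCPM(sub$chip_count, row$chip_total),
                              computeCPM(sub$input_count, row$input_total))
    for (f in families) {
      v <- fe[sub$family == f]
      nus[f, ds] <- length(v)
      if (length(v)) raw[f, ds] <- familyMedian(v, f)
    }
  }

  dropped <- families[apply(raw, 1L, anyNA)]
  if (length(dropped)) {
    warnf("dropping %d family(ies) with no surviving loci in some dataset: %s",
          length(dropped), paste(dropped, collapse = ", "))
    keep <- setdiff(families, dropped)
    raw <- raw[keep, , drop = FALSE]
    nus <- nus[keep, , drop = FALSE]
  }

  z <- raw
  for (ds in datasets) z[, ds] <- zscoreTransform(raw[, ds], ds)

  clustering <- list()
  if (cluster) {
    if (nrow(z) >= 2L) clustering$families <- clusterMatrix(z, "families")
    if (ncol(z) >= 2L) clustering$datasets <- clusterMatrix(z, "datasets")
  }
  new("FamilyEnrichment", rawMedian = raw, zscore = z, nLociUsed = nus,
      droppedFamilies = as.character(dropped), clustering = clustering)
}
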