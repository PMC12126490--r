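#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames strand start end width mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

VALID_ROLES <- c("LTR5", "LTR3", "internal", "orphanLTR")

#' Family-labelled repeat annotation
#'
#' A set of repeat loci as a \linkS4class{GRanges} whose metadata columns carry
#' the repeat \code{family}, the locus \code{role} within an integration
#' (\code{"LTR5"}, \code{"internal"}, \code{"LTR3"} for full-length elements,
#' \code{"orphanLTR"} for solitary LTRs) and an \code{integration_id} shared by
#' all loci of one genomic integration. Intervals are 0-based half-open on
#' disk (BED) and 1-based closed in memory, the GRanges convention; all
#' conversions happen at the I/O boundary.
#'
#' @slot ranges a \code{GRanges} with mcols \code{family}, \code{role},
#'   \code{integration_id}, \code{locus_id}.
#' @export
setClass("RepeatAnnotation", representation(ranges = "GRanges"))

setValidity("RepeatAnnotation", function(object) {
  gr <- object@ranges
  mc <- mcols(gr)
  need <- c("family", "role", "integration_id", "locus_id")
  miss <- setdiff(need, colnames(mc))
  if (length(miss)) {
    return(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")))
  }
  if (length(gr) == 0L) return(TRUE)
  if (!all(mc$role %in% VALID_ROLES)) {
    return(paste0("role must be one of ", paste(VALID_ROLES, collapse = ", ")))
  }
  if (anyDuplicated(mc$locus_id)) return("locus_id values must be unique")
  # non-overlap within the annotation
  if (length(gr) > 1L) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) > 0L) {
      return(sprintf("annotation contains %d overlapping locus pairs", length(hits)))
    }
  }
  # a full-length integration has exactly one internal segment per LTR pair
  byint <- split(mc$role, mc$integration_id)
  for (id in names(byint)) {
    roles <- byint[[id]]
    if (sum(roles == "LTR5") > 1L) {
      return(sprintf("integration '%s' carries two 5' LTR records", id))
    }
    if (any(roles %in% c("LTR5", "LTR3")) && any(roles == "orphanLTR")) {
      return(sprintf("integration '%s' mixes orphan and full-length roles", id))
    }
  }
  TRUE
})

#' Construct a RepeatAnnotation
#'
#' @param ranges a `GRanges` with mcols `family`, `role`, `integration_id`
#'   and (optionally) `locus_id`; locus ids are generated when absent.
#' @return a validated [RepeatAnnotation-class] object.
#' @export
RepeatAnnotation <- function(ranges) {
  if (!is(ranges, "GRanges")) stop("'ranges' must be a GRanges")
  if (!"locus_id" %in% colnames(mcols(ranges))) {
    mcols(ranges)$locus_id <- sprintf("locus_%06d", seq_along(ranges))
  }
  ranges <- GenomicRanges::sort(ranges, ignore.strand = TRUE)
  new("RepeatAnnotation", ranges = ranges)
}

#' Per-locus ChIP/input count table with library totals
#'
#' Long-format fragment counts: one row per (locus, dataset) pair with the
#' ChIP and matched-input count, plus per-dataset library totals used for CPM
#' normalization. ChIP and input libraries carry separate totals because each
#' track is depth-normalized to itself.
#'
#' @slot counts data.frame with columns `locus_id`, `dataset`, `chip_count`,
#'   `input_count`.
#' @slot libraryTotals data.frame with columns `dataset`, `chip_total`,
#'   `input_total`.
#' @export
setClass("LocusCounts",
  representation(counts = "data.frame", libraryTotals = "data.frame"))

setValidity("LocusCounts", function(object) {
  cc <- object@counts
  lt <- object@libraryTotals
  need <- c("locus_id", "dataset", "chip_count", "input_count")
  if (!all(need %in% names(cc))) {
    return(paste0("counts needs columns ", paste(need, collapse = ", ")))
  }
  if (!all(c("dataset", "chip_total", "input_total") %in% names(lt))) {
    return("libraryTotals needs columns dataset, chip_total, input_total")
  }
  if (nrow(cc)) {
    if (any(cc$chip_count < 0) || any(cc$input_count < 0)) {
      return("counts must be non-negative")
    }
    if (any(cc$chip_count != round(cc$chip_count)) ||
        any(cc$input_count != round(cc$input_count))) {
      return("counts must be integers")
    }
    if (!all(cc$dataset %in% lt$dataset)) {
      return("every dataset in counts needs a library total")
    }
    agg_c <- tapply(cc$chip_count, cc$dataset, sum)
    agg_i <- tapply(cc$input_count, cc$dataset, sum)
    idx <- match(names(agg_c), lt$dataset)
    if (any(lt$chip_total[idx] < agg_c) || any(lt$input_total[idx] < agg_i)) {
      return("library totals must be >= column sums")
    }
  }
  if (any(lt$chip_total <= 0) || any(lt$input_total <= 0)) {
    return("library totals must be positive")
  }
  TRUE
})

#' @param counts,libraryTotals see the class slots.
#' @rdname LocusCounts-class
#' @export
LocusCounts <- function(counts, libraryTotals) {
  counts <- as.data.frame(counts)
  libraryTotals <- as.data.frame(libraryTotals)
  rownames(counts) <- NULL
  rownames(libraryTotals) <- NULL
  new("LocusCounts", counts = counts, libraryTotals = libraryTotals)
}

#' Families-by-datasets enrichment matrix
#'
#' The central result of the enrichment pipeline: per-family median fold
#' enrichment (`rawMedian`), its per-dataset z-score transform (`zscore`),
#' and the number of loci surviving the input-coverage filter in each cell
#' (`nLociUsed`). Row/column dendrogram orderings from Spearman-rank
#' clustering are kept in `clustering`.
#'
#' @slot rawMedian,zscore numeric matrices, families x datasets.
#' @slot nLociUsed integer matrix of the same shape.
#' @slot droppedFamilies character, families removed because no locus survived
#'   filtering in some dataset.
#' @slot clustering list with optional `families` / `datasets` hclust objects.
#' @export
setClass("FamilyEnrichment",
  representation(rawMedian = "matrix", zscore = "matrix",
                 nLociUsed = "matrix", droppedFamilies = "character",
                 clustering = "list"))

setValidity("FamilyEnrichment", function(object) {
  d <- dim(object@rawMedian)
  if (!identical(d, dim(object@zscore)) || !identical(d, dim(object@nLociUsed))) {
    return("rawMedian, zscore and nLociUsed must share dimensions")
  }
  if (is.null(rownames(object@rawMedian)) || is.null(colnames(object@rawMedian))) {
    return("matrices must carry family rownames and dataset colnames")
  }
  TRUE
})

#' Anchored coverage profile matrix
#'
#' Rows are deduplicated LTR anchors, columns fixed-width bins spanning
#' `[-windowUp, +windowDown)` around each anchor in strand orientation.
#' Cells hold mean per-base coverage in the bin; bins falling outside the
#' genome are `NA` (masked, never zero-filled).
#'
#' @slot values numeric matrix (anchors x bins), `NA` = masked.
#' @slot anchors data.frame describing each row (chrom, position, strand,
#'   family, integration_id).
#' @slot windowUp,windowDown,binSize single integers, bp.
#' @export
setClass("ProfileMatrix",
  representation(values = "matrix", anchors = "data.frame",
                 windowUp = "integer", windowDown = "integer",
                 binSize = "integer"))

setValidity("ProfileMatrix", function(object) {
  nb <- (object@windowUp + object@windowDown) / object@binSize
  if (nb != round(nb)) return("window span must be divisible by binSize")
  if (ncol(object@values) != nb) {
    return(sprintf("expected %d bin columns, found %d", nb, ncol(object@values)))
  }
  if (nrow(object@values) != nrow(object@anchors)) {
    return("one anchor row per matrix row required")
  }
  TRUE
})

#' Binding-isotherm fit result
#'
#' Least-squares estimates of the dissociation constant and maximal signal
#' change under the ligand-depletion (quadratic) binding model, with
#' covariance-derived standard errors.
#'
#' @slot kd,deltaIMax,residualNorm single numerics.
#' @slot se named numeric, standard errors for `kd` and `deltaIMax`.
#' @slot fitted numeric, fitted response at the observed ligand points.
#' @slot converged logical.
#' @slot pTotal protein concentration used in the model.
#' @export
setClass("TitrationFit",
  representation(kd = "numeric", deltaIMax = "numeric", se = "numeric",
                 residualNorm = "numeric", fitted = "numeric",
                 converged = "logical", pTotal = "numeric"))
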