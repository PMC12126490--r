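#' @include AllClasses.R
NULL

#' Accessors
#'
#' @param x an ervscape S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("annotationRanges", function(x) standardGeneric("annotationRanges"))

#' @rdname accessors
#' @export
setMethod("annotationRanges", "RepeatAnnotation", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))

#' @rdname accessors
#' @export
setMethod("countTable", "LocusCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @rdname accessors
#' @export
setMethod("libraryTotals", "LocusCounts", function(x) x@libraryTotals)

#' @rdname accessors
#' @export
setGeneric("rawMedian", function(x) standardGeneric("rawMedian"))

#' @rdname accessors
#' @export
setMethod("rawMedian", "FamilyEnrichment", function(x) x@rawMedian)

#' @rdname accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname accessors
#' @export
setMethod("zscores", "FamilyEnrichment", function(x) x@zscore)

#' @rdname accessors
#' @export
setGeneric("nLociUsed", function(x) standardGeneric("nLociUsed"))

#' @rdname accessors
#' @export
setMethod("nLociUsed", "FamilyEnrichment", function(x) x@nLociUsed)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setMethod("profileValues", "ProfileMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("profileAnchors", function(x) standardGeneric("profileAnchors"))

#' @rdname accessors
#' @export
setMethod("profileAnchors", "ProfileMatrix", function(x) x@anchors)

#' @rdname accessors
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))

#' @rdname accessors
#' @export
setMethod("kd", "TitrationFit", function(x) x@kd)

#' @rdname accessors
#' @export
setGeneric("deltaIMax", function(x) standardGeneric("deltaIMax"))

#' @rdname accessors
#' @export
setMethod("deltaIMax", "TitrationFit", function(x) x@deltaIMax)

setMethod("show", "RepeatAnnotation", function(object) {
  gr <- object@ranges
  fams <- unique(mcols(gr)$family)
  cat(sprintf("RepeatAnnotation: %d loci, %d families, %d integrations\n",
              length(gr), length(fams),
              length(unique(mcols(gr)$integration_id))))
  roles <- table(mcols(gr)$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = " "), "\n")
})

setMethod("show", "LocusCounts", function(object) {
  cat(sprintf("LocusCounts: %d rows, %d datasets\n",
              nrow(object@counts), nrow(object@libraryTotals)))
})

setMethod("show", "FamilyEnrichment", function(object) {
  cat(sprintf("FamilyEnrichment: %d families x %d datasets\n",
              nrow(object@rawMedian), ncol(object@rawMedian)))
  if (length(object@droppedFamilies)) {
    cat("  dropped families:", paste(object@droppedFamilies, collapse = ", "), "\n")
  }
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d anchors x %d bins (-%d/+%d bp, %d bp bins)\n",
              nrow(object@values), ncol(object@values),
              object@windowUp, object@windowDown, object@binSize))
})

setMethod("show", "TitrationFit", function(object) {
  cat(sprintf("TitrationFit: Kd = %.4g +/- %.3g, dImax = %.4g +/- %.3g (%s)\n",
              object@kd, object@se[["kd"]],
              object@deltaIMax, object@se[["deltaIMax"]],
              if (object@converged) "converged" else "NOT converged"))
})
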