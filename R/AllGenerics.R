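## Generics, accessors and show methods.

#' @describeIn LadderCalibration-class estimate molecular weight (kDa) at a
#'   relative mobility.
#' @param calibration a [LadderCalibration-class] object.
#' @param mobility numeric vector of relative mobilities in `[0, 1]`.
#' @export
setGeneric("mwOf", function(calibration, mobility) standardGeneric("mwOf"))

#' @export
setMethod("mwOf", "LadderCalibration", function(calibration, mobility) {
  if (any(mobility < 0 | mobility > 1, na.rm = TRUE))
    stopValidation("mobility must lie in [0, 1]")
  10^(calibration@intercept + calibration@slope * mobility)
})

#' Accessors for BandMatrix
#'
#' `presenceMatrix()` returns the 0/1 bands-by-lanes matrix,
#' `bandClasses()` the per-band class vector, `consensusMW()` the consensus
#' molecular weights and `laneNames()` the lane labels.
#'
#' @param x a [BandMatrix-class].
#' @return matrix / character vector / numeric vector / character vector
#'   respectively.
#' @name BandMatrix-accessors
NULL

#' @rdname BandMatrix-accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname BandMatrix-accessors
#' @export
setMethod("presenceMatrix", "BandMatrix", function(x) x@presence)

#' @rdname BandMatrix-accessors
#' @export
setGeneric("bandClasses", function(x) standardGeneric("bandClasses"))
#' @rdname BandMatrix-accessors
#' @export
setMethod("bandClasses", "BandMatrix", function(x) x@bandClass)

#' @rdname BandMatrix-accessors
#' @export
setGeneric("consensusMW", function(x) standardGeneric("consensusMW"))
#' @rdname BandMatrix-accessors
#' @export
setMethod("consensusMW", "BandMatrix", function(x) x@consensusMW)

#' @rdname BandMatrix-accessors
#' @export
setGeneric("laneNames", function(x) standardGeneric("laneNames"))
#' @rdname BandMatrix-accessors
#' @export
setMethod("laneNames", "BandMatrix", function(x) colnames(x@presence))

#' Accessors for PolymorphismReport
#'
#' `perLane()` returns the per-lane statistics data.frame (full-precision
#' percentages), `reportTotals()` the totals row and `reportAverages()` the
#' averages row (including both percentage conventions, see
#' [PolymorphismReport-class]).
#'
#' @param x a [PolymorphismReport-class].
#' @name PolymorphismReport-accessors
NULL

#' @rdname PolymorphismReport-accessors
#' @export
setGeneric("perLane", function(x) standardGeneric("perLane"))
#' @rdname PolymorphismReport-accessors
#' @export
setMethod("perLane", "PolymorphismReport", function(x) x@perLane)

#' @rdname PolymorphismReport-accessors
#' @export
setGeneric("reportTotals", function(x) standardGeneric("reportTotals"))
#' @rdname PolymorphismReport-accessors
#' @export
setMethod("reportTotals", "PolymorphismReport", function(x) x@totals)

#' @rdname PolymorphismReport-accessors
#' @export
setGeneric("reportAverages", function(x) standardGeneric("reportAverages"))
#' @rdname PolymorphismReport-accessors
#' @export
setMethod("reportAverages", "PolymorphismReport", function(x) x@averages)

#' @describeIn SimilarityMatrix-class similarity values as a plain matrix.
#' @param x a [SimilarityMatrix-class].
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @describeIn AlignmentResult-class percent identity of a hit or alignment.
#' @export
setGeneric("pctIdentity", function(x) standardGeneric("pctIdentity"))
#' @export
setMethod("pctIdentity", "AlignmentResult", function(x) x@pctIdentity)

#' @describeIn AlignmentResult-class alignment score.
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

## show methods -------------------------------------------------------------

setMethod("show", "LadderCalibration", function(object) {
  cat(sprintf("LadderCalibration: log10(MW) = %.4f * mobility + %.4f (%d markers)\n",
              object@slope, object@intercept, nrow(object@markers)))
})

setMethod("show", "BandMatrix", function(object) {
  p <- object@presence
  cat(sprintf("BandMatrix: %d consensus bands x %d lanes\n", nrow(p), ncol(p)))
  if (!anyNA(object@bandClass) && nrow(p)) {
    tab <- table(factor(object@bandClass,
                        levels = c("monomorphic", "polymorphic", "unique")))
    cat(sprintf("  classes: %d monomorphic, %d polymorphic (non-unique), %d unique\n",
                tab[["monomorphic"]], tab[["polymorphic"]], tab[["unique"]]))
  }
  cat("  lanes:", paste(colnames(p), collapse = ", "), "\n")
})

setMethod("show", "PolymorphismReport", function(object) {
  cat(sprintf("PolymorphismReport (unit: %s)\n", object@unit))
  pl <- object@perLane
  digits <- if (object@unit == "locus") 1 else 2
  out <- data.frame(lane = pl$lane, monomorphic = pl$monomorphic,
                    polymorphic = pl$polymorphic, total = pl$total,
                    unique = pl$unique,
                    pct = displayPct(pl$pctPolymorphism, digits))
  print(out, row.names = FALSE)
  tot <- object@totals
  avg <- object@averages
  cat(sprintf("  totals : %d monomorphic, %d polymorphic, %d total, %d unique\n",
              tot[["monomorphic"]], tot[["polymorphic"]], tot[["total"]],
              tot[["unique"]]))
  cat(sprintf("  average pct: %.2f (mean of lanes), %.2f (pooled)\n",
              displayPct(avg[["pctMeanOfLanes"]]),
              displayPct(avg[["pctPooled"]])))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s coefficient), %d lanes\n",
              object@coefficient, ncol(object@values)))
  print(round(object@values, 4))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("Global alignment %s vs %s: %.2f%% identity (%d/%d columns), score %g\n",
              object@queryId, object@refId, object@pctIdentity,
              object@matches, object@alignmentLength, object@score))
})

#' @describeIn PolymorphismReport-class coerce to the printed table layout
#'   (per-lane rows plus `Total` and `Average` rows, truncated percentages).
#' @param row.names,optional,... ignored; standard [as.data.frame()]
#'   arguments.
#' @export
as.data.frame.PolymorphismReport <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  pl <- x@perLane
  digits <- if (x@unit == "locus") 1 else 2
  avgPct <- if (x@unit == "locus") x@averages[["pctPooled"]] else
    x@averages[["pctMeanOfLanes"]]
  df <- data.frame(
    lane = c(as.character(pl$lane), "Total", "Average"),
    monomorphic = c(pl$monomorphic, x@totals[["monomorphic"]],
                    x@averages[["monomorphic"]]),
    polymorphic = c(pl$polymorphic, x@totals[["polymorphic"]],
                    x@averages[["polymorphic"]]),
    total = c(pl$total, x@totals[["total"]], x@averages[["total"]]),
    unique = c(pl$unique, x@totals[["unique"]], x@averages[["unique"]]),
    pct_polymorphism = c(displayPct(pl$pctPolymorphism, digits), NA,
                         displayPct(avgPct, 2)),
    stringsAsFactors = FALSE)
  df
}
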