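## S4 classes for the gel-fingerprint track and pairwise alignment results.
## Trees are ape "phylo" objects and sequence sets are Biostrings
## DNAStringSets throughout; only the containers this package defines get
## their own classes.

#' LadderCalibration: log-linear molecular-weight calibration
#'
#' Migration of a protein in a denaturing gel is (to good approximation)
#' linear in log10 of its molecular weight, so a marker ladder run alongside
#' the samples calibrates `log10(MW) = slope * mobility + intercept` with
#' `slope < 0` (smaller proteins migrate farther).
#'
#' @slot slope numeric; fitted slope (negative).
#' @slot intercept numeric; fitted intercept.
#' @slot markers data.frame with columns `mobility`, `mw_kda` used for the
#'   fit.
#' @seealso [calibrateLadder()], [mwOf()]
#' @export
setClass("LadderCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 markers = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@slope) != 1L || !is.finite(object@slope))
      msg <- c(msg, "slope must be a single finite number")
    else if (object@slope >= 0)
      msg <- c(msg, "fitted slope must be negative (smaller proteins migrate farther)")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
      msg <- c(msg, "intercept must be a single finite number")
    if (nrow(object@markers) < 2L)
      msg <- c(msg, "at least 2 marker points required")
    if (length(msg)) msg else TRUE
  })

#' BandMatrix: binary band-by-lane presence matrix
#'
#' Rows are consensus bands (gel positions shared across lanes after
#' tolerance matching), columns are lanes. Each band carries a consensus
#' molecular weight (mean of its member bands; `NA` for mobility-only gels)
#' and a class: `monomorphic` (present in every lane), `unique` (present in
#' exactly one lane) or `polymorphic` (absent from at least one lane but
#' present in more than one). Unique bands are a subset of the polymorphic
#' ones, which is how the per-lane statistics count them.
#'
#' @slot presence integer matrix of 0/1, bands x lanes, with dimnames.
#' @slot consensusMW numeric; one consensus molecular weight (kDa) per row,
#'   `NA` allowed.
#' @slot bandClass character; `"monomorphic"`, `"polymorphic"` or
#'   `"unique"` per row.
#' @slot members list; one data.frame of member bands per row.
#' @seealso [matchBands()], [classifyBands()], [polymorphismStats()]
#' @export
setClass("BandMatrix",
  representation(presence = "matrix", consensusMW = "numeric",
                 bandClass = "character", members = "list"),
  validity = function(object) {
    msg <- character()
    p <- object@presence
    if (!is.numeric(p) || any(!p %in% c(0L, 1L)))
      msg <- c(msg, "presence must be a 0/1 matrix")
    if (is.null(rownames(p)) || is.null(colnames(p)))
      msg <- c(msg, "presence must have band and lane dimnames")
    if (anyDuplicated(colnames(p)))
      msg <- c(msg, "lane labels must be unique")
    if (nrow(p) > 0 && any(rowSums(p) < 1))
      msg <- c(msg, "every band row must be present in at least one lane")
    if (length(object@consensusMW) != nrow(p))
      msg <- c(msg, "consensusMW length must equal number of band rows")
    if (length(object@bandClass) != nrow(p))
      msg <- c(msg, "bandClass length must equal number of band rows")
    cls <- object@bandClass
    known <- cls %in% c("monomorphic", "polymorphic", "unique")
    if (any(!is.na(cls) & !known))
      msg <- c(msg, "bandClass values must be monomorphic/polymorphic/unique")
    if (nrow(p) > 0 && !anyNA(cls)) {
      rs <- rowSums(p)
      if (any(cls == "monomorphic" & rs != ncol(p)))
        msg <- c(msg, "monomorphic bands must be present in all lanes")
      if (any(cls == "unique" & rs != 1L))
        msg <- c(msg, "unique bands must be present in exactly one lane")
      if (any(cls != "monomorphic" & rs == ncol(p)))
        msg <- c(msg, "bands present in all lanes must be monomorphic")
    }
    if (length(msg)) msg else TRUE
  })

#' PolymorphismReport: per-lane polymorphism statistics
#'
#' Mirrors the layout of a published polymorphism table: one row per lane
#' with monomorphic/polymorphic/unique counts, total items and the
#' polymorphism percentage `polymorphic * 100 / total`, plus a totals row
#' (column sums over lanes) and an averages row. Two averages of the
#' percentage are carried because both conventions occur in practice:
#' `pctMeanOfLanes` (mean of the per-lane percentages) and `pctPooled`
#' (summed polymorphic count x 100 / summed total). Band-level reports
#' conventionally display the former, locus-level (zymogram) reports the
#' latter. Percentages are stored at full precision; display truncates via
#' [displayPct()].
#'
#' @slot perLane data.frame with columns `lane`, `monomorphic`,
#'   `polymorphic`, `unique`, `total`, `pctPolymorphism`.
#' @slot totals named numeric: `monomorphic`, `polymorphic`, `unique`,
#'   `total`.
#' @slot averages named numeric: the count averages plus `pctMeanOfLanes`
#'   and `pctPooled`.
#' @slot unit character; `"band"` or `"locus"`.
#' @seealso [polymorphismStats()], [zymogramStats()]
#' @export
setClass("PolymorphismReport",
  representation(perLane = "data.frame", totals = "numeric",
                 averages = "numeric", unit = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("lane", "monomorphic", "polymorphic", "unique", "total",
              "pctPolymorphism")
    if (!all(need %in% names(object@perLane)))
      msg <- c(msg, "perLane must have lane/monomorphic/polymorphic/unique/total/pctPolymorphism")
    pl <- object@perLane
    if (nrow(pl)) {
      ok <- is.na(pl$pctPolymorphism) |
        (pl$pctPolymorphism >= 0 & pl$pctPolymorphism <= 100)
      if (!all(ok)) msg <- c(msg, "percentages must lie in [0, 100] or be NA")
      if (any(pl$monomorphic + pl$polymorphic != pl$total))
        msg <- c(msg, "per-lane monomorphic + polymorphic must equal total")
    }
    if (!object@unit %in% c("band", "locus"))
      msg <- c(msg, "unit must be 'band' or 'locus'")
    if (length(msg)) msg else TRUE
  })

#' SimilarityMatrix: lane-to-lane binary similarity
#'
#' Symmetric matrix of similarities in `[0, 1]` between gel lanes, tagged
#' with the binary coefficient used (`dice`, `jaccard` or
#' `simple_matching`).
#'
#' @slot values numeric matrix, symmetric, unit diagonal, with lane
#'   dimnames.
#' @slot coefficient character tag.
#' @seealso [similarityMatrix()], [upgmaDendrogram()]
#' @export
setClass("SimilarityMatrix",
  representation(values = "matrix", coefficient = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (!isSymmetric(unname(v))) msg <- c(msg, "values must be symmetric")
    if (any(v < 0 | v > 1)) msg <- c(msg, "similarities must lie in [0, 1]")
    if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
    if (is.null(rownames(v))) msg <- c(msg, "values must carry lane labels")
    if (!object@coefficient %in% c("dice", "jaccard", "simple_matching"))
      msg <- c(msg, "unknown coefficient tag")
    if (length(msg)) msg else TRUE
  })

#' AlignmentResult: one global pairwise alignment
#'
#' Result of an exact global affine-gap (Needleman-Wunsch/Gotoh) alignment.
#' Percent identity is `matches * 100 / alignmentLength`, where the
#' denominator counts every alignment column including gap columns, and a
#' column only counts as a match when both residues are equal and neither is
#' a gap or `N`.
#'
#' @slot queryId,refId character labels.
#' @slot alignedQuery,alignedRef character; gapped aligned strings of equal
#'   length.
#' @slot matches integer; identical non-gap, non-N columns.
#' @slot alignmentLength integer; total alignment columns.
#' @slot pctIdentity numeric in `[0, 100]`.
#' @slot score numeric alignment score.
#' @seealso [globalAlign()], [rankReferences()]
#' @export
setClass("AlignmentResult",
  representation(queryId = "character", refId = "character",
                 alignedQuery = "character", alignedRef = "character",
                 matches = "integer", alignmentLength = "integer",
                 pctIdentity = "numeric", score = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@alignedQuery) != nchar(object@alignedRef))
      msg <- c(msg, "aligned strings must have equal length")
    if (object@pctIdentity < 0 || object@pctIdentity > 100)
      msg <- c(msg, "pctIdentity must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })
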