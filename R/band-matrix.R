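## Band matching, classification and polymorphism statistics.

#' Calibrate a molecular-weight ladder
#'
#' Least-squares fit of `log10(MW) = slope * mobility + intercept` to the
#' marker lane, the standard log-linear model for protein migration in a
#' denaturing gel. With exactly two markers the fit interpolates them
#' exactly.
#'
#' @param markers data.frame with columns `mobility` (relative front in
#'   `[0, 1]`) and `mw_kda` (known molecular weight, kDa).
#' @return a [LadderCalibration-class]; use [mwOf()] to estimate weights.
#' @examples
#' cal <- calibrateLadder(data.frame(mobility = c(0.2, 0.8),
#'                                   mw_kda = c(100, 10)))
#' mwOf(cal, 0.5)  # 10^1.5 ~ 31.62 kDa
#' @export
calibrateLadder <- function(markers) {
  if (!all(c("mobility", "mw_kda") %in% names(markers)))
    stopParse("markers need columns mobility and mw_kda")
  if (nrow(markers) < 2L)
    stopValidation("at least 2 marker points required")
  if (anyDuplicated(markers$mobility))
    stopValidation("marker mobilities must be distinct")
  if (any(markers$mw_kda <= 0))
    stopValidation("marker molecular weights must be positive")
  fit <- lm(log10(mw_kda) ~ mobility, data = markers)
  slope <- unname(coef(fit)[2])
  if (slope >= 0)
    stopValidation("fitted slope is nonnegative; check marker orientation")
  new("LadderCalibration", slope = slope, intercept = unname(coef(fit)[1]),
      markers = markers[, c("mobility", "mw_kda")])
}

## Same-lane split: a cluster that contains two bands from one lane is cut
## at its largest internal relative gap, recursively, until every piece is
## lane-unique. `rows` is a data.frame sorted by ascending mw.
splitSameLane <- function(rows) {
  if (!anyDuplicated(rows$lane_id)) return(list(rows))
  mws <- rows$mw_kda
  gaps <- (mws[-1] - mws[-length(mws)]) / mws[-length(mws)]
  cut <- which.max(gaps)
  c(splitSameLane(rows[seq_len(cut), , drop = FALSE]),
    splitSameLane(rows[-seq_len(cut), , drop = FALSE]))
}

#' Match bands across lanes into a binary presence matrix
#'
#' Bands from different lanes whose molecular weights differ by at most
#' `relTolerance` (relative to the smaller weight) are merged into one
#' consensus band by single linkage, i.e. by the transitive closure of the
#' pairwise-within-tolerance relation. A merged group that would contain two
#' bands from the same lane is split at its largest internal gap until every
#' group is lane-unique. Rows are ordered by descending consensus weight
#' (mean of member weights).
#'
#' If a lane reports only mobilities, a [calibrateLadder()] fit converts
#' them to weights first.
#'
#' @param bands a band table (see [bandTable()]).
#' @param relTolerance relative MW tolerance for merging (default 0.02).
#' @param calibration optional [LadderCalibration-class] for mobility-only
#'   bands.
#' @param classify fill band classes via [classifyBands()] (default `TRUE`).
#' @return a [BandMatrix-class].
#' @examples
#' gel <- bandTable(lane_id = c("L1", "L2"), mw_kda = c(50, 50.4),
#'                  intensity_pct = 1)
#' presenceMatrix(matchBands(gel))        # one shared (monomorphic) band
#' @export
matchBands <- function(bands, relTolerance = 0.02, calibration = NULL,
                       classify = TRUE) {
  bands <- validateBandTable(bands)
  if (relTolerance <= 0) stopValidation("relTolerance must be > 0")
  lanes <- unique(bands$lane_id)
  if (length(lanes) < 2L) stopValidation("at least 2 lanes required")
  noMW <- is.na(bands$mw_kda)
  if (any(noMW)) {
    if (is.null(calibration))
      stopValidation("bands without mw_kda need a ladder calibration")
    bands$mw_kda[noMW] <- mwOf(calibration, bands$mobility[noMW])
  }
  ord <- order(bands$mw_kda)
  sorted <- bands[ord, , drop = FALSE]
  mws <- sorted$mw_kda
  ## single linkage in one dimension: cut the sorted chain wherever the
  ## relative gap between consecutive bands exceeds the tolerance
  gaps <- if (length(mws) > 1) (mws[-1] - mws[-length(mws)]) / mws[-length(mws)]
          else numeric()
  grp <- cumsum(c(1, gaps > relTolerance))
  pieces <- unlist(lapply(split(sorted, grp), splitSameLane),
                   recursive = FALSE)
  cmw <- vapply(pieces, function(p) mean(p$mw_kda), numeric(1))
  o <- order(-cmw)
  pieces <- pieces[o]
  cmw <- cmw[o]
  presence <- matrix(0L, nrow = length(pieces), ncol = length(lanes),
                     dimnames = list(sprintf("band%02d", seq_along(pieces)),
                                     lanes))
  for (i in seq_along(pieces))
    presence[i, unique(pieces[[i]]$lane_id)] <- 1L
  bm <- new("BandMatrix", presence = presence, consensusMW = unname(cmw),
            bandClass = rep(NA_character_, length(pieces)),
            members = unname(pieces))
  if (classify) classifyBands(bm) else bm
}

#' Classify bands as monomorphic, polymorphic or unique
#'
#' A band present in every lane is monomorphic; any band absent from at
#' least one lane is polymorphic; a polymorphic band present in exactly one
#' lane is additionally unique. The stored class is `"unique"` for unique
#' bands — they remain a subset of the polymorphic bands for counting.
#'
#' @param x a [BandMatrix-class].
#' @return the matrix with its `bandClass` slot filled.
#' @export
classifyBands <- function(x) {
  stopifnot(is(x, "BandMatrix"))
  p <- x@presence
  if (nrow(p) == 0) stopValidation("presence matrix is empty")
  rs <- rowSums(p)
  cls <- unname(ifelse(rs == ncol(p), "monomorphic",
                       ifelse(rs == 1L, "unique", "polymorphic")))
  initialize(x, bandClass = cls)
}

## shared worker for band- and locus-level reports
buildReport <- function(presence, cls, unit) {
  lanes <- colnames(presence)
  isPoly <- cls %in% c("polymorphic", "unique")
  perLane <- do.call(rbind, lapply(lanes, function(l) {
    present <- presence[, l] == 1L
    mono <- sum(present & cls == "monomorphic")
    poly <- sum(present & isPoly)
    uniq <- sum(present & cls == "unique")
    total <- mono + poly
    data.frame(lane = l, monomorphic = mono, polymorphic = poly,
               unique = uniq, total = total,
               pctPolymorphism = if (total == 0) NA_real_ else
                 poly * 100 / total,
               stringsAsFactors = FALSE)
  }))
  totals <- c(monomorphic = sum(perLane$monomorphic),
              polymorphic = sum(perLane$polymorphic),
              unique = sum(perLane$unique),
              total = sum(perLane$total))
  averages <- c(totals / nrow(perLane),
                pctMeanOfLanes = mean(perLane$pctPolymorphism, na.rm = TRUE),
                pctPooled = if (totals[["total"]] == 0) NA_real_ else
                  totals[["polymorphic"]] * 100 / totals[["total"]])
  new("PolymorphismReport", perLane = perLane, totals = totals,
      averages = averages, unit = unit)
}

#' Per-lane polymorphism statistics from a band matrix
#'
#' For each lane, counts are restricted to bands present in that lane:
#' monomorphic, polymorphic (including unique) and unique band counts,
#' total bands, and the polymorphism percentage
#' `polymorphic x 100 / total`. The totals row is the column sum over
#' lanes (a band shared by k lanes contributes k), the averages row holds
#' the count means plus both percentage conventions (see
#' [PolymorphismReport-class]). A lane with no bands reports a missing
#' percentage rather than 0 — 0/0 is undefined and a silent zero would
#' corrupt the average.
#'
#' @param x a [BandMatrix-class] with classes filled.
#' @return a [PolymorphismReport-class] with unit `"band"`.
#' @export
polymorphismStats <- function(x) {
  stopifnot(is(x, "BandMatrix"))
  if (anyNA(x@bandClass)) x <- classifyBands(x)
  buildReport(x@presence, x@bandClass, unit = "band")
}

#' Locus-level polymorphism statistics for a zymogram
#'
#' In an isozyme zymogram the unit of counting is the activity zone
#' (locus), not the band: a locus counts once for a lane if at least one
#' band falls inside its zone there, so a double-banded (heterozygous) zone
#' is still a single locus. A locus active in every lane is monomorphic,
#' otherwise polymorphic. Bands falling outside every zone are excluded
#' with a warning.
#'
#' @param bands a band table whose bands carry mobilities.
#' @param zones data.frame with columns `locus`, `mobility_min`,
#'   `mobility_max`; zones must not overlap.
#' @return a [PolymorphismReport-class] with unit `"locus"`. Its displayed
#'   average is the pooled percentage (summed polymorphic loci x 100 /
#'   summed loci), the convention of locus-level tables.
#' @export
zymogramStats <- function(bands, zones) {
  bands <- validateBandTable(bands)
  if (!all(c("locus", "mobility_min", "mobility_max") %in% names(zones)))
    stopParse("zones need columns locus, mobility_min, mobility_max")
  z <- zones[order(zones$mobility_min), , drop = FALSE]
  if (any(z$mobility_min >= z$mobility_max))
    stopValidation("each zone needs mobility_min < mobility_max")
  if (nrow(z) > 1 && any(z$mobility_min[-1] < z$mobility_max[-nrow(z)]))
    stopValidation("zones must not overlap")
  if (anyNA(bands$mobility))
    stopValidation("zymogram bands need mobilities to assign zones")
  lanes <- unique(bands$lane_id)   # before exclusion: empty lanes stay
  idx <- vapply(bands$mobility, function(m) {
    hit <- which(m >= z$mobility_min & m <= z$mobility_max)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    warning(sprintf("%d band(s) outside all zones excluded", sum(is.na(idx))))
    bands <- bands[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  presence <- matrix(0L, nrow = nrow(z), ncol = length(lanes),
                     dimnames = list(as.character(z$locus), lanes))
  presence[cbind(idx, match(bands$lane_id, lanes))] <- 1L
  active <- rowSums(presence) > 0
  presence <- presence[active, , drop = FALSE]
  rs <- rowSums(presence)
  cls <- unname(ifelse(rs == ncol(presence), "monomorphic",
                       ifelse(rs == 1L, "unique", "polymorphic")))
  buildReport(presence, cls, unit = "locus")
}

#' Per-lane mean relative band intensity
#'
#' Band intensities are normalized to sum to 100 over the whole gel, then
#' averaged within each lane, giving the "percentage average of band
#' intensity" used to compare expression levels across lanes.
#'
#' @param bands a band table.
#' @return data.frame with columns `lane`, `n_bands`,
#'   `mean_intensity_pct`.
#' @export
intensitySummary <- function(bands) {
  bands <- validateBandTable(bands)
  tot <- sum(bands$intensity_pct)
  if (tot == 0) stopValidation("all band intensities are zero")
  norm <- bands$intensity_pct * 100 / tot
  lanes <- unique(bands$lane_id)
  do.call(rbind, lapply(lanes, function(l) {
    sel <- bands$lane_id == l
    data.frame(lane = l, n_bands = sum(sel),
               mean_intensity_pct = mean(norm[sel]),
               stringsAsFactors = FALSE)
  }))
}

#' Write a polymorphism report as CSV
#'
#' Mirrors the printed table layout: one row per lane plus `Total` and
#' `Average` rows, with percentages truncated for display (2 decimals for
#' band reports, 1 for locus reports; the average always at 2).
#'
#' @param report a [PolymorphismReport-class].
#' @param path file path.
#' @param header optional comment lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
writePolymorphismReport <- function(report, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.csv(as.data.frame(report), con, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Write / read a presence matrix as CSV
#'
#' Band rows by lane columns of 0/1, with consensus molecular weights in a
#' `consensus_mw_kda` column.
#'
#' @param x a [BandMatrix-class].
#' @param path file path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
writePresenceMatrix <- function(x, path, header = NULL) {
  stopifnot(is(x, "BandMatrix"))
  df <- data.frame(band = rownames(x@presence),
                   consensus_mw_kda = x@consensusMW,
                   x@presence, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
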