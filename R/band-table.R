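## Band tables: the tidy representation of gel lanes.
## One row per band with columns lane_id, band_id, mobility, mw_kda,
## intensity_pct. Every band needs at least one coordinate (mobility or
## molecular weight).

#' Construct and validate a band table
#'
#' A band table is a plain data.frame describing a gel: one row per band
#' with the lane it belongs to, an optional relative mobility (front in
#' `[0, 1]`), an optional estimated molecular weight (kDa, `> 0`) and a
#' nonnegative relative intensity. Each band must carry at least one of the
#' two coordinates.
#'
#' @param lane_id character/factor; lane label per band.
#' @param mobility numeric or `NA`; relative front in `[0, 1]`.
#' @param mw_kda numeric or `NA`; molecular weight in kDa.
#' @param intensity_pct numeric; relative intensity (nonnegative).
#' @param band_id optional band labels; autogenerated when missing.
#' @return data.frame with columns `lane_id`, `band_id`, `mobility`,
#'   `mw_kda`, `intensity_pct`. Lane order of first appearance is kept in
#'   the `lanes` attribute.
#' @examples
#' bandTable(lane_id = c("L1", "L1", "L2"),
#'           mw_kda = c(50, 20, 50.4),
#'           intensity_pct = c(10, 5, 8))
#' @export
bandTable <- function(lane_id, mobility = NA_real_, mw_kda = NA_real_,
                      intensity_pct, band_id = NULL) {
  n <- length(lane_id)
  df <- data.frame(
    lane_id = as.character(lane_id),
    band_id = if (is.null(band_id)) sprintf("b%03d", seq_len(n))
              else as.character(band_id),
    mobility = rep_len(as.numeric(mobility), n),
    mw_kda = rep_len(as.numeric(mw_kda), n),
    intensity_pct = rep_len(as.numeric(intensity_pct), n),
    stringsAsFactors = FALSE)
  validateBandTable(df)
}

validateBandTable <- function(df) {
  need <- c("lane_id", "band_id", "mobility", "mw_kda", "intensity_pct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopParse("band table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(!is.na(df$mobility) & (df$mobility < 0 | df$mobility > 1)))
    stopValidation("mobility must lie in [0, 1]")
  if (any(!is.na(df$mw_kda) & df$mw_kda <= 0))
    stopValidation("mw_kda must be positive")
  if (any(is.na(df$intensity_pct) | df$intensity_pct < 0))
    stopValidation("intensity_pct must be nonnegative")
  if (any(is.na(df$mobility) & is.na(df$mw_kda)))
    stopValidation("every band needs a mobility or a molecular weight")
  attr(df, "lanes") <- unique(df$lane_id)
  df
}

#' Read / write band tables as CSV
#'
#' CSV with header `lane_id, band_id, mobility, mw_kda, intensity_pct`
#' (UTF-8, '.' decimal). Lines starting with `#` are treated as comments so
#' pipeline outputs can echo their configuration in the header.
#'
#' @param path file path.
#' @param bands a band table (see [bandTable()]).
#' @param header optional character vector of comment lines (written
#'   prefixed with `# `).
#' @return `readBandTable()` returns a validated band table;
#'   `writeBandTable()` returns `path` invisibly.
#' @export
readBandTable <- function(path) {
  if (!file.exists(path)) stopParse("band table not found: %s", path)
  df <- tryCatch(read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
                 error = function(e) stopParse("cannot parse %s: %s", path,
                                               conditionMessage(e)))
  validateBandTable(df)
}

#' @rdname readBandTable
#' @export
writeBandTable <- function(bands, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.csv(bands, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## split a band table into a list of per-lane data.frames (lane order kept)
splitLanes <- function(bands) {
  lanes <- unique(bands$lane_id)
  lapply(setNames(lanes, lanes), function(l) bands[bands$lane_id == l, ,
                                                   drop = FALSE])
}
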