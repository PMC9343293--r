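## 18S rDNA identification: FASTA handling, exact global affine-gap
## alignment and percent-identity ranking against a local reference
## library.

## normalize a nucleotide string: upper case, U -> T, validate alphabet
normalizeResidues <- function(x, id = "sequence") {
  x <- chartr("u", "T", chartr("U", "T", toupper(x)))
  bad <- unique(strsplit(gsub("[ACGTN-]", "", x), "")[[1]])
  if (length(bad))
    stopValidation("%s contains characters outside {A,C,G,T,N,-}: %s",
                   id, paste(bad, collapse = ""))
  x
}

#' Read / write FASTA sequence sets
#'
#' Reading normalizes residues to the uppercase T-alphabet (`U` mapped to
#' `T`) and validates against `{A,C,G,T,N,-}`. Record ids are the first
#' whitespace-delimited token of the header; the full header is kept in
#' the `description` metadata column. Duplicate ids are made unique with a
#' numeric suffix and a warning. Writing wraps at 60 columns; a write/read
#' round trip preserves ids and residues.
#'
#' @param path FASTA file path.
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @return `readFastaSequences()` returns a [Biostrings::DNAStringSet]
#'   named by id, with a `description` element in its metadata columns;
#'   `writeFastaSequences()` returns `path` invisibly.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stopParse("FASTA file not found: %s", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopParse("cannot parse FASTA %s: %s",
                                                path, conditionMessage(e)))
  if (length(raw) == 0) stopParse("FASTA file %s contains no records", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids made unique with numeric suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  res <- vapply(seq_along(raw), function(i)
    normalizeResidues(as.character(raw[[i]]), ids[i]), character(1))
  out <- Biostrings::DNAStringSet(res)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- headers
  out
}

#' @rdname readFastaSequences
#' @export
writeFastaSequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

## 5x5 scoring matrix in which N never matches (scored as a mismatch, even
## against itself)
scoringMatrix <- function(match, mismatch) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

#' Exact global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch/Gotoh alignment of two nucleotide sequences
#' under affine gap scoring: a gap of length L costs
#' `gapOpen + L * gapExtend` (both negative), end gaps included. `N`
#' matches nothing — it scores as a mismatch against every base including
#' another `N`, and never counts toward identity. Percent identity is
#' `matches x 100 / alignment columns` (gap columns in the denominator).
#' The defaults (+5 / -4 / -10 / -1) are conventional DNA scoring values.
#'
#' @param query,ref sequences: character strings, [Biostrings::DNAString]s
#'   or length-1 [Biostrings::DNAStringSet]s. Gap characters are stripped
#'   before aligning.
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; `match > 0`,
#'   the others `<= 0`.
#' @param queryId,refId labels; default to names when present.
#' @return an [AlignmentResult-class].
#' @examples
#' globalAlign("ACGT", "ACGA")   # 3/4 columns identical, 75%
#' @export
globalAlign <- function(query, ref, match = 5, mismatch = -4, gapOpen = -10,
                        gapExtend = -1, queryId = NULL, refId = NULL) {
  getOne <- function(x, fallback) {
    id <- fallback
    if (!is.null(names(x)) && nzchar(names(x)[1])) id <- names(x)[1]
    if (is(x, "DNAStringSet")) x <- x[[1]]
    list(seq = gsub("-", "", normalizeResidues(as.character(x), id)), id = id)
  }
  q <- getOne(query, if (is.null(queryId)) "query" else queryId)
  r <- getOne(ref, if (is.null(refId)) "ref" else refId)
  if (!is.null(queryId)) q$id <- queryId
  if (!is.null(refId)) r$id <- refId
  if (!nzchar(q$seq) || !nzchar(r$seq))
    stopValidation("sequences must be nonempty")
  if (match <= 0 || mismatch > 0 || gapOpen > 0 || gapExtend > 0)
    stopValidation("need match > 0 and mismatch/gapOpen/gapExtend <= 0")
  pa <- Biostrings::pairwiseAlignment(
    q$seq, r$seq, type = "global",
    substitutionMatrix = scoringMatrix(match, mismatch),
    gapOpening = -gapOpen, gapExtension = -gapExtend)
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(aq, "")[[1]]
  rc <- strsplit(ar, "")[[1]]
  matches <- sum(qc == rc & qc != "-" & qc != "N")
  len <- length(qc)
  new("AlignmentResult", queryId = q$id, refId = r$id, alignedQuery = aq,
      alignedRef = ar, matches = as.integer(matches),
      alignmentLength = as.integer(len),
      pctIdentity = matches * 100 / len, score = Biostrings::score(pa))
}

#' Rank a reference library by percent identity to a query
#'
#' Aligns the query globally against every reference (see [globalAlign()])
#' and ranks hits by percent identity, descending; ties are broken by
#' reference id so the ranking is deterministic. This is the local,
#' exact-alignment analogue of identifying an 18S rDNA amplicon by its
#' closest database matches.
#'
#' @param query a sequence (character / DNAString / length-1 DNAStringSet).
#' @param library a named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences.
#' @param topK keep the best `topK` hits (default all).
#' @inheritParams globalAlign
#' @return data.frame with columns `query_id`, `ref_id`,
#'   `ref_description`, `pct_identity`, `score`, `alignment_length`,
#'   `rank` (1..k, non-increasing identity).
#' @export
rankReferences <- function(query, library, match = 5, mismatch = -4,
                           gapOpen = -10, gapExtend = -1, topK = Inf,
                           queryId = NULL) {
  if (length(library) == 0) stopValidation("reference library is empty")
  if (is.character(library)) library <- Biostrings::DNAStringSet(library)
  ids <- names(library)
  if (is.null(ids) || any(!nzchar(ids)))
    stopValidation("reference library must be named")
  desc <- S4Vectors::mcols(library)$description
  if (is.null(desc)) desc <- ids
  hits <- lapply(seq_along(library), function(i) {
    al <- globalAlign(query, library[[i]], match = match,
                      mismatch = mismatch, gapOpen = gapOpen,
                      gapExtend = gapExtend, queryId = queryId,
                      refId = ids[i])
    data.frame(query_id = al@queryId, ref_id = ids[i],
               ref_description = desc[i], pct_identity = al@pctIdentity,
               score = al@score, alignment_length = al@alignmentLength,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, hits)
  tab <- tab[order(-tab$pct_identity, tab$ref_id), , drop = FALSE]
  tab <- head(tab, n = if (is.finite(topK)) topK else nrow(tab))
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Write a hit table as TSV
#'
#' @param hits data.frame from [rankReferences()].
#' @param path file path.
#' @param header optional comment lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.table(hits, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
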