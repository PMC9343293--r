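## End-to-end pipeline stages. Each stage is an exported function taking
## explicit parameters, validating them before any work, writing its
## outputs with an echoed configuration header, and returning the paths it
## wrote. A thin command-line wrapper over these functions ships in
## inst/scripts/habid; the functions are the tested surface. Errors carry
## classes habid_parse_error / habid_validation_error /
## habid_compute_error so callers can map them to distinct exit codes.

pkgVersion <- function() {
  as.character(utils::packageVersion("habid"))
}

configHeader <- function(stage, params) {
  c(sprintf("habid %s v%s", stage, pkgVersion()),
    sprintf("%s: %s", names(params),
            vapply(params, function(p) paste(format(p), collapse = " "),
                   character(1))))
}

writeMetadata <- function(path, stage, params) {
  meta <- c(list(tool = "habid", stage = stage, version = pkgVersion()),
            params)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline stage: simulate inputs
#'
#' Writes the deterministic study fixture (protein gel and zymogram band
#' tables plus the zone definition), a noisy simulated gel from the
#' fixture's generating profiles, and a tree-evolved aligned sequence set
#' with its true tree.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the stochastic outputs.
#' @param mwNoiseSD,intensityNoiseSD gel noise levels (see
#'   [simulateGel()]).
#' @param rootLength simulated sequence length (see
#'   [simulateSequences()]).
#' @param tree Newick string for the generating tree; the default is a
#'   balanced four-taxon tree of depth 0.1 substitutions/site.
#' @return named character vector of the files written, invisibly.
#' @export
pipelineSimulate <- function(outDir, seed = 1, mwNoiseSD = 0.005,
                             intensityNoiseSD = 0.05, rootLength = 1000,
                             tree = "((EukEH1:0.05,EukEH2:0.05):0.05,(EukEH3:0.05,EukEH4:0.05):0.05);") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fx <- makeStudyFixture()
  paths <- c(protein = file.path(outDir, "protein_bands.csv"),
             zymogram = file.path(outDir, "zymogram_bands.csv"),
             zones = file.path(outDir, "zymogram_zones.csv"),
             gel = file.path(outDir, "simulated_gel.csv"),
             alignment = file.path(outDir, "simulated_alignment.fasta"),
             trueTree = file.path(outDir, "true_tree.nwk"))
  hdr <- configHeader("simulate", list(seed = seed, mwNoiseSD = mwNoiseSD,
                                       intensityNoiseSD = intensityNoiseSD,
                                       rootLength = rootLength))
  writeBandTable(fx$protein, paths["protein"],
                 header = c(hdr, "deterministic study fixture: protein gel"))
  writeBandTable(fx$zymogram, paths["zymogram"],
                 header = c(hdr, "deterministic study fixture: zymogram"))
  con <- file(paths["zones"], "w"); write.csv(fx$zones, con,
                                              row.names = FALSE,
                                              quote = FALSE); close(con)
  gel <- simulateGel(studyBandProfiles(), mwNoiseSD = mwNoiseSD,
                     intensityNoiseSD = intensityNoiseSD, seed = seed)
  writeBandTable(gel, paths["gel"], header = hdr)
  phy <- readNewickTree(text = tree)
  sim <- simulateSequences(phy, rootLength = rootLength, seed = seed)
  writeFastaSequences(sim$alignment, paths["alignment"])
  writeNewickTree(sim$tree, paths["trueTree"])
  invisible(paths)
}

#' Pipeline stage: band matrix and polymorphism report
#'
#' Reads a band-table CSV, matches bands across lanes and writes the
#' presence matrix plus the polymorphism report. When a zone definition is
#' supplied the input is treated as a zymogram and scored per locus
#' instead.
#'
#' @param bandsCsv input band table CSV.
#' @param outPrefix path prefix for the two outputs
#'   (`<prefix>_matrix.csv`, `<prefix>_report.csv`).
#' @param relTolerance band-matching tolerance (see [matchBands()]).
#' @param zonesCsv optional zone-definition CSV (columns `locus`,
#'   `mobility_min`, `mobility_max`).
#' @return named character vector of the files written, invisibly.
#' @export
pipelineBands <- function(bandsCsv, outPrefix, relTolerance = 0.02,
                          zonesCsv = NULL) {
  if (relTolerance <= 0) stopValidation("relTolerance must be > 0")
  bands <- readBandTable(bandsCsv)
  hdr <- configHeader("bands", list(input = bandsCsv,
                                    relTolerance = relTolerance,
                                    zones = if (is.null(zonesCsv)) "none"
                                            else zonesCsv))
  reportPath <- paste0(outPrefix, "_report.csv")
  if (!is.null(zonesCsv)) {
    zones <- tryCatch(read.csv(zonesCsv, stringsAsFactors = FALSE),
                      error = function(e) stopParse("cannot parse %s: %s",
                                                    zonesCsv,
                                                    conditionMessage(e)))
    rep <- zymogramStats(bands, zones)
    writePolymorphismReport(rep, reportPath, header = hdr)
    return(invisible(c(report = reportPath)))
  }
  bm <- matchBands(bands, relTolerance = relTolerance)
  matrixPath <- paste0(outPrefix, "_matrix.csv")
  writePresenceMatrix(bm, matrixPath, header = hdr)
  rep <- polymorphismStats(bm)
  writePolymorphismReport(rep, reportPath, header = hdr)
  invisible(c(matrix = matrixPath, report = reportPath))
}

#' Pipeline stage: similarity and UPGMA dendrogram
#'
#' Reads a band-table CSV, computes lane-to-lane similarity under the
#' chosen coefficient and writes the similarity matrix (CSV) and the UPGMA
#' dendrogram (Newick plus a merge-table CSV).
#'
#' @param bandsCsv input band table CSV.
#' @param outPrefix path prefix for outputs (`<prefix>_similarity.csv`,
#'   `<prefix>_dendrogram.nwk`, `<prefix>_merges.csv`).
#' @param coefficient similarity coefficient (see [similarityMatrix()]).
#' @param relTolerance band-matching tolerance.
#' @return named character vector of the files written, invisibly.
#' @export
pipelineCluster <- function(bandsCsv, outPrefix, coefficient = "dice",
                            relTolerance = 0.02) {
  bands <- readBandTable(bandsCsv)
  bm <- matchBands(bands, relTolerance = relTolerance)
  sim <- similarityMatrix(bm, coefficient = coefficient)
  hdr <- configHeader("cluster", list(input = bandsCsv,
                                      coefficient = coefficient,
                                      relTolerance = relTolerance))
  paths <- c(similarity = paste0(outPrefix, "_similarity.csv"),
             dendrogram = paste0(outPrefix, "_dendrogram.nwk"),
             merges = paste0(outPrefix, "_merges.csv"))
  writeSimilarityMatrix(sim, paths["similarity"], header = hdr)
  dend <- upgmaDendrogram(sim)
  dendrogramNewick(dend, paths["dendrogram"])
  merges <- data.frame(merge1 = dend$merge[, 1], merge2 = dend$merge[, 2],
                       height = dend$height)
  con <- file(paths["merges"], "w")
  writeLines(paste("#", hdr), con)
  write.csv(merges, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(paths)
}

#' Pipeline stage: identify queries against a reference library
#'
#' Ranks every query sequence against the reference FASTA by global
#' alignment percent identity and writes one combined TSV hit table.
#'
#' @param queryFasta,libraryFasta FASTA paths.
#' @param out output TSV path.
#' @param topK hits kept per query (default all).
#' @inheritParams globalAlign
#' @return the output path, invisibly.
#' @export
pipelineIdentify <- function(queryFasta, libraryFasta, out, match = 5,
                             mismatch = -4, gapOpen = -10, gapExtend = -1,
                             topK = Inf) {
  queries <- readFastaSequences(queryFasta)
  library <- readFastaSequences(libraryFasta)
  hits <- do.call(rbind, lapply(names(queries), function(q)
    rankReferences(queries[[q]], library, match = match,
                   mismatch = mismatch, gapOpen = gapOpen,
                   gapExtend = gapExtend, topK = topK, queryId = q)))
  hdr <- configHeader("identify",
                      list(query = queryFasta, library = libraryFasta,
                           match = match, mismatch = mismatch,
                           gapOpen = gapOpen, gapExtend = gapExtend,
                           topK = if (is.finite(topK)) topK else "all",
                           identity_denominator = "all alignment columns incl. gaps"))
  writeHitTable(hits, out, header = hdr)
  invisible(out)
}

#' Pipeline stage: bootstrap tree from an aligned FASTA
#'
#' Builds the distance tree with bootstrap supports and writes the Newick
#' (supports as internal node labels) plus a JSON metadata sidecar
#' recording seed, replicates and skip count.
#'
#' @param alignedFasta aligned FASTA path.
#' @param outPrefix path prefix for outputs (`<prefix>.nwk`,
#'   `<prefix>_meta.json`).
#' @param builder,replicates,seed,model see [bootstrapSupport()].
#' @return named character vector of the files written, invisibly.
#' @export
pipelineTree <- function(alignedFasta, outPrefix, builder = "nj",
                         replicates = 500, seed = 1, model = "jc69") {
  aln <- readFastaSequences(alignedFasta)
  bs <- bootstrapSupport(aln, builder = builder, replicates = replicates,
                         seed = seed, model = model)
  paths <- c(tree = paste0(outPrefix, ".nwk"),
             meta = paste0(outPrefix, "_meta.json"))
  writeNewickTree(bs$tree, paths["tree"])
  writeMetadata(paths["meta"], "tree",
                list(input = alignedFasta, builder = builder,
                     model = model, replicates = bs$replicates,
                     kept = bs$kept, skipped = bs$skipped, seed = seed,
                     gap_handling = "pairwise deletion",
                     resampling = "alignment columns with replacement"))
  invisible(paths)
}
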