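.stageLog <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full case/control association pipeline
#'
#' Executes the stages in dependency order: read and length-filter
#' contigs and counts, score and classify contigs, test domain families
#' for association, call candidate genes, run domain co-occurrence on
#' the top associated families, and (when an alignment and labels are
#' supplied) compute the differential conservation profile. Optional
#' inputs that are missing skip their stage with a notice. All result
#' tables are written as TSV with a provenance header reproducing the
#' parameter set, so a rerun with the same inputs and configuration is
#' byte-identical.
#'
#' @param contigsFile contigs FASTA.
#' @param countsFile per-contig case/control counts TSV.
#' @param hitsFile domtblout-layout domain hits.
#' @param orfsFile ORF coordinates (GFF3 or TSV).
#' @param outDir output directory.
#' @param alignmentFile,labelsFile optional aligned FASTA plus
#'   sequence-group labels TSV for the conservation stage.
#' @param matrixFile substitution matrix (default: packaged BLOSUM80).
#' @param referenceId optional reference row for position numbering.
#' @param treeFile optional newick tree scored for clade purity against
#'   the alignment group labels.
#' @param minLength,threshold,pseudocount enrichment stage parameters.
#' @param evalueCeiling domain-hit i-Evalue ceiling.
#' @param alphaAssoc,alphaCooccur significance levels of the association
#'   and co-occurrence stages.
#' @param topK number of top associated families carried into
#'   co-occurrence (default 20).
#' @param minOccupancy conservation stage occupancy filter.
#' @param candidateBy candidate-gene assignment path (`"target"` or
#'   `"overlap"`).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with elements `enrichment`, `association`,
#'   `candidates`, `cooccurrence`, `conservation` (NULL when skipped),
#'   `cladePurity` (NULL when skipped) and `files` (paths written).
#' @export
runPipeline <- function(contigsFile, countsFile, hitsFile, orfsFile,
                        outDir, alignmentFile = NULL, labelsFile = NULL,
                        matrixFile = NULL, referenceId = NA_character_,
                        treeFile = NULL, minLength = 1000L, threshold = 3,
                        pseudocount = 0, evalueCeiling = 1e-5,
                        alphaAssoc = 0.01, alphaCooccur = 0.05,
                        topK = 20L, minOccupancy = 0.5,
                        candidateBy = c("target", "overlap"),
                        quiet = FALSE) {
  candidateBy <- match.arg(candidateBy)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c()

  .stageLog(quiet, "[1/5] reading inputs")
  contigs <- readContigs(contigsFile)
  coverage <- readCountsTable(countsFile, contigs)
  orfs <- readOrfs(orfsFile, contigs = contigs)
  hits <- readDomainHits(hitsFile, evalueCeiling, orfs)

  .stageLog(quiet, "[2/5] enrichment scoring (min length %d, threshold %g)",
            minLength, threshold)
  enrichment <- classifyContigs(coverage, threshold, minLength, pseudocount)
  files["enrichment"] <- file.path(outDir, "enrichment.tsv")
  writeEnrichmentTable(enrichment, files[["enrichment"]])
  labs <- contigLabels(enrichment)
  .stageLog(quiet, "  %d contigs retained: %d modified, %d unmodified",
            nrow(resultTable(enrichment)), sum(labs == "modified"),
            sum(labs == "unmodified"))

  .stageLog(quiet, "[3/5] domain association (alpha %g)", alphaAssoc)
  association <- associateDomains(hits, enrichment, alphaAssoc)
  files["association"] <- file.path(outDir, "assoc.tsv")
  writeAssociationTable(association, files[["association"]])
  sig <- significantDomains(association)
  .stageLog(quiet, "  %d families tested, %d significant",
            association@m, length(sig))

  candidates <- callCandidateGenes(orfs, hits, association, enrichment,
                                   by = candidateBy)
  files["candidates"] <- file.path(outDir, "candidates.tsv")
  writeResultTable(candidates, files[["candidates"]], "candidates",
                   list(alpha = alphaAssoc, by = candidateBy))
  .stageLog(quiet, "  %d candidate genes", nrow(candidates))

  .stageLog(quiet, "[4/5] co-occurrence of top %d families (alpha %g)",
            topK, alphaCooccur)
  cooccurrence <- NULL
  adf <- resultTable(association)
  topDoms <- utils::head(
    adf$accession[adf$direction == "modified-enriched"], topK)
  if (length(topDoms) >= 2L) {
    pm <- buildPresenceMatrix(hits, enrichment, scope = "all")
    cooccurrence <- testPairs(pm, topDoms, alphaCooccur)
    files["cooccurrence"] <- file.path(outDir, "edges.tsv")
    writeCooccurrenceTable(cooccurrence, files[["cooccurrence"]])
    .stageLog(quiet, "  %d significant positive edges",
              sum(resultTable(cooccurrence)$significant))
  } else {
    .stageLog(quiet, "  skipped: fewer than two modified-enriched families")
  }

  conservation <- NULL
  purity <- NULL
  if (!is.null(alignmentFile) && !is.null(labelsFile)) {
    .stageLog(quiet, "[5/5] differential conservation (min occupancy %g)",
              minOccupancy)
    mat <- if (is.null(matrixFile)) blosum80()
           else readSubstitutionMatrix(matrixFile)
    ga <- readGroupedAlignment(alignmentFile, labelsFile, referenceId)
    conservation <- conservationProfile(ga, mat, minOccupancy)
    files["conservation"] <- file.path(outDir, "profile.tsv")
    writeConservationProfile(conservation, files[["conservation"]])
    if (!is.null(treeFile)) {
      grp <- alignmentGroups(ga)
      purity <- cladePurity(treeFile,
                            stats::setNames(as.character(grp), names(grp)))
    }
  } else {
    .stageLog(quiet, "[5/5] conservation stage skipped: no alignment input")
  }

  invisible(list(enrichment = enrichment, association = association,
                 candidates = candidates, cooccurrence = cooccurrence,
                 conservation = conservation, cladePurity = purity,
                 files = files))
}
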