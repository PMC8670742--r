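#' Extract the per-contig result table of an object
#'
#' @param x a result object (`CoverageTable`, `EnrichmentTable`,
#'   `AssociationTable`, `ConservationProfile` or `CooccurrenceTable`).
#' @return a `DataFrame` of per-row results.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname resultTable
#' @export
setMethod("resultTable", "CoverageTable", function(x) x@counts)
#' @rdname resultTable
#' @export
setMethod("resultTable", "EnrichmentTable", function(x) x@results)
#' @rdname resultTable
#' @export
setMethod("resultTable", "AssociationTable", function(x) x@results)
#' @rdname resultTable
#' @export
setMethod("resultTable", "ConservationProfile", function(x) x@profile)
#' @rdname resultTable
#' @export
setMethod("resultTable", "CooccurrenceTable", function(x) x@results)

#' Library totals of a coverage or enrichment table
#'
#' @param x a `CoverageTable` or `EnrichmentTable`.
#' @return named numeric vector with elements `case` and `control`.
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @rdname libraryTotals
#' @export
setMethod("libraryTotals", "CoverageTable", function(x)
  c(case = x@totalCase, control = x@totalControl))
#' @rdname libraryTotals
#' @export
setMethod("libraryTotals", "EnrichmentTable", function(x)
  c(case = x@totalCase, control = x@totalControl))

#' Modified/unmodified contig labels
#'
#' Returns the label assigned to each determinate contig; indeterminate
#' contigs (no coverage in either library) are omitted.
#'
#' @param x an `EnrichmentTable`.
#' @return named character vector of `"modified"` / `"unmodified"`.
#' @export
setGeneric("contigLabels", function(x) standardGeneric("contigLabels"))

#' @rdname contigLabels
#' @export
setMethod("contigLabels", "EnrichmentTable", function(x) {
  df <- x@results
  keep <- df$label != "indeterminate"
  stats::setNames(as.character(df$label[keep]), df$contig_id[keep])
})

#' Ids of contigs labelled modified
#'
#' @param x an `EnrichmentTable`.
#' @return character vector of contig ids.
#' @export
setGeneric("modifiedContigs", function(x) standardGeneric("modifiedContigs"))

#' @rdname modifiedContigs
#' @export
setMethod("modifiedContigs", "EnrichmentTable", function(x) {
  df <- x@results
  as.character(df$contig_id[df$label == "modified"])
})

#' Accessions of significantly phenotype-associated domain families
#'
#' @param x an `AssociationTable`.
#' @return character vector of (version-stripped) accessions that are
#'   modified-enriched with Bonferroni-adjusted p below alpha.
#' @export
setGeneric("significantDomains",
           function(x) standardGeneric("significantDomains"))

#' @rdname significantDomains
#' @export
setMethod("significantDomains", "AssociationTable", function(x) {
  df <- x@results
  as.character(df$accession[df$significant])
})

#' Group labels of a grouped alignment
#'
#' @param x a `GroupedAlignment`.
#' @return named factor with levels `modified`, `unmodified`.
#' @export
setGeneric("alignmentGroups", function(x) standardGeneric("alignmentGroups"))

#' @rdname alignmentGroups
#' @export
setMethod("alignmentGroups", "GroupedAlignment", function(x) x@groups)

#' @describeIn GroupedAlignment-class number of alignment columns
#' @param x a `GroupedAlignment`.
#' @export
setMethod("ncol", "GroupedAlignment", function(x)
  unique(Biostrings::width(x@aln)))

#' @describeIn GroupedAlignment-class number of sequences
#' @export
setMethod("nrow", "GroupedAlignment", function(x) length(x@aln))

setMethod("show", "CoverageTable", function(object) {
  cat(sprintf("CoverageTable: %d contigs; totals case=%g control=%g%s\n",
              nrow(object@counts), object@totalCase, object@totalControl,
              if (object@totalsSupplied) " (supplied)" else ""))
})

setMethod("show", "EnrichmentTable", function(object) {
  tab <- table(factor(object@results$label,
                      c("modified", "unmodified", "indeterminate")))
  cat(sprintf(paste0("EnrichmentTable: %d contigs (>= %d bp), threshold %g\n",
                     "  modified=%d unmodified=%d indeterminate=%d\n"),
              nrow(object@results), object@minLength, object@threshold,
              tab["modified"], tab["unmodified"], tab["indeterminate"]))
})

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf(paste0("AssociationTable: %d domain families tested ",
                     "(Bonferroni m=%d, alpha=%g); %d significant\n"),
              nrow(object@results), object@m, object@alpha,
              sum(object@results$significant)))
})

setMethod("show", "GroupedAlignment", function(object) {
  tab <- table(object@groups)
  cat(sprintf(paste0("GroupedAlignment: %d sequences x %d columns ",
                     "(modified=%d, unmodified=%d)%s\n"),
              length(object@aln), ncol(object), tab["modified"],
              tab["unmodified"],
              if (!is.na(object@referenceId))
                paste0("; reference ", object@referenceId) else ""))
})

setMethod("show", "ConservationProfile", function(object) {
  s <- object@profile$S
  cat(sprintf(paste0("ConservationProfile: %d retained columns ",
                     "(min occupancy %g, matrix %s); max S = %s\n"),
              nrow(object@profile), object@minOccupancy, object@matrixName,
              if (all(is.na(s))) "NA" else format(max(s, na.rm = TRUE))))
})

setMethod("show", "CooccurrenceTable", function(object) {
  cat(sprintf(paste0("CooccurrenceTable: %d pairs on %s contigs; ",
                     "%d significant positive edges (alpha=%g)\n"),
              nrow(object@results), object@scope,
              sum(object@results$significant), object@alpha))
})

setMethod("show", "CladePurity", function(object) {
  cat(sprintf(paste0("CladePurity: best clade of %d leaves; purity=%.3f ",
                     "coverage=%.3f F1=%.3f (%d edges scanned)\n"),
              length(object@leaves), object@purity, object@coverage,
              object@f1, object@nEdges))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: seed=%d, %d contigs ",
                     "(%.0f%% modified, %d-%d bp), %s counts ",
                     "(cov %g/kb, disp %g), EF=%g DF=%g\n",
                     "  domains: %d planted @ %g vs %g background ",
                     "(%d families); MSA %dx2 rows x %d cols, ",
                     "%d planted col(s), noise %g, gaps %g\n"),
              object@seed, object@nContigs, 100 * object@fractionModified,
              object@lengthRange[1], object@lengthRange[2],
              object@countModel, object@meanCoverage, object@dispersion,
              object@enrichmentFactor, object@depletionFactor,
              object@nPlantedDomains, object@plantedPrevalence,
              object@backgroundPrevalence, object@nDomains,
              object@msaRowsPerGroup, object@msaWidth,
              object@msaPlantedColumns, object@msaNoise, object@msaGapRate))
})
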