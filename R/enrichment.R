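#' Drop contigs below a minimum length
#'
#' Short contigs carry noisy coverage estimates, so only contigs of at
#' least `minLength` bp (default 1000) enter the enrichment analysis.
#'
#' @param contigs a [Biostrings::DNAStringSet], a [CoverageTable-class],
#'   or a named integer vector of lengths.
#' @param minLength minimum retained length in bp; the boundary length is
#'   kept.
#' @return object of the same kind restricted to retained contigs.
#' @export
filterContigs <- function(contigs, minLength = 1000) {
  if (methods::is(contigs, "CoverageTable")) {
    keep <- contigs@counts$length >= minLength
    n_removed <- sum(!keep)
    if (n_removed) message(n_removed, " contig(s) below ", minLength,
                           " bp removed")
    if (!any(keep)) stop("no contigs of length >= ", minLength)
    return(CoverageTable(contigs@counts[keep, , drop = FALSE],
                         totalCase = if (contigs@totalsSupplied)
                           contigs@totalCase else NA_real_,
                         totalControl = if (contigs@totalsSupplied)
                           contigs@totalControl else NA_real_))
  }
  lens <- if (methods::is(contigs, "XStringSet")) Biostrings::width(contigs)
          else contigs
  keep <- lens >= minLength
  n_removed <- sum(!keep)
  if (n_removed) message(n_removed, " contig(s) below ", minLength,
                         " bp removed")
  contigs[keep]
}

#' Reads per kilobase of contig per million mapped reads
#'
#' RPKM = count / (length / 1000) / (total / 1e6), normalising each
#' contig's mapped-read count for contig length and library depth.
#'
#' @param count mapped reads on the contig (vectorised).
#' @param contigLength contig length in bp (> 0).
#' @param libraryTotal total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @export
computeRPKM <- function(count, contigLength, libraryTotal) {
  if (any(libraryTotal <= 0)) stop("empty library: library total must be > 0")
  if (any(contigLength <= 0)) stop("contig length must be > 0")
  if (any(count < 0)) stop("negative count")
  count / (contigLength / 1000) / (libraryTotal / 1e6)
}

#' Per-contig enrichment score
#'
#' The enrichment score of a contig is the ratio of its case (selected)
#' RPKM to its control RPKM. The ratio is unguarded: when the control
#' RPKM is zero but the case RPKM positive the score is `Inf` (the contig
#' is maximally enriched), and when both are zero the score is `NA`
#' (indeterminate). Users who want finite scores can add a pseudocount at
#' the counting stage ([classifyContigs()]).
#'
#' @param rpkmCase,rpkmControl non-negative RPKM values (vectorised).
#' @return numeric score(s); `Inf` for case-only coverage, `NA` for no
#'   coverage.
#' @export
enrichmentScore <- function(rpkmCase, rpkmControl) {
  if (any(rpkmCase < 0) || any(rpkmControl < 0))
    stop("RPKM values must be non-negative")
  score <- rpkmCase / rpkmControl          # Inf when control 0, case > 0
  score[rpkmCase == 0 & rpkmControl == 0] <- NA_real_
  score
}

#' Label enrichment scores as modified / unmodified
#'
#' A contig is modified when its score is greater than or equal to the
#' threshold (default 3), unmodified when below, and indeterminate when
#' the score is `NA`. Raising the threshold never converts an unmodified
#' contig to modified.
#'
#' @param score numeric enrichment scores (`Inf` and `NA` allowed).
#' @param threshold modification threshold (default 3).
#' @return character vector of `"modified"` / `"unmodified"` /
#'   `"indeterminate"`.
#' @export
scoreLabels <- function(score, threshold = 3) {
  ifelse(is.na(score), "indeterminate",
         ifelse(score >= threshold, "modified", "unmodified"))
}

#' Score and classify contigs from a case/control coverage table
#'
#' Applies the full enrichment stage: length filtering, RPKM
#' normalisation of both libraries, enrichment scoring, and
#' classification at the score threshold. Unless totals were supplied
#' externally, library totals are the mapped reads on the *retained*
#' contig set, so normalisation is internally consistent with the
#' filtering.
#'
#' @param coverage a [CoverageTable-class].
#' @param threshold score at or above which a contig is called modified
#'   (default 3).
#' @param minLength minimum contig length in bp (default 1000).
#' @param pseudocount constant added to both counts of every contig
#'   before normalisation (default 0, i.e. the unguarded ratio).
#' @return an [EnrichmentTable-class].
#' @export
classifyContigs <- function(coverage, threshold = 3, minLength = 1000L,
                            pseudocount = 0) {
  stopifnot(methods::is(coverage, "CoverageTable"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  coverage <- filterContigs(coverage, minLength)
  df <- coverage@counts
  cc <- df$count_case + pseudocount
  ct <- df$count_control + pseudocount
  totalCase <- if (coverage@totalsSupplied) coverage@totalCase
               else sum(cc)
  totalControl <- if (coverage@totalsSupplied) coverage@totalControl
                  else sum(ct)
  rpkm_case <- computeRPKM(cc, df$length, totalCase)
  rpkm_control <- computeRPKM(ct, df$length, totalControl)
  score <- enrichmentScore(rpkm_case, rpkm_control)
  label <- scoreLabels(score, threshold)
  res <- S4Vectors::DataFrame(
    contig_id = df$contig_id, length = df$length,
    count_case = df$count_case, count_control = df$count_control,
    rpkm_case = rpkm_case, rpkm_control = rpkm_control,
    score = score, zero_control = is.infinite(score), label = label)
  n_ind <- sum(label == "indeterminate")
  if (n_ind) message(n_ind, " contig(s) with no coverage in either ",
                     "library are indeterminate")
  methods::new("EnrichmentTable", results = res,
               threshold = as.numeric(threshold),
               minLength = as.integer(minLength),
               pseudocount = as.numeric(pseudocount),
               totalCase = totalCase, totalControl = totalControl)
}

#' Write an EnrichmentTable as TSV
#'
#' @param x an [EnrichmentTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(x, path) {
  stopifnot(methods::is(x, "EnrichmentTable"))
  writeResultTable(x@results, path, "enrichment",
                   list(threshold = x@threshold, min_length = x@minLength,
                        pseudocount = x@pseudocount,
                        total_case = x@totalCase,
                        total_control = x@totalControl))
}

#' Read an enrichment TSV back into contig labels
#'
#' Convenience reader for pipeline stages that only need the
#' modified/unmodified partition of a previously written enrichment
#' table.
#'
#' @param path file written by [writeEnrichmentTable()].
#' @return named character vector of contig labels, indeterminate contigs
#'   omitted.
#' @export
readContigLabels <- function(path) {
  df <- readResultTable(path)
  keep <- df$label != "indeterminate"
  stats::setNames(df$label[keep], df$contig_id[keep])
}
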