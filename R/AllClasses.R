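#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Per-contig mapped-read counts for a case/control library pair
#'
#' Holds one row per contig with its length and the number of reads mapped
#' to it in the case (phenotype-selected) and control (total) libraries,
#' plus the two library totals used for RPKM normalisation. Totals are
#' column sums unless they were supplied externally (e.g. via a header
#' directive in the counts file), in which case `totalsSupplied` is `TRUE`
#' and downstream steps keep them fixed.
#'
#' @slot counts `DataFrame` with columns `contig_id`, `length`,
#'   `count_case`, `count_control`.
#' @slot totalCase,totalControl numeric(1) library totals (mapped reads).
#' @slot totalsSupplied logical(1); `TRUE` when totals came from the input
#'   file rather than from column sums.
#' @exportClass CoverageTable
setClass("CoverageTable",
  representation(
    counts        = "DataFrame",
    totalCase     = "numeric",
    totalControl  = "numeric",
    totalsSupplied = "logical"
  )
)

setValidity("CoverageTable", function(object) {
  df <- object@counts
  need <- c("contig_id", "length", "count_case", "count_control")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L)
    return("no contigs")
  if (anyDuplicated(df$contig_id))
    return(paste("duplicated contig_id:",
                 df$contig_id[duplicated(df$contig_id)][1L]))
  if (any(df$count_case < 0) || any(df$count_control < 0))
    return("negative counts")
  if (any(df$length <= 0))
    return("contig lengths must be positive")
  if (object@totalCase < sum(df$count_case) - 1e-8 ||
      object@totalControl < sum(df$count_control) - 1e-8)
    return("library totals smaller than column sums")
  TRUE
})

#' Per-contig enrichment scores and modified/unmodified labels
#'
#' Result of [classifyContigs()]: RPKM values for both libraries, the
#' enrichment score (case RPKM / control RPKM) and the label assigned at
#' the score threshold. Contigs with zero control RPKM but nonzero case
#' RPKM get an infinite score, a `modified` label and `zero_control =
#' TRUE`; contigs with zero coverage in both libraries are
#' `indeterminate` and excluded from both groups.
#'
#' @slot results `DataFrame` with columns `contig_id`, `length`,
#'   `count_case`, `count_control`, `rpkm_case`, `rpkm_control`, `score`,
#'   `zero_control`, `label`.
#' @slot threshold numeric(1) score at or above which a contig is modified.
#' @slot minLength integer(1) minimum contig length applied before scoring.
#' @slot pseudocount numeric(1) constant added to both counts (0 = none).
#' @slot totalCase,totalControl numeric(1) library totals used for RPKM.
#' @exportClass EnrichmentTable
setClass("EnrichmentTable",
  representation(
    results     = "DataFrame",
    threshold   = "numeric",
    minLength   = "integer",
    pseudocount = "numeric",
    totalCase   = "numeric",
    totalControl = "numeric"
  )
)

setValidity("EnrichmentTable", function(object) {
  df <- object@results
  need <- c("contig_id", "length", "rpkm_case", "rpkm_control", "score",
            "zero_control", "label")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(df$label %in% c("modified", "unmodified", "indeterminate")))
    return("labels must be modified/unmodified/indeterminate")
  ok <- !is.na(df$score)
  if (any(df$label[ok] == "modified" & df$score[ok] < object@threshold))
    return("modified label below threshold")
  if (any(df$label[ok] == "unmodified" & df$score[ok] >= object@threshold))
    return("unmodified label at or above threshold")
  TRUE
})

#' Domain-family association test results
#'
#' One row per domain family tested: the 2x2 contingency counts (a =
#' modified contigs carrying the domain, b = modified lacking it, c =
#' unmodified carrying it, d = unmodified lacking it), the raw two-sided
#' Fisher p-value, the Bonferroni-adjusted p-value, the direction of the
#' imbalance and the significance call (adjusted p below alpha *and*
#' modified-enriched). Rows are ranked by ascending raw p.
#'
#' @slot results `DataFrame` with columns `accession`, `name`, `a`, `b`,
#'   `c`, `d`, `p_raw`, `p_adjusted`, `direction`, `significant`.
#' @slot m integer(1) number of domain families tested (the Bonferroni
#'   multiplier).
#' @slot alpha numeric(1) significance level on the adjusted p-value.
#' @exportClass AssociationTable
setClass("AssociationTable",
  representation(results = "DataFrame", m = "integer", alpha = "numeric")
)

setValidity("AssociationTable", function(object) {
  df <- object@results
  need <- c("accession", "a", "b", "c", "d", "p_raw", "p_adjusted",
            "direction", "significant")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (object@m < 1L) return("m must be >= 1")
  if (any(df$p_raw < 0 | df$p_raw > 1)) return("p_raw outside [0,1]")
  if (any(abs(df$p_adjusted - pmin(1, df$p_raw * object@m)) > 1e-12))
    return("p_adjusted != min(1, p_raw * m)")
  TRUE
})

#' Group-labelled protein multiple alignment
#'
#' An amino-acid alignment in which every row carries a `modified` or
#' `unmodified` group label (whether the protein was encoded on modified
#' or unmodified DNA), optionally with one row designated as the
#' reference used for position numbering. Both groups must contain at
#' least two sequences, otherwise the intra-group similarity denominator
#' N(N-1) vanishes.
#'
#' @slot aln `AAStringSet`, all elements the same width; `-` and `.` are
#'   gap characters.
#' @slot groups named factor with levels `modified`, `unmodified`; names
#'   match the alignment row names.
#' @slot referenceId character(1) row id used by [mapToReference()], or
#'   `NA`.
#' @exportClass GroupedAlignment
setClass("GroupedAlignment",
  representation(aln = "AAStringSet", groups = "factor",
                 referenceId = "character")
)

setValidity("GroupedAlignment", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(w) == 0L) return("empty alignment")
  if (length(unique(w)) != 1L) return("ragged alignment: unequal row widths")
  ids <- names(object@aln)
  if (is.null(ids) || anyDuplicated(ids)) return("rows must have unique ids")
  if (!identical(sort(names(object@groups)), sort(ids))) {
    missing <- setdiff(ids, names(object@groups))
    if (length(missing))
      return(paste("unlabelled row(s):", paste(missing, collapse = ", ")))
    return("labels for rows absent from the alignment")
  }
  if (!identical(levels(object@groups), c("modified", "unmodified")))
    return("group levels must be modified, unmodified")
  tab <- table(object@groups)
  if (any(tab < 2L))
    return(paste("each group needs >= 2 sequences; got",
                 paste(tab, collapse = "/"),
                 "(intra-group similarity undefined)"))
  if (!is.na(object@referenceId) && !(object@referenceId %in% ids))
    return(paste("reference row not in alignment:", object@referenceId))
  TRUE
})

#' Per-column differential conservation profile
#'
#' Result of [conservationProfile()]: for every alignment column passing
#' the occupancy filter, the per-group residue counts, the two intra-group
#' similarity scores, the inter-group similarity and the differential
#' conservation score S = (I_modified + I_unmodified)/2 - J. Columns where
#' a group has fewer than two residues are reported with S missing rather
#' than zero.
#'
#' @slot profile `DataFrame` with columns `column`, `ref_position`,
#'   `occupancy`, `n_modified`, `n_unmodified`, `I_modified`,
#'   `I_unmodified`, `J`, `S`.
#' @slot minOccupancy numeric(1) occupancy filter applied.
#' @slot matrixName character(1) substitution matrix used.
#' @exportClass ConservationProfile
setClass("ConservationProfile",
  representation(profile = "DataFrame", minOccupancy = "numeric",
                 matrixName = "character")
)

setValidity("ConservationProfile", function(object) {
  df <- object@profile
  need <- c("column", "occupancy", "n_modified", "n_unmodified",
            "I_modified", "I_unmodified", "J", "S")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(df$occupancy < object@minOccupancy - 1e-12))
    return("column below occupancy filter retained")
  ok <- !is.na(df$S)
  if (any(abs(df$S[ok] -
              ((df$I_modified[ok] + df$I_unmodified[ok]) / 2 - df$J[ok])) >
          1e-9))
    return("S != (I_modified + I_unmodified)/2 - J")
  TRUE
})

#' Pairwise domain co-occurrence test results
#'
#' One row per unordered domain pair: presence counts, the observed joint
#' count and the exact upper-/lower-tail probabilities under the
#' fixed-marginal hypergeometric null. An edge is significant when the
#' upper-tail probability (positive association) falls below alpha.
#'
#' @slot results `DataFrame` with columns `domain1`, `domain2`, `N`, `n1`,
#'   `n2`, `j_obs`, `p_ge`, `p_le`, `significant`.
#' @slot alpha numeric(1) threshold on `p_ge`.
#' @slot scope character(1) contig scope the matrix was built on.
#' @exportClass CooccurrenceTable
setClass("CooccurrenceTable",
  representation(results = "DataFrame", alpha = "numeric",
                 scope = "character")
)

setValidity("CooccurrenceTable", function(object) {
  df <- object@results
  need <- c("domain1", "domain2", "N", "n1", "n2", "j_obs", "p_ge", "p_le")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  lo <- pmax(0, df$n1 + df$n2 - df$N)
  hi <- pmin(df$n1, df$n2)
  if (any(df$j_obs < lo | df$j_obs > hi))
    return("j_obs outside feasibility bounds")
  if (any(df$p_ge < 0 | df$p_ge > 1 + 1e-12) ||
      any(df$p_le < 0 | df$p_le > 1 + 1e-12))
    return("tail probabilities outside [0,1]")
  TRUE
})

#' Best label-pure clade of a phenotype-labelled tree
#'
#' Quantifies how well the modified-labelled leaves cluster on a tree:
#' every edge of the (unrooted) tree bipartitions the leaves, and the
#' side maximising the F1 of purity (fraction of the side's leaves that
#' are modified) and coverage (fraction of all modified leaves captured)
#' is reported.
#'
#' @slot leaves character vector of leaf ids in the best clade side.
#' @slot purity,coverage,f1 numeric(1) scores of the best side.
#' @slot nEdges integer(1) number of edges scanned.
#' @exportClass CladePurity
setClass("CladePurity",
  representation(leaves = "character", purity = "numeric",
                 coverage = "numeric", f1 = "numeric", nEdges = "integer")
)

#' Configuration for the synthetic case/control fixture generator
#'
#' Bundles every knob of the simulator: community size and composition,
#' the count model for the two libraries, domain planting rates, and the
#' grouped-alignment generator. Identical configurations produce
#' byte-identical outputs; all randomness flows from `seed`.
#'
#' @slot seed integer(1) master seed.
#' @slot nContigs integer(1) contigs in the community.
#' @slot fractionModified numeric(1) fraction of contigs carrying the
#'   phenotype.
#' @slot lengthRange integer(2) contig length range (bp).
#' @slot meanCoverage numeric(1) expected control-library reads per kb.
#' @slot dispersion numeric(1) negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); ignored for the Poisson model.
#' @slot countModel character(1) `"nb"` or `"poisson"`.
#' @slot enrichmentFactor numeric(1) case-coverage multiplier for
#'   modified contigs.
#' @slot depletionFactor numeric(1) case-coverage multiplier for
#'   unmodified contigs.
#' @slot nDomains integer(1) background domain families.
#' @slot nPlantedDomains integer(1) phenotype-associated families.
#' @slot plantedPrevalence numeric(1) probability a modified contig
#'   carries each planted family.
#' @slot backgroundPrevalence numeric(1) probability an unmodified contig
#'   carries each planted family (and any contig each background family).
#' @slot hitDuplicationRate numeric(1) probability a placed hit is
#'   duplicated on its contig (exercises once-per-contig counting).
#' @slot msaRowsPerGroup,msaWidth,msaPlantedColumns integer(1) grouped
#'   alignment geometry.
#' @slot msaNoise numeric(1) per-residue substitution rate applied after
#'   planting.
#' @slot msaGapRate numeric(1) per-cell gap injection rate.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer", nContigs = "integer", fractionModified = "numeric",
    lengthRange = "integer", meanCoverage = "numeric",
    dispersion = "numeric", countModel = "character",
    enrichmentFactor = "numeric", depletionFactor = "numeric",
    nDomains = "integer", nPlantedDomains = "integer",
    plantedPrevalence = "numeric", backgroundPrevalence = "numeric",
    hitDuplicationRate = "numeric",
    msaRowsPerGroup = "integer", msaWidth = "integer",
    msaPlantedColumns = "integer", msaNoise = "numeric",
    msaGapRate = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  rates <- c(object@fractionModified, object@plantedPrevalence,
             object@backgroundPrevalence, object@hitDuplicationRate,
             object@msaNoise, object@msaGapRate)
  if (any(rates < 0 | rates > 1)) return("all rates must lie in [0,1]")
  if (object@enrichmentFactor <= 0 || object@depletionFactor <= 0)
    return("coverage factors must be positive")
  if (!object@countModel %in% c("nb", "poisson"))
    return("countModel must be 'nb' or 'poisson'")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 1L)
    return("lengthRange must be an increasing pair of positive lengths")
  if (object@nContigs < 1L) return("need at least one contig")
  TRUE
})
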