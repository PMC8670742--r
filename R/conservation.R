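.GAP_CHARS <- c("-", ".")

# alignment as a character matrix (rows = sequences, cols = positions)
.alnMatrix <- function(ga) {
  m <- do.call(rbind, strsplit(as.character(ga@aln), ""))
  rownames(m) <- names(ga@aln)
  m
}

#' Columns passing the occupancy filter
#'
#' A column is retained when the fraction of rows holding a residue
#' (anything but `-` or `.`) is at least `minOccupancy`; columns with
#' less than that are ignored. The boundary occupancy is kept. The
#' denominator is all rows of the alignment, both groups combined.
#'
#' @param alignment a [GroupedAlignment-class].
#' @param minOccupancy minimum residue fraction (default 0.5).
#' @return integer vector of retained 1-based column indices.
#' @export
filterColumns <- function(alignment, minOccupancy = 0.5) {
  m <- .alnMatrix(alignment)
  occ <- colMeans(matrix(!(m %in% .GAP_CHARS), nrow(m), ncol(m)))
  keep <- which(occ >= minOccupancy)
  if (length(keep) == 0L)
    stop("alignment too gappy: no column with occupancy >= ", minOccupancy)
  keep
}

#' Mean within-group pairwise similarity at one column
#'
#' The intra-group similarity I is the average substitution-matrix score
#' over all unordered pairs of the group's residues at the column:
#' I = sum over i < j of M(ai, aj) * 2 / (N (N - 1)), where N counts the
#' group's non-gap residues. With fewer than two residues the pair set is
#' empty and the column is not scorable for the group (`NA`).
#'
#' @param residues character vector of one group's residues at the
#'   column (gaps already removed).
#' @param matrix substitution matrix (see [readSubstitutionMatrix()]).
#' @return mean pairwise score, or `NA` if fewer than two scorable
#'   residues.
#' @export
intraGroupSimilarity <- function(residues, matrix) {
  residues <- residues[residues %in% rownames(matrix)]
  n <- length(residues)
  if (n < 2L) return(NA_real_)
  s <- matrix[residues, residues, drop = FALSE]
  (sum(s) - sum(diag(s))) / (n * (n - 1))
}

#' Mean across-group pairwise similarity at one column
#'
#' The inter-group similarity J is the average score over all ordered
#' cross-group residue pairs: J = sum over i, j of M(ai, bj) / (N1 N2).
#'
#' @param residues1,residues2 residue vectors of the two groups at the
#'   column (gaps removed).
#' @param matrix substitution matrix.
#' @return mean cross-group score, or `NA` if either group is empty.
#' @export
interGroupSimilarity <- function(residues1, residues2, matrix) {
  residues1 <- residues1[residues1 %in% rownames(matrix)]
  residues2 <- residues2[residues2 %in% rownames(matrix)]
  if (length(residues1) == 0L || length(residues2) == 0L)
    return(NA_real_)
  mean(matrix[residues1, residues2, drop = FALSE])
}

#' Differential conservation score of one column
#'
#' S = (I_modified + I_unmodified)/2 - J: the average of the two
#' within-group similarities minus the between-group similarity. S is 0
#' for a perfectly conserved column, positive when each group is
#' conserved around a different residue, and propagates `NA` when either
#' intra-group score is unscorable.
#'
#' @param residuesModified,residuesUnmodified residue vectors of the two
#'   groups at the column.
#' @param matrix substitution matrix.
#' @return list with elements `I_modified`, `I_unmodified`, `J`, `S`.
#' @export
differentialScore <- function(residuesModified, residuesUnmodified, matrix) {
  I1 <- intraGroupSimilarity(residuesModified, matrix)
  I2 <- intraGroupSimilarity(residuesUnmodified, matrix)
  J <- interGroupSimilarity(residuesModified, residuesUnmodified, matrix)
  list(I_modified = I1, I_unmodified = I2, J = J,
       S = (I1 + I2) / 2 - J)
}

#' Map an alignment column to reference-sequence numbering
#'
#' Returns the 1-based count of non-gap reference residues up to and
#' including the column, i.e. the position on the ungapped reference
#' sequence; `NA` when the reference itself is gapped at the column.
#'
#' @param alignment a [GroupedAlignment-class] with a reference row, or
#'   with `referenceId` given here.
#' @param column 1-based alignment column index (vectorised).
#' @param referenceId reference row id (defaults to the alignment's).
#' @return integer reference position(s), `NA` where the reference is
#'   gapped.
#' @export
mapToReference <- function(alignment, column,
                           referenceId = alignment@referenceId) {
  if (is.na(referenceId)) stop("no reference row set")
  if (!referenceId %in% names(alignment@aln))
    stop("reference row not in alignment: ", referenceId)
  refchars <- strsplit(as.character(alignment@aln[[referenceId]]), "")[[1L]]
  isres <- !(refchars %in% .GAP_CHARS)
  pos <- cumsum(isres)
  out <- pos[column]
  out[!isres[column]] <- NA_integer_
  as.integer(out)
}

#' Per-column differential conservation profile of a grouped alignment
#'
#' Runs the full conservation stage: occupancy filtering, per-column
#' group residue extraction (non-gap residues present in the matrix
#' alphabet), intra- and inter-group similarity, the differential score
#' S, and optional mapping to reference numbering. Columns where a group
#' has fewer than two scorable residues get `S = NA` (reported, not
#' silently zeroed, to avoid fake nulls in the ranking).
#'
#' @param alignment a [GroupedAlignment-class].
#' @param matrix substitution matrix (default: packaged BLOSUM80).
#' @param minOccupancy occupancy filter (default 0.5).
#' @param matrixName matrix name recorded in the profile.
#' @return a [ConservationProfile-class].
#' @export
conservationProfile <- function(alignment, matrix = blosum80(),
                                minOccupancy = 0.5,
                                matrixName = "BLOSUM80") {
  stopifnot(methods::is(alignment, "GroupedAlignment"))
  keep <- filterColumns(alignment, minOccupancy)
  m <- .alnMatrix(alignment)
  grp <- alignment@groups[rownames(m)]
  isMod <- grp == "modified"
  hasRef <- !is.na(alignment@referenceId)
  rows <- lapply(keep, function(j) {
    col <- m[, j]
    res <- col[!(col %in% .GAP_CHARS)]
    occ <- length(res) / nrow(m)
    r1 <- col[isMod]; r1 <- r1[!(r1 %in% .GAP_CHARS) & r1 %in% rownames(matrix)]
    r2 <- col[!isMod]; r2 <- r2[!(r2 %in% .GAP_CHARS) & r2 %in% rownames(matrix)]
    sc <- differentialScore(r1, r2, matrix)
    data.frame(column = j, occupancy = occ,
               n_modified = length(r1), n_unmodified = length(r2),
               I_modified = sc$I_modified, I_unmodified = sc$I_unmodified,
               J = sc$J, S = sc$S)
  })
  df <- S4Vectors::DataFrame(do.call(rbind, rows))
  df$ref_position <- if (hasRef) mapToReference(alignment, df$column)
                     else NA_integer_
  df <- df[, c("column", "ref_position", "occupancy", "n_modified",
               "n_unmodified", "I_modified", "I_unmodified", "J", "S")]
  methods::new("ConservationProfile", profile = df,
               minOccupancy = as.numeric(minOccupancy),
               matrixName = matrixName)
}

#' Rank alignment columns by differential conservation
#'
#' Stable sort by S descending; ties broken by ascending column index;
#' unscorable columns (S missing) are dropped from the ranking.
#'
#' @param profile a [ConservationProfile-class].
#' @param topK number of top columns to return (default: all).
#' @return `DataFrame` of the top rows of the profile in rank order.
#' @export
rankPositions <- function(profile, topK = Inf) {
  stopifnot(methods::is(profile, "ConservationProfile"))
  df <- profile@profile
  df <- df[!is.na(df$S), , drop = FALSE]
  df <- df[order(-df$S, df$column), , drop = FALSE]
  utils::head(df, topK)
}

#' Write a ConservationProfile as TSV
#'
#' @param x a [ConservationProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConservationProfile <- function(x, path) {
  stopifnot(methods::is(x, "ConservationProfile"))
  writeResultTable(x@profile, path, "conservation",
                   list(min_occupancy = x@minOccupancy,
                        matrix = x@matrixName))
}
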