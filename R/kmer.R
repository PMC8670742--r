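#' Canonical k-mer counts of a sequence collection
#'
#' Counts every k-long substring of every sequence, collapsing each
#' k-mer with its reverse complement onto the lexicographically smaller
#' of the two (the canonical form), as read-level k-mer counters do.
#' K-mers containing characters other than A/C/G/T are skipped.
#'
#' @param reads a [Biostrings::DNAStringSet] or character vector.
#' @param k word size (>= 1).
#' @return named integer vector of canonical k-mer counts.
#' @export
canonicalKmerCounts <- function(reads, k) {
  if (k < 1) stop("k must be >= 1")
  reads <- as.character(reads)
  reads <- toupper(reads[nchar(reads) >= k])
  if (length(reads) == 0L) return(stats::setNames(integer(0), character(0)))
  kmers <- unlist(lapply(reads, function(s) {
    substring(s, seq_len(nchar(s) - k + 1L), seq(k, nchar(s)))
  }), use.names = FALSE)
  kmers <- kmers[grepl("^[ACGT]+$", kmers)]
  if (length(kmers) == 0L)
    return(stats::setNames(integer(0), character(0)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  tab <- table(canon)
  stats::setNames(as.integer(tab), names(tab))
}

#' Compare normalised k-mer frequencies between two read cohorts
#'
#' Counts canonical k-mers (default k = 16, chosen for resolution at
#' typical read lengths) separately in the case and control cohorts and
#' normalises each cohort's counts to counts per million, so the two
#' frequency columns are directly comparable regardless of sequencing
#' depth. K-mers over- or under-represented in the case cohort stand out
#' as off-diagonal points in a case-versus-control frequency plot.
#'
#' @param readsCase,readsControl read collections
#'   ([Biostrings::DNAStringSet] or character).
#' @param k word size (default 16).
#' @return `DataFrame` with columns `kmer`, `count_case`,
#'   `count_control`, `freq_case`, `freq_control` (counts per million
#'   within the cohort), sorted by decreasing `freq_case`.
#' @export
kmerFrequencyCompare <- function(readsCase, readsControl, k = 16) {
  countsCase <- canonicalKmerCounts(readsCase, k)
  countsControl <- canonicalKmerCounts(readsControl, k)
  if (length(countsCase) == 0L && length(countsControl) == 0L) {
    warning("no read of length >= ", k, "; empty k-mer table")
    return(S4Vectors::DataFrame(kmer = character(), count_case = integer(),
                                count_control = integer(),
                                freq_case = numeric(),
                                freq_control = numeric()))
  }
  kmers <- sort(union(names(countsCase), names(countsControl)))
  cc <- unname(countsCase[kmers]); cc[is.na(cc)] <- 0L
  ct <- unname(countsControl[kmers]); ct[is.na(ct)] <- 0L
  fc <- if (sum(cc) > 0) 1e6 * cc / sum(cc) else rep(0, length(cc))
  ft <- if (sum(ct) > 0) 1e6 * ct / sum(ct) else rep(0, length(ct))
  out <- S4Vectors::DataFrame(kmer = kmers, count_case = as.integer(cc),
                              count_control = as.integer(ct),
                              freq_case = fc, freq_control = ft)
  out[order(-out$freq_case), , drop = FALSE]
}
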