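#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value for a 2x2 contingency table under
#' the hypergeometric null with all margins fixed: the sum of the point
#' probabilities of every table (sharing the observed margins) whose
#' probability does not exceed that of the observed table, ties included
#' (the minimum-likelihood convention used by mainstream scientific
#' libraries). Point probabilities are evaluated in log space for
#' numerical stability; a relative tolerance of `1e-7` guards the tie
#' comparison against floating-point noise, as is conventional.
#'
#' A table with a zero row or column margin admits only one realisable
#' table, so its p-value is 1.
#'
#' @param a,b,c,d non-negative integer cell counts: a = modified contigs
#'   with the domain, b = modified without, c = unmodified with,
#'   d = unmodified without.
#' @return p-value in \[0, 1\].
#' @export
fisherTwoSided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  n1 <- a + b                       # modified contigs
  K <- a + c                        # contigs carrying the domain
  N <- a + b + c + d
  lo <- max(0L, n1 + K - N)
  hi <- min(n1, K)
  if (lo == hi) return(1)           # degenerate margin: single table
  x <- lo:hi
  logp <- stats::dhyper(x, K, N - K, n1, log = TRUE)
  logobs <- logp[a - lo + 1L]
  p <- sum(exp(logp[logp <= logobs + log1p(1e-7)]))
  min(1, p)
}

#' Build the 2x2 contingency table for one domain family
#'
#' Counts modified and unmodified contigs carrying at least one hit of
#' the domain. A contig contributes at most once per domain no matter
#' how many hits it carries; hits on contigs without a label are dropped
#' with a warning.
#'
#' @param domain accession of the family (version ignored).
#' @param hits domain-hit `DataFrame` (see [readDomainHits()]).
#' @param labels named character vector of contig labels
#'   (`"modified"`/`"unmodified"`), e.g. from [contigLabels()].
#' @return named integer vector `c(a, b, c, d)`.
#' @export
buildContingency <- function(domain, hits, labels) {
  unl <- setdiff(unique(hits$contig_id), names(labels))
  if (length(unl))
    warning("hit(s) on unlabelled contig excluded: ",
            paste(utils::head(unl, 3L), collapse = ", "))
  hits <- hits[hits$contig_id %in% names(labels), , drop = FALSE]
  carriers <- unique(hits$contig_id[stripVersion(hits$pfam_accession) ==
                                      stripVersion(domain)])
  nMod <- sum(labels == "modified")
  nUnmod <- sum(labels == "unmodified")
  a <- sum(labels[carriers] == "modified")
  c <- sum(labels[carriers] == "unmodified")
  c(a = a, b = nMod - a, c = c, d = nUnmod - c)
}

#' Bonferroni adjustment of p-values
#'
#' @param p raw p-values.
#' @param m number of tests (defaults to `length(p)`, in which case the
#'   adjustment is delegated to [stats::p.adjust()]).
#' @return adjusted p-values, `min(1, p * m)`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (m == length(p)) stats::p.adjust(p, method = "bonferroni")
  else pmin(1, p * m)
}

#' Test every domain family for association with modified contigs
#'
#' For each family with at least one hit on a labelled contig, builds
#' the 2x2 table of modified/unmodified contigs carrying versus lacking
#' the family (once-per-contig counting), computes the two-sided Fisher
#' exact p-value, and applies a Bonferroni correction with m = number of
#' families tested. A family is called significant when its adjusted p
#' falls below `alpha` *and* the family is over-represented on modified
#' contigs (a/(a+b) > c/(c+d)); families enriched on unmodified contigs
#' are reported with direction `"unmodified-enriched"` and never flagged.
#' Results are ranked by ascending raw p, ties broken by descending `a`
#' then accession.
#'
#' @param hits domain-hit `DataFrame` (see [readDomainHits()]).
#' @param labels named character vector of contig labels, or an
#'   [EnrichmentTable-class].
#' @param alpha significance level on the adjusted p (default 0.01).
#' @return an [AssociationTable-class].
#' @export
associateDomains <- function(hits, labels, alpha = 0.01) {
  if (methods::is(labels, "EnrichmentTable")) labels <- contigLabels(labels)
  if (length(labels) == 0L) stop("no labelled contigs")
  unl <- setdiff(unique(hits$contig_id), names(labels))
  if (length(unl))
    warning(length(unl), " contig(s) with hits but no label excluded")
  hits <- hits[hits$contig_id %in% names(labels), , drop = FALSE]
  key <- stripVersion(hits$pfam_accession)
  if (nrow(hits) == 0L)
    return(methods::new("AssociationTable",
                        results = S4Vectors::DataFrame(
                          accession = character(), name = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p_raw = numeric(),
                          p_adjusted = numeric(), direction = character(),
                          significant = logical()),
                        m = 1L, alpha = as.numeric(alpha)))
  # once-per-contig presence
  pres <- unique(data.frame(key = key, contig = hits$contig_id,
                            stringsAsFactors = FALSE))
  pres$lab <- labels[pres$contig]
  doms <- sort(unique(pres$key))
  m <- length(doms)
  nMod <- sum(labels == "modified")
  nUnmod <- sum(labels == "unmodified")
  a <- vapply(doms, function(dm)
    sum(pres$lab[pres$key == dm] == "modified"), integer(1),
    USE.NAMES = FALSE)
  cc <- vapply(doms, function(dm)
    sum(pres$lab[pres$key == dm] == "unmodified"), integer(1),
    USE.NAMES = FALSE)
  b <- nMod - a
  d <- nUnmod - cc
  p_raw <- unname(mapply(fisherTwoSided, a, b, cc, d))
  p_adj <- bonferroniAdjust(p_raw, m)
  propMod <- ifelse(a + b > 0, a / (a + b), 0)
  propUn <- ifelse(cc + d > 0, cc / (cc + d), 0)
  direction <- ifelse(propMod > propUn, "modified-enriched",
                      "unmodified-enriched")
  significant <- p_adj < alpha & direction == "modified-enriched"
  nm <- vapply(doms, function(dm) hits$pfam_name[key == dm][1L],
               character(1), USE.NAMES = FALSE)
  res <- S4Vectors::DataFrame(
    accession = doms, name = nm, a = a, b = b, c = cc, d = d,
    p_raw = p_raw, p_adjusted = p_adj, direction = direction,
    significant = significant)
  ord <- order(res$p_raw, -res$a, res$accession)
  methods::new("AssociationTable", results = res[ord, , drop = FALSE],
               m = m, alpha = as.numeric(alpha))
}

#' Write an AssociationTable as TSV
#'
#' @param x an [AssociationTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssociationTable <- function(x, path) {
  stopifnot(methods::is(x, "AssociationTable"))
  writeResultTable(x@results, path, "association",
                   list(m = x@m, alpha = x@alpha))
}

#' Call candidate genes from significant domain families
#'
#' A candidate gene is an ORF on a modified contig that carries at least
#' one hit of a significantly modified-enriched domain family. Two
#' assignment paths are supported: by hit target (`by = "target"`; the
#' hit's `orf_id` names the ORF, for hits produced by searching predicted
#' proteins), or by coordinate overlap (`by = "overlap"`; the hit's
#' alignment interval, taken as contig coordinates, must lie within the
#' ORF span, any strand). Each qualifying ORF is emitted once with the
#' list of associated families it contains; significant-domain hits that
#' match no ORF are reported separately as orphan hits.
#'
#' @param orfs `GRanges` from [readOrfs()].
#' @param hits domain-hit `DataFrame`.
#' @param association an [AssociationTable-class] (or character vector of
#'   significant accessions).
#' @param enrichment an [EnrichmentTable-class] (or character vector of
#'   modified contig ids).
#' @param by `"target"` or `"overlap"` (see above).
#' @return `DataFrame` with columns `contig_id`, `orf_id`, `domains`
#'   (comma-separated accessions), `n_domains`, `score` (contig
#'   enrichment score when available); orphan hits in
#'   `metadata(x)$orphan_hits`.
#' @export
callCandidateGenes <- function(orfs, hits, association, enrichment,
                               by = c("target", "overlap")) {
  by <- match.arg(by)
  sig <- if (methods::is(association, "AssociationTable"))
    significantDomains(association) else stripVersion(association)
  scores <- NULL
  mod <- if (methods::is(enrichment, "EnrichmentTable")) {
    df <- enrichment@results
    scores <- stats::setNames(df$score, df$contig_id)
    modifiedContigs(enrichment)
  } else as.character(enrichment)
  empty <- S4Vectors::DataFrame(contig_id = character(),
                                orf_id = character(), domains = character(),
                                n_domains = integer(), score = numeric())
  if (length(sig) == 0L) return(empty)
  key <- stripVersion(hits$pfam_accession)
  hits <- hits[key %in% sig & hits$contig_id %in% mod, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  if (by == "target") {
    orphan <- is.na(hits$orf_id) | !(hits$orf_id %in% orfs$orf_id)
    hit_orf <- hits$orf_id
  } else {
    hitGR <- GenomicRanges::GRanges(hits$contig_id,
                                    IRanges::IRanges(hits$ali_start,
                                                     hits$ali_end))
    ov <- GenomicRanges::findOverlaps(hitGR, orfs, type = "within",
                                      ignore.strand = TRUE)
    hit_orf <- rep(NA_character_, nrow(hits))
    hit_orf[S4Vectors::queryHits(ov)] <-
      orfs$orf_id[S4Vectors::subjectHits(ov)]
    orphan <- is.na(hit_orf)
  }
  if (any(orphan))
    message(sum(orphan), " significant-domain hit(s) with no ",
            "containing ORF (orphan hits)")
  orphan_hits <- hits[orphan, , drop = FALSE]
  hits <- hits[!orphan, , drop = FALSE]
  hit_orf <- hit_orf[!orphan]
  if (nrow(hits) == 0L) {
    S4Vectors::metadata(empty)$orphan_hits <- orphan_hits
    return(empty)
  }
  key <- stripVersion(hits$pfam_accession)
  byOrf <- split(key, hit_orf)
  orf_ids <- names(byOrf)
  contig <- as.character(GenomicRanges::seqnames(orfs))[
    match(orf_ids, orfs$orf_id)]
  doms <- vapply(byOrf, function(k)
    paste(sort(unique(k)), collapse = ","), character(1))
  ndom <- vapply(byOrf, function(k) length(unique(k)), integer(1))
  out <- S4Vectors::DataFrame(
    contig_id = contig, orf_id = orf_ids, domains = unname(doms),
    n_domains = unname(ndom),
    score = if (is.null(scores)) NA_real_ else unname(scores[contig]))
  out <- out[order(out$contig_id, out$orf_id), , drop = FALSE]
  S4Vectors::metadata(out)$orphan_hits <- orphan_hits
  out
}
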