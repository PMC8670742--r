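#' Domain presence-absence matrix over contigs
#'
#' Builds the boolean matrix with rows = domain families and columns =
#' contigs, an entry being `TRUE` when the contig carries at least one
#' hit of the family (hit multiplicity collapses to presence). The
#' matrix can be restricted to modified or unmodified contigs.
#'
#' @param hits domain-hit `DataFrame` (see [readDomainHits()]).
#' @param labels named character vector of contig labels, or an
#'   [EnrichmentTable-class].
#' @param scope `"all"`, `"modified"` or `"unmodified"` contigs.
#' @return logical matrix, rows named by version-stripped accession,
#'   columns by contig id.
#' @export
buildPresenceMatrix <- function(hits, labels,
                                scope = c("all", "modified", "unmodified")) {
  scope <- match.arg(scope)
  if (methods::is(labels, "EnrichmentTable")) labels <- contigLabels(labels)
  contigs <- if (scope == "all") names(labels)
             else names(labels)[labels == scope]
  if (length(contigs) == 0L) stop("no contigs in scope '", scope, "'")
  hits <- hits[hits$contig_id %in% contigs, , drop = FALSE]
  doms <- sort(unique(stripVersion(hits$pfam_accession)))
  mat <- matrix(FALSE, length(doms), length(contigs),
                dimnames = list(doms, contigs))
  if (nrow(hits))
    mat[cbind(stripVersion(hits$pfam_accession), hits$contig_id)] <- TRUE
  mat
}

#' Probability of exactly j joint presences under the co-occurrence null
#'
#' Null model for the co-occurrence of two domain families across N
#' contigs: with each family's presence count (n1, n2) fixed, the n1
#' carrier contigs of family 1 are an equiprobable draw of size n1 from
#' the N contigs, so the joint count j is hypergeometric:
#' P(j) = C(n2, j) C(N - n2, n1 - j) / C(N, n1), evaluated in log space.
#' Infeasible j (outside \[max(0, n1 + n2 - N), min(n1, n2)\]) has
#' probability 0.
#'
#' @param N contigs considered.
#' @param n1,n2 presence counts of the two families.
#' @param j joint presence count (vectorised).
#' @return probability/ies of exactly `j` joint presences.
#' @export
pairProbability <- function(N, n1, n2, j) {
  stopifnot(N >= 0, n1 >= 0, n2 >= 0, n1 <= N, n2 <= N)
  p <- exp(stats::dhyper(j, n2, N - n2, n1, log = TRUE))
  p[j < pmax(0, n1 + n2 - N) | j > pmin(n1, n2)] <- 0
  p
}

# upper/lower tail of the joint-count null, by summation of pairProbability
.pairTails <- function(N, n1, n2, j_obs) {
  lo <- max(0, n1 + n2 - N)
  hi <- min(n1, n2)
  support <- lo:hi
  p <- pairProbability(N, n1, n2, support)
  c(p_ge = sum(p[support >= j_obs]), p_le = sum(p[support <= j_obs]))
}

#' Test domain pairs for co-occurrence across contigs
#'
#' For every unordered pair of the requested families, computes the
#' observed joint presence count and the exact probability of a joint
#' count at least that large (`p_ge`, positive association) and at most
#' that large (`p_le`) under the fixed-marginal hypergeometric null. A
#' significant positive edge is one with `p_ge < alpha` (raw, no
#' multiplicity correction by default, with an optional
#' Benjamini-Hochberg adjustment); the edge weight is `p_ge`.
#'
#' @param matrix presence matrix from [buildPresenceMatrix()].
#' @param domains families to test (default: all rows); families absent
#'   from the matrix are skipped with a warning.
#' @param alpha threshold on `p_ge` (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a [CooccurrenceTable-class], pairs ordered by ascending
#'   `p_ge`.
#' @export
testPairs <- function(matrix, domains = rownames(matrix), alpha = 0.05,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  missing <- setdiff(domains, rownames(matrix))
  if (length(missing))
    warning("domain(s) absent from matrix skipped: ",
            paste(utils::head(missing, 3L), collapse = ", "))
  domains <- intersect(domains, rownames(matrix))
  if (length(domains) < 2L)
    stop("need at least two domains present in the matrix")
  N <- ncol(matrix)
  pres <- matrix[domains, , drop = FALSE]
  n <- rowSums(pres)
  pairs <- utils::combn(domains, 2L)
  res <- apply(pairs, 2L, function(pr) {
    n1 <- n[[pr[1L]]]; n2 <- n[[pr[2L]]]
    j <- sum(pres[pr[1L], ] & pres[pr[2L], ])
    tails <- .pairTails(N, n1, n2, j)
    data.frame(domain1 = pr[1L], domain2 = pr[2L], N = N, n1 = n1,
               n2 = n2, j_obs = j, p_ge = tails[["p_ge"]],
               p_le = tails[["p_le"]])
  })
  df <- S4Vectors::DataFrame(do.call(rbind, res))
  p <- if (adjust == "BH") stats::p.adjust(df$p_ge, "BH") else df$p_ge
  df$significant <- p < alpha
  df <- df[order(df$p_ge), , drop = FALSE]
  methods::new("CooccurrenceTable", results = df,
               alpha = as.numeric(alpha), scope = "matrix")
}

# contig-coordinate interval of each hit: the hit's own alignment
# interval when contig-relative, else the span of its ORF
.hitIntervals <- function(hits, orfs = NULL) {
  start <- hits$ali_start
  end <- hits$ali_end
  if (!is.null(orfs) && any(!is.na(hits$orf_id))) {
    idx <- match(hits$orf_id, orfs$orf_id)
    use <- !is.na(idx)
    start[use] <- GenomicRanges::start(orfs)[idx[use]]
    end[use] <- GenomicRanges::end(orfs)[idx[use]]
  }
  data.frame(contig_id = hits$contig_id,
             accession = stripVersion(hits$pfam_accession),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Domains in the genomic neighborhood of an anchor domain
#'
#' For every hit of the anchor family, reports all domain hits on the
#' same contig whose interval lies within `window` bp of the anchor
#' interval's nearest edge (default 3 kb upstream and downstream).
#' Offsets are signed distances between nearest interval edges in contig
#' coordinates (0 for overlap, positive downstream of the anchor),
#' independent of the anchor's strand. Hits with protein-relative
#' coordinates are placed at their ORF's contig span. A per-family
#' summary of co-neighbor counts, split by contig label when labels are
#' given, accompanies the per-anchor detail.
#'
#' @param domain anchor family accession (version ignored).
#' @param hits domain-hit `DataFrame`.
#' @param orfs optional `GRanges` from [readOrfs()] used to place
#'   ORF-relative hits on the contig.
#' @param labels optional contig labels (named character or
#'   [EnrichmentTable-class]) for the label split.
#' @param window neighborhood half-width in bp (default 3000).
#' @return list with `DataFrame`s `neighbors` (one row per
#'   anchor-neighbor pair: contig, anchor interval, neighbor accession,
#'   interval and signed offset) and `summary` (per neighbor family:
#'   total co-neighbor count and counts on modified/unmodified contigs).
#' @export
domainNeighborhood <- function(domain, hits, orfs = NULL, labels = NULL,
                               window = 3000) {
  if (methods::is(labels, "EnrichmentTable")) labels <- contigLabels(labels)
  iv <- .hitIntervals(hits, orfs)
  key <- stripVersion(domain)
  anchors <- iv[iv$accession == key, , drop = FALSE]
  if (nrow(anchors) == 0L) {
    empty <- S4Vectors::DataFrame(contig_id = character(),
                                  anchor_start = integer(),
                                  anchor_end = integer(),
                                  neighbor = character(),
                                  neighbor_start = integer(),
                                  neighbor_end = integer(),
                                  offset = integer())
    return(list(neighbors = empty,
                summary = S4Vectors::DataFrame(neighbor = character(),
                                               n = integer(),
                                               n_modified = integer(),
                                               n_unmodified = integer())))
  }
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    nb <- iv[iv$contig_id == a$contig_id, , drop = FALSE]
    nb <- nb[!(nb$start == a$start & nb$end == a$end &
                 nb$accession == a$accession), , drop = FALSE]
    if (nrow(nb) == 0L) return(NULL)
    gap_right <- nb$start - a$end       # neighbor downstream of anchor
    gap_left <- a$start - nb$end        # neighbor upstream
    offset <- ifelse(gap_right > 0, gap_right,
                     ifelse(gap_left > 0, -gap_left, 0L))
    keep <- abs(offset) <= window
    if (!any(keep)) return(NULL)
    data.frame(contig_id = a$contig_id, anchor_start = a$start,
               anchor_end = a$end, neighbor = nb$accession[keep],
               neighbor_start = nb$start[keep],
               neighbor_end = nb$end[keep],
               offset = as.integer(offset[keep]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(domainNeighborhood(domain, hits[0, , drop = FALSE], orfs,
                              labels, window))
  det <- S4Vectors::DataFrame(do.call(rbind, rows))
  lab <- if (is.null(labels)) rep(NA_character_, nrow(det))
         else unname(labels[det$contig_id])
  bySummary <- split(lab, det$neighbor)
  summ <- S4Vectors::DataFrame(
    neighbor = names(bySummary),
    n = lengths(bySummary),
    n_modified = vapply(bySummary, function(v)
      sum(v == "modified", na.rm = TRUE), integer(1)),
    n_unmodified = vapply(bySummary, function(v)
      sum(v == "unmodified", na.rm = TRUE), integer(1)))
  summ <- summ[order(-summ$n), , drop = FALSE]
  list(neighbors = det, summary = summ)
}

#' Best phenotype-pure clade of a labelled tree
#'
#' Treats the tree as unrooted: every edge bipartitions the leaves into
#' two sides. For each side of each edge the function computes the
#' purity (fraction of the side's leaves labelled modified) and coverage
#' (fraction of all modified leaves inside the side) and returns the
#' side maximising their F1, quantifying how strongly the
#' modified-labelled leaves cluster into a single branch.
#'
#' @param tree an [ape::phylo] object or path to a newick file.
#' @param labels named character vector (`"modified"`/`"unmodified"`)
#'   covering every leaf.
#' @return a [CladePurity-class].
#' @export
cladePurity <- function(tree, labels) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("tree must have >= 3 leaves")
  miss <- setdiff(tree$tip.label, names(labels))
  if (length(miss))
    stop("unlabelled leaf: ", miss[1L])
  isMod <- labels[tree$tip.label] == "modified"
  totalMod <- sum(isMod)
  # leaves under each node, one postorder pass
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    desc[[edge[k, 1L]]] <- c(desc[[edge[k, 1L]]], desc[[edge[k, 2L]]])
  best <- list(f1 = -1)
  for (k in seq_len(nrow(edge))) {
    side <- desc[[edge[k, 2L]]]
    for (leaves in list(side, setdiff(seq_len(ntip), side))) {
      if (length(leaves) == 0L) next
      nMod <- sum(isMod[leaves])
      purity <- nMod / length(leaves)
      coverage <- if (totalMod > 0) nMod / totalMod else 0
      f1 <- if (purity + coverage > 0)
        2 * purity * coverage / (purity + coverage) else 0
      if (f1 > best$f1)
        best <- list(f1 = f1, purity = purity, coverage = coverage,
                     leaves = tree$tip.label[leaves])
    }
  }
  methods::new("CladePurity", leaves = best$leaves, purity = best$purity,
               coverage = best$coverage, f1 = best$f1,
               nEdges = nrow(edge))
}

#' Write a CooccurrenceTable as TSV
#'
#' @param x a [CooccurrenceTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCooccurrenceTable <- function(x, path) {
  stopifnot(methods::is(x, "CooccurrenceTable"))
  writeResultTable(x@results, path, "cooccurrence",
                   list(alpha = x@alpha, scope = x@scope))
}
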