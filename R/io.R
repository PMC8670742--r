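#' Read assembled contigs from a FASTA file
#'
#' Contig ids are the first whitespace-delimited token of each header.
#' Duplicate ids and zero-length entries are rejected; an empty file
#' yields an empty set with a warning.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by contig id.
#' @export
readContigs <- function(path) {
  .checkFile(path)
  contigs <- Biostrings::readDNAStringSet(path)
  if (length(contigs) == 0L) {
    warning("no contigs in ", path)
    return(contigs)
  }
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  dup <- names(contigs)[duplicated(names(contigs))]
  if (length(dup))
    stop("duplicate contig id: ", dup[1L])
  if (any(Biostrings::width(contigs) == 0L))
    stop("zero-length contig: ",
         names(contigs)[Biostrings::width(contigs) == 0L][1L])
  contigs
}

# domtblout column layout (22 fixed fields + free-text description)
.DOMTBL_FIELDS <- c("target_name", "target_accession", "tlen", "query_name",
                    "query_accession", "qlen", "evalue_full", "score_full",
                    "bias_full", "dom_num", "dom_of", "c_evalue", "i_evalue",
                    "score_dom", "bias_dom", "hmm_from", "hmm_to",
                    "ali_from", "ali_to", "env_from", "env_to", "acc")

#' Read protein-domain hits from an HMMER domtblout table
#'
#' Parses the per-domain tabular output layout of `hmmsearch
#' --domtblout` run with profile HMMs (e.g. Pfam-A) as queries. The
#' query accession is taken as the domain accession (kept verbatim, e.g.
#' `"PF02543.16"`); the target is the ORF (or contig) the domain was
#' found on. Rows with independent E-value above `evalueCeiling` are
#' dropped. No E-value cutoff is inherent to the format, so the ceiling
#' is explicit and configurable.
#'
#' @param path domtblout-layout text file; lines starting `#` are ignored.
#' @param evalueCeiling keep rows with i-Evalue at or below this (default
#'   `1e-5`, common practice for Pfam annotation).
#' @param orfs optional ORF table (a `GRanges` from [readOrfs()]). When
#'   supplied, target names are interpreted as ORF ids and each hit is
#'   assigned the ORF's contig and strand; otherwise target names are
#'   taken to be contig ids directly.
#' @return a `DataFrame` with columns `contig_id`, `orf_id`,
#'   `pfam_accession`, `pfam_name`, `i_evalue`, `ali_start`, `ali_end`,
#'   `strand`; the E-value ceiling is stored in its metadata.
#' @export
readDomainHits <- function(path, evalueCeiling = 1e-5, orfs = NULL) {
  .checkFile(path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) {
    out <- S4Vectors::DataFrame(
      contig_id = character(), orf_id = character(),
      pfam_accession = character(), pfam_name = character(),
      i_evalue = numeric(), ali_start = integer(), ali_end = integer(),
      strand = character())
    S4Vectors::metadata(out)$evalueCeiling <- evalueCeiling
    return(out)
  }
  fields <- strsplit(trimws(lines[rows]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 22L))
    stop("malformed domtblout row at line ", rows[which(nf < 22L)[1L]],
         ": expected >= 22 fields, got ", nf[nf < 22L][1L])
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(getcol(i)))
    if (anyNA(v))
      stop("malformed domtblout row at line ", rows[which(is.na(v))[1L]],
           ": non-numeric ", what)
    v
  }
  acc <- getcol(5)
  if (any(!grepl("^PF[0-9]+(\\.[0-9]+)?$", acc)))
    warning("unrecognised accession format (row kept): ",
            acc[!grepl("^PF[0-9]+(\\.[0-9]+)?$", acc)][1L])
  ali_from <- num(18, "ali_from")
  ali_to <- num(19, "ali_to")
  if (any(ali_from > ali_to))
    stop("malformed domtblout row at line ",
         rows[which(ali_from > ali_to)[1L]], ": ali_from > ali_to")
  target <- getcol(1)
  hits <- S4Vectors::DataFrame(
    contig_id = target, orf_id = NA_character_,
    pfam_accession = acc, pfam_name = getcol(4),
    i_evalue = num(13, "i-Evalue"),
    ali_start = as.integer(ali_from), ali_end = as.integer(ali_to),
    strand = "unknown")
  if (!is.null(orfs)) {
    idx <- match(target, orfs$orf_id)
    if (anyNA(idx))
      stop("hit target not in ORF table: ", target[is.na(idx)][1L])
    hits$orf_id <- target
    hits$contig_id <- as.character(GenomicRanges::seqnames(orfs))[idx]
    hits$strand <- as.character(GenomicRanges::strand(orfs))[idx]
  }
  hits <- hits[hits$i_evalue <= evalueCeiling, , drop = FALSE]
  S4Vectors::metadata(hits)$evalueCeiling <- evalueCeiling
  hits
}

#' Read a per-contig case/control counts table
#'
#' Expects tab-separated columns `contig_id`, `count_case`,
#' `count_control` and optionally `length`; one row per contig. Library
#' totals default to the column sums; a header directive of the form
#' `# totals: case=<n> control=<n>` overrides them (for counts derived
#' from alignments where some reads mapped to contigs outside the table).
#'
#' @param path TSV file.
#' @param contigs optional contig set ([Biostrings::DNAStringSet] or a
#'   named integer vector of lengths) used to attach lengths and to
#'   reject counts for unknown contigs.
#' @return a [CoverageTable-class].
#' @export
readCountsTable <- function(path, contigs = NULL) {
  .checkFile(path)
  lines <- readLines(path)
  dirline <- grep("^#\\s*totals:", lines, value = TRUE)
  df <- utils::read.delim(text = lines, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no contigs in counts table ", path)
  need <- c("contig_id", "count_case", "count_control")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("counts table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$contig_id))
    stop("duplicated contig row: ",
         df$contig_id[duplicated(df$contig_id)][1L])
  if (any(df$count_case < 0) || any(df$count_control < 0))
    stop("negative counts in ", path)
  lens <- df$length
  if (!is.null(contigs)) {
    clen <- if (methods::is(contigs, "XStringSet"))
      stats::setNames(Biostrings::width(contigs), names(contigs))
    else contigs
    unknown <- setdiff(df$contig_id, names(clen))
    if (length(unknown))
      stop("contig not in contig set: ", unknown[1L])
    lens <- unname(clen[df$contig_id])
  }
  if (is.null(lens))
    stop("contig lengths unavailable: supply a 'length' column or contigs")
  totalCase <- totalControl <- NA_real_
  if (length(dirline)) {
    m <- regmatches(dirline[1L],
                    regexec("case=([0-9.eE+]+)\\s+control=([0-9.eE+]+)",
                            dirline[1L]))[[1L]]
    if (length(m) == 3L) {
      totalCase <- as.numeric(m[2L])
      totalControl <- as.numeric(m[3L])
    }
  }
  CoverageTable(S4Vectors::DataFrame(contig_id = df$contig_id,
                                     length = as.integer(lens),
                                     count_case = df$count_case,
                                     count_control = df$count_control),
                totalCase = totalCase, totalControl = totalControl)
}

#' Construct a CoverageTable
#'
#' @param counts `DataFrame`/data.frame with columns `contig_id`,
#'   `length`, `count_case`, `count_control`.
#' @param totalCase,totalControl library totals; `NA` (default) means
#'   "use the column sums".
#' @return a [CoverageTable-class].
#' @export
CoverageTable <- function(counts, totalCase = NA_real_,
                          totalControl = NA_real_) {
  counts <- S4Vectors::DataFrame(as.data.frame(counts))
  supplied <- !is.na(totalCase) || !is.na(totalControl)
  if (is.na(totalCase)) totalCase <- sum(counts$count_case)
  if (is.na(totalControl)) totalControl <- sum(counts$count_control)
  methods::new("CoverageTable", counts = counts,
               totalCase = as.numeric(totalCase),
               totalControl = as.numeric(totalControl),
               totalsSupplied = supplied)
}

#' Write a CoverageTable as TSV (round-trips through readCountsTable)
#'
#' @param x a [CoverageTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(x, path) {
  stopifnot(methods::is(x, "CoverageTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.paramHeader("counts", list()), con)
  if (x@totalsSupplied)
    writeLines(sprintf("# totals: case=%.10g control=%.10g",
                       x@totalCase, x@totalControl), con)
  utils::write.table(as.data.frame(x@counts), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ORF coordinates
#'
#' Reads gene/ORF records either from GFF3 (via rtracklayer; the `ID`
#' attribute is the ORF id) or from a tab-separated table with columns
#' `contig_id`, `orf_id`, `start`, `end`, `strand`. Coordinates are
#' 1-based inclusive on the contig.
#'
#' @param path GFF3 or TSV file.
#' @param format `"gff3"` or `"tsv"`; guessed from the extension by
#'   default.
#' @param contigs optional contig set used to check that ORFs fall within
#'   contig bounds.
#' @return a [GenomicRanges::GRanges] with seqnames = contig id and a
#'   metadata column `orf_id`.
#' @export
readOrfs <- function(path, format = c("auto", "gff3", "tsv"),
                     contigs = NULL) {
  .checkFile(path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import.gff3(path)
    orf_id <- if (!is.null(gr$ID)) as.character(gr$ID)
              else as.character(gr$Name)
    if (anyNA(orf_id)) stop("GFF3 record without ID attribute")
    mcols(gr) <- S4Vectors::DataFrame(orf_id = orf_id)
  } else {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("contig_id", "orf_id", "start", "end", "strand")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop("ORF table missing column(s): ", paste(miss, collapse = ", "))
    gr <- GenomicRanges::GRanges(
      df$contig_id, IRanges::IRanges(df$start, df$end),
      strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
      orf_id = df$orf_id)
  }
  if (anyDuplicated(gr$orf_id))
    stop("duplicated orf_id: ", gr$orf_id[duplicated(gr$orf_id)][1L])
  if (any(GenomicRanges::start(gr) < 1L))
    stop("ORF start below 1")
  if (!is.null(contigs)) {
    clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
    cid <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(cid, names(clen))
    if (length(unknown)) stop("ORF on unknown contig: ", unknown[1L])
    if (any(GenomicRanges::end(gr) > clen[cid]))
      stop("ORF extends past contig end: ",
           gr$orf_id[GenomicRanges::end(gr) > clen[cid]][1L])
  }
  gr
}

#' Read a group-labelled protein multiple alignment
#'
#' @param path aligned FASTA; all rows must have equal width; `-` and `.`
#'   are gaps.
#' @param labels group assignment: a named character vector of
#'   `"modified"` / `"unmodified"`, or the path of a two-column TSV
#'   (`sequence_id`, `group`).
#' @param referenceId optional row id used for position numbering.
#' @return a [GroupedAlignment-class].
#' @export
readGroupedAlignment <- function(path, labels, referenceId = NA_character_) {
  .checkFile(path)
  aln <- Biostrings::readAAStringSet(path)
  names(aln) <- sub("\\s.*$", "", names(aln))
  if (is.character(labels) && is.null(names(labels)) &&
      length(labels) == 1L && file.exists(labels)) {
    df <- utils::read.delim(labels, comment.char = "#",
                            stringsAsFactors = FALSE)
    labels <- stats::setNames(df[[2L]], df[[1L]])
  }
  GroupedAlignment(aln, labels, referenceId)
}

#' Construct a GroupedAlignment
#'
#' @param aln [Biostrings::AAStringSet] of equal-width aligned rows.
#' @param labels named character vector mapping every row id to
#'   `"modified"` or `"unmodified"`.
#' @param referenceId optional reference row id.
#' @return a [GroupedAlignment-class].
#' @export
GroupedAlignment <- function(aln, labels, referenceId = NA_character_) {
  if (!methods::is(aln, "AAStringSet"))
    aln <- Biostrings::AAStringSet(aln)
  bad <- setdiff(labels, c("modified", "unmodified"))
  if (length(bad))
    stop("unknown group label: ", bad[1L])
  groups <- factor(unname(labels[names(aln)]),
                   levels = c("modified", "unmodified"))
  names(groups) <- names(aln)
  if (anyNA(groups)) {
    miss <- names(aln)[is.na(groups)]
    stop("unlabelled row(s): ", paste(miss, collapse = ", "))
  }
  methods::new("GroupedAlignment", aln = aln, groups = groups,
               referenceId = as.character(referenceId))
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout (comment lines, a header row of
#' residue symbols, then one labelled score row per symbol). The matrix
#' must be complete and symmetric.
#'
#' @param path matrix file; see `system.file("extdata", "BLOSUM80.txt",
#'   package = "metagpa")` for the packaged BLOSUM80.
#' @return symmetric integer matrix with residue-symbol dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  .checkFile(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("truncated matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- length(header)
  if (length(lines) < n + 1L)
    stop("truncated matrix file: expected ", n, " score rows, found ",
         length(lines) - 1L)
  m <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) != n + 1L)
      stop("matrix row for '", parts[1L], "' has ", length(parts) - 1L,
           " scores, expected ", n)
    sym <- parts[1L]
    if (!sym %in% header) stop("unknown row symbol: ", sym)
    m[sym, ] <- as.integer(parts[-1L])
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing score for pair ", header[idx[1L]], "/", header[idx[2L]])
  }
  if (!isSymmetric(unname(m))) {
    idx <- which(m != t(m), arr.ind = TRUE)[1L, ]
    stop("asymmetric matrix: M(", header[idx[1L]], ",", header[idx[2L]],
         ") != M(", header[idx[2L]], ",", header[idx[1L]], ")")
  }
  m
}

#' The packaged BLOSUM80 substitution matrix
#'
#' @return symmetric integer matrix over the 20 canonical residues plus
#'   B, Z, X and `*`, in half-bit units.
#' @export
blosum80 <- function() {
  readSubstitutionMatrix(system.file("extdata", "BLOSUM80.txt",
                                     package = "metagpa"))
}

#' Write domain hits in HMMER domtblout layout
#'
#' Emits the 23-column per-domain table layout so simulated annotation
#' can be consumed by [readDomainHits()] and by external tools.
#'
#' @param hits `DataFrame` as returned by [readDomainHits()] /
#'   [simulateDomainHits()].
#' @param path output file.
#' @param orfLengths named integer vector of ORF protein lengths (tlen);
#'   defaults to `ali_end` when absent.
#' @return `path`, invisibly.
#' @export
writeDomtblout <- function(hits, path, orfLengths = NULL) {
  target <- ifelse(is.na(hits$orf_id), hits$contig_id, hits$orf_id)
  tlen <- if (is.null(orfLengths)) hits$ali_end
          else unname(orfLengths[target])
  lines <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    sprintf("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
            target, "-", tlen, hits$pfam_name, hits$pfam_accession,
            hits$ali_end - hits$ali_start + 1L,
            hits$i_evalue, 50, 0.1, 1L, 1L, hits$i_evalue, hits$i_evalue,
            50, 0.1, 1L, hits$ali_end - hits$ali_start + 1L,
            hits$ali_start, hits$ali_end, hits$ali_start, hits$ali_end,
            0.95))
  writeLines(lines, path)
  invisible(path)
}
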