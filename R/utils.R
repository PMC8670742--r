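.pkgVersion <- function() as.character(utils::packageVersion("metagpa"))

#' Strip the version suffix from a Pfam-style accession
#'
#' Domain families are counted by accession with the release version
#' removed ("PF02543.16" -> "PF02543") so that annotation against
#' different database releases does not fragment the counts.
#'
#' @param accession character vector of accessions.
#' @return character vector with trailing `.<digits>` removed.
#' @export
stripVersion <- function(accession) sub("\\.[0-9]+$", "", accession)

.checkFile <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  invisible(path)
}

# header lines: "# metagpa <version> <table>" then "# key=value; ..."
.paramHeader <- function(table, params) {
  line1 <- sprintf("# metagpa %s %s", .pkgVersion(), table)
  if (length(params) == 0L) return(line1)
  kv <- vapply(seq_along(params), function(i)
    sprintf("%s=%s", names(params)[i],
            paste(format(params[[i]], trim = TRUE), collapse = ",")),
    character(1))
  c(line1, paste0("# ", paste(kv, collapse = "; ")))
}

#' Write a result table as TSV with a provenance header
#'
#' All pipeline writers emit one or two comment lines (tool version,
#' table name and the exact parameter set) followed by a plain
#' tab-separated table, so every output is independently re-runnable and
#' diffable.
#'
#' @param x a `data.frame` or `DataFrame`.
#' @param path output file.
#' @param table short table name recorded in the header.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(x, path, table = "table", params = list()) {
  x <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.paramHeader(table, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table, ignoring provenance comment lines
#'
#' @param path file written by [writeResultTable()] or any TSV whose
#'   comment lines start with `#`.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  .checkFile(path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
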