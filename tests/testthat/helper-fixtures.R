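# Independent enumeration oracle for the two-sided Fisher exact test:
# explicit hypergeometric point probabilities from choose() ratios
# (never dhyper), minimum-likelihood summation with the conventional
# 1e-7 relative tie tolerance.
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  if (lo == hi) return(1)
  x <- lo:hi
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# one domtblout-layout line with the given key fields
domtbloutLine <- function(target, pfam_name, pfam_acc, ievalue,
                          ali_from = 5L, ali_to = 60L) {
  paste(target, "-", 300, pfam_name, pfam_acc, 80,
        ievalue, 55.0, 0.1, 1, 1, ievalue, ievalue, 55.0, 0.1,
        1, 80, ali_from, ali_to, ali_from, ali_to, 0.97,
        "test fixture", sep = " ")
}

writeDomtbloutFixture <- function(lines, path = tempfile(fileext = ".dom")) {
  writeLines(c("# comment header", lines), path)
  path
}

writeCountsFixture <- function(df, path = tempfile(fileext = ".tsv"),
                               directive = NULL) {
  con <- file(path, "w")
  if (!is.null(directive)) writeLines(directive, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

writeFastaFixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(mapply(function(id, s) c(paste0(">", id), s),
                           names(seqs), seqs, SIMPLIFY = FALSE)),
             path)
  path
}

# small labelled alignment used across conservation tests
tinyAlignment <- function(rows, labels, referenceId = NA_character_) {
  GroupedAlignment(Biostrings::AAStringSet(rows), labels, referenceId)
}

BLOSUM <- metagpa::blosum80()
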