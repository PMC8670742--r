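test_that("two-sided Fisher p matches hand enumeration and the oracle", {
  # margins (2,2)/(2,2): three tables with probs {1/6, 4/6, 1/6}
  expect_equal(fisherTwoSided(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisherTwoSided(0, 0, 3, 4), 1)          # zero row margin
  expect_equal(fisherTwoSided(5, 0, 5, 0), 1)          # zero column margin

  set.seed(11)
  for (i in 1:200) {
    tb <- as.integer(rmultinom(1, sample(4:40, 1), rep(1 / 4, 4)))
    p <- fisherTwoSided(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisherEnumOracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    # second independent oracle: stats::fisher.test
    expect_equal(p, stats::fisher.test(matrix(tb, 2))$p.value,
                 tolerance = 1e-9)
    # invariance under simultaneous row swap + column swap
    expect_equal(p, fisherTwoSided(tb[4], tb[3], tb[2], tb[1]),
                 tolerance = 1e-12)
  }
})

test_that("contingency tables count each contig once per domain", {
  labels <- setNames(c(rep("modified", 10), rep("unmodified", 90)),
                     sprintf("c%03d", 1:100))
  hits <- S4Vectors::DataFrame(
    contig_id = c("c001", "c001", "c001"), orf_id = NA_character_,
    pfam_accession = "PF00001.3", pfam_name = "x", i_evalue = 1e-9,
    ali_start = 1L, ali_end = 10L, strand = "unknown")
  expect_equal(buildContingency("PF00001", hits, labels),
               c(a = 1, b = 9, c = 0, d = 90))
  # absent domain
  expect_equal(buildContingency("PF09999", hits, labels),
               c(a = 0, b = 10, c = 0, d = 90))
  # unlabelled contigs are excluded with a warning
  hits2 <- hits; hits2$contig_id <- c("c001", "zzz", "zzz")
  expect_warning(tb <- buildContingency("PF00001", hits2, labels),
                 "unlabelled")
  expect_equal(tb[["a"]], 1)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.001, m = 10), 0.01)
  expect_equal(bonferroniAdjust(0.5, m = 10), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.9), m = 1), c(0.2, 0.9))
  expect_equal(bonferroniAdjust(c(0.001, 0.03)), c(0.002, 0.06))
})

test_that("a planted domain ranks first and is the only significant hit", {
  set.seed(3)
  labels <- setNames(c(rep("modified", 20), rep("unmodified", 80)),
                     sprintf("c%03d", 1:100))
  rows <- list()
  # planted domain: all 20 modified contigs, no unmodified
  rows[["planted"]] <- data.frame(contig_id = names(labels)[1:20],
                                  acc = "PF99999.1")
  # 50 background domains at equal prevalence in both groups
  for (i in 1:50) {
    on <- sample(names(labels), 12)
    rows[[i + 1]] <- data.frame(contig_id = on,
                                acc = sprintf("PF%05d.1", i))
  }
  df <- do.call(rbind, rows)
  hits <- S4Vectors::DataFrame(
    contig_id = df$contig_id, orf_id = NA_character_,
    pfam_accession = df$acc, pfam_name = df$acc, i_evalue = 1e-10,
    ali_start = 1L, ali_end = 50L, strand = "unknown")
  at <- associateDomains(hits, labels, alpha = 0.01)
  res <- resultTable(at)
  expect_equal(at@m, 51L)
  expect_equal(res$accession[1], "PF99999")
  expect_equal(significantDomains(at), "PF99999")
  expect_equal(res$direction[1], "modified-enriched")
  # p_adjusted = min(1, p_raw * m)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * at@m))
  # oracle agreement on the planted table
  expect_equal(res$p_raw[1], fisherEnumOracle(20, 0, 0, 80),
               tolerance = 1e-12)
  expect_error(associateDomains(hits, character(0)), "no labelled")
})

test_that("label permutation keeps family-wise error under alpha", {
  set.seed(17)
  contigs <- sprintf("c%02d", 1:60)
  hits <- do.call(rbind, lapply(1:20, function(i)
    data.frame(contig_id = sample(contigs, sample(5:25, 1)),
               acc = sprintf("PF%05d.1", i))))
  hits <- S4Vectors::DataFrame(
    contig_id = hits$contig_id, orf_id = NA_character_,
    pfam_accession = hits$acc, pfam_name = hits$acc, i_evalue = 1e-10,
    ali_start = 1L, ali_end = 50L, strand = "unknown")
  alpha <- 0.05
  nperm <- 400
  anySig <- logical(nperm)
  base <- c(rep("modified", 15), rep("unmodified", 45))
  for (b in seq_len(nperm)) {
    labels <- setNames(sample(base), contigs)
    at <- associateDomains(hits, labels, alpha = alpha)
    anySig[b] <- any(resultTable(at)$significant)
  }
  # binomial tolerance: alpha + 3 * SE
  expect_lte(mean(anySig), alpha + 3 * sqrt(alpha * (1 - alpha) / nperm))
})

test_that("candidate genes are ORFs on modified contigs with significant domains", {
  orfs <- GenomicRanges::GRanges(
    c("mod1", "mod1", "unmod1"),
    IRanges::IRanges(c(100, 2000, 100), c(1000, 2900, 1000)),
    strand = "+", orf_id = c("o1", "o2", "o3"))
  mkhits <- function(acc, orf, contig, s = 10L, e = 60L)
    S4Vectors::DataFrame(contig_id = contig, orf_id = orf,
                         pfam_accession = acc, pfam_name = acc,
                         i_evalue = 1e-9, ali_start = s, ali_end = e,
                         strand = "+")
  hits <- rbind(mkhits("PF00001.2", "o2", "mod1"),
                mkhits("PF00002.1", "o2", "mod1"),
                mkhits("PF00001.2", "o3", "unmod1"),
                mkhits("PF00003.1", "o1", "mod1"))
  cand <- callCandidateGenes(orfs, hits, c("PF00001", "PF00002"), "mod1")
  expect_equal(cand$orf_id, "o2")          # only ORF with significant hits
  expect_equal(cand$domains, "PF00001,PF00002")
  expect_equal(cand$n_domains, 2L)
  # no significant domains -> empty
  expect_equal(nrow(callCandidateGenes(orfs, hits, character(0), "mod1")), 0L)
  # coordinate-overlap path: hit interval must fall within the ORF span
  hov <- rbind(mkhits("PF00001.2", NA_character_, "mod1", 150L, 700L),
               mkhits("PF00001.2", NA_character_, "mod1", 1500L, 1600L))
  cand2 <- suppressMessages(
    callCandidateGenes(orfs, hov, "PF00001", "mod1", by = "overlap"))
  expect_equal(cand2$orf_id, "o1")
  expect_equal(nrow(S4Vectors::metadata(cand2)$orphan_hits), 1L)
  # removing a domain from the significant set never adds a candidate
  candAll <- callCandidateGenes(orfs, hits,
                                c("PF00001", "PF00002", "PF00003"), "mod1")
  candLess <- callCandidateGenes(orfs, hits, c("PF00001", "PF00002"), "mod1")
  expect_true(all(candLess$orf_id %in% candAll$orf_id))
})
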