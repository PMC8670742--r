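smallConfig <- function(seed = 1L, ...) {
  simulationConfig(seed = seed, nContigs = 60L, lengthRange = c(1000L, 3000L),
                   ...)
}

test_that("fixtures are byte-identical under a fixed seed and differ across seeds", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  d3 <- file.path(tempdir(), "fx3")
  p1 <- writeFixtures(smallConfig(7L), d1)
  p2 <- writeFixtures(smallConfig(7L), d2)
  p3 <- writeFixtures(smallConfig(8L), d3)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("file", nm))
  expect_false(identical(readLines(p1[["contigs"]]),
                         readLines(p3[["contigs"]])))
})

test_that("community respects the configured composition", {
  com0 <- simulateCommunity(smallConfig(2L, fractionModified = 0))
  expect_true(all(com0$truth$true_status == "unmodified"))
  com1 <- simulateCommunity(simulationConfig(seed = 2L, nContigs = 1L))
  expect_equal(length(com1$contigs), 1L)
  com <- simulateCommunity(smallConfig(2L))
  expect_equal(sum(com$truth$true_status == "modified"), 6L)  # 10% of 60
  w <- Biostrings::width(com$contigs)
  expect_true(all(w >= 1000L & w <= 3000L))
})

test_that("simulated counts carry the planted enrichment signal", {
  cfg <- smallConfig(4L)
  com <- simulateCommunity(cfg)
  cov <- simulateCounts(cfg, com)
  et <- classifyContigs(cov)
  labs <- contigLabels(et)
  truth <- setNames(com$truth$true_status, com$truth$contig_id)
  expect_gte(mean(labs == truth[names(labs)]), 0.95)
  # factors of 1 give a null dataset with (almost) no modified calls
  cfgNull <- smallConfig(4L, enrichmentFactor = 1, depletionFactor = 1)
  covN <- simulateCounts(cfgNull, simulateCommunity(cfgNull))
  etN <- classifyContigs(covN)
  # overdispersed counts put a few null contigs past the threshold, but
  # nothing like the planted 90% call rate on modified contigs
  expect_lte(length(modifiedContigs(etN)), 10L)
})

test_that("simulated annotation round-trips through the readers", {
  cfg <- smallConfig(5L)
  dir <- file.path(tempdir(), "fx_rt")
  paths <- writeFixtures(cfg, dir)
  contigs <- readContigs(paths[["contigs"]])
  expect_equal(length(contigs), 60L)
  cov <- readCountsTable(paths[["counts"]], contigs)
  expect_equal(nrow(resultTable(cov)), 60L)
  orfs <- readOrfs(paths[["orfs"]], contigs = contigs)
  hits <- readDomainHits(paths[["hits"]], evalueCeiling = 1, orfs = orfs)
  ann <- simulateDomainHits(cfg, simulateCommunity(cfg))
  expect_equal(nrow(hits), nrow(ann$hits))
  expect_setequal(unique(hits$pfam_accession),
                  unique(ann$hits$pfam_accession))
  ga <- readGroupedAlignment(paths[["alignment"]], paths[["labels"]])
  expect_equal(nrow(ga), 40L)
  expect_equal(ncol(ga), 100L)
})

test_that("planted alignment columns have the predicted score at zero noise", {
  cfg <- smallConfig(6L, msaNoise = 0, msaGapRate = 0)
  msa <- simulateGroupedAlignment(cfg)
  prof <- conservationProfile(msa$alignment, BLOSUM)
  df <- resultTable(prof)
  M <- BLOSUM
  pl <- msa$plantedResidues
  x <- pl$residue_modified; y <- pl$residue_unmodified
  expect_equal(df$S[df$column == pl$column],
               (M[x, x] + M[y, y]) / 2 - M[x, y])
  # background columns are perfectly conserved: S = 0
  expect_true(all(df$S[df$column != pl$column] == 0))
  # planted prevalence equal to background yields a null association
  cfgNull <- smallConfig(6L, plantedPrevalence = 0.02)
  comN <- simulateCommunity(cfgNull)
  annN <- simulateDomainHits(cfgNull, comN)
  labsN <- setNames(comN$truth$true_status, comN$truth$contig_id)
  atN <- associateDomains(annN$hits, labsN)
  expect_equal(sum(resultTable(atN)$significant), 0L)
})

test_that("heavy gap injection drops columns from the profile", {
  cfg <- smallConfig(9L, msaGapRate = 0.6, msaWidth = 40L)
  msa <- simulateGroupedAlignment(cfg)
  kept <- tryCatch(filterColumns(msa$alignment), error = function(e) integer(0))
  expect_lt(length(kept), 40L)
})
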