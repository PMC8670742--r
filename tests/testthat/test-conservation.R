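test_that("occupancy filter keeps the exact 50% boundary", {
  ga <- tinyAlignment(
    c(m1 = "A-A-", m2 = "A--A", u1 = "AA--", u2 = "A-AA"),
    c(m1 = "modified", m2 = "modified", u1 = "unmodified",
      u2 = "unmodified"))
  # occupancies: 1.0, 0.25, 0.5, 0.5
  expect_equal(filterColumns(ga), c(1L, 3L, 4L))
  gap <- tinyAlignment(
    c(m1 = "--", m2 = "--", u1 = "--", u2 = "A-"),
    c(m1 = "modified", m2 = "modified", u1 = "unmodified",
      u2 = "unmodified"))
  expect_error(filterColumns(gap), "too gappy")
  full <- tinyAlignment(
    c(m1 = "AC", m2 = "AC", u1 = "AC", u2 = "AC"),
    c(m1 = "modified", m2 = "modified", u1 = "unmodified",
      u2 = "unmodified"))
  expect_equal(filterColumns(full), c(1L, 2L))
})

test_that("intra- and inter-group similarities expand over residue pairs", {
  M <- BLOSUM
  expect_equal(intraGroupSimilarity(c("N", "N"), M), M["N", "N"])
  expect_equal(intraGroupSimilarity(c("A", "A", "A"), M), M["A", "A"])
  expect_equal(intraGroupSimilarity(c("N", "D", "N"), M),
               (2 * M["N", "D"] + M["N", "N"]) / 3)
  expect_true(is.na(intraGroupSimilarity("N", M)))   # single residue

  expect_equal(interGroupSimilarity("N", "N", M), M["N", "N"])
  expect_equal(interGroupSimilarity(c("N", "N"), c("D", "D"), M),
               M["N", "D"])
  expect_equal(interGroupSimilarity(c("A", "R"), "N", M),
               (M["A", "N"] + M["R", "N"]) / 2)
  expect_true(is.na(interGroupSimilarity(character(0), "N", M)))
})

test_that("differential score separates fixed-residue groups", {
  M <- BLOSUM
  # perfectly conserved column
  s0 <- differentialScore(c("W", "W"), c("W", "W", "W"), M)
  expect_identical(s0$S, 0)
  # group-fixed distinct residues
  s1 <- differentialScore(rep("N", 3), rep("D", 4), M)
  expect_equal(s1$S, (M["N", "N"] + M["D", "D"]) / 2 - M["N", "D"])
  # identical residue multisets in both groups: S <= 0
  s2 <- differentialScore(c("A", "R"), c("A", "R"), M)
  expect_equal(s2$S, (2 * M["A", "R"] - M["A", "A"] - M["R", "R"]) / 4)
  expect_lte(s2$S, 0)
  # unscorable group propagates as missing
  s3 <- differentialScore("N", c("D", "D"), M)
  expect_true(is.na(s3$S))
})

test_that("swapping group labels leaves S unchanged", {
  M <- BLOSUM
  aa <- rownames(M)[1:20]
  set.seed(5)
  for (i in 1:100) {
    r1 <- sample(aa, sample(2:8, 1), replace = TRUE)
    r2 <- sample(aa, sample(2:8, 1), replace = TRUE)
    expect_equal(differentialScore(r1, r2, M)$S,
                 differentialScore(r2, r1, M)$S, tolerance = 1e-12)
  }
})

test_that("reference mapping skips reference gaps", {
  ga <- tinyAlignment(
    c(ref = "A-CD", m2 = "AACD", u1 = "AACD", u2 = "AAC-"),
    c(ref = "modified", m2 = "modified", u1 = "unmodified",
      u2 = "unmodified"), referenceId = "ref")
  expect_equal(mapToReference(ga, 3L), 2L)
  expect_true(is.na(mapToReference(ga, 2L)))
  expect_equal(mapToReference(ga, c(1L, 4L)), c(1L, 3L))
  expect_error(mapToReference(ga, 1L, referenceId = "nope"),
               "not in alignment")
  # gap-free reference: position equals column
  gb <- tinyAlignment(
    c(ref = "ACDE", m2 = "ACDE", u1 = "ACDE", u2 = "ACDE"),
    c(ref = "modified", m2 = "modified", u1 = "unmodified",
      u2 = "unmodified"), referenceId = "ref")
  expect_equal(mapToReference(gb, 1:4), 1:4)
})

test_that("profile computation and ranking surface the divergent column", {
  rows <- c(m1 = "AAWAC", m2 = "AAWAC", m3 = "AAWAC",
            u1 = "AADAC", u2 = "AADAC", u3 = "AADA-")
  labels <- setNames(rep(c("modified", "unmodified"), each = 3),
                     names(rows))
  ga <- tinyAlignment(rows, labels, referenceId = "m1")
  prof <- conservationProfile(ga, BLOSUM)
  df <- resultTable(prof)
  expect_equal(df$column, 1:5)
  expect_equal(df$ref_position, 1:5)
  # S = (I1+I2)/2 - J holds on every scored column
  ok <- !is.na(df$S)
  expect_equal(df$S[ok],
               (df$I_modified[ok] + df$I_unmodified[ok]) / 2 - df$J[ok])
  top <- rankPositions(prof, 2)
  expect_equal(top$column[1], 3L)    # the W/D column
  M <- BLOSUM
  expect_equal(top$S[1], (M["W", "W"] + M["D", "D"]) / 2 - M["W", "D"])
  # all-identical alignment: S = 0 everywhere, rank order = column order
  same <- tinyAlignment(
    c(m1 = "CCC", m2 = "CCC", u1 = "CCC", u2 = "CCC"),
    c(m1 = "modified", m2 = "modified", u1 = "unmodified",
      u2 = "unmodified"))
  pr2 <- conservationProfile(same, BLOSUM)
  rk <- rankPositions(pr2, 10)
  expect_true(all(rk$S == 0))
  expect_equal(rk$column, 1:3)
})
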