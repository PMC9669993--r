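## A small diverged seed alignment reused across scanning tests.
makeSeed <- function(L = 60, rows = 20, mutated = 12, seed = 99) {
  set.seed(seed)
  cons <- sample(AA20, L, replace = TRUE)
  out <- vapply(seq_len(rows), function(i) {
    v <- cons
    idx <- sample(L, mutated)
    v[idx] <- sample(AA20, mutated, replace = TRUE)
    paste(v, collapse = "")
  }, character(1))
  names(out) <- paste0("r", seq_len(rows))
  list(rows = out, consensus = paste(cons, collapse = ""))
}

test_that("profile construction matches a counting oracle", {
  ## forced signs on a one-residue column
  pr <- buildProfile(c(a = "AM", b = "AM", c = "AM"))
  expect_gt(pr@logOdds[1, "A"], 0)
  expect_lt(pr@logOdds[1, "W"], 0)

  ## huge pseudocount drives log-odds to 0
  pr2 <- buildProfile(c(a = "AM", b = "AM"), pseudocount = 1e9)
  expect_true(all(abs(pr2@logOdds) < 1e-6))

  ## 3-row toy alignment vs hand-counted frequencies
  rows <- c(a = "AC", b = "AD", c = "CC")
  pr3 <- buildProfile(rows, pseudocount = 1)
  bg <- 1 / 20
  freqA1 <- (2 + 1 * bg) / (3 + 1)   # col 1: two A, one C
  expect_equal(unname(pr3@logOdds[1, "A"]), log2(freqA1 / bg))
  freqC2 <- (2 + 1 * bg) / (3 + 1)   # col 2: two C, one D
  expect_equal(unname(pr3@logOdds[2, "C"]), log2(freqC2 / bg))
  expect_true(all(is.finite(pr3@logOdds)))

  expect_warning(buildProfile(c(a = "A-M", b = "A-M")), "all-gap")
  expect_error(buildProfile(c(a = "AM")), ">= 2")
})

test_that("Gumbel calibration yields a monotone vanishing E-value", {
  sd <- makeSeed()
  pr <- calibrateNull(buildProfile(sd$rows), 150, seed = 4)
  expect_true(isCalibrated(pr))
  expect_gt(pr@beta, 0)
  expect_equal(evalueLike(pr, Inf), 0)
  s <- seq(-10, 60, by = 5)
  expect_true(all(diff(evalueLike(pr, s)) < 0))
  expect_error(scanSequence("MKLV", buildProfile(sd$rows)),
               "not calibrated")
})

test_that("consensus scores at least as high as any point mutant", {
  sd <- makeSeed(L = 30)
  pr <- buildProfile(sd$rows)
  consScore <- sum(pr@logOdds[cbind(1:30, match(strsplit(sd$consensus, "")[[1]],
                                                AA20))])
  set.seed(5)
  for (i in 1:25) {
    v <- strsplit(sd$consensus, "")[[1]]
    pos <- sample(30, 1)
    v[pos] <- sample(setdiff(AA20, v[pos]), 1)
    mutScore <- sum(pr@logOdds[cbind(1:30, match(v, AA20))])
    expect_lte(mutScore, consScore)
  }
})

test_that("planted domains are recovered with copy indices and flags", {
  sd <- makeSeed()
  pr <- calibrateNull(buildProfile(sd$rows), 200, seed = 4)
  set.seed(12)
  bg1 <- randAA(50); bg2 <- randAA(40)

  ## single planted copy at offset 50
  seq1 <- paste0(bg1, sd$consensus, bg2)
  h1 <- scanSequence(seq1, pr, id = "planted")
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$start, 51L)
  expect_identical(h1$copy_index, 1L)
  expect_false(h1$partial)

  ## tandem copies: indices 1 and 2, non-overlapping
  seq2 <- paste0(bg1, sd$consensus, sd$consensus, bg2)
  h2 <- scanSequence(seq2, pr)
  expect_identical(h2$copy_index, c(1L, 2L))
  expect_true(all(h2$end[-nrow(h2)] < h2$start[-1]))

  ## N-terminally truncated half domain is reported and flagged partial
  half <- substr(sd$consensus, 31, 60)
  seq3 <- paste0(half, bg1, bg2)
  h3 <- scanSequence(seq3, pr)
  expect_gte(nrow(h3), 1L)
  expect_true(h3$partial[1])
  expect_identical(h3$start[1], 1L)
  expect_equal(h3$coverage[1], 0.5)
})

test_that("symmetric input gives symmetric copy scores", {
  cfg <- simConfig(nTips = 10, siteSubProb = 0,
                   cladeMotifs = c(A = "NLCSE", B = "NPCGE"),
                   domainPrevalence = c(A = 1, B = 1),
                   duplicationClades = "B", innerDegradationFactor = 1,
                   seed = 6)
  fam <- evolveFamily(cfg)
  truth <- familyTruth(fam)
  dl <- fam@config@domainLength
  seedRows <- setNames(substr(as.character(familySequences(fam)), 1, dl),
                       truth$id)
  pr <- calibrateNull(buildProfile(seedRows), 150, seed = 2)
  dup <- truth$id[truth$n_copies == 2L][1]
  h <- scanSequence(substr(as.character(familySequences(fam)[[dup]]),
                           1, 2 * dl), pr, id = dup)
  expect_identical(nrow(h), 2L)
  expect_equal(h$score[1], h$score[2])
})

test_that("architecture table matches simulator truth and ignores order", {
  cfg <- simConfig(nTips = 20, siteSubProb = 0,
                   cladeMotifs = c(A = "NLCSE", B = "NPCGE"),
                   domainPrevalence = c(A = 0.7, B = 0.7),
                   duplicationClades = "B", seed = 10)
  fam <- evolveFamily(cfg)
  truth <- familyTruth(fam)
  aln <- familyAlignment(fam)
  nt <- extractRegion(aln, buildColumnMap(aln), familyRegionSpecs(fam)$nterm)
  dl <- fam@config@domainLength
  seedIds <- truth$id[truth$n_copies >= 1L]
  seedRows <- setNames(substr(as.character(familySequences(fam)[seedIds]),
                              1, dl), seedIds)
  pr <- calibrateNull(buildProfile(seedRows), 150, seed = 3)
  targets <- setNames(nt$seq[!nt$empty], nt$parent_id[!nt$empty])
  hits <- scanSequences(targets, pr)
  arch <- architectureTable(hits, ids = truth$id)
  expect_identical(arch$n_copies[match(truth$id, arch$parent_id)],
                   truth$n_copies)

  ## permutation invariance
  perm <- sample(length(targets))
  arch2 <- architectureTable(scanSequences(targets[perm], pr),
                             ids = truth$id)
  expect_identical(arch, arch2)

  ## no hits anywhere -> all counts zero
  empty <- architectureTable(coneSSN:::.emptyHits(), ids = c("x", "y"))
  expect_identical(empty$n_copies, c(0L, 0L))
})
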