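test_that("finger-loop rule table reproduces the published motif classes", {
  expect_identical(classifyFingerLoop(window5 = "NLCSE")$class, "I_like")
  expect_identical(classifyFingerLoop(window5 = "NLCTE")$class, "I_like")
  expect_identical(classifyFingerLoop(window5 = "NPCGE")$class, "II_like")
  expect_identical(classifyFingerLoop(window5 = "NPCSE")$class, "II_like")
  expect_identical(classifyFingerLoop(window5 = "NVCLE")$class, "zero_like")
  expect_identical(classifyFingerLoop(window5 = "AAAAA")$class, "other")

  m <- classifyFingerLoop(window4 = "MGCR")
  expect_identical(m$class, "III_single_cys")
  expect_identical(m$reductant, "formate_capable")
  expect_true(m$has_met)

  expect_identical(classifyFingerLoop(window4 = "MCCR")$class,
                   "III_double_cys_met")

  s <- classifyFingerLoop(window4 = "SCCR", hasActiveGlu = TRUE)
  expect_identical(s$class, "III_double_cys_nomet")
  expect_identical(s$reductant, "thioredoxin_only")

  q <- classifyFingerLoop(window4 = "QCCR", hasActiveGlu = FALSE)
  expect_identical(q$class, "nrdD3_like")
  expect_identical(q$reductant, "novel")
  expect_identical(classifyFingerLoop(window4 = "QCCA")$class, "nrdD3_like")

  ## wildcard positions accept any residue; the observed residue is kept
  expect_identical(classifyFingerLoop(window5 = "NLCWE")$x_residue, "W")

  expect_error(classifyFingerLoop(window5 = "NLC"), "length")
  expect_error(classifyFingerLoop(window5 = "NLCSE", window4 = "MGCR"),
               "exactly one")
  expect_error(classifyFingerLoop(), "exactly one")
})

test_that("classification is total and pure over random windows", {
  set.seed(61)
  labels5 <- c("I_like", "II_like", "zero_like", "other")
  for (i in 1:200) {
    w <- randAA(5)
    c1 <- classifyFingerLoop(window5 = w)
    c2 <- classifyFingerLoop(window5 = w)
    expect_identical(c1$class, c2$class)
    expect_true(c1$class %in% labels5)
  }
  labels4 <- c("III_single_cys", "III_double_cys_met",
               "III_double_cys_nomet", "nrdD3_like", "other")
  for (i in 1:200) {
    w <- randAA(4)
    expect_true(classifyFingerLoop(window4 = w)$class %in% labels4)
  }
})

test_that("unknown-anchor windows fall back from aerobic to anaerobic rules", {
  expect_identical(classifyMotifWindow("NLCSE")$class, "I_like")
  expect_identical(classifyMotifWindow("MGCRA")$class, "III_single_cys")
  expect_identical(classifyMotifWindow("SCCRA", TRUE)$class,
                   "III_double_cys_nomet")
  expect_identical(classifyMotifWindow("AAAAA")$class, "other")
  expect_identical(classifyMotifWindow("QCCR")$class, "nrdD3_like")
})

test_that("conservation percentages match a tally oracle", {
  p <- conservationProfile(c("MKC", "MKC", "MKC"))
  expect_true(all(p[cbind(1:3, c("M", "K", "C"))] == 100))

  p2 <- conservationProfile(c("M", "G"))
  expect_equal(unname(p2[1, c("G", "M")]), c(50, 50))

  set.seed(15)
  rows <- vapply(1:50, function(i) randAA(8), character(1))
  p3 <- conservationProfile(rows)
  M <- do.call(rbind, strsplit(rows, ""))
  for (j in 1:8) {
    tab <- table(M[, j])
    for (res in names(tab))
      expect_equal(p3[j, res], 100 * as.numeric(tab[[res]]) / 50)
  }
  expect_true(all(abs(rowSums(p3) - 100) < 1e-9))
  expect_error(conservationProfile(c("AA", "AAA")), "ragged")
})

test_that("C-terminal cysteine architectures are recognised", {
  base <- strrep("A", 120)
  two <- classifyCterm(paste0(base, "GGCPACGG"))
  expect_identical(two$spacing, "CXXC")
  expect_false(two$zinc_finger)
  expect_identical(two$n_cys, 2L)

  four <- classifyCterm(paste0(base, "CAAAAC"))
  expect_identical(four$spacing, "CXXXXC")

  none <- classifyCterm(base)
  expect_identical(none$n_cys, 0L)
  expect_identical(none$spacing, "none")

  one <- classifyCterm(paste0(base, "ACAA"))
  expect_identical(one$spacing, "single")

  ## four cysteines in two tight pairs near the end: zinc finger
  zf <- classifyCterm(paste0(strrep("A", 200), "CAAC",
                             strrep("G", 15), "CAAC", "AAAA"))
  expect_true(zf$zinc_finger)
  expect_identical(zf$length_class, "long")

  ## the same pairs far from the terminus are not a zinc finger
  notzf <- classifyCterm(paste0("CAAC", strrep("G", 15), "CAAC",
                                strrep("A", 200)))
  expect_false(notzf$zinc_finger)

  empty <- classifyCterm("")
  expect_identical(empty$n_cys, 0L)
  expect_identical(empty$length_class, "short")
})

test_that("two-means length split recovers the planted boundary", {
  expect_error(lengthSplit(rep(100, 5)), "10")

  same <- lengthSplit(rep(100, 20))
  expect_false(same$bimodal)

  set.seed(33)
  lens <- c(rnorm(250, 80, 15), rnorm(250, 250, 50))
  sp <- lengthSplit(lens)
  expect_true(sp$bimodal)
  expect_gt(sp$threshold, 140)
  expect_lt(sp$threshold, 180)

  ## labels invariant to input order
  perm <- sample(500)
  sp2 <- lengthSplit(lens[perm])
  expect_identical(sp2$labels, sp$labels[perm])
  expect_equal(sp2$threshold, sp$threshold)

  ## unimodal data is not flagged
  uni <- lengthSplit(rnorm(200, 150, 20))
  expect_false(uni$bimodal)
})

test_that("operon orientation is strand-aware", {
  rec <- function(genome, role, start, end, strand)
    data.frame(genome = genome, role = role, start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  ba <- rbind(rec("g1", "beta", 1000, 2000, "+"),
              rec("g1", "alpha", 2500, 4000, "+"))
  expect_identical(operonOrientation(ba)$orientation, "beta_alpha")

  ab <- rbind(rec("g2", "alpha", 1000, 2000, "+"),
              rec("g2", "beta", 2500, 4000, "+"))
  expect_identical(operonOrientation(ab)$orientation, "alpha_beta")

  ## on the minus strand downstream means a smaller start
  baMinus <- rbind(rec("g3", "beta", 2500, 4000, "-"),
                   rec("g3", "alpha", 1000, 2000, "-"))
  expect_identical(operonOrientation(baMinus)$orientation, "beta_alpha")

  disc <- rbind(rec("g4", "alpha", 1000, 2000, "+"),
                rec("g4", "beta", 2500, 4000, "-"))
  expect_identical(operonOrientation(disc)$orientation, "discordant")

  bad <- rec("g5", "alpha", 1000, 2000, "+")
  expect_error(operonOrientation(bad), "exactly one")
  expect_error(operonOrientation(rec("g6", "alpha", 10, 5, "+")), "start")
})
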