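test_that("newick parsing validates and round-trips", {
  tr <- readNewick("(A:1,B:2);")
  expect_identical(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))

  expect_error(readNewick("((A:1,B:2);"), "parse error")
  expect_error(readNewick("(A:1,B:2));"), "parse error")

  set.seed(19)
  for (i in 1:100) {
    t1 <- ape::rtree(sample(3:15, 1))
    t2 <- readNewick(writeNewick(t1))
    expect_true(ape::all.equal.phylo(t1, t2, tolerance = 1e-8))
  }
})

test_that("midpoint rooting balances the deepest pair", {
  r <- midpointRoot(readNewick("(A:1,B:1);"))
  d <- ape::node.depth.edgelength(r)
  expect_equal(unname(d[1:2]), c(1, 1))

  ## longest path A-C of length 5; midpoint 2.5 from each end, on C's edge
  r2 <- midpointRoot(readNewick("(A:1,(B:1,C:3):1);"))
  d2 <- ape::node.depth.edgelength(r2)[seq_len(3)]
  names(d2) <- r2$tip.label
  expect_equal(unname(d2["A"]), 2.5)
  expect_equal(unname(d2["C"]), 2.5)

  ## 100 random trees: deepest tip depth equals half the oracle diameter
  set.seed(23)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:12, 1))
    diam <- max(tipDistOracle(tr))
    r <- midpointRoot(tr)
    depths <- ape::node.depth.edgelength(r)[seq_along(r$tip.label)]
    expect_equal(max(depths), diam / 2, tolerance = 1e-6)
  }

  zero <- readNewick("(A:0,B:0);")
  expect_error(midpointRoot(zero), "degenerate")
})

test_that("pruning a monophyletic clade preserves path lengths", {
  tr <- readNewick("((A:1,B:2):1,(C:1,(D:2,E:1):1):2);")
  expect_true(ape::all.equal.phylo(pruneClade(tr, tr$tip.label), tr))

  sub <- pruneClade(tr, c("D", "E"))
  expect_setequal(sub$tip.label, c("D", "E"))

  expect_error(pruneClade(tr, c("A", "C")), "intruding")
  expect_error(pruneClade(tr, c("A", "Z")), "unknown")
  expect_error(pruneClade(tr, character()), "empty")

  ## random clades of random trees: pairwise distances preserved
  set.seed(29)
  for (i in 1:30) {
    tr <- ape::rtree(sample(6:12, 1))
    ntip <- length(tr$tip.label)
    node <- sample((ntip + 2):(ntip + tr$Nnode), 1)  # exclude the root
    tips <- tr$tip.label[unlist(phangorn::Descendants(tr, node, "tips"))]
    if (length(tips) < 2) next
    sub <- pruneClade(tr, tips)
    Dfull <- tipDistOracle(tr)[tips, tips]
    Dsub <- tipDistOracle(sub)[tips, tips]
    expect_equal(Dsub, Dfull, tolerance = 1e-9)
  }
})

test_that("Fitch counts match brute force and an independent library", {
  tr <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(fitchChanges(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_identical(fitchChanges(tr, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_error(fitchChanges(tr, c(A = 1, B = 1)), "missing")

  set.seed(37)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    k <- sample(2:3, 1)
    states <- setNames(sample(seq_len(k), n, replace = TRUE), tr$tip.label)
    got <- fitchChanges(tr, states)
    expect_identical(got, fitchBrute(tr, states))
    ## cross-check against phangorn on binary characters
    if (k == 2) {
      pd <- phangorn::phyDat(matrix(as.character(states[tr$tip.label]),
                                    ncol = 1,
                                    dimnames = list(tr$tip.label, NULL)),
                             type = "USER", levels = c("1", "2"))
      expect_identical(got, as.integer(phangorn::fitch(tr, pd)))
    }
  }
})

test_that("Fitch count is invariant under re-rooting", {
  set.seed(41)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    states <- setNames(sample(0:1, 8, replace = TRUE), tr$tip.label)
    base <- fitchChanges(tr, states)
    for (tip in sample(tr$tip.label, 3)) {
      rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_identical(fitchChanges(rr, states), base)
    }
  }
})

test_that("single-origin test flags planted gains and degenerate traits", {
  set.seed(43)
  tr <- ape::rtree(40)
  node <- 40 + 10
  cladeTips <- tr$tip.label[unlist(phangorn::Descendants(tr, node, "tips"))]
  states <- setNames(ifelse(tr$tip.label %in% cladeTips, 1L, 0L),
                     tr$tip.label)
  res <- singleOriginTest(tr, states, nShuffles = 300, seed = 7)
  expect_identical(res$observed, 1L)
  expect_gt(res$exceedance, 0)
  expect_false(res$degenerate)

  const <- singleOriginTest(tr, setNames(rep(1, 40), tr$tip.label),
                            nShuffles = 300, seed = 7)
  expect_true(const$degenerate)
  expect_identical(const$observed, 0L)
})

test_that("concordance reports monophyly and scattering", {
  tr <- readNewick("((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
  ann <- c(A = "x", B = "x", C = "y", D = "y", E = "x")
  res <- clusterCladeConcordance(tr, ann)
  res <- res[order(res$category), ]
  expect_identical(res$monophyletic, c(FALSE, TRUE))
  expect_identical(res$scattering[res$category == "y"], 1L)
  expect_identical(res$scattering[res$category == "x"], 2L)

  expect_error(clusterCladeConcordance(tr, c(Z = "x")), "unknown")

  set.seed(47)
  for (i in 1:40) {
    tr <- ape::rtree(sample(5:12, 1))
    ann <- setNames(sample(c("p", "q"), length(tr$tip.label), replace = TRUE),
                    tr$tip.label)
    res <- clusterCladeConcordance(tr, ann)
    for (cat in unique(ann)) {
      tips <- names(ann)[ann == cat]
      expect_identical(res$scattering[res$category == cat],
                       blockOracle(tr, tips))
    }
  }
})

test_that("annotation export covers every tip exactly once", {
  tr <- ape::rtree(6)
  p <- tempfile(fileext = ".tsv")
  ann <- setNames(sample(c("a", "b"), 6, replace = TRUE), tr$tip.label)
  out <- writeTipAnnotations(tr, list(grp = ann), p)
  expect_identical(sort(out$tip_id), sort(tr$tip.label))
  expect_identical(anyDuplicated(out$tip_id), 0L)
  unlink(p)
})
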