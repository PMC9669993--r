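test_that("pairwise local alignment scores and statistics behave", {
  p <- scoringParams()
  r <- alignPair("AAAA", "AAAA", p, idA = "x", idB = "y")
  expect_equal(r$raw, 16)                       # 4 x BLOSUM62 A:A
  expect_equal(r$aln_score, -log10(r$evalue))
  expect_equal(r$bits, (p@lambda * 16 - log(p@K)) / log(2))

  ## symmetry under argument swap
  set.seed(44)
  for (i in 1:10) {
    a <- randAA(sample(5:30, 1)); b <- randAA(sample(5:30, 1))
    f <- alignPair(a, b, p, idA = "s1", idB = "s2")
    g <- alignPair(b, a, p, idA = "s2", idB = "s1")
    expect_equal(f$raw, g$raw)
    expect_equal(f$evalue, g$evalue)
  }
  expect_error(alignPair("", "AA"), "empty")

  ## nonstandard residues score 0 (neutral), so an all-X pair has raw 0
  expect_equal(alignPair("XXXX", "XXXX", p)$raw, 0)
})

test_that("alignment score is -log10 of the E-value", {
  expect_identical(alnScoreFromEvalue(1e-20), 20)
  expect_identical(alnScoreFromEvalue(1e-30), 30)
  expect_identical(alnScoreFromEvalue(1), 0)
  expect_error(alnScoreFromEvalue(0), "positive")
  expect_error(alnScoreFromEvalue(-1), "positive")
})

test_that("aligner matches the exhaustive enumeration oracle (spot sample)", {
  p <- scoringParams()
  set.seed(8)
  alph <- c("A", "C", "D", "E")
  for (i in 1:40) {
    a <- randAA(sample(1:5, 1), alph)
    b <- randAA(sample(1:5, 1), alph)
    expect_equal(alignPair(a, b, p)$raw,
                 swOracle(a, b, p@matrix, p@gapOpen, p@gapExt),
                 info = paste(a, b))
  }
})

test_that("network edges respect the threshold and nest monotonically", {
  set.seed(3)
  s <- randAA(100)
  g <- buildSSN(c(a = s, b = s, c = randAA(100)), threshold = 20.5)
  e <- ssnEdges(g)
  expect_true(any(e$id_a == "a" & e$id_b == "b"))   # identical pair connected
  expect_true(all(e$aln_score >= 20.5))

  ## edge sets shrink as the threshold grows
  seqs <- setNames(vapply(1:8, function(i) randAA(60), character(1)),
                   paste0("n", 1:8))
  g2 <- buildSSN(seqs, threshold = 5)
  edgeKey <- function(g, t) {
    e <- g@pairs[g@pairs$aln_score >= t, ]
    sort(paste(e$id_a, e$id_b))
  }
  for (t in c(5, 10, 15, 20)) {
    expect_true(all(edgeKey(g2, t + 5) %in% edgeKey(g2, t)))
  }

  ## absurdly high threshold leaves the graph edgeless
  g3 <- buildSSN(seqs, threshold = 1e6)
  expect_identical(nrow(ssnEdges(g3)), 0L)
})

test_that("graph output is invariant to input order", {
  set.seed(13)
  seqs <- setNames(vapply(1:10, function(i) randAA(50), character(1)),
                   paste0("n", 1:10))
  g1 <- buildSSN(seqs, threshold = 10)
  g2 <- buildSSN(seqs[sample(10)], threshold = 10)
  key <- function(g) {
    e <- ssnEdges(g)
    sort(sprintf("%s|%s|%.6f", pmin(e$id_a, e$id_b), pmax(e$id_a, e$id_b),
                 e$aln_score))
  }
  expect_identical(key(g1), key(g2))
  c1 <- clusterComponents(g1); c2 <- clusterComponents(g2)
  expect_identical(c1[order(c1$id), ], c2[order(c2$id), ],
                   ignore_attr = TRUE)
})

test_that("components are labelled like a union-find oracle", {
  g <- graphFromEdges(paste0("v", 1:5), character(), character())
  cl <- clusterComponents(g)
  expect_true(all(cl$singleton))
  expect_identical(sort(cl$cluster), 1:5)

  ## two planted cliques
  ids <- paste0("v", 1:6)
  ea <- c("v1", "v1", "v2", "v4", "v4", "v5")
  eb <- c("v2", "v3", "v3", "v5", "v6", "v6")
  cl2 <- clusterComponents(graphFromEdges(ids, ea, eb))
  expect_identical(length(unique(cl2$cluster)), 2L)
  expect_identical(length(unique(cl2$cluster[cl2$id %in% c("v1", "v2", "v3")])),
                   1L)

  ## random graphs against the oracle
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(4:15, 1)
    ids <- paste0("v", seq_len(n))
    m <- sample(0:12, 1)
    ea <- sample(ids, m, replace = TRUE)
    eb <- sample(ids, m, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    cl <- clusterComponents(graphFromEdges(ids, ea, eb))
    oracle <- unionFindOracle(ids, ea, eb)
    ## same partition: cluster labels must be a bijection of oracle roots
    expect_identical(length(unique(cl$cluster)), length(unique(oracle)))
    expect_true(all(tapply(oracle[cl$id], cl$cluster,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("threshold sweeps refine and report separations", {
  set.seed(9)
  seqs <- setNames(vapply(1:12, function(i) randAA(60), character(1)),
                   paste0("n", 1:12))
  g <- buildSSN(seqs, threshold = 10)
  sw <- thresholdSweep(g, c(5, 10, 15, 20, 25))

  ## single threshold equals clusterComponents
  sw1 <- thresholdSweep(g, 10)
  expect_identical(unname(sw1$membership[, 1]),
                   clusterComponents(g, 10)$cluster)

  ## partitions refine: co-membership at a higher threshold implies
  ## co-membership at every lower one
  for (k in seq_len(ncol(sw$membership) - 1)) {
    lo <- sw$membership[, k]; hi <- sw$membership[, k + 1]
    for (i in seq_along(lo)) for (j in seq_along(lo)) {
      if (hi[i] == hi[j]) expect_true(lo[i] == lo[j])
    }
  }
  expect_error(thresholdSweep(g, c(10, 5)), "ascending")
})

test_that("hub-spoke names the large central cluster and orders spokes", {
  ## single cluster: it is the hub, no spokes
  g1 <- graphFromEdges(c("a", "b"), "a", "b")
  hs1 <- hubSpoke(g1)
  expect_identical(nrow(hs1$spokes), 0L)
  expect_identical(hs1$hub, clusterComponents(g1)$cluster[1])

  ## planted star: central cluster (largest, touching 3 others at the
  ## relaxed threshold) is the hub; spokes sit at distance 1
  ids <- c(paste0("h", 1:4), paste0("a", 1:2), paste0("b", 1:2),
           paste0("c", 1:2))
  ea <- c("h1", "h1", "h1", "a1", "b1", "c1")
  eb <- c("h2", "h3", "h4", "a2", "b2", "c2")
  pairs <- data.frame(id_a = ea, id_b = eb, raw = 100, bits = 100,
                      evalue = 1e-100, aln_score = 100,
                      stringsAsFactors = FALSE)
  relaxed <- data.frame(id_a = c("h2", "h3", "h4"),
                        id_b = c("a1", "b1", "c1"), raw = 48, bits = 48,
                        evalue = 1e-48, aln_score = 48,
                        stringsAsFactors = FALSE)
  g2 <- methods::new("SSNGraph",
                     nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                     pairs = rbind(pairs, relaxed), threshold = 50)
  cl <- clusterComponents(g2)
  hs2 <- hubSpoke(g2, cl, delta = 5)
  hubIds <- cl$id[cl$cluster == hs2$hub]
  expect_setequal(hubIds, paste0("h", 1:4))
  expect_true(all(hs2$spokes$distance[!is.na(hs2$spokes$distance)] == 1L))

  expect_error(hubSpoke(methods::new("SSNGraph",
                                     nodes = data.frame(id = character()),
                                     pairs = pairs[0, ], threshold = 1)),
               "empty")
})
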