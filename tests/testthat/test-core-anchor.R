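test_that("column map walks the anchor row", {
  aln <- anchoredAlignment(c(ref = "MKLVAEQWTY", s = "MKLVAEQWTY"), "ref")
  expect_identical(buildColumnMap(aln), 1:10)

  aln2 <- anchoredAlignment(c(ref = "A-CD", s = "AQCD"), "ref")
  expect_identical(buildColumnMap(aln2), c(1L, 3L, 4L))

  expect_error(buildColumnMap(anchoredAlignment(c(ref = "---", s = "AAA"),
                                                "ref")),
               "all gaps")

  ## 100 random gapped rows against a per-character walk oracle
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    chars <- sample(c(AA20, "-"), n, replace = TRUE, prob = c(rep(1, 20), 8))
    if (all(chars == "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    aln <- anchoredAlignment(c(ref = row, s = paste(rep("A", n), collapse = "")),
                             "ref")
    walk <- integer(0)
    for (j in seq_len(n)) if (chars[j] != "-") walk <- c(walk, j)
    expect_identical(buildColumnMap(aln), walk)
  }
})

test_that("region extraction honours coordinates, boundaries and empty rows", {
  aln <- anchoredAlignment(c(ref = "MKLVAEQW", s2 = "MRLVAEQW"), "ref")
  cmap <- buildColumnMap(aln)
  sp <- extractRegion(aln, cmap, regionSpec("mid", "span", 3, 5))
  expect_identical(sp$seq, c("LVA", "LVA"))
  expect_identical(sp$start, c(3L, 3L))
  expect_identical(sp$end, c(5L, 5L))

  ## one-residue span on gapless rows gives length-1 subsequences
  one <- extractRegion(aln, cmap, regionSpec("one", "span", 4, 4))
  expect_identical(nchar(one$seq), c(1L, 1L))

  ## cterm at the last anchor residue: anchor's own tail is empty
  ct <- extractRegion(aln, cmap, regionSpec("tail", "cterm",
                                            boundaryResidue = 8))
  expect_true(all(ct$empty))

  ## all-gap window rows are flagged empty, not dropped
  aln3 <- anchoredAlignment(c(ref = "MKLV", s = "MK-V"), "ref")
  sp3 <- extractRegion(aln3, buildColumnMap(aln3),
                       regionSpec("gap", "span", 3, 3))
  expect_identical(sp3$empty, c(FALSE, TRUE))
  expect_true(is.na(sp3$start[2]))

  expect_error(extractRegion(aln, cmap, regionSpec("bad", "span", 3, 99)),
               "outside")
})

test_that("nterm + core + cterm reconstruct every simulated sequence", {
  for (s in c(3, 17)) {
    fam <- evolveFamily(simConfig(nTips = 25, seed = s))
    aln <- familyAlignment(fam)
    cmap <- buildColumnMap(aln)
    specs <- familyRegionSpecs(fam)
    off <- familyTruth(fam)$nterm_length[
      match(refId(aln), familyTruth(fam)$id)]
    core <- extractRegion(aln, cmap,
                          regionSpec("core", "span", off + 1L,
                                     off + fam@config@coreLength))
    nt <- extractRegion(aln, cmap, specs$nterm)
    ct <- extractRegion(aln, cmap, specs$cterm)
    recon <- paste0(ifelse(nt$empty, "", nt$seq), core$seq,
                    ifelse(ct$empty, "", ct$seq))
    full <- as.character(familySequences(fam))[nt$parent_id]
    expect_identical(recon, unname(full))
  }
})

test_that("column map is stable under write/read round trip", {
  fam <- evolveFamily(simConfig(nTips = 12, seed = 8))
  aln <- familyAlignment(fam)
  p <- tempfile(fileext = ".afa")
  writeAnchoredAlignment(aln, p)
  aln2 <- readAnchoredAlignment(p, refId(aln))
  expect_identical(buildColumnMap(aln2), buildColumnMap(aln))
  unlink(p)
})

test_that("center-star alignment behaves on degenerate and small inputs", {
  ## identical sequences align without gaps
  out <- msaCenterStar(c(a = "MKLVAE", b = "MKLVAE", c = "MKLVAE"))
  expect_true(all(!grepl("-", alnRows(out), fixed = TRUE)))

  ## two sequences: identical to the pairwise global alignment
  p <- scoringParams()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("MKLVAE"), Biostrings::AAString("MKVAE"),
    substitutionMatrix = p@matrix, gapOpening = p@gapOpen,
    gapExtension = p@gapExt, type = "global")
  out2 <- msaCenterStar(c(x = "MKLVAE", y = "MKVAE"))
  rows <- alnRows(out2)
  got <- sort(unname(rows))
  want <- sort(c(as.character(Biostrings::alignedPattern(pa)),
                 as.character(Biostrings::alignedSubject(pa))))
  expect_identical(got, want)

  expect_error(msaCenterStar(c(a = "MK", b = "")), "empty")
  expect_error(msaCenterStar(c(a = "MK")), "two sequences")
})

test_that("center-star merge preserves each pairwise center alignment", {
  set.seed(77)
  p <- scoringParams()
  for (rep in 1:10) {
    seqs <- setNames(vapply(1:4, function(i) randAA(sample(8:14, 1)),
                            character(1)), paste0("s", 1:4))
    out <- msaCenterStar(seqs, p)
    rows <- alnRows(out)
    center <- refId(out)
    for (id in setdiff(names(seqs), center)) {
      ## drop columns gapped in both the center and this row
      c1 <- strsplit(rows[[center]], "")[[1]]
      c2 <- strsplit(rows[[id]], "")[[1]]
      keep <- !(c1 == "-" & c2 == "-")
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[center]]),
        Biostrings::AAString(seqs[[id]]),
        substitutionMatrix = p@matrix, gapOpening = p@gapOpen,
        gapExtension = p@gapExt, type = "global")
      expect_identical(paste(c1[keep], collapse = ""),
                       as.character(Biostrings::alignedPattern(pa)))
      expect_identical(paste(c2[keep], collapse = ""),
                       as.character(Biostrings::alignedSubject(pa)))
    }
  }
})
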