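## Synthetic family generator: pure-birth tree, per-site substitution of a
## conserved core, clade-planted finger-loop motifs, N-terminal regulatory
## domains with tandem duplication and inner-copy degradation, and bimodal
## C-terminal tails with planted cysteine architectures.

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Stand-in for an inferred family phylogeny: a binary rooted tree with
#' heterogeneous, strictly positive branch lengths. Deterministic for a fixed
#' seed.
#'
#' @param nTips Number of tips (>= 2).
#' @param birthRate Speciation rate per unit time (> 0).
#' @param seed Integer RNG seed.
#' @return An \code{ape::phylo} with tips labelled \code{t001, t002, ...}.
#' @examples
#' tr <- simulateTree(8, 1, seed = 7)
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = 1L) {
  nTips <- .assertCount(nTips, "nTips", min = 2L)
  if (!is.finite(birthRate) || birthRate <= 0)
    stop("'birthRate' must be > 0", call. = FALSE)
  tr <- .withSeed(seed, ape::rphylo(nTips, birth = birthRate, death = 0))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr$tip.label <- sprintf("t%03d", seq_len(nTips))
  tr
}

#' Configure the synthetic family generator
#'
#' Defaults mirror the study conditions the generator emulates: five clades
#' carrying the finger-loop motifs NLCSE, NPCGE, NVCLE, MGCR and MCCR; an
#' N-terminal regulatory domain present in 48.7%, 11.3% and 48.6% of the
#' aerobic-class-like and anaerobic-like clades (absent from the minimal
#' clade); tandem duplication in one clade with the inner copy evolving
#' faster; and C-terminal tails drawn from a short (mean 80, sd 15) and a
#' long (mean 250, sd 50) mode bracketing a 160-residue split, with
#' cysteine-pattern frequencies of 64/6/4/26% (two/multi/single/none) among
#' non-zinc-finger tails.
#'
#' @param nTips Number of tips.
#' @param birthRate Yule speciation rate (per unit time).
#' @param coreLength Length of the conserved core (residues).
#' @param siteSubProb Substitution rate per site per unit branch length; a
#'   site on a branch of length b mutates with probability
#'   \code{1 - exp(-siteSubProb * b)}.
#' @param cladeMotifs Named character vector, clade label -> finger-loop
#'   motif (4 or 5 residues).
#' @param domainPrevalence Named numeric, clade -> fraction of tips carrying
#'   the N-terminal domain.
#' @param duplicationClades Clade labels whose domain occurs in tandem
#'   (two copies, the inner one degraded).
#' @param domainLength Length of the regulatory domain (residues).
#' @param innerDegradationFactor Rate multiplier (>= 1) applied to degraded
#'   sites of the inner copy.
#' @param degradedSiteFraction Fraction of inner-copy sites receiving the
#'   elevated rate (default 0.2, emulating drift concentrated at
#'   ligand-binding positions; set 1 to degrade the whole copy).
#' @param ctermLengthModes 2x2 matrix, rows = (mean, sd) of the short and
#'   long tail length modes.
#' @param ctermPatternProbs Probabilities of the five planted C-terminal
#'   cysteine architectures (must sum to 1).
#' @param motifNoise Probability that a tip's planted motif window receives
#'   one random site flip (0 = motifs inherited exactly); a noise level of x
#'   perturbs about a fraction x of the windows.
#' @param glulessClades Clades lacking the active-site glutamate.
#' @param operonOrders Named character, clade -> \code{"alpha_beta"} or
#'   \code{"beta_alpha"}; default puts beta upstream in duplication clades
#'   and alpha upstream elsewhere.
#' @param motifStart 1-based core position of the 5-residue motif window.
#' @param gluPos 1-based core position of the active-site glutamate.
#' @param seed Integer RNG seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nTips = 20, seed = 3)
#' @export
simConfig <- function(nTips,
                      birthRate = 1,
                      coreLength = 150L,
                      siteSubProb = 0.05,
                      cladeMotifs = c(I = "NLCSE", II = "NPCGE",
                                      O = "NVCLE", IIIa = "MGCR",
                                      IIIb = "MCCR"),
                      domainPrevalence = NULL,
                      duplicationClades = NULL,
                      domainLength = 100L,
                      innerDegradationFactor = 3,
                      degradedSiteFraction = 0.2,
                      ctermLengthModes = rbind(short = c(80, 15),
                                               long = c(250, 50)),
                      ctermPatternProbs = NULL,
                      motifNoise = 0,
                      glulessClades = character(),
                      operonOrders = NULL,
                      motifStart = 61L,
                      gluPos = 100L,
                      seed = 1L) {
  labels <- names(cladeMotifs)
  if (is.null(domainPrevalence)) {
    domainPrevalence <- setNames(rep(0.5, length(labels)), labels)
    defaults <- c(I = 0.487, II = 0.113, O = 0, IIIa = 0.486, IIIb = 0.486)
    hit <- intersect(labels, names(defaults))
    domainPrevalence[hit] <- defaults[hit]
  }
  if (is.null(duplicationClades))
    duplicationClades <- intersect("I", labels)
  if (is.null(ctermPatternProbs)) {
    zf <- 0.3  # zinc fingers are common among long tails; see vignette
    ctermPatternProbs <- c(two_cys = 0.64, multi_cys = 0.06,
                           single_cys = 0.04, no_cys = 0.26) * (1 - zf)
    ctermPatternProbs <- c(ctermPatternProbs, zinc_finger = zf)
  }
  if (is.null(operonOrders))
    operonOrders <- setNames(
      ifelse(labels %in% duplicationClades, "beta_alpha", "alpha_beta"),
      labels)
  new("SimConfig",
      nTips = .assertCount(nTips, "nTips", 2L),
      birthRate = birthRate, coreLength = as.integer(coreLength),
      siteSubProb = siteSubProb, cladeMotifs = cladeMotifs,
      domainPrevalence = domainPrevalence,
      duplicationClades = as.character(duplicationClades),
      domainLength = as.integer(domainLength),
      innerDegradationFactor = innerDegradationFactor,
      degradedSiteFraction = degradedSiteFraction,
      ctermLengthModes = ctermLengthModes,
      ctermPatternProbs = ctermPatternProbs,
      motifNoise = motifNoise, glulessClades = as.character(glulessClades),
      operonOrders = operonOrders, motifStart = as.integer(motifStart),
      gluPos = as.integer(gluPos), seed = as.integer(seed))
}

## Split a rooted binary tree into k monophyletic tip groups by repeatedly
## replacing the largest group with the two child subtrees of its root node.
.cladeGroups <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k > ntip) stop("more clades than tips", call. = FALSE)
  root <- ntip + 1L
  children <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
  nodes <- if (k == 1L) root else children(root)
  tipsOf <- function(node) {
    if (node <= ntip) return(node)
    unlist(phangorn::Descendants(tree, node, type = "tips"))
  }
  while (length(nodes) < k) {
    sizes <- vapply(nodes, function(n) length(tipsOf(n)), integer(1))
    internal <- nodes > ntip
    if (!any(internal)) stop("cannot split tree further", call. = FALSE)
    cand <- which(internal)
    pick <- cand[order(-sizes[cand], nodes[cand])][1L]
    nodes <- c(nodes[-pick], children(nodes[pick]))
  }
  groups <- lapply(nodes, tipsOf)
  ## deterministic labelling: largest group first, ties by smallest tip index
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, min, integer(1)))
  lapply(groups[ord], function(idx) tree$tip.label[idx])
}

## One branch of per-site substitution: each site mutates with probability
## 1 - exp(-rate * branchlength), uniformly over the 19 other residues.
.mutateSeq <- function(s, rates, bl) {
  p <- 1 - exp(-rates * bl)
  hit <- which(stats::runif(length(s)) < p)
  if (length(hit))
    s[hit] <- ((s[hit] - 1L + sample.int(19L, length(hit), replace = TRUE))
               %% 20L) + 1L
  s
}

## Evolve a start sequence (integer-encoded 1..20) from `node` down to every
## descendant tip; `node` defaults to the root. Returns a list with `tips`
## (matrix, rows named by reachable tip labels) and `nodes` (per-node
## sequences, NULL outside the subtree).
.evolveFromNode <- function(tree, startSeq, rates, node = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(node)) node <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[node]] <- startSeq
  tr <- stats::reorder(tree, "cladewise")   # parents precede children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    if (is.null(seqs[[parent]])) next
    seqs[[child]] <- .mutateSeq(seqs[[parent]], rates, tr$edge.length[e])
  }
  reach <- which(!vapply(seqs[seq_len(ntip)], is.null, logical(1)))
  tips <- do.call(rbind, seqs[reach])
  rownames(tips) <- tree$tip.label[reach]
  list(tips = tips, nodes = seqs)
}

.intToAA <- function(m) {
  if (is.matrix(m))
    apply(m, 1L, function(r) paste(AA20[r], collapse = ""))
  else paste(AA20[m], collapse = "")
}

#' Evolve a synthetic protein family with planted ground truth
#'
#' Simulates a tree, splits it into monophyletic clades (one per configured
#' motif), evolves a conserved core plus an optional N-terminal domain along
#' the tree, plants clade motifs and the active-site glutamate, duplicates
#' the domain in the configured clades with a degraded inner copy, and
#' attaches a bimodal C-terminal tail with a planted cysteine architecture.
#' Every planted attribute is recorded in the truth table and is recoverable
#' from the emitted sequences by direct string inspection.
#'
#' @param cfg A [SimConfig-class].
#' @return A [SyntheticFamily-class].
#' @examples
#' fam <- evolveFamily(simConfig(nTips = 12, seed = 5))
#' head(familyTruth(fam))
#' @export
evolveFamily <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  tree <- simulateTree(cfg@nTips, cfg@birthRate, .childSeed(cfg@seed, 1L))
  .withSeed(.childSeed(cfg@seed, 2L), .evolveFamilyImpl(cfg, tree))
}

.evolveFamilyImpl <- function(cfg, tree) {
  tips <- tree$tip.label
  n <- length(tips)
  labels <- names(cfg@cladeMotifs)
  groups <- .cladeGroups(tree, length(labels))
  clade <- setNames(rep(NA_character_, n), tips)
  for (i in seq_along(groups)) clade[groups[[i]]] <- labels[i]

  ## conserved core: motif window and glutamate position are frozen sites
  Lc <- cfg@coreLength
  motifWin <- cfg@motifStart:(cfg@motifStart + 4L)
  coreRates <- rep(cfg@siteSubProb, Lc)
  coreRates[c(motifWin, cfg@gluPos)] <- 0
  rootCore <- sample.int(20L, Lc, replace = TRUE)
  coreM <- .evolveFromNode(tree, rootCore, coreRates)$tips

  ## clade motif assignment (4-residue motifs padded to the 5-column window)
  aaIndex <- setNames(seq_along(AA20), AA20)
  for (tp in tips) {
    motif <- cfg@cladeMotifs[[clade[tp]]]
    win <- .strsplit1(if (nchar(motif) == 4L) paste0(motif, "A") else motif)
    coreM[tp, motifWin] <- aaIndex[win]
    glu <- if (clade[tp] %in% cfg@glulessClades) "Q" else "E"
    coreM[tp, cfg@gluPos] <- aaIndex[[glu]]
  }
  ## motif noise: with probability motifNoise a window receives one random
  ## site flip (so a noise level of x perturbs ~x of the windows)
  if (cfg@motifNoise > 0) {
    for (tp in tips) {
      if (stats::runif(1L) < cfg@motifNoise) {
        site <- motifWin[sample.int(5L, 1L)]
        cur <- coreM[tp, site]
        coreM[tp, site] <- ((cur - 1L + sample.int(19L, 1L)) %% 20L) + 1L
      }
    }
  }

  ## N-terminal domain: one ancestral sequence evolving at the base rate
  ## (the outer copy). In each duplication clade the domain is duplicated at
  ## the clade ancestor and the inner copy then drifts within the clade at
  ## the elevated rate on the degraded site subset.
  Ld <- cfg@domainLength
  rootDom <- sample.int(20L, Ld, replace = TRUE)
  outerEv <- .evolveFromNode(tree, rootDom, rep(cfg@siteSubProb, Ld))
  outerM <- outerEv$tips
  nDeg <- ceiling(cfg@degradedSiteFraction * Ld)
  degSites <- if (nDeg > 0) sort(sample.int(Ld, nDeg)) else integer()
  innerRates <- rep(cfg@siteSubProb, Ld)
  innerRates[degSites] <- cfg@siteSubProb * cfg@innerDegradationFactor
  innerM <- matrix(integer(0), 0L, Ld)
  for (dc in intersect(cfg@duplicationClades, labels)) {
    cladeTips <- names(clade)[clade == dc]
    if (length(cladeTips) == 1L) {
      seg <- matrix(outerM[cladeTips, ], 1L, Ld,
                    dimnames = list(cladeTips, NULL))
    } else {
      mrca <- ape::getMRCA(tree, cladeTips)
      seg <- .evolveFromNode(tree, outerEv$nodes[[mrca]], innerRates,
                             node = mrca)$tips
    }
    innerM <- rbind(innerM, seg)
  }

  hasDomain <- stats::runif(n) < cfg@domainPrevalence[clade]
  nCopies <- ifelse(hasDomain,
                    ifelse(clade %in% cfg@duplicationClades, 2L, 1L), 0L)

  ## C-terminal tails: two length modes, planted cysteine architecture
  mode <- sample.int(2L, n, replace = TRUE)
  lens <- pmax(40L, as.integer(round(stats::rnorm(
    n, cfg@ctermLengthModes[mode, 1L], cfg@ctermLengthModes[mode, 2L]))))
  pattern <- sample(names(cfg@ctermPatternProbs), n, replace = TRUE,
                    prob = cfg@ctermPatternProbs)
  noCys <- setdiff(AA20, "C")
  tails <- character(n)
  for (i in seq_len(n)) {
    tl <- sample(noCys, lens[i], replace = TRUE)
    pos <- switch(pattern[i],
      two_cys     = lens[i] - c(8L, 5L),
      multi_cys   = lens[i] - c(12L, 8L, 5L),
      single_cys  = lens[i] - 6L,
      no_cys      = integer(),
      zinc_finger = lens[i] - c(30L, 27L, 10L, 7L))
    tl[pos] <- "C"
    tails[i] <- paste(tl, collapse = "")
  }

  ## assemble sequences and the generative (true) alignment
  coreStr <- .intToAA(coreM)
  outerStr <- .intToAA(outerM)
  innerStr <- if (nrow(innerM)) .intToAA(innerM) else character()
  maxTail <- max(lens)
  gapsDom <- strrep("-", Ld)
  seqs <- character(n); rows <- character(n)
  for (i in seq_len(n)) {
    tp <- tips[i]
    outer <- if (nCopies[i] >= 1L) outerStr[[tp]] else ""
    inner <- if (nCopies[i] == 2L) innerStr[[tp]] else ""
    seqs[i] <- paste0(outer, inner, coreStr[[tp]], tails[i])
    rows[i] <- paste0(
      if (nCopies[i] >= 1L) outerStr[[tp]] else gapsDom,
      if (nCopies[i] == 2L) innerStr[[tp]] else gapsDom,
      coreStr[[tp]],
      tails[i], strrep("-", maxTail - lens[i]))
  }
  names(seqs) <- tips; names(rows) <- tips

  ## anchor = a tip with the fewest domain copies (clean core numbering)
  refCand <- tips[order(nCopies, tips)]
  refTip <- refCand[1L]

  ntermLen <- nCopies * Ld
  motifClass <- character(n); reductant <- character(n)
  for (i in seq_len(n)) {
    m <- cfg@cladeMotifs[[clade[i]]]
    call <- if (nchar(m) == 5L)
      classifyFingerLoop(window5 = m, hasActiveGlu = !(clade[i] %in% cfg@glulessClades))
    else
      classifyFingerLoop(window4 = m, hasActiveGlu = !(clade[i] %in% cfg@glulessClades))
    motifClass[i] <- call$class
    reductant[i] <- call$reductant
  }

  truth <- data.frame(
    id = tips, clade = unname(clade[tips]),
    motif = unname(cfg@cladeMotifs[clade[tips]]),
    motif_class = motifClass, reductant = reductant,
    has_glu = !(clade[tips] %in% cfg@glulessClades),
    n_copies = nCopies, inner_degraded = nCopies == 2L,
    nterm_length = ntermLen,
    core_start = ntermLen + 1L, core_end = ntermLen + Lc,
    motif_parent_start = ntermLen + cfg@motifStart,
    cterm_length = lens,
    cterm_length_class = c("short", "long")[mode],
    cterm_pattern = pattern,
    operon_order = unname(cfg@operonOrders[clade[tips]]),
    stringsAsFactors = FALSE)

  ## synthetic operon coordinates consistent with the per-clade order label
  op <- do.call(rbind, lapply(seq_len(n), function(i) {
    first <- c(1000L, 2000L); second <- c(2500L, 3500L)
    if (truth$operon_order[i] == "alpha_beta") {
      data.frame(genome = tips[i], role = c("alpha", "beta"),
                 start = c(first[1L], second[1L]),
                 end = c(first[2L], second[2L]),
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      data.frame(genome = tips[i], role = c("beta", "alpha"),
                 start = c(first[1L], second[1L]),
                 end = c(first[2L], second[2L]),
                 strand = "+", stringsAsFactors = FALSE)
    }
  }))

  new("SyntheticFamily",
      sequences = Biostrings::AAStringSet(seqs),
      alignment = anchoredAlignment(rows, refTip),
      tree = tree, truth = truth, operons = op, config = cfg)
}

#' Region specifications for a simulated family
#'
#' Translates the generator's planted coordinates into [RegionSpec-class]
#' objects expressed in the anchor tip's residue numbering, ready for
#' [extractRegion()]: the N-terminal extension, the 5-residue finger-loop
#' motif window, and the C-terminal tail. Also reports the anchor-coordinate
#' position of the active-site glutamate.
#'
#' @param fam A [SyntheticFamily-class].
#' @return List with elements \code{nterm}, \code{fingerLoop}, \code{cterm}
#'   ([RegionSpec-class] objects) and \code{gluResidue} (integer).
#' @export
familyRegionSpecs <- function(fam) {
  stopifnot(is(fam, "SyntheticFamily"))
  cfg <- fam@config
  off <- fam@truth$nterm_length[match(refId(fam@alignment), fam@truth$id)]
  list(
    nterm = regionSpec("nterm", "nterm",
                       boundaryResidue = if (off > 0L) off + 1L
                                         else NA_integer_),
    fingerLoop = regionSpec("finger_loop", "span",
                            refStart = off + cfg@motifStart,
                            refEnd = off + cfg@motifStart + 4L),
    cterm = regionSpec("cterm", "cterm",
                       boundaryResidue = off + cfg@coreLength),
    gluResidue = off + cfg@gluPos)
}

.configAsList <- function(cfg) {
  list(nTips = cfg@nTips, birthRate = cfg@birthRate,
       coreLength = cfg@coreLength, siteSubProb = cfg@siteSubProb,
       cladeMotifs = as.list(cfg@cladeMotifs),
       domainPrevalence = as.list(cfg@domainPrevalence),
       duplicationClades = cfg@duplicationClades,
       domainLength = cfg@domainLength,
       innerDegradationFactor = cfg@innerDegradationFactor,
       degradedSiteFraction = cfg@degradedSiteFraction,
       ctermLengthModes = list(short = unname(cfg@ctermLengthModes[1L, ]),
                               long = unname(cfg@ctermLengthModes[2L, ])),
       ctermPatternProbs = as.list(cfg@ctermPatternProbs),
       motifNoise = cfg@motifNoise, glulessClades = cfg@glulessClades,
       operonOrders = as.list(cfg@operonOrders),
       motifStart = cfg@motifStart, gluPos = cfg@gluPos, seed = cfg@seed)
}

.configFromList <- function(x) {
  simConfig(nTips = x$nTips, birthRate = x$birthRate,
            coreLength = x$coreLength, siteSubProb = x$siteSubProb,
            cladeMotifs = unlist(x$cladeMotifs),
            domainPrevalence = unlist(x$domainPrevalence),
            duplicationClades = as.character(unlist(x$duplicationClades)),
            domainLength = x$domainLength,
            innerDegradationFactor = x$innerDegradationFactor,
            degradedSiteFraction = x$degradedSiteFraction,
            ctermLengthModes = rbind(short = unlist(x$ctermLengthModes$short),
                                     long = unlist(x$ctermLengthModes$long)),
            ctermPatternProbs = unlist(x$ctermPatternProbs),
            motifNoise = x$motifNoise,
            glulessClades = as.character(unlist(x$glulessClades)),
            operonOrders = unlist(x$operonOrders),
            motifStart = x$motifStart, gluPos = x$gluPos, seed = x$seed)
}

#' Write a synthetic family to disk
#'
#' Emits \code{sequences.fasta}, \code{true_alignment.afa}, \code{tree.nwk},
#' \code{truth.tsv}, \code{operons.tsv} and a \code{manifest.json} carrying
#' the seed and a full config echo. [readDataset()] reproduces the in-memory
#' family from these files.
#'
#' @param fam A [SyntheticFamily-class].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
emitDataset <- function(fam, outdir) {
  stopifnot(is(fam, "SyntheticFamily"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  paths <- list(
    sequences = file.path(outdir, "sequences.fasta"),
    alignment = file.path(outdir, "true_alignment.afa"),
    tree = file.path(outdir, "tree.nwk"),
    truth = file.path(outdir, "truth.tsv"),
    operons = file.path(outdir, "operons.tsv"),
    manifest = file.path(outdir, "manifest.json"))
  Biostrings::writeXStringSet(fam@sequences, paths$sequences)
  writeAnchoredAlignment(fam@alignment, paths$alignment)
  ape::write.tree(fam@tree, paths$tree)
  utils::write.table(fam@truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fam@operons, paths$operons, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(seed = fam@config@seed, ref_id = refId(fam@alignment),
                   config = .configAsList(fam@config))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic family back from disk
#'
#' @param dir Directory written by [emitDataset()].
#' @return A [SyntheticFamily-class].
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  seqs <- Biostrings::readAAStringSet(file.path(dir, "sequences.fasta"))
  aln <- readAnchoredAlignment(file.path(dir, "true_alignment.afa"),
                               manifest$ref_id)
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  op <- utils::read.table(file.path(dir, "operons.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  new("SyntheticFamily", sequences = seqs, alignment = aln, tree = tree,
      truth = truth, operons = op, config = .configFromList(manifest$config))
}
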