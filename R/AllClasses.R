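#' @import methods
#' @importFrom stats sd rnorm rbinom quantile
#' @importFrom utils head combn write.table read.table
NULL

setOldClass("phylo")

## ---------------------------------------------------------------------------
## AnchoredAlignment
## ---------------------------------------------------------------------------

#' Reference-anchored multiple sequence alignment
#'
#' A gapped protein alignment together with the identifier of one row, the
#' anchor, whose ungapped residue numbering (1-based, UniProt style) defines
#' the coordinate system for region extraction. Gap character is \code{"-"}.
#'
#' @slot rows Named character vector of equal-length gapped strings.
#' @slot refId Identifier of the anchor row; must be one of \code{names(rows)}.
#'
#' @seealso [buildColumnMap()], [extractRegion()], [msaCenterStar()]
#' @export
setClass("AnchoredAlignment",
  representation(rows = "character", refId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@rows) < 1L) msg <- c(msg, "alignment has no rows")
    if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
      msg <- c(msg, "rows must have unique names")
    w <- unique(nchar(object@rows))
    if (length(w) > 1L) msg <- c(msg, "rows differ in gapped length")
    if (length(object@refId) != 1L || !(object@refId %in% names(object@rows)))
      msg <- c(msg, "refId must name one alignment row")
    if (length(msg)) msg else TRUE
  })

#' Construct an AnchoredAlignment
#'
#' @param rows Named character vector of gapped strings (or an
#'   [Biostrings::AAStringSet] whose names are sequence IDs).
#' @param refId Name of the anchor row.
#' @return An [AnchoredAlignment-class] object.
#' @examples
#' aln <- anchoredAlignment(c(ref = "A-CD", s2 = "AQC-"), "ref")
#' @export
anchoredAlignment <- function(rows, refId) {
  if (methods::is(rows, "XStringSet")) {
    nm <- names(rows)
    rows <- as.character(rows)
    names(rows) <- nm
  }
  new("AnchoredAlignment", rows = rows, refId = as.character(refId))
}

#' @describeIn AnchoredAlignment-class anchor row identifier
#' @param x,object An \code{AnchoredAlignment}.
#' @export
refId <- function(x) x@refId

#' @describeIn AnchoredAlignment-class named gapped rows
#' @export
alnRows <- function(x) x@rows

#' @describeIn AnchoredAlignment-class alignment width (columns)
#' @export
alnWidth <- function(x) nchar(x@rows[[1L]])

setMethod("show", "AnchoredAlignment", function(object) {
  cat(sprintf("AnchoredAlignment: %d rows x %d columns, anchored on '%s'\n",
              length(object@rows), alnWidth(object), object@refId))
  ids <- utils::head(names(object@rows), 3L)
  for (id in ids)
    cat(sprintf("  %-12s %s\n", id,
                substr(object@rows[[id]], 1L, min(50L, alnWidth(object)))))
  if (length(object@rows) > 3L) cat("  ...\n")
})

## ---------------------------------------------------------------------------
## RegionSpec
## ---------------------------------------------------------------------------

#' Region specification in reference coordinates
#'
#' Describes a region to extract from every row of an anchored alignment:
#' an N-terminal extension (everything before the first anchor residue), a
#' C-terminal tail (everything strictly after a boundary residue), or an
#' internal span (inclusive residue range of the anchor). All coordinates are
#' 1-based residue numbers of the ungapped anchor sequence.
#'
#' @slot name Region label.
#' @slot kind One of \code{"nterm"}, \code{"cterm"}, \code{"span"}.
#' @slot refStart,refEnd Inclusive anchor residues (span only).
#' @slot boundaryResidue Anchor residue after which the tail starts (cterm).
#' @export
setClass("RegionSpec",
  representation(name = "character", kind = "character",
                 refStart = "integer", refEnd = "integer",
                 boundaryResidue = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("nterm", "cterm", "span"))
      msg <- c(msg, "kind must be nterm, cterm or span")
    if (object@kind == "span" &&
        (length(object@refStart) != 1L || length(object@refEnd) != 1L ||
         is.na(object@refStart) || is.na(object@refEnd) ||
         object@refStart < 1L || object@refStart > object@refEnd))
      msg <- c(msg, "span requires 1 <= refStart <= refEnd")
    if (object@kind == "cterm" &&
        (length(object@boundaryResidue) != 1L || is.na(object@boundaryResidue) ||
         object@boundaryResidue < 1L))
      msg <- c(msg, "cterm requires boundaryResidue >= 1")
    if (object@kind == "nterm" && !is.na(object@boundaryResidue) &&
        object@boundaryResidue < 1L)
      msg <- c(msg, "nterm boundaryResidue must be >= 1 when given")
    if (length(msg)) msg else TRUE
  })

#' Construct a RegionSpec
#'
#' @param name Region label.
#' @param kind \code{"nterm"}, \code{"cterm"} or \code{"span"}.
#' @param refStart,refEnd Inclusive 1-based anchor residues (span only).
#' @param boundaryResidue For \code{cterm}, the anchor residue after which
#'   the tail begins (e.g. the last residue of the catalytic barrel). For
#'   \code{nterm}, optionally the anchor residue before which the extension
#'   ends (default 1; set it past the anchor's own N-terminal domain copies
#'   when the anchor itself carries the extension).
#' @return A [RegionSpec-class] object.
#' @examples
#' regionSpec("finger_loop", "span", refStart = 319, refEnd = 367)
#' regionSpec("cterm", "cterm", boundaryResidue = 639)
#' @export
regionSpec <- function(name, kind, refStart = NA_integer_, refEnd = NA_integer_,
                       boundaryResidue = NA_integer_) {
  new("RegionSpec", name = as.character(name), kind = as.character(kind),
      refStart = as.integer(refStart), refEnd = as.integer(refEnd),
      boundaryResidue = as.integer(boundaryResidue))
}

setMethod("show", "RegionSpec", function(object) {
  detail <- switch(object@kind,
    span  = sprintf("residues %d..%d", object@refStart, object@refEnd),
    cterm = sprintf("after residue %d", object@boundaryResidue),
    nterm = "before residue 1")
  cat(sprintf("RegionSpec '%s' (%s: %s)\n", object@name, object@kind, detail))
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic family generator
#'
#' Houses every knob of the generative model: a pure-birth tree, a conserved
#' core evolving by per-site substitution, clade-specific finger-loop motifs,
#' clade-specific prevalence of an N-terminal regulatory domain, tandem
#' duplication with a faster-evolving (degraded) inner copy, and bimodal
#' C-terminal tails with planted cysteine architectures. Built with
#' [simConfig()]; see that constructor for defaults and units.
#'
#' @slot nTips,coreLength,domainLength,motifStart,gluPos Integer sizes and
#'   1-based core coordinates.
#' @slot birthRate,siteSubProb,innerDegradationFactor,degradedSiteFraction,motifNoise
#'   Numeric rates/fractions.
#' @slot cladeMotifs Named character: clade label to motif string (4 or 5 aa).
#' @slot domainPrevalence Named numeric in [0,1] per clade.
#' @slot duplicationClades,glulessClades Character vectors of clade labels.
#' @slot ctermLengthModes 2x2 numeric matrix, rows = (mean, sd) of the short
#'   and long tail mode.
#' @slot ctermPatternProbs Named numeric over \code{two_cys, multi_cys,
#'   single_cys, no_cys, zinc_finger}, summing to 1.
#' @slot operonOrders Named character per clade: \code{alpha_beta} or
#'   \code{beta_alpha}.
#' @slot seed Integer RNG seed.
#' @export
setClass("SimConfig",
  representation(nTips = "integer", birthRate = "numeric",
                 coreLength = "integer", siteSubProb = "numeric",
                 cladeMotifs = "character", domainPrevalence = "numeric",
                 duplicationClades = "character", domainLength = "integer",
                 innerDegradationFactor = "numeric",
                 degradedSiteFraction = "numeric",
                 ctermLengthModes = "matrix", ctermPatternProbs = "numeric",
                 motifNoise = "numeric", glulessClades = "character",
                 operonOrders = "character", motifStart = "integer",
                 gluPos = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nTips < 2L) msg <- c(msg, "nTips must be >= 2")
    if (object@birthRate <= 0) msg <- c(msg, "birthRate must be > 0")
    if (object@nTips < length(object@cladeMotifs))
      msg <- c(msg, "need at least one tip per clade")
    if (is.null(names(object@cladeMotifs)))
      msg <- c(msg, "cladeMotifs must be named by clade label")
    if (!all(nchar(object@cladeMotifs) %in% c(4L, 5L)))
      msg <- c(msg, "clade motifs must be 4 or 5 residues")
    if (any(object@domainPrevalence < 0) || any(object@domainPrevalence > 1))
      msg <- c(msg, "domainPrevalence must lie in [0,1]")
    if (!all(names(object@cladeMotifs) %in% names(object@domainPrevalence)))
      msg <- c(msg, "domainPrevalence must cover every clade")
    if (!all(object@duplicationClades %in% names(object@cladeMotifs)))
      msg <- c(msg, "duplicationClades must be clade labels")
    if (object@innerDegradationFactor < 1)
      msg <- c(msg, "innerDegradationFactor must be >= 1")
    if (object@degradedSiteFraction < 0 || object@degradedSiteFraction > 1)
      msg <- c(msg, "degradedSiteFraction must lie in [0,1]")
    if (object@siteSubProb < 0) msg <- c(msg, "siteSubProb must be >= 0")
    if (object@motifNoise < 0 || object@motifNoise > 1)
      msg <- c(msg, "motifNoise must lie in [0,1]")
    pp <- object@ctermPatternProbs
    if (!setequal(names(pp),
                  c("two_cys", "multi_cys", "single_cys", "no_cys",
                    "zinc_finger")))
      msg <- c(msg, "ctermPatternProbs must name the five pattern classes")
    if (any(pp < 0) || abs(sum(pp) - 1) > 1e-8)
      msg <- c(msg, "ctermPatternProbs must be non-negative and sum to 1")
    if (!all(dim(object@ctermLengthModes) == c(2L, 2L)))
      msg <- c(msg, "ctermLengthModes must be a 2x2 (mean, sd) matrix")
    longest <- max(nchar(object@cladeMotifs))
    if (object@coreLength < object@motifStart + 5L ||
        object@coreLength < longest)
      msg <- c(msg, "coreLength too short for the motif window")
    if (object@gluPos > object@coreLength ||
        (object@gluPos >= object@motifStart && object@gluPos <= object@motifStart + 4L))
      msg <- c(msg, "gluPos must lie in the core outside the motif window")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d tips, birth rate %.3g, core %d aa, domain %d aa\n",
    "  clades: %s\n  substitution prob/branch-length %.3g; inner copy x%.1f",
    " on %.0f%% of domain sites\n"),
    object@nTips, object@birthRate, object@coreLength, object@domainLength,
    paste(sprintf("%s=%s", names(object@cladeMotifs), object@cladeMotifs),
          collapse = " "),
    object@siteSubProb, object@innerDegradationFactor,
    100 * object@degradedSiteFraction))
})

## ---------------------------------------------------------------------------
## SyntheticFamily
## ---------------------------------------------------------------------------

#' A simulated protein family with planted ground truth
#'
#' Output of [evolveFamily()]: tip sequences, the true (generative) anchored
#' alignment, the simulated tree, a per-tip truth table, a synthetic operon
#' table, and the generating configuration.
#'
#' @slot sequences [Biostrings::AAStringSet] of tip sequences.
#' @slot alignment [AnchoredAlignment-class] whose ungapped rows reproduce the
#'   sequences exactly.
#' @slot tree \code{ape::phylo} with tip labels matching sequence names.
#' @slot truth data.frame, one row per tip (clade, motif, motif_class,
#'   has_glu, n_copies, inner_degraded, cterm length/class/pattern,
#'   operon_order, coordinate bookkeeping).
#' @slot operons data.frame of synthetic alpha/beta gene coordinates.
#' @slot config The generating [SimConfig-class].
#' @export
setClass("SyntheticFamily",
  representation(sequences = "ANY", alignment = "AnchoredAlignment",
                 tree = "phylo", truth = "data.frame",
                 operons = "data.frame", config = "SimConfig"),
  validity = function(object) {
    msg <- character()
    ids <- names(object@sequences)
    if (!setequal(ids, object@tree$tip.label))
      msg <- c(msg, "sequence names and tree tips differ")
    if (!setequal(ids, object@truth$id))
      msg <- c(msg, "sequence names and truth rows differ")
    if (!setequal(ids, names(object@alignment@rows)))
      msg <- c(msg, "sequence names and alignment rows differ")
    ung <- .ungap(object@alignment@rows[ids])
    if (!identical(unname(ung), unname(as.character(object@sequences[ids]))))
      msg <- c(msg, "ungapped alignment rows do not reproduce the sequences")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SyntheticFamily", function(object) {
  cat(sprintf(
    "SyntheticFamily: %d tips, %d clades, alignment %d columns\n",
    length(object@sequences), length(unique(object@truth$clade)),
    alnWidth(object@alignment)))
  print(table(clade = object@truth$clade, copies = object@truth$n_copies))
})

#' @describeIn SyntheticFamily-class per-tip truth table
#' @param x A \code{SyntheticFamily}.
#' @export
familyTruth <- function(x) x@truth

#' @describeIn SyntheticFamily-class tip sequences as an AAStringSet
#' @export
familySequences <- function(x) x@sequences

#' @describeIn SyntheticFamily-class the true anchored alignment
#' @export
familyAlignment <- function(x) x@alignment

#' @describeIn SyntheticFamily-class the simulated phylogeny
#' @export
familyTree <- function(x) x@tree

## ---------------------------------------------------------------------------
## ProfileModel
## ---------------------------------------------------------------------------

#' Position-specific scoring model for domain detection
#'
#' Log-odds profile (log2 of pseudocounted column frequency over background)
#' built from a seed alignment, optionally calibrated against a Gumbel null
#' so that window scores convert to E-value-like expected exceedance counts.
#'
#' @slot logOdds Numeric matrix, profile columns x 20 residues, in bits.
#' @slot background Numeric 20-vector of residue frequencies.
#' @slot mu,beta Gumbel per-window location and scale; \code{NA} until
#'   [calibrateNull()] is run. \code{beta > 0} once calibrated.
#' @slot nWindows Number of windows per sequence used during calibration.
#' @slot consensus Consensus (argmax) sequence of the profile.
#' @export
setClass("ProfileModel",
  representation(logOdds = "matrix", background = "numeric",
                 mu = "numeric", beta = "numeric", nWindows = "integer",
                 consensus = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@logOdds) != 20L || !identical(colnames(object@logOdds), AA20))
      msg <- c(msg, "logOdds must have the 20 standard residues as columns")
    if (length(object@background) != 20L ||
        abs(sum(object@background) - 1) > 1e-6)
      msg <- c(msg, "background must be 20 frequencies summing to 1")
    if (!is.na(object@beta) && object@beta <= 0)
      msg <- c(msg, "calibration beta must be > 0")
    if (any(!is.finite(object@logOdds)))
      msg <- c(msg, "logOdds must be finite everywhere")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ProfileModel-class number of profile columns
#' @param x,object A \code{ProfileModel}.
#' @export
profileLength <- function(x) nrow(x@logOdds)

#' @describeIn ProfileModel-class TRUE once a Gumbel null has been fitted
#' @export
isCalibrated <- function(x) !is.na(x@beta)

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel: %d columns; consensus %s%s\n",
              profileLength(object),
              substr(object@consensus, 1L, 40L),
              if (nchar(object@consensus) > 40L) "..." else ""))
  if (isCalibrated(object))
    cat(sprintf("  Gumbel null: mu = %.3f, beta = %.3f (%d windows)\n",
                object@mu, object@beta, object@nWindows))
  else cat("  not calibrated\n")
})

## ---------------------------------------------------------------------------
## ScoringParams
## ---------------------------------------------------------------------------

#' Pairwise alignment scoring and Karlin-Altschul statistics
#'
#' Substitution matrix, affine gap penalties (a gap of length k costs
#' \code{gapOpen + k * gapExt}) and the gapped Karlin-Altschul constants used
#' to convert raw local-alignment scores to bit scores and E-values. Defaults
#' are the standard published gapped BLOSUM62/11/1 values.
#'
#' @slot matrix Substitution matrix (residues x residues); nonstandard codes
#'   score 0 against everything.
#' @slot gapOpen,gapExt Positive gap penalties.
#' @slot lambda,K Karlin-Altschul constants (lambda in nats per score unit).
#' @slot dbScale Effective database size in residues; \code{NA} means "set
#'   from the input set" when a network is built.
#' @export
setClass("ScoringParams",
  representation(matrix = "matrix", gapOpen = "numeric", gapExt = "numeric",
                 lambda = "numeric", K = "numeric", dbScale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@gapOpen <= 0 || object@gapExt <= 0)
      msg <- c(msg, "gap penalties must be > 0")
    if (object@lambda <= 0 || object@K <= 0)
      msg <- c(msg, "lambda and K must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf(
    "ScoringParams: gap %g/%g, lambda = %g, K = %g, dbScale = %s\n",
    object@gapOpen, object@gapExt, object@lambda, object@K,
    if (is.na(object@dbScale)) "auto" else format(object@dbScale)))
})

## ---------------------------------------------------------------------------
## SSNGraph
## ---------------------------------------------------------------------------

#' Sequence similarity network
#'
#' All-vs-all pairwise local alignments over a set of region sequences. The
#' full pair table is retained so that edges can be re-thresholded cheaply;
#' the graph at the stored threshold keeps an undirected edge wherever the
#' alignment score (-log10 E-value) is at least the threshold. No self edges.
#'
#' @slot nodes data.frame with column \code{id} plus optional attributes
#'   (class, copy index, ...).
#' @slot pairs data.frame of all pairs: \code{id_a, id_b, raw, bits, evalue,
#'   aln_score, pident}.
#' @slot threshold Alignment-score cutoff defining the edge set.
#' @export
setClass("SSNGraph",
  representation(nodes = "data.frame", pairs = "data.frame",
                 threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("id_a", "id_b", "aln_score")
    if (!all(need %in% names(object@pairs)))
      msg <- c(msg, "pairs must have id_a, id_b, aln_score")
    if (nrow(object@pairs) && any(object@pairs$id_a == object@pairs$id_b))
      msg <- c(msg, "self-edges are not allowed")
    if (!"id" %in% names(object@nodes)) msg <- c(msg, "nodes must have an id")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SSNGraph-class node attribute table
#' @param x,object An \code{SSNGraph}.
#' @export
ssnNodes <- function(x) x@nodes

#' @describeIn SSNGraph-class edge table at the stored threshold
#' @export
ssnEdges <- function(x) x@pairs[x@pairs$aln_score >= x@threshold, , drop = FALSE]

#' @describeIn SSNGraph-class the full all-vs-all pair table
#' @export
ssnPairs <- function(x) x@pairs

#' @describeIn SSNGraph-class alignment-score threshold in use
#' @export
ssnThreshold <- function(x) x@threshold

setMethod("show", "SSNGraph", function(object) {
  cat(sprintf("SSNGraph: %d nodes, %d/%d pairs >= threshold %.3g\n",
              nrow(object@nodes), nrow(ssnEdges(object)),
              nrow(object@pairs), object@threshold))
})
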