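## Reference-anchored coordinate mapping and region extraction. All residue
## coordinates are 1-based inclusive, matching UniProt numbering, so that
## published anchors (e.g. a finger loop at residues 319-367, a C-terminal
## boundary after residue 639) can be used verbatim.

#' Read/write an anchored alignment as aligned FASTA
#'
#' @param path File path.
#' @param refId Anchor row ID; defaults to the first record.
#' @return [readAnchoredAlignment()] returns an [AnchoredAlignment-class];
#'   [writeAnchoredAlignment()] returns the path invisibly.
#' @export
readAnchoredAlignment <- function(path, refId = NULL) {
  x <- Biostrings::readAAStringSet(path)
  if (is.null(refId)) refId <- names(x)[1L]
  anchoredAlignment(x, refId)
}

#' @rdname readAnchoredAlignment
#' @param aln An [AnchoredAlignment-class].
#' @export
writeAnchoredAlignment <- function(aln, path) {
  stopifnot(is(aln, "AnchoredAlignment"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln@rows), path)
  invisible(path)
}

#' Map anchor residues to alignment columns
#'
#' Walks the anchor row left to right; the k-th non-gap column is the column
#' of anchor residue k. The returned map is strictly increasing in both
#' coordinates and covers residues 1..(ungapped anchor length).
#'
#' @param aln An [AnchoredAlignment-class].
#' @return Integer vector \code{map} with \code{map[k]} = alignment column of
#'   anchor residue k.
#' @examples
#' aln <- anchoredAlignment(c(ref = "A-CD", s = "AQCD"), "ref")
#' buildColumnMap(aln)  # 1, 3, 4
#' @export
buildColumnMap <- function(aln) {
  stopifnot(is(aln, "AnchoredAlignment"))
  cols <- which(.strsplit1(aln@rows[[aln@refId]]) != "-")
  if (length(cols) == 0L)
    stop("anchor row is all gaps: invalid alignment", call. = FALSE)
  cols
}

## Resolve a RegionSpec to an inclusive column window [c1, c2] (c1 > c2 means
## an empty window, e.g. a C-terminal region when the boundary is the last
## anchor residue).
.regionColumns <- function(spec, cmap, width) {
  switch(spec@kind,
    span = {
      if (spec@refStart > length(cmap) || spec@refEnd > length(cmap))
        stop(sprintf("region '%s': residues outside the anchor (1..%d)",
                     spec@name, length(cmap)), call. = FALSE)
      c(cmap[spec@refStart], cmap[spec@refEnd])
    },
    cterm = {
      if (spec@boundaryResidue > length(cmap))
        stop(sprintf("region '%s': boundary residue outside the anchor (1..%d)",
                     spec@name, length(cmap)), call. = FALSE)
      c(cmap[spec@boundaryResidue] + 1L, width)
    },
    nterm = {
      b <- if (is.na(spec@boundaryResidue)) 1L else spec@boundaryResidue
      if (b > length(cmap))
        stop(sprintf("region '%s': boundary residue outside the anchor (1..%d)",
                     spec@name, length(cmap)), call. = FALSE)
      c(1L, cmap[b] - 1L)
    })
}

#' Extract a region from every row of an anchored alignment
#'
#' For a \code{span} the degapped content of the columns mapping to anchor
#' residues \code{refStart..refEnd}; for a \code{cterm} everything strictly
#' after the column of the boundary residue; for an \code{nterm} everything
#' strictly before the column of anchor residue 1. Rows whose window is all
#' gaps are retained with an \code{empty} flag rather than dropped, so that
#' census stages can decide exclusion explicitly. Span rows carrying an
#' insertion longer than \code{maxInsertion} relative to the anchor span are
#' flagged \code{long_insertion} (the automated analogue of removing
#' insertion-bearing rows by hand).
#'
#' @param aln An [AnchoredAlignment-class].
#' @param cmap Column map from [buildColumnMap()].
#' @param spec A [RegionSpec-class].
#' @param maxInsertion Span-region insertion length (extracted residues minus
#'   anchor span length) above which a row is flagged. Default 5.
#' @return data.frame with columns \code{parent_id, region, start, end, seq,
#'   empty} (+ \code{long_insertion} for spans); \code{start}/\code{end} are
#'   1-based inclusive positions in the ungapped parent, \code{NA} for empty
#'   rows.
#' @examples
#' aln <- anchoredAlignment(c(ref = "MKLVAE", s2 = "MRLV-E"), "ref")
#' extractRegion(aln, buildColumnMap(aln), regionSpec("mid", "span", 3, 5))
#' @export
extractRegion <- function(aln, cmap, spec, maxInsertion = 5L) {
  stopifnot(is(aln, "AnchoredAlignment"), is(spec, "RegionSpec"))
  validObject(spec)
  width <- alnWidth(aln)
  cc <- .regionColumns(spec, cmap, width)
  ids <- names(aln@rows)
  win <- if (cc[1L] > cc[2L]) rep("", length(ids))
         else substr(aln@rows, cc[1L], cc[2L])
  sub <- .ungap(win)
  prefix <- if (cc[1L] > 1L) substr(aln@rows, 1L, cc[1L] - 1L)
            else rep("", length(ids))
  before <- nchar(.ungap(prefix))
  len <- nchar(sub)
  empty <- len == 0L
  out <- data.frame(
    parent_id = ids, region = spec@name,
    start = ifelse(empty, NA_integer_, before + 1L),
    end = ifelse(empty, NA_integer_, before + len),
    seq = unname(sub), empty = empty,
    stringsAsFactors = FALSE)
  if (spec@kind == "span") {
    spanLen <- spec@refEnd - spec@refStart + 1L
    out$long_insertion <- !empty & (len - spanLen > maxInsertion)
  }
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Center-star multiple alignment
## ---------------------------------------------------------------------------

## Gapped global alignment of two sequences; returns the two aligned strings.
.globalAligned <- function(a, b, p) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = p@matrix, gapOpening = p@gapOpen,
    gapExtension = p@gapExt, type = "global")
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

#' Center-star multiple alignment
#'
#' A dependency-free progressive alignment: the center sequence maximising
#' the summed pairwise global scores is chosen as the star center, every
#' other sequence is globally aligned to it, and the pairwise alignments are
#' merged under the "once a gap, always a gap" rule. The merge preserves each
#' pairwise center alignment exactly. Not a substitute for a modern profile
#' aligner; intended for pipelines that must run self-contained.
#'
#' @param seqs Named character vector or [Biostrings::AAStringSet] (>= 2
#'   nonempty sequences).
#' @param scoring A [ScoringParams-class]; see [scoringParams()].
#' @return An [AnchoredAlignment-class] with \code{refId} = the center
#'   sequence.
#' @examples
#' msaCenterStar(c(a = "MKLV", b = "MKV", c = "MKLV"))
#' @export
msaCenterStar <- function(seqs, scoring = scoringParams()) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  if (any(nchar(seqs) == 0L)) stop("empty sequence", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%03d", seq_len(n))

  ## center = argmax of summed pairwise global scores (ties: first)
  S <- matrix(0, n, n)
  for (j in 2:n) for (i in 1:(j - 1L)) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
      substitutionMatrix = scoring@matrix, gapOpening = scoring@gapOpen,
      gapExtension = scoring@gapExt, type = "global", scoreOnly = TRUE)
    S[i, j] <- S[j, i] <- s
  }
  center <- which.max(rowSums(S))

  centerChars <- .strsplit1(seqs[[center]])
  masterCenter <- centerChars            # center row of the master alignment
  rows <- list(); rows[[names(seqs)[center]]] <- centerChars

  for (k in seq_len(n)) {
    if (k == center) next
    al <- .globalAligned(seqs[[center]], seqs[[k]], scoring)
    aC <- .strsplit1(al[1L]); aS <- .strsplit1(al[2L])
    newCenter <- character(0); newRow <- character(0)
    padOld <- integer(0)                 # master columns of the new layout
    i <- 1L; j <- 1L
    nM <- length(masterCenter); nP <- length(aC)
    while (i <= nM || j <= nP) {
      if (i <= nM && masterCenter[i] == "-") {
        ## insertion column from a previous merge: new row gets a gap
        newCenter <- c(newCenter, "-"); newRow <- c(newRow, "-")
        padOld <- c(padOld, i); i <- i + 1L
      } else if (j <= nP && aC[j] == "-") {
        ## insertion relative to the center in this pairwise alignment:
        ## open a fresh column (gap in all previously merged rows)
        newCenter <- c(newCenter, "-"); newRow <- c(newRow, aS[j])
        padOld <- c(padOld, NA_integer_); j <- j + 1L
      } else {
        newCenter <- c(newCenter, masterCenter[i])
        newRow <- c(newRow, aS[j])
        padOld <- c(padOld, i); i <- i + 1L; j <- j + 1L
      }
    }
    rows <- lapply(rows, function(r)
      ifelse(is.na(padOld), "-", r[ifelse(is.na(padOld), 1L, padOld)]))
    masterCenter <- newCenter
    rows[[names(seqs)[k]]] <- newRow
  }

  out <- vapply(rows, paste, character(1), collapse = "")
  anchoredAlignment(out[names(seqs)], names(seqs)[center])
}
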