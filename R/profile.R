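## Profile-based detection of an N-terminal regulatory domain: ungapped
## sliding-window log-odds scoring with a moment-matched Gumbel null giving
## E-value-like expected exceedance counts, greedy non-overlap resolution,
## N-to-C tandem copy indexing and partial-hit flagging. Deliberately not a
## full profile HMM: the use case is detect / count / copy-index behind a
## single E-value cutoff, and ungapped scanning plus Gumbel calibration
## reproduces that with far less machinery (a documented fidelity
## limitation relative to HMMER).

## Encode an AA string as integers 1..20, nonstandard codes -> 21 (neutral).
.encodeAA <- function(x) {
  idx <- match(.strsplit1(toupper(x)), AA20)
  idx[is.na(idx)] <- 21L
  idx
}

#' Build a position-specific scoring model from a seed alignment
#'
#' Column frequencies are pseudocounted towards the background:
#' \code{freq = (counts + pseudocount * background) / (n + pseudocount)}
#' with \code{n} the non-gap rows of the column, so log-odds
#' (\code{log2(freq / background)}) are finite everywhere. All-gap columns
#' are dropped with a warning. Nonstandard residues are ignored in the
#' counts and score 0 when scanned.
#'
#' @param seedAln An [AnchoredAlignment-class] or named character vector of
#'   equal-length gapped strings (>= 2 rows).
#' @param pseudocount Positive pseudocount weight (default 1).
#' @param background 20 residue background frequencies (default uniform).
#' @return An uncalibrated [ProfileModel-class].
#' @seealso [calibrateNull()], [scanSequence()]
#' @export
buildProfile <- function(seedAln, pseudocount = 1,
                         background = rep(1 / 20, 20)) {
  rows <- if (is(seedAln, "AnchoredAlignment")) seedAln@rows else seedAln
  if (length(rows) < 2L) stop("need >= 2 seed rows", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    stop("seed rows differ in length", call. = FALSE)
  background <- background / sum(background)
  names(background) <- AA20
  M <- do.call(rbind, lapply(rows, .strsplit1))
  keep <- colSums(M != "-") > 0L
  if (!all(keep)) {
    warning(sum(!keep), " all-gap column(s) dropped from the seed alignment")
    M <- M[, keep, drop = FALSE]
  }
  L <- ncol(M)
  lo <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- M[, j]
    col <- col[col %in% AA20]
    counts <- table(factor(col, levels = AA20))
    freq <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
    lo[j, ] <- log2(freq / background)
  }
  new("ProfileModel", logOdds = lo, background = background,
      mu = NA_real_, beta = NA_real_, nWindows = NA_integer_,
      consensus = paste(AA20[apply(lo, 1L, which.max)], collapse = ""))
}

## Score every full window of integer-encoded sequences (rows of `mat`,
## values 1..21) against the profile; returns an nSeq x nWindows matrix.
## Vectorised over sequences so Monte-Carlo calibration stays cheap.
.windowScores <- function(profile, mat) {
  lo <- cbind(profile@logOdds, 0)      # column 21: neutral nonstandard score
  L <- nrow(profile@logOdds)
  n <- ncol(mat)
  nw <- n - L + 1L
  if (nw < 1L) return(matrix(numeric(0), nrow(mat), 0L))
  S <- matrix(0, nrow(mat), nw)
  for (j in seq_len(L))
    S <- S + matrix(lo[j, mat[, j:(j + nw - 1L), drop = FALSE]],
                    nrow(mat), nw)
  S
}

#' Calibrate a profile against a Gumbel null
#'
#' Scores i.i.d. background sequences, fits a Gumbel distribution to the
#' best-window scores by moment matching, and stores the per-window location
#' \code{mu} and scale \code{beta} so that
#' \code{evalueLike(s) = nWindows * exp(-(s - mu) / beta)} is the expected
#' number of null windows scoring at least \code{s} in a query with
#' \code{nWindows} windows. Monotone decreasing in \code{s} and 0 at
#' \code{s = Inf}.
#'
#' @param profile A [ProfileModel-class].
#' @param nShuffles Number of null sequences (>= 100).
#' @param seed RNG seed.
#' @param seqLength Null sequence length (default 3x profile length).
#' @return The profile with calibration slots filled.
#' @export
calibrateNull <- function(profile, nShuffles = 200L, seed = 1L,
                          seqLength = NULL) {
  stopifnot(is(profile, "ProfileModel"))
  nShuffles <- .assertCount(nShuffles, "nShuffles", 100L)
  L <- profileLength(profile)
  if (is.null(seqLength)) seqLength <- 3L * L
  if (seqLength < L) stop("seqLength shorter than the profile", call. = FALSE)
  best <- .withSeed(seed, {
    mat <- matrix(sample.int(20L, nShuffles * seqLength, replace = TRUE,
                             prob = profile@background),
                  nShuffles, seqLength)
    apply(.windowScores(profile, mat), 1L, max)
  })
  s <- stats::sd(best)
  if (!is.finite(s) || s < 1e-9)
    stop("degenerate null score variance: calibration error", call. = FALSE)
  beta <- s * sqrt(6) / pi
  muMax <- mean(best) - 0.5772156649 * beta
  nw <- seqLength - L + 1L
  profile@beta <- beta
  profile@mu <- muMax - beta * log(nw)   # per-window Gumbel location
  profile@nWindows <- as.integer(nw)
  profile
}

#' Expected null exceedances for a window score
#'
#' @param profile A calibrated [ProfileModel-class].
#' @param score Window score(s), bits.
#' @param nWindows Window count of the query (defaults to the calibration
#'   count).
#' @return Numeric E-value-like expected exceedance count(s).
#' @export
evalueLike <- function(profile, score, nWindows = profile@nWindows) {
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrateNull()", call. = FALSE)
  nWindows * exp(-(score - profile@mu) / profile@beta)
}

#' Empirical check of the fitted null
#'
#' Draws fresh background sequences of the calibration length and counts
#' windows whose E-value-like exceedance is at most \code{cutoff}. If the
#' Gumbel fit is adequate the count is Poisson with mean
#' \code{nSeqs * cutoff} (each sequence contributes \code{cutoff} expected
#' false windows at the cutoff, by construction of the E-value).
#'
#' @param profile A calibrated [ProfileModel-class].
#' @param nSeqs Number of fresh null sequences.
#' @param seed RNG seed (must differ from the calibration seed for a fair
#'   check).
#' @param cutoff E-value cutoff (default 1e-3).
#' @return List: \code{observed} (window count), \code{expected}
#'   (\code{nSeqs * cutoff}), \code{se} (Poisson standard error
#'   \code{sqrt(expected)}).
#' @export
nullExceedanceCheck <- function(profile, nSeqs = 10000L, seed = 2L,
                                cutoff = 1e-3) {
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrateNull()", call. = FALSE)
  L <- profileLength(profile)
  len <- profile@nWindows + L - 1L
  sCut <- profile@mu + profile@beta * log(profile@nWindows / cutoff)
  observed <- .withSeed(seed, {
    total <- 0L
    chunk <- 1000L
    done <- 0L
    while (done < nSeqs) {
      k <- min(chunk, nSeqs - done)
      mat <- matrix(sample.int(20L, k * len, replace = TRUE,
                               prob = profile@background), k, len)
      total <- total + sum(.windowScores(profile, mat) >= sCut)
      done <- done + k
    }
    total
  })
  expected <- nSeqs * cutoff
  list(observed = observed, expected = expected, se = sqrt(expected))
}

#' Scan a sequence for domain occurrences
#'
#' Slides the profile along the sequence (including windows overhanging the
#' N- or C-terminus down to \code{coverageMin} of the profile length, so that
#' truncated "half-domain" architectures are found), keeps windows with
#' E-value-like exceedance at most \code{evalueCutoff}, resolves overlaps
#' greedily by ascending E (ties to the leftmost start), and assigns copy
#' indices 1..k from the N-terminus. Any hit covering less than the full
#' profile is flagged \code{partial}. Truncated windows are completed with
#' the expected background score of the missing profile columns, so the
#' full-window null applies and a random sequence edge cannot outscore a
#' random full window merely by summing fewer (mostly negative) columns.
#'
#' @param seq Character scalar or \code{AAString}.
#' @param profile A calibrated [ProfileModel-class].
#' @param evalueCutoff Report hits with E <= this (default 1e-3).
#' @param coverageMin Minimum profile coverage for an overhanging edge window
#'   to be considered at all (default 0.5).
#' @param id Parent identifier recorded in the hits (defaults to "seq1").
#' @return data.frame of hits: \code{parent_id, start, end, score, evalue,
#'   copy_index, partial, coverage}, sorted by \code{start}; zero rows when
#'   nothing passes the cutoff.
#' @export
scanSequence <- function(seq, profile, evalueCutoff = 1e-3,
                         coverageMin = 0.5, id = NULL) {
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrateNull()", call. = FALSE)
  if (methods::is(seq, "AAString")) seq <- as.character(seq)
  if (is.null(id)) id <- "seq1"
  enc <- .encodeAA(seq)
  n <- length(enc)
  L <- profileLength(profile)
  lo <- cbind(profile@logOdds, 0)
  ## expected per-column background score, used to complete truncated windows
  bgCol <- as.numeric(profile@logOdds %*% profile@background)
  minOv <- max(1L, ceiling(coverageMin * L))

  starts <- integer(0); scores <- numeric(0); ovs <- integer(0)
  ## full windows (vectorised)
  if (n >= L) {
    S <- .windowScores(profile, matrix(enc, 1L))
    starts <- seq_len(n - L + 1L)
    scores <- as.numeric(S[1L, ])
    ovs <- rep(L, length(starts))
  }
  ## N-terminal overhangs: profile suffix vs sequence prefix, missing
  ## columns completed at background expectation
  if (minOv <= min(L - 1L, n)) {
    for (ov in minOv:min(L - 1L, n)) {
      s <- sum(lo[cbind((L - ov + 1L):L, enc[seq_len(ov)])]) +
        sum(bgCol[seq_len(L - ov)])
      starts <- c(starts, 1L - (L - ov)); scores <- c(scores, s)
      ovs <- c(ovs, ov)
    }
  }
  ## C-terminal overhangs: profile prefix vs sequence suffix
  if (n >= L && minOv <= L - 1L) {
    for (ov in minOv:(L - 1L)) {
      s <- sum(lo[cbind(seq_len(ov), enc[(n - ov + 1L):n])]) +
        sum(bgCol[(ov + 1L):L])
      starts <- c(starts, n - ov + 1L); scores <- c(scores, s)
      ovs <- c(ovs, ov)
    }
  }
  if (length(starts) == 0L)
    return(.emptyHits())
  ev <- evalueLike(profile, scores, nWindows = length(starts))
  keep <- which(ev <= evalueCutoff)
  if (length(keep) == 0L) return(.emptyHits())

  ## greedy non-overlap selection: best E first, ties to leftmost start
  pStart <- pmax(1L, starts[keep])
  pEnd <- pmin(n, starts[keep] + L - 1L)
  ord <- order(ev[keep], pStart)
  chosen <- integer(0)
  for (i in ord) {
    if (!any(pStart[i] <= pEnd[chosen] & pEnd[i] >= pStart[chosen]))
      chosen <- c(chosen, i)
  }
  chosen <- chosen[order(pStart[chosen])]
  cov <- ovs[keep][chosen] / L
  data.frame(parent_id = id, start = pStart[chosen], end = pEnd[chosen],
             score = scores[keep][chosen], evalue = ev[keep][chosen],
             copy_index = seq_along(chosen),
             partial = cov < 1 - 1e-9, coverage = cov,
             stringsAsFactors = FALSE)
}

.emptyHits <- function() {
  data.frame(parent_id = character(), start = integer(), end = integer(),
             score = numeric(), evalue = numeric(), copy_index = integer(),
             partial = logical(), coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname scanSequence
#' @param seqs Named character vector or \code{AAStringSet}.
#' @export
scanSequences <- function(seqs, profile, evalueCutoff = 1e-3,
                          coverageMin = 0.5) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  out <- lapply(names(seqs), function(id)
    scanSequence(seqs[[id]], profile, evalueCutoff, coverageMin, id = id))
  do.call(rbind, out)
}

#' Per-sequence domain architecture table
#'
#' Summarises scan hits into per-sequence copy counts, per-copy coordinates
#' and partial flags, with the copy-count distribution attached as the
#' \code{"count_distribution"} attribute. Sequences listed in \code{ids} but
#' absent from the hits get count 0, and the output is sorted by id so it is
#' invariant to input order.
#'
#' @param hits data.frame of hits from [scanSequences()].
#' @param ids Optional character vector of all sequence ids.
#' @return data.frame: \code{parent_id, n_copies, n_partial, coords}
#'   (semicolon-separated \code{start-end} per copy, N to C).
#' @export
architectureTable <- function(hits, ids = NULL) {
  if (is.null(ids)) ids <- unique(hits$parent_id)
  ids <- sort(unique(as.character(ids)))
  rows <- lapply(ids, function(id) {
    h <- hits[hits$parent_id == id, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    data.frame(parent_id = id, n_copies = nrow(h),
               n_partial = sum(h$partial),
               coords = paste(sprintf("%d-%d", h$start, h$end),
                              collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "count_distribution") <- table(out$n_copies)
  out
}
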