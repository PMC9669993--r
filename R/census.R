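## Motif censuses: finger-loop classification, per-column conservation,
## C-terminal cysteine architecture and length bimodality, operon gene
## order.

#' Classify a finger-loop motif window
#'
#' Rule table (first match wins). Five-residue windows (aerobic anchoring,
#' catalytic-cysteine motifs of the form NXCXE): positions 1/3/5 must be
#' N/C/E, then position 2 selects the class (L -> \code{I_like},
#' P -> \code{II_like}, V with position 4 = L -> \code{zero_like}).
#' Four-residue windows (anaerobic anchoring) require position 4 in
#' \{R, A\}: an M.C. shape with a single cysteine (position 2 not C) is
#' \code{III_single_cys}; a CC core preceded by M is
#' \code{III_double_cys_met}, preceded by Q is \code{nrdD3_like}, and
#' anything else with the CC core is \code{III_double_cys_nomet} (e.g. the
#' SCCR motif). Everything else is \code{other}. Wildcard positions accept
#' any residue; the observed residue is recorded for sub-tabulation.
#'
#' The reductant call applies to the anaerobic classes only: a leading
#' methionine implies \code{formate_capable}; no methionine but an
#' active-site glutamate implies \code{thioredoxin_only}; neither implies
#' \code{novel}.
#'
#' @param window5 Five-residue window (aerobic anchoring), or \code{NULL}.
#' @param window4 Four-residue window (anaerobic anchoring), or \code{NULL}.
#'   Exactly one of the two must be given.
#' @param hasActiveGlu Is the active-site glutamate present in this
#'   sequence?
#' @return Named list: \code{window, class, has_met, has_active_glu,
#'   reductant, x_residue} (the observed wildcard residue, \code{NA} when
#'   the window did not match a wildcard rule).
#' @examples
#' classifyFingerLoop(window5 = "NLCSE")$class            # I_like
#' classifyFingerLoop(window4 = "MGCR")$reductant          # formate_capable
#' classifyFingerLoop(window4 = "SCCR", hasActiveGlu = TRUE)$reductant
#' @export
classifyFingerLoop <- function(window5 = NULL, window4 = NULL,
                               hasActiveGlu = FALSE) {
  if (is.null(window5) == is.null(window4))
    stop("provide exactly one of window5/window4", call. = FALSE)
  anaerobic <- is.null(window5)
  win <- toupper(if (anaerobic) window4 else window5)
  if (nchar(win) != (if (anaerobic) 4L else 5L))
    stop("wrong window length", call. = FALSE)
  p <- .strsplit1(win)
  cls <- "other"; hasMet <- FALSE; xres <- NA_character_
  if (!anaerobic) {
    if (p[1L] == "N" && p[3L] == "C" && p[5L] == "E") {
      if (p[2L] == "L") { cls <- "I_like"; xres <- p[4L] }
      else if (p[2L] == "P") { cls <- "II_like"; xres <- p[4L] }
      else if (p[2L] == "V" && p[4L] == "L") cls <- "zero_like"
    }
  } else {
    hasMet <- p[1L] == "M"
    if (p[4L] %in% c("R", "A")) {
      if (p[1L] == "M" && p[3L] == "C" && p[2L] != "C") {
        cls <- "III_single_cys"; xres <- p[2L]
      } else if (p[2L] == "C" && p[3L] == "C") {
        cls <- if (p[1L] == "M") "III_double_cys_met"
               else if (p[1L] == "Q") "nrdD3_like"
               else "III_double_cys_nomet"
      }
    }
  }
  reductant <- if (!anaerobic || cls == "other") "n/a"
    else if (hasMet) "formate_capable"
    else if (hasActiveGlu) "thioredoxin_only"
    else "novel"
  list(window = win, class = cls, has_met = hasMet,
       has_active_glu = isTRUE(hasActiveGlu), reductant = reductant,
       x_residue = xres)
}

#' Classify an extracted motif window of unknown anchoring
#'
#' Convenience for census pipelines where the biochemical class (and hence
#' whether the window is 5-residue aerobic or 4-residue anaerobic) is not
#' known a priori: a 5-residue window is first classified as aerobic; if
#' that yields \code{other}, its first four residues are re-tried as an
#' anaerobic window. A 4-residue window is classified directly.
#'
#' @param window Extracted window string (4 or 5 residues; anything else
#'   returns class \code{other}).
#' @inheritParams classifyFingerLoop
#' @return As [classifyFingerLoop()].
#' @export
classifyMotifWindow <- function(window, hasActiveGlu = FALSE) {
  n <- nchar(window)
  if (n == 4L) return(classifyFingerLoop(window4 = window,
                                         hasActiveGlu = hasActiveGlu))
  if (n != 5L)
    return(list(window = toupper(window), class = "other", has_met = FALSE,
                has_active_glu = isTRUE(hasActiveGlu), reductant = "n/a",
                x_residue = NA_character_))
  call5 <- classifyFingerLoop(window5 = window, hasActiveGlu = hasActiveGlu)
  if (call5$class != "other") return(call5)
  call4 <- classifyFingerLoop(window4 = substr(window, 1L, 4L),
                              hasActiveGlu = hasActiveGlu)
  if (call4$class != "other") call4 else call5
}

#' Per-column residue conservation of an aligned window
#'
#' @param regions Character vector of equal-length (aligned) strings.
#' @return Numeric matrix, positions x residues, of percentages among
#'   non-gap entries per column; attribute \code{"n"} gives the non-gap
#'   count per column. Percentages sum to 100 per column (where any residue
#'   is present).
#' @export
conservationProfile <- function(regions) {
  if (length(regions) < 1L) stop("no rows", call. = FALSE)
  if (length(unique(nchar(regions))) != 1L)
    stop("ragged input: aligned window required", call. = FALSE)
  M <- do.call(rbind, lapply(regions, .strsplit1))
  letters <- sort(setdiff(unique(as.vector(M)), "-"))
  out <- matrix(0, ncol(M), length(letters),
                dimnames = list(seq_len(ncol(M)), letters))
  nn <- integer(ncol(M))
  for (j in seq_len(ncol(M))) {
    col <- M[, j]; col <- col[col != "-"]
    nn[j] <- length(col)
    if (length(col))
      out[j, ] <- 100 * as.numeric(table(factor(col, levels = letters))) /
        length(col)
  }
  attr(out, "n") <- nn
  out
}

#' Classify a C-terminal tail's cysteine architecture
#'
#' A tail is called a zinc finger when at least four cysteines fall within
#' its final \code{zfWindow} residues and form at least two pairs with at
#' most 5 intervening residues per pair (a sequence-only approximation of
#' the structurally defined four-cysteine Zn-coordinating fold). Otherwise
#' the spacing label comes from the distal-most cysteine pair:
#' n intervening residues gives \code{"CX..XC"} (\code{CXXC} at n = 2, the
#' class I consensus; \code{CXXXXC} at n = 4), a lone cysteine gives
#' \code{"single"}, none gives \code{"none"}. Length class is
#' \code{"short"} below \code{split} (default 160 residues).
#'
#' @param tail Tail sequence (possibly empty), or one row of an
#'   [extractRegion()] table.
#' @param zfWindow Terminal window searched for the zinc finger (default 60).
#' @param split Length threshold separating short from long tails.
#' @param id Identifier recorded in the output.
#' @return One-row data.frame: \code{id, length, length_class, n_cys,
#'   spacing, zinc_finger}.
#' @examples
#' classifyCterm(paste0(strrep("A", 100), "CPPC", "AA"))
#' @export
classifyCterm <- function(tail, zfWindow = 60L, split = 160L, id = "tail") {
  if (is.data.frame(tail)) {
    id <- tail$parent_id[1L]
    tail <- if (isTRUE(tail$empty[1L])) "" else tail$seq[1L]
  }
  chars <- if (nchar(tail)) .strsplit1(toupper(tail)) else character()
  len <- length(chars)
  cys <- which(chars == "C")
  nCys <- length(cys)
  zf <- FALSE
  if (nCys >= 4L) {
    cw <- cys[cys > len - zfWindow]
    if (length(cw) >= 4L) {
      ## greedy left-to-right pairing with <= 5 intervening residues
      pairs <- 0L; i <- 1L
      while (i < length(cw)) {
        if (cw[i + 1L] - cw[i] - 1L <= 5L) { pairs <- pairs + 1L; i <- i + 2L }
        else i <- i + 1L
      }
      zf <- pairs >= 2L
    }
  }
  spacing <- if (nCys == 0L) "none"
    else if (nCys == 1L) "single"
    else {
      gap <- cys[nCys] - cys[nCys - 1L] - 1L
      paste0("C", strrep("X", gap), "C")
    }
  data.frame(id = id, length = len,
             length_class = if (len < split) "short" else "long",
             n_cys = nCys, spacing = spacing, zinc_finger = zf,
             stringsAsFactors = FALSE)
}

#' @rdname classifyCterm
#' @param regions An [extractRegion()] table (one row per sequence).
#' @export
classifyCterms <- function(regions, zfWindow = 60L, split = 160L) {
  out <- lapply(seq_len(nrow(regions)), function(i)
    classifyCterm(regions[i, , drop = FALSE], zfWindow, split))
  do.call(rbind, out)
}

#' Two-means split of a length distribution
#'
#' One-dimensional k = 2 clustering of tail lengths (deterministic
#' initialisation at the 10th and 90th percentiles); the threshold is the
#' midpoint of the two cluster means, and the distribution is flagged
#' bimodal when the between-mode separation exceeds \code{ratio} times the
#' pooled within-mode spread.
#'
#' @param lengths Numeric vector (>= 10 values).
#' @param ratio Separation/spread ratio required for bimodality (default 2).
#' @return List: \code{threshold}, \code{labels} (\code{"short"}/
#'   \code{"long"}, in input order), \code{bimodal}, \code{means},
#'   \code{separation_ratio}.
#' @export
lengthSplit <- function(lengths, ratio = 2) {
  if (length(lengths) < 10L)
    stop("need at least 10 lengths", call. = FALSE)
  if (diff(range(lengths)) == 0) {
    return(list(threshold = lengths[1L],
                labels = rep("short", length(lengths)), bimodal = FALSE,
                means = c(lengths[1L], lengths[1L]), separation_ratio = 0))
  }
  init <- stats::quantile(lengths, c(0.1, 0.9), names = FALSE)
  if (init[1L] == init[2L]) init <- range(lengths)
  km <- stats::kmeans(matrix(as.numeric(lengths)), centers = matrix(init))
  means <- sort(as.numeric(km$centers))
  threshold <- mean(means)
  grp <- km$cluster
  within <- sqrt(sum(km$withinss) / length(lengths))
  sep <- if (within < 1e-12) Inf else abs(diff(means)) / (2 * within)
  list(threshold = threshold,
       labels = ifelse(lengths < threshold, "short", "long"),
       bimodal = sep >= ratio, means = means, separation_ratio = sep)
}

#' Operon gene-order orientation
#'
#' For each genome with one alpha and one beta record on the same strand,
#' calls \code{beta_alpha} when alpha is transcribed downstream of beta
#' (larger start on the + strand, smaller start on the - strand),
#' \code{alpha_beta} otherwise; records on different strands are
#' \code{discordant}.
#'
#' @param records data.frame with columns \code{genome, role, start, end,
#'   strand} (role in alpha/beta, start < end, strand + or -).
#' @return data.frame: \code{genome, orientation}.
#' @export
operonOrientation <- function(records) {
  need <- c("genome", "role", "start", "end", "strand")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(records$start >= records$end))
    stop("start must be < end", call. = FALSE)
  out <- lapply(split(records, records$genome), function(d) {
    a <- d[d$role == "alpha", , drop = FALSE]
    b <- d[d$role == "beta", , drop = FALSE]
    if (nrow(a) != 1L || nrow(b) != 1L)
      stop("genome ", d$genome[1L],
           ": need exactly one alpha and one beta record", call. = FALSE)
    orient <- if (a$strand != b$strand) "discordant"
      else {
        alphaDownstream <- if (a$strand == "+") a$start > b$start
                           else a$start < b$start
        if (alphaDownstream) "beta_alpha" else "alpha_beta"
      }
    data.frame(genome = d$genome[1L], orientation = orient,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
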