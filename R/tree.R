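## Phylogeny mapping: newick IO, midpoint rooting, monophyletic pruning,
## Fitch parsimony with a permutation single-origin test, and
## cluster-vs-clade concordance (monophyly + scattering).

#' Parse / serialise newick
#'
#' Thin, validating wrappers around \pkg{ape}: unbalanced parentheses are
#' reported with their string position before parsing is attempted, and a
#' round trip preserves topology and branch lengths to newick precision.
#'
#' @param text Newick string (must end in \code{;}).
#' @return [readNewick()] an \code{ape::phylo}; [writeNewick()] a string.
#' @examples
#' tr <- readNewick("(A:1,(B:1,C:3):1);")
#' writeNewick(tr)
#' @export
readNewick <- function(text) {
  chars <- .strsplit1(text)
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop("newick parse error at position ", which(depth < 0)[1L],
         ": unbalanced ')'", call. = FALSE)
  if (depth[length(depth)] != 0L)
    stop("newick parse error at position ", length(chars),
         ": unbalanced '('", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("newick parse error: missing terminal ';'", call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error", call. = FALSE)
  tr
}

#' @rdname readNewick
#' @param tree An \code{ape::phylo}.
#' @export
writeNewick <- function(tree) {
  ape::write.tree(tree)
}

## All-pairs tip path-length matrix (used for the diameter; small trees).
.tipDistances <- function(tree) {
  d <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  d <- d[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Midpoint rooting
#'
#' Places the root on the edge containing the midpoint of the longest
#' tip-to-tip path, so the two deepest tips on either side of the root are
#' equidistant from it (up to numerical tolerance when the midpoint is
#' interior to an edge).
#'
#' @param tree An \code{ape::phylo} with >= 2 tips and positive path
#'   lengths.
#' @return A rooted \code{ape::phylo}.
#' @export
midpointRoot <- function(tree) {
  if (length(tree$tip.label) < 2L)
    stop("need >= 2 tips", call. = FALSE)
  if (max(.tipDistances(tree)) <= 0)
    stop("zero-diameter tree: degenerate input", call. = FALSE)
  phangorn::midpoint(tree)
}

#' Prune a monophyletic clade
#'
#' Returns the subtree spanning exactly the requested tips, with internal
#' degree-2 nodes suppressed and their branch lengths summed (pairwise tip
#' path lengths are preserved). The tip set must be monophyletic in the
#' rooted tree; otherwise the error lists the intruding tips.
#'
#' @param tree A rooted \code{ape::phylo}.
#' @param tips Character vector of >= 2 tip labels.
#' @return An \code{ape::phylo}.
#' @export
pruneClade <- function(tree, tips) {
  if (length(tips) == 0L) stop("empty tip set", call. = FALSE)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tips: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(tips) < 2L)
    stop("a clade of fewer than 2 tips cannot form a tree", call. = FALSE)
  if (setequal(tips, tree$tip.label)) return(tree)
  mrca <- ape::getMRCA(tree, tips)
  below <- tree$tip.label[unlist(phangorn::Descendants(tree, mrca, "tips"))]
  intruders <- setdiff(below, tips)
  if (length(intruders))
    stop("tip set is not monophyletic; intruding tips: ",
         paste(sort(intruders), collapse = ", "), call. = FALSE)
  ape::keep.tip(tree, tips)
}

#' Minimal parsimony changes of a discrete tip trait
#'
#' Bottom-up Fitch set algorithm: at each internal node the child state
#' sets are intersected (union and one counted change when the
#' intersection is empty). The count is invariant under re-rooting.
#' Multifurcations are resolved arbitrarily first (zero-length branches),
#' which leaves the count of a root trifurcation unchanged.
#'
#' @param tree An \code{ape::phylo}.
#' @param states Named vector (factor/character/numeric) of tip states;
#'   every tip must be present.
#' @return Integer: the minimal number of state changes.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' fitchChanges(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' @export
fitchChanges <- function(tree, states) {
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("missing states for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  lev <- sort(unique(as.character(states)))
  if (length(lev) > 30L) stop("too many states", call. = FALSE)
  code <- bitwShiftL(1L, match(as.character(states), lev) - 1L)
  names(code) <- names(states)
  ntip <- length(tree$tip.label)
  sets <- integer(ntip + tree$Nnode)
  sets[seq_len(ntip)] <- code[tree$tip.label]
  tr <- stats::reorder(tree, "postorder")
  changes <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    if (sets[parent] == 0L) {
      sets[parent] <- sets[child]
    } else {
      inter <- bitwAnd(sets[parent], sets[child])
      if (inter != 0L) sets[parent] <- inter
      else {
        sets[parent] <- bitwOr(sets[parent], sets[child])
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Permutation test for a single trait origin
#'
#' The observed Fitch change count is compared with a null in which tip
#' states are randomly permuted across tips (state counts preserved). The
#' exceedance fraction is \code{(1 + #\{null <= observed\}) / (nShuffles +
#' 1)}, i.e. the identity permutation is included, so the fraction is
#' always positive. A single planted origin gives observed = 1 and a small
#' exceedance on trees where the trait is not near-constant.
#'
#' @param tree An \code{ape::phylo}.
#' @param states Named tip-state vector.
#' @param nShuffles Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List: \code{observed}, \code{exceedance}, \code{null} (vector of
#'   permuted counts), \code{degenerate} (TRUE for constant states).
#' @export
singleOriginTest <- function(tree, states, nShuffles = 1000L, seed = 1L) {
  nShuffles <- .assertCount(nShuffles, "nShuffles", 100L)
  observed <- fitchChanges(tree, states)
  if (length(unique(as.character(states))) < 2L)
    return(list(observed = 0L, exceedance = 1, null = integer(),
                degenerate = TRUE))
  states <- states[tree$tip.label]
  null <- .withSeed(seed, vapply(seq_len(nShuffles), function(i) {
    perm <- setNames(sample(states), names(states))
    fitchChanges(tree, perm)
  }, integer(1)))
  list(observed = observed,
       exceedance = (1 + sum(null <= observed)) / (nShuffles + 1),
       null = null, degenerate = FALSE)
}

#' Cluster-vs-clade concordance
#'
#' For each category of a tip annotation: is the category monophyletic in
#' the rooted tree, and across how many maximal monophyletic blocks is it
#' scattered (1 = monophyletic)?
#'
#' @param tree A rooted \code{ape::phylo}.
#' @param ann Named character vector (tip -> category) or data.frame with
#'   columns \code{tip_id} and \code{category}.
#' @return data.frame: \code{category, n_tips, monophyletic, scattering}.
#' @export
clusterCladeConcordance <- function(tree, ann) {
  if (is.data.frame(ann)) {
    v <- ann$category; names(v) <- ann$tip_id; ann <- v
  }
  unknown <- setdiff(names(ann), tree$tip.label)
  if (length(unknown))
    stop("unknown tips: ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  if (length(ann) == 0L) stop("no annotations", call. = FALSE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tr <- stats::reorder(tree, "postorder")
  parent <- integer(ntip + tree$Nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  out <- lapply(sort(unique(as.character(ann))), function(cat) {
    tips <- names(ann)[ann == cat]
    ## allIn[node]: every tip below the node belongs to the category
    allIn <- logical(ntip + tree$Nnode)
    allIn[match(tips, tree$tip.label)] <- TRUE
    allIn[(ntip + 1L):(ntip + tree$Nnode)] <- TRUE
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      allIn[p] <- allIn[p] && allIn[ch]
    }
    blocks <- sum(vapply(seq_len(ntip + tree$Nnode), function(nd) {
      allIn[nd] && (nd == root || !allIn[parent[nd]])
    }, logical(1)))
    data.frame(category = cat, n_tips = length(tips),
               monophyletic = blocks == 1L, scattering = blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export tip annotations
#'
#' Writes a TSV with one row per tip (every tip exactly once); tips without
#' a value get \code{NA}.
#'
#' @param tree An \code{ape::phylo}.
#' @param ann Named vector or list of named vectors (one column each).
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
writeTipAnnotations <- function(tree, ann, path) {
  if (!is.list(ann)) ann <- list(category = ann)
  out <- data.frame(tip_id = tree$tip.label, stringsAsFactors = FALSE)
  for (nm in names(ann))
    out[[nm]] <- unname(ann[[nm]][tree$tip.label])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
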