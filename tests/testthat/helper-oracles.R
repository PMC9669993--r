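## Brute-force oracles, independent of the implementation paths they check.

## Optimal local alignment score by exhaustive enumeration of aligned-column
## sets: every local alignment is a strictly increasing set of residue pairs
## plus affine gap runs for the skipped internal residues (one run per
## sequence between consecutive pairs is the cheapest arrangement; local
## alignments never start or end with a gap under positive penalties). The
## empty alignment scores 0.
swOracle <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  best <- 0
  for (k in seq_len(min(la, lb))) {
    ia <- utils::combn(la, k)
    ib <- utils::combn(lb, k)
    for (x in seq_len(ncol(ia))) {
      i <- ia[, x]
      for (y in seq_len(ncol(ib))) {
        j <- ib[, y]
        s <- sum(mat[cbind(A[i], B[j])])
        if (k > 1L) {
          di <- diff(i) - 1L; dj <- diff(j) - 1L
          s <- s - sum((open + di * ext)[di > 0L]) -
            sum((open + dj * ext)[dj > 0L])
        }
        if (s > best) best <- s
      }
    }
  }
  best
}

## Minimal parsimony changes by exhaustive internal-state assignment.
fitchBrute <- function(tree, states) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  lev <- sort(unique(as.character(states)))
  ntip <- length(tree$tip.label)
  tipState <- match(as.character(states[tree$tip.label]), lev)
  combos <- as.matrix(expand.grid(rep(list(seq_along(lev)), tree$Nnode)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    st <- c(tipState, combos[r, ])
    ch <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
    if (ch < best) best <- ch
  }
  best
}

## All-pairs tip path lengths by breadth-first traversal of the (undirected)
## tree graph.
tipDistOracle <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0; frontier <- s
    while (length(frontier)) {
      nf <- integer(0)
      for (v in frontier) {
        for (r in seq_len(NROW(adj[[v]]))) {
          u <- adj[[v]][r, 1L]
          if (is.na(dist[u])) {
            dist[u] <- dist[v] + adj[[v]][r, 2L]
            nf <- c(nf, u)
          }
        }
      }
      frontier <- nf
    }
    D[s, ] <- dist[seq_len(ntip)]
  }
  D
}

## Connected components by union-find.
unionFindOracle <- function(ids, edgeA, edgeB) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edgeA)) {
    ra <- find(edgeA[k]); rb <- find(edgeB[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(ids, find, character(1))
}

## Maximal monophyletic block count via explicit per-node tip sets.
blockOracle <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  nodes <- seq_len(ntip + tree$Nnode)
  tipsOf <- function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else tree$tip.label[unlist(phangorn::Descendants(tree, nd, "tips"))]
  }
  inside <- vapply(nodes, function(nd) all(tipsOf(nd) %in% tips), logical(1))
  parent <- rep(NA_integer_, length(nodes))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  sum(vapply(nodes, function(nd)
    inside[nd] && (is.na(parent[nd]) || !inside[parent[nd]]), logical(1)))
}

## Random amino-acid string.
randAA <- function(len, alphabet = coneSSN::AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## An SSNGraph built directly from an edge list (for clustering tests).
graphFromEdges <- function(ids, edgeA, edgeB, weight = 100, threshold = 50) {
  if (length(edgeA)) {
    pairs <- data.frame(id_a = edgeA, id_b = edgeB, raw = weight,
                        bits = weight, evalue = 10^(-weight),
                        aln_score = weight, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id_a = character(), id_b = character(),
                        raw = numeric(), bits = numeric(),
                        evalue = numeric(), aln_score = numeric(),
                        stringsAsFactors = FALSE)
  }
  methods::new("SSNGraph",
               nodes = data.frame(id = ids, stringsAsFactors = FALSE),
               pairs = pairs, threshold = threshold)
}
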