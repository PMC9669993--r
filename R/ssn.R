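## Sequence similarity networks: all-vs-all affine-gap Smith-Waterman local
## alignments, Karlin-Altschul bit scores and E-values, the "alignment
## score" edge weight -log10(E), connected-component clustering, threshold
## sweeps and hub-spoke topology reports.

#' Construct scoring parameters
#'
#' Defaults are the standard published gapped constants for BLOSUM62 with
#' gap open 11 / extend 1: lambda = 0.267 nats per score unit, K = 0.041.
#' Nonstandard residue codes (B, J, Z, X, U, O) score 0 against everything.
#'
#' @param matrixName Name of a Biostrings substitution matrix ("BLOSUM62").
#' @param gapOpen,gapExt Positive affine gap penalties; a gap of length k
#'   costs \code{gapOpen + k * gapExt}.
#' @param lambda,K Karlin-Altschul constants.
#' @param dbScale Effective database size (residues); \code{NA} = set from
#'   the input set when building a network (total residues), or the summed
#'   pair length for a standalone [alignPair()].
#' @return A [ScoringParams-class].
#' @export
scoringParams <- function(matrixName = "BLOSUM62", gapOpen = 11, gapExt = 1,
                          lambda = 0.267, K = 0.041, dbScale = NA_real_) {
  base <- get(utils::data(list = matrixName, package = "Biostrings",
                          envir = environment()))
  letters <- unique(c(AA20, .AA_NONSTD, "*"))
  M <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  M[AA20, AA20] <- base[AA20, AA20]
  new("ScoringParams", matrix = M, gapOpen = gapOpen, gapExt = gapExt,
      lambda = lambda, K = K, dbScale = dbScale)
}

#' Alignment score from an E-value
#'
#' The SSN edge weight: \code{-log10(E)}. An E-value of 1e-20 maps to 20.0
#' and 1e-30 to 30.0, the conventional cutoffs for domain and C-terminal
#' networks respectively.
#'
#' @param E Positive E-value(s).
#' @return \code{-log10(E)}.
#' @examples
#' alnScoreFromEvalue(1e-20)  # 20
#' @export
alnScoreFromEvalue <- function(E) {
  if (any(!is.finite(E)) || any(E <= 0))
    stop("E-values must be positive", call. = FALSE)
  -log10(E)
}

## Raw -> derived Karlin-Altschul fields. `m` is the query length and
## `dbScale` the database-size factor.
.kaDerived <- function(raw, m, p, dbScale) {
  bits <- (p@lambda * raw - log(p@K)) / log(2)
  evalue <- m * dbScale * 2^(-bits)
  list(bits = bits, evalue = evalue, aln_score = -log10(evalue))
}

#' Pairwise local alignment with Karlin-Altschul statistics
#'
#' Optimal affine-gap Smith-Waterman score (an empty alignment scores 0, so
#' raw >= 0), converted to a bit score
#' \code{(lambda * raw - ln K) / ln 2}, an E-value
#' \code{m * dbScale * 2^(-bits)} with \code{m} the query length, and the
#' alignment score \code{-log10(E)}. The query is the member of the pair
#' with the lexicographically smaller ID, which makes the statistics
#' symmetric under argument swap.
#'
#' @param a,b Sequences (character or \code{AAString}), nonempty.
#' @param p A [ScoringParams-class].
#' @param idA,idB Identifiers (default "a", "b").
#' @return One-row data.frame: \code{id_a, id_b, raw, bits, evalue,
#'   aln_score, pident} (percent identity over aligned columns; \code{NA}
#'   for an empty alignment).
#' @export
alignPair <- function(a, b, p = scoringParams(), idA = "a", idB = "b") {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("empty sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = p@matrix, gapOpening = p@gapOpen,
    gapExtension = p@gapExt, type = "local")
  raw <- max(0, Biostrings::score(pa))
  pident <- if (raw > 0) Biostrings::pid(pa) else NA_real_
  qlen <- if (idA <= idB) nchar(a) else nchar(b)
  db <- if (is.na(p@dbScale)) nchar(a) + nchar(b) else p@dbScale
  ka <- .kaDerived(raw, qlen, p, db)
  data.frame(id_a = idA, id_b = idB, raw = raw, bits = ka$bits,
             evalue = ka$evalue, aln_score = ka$aln_score, pident = pident,
             stringsAsFactors = FALSE)
}

## Coerce network input (extractRegion table / AAStringSet / named character)
## to a named character vector, dropping empty-flagged rows.
.asSeqVector <- function(regions) {
  if (is.data.frame(regions)) {
    keep <- !regions$empty
    out <- regions$seq[keep]
    names(out) <- regions$parent_id[keep]
    return(out)
  }
  if (methods::is(regions, "XStringSet")) {
    nm <- names(regions)
    regions <- as.character(regions)
    names(regions) <- nm
  }
  if (is.null(names(regions)))
    names(regions) <- sprintf("s%03d", seq_along(regions))
  regions
}

#' Build a sequence similarity network
#'
#' Aligns all n(n-1)/2 pairs locally, converts raw scores to alignment
#' scores (-log10 E), and stores the full pair table so that edge sets at
#' any threshold are a cheap filter. An edge is kept at the stored threshold
#' iff its alignment score is at least the threshold.
#'
#' @param regions Region table from [extractRegion()] (empty rows dropped),
#'   an \code{AAStringSet}, or a named character vector (>= 2 sequences).
#' @param p A [ScoringParams-class]; an \code{NA} \code{dbScale} becomes the
#'   total residue count of the input set.
#' @param threshold Alignment-score cutoff (default 20.5, the conventional
#'   domain-network cutoff corresponding to E = 10^-20.5).
#' @param nodeAttrs Optional data.frame of node attributes with an \code{id}
#'   column (e.g. copy index or class, for shape/colour annotation).
#' @return An [SSNGraph-class].
#' @export
buildSSN <- function(regions, p = scoringParams(), threshold = 20.5,
                     nodeAttrs = NULL) {
  seqs <- .asSeqVector(regions)
  n <- length(seqs)
  if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids", call. = FALSE)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  db <- if (is.na(p@dbScale)) sum(nchar(seqs)) else p@dbScale
  set <- Biostrings::AAStringSet(seqs)
  ids <- names(seqs)
  pairs <- vector("list", n - 1L)
  for (j in 2:n) {
    raw <- Biostrings::pairwiseAlignment(
      set[seq_len(j - 1L)], set[[j]],
      substitutionMatrix = p@matrix, gapOpening = p@gapOpen,
      gapExtension = p@gapExt, type = "local", scoreOnly = TRUE)
    raw <- pmax(0, raw)
    ia <- ids[seq_len(j - 1L)]; ib <- ids[j]
    qlen <- ifelse(ia <= ib, nchar(seqs[seq_len(j - 1L)]), nchar(seqs[j]))
    ka <- .kaDerived(raw, qlen, p, db)
    pairs[[j - 1L]] <- data.frame(
      id_a = ia, id_b = ib, raw = raw, bits = ka$bits, evalue = ka$evalue,
      aln_score = ka$aln_score, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(nodeAttrs))
    nodes <- merge(nodes, nodeAttrs, by = "id", all.x = TRUE, sort = FALSE)
  new("SSNGraph", nodes = nodes, pairs = pairs, threshold = threshold)
}

## igraph view of an SSNGraph at an arbitrary threshold.
.ssnIgraph <- function(g, threshold = ssnThreshold(g)) {
  e <- g@pairs[g@pairs$aln_score >= threshold, c("id_a", "id_b"), drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = g@nodes$id)
}

#' Label connected components of a network
#'
#' Components at the given threshold, labelled in decreasing size order
#' (ties broken by the lexicographically smallest member id, so labels are
#' invariant to input order). Singletons are flagged.
#'
#' @param g An [SSNGraph-class].
#' @param threshold Alignment-score cutoff (default: the graph's own).
#' @return data.frame: \code{id, cluster, cluster_size, singleton}.
#' @export
clusterComponents <- function(g, threshold = ssnThreshold(g)) {
  stopifnot(is(g, "SSNGraph"))
  ig <- .ssnIgraph(g, threshold)
  comp <- igraph::components(ig)
  member <- comp$membership[g@nodes$id]
  sizes <- comp$csize[member]
  ## stable relabel: by decreasing size, then smallest member id
  reps <- tapply(g@nodes$id, member, min)
  ord <- order(-comp$csize, reps)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  data.frame(id = g@nodes$id, cluster = relabel[member],
             cluster_size = as.integer(sizes),
             singleton = sizes == 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sweep a network across edge thresholds
#'
#' Re-thresholds the stored pair table at each cutoff (ascending) and
#' records the component partition; partitions at successive thresholds form
#' a refinement chain because edge sets are nested.
#'
#' @param g An [SSNGraph-class].
#' @param thresholds Numeric vector of alignment-score cutoffs, sorted
#'   ascending.
#' @return An object of class \code{"ssnSweep"}: list with
#'   \code{thresholds} and \code{membership} (node x threshold matrix of
#'   cluster labels).
#' @seealso [separationThreshold()]
#' @export
thresholdSweep <- function(g, thresholds) {
  stopifnot(is(g, "SSNGraph"))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted strictly ascending", call. = FALSE)
  mem <- sapply(thresholds, function(t) clusterComponents(g, t)$cluster)
  mem <- matrix(mem, nrow = nrow(g@nodes),
                dimnames = list(g@nodes$id, format(thresholds)))
  structure(list(thresholds = thresholds, membership = mem),
            class = "ssnSweep")
}

#' @export
print.ssnSweep <- function(x, ...) {
  cat(sprintf("ssnSweep: %d nodes x %d thresholds (%s)\n",
              nrow(x$membership), length(x$thresholds),
              paste(format(x$thresholds), collapse = ", ")))
  cat("clusters per threshold:",
      apply(x$membership, 2L, function(m) length(unique(m))), "\n")
  invisible(x)
}

#' Threshold at which two node groups separate
#'
#' The smallest sweep threshold at which no member of \code{idsA} shares a
#' connected component with any member of \code{idsB}; \code{NA} if they
#' still co-cluster at the top of the sweep.
#'
#' @param sweep An \code{"ssnSweep"} from [thresholdSweep()].
#' @param idsA,idsB Node id vectors.
#' @return A single threshold value or \code{NA}.
#' @export
separationThreshold <- function(sweep, idsA, idsB) {
  for (k in seq_along(sweep$thresholds)) {
    m <- sweep$membership[, k]
    if (length(intersect(m[idsA], m[idsB])) == 0L)
      return(sweep$thresholds[k])
  }
  NA_real_
}

#' Hub-spoke topology of a clustered network
#'
#' Builds the cluster-adjacency graph at a relaxed threshold (the network
#' threshold minus \code{delta}): two clusters are adjacent if any relaxed
#' edge joins them. The hub is the largest cluster (ties broken by the
#' number of adjacent clusters, then the smaller label) -- the "large
#' central" pool that peripheral clusters bud from; a degree-based hub
#' choice would misname the middle of a budding chain as the hub whenever
#' a single degraded lineage sheds sub-clusters. Spokes are ordered by
#' shortest-path distance from the hub in the cluster-adjacency graph
#' (spoke order 1 = adjacent to the hub, 2 = adjacent to a spoke-1
#' cluster, ...).
#'
#' @param g An [SSNGraph-class] (nonempty).
#' @param clusters Cluster labelling from [clusterComponents()]; computed at
#'   the graph threshold if missing.
#' @param delta Threshold relaxation (default 5 alignment-score units).
#' @return An object of class \code{"hubSpokeReport"}: list with
#'   \code{clusters} (the labelling), \code{hub} (cluster label),
#'   \code{spokes} (data.frame cluster/size/distance, ordered), and
#'   \code{adjacency} (inter-cluster relaxed edge counts and densities).
#' @export
hubSpoke <- function(g, clusters = NULL, delta = 5) {
  stopifnot(is(g, "SSNGraph"))
  if (nrow(g@nodes) == 0L) stop("empty graph", call. = FALSE)
  if (is.null(clusters)) clusters <- clusterComponents(g)
  lab <- setNames(clusters$cluster, clusters$id)
  relaxed <- g@pairs[g@pairs$aln_score >= g@threshold - delta, , drop = FALSE]
  ca <- lab[relaxed$id_a]; cb <- lab[relaxed$id_b]
  cross <- ca != cb
  adj <- data.frame(cluster_a = pmin(ca[cross], cb[cross]),
                    cluster_b = pmax(ca[cross], cb[cross]))
  sizes <- table(clusters$cluster)
  if (nrow(adj)) {
    adj <- stats::aggregate(list(n_edges = rep(1L, nrow(adj))),
                            adj, FUN = sum)
    adj$density <- adj$n_edges /
      (as.integer(sizes[as.character(adj$cluster_a)]) *
       as.integer(sizes[as.character(adj$cluster_b)]))
  } else {
    adj <- data.frame(cluster_a = integer(), cluster_b = integer(),
                      n_edges = integer(), density = numeric())
  }
  cl <- sort(unique(clusters$cluster))
  deg <- vapply(cl, function(k)
    sum(adj$cluster_a == k) + sum(adj$cluster_b == k), integer(1))
  ord <- order(-as.integer(sizes[as.character(cl)]), -deg, cl)
  hub <- cl[ord[1L]]
  ## BFS distances from the hub in the cluster-adjacency graph
  dist <- setNames(rep(NA_integer_, length(cl)), cl)
  dist[as.character(hub)] <- 0L
  frontier <- hub
  while (length(frontier)) {
    nxt <- unique(c(adj$cluster_b[adj$cluster_a %in% frontier],
                    adj$cluster_a[adj$cluster_b %in% frontier]))
    nxt <- nxt[is.na(dist[as.character(nxt)])]
    if (!length(nxt)) break
    dist[as.character(nxt)] <- dist[as.character(frontier[1L])] + 1L
    frontier <- nxt
  }
  spokes <- data.frame(cluster = cl, size = as.integer(sizes[as.character(cl)]),
                       distance = as.integer(dist[as.character(cl)]))
  spokes <- spokes[spokes$cluster != hub, , drop = FALSE]
  spokes <- spokes[order(spokes$distance, -spokes$size, spokes$cluster), ,
                   drop = FALSE]
  rownames(spokes) <- NULL
  structure(list(clusters = clusters, hub = hub, spokes = spokes,
                 adjacency = adj, delta = delta),
            class = "hubSpokeReport")
}

#' @export
print.hubSpokeReport <- function(x, ...) {
  cat(sprintf("hubSpokeReport: hub = cluster %d (delta = %g)\n",
              x$hub, x$delta))
  if (nrow(x$spokes)) {
    cat("spokes (by distance from hub):\n")
    print(x$spokes)
  } else cat("no spokes (single cluster)\n")
  invisible(x)
}

#' Export network tables
#'
#' Writes the node table (with cluster labels) and the edge table at the
#' stored threshold as TSV; optionally a GraphML file.
#'
#' @param g An [SSNGraph-class].
#' @param nodePath,edgePath,graphmlPath Output paths (\code{NULL} = skip).
#' @param clusters Optional labelling from [clusterComponents()].
#' @return Invisibly, the written paths.
#' @export
writeSSN <- function(g, nodePath = NULL, edgePath = NULL,
                     graphmlPath = NULL, clusters = NULL) {
  stopifnot(is(g, "SSNGraph"))
  if (is.null(clusters)) clusters <- clusterComponents(g)
  nodes <- merge(g@nodes, clusters, by = "id", sort = TRUE)
  if (!is.null(nodePath))
    utils::write.table(nodes, nodePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(edgePath))
    utils::write.table(ssnEdges(g), edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphmlPath)) {
    ig <- .ssnIgraph(g)
    igraph::write_graph(ig, graphmlPath, format = "graphml")
  }
  invisible(c(nodePath, edgePath, graphmlPath))
}
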