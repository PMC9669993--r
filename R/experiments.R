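## Seeded in-silico experiments combining the generator with the analysis
## stages. These are the package's own study conditions for validating the
## duplication-degradation reading of hub-spoke network topology.

#' Duplication-degradation sweep experiment
#'
#' Simulates families with a single-cone ancestor and one tandem-duplicated
#' clade whose inner copy drifts at an elevated substitution rate across the
#' whole copy, scans and extracts every domain copy, builds the copy-level
#' similarity network, and sweeps the edge threshold. Per replicate it
#' records the threshold at which inner copies stop sharing a cluster with
#' the single-cone copies, the same threshold for outer copies (\code{Inf}
#' when they never separate within the sweep), and whether [hubSpoke()] --
#' evaluated at the inner-copy detachment threshold, where the spoke has
#' just come off -- names the single-cone + outer-copy cluster as the hub.
#'
#' Conditions: 48 tips over three clades, domain in every tip, duplication
#' in the largest clade, inner copy at \code{degradationFactor} times the
#' base rate on all sites, sweep over alignment scores 5 to 60 in steps of
#' 2.5.
#'
#' @param nReplicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses a child seed derived from it.
#' @param nTips Tips per family.
#' @param degradationFactor Inner-copy rate multiplier (default 3).
#' @return data.frame with one row per replicate: \code{seed, n_duplicated,
#'   t_inner, t_outer, inner_first} (inner detaches strictly below outer),
#'   \code{hub_correct}.
#' @export
duplicationSweepExperiment <- function(nReplicates = 10L, seed = 1L,
                                       nTips = 48L, degradationFactor = 3) {
  rows <- lapply(seq_len(nReplicates), function(r) {
    rs <- .childSeed(seed, 100L + r)
    cfg <- simConfig(nTips = nTips,
                     cladeMotifs = c(A = "NLCSE", B = "NPCGE", C = "NVCLE"),
                     domainPrevalence = c(A = 1, B = 1, C = 1),
                     duplicationClades = "A",
                     degradedSiteFraction = 1,
                     innerDegradationFactor = degradationFactor,
                     seed = rs)
    fam <- evolveFamily(cfg)
    truth <- familyTruth(fam)
    aln <- familyAlignment(fam)
    cmap <- buildColumnMap(aln)
    nt <- extractRegion(aln, cmap, familyRegionSpecs(fam)$nterm)

    seedIds <- utils::head(sort(truth$id[truth$n_copies >= 1L]), 25L)
    seedRows <- setNames(
      substr(as.character(familySequences(fam)[seedIds]), 1L,
             fam@config@domainLength), seedIds)
    pr <- calibrateNull(buildProfile(seedRows), 200L,
                        seed = .childSeed(rs, 1L))
    targets <- setNames(nt$seq[!nt$empty], nt$parent_id[!nt$empty])
    hits <- scanSequences(targets, pr)
    copySeqs <- setNames(
      substr(nt$seq[match(hits$parent_id, nt$parent_id)],
             hits$start, hits$end),
      sprintf("%s|c%d", hits$parent_id, hits$copy_index))

    singles <- intersect(sprintf("%s|c1", truth$id[truth$n_copies == 1L]),
                         names(copySeqs))
    outer <- intersect(sprintf("%s|c1", truth$id[truth$n_copies == 2L]),
                       names(copySeqs))
    inner <- intersect(sprintf("%s|c2", truth$id[truth$n_copies == 2L]),
                       names(copySeqs))
    g <- buildSSN(copySeqs, threshold = 20.5)
    sw <- thresholdSweep(g, seq(5, 60, by = 2.5))
    tIn <- separationThreshold(sw, inner, singles)
    tOut <- separationThreshold(sw, outer, singles)
    if (is.na(tOut)) tOut <- Inf
    hubOK <- NA
    if (!is.na(tIn)) {
      g@threshold <- tIn
      cl <- clusterComponents(g)
      hs <- hubSpoke(g, cl)
      hubIds <- cl$id[cl$cluster == hs$hub]
      hubOK <- mean(c(singles, outer) %in% hubIds) > 0.5 &&
        !any(inner %in% hubIds)
    }
    data.frame(seed = rs, n_duplicated = sum(truth$n_copies == 2L),
               t_inner = tIn, t_outer = tOut,
               inner_first = !is.na(tIn) && tIn < tOut,
               hub_correct = hubOK)
  })
  do.call(rbind, rows)
}

#' Motif recovery experiment
#'
#' Simulates one family under the default five-clade motif table, extracts
#' the finger-loop window and the active-site glutamate through the anchored
#' alignment, classifies every window with [classifyMotifWindow()], and
#' compares the calls against the planted truth.
#'
#' @param nTips Tips in the family.
#' @param motifNoise Per-site motif flip probability (0 = exact planting).
#' @param seed RNG seed.
#' @return List: \code{accuracy} (fraction of tips whose class matches
#'   truth), \code{n}, \code{calls} (per-tip data.frame with truth and call).
#' @export
motifRecoveryExperiment <- function(nTips = 200L, motifNoise = 0,
                                    seed = 1L) {
  cfg <- simConfig(nTips = nTips, motifNoise = motifNoise, seed = seed)
  fam <- evolveFamily(cfg)
  truth <- familyTruth(fam)
  aln <- familyAlignment(fam)
  cmap <- buildColumnMap(aln)
  specs <- familyRegionSpecs(fam)
  fl <- extractRegion(aln, cmap, specs$fingerLoop)
  glu <- extractRegion(aln, cmap,
                       regionSpec("glu", "span", specs$gluResidue,
                                  specs$gluResidue))
  hasGlu <- setNames(glu$seq == "E", glu$parent_id)
  calls <- vapply(seq_len(nrow(fl)), function(i)
    classifyMotifWindow(fl$seq[i], isTRUE(hasGlu[[fl$parent_id[i]]]))$class,
    character(1))
  names(calls) <- fl$parent_id
  tr <- setNames(truth$motif_class, truth$id)[names(calls)]
  list(accuracy = mean(calls == tr), n = length(calls),
       calls = data.frame(id = names(calls), truth = unname(tr),
                          call = unname(calls), stringsAsFactors = FALSE))
}
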