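## End-to-end orchestration: simulate (or load) -> extract -> scan -> ssn ->
## census -> treemap, with per-stage derived seeds, stage-labelled errors,
## and a TSV/JSON report bundle.

.defaultThresholds <- function() {
  list(domain_evalue = 1e-3, ssn_domain = 20.5, ssn_cterm = 30,
       length_split_ratio = 2, shuffles = 1000L, coverage_min = 0.5,
       hub_delta = 5)
}

#' Read a pipeline configuration from YAML
#'
#' The config has a \code{seed}, an \code{outdir}, exactly one of a
#' \code{simulate} block (arguments of [simConfig()]) or an \code{inputs}
#' block (paths: \code{sequences}, \code{alignment}, \code{ref_id},
#' optional \code{tree}, \code{seed_alignment}, \code{operons}, plus a
#' \code{regions} list of [regionSpec()] arguments and optional
#' \code{glu_residue}), an optional \code{thresholds} block (defaults:
#' domain E-value 1e-3, domain SSN 20.5, C-terminal SSN 30), an optional
#' \code{scoring} block ([scoringParams()] arguments) and an optional
#' \code{sweep} vector of SSN thresholds.
#'
#' @param path YAML file.
#' @return A config list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  log(sprintf("stage %-9s done in %.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages over either a simulated family or user-supplied
#' files: region extraction anchored on the reference, profile calibration
#' and domain scanning with copy indexing, domain-copy and C-terminal
#' similarity networks with clustering and a hub-spoke report, the motif /
#' C-terminal / operon censuses, and tree mapping (midpoint rooting,
#' single-origin permutation test for tandem duplication, cluster-clade
#' concordance). Deterministic for a fixed seed: one seed fans out to
#' per-stage child streams. Stage failures abort with the stage named.
#'
#' @param cfg Config list (see [readRunConfig()]) or a YAML path.
#' @return Invisibly, a list with every stage product (\code{family},
#'   \code{regions}, \code{profile}, \code{hits}, \code{architecture},
#'   \code{ssn}, \code{census}, \code{treemap}, \code{paths}).
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 1, outdir = tempfile(),
#'                         simulate = list(nTips = 24),
#'                         thresholds = list(shuffles = 100)))
#' }
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  if (is.null(cfg$seed)) stop("config error: 'seed' is required", call. = FALSE)
  if (is.null(cfg$outdir))
    stop("config error: 'outdir' is required", call. = FALSE)
  if (is.null(cfg$simulate) == is.null(cfg$inputs))
    stop("config error: exactly one of 'simulate'/'inputs'", call. = FALSE)
  thr <- utils::modifyList(.defaultThresholds(), cfg$thresholds %||% list())
  scoring <- do.call(scoringParams, cfg$scoring %||% list())
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outdir, "pipeline.log")
  cat(sprintf("# pipeline run %s\n", format(Sys.time())), file = logPath)
  log <- function(msg) {
    message(msg)
    cat(msg, "\n", file = logPath, append = TRUE)
  }
  seed <- as.integer(cfg$seed)
  tsv <- function(x, name) {
    p <- file.path(cfg$outdir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(log = logPath)

  ## ---- simulate / load -----------------------------------------------
  fam <- NULL; tree <- NULL; truth <- NULL
  if (!is.null(cfg$simulate)) {
    st <- .stage("simulate", log, {
      simArgs <- cfg$simulate
      if (!is.null(simArgs$cladeMotifs))
        simArgs$cladeMotifs <- unlist(simArgs$cladeMotifs)
      if (!is.null(simArgs$domainPrevalence))
        simArgs$domainPrevalence <- unlist(simArgs$domainPrevalence)
      simArgs$seed <- .childSeed(seed, 1L)
      fam <- evolveFamily(do.call(simConfig, simArgs))
      emitDataset(fam, file.path(cfg$outdir, "dataset"))
      fam
    })
    fam <- st
    aln <- familyAlignment(fam)
    tree <- familyTree(fam)
    truth <- familyTruth(fam)
    specs <- familyRegionSpecs(fam)
    specList <- specs[c("nterm", "fingerLoop", "cterm")]
    gluResidue <- specs$gluResidue
    seqs <- familySequences(fam)
    operons <- fam@operons
  } else {
    inp <- cfg$inputs
    aln <- .stage("load", log,
                  readAnchoredAlignment(inp$alignment, inp$ref_id))
    seqs <- Biostrings::readAAStringSet(inp$sequences)
    tree <- if (!is.null(inp$tree))
      readNewick(paste(readLines(inp$tree), collapse = "")) else NULL
    operons <- if (!is.null(inp$operons))
      utils::read.table(inp$operons, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
    specList <- lapply(inp$regions, function(a) do.call(regionSpec, a))
    names(specList) <- vapply(specList, function(s) s@name, character(1))
    gluResidue <- inp$glu_residue
  }

  ## ---- extract --------------------------------------------------------
  regions <- .stage("extract", log, {
    cmap <- buildColumnMap(aln)
    out <- lapply(specList, function(sp) extractRegion(aln, cmap, sp))
    names(out) <- vapply(specList, function(s) s@name, character(1))
    if (!is.null(gluResidue)) {
      gl <- extractRegion(aln, cmap,
                          regionSpec("glu_site", "span", gluResidue,
                                     gluResidue))
      out$glu_site <- gl
    }
    for (nm in names(out)) paths[[paste0("region_", nm)]] <-
      tsv(out[[nm]], sprintf("regions_%s.tsv", nm))
    out
  })

  ## ---- scan -----------------------------------------------------------
  scan <- .stage("scan", log, {
    seedRows <- if (!is.null(fam)) {
      dl <- fam@config@domainLength
      withDom <- truth$id[truth$n_copies >= 1L]
      withDom <- utils::head(sort(withDom), 25L)
      if (length(withDom) < 2L)
        stop("too few domain-bearing tips to seed a profile")
      setNames(substr(as.character(seqs[withDom]), 1L, dl), withDom)
    } else {
      readAnchoredAlignment(cfg$inputs$seed_alignment)@rows
    }
    profile <- buildProfile(seedRows)
    profile <- calibrateNull(profile, nShuffles = 200L,
                             seed = .childSeed(seed, 2L))
    nterm <- regions$nterm
    targets <- setNames(nterm$seq[!nterm$empty], nterm$parent_id[!nterm$empty])
    hits <- if (length(targets))
      scanSequences(targets, profile, thr$domain_evalue, thr$coverage_min)
    else .emptyHits()
    arch <- architectureTable(hits, ids = names(seqs))
    paths$hits <- tsv(hits, "domain_hits.tsv")
    paths$architecture <- tsv(arch, "architecture.tsv")
    list(profile = profile, hits = hits, architecture = arch)
  })

  ## ---- ssn ------------------------------------------------------------
  ssn <- .stage("ssn", log, {
    h <- scan$hits
    out <- list()
    if (nrow(h) >= 2L) {
      copySeqs <- setNames(
        substr(regions$nterm$seq[match(h$parent_id, regions$nterm$parent_id)],
               h$start, h$end),
        sprintf("%s|c%d", h$parent_id, h$copy_index))
      attrs <- data.frame(id = names(copySeqs), parent_id = h$parent_id,
                          copy_index = h$copy_index, stringsAsFactors = FALSE)
      g <- buildSSN(copySeqs, scoring, threshold = thr$ssn_domain,
                    nodeAttrs = attrs)
      cl <- clusterComponents(g)
      out$domain <- g
      out$domain_clusters <- cl
      out$hub_spoke <- hubSpoke(g, cl, delta = thr$hub_delta)
      paths$domain_nodes <- tsv(merge(attrs, cl, by = "id", sort = TRUE),
                                 "ssn_domain_nodes.tsv")
      paths$domain_edges <- tsv(ssnEdges(g), "ssn_domain_edges.tsv")
      if (!is.null(cfg$sweep))
        out$sweep <- thresholdSweep(g, sort(unlist(cfg$sweep)))
    }
    ct <- regions$cterm
    ct <- ct[!ct$empty & nchar(ct$seq) >= 10L, , drop = FALSE]
    if (nrow(ct) >= 2L) {
      gC <- buildSSN(ct, scoring, threshold = thr$ssn_cterm)
      out$cterm <- gC
      out$cterm_clusters <- clusterComponents(gC)
      paths$cterm_nodes <- tsv(out$cterm_clusters, "ssn_cterm_nodes.tsv")
    }
    out
  })

  ## ---- census ---------------------------------------------------------
  census <- .stage("census", log, {
    fl <- regions$fingerLoop %||% regions$finger_loop
    out <- list()
    if (!is.null(fl)) {
      hasGlu <- if (!is.null(regions$glu_site))
        setNames(regions$glu_site$seq == "E", regions$glu_site$parent_id)
      else setNames(rep(FALSE, nrow(fl)), fl$parent_id)
      calls <- lapply(seq_len(nrow(fl)), function(i) {
        if (fl$empty[i])
          return(data.frame(id = fl$parent_id[i], window = "", class = "other",
                            has_met = FALSE, has_active_glu = FALSE,
                            reductant = "n/a", stringsAsFactors = FALSE))
        cl <- classifyMotifWindow(fl$seq[i],
                                  isTRUE(hasGlu[[fl$parent_id[i]]]))
        data.frame(id = fl$parent_id[i], window = cl$window,
                   class = cl$class, has_met = cl$has_met,
                   has_active_glu = cl$has_active_glu,
                   reductant = cl$reductant, stringsAsFactors = FALSE)
      })
      out$motifs <- do.call(rbind, calls)
      paths$motifs <- tsv(out$motifs, "motif_census.tsv")
    }
    ct <- regions$cterm
    if (!is.null(ct)) {
      out$cterm <- classifyCterms(ct)
      lens <- out$cterm$length[out$cterm$length > 0L]
      if (length(lens) >= 10L)
        out$length_split <- lengthSplit(lens, thr$length_split_ratio)
      paths$cterm_census <- tsv(out$cterm, "cterm_census.tsv")
    }
    if (!is.null(operons)) {
      out$operons <- operonOrientation(operons)
      paths$operon_orientation <- tsv(out$operons, "operon_orientation.tsv")
    }
    out
  })

  ## ---- treemap --------------------------------------------------------
  treemap <- if (is.null(tree)) {
    log("stage treemap  skipped (no tree input)")
    NULL
  } else .stage("treemap", log, {
    rooted <- midpointRoot(tree)
    arch <- scan$architecture
    dup <- setNames(ifelse(arch$n_copies >= 2L, 1L, 0L), arch$parent_id)
    so <- singleOriginTest(rooted, dup, nShuffles = thr$shuffles,
                           seed = .childSeed(seed, 3L))
    ann <- list()
    if (!is.null(census$motifs))
      ann$motif_class <- setNames(census$motifs$class, census$motifs$id)
    if (!is.null(ssn$domain_clusters)) {
      cl <- merge(ssn$domain_clusters,
                  ssnNodes(ssn$domain)[, c("id", "parent_id", "copy_index")],
                  by = "id")
      outer <- cl[cl$copy_index == 1L, , drop = FALSE]
      ann$domain_cluster <- setNames(paste0("cluster", outer$cluster),
                                     outer$parent_id)
    }
    conc <- do.call(rbind, lapply(names(ann), function(nm) {
      a <- ann[[nm]][!is.na(ann[[nm]])]
      a <- a[names(a) %in% rooted$tip.label]
      if (!length(a)) return(NULL)
      d <- clusterCladeConcordance(rooted, a)
      d$annotation <- nm
      d
    }))
    paths$tree <- file.path(cfg$outdir, "tree_rooted.nwk")
    cat(writeNewick(rooted), "\n", file = paths$tree)
    if (length(ann))
      paths$annotations <- {
        writeTipAnnotations(rooted, ann,
                            file.path(cfg$outdir, "tip_annotations.tsv"))
        file.path(cfg$outdir, "tip_annotations.tsv")
      }
    if (!is.null(conc)) paths$concordance <- tsv(conc, "concordance.tsv")
    list(rooted = rooted, single_origin = so, concordance = conc)
  })

  ## ---- summary --------------------------------------------------------
  summary <- list(
    seed = seed,
    n_sequences = length(seqs),
    copy_count_distribution = as.list(
      table(scan$architecture$n_copies)),
    motif_class_counts = if (!is.null(census$motifs))
      as.list(table(census$motifs$class)) else NULL,
    cterm_length_threshold = census$length_split$threshold,
    cterm_bimodal = census$length_split$bimodal,
    hub_cluster = ssn$hub_spoke$hub,
    single_origin = if (!is.null(treemap)) list(
      observed_changes = treemap$single_origin$observed,
      exceedance = treemap$single_origin$exceedance) else NULL,
    config_echo = cfg)
  paths$summary <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log("pipeline complete")

  invisible(list(family = fam, alignment = aln, regions = regions,
                 profile = scan$profile, hits = scan$hits,
                 architecture = scan$architecture, ssn = ssn,
                 census = census, treemap = treemap, summary = summary,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
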