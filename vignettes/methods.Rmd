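---
title: "Methods: anchored regions, similarity networks and motif censuses around a conserved core"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored regions, similarity networks and motif censuses around a conserved core}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneSSN)
```

## The problem

Large enzyme families such as the ribonucleotide reductases (RNRs) share a
conserved catalytic core -- for RNR alpha subunits, a 10-stranded
alpha/beta barrel -- while most of their functional diversification is
written in the parts *around* that core: N-terminal regulatory extensions
(the ~100-residue ATP-cone, present in 0--3 tandem copies), a
class-specific C-terminal tail, and short internal insertions such as the
finger loop that carries the catalytic cysteine. coneSSN provides the
comparative machinery to study those decorations: extracting them from a
reference-anchored multiple sequence alignment, detecting tandem domain
copies with a scored profile, relating the extracted regions to each other
in sequence similarity networks (SSNs), classifying short motifs and
cysteine architectures, and mapping everything back onto a phylogeny.

Because the family-scale datasets on which such analyses are performed are
typically not redistributable, the package ships a synthetic family
generator with planted ground truth. Every downstream stage is exercised
and tested end-to-end against what the generator planted.

## Coordinate conventions and region extraction

All residue coordinates are 1-based and inclusive, matching UniProt
numbering, so published anchor residues (a finger loop at reference
residues 319--367 with the motif at 328--331, an active-site glutamate at
495, a C-terminal boundary after residue 639) can be used verbatim.
`buildColumnMap()` walks the anchor row of the alignment: the k-th non-gap
column is the column of anchor residue k. Three region kinds exist:
`span` (inclusive anchor-residue range), `cterm` (strictly after a
boundary residue) and `nterm` (strictly before anchor residue 1, or before
an explicit boundary residue when the anchor itself carries N-terminal
domain copies).

Rows whose extracted window contains only gaps are retained with an
`empty` flag rather than silently dropped; exclusion is a census-stage
decision that stays visible in the tables. Span rows carrying an insertion
longer than `maxInsertion` (default 5 residues) relative to the anchor
span are flagged `long_insertion` -- the automated counterpart of removing
insertion-bearing rows from a motif window by hand, with the threshold
exposed because no principled value exists; 5 residues is large enough to
pass alignment wobble and small enough to catch real insertions.

The reconstruction identity `nterm + core + cterm == parent` holds exactly
for every sequence of every simulated family and is asserted at scale in
the test suite.

`msaCenterStar()` is a deliberately simple progressive aligner (best-sum
center sequence, pairwise global alignments merged under "once a gap,
always a gap") so that a pipeline can run fully self-contained. It is not
a substitute for a modern profile aligner, and the merge-consistency
property (each pairwise center alignment is preserved exactly in the
merged output) is what the tests assert -- not alignment quality.

## Domain scanning

`buildProfile()` turns a seed alignment into a position-specific log-odds
model: column frequencies are pseudocounted towards the background
(`(counts + pc * background) / (n + pc)` over the non-gap rows), scores
are `log2(freq / background)` bits. `calibrateNull()` fits a Gumbel
distribution to best-window scores of i.i.d. background sequences by
moment matching and stores the per-window location, so that

```
evalue_like(s) = n_windows * exp(-(s - mu) / beta)
```

is the expected number of null windows scoring at least `s` in a query.
This is a detector with one cutoff, not a profile HMM: there is no gap
state and no posterior decoding, which is a documented fidelity limitation
relative to HMMER. The default cutoff is `1e-3`, the conventional value
for this kind of domain census.

Two numerical choices matter:

* **Truncated edge windows.** Windows may overhang the N- or C-terminus
  down to `coverageMin` (default 0.5) of the profile length so that
  "half-domain" architectures -- a real feature of some class Ib enzymes
  -- are found. The missing profile columns are completed with their
  expected background score; without this, a random sequence edge would
  outscore a random full window simply by summing fewer (mostly negative)
  columns, and noise edges would pass any cutoff. Any hit covering less
  than the full profile is flagged `partial`, and `coverageMin` is the
  reporting floor for such hits.
* **Overlap resolution.** Hits are selected greedily by ascending E-value
  with ties broken toward the leftmost start, then numbered 1..k from the
  N-terminus. This is deterministic and matches tandem-copy semantics; it
  is a choice, since the upstream literature does not state how
  overlapping hits in multi-copy proteins were resolved.

Moment-matched Gumbel tails are slightly conservative: in the empirical
check (`nullExceedanceCheck()`, fresh background sequences at the
calibration length) the observed count of false windows at `E <= 1e-3`
runs a factor of ~2 below the nominal expectation while remaining within
three Poisson standard errors. The package reports E-values as calibrated;
users should read them as order-of-magnitude quantities, which is how the
single-cutoff census uses them.

## Similarity networks

`alignPair()`/`buildSSN()` score all pairs with affine-gap Smith-Waterman
local alignment (BLOSUM62, gap open 11, extend 1; an empty alignment
scores 0; nonstandard residue codes score 0 against everything). Raw
scores convert to bits via the standard gapped Karlin-Altschul constants
(`lambda = 0.267` nats, `K = 0.041`; configurable), and to E-values as
`E = m * db_scale * 2^(-bits)` with `m` the query length -- always the
member of the pair with the lexicographically smaller ID, which makes the
statistic symmetric -- and `db_scale` the total residue count of the input
set. The SSN edge weight is the *alignment score* `-log10(E)`; the
conventional cutoffs 20.5 (domain networks) and 30 (C-terminal networks)
correspond to E-values of 10^-20.5 and 10^-30 by construction.

The full pair table is retained in the `SSNGraph`, so thresholding,
`thresholdSweep()` (partitions provably refine as the threshold grows) and
the relaxed-threshold cluster adjacency of `hubSpoke()` are cheap filters.
Clustering is by connected components, matching the "edges above cutoff"
semantics of SSN practice; community detection is deliberately not the
default.

**Hub identification.** A recurring SSN pattern is a large central "hub"
cluster from which smaller clusters appear to bud as a domain lineage
degrades. We identify the hub as the *largest* cluster, breaking ties by
the number of adjacent clusters in the relaxed-threshold adjacency graph
(threshold minus `delta`, default 5). A pure adjacency-degree rule was
considered and rejected: when a single degraded lineage buds off, the true
hub is an *endpoint* of the budding chain (degree 1), while the degraded
cluster sits in the middle shedding sub-clusters and always wins on
degree. Size-primary selection matches the phenomenon being formalised --
the hub is the big ancestral pool -- and makes the spoke ordering (BFS
distance from the hub) recover planted chains. In the
duplication-degradation experiment the hub is evaluated at the threshold
where the inner copies have just detached, i.e. where the spoke is
visible.

## Motif censuses

`classifyFingerLoop()` is a pure rule table over 5-residue (aerobic
anchoring, NXCXE-type) or 4-residue (anaerobic anchoring) windows, with
first-match-wins semantics: NL CXE-shaped windows are class I-like, NPCXE
class II-like, NVCLE class 0-like; MGCR-shaped single-cysteine windows,
MCCR/SCCR-type double-cysteine windows and QCCR/A windows map to the
anaerobic classes. Wildcard positions accept any residue and the observed
residue is recorded, because published per-X counts (e.g. the NPCGE
subset) are sub-tabulations, not filters. The reductant call (formate vs
thioredoxin vs novel) combines the leading methionine with the presence of
the active-site glutamate. `classifyMotifWindow()` handles windows of
unknown anchoring by trying the aerobic rule first and falling back to the
first four residues.

`classifyCterm()` reports tail length, a length class (short below a
160-residue split, the family's published boundary, unless `lengthSplit()`
re-estimates it), the cysteine count and the spacing label of the
distal-most cysteine pair (`CXXC`, `CXXXXC`, ...). The zinc-finger call
(at least four cysteines in the final 60 residues forming two pairs with
at most five intervening residues each) is a sequence-only approximation
of a structurally defined four-cysteine fold and is flagged as such: the
structural route to that call is out of scope here.

`lengthSplit()` is a one-dimensional two-means split with deterministic
initialisation (10th/90th percentiles); the threshold is the midpoint of
the cluster means and bimodality requires the between-mode separation to
exceed twice the pooled within-mode spread. `operonOrientation()` is a
strand-aware comparison of alpha/beta gene starts.

## Tree mapping

Newick IO, midpoint rooting and monophyletic pruning wrap ape/phangorn;
Fitch parsimony is implemented directly (bitmask state sets, postorder)
and cross-checked against both an exhaustive-assignment oracle and an
independent library implementation in the tests. `singleOriginTest()`
formalises "this trait arose once" as: observed Fitch changes = 1, with a
permutation null that shuffles tip states (state counts preserved) and
reports `(1 + #{null <= observed}) / (n + 1)` -- the identity permutation
is included, so the fraction is never zero. The test is run on the
midpoint-rooted tree for presentation; the Fitch count itself is invariant
under re-rooting, which the tests assert. The permutation formalisation is
an addition of this package, not a published statistic, and is labelled as
such in reports. `clusterCladeConcordance()` quantifies the usual
"colour strips" figure: per category, monophyly and the number of maximal
monophyletic blocks (scattering).

## The synthetic generator

`simConfig()`/`evolveFamily()` emulate the study conditions the analyses
target:

* **Tree**: pure-birth (Yule), default birth rate 1; the simplest process
  with heterogeneous branch lengths. Clades are obtained by repeatedly
  splitting the largest subtree until there is one monophyletic group per
  configured motif, labelled largest-first.
* **Core**: default 150 residues, i.i.d. background root sequence, per-site
  substitution with probability `1 - exp(-rate * branchlength)` and uniform
  replacement over the 19 alternatives (a single fixed exchangeability; the
  downstream stages test recovery, not phylogenetic realism). The default
  rate of 0.05 per unit branch length yields families whose deepest pairs
  are ~60-70% identical over the core -- diverged enough that network
  thresholds discriminate, conserved enough that anchoring is trivial.
* **Motifs**: the five default clade motifs are NLCSE, NPCGE, NVCLE, MGCR
  and MCCR, planted in a frozen 5-column window (4-residue motifs padded
  with a fixed alanine); the active-site glutamate is planted at a frozen
  core position, replaced by glutamine in configured glutamate-less clades.
  `motifNoise` is the probability that a window receives *one* random site
  flip, so a noise level of x perturbs about a fraction x of the windows
  (and exact-match classification then recovers about `1 - 0.8x` of the
  labels, since four of five window positions are constrained).
* **Domains**: one ancestral ~100-residue domain evolving at the base rate
  (the outer copy). Domain presence is Bernoulli per tip with clade
  prevalences defaulting to 48.7% / 11.3% / 0% / 48.6% / 48.6% across the
  five default clades. In duplication clades the domain is duplicated *at
  the clade ancestor* and the inner copy then drifts within the clade at
  `innerDegradationFactor` (default 3) times the base rate on a
  configurable fraction of sites (default 20%, emulating drift concentrated
  at ligand-binding positions; the sweep experiment uses 1.0, i.e. the
  whole copy). No quantitative degradation rate is published; 3x is this
  package's choice and is stated wherever results depend on it.
* **C-termini**: lengths drawn from a short (mean 80, sd 15) and a long
  (mean 250, sd 50) mode in equal proportion, bracketing the 160-residue
  split; cysteine architectures planted near the tail end with frequencies
  64/6/4/26% (two/multi/single/none) among non-zinc-finger tails and a 30%
  zinc-finger fraction (zinc fingers are common among long tails in the
  motivating family; the exact fraction is not published and only the
  *conditional* pattern frequencies are asserted anywhere).
* **Operons**: a per-clade alpha/beta order label with consistent synthetic
  coordinates, beta-upstream in duplication clades by default.

What the generator does **not** emulate: indels inside the core (the true
alignment is block-structured by construction), rate heterogeneity across
core sites, codon-level processes, compositional bias, horizontal
transfer, and any structural feature. Passing tests therefore show that
the analysis stages recover what they claim from sequences shaped like
this -- clean anchoring, planted motifs, tandem copies with elevated
divergence, bimodal tails -- not that they are robust to real-data
alignment error.

## Experiment and test scales

The packaged experiments run at sizes chosen to make their statistics
meaningful while keeping a full run interactive: 10 families of 100 tips
for reconstruction; 200 tips for motif recovery; 10 replicates of 48-tip
families for the duplication sweep (threshold grid 5 to 60 in steps of
2.5, spanning the range from fully connected to beyond the identical-copy
score cap); 500-sequence mixtures for the length split; 10^4 fresh null
sequences against a 500-shuffle calibration for the E-value check; 100
random trees of up to 12 tips for the exact tree oracles and 20 planted
single-gain replicates on 100-tip trees with 1,000-shuffle nulls.

## Known limitations

* Ungapped profile scanning cannot model inserted domains inside a repeat
  and will fuse or truncate copies separated by large insertions.
* The Karlin-Altschul constants are fixed database-wide; no per-pair
  length correction is applied beyond the query-length factor, so edge
  weights for very short regions are coarse.
* The center-star aligner is for self-contained pipelines and small
  region sets; use a profile aligner for production alignments.
* The zinc-finger and length-class calls are sequence-only surrogates for
  structure-based assignments.
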