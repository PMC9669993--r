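# coneSSN

Comparative analysis of the extensions and insertions that decorate a
conserved catalytic core in large enzyme families — written for the
ribonucleotide reductase (RNR) case, where functional diversification is
carried by N-terminal ATP-cone regulatory domains (0–3 tandem copies), a
class-specific C-terminal tail, and the finger-loop insertion holding the
catalytic cysteine, all arranged around a conserved α/β-barrel core.

The package provides, as composable S4-based building blocks:

* **Core-anchored region extraction** — a `ColumnMap` between alignment
  columns and the 1-based (UniProt-style) residue numbering of a reference
  sequence, and extraction of N-terminal extensions, internal spans (e.g.
  a finger loop at reference residues 319–367) and C-terminal tails
  (everything after a boundary residue such as 639) from every row of an
  anchored MSA.
* **Tandem domain detection** — position-specific log-odds scanning with a
  moment-matched Gumbel null giving E-value-like scores
  (`E(s) = n_windows · exp(−(s − μ)/β)`), greedy non-overlap resolution,
  N→C copy indexing and partial-hit flags for truncated "half domains".
* **Sequence similarity networks** — all-vs-all affine-gap Smith–Waterman
  (BLOSUM62/11/1), Karlin–Altschul statistics
  (`bits = (λ·raw − ln K)/ln 2`, `E = m · db · 2^−bits`), edges weighted by
  the *alignment score* `−log10(E)` (so the conventional cutoffs 20.5 and
  30 correspond to E = 10^−20.5 and 10^−30), connected-component
  clustering, threshold sweeps with provable partition refinement, and a
  hub–spoke topology report.
* **Motif censuses** — the finger-loop rule table (NLCXE / NPCXE / NVCLE /
  MGCR / MCCR / SCCR / QCCR-type classes with Met/Glu reductant calls),
  per-column conservation, C-terminal cysteine architectures (CXXC,
  CXXXXC, zinc-finger surrogate) and a two-means length split, and
  strand-aware α/β operon orientation.
* **Tree mapping** — newick IO, midpoint rooting, monophyletic pruning,
  Fitch parsimony with a permutation single-origin test, and
  cluster–clade concordance (monophyly + scattering).
* **A synthetic family generator** (`simConfig()` / `evolveFamily()`) with
  planted clade motifs, tandem duplication with a degraded inner copy and
  bimodal C-termini, plus a per-tip truth table — so the whole pipeline is
  testable end to end without any external dataset.

## Worked example

Simulate a 60-tip family, extract the finger-loop window through the
anchored alignment, and run the motif census and the C-terminal length
split:

```r
library(coneSSN)

fam  <- evolveFamily(simConfig(nTips = 60, seed = 101))
fam
#> SyntheticFamily: 60 tips, 5 clades, alignment 756 columns
#>       copies
#> clade   0  1  2
#>   I     8  0  9
#>   II   17  0  0
#>   IIIa  5  4  0
#>   IIIb  0  1  0
#>   O    16  0  0

aln   <- familyAlignment(fam)
cmap  <- buildColumnMap(aln)
specs <- familyRegionSpecs(fam)

fl <- extractRegion(aln, cmap, specs$fingerLoop)
head(fl, 3)
#>   parent_id      region start end   seq empty long_insertion
#> 1      t001 finger_loop    61  65 NLCSE FALSE          FALSE
#> 2      t002 finger_loop    61  65 NLCSE FALSE          FALSE
#> 3      t003 finger_loop    61  65 NVCLE FALSE          FALSE

glu    <- extractRegion(aln, cmap,
                        regionSpec("glu", "span", specs$gluResidue,
                                   specs$gluResidue))
hasGlu <- setNames(glu$seq == "E", glu$parent_id)
table(vapply(seq_len(nrow(fl)), function(i)
  classifyMotifWindow(fl$seq[i], hasGlu[[fl$parent_id[i]]])$class,
  character(1)))
#>             I_like            II_like III_double_cys_met
#>                 17                 17                  1
#>     III_single_cys          zero_like
#>                  9                 16

ct <- extractRegion(aln, cmap, specs$cterm)
sp <- lengthSplit(nchar(ct$seq[!ct$empty]))
sp$threshold   # 179.9  -- two-means boundary between short and long tails
sp$bimodal     # TRUE
```

The copy-count table reads directly off the planted architecture: clade I
tips carrying the domain have it in tandem (the inner copy drifting at an
elevated rate), clade II carries it rarely, the minimal clade O never. The
motif census recovers every planted class label, and the length split
lands near the 160-residue short/long boundary that the generator's two
tail modes (80 ± 15 and 250 ± 50) bracket.

`runPipeline()` chains all stages (simulate/load → extract → scan → SSN →
census → treemap) into a seeded, logged run emitting TSV tables and a
JSON summary; `inst/scripts/conessn.R` exposes the same stages as shell
subcommands.

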