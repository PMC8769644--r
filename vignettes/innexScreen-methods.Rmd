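---
title: "Methods: screening innexins for extracellular N-glycosylation sequons"
author: "innexScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening innexins for extracellular N-glycosylation sequons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `innexScreen`, the meaning and
defaults of every tunable parameter, the design of the synthetic data
generator, and the limitations of the approach. It makes no empirical claims
beyond what the package's own test suite and `scripts/acceptance.R` compute.

# The biological model

Innexins are invertebrate gap-junction proteins with a conserved membrane
architecture: four transmembrane helices (TM1–TM4), two extracellular loops
(EL1 between TM1 and TM2, EL2 between TM3 and TM4), one cytoplasmic loop (CL
between TM2 and TM3), and cytoplasmic N- and C-termini. Because N-linked
glycosylation occurs in the secretory pathway lumen, only asparagines that
end up **extracellular** can carry an N-glycan in the mature protein. The
screen therefore asks, for each candidate protein:

1. Is it a plausible full-length innexin (long enough, four TM helices, not
   a duplicate database entry)?
2. Where are its extracellular loops?
3. Does it carry an N-glycosylation sequon — the tripeptide N-X-S/T with X
   any residue except proline — **inside** EL1 or EL2, with a predicted
   occupancy above threshold?

Aggregation then summarizes sequon presence per taxonomic group, and the
conservation and phylogenetic modules ask whether a sequon is maintained at
the same alignment column across orthologs and how presence/absence
distributes over a tree. The combinatorial function `hemichannelDiversity()`
computes the upper bound $n^s$ on distinct ordered subunit arrangements of a
hemichannel built from $s$ subunits drawn from $n$ isoforms ($s = 8$ for
innexin octamers, $s = 6$ for connexin hexamers).

# Topology inference

## Hydropathy profile

`hydropathyProfile(seq, window = 19)` maps each residue to its
Kyte–Doolittle hydropathy value and smooths with a centered moving average.
The window must be odd and in $[5, 31]$; 19 is the classical choice for
membrane-helix detection, long enough to suppress single-residue noise and
short enough to resolve helices separated by short loops. Windows are
**truncated at the ends** (the mean is over the residues actually present)
rather than leaving the margins undefined, so the profile has exactly one
value per residue and short termini are still scanned.

## Calling transmembrane segments

`callTmSegments(profile, threshold = 1.6, minLen = 15, mergeGap = 3,
maxLen = 35)` converts the profile to intervals:

1. **Runs**: maximal runs with profile $\ge$ 1.6 — a standard cutoff for
   Kyte–Doolittle detection of membrane-spanning segments.
2. **Merge**: adjacent runs separated by fewer than 3 sub-threshold
   positions fuse, since one polar residue inside a helix can notch the
   profile without breaking the helix.
3. **Length filter**: intervals shorter than 15 are dropped. A
   membrane-spanning α-helix needs ~20 residues; 15 allows for smoothing
   erosion at the edges while rejecting short hydrophobic patches.
4. **Split**: intervals longer than 35 (too long for one helix) are split
   at their lowest internal profile point, recursively.

`assignTopology(intervals, seqLength)` accepts exactly four intervals and
assembles the nine-segment model (`NTERM_IN`, `TM1`, `EL1`, `TM2`, `CL`,
`TM3`, `EL2`, `TM4`, `CTERM_IN`), omitting empty termini. Any other TM count
returns a structured failure object (class `innexTopologyFailure`) carrying
the count — a *result*, not an error, because non-four-TM proteins are an
expected input class that the screen must label, not crash on. The
N-terminus is taken as intracellular (innexin orientation), which fixes EL1
and EL2 as the first and third inter-helix segments.

# Sequon detection and scoring

`findSequons(seq)` finds every N-X-S/T with X ≠ P by direct vectorized
character comparison. `localizeSequons()` assigns each sequon to the segment
containing its **asparagine** (the N is the glycan acceptor; a sequon
straddling a boundary is glycosylatable only if the N itself is
extracellular). `occupancyScore()` applies `sequonRules()`:

| rule | default | rationale |
|---|---|---|
| base score | 0.55 | a canonical extracellular sequon is more likely occupied than not |
| +2 is T bonus | +0.15 | N-X-T sequons are occupied more efficiently than N-X-S |
| +3 proline penalty | −0.25 | proline immediately after the sequon strongly suppresses transfer |
| near-membrane penalty | −0.10 within 3 residues of a TM boundary | the oligosaccharyltransferase active site cannot reach acceptors too close to the bilayer |
| pass threshold | score **strictly greater than** 0.5 | "more likely than not" occupancy |

Scores are clamped to $[0, 1]$. The threshold is strict: a score of exactly
0.5 does not pass. A sequon **passes** only if it scores above threshold
*and* lies in EL1 or EL2. The scores are a deterministic rule-based
surrogate, not a trained predictor — see Limitations.

# Screening

`screenDataset()` applies, per record, **all** applicable rejection reasons
(they accumulate rather than short-circuit):

* `FRAGMENT` — length < 200 aa (`minLength`), too short for a full
  four-TM innexin;
* `NOT_FOUR_TM` — topology inference did not produce exactly four helices;
* `DUPLICATE` — another record of the *same species* has a byte-identical
  sequence; all but the lexicographically smallest id are flagged, a
  deterministic tie-break that keeps exactly one representative.

Accepted records get a topology model and scored sequons; rejected records
carry no sequons by construction (enforced by the `ScreenResult` validity
method).

# Aggregation

`summarizeByTaxon()` computes, per taxon group and **over accepted proteins
only**, the count and fraction with ≥1 passing extracellular sequon, the
number of distinct species among accepted proteins, and mean isoforms per
species. Groups with no accepted proteins report `NA` fractions rather than
0 — absence of evidence is not a measured zero.
`speciesNgsUniversality()` is the stricter statement "every accepted protein
in the group has a passing sequon"; for an empty group it is vacuously
`TRUE` with a warning.

# Conservation and phylogenetics

`sequonColumnConservation()` maps each passing sequon's N to its alignment
column (via per-sequence residue→column maps), and counts, per group and
column, how many species have a passing sequon at that column. A column is
`conserved_all` only when *every* member species has one. `trimColumns()`
optionally removes columns with gap fraction > 0.5 and surviving blocks
shorter than 5, the usual guard against alignment regions too gappy to
compare.

`pDistance()` is the proportion of differing sites under pairwise deletion
(shared non-gap columns only; zero comparable columns is an error, not a
silent 0). `njTree()` wraps `ape::nj()` and clamps negative branch lengths
to zero, transferring the deficit to the sister edge so path lengths are
preserved. `robinsonFoulds()` counts the symmetric difference of
non-trivial bipartitions (canonicalized to the side containing a reference
tip); the test suite cross-checks it against `phangorn::RF.dist`.
`annotateTree()` joins screen verdicts onto tree leaves, failing loudly on
any leaf without a verdict.

# The synthetic generator

Because no curated innexin data ship with the package, every claim is
validated on synthetic proteins with **planted, exhaustive ground truth**.

## Alphabet design

Segments are drawn from disjoint-by-purpose alphabets:

* **TM segments**: {I, V, L, F} with weights 0.30/0.30/0.30/0.10 —
  Kyte–Doolittle mean ≈ +4.0.
* **Loops/termini**: {G, P, Y, W, Q, E, D, K, H, R} with weights
  0.45/0.12/0.10/0.08/0.07/0.06/0.05/0.04/0.02/0.01 —
  Kyte–Doolittle mean ≈ −1.5.

Two properties are engineered in:

1. **Exhaustive sequon truth.** The loop alphabet excludes N, S and T, so
   the *only* sequons in a generated innexin are the planted ones. Tests can
   therefore assert exact set equality between detected and planted sequons,
   not merely overlap.
2. **Boundary arithmetic.** With window $w = 19$, the smoothed profile at a
   position $k$ residues inside a TM segment mixes roughly $k + w/2$ TM
   residues with the rest loop residues. Solving
   $\frac{k\,\mu_T + (w - k)\,\mu_L}{w} \ge 1.6$ for the chosen means puts
   the expected threshold crossing about one residue inside the true
   boundary, so called boundaries track planted ones to within a few
   residues. These alphabets and weights were fixed once from this
   arithmetic, not iterated against test outcomes.

## Segment lengths and planting

Default length ranges (uniform integer draws): N-terminus 30–60, TM 24–30,
EL1/EL2 40–80, CL 60–120, C-terminus 40–100. The TM range sits well above
the caller's 15-residue minimum — smoothing against a charged loop cluster
can erode several positions from an above-threshold run, and a helix near
the minimum would make recovery fragile — and below the 35-residue split
threshold. Sequons are planted with the N at least 4 residues inside the
loop (clear of the near-membrane penalty), X and the +3 residue drawn from
the loop alphabet minus {P, N, S, T, C}, and +2 ∈ {S, T}, so every planted
sequon passes under default rules. Each extracellular loop also receives 2
cysteines (placed clear of the sequon footprint), mimicking the conserved
loop cysteines of real innexins.

## Datasets, contaminants and clades

`simulateDataset()` builds per-taxon species with configurable isoform
counts and per-protein planting probability `pElNgs`, then appends
contaminants at configurable fractions of the innexin count: decoys with 3
or 5 TM helices (alternating), fragments truncated to 150–199 aa, and exact
duplicates that share the source's species and sort lexicographically after
it. `defaultTaxa()` encodes three illustrative designs: a ctenophore-like
group (10 species, 2–6 isoforms, `pElNgs = 0.67`), a lancelet-like group
(5 species, 1 isoform, 1.0), and a mammal-like group (8 species, 2–5
isoforms, 1.0). These sizes, like all problem sizes in the tests and the
acceptance script, are the package's own choices for exercising the code at
meaningful scale.

`simulateCladeAlignment()` evolves one ancestral innexin (always carrying a
sequon) into $n$ aligned descendants by per-site substitution within the
segment-appropriate alphabet, with no indels (so residue positions equal
alignment columns — the identity-map limit the conservation tests exploit).
For members flagged as preserving the sequon, the four sequon-footprint
sites are frozen; for knockouts, the N is replaced by Q. Freezing the +3
site too keeps the *score* of preserved sequons identical across members,
so conservation tests measure the counting logic, not scoring jitter.

## Determinism

`simConfig(seed = ...)` seeds all generation; derived draws flow from R's
RNG stream. TSV output formats floating point via `%.6g`, making files
byte-comparable across runs — the end-to-end determinism test hashes every
output file of two independent pipeline runs.

# Command-line interface

`innexCli()` dispatches `simulate`, `screen`, `aggregate`, `conserve` and
`tree-annotate`, reading flat `key=value` config files plus `--flag value`
overrides. Exit status 0 means success, 1 an input/data error (missing or
malformed files, unmatched ids), 2 a usage/configuration error (unknown
command, invalid parameter value). `inst/cli/innexscreen.R` is a thin
`Rscript` wrapper around the same exported function, so the CLI is testable
in-process.

# Limitations

* **The occupancy score is a surrogate.** It encodes well-known qualitative
  determinants (N-X-T > N-X-S, +3 proline suppression, membrane proximity)
  as fixed additive rules; it is not trained on glycoproteomics data and its
  numeric values should not be interpreted as probabilities of occupancy for
  real proteins.
* **Topology inference is single-scale hydropathy.** Real topology
  predictors use evolutionary profiles and learned emissions; a pure
  Kyte–Doolittle scanner will misassign marginally hydrophobic helices. The
  recovery rates quoted by the test suite hold for the generator's alphabet
  contrast, not for arbitrary natural sequences.
* **The generator is stylized.** Disjoint alphabets, no indels in clade
  evolution, uniform length draws and independent sites are deliberate
  simplifications that make truth exhaustive and arithmetic tractable; they
  do not model real innexin composition.
* **Duplicate detection is exact-match within species.** Near-duplicates
  (alleles, sequencing variants) are not flagged.
* **Conservation requires a trusted alignment.** Column mapping is only as
  good as the input alignment; the package aligns nothing itself.
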