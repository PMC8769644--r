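# innexScreen

Screening gap-junction proteins for extracellular N-glycosylation sequons.

## The scientific problem

Innexins — the invertebrate gap-junction family — share a canonical membrane
architecture: four transmembrane helices (TM1–TM4), two extracellular loops
(EL1, EL2), a cytoplasmic loop, and cytoplasmic N- and C-termini. N-linked
glycosylation happens in the secretory-pathway lumen, so only asparagines
that end up **extracellular** in the mature protein can carry a glycan. The
glycosylation acceptor site is the *sequon* **N-X-S/T**, where X is any
residue except proline.

`innexScreen` implements a reproducible screen over protein sequence sets:

1. **Topology** — infer the four-TM topology from a Kyte–Doolittle
   hydropathy profile (window 19, threshold 1.6) and delineate EL1/EL2.
2. **Sequon detection** — find every N-X-S/T (X ≠ P), localize it by its
   asparagine, and score predicted occupancy with fixed additive rules
   (N-X-T bonus, +3-proline penalty, near-membrane penalty); a sequon
   *passes* only if it lies in EL1 or EL2 and scores strictly above 0.5.
3. **Screening** — reject fragments (< 200 aa), proteins without exactly
   four TM helices, and per-species exact duplicates, accumulating all
   applicable reason codes.
4. **Aggregation** — per-taxon fractions of accepted proteins with a
   passing extracellular sequon, and a stricter per-group universality
   statement ("every accepted protein has one").
5. **Conservation** — map passing sequons to alignment columns and ask
   whether every species in a group keeps a sequon at the same column.
6. **Phylogenetics** — p-distances, neighbor-joining trees with
   negative-branch clamping, Robinson–Foulds distances, and annotation of
   tree leaves with screen verdicts.
7. **Diversity bound** — `hemichannelDiversity(n, s)` computes the upper
   bound *n^s* on ordered subunit arrangements of a hemichannel (*s* = 8
   for innexin octamers, 6 for connexin hexamers).

Because no curated data ship with the package, a synthetic innexin generator
with **planted, exhaustive ground truth** (`simulateDataset()`,
`simulateCladeAlignment()`) backs every claim in the test suite. See the
methods vignette (`vignettes/innexScreen-methods.Rmd`) for the model,
parameter rationale and limitations.

## Worked example

```r
library(innexScreen)

cfg <- simConfig(seed = 7, taxa = list(
  simTaxon("ctenophoreLike", 4L, c(2L, 3L), 0.67),
  simTaxon("mammalLike", 3L, c(2L, 2L), 1.0)))
ds  <- simulateDataset(cfg)
res <- screenDataset(ds$proteins, ds$taxonomy)
res
#> ScreenResult: 21 record(s); 17 accepted, 4 rejected; 15 with extracellular NGS
```

Every record gets a verdict; rejection reasons accumulate:

```r
tail(verdicts(res)[, c("protein_id", "status", "reason_codes", "has_el_ngs")], 4)
#>                     protein_id   status         reason_codes has_el_ngs
#>                   decoy3tm_001 REJECTED          NOT_FOUR_TM      FALSE
#>                   decoy5tm_002 REJECTED          NOT_FOUR_TM      FALSE
#>                       frag_001 REJECTED FRAGMENT,NOT_FOUR_TM      FALSE
#>  ctenophoreLike_sp02_i02_dup01 REJECTED            DUPLICATE      FALSE
```

Passing sequons are extracellular and above the strict 0.5 threshold:

```r
s <- sequons(res)
head(s[s$passes, ], 5)
#>               protein_id n_position triplet loop_label score passes
#>  ctenophoreLike_sp01_i01        122     NDS        EL1  0.55   TRUE
#>  ctenophoreLike_sp01_i02        137     NYT        EL1  0.70   TRUE
#>  ctenophoreLike_sp01_i03        342     NQT        EL2  0.70   TRUE
#>  ctenophoreLike_sp02_i01        113     NRT        EL1  0.70   TRUE
#>  ctenophoreLike_sp02_i02        288     NKT        EL2  0.70   TRUE
```

Per-taxon aggregation and the universality check:

```r
summarizeByTaxon(res, ds$taxonomy)
#>     taxon_group n_species n_proteins n_with_el_ngs fraction_with_el_ngs
#>  ctenophoreLike         4         11             9            0.8181818
#>      mammalLike         3          6             6            1.0000000
#>  mean_isoforms_per_species
#>                       2.75
#>                       2.00

speciesNgsUniversality(res, ds$taxonomy)
#> ctenophoreLike     mammalLike 
#>          FALSE           TRUE
```

The inferred topology of an accepted protein, and the diversity bound for
two isoforms forming an octameric hemichannel:

```r
topologies(res)[["ctenophoreLike_sp01_i01"]]
#> TopologyModel over 407 residues
#>   NTERM_IN:1-49;TM1:50-78;EL1:79-147;TM2:148-174;CL:175-237;TM3:238-265;EL2:266-331;TM4:332-359;CTERM_IN:360-407

hemichannelDiversity(2, 8)
#> [1] 256
```

## Command-line interface

The same pipeline is scriptable via the exported dispatcher `innexCli()` or
the wrapper script `inst/cli/innexscreen.R`:

```sh
Rscript inst/cli/innexscreen.R simulate --seed 7 --out run/
Rscript inst/cli/innexscreen.R screen --fasta run/proteins.fasta \
    --taxonomy run/taxonomy.tsv --out run/
Rscript inst/cli/innexscreen.R aggregate --verdicts run/verdicts.tsv \
    --sequons run/sequons.tsv --taxonomy run/taxonomy.tsv --out run/
```

Exit status 0 = success, 1 = input/data error, 2 = usage/configuration
error. All TSV output is byte-deterministic for a given input and seed.

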