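# hrdscar

Homologous recombination deficiency (HRD) scoring from structural-variant,
copy-number and aneuploidy calls, with a CNA-only mode for platform
comparison.

Tumors that cannot repair double-strand breaks through the homologous
recombination repair pathway accumulate characteristic genomic scars, and
their burden predicts sensitivity to PARP inhibitors and platinum drugs.
`hrdscar` quantifies that burden from the call files produced by
optical-genome-mapping (OGM) rare-variant pipelines — which see balanced
rearrangements (translocations, inversions, insertions) in addition to copy
number — and, in CNA-only mode, from copy-number/AOH evidence alone, the way
a chromosomal microarray (CMA) or NGS gene panel sees the genome. Comparing
the two modes on the same sample shows exactly which scars are cryptic to
copy-number-only platforms. The package is aimed at cytogeneticists and
pipeline developers working with OGM or array/panel copy-number data.

## The scoring model

Three established scar signatures are combined, each class carrying a fixed
point weight:

| class | definition | points |
|---|---|---|
| TAI-0 | terminal gain/loss/AOH, > 3 Mb and < 10 Mb | 1 |
| TAI-1 | terminal gain/loss/AOH > 10 Mb | 2 |
| TAI-LOH-1 | terminal loss/AOH > 15 Mb (meets LOH and TAI) | 3 |
| LOH-0 | interstitial loss/AOH > 15 Mb, 0 chromosome breakpoints | 1 |
| LOH-1 | interstitial loss/AOH > 15 Mb, 1 breakpoint | 2 |
| LOH-2 | interstitial loss/AOH > 15 Mb, 2 breakpoints | 3 |
| LST-1 | state transition > 10 Mb, 1 breakpoint | 1 |
| LST-2 | state transition > 10 Mb, 2 breakpoints (incl. large inversions) | 2 |
| LST-3 | insertion > 10 Mb | 3 |

TAI (telomeric allelic imbalance) regions must reach a telomere without
involving the centromere; whole-chromosome events and intervals < 3 Mb never
score; segment ends at telomeres or inside the (mask-extended) centromere do
not count as breakpoints. Before scoring, variants are filtered on per-type
confidence (insertion 0, deletion 0, inversion 0.01, duplication −1,
translocation 0, copy number 0.99), control-database frequency (0% by
default) and molecule support (≥ 5), and fragmented copy-number calls within
500 kbp are stitched.

Two rules make rearrangement evidence count:

* **Rearrangement bonus** — each segment end coinciding (± 500 kbp) with a
  filtered translocation junction earns one extra point, so a deletion shown
  to arise from two translocations scores even when the deletion itself is
  sub-threshold.
* **Chromothripsis flag** — chromosomes with more than 15 intrachromosomal
  fusion events are flagged, and can optionally be excluded from the total.

## Worked example

A 16 Mb interstitial 7q deletion whose proximal breakpoint lies on a
t(7;11) translocation:

```r
library(hrdscar)
g   <- load_genome("GRCh38")
cnv <- data.frame(chrom = "7", start = 80e6, end = 96e6 - 1,
                  state = "loss", confidence = 0.995)
sv  <- data.frame(id = "t7_11", chrom_a = "7", pos_a = 80e6,
                  chrom_b = "11", pos_b = 50e6, sv_type = "translocation",
                  size = 0, confidence = 0.5, molecule_support = 10,
                  control_frequency = 0)
compute_hrd(sv, cnv, genome = g, mode = "ogm")
#> HRD score (OGM mode): 4
#>   signatures (points): LOH=4  TAI=0  LST=0
#>   signatures (events): LOH=1  TAI=0  LST=0
#>   scars:
#>  scar_class chrom    start      end base_points bonus_points total_points
#>       LOH-2     7 80000000 95999999           3            1            4
compute_hrd(sv, cnv, genome = g, mode = "cna")
#> HRD score (CNA mode): 3
```

The deletion is an LOH-2 (3 points) on any platform; the translocation at
its proximal end adds one bonus point that only the SV-aware mode can see.

From a shell, the same computation runs through the bundled CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/hrd.R", package = "hrdscar"))') \
  score --sv sv.tsv --cnv cnv.tsv --mode ogm --out result.json
```

`hrd simulate` generates synthetic call sets with known ground-truth scores
(see `?case_spec`), and `hrd report` renders a stored result with
chromothripsis warnings.

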