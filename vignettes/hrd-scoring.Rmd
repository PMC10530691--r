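---
title: "Scoring HRD genomic scars from OGM-style variant calls"
author: "hrdscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring HRD genomic scars from OGM-style variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscar)
```

# The model

Homologous recombination deficiency leaves three quantifiable scar
signatures on a tumor genome: loss of heterozygosity (LOH) over regions
larger than 15 Mb but smaller than a whole chromosome, telomeric allelic
imbalance (TAI) — allelic imbalance reaching the sub-telomere without
crossing the centromere — and large-scale state transitions (LST),
chromosome breaks larger than 10 Mb. `hrdscar` scores each detected scar
with a fixed integer weight (1–3 points, see `scar_classes()`) and reports
the sum per chromosome, per signature and genome-wide. The key assumption
inherited from this scoring tradition is that scar *burden*, not scar
identity, tracks the HRD phenotype, so points are additive and classes are
mutually exclusive per segment (first match in a fixed decision order
wins).

The pipeline is: filter → stitch → geometry → classify → rearrangement
bonus → SV-level scars → chromothripsis flag → aggregate. All coordinates
are 1-based closed intervals; segment length is `end − start + 1`.

## Geometry and breakpoint counting

A genome build (`load_genome()`) supplies chromosome lengths, centromere
intervals and masked regions — intervals where the upstream CNV caller has
reduced sensitivity. Because calls cannot be expected to extend into such
regions, the *effective* centromeric and telomeric regions are the raw
anchors extended through any masks contiguous with them (gap at most the
stitch distance). A segment is terminal when it overlaps an effective
terminal region — overlap, not endpoint equality, because mask-shortened
calls rarely reach base 1 exactly. Each of a segment's two ends is a
genuine chromosome breakpoint only if it lies neither in an effective
terminal region nor in the effective centromeric region; centromeric breaks
are deliberately not counted, which is what distinguishes LOH-1 from LOH-2
and LST-1 from LST-2. Whole-chromosome status is geometric (both arms'
terminal regions reached), so aneuploidies contribute zero in every mode
without any special casing; a `whole_chrom`-by-fraction override was
considered and rejected because mosaic fractions are platform-dependent.

Acrocentric p-arms are handled by the same rules: the bundled annotation
masks them, so their effective centromeric region reaches position 1 and a
q-arm event can never be mistaken for a centromere-crossing one. The
bundled mask catalog (telomeric assembly gaps plus acrocentric p-arms) is a
deliberate minimal approximation — real OGM/CMA mask sets are proprietary —
and any annotation TSV can replace it.

One classification subtlety is resolved against the TAI definition: a
telomere-anchored loss that also overlaps the effective centromere is *not*
TAI (TAI must not involve the centromere) and falls through to the LOH
branch. A telomere-to-centromere loss therefore scores as LOH with its
genuine-breakpoint count (possibly LOH-0, when both ends are absorbed by
telomere and centromere), not as TAI-LOH-1.

## Rearrangement evidence

Two rules let balanced rearrangements contribute:

* Each segment end lying within the breakpoint-match tolerance of a
  filtered translocation junction adds one bonus point (OGM mode only).
  Matching is greedy nearest-first; each junction supports at most one end
  and each end one junction, with ties broken deterministically by record
  order. A segment with no base class but matched ends still scores — it is
  recorded under the nearest LST class (LST-1 for one end, LST-2 for two),
  since a rearrangement-caused copy-number change is a state transition.
  This is the minimal rule consistent with both printed platform
  comparisons the package reproduces (0 base + 2 ends = 2; 3 base + 1 end
  = 4), and it can be disabled (`rearrangement_bonus = FALSE`) to test
  alternative interpretations.
* Filtered SVs not consumed as bonus evidence score on their own:
  inversions, duplications and intrachromosomal rearrangements spanning
  more than the LST minimum are LST-2; insertions above the LST minimum are
  LST-3; unmatched interchromosomal translocations score 1 point each,
  recorded under LST-1 (the nearest class with weight 1). The
  translocation rule is required for rearrangement-rich genomes where the
  score is LST-dominated, and is switchable (`score_translocations`).
  SV-level deletions and duplicative gains are *not* scored directly when a
  CNV file is supplied — the CNV track is the copy-number authority, which
  avoids double counting the same event from two files. Duplications are
  otherwise treated like gains; the LST definition includes them even
  though the scored class list names only gains/losses/AOH.

Intervals below the 3 Mb exclusion never score — not even through the
bonus. The printed examples only constrain segments above 3 Mb, so the
exclusion is applied uniformly before any scoring.

# Tunable parameters

All sizes in bp. Defaults are the recommended operating point of the
scoring scheme; every one is overridable per call or via one YAML file
(`load_hrd_config()`).

| parameter | default | meaning |
|---|---|---|
| `confidence_thresholds` | ins 0, del 0, inv 0.01, dup −1, tra 0 | per-type minimum SV confidence (inclusive) |
| `cnv_confidence` | 0.99 | minimum CNV call confidence (inclusive) |
| `max_control_frequency` | 0 | retain only variants absent from controls |
| `min_molecule_support` | 5 | molecules spanning the SV breakpoints |
| `apply_mask_filter` | off | drop SVs in difficult-to-map regions |
| stitch distance | 500 kbp | CNV stitching and mask contiguity |
| `tai_min` / `tai0_max` | 3 / 10 Mb | TAI window |
| `loh_min` | 15 Mb | LOH size floor |
| `lst_min` / `lst_exclusion` | 10 / 3 Mb | LST floor, never-score floor |
| `breakpoint_match_tolerance` | 500 kbp | junction-to-end matching |
| `chromothripsis_threshold` | 15 | intrachromosomal fusions per chromosome |
| `exclude_chromothripsis` | off | zero out flagged chromosomes |

Notes on deliberate choices: size comparisons are strict (`>`/`<`) as
printed in the scheme, so a 10 Mb terminal segment is neither TAI-0 nor
TAI-1 — a documented boundary, not a bug. Filter comparisons are inclusive
at the threshold (a variant at exactly the recommended confidence is
retained). The CNV confidence scheme is stated ambiguously in the field
("0.99, low stringency, filter set to 0"); the default here is 0.99 with
`cnv_confidence` as the escape hatch. AOH segments without a confidence
value pass the CNV filter, since AOH calls are not on the copy-number
confidence scale. The breakpoint-match tolerance reuses the one stated
adjacency constant (500 kbp) rather than introducing a second magic
number. Stitching may bridge the centromere — only gap and state matter —
because fragmented whole-arm events would otherwise double-count
breakpoints. Chromothripsis-flagged chromosomes are *included* by default
and only flagged, leaving exclusion as an explicit analyst decision.

# Degenerate inputs and numerical behavior

Empty inputs at any stage yield a valid zero result. Readers are strict:
every row parses or the read fails with its line number — no silent
dropping. VCF input lacks OGM-specific fields; they default to pass-through
values with a warning, so the weaker filtering stays auditable. Identical
inputs produce byte-identical JSON output (results are timestamp-free; the
run manifest written by the CLI carries the timestamp separately).
Chromosome names are normalized (`chr1` ≡ `1`) on every input path.

# The synthetic-data generator

`generate_case()` turns a `case_spec()` — planted scar classes, per-scar
translocation-evidenced ends, decoy counts, aneuploidies, a fragmentation
probability and a seed — into call files plus the ground-truth score
implied by construction. It emulates the *call-level* behavior of an
OGM-style pipeline: class-conformant segment geometry on the real GRCh38
frame, fragmented CNV calls with sub-stitch gaps, whole-chromosome
aneuploidies, and decoys that each fail exactly one retention rule
(low-confidence and low-support SVs, polymorphic SVs present in controls,
sub-threshold segments), with a 1e-6 guard below each threshold to avoid
boundary flakiness. Each scar is planted on its own chromosome and decoys
are confined to unused chromosomes, so planted events cannot stitch into
each other or donate breakpoint evidence across scars.

What it does **not** emulate: molecule-level noise, tumor purity and
mosaic fractions, breakpoint-position uncertainty, overlapping or nested
real-world events, reference-genome artifacts beyond the bundled masks, or
realistic genome-wide variant densities. Passing the generator round-trip
(compute ∘ generate = truth, over hundreds of seeded random specs)
therefore demonstrates that the scoring rules are implemented correctly and
consistently with the construction, not that the tool's calls on real
samples are accurate — that depends on the upstream caller.

The test suite runs the round-trip over 200 random specs of up to 4 scars
each, an exhaustive oracle grid (state × {2,4,8,11,16,20} Mb × four
placements × 0–2 matched translocations × two modes) checked against a
hand-written rule table on a toy two-chromosome genome, and the fixture
set reproducing the published worked-example scores; the whole suite runs
in a couple of minutes on one CPU.

# Known limitations

* No HR-deficient/proficient cutoff is applied — reported thresholds in
  the literature vary widely (e.g. >42 vs 57 in breast tumors), so the
  package reports scores only.
* Scores depend on the upstream caller's segmentation; the package
  normalizes fragmentation (stitching) but cannot recover missed calls.
* The per-signature report prints both point sums and event counts, since
  published per-signature breakdowns are ambiguous between the two
  readings.
* Interchromosomal translocation points are attributed to the first-named
  chromosome of the pair in per-chromosome tables.
* The bundled centromere intervals are cytoband approximations; analyses
  sensitive to ±100 kb around centromeres should supply their own
  annotation.
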