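Package: hrdscar
Title: Homologous Recombination Deficiency Scar Scoring from Optical Genome Mapping Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes homologous recombination deficiency (HRD) scores from
    structural-variant, copy-number and aneuploidy call files of the kind
    produced by optical genome mapping (OGM) rare-variant pipelines. Calls are
    filtered on confidence, molecule support and control-database frequency,
    fragmented copy-number segments are stitched, each qualifying segment is
    classified into the LOH/TAI/LST genomic-scar taxonomy with fixed point
    weights, translocation-evidenced segment breakpoints earn a rearrangement
    bonus, chromosomes with excessive intrachromosomal fusions are flagged as
    possible chromothripsis, and per-chromosome and total scores are reported.
    A CNA-only mode restricts scoring to copy-number evidence, emulating
    chromosomal microarray or NGS-panel visibility for platform comparison.
    A seeded synthetic-case generator produces call sets with known
    ground-truth scores for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
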