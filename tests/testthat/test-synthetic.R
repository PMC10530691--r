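test_that("single planted scars reproduce their class weights", {
  for (cls in scar_classes()$name) {
    spec <- case_spec(scars = list(list(class = cls)), seed = 42)
    case <- generate_case(spec, grch38)
    expect_equal(case$truth$total, scar_classes()$weight[
      scar_classes()$name == cls], info = cls)
    got <- compute_hrd(case$svs, case$cnvs, case$aneuploidies,
                       genome = grch38, mode = "ogm")
    expect_equal(got$total, case$truth$total, info = cls)
    expect_equal(unname(got$signature_totals[scar_signature(cls)]),
                 case$truth$total, info = cls)
  }
})

test_that("planted bonus ends add translocation evidence worth one point each", {
  spec <- case_spec(scars = list(list(class = "LOH-2", bonus_ends = 1)),
                    seed = 3)
  case <- generate_case(spec, grch38)
  expect_equal(case$truth$total, 4)       # 3 + 1
  expect_equal(case$truth$total_cna, 3)   # the SV is invisible to CNA
  expect_equal(compute_hrd(case$svs, case$cnvs, genome = grch38,
                           mode = "ogm")$total, 4)
  expect_equal(compute_hrd(NULL, case$cnvs, genome = grch38,
                           mode = "cna")$total, 3)
})

test_that("generation is deterministic in the seed and files round-trip", {
  spec <- case_spec(scars = list("TAI-1", list(class = "LST-2", via = "sv")),
                    decoys = list(subthreshold_cnv = 2, low_confidence_sv = 1),
                    n_aneuploidy = 1, fragmentation = 1, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_case(generate_case(spec, grch38), d1)
  write_case(generate_case(spec, grch38), d2)
  for (f in c("sv.tsv", "cnv.tsv", "aneuploidy.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # files parse back through the package readers and score to truth
  svs <- read_sv_table(file.path(d1, "sv.tsv"))
  cnvs <- read_cnv_table(file.path(d1, "cnv.tsv"))
  an <- read_aneuploidy_table(file.path(d1, "aneuploidy.tsv"))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(compute_hrd(svs, cnvs, an, genome = grch38, mode = "ogm")$total,
               truth$total)
  # a different seed produces different placements
  spec2 <- spec; spec2$seed <- 100L
  d3 <- tempfile()
  write_case(generate_case(spec2, grch38), d3)
  expect_false(identical(readLines(file.path(d1, "cnv.tsv")),
                         readLines(file.path(d3, "cnv.tsv"))))
})

test_that("decoys never change the computed score", {
  for (seed in c(5, 17, 23)) {
    with_decoys <- case_spec(
      scars = list("TAI-0", list(class = "LOH-1", bonus_ends = 2)),
      decoys = list(subthreshold_cnv = 2, low_confidence_cnv = 1,
                    low_confidence_sv = 2, low_support_sv = 1,
                    polymorphic_sv = 1),
      seed = seed)
    without <- case_spec(
      scars = list("TAI-0", list(class = "LOH-1", bonus_ends = 2)),
      seed = seed)
    a <- generate_case(with_decoys, grch38)
    b <- generate_case(without, grch38)
    expect_gt(nrow(a$svs), nrow(b$svs))
    ra <- compute_hrd(a$svs, a$cnvs, a$aneuploidies, genome = grch38)
    rb <- compute_hrd(b$svs, b$cnvs, b$aneuploidies, genome = grch38)
    expect_equal(ra$total, rb$total)
    expect_equal(ra$total, a$truth$total)
  }
})

test_that("fragmented scars stitch back to full class weight", {
  spec <- case_spec(scars = list("LOH-2"), fragmentation = 1, seed = 8)
  case <- generate_case(spec, grch38)
  expect_gt(nrow(case$cnvs), 1)  # actually fragmented
  expect_equal(compute_hrd(NULL, case$cnvs, genome = grch38)$total, 3)
})

test_that("impossible placements are rejected", {
  expect_error(generate_case(case_spec(scars = list(
    list(class = "LOH-0", chrom = "13"))), grch38), "impossible")
  expect_error(case_spec(scars = list(list(class = "TAI-0", bonus_ends = 3))))
})

test_that("platform degradation drops SVs and fractures whole-chromosome gains", {
  an <- data.frame(chrom = "13", event = "gain", fraction = 0.8)
  whole <- aneuploidy_to_segments(an, grch38)
  frac <- degrade_to_cna_platform(whole, grch38, fracture = TRUE)
  expect_equal(nrow(frac), 2)
  expect_true(all(frac$state == "gain"))
  expect_true(all(frac$end - frac$start + 1 > 10e6))
  # the false-positive mechanism: fractured trisomy now scores, whole does not
  expect_equal(compute_hrd(NULL, whole, genome = grch38, mode = "cna")$total, 0)
  expect_gt(compute_hrd(NULL, frac, genome = grch38, mode = "cna")$total, 0)
  keep <- degrade_to_cna_platform(whole, grch38, fracture = FALSE)
  expect_equal(keep, whole)
  expect_equal(nrow(degrade_to_cna_platform(empty_cnv <- whole[0, ], grch38)), 0)
})
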