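test_that("the scar weight table is the fixed nine-class taxonomy", {
  tab <- scar_classes()
  expect_equal(tab$name, c("TAI-0", "TAI-1", "TAI-LOH-1", "LOH-0", "LOH-1",
                           "LOH-2", "LST-1", "LST-2", "LST-3"))
  expect_equal(tab$weight, c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L))
  expect_equal(tab$signature,
               c("TAI", "TAI", "TAI", "LOH", "LOH", "LOH", "LST", "LST", "LST"))
})

test_that("segment classification follows the decision order", {
  g <- masked_genome()  # 100 Mb, cen 45-50 Mb
  classify <- function(start, end, state) {
    seg <- make_cnv("M1", start, end, state = state)
    classify_scar(seg, classify_geometry(seg, g))
  }
  expect_equal(classify(95e6 + 1, 100e6, "loss"), "TAI-0")      # terminal 5 Mb
  expect_equal(classify(88e6 + 1, 100e6, "gain"), "TAI-1")      # terminal 12 Mb
  expect_equal(classify(80e6 + 1, 100e6, "loss"), "TAI-LOH-1")  # terminal 20 Mb
  expect_equal(classify(80e6 + 1, 100e6, "aoh"), "TAI-LOH-1")
  expect_equal(classify(80e6 + 1, 100e6, "gain"), "TAI-1")      # gain never LOH
  # interstitial loss/AOH > 15 Mb by breakpoint count
  expect_equal(classify(20e6, 40e6, "loss"), "LOH-2")
  expect_equal(classify(47e6, 70e6, "aoh"), "LOH-1")            # one end in cen
  # telomere-to-centromere loss involves the centromere: LOH, not TAI
  expect_equal(classify(1, 47e6, "loss"), "LOH-0")
  expect_equal(classify(20e6, 31e6, "gain"), "LST-2")           # 11 Mb, 2 bp
  expect_equal(classify(47e6, 59e6, "gain"), "LST-1")           # 12 Mb, 1 bp
  expect_null(classify(20e6, 22.5e6, "loss"))                   # below exclusion
  expect_null(classify(20e6, 28e6, "gain"))                     # 8 Mb interstitial
  expect_null(classify(1, 100e6, "loss"))                       # whole chromosome
  # strict comparisons at the printed sizes
  expect_null(classify(20e6 + 1, 30e6, "gain"))                 # exactly 10 Mb
  expect_equal(classify(90e6 + 1, 100e6, "loss"), "TAI-0")      # exactly 10 Mb terminal
})

test_that("breakpoint matching is tolerance-bounded and never double counts", {
  seg <- make_cnv("T1", 60e6, 65.3e6 - 1)
  two <- make_sv(chrom_a = c("T1", "T1"), pos_a = c(60e6 + 1e5, 65.2e6),
                 chrom_b = c("T2", "T2"), pos_b = c(10e6, 12e6))
  expect_equal(as.integer(match_rearrangement_breakpoints(seg, two)), 2L)
  one <- two[1, ]
  expect_equal(as.integer(match_rearrangement_breakpoints(seg, one)), 1L)
  # one junction cannot support both ends
  close_both <- make_sv("T1", 62e6, "T2", 10e6)
  expect_equal(as.integer(match_rearrangement_breakpoints(seg, close_both,
                                                          tolerance = 5e6)), 1L)
  # beyond tolerance
  far <- make_sv("T1", 61e6, "T2", 10e6)
  expect_equal(as.integer(match_rearrangement_breakpoints(seg, far)), 0L)
  # non-translocation SVs are not junction evidence
  inv <- make_sv("T1", 60e6, "T1", 65.3e6 - 1, sv_type = "inversion")
  expect_equal(as.integer(match_rearrangement_breakpoints(seg, inv)), 0L)
  expect_equal(as.integer(match_rearrangement_breakpoints(seg, NULL)), 0L)
})

test_that("SV-level scars cover inversions, insertions and lone translocations", {
  cfg <- score_config()
  expect_equal(classify_sv_scar(make_sv("1", 10e6, "1", 21e6,
                                        sv_type = "inversion"), cfg), "LST-2")
  expect_null(classify_sv_scar(make_sv("1", 10e6, "1", 18e6,
                                       sv_type = "inversion"), cfg))
  ins <- make_sv("1", 10e6, "1", 10e6, sv_type = "insertion", size = 11e6)
  expect_equal(classify_sv_scar(ins, cfg), "LST-3")
  expect_equal(classify_sv_scar(make_sv("1", 1e6, "2", 2e6), cfg), "LST-1")
  no_tra <- score_config(score_translocations = FALSE)
  expect_null(classify_sv_scar(make_sv("1", 1e6, "2", 2e6), no_tra))
  # large intrachromosomal rearrangements count like inversions
  expect_equal(classify_sv_scar(make_sv("1", 10e6, "1", 22e6,
                                        sv_type = "duplication"), cfg), "LST-2")
})

test_that("sub-threshold segments score only through rearrangement evidence", {
  g <- toy_genome()
  seg <- make_cnv("T1", 60e6, 65.3e6 - 1)
  geo <- classify_geometry(seg, g)
  svs <- make_sv(chrom_a = c("T1", "T1"), pos_a = c(60e6, 65.3e6 - 1),
                 chrom_b = c("T2", "T2"), pos_b = c(10e6, 12e6))
  sc <- score_segment(seg, geo, svs, score_config(), "ogm")
  expect_equal(sc$base_points, 0L)
  expect_equal(sc$bonus_points, 2L)
  expect_equal(sc$total_points, 2L)
  expect_equal(sc$scar_class, "LST-2")
  expect_null(score_segment(seg, geo, svs, score_config(), "cna"))
  expect_null(score_segment(seg, geo, NULL, score_config(), "ogm"))
  # intervals below the 3 Mb exclusion never score, bonus or not
  tiny <- make_cnv("T1", 60e6, 62e6)
  tiny_sv <- make_sv(chrom_a = c("T1", "T1"), pos_a = c(60e6, 62e6),
                     chrom_b = c("T2", "T2"), pos_b = c(10e6, 12e6))
  expect_null(score_segment(tiny, classify_geometry(tiny, g), tiny_sv,
                            score_config(), "ogm"))
})

test_that("chromothripsis flag uses a strict intrachromosomal fusion count", {
  fused <- function(n) make_sv(chrom_a = rep("9", n),
                               pos_a = seq(1e6, by = 2e6, length.out = n),
                               chrom_b = rep("9", n),
                               pos_b = seq(1.5e6, by = 2e6, length.out = n))
  d15 <- detect_chromothripsis(fused(15))
  expect_false(d15$flagged)
  d16 <- detect_chromothripsis(fused(16))
  expect_true(d16$flagged)
  expect_equal(d16$fusions, 16L)
  # interchromosomal translocations are not intrachromosomal fusions
  inter <- make_sv(chrom_a = rep("9", 16),
                   pos_a = seq(1e6, by = 2e6, length.out = 16),
                   chrom_b = rep("11", 16), pos_b = rep(5e6, 16))
  expect_equal(nrow(detect_chromothripsis(inter)), 0)
  # exclusion zeroes out flagged chromosomes in the total
  g <- toy_genome()
  many <- make_sv(chrom_a = rep("T1", 16),
                  pos_a = seq(100e6, by = 2e6, length.out = 16),
                  chrom_b = rep("T1", 16),
                  pos_b = seq(111e6, by = 2e6, length.out = 16))
  cnv <- make_cnv("T1", 10e6, 26e6)  # LOH-2 on the same chromosome
  keep <- compute_hrd(many, cnv, genome = g, mode = "ogm")
  expect_true("T1" %in% keep$chromothripsis$chrom[keep$chromothripsis$flagged])
  expect_gte(keep$total, 3)
  drop <- compute_hrd(many, cnv, genome = g, mode = "ogm",
                      score_config = score_config(exclude_chromothripsis = TRUE))
  expect_equal(drop$total, 0L)
  expect_equal(drop$excluded_chroms, "T1")
})

test_that("segment scoring matches the brute-force oracle over the grid", {
  g <- toy_genome()
  for (state in c("gain", "loss", "aoh")) {
    for (size_mb in c(2, 4, 8, 11, 16, 20)) {
      for (placement in c("terminal", "interstitial", "cen_anchored",
                          "cen_spanning")) {
        for (n_trans in 0:2) {
          fix <- oracle_fixture(state, size_mb, placement, n_trans)
          for (mode in c("ogm", "cna")) {
            got <- compute_hrd(fix$svs, fix$cnv, genome = g, mode = mode)$total
            expect_equal(
              got, oracle_total(state, size_mb, placement, n_trans, mode),
              info = paste(state, size_mb, placement, n_trans, mode))
          }
        }
      }
    }
  }
})
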