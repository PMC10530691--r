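test_that("stitching merges same-state segments within the gap, transitively", {
  cnvs <- rbind(make_cnv("1", 1e6, 2e6, confidence = 0.999),
                make_cnv("1", 2.4e6, 3e6, confidence = 0.992))  # 400 kb gap
  out <- stitch_segments(cnvs)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(1e6, 3e6))
  expect_equal(out$confidence, 0.992)  # min of parts

  far <- rbind(make_cnv("1", 1e6, 2e6), make_cnv("1", 2.6e6 + 1, 3e6))  # 600 kb
  expect_equal(nrow(stitch_segments(far)), 2)

  # boundary: 500,000 merges, 500,001 does not
  at <- rbind(make_cnv("1", 1e6, 2e6), make_cnv("1", 2e6 + 500000 + 1, 3e6))
  expect_equal(nrow(stitch_segments(at)), 1)
  over <- rbind(make_cnv("1", 1e6, 2e6), make_cnv("1", 2e6 + 500001 + 1, 3e6))
  expect_equal(nrow(stitch_segments(over)), 2)

  # different states never merge, even when abutting
  mixed <- rbind(make_cnv("1", 1e6, 2e6, state = "loss"),
                 make_cnv("1", 2e6 + 1, 3e6, state = "gain"))
  expect_equal(nrow(stitch_segments(mixed)), 2)

  # transitive chain collapses to one segment
  chain <- make_cnv("1", c(1e6, 1.6e6, 2.2e6), c(1.5e6, 2.1e6, 2.7e6))
  expect_equal(nrow(stitch_segments(chain)), 1)
})

test_that("stitching is order-independent and coverage-preserving", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    starts <- sort(sample(seq(1e6, 60e6, by = 1e5), n))
    lens <- sample(seq(1e5, 5e6, by = 1e5), n, replace = TRUE)
    cnvs <- make_cnv("1", starts, starts + lens - 1,
                     state = sample(c("loss", "gain"), n, TRUE))
    a <- stitch_segments(cnvs)
    b <- stitch_segments(cnvs[sample(n), ])
    expect_equal(a, b)
    expect_lte(nrow(a), n)
    # every input segment is contained in one output segment of its state
    for (i in seq_len(n)) {
      hit <- a$state == cnvs$state[i] & a$start <= cnvs$start[i] &
        a$end >= cnvs$end[i]
      expect_true(any(hit))
    }
    # same-state outputs are pairwise disjoint
    for (st in unique(a$state)) {
      s <- a[a$state == st, ]
      if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    }
  }
})

test_that("geometry classification reads terminal, centromeric and whole-chromosome status", {
  g <- masked_genome()  # 100 Mb, centromere 45-50 Mb, no masks
  geo <- classify_geometry(make_cnv("M1", 1, 20e6), g)
  expect_true(geo$terminal_p)
  expect_false(geo$terminal_q)
  expect_false(geo$spans_centromere)
  expect_equal(geo$cn_breakpoints, 1L)

  geo2 <- classify_geometry(make_cnv("M1", 40e6, 60e6), g)
  expect_false(geo2$terminal_p || geo2$terminal_q)
  expect_true(geo2$spans_centromere)
  expect_equal(geo2$cn_breakpoints, 2L)

  geo3 <- classify_geometry(make_cnv("M1", 1, 100e6), g)
  expect_true(geo3$whole_chromosome)
  expect_equal(geo3$cn_breakpoints, 0L)

  # an end inside the effective centromere is not a genuine break
  geo4 <- classify_geometry(make_cnv("M1", 47e6, 70e6), g)
  expect_equal(geo4$cn_breakpoints, 1L)

  # mask-shortened call still counts as terminal via the effective region
  gm <- masked_genome(rbind(c(1, 2e6)))
  geo5 <- classify_geometry(make_cnv("M1", 1.5e6, 20e6), gm)
  expect_true(geo5$terminal_p)
  expect_equal(geo5$cn_breakpoints, 1L)

  expect_error(classify_geometry(make_cnv("M1", 90e6, 120e6), g), "outside")
  expect_error(classify_geometry(make_cnv("nope", 1, 2), g), "not in genome")
})

test_that("whole-chromosome detection is geometric and mask-robust", {
  gm <- masked_genome(rbind(c(1, 10000), c(100e6 - 9999, 100e6)))
  geo <- classify_geometry(make_cnv("M1", 5000, 100e6 - 5000), gm)
  expect_true(geo$whole_chromosome)
  expect_equal(geo$cn_breakpoints, 0L)
})

test_that("aneuploidies become whole-chromosome segments of the right state", {
  an <- data.frame(chrom = c("13", "21", "X"),
                   event = c("gain", "loss", "whole_chrom_aoh"),
                   fraction = c(0.8, 0.5, 1))
  segs <- aneuploidy_to_segments(an, grch38)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start, rep(1, 3))
  expect_equal(segs$end[1], 114364328)
  expect_equal(segs$state, c("gain", "loss", "aoh"))
  expect_true(all(vapply(seq_len(3), function(i) {
    classify_geometry(segs[i, ], grch38)$whole_chromosome
  }, logical(1))))
  expect_equal(nrow(aneuploidy_to_segments(an[0, ], grch38)), 0)
})
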