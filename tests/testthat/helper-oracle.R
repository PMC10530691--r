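# Independent brute-force oracle for segment scoring on the toy genome.
# Encodes the scar rule table directly as a lookup, without reusing any of
# the package's geometry or classification code: placements map to a known
# breakpoint count and terminal/centromere status by construction on T1
# (200 Mb, centromere 95-96 Mb, no masks).
#
# placements:
#   terminal      q-telomere-anchored, away from the centromere (1 genuine end)
#   interstitial  both ends genuine, no centromere contact
#   cen_anchored  one end inside the centromere, one genuine
#   cen_spanning  crosses the centromere, both ends genuine
oracle_base_points <- function(state, size_mb, placement) {
  loh_state <- state %in% c("loss", "aoh")
  if (size_mb < 3) return(0L)
  if (placement == "terminal") {
    if (loh_state && size_mb > 15) return(3L)   # TAI-LOH-1
    if (size_mb > 10) return(2L)                # TAI-1
    if (size_mb > 3) return(1L)                 # TAI-0
    return(0L)
  }
  n_bp <- switch(placement, interstitial = 2L, cen_spanning = 2L,
                 cen_anchored = 1L)
  if (loh_state && size_mb > 15) return(c(1L, 2L, 3L)[n_bp + 1L])  # LOH-k
  if (size_mb > 10 && n_bp >= 1) return(n_bp)                      # LST-1/2
  0L
}

oracle_total <- function(state, size_mb, placement, n_trans, mode) {
  base <- oracle_base_points(state, size_mb, placement)
  if (mode == "ogm") base + n_trans else base
}

# Build the T1 segment for a placement, plus translocations at its ends
# (interior-first) when n_trans > 0.
oracle_fixture <- function(state, size_mb, placement, n_trans) {
  size <- size_mb * 1e6
  L <- 200e6
  seg <- switch(placement,
    terminal = c(L - size + 1, L),
    interstitial = c(10e6, 10e6 + size - 1),
    cen_anchored = c(95.2e6, 95.2e6 + size - 1),
    cen_spanning = c(95e6 - floor(size / 2), 95e6 - floor(size / 2) + size - 1))
  cnv <- make_cnv("T1", seg[1], seg[2], state = state)
  svs <- NULL
  if (n_trans > 0) {
    ends <- if (placement == "terminal") c(seg[1], seg[2]) else c(seg[2], seg[1])
    svs <- make_sv(chrom_a = rep("T1", n_trans), pos_a = ends[seq_len(n_trans)],
                   chrom_b = rep("T2", n_trans),
                   pos_b = 60e6 + seq_len(n_trans) * 2e6,
                   sv_type = "translocation")
  }
  list(cnv = cnv, svs = svs)
}
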