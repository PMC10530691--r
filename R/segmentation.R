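#' Stitch fragmented copy-number segments
#'
#' CNV callers fragment long events across low-sensitivity regions. Any two
#' segments on the same chromosome with the same state whose gap is at most
#' `max_gap` (default 500 kbp) are merged, transitively, before scoring.
#' Merged confidence is the minimum of the parts; different states never
#' merge. Output is canonically sorted, so stitching is independent of input
#' order. Stitching may bridge the centromere: only gap size and state
#' matter.
#'
#' @param cnvs CNV data.frame ([read_cnv_table()] columns).
#' @param max_gap Maximum inter-segment gap in bp for merging.
#' @return A CNV data.frame with non-overlapping same-state segments.
#' @export
stitch_segments <- function(cnvs, max_gap = 500000) {
  if (nrow(cnvs) == 0) return(cnvs)
  has_cn <- "copy_number" %in% names(cnvs)
  groups <- split(seq_len(nrow(cnvs)), paste(cnvs$chrom, cnvs$state, sep = "\r"))
  pieces <- lapply(groups, function(idx) {
    g <- cnvs[idx, , drop = FALSE]
    ir <- IRanges::IRanges(start = g$start, end = g$end)
    # reduce() merges at gap < min.gapwidth, so gap <= max_gap needs + 1
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(
      chrom = g$chrom[1],
      start = IRanges::start(red),
      end = IRanges::end(red),
      state = g$state[1],
      confidence = vapply(revmap, function(j) {
        v <- g$confidence[j]
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
      }, numeric(1)),
      copy_number = if (has_cn) {
        vapply(revmap, function(j) {
          v <- g$copy_number[j]
          if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
        }, numeric(1))
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the geometry of a segment against the genome frame
#'
#' Determines how a segment sits on its chromosome: whether it reaches the
#' effective terminal region of the p and/or q arm, whether it overlaps the
#' effective centromeric region, whether it covers the whole chromosome
#' (both arms' terminal regions reached), and how many of its two ends are
#' genuine chromosome breakpoints. An end is *not* a breakpoint when it lies
#' inside an effective terminal region (the call simply ran to the telomere)
#' or inside the effective centromeric region (centromeric breaks are not
#' counted). "Terminal" requires only overlap with the effective terminal
#' region, not exact endpoint equality, because masked-region-shortened
#' calls rarely hit base 1 exactly.
#'
#' @param segment A one-row CNV data.frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param genome A [load_genome()] build.
#' @param max_gap Mask-contiguity distance, shared with [stitch_segments()].
#' @return A list with logicals `terminal_p`, `terminal_q`,
#'   `spans_centromere`, `whole_chromosome` and integer `cn_breakpoints`
#'   (0-2).
#' @export
classify_geometry <- function(segment, genome, max_gap = 500000) {
  ann <- get_chrom(genome, segment$chrom)
  s <- segment$start
  e <- segment$end
  if (s < 1 || e > ann$length) {
    stop("segment [", s, ", ", e, "] outside chromosome ", ann$name,
         " (length ", ann$length, ")", call. = FALSE)
  }
  term_p <- effective_terminal_region(ann, "p", max_gap)
  term_q <- effective_terminal_region(ann, "q", max_gap)
  cen <- effective_centromeric_region(ann, max_gap)
  overlaps <- function(iv) s <= iv[2] && e >= iv[1]
  inside <- function(p, iv) iv[1] <= p && p <= iv[2]
  terminal_p <- overlaps(term_p)
  terminal_q <- overlaps(term_q)
  whole <- terminal_p && terminal_q
  n_bp <- sum(vapply(c(s, e), function(p) {
    !(inside(p, term_p) || inside(p, term_q) || inside(p, cen))
  }, logical(1)))
  if (whole) n_bp <- 0L
  list(terminal_p = terminal_p, terminal_q = terminal_q,
       spans_centromere = overlaps(cen), whole_chromosome = whole,
       cn_breakpoints = as.integer(n_bp))
}

#' Expand aneuploidy calls to whole-chromosome segments
#'
#' Each aneuploidy becomes a segment covering its entire chromosome with the
#' corresponding state (`whole_chrom_aoh` maps to state `aoh`). Because the
#' scar taxonomy excludes whole-chromosome events, these segments are carried
#' through scoring but always contribute 0 points.
#'
#' @param calls Aneuploidy data.frame from [read_aneuploidy_table()].
#' @param genome A [load_genome()] build.
#' @return A CNV data.frame of whole-chromosome segments.
#' @export
aneuploidy_to_segments <- function(calls, genome) {
  if (nrow(calls) == 0) return(empty_cnv_table())
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    ann <- get_chrom(genome, calls$chrom[i])
    state <- if (calls$event[i] == "whole_chrom_aoh") "aoh" else calls$event[i]
    data.frame(chrom = ann$name, start = 1, end = ann$length, state = state,
               confidence = NA_real_, copy_number = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
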