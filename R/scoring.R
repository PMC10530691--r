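# The fixed scar taxonomy: nine classes, three signatures, immutable weights.
SCAR_CLASSES <- data.frame(
  name = c("TAI-0", "TAI-1", "TAI-LOH-1",
           "LOH-0", "LOH-1", "LOH-2",
           "LST-1", "LST-2", "LST-3"),
  weight = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L),
  signature = c("TAI", "TAI", "TAI", "LOH", "LOH", "LOH", "LST", "LST", "LST"),
  stringsAsFactors = FALSE
)

#' The scar-class weight table
#'
#' Nine scored classes in three signatures. TAI classes are telomere-anchored
#' allelic-imbalance regions not involving the centromere (TAI-0: 3-10 Mb,
#' 1 point; TAI-1: >10 Mb, 2 points; TAI-LOH-1: losses/AOH >15 Mb reaching a
#' telomere, 3 points — meeting both the TAI and LOH definitions, counted
#' once under TAI). LOH classes are interstitial losses/AOH >15 Mb, weighted
#' by the number of genuine chromosome breakpoints (LOH-0: 1, LOH-1: 2,
#' LOH-2: 3 points). LST classes are large-scale state transitions >10 Mb
#' (LST-1: 1 breakpoint, 1 point; LST-2: 2 breakpoints — including large
#' inversions and intrachromosomal rearrangements — 2 points; LST-3:
#' insertions >10 Mb, 3 points).
#'
#' @return A data.frame with columns `name`, `weight`, `signature`.
#' @export
scar_classes <- function() SCAR_CLASSES

scar_weight <- function(name) {
  SCAR_CLASSES$weight[match(name, SCAR_CLASSES$name)]
}

scar_signature <- function(name) {
  SCAR_CLASSES$signature[match(name, SCAR_CLASSES$name)]
}

#' Scoring configuration
#'
#' Size thresholds and toggles of the scar-scoring rules, all in bp. Size
#' comparisons are strict (`>` / `<`) at the printed thresholds: a terminal
#' segment of exactly 10 Mb is neither TAI-0 nor TAI-1. Defaults:
#' TAI minimum 3 Mb, TAI-0/TAI-1 split at 10 Mb, LOH minimum 15 Mb, LST
#' minimum 10 Mb, a 3 Mb exclusion below which intervals never score,
#' a 500 kbp tolerance when matching translocation junctions to segment ends
#' (shared with the stitch distance), and a chromothripsis flag at more than
#' 15 intrachromosomal fusion events per chromosome.
#'
#' @param tai_min Minimum terminal allelic-imbalance size.
#' @param tai0_max TAI-0 / TAI-1 boundary.
#' @param loh_min Minimum LOH size.
#' @param lst_min Minimum LST size.
#' @param lst_exclusion Intervals below this size never score.
#' @param breakpoint_match_tolerance Max distance (bp) between a segment end
#'   and a translocation junction for the rearrangement bonus.
#' @param chromothripsis_threshold Flag chromosomes with strictly more
#'   intrachromosomal fusions than this.
#' @param exclude_chromothripsis Zero out flagged chromosomes in the totals?
#' @param rearrangement_bonus Award +1 point per translocation-evidenced
#'   segment end (the mechanism by which balanced-SV-aware platforms score
#'   higher than CNA-only ones)?
#' @param score_translocations Score unmatched interchromosomal
#'   translocations 1 point each under the LST signature?
#' @return A `ScoreConfig` list.
#' @export
score_config <- function(tai_min = 3e6, tai0_max = 10e6, loh_min = 15e6,
                         lst_min = 10e6, lst_exclusion = 3e6,
                         breakpoint_match_tolerance = 500000,
                         chromothripsis_threshold = 15,
                         exclude_chromothripsis = FALSE,
                         rearrangement_bonus = TRUE,
                         score_translocations = TRUE) {
  stopifnot(tai_min > 0, tai0_max > 0, loh_min > 0, lst_min > 0,
            lst_exclusion > 0, breakpoint_match_tolerance >= 0,
            chromothripsis_threshold >= 0)
  structure(list(tai_min = tai_min, tai0_max = tai0_max, loh_min = loh_min,
                 lst_min = lst_min, lst_exclusion = lst_exclusion,
                 breakpoint_match_tolerance = breakpoint_match_tolerance,
                 chromothripsis_threshold = chromothripsis_threshold,
                 exclude_chromothripsis = exclude_chromothripsis,
                 rearrangement_bonus = rearrangement_bonus,
                 score_translocations = score_translocations),
            class = "ScoreConfig")
}

#' Match rearrangement breakpoints to segment ends
#'
#' Counts how many of a segment's two ends (0, 1 or 2) lie within `tolerance`
#' of a translocation junction among the filtered SVs. Each junction can
#' support at most one segment end and each end at most one junction
#' (greedy nearest-distance matching, no double counting). This is the
#' evidence that a copy-number change arose from a rearrangement — e.g. a
#' deletion flanked by translocations at both breakpoints matches 2.
#'
#' @param segment One-row CNV data.frame or list with `chrom`, `start`, `end`.
#' @param svs Filtered SV data.frame.
#' @param tolerance Max distance in bp.
#' @return Integer 0-2, with attribute `sv_ids`: the ids of the matched
#'   translocation records (consumed, so they are not scored again).
#' @export
match_rearrangement_breakpoints <- function(segment, svs, tolerance = 500000) {
  if (is.null(svs) || nrow(svs) == 0) {
    return(structure(0L, sv_ids = character(0)))
  }
  tr <- svs[svs$sv_type == "translocation", , drop = FALSE]
  if (nrow(tr) == 0) return(structure(0L, sv_ids = character(0)))
  chrom <- norm_chrom(segment$chrom)
  ends <- c(segment$start, segment$end)
  # candidate (end, junction) pairs within tolerance, on this chromosome
  cand <- NULL
  for (j in seq_len(nrow(tr))) {
    for (side in c("a", "b")) {
      if (norm_chrom(tr[[paste0("chrom_", side)]][j]) != chrom) next
      p <- tr[[paste0("pos_", side)]][j]
      for (e in 1:2) {
        d <- abs(ends[e] - p)
        if (d <= tolerance) {
          cand <- rbind(cand, data.frame(end = e, junction = j, dist = d))
        }
      }
    }
  }
  if (is.null(cand)) return(structure(0L, sv_ids = character(0)))
  cand <- cand[order(cand$dist, cand$junction, cand$end), , drop = FALSE]
  used_end <- logical(2)
  used_junction <- logical(nrow(tr))
  ids <- character(0)
  for (i in seq_len(nrow(cand))) {
    e <- cand$end[i]; j <- cand$junction[i]
    if (used_end[e] || used_junction[j]) next
    used_end[e] <- TRUE
    used_junction[j] <- TRUE
    ids <- c(ids, tr$id[j])
  }
  structure(sum(used_end), sv_ids = ids)
}

#' Classify a copy-number/AOH segment into a scar class
#'
#' Applies the scar taxonomy in fixed decision order (first match wins):
#' whole-chromosome segments never score; telomere-anchored segments not
#' involving the centromere are TAI-LOH-1 (losses/AOH >15 Mb), TAI-1
#' (>10 Mb) or TAI-0 (3-10 Mb); remaining losses/AOH >15 Mb are LOH-0/1/2 by
#' genuine breakpoint count; remaining segments >10 Mb with 1 or 2
#' breakpoints are LST-1/LST-2 (duplication-state segments are treated like
#' gains). Intervals below the 3 Mb exclusion never score. A terminal
#' loss >15 Mb that also spans the centromere is not TAI (allelic-imbalance
#' regions must not involve the centromere) and falls through to the LOH
#' branch — a telomere-to-centromere loss with one genuine break is LOH-1.
#'
#' @param segment One-row CNV data.frame or list (`chrom`, `start`, `end`,
#'   `state`).
#' @param geometry Output of [classify_geometry()] for the segment.
#' @param config A [score_config()].
#' @return A scar class name (see [scar_classes()]) or `NULL`.
#' @export
classify_scar <- function(segment, geometry, config = score_config()) {
  len <- segment$end - segment$start + 1
  if (geometry$whole_chromosome) return(NULL)
  if (len < config$lst_exclusion) return(NULL)
  is_loh_state <- segment$state %in% c("loss", "aoh")
  terminal <- geometry$terminal_p || geometry$terminal_q
  if (terminal && !geometry$spans_centromere) {
    if (is_loh_state && len > config$loh_min) return("TAI-LOH-1")
    if (len > config$tai0_max) return("TAI-1")
    if (len > config$tai_min) return("TAI-0")
    return(NULL)
  }
  if (is_loh_state && len > config$loh_min) {
    k <- geometry$cn_breakpoints
    if (k < 0 || k > 2) stop("cn_breakpoints out of range for LOH candidate")
    return(paste0("LOH-", k))
  }
  if (len > config$lst_min) {
    if (geometry$cn_breakpoints == 1) return("LST-1")
    if (geometry$cn_breakpoints == 2) return("LST-2")
  }
  NULL
}

#' Classify a structural variant as a stand-alone scar
#'
#' Balanced or copy-neutral rearrangements invisible to copy-number calling
#' can still be scars: an inversion, duplication or intrachromosomal
#' rearrangement spanning more than the LST minimum is an LST-2 (2 points);
#' an insertion larger than the LST minimum is an LST-3 (3 points); an
#' interchromosomal translocation not already consumed as segment-end
#' evidence contributes 1 point, recorded under LST-1 (config-switchable via
#' `score_translocations`). SV-level deletion and gain records are never
#' scored directly — the CNV file is the copy-number authority.
#'
#' @param sv One-row SV data.frame or list.
#' @param config A [score_config()].
#' @return A scar class name or `NULL`.
#' @export
classify_sv_scar <- function(sv, config = score_config()) {
  intra <- norm_chrom(sv$chrom_a) == norm_chrom(sv$chrom_b)
  if (sv$sv_type == "insertion") {
    if (sv$size > config$lst_min) return("LST-3")
    return(NULL)
  }
  if (intra) {
    span <- if (!is.na(sv$size) && sv$size > 0) sv$size else sv$pos_b - sv$pos_a
    if (sv$sv_type %in% c("inversion", "duplication", "translocation") &&
        span > config$lst_min) {
      return("LST-2")
    }
    return(NULL)
  }
  if (sv$sv_type == "translocation" && config$score_translocations) {
    return("LST-1")
  }
  NULL
}

empty_scar_table <- function() {
  data.frame(scar_class = character(0), signature = character(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             base_points = integer(0), bonus_points = integer(0),
             total_points = integer(0), evidence = character(0),
             stringsAsFactors = FALSE)
}

scar_row <- function(scar_class, chrom, start, end, base, bonus, evidence) {
  data.frame(scar_class = scar_class, signature = scar_signature(scar_class),
             chrom = chrom, start = start, end = end,
             base_points = as.integer(base), bonus_points = as.integer(bonus),
             total_points = as.integer(base + bonus),
             evidence = paste(evidence, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Score one segment, combining scar class and rearrangement evidence
#'
#' Base points come from [classify_scar()]; bonus points (in OGM mode) from
#' [match_rearrangement_breakpoints()] — one extra point per segment end that
#' coincides with a translocation junction. A segment whose class earns no
#' base points but whose ends are translocation-evidenced still emits a scar
#' call, recorded under the nearest LST class with points equal to the bonus:
#' this is how a sub-threshold deletion flanked by translocations scores.
#' Segments below the exclusion size and whole-chromosome segments never
#' score in any mode.
#'
#' @param segment One-row CNV data.frame or list.
#' @param geometry [classify_geometry()] output for the segment.
#' @param svs Filtered SV data.frame (ignored in CNA-only mode).
#' @param config A [score_config()].
#' @param mode `"ogm"` (use SV evidence) or `"cna"` (copy-number only).
#' @return A one-row scar data.frame, or `NULL` if the segment scores 0.
#'   The `sv_ids` attribute lists translocation ids consumed as bonus
#'   evidence.
#' @export
score_segment <- function(segment, geometry, svs = NULL,
                          config = score_config(), mode = c("ogm", "cna")) {
  mode <- match.arg(mode)
  len <- segment$end - segment$start + 1
  if (geometry$whole_chromosome || len < config$lst_exclusion) return(NULL)
  cls <- classify_scar(segment, geometry, config)
  base <- if (is.null(cls)) 0L else scar_weight(cls)
  bonus <- 0L
  sv_ids <- character(0)
  if (mode == "ogm" && isTRUE(config$rearrangement_bonus)) {
    m <- match_rearrangement_breakpoints(segment, svs,
                                         config$breakpoint_match_tolerance)
    bonus <- as.integer(m)
    sv_ids <- attr(m, "sv_ids")
  }
  if (base + bonus == 0) return(NULL)
  if (is.null(cls)) cls <- if (bonus >= 2) "LST-2" else "LST-1"
  out <- scar_row(cls, norm_chrom(segment$chrom), segment$start, segment$end,
                  base, bonus,
                  c(paste0("cnv:", norm_chrom(segment$chrom), ":",
                           segment$start, "-", segment$end), sv_ids))
  attr(out, "sv_ids") <- sv_ids
  out
}

#' Flag chromosomes with possible chromothripsis
#'
#' Counts intrachromosomal fusion events (translocation records with both
#' breakpoints on the same chromosome) per chromosome among the filtered
#' SVs; a chromosome is flagged when the count strictly exceeds the
#' threshold (default 15). Flagged chromosomes are reported so the user can
#' decide whether to keep their scar points; with
#' `exclude_chromothripsis = TRUE` in the [score_config()] they contribute 0.
#'
#' @param svs Filtered SV data.frame.
#' @param config A [score_config()].
#' @return A data.frame with columns `chrom`, `fusions`, `flagged`.
#' @export
detect_chromothripsis <- function(svs, config = score_config()) {
  if (is.null(svs) || nrow(svs) == 0) {
    return(data.frame(chrom = character(0), fusions = integer(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  intra <- svs$sv_type == "translocation" &
    norm_chrom(svs$chrom_a) == norm_chrom(svs$chrom_b)
  counts <- table(norm_chrom(svs$chrom_a[intra]))
  data.frame(chrom = names(counts), fusions = as.integer(counts),
             flagged = as.integer(counts) > config$chromothripsis_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
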