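new_hrd_result <- function(mode, scars, per_chromosome, signature_totals,
                           signature_counts, total, chromothripsis,
                           excluded_chroms) {
  structure(list(mode = mode, total = as.integer(total),
                 signature_totals = signature_totals,
                 signature_counts = signature_counts,
                 per_chromosome = per_chromosome,
                 chromothripsis = chromothripsis,
                 excluded_chroms = excluded_chroms,
                 scars = scars),
            class = "HRDResult")
}

aggregate_scars <- function(scars, chromothripsis, mode, exclude = FALSE) {
  flagged <- chromothripsis$chrom[chromothripsis$flagged]
  excluded <- if (exclude) flagged else character(0)
  counted <- scars[!scars$chrom %in% excluded, , drop = FALSE]
  per_chrom <- if (nrow(scars) == 0) {
    data.frame(chrom = character(0), points = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(total_points ~ chrom, data = scars, FUN = sum)
    names(agg) <- c("chrom", "points")
    agg[order(agg$chrom), , drop = FALSE]
  }
  rownames(per_chrom) <- NULL
  sig_tot <- vapply(c("LOH", "TAI", "LST"), function(s) {
    as.integer(sum(counted$total_points[counted$signature == s]))
  }, integer(1))
  sig_cnt <- vapply(c("LOH", "TAI", "LST"), function(s) {
    as.integer(sum(counted$signature == s))
  }, integer(1))
  new_hrd_result(mode = mode, scars = scars, per_chromosome = per_chrom,
                 signature_totals = sig_tot, signature_counts = sig_cnt,
                 total = sum(counted$total_points),
                 chromothripsis = chromothripsis, excluded_chroms = excluded)
}

#' Compute the HRD score from SV, CNV and aneuploidy calls
#'
#' Runs the full scoring pipeline: filter SVs (confidence, control-database
#' frequency, molecule support) and CNV segments (confidence); optionally
#' drop SVs in masked regions; stitch fragmented same-state CNV segments
#' within the stitch distance; expand aneuploidies to whole-chromosome
#' segments (which never score); classify each segment's geometry and scar
#' class; in OGM mode, add one bonus point per segment end evidenced by a
#' translocation junction and score unconsumed balanced SVs (large
#' inversions, insertions, translocations) as stand-alone scars; flag
#' chromosomes with more intrachromosomal fusions than the chromothripsis
#' threshold; and aggregate points per chromosome, per signature and in
#' total. In CNA-only mode (`mode = "cna"`) the SV input is ignored
#' entirely, emulating what a chromosomal-microarray or NGS-panel platform
#' can see, so OGM-mode totals are always at least the CNA-only totals on
#' the same copy-number input.
#'
#' @param svs SV data.frame ([read_sv_table()] columns) or `NULL`.
#' @param cnvs CNV data.frame ([read_cnv_table()] columns) or `NULL`.
#' @param aneuploidies Aneuploidy data.frame or `NULL`.
#' @param genome A [load_genome()] build or a build name / annotation path.
#' @param filter_config A [filter_config()].
#' @param score_config A [score_config()].
#' @param mode `"ogm"` or `"cna"`.
#' @param stitch_gap CNV stitch distance in bp (also the mask-contiguity
#'   distance for effective centromeric/telomeric regions).
#' @return An `HRDResult`: scar table, per-chromosome points, per-signature
#'   point totals and event counts, overall total, chromothripsis flags and
#'   excluded chromosomes.
#' @examples
#' g <- load_genome("GRCh38")
#' cnv <- data.frame(chrom = "4", start = 190214555 - 5e6 + 1, end = 190214555,
#'                   state = "loss", confidence = 0.995)
#' compute_hrd(cnvs = cnv, genome = g)$total  # one TAI-0 scar
#' @export
compute_hrd <- function(svs = NULL, cnvs = NULL, aneuploidies = NULL,
                        genome = "GRCh38",
                        filter_config = hrdscar::filter_config(),
                        score_config = hrdscar::score_config(),
                        mode = c("ogm", "cna"), stitch_gap = 500000) {
  mode <- match.arg(mode)
  if (!inherits(genome, "GenomeBuild")) genome <- load_genome(genome)
  svs <- if (is.null(svs)) empty_sv_table() else as_sv_table(svs)
  cnvs <- if (is.null(cnvs)) empty_cnv_table() else as_cnv_table(cnvs)
  if (is.null(aneuploidies)) aneuploidies <- empty_aneuploidy_table()

  svs_f <- filter_svs(svs, filter_config)
  if (isTRUE(filter_config$apply_mask_filter)) {
    svs_f <- apply_mask_filter(svs_f, genome)
  }
  cnvs_f <- filter_cnvs(cnvs, filter_config)
  segments <- stitch_segments(cnvs_f, max_gap = stitch_gap)
  segments <- rbind(segments[, names(empty_cnv_table())],
                    aneuploidy_to_segments(aneuploidies, genome))

  sv_evidence <- if (mode == "ogm") svs_f else empty_sv_table()
  scars <- list()
  consumed <- character(0)
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, , drop = FALSE]
    geo <- classify_geometry(seg, genome, max_gap = stitch_gap)
    sc <- score_segment(seg, geo, sv_evidence, score_config, mode)
    if (!is.null(sc)) {
      consumed <- c(consumed, attr(sc, "sv_ids"))
      scars[[length(scars) + 1]] <- sc
    }
  }
  if (mode == "ogm") {
    remaining <- svs_f[!svs_f$id %in% consumed, , drop = FALSE]
    for (i in seq_len(nrow(remaining))) {
      sv <- remaining[i, , drop = FALSE]
      cls <- classify_sv_scar(sv, score_config)
      if (!is.null(cls)) {
        scars[[length(scars) + 1]] <- scar_row(
          cls, norm_chrom(sv$chrom_a), sv$pos_a,
          if (norm_chrom(sv$chrom_a) == norm_chrom(sv$chrom_b)) sv$pos_b else sv$pos_a,
          scar_weight(cls), 0L, paste0("sv:", sv$id))
      }
    }
  }
  scar_tab <- if (length(scars) == 0) empty_scar_table() else {
    out <- do.call(rbind, scars)
    rownames(out) <- NULL
    attr(out, "sv_ids") <- NULL
    out
  }
  chromo <- detect_chromothripsis(if (mode == "ogm") svs_f else empty_sv_table(),
                                  score_config)
  aggregate_scars(scar_tab, chromo, mode,
                  exclude = isTRUE(score_config$exclude_chromothripsis))
}

#' @export
print.HRDResult <- function(x, ...) {
  cat("HRD score (", toupper(x$mode), " mode): ", x$total, "\n", sep = "")
  cat("  signatures (points): ",
      paste(names(x$signature_totals), x$signature_totals, sep = "=",
            collapse = "  "), "\n", sep = "")
  cat("  signatures (events): ",
      paste(names(x$signature_counts), x$signature_counts, sep = "=",
            collapse = "  "), "\n", sep = "")
  if (nrow(x$scars) > 0) {
    cat("  scars:\n")
    print(x$scars[, c("scar_class", "chrom", "start", "end", "base_points",
                      "bonus_points", "total_points")], row.names = FALSE)
  }
  flagged <- x$chromothripsis$chrom[x$chromothripsis$flagged]
  if (length(flagged) > 0) {
    cat("  possible chromothripsis (fusion count > threshold): ",
        paste(flagged, collapse = ", "), "\n", sep = "")
  }
  if (length(x$excluded_chroms) > 0) {
    cat("  excluded chromosomes: ", paste(x$excluded_chroms, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
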