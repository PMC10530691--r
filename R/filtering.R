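#' Variant-retention configuration
#'
#' Defaults follow the OGM rare-variant pipeline's recommended settings:
#' per-type minimum confidence scores (insertion 0, deletion 0, inversion
#' 0.01, duplication -1, translocation 0), a copy-number confidence floor of
#' 0.99, retention only of variants absent from the control-sample database
#' (`max_control_frequency = 0`), and at least five molecules spanning the SV
#' breakpoints. All comparisons are inclusive at the threshold, so a variant
#' at exactly the recommended score is retained. The difficult-to-map-region
#' mask filter is off by default, matching the recommended analysis setting
#' for scar scoring; enable `apply_mask_filter` to drop SVs with a breakpoint
#' inside a masked region.
#'
#' @param confidence_thresholds Named numeric vector, minimum confidence per
#'   SV type; must cover the full type vocabulary.
#' @param cnv_confidence Minimum CNV segment confidence in \[0, 1\].
#' @param max_control_frequency Maximum tolerated control-database frequency.
#' @param min_molecule_support Minimum number of spanning molecules.
#' @param apply_mask_filter Drop SVs with a breakpoint in a masked region?
#' @return A `FilterConfig` list.
#' @export
filter_config <- function(confidence_thresholds = c(insertion = 0, deletion = 0,
                                                    inversion = 0.01,
                                                    duplication = -1,
                                                    translocation = 0),
                          cnv_confidence = 0.99,
                          max_control_frequency = 0,
                          min_molecule_support = 5,
                          apply_mask_filter = FALSE) {
  missing <- setdiff(SV_TYPES, names(confidence_thresholds))
  if (length(missing) > 0) {
    stop("confidence_thresholds must cover every sv_type; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(max_control_frequency >= 0, max_control_frequency <= 1,
            min_molecule_support >= 0, is.logical(apply_mask_filter))
  structure(list(confidence_thresholds = confidence_thresholds,
                 cnv_confidence = cnv_confidence,
                 max_control_frequency = max_control_frequency,
                 min_molecule_support = min_molecule_support,
                 apply_mask_filter = apply_mask_filter),
            class = "FilterConfig")
}

#' Filter structural-variant calls
#'
#' Retains exactly the SVs with confidence at or above the configured
#' threshold for their type, control-database frequency at or below the
#' maximum, and molecule support at or above the minimum. Input order is
#' preserved; each removal is attributable to one named rule (returned in the
#' `"removed"` attribute and, with `verbose = TRUE`, logged via `message()`).
#'
#' @param svs SV data.frame from [read_sv_table()] / [read_sv_vcf()].
#' @param config A [filter_config()].
#' @param verbose Log each removed variant and the rule that removed it.
#' @return The retained subset, with attribute `removed`: a data.frame of
#'   `id` and `rule` for every dropped record.
#' @export
filter_svs <- function(svs, config = filter_config(), verbose = FALSE) {
  stopifnot(inherits(config, "FilterConfig"))
  if (nrow(svs) == 0) return(svs)
  unknown <- setdiff(unique(svs$sv_type), names(config$confidence_thresholds))
  if (length(unknown) > 0) {
    stop("no confidence threshold configured for sv_type: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  thr <- config$confidence_thresholds[svs$sv_type]
  rule <- rep(NA_character_, nrow(svs))
  rule[is.na(rule) & svs$confidence < thr] <- "confidence"
  rule[is.na(rule) & svs$control_frequency > config$max_control_frequency] <-
    "control_frequency"
  rule[is.na(rule) & svs$molecule_support < config$min_molecule_support] <-
    "molecule_support"
  keep <- is.na(rule)
  removed <- data.frame(id = svs$id[!keep], rule = rule[!keep],
                        stringsAsFactors = FALSE)
  if (verbose && nrow(removed) > 0) {
    for (i in seq_len(nrow(removed))) {
      message("filter_svs: removed ", removed$id[i], " (", removed$rule[i], ")")
    }
  }
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Filter copy-number / AOH segments on call confidence
#'
#' Retains segments with confidence at or above `cnv_confidence`. AOH
#' segments whose caller supplied no confidence (`NA`) are treated as
#' passing, since AOH calls are not covered by the copy-number confidence
#' scale; this is logged when it happens.
#'
#' @param cnvs CNV data.frame from [read_cnv_table()].
#' @inheritParams filter_svs
#' @return The retained subset with a `removed` attribute as in [filter_svs()].
#' @export
filter_cnvs <- function(cnvs, config = filter_config(), verbose = FALSE) {
  stopifnot(inherits(config, "FilterConfig"))
  if (nrow(cnvs) == 0) return(cnvs)
  no_conf_aoh <- is.na(cnvs$confidence) & cnvs$state == "aoh"
  if (any(no_conf_aoh) && verbose) {
    message("filter_cnvs: ", sum(no_conf_aoh),
            " AOH segment(s) without confidence treated as passing")
  }
  keep <- no_conf_aoh | (!is.na(cnvs$confidence) &
                           cnvs$confidence >= config$cnv_confidence)
  removed <- data.frame(
    id = paste0(cnvs$chrom[!keep], ":", cnvs$start[!keep], "-", cnvs$end[!keep]),
    rule = "cnv_confidence", stringsAsFactors = FALSE)
  if (verbose && nrow(removed) > 0) {
    for (i in seq_len(nrow(removed))) {
      message("filter_cnvs: removed ", removed$id[i], " (cnv_confidence)")
    }
  }
  out <- cnvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Remove SVs with a breakpoint in a masked region
#'
#' Implements the difficult-to-map-region mask filter. The default scoring
#' pipeline does not call this (the mask filter is off for scar analysis);
#' it runs only when `apply_mask_filter` is enabled in the [filter_config()].
#'
#' @param svs SV data.frame.
#' @param genome A [load_genome()] build supplying the masked regions.
#' @return The subset of `svs` with neither breakpoint inside a mask.
#' @export
apply_mask_filter <- function(svs, genome) {
  if (nrow(svs) == 0) return(svs)
  in_mask <- function(chrom, pos) {
    mapply(function(c, p) {
      ann <- genome$chroms[[norm_chrom(c)]]
      if (is.null(ann) || nrow(ann$masks) == 0) return(FALSE)
      any(ann$masks[, 1] <= p & p <= ann$masks[, 2])
    }, chrom, pos, USE.NAMES = FALSE)
  }
  keep <- !(in_mask(svs$chrom_a, svs$pos_a) | in_mask(svs$chrom_b, svs$pos_b))
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
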