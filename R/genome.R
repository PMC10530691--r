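#' @importFrom IRanges IRanges reduce start end
NULL

# Strip "chr" prefixes and upper-case X/Y so "chr1"/"1" and "x"/"X" compare equal.
norm_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  toupper(x)
}

merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]))
  cbind(start = IRanges::start(ir), end = IRanges::end(ir))
}

new_chrom_annotation <- function(name, length, cen_start, cen_end, masks = NULL) {
  length <- as.numeric(length)
  cen_start <- as.numeric(cen_start)
  cen_end <- as.numeric(cen_end)
  if (is.na(length) || length <= 0) {
    stop("chromosome ", name, ": length must be a positive number", call. = FALSE)
  }
  if (is.na(cen_start) || is.na(cen_end) || cen_start < 1 || cen_start > cen_end ||
      cen_end > length) {
    stop("chromosome ", name, ": centromere [", cen_start, ", ", cen_end,
         "] must satisfy 1 <= start <= end <= length (", length, ")", call. = FALSE)
  }
  masks <- merge_intervals(masks)
  if (nrow(masks) > 0 && (any(masks[, 1] < 1) || any(masks[, 2] > length))) {
    stop("chromosome ", name, ": masked region outside [1, length]", call. = FALSE)
  }
  list(name = name, length = length, centromere = c(cen_start, cen_end), masks = masks)
}

#' Load a genome build (chromosome lengths, centromeres, masked regions)
#'
#' A genome build is the spatial frame for scar classification: it answers
#' whether a segment is telomere-anchored, spans the centromere, or covers a
#' whole chromosome. `"GRCh38"` loads the bundled annotation (24 chromosomes,
#' cytoband-derived centromere intervals, and an approximate masked-region
#' catalog covering telomeric assembly gaps and acrocentric p-arms). Any
#' other value is taken as the path of an annotation TSV in the same format.
#'
#' The TSV has a header line `chrom length cen_start cen_end`. Rows with four
#' fields define a chromosome; rows with three fields (`chrom mask_start
#' mask_end`) attach a masked region — an interval where the upstream
#' CNV-calling algorithm has reduced sensitivity — to an already defined
#' chromosome. Overlapping masks are merged on load. Coordinates are 1-based
#' closed intervals throughout the package.
#'
#' @param source `"GRCh38"` or the path of an annotation TSV.
#' @return An object of class `GenomeBuild`: a list with `build_name` and
#'   `chroms`, a named list of per-chromosome annotations (`name`, `length`,
#'   `centromere`, `masks`).
#' @examples
#' g <- load_genome("GRCh38")
#' length(g$chroms)
#' @export
load_genome <- function(source = "GRCh38") {
  stopifnot(is.character(source), length(source) == 1)
  build_name <- source
  if (identical(source, "GRCh38")) {
    path <- system.file("extdata", "grch38_annotation.tsv", package = "hrdscar")
  } else {
    path <- source
    build_name <- sub("\\.[^.]*$", "", basename(source))
    if (!file.exists(path)) {
      stop("genome annotation not found: '", source,
           "' is neither a bundled build name nor an existing file", call. = FALSE)
    }
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("annotation file '", path, "' has no data rows", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("chrom", "length", "cen_start", "cen_end"))) {
    stop("annotation file '", path,
         "': expected header 'chrom\\tlength\\tcen_start\\tcen_end'", call. = FALSE)
  }
  chrom_rows <- list()
  mask_rows <- list()
  for (i in seq.int(2, length(lines))) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals)) {
      stop("annotation file '", path, "', line ", i, ": non-numeric field", call. = FALSE)
    }
    key <- norm_chrom(f[1])
    if (length(f) == 4) {
      if (key %in% names(chrom_rows)) {
        stop("annotation file '", path, "', line ", i, ": duplicate chromosome '",
             key, "'", call. = FALSE)
      }
      chrom_rows[[key]] <- vals
    } else if (length(f) == 3) {
      mask_rows[[length(mask_rows) + 1]] <- c(key, vals)
    } else {
      stop("annotation file '", path, "', line ", i,
           ": expected 4 fields (chromosome) or 3 (mask), got ", length(f), call. = FALSE)
    }
  }
  masks_by_chrom <- list()
  for (m in mask_rows) {
    key <- m[[1]]
    if (!key %in% names(chrom_rows)) {
      stop("annotation file '", path, "': mask row for undefined chromosome '",
           key, "'", call. = FALSE)
    }
    masks_by_chrom[[key]] <- rbind(masks_by_chrom[[key]],
                                   as.numeric(m[2:3]))
  }
  chroms <- lapply(names(chrom_rows), function(key) {
    v <- chrom_rows[[key]]
    new_chrom_annotation(key, v[1], v[2], v[3], masks_by_chrom[[key]])
  })
  names(chroms) <- names(chrom_rows)
  structure(list(build_name = build_name, chroms = chroms), class = "GenomeBuild")
}

#' @export
print.GenomeBuild <- function(x, ...) {
  n_mask <- sum(vapply(x$chroms, function(ch) nrow(ch$masks), integer(1)))
  cat("GenomeBuild '", x$build_name, "': ", length(x$chroms),
      " chromosomes, ", n_mask, " masked regions\n", sep = "")
  invisible(x)
}

get_chrom <- function(genome, chrom) {
  key <- norm_chrom(chrom)
  ann <- genome$chroms[[key]]
  if (is.null(ann)) {
    stop("chromosome '", chrom, "' not in genome build '", genome$build_name, "'",
         call. = FALSE)
  }
  ann
}

# Grow [lo, hi] through masks whose gap to the current region is <= max_gap,
# repeating until no further mask attaches. Monotone: adding masks never
# shrinks the result.
extend_through_masks <- function(lo, hi, masks, max_gap) {
  if (nrow(masks) == 0) return(c(lo, hi))
  repeat {
    # gap between a mask and [lo, hi]; 0 when overlapping/abutting
    gaps <- pmax(masks[, 1] - hi - 1, lo - masks[, 2] - 1, 0)
    touching <- gaps <= max_gap
    new_lo <- min(lo, masks[touching, 1])
    new_hi <- max(hi, masks[touching, 2])
    if (new_lo == lo && new_hi == hi) break
    lo <- new_lo
    hi <- new_hi
  }
  c(lo, hi)
}

#' Effective terminal region of a chromosome arm
#'
#' The telomere-anchored interval used to decide whether a segment is
#' "terminal". It starts as the single terminal base (position 1 on p, the
#' chromosome length on q) and is extended inward through any masked regions
#' contiguous with the chromosome end, because copy-number calls cannot be
#' expected to reach into regions where the caller has reduced sensitivity.
#' "Contiguous" means a gap no larger than `max_gap` (shared with the CNV
#' stitching distance).
#'
#' @param chrom A per-chromosome annotation from a [load_genome()] build.
#' @param arm `"p"` or `"q"`.
#' @param max_gap Maximum gap (bp) for a mask to count as contiguous.
#' @return Numeric length-2 vector `c(start, end)`, a 1-based closed interval.
#' @export
effective_terminal_region <- function(chrom, arm = c("p", "q"), max_gap = 500000) {
  arm <- match.arg(arm)
  anchor <- if (arm == "p") 1 else chrom$length
  extend_through_masks(anchor, anchor, chrom$masks, max_gap)
}

#' Effective centromeric region of a chromosome
#'
#' The centromere interval extended through masked regions contiguous with it
#' on either side (gap at most `max_gap`). Segment ends falling inside this
#' region are not counted as genuine chromosome breakpoints.
#'
#' @inheritParams effective_terminal_region
#' @return Numeric length-2 vector `c(start, end)`.
#' @export
effective_centromeric_region <- function(chrom, max_gap = 500000) {
  extend_through_masks(chrom$centromere[1], chrom$centromere[2], chrom$masks, max_gap)
}
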