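SV_TYPES <- c("insertion", "deletion", "duplication", "inversion", "translocation")
CNV_STATES <- c("gain", "loss", "aoh")
ANEUPLOIDY_EVENTS <- c("gain", "loss", "whole_chrom_aoh")

read_tsv_strict <- function(path, required, optional = character(0), aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", blank.lines.skip = TRUE)
  if (!is.null(aliases)) {
    for (canon in names(aliases)) {
      hit <- which(names(df) == aliases[[canon]])
      if (length(hit) == 1) names(df)[hit] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "': missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

num_col <- function(df, col, path, allow_na = FALSE) {
  raw <- df[[col]]
  out <- suppressWarnings(as.numeric(raw))
  raw_t <- trimws(raw)
  empty <- is.na(raw) | raw_t == "" | raw_t == "NA"
  bad <- is.na(out) & !empty
  if (allow_na) out[empty] <- NA_real_ else bad <- bad | empty
  if (any(bad)) {
    stop("file '", path, "', line ", which(bad)[1] + 1L,
         ": cannot parse '", raw[which(bad)[1]], "' in column '", col, "'",
         call. = FALSE)
  }
  out
}

vocab_col <- function(df, col, vocab, path) {
  out <- tolower(trimws(df[[col]]))
  bad <- !out %in% vocab
  if (any(bad)) {
    stop("file '", path, "', line ", which(bad)[1] + 1L, ": unknown ", col, " '",
         df[[col]][which(bad)[1]], "' (expected one of ",
         paste(vocab, collapse = ", "), ")", call. = FALSE)
  }
  out
}

#' Read a structural-variant call table
#'
#' Reads the package's SMAP-like tab-separated SV dialect: one row per
#' structural variant with a paired breakpoint (`chrom_a`/`pos_a`,
#' `chrom_b`/`pos_b`), a type from the closed vocabulary *insertion,
#' deletion, duplication, inversion, translocation*, a size in bp (0 for
#' interchromosomal translocations), a confidence score in \[-1, 1\], the
#' number of molecules spanning the breakpoints, and the fraction of a
#' control-sample database carrying the variant. The reader is strict: every
#' data row is parsed or the read fails naming the offending line; no row is
#' silently dropped. Real-world headers can be adapted with `aliases`
#' (e.g. `aliases = c(confidence = "Confidence")`).
#'
#' @param path Path of a tab-separated file with header
#'   `id chrom_a pos_a chrom_b pos_b sv_type size confidence molecule_support
#'   control_frequency`.
#' @param aliases Optional named character vector mapping canonical column
#'   names to the names actually present in the file.
#' @return A data.frame of SV calls, one row per record.
#' @export
read_sv_table <- function(path, aliases = NULL) {
  cols <- c("id", "chrom_a", "pos_a", "chrom_b", "pos_b", "sv_type", "size",
            "confidence", "molecule_support", "control_frequency")
  df <- read_tsv_strict(path, cols, aliases = aliases)
  out <- data.frame(
    id = as.character(df$id),
    chrom_a = norm_chrom(df$chrom_a),
    pos_a = num_col(df, "pos_a", path),
    chrom_b = norm_chrom(df$chrom_b),
    pos_b = num_col(df, "pos_b", path),
    sv_type = vocab_col(df, "sv_type", SV_TYPES, path),
    size = num_col(df, "size", path),
    confidence = num_col(df, "confidence", path),
    molecule_support = num_col(df, "molecule_support", path),
    control_frequency = num_col(df, "control_frequency", path),
    stringsAsFactors = FALSE
  )
  bad <- out$chrom_a == out$chrom_b & out$pos_a > out$pos_b
  if (any(bad)) {
    stop("file '", path, "', line ", which(bad)[1] + 1L,
         ": intrachromosomal record with pos_a > pos_b", call. = FALSE)
  }
  validate_sv_calls(out)
}

validate_sv_calls <- function(svs) {
  stopifnot(is.data.frame(svs))
  if (nrow(svs) == 0) return(svs)
  if (any(svs$confidence < -1 | svs$confidence > 1, na.rm = TRUE)) {
    stop("SV confidence outside [-1, 1]", call. = FALSE)
  }
  if (any(svs$control_frequency < 0 | svs$control_frequency > 1, na.rm = TRUE)) {
    stop("SV control_frequency outside [0, 1]", call. = FALSE)
  }
  svs
}

#' Read a copy-number / AOH segment table
#'
#' Tab-separated with header `chrom start end state confidence` and an
#' optional `copy_number` column. `state` is one of *gain*, *loss*, *aoh*
#' (absence of heterozygosity, i.e. copy-neutral LOH as called by the
#' upstream platform). Filtering happens later; this reader only validates.
#'
#' @inheritParams read_sv_table
#' @return A data.frame of CNV/AOH segments.
#' @export
read_cnv_table <- function(path, aliases = NULL) {
  df <- read_tsv_strict(path, c("chrom", "start", "end", "state", "confidence"),
                        optional = "copy_number", aliases = aliases)
  out <- data.frame(
    chrom = norm_chrom(df$chrom),
    start = num_col(df, "start", path),
    end = num_col(df, "end", path),
    state = vocab_col(df, "state", CNV_STATES, path),
    confidence = num_col(df, "confidence", path, allow_na = TRUE),
    stringsAsFactors = FALSE
  )
  out$copy_number <- if ("copy_number" %in% names(df)) {
    num_col(df, "copy_number", path, allow_na = TRUE)
  } else NA_real_
  bad <- out$start > out$end
  if (any(bad)) {
    stop("file '", path, "', line ", which(bad)[1] + 1L, ": start > end",
         call. = FALSE)
  }
  out
}

#' Read an aneuploidy call table
#'
#' Tab-separated with header `chrom event fraction`; `event` is one of
#' *gain*, *loss*, *whole_chrom_aoh* and `fraction` is the cell fraction in
#' (0, 1\]. Aneuploidies are whole-chromosome events; they are carried
#' through the pipeline but contribute no scar points.
#'
#' @inheritParams read_sv_table
#' @return A data.frame of aneuploidy calls.
#' @export
read_aneuploidy_table <- function(path, aliases = NULL) {
  df <- read_tsv_strict(path, c("chrom", "event", "fraction"), aliases = aliases)
  out <- data.frame(
    chrom = norm_chrom(df$chrom),
    event = vocab_col(df, "event", ANEUPLOIDY_EVENTS, path),
    fraction = num_col(df, "fraction", path),
    stringsAsFactors = FALSE
  )
  bad <- out$fraction <= 0 | out$fraction > 1
  if (any(bad)) {
    stop("file '", path, "', line ", which(bad)[1] + 1L,
         ": fraction outside (0, 1]", call. = FALSE)
  }
  out
}

# Canonicalize a hand-constructed CNV data.frame: required columns present,
# chromosome names normalized, optional columns filled with NA.
as_cnv_table <- function(df) {
  req <- c("chrom", "start", "end", "state")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("CNV input missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"confidence" %in% names(df)) df$confidence <- 1
  if (!"copy_number" %in% names(df)) df$copy_number <- NA_real_
  df$chrom <- norm_chrom(df$chrom)
  df$state <- tolower(df$state)
  bad <- !df$state %in% CNV_STATES
  if (any(bad)) {
    stop("unknown CNV state '", df$state[which(bad)[1]], "'", call. = FALSE)
  }
  if (any(df$start > df$end)) stop("CNV segment with start > end", call. = FALSE)
  df[, c("chrom", "start", "end", "state", "confidence", "copy_number")]
}

as_sv_table <- function(df) {
  req <- c("chrom_a", "pos_a", "chrom_b", "pos_b", "sv_type")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("SV input missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(df)) df$id <- paste0("sv", seq_len(nrow(df)))
  if (!"size" %in% names(df)) {
    df$size <- ifelse(df$chrom_a == df$chrom_b, df$pos_b - df$pos_a, 0)
  }
  if (!"confidence" %in% names(df)) df$confidence <- 1
  if (!"molecule_support" %in% names(df)) df$molecule_support <- Inf
  if (!"control_frequency" %in% names(df)) df$control_frequency <- 0
  df$chrom_a <- norm_chrom(df$chrom_a)
  df$chrom_b <- norm_chrom(df$chrom_b)
  df$sv_type <- tolower(df$sv_type)
  bad <- !df$sv_type %in% SV_TYPES
  if (any(bad)) {
    stop("unknown sv_type '", df$sv_type[which(bad)[1]], "'", call. = FALSE)
  }
  validate_sv_calls(df[, names(empty_sv_table())])
}

empty_sv_table <- function() {
  data.frame(id = character(0), chrom_a = character(0), pos_a = numeric(0),
             chrom_b = character(0), pos_b = numeric(0), sv_type = character(0),
             size = numeric(0), confidence = numeric(0),
             molecule_support = numeric(0), control_frequency = numeric(0),
             stringsAsFactors = FALSE)
}

empty_cnv_table <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             state = character(0), confidence = numeric(0),
             copy_number = numeric(0), stringsAsFactors = FALSE)
}

empty_aneuploidy_table <- function() {
  data.frame(chrom = character(0), event = character(0), fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write (and read back) an HRD scoring result
#'
#' `format = "json"` writes the full [compute_hrd()] result as a JSON
#' document that `read_result()` restores exactly (every scar field and every
#' score round-trips); the document is deterministic — identical results
#' produce byte-identical files. `format = "tsv"` writes one scar per row
#' with `#`-prefixed summary lines (mode, total, per-signature and
#' per-chromosome points, chromothripsis flags) on top.
#'
#' @param result An `HRDResult` from [compute_hrd()].
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `result`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "HRDResult"))
  if (format == "json") {
    doc <- list(
      mode = result$mode,
      total = result$total,
      signature_totals = as.list(result$signature_totals),
      signature_counts = as.list(result$signature_counts),
      per_chromosome = result$per_chromosome,
      chromothripsis = result$chromothripsis,
      excluded_chroms = I(result$excluded_chroms),
      scars = result$scars
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# mode\t", result$mode),
      paste0("# total\t", result$total),
      paste0("# signature\t", paste(names(result$signature_totals),
                                    result$signature_totals, sep = "=", collapse = "\t")),
      paste0("# chromosome\t", paste(result$per_chromosome$chrom,
                                     result$per_chromosome$points, sep = "=",
                                     collapse = "\t")),
      paste0("# chromothripsis\t",
             paste(result$chromothripsis$chrom[result$chromothripsis$flagged],
                   collapse = "\t")),
      paste0("# excluded\t", paste(result$excluded_chroms, collapse = "\t"))
    ), con)
    utils::write.table(result$scars, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scars <- doc$scars
  if (length(scars) == 0) scars <- empty_scar_table()
  chromo <- doc$chromothripsis
  if (length(chromo) == 0) {
    chromo <- data.frame(chrom = character(0), fusions = numeric(0),
                         flagged = logical(0), stringsAsFactors = FALSE)
  }
  per_chrom <- doc$per_chromosome
  if (length(per_chrom) == 0) {
    per_chrom <- data.frame(chrom = character(0), points = numeric(0),
                            stringsAsFactors = FALSE)
  }
  new_hrd_result(
    mode = doc$mode,
    scars = scars,
    per_chromosome = per_chrom,
    signature_totals = unlist(doc$signature_totals),
    signature_counts = unlist(doc$signature_counts),
    total = doc$total,
    chromothripsis = chromo,
    excluded_chroms = as.character(unlist(doc$excluded_chroms))
  )
}
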