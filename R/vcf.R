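#' Read structural variants from a VCF
#'
#' Accepts a VCF 4.2 file with `SVTYPE` INFO records (DEL, DUP, INS, INV,
#' BND) and converts them to the same records as [read_sv_table()]. Breakend
#' (BND) records are resolved pairwise into single translocation records; a
#' BND without its mate is an error. VCFs carry no OGM-specific molecule
#' support, confidence or control-database frequency, so those fields default
#' to pass-through values (`confidence = 1`, `molecule_support = Inf`,
#' `control_frequency = 0`) that survive every filter; a warning notes the
#' weaker filtering so it stays auditable.
#'
#' Requires the VariantAnnotation package.
#'
#' @param path Path of a VCF file.
#' @return A data.frame of SV calls with the [read_sv_table()] columns.
#' @export
read_sv_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_sv_vcf() requires the VariantAnnotation package", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  if (!"SVTYPE" %in% names(info)) {
    stop("VCF '", path, "' has no SVTYPE INFO field", call. = FALSE)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- norm_chrom(as.character(GenomicRanges::seqnames(rr)))
  pos <- as.numeric(GenomicRanges::start(rr))
  ids <- names(rr)
  svtype <- toupper(as.character(info$SVTYPE))
  alt <- vapply(seq_along(rr), function(i) {
    as.character(unlist(rr$ALT[i]))[1]
  }, character(1))

  get_num <- function(field, i) {
    if (!field %in% names(info)) return(NA_real_)
    v <- info[[field]][[i]]
    v <- suppressWarnings(as.numeric(unlist(v))[1])
    v
  }

  type_map <- c(DEL = "deletion", DUP = "duplication", INS = "insertion",
                INV = "inversion")
  rows <- list()
  bnd_idx <- which(svtype == "BND")
  simple_idx <- which(svtype %in% names(type_map))
  unknown <- setdiff(seq_along(svtype), c(bnd_idx, simple_idx))
  if (length(unknown) > 0) {
    stop("VCF '", path, "': unsupported SVTYPE '", svtype[unknown[1]],
         "' in record ", ids[unknown[1]], call. = FALSE)
  }

  for (i in simple_idx) {
    svlen <- abs(get_num("SVLEN", i))
    end <- get_num("END", i)
    if (is.na(end)) end <- if (!is.na(svlen)) pos[i] + svlen - 1 else pos[i]
    size <- if (!is.na(svlen)) svlen else end - pos[i] + 1
    rows[[length(rows) + 1]] <- data.frame(
      id = ids[i], chrom_a = chrom[i], pos_a = pos[i], chrom_b = chrom[i],
      pos_b = if (svtype[i] == "INS") pos[i] else end,
      sv_type = unname(type_map[svtype[i]]), size = size,
      confidence = 1, molecule_support = Inf, control_frequency = 0,
      stringsAsFactors = FALSE)
  }

  if (length(bnd_idx) > 0) {
    bnd_re <- "[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]"
    m <- regexpr(bnd_re, alt[bnd_idx], perl = TRUE)
    if (any(m == -1L)) {
      bad <- bnd_idx[which(m == -1L)[1]]
      stop("VCF '", path, "': cannot parse BND ALT '", alt[bad], "' in record ",
           ids[bad], call. = FALSE)
    }
    mate <- regmatches(alt[bnd_idx], m)
    mate_chrom <- norm_chrom(sub(paste0("^", bnd_re, "$"), "\\1", mate,
                                 perl = TRUE))
    mate_pos <- as.numeric(sub(paste0("^", bnd_re, "$"), "\\2", mate,
                               perl = TRUE))
    key_self <- paste(chrom[bnd_idx], pos[bnd_idx], sep = ":")
    key_mate <- paste(mate_chrom, mate_pos, sep = ":")
    pair_key <- ifelse(key_self < key_mate,
                       paste(key_self, key_mate, sep = "|"),
                       paste(key_mate, key_self, sep = "|"))
    for (k in unique(pair_key)) {
      members <- which(pair_key == k)
      if (length(members) != 2) {
        stop("VCF '", path, "': BND record ", ids[bnd_idx[members[1]]],
             " has no mate record", call. = FALSE)
      }
      i <- bnd_idx[members[1]]
      ca <- chrom[i]; pa <- pos[i]
      cb <- mate_chrom[members[1]]; pb <- mate_pos[members[1]]
      if (ca == cb && pa > pb) { tmp <- pa; pa <- pb; pb <- tmp }
      rows[[length(rows) + 1]] <- data.frame(
        id = ids[i], chrom_a = ca, pos_a = pa, chrom_b = cb, pos_b = pb,
        sv_type = "translocation",
        size = if (ca == cb) pb - pa else 0,
        confidence = 1, molecule_support = Inf, control_frequency = 0,
        stringsAsFactors = FALSE)
    }
  }

  out <- if (length(rows) == 0) empty_sv_table() else do.call(rbind, rows)
  if (nrow(out) > 0) {
    warning("VCF input carries no molecule support / confidence / control ",
            "frequency; defaults pass all OGM filters", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
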