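# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards: generation never perturbs global randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic HRD case
#'
#' Describes a call set to be generated by [generate_case()]: a list of
#' planted scars with known classes (hence a known ground-truth score),
#' decoy calls that must not survive filtering or scoring, optional
#' whole-chromosome aneuploidies (which score 0), and a fragmentation
#' probability with which planted copy-number segments are split into
#' stitchable pieces (gaps below the stitch distance), exercising the
#' stitch-then-score path.
#'
#' @param scars List of scar descriptions: each a list with `class` (one of
#'   the nine [scar_classes()] names), optional `chrom`, optional
#'   `bonus_ends` (0-2 translocation-evidenced segment ends, segment classes
#'   only) and optional `via` (`"segment"` or `"sv"`; LST-2 can be realized
#'   as a large inversion with `via = "sv"`, LST-3 is always an insertion
#'   SV).
#' @param decoys Named counts: `subthreshold_cnv`, `low_confidence_cnv`,
#'   `low_confidence_sv`, `low_support_sv`, `polymorphic_sv`.
#' @param n_aneuploidy Number of whole-chromosome aneuploidies to add on
#'   otherwise untouched chromosomes.
#' @param fragmentation Probability of splitting each planted CNV segment
#'   into 2-3 stitchable fragments.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   identical call sets.
#' @return A `CaseSpec` list.
#' @export
case_spec <- function(scars = list(), decoys = list(), n_aneuploidy = 0,
                      fragmentation = 0, seed = 1) {
  default_decoys <- list(subthreshold_cnv = 0, low_confidence_cnv = 0,
                         low_confidence_sv = 0, low_support_sv = 0,
                         polymorphic_sv = 0)
  unknown <- setdiff(names(decoys), names(default_decoys))
  if (length(unknown) > 0) {
    stop("unknown decoy type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  default_decoys[names(decoys)] <- decoys
  scars <- lapply(scars, function(s) {
    if (is.character(s)) s <- list(class = s)
    stopifnot(s$class %in% SCAR_CLASSES$name)
    if (is.null(s$bonus_ends)) s$bonus_ends <- 0L
    stopifnot(s$bonus_ends %in% 0:2)
    if (is.null(s$via)) s$via <- if (s$class == "LST-3") "sv" else "segment"
    if (s$class == "LST-3") s$via <- "sv"
    if (s$via == "sv" && !s$class %in% c("LST-2", "LST-3")) {
      stop("via='sv' is only meaningful for LST-2 (inversion) and LST-3 ",
           "(insertion)", call. = FALSE)
    }
    if (s$via == "sv" && s$bonus_ends > 0) {
      stop("bonus_ends applies to segment-based scars only", call. = FALSE)
    }
    s
  })
  stopifnot(fragmentation >= 0, fragmentation <= 1)
  structure(list(scars = scars, decoys = default_decoys,
                 n_aneuploidy = n_aneuploidy, fragmentation = fragmentation,
                 seed = as.integer(seed)),
            class = "CaseSpec")
}

# Chromosomes whose geometry supports a planted scar of the given class.
eligible_chroms <- function(class, genome) {
  ok <- vapply(genome$chroms, function(ann) {
    L <- ann$length
    cs <- ann$centromere[1]; ce <- ann$centromere[2]
    q_len <- L - ce
    switch(class,
           "TAI-0" = q_len > 14e6,
           "TAI-1" = q_len > 18e6,
           "TAI-LOH-1" = q_len > 24e6,
           "LOH-0" = cs > 17e6 &&
             !any(ann$masks[, 1] <= 1 & ann$masks[, 2] >= cs - 1),
           "LOH-1" = q_len > 26e6,
           "LOH-2" = q_len > 22e6,
           "LST-1" = q_len > 18e6,
           "LST-2" = q_len > 20e6,
           "LST-3" = q_len > 16e6)
  }, logical(1))
  names(genome$chroms)[ok]
}

runif1 <- function(lo, hi) round(stats::runif(1, lo, hi))

# Place one scar on its assigned chromosome; returns segment (or sv) rows
# satisfying the class's geometric definition, given the package's effective
# centromere/telomere rules.
place_scar <- function(scar, ann) {
  L <- ann$length
  cs <- ann$centromere[1]; ce <- ann$centromere[2]
  margin <- 2e6
  cls <- scar$class
  state_ai <- sample(c("gain", "loss", "aoh"), 1)
  state_loh <- sample(c("loss", "aoh"), 1)
  if (scar$via == "sv") {
    if (cls == "LST-2") {  # large balanced inversion on the q arm
      len <- runif1(10.6e6, min(20e6, L - ce - 2 * margin))
      start <- runif1(ce + margin, L - margin - len)
      return(list(sv = data.frame(
        chrom_a = ann$name, pos_a = start, chrom_b = ann$name,
        pos_b = start + len, sv_type = "inversion", size = len,
        stringsAsFactors = FALSE)))
    }
    # LST-3: insertion > 10 Mb
    len <- runif1(10.6e6, 15e6)
    pos <- runif1(ce + margin, L - margin)
    return(list(sv = data.frame(
      chrom_a = ann$name, pos_a = pos, chrom_b = ann$name, pos_b = pos,
      sv_type = "insertion", size = len, stringsAsFactors = FALSE)))
  }
  seg <- switch(cls,
    "TAI-0" = {
      len <- runif1(3.3e6, 9.4e6)
      list(start = L - len + 1, end = L, state = state_ai)
    },
    "TAI-1" = {
      len <- runif1(10.6e6, min(15e6, L - ce - margin))
      list(start = L - len + 1, end = L, state = state_ai)
    },
    "TAI-LOH-1" = {
      len <- runif1(15.6e6, min(22e6, L - ce - margin))
      list(start = L - len + 1, end = L, state = state_loh)
    },
    "LOH-0" = {  # p telomere through to the centromere: 0 genuine breaks
      end <- runif1(max(cs, 15.7e6), ce)
      list(start = 1, end = end, state = state_loh)
    },
    "LOH-1" = {  # anchored inside the centromere, one genuine q-arm break
      len <- runif1(15.6e6, min(24e6, L - ce - margin - 1))
      start <- runif1(cs, ce)
      list(start = start, end = start + len - 1, state = state_loh)
    },
    "LOH-2" = {  # fully interstitial q-arm loss/AOH
      len <- runif1(15.6e6, min(20e6, L - ce - 2 * margin - 1))
      start <- runif1(ce + margin, L - margin - len)
      list(start = start, end = start + len - 1, state = state_loh)
    },
    "LST-1" = {  # gain anchored inside the centromere: one genuine break
      len <- runif1(10.6e6, min(16e6, L - ce - margin - 1))
      start <- runif1(cs, ce)
      list(start = start, end = start + len - 1, state = "gain")
    },
    "LST-2" = {  # interstitial gain, two genuine breaks
      len <- runif1(10.6e6, min(14.5e6, L - ce - 2 * margin - 1))
      start <- runif1(ce + margin, L - margin - len)
      list(start = start, end = start + len - 1, state = "gain")
    },
    stop("unplaceable class ", cls))
  list(segment = data.frame(chrom = ann$name, start = seg$start, end = seg$end,
                            state = seg$state, confidence = 0.995,
                            copy_number = NA_real_, stringsAsFactors = FALSE))
}

fragment_segment <- function(seg, max_gap = 500000) {
  len <- seg$end - seg$start + 1
  if (len < 4e6) return(seg)
  n_gaps <- sample(1:2, 1)
  inner_lo <- seg$start + 1e6
  inner_hi <- seg$end - 1e6
  cuts <- sort(round(stats::runif(n_gaps, inner_lo, inner_hi)))
  if (n_gaps == 2 && diff(cuts) < 1e6) cuts <- cuts[1]
  gaps <- round(stats::runif(length(cuts), 5e4, max_gap - 1e5))
  starts <- c(seg$start, cuts + gaps + 1)
  ends <- c(cuts, seg$end)
  keep <- starts <= ends
  data.frame(chrom = seg$chrom, start = starts[keep], end = ends[keep],
             state = seg$state, confidence = seg$confidence,
             copy_number = seg$copy_number, stringsAsFactors = FALSE)
}

#' Generate a synthetic case with known ground truth
#'
#' Produces SV, CNV and aneuploidy call tables that parse through the
#' package readers, plus the ground-truth score implied by the planted
#' scars: `truth$total` is the OGM-mode total (scar weights plus
#' rearrangement bonuses), `truth$total_cna` the CNA-only total (segment
#' scar weights only), and `truth$signature_totals` the OGM per-signature
#' points. Decoy calls are constructed to fail exactly one filter (with a
#' safety margin below each threshold) or to fall below the scoring
#' exclusion size, so removing them never changes the computed score.
#' Identical spec and seed give identical output.
#'
#' @param spec A [case_spec()].
#' @param genome A [load_genome()] build.
#' @return A list with `svs`, `cnvs`, `aneuploidies`, `truth`, `spec`.
#' @export
generate_case <- function(spec, genome = load_genome("GRCh38")) {
  stopifnot(inherits(spec, "CaseSpec"))
  with_seed(spec$seed, generate_case_impl(spec, genome))
}

generate_case_impl <- function(spec, genome) {
  all_chroms <- names(genome$chroms)
  used <- character(0)
  svs <- empty_sv_table()
  cnvs <- empty_cnv_table()
  sv_n <- 0L
  next_sv_id <- function() {
    sv_n <<- sv_n + 1L
    sprintf("sv%03d", sv_n)
  }
  truth_rows <- list()

  for (scar in spec$scars) {
    pool <- eligible_chroms(scar$class, genome)
    if (!is.null(scar$chrom)) {
      key <- norm_chrom(scar$chrom)
      if (!key %in% pool) {
        stop("scar ", scar$class, " is geometrically impossible on chromosome ",
             scar$chrom, call. = FALSE)
      }
      pool <- key
    } else {
      pool <- setdiff(pool, used)
      if (length(pool) == 0) {
        stop("no free chromosome can host a ", scar$class, " scar", call. = FALSE)
      }
    }
    chrom <- if (length(pool) == 1) pool else sample(pool, 1)
    used <- c(used, chrom)
    ann <- genome$chroms[[chrom]]
    placed <- place_scar(scar, ann)
    bonus <- 0L
    if (!is.null(placed$segment)) {
      seg <- placed$segment
      if (scar$bonus_ends > 0) {
        # attach translocation junctions at the segment's genuine end(s);
        # interior-first so terminal classes get their breakpoint end
        ends <- if (seg$end >= ann$length - 1e4) c(seg$start, seg$end)
                else c(seg$end, seg$start)
        partner_pool <- setdiff(all_chroms, c(used, chrom))
        for (k in seq_len(scar$bonus_ends)) {
          partner <- if (length(partner_pool) > 0) partner_pool[1] else "Y"
          p_ann <- genome$chroms[[partner]]
          svs <- rbind(svs, data.frame(
            id = next_sv_id(), chrom_a = chrom, pos_a = ends[k],
            chrom_b = partner,
            pos_b = runif1(p_ann$centromere[2] + 3e6, p_ann$length - 3e6),
            sv_type = "translocation", size = 0, confidence = 0.5,
            molecule_support = 12, control_frequency = 0,
            stringsAsFactors = FALSE))
        }
        bonus <- as.integer(scar$bonus_ends)
      }
      if (stats::runif(1) < spec$fragmentation) seg <- fragment_segment(seg)
      cnvs <- rbind(cnvs, seg)
    } else {
      sv <- placed$sv
      sv$id <- next_sv_id()
      sv$confidence <- 0.5
      sv$molecule_support <- 12
      sv$control_frequency <- 0
      svs <- rbind(svs, sv[, names(empty_sv_table())])
    }
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      scar_class = scar$class, signature = scar_signature(scar$class),
      chrom = chrom, base_points = scar_weight(scar$class),
      bonus_points = bonus, via = scar$via, stringsAsFactors = FALSE)
  }

  # aneuploidies on untouched chromosomes: ground-truth contribution 0
  aneu <- empty_aneuploidy_table()
  free <- setdiff(all_chroms, used)
  if (spec$n_aneuploidy > 0) {
    if (spec$n_aneuploidy > length(free)) {
      stop("not enough free chromosomes for ", spec$n_aneuploidy,
           " aneuploidies", call. = FALSE)
    }
    picked <- sample(free, spec$n_aneuploidy)
    used <- c(used, picked)
    aneu <- data.frame(chrom = picked,
                       event = sample(ANEUPLOIDY_EVENTS, spec$n_aneuploidy,
                                      replace = TRUE),
                       fraction = round(stats::runif(spec$n_aneuploidy, 0.3, 1), 3),
                       stringsAsFactors = FALSE)
  }

  # decoys live on chromosomes without planted scars so they cannot stitch
  # into, or lend breakpoint evidence to, a real scar
  free <- setdiff(all_chroms, used)
  decoy_chrom <- function(i) free[(i - 1L) %% length(free) + 1L]
  d <- spec$decoys
  guard <- 1e-6
  if (d$subthreshold_cnv > 0) {
    for (i in seq_len(d$subthreshold_cnv)) {
      ann <- genome$chroms[[decoy_chrom(i)]]
      start <- ann$centromere[2] + 3e6 + (i %/% length(free)) * 5e6
      len <- runif1(1.5e6, 2.4e6)
      cnvs <- rbind(cnvs, data.frame(
        chrom = ann$name, start = start, end = start + len - 1,
        state = "loss", confidence = 0.995, copy_number = NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  if (any(unlist(d) > 0) && length(free) == 0) {
    stop("no free chromosome left for decoy calls", call. = FALSE)
  }
  if (d$low_confidence_cnv > 0) {
    for (i in seq_len(d$low_confidence_cnv)) {
      ann <- genome$chroms[[decoy_chrom(i)]]
      start <- min(ann$centromere[2] + 30e6, ann$length - 20e6)
      cnvs <- rbind(cnvs, data.frame(
        chrom = ann$name, start = start,
        end = min(start + 18e6, ann$length - 1e6),
        state = "loss", confidence = stats::runif(1, 0.5, 0.99 - guard),
        copy_number = NA_real_, stringsAsFactors = FALSE))
    }
  }
  add_decoy_sv <- function(i, type, confidence, support, ctrl_freq) {
    ann <- genome$chroms[[decoy_chrom(i)]]
    start <- runif1(ann$centromere[2] + 2e6, ann$length - 15e6)
    svs <<- rbind(svs, data.frame(
      id = next_sv_id(), chrom_a = ann$name, pos_a = start,
      chrom_b = ann$name, pos_b = start + 12e6, sv_type = type, size = 12e6,
      confidence = confidence, molecule_support = support,
      control_frequency = ctrl_freq, stringsAsFactors = FALSE))
  }
  if (d$low_confidence_sv > 0) {
    for (i in seq_len(d$low_confidence_sv)) {
      add_decoy_sv(i, "inversion", stats::runif(1, 0, 0.01 - guard), 12, 0)
    }
  }
  if (d$low_support_sv > 0) {
    for (i in seq_len(d$low_support_sv)) {
      add_decoy_sv(i, "inversion", 0.5, sample(0:4, 1), 0)
    }
  }
  if (d$polymorphic_sv > 0) {
    for (i in seq_len(d$polymorphic_sv)) {
      add_decoy_sv(i, "inversion", 0.5, 12, stats::runif(1, 0.01, 0.2))
    }
  }

  truth_tab <- if (length(truth_rows) == 0) {
    data.frame(scar_class = character(0), signature = character(0),
               chrom = character(0), base_points = integer(0),
               bonus_points = integer(0), via = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, truth_rows)
  sig_tot <- vapply(c("LOH", "TAI", "LST"), function(s) {
    idx <- truth_tab$signature == s
    as.integer(sum(truth_tab$base_points[idx] + truth_tab$bonus_points[idx]))
  }, integer(1))
  truth <- list(
    total = sum(truth_tab$base_points + truth_tab$bonus_points),
    total_cna = sum(truth_tab$base_points[truth_tab$via == "segment"]),
    signature_totals = sig_tot,
    scars = truth_tab)

  rownames(svs) <- rownames(cnvs) <- rownames(aneu) <- NULL
  list(svs = svs, cnvs = cnvs, aneuploidies = aneu, truth = truth, spec = spec)
}

#' Draw a random case specification
#'
#' Samples a spec for property testing: up to `max_scars` scars with random
#' classes, random bonus ends on segment scars, random decoy counts,
#' aneuploidies and fragmentation. Deterministic in `seed` (which also seeds
#' the generated case).
#'
#' @param seed Integer seed.
#' @param max_scars Maximum number of planted scars.
#' @return A [case_spec()].
#' @export
random_case_spec <- function(seed, max_scars = 4) {
  with_seed(seed, {
    n <- sample(0:max_scars, 1)
    scars <- lapply(seq_len(n), function(i) {
      cls <- sample(SCAR_CLASSES$name, 1)
      via <- if (cls == "LST-3") "sv"
             else if (cls == "LST-2" && stats::runif(1) < 0.3) "sv"
             else "segment"
      list(class = cls,
           bonus_ends = if (via == "segment") sample(0:2, 1, prob = c(.6, .25, .15)) else 0L,
           via = via)
    })
    case_spec(
      scars = scars,
      decoys = list(subthreshold_cnv = sample(0:2, 1),
                    low_confidence_cnv = sample(0:1, 1),
                    low_confidence_sv = sample(0:2, 1),
                    low_support_sv = sample(0:1, 1),
                    polymorphic_sv = sample(0:1, 1)),
      n_aneuploidy = sample(0:2, 1),
      fragmentation = sample(c(0, 0.5, 1), 1),
      seed = seed)
  })
}

#' Write a generated case to call files
#'
#' Writes `sv.tsv`, `cnv.tsv`, `aneuploidy.tsv` (package TSV dialects, so
#' they round-trip through the readers) and `truth.json` into `dir`.
#'
#' @param case Output of [generate_case()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_case <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(sv = file.path(dir, "sv.tsv"), cnv = file.path(dir, "cnv.tsv"),
             aneuploidy = file.path(dir, "aneuploidy.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(case$svs, paths["sv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(case$cnvs, paths["cnv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(case$aneuploidies, paths["aneuploidy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(case$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Degrade a call set to copy-number-only platform visibility
#'
#' Emulates what a chromosomal microarray or NGS panel sees: all SVs are
#' invisible, and (optionally) whole-chromosome gains present as fractured
#' segmental gains because of mosaicism and uneven coverage — the mechanism
#' behind false-positive scar calls on CNA-only platforms. With
#' `fracture = TRUE` each whole-chromosome gain is replaced by a terminal
#' q-arm gain and a centromere-anchored interstitial gain, both above the
#' LST minimum.
#'
#' @param cnvs CNV data.frame (may include whole-chromosome segments, e.g.
#'   from [aneuploidy_to_segments()]).
#' @param genome A [load_genome()] build.
#' @param fracture Fracture whole-chromosome gains into segmental gains?
#' @return The CNA-platform CNV data.frame.
#' @export
degrade_to_cna_platform <- function(cnvs, genome, fracture = TRUE) {
  if (nrow(cnvs) == 0) return(cnvs)
  rows <- list()
  for (i in seq_len(nrow(cnvs))) {
    seg <- cnvs[i, , drop = FALSE]
    ann <- get_chrom(genome, seg$chrom)
    geo <- classify_geometry(seg, genome)
    if (fracture && geo$whole_chromosome && seg$state == "gain") {
      L <- ann$length; ce <- ann$centromere[2]
      cen_mid <- round(mean(ann$centromere))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = seg$chrom,
        start = c(L - 12e6 + 1, cen_mid),
        end = c(L, min(cen_mid + 12e6, L - 14e6)),
        state = "gain",
        # fractured segments present as ordinary high-confidence platform calls
        confidence = if (is.na(seg$confidence)) 0.995 else seg$confidence,
        copy_number = seg$copy_number, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- seg
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
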