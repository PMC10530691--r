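# Shared fixtures, built in code at load time.

grch38 <- load_genome("GRCh38")

# Two toy chromosomes with simple geometry: T1 200 Mb (narrow centromere
# 95-96 Mb, so segments can span it with both ends outside) and T2 100 Mb
# (centromere 45-50 Mb). No masks, so the terminal regions are single bases.
toy_genome <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- tempfile(fileext = ".tsv")
    writeLines(c("chrom\tlength\tcen_start\tcen_end",
                 "T1\t200000000\t95000000\t96000000",
                 "T2\t100000000\t45000000\t50000000"), path)
    cache <<- load_genome(path)
    cache
  }
})

# One-chromosome build with configurable masks, for effective-region tests.
masked_genome <- function(masks = NULL, length = 100e6,
                          cen = c(45e6, 50e6)) {
  path <- tempfile(fileext = ".tsv")
  rows <- c("chrom\tlength\tcen_start\tcen_end",
            paste("M1", format(length, scientific = FALSE),
                  format(cen[1], scientific = FALSE),
                  format(cen[2], scientific = FALSE), sep = "\t"))
  if (!is.null(masks)) {
    rows <- c(rows, apply(masks, 1, function(m) {
      paste("M1", format(m[1], scientific = FALSE),
            format(m[2], scientific = FALSE), sep = "\t")
    }))
  }
  writeLines(rows, path)
  load_genome(path)
}

make_sv <- function(chrom_a, pos_a, chrom_b = chrom_a, pos_b = pos_a,
                    sv_type = "translocation", size = NULL,
                    confidence = 0.5, molecule_support = 10,
                    control_frequency = 0, id = NULL) {
  n <- max(length(chrom_a), length(pos_a))
  if (is.null(size)) {
    size <- ifelse(chrom_a == chrom_b, pos_b - pos_a, 0)
  }
  data.frame(id = if (is.null(id)) paste0("sv", seq_len(n)) else id,
             chrom_a = chrom_a, pos_a = pos_a, chrom_b = chrom_b,
             pos_b = pos_b, sv_type = sv_type, size = size,
             confidence = confidence, molecule_support = molecule_support,
             control_frequency = control_frequency, stringsAsFactors = FALSE)
}

make_cnv <- function(chrom, start, end, state = "loss", confidence = 0.995,
                     copy_number = NA_real_) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             confidence = confidence, copy_number = copy_number,
             stringsAsFactors = FALSE)
}

write_sv_file <- function(svs, path = tempfile(fileext = ".tsv")) {
  write.table(svs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_cnv_file <- function(cnvs, path = tempfile(fileext = ".tsv")) {
  write.table(cnvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
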