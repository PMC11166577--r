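# Amplicon read rendering (simulator side) and FASTQ I/O. Reads follow the
# panel layout 5'->3': UMI - protein barcode - BS1 - UPI-A - BS2 - UPI-B.

#' Sequencing/PCR error model
#'
#' @param substitution_rate per-base substitution probability in `[0, 1]`
#' @param pcr_duplication mean reads per molecule (>= 1); duplicate counts are
#'   `1 + Geometric`, giving the heavy right tail of PCR amplification
#' @param dropout_rate probability a molecule yields no read
#' @return an `mpx_error_model`
#' @export
error_model <- function(substitution_rate = 0, pcr_duplication = 1,
                        dropout_rate = 0) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1, pcr_duplication >= 1)
  structure(list(substitution_rate = substitution_rate,
                 pcr_duplication = pcr_duplication,
                 dropout_rate = dropout_rate),
            class = "mpx_error_model")
}

#' Render simulated molecules as FASTQ reads
#'
#' Each ground-truth molecule emits `1 + Geometric` PCR duplicate reads with
#' mean `pcr_duplication`, each base substituted independently at
#' `substitution_rate`; quality strings are a constant placeholder (Phred 40).
#'
#' @param sim an `mpx_sim`
#' @param panel the `mpx_panel` defining barcodes and the read layout
#' @param errors an [error_model()]
#' @param seed integer seed
#' @param path output FASTQ path
#' @return the path, invisibly; attribute `n_reads` carries the read count
#' @export
render_fastq <- function(sim, panel, errors = error_model(), seed = 1L,
                         path = tempfile(fileext = ".fastq")) {
  stopifnot(inherits(sim, "mpx_sim"), inherits(errors, "mpx_error_model"))
  validate_panel(panel)
  mol <- sim$edges
  if (nrow(mol) == 0L) stop("simulation truth contains no molecules")
  unknown <- setdiff(unique(mol$marker), panel$markers$marker)
  if (length(unknown)) {
    stop("markers absent from panel: ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)

  if (errors$dropout_rate > 0) {
    mol <- mol[stats::runif(nrow(mol)) >= errors$dropout_rate, , drop = FALSE]
  }
  barcode_of <- stats::setNames(panel$markers$barcode, panel$markers$marker)
  parts <- list(umi = mol$umi, marker = unname(barcode_of[mol$marker]),
                bs1 = panel$bs1, bs2 = panel$bs2,
                upia = mol$upia, upib = mol$upib)
  seqs <- do.call(paste0, parts[panel$layout])

  ndup <- if (errors$pcr_duplication > 1) {
    1L + stats::rgeom(nrow(mol), prob = 1 / errors$pcr_duplication)
  } else {
    rep(1L, nrow(mol))
  }
  reads <- rep(seqs, ndup)

  if (errors$substitution_rate > 0 && length(reads) > 0) {
    len <- nchar(reads[1])
    nmut <- stats::rbinom(length(reads), len, errors$substitution_rate)
    hit <- which(nmut > 0L)
    for (i in hit) {
      pos <- sample.int(len, nmut[i])
      chars <- strsplit(reads[i], "")[[1]]
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
      reads[i] <- paste(chars, collapse = "")
    }
  }
  reads <- reads[sample.int(length(reads))]

  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- sprintf("read%07d", seq_along(reads))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(dna, qual))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  attr(path, "n_reads") <- length(reads)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (gzip allowed)
#' @return list with character vectors `id`, `seq` and `qual`
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here; benign
  qs <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  list(id = names(qs),
       seq = as.character(qs),
       qual = as.character(Biostrings::quality(qs)))
}
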