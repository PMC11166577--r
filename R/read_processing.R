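# FASTQ reads -> deduplicated, error-corrected edge list of unique molecules.

#' Parse amplicon reads against a panel layout
#'
#' Regions are extracted positionally per the panel layout. Reads are rejected
#' when shorter than the layout, when mean Phred quality falls below
#' `min_mean_phred` (if qualities are supplied), when either binding-site
#' motif mismatches by more than `max_motif_mismatch` (fraction of motif
#' length, the assay's >10% discard rule), or when the protein barcode matches
#' no panel entry within `barcode_max_mismatch` substitutions (panels are
#' distance->=3 by construction, so one mismatch resolves uniquely).
#'
#' @param seqs character vector of read sequences (or the list returned by
#'   [read_fastq()])
#' @param panel an `mpx_panel`
#' @param qualities optional character vector of Phred-33 quality strings
#' @param max_motif_mismatch maximum mismatch fraction per binding-site motif
#' @param barcode_max_mismatch maximum substitutions for barcode assignment
#' @param min_mean_phred minimum mean base quality
#' @return list with `molecules` (tibble `umi`, `marker`, `upia`, `upib`) and
#'   `qc` (named counts: total, rejected_length, rejected_quality,
#'   rejected_motif, rejected_barcode, accepted)
#' @export
parse_reads <- function(seqs, panel, qualities = NULL,
                        max_motif_mismatch = 0.10,
                        barcode_max_mismatch = 1L,
                        min_mean_phred = 20) {
  if (is.list(seqs) && !is.null(seqs$seq)) {
    qualities <- qualities %||% seqs$qual
    seqs <- seqs$seq
  }
  validate_panel(panel)
  regions <- layout_regions(panel)
  layout_len <- sum(regions$width)
  n <- length(seqs)
  qc <- c(total = n, rejected_length = 0L, rejected_quality = 0L,
          rejected_motif = 0L, rejected_barcode = 0L, accepted = 0L)

  ok <- nchar(seqs) >= layout_len
  qc["rejected_length"] <- sum(!ok)

  if (!is.null(qualities) && any(ok)) {
    idx <- which(ok)
    mean_q <- vapply(qualities[idx],
                     function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                     USE.NAMES = FALSE)
    low <- mean_q < min_mean_phred
    qc["rejected_quality"] <- sum(low)
    ok[idx[low]] <- FALSE
  }

  get_region <- function(x, name) {
    r <- regions[regions$region == name, ]
    substring(x, r$start, r$end)
  }
  idx <- which(ok)
  sub <- seqs[idx]
  bs1_mm <- hamming_to_ref(get_region(sub, "bs1"), panel$bs1) / nchar(panel$bs1)
  bs2_mm <- hamming_to_ref(get_region(sub, "bs2"), panel$bs2) / nchar(panel$bs2)
  motif_bad <- bs1_mm > max_motif_mismatch | bs2_mm > max_motif_mismatch
  qc["rejected_motif"] <- sum(motif_bad)
  idx <- idx[!motif_bad]
  sub <- sub[!motif_bad]

  bc <- get_region(sub, "marker")
  marker <- panel$markers$marker[match(bc, panel$markers$barcode)]
  if (barcode_max_mismatch > 0 && anyNA(marker)) {
    miss <- which(is.na(marker))
    dists <- vapply(panel$markers$barcode,
                    function(b) hamming_to_ref(bc[miss], b),
                    integer(length(miss)))
    dists <- matrix(dists, nrow = length(miss))
    best <- max.col(-dists, ties.method = "first")
    bestd <- dists[cbind(seq_along(miss), best)]
    hit <- bestd <= barcode_max_mismatch
    marker[miss[hit]] <- panel$markers$marker[best[hit]]
  }
  bc_bad <- is.na(marker)
  qc["rejected_barcode"] <- sum(bc_bad)
  idx <- idx[!bc_bad]
  sub <- sub[!bc_bad]
  marker <- marker[!bc_bad]
  qc["accepted"] <- length(idx)

  molecules <- tibble::tibble(
    umi = get_region(sub, "umi"),
    marker = marker,
    upia = get_region(sub, "upia"),
    upib = get_region(sub, "upib")
  )
  list(molecules = molecules, qc = qc)
}

#' Collapse PCR duplicate reads into unique molecules
#'
#' Reads are grouped on the (UMI, UPI-A) key; `reads` is the group size, and
#' the representative marker and UPI-B are the most read-supported values in
#' the group (ties broken lexicographically).
#'
#' @param parsed tibble of parsed reads (`umi`, `marker`, `upia`, `upib`)
#' @return tibble of edge records: `upia`, `upib`, `marker`, `umi`, `reads`,
#'   one row per (UMI, UPI-A) key
#' @export
collapse_molecules <- function(parsed) {
  if (nrow(parsed) == 0L) {
    return(tibble::tibble(upia = character(0), upib = character(0),
                          marker = character(0), umi = character(0),
                          reads = integer(0)))
  }
  dt <- data.table::as.data.table(parsed)
  umi <- upia <- upib <- marker <- NULL # NSE guards
  out <- dt[, list(upib = majority_vote(upib),
                   marker = majority_vote(marker),
                   reads = .N),
            by = list(umi, upia)]
  tibble::tibble(upia = out$upia, upib = out$upib, marker = out$marker,
                 umi = out$umi, reads = as.integer(out$reads))
}

# Directional clustering of sequences by Hamming distance: key b joins
# representative a when dist(a, b) <= max_dist and reads(a) >= 2*reads(b) - 1.
# Assignment is one-hop (b must be a direct neighbour of the representative,
# no transitive chaining, which would let low-count error keys bridge two
# distinct molecules). Candidate neighbour pairs are found by the pigeonhole
# partition of each key into max_dist + 1 slices (two keys within max_dist
# substitutions must agree on at least one slice). Returns the index of each
# key's cluster representative (the highest-read key, ties lexicographic).
directional_cluster <- function(keys, counts, max_dist = 2L) {
  n <- length(keys)
  if (n <= 1L) return(rep(1L, n))
  len <- nchar(keys[1])
  n_slices <- max_dist + 1L
  bounds <- round(seq(0, len, length.out = n_slices + 1L))

  pairs_i <- integer(0); pairs_j <- integer(0)
  for (s in seq_len(n_slices)) {
    slice <- substring(keys, bounds[s] + 1L, bounds[s + 1L])
    grp <- split(seq_len(n), slice)
    grp <- grp[lengths(grp) > 1L]
    for (g in grp) {
      cmb <- utils::combn(g, 2L)
      pairs_i <- c(pairs_i, cmb[1L, ]); pairs_j <- c(pairs_j, cmb[2L, ])
    }
  }
  if (length(pairs_i)) {
    key <- paste(pairs_i, pairs_j)
    keep <- !duplicated(key)
    pairs_i <- pairs_i[keep]; pairs_j <- pairs_j[keep]
    d <- hamming_pairwise(keys[pairs_i], keys[pairs_j])
    near <- d <= max_dist & d > 0L
    pairs_i <- pairs_i[near]; pairs_j <- pairs_j[near]
  }

  adj <- vector("list", n)
  for (k in seq_along(pairs_i)) {
    i <- pairs_i[k]; j <- pairs_j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  ord <- order(-counts, keys)
  assigned <- integer(n) # 0 = unassigned
  for (root in ord) {
    if (assigned[root] != 0L) next
    assigned[root] <- root
    for (b in adj[[root]]) {
      if (assigned[b] == 0L && counts[root] >= 2 * counts[b] - 1) {
        assigned[b] <- root
      }
    }
  }
  assigned
}

#' Correct PCR/sequencing errors in collapsed molecules
#'
#' Concatenated UMI-UPI-A keys are clustered by directional adjacency
#' (Hamming distance <= `max_dist` with the `reads(a) >= 2*reads(b) - 1`
#' count-ratio rule, merging direct neighbours of each representative only);
#' each cluster's reads are merged into its most frequent key, and the pass
#' repeats until no further merge occurs, so the operation is idempotent.
#' The same directional procedure is applied to the UPI-B values within each
#' merged cluster, and the representative marker is the cluster's
#' read-weighted majority.
#'
#' @param records collapsed edge records from [collapse_molecules()]
#' @param max_dist maximum Hamming distance for a merge (default 2)
#' @return corrected edge records, one row per surviving (UMI, UPI-A) key
#' @export
correct_sequences <- function(records, max_dist = 2L) {
  if (max_dist < 0) stop("max_dist must be >= 0")
  if (nrow(records) <= 1L || max_dist == 0L) return(records)
  for (pass in 1:10) {
    n_before <- nrow(records)
    records <- correct_pass(records, max_dist)
    if (nrow(records) == n_before) break
  }
  records
}

correct_pass <- function(records, max_dist) {
  keys <- paste0(records$umi, records$upia)
  cl <- directional_cluster(keys, records$reads, max_dist)
  dt <- data.table::as.data.table(records)
  dt$cluster <- cl
  merge_cluster <- function(sd) {
    if (nrow(sd) == 1L) {
      return(list(upia = sd$upia, upib = sd$upib, marker = sd$marker,
                  umi = sd$umi, reads = sd$reads))
    }
    rep_i <- order(-sd$reads, paste0(sd$umi, sd$upia))[1]
    # correct UPI-B variants inside the cluster with the same directional
    # rule, pooling read support of identical UPI-B values first
    bag <- rowsum(as.numeric(sd$reads), sd$upib)
    ukeys <- rownames(bag); uw <- bag[, 1]
    bcl <- directional_cluster(ukeys, uw, max_dist)
    bsum <- rowsum(uw, bcl)
    reps <- as.integer(rownames(bsum))
    upib_rep <- ukeys[reps[order(-bsum[, 1], ukeys[reps])]][1]
    list(upia = sd$upia[rep_i], upib = upib_rep,
         marker = majority_vote(sd$marker, sd$reads),
         umi = sd$umi[rep_i], reads = sum(sd$reads))
  }
  cluster <- NULL
  out <- dt[, merge_cluster(.SD), by = cluster]
  tibble::tibble(upia = out$upia, upib = out$upib, marker = out$marker,
                 umi = out$umi, reads = as.integer(out$reads))
}

#' Full read-processing stage
#'
#' Parse, collapse and error-correct a FASTQ file into an edge list, with a
#' QC report accounting for every input read.
#'
#' @param fastq path to a FASTQ file
#' @param panel an `mpx_panel`
#' @param max_dist Hamming radius for [correct_sequences()]
#' @param ... passed to [parse_reads()]
#' @return list with `edges` (corrected edge records) and `qc` (named counts)
#' @export
process_reads <- function(fastq, panel, max_dist = 2L, ...) {
  reads <- read_fastq(fastq)
  parsed <- parse_reads(reads, panel, ...)
  edges <- correct_sequences(collapse_molecules(parsed$molecules), max_dist)
  qc <- as.list(parsed$qc)
  qc$unique_molecules <- nrow(edges)
  qc$reads_per_molecule <- if (nrow(edges)) {
    as.list(stats::setNames(
      as.numeric(summary(edges$reads)),
      c("min", "q1", "median", "mean", "q3", "max")))
  } else NULL
  list(edges = edges, qc = qc)
}

#' Write a QC report as JSON
#'
#' @param qc the `qc` element returned by [process_reads()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write or read an edge list as TSV
#'
#' @param edges edge-record tibble
#' @param path file path
#' @return the path invisibly, or the edge tibble
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  dt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(dt)
}
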