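# Antibody panel configuration: marker names, protein barcodes and the
# amplicon layout shared by the simulator and the read parser.

# Canonical immune surface targets used for default marker naming; the first
# entries cover the lineage markers referenced by the built-in gating helpers.
.DEFAULT_MARKER_NAMES <- c(
  "CD3", "CD4", "CD8", "CD19", "CD20", "CD14", "CD45", "HLA-ABC", "B2M",
  "CD50", "CD162", "CD37", "CD11a", "CD43", "CD44", "CD54", "CD82", "CD102",
  "CD16", "CD56", "CD25", "CD27", "CD28", "CD38", "CD69", "CD45RA", "CD45RB",
  "CD2", "CD5", "CD7", "CD11b", "CD11c", "CD18", "CD22", "CD24", "CD26",
  "CD29", "CD31", "CD32", "CD33", "CD35", "CD36", "CD40", "CD41", "CD47",
  "CD48", "CD49d", "CD52", "CD53", "CD55", "CD58", "CD59", "CD62L", "CD62P",
  "CD63", "CD64", "CD71", "CD72", "CD79b", "CD81", "CD84", "CD86", "CD9",
  "CD95", "CD101", "CD119", "CD127", "CD150", "CD152", "CD154", "CD163",
  "CD200", "CD229", "CD244", "CD268", "CD328"
)
.DEFAULT_CONTROL_NAMES <- c("mIgG1", "mIgG2a", "mIgG2b", "ACTB")

# Universal binding-site motifs used as read anchors (arbitrary fixed 20-mers).
.DEFAULT_BS1 <- "ACTGGTCAGTCCGATACTGA"
.DEFAULT_BS2 <- "TGACGATCCGTTAGCACTGA"

#' Generate an antibody panel configuration
#'
#' Creates a panel of `n_markers` protein markers with unique DNA barcodes at
#' pairwise Hamming distance >= 3 (so single-substitution demultiplexing is
#' unambiguous), plus the amplicon layout parameters shared by the simulator
#' and the read parser. The last `n_controls` markers are flagged as
#' non-targeting/isotype controls.
#'
#' @param n_markers total number of markers in the panel (including controls)
#' @param seed integer seed; the panel is deterministic given `(n_markers, seed)`
#' @param barcode_length protein barcode length in nt
#' @param n_controls number of control markers (default 4 for panels of >= 20
#'   markers, else 0); must be < `n_markers`
#' @param umi_length unique molecular identifier length in nt
#' @param upi_length unique pixel identifier length in nt
#' @param bs1,bs2 binding-site motif sequences used as read anchors
#' @return an object of class `mpx_panel`: a list with a `markers` tibble
#'   (`marker`, `barcode`, `is_control`), lengths, motifs and the read layout
#' @export
#' @examples
#' p <- generate_panel(8, seed = 1)
#' p$markers
generate_panel <- function(n_markers, seed,
                           barcode_length = 8L,
                           n_controls = if (n_markers >= 20) 4L else 0L,
                           umi_length = 10L, upi_length = 25L,
                           bs1 = .DEFAULT_BS1, bs2 = .DEFAULT_BS2) {
  stopifnot(n_markers >= 1, umi_length > 0, upi_length > 0)
  if (n_controls >= n_markers) stop("n_controls must be smaller than n_markers")
  set.seed(seed)
  barcodes <- .sample_barcodes(n_markers, barcode_length, min_dist = 3L)
  n_targets <- n_markers - n_controls
  names <- if (n_targets <= length(.DEFAULT_MARKER_NAMES)) {
    .DEFAULT_MARKER_NAMES[seq_len(n_targets)]
  } else {
    c(.DEFAULT_MARKER_NAMES,
      sprintf("MKR%03d", seq_len(n_targets - length(.DEFAULT_MARKER_NAMES))))
  }
  names <- c(names, .DEFAULT_CONTROL_NAMES[seq_len(n_controls)])
  panel <- structure(list(
    markers = tibble::tibble(
      marker = names,
      barcode = barcodes,
      is_control = c(rep(FALSE, n_targets), rep(TRUE, n_controls))
    ),
    umi_length = as.integer(umi_length),
    upi_length = as.integer(upi_length),
    bs1 = bs1, bs2 = bs2,
    layout = c("umi", "marker", "bs1", "upia", "bs2", "upib")
  ), class = "mpx_panel")
  validate_panel(panel)
  panel
}

# Rejection-sample barcodes at pairwise Hamming distance >= min_dist.
.sample_barcodes <- function(n, len, min_dist = 3L) {
  if (len < min_dist) {
    stop("barcode space exhausted: length-", len,
         " barcodes cannot reach pairwise distance ", min_dist)
  }
  picked <- character(0)
  attempts <- 0L
  max_attempts <- 2000L * n
  while (length(picked) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("barcode space exhausted: could not place ", n,
           " barcodes of length ", len, " at pairwise distance ", min_dist)
    }
    cand <- random_seq(1L, len)
    if (length(picked) == 0L || all(hamming_to_ref(picked, cand) >= min_dist)) {
      picked <- c(picked, cand)
    }
  }
  picked
}

#' Validate a panel configuration
#'
#' Checks marker-name and barcode uniqueness, equal barcode lengths, pairwise
#' barcode Hamming distance >= 3 and positive UMI/UPI lengths.
#'
#' @param panel an `mpx_panel`
#' @return the panel, invisibly; errors on violation
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "mpx_panel"))
  m <- panel$markers
  if (anyDuplicated(m$marker)) stop("duplicate marker names")
  if (anyDuplicated(m$barcode)) stop("duplicate barcodes")
  if (length(unique(nchar(m$barcode))) != 1L) stop("barcodes differ in length")
  if (panel$umi_length <= 0 || panel$upi_length <= 0) {
    stop("umi_length and upi_length must be positive")
  }
  if (nrow(m) > 1L) {
    for (i in seq_len(nrow(m) - 1L)) {
      d <- hamming_to_ref(m$barcode[(i + 1L):nrow(m)], m$barcode[i])
      if (any(d < 3L)) stop("barcodes closer than Hamming distance 3")
    }
  }
  invisible(panel)
}

#' @export
print.mpx_panel <- function(x, ...) {
  cat("Antibody panel:", nrow(x$markers), "markers (",
      sum(x$markers$is_control), "controls ),",
      nchar(x$markers$barcode[1]), "nt barcodes\n")
  cat("UMI", x$umi_length, "nt; UPI", x$upi_length, "nt; layout:",
      paste(x$layout, collapse = " - "), "\n")
  invisible(x)
}

# Ordered region table (region, width, start, end) for one amplicon read.
layout_regions <- function(panel) {
  widths <- vapply(panel$layout, function(r) switch(
    r,
    umi = panel$umi_length,
    marker = nchar(panel$markers$barcode[1]),
    bs1 = nchar(panel$bs1),
    bs2 = nchar(panel$bs2),
    upia = panel$upi_length,
    upib = panel$upi_length,
    stop("unknown layout region: ", r)
  ), numeric(1))
  ends <- cumsum(widths)
  data.frame(region = panel$layout, width = widths,
             start = ends - widths + 1, end = ends,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write or read a panel configuration file
#'
#' Panels are stored as flat YAML; `read_panel()` inverts `write_panel()`.
#'
#' @param panel an `mpx_panel`
#' @param path file path
#' @return `write_panel()` the path invisibly; `read_panel()` an `mpx_panel`
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  yaml::write_yaml(list(
    umi_length = panel$umi_length, upi_length = panel$upi_length,
    bs1 = panel$bs1, bs2 = panel$bs2, layout = as.list(panel$layout),
    markers = lapply(seq_len(nrow(panel$markers)), function(i) list(
      marker = panel$markers$marker[i],
      barcode = panel$markers$barcode[i],
      is_control = panel$markers$is_control[i]
    ))
  ), path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- structure(list(
    markers = tibble::tibble(
      marker = vapply(y$markers, `[[`, character(1), "marker"),
      barcode = vapply(y$markers, `[[`, character(1), "barcode"),
      is_control = vapply(y$markers, `[[`, logical(1), "is_control")
    ),
    umi_length = as.integer(y$umi_length),
    upi_length = as.integer(y$upi_length),
    bs1 = y$bs1, bs2 = y$bs2, layout = unlist(y$layout)
  ), class = "mpx_panel")
  validate_panel(panel)
  panel
}
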