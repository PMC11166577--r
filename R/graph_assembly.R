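# Bipartite UPI graph assembly, spurious-edge removal, component calling,
# size filtering, count matrix and one-mode projection.

#' Build the bipartite pixel graph from an edge list
#'
#' One vertex per distinct UPI-A / UPI-B string (vertex attribute `type` is
#' `FALSE` for A, `TRUE` for B), one edge per unique molecule, annotated with
#' `marker`, `umi` and `reads`. Parallel edges between the same pixel pair
#' (distinct UMIs) are kept.
#'
#' @param edges edge-record tibble (`upia`, `upib`, `marker`, `umi`, `reads`)
#' @return an igraph multigraph
#' @export
build_graph <- function(edges) {
  a <- unique(edges$upia)
  b <- unique(edges$upib)
  if (length(intersect(a, b))) {
    stop("UPI strings occur on both the A and the B side")
  }
  verts <- data.frame(name = c(a, b),
                      type = rep(c(FALSE, TRUE), c(length(a), length(b))))
  igraph::graph_from_data_frame(
    data.frame(from = edges$upia, to = edges$upib,
               marker = edges$marker, umi = edges$umi, reads = edges$reads,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Remove spurious inter-cell edges by Leiden community detection
#'
#' Per connected component, modularity-maximising Leiden communities are
#' computed on the simplified (deduplicated) graph; for every community pair
#' connected by between 1 and `crossing_max` distinct pixel pairs, those
#' crossing edges are deleted (with all their parallel molecules). The pass
#' repeats until no edge is removed or `max_iter` is reached. Dense single
#' cells are untouched, while rare technical doublets bridged by a few edges
#' split into their constituent components.
#'
#' @param g bipartite multigraph from [build_graph()]
#' @param resolution Leiden resolution parameter; the default is deliberately
#'   low so that one dense cell resolves as one community and only genuinely
#'   weakly-bridged blobs (doublets) split
#' @param max_iter maximum refinement passes
#' @param crossing_max community pairs joined by more than this many distinct
#'   edges are left intact
#' @param min_community crossing edges are only removed when both communities
#'   have at least this many nodes, protecting dangling fringes of a single
#'   cell from being clipped off
#' @param crossing_rel crossing edges are only removed when they number at
#'   most this fraction of the smaller community's internal edges, so only
#'   genuinely weak bridges between dense blobs are cut
#' @return the refined graph
#' @export
refine_components <- function(g, resolution = 0.01, max_iter = 3L,
                              crossing_max = 10L, min_community = 20L,
                              crossing_rel = 0.01) {
  for (iter in seq_len(max_iter)) {
    cut_keys <- character(0)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      vids <- which(comp$membership == ci)
      if (length(vids) < 4L) next
      sub <- igraph::induced_subgraph(g, vids)
      simple <- igraph::simplify(sub)
      cl <- igraph::cluster_leiden(simple, objective_function = "modularity",
                                   resolution = resolution, n_iterations = 5)
      memb <- igraph::membership(cl)
      if (max(memb) < 2L) next
      ends <- igraph::ends(simple, igraph::E(simple), names = TRUE)
      m1 <- memb[ends[, 1]]; m2 <- memb[ends[, 2]]
      crossing <- m1 != m2
      if (!any(crossing)) next
      pair <- paste(pmin(m1, m2), pmax(m1, m2))[crossing]
      n_cross <- table(pair)
      csize <- table(memb)
      internal <- table(factor(m1[!crossing], levels = seq_len(max(memb))))
      ok_pair <- vapply(strsplit(names(n_cross), " "), function(ij) {
        min(csize[ij]) >= min_community &&
          n_cross[paste(ij, collapse = " ")] <=
            crossing_rel * min(internal[ij])
      }, logical(1))
      cut_pairs <- names(n_cross)[n_cross <= crossing_max & ok_pair]
      if (!length(cut_pairs)) next
      cut <- which(crossing)[pair %in% cut_pairs]
      cut_keys <- c(cut_keys,
                    paste(pmin(ends[cut, 1], ends[cut, 2]),
                          pmax(ends[cut, 1], ends[cut, 2])))
    }
    if (!length(cut_keys)) break
    # delete every parallel molecule between the flagged pixel pairs
    eg <- igraph::ends(g, igraph::E(g), names = TRUE)
    key <- paste(pmin(eg[, 1], eg[, 2]), pmax(eg[, 1], eg[, 2]))
    g <- igraph::delete_edges(g, which(key %in% cut_keys))
  }
  g
}

#' Call connected components as putative cells
#'
#' Labels every vertex and edge with its component. Components are labelled
#' `C0001`, `C0002`, ... in decreasing order of molecule (edge) count, ties
#' broken by the lexicographically smallest member UPI, so labels do not
#' depend on vertex insertion order.
#'
#' @param g refined bipartite graph
#' @return the graph with `component` vertex and edge attributes
#' @export
call_components <- function(g) {
  comp <- igraph::components(g)
  memb <- comp$membership
  edge_comp <- memb[igraph::ends(g, igraph::E(g), names = FALSE)[, 1]]
  n_edges <- tabulate(edge_comp, nbins = comp$no)
  first_name <- vapply(seq_len(comp$no), function(ci) {
    min(igraph::V(g)$name[memb == ci])
  }, character(1))
  ord <- order(-n_edges, first_name)
  label <- character(comp$no)
  label[ord] <- sprintf("C%04d", seq_len(comp$no))
  igraph::V(g)$component <- label[memb]
  igraph::E(g)$component <- label[edge_comp]
  g
}

#' Molecule counts per called component
#'
#' @param g graph labelled by [call_components()]
#' @return named integer vector of edge (molecule) counts, decreasing
#' @export
component_sizes <- function(g) {
  tab <- table(igraph::E(g)$component)
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  sort(sizes, decreasing = TRUE)
}

#' Spline-elbow size threshold from ranked component sizes
#'
#' Sizes are ranked in decreasing order and a cubic smoothing spline (GCV
#' smoothing) is fitted to log10(size) against rank; first and second
#' derivatives of the fit locate the sharp decline between the cell mode and
#' the debris mode, and the threshold is the fitted size at the steepest
#' point of that decline (the first-derivative minimum). Reading the fitted
#' mid-cliff value, rather than a raw size at a shoulder rank, keeps the
#' cutoff strictly between the two modes even when the cell mode is tight.
#'
#' @param sizes integer component sizes (any order)
#' @param min_components below this many components no stable elbow exists and
#'   a condition of class `mpx_size_fallback` is raised, instructing use of
#'   the manual minimum cutoff
#' @return integer size threshold
#' @export
size_threshold <- function(sizes, min_components = 20L) {
  fallback <- function(msg) {
    stop(structure(class = c("mpx_size_fallback", "error", "condition"),
                   list(message = paste0(msg, "; use the manual minimum cutoff"),
                        call = sys.call(-1))))
  }
  if (length(sizes) < min_components) {
    fallback(sprintf("only %d components (< %d)", length(sizes),
                     min_components))
  }
  sizes <- sort(as.numeric(sizes), decreasing = TRUE)
  rank <- seq_along(sizes)
  ly <- log10(sizes)
  if (diff(range(ly)) < 1e-8) fallback("all components have equal size")
  fit <- stats::smooth.spline(rank, ly, cv = FALSE)
  d1 <- stats::predict(fit, rank, deriv = 1)$y
  d2 <- stats::predict(fit, rank, deriv = 2)$y
  if (max(abs(d2)) < 1e-10) fallback("rank curve has no curvature")
  elbow <- which.min(d1)
  as.integer(round(10^stats::predict(fit, elbow)$y))
}

#' Filter called components by size
#'
#' Drops the `drop_top_k` largest components (aggregates and debris clumps in
#' real libraries), then every component smaller than
#' `max(threshold, manual_min)` molecules.
#'
#' @param sizes named component sizes from [component_sizes()]
#' @param threshold spline-derived size threshold (0 to disable)
#' @param manual_min manual minimum molecules per cell (e.g. 4000 for an
#'   unstimulated PBMC library)
#' @param drop_top_k number of largest components to discard
#' @return list with `retained` (component ids), and `edge_rank` tibble
#'   (`rank`, `component`, `size`, `retained`) for edge-rank plots
#' @export
filter_components <- function(sizes, threshold = 0L, manual_min = 0L,
                              drop_top_k = 10L) {
  if (manual_min < 0) stop("manual_min must be >= 0")
  if (drop_top_k < 0) stop("drop_top_k must be >= 0")
  sizes <- sort(sizes, decreasing = TRUE)
  keep <- rep(TRUE, length(sizes))
  if (drop_top_k > 0) keep[seq_len(min(drop_top_k, length(sizes)))] <- FALSE
  keep <- keep & sizes >= max(threshold, manual_min)
  list(retained = names(sizes)[keep],
       edge_rank = tibble::tibble(rank = seq_along(sizes),
                                  component = names(sizes),
                                  size = as.integer(sizes),
                                  retained = keep))
}

#' Component-by-marker count matrix
#'
#' Sums unique molecules per component and marker. Panel markers absent from
#' a component are explicit zeros; every panel marker is a column.
#'
#' @param edges edge-record tibble carrying a `component` column (see
#'   [component_edge_list()])
#' @param panel an `mpx_panel` (or character vector of marker names)
#' @param components optional component ids to keep (e.g. the retained set);
#'   default all
#' @return sparse `dgCMatrix`, components x markers
#' @export
count_matrix <- function(edges, panel, components = NULL) {
  markers <- if (inherits(panel, "mpx_panel")) panel$markers$marker else panel
  comps <- components %||% sort(unique(edges$component))
  edges <- edges[edges$component %in% comps, , drop = FALSE]
  unknown <- setdiff(unique(edges$marker), markers)
  if (length(unknown)) {
    stop("edge markers absent from panel: ", paste(unknown, collapse = ", "))
  }
  i <- match(edges$component, comps)
  j <- match(edges$marker, markers)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(comps), length(markers)),
                            dimnames = list(comps, markers))
  methods::as(m, "CsparseMatrix")
}

#' Extract the component-annotated edge list from a called graph
#'
#' @param g graph labelled by [call_components()]
#' @return tibble `upia`, `upib`, `marker`, `umi`, `reads`, `component`
#' @export
component_edge_list <- function(g) {
  ed <- igraph::as_data_frame(g, what = "edges")
  tibble::tibble(upia = ed$from, upib = ed$to, marker = ed$marker,
                 umi = ed$umi, reads = as.integer(ed$reads),
                 component = ed$component)
}

#' Tau marker-skewness score and outlier flags
#'
#' For a component with marker counts `x` over `n` markers, the Tau score is
#' `sum(1 - x / max(x)) / (n - 1)`: 0 for perfectly even counts, 1 when all
#' counts sit on a single marker. Components are flagged `HighTau` when tau
#' exceeds `high_cut` or lies more than `high_iqr` interquartile ranges from
#' the population median (antibody aggregates of a single clone), and
#' `LowTau` when tau lies more than `low_iqr` IQRs below/above the median
#' (high-complexity aggregates); `HighTau` takes precedence.
#'
#' @param m count matrix (components x markers), dense or sparse
#' @param high_cut absolute tau cutoff for `HighTau`
#' @param high_iqr IQR multiple for `HighTau`
#' @param low_iqr IQR multiple for `LowTau`
#' @return tibble `component`, `tau`, `flag` (`OK`/`HighTau`/`LowTau`)
#' @export
tau_filter <- function(m, high_cut = 0.995, high_iqr = 2, low_iqr = 5) {
  m <- as.matrix(m)
  if (nrow(m) < 1L) stop("need at least one component")
  n <- ncol(m)
  mx <- apply(m, 1, max)
  tau <- rep(NA_real_, nrow(m))
  ok <- mx > 0
  if (n > 1L) {
    tau[ok] <- rowSums(1 - m[ok, , drop = FALSE] / mx[ok]) / (n - 1)
  } else {
    tau[ok] <- 0
  }
  if (any(!ok)) warning(sum(!ok), " all-zero component(s): tau undefined")
  med <- stats::median(tau, na.rm = TRUE)
  iqr <- stats::IQR(tau, na.rm = TRUE)
  dev <- abs(tau - med)
  flag <- rep("OK", nrow(m))
  flag[dev > low_iqr * iqr] <- "LowTau"
  flag[tau > high_cut | dev > high_iqr * iqr] <- "HighTau"
  flag[!ok] <- "LowTau"
  tibble::tibble(component = rownames(m) %||% as.character(seq_len(nrow(m))),
                 tau = tau, flag = flag)
}

#' One-mode UPI-A projection of a cell component
#'
#' A-pixels become nodes; two A-pixels are joined when they share at least one
#' B-pixel neighbour. Each node carries the vector of unique-molecule counts
#' per marker of the molecules incident to it.
#'
#' @param g bipartite graph (a single connected component, or a called graph
#'   plus `component` to select one)
#' @param panel an `mpx_panel` or character marker universe for the count
#'   columns (default: markers seen in the component)
#' @param component optional component label to extract first
#' @return an `mpx_projection`: list with `graph` (simple undirected igraph),
#'   `counts` (sparse node x marker matrix) and `component`
#' @export
project_a_graph <- function(g, panel = NULL, component = NULL) {
  if (!is.null(component)) {
    vids <- which(igraph::V(g)$component == component)
    if (!length(vids)) stop("unknown component: ", component)
    g <- igraph::induced_subgraph(g, vids)
  } else if (igraph::components(g)$no != 1L) {
    stop("graph has multiple components; pass `component`")
  }
  proj <- igraph::bipartite_projection(g, which = "false",
                                       multiplicity = FALSE)
  ed <- igraph::as_data_frame(g, what = "edges")
  # bipartite edges always run A -> B as built; guard for safety
  a_side <- ifelse(igraph::V(g)$type[match(ed$from, igraph::V(g)$name)],
                   ed$to, ed$from)
  markers <- if (is.null(panel)) sort(unique(ed$marker))
             else if (inherits(panel, "mpx_panel")) panel$markers$marker
             else panel
  nodes <- igraph::V(proj)$name
  counts <- Matrix::sparseMatrix(
    i = match(a_side, nodes), j = match(ed$marker, markers), x = 1,
    dims = c(length(nodes), length(markers)),
    dimnames = list(nodes, markers))
  structure(list(graph = proj,
                 counts = methods::as(counts, "CsparseMatrix"),
                 component = component %||% NA_character_),
            class = "mpx_projection")
}

#' @export
print.mpx_projection <- function(x, ...) {
  cat("One-mode pixel projection:", igraph::vcount(x$graph), "A-pixels,",
      igraph::ecount(x$graph), "edges,", sum(x$counts), "molecules\n")
  invisible(x)
}

#' Export a graph as GraphML
#'
#' @param g an igraph (bipartite or projected)
#' @param path output path
#' @return the path, invisibly
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a count matrix as Matrix Market with row/column sidecars
#'
#' @param m sparse count matrix
#' @param dir output directory
#' @param prefix file name prefix
#' @return the directory, invisibly
#' @export
write_count_matrix <- function(m, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, paste0(prefix, ".mtx")))
  writeLines(rownames(m), file.path(dir, paste0(prefix, "_components.tsv")))
  writeLines(colnames(m), file.path(dir, paste0(prefix, "_markers.tsv")))
  invisible(dir)
}
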