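# Graph-spatial statistics: CLR transform, Moran's-I polarity scores,
# permutation colocalization scores, differential comparisons and CLR gating.

#' Centered log-ratio transform of count vectors
#'
#' Uses the log1p variant, `clr_i = ln(1 + x_i) - mean_j ln(1 + x_j)`, which
#' is defined for the zero counts that dominate sparse antibody panels; every
#' transformed vector sums to zero.
#'
#' @param x non-negative numeric vector, or a matrix/sparse matrix whose rows
#'   are transformed independently
#' @return transformed vector or dense matrix
#' @export
#' @examples
#' clr_transform(c(3, 0, 0))
clr_transform <- function(x) {
  if (is.matrix(x) || inherits(x, "Matrix")) {
    m <- log1p(as.matrix(x))
    return(m - rowMeans(m))
  }
  if (length(x) == 0L) stop("empty count vector")
  if (any(x < 0)) stop("counts must be non-negative")
  lx <- log1p(x)
  lx - mean(lx)
}

# Row-normalised spatial weight matrix of a connected graph.
row_normalised_weights <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  rs <- Matrix::rowSums(A)
  if (any(rs == 0)) stop("graph has isolated nodes")
  Matrix::Diagonal(x = 1 / rs) %*% A
}

# Constants S0, S1, S2 of a (possibly asymmetric) weight matrix, reused
# across markers of one cell.
moran_constants <- function(W) {
  S0 <- sum(W)
  Wt <- Matrix::t(W)
  S1 <- sum((W + Wt)^2) / 2
  S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
  list(S0 = S0, S1 = S1, S2 = S2, N = nrow(W))
}

# Moran's I plus closed-form randomization moments for precomputed weights.
moran_stat <- function(W, consts, x) {
  N <- consts$N
  z <- x - mean(x)
  den <- sum(z^2)
  if (den < .Machine$double.eps * N) {
    return(list(I = NA_real_, expected = NA_real_, sd = NA_real_,
                z = NA_real_, p = NA_real_, flag = "zero_variance"))
  }
  num <- sum(z * as.numeric(W %*% z))
  I <- (N / consts$S0) * num / den
  EI <- -1 / (N - 1)
  out <- list(I = I, expected = EI, sd = NA_real_, z = NA_real_,
              p = NA_real_, flag = "ok")
  if (N >= 4) {
    b2 <- N * sum(z^4) / den^2
    S0 <- consts$S0; S1 <- consts$S1; S2 <- consts$S2
    EI2 <- (N * ((N^2 - 3 * N + 3) * S1 - N * S2 + 3 * S0^2) -
              b2 * ((N^2 - N) * S1 - 2 * N * S2 + 6 * S0^2)) /
      ((N - 1) * (N - 2) * (N - 3) * S0^2)
    v <- EI2 - EI^2
    if (v > 0) {
      out$sd <- sqrt(v)
      out$z <- (I - EI) / out$sd
      out$p <- 2 * stats::pnorm(-abs(out$z))
    }
  }
  out
}

#' Moran's I spatial autocorrelation on a graph
#'
#' Computes Moran's I of `values` over the row-normalised adjacency of a
#' connected graph, `I = (N / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)`, together with the closed-form expectation
#' `E[I] = -1/(N-1)`, standard deviation, z-score and two-sided p-value under
#' the randomization null (moments require N >= 4).
#'
#' @param graph connected igraph (one cell component's projection)
#' @param values numeric node attribute vector, in vertex order
#' @return one-row tibble: `morans_i`, `expected`, `sd`, `z`, `p`, `n_nodes`,
#'   `flag` (`ok` or `zero_variance`)
#' @export
morans_i <- function(graph, values) {
  if (igraph::components(graph)$no != 1L) {
    stop("graph must be a single connected component")
  }
  n <- igraph::vcount(graph)
  if (n < 2L) stop("need at least 2 nodes")
  if (length(values) != n) stop("values length must equal node count")
  W <- row_normalised_weights(graph)
  st <- moran_stat(W, moran_constants(W), values)
  tibble::tibble(morans_i = st$I, expected = st$expected, sd = st$sd,
                 z = st$z, p = st$p, n_nodes = n, flag = st$flag)
}

#' Per-marker polarity scores of one cell
#'
#' The polarity score of a marker is Moran's I of that marker's CLR value
#' over the one-mode pixel projection: each node's marker counts are CLR
#' transformed across markers ([clr_transform()]), and the marker's column is
#' tested for spatial autocorrelation. Positive scores indicate spatial
#' clustering; scores near zero indicate random placement. Markers with zero
#' variance across nodes are flagged, not silently zeroed.
#'
#' @param proj an `mpx_projection` from [project_a_graph()]
#' @return tibble `component`, `marker`, `morans_i`, `z`, `p`, `n_nodes`,
#'   `flag`
#' @export
polarity_scores <- function(proj) {
  stopifnot(inherits(proj, "mpx_projection"))
  g <- proj$graph
  n <- igraph::vcount(g)
  markers <- colnames(proj$counts)
  if (n < 3L) {
    return(tibble::tibble(component = proj$component, marker = markers,
                          morans_i = NA_real_, z = NA_real_, p = NA_real_,
                          n_nodes = n, flag = "too_few_nodes"))
  }
  W <- row_normalised_weights(g)
  consts <- moran_constants(W)
  vals <- clr_transform(proj$counts)
  res <- lapply(markers, function(mk) {
    st <- moran_stat(W, consts, vals[, mk])
    tibble::tibble(component = proj$component, marker = mk,
                   morans_i = st$I, z = st$z, p = st$p, n_nodes = n,
                   flag = st$flag)
  })
  do.call(rbind, res)
}

#' Pairwise colocalization scores of one cell
#'
#' Six-step permutation score per unordered marker pair on the one-mode
#' projection: (1) markers with fewer than `min_marker` total molecules are
#' dropped; (2) each node's counts are aggregated over the node and its
#' immediate neighbours, and nodes whose aggregated total across markers is
#' below `min_neighborhood` are dropped; (3) `n_perm` permuted cells are
#' built by shuffling each marker's node counts across nodes independently
#' (preserving marker totals and graph topology), re-aggregated the same way;
#' (4) aggregated counts are log1p transformed; (5) Pearson's r is computed
#' per marker pair; (6) the permuted r values are fitted as a Gaussian null,
#' yielding `z = (r - perm_mean) / perm_sd` and a two-sided p-value. The
#' colocalization score reported in comparisons is `z`; negative scores
#' indicate spatial segregation of the pair.
#'
#' @param proj an `mpx_projection`
#' @param min_marker minimum total molecules for a marker to enter
#' @param min_neighborhood minimum aggregated neighbourhood total for a node
#' @param n_perm number of permutations (>= 10)
#' @param seed integer seed for the permutations
#' @return tibble `component`, `marker_1`, `marker_2`, `pearson_r`,
#'   `perm_mean`, `perm_sd`, `z`, `p`, `n_permutations`, `n_nodes_used`,
#'   `flag`
#' @export
colocalization_scores <- function(proj, min_marker = 10L,
                                  min_neighborhood = 5L, n_perm = 50L,
                                  seed = 1L) {
  stopifnot(inherits(proj, "mpx_projection"), n_perm >= 10L)
  counts <- as.matrix(proj$counts)
  keep_mk <- colSums(counts) >= min_marker
  empty <- tibble::tibble(component = character(0), marker_1 = character(0),
                          marker_2 = character(0), pearson_r = numeric(0),
                          perm_mean = numeric(0), perm_sd = numeric(0),
                          z = numeric(0), p = numeric(0),
                          n_permutations = integer(0),
                          n_nodes_used = integer(0), flag = character(0))
  if (sum(keep_mk) < 2L) return(empty)
  counts <- counts[, keep_mk, drop = FALSE]
  markers <- colnames(counts)
  A1 <- igraph::as_adjacency_matrix(proj$graph, sparse = TRUE) +
    Matrix::Diagonal(igraph::vcount(proj$graph))

  aggregate <- function(cm) {
    agg <- as.matrix(A1 %*% cm)
    agg[rowSums(agg) >= min_neighborhood, , drop = FALSE]
  }
  obs <- aggregate(counts)
  if (nrow(obs) < 3L) return(empty)
  r_obs <- stats::cor(log1p(obs))

  set.seed(seed)
  nmk <- length(markers)
  perm_r <- array(NA_real_, dim = c(nmk, nmk, n_perm))
  n_nodes <- nrow(counts)
  for (p in seq_len(n_perm)) {
    shuffled <- counts
    for (j in seq_len(nmk)) {
      shuffled[, j] <- counts[sample.int(n_nodes), j]
    }
    ap <- aggregate(shuffled)
    if (nrow(ap) >= 3L) perm_r[, , p] <- stats::cor(log1p(ap))
  }
  pairs <- utils::combn(seq_len(nmk), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    null_r <- perm_r[i, j, ]
    null_r <- null_r[is.finite(null_r)]
    mu <- mean(null_r); sdv <- stats::sd(null_r)
    r <- r_obs[i, j]
    flag <- "ok"
    z <- pv <- NA_real_
    if (!is.finite(r)) {
      flag <- "undefined_r"
    } else if (!is.finite(sdv) || sdv == 0) {
      flag <- "degenerate_null"
    } else {
      z <- (r - mu) / sdv
      pv <- 2 * stats::pnorm(-abs(z))
    }
    tibble::tibble(component = proj$component,
                   marker_1 = markers[i], marker_2 = markers[j],
                   pearson_r = r, perm_mean = mu, perm_sd = sdv,
                   z = z, p = pv, n_permutations = length(null_r),
                   n_nodes_used = nrow(obs), flag = flag)
  })
  do.call(rbind, res)
}

#' Differential comparison of abundance or spatial scores between conditions
#'
#' For each condition against the reference and each marker (or marker pair),
#' cells are downsampled without replacement to `downsample_n` per group and
#' compared by a two-sided Wilcoxon rank-sum test; p-values are adjusted
#' across features within each condition. The effect size is the group mean
#' difference, reported as log2 fold change when `mode = "abundance"` (values
#' are natural-log CLR counts, so the difference is divided by `ln 2`).
#'
#' @param data tibble with columns `component`, `condition`, `feature`
#'   (marker or `"A/B"` pair label) and `value`
#' @param reference condition label used as baseline
#' @param mode `"abundance"`, `"polarity"` or `"colocalization"`
#' @param downsample_n cells per group (default 50; 100 is conventional for
#'   colocalization); groups smaller than this are used whole, with a warning
#' @param adjust `"BH"` or `"bonferroni"`
#' @param seed seed for the downsampling draw
#' @return tibble `condition`, `reference`, `feature`, `effect`, `p`,
#'   `p_adjusted`, `n_reference`, `n_condition`, `method`
#' @export
differential_analysis <- function(data, reference,
                                  mode = c("abundance", "polarity",
                                           "colocalization"),
                                  downsample_n = 50L,
                                  adjust = c("BH", "bonferroni"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  stopifnot(all(c("component", "condition", "feature", "value") %in%
                  names(data)))
  if (!reference %in% data$condition) stop("reference condition absent")
  set.seed(seed)
  conditions <- setdiff(unique(data$condition), reference)
  sample_cells <- function(cells) {
    cells <- unique(cells)
    if (length(cells) < downsample_n) {
      warning("group smaller than downsample_n; using all ", length(cells),
              " cells")
      return(cells)
    }
    sample(cells, downsample_n)
  }
  out <- lapply(conditions, function(cond) {
    ref_cells <- sample_cells(data$component[data$condition == reference])
    cond_cells <- sample_cells(data$component[data$condition == cond])
    feats <- sort(unique(data$feature))
    rows <- lapply(feats, function(f) {
      xr <- data$value[data$condition == reference & data$feature == f &
                         data$component %in% ref_cells]
      xc <- data$value[data$condition == cond & data$feature == f &
                         data$component %in% cond_cells]
      if (length(xr) < 2L || length(xc) < 2L) return(NULL)
      p <- suppressWarnings(
        stats::wilcox.test(xc, xr, alternative = "two.sided")$p.value)
      eff <- mean(xc) - mean(xr)
      if (mode == "abundance") eff <- eff / log(2)
      tibble::tibble(condition = cond, reference = reference, feature = f,
                     effect = eff, p = p, n_reference = length(xr),
                     n_condition = length(xc))
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) return(NULL)
    rows$p_adjusted <- stats::p.adjust(
      rows$p, method = if (adjust == "BH") "BH" else "bonferroni")
    rows$method <- adjust
    rows
  })
  do.call(rbind, out)
}

#' Gating rules on CLR-transformed counts
#'
#' `gate_rule()` is a single cutoff (`marker > cutoff` or `marker < cutoff`);
#' `gate_any()` groups rules as a disjunction (e.g. CD4-positive *or*
#' CD8-positive). [gate_components()] retains the components satisfying the
#' conjunction of all top-level rules.
#'
#' @param marker marker name
#' @param op `">"` or `"<"`
#' @param cutoff CLR cutoff
#' @return rule objects consumed by [gate_components()]
#' @export
gate_rule <- function(marker, op = c(">", "<"), cutoff) {
  op <- match.arg(op)
  structure(list(marker = marker, op = op, cutoff = cutoff),
            class = "mpx_gate_rule")
}

#' @rdname gate_rule
#' @param ... `gate_rule()`s to combine with OR
#' @export
gate_any <- function(...) {
  rules <- list(...)
  stopifnot(all(vapply(rules, inherits, logical(1), "mpx_gate_rule")))
  structure(rules, class = "mpx_gate_any")
}

#' Gate components on CLR counts
#'
#' @param clr matrix of CLR-transformed counts (components x markers)
#' @param rules list of [gate_rule()] / [gate_any()] objects (conjunction);
#'   an empty list retains everything
#' @return character vector of retained component ids
#' @export
#' @examples
#' clr <- matrix(c(1.0, 2.0, 0.1), 1, dimnames = list("C0001",
#'               c("CD3", "CD4", "CD19")))
#' gate_components(clr, list(gate_rule("CD3", ">", 0.9)))
gate_components <- function(clr, rules = list()) {
  clr <- as.matrix(clr)
  eval_rule <- function(r) {
    if (inherits(r, "mpx_gate_any")) {
      return(Reduce(`|`, lapply(unclass(r), eval_rule)))
    }
    if (!r$marker %in% colnames(clr)) stop("unknown marker: ", r$marker)
    if (r$op == ">") clr[, r$marker] > r$cutoff else clr[, r$marker] < r$cutoff
  }
  keep <- rep(TRUE, nrow(clr))
  for (r in rules) keep <- keep & eval_rule(r)
  rownames(clr)[keep]
}

#' The paper-style T cell gate
#'
#' Convenience rule set for extracting the T cell fraction from a PBMC count
#' matrix on CLR counts: CD3 > 0.9 and (CD4 > 1.8 or CD8 > 1.5), excluding
#' B cells and monocytes via CD19 < 0.5, CD20 < 1.1 and CD14 < 0.5.
#'
#' @return a rule list for [gate_components()]
#' @export
t_cell_gate <- function() {
  list(gate_rule("CD3", ">", 0.9),
       gate_any(gate_rule("CD4", ">", 1.8), gate_rule("CD8", ">", 1.5)),
       gate_rule("CD19", "<", 0.5),
       gate_rule("CD20", "<", 1.1),
       gate_rule("CD14", "<", 0.5))
}
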