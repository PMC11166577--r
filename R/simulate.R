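# Ground-truth simulator of a molecular pixelation experiment. A cell is a
# unit sphere; antibody-conjugate molecules are points on it (uniform or von
# Mises-Fisher distributed); pixel zones are spherical caps whose centers are
# uniform on the sphere; each molecule hybridises to one uniformly chosen
# zone per set among those whose reach covers it, or is dropped.

#' Spatial placement patterns for a marker
#'
#' `pattern_uniform()` places molecules uniformly on the cell sphere.
#' `pattern_polarized()` draws molecule positions from a von Mises-Fisher
#' distribution with concentration `kappa` around a pole (random per cell if
#' `pole` is `NULL`). `pattern_colocalized()` polarizes a marker around the
#' *partner marker's* pole, so the pair co-occupies one cap.
#'
#' @param kappa von Mises-Fisher concentration (>= 0; 0 is uniform)
#' @param pole optional length-3 unit vector; `NULL` draws a random pole
#' @param partner marker name whose pole is shared
#' @return an `mpx_pattern` list
#' @export
pattern_uniform <- function() {
  structure(list(type = "uniform"), class = "mpx_pattern")
}

#' @rdname pattern_uniform
#' @export
pattern_polarized <- function(kappa, pole = NULL) {
  stopifnot(kappa >= 0)
  if (!is.null(pole)) pole <- pole / sqrt(sum(pole^2))
  structure(list(type = "polarized", kappa = kappa, pole = pole),
            class = "mpx_pattern")
}

#' @rdname pattern_uniform
#' @export
pattern_colocalized <- function(partner, kappa, pole = NULL) {
  stopifnot(kappa >= 0, is.character(partner))
  if (!is.null(pole)) pole <- pole / sqrt(sum(pole^2))
  structure(list(type = "colocalized", partner = partner, kappa = kappa,
                 pole = pole), class = "mpx_pattern")
}

#' Specify one simulated cell
#'
#' @param abundance named numeric vector: expected molecule count per marker
#'   (realised counts are Poisson draws)
#' @param cell_type label carried into the ground truth
#' @param patterns named list of [pattern_uniform()]/[pattern_polarized()]/
#'   [pattern_colocalized()] entries; markers absent from the list are uniform
#' @param n_pixels_a,n_pixels_b number of A / B pixel zones on the cell
#' @param pixel_radius angular radius (radians) of a zone cap on the unit
#'   sphere; default `4 / sqrt(n_pixels_a)`, twice the close-packing radius,
#'   which captures ~96% of molecules at the calibration defaults
#' @return an `mpx_cell_spec`
#' @export
#' @examples
#' spec <- cell_spec(abundance = c(CD3 = 200, CD45 = 300),
#'                   patterns = list(CD3 = pattern_polarized(10)),
#'                   n_pixels_a = 100, n_pixels_b = 100)
cell_spec <- function(abundance, cell_type = "cell", patterns = list(),
                      n_pixels_a = 1737L, n_pixels_b = 1737L,
                      pixel_radius = NULL) {
  stopifnot(is.numeric(abundance), length(abundance) >= 1,
            !is.null(names(abundance)), all(abundance >= 0),
            n_pixels_a >= 1, n_pixels_b >= 1)
  pixel_radius <- pixel_radius %||% (4 / sqrt(n_pixels_a))
  if (pixel_radius <= 0) stop("pixel_radius must be positive")
  bad <- setdiff(names(patterns), names(abundance))
  if (length(bad)) stop("patterns for unknown markers: ", paste(bad, collapse = ", "))
  for (p in patterns) {
    stopifnot(inherits(p, "mpx_pattern"))
    if (!is.null(p$kappa) && p$kappa < 0) stop("kappa must be >= 0")
  }
  structure(list(cell_type = cell_type, abundance = abundance,
                 patterns = patterns,
                 n_pixels_a = as.integer(n_pixels_a),
                 n_pixels_b = as.integer(n_pixels_b),
                 pixel_radius = pixel_radius),
            class = "mpx_cell_spec")
}

#' Paper-calibrated default cell specification
#'
#' Expected totals follow the assay calibration of ~1,737 A zones and ~9,580
#' unique molecules per cell, spread over the panel with a mildly skewed
#' (log-normal) abundance profile.
#'
#' @param panel an `mpx_panel`
#' @param total_molecules expected molecules per cell
#' @param skew log-normal sdlog of the per-marker abundance profile
#' @param seed seed for the abundance profile draw
#' @inheritParams cell_spec
#' @return an `mpx_cell_spec`
#' @export
default_cell_spec <- function(panel, total_molecules = 9580, skew = 1,
                              seed = 1L, cell_type = "cell",
                              patterns = list(),
                              n_pixels_a = 1737L, n_pixels_b = 1737L) {
  set.seed(seed)
  w <- stats::rlnorm(nrow(panel$markers), sdlog = skew)
  ab <- total_molecules * w / sum(w)
  names(ab) <- panel$markers$marker
  cell_spec(ab, cell_type = cell_type, patterns = patterns,
            n_pixels_a = n_pixels_a, n_pixels_b = n_pixels_b)
}

# Redraw UMIs until molecules within one zone group are pairwise at
# Hamming distance >= min_dist (and globally unique).
resolve_umi_conflicts <- function(umi, group, min_dist = 3L,
                                  max_rounds = 50L) {
  if (length(umi) < 2L) return(umi)
  len <- nchar(umi[1])
  grp <- split(seq_along(umi), group)
  grp <- grp[lengths(grp) > 1L]
  if (!length(grp)) return(umi)
  pair_mat <- do.call(cbind, lapply(grp, utils::combn, m = 2L))
  pi <- pair_mat[1L, ]; pj <- pair_mat[2L, ]
  for (round in seq_len(max_rounds)) {
    d <- hamming_pairwise(umi[pi], umi[pj])
    bad <- unique(pj[d < min_dist])
    if (!length(bad)) return(umi)
    repeat {
      umi[bad] <- random_seq(length(bad), len)
      if (!anyDuplicated(umi)) break
    }
  }
  warning("unresolved UMI proximity within a zone after ", max_rounds,
          " rounds")
  umi
}

# Uniform points on the unit sphere.
runif_sphere <- function(n) {
  z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
  m <- cbind(x, y, z)
  m / sqrt(rowSums(m^2))
}

# von Mises-Fisher samples on S2 around unit vector mu, concentration kappa.
# Uses the closed-form inverse CDF of the cosine for d = 3.
rvmf <- function(n, mu, kappa) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  if (kappa == 0) return(runif_sphere(n))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  # orthonormal frame around mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  outer(w, mu) + outer(s * cos(phi), e1) + outer(s * sin(phi), e2)
}

#' Simulate one cell
#'
#' Draws molecule positions per the spatial patterns, places `n_pixels_a` +
#' `n_pixels_b` zone centers uniformly on the sphere, and hybridises every
#' molecule to one uniformly chosen A zone and one B zone among those whose
#' angular reach (`pixel_radius`) covers the molecule; molecules outside all
#' zones of either set are dropped, modelling unhybridised conjugates. Each
#' zone carries a globally unique UPI sequence, each molecule a UMI unique
#' within the cell.
#'
#' @param spec an [cell_spec()]
#' @param seed integer seed (deterministic truth for fixed `(spec, seed)`)
#' @param cell_id identifier prefix for zones and molecules
#' @param upi_length,umi_length sequence lengths used for UPIs/UMIs
#' @return an `mpx_sim` ground truth: tibbles `molecules` (cell, marker, x/y/z,
#'   zone_a, zone_b, umi), `zones` (zone, set, upi, x/y/z), `cells`, and the
#'   derived bipartite `edges` tibble (`upia`, `upib`, `marker`, `umi`, `reads`)
#' @export
simulate_cell <- function(spec, seed, cell_id = "cell1",
                          upi_length = 25L, umi_length = 10L) {
  stopifnot(inherits(spec, "mpx_cell_spec"))
  set.seed(seed)
  markers <- names(spec$abundance)
  counts <- stats::rpois(length(markers), spec$abundance)
  names(counts) <- markers
  total <- sum(counts)

  # resolve poles: polarized markers first, colocalized borrow the partner's
  poles <- list()
  for (mk in markers) {
    p <- spec$patterns[[mk]]
    if (!is.null(p) && p$type == "polarized") {
      poles[[mk]] <- p$pole %||% as.numeric(runif_sphere(1))
    }
  }
  for (mk in markers) {
    p <- spec$patterns[[mk]]
    if (!is.null(p) && p$type == "colocalized") {
      poles[[mk]] <- p$pole %||% poles[[p$partner]] %||%
        as.numeric(runif_sphere(1))
      # a colocalized partner that is itself unpatterned gets the shared pole
      pp <- spec$patterns[[p$partner]]
      if (is.null(pp) && is.null(poles[[p$partner]])) {
        poles[[p$partner]] <- poles[[mk]]
      }
    }
  }

  if (total == 0) {
    warning("cell ", cell_id, " realised zero molecules")
    return(.empty_sim(spec, seed, cell_id))
  }

  pos <- matrix(0, nrow = total, ncol = 3)
  marker_col <- rep(markers, counts)
  at <- 1L
  for (mk in markers) {
    n <- counts[[mk]]
    if (n == 0L) next
    p <- spec$patterns[[mk]]
    kap <- if (!is.null(p) && p$type %in% c("polarized", "colocalized")) p$kappa else 0
    # uniform markers that were promoted to a shared pole stay uniform unless
    # they have an explicit pattern
    pts <- if (kap > 0) rvmf(n, poles[[mk]], kap) else runif_sphere(n)
    pos[at:(at + n - 1L), ] <- pts
    at <- at + n
  }

  zones_a <- runif_sphere(spec$n_pixels_a)
  zones_b <- runif_sphere(spec$n_pixels_b)
  min_cos <- cos(spec$pixel_radius)

  # a molecule hybridises to a uniformly chosen zone whose reach covers it
  # (dropped when no zone of the set is within pixel_radius); candidate
  # lookups are restricted to neighbouring z-slabs, whose height is at least
  # the chord length of pixel_radius, so no candidate is missed
  chord <- 2 * sin(min(spec$pixel_radius, pi) / 2)
  assign_zone <- function(pos, centers) {
    n <- nrow(pos)
    idx <- rep(NA_integer_, n)
    nb <- max(1L, min(64L, floor(2 / chord)))
    slab <- function(z) pmin(nb, pmax(1L, ceiling((z + 1) / 2 * nb)))
    zb_zone <- slab(centers[, 3])
    zb_mol <- slab(pos[, 3])
    for (b in seq_len(nb)) {
      mi <- which(zb_mol == b)
      if (!length(mi)) next
      zi <- which(zb_zone >= b - 1L & zb_zone <= b + 1L)
      if (!length(zi)) next
      dots <- pos[mi, , drop = FALSE] %*% t(centers[zi, , drop = FALSE])
      mask <- dots >= min_cos
      n_cand <- rowSums(mask)
      hit <- which(mask, arr.ind = TRUE)
      hit <- hit[order(hit[, 1]), , drop = FALSE]
      has <- n_cand > 0
      pick <- floor(stats::runif(length(mi)) * n_cand) + 1
      starts <- cumsum(c(0, n_cand))[seq_along(mi)]
      idx[mi[has]] <- zi[hit[starts[has] + pick[has], 2]]
    }
    idx
  }
  ia <- assign_zone(pos, zones_a)
  ib <- assign_zone(pos, zones_b)
  keep <- !is.na(ia) & !is.na(ib)

  upi_a <- random_unique_seq(spec$n_pixels_a, upi_length)
  upi_b <- random_unique_seq(spec$n_pixels_b, upi_length)
  umi <- random_unique_seq(total, umi_length)
  # molecules sharing an A zone share the deduplication key up to their UMI;
  # keep those UMIs at Hamming distance >= 3 so distinct molecules are never
  # conflated by error correction (collision-robust key design)
  umi[keep] <- resolve_umi_conflicts(umi[keep], ia[keep], min_dist = 3L)

  zone_a_id <- sprintf("%s_A%04d", cell_id, seq_len(spec$n_pixels_a))
  zone_b_id <- sprintf("%s_B%04d", cell_id, seq_len(spec$n_pixels_b))

  molecules <- tibble::tibble(
    cell_id = cell_id,
    marker = marker_col[keep],
    x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
    zone_a = zone_a_id[ia[keep]],
    zone_b = zone_b_id[ib[keep]],
    umi = umi[keep]
  )
  zones <- tibble::tibble(
    zone = c(zone_a_id, zone_b_id),
    set = rep(c("A", "B"), c(spec$n_pixels_a, spec$n_pixels_b)),
    upi = c(upi_a, upi_b),
    x = c(zones_a[, 1], zones_b[, 1]),
    y = c(zones_a[, 2], zones_b[, 2]),
    z = c(zones_a[, 3], zones_b[, 3])
  )
  cells <- tibble::tibble(cell_id = cell_id, cell_type = spec$cell_type,
                          entity = cell_id, is_doublet = FALSE)
  .as_sim(molecules, zones, cells, list(spec), seed)
}

.empty_sim <- function(spec, seed, cell_id) {
  .as_sim(
    tibble::tibble(cell_id = character(0), marker = character(0),
                   x = numeric(0), y = numeric(0), z = numeric(0),
                   zone_a = character(0), zone_b = character(0),
                   umi = character(0)),
    tibble::tibble(zone = character(0), set = character(0), upi = character(0),
                   x = numeric(0), y = numeric(0), z = numeric(0)),
    tibble::tibble(cell_id = cell_id, cell_type = spec$cell_type,
                   entity = cell_id, is_doublet = FALSE),
    list(spec), seed)
}

.as_sim <- function(molecules, zones, cells, specs, seed) {
  upi_of <- stats::setNames(zones$upi, zones$zone)
  edges <- tibble::tibble(
    upia = unname(upi_of[molecules$zone_a]),
    upib = unname(upi_of[molecules$zone_b]),
    marker = molecules$marker,
    umi = molecules$umi,
    reads = rep(1L, nrow(molecules))
  )
  structure(list(molecules = molecules, zones = zones, cells = cells,
                 edges = edges, specs = specs, seed = seed),
            class = "mpx_sim")
}

#' @export
print.mpx_sim <- function(x, ...) {
  cat("Simulated pixelation truth:", nrow(x$cells), "cells,",
      nrow(x$molecules), "molecules,", nrow(x$zones), "zones\n")
  invisible(x)
}

#' Simulate a multi-cell sample
#'
#' Emits `n_cells` independent cells cycling over `specs`. Each cell draws its
#' own RNG stream from a fixed per-cell offset of `seed`, so cell order does
#' not change any cell's truth. A fraction of cells are merged pairwise into
#' doublet entities: both cells' molecules are kept with their own zone sets,
#' and a small interface fraction of the second cell's molecules re-hybridise
#' to B zones of the first, creating the few spurious cross-edges a fused
#' particle contributes.
#'
#' @param specs a single [cell_spec()] or list of specs (recycled over cells)
#' @param n_cells number of cells to emit
#' @param doublet_fraction fraction of cells converted into doublets;
#'   `floor(doublet_fraction * n_cells)` doublet entities are formed (capped at
#'   `floor(n_cells / 2)`), each consuming two cells
#' @param seed integer seed
#' @param interface_fraction fraction of the smaller partner's molecules that
#'   cross the doublet interface (a handful of bridging edges at realistic
#'   cell sizes)
#' @return an `mpx_sim`; `$edges` is the sample-wide edge list and
#'   `$cells$entity` groups cells merged into one doublet
#' @export
simulate_sample <- function(specs, n_cells, doublet_fraction = 0, seed = 1L,
                            interface_fraction = 0.001) {
  if (inherits(specs, "mpx_cell_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, n_cells >= 1,
            doublet_fraction >= 0, doublet_fraction <= 1)
  sims <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    spec <- specs[[(i - 1L) %% length(specs) + 1L]]
    sims[[i]] <- simulate_cell(spec, seed = stage_seed(seed, paste0("cell", i)),
                               cell_id = sprintf("cell%03d", i))
  }
  molecules <- do.call(rbind, lapply(sims, `[[`, "molecules"))
  zones <- do.call(rbind, lapply(sims, `[[`, "zones"))
  cells <- do.call(rbind, lapply(sims, `[[`, "cells"))
  # UPIs must be unique across the whole sample
  dup <- duplicated(zones$upi)
  if (any(dup)) {
    zones$upi[dup] <- random_unique_seq(sum(dup), nchar(zones$upi[1]))
  }

  n_doublets <- min(floor(doublet_fraction * n_cells), floor(n_cells / 2))
  if (n_doublets > 0) {
    set.seed(stage_seed(seed, "doublets"))
    order_ids <- sample(cells$cell_id)
    for (d in seq_len(n_doublets)) {
      c1 <- order_ids[2 * d - 1L]; c2 <- order_ids[2 * d]
      ent <- sprintf("doublet%02d", d)
      cells$entity[cells$cell_id %in% c(c1, c2)] <- ent
      cells$is_doublet[cells$cell_id %in% c(c1, c2)] <- TRUE
      i1 <- which(molecules$cell_id == c1)
      i2 <- which(molecules$cell_id == c2)
      n_int <- max(1L, ceiling(interface_fraction * min(length(i1), length(i2))))
      if (length(i2) > 0 && length(i1) > 0) {
        cross <- sample(i2, min(n_int, length(i2)))
        b1 <- zones$zone[zones$set == "B" & startsWith(zones$zone, paste0(c1, "_"))]
        molecules$zone_b[cross] <- sample(b1, length(cross), replace = TRUE)
      }
    }
  }
  sim <- .as_sim(molecules, zones, cells, specs, seed)
  sim
}

#' Extract the ground-truth edge list
#'
#' @param sim an `mpx_sim`
#' @return tibble with columns `upia`, `upib`, `marker`, `umi`, `reads`
#' @export
edge_list <- function(sim) {
  stopifnot(inherits(sim, "mpx_sim"))
  sim$edges
}

#' Write ground-truth tables as TSV
#'
#' @param sim an `mpx_sim`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$molecules, file.path(dir, "molecules.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$zones, file.path(dir, "zones.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
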