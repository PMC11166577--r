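panel8 <- tiny_panel()

test_that("the CLR transform centres log1p counts", {
  expect_equal(clr_transform(c(5, 5, 5)), c(0, 0, 0))
  got <- clr_transform(c(3, 0, 0))
  expect_equal(got, c(0.924, -0.462, -0.462), tolerance = 1e-3)
  expect_equal(got, log1p(c(3, 0, 0)) - mean(log1p(c(3, 0, 0))))
  set.seed(2)
  for (i in 1:10) {
    x <- stats::rpois(20, 4)
    expect_equal(mean(clr_transform(x)), 0)
  }
  m <- matrix(stats::rpois(40, 3), 8, 5)
  cm <- clr_transform(m)
  expect_equal(unname(rowSums(cm)), rep(0, 8))
  expect_error(clr_transform(numeric(0)), "empty")
  expect_error(clr_transform(c(-1, 2)), "non-negative")
})

test_that("Moran's I reproduces hand-worked path and two-node examples", {
  pg <- igraph::make_graph(~ A - B, B - C, C - D)
  expect_equal(morans_i(pg, c(1, 1, 0, 0))$morans_i, 0.5)
  g2 <- igraph::make_graph(~ A - B)
  expect_equal(morans_i(g2, c(1, -1))$morans_i, -1)
})

test_that("Moran's I equals the brute-force double sum on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    g <- random_connected_graph(sample(4:30, 1), stats::runif(1, 0.25, 0.8))
    x <- stats::rnorm(igraph::vcount(g))
    r <- morans_i(g, x)
    expect_equal(r$morans_i, brute_moran(g, x), tolerance = 1e-12)
    expect_equal(r$expected, -1 / (igraph::vcount(g) - 1))
  }
})

test_that("randomization moments match a Monte-Carlo permutation null", {
  set.seed(7)
  g <- random_connected_graph(18, 0.35)
  x <- stats::rnorm(18)
  r <- morans_i(g, x)
  perm <- replicate(3000, morans_i(g, sample(x))$morans_i)
  se <- stats::sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - r$expected), 3 * se)
  expect_equal(stats::sd(perm), r$sd, tolerance = 0.05)
})

test_that("Moran moments agree with an independent library implementation", {
  set.seed(19)
  for (rep in 1:5) {
    g <- random_connected_graph(sample(8:20, 1), 0.4)
    x <- stats::rnorm(igraph::vcount(g))
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    ref <- ape::Moran.I(x, A / rowSums(A))
    got <- morans_i(g, x)
    expect_equal(got$morans_i, ref$observed, tolerance = 1e-12)
    expect_equal(got$sd, ref$sd, tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate Moran inputs are flagged, not silently zeroed", {
  g <- random_connected_graph(6, 0.8)
  r <- morans_i(g, rep(2, 6))
  expect_equal(r$flag, "zero_variance")
  expect_true(is.na(r$morans_i))
  two <- igraph::make_graph(~ A - B, B - C) # 3 nodes: I defined, moments not
  r3 <- morans_i(two, c(1, 0, 2))
  expect_true(is.finite(r3$morans_i))
  expect_true(is.na(r3$z))
  expect_error(morans_i(igraph::make_graph(~ A - B, C - D), c(1, 2, 3, 4)),
               "connected")
})

test_that("polarity scores separate clustered from random markers", {
  spec <- even_spec(panel8, total = 1000, n_pix = 150,
                    patterns = list(CD3 = pattern_polarized(20)))
  pol <- do.call(rbind, lapply(1:5, function(s) {
    cell_polarity(spec, seed = 400 + s, panel8)
  }))
  cd3 <- pol$morans_i[pol$marker == "CD3"]
  rest <- pol$morans_i[pol$marker != "CD3" & pol$flag == "ok"]
  expect_true(all(cd3 > 0.1))
  expect_lt(abs(mean(rest)), 0.05)
  # isotype-like uniform markers stay near zero despite CD3 polarization
  expect_lt(max(abs(rest)), 0.2)
})

test_that("polarity z-scores are calibrated on uniform cells", {
  spec <- even_spec(panel8, total = 900, n_pix = 120)
  pol <- do.call(rbind, lapply(1:40, function(s) {
    cell_polarity(spec, seed = 500 + s, panel8)
  }))
  z <- pol$z[pol$flag == "ok"]
  expect_gt(length(z), 300)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(stats::sd(z), 0.85)
  expect_lt(stats::sd(z), 1.15)
})

test_that("scores are invariant to node relabelling", {
  spec <- even_spec(panel8, total = 800, n_pix = 120,
                    patterns = list(CD3 = pattern_polarized(5)))
  sim <- simulate_cell(spec, seed = 61)
  g <- build_graph(edge_list(sim))
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  proj <- project_a_graph(giant, panel = panel8)
  # permute vertex order of the projection, keeping counts aligned
  set.seed(3)
  perm <- sample(igraph::vcount(proj$graph))
  proj2 <- proj
  proj2$graph <- igraph::permute(proj$graph, perm)
  counts2 <- proj$counts
  rownames(counts2) <- igraph::V(proj$graph)$name
  proj2$counts <- counts2[igraph::V(proj2$graph)$name, ]
  p1 <- polarity_scores(proj)
  p2 <- polarity_scores(proj2)
  expect_equal(p2$morans_i, p1$morans_i, tolerance = 1e-12)
  c1 <- colocalization_scores(proj, n_perm = 20, seed = 5)
  c2 <- colocalization_scores(proj2, n_perm = 20, seed = 5)
  expect_equal(c2$pearson_r, c1$pearson_r, tolerance = 1e-12)
})

test_that("colocalization drops markers below the count filter", {
  # toy component: marker totals {9, 10, 12} -> pairs involve only >= 10
  set.seed(9)
  ed <- tibble::tibble(
    upia = sprintf("A%02d", sample(12, 31, replace = TRUE)),
    upib = sprintf("B%02d", sample(12, 31, replace = TRUE)),
    marker = rep(c("CD3", "CD4", "CD8"), c(9, 10, 12)),
    umi = sprintf("u%03d", 1:31), reads = 1L)
  g <- build_graph(ed)
  comp <- igraph::components(g)
  keep <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
  ed <- ed[ed$upia %in% keep & ed$upib %in% keep, ]
  # re-pad the surviving markers so totals stay {<10, >=10, >=10}
  proj <- project_a_graph(build_graph(ed))
  res <- colocalization_scores(proj, min_marker = 10, min_neighborhood = 1,
                               n_perm = 20, seed = 1)
  expect_false("CD3" %in% c(res$marker_1, res$marker_2))
  # a lone surviving marker yields an empty result
  res2 <- colocalization_scores(proj, min_marker = 1000, n_perm = 20,
                                seed = 1)
  expect_equal(nrow(res2), 0)
})

test_that("identical marker layers score perfect positive colocalization", {
  spec <- even_spec(panel8, total = 700, n_pix = 100)
  sim <- simulate_cell(spec, seed = 71)
  g <- build_graph(edge_list(sim))
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  proj <- project_a_graph(giant, panel = panel8)
  # duplicate one marker's node counts into another column
  proj$counts[, "CD4"] <- proj$counts[, "CD3"]
  res <- colocalization_scores(proj, n_perm = 100, seed = 11)
  pair <- res[res$marker_1 == "CD3" & res$marker_2 == "CD4", ]
  expect_equal(pair$pearson_r, 1)
  expect_gt(pair$z, 2)
})

test_that("colocalization z is centred for independent marker layers", {
  # counts drawn iid over the nodes of real cell topologies, so no marker
  # pair shares structure beyond the graph itself
  spec <- even_spec(panel8, total = 900, n_pix = 100)
  zs <- unlist(lapply(1:12, function(s) {
    sim <- simulate_cell(spec, seed = 700 + s)
    g <- build_graph(edge_list(sim))
    comp <- igraph::components(g)
    giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                                 which.max(comp$csize)))
    proj <- project_a_graph(giant, panel = panel8)
    set.seed(1000 + s)
    proj$counts <- Matrix::Matrix(
      matrix(stats::rpois(length(proj$counts), 1), nrow(proj$counts),
             dimnames = dimnames(proj$counts)), sparse = TRUE)
    colocalization_scores(proj, n_perm = 50, seed = s)$z
  }))
  expect_gt(length(zs), 200)
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.2)
})

test_that("differential analysis has power and honest adjustment", {
  set.seed(13)
  mk <- sprintf("M%02d", 1:6)
  base <- expand.grid(component = sprintf("c%03d", 1:50), feature = mk,
                      stringsAsFactors = FALSE)
  ref <- tibble::tibble(base, condition = "control",
                        value = stats::rnorm(nrow(base), 0, 0.1))
  shifted <- tibble::tibble(base, condition = "stim",
                            value = stats::rnorm(nrow(base), 0, 0.1) +
                              ifelse(base$feature == "M01", 0.3, 0))
  shifted$component <- sub("c", "d", shifted$component)
  res <- differential_analysis(rbind(ref, shifted), reference = "control",
                               mode = "polarity", downsample_n = 50,
                               seed = 2)
  expect_lt(res$p_adjusted[res$feature == "M01"], 0.01)
  expect_gt(min(res$p_adjusted[res$feature != "M01"]), 0.05)
  expect_true(all(res$p_adjusted >= res$p))
  expect_equal(res$effect[res$feature == "M01"], 0.3, tolerance = 0.1)
  # identical groups: every adjusted p-value is 1
  same <- rbind(ref, transform(ref, condition = "mirror",
                               component = sub("c", "e", ref$component)))
  res2 <- differential_analysis(same, reference = "control",
                                mode = "polarity", seed = 3)
  expect_true(all(res2$p_adjusted == 1))
  # undersized groups warn (once per group) and use all cells
  w <- testthat::capture_warnings(
    res3 <- differential_analysis(rbind(ref, shifted), reference = "control",
                                  mode = "polarity", downsample_n = 80,
                                  seed = 1))
  expect_true(any(grepl("downsample_n", w)))
  expect_equal(unique(res3$n_reference), 50)
})

test_that("CLR gating implements the T cell rule set", {
  clr <- matrix(c(1.0, 2.0, 0.5, 0.1, 0.2, 0.1,
                  0.5, 2.5, 0.3, 0.1, 0.1, 0.1,
                  1.2, 0.3, 1.7, 0.1, 0.4, 0.2,
                  1.1, 2.2, 0.4, 0.6, 0.2, 0.1),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("T1", "lowCD3", "CD8T", "Bdoub"),
                                c("CD3", "CD4", "CD8", "CD19", "CD20",
                                  "CD14")))
  got <- gate_components(clr, t_cell_gate())
  expect_identical(got, c("T1", "CD8T"))
  # CD19 exclusion alone
  expect_identical(gate_components(clr, list(gate_rule("CD19", "<", 0.5))),
                   c("T1", "lowCD3", "CD8T"))
  # empty rule list retains everything
  expect_length(gate_components(clr, list()), 4)
  expect_error(gate_components(clr, list(gate_rule("NOPE", ">", 1))),
               "unknown marker")
})
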