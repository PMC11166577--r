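panel8 <- tiny_panel()

test_that("build_graph constructs a bipartite multigraph", {
  ed <- tibble::tibble(upia = c("A1", "A1", "A2"),
                       upib = c("B1", "B2", "B1"),
                       marker = "CD3", umi = c("u1", "u2", "u3"), reads = 1L)
  g <- build_graph(ed)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_true(igraph::bipartite_mapping(g)$res)
  # parallel edges for distinct UMIs on the same pixel pair
  ed2 <- tibble::tibble(upia = c("A1", "A1"), upib = c("B1", "B1"),
                        marker = "CD3", umi = c("u1", "u2"), reads = 1L)
  g2 <- build_graph(ed2)
  expect_equal(igraph::ecount(g2), 2)
  expect_equal(igraph::vcount(g2), 2)
  expect_error(build_graph(tibble::tibble(upia = "X", upib = "X",
                                          marker = "CD3", umi = "u",
                                          reads = 1L)),
               "both the A and the B side")
})

test_that("refinement removes a single spurious bridge between dense blocks", {
  ed <- rbind(block_edges(20, 20, "A", "B"),
              block_edges(20, 20, "C", "D"))
  bridge <- tibble::tibble(upia = "A01", upib = "D01", marker = "CD3",
                           umi = "UBRIDGE", reads = 1L)
  g <- build_graph(rbind(ed, bridge))
  expect_equal(igraph::components(g)$no, 1)
  set.seed(1)
  g2 <- refine_components(g)
  expect_equal(igraph::components(g2)$no, 2)
  expect_equal(igraph::ecount(g2), 800)
})

test_that("refinement leaves a single dense block unchanged", {
  g <- build_graph(block_edges(20, 20))
  set.seed(1)
  g2 <- refine_components(g)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(igraph::components(g2)$no, 1)
})

test_that("blocks joined by more than crossing_max edges stay together", {
  ed <- rbind(block_edges(20, 20, "A", "B"),
              block_edges(20, 20, "C", "D"))
  set.seed(5)
  bridges <- tibble::tibble(
    upia = sprintf("A%02d", sample(20, 15, replace = TRUE)),
    upib = sprintf("D%02d", sample(20, 15, replace = TRUE)),
    marker = "CD3", umi = sprintf("UB%03d", 1:15), reads = 1L)
  bridges <- bridges[!duplicated(paste(bridges$upia, bridges$upib)), ]
  g <- build_graph(rbind(ed, bridges))
  set.seed(1)
  g2 <- refine_components(g)
  expect_equal(igraph::components(g2)$no, 1)
})

test_that("refinement splits a simulated doublet but not single cells", {
  spec <- even_spec(panel8, total = 900, n_pix = 150)
  sim <- simulate_sample(spec, n_cells = 4, doublet_fraction = 0.5,
                         seed = 33)
  g <- build_graph(sim$edges)
  # the two doublets fuse their partner cells into single components
  n_big_before <- sum(igraph::components(g)$csize > 100)
  set.seed(2)
  g2 <- call_components(refine_components(g))
  n_big_after <- sum(component_sizes(g2) > 100)
  expect_equal(n_big_before, 2)
  expect_equal(n_big_after, 4)
})

test_that("component labels are stable under edge-order permutation", {
  spec <- even_spec(panel8, total = 400, n_pix = 80)
  sim <- simulate_sample(spec, n_cells = 3, seed = 41)
  ed <- sim$edges
  g1 <- call_components(build_graph(ed))
  set.seed(9)
  g2 <- call_components(build_graph(ed[sample(nrow(ed)), ]))
  s1 <- component_sizes(g1)
  s2 <- component_sizes(g2)
  expect_identical(s1, s2)
  # same label -> same vertex set
  v1 <- split(igraph::V(g1)$name, igraph::V(g1)$component)
  v2 <- split(igraph::V(g2)$name, igraph::V(g2)$component)
  expect_identical(lapply(v1, sort), lapply(v2, sort))
})

test_that("the spline elbow lands between the cell and debris modes", {
  set.seed(77)
  sizes <- c(round(stats::rlnorm(500, log(10000), 0.2)),
             round(stats::rlnorm(5000, log(50), 0.4)))
  thr <- size_threshold(sizes)
  expect_gt(thr, stats::quantile(round(stats::rlnorm(5000, log(50), 0.4)),
                                 0.999))
  expect_lt(thr, 10000)
  # order invariance
  expect_identical(size_threshold(sample(sizes)), thr)
})

test_that("degenerate size distributions raise the fallback signal", {
  expect_error(size_threshold(rep(100L, 50)), class = "mpx_size_fallback")
  expect_error(size_threshold(c(10L, 20L)), class = "mpx_size_fallback")
})

test_that("filter_components applies top-k drop and size cutoffs", {
  sizes <- stats::setNames(c(5000L, 4000L, 3000L, 300L, 200L, 10L),
                           paste0("C", 1:6))
  out <- filter_components(sizes, threshold = 0, manual_min = 100,
                           drop_top_k = 2)
  expect_identical(out$retained, c("C3", "C4", "C5"))
  # identity when everything is disabled
  out2 <- filter_components(sizes, threshold = 0, manual_min = 0,
                            drop_top_k = 0)
  expect_length(out2$retained, 6)
  # 12 components with drop_top_k = 10 leave 2 before size filtering
  s12 <- stats::setNames(rep(100L, 12), paste0("K", 1:12))
  expect_length(filter_components(s12, drop_top_k = 10)$retained, 2)
  expect_error(filter_components(sizes, manual_min = -1), "manual_min")
  # the edge-rank table covers every component in rank order
  expect_equal(out$edge_rank$size, sort(sizes, decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("count matrix sums unique molecules with explicit zeros", {
  ed <- tibble::tibble(
    upia = c("A1", "A2", "A1", "A3", "A3"),
    upib = c("B1", "B1", "B2", "B3", "B4"),
    marker = c("CD3", "CD3", "CD4", "CD3", "CD8"),
    umi = sprintf("u%d", 1:5), reads = 1L,
    component = c("C0001", "C0001", "C0001", "C0002", "C0002"))
  m <- count_matrix(ed, panel8)
  expect_equal(dim(m), c(2, 8))
  expect_equal(m["C0001", "CD3"], 2)
  expect_equal(m["C0001", "CD4"], 1)
  expect_equal(m["C0001", "CD19"], 0)
  expect_equal(unname(Matrix::rowSums(m)), c(3, 2))
  expect_error(count_matrix(transform(ed, marker = "NOPE"), panel8),
               "absent from panel")
})

test_that("tau endpoints and the worked example evaluate exactly", {
  even <- matrix(25, 1, 80, dimnames = list("C1", sprintf("M%02d", 1:80)))
  single <- matrix(c(2000, rep(0, 79)), 1, 80, byrow = TRUE,
                   dimnames = list("C1", sprintf("M%02d", 1:80)))
  expect_identical(tau_filter(even)$tau, 0)
  expect_identical(tau_filter(single)$tau, 1)
  hand <- matrix(c(4, 2, 2, 2), 1, 4)
  expect_identical(tau_filter(hand)$tau, 0.5)
})

test_that("tau is bounded in [0, 1] and flags fire correctly", {
  set.seed(12)
  m <- matrix(stats::rpois(100 * 8, 5), 100, 8)
  res <- tau_filter(m)
  expect_true(all(res$tau >= 0 & res$tau <= 1))
  # an aggregate-like single-marker row is HighTau even when IQR rules also fire
  m2 <- rbind(matrix(stats::rpois(50 * 8, 20), 50, 8),
              c(5000, rep(0, 7)))
  res2 <- tau_filter(m2)
  expect_equal(res2$flag[51], "HighTau")
  expect_warning(res3 <- tau_filter(rbind(m, 0)), "all-zero")
  expect_equal(res3$flag[101], "LowTau")
  expect_true(is.na(res3$tau[101]))
})

test_that("one-mode projection matches the brute-force construction", {
  # hand examples: path A1-B1-A2 and the 5-star around B1
  path <- tibble::tibble(upia = c("A1", "A2"), upib = "B1",
                         marker = "CD3", umi = c("u1", "u2"), reads = 1L)
  proj <- project_a_graph(build_graph(path))
  expect_equal(igraph::ecount(proj$graph), 1)
  star <- tibble::tibble(upia = sprintf("A%d", 1:5), upib = "B1",
                         marker = "CD3", umi = sprintf("u%d", 1:5),
                         reads = 1L)
  proj <- project_a_graph(build_graph(star))
  expect_equal(igraph::ecount(proj$graph), 10) # 5-clique
  # randomized graphs against the shared-neighbour oracle
  set.seed(55)
  for (rep in 1:20) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    ed <- tibble::tibble(
      upia = c(sprintf("A%d", 1:na),
               sprintf("A%d", sample(na, 25, replace = TRUE))),
      upib = c(sprintf("B%d", sample(nb, na, replace = TRUE)),
               sprintf("B%d", sample(nb, 25, replace = TRUE))),
      marker = sample(c("CD3", "CD4"), na + 25, replace = TRUE),
      umi = sprintf("u%03d", seq_len(na + 25)), reads = 1L)
    # keep one connected component for the projection contract
    g <- build_graph(ed)
    comp <- igraph::components(g)
    keep_v <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    ed <- ed[ed$upia %in% keep_v & ed$upib %in% keep_v, ]
    proj <- project_a_graph(build_graph(ed))
    got <- igraph::as_data_frame(proj$graph, what = "edges")
    got_pairs <- sort(paste(pmin(got$from, got$to), pmax(got$from, got$to)))
    expect_identical(got_pairs, brute_projection_pairs(ed))
    # node count vectors sum to the component's marker totals
    expect_equal(Matrix::colSums(proj$counts)[sort(unique(ed$marker))],
                 table(ed$marker)[sort(unique(ed$marker))],
                 ignore_attr = TRUE)
  }
})

test_that("graph and count matrix exports are readable standard formats", {
  spec <- even_spec(panel8, total = 300, n_pix = 60)
  sim <- simulate_sample(spec, n_cells = 2, seed = 3)
  g <- call_components(build_graph(sim$edges))
  dir <- withr::local_tempdir()
  write_graphml(g, file.path(dir, "g.graphml"))
  g2 <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  m <- count_matrix(component_edge_list(g), panel8)
  write_count_matrix(m, dir)
  m2 <- Matrix::readMM(file.path(dir, "counts.mtx"))
  expect_equal(unname(as.matrix(m2)), unname(as.matrix(m)))
})
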