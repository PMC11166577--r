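# Pipeline orchestration: a single config drives simulate -> amplicon ->
# reads -> graph -> analyze -> layout, each stage a file-to-file function so
# chained subcommands and the monolithic runner produce identical outputs.

#' Default pipeline configuration
#'
#' Returns the full configuration tree with every stage parameter at its
#' default. `simulate` controls the built-in experiment generator (set
#' `input$fastq` to process external reads instead); stage seeds are derived
#' from the top-level seed and the stage name, so re-running one stage does
#' not depend on execution order.
#'
#' @param seed top-level integer seed
#' @param out_dir output directory
#' @return nested configuration list of class `mpx_config`
#' @export
default_config <- function(seed = 1L, out_dir = "pixelgraph_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = list(fastq = NULL, edges = NULL),
    panel = list(n_markers = 80L, path = NULL),
    simulate = list(n_cells = 10L, total_molecules = 9580,
                    n_pixels_a = 1737L, n_pixels_b = 1737L,
                    doublet_fraction = 0, abundance_skew = 1),
    amplicon = list(substitution_rate = 0, pcr_duplication = 1,
                    dropout_rate = 0),
    reads = list(max_motif_mismatch = 0.10, barcode_max_mismatch = 1L,
                 min_mean_phred = 20, max_dist = 2L),
    graph = list(resolution = 0.01, max_iter = 3L, crossing_max = 10L,
                 drop_top_k = 10L, manual_min = 0L, use_spline = TRUE),
    analyze = list(polarity = TRUE, colocalization = TRUE,
                   min_marker = 10L, min_neighborhood = 5L, n_perm = 50L),
    layout = list(enabled = FALSE, n_components = 1L,
                  distance_cutoff = 0.3, grid_points = 2000L),
    log_level = "info"
  ), class = "mpx_config")
}

#' Read or write a pipeline configuration
#'
#' Configurations round-trip through YAML unchanged; unknown keys raise a
#' validation error naming the key.
#'
#' @param config an `mpx_config`
#' @param path YAML file path
#' @return the path invisibly, or the configuration
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  template <- unclass(default_config())
  validate_keys <- function(got, ref, prefix = "") {
    unknown <- setdiff(names(got), names(ref))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    }
    for (k in names(got)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        validate_keys(got[[k]] %||% list(), ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  validate_keys(y, template)
  merged <- utils::modifyList(template, y, keep.null = TRUE)
  structure(merged, class = "mpx_config")
}

.log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[pixelgraph] ", ...)
}

#' Pipeline stages
#'
#' Each stage reads its predecessor's standard files from `config$out_dir`
#' and writes its own, so chained stage calls equal [run_pipeline()].
#' `stage_simulate()` writes the panel, ground-truth tables and true edge
#' list; `stage_amplicon()` renders FASTQ reads; `stage_reads()` parses,
#' collapses and corrects them into `edge_list.tsv` + `qc.json`;
#' `stage_graph()` builds/refines the graph, calls and filters components and
#' writes the count matrix, Tau flags and edge-rank table; `stage_analyze()`
#' writes polarity and colocalization tables; `stage_layout()` writes 3D
#' layouts and density grids for the largest retained components.
#'
#' @param config an `mpx_config`
#' @return the config, invisibly
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- if (!is.null(config$panel$path)) {
    read_panel(config$panel$path)
  } else {
    generate_panel(config$panel$n_markers, seed = stage_seed(config$seed, "panel"))
  }
  write_panel(panel, file.path(config$out_dir, "panel.yaml"))
  spec <- default_cell_spec(panel,
                            total_molecules = config$simulate$total_molecules,
                            skew = config$simulate$abundance_skew,
                            seed = stage_seed(config$seed, "abundance"),
                            n_pixels_a = config$simulate$n_pixels_a,
                            n_pixels_b = config$simulate$n_pixels_b)
  sim <- simulate_sample(spec, n_cells = config$simulate$n_cells,
                         doublet_fraction = config$simulate$doublet_fraction,
                         seed = stage_seed(config$seed, "simulate"))
  write_sim_truth(sim, file.path(config$out_dir, "truth"))
  .log(config, "simulated ", nrow(sim$cells), " cells, ",
       nrow(sim$molecules), " molecules")
  invisible(config)
}

#' @rdname pipeline_stages
#' @export
stage_amplicon <- function(config) {
  truth_dir <- file.path(config$out_dir, "truth")
  if (!file.exists(file.path(truth_dir, "edges.tsv"))) {
    stop("amplicon stage requires simulate outputs in ", truth_dir)
  }
  panel <- read_panel(file.path(config$out_dir, "panel.yaml"))
  edges <- read_edge_list(file.path(truth_dir, "edges.tsv"))
  sim <- structure(list(edges = edges), class = "mpx_sim")
  errs <- error_model(config$amplicon$substitution_rate,
                      config$amplicon$pcr_duplication,
                      config$amplicon$dropout_rate)
  render_fastq(sim, panel, errs, seed = stage_seed(config$seed, "amplicon"),
               path = file.path(config$out_dir, "reads.fastq"))
  invisible(config)
}

#' @rdname pipeline_stages
#' @export
stage_reads <- function(config) {
  fastq <- config$input$fastq %||% file.path(config$out_dir, "reads.fastq")
  if (!file.exists(fastq)) stop("reads stage: FASTQ not found: ", fastq)
  panel <- read_panel(file.path(config$out_dir, "panel.yaml"))
  res <- process_reads(fastq, panel,
                       max_dist = config$reads$max_dist,
                       max_motif_mismatch = config$reads$max_motif_mismatch,
                       barcode_max_mismatch = config$reads$barcode_max_mismatch,
                       min_mean_phred = config$reads$min_mean_phred)
  write_edge_list(res$edges, file.path(config$out_dir, "edge_list.tsv"))
  write_qc_report(res$qc, file.path(config$out_dir, "qc.json"))
  .log(config, res$qc$accepted, "/", res$qc$total, " reads accepted, ",
       nrow(res$edges), " unique molecules")
  invisible(config)
}

#' @rdname pipeline_stages
#' @export
stage_graph <- function(config) {
  path <- config$input$edges %||% file.path(config$out_dir, "edge_list.tsv")
  if (!file.exists(path)) stop("graph stage: edge list not found: ", path)
  panel <- read_panel(file.path(config$out_dir, "panel.yaml"))
  edges <- read_edge_list(path)
  set.seed(stage_seed(config$seed, "graph"))
  g <- build_graph(edges)
  g <- refine_components(g, resolution = config$graph$resolution,
                         max_iter = config$graph$max_iter,
                         crossing_max = config$graph$crossing_max)
  g <- call_components(g)
  sizes <- component_sizes(g)
  thr <- 0L
  if (isTRUE(config$graph$use_spline)) {
    thr <- tryCatch(size_threshold(sizes),
                    mpx_size_fallback = function(e) {
                      .log(config, "size threshold fallback: ",
                           conditionMessage(e))
                      0L
                    })
  }
  filt <- filter_components(sizes, threshold = thr,
                            manual_min = config$graph$manual_min,
                            drop_top_k = config$graph$drop_top_k)
  ed <- component_edge_list(g)
  retained_edges <- ed[ed$component %in% filt$retained, , drop = FALSE]
  m <- count_matrix(retained_edges, panel, components = filt$retained)
  tau <- if (nrow(m) > 0) tau_filter(m) else
    tibble::tibble(component = character(0), tau = numeric(0),
                   flag = character(0))
  write_edge_list(retained_edges, file.path(config$out_dir,
                                            "retained_edges.tsv"))
  utils::write.csv(filt$edge_rank, file.path(config$out_dir, "edge_rank.csv"),
                   row.names = FALSE)
  utils::write.csv(tau, file.path(config$out_dir, "tau.csv"),
                   row.names = FALSE)
  write_count_matrix(m, config$out_dir)
  if (nrow(m) > 0) {
    utils::write.csv(as.data.frame(clr_transform(m)),
                     file.path(config$out_dir, "counts_clr.csv"))
  }
  write_graphml(g, file.path(config$out_dir, "graph.graphml"))
  .log(config, length(filt$retained), " retained components (threshold ", thr,
       ")")
  invisible(config)
}

#' @rdname pipeline_stages
#' @export
stage_analyze <- function(config) {
  panel <- read_panel(file.path(config$out_dir, "panel.yaml"))
  edges <- read_edge_list(file.path(config$out_dir, "retained_edges.tsv"))
  if (nrow(edges) == 0L) stop("analyze stage: no retained components")
  comps <- sort(unique(edges$component))
  pol <- list(); col <- list()
  for (cmp in comps) {
    sub <- edges[edges$component == cmp, , drop = FALSE]
    pg <- build_graph(sub)
    proj <- suppressWarnings(project_a_graph(pg, panel = panel))
    proj$component <- cmp
    if (isTRUE(config$analyze$polarity)) pol[[cmp]] <- polarity_scores(proj)
    if (isTRUE(config$analyze$colocalization)) {
      col[[cmp]] <- colocalization_scores(
        proj, min_marker = config$analyze$min_marker,
        min_neighborhood = config$analyze$min_neighborhood,
        n_perm = config$analyze$n_perm,
        seed = stage_seed(config$seed, paste0("coloc", cmp)))
    }
  }
  if (length(pol)) {
    utils::write.csv(do.call(rbind, pol),
                     file.path(config$out_dir, "polarity.csv"),
                     row.names = FALSE)
  }
  if (length(col)) {
    utils::write.csv(do.call(rbind, col),
                     file.path(config$out_dir, "colocalization.csv"),
                     row.names = FALSE)
  }
  invisible(config)
}

#' @rdname pipeline_stages
#' @export
stage_layout <- function(config) {
  edges <- read_edge_list(file.path(config$out_dir, "retained_edges.tsv"))
  if (nrow(edges) == 0L) stop("layout stage: no retained components")
  sizes <- sort(table(edges$component), decreasing = TRUE)
  take <- names(sizes)[seq_len(min(config$layout$n_components,
                                   length(sizes)))]
  for (cmp in take) {
    sub <- edges[edges$component == cmp, , drop = FALSE]
    proj <- project_a_graph(build_graph(sub))
    coords <- layout_3d(proj, seed = stage_seed(config$seed,
                                                paste0("layout", cmp)))
    unit <- sphere_project(coords)
    out <- tibble::tibble(node = rownames(coords), x = coords[, 1],
                          y = coords[, 2], z = coords[, 3],
                          sx = unit[, 1], sy = unit[, 2], sz = unit[, 3])
    utils::write.csv(out, file.path(config$out_dir,
                                    paste0("layout_", cmp, ".csv")),
                     row.names = FALSE)
    dens <- density_grid(unit, proj$counts[rownames(coords), , drop = FALSE],
                         distance_cutoff = config$layout$distance_cutoff,
                         grid = fibonacci_sphere(config$layout$grid_points))
    utils::write.csv(dens, file.path(config$out_dir,
                                     paste0("density_", cmp, ".csv")),
                     row.names = FALSE)
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes simulate (unless an input FASTQ or edge list is configured),
#' amplicon, reads, graph, analyze and layout in order, then writes a
#' manifest recording the package version, configuration and derived stage
#' seeds. Identical configurations produce identical outputs.
#'
#' @param config an `mpx_config` (see [default_config()])
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mpx_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  external <- !is.null(config$input$fastq) || !is.null(config$input$edges)
  run_stage <- function(name, fun) {
    .log(config, "stage: ", name)
    fun(config)
    stages <<- c(stages, name)
  }
  tryCatch({
    if (!external) {
      run_stage("simulate", stage_simulate)
      run_stage("amplicon", stage_amplicon)
    } else if (!is.null(config$panel$path)) {
      file.copy(config$panel$path, file.path(config$out_dir, "panel.yaml"),
                overwrite = TRUE)
    } else {
      stop("external input requires panel$path")
    }
    if (is.null(config$input$edges)) run_stage("reads", stage_reads)
    run_stage("graph", stage_graph)
    run_stage("analyze", stage_analyze)
    if (isTRUE(config$layout$enabled)) run_stage("layout", stage_layout)
  }, error = function(e) {
    .write_manifest(config, stages, failed = conditionMessage(e))
    stop(e)
  })
  .write_manifest(config, stages, failed = NULL)
  invisible(config$out_dir)
}

.write_manifest <- function(config, stages, failed = NULL) {
  all_stages <- c("panel", "abundance", "simulate", "amplicon", "reads",
                  "graph")
  jsonlite::write_json(list(
    tool = "pixelgraph",
    version = as.character(utils::packageVersion("pixelgraph")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(all_stages, function(s) stage_seed(config$seed, s)), all_stages),
    stages_completed = stages,
    failed_at = failed,
    config = unclass(config)
  ), file.path(config$out_dir, "manifest.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible()
}
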