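#' Default pipeline configuration
#'
#' All tunable thresholds of the analysis surface in one validated list,
#' serializable to YAML. Defaults are the method's standard operating
#' values: period window 18--26.8 h, error-factor ceiling 0.2, family-wise
#' alpha 0.05, LOWESS span 0.25, correlation cutoff 0.90.
#'
#' @param ... Named overrides of any default entry.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 1000L,
    fraction_cyclic = 0.4,
    noise_sd = 0.2,
    background_floor = 1,
    window_fraction = 0.25,
    period_window = c(18, 26.8),
    ef_max = 0.2,
    alpha = 0.05,
    k_labels = 3L,
    network_threshold = 0.90,
    cap_activity = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  .validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (ef_max <= 0 || alpha <= 0 || window_fraction <= 0 || network_threshold <= 0)
      stop("thresholds must be positive")
    if (length(period_window) != 2 || period_window[1] >= period_window[2])
      stop("period_window must be an increasing pair")
    pg <- period_grid()
    if (period_window[1] < min(pg) || period_window[2] > max(pg))
      stop("period_window must lie within the fitting grid [",
           min(pg), ", ", max(pg), "] h")
  })
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_config()` returns a `"pipeline_config"`; `write_config()`
#'   returns `path` invisibly. A config round-trips unchanged.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- data.frame(stats::setNames(list(rownames(df)), rownames_as),
                     as.data.frame(df), check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a `gene` column followed by the 24 timepoint columns in grid
#' order.
#'
#' @param path TSV file.
#' @param scaled Mark the matrix as feature-scaled?
#' @param grid The [diel_grid()].
#' @return Gene x 24 matrix with `scaled`/`grid` attributes.
#' @export
read_matrix_tsv <- function(path, scaled = FALSE, grid = diel_grid()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("'", path, "' lacks a 'gene' column")
  mat <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(mat) <- df$gene
  if (ncol(mat) != length(grid$time))
    stop("expected ", length(grid$time), " timepoint columns, found ", ncol(mat))
  attr(mat, "scaled") <- scaled
  attr(mat, "grid") <- grid
  mat
}

.manifest <- function(outdir, stage, config, inputs = character(0)) {
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  names(hashes) <- basename(files)
  obj <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cyanodiel")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    inputs = as.list(inputs),
    output_md5 = hashes
  )
  jsonlite::write_json(obj, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(obj)
}

#' Run the diel analysis pipeline
#'
#' Chains the stages over a shared configuration, writing each stage's
#' artifacts plus a machine-readable run manifest (config, seed, versions,
#' output checksums) to `outdir`. `"all"` runs
#' simulate -> preprocess -> rhythm -> network -> flux; a single stage
#' reads its inputs from the same directory.
#'
#' Artifacts: `expression.tsv`, `truth.tsv`, `probes.tsv`, `model.json`
#' (simulate); `matrix_scaled.tsv` (preprocess); `rhythm_calls.tsv`,
#' `peak_summary.tsv` (rhythm); `edges.tsv`, `components.tsv`,
#' `isolated.tsv`, `network.graphml` (network); `fluxes.tsv`,
#' `pathway_profiles.tsv` (flux).
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"rhythm"`,
#'   `"network"`, `"flux"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress per-stage count logging?
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "preprocess", "rhythm",
                                   "network", "flux"),
                         config = pipeline_config(), outdir = ".",
                         quiet = FALSE) {
  stage <- match.arg(stage)
  .validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- diel_grid()
  say <- function(...) if (!quiet) message("[", stage, "] ", ...)
  res <- list()

  stages <- if (stage == "all")
    c("simulate", "preprocess", "rhythm", "network", "flux") else stage

  need <- function(file) {
    p <- file.path(outdir, file)
    if (!file.exists(p)) stop("missing input for stage: ", p)
    p
  }

  for (st in stages) {
    if (st == "simulate") {
      spec <- synthetic_spec(n_genes = config$n_genes,
                             fraction_cyclic = config$fraction_cyclic,
                             noise_sd = config$noise_sd, seed = config$seed)
      sim <- generate_expression(spec, grid)
      probes <- generate_probe_intensities(sim$matrix, grid,
                                           seed = config$seed + 1L,
                                           bg_level = 20)
      model <- generate_toy_model(config$seed)
      .write_tsv(sim$matrix, file.path(outdir, "expression.tsv"), "gene")
      .write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
      .write_tsv(probes, file.path(outdir, "probes.tsv"))
      write_model_json(model, file.path(outdir, "model.json"))
      say(nrow(sim$matrix), " genes simulated (", sum(sim$truth$cyclic),
          " cyclic), ", length(unique(probes$probe)), " probes")
      res$simulate <- list(sim = sim, probes = probes, model = model)
    } else if (st == "preprocess") {
      probes <- if (!is.null(res$simulate)) res$simulate$probes else {
        p <- utils::read.delim(need("probes.tsv"), stringsAsFactors = FALSE)
        p$gene[p$gene == ""] <- NA
        class(p) <- c("probe_table", "data.frame"); p
      }
      corrected <- subtract_background(probes, floor = config$background_floor)
      ratios <- lowess_normalize(corrected, window_fraction = config$window_fraction)
      mat <- aggregate_probes(ratios, grid)
      scaled <- feature_scale(mat)
      .write_tsv(scaled, file.path(outdir, "matrix_scaled.tsv"), "gene")
      say(nrow(scaled), " genes aggregated and feature-scaled")
      res$preprocess <- list(matrix = mat, scaled = scaled)
    } else if (st == "rhythm") {
      scaled <- if (!is.null(res$preprocess)) res$preprocess$scaled
                else read_matrix_tsv(need("matrix_scaled.tsv"), scaled = TRUE, grid = grid)
      calls <- classify_rhythms(scaled, grid,
                                period_window = config$period_window,
                                ef_max = config$ef_max, alpha = config$alpha,
                                k_labels = config$k_labels)
      .write_tsv(calls, file.path(outdir, "rhythm_calls.tsv"))
      .write_tsv(summarize_peaks(calls, grid = grid),
                 file.path(outdir, "peak_summary.tsv"), "category")
      say(sum(calls$is_cyclic), " of ", nrow(calls), " genes called cyclic")
      res$rhythm <- list(scaled = scaled, calls = calls)
    } else if (st == "network") {
      scaled <- if (!is.null(res$rhythm)) res$rhythm$scaled
                else read_matrix_tsv(need("matrix_scaled.tsv"), scaled = TRUE, grid = grid)
      calls <- if (!is.null(res$rhythm)) res$rhythm$calls
               else .read_calls(need("rhythm_calls.tsv"))
      cyc <- calls$gene[calls$is_cyclic]
      if (length(cyc) < 2) stop("fewer than two cyclic genes; no network to build")
      r <- pearson_matrix(scaled, cyc)
      graph <- build_graph(r, calls, threshold = config$network_threshold)
      comps <- graph_components(graph)
      write_edge_list(graph, file.path(outdir, "edges.tsv"))
      write_graphml(graph, file.path(outdir, "network.graphml"))
      .write_tsv(comps$components, file.path(outdir, "components.tsv"))
      .write_tsv(data.frame(gene = comps$isolated), file.path(outdir, "isolated.tsv"))
      say(igraph::ecount(graph), " edges, ", nrow(comps$components),
          " components, ", length(comps$isolated), " isolated genes")
      res$network <- list(graph = graph, components = comps)
    } else if (st == "flux") {
      scaled <- if (!is.null(res$rhythm)) res$rhythm$scaled
                else read_matrix_tsv(need("matrix_scaled.tsv"), scaled = TRUE, grid = grid)
      calls <- if (!is.null(res$rhythm)) res$rhythm$calls
               else .read_calls(need("rhythm_calls.tsv"))
      model <- if (!is.null(res$simulate)) res$simulate$model
               else read_model_json(need("model.json"))
      # the toy model's genes are not the simulated gene ids: deterministically
      # alias the first cyclic genes to the model's genes so GPR mapping is
      # exercised end to end
      profile <- activity_profile(scaled, calls, grid)
      mg <- sort(model_genes(model))
      if (!any(mg %in% rownames(profile)) && nrow(profile) >= length(mg))
        rownames(profile)[seq_along(mg)] <- mg
      sols <- solve_fba_series(model, profile, grid, cap = config$cap_activity)
      flux_tab <- do.call(cbind, lapply(sols, function(s) s$fluxes))
      .write_tsv(flux_tab, file.path(outdir, "fluxes.tsv"), "reaction")
      prof <- pathway_fluxes(sols, model)
      .write_tsv(prof, file.path(outdir, "pathway_profiles.tsv"), "pathway")
      say("LP optimal at all ", length(sols), " labels; biomass range ",
          signif(min(vapply(sols, `[[`, numeric(1), "objective")), 4), "..",
          signif(max(vapply(sols, `[[`, numeric(1), "objective")), 4))
      res$flux <- list(solutions = sols, profiles = prof)
    }
  }
  .manifest(outdir, stage, config)
  invisible(res)
}

.read_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(calls) <- c("rhythm_calls", "data.frame")
  calls
}
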