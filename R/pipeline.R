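#' Validate a pipeline run configuration
#'
#' Fills defaults for every stage parameter and checks the referenced paths
#' and the control class before any computation. Defaults follow the
#' portraying configuration: 50 x 50 grid, learning rate 0.02,
#' inverse-learning-rate constant 0.01, neighborhood radius 3, 12 epochs,
#' significance thresholds p < 0.05 and q < 0.2, spot threshold 0.90.
#'
#' @param config Named list (or path to a JSON file) with at least
#'   `pathway_dir`, `expression_file`, `sample_sheet`, `control_class` and
#'   `out_dir`. Optional: `probe_map`, `pathway_exclusion_file`,
#'   `series_matrix` flag, `scale` (passed to [detect_and_linearize()]),
#'   `input_signal`, `missing_fc`, `grid_rows`, `grid_cols`, `learning_rate`,
#'   `lr_constant`, `radius`, `epochs`, `spot_method`, `spot_threshold`,
#'   `alpha_p`, `alpha_q`, `coreg_level`, `walktrap_steps`, `seed`.
#' @return Validated config list with all defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  defaults <- list(probe_map = NULL, pathway_exclusion_file = NULL,
                   series_matrix = FALSE, scale = "auto",
                   input_signal = 1, missing_fc = 1,
                   grid_rows = 50, grid_cols = 50, learning_rate = 0.02,
                   lr_constant = 0.01, radius = 3, epochs = 12,
                   spot_method = "threshold", spot_threshold = 0.90,
                   alpha_p = 0.05, alpha_q = 0.2,
                   coreg_level = "pathway", walktrap_steps = 4, seed = 1)
  config <- utils::modifyList(defaults, config)
  need <- c("pathway_dir", "expression_file", "sample_sheet",
            "control_class", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "))
  for (f in c("pathway_dir", "expression_file", "sample_sheet")) {
    if (!file.exists(config[[f]])) stop("config path does not exist (", f,
                                        "): ", config[[f]])
  }
  sheet <- read_sample_sheet(config$sample_sheet)
  if (!config$control_class %in% sheet$class_label) {
    stop("control class '", config$control_class,
         "' absent from the sample sheet")
  }
  config
}

#' Run the full PSF-SOM pipeline
#'
#' Chains every stage: expression preprocessing (probe collapsing when a
#' probe map is given, log-scale autodetection, fold change versus the
#' in-dataset control mean), pathway parsing, cycle breaking and filtering,
#' PSF propagation, sink-wise centralization, SOM training, per-class
#' portraits and spot detection, differential PSF of every class versus the
#' control class, the disease co-regulation graph, and walktrap communities.
#' Every intermediate artifact is written under `out_dir`, and a
#' `manifest.json` records the package version, seed, parameters and MD5
#' checksums of every output file, so reruns with the same config are
#' byte-verifiable.
#'
#' @param config See [validate_config()].
#' @return The run directory path, invisibly; the manifest is also returned
#'   as the attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "run.log")
  stage <- function(name, expr) {
    psf_log("stage ", name, " ...", file = log_file)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    psf_log(sprintf("stage %s done (%.1fs)", name,
                    proc.time()[["elapsed"]] - t0), file = log_file)
    res
  }

  sheet <- read_sample_sheet(config$sample_sheet)

  fc <- stage("preprocess", {
    m <- if (isTRUE(config$series_matrix)) {
      read_series_matrix(config$expression_file)$values
    } else {
      read_expression_tsv(config$expression_file)
    }
    if (!is.null(config$probe_map)) m <- collapse_probes(m, config$probe_map)
    m <- detect_and_linearize(m, assume = config$scale)$values
    res <- compute_fold_change(m, sheet)
    write_matrix_tsv(res$values, file.path(out, "fold_change.tsv"),
                     id_col = "gene_id")
    res$values
  })

  graphs <- stage("pathways", {
    gs <- read_pathway_dir(config$pathway_dir)
    excl <- if (!is.null(config$pathway_exclusion_file)) {
      read_exclusion_file(config$pathway_exclusion_file)
    } else character(0)
    gs <- filter_pathway_collection(gs, excl)
    lapply(gs, break_cycles)
  })

  psf <- stage("psf", {
    p <- compute_psf_matrix(graphs, fc, input_signal = config$input_signal,
                            missing_fc = config$missing_fc)
    write_matrix_tsv(p, file.path(out, "psf_matrix.tsv"), id_col = "sink_id")
    p
  })

  centralized <- stage("centralize", {
    cc <- centralize_psf(psf)
    write_matrix_tsv(cc, file.path(out, "psf_centralized.tsv"),
                     id_col = "sink_id")
    cc
  })

  model <- stage("som", {
    m <- train_som(centralized, grid_rows = config$grid_rows,
                   grid_cols = config$grid_cols,
                   learning_rate = config$learning_rate,
                   lr_constant = config$lr_constant, radius = config$radius,
                   epochs = config$epochs, seed = config$seed)
    save_som_model(m, file.path(out, "som"))
    m
  })

  classes <- sort(unique(sheet$class_label))
  spotsets <- stage("portraits_spots", {
    ss <- list()
    for (cl in classes) {
      po <- class_portrait(model, sheet, cl)
      write_matrix_tsv(unclass(po),
                       file.path(out, paste0("portrait_", cl, ".tsv")),
                       id_col = "grid_row")
      ss[[cl]] <- detect_spots(po, model,
                               threshold_fraction = config$spot_threshold,
                               method = config$spot_method,
                               seed = config$seed)
    }
    summ <- summary_spot_map(ss, config$grid_rows, config$grid_cols)
    jsonlite::write_json(spots_to_list(ss, summ),
                         file.path(out, "spots.json"),
                         auto_unbox = TRUE, digits = NA)
    ss
  })

  diffs <- stage("differential", {
    dl <- list()
    for (cl in setdiff(classes, config$control_class)) {
      d <- differential_psf(psf, sheet, cl, config$control_class,
                            alpha_p = config$alpha_p,
                            alpha_q = config$alpha_q)
      utils::write.table(d, file.path(out, paste0("differential_", cl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dl[[cl]] <- d
    }
    dl
  })

  stage("disease_graph", {
    g <- build_disease_graph(diffs, level = config$coreg_level)
    write_disease_graph(g, file.path(out, "disease_graph.tsv"),
                        file.path(out, "disease_graph.graphml"))
    comm <- walktrap_communities(g, steps = config$walktrap_steps)
    jsonlite::write_json(
      list(communities = split(names(comm), as.integer(comm)),
           modularity = attr(comm, "modularity")),
      file.path(out, "communities.json"), auto_unbox = TRUE, digits = NA)
    comm
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          c("manifest.json", "run.log")))
    man <- list(
      package = "psfsom",
      version = as.character(utils::packageVersion("psfsom")),
      seed = config$seed,
      parameters = config[setdiff(names(config), "out_dir")],
      checksums = as.list(tools::md5sum(file.path(out, files)))
    )
    names(man$checksums) <- files
    jsonlite::write_json(man, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })

  invisible(structure(out, manifest = manifest))
}

# plain-list view of per-class spot sets plus the summary map, for JSON
spots_to_list <- function(spotsets, summary_map) {
  per_class <- lapply(spotsets, function(ss) {
    lapply(unclass(ss), function(s) {
      list(polarity = s$polarity, units = s$units, peak = s$peak,
           sinks = s$sinks)
    })
  })
  summary <- lapply(summary_map$spots, function(s) {
    list(label = s$label, units = s$units, peak = s$peak,
         classes = s$classes, sinks = s$sinks)
  })
  list(classes = per_class, summary = summary)
}
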