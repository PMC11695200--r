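#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their default profile:
#' window width 20 TR, Gaussian taper sigma 3 TR, step 1 TR; k = 6 states,
#' city-block distance, 20 restarts; sparsity grid 0.10-0.34 step 0.01
#' with signed edge ranking; multilayer gamma = 1.1, omega = 0.5, 20
#' repeats; GLM covariates age/gender/education with BH q < 0.05.
#'
#' @param ... Named overrides using `section$key` structure, e.g.
#'   `window = list(width = 30)`; unknown sections or keys are rejected.
#' @return A `run_config` nested list.
#' @export
run_config <- function(...) {
  defaults <- list(
    window = list(width = 20, sigma = 3, step = 1),
    states = list(k = 6, metric = "cityblock", restarts = 20, seed = 1),
    topology = list(sparsity_min = 0.10, sparsity_max = 0.34, step = 0.01,
                    edge_ranking = "signed"),
    multilayer = list(gamma = 1.1, omega = 0.5, repeats = 20, seed = 1,
                      enabled = TRUE),
    stats = list(fdr_q = 0.05,
                 covariates = c("age", "gender", "education"),
                 fd_validation = TRUE)
  )
  merge_config(defaults, list(...))
}

merge_config <- function(defaults, overrides) {
  for (sec in names(overrides)) {
    if (!sec %in% names(defaults)) {
      abort(sprintf("unknown config section `%s`", sec))
    }
    for (key in names(overrides[[sec]])) {
      if (!key %in% names(defaults[[sec]])) {
        abort(sprintf("unknown config key `%s$%s`", sec, key))
      }
      defaults[[sec]][[key]] <- overrides[[sec]][[key]]
    }
  }
  structure(defaults, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  merge_config(unclass(run_config()), yaml::read_yaml(path))
}

#' Write a panel to disk
#'
#' One TSV matrix per subject (header row of channel labels), a manifest
#' TSV with a `file` column, a channel table TSV and, when truth is
#' supplied, a JSON truth file.
#'
#' @param panel A [ts_panel].
#' @param dir Output directory (created if needed).
#' @param truth Optional simulation truth list to serialize as JSON.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, truth = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(panel$series))
  for (i in seq_along(panel$series)) {
    id <- names(panel$series)[i]
    files[i] <- paste0(id, ".tsv")
    readr::write_tsv(as_tibble(as.data.frame(panel$series[[i]])),
                     file.path(dir, files[i]), progress = FALSE)
  }
  manifest <- dplyr::mutate(panel$manifest, file = files)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(panel$channels, file.path(dir, "channels.tsv"),
                   progress = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(state_sequences = truth$state_sequences,
           stationary_distribution = truth$stationary_distribution),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a panel from a manifest
#'
#' Validates that every referenced time-series file exists, parses, has
#' consistent dimensions across subjects, and contains no missing values;
#' failures are reported with the offending subject id.
#'
#' @param manifest_path Path to a manifest TSV with `subject_id`, `group`,
#'   `file` columns (file paths relative to the manifest's directory);
#'   a `channels.tsv` in the same directory supplies the channel table.
#' @param tr Sampling interval in seconds.
#' @return A [ts_panel].
#' @export
read_panel <- function(manifest_path, tr = 2) {
  dir <- dirname(manifest_path)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  stopifnot(all(c("subject_id", "group", "file") %in% names(manifest)))
  ch_path <- file.path(dir, "channels.tsv")
  if (!file.exists(ch_path)) abort(sprintf("channel table not found: %s", ch_path))
  channels <- readr::read_tsv(ch_path, show_col_types = FALSE, progress = FALSE)
  series <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    id <- manifest$subject_id[i]
    if (!file.exists(f)) {
      abort(sprintf("subject %s: time-series file missing: %s", id, f))
    }
    x <- as.matrix(readr::read_tsv(f, show_col_types = FALSE, progress = FALSE))
    if (anyNA(x)) abort(sprintf("subject %s: missing values in %s", id, f))
    series[[i]] <- x
  }
  names(series) <- manifest$subject_id
  ts_panel(series, channels, dplyr::select(manifest, -"file"), tr = tr)
}

write_csv_with_schema <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  schema <- list(columns = purrr::imap(df, function(col, nm) {
    list(name = nm, type = class(col)[1])
  }) |> unname())
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Validate sidecar schemas of a results directory
#'
#' Checks that every CSV in `dir` has a `.schema.json` sidecar whose
#' column names and types match the file.
#'
#' @param dir Results directory.
#' @return `TRUE` invisibly; aborts on mismatch.
#' @export
validate_output_schemas <- function(dir) {
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  for (f in csvs) {
    sf <- paste0(f, ".schema.json")
    if (!file.exists(sf)) abort(sprintf("missing schema sidecar for %s", f))
    schema <- jsonlite::read_json(sf, simplifyVector = TRUE)
    df <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (!identical(schema$columns$name, names(df))) {
      abort(sprintf("schema column mismatch for %s", f))
    }
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: static FNC, windowed dynamic FNC, state clustering
#' with temporal metrics, dFNC variability, efficiency flexibility,
#' (optionally) the multilayer switching analysis on the node-level
#' series, and the GLM group contrasts with BH correction — writing every
#' result as CSV with a JSON schema sidecar plus a `run_info.json` stamp
#' (config hash, seed, package version). Runs are deterministic given the
#' config.
#'
#' @param panel A [ts_panel] (e.g. from [make_cohort()] or [read_panel()]).
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Named list of result objects, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(panel, config = run_config(), out_dir) {
  stopifnot(inherits(panel, "ts_panel"), inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(..., collapse = " ")))
  }
  spec <- window_spec(config$window$width, config$window$sigma,
                      config$window$step)
  covars <- intersect(config$stats$covariates, names(panel$manifest))

  log_stage("sfnc")
  sf <- sfnc(panel)
  sf_tbl <- tidy(sf)
  write_csv_with_schema(sf_tbl, file.path(out_dir, "sfnc_pairs.csv"))

  log_stage("dfnc", sprintf("width=%d sigma=%g step=%d", spec$width,
                            spec$gaussian_sigma, spec$step))
  dk <- dfnc(panel, spec)

  log_stage("states", sprintf("k=%d metric=%s", config$states$k,
                              config$states$metric))
  model <- cluster_states(dk, k = config$states$k,
                          distance = config$states$metric,
                          n_restarts = config$states$restarts,
                          seed = config$states$seed)
  write_csv_with_schema(tidy(model), file.path(out_dir, "state_assignments.csv"))
  metrics <- state_metrics_table(model)
  write_csv_with_schema(metrics, file.path(out_dir, "state_metrics.csv"))

  log_stage("variability")
  variab <- dfnc_variability(dk)
  write_csv_with_schema(tidy(variab), file.path(out_dir, "dfnc_variability.csv"))

  log_stage("topology")
  grid <- seq(config$topology$sparsity_min, config$topology$sparsity_max,
              by = config$topology$step)
  flex <- efficiency_flexibility(dk, grid,
                                 ranking = config$topology$edge_ranking)
  write_csv_with_schema(flex, file.path(out_dir, "efficiency_flexibility.csv"))

  switching <- NULL
  if (isTRUE(config$multilayer$enabled) && !is.null(panel$node_series)) {
    log_stage("multilayer", sprintf("gamma=%g omega=%g",
                                    config$multilayer$gamma,
                                    config$multilayer$omega))
    mlp <- multilayer_params(config$multilayer$gamma, config$multilayer$omega,
                             n_repeats = config$multilayer$repeats,
                             seed = config$multilayer$seed)
    switching <- purrr::imap(panel$node_series, function(ts, id) {
      net <- layered_network_from_ts(ts, spec,
                                     node_networks = panel$node_networks)
      dplyr::mutate(consensus_switching(net, mlp), subject_id = id,
                    .before = 1)
    }) |> purrr::list_rbind()
    write_csv_with_schema(switching, file.path(out_dir, "switching_rates.csv"))
  }

  log_stage("stats")
  feat_sfnc <- sf_tbl |>
    tidyr::unite("feature", "channel_i", "channel_j", sep = "~") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "z")
  glm_sfnc <- group_glm(feat_sfnc, panel$manifest, covariates = covars,
                        q_threshold = config$stats$fdr_q)
  write_csv_with_schema(as_tibble(glm_sfnc),
                        file.path(out_dir, "glm_sfnc.csv"))

  glm_states <- group_glm(
    dplyr::select(metrics, "subject_id", dplyr::starts_with("ft_"),
                  "n_transitions"),
    panel$manifest, covariates = covars, fdr = FALSE,
    q_threshold = config$stats$fdr_q)
  write_csv_with_schema(as_tibble(glm_states),
                        file.path(out_dir, "glm_state_metrics.csv"))

  if (isTRUE(config$stats$fd_validation) && "mean_fd" %in% names(panel$manifest)) {
    glm_fd <- group_glm(feat_sfnc, panel$manifest,
                        covariates = c(covars, "mean_fd"),
                        q_threshold = config$stats$fdr_q)
    write_csv_with_schema(as_tibble(glm_fd),
                          file.path(out_dir, "glm_sfnc_fd_validation.csv"))
  }

  info <- list(config = unclass(config),
               config_hash = rlang::hash(unclass(config)),
               n_subjects = length(panel$series),
               elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               package_version = as.character(utils::packageVersion("dynfnc")))
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done", sprintf("%.1fs", info$elapsed_seconds))
  invisible(list(sfnc = sf, dfnc = dk, states = model, metrics = metrics,
                 variability = variab, flexibility = flex,
                 switching = switching, glm_sfnc = glm_sfnc))
}
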