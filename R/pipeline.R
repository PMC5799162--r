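#' Pipeline run configuration
#'
#' Every knob of the metrics -> modules -> classify -> compare pipeline in
#' one object, round-trippable through YAML so any reported number can be
#' reproduced from the echoed config file.
#'
#' @param dialect A [matrix_dialect()].
#' @param detection `"greedy"` (deterministic CNM, default) or
#'   `"exhaustive"` (exact, networks up to 12 nodes).
#' @param classify A [classify_config()].
#' @param round_D,round_CLH Report rounding (decimals) for D and for C/L/H.
#' @param seed Integer seed recorded with the run (the deterministic stages
#'   do not consume randomness, but the seed is part of the provenance
#'   record).
#' @return A list of class `run_config`.
#' @export
run_config <- function(dialect = matrix_dialect(),
                       detection = c("greedy", "exhaustive"),
                       classify = classify_config(),
                       round_D = 3, round_CLH = 2, seed = 1) {
  detection <- match.arg(detection)
  structure(list(dialect = unclass(dialect), detection = detection,
                 classify = unclass(classify),
                 round_D = round_D, round_CLH = round_CLH, seed = seed),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    dialect = do.call(matrix_dialect, raw$dialect),
    detection = raw$detection,
    classify = do.call(classify_config, raw$classify),
    round_D = raw$round_D, round_CLH = raw$round_CLH, seed = raw$seed)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on one or more taxa
#'
#' For each input matrix: read and validate, compute the six-parameter
#' summary, detect modules, profile and classify them, and assemble the
#' cross-taxon table with its fixture report. Writes a result bundle
#' (`parameters.json`, `partition_<taxon>.csv`, `profiles.json`,
#' `table.csv`, `fixture_report.csv`, `config.yaml`, `run_log.txt`) to
#' `out_dir`. Re-running with identical config and inputs reproduces
#' identical outputs; the log records MD5 hashes of inputs and outputs so
#' that can be verified.
#'
#' @param matrix_files Character vector of adjacency matrix paths.
#' @param meta_files Optional parallel vector of metadata paths (NA entries
#'   allowed).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param kinds Network kinds passed to [build_table()].
#' @return Invisibly, a list with `table`, `fixture_report`, `partitions`,
#'   `profiles`, `parameters`, `warnings` and the output `paths`.
#' @export
run_pipeline <- function(matrix_files, meta_files = NULL, out_dir,
                         config = run_config(), kinds = "muscle_bone") {
  stopifnot(length(matrix_files) >= 1)
  if (is.null(meta_files)) meta_files <- rep(NA_character_, length(matrix_files))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)
  note <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  dialect <- do.call(matrix_dialect, config$dialect)
  classify <- do.call(classify_config, config$classify)

  nets <- list(); partitions <- list(); profiles <- list(); params <- list()
  for (i in seq_along(matrix_files)) {
    net <- stage("read_adjacency", withCallingHandlers(
      read_adjacency(matrix_files[i], dialect = dialect,
                     metadata = if (is.na(meta_files[i])) NULL else
                       read_metadata(meta_files[i])),
      warning = note))
    ps <- stage("parameter_set",
                withCallingHandlers(parameter_set(net), warning = note))
    part <- stage("module_detection",
                  if (config$detection == "exhaustive")
                    detect_modules_exhaustive(net)
                  else detect_modules_greedy(net))
    prof <- stage("module_classify",
                  profile_modules(net, part, config = classify))
    nets[[net$taxon_id]] <- net
    partitions[[net$taxon_id]] <- part
    profiles[[net$taxon_id]] <- prof
    params[[net$taxon_id]] <- ps
  }

  tab <- stage("build_table", withCallingHandlers(
    build_table(nets, kinds = kinds, config = classify), warning = note))
  report <- stage("fixture_check", check_against_fixture(tab))

  paths <- list(
    parameters = file.path(out_dir, "parameters.json"),
    profiles = file.path(out_dir, "profiles.json"),
    table = file.path(out_dir, "table.csv"),
    fixture_report = file.path(out_dir, "fixture_report.csv"),
    config = file.path(out_dir, "config.yaml"),
    log = file.path(out_dir, "run_log.txt"))

  param_report <- lapply(params, function(p) {
    out <- unclass(p)
    out$D_report <- round(p$D, config$round_D)
    out$C_report <- round(p$C, config$round_CLH)
    out$L_report <- round(p$L, config$round_CLH)
    out$H_report <- round(p$H, config$round_CLH)
    out
  })
  jsonlite::write_json(param_report, paths$parameters, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (tx in names(partitions)) {
    p <- partitions[[tx]]
    utils::write.csv(
      data.frame(node = names(p$assignment), module_id = p$assignment),
      file.path(out_dir, sprintf("partition_%s.csv", tx)), row.names = FALSE)
  }
  prof_report <- lapply(profiles, function(pl) lapply(pl, function(p) {
    list(module_id = p$module_id, size = p$size, label = p$label,
         asymmetric = p$asymmetric,
         facial_muscle_count = p$facial_muscle_count,
         tissue_counts = as.list(p$tissue_counts),
         side_counts = as.list(p$side_counts),
         members = p$members)
  }))
  jsonlite::write_json(prof_report, paths$profiles, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(tab, paths$table, row.names = FALSE)
  utils::write.csv(report, paths$fixture_report, row.names = FALSE)
  write_config(config, paths$config)

  in_hash <- tools::md5sum(c(matrix_files, meta_files[!is.na(meta_files)]))
  out_files <- c(unlist(paths[names(paths) != "log"]),
                 file.path(out_dir, sprintf("partition_%s.csv",
                                            names(partitions))))
  out_hash <- tools::md5sum(out_files)
  log_lines <- c(
    sprintf("anatnet run, %d input(s), detection=%s, seed=%d",
            length(matrix_files), config$detection, config$seed),
    "input md5:",
    sprintf("  %s  %s", in_hash, names(in_hash)),
    "output md5:",
    sprintf("  %s  %s", out_hash, names(out_hash)),
    sprintf("warnings: %d", length(warn_log)),
    if (length(warn_log) > 0) paste0("  - ", warn_log))
  writeLines(log_lines, paths$log)

  invisible(list(table = tab, fixture_report = report,
                 partitions = partitions, profiles = profiles,
                 parameters = params, warnings = warn_log, paths = paths))
}
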