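#' Run a complete sensitivity analysis from a configuration file
#'
#' End-to-end orchestration of the randomized OAT analysis: load and validate
#' the configuration, run the randomized ranking (and, if requested, the
#' classical sensitivity-function baseline), and write the outputs to
#' `out_dir`: `ranking.csv` (one row per parameter), `ranking.json` (ranking
#' plus, when `include_samples: true`, every sampled alpha and S value),
#' `classical_ranking.csv` when the baseline is enabled, `report.json` (run
#' metadata sufficient to reproduce the analysis with the same package
#' version: model, seed, n, distribution, solver settings, timings) and
#' `analysis.log` (one machine-parsable `key=value` line per parameter).
#'
#' @param config_path Path to a YAML/JSON configuration, see
#'   [load_model_config()].
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages.
#' @return An object of class `analysis_report` (invisibly): list with
#'   `ranking` (the `oat_ranking`), `classical` (a `classical_ranking` or
#'   `NULL`), `metadata` and `files`.
#' @export
run_analysis <- function(config_path, out_dir, quiet = FALSE) {
  t0 <- Sys.time()
  loaded <- load_model_config(config_path)
  model <- loaded$model
  cfg <- loaded$config
  an <- loaded$analysis
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say <- function(...) if (!quiet) message(sprintf(...))
  say("model=%s states=%d ranked_params=%d n=%d seed=%d",
      model$name, length(model$state_names), length(ranked_params(model)),
      an$n, an$seed)

  t_rank0 <- Sys.time()
  ranking <- rank_parameters(
    model, cfg, dist = an$distribution, n = an$n, seed = an$seed,
    neutral_band = an$neutral_band
  )
  t_rank <- as.numeric(difftime(Sys.time(), t_rank0, units = "secs"))

  classical <- NULL
  t_cl <- NA_real_
  if (an$classical) {
    t_cl0 <- Sys.time()
    classical <- rank_classical(model, cfg, rel_step = an$rel_step)
    t_cl <- as.numeric(difftime(Sys.time(), t_cl0, units = "secs"))
  }

  files <- list(
    ranking_csv = file.path(out_dir, "ranking.csv"),
    ranking_json = file.path(out_dir, "ranking.json"),
    report_json = file.path(out_dir, "report.json"),
    log = file.path(out_dir, "analysis.log")
  )
  write.csv(as.data.frame(ranking$ranking), files$ranking_csv,
            row.names = FALSE)
  json_payload <- list(
    ranking = ranking$ranking,
    samples = if (an$include_samples) ranking$samples else NULL
  )
  jsonlite::write_json(json_payload, files$ranking_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(classical)) {
    files$classical_csv <- file.path(out_dir, "classical_ranking.csv")
    write.csv(as.data.frame(classical$ranking), files$classical_csv,
              row.names = FALSE)
  }

  dist <- an$distribution
  metadata <- list(
    tool = "aucsens",
    version = as.character(packageVersion("aucsens")),
    config_path = normalizePath(config_path),
    model = model$name,
    output_variable = model$output_variable,
    horizon = cfg$horizon,
    grid_points = length(cfg$times),
    rtol = cfg$rtol, atol = cfg$atol, stiff = cfg$stiff,
    n_samples = an$n,
    seed = an$seed,
    neutral_band = an$neutral_band,
    distribution = list(kind = dist$kind, meanlog = dist$meanlog,
                        sdlog = dist$sdlog, value = dist$value,
                        mode = dist$mode),
    excluded = model$non_ranked_params,
    timing_seconds = list(
      total = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      randomized_ranking = t_rank,
      classical_ranking = t_cl
    )
  )
  jsonlite::write_json(metadata, files$report_json, auto_unbox = TRUE,
                       digits = NA, null = "null")

  log_lines <- c(
    sprintf("model=%s seed=%d n=%d total_simulations=%d",
            model$name, an$seed, an$n,
            1L + sum(ranking$ranking$n_effective + ranking$ranking$failed_runs)),
    sprintf("param=%s A=%.6g n_effective=%d failed=%d class=%s",
            ranking$ranking$parameter, ranking$ranking$A,
            ranking$ranking$n_effective, ranking$ranking$failed_runs,
            ranking$ranking$classification)
  )
  writeLines(log_lines, files$log)
  for (line in log_lines) say("%s", line)

  invisible(structure(
    list(ranking = ranking, classical = classical, metadata = metadata,
         files = files),
    class = "analysis_report"
  ))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> model '%s', %d parameters ranked, outputs in %s\n",
              x$metadata$model, nrow(x$ranking$ranking),
              dirname(x$files$ranking_csv)))
  print(x$ranking$ranking, ...)
  invisible(x)
}

#' Save a ranking figure to a file
#'
#' Renders the [autoplot()] of a randomized or classical ranking (display
#' value per parameter on a log axis with the no-effect threshold line at 1,
#' or the unsigned classical index) and writes it to `out_path`.
#'
#' @param ranking An `oat_ranking` or `classical_ranking`.
#' @param out_path Figure path; the extension selects the device (png, pdf,
#'   svg, ...).
#' @param width,height Figure size in inches.
#' @return `out_path`, invisibly.
#' @export
plot_ranking <- function(ranking, out_path, width = 7, height = 4) {
  if (!inherits(ranking, c("oat_ranking", "classical_ranking"))) {
    abort_validation("`ranking` must be an oat_ranking or classical_ranking.")
  }
  if (nrow(ranking$ranking) == 0L) {
    abort_validation("Cannot plot an empty ranking.")
  }
  ggplot2::ggsave(out_path, autoplot(ranking), width = width, height = height)
  invisible(out_path)
}

cli_usage <- "usage: aucsens <command> [options]

commands:
  rank            randomized OAT ranking
                  --model <config> --out <dir> [--n N] [--seed S]
                  [--dist lognormal|degenerate] [--mu M] [--sigma SD]
                  [--value V] [--exclude p]... [--classical] [--quiet]
  rank-classical  classical sensitivity-function ranking only
                  --model <config> --out <dir> [--rel-step H]
  ensemble        population ensemble for one or more parameters
                  --model <config> --param <name>[,name...] --out <dir>
                  [--n N] [--seed S] [--mu M] [--sigma SD]
  plot            write the ranking figure
                  --model <config> --out <dir> [--n N] [--seed S]
"

parse_cli <- function(args) {
  flags <- list(exclude = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      abort_config(sprintf("Unexpected argument '%s'.", a))
    }
    key <- sub("^--", "", a)
    if (key %in% c("classical", "quiet")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) abort_config(sprintf("--%s needs a value.", key))
      val <- args[[i + 1L]]
      if (key == "exclude") {
        flags$exclude <- c(flags$exclude, val)
      } else {
        flags[[key]] <- val
      }
      i <- i + 2L
    }
  }
  flags
}

cli_config_overrides <- function(flags) {
  ov <- list()
  if (!is.null(flags$n)) ov$n_samples <- as.integer(flags$n)
  if (!is.null(flags$seed)) ov$seed <- as.integer(flags$seed)
  if (!is.null(flags$`rel-step`)) ov$rel_step <- as.numeric(flags$`rel-step`)
  dist <- list()
  if (!is.null(flags$dist)) dist$kind <- flags$dist
  if (!is.null(flags$mu)) dist$meanlog <- as.numeric(flags$mu)
  if (!is.null(flags$sigma)) dist$sdlog <- as.numeric(flags$sigma)
  if (!is.null(flags$value)) dist$value <- as.numeric(flags$value)
  if (length(dist)) ov$distribution <- dist
  if (length(flags$exclude)) ov$exclude <- flags$exclude
  if (isTRUE(flags$classical)) ov$classical <- TRUE
  ov
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over [run_analysis()], [rank_classical()],
#' [population_ensemble()] and [plot_ranking()], intended to be called from
#' an `Rscript` wrapper (one ships in `inst/scripts/aucsens.R`). Command-line
#' flags override the corresponding configuration-file values by writing a
#' merged temporary configuration.
#'
#' @param args Character vector of command-line arguments, e.g.
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
aucsens_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[[1L]] %in% c("-h", "--help", "help")) {
    cat(cli_usage)
    return(invisible(0L))
  }
  command <- args[[1L]]
  status <- tryCatch({
    flags <- parse_cli(args[-1L])
    if (is.null(flags$model)) abort_config("--model <config> is required.")
    merged_cfg <- merge_config_file(flags$model, cli_config_overrides(flags))
    on.exit(unlink(merged_cfg), add = TRUE)
    out_dir <- flags$out %||% "."
    switch(command,
      rank = {
        run_analysis(merged_cfg, out_dir, quiet = isTRUE(flags$quiet))
        0L
      },
      `rank-classical` = {
        loaded <- load_model_config(merged_cfg)
        cl <- rank_classical(loaded$model, loaded$config,
                             rel_step = loaded$analysis$rel_step)
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write.csv(as.data.frame(cl$ranking),
                  file.path(out_dir, "classical_ranking.csv"),
                  row.names = FALSE)
        0L
      },
      ensemble = {
        if (is.null(flags$param)) abort_config("--param <name> is required.")
        loaded <- load_model_config(merged_cfg)
        ens <- population_ensemble(
          loaded$model, loaded$config,
          param = strsplit(flags$param, ",")[[1L]],
          dist = loaded$analysis$distribution,
          n = loaded$analysis$n, seed = loaded$analysis$seed
        )
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write.csv(as.data.frame(ens$mean_trajectory),
                  file.path(out_dir, "ensemble_mean.csv"), row.names = FALSE)
        write.csv(as.data.frame(ens$runs),
                  file.path(out_dir, "ensemble_runs.csv"), row.names = FALSE)
        0L
      },
      plot = {
        loaded <- load_model_config(merged_cfg)
        r <- rank_parameters(loaded$model, loaded$config,
                             dist = loaded$analysis$distribution,
                             n = loaded$analysis$n, seed = loaded$analysis$seed)
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        plot_ranking(r, file.path(out_dir, "ranking.png"))
        0L
      },
      {
        cat(cli_usage)
        abort_config(sprintf("Unknown command '%s'.", command))
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

merge_config_file <- function(config_path, overrides) {
  if (!file.exists(config_path)) {
    abort_config(sprintf("No such file: %s", config_path))
  }
  doc <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  if (length(overrides)) {
    if (!is.null(overrides$exclude)) {
      doc$exclude <- union(unlist(doc$exclude), overrides$exclude)
      overrides$exclude <- NULL
    }
    if (!is.null(overrides$distribution)) {
      doc$distribution <- modifyList(doc$distribution %||% list(),
                                     overrides$distribution)
      overrides$distribution <- NULL
    }
    doc <- modifyList(doc, overrides)
  }
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, tmp)
  tmp
}
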