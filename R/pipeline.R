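#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> fit -> validate -> project and writes all
#' artifacts to a directory: the surface and projection CSVs, tidy fit
#' summaries, the hold-out validation report, scenario tables with percent
#' changes, and a machine-readable JSON manifest (package version, seeds,
#' config echo, file checksums). Reruns with the same config and seeds
#' reproduce the deterministic outputs checksum-for-checksum.
#'
#' @param config A named list or the path of a YAML file. Recognised keys:
#'   \describe{
#'     \item{simulate}{list of [sim_config()] arguments (used when no input
#'       files are given)}
#'     \item{surface, projection}{paths of input CSVs (alternative to
#'       `simulate`); `sex` selects the rows}
#'     \item{model}{`"bapc"` (default) or `"lee_carter"`; `model_args` are
#'       passed to [bapc_spec()] / [lc_control()]}
#'     \item{split_year}{hold-out split for validation (omit to skip
#'       validation)}
#'     \item{project}{logical: run the two scenarios (default `TRUE`)}
#'     \item{reference_year}{for [percent_change()]; default last observed}
#'     \item{seed}{base seed for every stochastic stage}
#'   }
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S"),
                                           " [pipeline] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    proj <- NULL
    if (!is.null(config$surface)) {
      if (!file.exists(config$surface)) {
        stop("missing input: surface file '", config$surface, "'")
      }
      surface <- read_surface(config$surface, config$sex %||% "male")
      if (!is.null(config$projection)) {
        if (!file.exists(config$projection)) {
          stop("missing input: projection file '", config$projection, "'")
        }
        proj <- read_projection(config$projection, config$sex %||% "male")
      }
      say("read surface from ", config$surface)
    } else {
      args <- config$simulate %||% list()
      args$seed <- args$seed %||% seed
      cfg <- do.call(sim_config, args)
      surface <- simulate_surface(cfg)$surface
      proj <- simulate_projection(cfg)
      say("simulated surface I=", cfg$I, " J=", cfg$J)
    }
    write_forecast(surface, file.path(out_dir, "surface.csv"))
    if (!is.null(proj)) {
      write_forecast(proj, file.path(out_dir, "projection.csv"))
    }
  }, error = fail)

  stage <- "fit"
  tryCatch({
    model_name <- config$model %||% "bapc"
    margs <- config$model_args %||% list()
    model <- switch(model_name,
      bapc = do.call(bapc_spec, c(margs, list(seed = seed))),
      lee_carter = do.call(lc_control, margs),
      stop("unknown model '", model_name, "'")
    )
    horizon <- if (!is.null(proj)) length(unique(proj$year)) else 10L
    say("fitting ", model_name)
    if (inherits(model, "bapc_spec")) {
      fit <- fit_bapc(surface, model)
      fc <- predict(fit, horizon = horizon, seed = seed)
      fit_summary <- dplyr::bind_cols(glance(fit),
                                      tibble::tibble(model = "bapc"))
    } else {
      lc <- fit_lee_carter(central_rates(surface))
      fc <- forecast_lee_carter(lc, horizon, n_sims = model$n_sims,
                                seed = seed, jump_off = model$jump_off)
      fit_summary <- dplyr::bind_cols(glance(lc),
                                      tibble::tibble(model = "lee_carter"))
    }
    readr::write_csv(fit_summary, file.path(out_dir, "fit_summary.csv"),
                     progress = FALSE)
    write_forecast(fc, file.path(out_dir, "forecast.csv"))
  }, error = fail)

  stage <- "validate"
  tryCatch({
    if (!is.null(config$split_year)) {
      say("hold-out validation at split ", config$split_year)
      rep <- compare_models(
        surface,
        models = list(constant = "constant",
                      lee_carter = lc_control(),
                      bapc = do.call(bapc_spec,
                                     c(config$model_args %||% list(),
                                       list(seed = seed)))),
        split_year = config$split_year, seed = seed
      )
      readr::write_csv(tibble::as_tibble(rep),
                       file.path(out_dir, "validation.csv"),
                       progress = FALSE)
    }
  }, error = fail)

  stage <- "project"
  tryCatch({
    if (isTRUE(config$project %||% TRUE)) {
      if (is.null(proj)) {
        stop("missing input: no population projection available but ",
             "'project' was requested")
      }
      say("projecting scenarios")
      scA <- scenario_constant(surface, proj, n_sims = 1000, seed = seed)
      scB <- scenario_forecast(fc, proj, observed = surface)
      write_forecast(scA, file.path(out_dir, "scenario_constant.csv"))
      write_forecast(scB, file.path(out_dir, "scenario_forecast.csv"))
      ref <- config$reference_year %||% max(surface$year)
      pc <- dplyr::bind_rows(
        dplyr::mutate(percent_change(scA, ref), scenario = "constant"),
        dplyr::mutate(percent_change(scB, ref), scenario = "forecast")
      )
      readr::write_csv(pc, file.path(out_dir, "percent_change.csv"),
                       progress = FALSE)
    }
  }, error = fail)

  stage <- "manifest"
  tryCatch({
    files <- setdiff(list.files(out_dir), "manifest.json")
    sums <- tools::md5sum(file.path(out_dir, files))
    names(sums) <- files
    manifest <- list(
      id = substr(paste(sums, collapse = ""), 1, 12),
      package = "apcforecast",
      version = as.character(utils::packageVersion("apcforecast")),
      seed = seed,
      config = config,
      checksums = as.list(sums)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("done; manifest id ", manifest$id)
    invisible(manifest)
  }, error = fail)
}
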