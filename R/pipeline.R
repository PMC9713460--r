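# End-to-end pipeline: counts -> parameters -> cube -> simulation -> metrics.

read_csv_checked <- function(path, required, stage) {
  if (!file.exists(path)) {
    abort(paste0(stage, ": input file not found: ", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(paste0(stage, ": parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      stage, ": parse error in ", path, ": missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in required) {
    bad <- which(is.na(df[[col]]))
    if (col %in% c("n_assessed", "gdbi_tested", "gdbi_positive") &&
        length(bad) > 0) {
      abort(paste0(stage, ": parse error in ", path, ", row ", bad[1],
                   ", column ", col, ": missing value"))
    }
  }
  as_tibble(df)
}

#' Run the full assessment pipeline for one drive line
#'
#' Composes the package end to end: pooled cross counts are converted to
#' cutting/homing/resistance rates, the deposition rate and fitness
#' modifiers are attached, the inheritance cube is built, the demographic
#' equilibrium calibrated, the release scenario simulated, and outcome
#' metrics summarised. All artifacts are written under `out_dir` and every
#' derived parameter's provenance (source file or override) is recorded in
#' the run log. Given the same config the artifact files are reproduced
#' byte-identically.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   `pools_csv` (pooled cross counts; required), `line` (line to select),
#'   `dF` (deposition rate) or `transhet_csv` (replicate assay for
#'   [estimate_deposition()]), `fitness_csv` + `reference_line` (optional
#'   fitness table), `overrides` (named list passed to
#'   [scenario_substitute()]), `release` (list with `day`, `count`),
#'   `days`, `reps`, `seed`, `mode`, `out_dir`.
#' @return Invisibly, a list with `params`, `lifecycle`, `cube`, `sim`,
#'   `metrics` and the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$pools_csv)) abort("run_pipeline: config needs `pools_csv`")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # --- parameter estimation ---------------------------------------------
  pools <- read_csv_checked(
    config$pools_csv,
    c("line", "parent_sex", "n_assessed", "gdbi_tested", "gdbi_positive"),
    "estimate"
  )
  if (!is.null(config$line)) pools <- pools[pools$line == config$line, ]
  if (nrow(pools) == 0) abort("run_pipeline: no pool rows for requested line")
  cuts <- estimate_cut_params(pools)
  for (i in seq_len(nrow(cuts))) {
    note("param c/ch/cr [", cuts$parent_sex[i], "] <- ", config$pools_csv,
         " (line ", cuts$line[i], "): c=", signif(cuts$c[i], 6),
         " ch=", signif(cuts$ch[i], 6))
  }

  if (!is.null(config$dF)) {
    dF <- config$dF
    note("param dF <- config override: ", dF)
  } else if (!is.null(config$transhet_csv)) {
    assay <- read_csv_checked(
      config$transhet_csv,
      c("marker_class", "n_larvae", "n_active_drive_locus"), "estimate"
    )
    dF <- estimate_deposition(assay)$dF
    note("param dF <- ", config$transhet_csv, ": ", signif(dF, 6))
  } else {
    dF <- 0
    note("param dF <- default 0 (no deposition input)")
  }

  lc_row <- NULL
  lc <- lifecycle_params()
  if (!is.null(config$fitness_csv)) {
    fitness <- read_csv_checked(
      config$fitness_csv,
      c("line", "fecundity_mean", "larval_viability", "larva_to_pupa_days"),
      "estimate"
    )
    lc_row <- derive_lifecycle(fitness, config$line,
                               config$reference_line %||% "HWE")
    lc <- lifecycle_params(betaK = lc_row$betaK, tLarva = lc_row$tLarva)
    note("param betaK <- ", config$fitness_csv, ": ", signif(lc_row$betaK, 6))
    note("param tLarva <- ", config$fitness_csv, ": ", lc_row$tLarva)
    note("param xiF/xiM <- ", config$fitness_csv, ": ", lc_row$xiF)
  }
  params <- as_drive_params(cuts, dF = dF, lifecycle = lc_row,
                            line = config$line)

  cfg <- list(params = params, lifecycle = lc)
  if (!is.null(config$overrides) && length(config$overrides) > 0) {
    cfg <- scenario_substitute(cfg, config$overrides)
    ov <- attr(cfg, "overrides")
    for (i in seq_len(nrow(ov))) {
      note("param ", ov$field[i], " <- override: ", ov$new[i],
           " (was ", signif(ov$old[i], 6), ")")
    }
    params <- cfg$params
    lc <- cfg$lifecycle
  }

  # --- cube --------------------------------------------------------------
  cube <- build_cube(params)
  cube_path <- file.path(out_dir, "cube.csv")
  write_cube_csv(cube, cube_path)
  note("cube -> ", cube_path)

  params_path <- file.path(out_dir, "params.json")
  jsonlite::write_json(
    list(drive_params = unclass(params), lifecycle_params = unclass(lc)),
    params_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  note("params -> ", params_path)

  # --- simulation --------------------------------------------------------
  sim <- NULL
  metrics <- NULL
  if (!is.null(config$days)) {
    calib <- calibrate_equilibrium(lc)
    rel <- if (!is.null(config$release)) {
      release_schedule(
        day = config$release$day %||% 25,
        count = config$release$count %||% 2000,
        genotype = config$release$genotype %||% "HH",
        sex = config$release$sex %||% "M"
      )
    } else {
      release_schedule()
    }
    mode <- config$mode %||% "stochastic"
    sim <- simulate_release(
      cube, calib, params, release = rel, days = config$days,
      reps = config$reps %||% 1, seed = config$seed %||% 1, mode = mode
    )
    traj_path <- file.path(out_dir, "trajectories.csv")
    utils::write.csv(tidy.gd_sim(sim), traj_path, row.names = FALSE)
    note("trajectories -> ", traj_path)
    metrics <- glance.gd_sim(sim)
    metrics_path <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(as.list(metrics), metrics_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    note("metrics -> ", metrics_path)
  }

  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  invisible(list(
    params = params, lifecycle = lc, cube = cube, sim = sim,
    metrics = metrics,
    paths = list(params = params_path, cube = cube_path, log = log_path)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
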