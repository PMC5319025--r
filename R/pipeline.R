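#' Run a pipeline stage
#'
#' Single entry point tying the package's stages together, mirroring a
#' command-line interface: each call executes one subcommand with a
#' configuration, writes CSV artifacts plus a JSON manifest (config echo,
#' seed, output checksums) into `out`, and returns the manifest.  Output
#' files are never silently overwritten (`force = TRUE` required).
#' Seeded runs are byte-identical on re-execution.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{Gillespie trajectory at `params`; writes
#'     `trajectory.csv` (time, s, r1, r2, p1, p2). Options: `t_max`.}
#'   \item{sweep}{`p0` sweep of the stationary statistics; writes
#'     `sweep.csv`. Options: `p0_min`, `p0_max`, `n_points`, `method`.}
#'   \item{generate}{synthetic cotransfection population; writes
#'     `cells.csv` (+ sidecar and ground truth). Options: the
#'     [population_config()] fields under `population`.}
#'   \item{analyze}{cytometry pipeline on a cell table; writes
#'     `binned.csv` and, when a reference table is supplied,
#'     `fold_repression.csv` and `pearson_ratio.csv`. Options: `cells`
#'     (path), `reference` (path, optional), `n_bins`, `min_cells`.}
#'   \item{phase}{phase-diagram classification over a parameter grid;
#'     writes `phase.csv`. Options: `g2_over_g1` (vector), `k_r_values`
#'     (vector), `n_cells`.}
#' }
#'
#' @param config a list (or YAML/JSON file path) with at least
#'   `subcommand` and `out`; optionally `params` (path to a parameter
#'   file or a `cerna_params` list), `seed` (default 1), `force`, and
#'   subcommand options as above.
#' @return The manifest (list), invisibly.
#' @export
cerna_run <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  sub <- config$subcommand
  known <- c("simulate", "sweep", "generate", "analyze", "phase")
  if (is.null(sub) || !sub %in% known) {
    stop("unknown subcommand '", if (is.null(sub)) "<missing>" else sub,
         "'; expected one of: ", paste(known, collapse = ", "))
  }
  if (is.null(config$out)) stop("config$out (output directory) is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  force <- isTRUE(config$force)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  pars <- resolve_params(config$params)
  files <- switch(sub,
    simulate = run_simulate(config, pars, seed, force),
    sweep = run_sweep(config, pars, seed, force),
    generate = run_generate(config, pars, seed, force),
    analyze = run_analyze(config, pars, seed, force),
    phase = run_phase(config, pars, seed, force))
  manifest <- list(
    subcommand = sub, seed = seed,
    package_version = as.character(utils::packageVersion("cernasim")),
    config = config[setdiff(names(config), "force")],
    params = unclass(pars),
    outputs = as.list(tools::md5sum(files)))
  mpath <- file.path(config$out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

resolve_params <- function(params) {
  if (is.null(params)) return(cerna_params())
  if (is.character(params)) return(read_params(params, partial = TRUE))
  validate_params(modifyList(as.list(cerna_params()), params))
}

out_file <- function(config, name, force) {
  path <- file.path(config$out, name)
  if (file.exists(path) && !force) {
    stop("output exists (use force = TRUE to overwrite): ", path)
  }
  path
}

opt <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

run_simulate <- function(config, pars, seed, force) {
  path <- out_file(config, "trajectory.csv", force)
  tr <- gillespie(pars, t_max = opt(config, "t_max", 100), seed = seed)
  df <- data.frame(time = tr$times, tr$states)
  write.csv(df, path, row.names = FALSE)
  path
}

run_sweep <- function(config, pars, seed, force) {
  path <- out_file(config, "sweep.csv", force)
  p0_min <- opt(config, "p0_min", 5)
  p0_max <- opt(config, "p0_max", 5000)
  n_points <- opt(config, "n_points", 40)
  grid <- exp(seq(log(p0_min), log(p0_max), length.out = n_points))
  sw <- sweep_p0(pars, grid, method = opt(config, "method", "moments"),
                 n_cells = opt(config, "n_cells", 500), seed = seed)
  write.csv(as.data.frame(sw), path, row.names = FALSE)
  path
}

run_generate <- function(config, pars, seed, force) {
  path <- out_file(config, "cells.csv", force)
  pop <- opt(config, "population", list())
  pop$seed <- seed
  cfg <- do.call(population_config, pop)
  cells <- generate_population(cfg, pars)
  write_cells(cells, path)
  c(path, paste0(path, ".json"), sub("\\.csv$", "_truth.csv", path))
}

run_analyze <- function(config, pars, seed, force) {
  if (is.null(config$cells)) stop("analyze requires config$cells (CSV path)")
  binned_path <- out_file(config, "binned.csv", force)
  cells <- read_cells(config$cells)
  gated <- gate_positive(background_correct(cells))
  bs <- bin_and_summarize(gated, n_bins = opt(config, "n_bins", "auto"),
                          min_cells = opt(config, "min_cells", 100))
  write.csv(bs$aggregated, binned_path, row.names = FALSE)
  files <- binned_path
  thr <- tryCatch(binned_threshold(bs), error = function(e) NULL)
  if (!is.null(config$reference)) {
    ref <- read_cells(config$reference)
    ref_gated <- gate_positive(background_correct(ref))
    ref_bs <- bin_and_summarize(ref_gated, breaks = bs$breaks,
                                min_cells = opt(config, "min_cells", 100))
    f_path <- out_file(config, "fold_repression.csv", force)
    write.csv(empirical_fold_repression(bs, ref_bs), f_path,
              row.names = FALSE)
    files <- c(files, f_path)
    if (!is.null(thr) && thr$has_threshold) {
      pr_path <- out_file(config, "pearson_ratio.csv", force)
      pr <- pearson_ratio(gated, ref_gated, bs$breaks, thr$bin)
      write.csv(pr, pr_path, row.names = FALSE)
      files <- c(files, pr_path)
    }
  }
  files
}

run_phase <- function(config, pars, seed, force) {
  path <- out_file(config, "phase.csv", force)
  ratios <- opt(config, "g2_over_g1", c(0.05, 0.5, 2))
  krs <- opt(config, "k_r_values", c(5, 20, 80))
  rows <- NULL
  for (gr in ratios) {
    for (kr in krs) {
      p <- pars
      p$g_2 <- p$g_1 * gr
      p$k_r2 <- kr
      ph <- classify_phase(p, n_cells = opt(config, "n_cells", 1000),
                           seed = seed)
      rows <- rbind(rows, data.frame(
        g2_over_g1 = gr, k_r2 = kr, g_1 = p$g_1, g_2 = p$g_2,
        mean_targets = ph$mean_targets, rho_max = ph$rho_max,
        crosstalk = as.character(ph$crosstalk), bimodal = ph$bimodal,
        dip_p_value = ph$dip_p_value))
    }
  }
  write.csv(rows, path, row.names = FALSE)
  path
}
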