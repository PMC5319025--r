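#' Configuration of a synthetic cotransfection population
#'
#' Describes a virtual transient-cotransfection experiment with two
#' bidirectional plasmids: plasmid 1 carries the regulated reporter
#' mCherry (N_cherry miRNA sites) and the constitutive eYFP; plasmid 2
#' carries mCerulean (N_cerulean sites) and the constitutive mKOrange.
#' Per-cell plasmid copy numbers follow a correlated bivariate log-normal
#' (co-uptake during transfection); each copy contributes transcription
#' rate `k_r_unit`, so the population spans a broad range of constitutive
#' expression.  Fluorescence is a linear gain per molecule plus additive
#' Gaussian autofluorescence background, truncated at instrument zero.
#'
#' @param n_cells cells per replicate.
#' @param n_replicates biological replicates.
#' @param copy_meanlog,copy_sdlog log-normal parameters of the per-cell
#'   plasmid copy number (same law for both plasmids).
#' @param copy_cor correlation of the two plasmids' log copy numbers
#'   within a cell (co-uptake; default 0.3).
#' @param k_r_unit transcription rate contributed per plasmid copy.
#' @param N_cherry,N_cerulean number of miRNA regulatory elements on the
#'   regulated reporters (0, 1, 4 or 7).
#' @param g_unit interaction strength per miRNA site (see
#'   [mre_interaction()]).
#' @param saturating_mre use the saturating site-to-strength map.
#' @param premir_boost multiplicative boost of the miRNA transcription
#'   rate (co-transfected precursor miRNA); >= 1.
#' @param gains named numeric: a.u. per molecule for channels `eYFP`,
#'   `mCherry`, `mCerulean`, `mKOrange`.
#' @param bg_mean,bg_sd named numeric: autofluorescence background mean /
#'   sd per channel (a.u.).
#' @param n_control untransfected control cells per replicate
#'   (background only).
#' @param sampler `"gaussian"` (per-cell linear-noise conditional
#'   sampler, default) or `"ssa"` (exact per-cell Gillespie; slow).
#' @param seed integer seed.
#' @return A `population_config` list.
#' @export
population_config <- function(n_cells = 50000, n_replicates = 3,
                              copy_meanlog = log(30), copy_sdlog = 1.0,
                              copy_cor = 0.3, k_r_unit = 1,
                              N_cherry = 4, N_cerulean = 1,
                              g_unit = 0.5, saturating_mre = FALSE,
                              premir_boost = 1,
                              gains = c(eYFP = 2, mCherry = 2,
                                        mCerulean = 2, mKOrange = 2),
                              bg_mean = c(eYFP = 100, mCherry = 100,
                                          mCerulean = 100, mKOrange = 100),
                              bg_sd = c(eYFP = 25, mCherry = 25,
                                        mCerulean = 25, mKOrange = 25),
                              n_control = 10000,
                              sampler = c("gaussian", "ssa"),
                              seed = 1) {
  sampler <- match.arg(sampler)
  cfg <- list(n_cells = as.integer(n_cells),
              n_replicates = as.integer(n_replicates),
              copy_meanlog = copy_meanlog, copy_sdlog = copy_sdlog,
              copy_cor = copy_cor, k_r_unit = k_r_unit,
              N_cherry = N_cherry, N_cerulean = N_cerulean,
              g_unit = g_unit, saturating_mre = saturating_mre,
              premir_boost = premir_boost,
              gains = gains[CHANNELS], bg_mean = bg_mean[CHANNELS],
              bg_sd = bg_sd[CHANNELS], n_control = as.integer(n_control),
              sampler = sampler, seed = as.integer(seed))
  validate_population_config(cfg)
}

CHANNELS <- c("eYFP", "mCherry", "mCerulean", "mKOrange")

validate_population_config <- function(cfg) {
  if (cfg$n_cells < 1) stop("n_cells must be >= 1")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (cfg$copy_sdlog < 0) stop("copy_sdlog must be >= 0")
  if (abs(cfg$copy_cor) > 1) stop("copy_cor must lie in [-1,1]")
  if (cfg$k_r_unit <= 0) stop("k_r_unit must be > 0")
  if (!cfg$N_cherry %in% c(0, 1, 4, 7) || !cfg$N_cerulean %in% c(0, 1, 4, 7)) {
    stop("MRE counts must be one of 0, 1, 4, 7")
  }
  if (cfg$premir_boost < 1) stop("premir_boost must be >= 1")
  if (any(is.na(cfg$gains)) || any(cfg$gains <= 0)) {
    stop("gains must be positive for all four channels")
  }
  if (any(is.na(cfg$bg_mean)) || any(is.na(cfg$bg_sd)) || any(cfg$bg_sd < 0)) {
    stop("background law needs finite mean and sd >= 0 per channel")
  }
  structure(cfg, class = "population_config")
}

# blockwise linear-noise moments of (p1, p2) for vectors of per-cell
# transcription rates; exploits the triangular drift structure
# (mRNA/miRNA block feeds the protein block) so each cell costs three
# 3x3 solves instead of a 25-dimensional one.  Agrees with
# stationary_covariance() exactly (tested).
batch_protein_moments <- function(params, k_r1, k_r2) {
  n <- length(k_r1)
  s_all <- meanfield_s(params$k_s, k_r1, k_r2, params$g_s, params$g_r1,
                       params$g_r2, params$g_1, params$g_2, params$alpha)
  out <- matrix(NA_real_, n, 8,
                dimnames = list(NULL, c("s", "r1", "r2", "p1", "p2",
                                        "var_p1", "var_p2", "cov_p12")))
  I3 <- diag(3)
  L <- matrix(c(0, params$k_p1, 0, 0, 0, params$k_p2), 2, 3, byrow = TRUE)
  gp <- c(params$g_p1, params$g_p2)
  gpsum <- outer(gp, gp, "+")
  for (i in seq_len(n)) {
    s <- s_all[i]
    r1 <- k_r1[i] / (params$g_r1 + params$g_1 * s)
    r2 <- k_r2[i] / (params$g_r2 + params$g_2 * s)
    M <- matrix(c(
      -params$g_s - params$alpha * (params$g_1 * r1 + params$g_2 * r2),
      -params$alpha * params$g_1 * s, -params$alpha * params$g_2 * s,
      -params$g_1 * r1, -params$g_r1 - params$g_1 * s, 0,
      -params$g_2 * r2, 0, -params$g_r2 - params$g_2 * s),
      3, 3, byrow = TRUE)
    i1 <- params$g_1 * s * r1
    i2 <- params$g_2 * s * r2
    Bmm <- matrix(0, 3, 3)
    Bmm[1, 1] <- params$k_s + params$g_s * s + params$alpha * (i1 + i2)
    Bmm[2, 2] <- k_r1[i] + params$g_r1 * r1 + i1
    Bmm[3, 3] <- k_r2[i] + params$g_r2 * r2 + i2
    Bmm[1, 2] <- Bmm[2, 1] <- params$alpha * i1
    Bmm[1, 3] <- Bmm[3, 1] <- params$alpha * i2
    Cmm <- matrix(solve(kronecker(I3, M) + kronecker(M, I3),
                        -as.vector(Bmm)), 3, 3)
    RHS <- Cmm %*% t(L)
    Cmp <- cbind(solve(M - gp[1] * I3, -RHS[, 1]),
                 solve(M - gp[2] * I3, -RHS[, 2]))
    S <- L %*% Cmp
    p1 <- params$k_p1 * r1 / params$g_p1
    p2 <- params$k_p2 * r2 / params$g_p2
    Cpp <- (S + t(S) + diag(c(2 * gp[1] * p1, 2 * gp[2] * p2))) / gpsum
    out[i, ] <- c(s, r1, r2, p1, p2, Cpp[1, 1], Cpp[2, 2], Cpp[1, 2])
  }
  out
}

#' Generate a synthetic cotransfection population
#'
#' For each cell: draw correlated plasmid copy numbers `(D1, D2)`, scale
#' the target transcription rates (`k_r1 = D1 * k_r_unit`,
#' `k_r2 = D2 * k_r_unit`), obtain molecule counts for the regulated
#' proteins from the titration model (linear-noise conditional sampler by
#' default, exact SSA optionally) and for the constitutive reporters from
#' the unregulated two-stage law, then map molecules to fluorescence as
#' `gain * molecules + background`, truncated at instrument zero.  An
#' untransfected control population (background only) is appended per
#' replicate.
#'
#' @param config a [population_config()].
#' @param params_base a `cerna_params` object; its `k_r1`, `k_r2` are
#'   overridden per cell, `g_1`/`g_2` by the MRE maps, and `k_s` by the
#'   pre-miR boost.
#' @return A `cell_table` data.frame with columns `replicate`,
#'   `population` (`"transfected"`/`"control"`), the four channel
#'   intensities, and attributes `config`, `params` (effective model
#'   parameters) and `truth` (per-cell ground truth: copies and molecule
#'   counts).
#' @examples
#' cfg <- population_config(n_cells = 200, n_replicates = 1,
#'                          n_control = 100, seed = 42)
#' cells <- generate_population(cfg, cerna_params())
#' table(cells$population)
#' @export
generate_population <- function(config, params_base = cerna_params()) {
  config <- validate_population_config(config)
  params_base <- validate_params(params_base)
  pars <- params_base
  pars$g_1 <- mre_interaction(config$N_cherry, config$g_unit,
                              config$saturating_mre)
  pars$g_2 <- mre_interaction(config$N_cerulean, config$g_unit,
                              config$saturating_mre)
  pars$k_s <- pars$k_s * config$premir_boost
  set.seed(config$seed)
  reps <- lapply(seq_len(config$n_replicates), function(rep_id) {
    generate_replicate(config, pars, rep_id)
  })
  cells <- do.call(rbind, lapply(reps, `[[`, "cells"))
  truth <- do.call(rbind, lapply(reps, `[[`, "truth"))
  rownames(cells) <- rownames(truth) <- NULL
  structure(cells, config = config, params = pars, truth = truth,
            class = c("cell_table", "data.frame"))
}

generate_replicate <- function(config, pars, rep_id) {
  n <- config$n_cells
  # correlated log-normal plasmid copies
  z1 <- rnorm(n)
  z2 <- config$copy_cor * z1 + sqrt(1 - config$copy_cor^2) * rnorm(n)
  D1 <- exp(config$copy_meanlog + config$copy_sdlog * z1)
  D2 <- exp(config$copy_meanlog + config$copy_sdlog * z2)
  k_r1 <- D1 * config$k_r_unit
  k_r2 <- D2 * config$k_r_unit
  if (config$sampler == "gaussian") {
    mom <- batch_protein_moments(pars, k_r1, k_r2)
    # bivariate normal draw of (p1, p2) with the per-cell LNA covariance
    sd1 <- sqrt(pmax(mom[, "var_p1"], 0))
    sd2 <- sqrt(pmax(mom[, "var_p2"], 0))
    rho <- ifelse(sd1 > 0 & sd2 > 0,
                  pmin(pmax(mom[, "cov_p12"] / (sd1 * sd2), -1), 1), 0)
    u1 <- rnorm(n)
    u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(n)
    p1 <- pmax(mom[, "p1"] + sd1 * u1, 0)
    p2 <- pmax(mom[, "p2"] + sd2 * u2, 0)
  } else {
    p1 <- numeric(n)
    p2 <- numeric(n)
    for (i in seq_len(n)) {
      ci <- pars
      ci$k_r1 <- k_r1[i]
      ci$k_r2 <- k_r2[i]
      st <- sample_stationary(ci, n_cells = 1,
                              seed = config$seed * 1000003L + i)
      p1[i] <- st$states[1, "p1"]
      p2[i] <- st$states[1, "p2"]
    }
  }
  # constitutive reporters: unregulated two-stage law (Gaussian approx.)
  y <- constitutive_protein_draw(k_r1, pars$g_r1, pars$k_p1, pars$g_p1)
  ko <- constitutive_protein_draw(k_r2, pars$g_r2, pars$k_p2, pars$g_p2)
  mol <- cbind(eYFP = y, mCherry = p1, mCerulean = p2, mKOrange = ko)
  intens <- vapply(CHANNELS, function(ch) {
    pmax(config$gains[[ch]] * mol[, ch] +
           rnorm(n, config$bg_mean[[ch]], config$bg_sd[[ch]]), 0)
  }, numeric(n))
  ctrl <- vapply(CHANNELS, function(ch) {
    pmax(rnorm(config$n_control, config$bg_mean[[ch]], config$bg_sd[[ch]]), 0)
  }, numeric(config$n_control))
  cells <- rbind(
    data.frame(replicate = rep_id, population = "transfected", intens),
    data.frame(replicate = rep_id, population = "control", ctrl))
  truth <- data.frame(replicate = rep_id,
                      D1 = c(D1, rep(0, config$n_control)),
                      D2 = c(D2, rep(0, config$n_control)),
                      mol_eYFP = c(y, rep(0, config$n_control)),
                      mol_mCherry = c(p1, rep(0, config$n_control)),
                      mol_mCerulean = c(p2, rep(0, config$n_control)),
                      mol_mKOrange = c(ko, rep(0, config$n_control)))
  list(cells = cells, truth = truth)
}

# mean and variance of the unregulated two-stage (mRNA + protein)
# birth-death process: mean = k_p k_r / (g_r g_p),
# var = mean * (1 + k_p / (g_r + g_p))
constitutive_protein_draw <- function(k_r, g_r, k_p, g_p) {
  m <- k_p * k_r / (g_r * g_p)
  v <- m * (1 + k_p / (g_r + g_p))
  pmax(rnorm(length(k_r), m, sqrt(v)), 0)
}

#' Write / read a cell table
#'
#' Lossless CSV round trip with a JSON sidecar (`<path>.json`) carrying
#' the generating configuration and effective model parameters, and a
#' ground-truth CSV (`<path base>_truth.csv`) when ground truth is
#' attached.  `read_cells()` validates the schema: the four channel
#' columns, `replicate`, and a `population` column containing both
#' `transfected` and `control` tags.
#'
#' @param cells a `cell_table`.
#' @param path CSV path.
#' @return `write_cells()` returns `path` invisibly; `read_cells()`
#'   returns the `cell_table` (with config/truth attributes when the
#'   sidecar/truth files are present).
#' @export
write_cells <- function(cells, path) {
  df <- as.data.frame(cells)
  write.csv(df, path, row.names = FALSE)
  cfg <- attr(cells, "config")
  pars <- attr(cells, "params")
  cfg_out <- if (!is.null(cfg)) {
    cfg_out <- unclass(cfg)
    # named channel vectors must serialise as JSON objects, not arrays
    for (f in c("gains", "bg_mean", "bg_sd")) {
      cfg_out[[f]] <- as.list(cfg_out[[f]])
    }
    cfg_out
  }
  sidecar <- list(config = cfg_out,
                  params = if (!is.null(pars)) unclass(pars))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  truth <- attr(cells, "truth")
  if (!is.null(truth)) {
    write.csv(truth, sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("cell table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "population", CHANNELS)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("cell table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(df[CHANNELS])) stop("NaN/NA intensities in cell table")
  if (!"control" %in% df$population) {
    stop("cell table has no 'control' population rows")
  }
  if (!"transfected" %in% df$population) {
    stop("cell table has no 'transfected' population rows")
  }
  sidecar_path <- paste0(path, ".json")
  cfg <- NULL
  pars <- NULL
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(side$config)) {
      cfg <- side$config
      for (f in c("gains", "bg_mean", "bg_sd")) {
        cfg[[f]] <- unlist(cfg[[f]])[CHANNELS]
      }
      cfg$n_cells <- as.integer(cfg$n_cells)
      cfg$n_replicates <- as.integer(cfg$n_replicates)
      cfg$n_control <- as.integer(cfg$n_control)
      cfg$seed <- as.integer(cfg$seed)
      cfg <- validate_population_config(cfg)
    }
    if (!is.null(side$params)) pars <- validate_params(side$params)
  }
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  truth <- if (file.exists(truth_path) && truth_path != path) {
    read.csv(truth_path, stringsAsFactors = FALSE)
  }
  structure(df, config = cfg, params = pars, truth = truth,
            class = c("cell_table", "data.frame"))
}
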