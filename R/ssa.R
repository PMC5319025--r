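param_vector <- function(params) {
  unlist(params[PARAM_FIELDS], use.names = FALSE)
}

default_initial_state <- function(params) {
  mf <- meanfield_steady_state(params)
  pmax(round(mf), 0)
}

# slowest relaxation rate of the linearised dynamics; burn-in default is
# 20 relaxation times
relaxation_time <- function(params, means = meanfield_steady_state(params)) {
  A <- drift_jacobian(params, means)
  1 / abs(max(Re(eigen(A, only.values = TRUE)$values)))
}

#' Exact stochastic simulation of the titration network
#'
#' Gillespie direct-method realisation of the chemical master equation
#' with the 14 reaction channels of the model (transcription, free
#' degradation, translation, protein degradation, and per-target
#' joint-degradation / miRNA-recycling interaction channels).
#' Reproducible given `seed`.
#'
#' @param params a `cerna_params` object.
#' @param t_max simulation horizon (time units of mRNA degradation).
#' @param seed integer RNG seed.
#' @param initial named integer state `(s, r1, r2, p1, p2)`; default is
#'   the rounded mean-field state.
#' @param store if `TRUE` (default) keep the full jump trajectory;
#'   otherwise only the final state and event audit.
#' @param max_events hard cap on stored events.
#' @return An object of class `cerna_trajectory`: list with `times`,
#'   `states` (matrix, one row per jump, including the initial state),
#'   `channel_counts` (named per-channel event counts), `final_state`,
#'   `stalled` flag (`TRUE` when total propensity hit zero), `params`,
#'   `seed`.
#' @examples
#' tr <- gillespie(cerna_params(), t_max = 10, seed = 1)
#' head(tr$states)
#' @export
gillespie <- function(params, t_max, seed = 1,
                      initial = default_initial_state(params),
                      store = TRUE, max_events = 5e6) {
  params <- validate_params(params)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0")
  initial <- initial[SPECIES]
  if (any(initial < 0) || any(initial != round(initial))) {
    stop("initial state must be non-negative integers")
  }
  set.seed(seed)
  res <- cpp_gillespie(param_vector(params), as.numeric(initial), t_max,
                       as.integer(max_events), store)
  names(res$final_state) <- SPECIES
  names(res$channel_counts) <- colnames(cerna_stoichiometry())
  if (store) colnames(res$states) <- SPECIES
  res$params <- params
  res$seed <- seed
  class(res) <- "cerna_trajectory"
  res
}

#' @export
print.cerna_trajectory <- function(x, ...) {
  cat("Gillespie trajectory:", x$n_events, "events to t =",
      format(x$t_end), if (x$stalled) "(stalled)" else "", "\n")
  cat("final state:", paste(SPECIES, x$final_state, sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' Time-averaged moments of a long stochastic run
#'
#' Streams a single long Gillespie run and returns time-weighted first
#' and second moments after a burn-in, without storing the trajectory.
#'
#' @inheritParams gillespie
#' @param t_burn burn-in time discarded before averaging.
#' @param t_avg averaging window length.
#' @return List with `mean` (named 5-vector), `cov` (5x5), `n_events`.
#' @export
ssa_time_average <- function(params, t_burn, t_avg, seed = 1,
                             initial = default_initial_state(params)) {
  params <- validate_params(params)
  set.seed(seed)
  res <- cpp_time_average(param_vector(params), as.numeric(initial[SPECIES]),
                          t_burn, t_avg)
  mu <- setNames(as.numeric(res$mean), SPECIES)
  C <- res$second_moment - outer(mu, mu)
  dimnames(C) <- list(SPECIES, SPECIES)
  list(mean = mu, cov = C, n_events = res$n_events)
}

#' Stationary sample of virtual cells
#'
#' Draws `n_cells` approximately independent states from the stationary
#' law of the network.  In `independent-replicas` mode (default) each
#' virtual cell is its own Gillespie run recorded once after the burn-in;
#' in `long-run-thinned` mode a single run is recorded every
#' `spacing` time units after the burn-in.  The burn-in defaults to 20
#' relaxation times of the linearised dynamics.  A stationarity check
#' compares the first- and second-half means of the draw sequence.
#'
#' @param params a `cerna_params` object.
#' @param n_cells number of stationary draws (>= 1).
#' @param seed integer RNG seed.
#' @param burn_in burn-in time; default `20 * relaxation_time(params)`.
#' @param mode `"independent-replicas"` or `"long-run-thinned"`.
#' @param spacing thinning interval for the long-run mode; default 2
#'   relaxation times.
#' @param initial initial state (default rounded mean-field).
#' @param protein `"stochastic"` (default): proteins are simulated as
#'   species of the master equation; `"deterministic"`: proteins are
#'   mapped from the sampled mRNAs as `p_i = k_pi * r_i / g_pi` (the
#'   fast-tracking limit, which exposes mRNA-level structure such as
#'   titration bimodality that a slow protein would average out).
#' @return Object of class `cerna_sample`: list with `states`
#'   (n_cells x 5 matrix), `mode`, `protein`, `burn_in`, `spacing`,
#'   `seed`, `stationary_ok` flag (with a warning when the check fails).
#' @export
sample_stationary <- function(params, n_cells, seed = 1,
                              burn_in = NULL,
                              mode = c("independent-replicas",
                                       "long-run-thinned"),
                              spacing = NULL,
                              initial = default_initial_state(params),
                              protein = c("stochastic", "deterministic")) {
  params <- validate_params(params)
  mode <- match.arg(mode)
  protein <- match.arg(protein)
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  tau <- relaxation_time(params)
  if (is.null(burn_in)) burn_in <- 20 * tau
  if (is.null(spacing)) spacing <- 2 * tau
  set.seed(seed)
  init <- matrix(as.numeric(initial[SPECIES]), nrow = 1)
  if (mode == "independent-replicas") {
    X <- cpp_sample_cells(param_vector(params), init, burn_in, n_cells,
                          1L, spacing)
  } else {
    X <- cpp_sample_cells(param_vector(params), init, burn_in, 1L,
                          n_cells, spacing)
  }
  colnames(X) <- SPECIES
  if (protein == "deterministic") {
    X[, "p1"] <- params$k_p1 * X[, "r1"] / params$g_p1
    X[, "p2"] <- params$k_p2 * X[, "r2"] / params$g_p2
  }
  stationary_ok <- stationarity_check(X)
  if (!stationary_ok) {
    warning("stationarity check failed: first/second half means differ ",
            "by more than 5 standard errors; increase burn_in")
  }
  structure(list(states = X, mode = mode, protein = protein,
                 burn_in = burn_in, spacing = spacing, seed = seed,
                 params = params, stationary_ok = stationary_ok),
            class = "cerna_sample")
}

# first-half vs second-half mean comparison on each species, in units of
# the (independence-assuming) standard error; lenient 5-SE rule so that
# thinned long runs with residual autocorrelation do not false-alarm
stationarity_check <- function(X) {
  n <- nrow(X)
  if (n < 20) return(TRUE)
  h1 <- X[seq_len(n %/% 2), , drop = FALSE]
  h2 <- X[(n %/% 2 + 1):n, , drop = FALSE]
  for (j in seq_len(ncol(X))) {
    se <- sqrt(var(h1[, j]) / nrow(h1) + var(h2[, j]) / nrow(h2))
    if (se == 0) next
    if (abs(mean(h1[, j]) - mean(h2[, j])) > 5 * se) return(FALSE)
  }
  TRUE
}

#' @export
print.cerna_sample <- function(x, ...) {
  cat("Stationary sample:", nrow(x$states), "cells (", x$mode, ")\n")
  print(round(colMeans(x$states), 3))
  invisible(x)
}

#' Bimodality test for a single-cell marginal distribution
#'
#' Primary statistic: Hartigan's dip (departure of the empirical CDF from
#' the closest unimodal CDF), with a Monte-Carlo p-value under the
#' uniform null (the least-favourable unimodal distribution).  Secondary
#' cross-check: mode count of a Gaussian KDE at the Silverman bandwidth.
#' The verdict is `bimodal` when the dip p-value is below `level` and the
#' KDE sees more than one mode.
#'
#' Copy-number samples are dithered before the dip is computed: tied
#' integer counts are spread by adding uniform noise at the data's
#' resolution (the smallest positive gap).  A unimodal probability mass
#' function maps under dithering to a unimodal piecewise-constant
#' density, while the raw empirical CDF of heavily tied data lies far
#' from every convex-then-concave CDF purely because of its atoms, which
#' would fail any sample from a discrete law regardless of modality.
#'
#' @param values numeric sample of one species (n >= 500 recommended; a
#'   constant sample returns a unimodal verdict with p = 1).
#' @param level significance level for the verdict (default 0.01).
#' @param n_boot Monte-Carlo replicates for the null distribution.
#' @param seed RNG seed for the Monte-Carlo null and the dithering.
#' @return List with `statistic` (dip of the dithered sample), `p_value`,
#'   `n_modes` (KDE), `bimodal` (verdict), `level`, `n`.
#' @examples
#' bimodality_test(c(rpois(400, 5), rpois(400, 60)))$bimodal
#' @export
bimodality_test <- function(values, level = 0.01, n_boot = 500, seed = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2 || length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, n_modes = 1L,
                bimodal = FALSE, level = level, n = n))
  }
  set.seed(seed)
  if (anyDuplicated(values)) {
    gaps <- diff(sort(unique(values)))
    h <- min(gaps[gaps > 0])
    values <- values + runif(n, 0, h)
  }
  d <- dip_statistic(values)
  null_dips <- vapply(seq_len(n_boot),
                      function(i) dip_statistic(runif(n)), numeric(1))
  p <- (1 + sum(null_dips >= d)) / (n_boot + 1)
  nm <- kde_mode_count(values)
  list(statistic = d, p_value = p, n_modes = nm,
       bimodal = (p < level) && nm >= 2L, level = level, n = n)
}

# mode count of a Gaussian KDE at the Silverman reference bandwidth;
# counts strict local maxima of the density estimate
kde_mode_count <- function(values, adjust = 1) {
  if (length(unique(values)) < 3) return(1L)
  bw <- bw.nrd0(values) * adjust
  if (bw <= 0) return(1L)
  de <- density(values, bw = bw, n = 512)
  y <- de$y
  sum(diff(sign(diff(y))) == -2) |> max(1L) |> as.integer()
}
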