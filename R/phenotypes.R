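#' Sweep the constitutive expression of target 1
#'
#' Evaluates the stationary statistics of the regulated target along a
#' grid of its constitutive protein level `p0`.  The sweep varies the
#' transcription rate `k_r1 = p0 * g_r1 * g_p1 / k_p1` with translation
#' and degradation fixed, mirroring a transient-transfection experiment
#' where per-cell plasmid load varies while protein chemistry does not.
#'
#' @param params_base a `cerna_params` object; its `k_r1` is overridden
#'   along the grid.
#' @param p0_grid strictly increasing positive grid of constitutive
#'   protein levels.
#' @param method `"moments"` (Gaussian approximation, default) or
#'   `"ssa"` (stochastic simulation of virtual cells).
#' @param n_cells cells per grid point for `method = "ssa"`.
#' @param seed RNG seed for `method = "ssa"`.
#' @return A `cerna_sweep` data.frame with columns `p0`, `k_r1`,
#'   `mean_p1`, `mean_p2`, `cv_p1`, `cv_p2`, `pearson_p1p2`, `ok`
#'   (per-point solver flag) and attributes `method`, `params_base`.
#' @examples
#' sw <- sweep_p0(cerna_params(), p0_grid = 10^seq(0.5, 3, length.out = 12))
#' sensitivity_threshold(sw$p0, sw$mean_p1)$p0_star
#' @export
sweep_p0 <- function(params_base, p0_grid, method = c("moments", "ssa"),
                     n_cells = 500, seed = 1) {
  params_base <- validate_params(params_base)
  method <- match.arg(method)
  if (any(p0_grid <= 0) || any(diff(p0_grid) <= 0)) {
    stop("p0_grid must be positive and strictly increasing")
  }
  rows <- lapply(seq_along(p0_grid), function(i) {
    p0 <- p0_grid[i]
    pars <- params_base
    pars$k_r1 <- p0 * pars$g_r1 * pars$g_p1 / pars$k_p1
    point_stats(pars, p0, method, n_cells, seed + i - 1L)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "params_base") <- params_base
  class(out) <- c("cerna_sweep", "data.frame")
  out
}

point_stats <- function(pars, p0, method, n_cells, seed) {
  res <- tryCatch({
    if (method == "moments") {
      m <- stationary_covariance(pars)
      data.frame(p0 = p0, k_r1 = pars$k_r1,
                 mean_p1 = m$mean[["p1"]], mean_p2 = m$mean[["p2"]],
                 cv_p1 = m$cv[["p1"]], cv_p2 = m$cv[["p2"]],
                 pearson_p1p2 = m$pearson["p1", "p2"], ok = TRUE)
    } else {
      s <- sample_stationary(pars, n_cells = n_cells, seed = seed)
      X <- s$states
      data.frame(p0 = p0, k_r1 = pars$k_r1,
                 mean_p1 = mean(X[, "p1"]), mean_p2 = mean(X[, "p2"]),
                 cv_p1 = sd(X[, "p1"]) / mean(X[, "p1"]),
                 cv_p2 = sd(X[, "p2"]) / mean(X[, "p2"]),
                 pearson_p1p2 = suppressWarnings(cor(X[, "p1"], X[, "p2"])),
                 ok = TRUE)
    }
  }, error = function(e) {
    data.frame(p0 = p0, k_r1 = pars$k_r1, mean_p1 = NA_real_,
               mean_p2 = NA_real_, cv_p1 = NA_real_, cv_p2 = NA_real_,
               pearson_p1p2 = NA_real_, ok = FALSE)
  })
  res
}

#' Fold-repression along a sweep
#'
#' `F(p0) = mean_p1_unregulated / mean_p1_regulated` per grid point: the
#' ratio of the target's mean in the absence of miRNA sites to its mean
#' in their presence.  `F` tends to 1 far above the threshold and peaks
#' near it.
#'
#' @param sweep_reg sweep of the regulated construct.
#' @param sweep_unreg sweep with interaction strength zero, on the same
#'   `p0` grid.
#' @return Data.frame with `p0`, `F`.
#' @export
fold_repression <- function(sweep_reg, sweep_unreg) {
  if (nrow(sweep_reg) != nrow(sweep_unreg) ||
      any(abs(sweep_reg$p0 - sweep_unreg$p0) >
          1e-9 * pmax(1, abs(sweep_reg$p0)))) {
    stop("sweeps must share an identical p0 grid")
  }
  data.frame(p0 = sweep_reg$p0,
             F = sweep_unreg$mean_p1 / sweep_reg$mean_p1)
}

#' Family of response curves while varying the competitor
#'
#' Recomputes the `p0` sweep of target 1 for each value of a competitor
#' variable: either the competitor transcription rate `k_r2` or the
#' competitor interaction strength `g_2`.  Also returns the
#' `g_2 -> Inf` limiting curve: in that limit every transcribed `r2`
#' molecule is captured by the miRNA, so miRNA consumption through
#' channel 2 tends to `alpha * k_r2`; the limit is the `k_r2 = 0` model
#' with `k_s` replaced by `k_s - alpha * k_r2` when `k_s > alpha * k_r2`
#' (excess miRNA; a threshold survives), and the unregulated line when
#' `k_s <= alpha * k_r2` (excess target; regulation of target 1
#' vanishes).
#'
#' @param params_base a `cerna_params` object.
#' @param variable `"k_r2"` or `"g_2"`.
#' @param grid values of the swept variable.
#' @param p0_grid constitutive-level grid passed to [sweep_p0()].
#' @param method statistics method, as in [sweep_p0()].
#' @return A list with `curves` (data.frame with the swept variable value
#'   attached to each sweep row), `limit` (the `g_2 -> Inf` limiting
#'   curve: data.frame `p0`, `mean_p1`), `unregulated` (the `g_1 = 0`
#'   line) and `excess_mirna` (logical: `k_s > alpha * k_r2` at the base
#'   parameters).
#' @export
sweep_competitor <- function(params_base, variable = c("k_r2", "g_2"),
                             grid, p0_grid, method = "moments") {
  params_base <- validate_params(params_base)
  variable <- match.arg(variable)
  curves <- do.call(rbind, lapply(grid, function(v) {
    pars <- params_base
    pars[[variable]] <- v
    sw <- sweep_p0(pars, p0_grid, method = method)
    sw <- as.data.frame(sw)
    sw[[variable]] <- v
    sw
  }))
  # g_2 -> Inf limiting curve (mean-field; competitor fully absorbing)
  lim_pars <- params_base
  lim_pars$k_r2 <- 0
  lim_pars$g_2 <- 0
  k_s_eff <- params_base$k_s - params_base$alpha * params_base$k_r2
  excess_mirna <- k_s_eff > 0
  limit <- if (excess_mirna) {
    lim_pars$k_s <- k_s_eff
    sw <- sweep_p0(lim_pars, p0_grid, method = "moments")
    data.frame(p0 = sw$p0, mean_p1 = sw$mean_p1)
  } else {
    data.frame(p0 = p0_grid, mean_p1 = p0_grid)  # unregulated line
  }
  unreg_pars <- params_base
  unreg_pars$g_1 <- 0
  unreg <- sweep_p0(unreg_pars, p0_grid, method = "moments")
  list(curves = curves, limit = limit,
       unregulated = data.frame(p0 = unreg$p0, mean_p1 = unreg$mean_p1),
       excess_mirna = excess_mirna, variable = variable, grid = grid)
}

#' Classify a parameter point of the crosstalk phase diagram
#'
#' Places one operating condition on the phase diagram whose axes are the
#' interaction-strength ratio `g_2 / g_1` and the mean number of target
#' mRNA molecules.  Crosstalk is the maximum over a `p0` sweep of the
#' target-target Pearson correlation, bucketed `low < 0.1 <= medium <
#' 0.3 <= high` (configurable conventions), and the bimodality flag comes
#' from a dip test on an SSA sample of `p1` at the threshold operating
#' point.
#'
#' @param params a `cerna_params` object (the operating condition).
#' @param p0_grid sweep grid used to scan for the correlation maximum and
#'   locate the threshold.
#' @param n_cells SSA cells for the bimodality test.
#' @param seed RNG seed.
#' @param buckets numeric length-2: crosstalk bucket boundaries.
#' @param level dip-test significance level.
#' @return A list (`phase_point`) with `g_ratio`, `mean_targets`
#'   (constitutive target mRNA count `r0_1 + r0_2` at the operating
#'   point), `crosstalk` (factor low/medium/high),
#'   `rho_max`, `bimodal`, `dip_p_value`, `threshold`.
#' @export
classify_phase <- function(params, p0_grid = NULL, n_cells = 2000, seed = 1,
                           buckets = c(0.1, 0.3), level = 0.01) {
  params <- validate_params(params)
  if (is.null(p0_grid)) {
    p0_ref <- constitutive_levels(params)$p0_1
    hi <- max(p0_ref * 10, 1000)
    p0_grid <- exp(seq(log(max(hi / 1e3, 1)), log(hi), length.out = 40))
  }
  sw <- sweep_p0(params, p0_grid, method = "moments")
  if (any(!sw$ok)) stop("sweep failed at ", sum(!sw$ok), " grid points")
  rho_max <- max(sw$pearson_p1p2, na.rm = TRUE)
  thr <- sensitivity_threshold(sw$p0, sw$mean_p1)
  # operate at the threshold point (or mid-grid when no threshold)
  idx <- if (thr$has_threshold) thr$index else ceiling(nrow(sw) / 2)
  pars_op <- params
  pars_op$k_r1 <- sw$k_r1[idx]
  cl_op <- constitutive_levels(pars_op)
  # deterministic (fast-tracking) protein map: the bimodality of the
  # regulated target is an mRNA-level titration phenomenon that a slow
  # protein reporter averages out; see the methods vignette
  samp <- sample_stationary(pars_op, n_cells = n_cells, seed = seed,
                            protein = "deterministic")
  bim <- bimodality_test(samp$states[, "p1"], level = level)
  crosstalk <- cut(rho_max, breaks = c(-Inf, buckets, Inf),
                   labels = c("low", "medium", "high"))
  list(g_ratio = if (params$g_1 > 0) params$g_2 / params$g_1 else Inf,
       # diagram ordinate: total transcribed target mRNA at the operating
       # point (the experimentally quantified per-cell molecule number)
       mean_targets = cl_op$r0_1 + cl_op$r0_2,
       crosstalk = crosstalk, rho_max = rho_max,
       bimodal = bim$bimodal, dip_p_value = bim$p_value,
       threshold = thr)
}

#' Map an MRE count to an effective interaction strength
#'
#' Default linear map `g = N * g_unit`; optionally a saturating map
#' `g = g_max * N / (N + K)` expressing that additional binding sites
#' raise the binding probability with diminishing returns.
#'
#' @param N number of miRNA regulatory elements (non-negative integer).
#' @param g_unit interaction strength per site (linear map).
#' @param saturating use the saturating map.
#' @param g_max,K saturating-map parameters.
#' @return Effective interaction strength.
#' @export
mre_interaction <- function(N, g_unit = 0.1, saturating = FALSE,
                            g_max = 4 * g_unit, K = 2) {
  if (any(N < 0)) stop("N must be non-negative")
  if (saturating) g_max * N / (N + K) else N * g_unit
}
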