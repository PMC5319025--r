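#' Drift Jacobian of the rate equations at a fixed point
#'
#' Jacobian `A` of the deterministic drift of `(s, r1, r2, p1, p2)`
#' evaluated at the supplied means.  At the stable mean-field fixed point
#' all eigenvalues of `A` have negative real part.
#'
#' @param params a `cerna_params` object.
#' @param means named vector as returned by [meanfield_steady_state()].
#' @return A 5x5 matrix with dimnames `(s, r1, r2, p1, p2)`.
#' @export
drift_jacobian <- function(params, means = meanfield_steady_state(params)) {
  params <- validate_params(params)
  s <- means[["s"]]; r1 <- means[["r1"]]; r2 <- means[["r2"]]
  A <- matrix(0, 5, 5, dimnames = list(SPECIES, SPECIES))
  A["s", "s"]  <- -params$g_s - params$alpha * (params$g_1 * r1 + params$g_2 * r2)
  A["s", "r1"] <- -params$alpha * params$g_1 * s
  A["s", "r2"] <- -params$alpha * params$g_2 * s
  A["r1", "s"]  <- -params$g_1 * r1
  A["r1", "r1"] <- -params$g_r1 - params$g_1 * s
  A["r2", "s"]  <- -params$g_2 * r2
  A["r2", "r2"] <- -params$g_r2 - params$g_2 * s
  A["p1", "r1"] <- params$k_p1
  A["p1", "p1"] <- -params$g_p1
  A["p2", "r2"] <- params$k_p2
  A["p2", "p2"] <- -params$g_p2
  A
}

# reaction channels: stoichiometry matrix (species x channel) and a
# propensity evaluator.  The alpha split realises the interaction as two
# channels: joint degradation (s and r_i both removed, rate alpha*g_i*s*r_i)
# and recycling (only r_i removed, rate (1-alpha)*g_i*s*r_i).
cerna_stoichiometry <- function() {
  ch <- c("birth_s", "birth_r1", "birth_r2",
          "death_s", "death_r1", "death_r2",
          "joint_1", "recycle_1", "joint_2", "recycle_2",
          "transl_1", "death_p1", "transl_2", "death_p2")
  V <- matrix(0L, nrow = 5, ncol = length(ch), dimnames = list(SPECIES, ch))
  V["s", "birth_s"] <- 1L;  V["s", "death_s"] <- -1L
  V["r1", "birth_r1"] <- 1L; V["r1", "death_r1"] <- -1L
  V["r2", "birth_r2"] <- 1L; V["r2", "death_r2"] <- -1L
  V["s", "joint_1"] <- -1L; V["r1", "joint_1"] <- -1L
  V["r1", "recycle_1"] <- -1L
  V["s", "joint_2"] <- -1L; V["r2", "joint_2"] <- -1L
  V["r2", "recycle_2"] <- -1L
  V["p1", "transl_1"] <- 1L; V["p1", "death_p1"] <- -1L
  V["p2", "transl_2"] <- 1L; V["p2", "death_p2"] <- -1L
  V
}

cerna_propensities <- function(params, x) {
  with(params, c(
    birth_s = k_s, birth_r1 = k_r1, birth_r2 = k_r2,
    death_s = g_s * x[["s"]],
    death_r1 = g_r1 * x[["r1"]], death_r2 = g_r2 * x[["r2"]],
    joint_1 = alpha * g_1 * x[["s"]] * x[["r1"]],
    recycle_1 = (1 - alpha) * g_1 * x[["s"]] * x[["r1"]],
    joint_2 = alpha * g_2 * x[["s"]] * x[["r2"]],
    recycle_2 = (1 - alpha) * g_2 * x[["s"]] * x[["r2"]],
    transl_1 = k_p1 * x[["r1"]], death_p1 = g_p1 * x[["p1"]],
    transl_2 = k_p2 * x[["r2"]], death_p2 = g_p2 * x[["p2"]]))
}

#' Diffusion matrix of the linear-noise approximation
#'
#' `B = sum_j a_j(means) v_j v_j^T` over the 14 reaction channels
#' (3 transcriptions, 3 free degradations, 2 translations, 2 protein
#' degradations, and joint-degradation / recycling channels for each
#' miRNA-target interaction).  Symmetric positive semidefinite.
#'
#' @inheritParams drift_jacobian
#' @return A 5x5 symmetric matrix.
#' @export
diffusion_matrix <- function(params, means = meanfield_steady_state(params)) {
  params <- validate_params(params)
  V <- cerna_stoichiometry()
  a <- cerna_propensities(params, means)
  B <- V %*% (a * t(V))
  dimnames(B) <- list(SPECIES, SPECIES)
  (B + t(B)) / 2
}

#' Gaussian (linear-noise) stationary moments
#'
#' Linear-noise approximation around the mean-field fixed point: the
#' stationary covariance `C` solves the fluctuation-dissipation (Lyapunov)
#' relation `A C + C A^T + B = 0`, with `A` the drift Jacobian and `B` the
#' diffusion matrix.  The 25-dimensional linear system is solved directly
#' via the Kronecker vectorisation.  From `C` the per-species coefficients
#' of variation `CV_x = sd(x)/mean(x)` and all pairwise Pearson
#' correlations are derived.
#'
#' @param params a `cerna_params` object.
#' @param means optionally precomputed mean-field state.
#' @return An object of class `species_moments`: list with `mean` (named
#'   5-vector), `cov` (5x5), `cv` (named 5-vector, `NA` for zero means),
#'   `pearson` (5x5 correlation matrix), `fano` (named 5-vector), and the
#'   Lyapunov `residual`.
#' @examples
#' m <- stationary_covariance(cerna_params())
#' m$cv[["p1"]]; m$pearson["p1", "p2"]
#' @export
stationary_covariance <- function(params, means = meanfield_steady_state(params)) {
  params <- validate_params(params)
  A <- drift_jacobian(params, means)
  B <- diffusion_matrix(params, means)
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("unstable fixed point: max Re(eigenvalue) = ", format(max(Re(ev))))
  }
  I5 <- diag(5)
  M <- kronecker(I5, A) + kronecker(A, I5)
  Cv <- solve(M, -as.vector(B))
  C <- matrix(Cv, 5, 5, dimnames = list(SPECIES, SPECIES))
  C <- (C + t(C)) / 2
  resid <- norm(A %*% C + C %*% t(A) + B, "F")
  if (resid > 1e-8 * max(norm(B, "F"), 1e-300)) {
    stop("Lyapunov solve failed: residual ", format(resid))
  }
  sdv <- sqrt(pmax(diag(C), 0))
  mu <- means[SPECIES]
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  denom <- outer(sdv, sdv)
  P <- ifelse(denom > 0, C / denom, 0)
  diag(P) <- 1
  fano <- ifelse(mu > 0, diag(C) / mu, NA_real_)
  structure(list(mean = mu, cov = C, cv = setNames(cv, SPECIES),
                 pearson = P, fano = setNames(fano, SPECIES),
                 residual = resid, relaxation_time = 1 / abs(max(Re(ev)))),
            class = "species_moments")
}

#' @export
print.species_moments <- function(x, ...) {
  cat("Gaussian (linear-noise) stationary moments\n")
  tab <- rbind(mean = x$mean, cv = x$cv, fano = x$fano)
  print(round(tab, 4))
  cat("pearson(p1,p2) =", round(x$pearson["p1", "p2"], 4),
      "  pearson(s,r1) =", round(x$pearson["s", "r1"], 4), "\n")
  invisible(x)
}

#' Compare Gaussian-approximation moments with stochastic simulation
#'
#' Estimates means, CVs and the (p1, p2) / (s, r1) Pearson correlations
#' from a stationary SSA sample and tabulates them against the
#' linear-noise predictions with Monte-Carlo standard errors (batch
#' means over `n_batches` groups of cells) and z-scores.  When the SSA
#' marginal of the regulated target (`r1` or `p1`) is bimodal (Hartigan
#' dip test) the table carries a `gaussian_valid = FALSE` flag: the
#' Gaussian summary is then only a smooth trend predictor.
#'
#' @param params a `cerna_params` object.
#' @param n_cells number of virtual cells to simulate (default 1000).
#' @param seed RNG seed.
#' @param n_batches batch count for Monte-Carlo standard errors.
#' @return A list with `table` (data.frame: statistic, moments, ssa, se,
#'   z), `gaussian_valid`, and the dip p-value of the `p1` marginal.
#' @export
moments_vs_ssa_report <- function(params, n_cells = 1000, seed = 1,
                                  n_batches = 20) {
  params <- validate_params(params)
  mom <- stationary_covariance(params)
  samp <- sample_stationary(params, n_cells = n_cells, seed = seed)
  X <- samp$states
  if (nrow(X) < n_batches * 5) {
    stop("insufficient cells for ", n_batches, " batches")
  }
  batch <- rep_len(seq_len(n_batches), nrow(X))
  stat_fns <- list(
    mean_s  = function(d) mean(d[, "s"]),
    mean_r1 = function(d) mean(d[, "r1"]),
    mean_p1 = function(d) mean(d[, "p1"]),
    mean_p2 = function(d) mean(d[, "p2"]),
    cv_p1   = function(d) sd(d[, "p1"]) / mean(d[, "p1"]),
    cv_p2   = function(d) sd(d[, "p2"]) / mean(d[, "p2"]),
    rho_p1p2 = function(d) suppressWarnings(cor(d[, "p1"], d[, "p2"])),
    rho_sr1  = function(d) suppressWarnings(cor(d[, "s"], d[, "r1"]))
  )
  pred <- c(mean_s = mom$mean[["s"]], mean_r1 = mom$mean[["r1"]],
            mean_p1 = mom$mean[["p1"]], mean_p2 = mom$mean[["p2"]],
            cv_p1 = mom$cv[["p1"]], cv_p2 = mom$cv[["p2"]],
            rho_p1p2 = mom$pearson["p1", "p2"],
            rho_sr1 = mom$pearson["s", "r1"])
  rows <- lapply(names(stat_fns), function(nm) {
    fn <- stat_fns[[nm]]
    full <- fn(X)
    per_batch <- vapply(split.data.frame(X, batch), fn, numeric(1))
    per_batch <- per_batch[is.finite(per_batch)]
    se <- sd(per_batch) / sqrt(length(per_batch))
    low_info <- length(per_batch) < n_batches / 2 || !is.finite(se) || se == 0
    data.frame(statistic = nm, moments = pred[[nm]], ssa = full,
               se = se, z = if (low_info) NA_real_ else (full - pred[[nm]]) / se,
               insufficient = low_info)
  })
  tab <- do.call(rbind, rows)
  dip_r1 <- bimodality_test(X[, "r1"])
  dip_p1 <- bimodality_test(X[, "p1"])
  list(table = tab,
       gaussian_valid = !(dip_r1$bimodal || dip_p1$bimodal),
       dip_p_value = min(dip_r1$p_value, dip_p1$p_value))
}
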