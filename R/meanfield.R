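#' Deterministic (mean-field) stationary state
#'
#' Solves the stationary rate equations of the titration network:
#' \deqn{k_s = g_s s + \alpha s (g_1 r_1 + g_2 r_2)}
#' \deqn{k_{ri} = g_{ri} r_i + g_i s r_i, \quad p_i = k_{pi} r_i / g_{pi}.}
#' Substituting \eqn{r_i = k_{ri} / (g_{ri} + g_i s)} into the miRNA
#' balance leaves a single scalar equation in the free-miRNA level `s`
#' whose left-hand side is strictly increasing, so the non-negative root
#' is unique and bracketed by \eqn{[0, k_s / g_s]}.  A safeguarded
#' Newton/bisection iteration drives the relative residual below `tol`.
#'
#' @param params a `cerna_params` object.
#' @param tol relative residual tolerance (default `1e-12`, contract
#'   guarantees `1e-10`).
#' @return A named numeric vector with components `s`, `r1`, `r2`, `p1`,
#'   `p2` (stationary means, real-valued).
#' @examples
#' meanfield_steady_state(cerna_params(g_1 = 0, g_2 = 0))
#' @export
meanfield_steady_state <- function(params, tol = 1e-12) {
  params <- validate_params(params)
  s <- meanfield_s(params$k_s, params$k_r1, params$k_r2,
                   params$g_s, params$g_r1, params$g_r2,
                   params$g_1, params$g_2, params$alpha, tol = tol)
  r1 <- params$k_r1 / (params$g_r1 + params$g_1 * s)
  r2 <- params$k_r2 / (params$g_r2 + params$g_2 * s)
  p1 <- params$k_p1 * r1 / params$g_p1
  p2 <- params$k_p2 * r2 / params$g_p2
  out <- c(s = s, r1 = r1, r2 = r2, p1 = p1, p2 = p2)
  # contract check: relative residual of the full stationary system
  res <- meanfield_residual(params, out)
  if (res > 1e-10) {
    stop("mean-field solver failed to reach residual tolerance (residual = ",
         format(res), ")")
  }
  out
}

# vectorised over k_r1/k_r2 (used by sweeps and the population generator):
# solves k_s = g_s*s + alpha*s*(g_1*k_r1/(g_r1+g_1*s) + g_2*k_r2/(g_r2+g_2*s))
meanfield_s <- function(k_s, k_r1, k_r2, g_s, g_r1, g_r2, g_1, g_2, alpha,
                        tol = 1e-12) {
  n <- max(length(k_s), length(k_r1), length(k_r2))
  k_s <- rep_len(k_s, n); k_r1 <- rep_len(k_r1, n); k_r2 <- rep_len(k_r2, n)
  f <- function(s) {
    g_s * s + alpha * s * (g_1 * k_r1 / (g_r1 + g_1 * s) +
                           g_2 * k_r2 / (g_r2 + g_2 * s)) - k_s
  }
  fp <- function(s) {
    # d/ds of s*k*g/(g_r+g*s) = k*g*g_r/(g_r+g*s)^2
    g_s + alpha * (g_1 * k_r1 * g_r1 / (g_r1 + g_1 * s)^2 +
                   g_2 * k_r2 * g_r2 / (g_r2 + g_2 * s)^2)
  }
  lo <- rep(0, n)
  hi <- k_s / g_s          # f(hi) >= 0 since the titration term is >= 0
  s <- hi * 0.5
  for (iter in 1:200) {
    fv <- f(s)
    lo <- ifelse(fv < 0, s, lo)
    hi <- ifelse(fv > 0, s, hi)
    step <- fv / fp(s)
    s_new <- s - step
    bad <- !is.finite(s_new) | s_new <= lo | s_new >= hi
    s_new[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(s_new - s) <= tol * (1 + abs(s_new))
    s <- s_new
    if (all(done) && iter > 3) break
  }
  s[k_s == 0] <- 0
  s
}

# max relative residual of the 5 stationary conditions
meanfield_residual <- function(params, x) {
  with(params, {
    r_s  <- k_s - g_s * x[["s"]] -
      alpha * x[["s"]] * (g_1 * x[["r1"]] + g_2 * x[["r2"]])
    r_r1 <- k_r1 - g_r1 * x[["r1"]] - g_1 * x[["s"]] * x[["r1"]]
    r_r2 <- k_r2 - g_r2 * x[["r2"]] - g_2 * x[["s"]] * x[["r2"]]
    r_p1 <- k_p1 * x[["r1"]] - g_p1 * x[["p1"]]
    r_p2 <- k_p2 * x[["r2"]] - g_p2 * x[["p2"]]
    scale <- max(1, k_s, k_r1, k_r2)
    max(abs(c(r_s, r_r1, r_r2, r_p1, r_p2))) / scale
  })
}

#' Locate the expression threshold on a response curve
#'
#' The titration threshold is operationalised as the point of maximal
#' local logarithmic slope `d log(mean_p1) / d log(p0)` along a sweep of
#' the constitutive expression `p0` (central differences on the log-log
#' curve).  An unregulated (linear) response has slope identically 1; a
#' curve whose maximal slope does not exceed `1 + tol` is flagged as
#' having no threshold.
#'
#' @param p0 strictly increasing positive grid of constitutive levels.
#' @param mean_p1 positive regulated means on the same grid.
#' @param tol slope excess over 1 below which the threshold is declared
#'   absent (default 0.05).
#' @return A list with `p0_star` (threshold location, `NA` if absent),
#'   `index` (grid index), `max_slope`, `slopes` (per-grid-point local
#'   log-log slope, `NA` at the two ends) and `has_threshold`.
#' @export
sensitivity_threshold <- function(p0, mean_p1, tol = 0.05) {
  if (length(p0) < 3) stop("need at least 3 grid points")
  if (length(mean_p1) != length(p0)) stop("p0 and mean_p1 lengths differ")
  if (any(diff(p0) <= 0)) stop("p0 grid must be strictly increasing")
  if (any(p0 <= 0) || any(mean_p1 <= 0)) {
    stop("p0 and mean_p1 must be positive for log-log slopes")
  }
  lx <- log(p0); ly <- log(mean_p1)
  n <- length(p0)
  slopes <- rep(NA_real_, n)
  slopes[2:(n - 1)] <- (ly[3:n] - ly[1:(n - 2)]) / (lx[3:n] - lx[1:(n - 2)])
  idx <- which.max(slopes)
  max_slope <- slopes[idx]
  has_threshold <- isTRUE(max_slope > 1 + tol)
  list(p0_star = if (has_threshold) p0[idx] else NA_real_,
       index = if (has_threshold) idx else NA_integer_,
       max_slope = max_slope,
       slopes = slopes,
       has_threshold = has_threshold)
}
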