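test_that("mean-field state is exact in the decoupled limits", {
  p <- cerna_params(g_1 = 0, g_2 = 0)
  mf <- meanfield_steady_state(p)
  expect_equal(mf[["r1"]], p$k_r1 / p$g_r1)
  expect_equal(mf[["s"]], p$k_s / p$g_s)
  expect_equal(mf[["p1"]], constitutive_levels(p)$p0_1)
  # alpha = 0: miRNA balance closes on its own (pure catalytic degradation)
  p <- cerna_params(alpha = 0, g_1 = 1.5, g_2 = 0.7)
  mf <- meanfield_steady_state(p)
  expect_equal(mf[["s"]], p$k_s / p$g_s, tolerance = 1e-10)
  expect_lt(mf[["r1"]], p$k_r1 / p$g_r1)  # targets still repressed
})

test_that("mean-field solution is non-negative with tiny residual across random parameters", {
  set.seed(101)
  for (i in 1:50) {
    p <- cerna_params(k_s = runif(1, 0, 50), k_r1 = runif(1, 0, 50),
                      k_r2 = runif(1, 0, 50), g_s = runif(1, 0.05, 2),
                      g_r1 = runif(1, 0.2, 2), g_r2 = runif(1, 0.2, 2),
                      g_1 = runif(1, 0, 3), g_2 = runif(1, 0, 3),
                      alpha = runif(1), g_p1 = runif(1, 0.05, 1),
                      g_p2 = runif(1, 0.05, 1))
    mf <- meanfield_steady_state(p)
    expect_true(all(mf >= 0))
    expect_lt(cernasim:::meanfield_residual(p, mf), 1e-10)
  }
})

test_that("mean-field means match a long Gillespie run (independent oracle)", {
  p <- cerna_params(k_s = 10, k_r1 = 5, k_r2 = 5, g_s = 1, g_r1 = 1,
                    g_r2 = 1, g_1 = 0.05, g_2 = 0.05, alpha = 0.5,
                    k_p1 = 1, k_p2 = 1, g_p1 = 0.1, g_p2 = 0.1)
  mf <- meanfield_steady_state(p)
  ta <- ssa_time_average(p, t_burn = 300, t_avg = 30000, seed = 11)
  expect_gt(ta$n_events, 1e6)
  # effective MC standard error: sd scaled by the number of relaxation
  # windows in the averaging time (autocorrelated time average)
  tau <- cernasim:::relaxation_time(p)
  n_eff <- 30000 / (2 * tau)
  for (sp in c("s", "r1", "r2", "p1", "p2")) {
    se <- sqrt(ta$cov[sp, sp] / n_eff)
    expect_lt(abs(ta$mean[[sp]] - mf[[sp]]), 3 * se)
  }
})

test_that("mean-field response is monotone in each rate and swap-symmetric", {
  base <- params_ref()
  p1_of <- function(p) meanfield_steady_state(p)[["p1"]]
  ref <- p1_of(base)
  up <- function(field, value) {
    p <- base
    p[[field]] <- value
    p1_of(p)
  }
  expect_lt(up("g_1", base$g_1 * 2), ref)    # stronger binding: lower p1
  expect_lt(up("k_s", base$k_s * 2), ref)    # more miRNA: lower p1
  expect_gt(up("g_2", base$g_2 * 10), ref)   # stronger competitor: higher p1
  expect_gt(up("k_r2", base$k_r2 * 4), ref)  # more competitor: higher p1
  expect_gt(up("k_r1", base$k_r1 * 2), ref)  # more target: higher p1
  # swap symmetry: mirrored parameters give mirrored outputs exactly
  mf <- meanfield_steady_state(base)
  mfs <- meanfield_steady_state(swap_targets(base))
  expect_equal(mfs[["r1"]], mf[["r2"]])
  expect_equal(mfs[["p2"]], mf[["p1"]])
  expect_equal(mfs[["s"]], mf[["s"]])
})

test_that("large-g_2 limit splits into excess-target and excess-miRNA regimes", {
  # excess target: alpha*k_r2 > k_s; p1 approaches the unregulated level
  p <- params_ref(k_r2 = 60, alpha = 0.5, k_s = 20)
  p$g_2 <- 1e6
  mf <- meanfield_steady_state(p)
  expect_equal(mf[["p1"]], constitutive_levels(p)$p0_1, tolerance = 1e-3)
  # excess miRNA: alpha*k_r2 < k_s; repression persists at high g_2
  p <- params_ref(k_r2 = 10, alpha = 0.5, k_s = 20)
  p$g_2 <- 1e6
  mf <- meanfield_steady_state(p)
  expect_lt(mf[["p1"]], 0.7 * constitutive_levels(p)$p0_1)
})

test_that("threshold estimator flags linear responses and finds titration knees", {
  p0 <- exp(seq(log(1), log(100), length.out = 20))
  thr <- sensitivity_threshold(p0, 3.7 * p0)
  expect_false(thr$has_threshold)
  expect_equal(thr$max_slope, 1, tolerance = 1e-8)
  expect_error(sensitivity_threshold(p0[1:2], p0[1:2]), "3 grid points")
  expect_error(sensitivity_threshold(p0, -p0), "positive")
  expect_error(sensitivity_threshold(rev(p0), p0), "increasing")
  # strong-binding sweep: knee near the stoichiometric balance point where
  # target-1 transcription matches the residual miRNA consumption capacity
  base <- params_ref()
  grid <- p0_grid_ref(60)
  sw <- sweep_p0(base, grid)
  thr <- sensitivity_threshold(sw$p0, sw$mean_p1)
  expect_true(thr$has_threshold)
  expect_gt(thr$max_slope, 1)
  # mean-field balance: k_r1* ~ k_s/alpha - k_r2 (mRNA units), p0* in
  # protein units via k_p1/(g_r1*g_p1); dense-oracle agreement to 1 step
  k_r1_star <- base$k_s / base$alpha - base$k_r2
  p0_star_pred <- k_r1_star * base$k_p1 / (base$g_r1 * base$g_p1)
  step <- grid[2] / grid[1]
  expect_lt(abs(log(thr$p0_star / p0_star_pred)), 2 * log(step))
})
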