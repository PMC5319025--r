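test_that("population config validates its fields", {
  expect_s3_class(population_config(n_cells = 10), "population_config")
  expect_error(population_config(n_cells = 0), "n_cells")
  expect_error(population_config(N_cherry = 3), "MRE")
  expect_error(population_config(premir_boost = 0.5), "premir_boost")
  expect_error(population_config(copy_cor = 1.5), "copy_cor")
  expect_error(population_config(gains = c(eYFP = -1, mCherry = 1,
                                           mCerulean = 1, mKOrange = 1)),
               "gains")
})

test_that("unregulated reporters are linearly related through the gain ratio", {
  cfg <- population_config(n_cells = 4000, n_replicates = 1,
                           n_control = 2000, N_cherry = 0, N_cerulean = 0,
                           gains = c(eYFP = 2, mCherry = 4,
                                     mCerulean = 2, mKOrange = 2),
                           seed = 61)
  cells <- generate_population(cfg, cerna_params(g_s = 0.2, k_s = 20))
  g <- gate_positive(background_correct(cells))
  hi <- g[g$eYFP > quantile(g$eYFP, 0.5), ]  # away from the background floor
  fit <- lm(mCherry ~ eYFP, data = hi)
  # mCherry mean = (gain_cherry/gain_yfp) * eYFP mean, through the origin
  expect_equal(unname(coef(fit)[2]), 4 / 2, tolerance = 0.1)
  expect_lt(abs(coef(fit)[1]), 0.05 * mean(hi$mCherry))
})

test_that("regulated populations carry the generator's threshold", {
  cfg <- population_config(n_cells = 8000, n_replicates = 2,
                           n_control = 3000, N_cherry = 4, N_cerulean = 0,
                           seed = 62)
  pb <- cerna_params(k_s = 20, k_r2 = 5, g_s = 0.2, alpha = 0.5)
  cells <- generate_population(cfg, pb)
  gated <- gate_positive(background_correct(cells))
  bs <- bin_and_summarize(gated, n_bins = 30, min_cells = 50)
  thr <- binned_threshold(bs)
  expect_true(thr$has_threshold)
  # ground-truth oracle: mean-field threshold at matched parameters,
  # mapped to corrected eYFP units (gain * p0 - 2 * background sd)
  pars <- attr(cells, "params")
  sw <- sweep_p0(pars, exp(seq(log(5), log(8000), length.out = 60)))
  p0_star <- sensitivity_threshold(sw$p0, sw$mean_p1)$p0_star
  eyfp_star <- cfg$gains[["eYFP"]] * p0_star - 2 * cfg$bg_sd[["eYFP"]]
  true_bin <- findInterval(eyfp_star, bs$breaks)
  # small population here: allow 2 bins (the full-scale recovery bound of
  # one bin is asserted in the acceptance suite)
  expect_lte(abs(thr$bin - true_bin), 2)
})

test_that("pre-miR boost shifts the recovered threshold to higher eYFP", {
  pb <- cerna_params(k_s = 20, k_r2 = 5, g_s = 0.2, alpha = 0.5)
  thr_mid <- function(boost, seed) {
    cfg <- population_config(n_cells = 8000, n_replicates = 2,
                             n_control = 3000, N_cherry = 4,
                             N_cerulean = 0, premir_boost = boost,
                             seed = seed)
    cells <- generate_population(cfg, pb)
    gated <- gate_positive(background_correct(cells))
    bs <- bin_and_summarize(gated, n_bins = 30, min_cells = 50)
    binned_threshold(bs)$mid
  }
  expect_gt(thr_mid(2, 63), thr_mid(1, 63))
})

test_that("cell tables round-trip losslessly with their sidecar", {
  cfg <- population_config(n_cells = 300, n_replicates = 2,
                           n_control = 150, seed = 64)
  cells <- generate_population(cfg, cerna_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cells(cells, path)
  back <- read_cells(path)
  expect_equal(as.data.frame(back), as.data.frame(cells), tolerance = 1e-12)
  expect_equal(attr(back, "config")$seed, cfg$seed)
  expect_equal(validate_params(attr(back, "params")),
               attr(cells, "params"))
  expect_equal(nrow(attr(back, "truth")), nrow(cells))
  # regenerating from the sidecar config reproduces the table exactly
  regen <- generate_population(attr(back, "config"), cerna_params())
  expect_equal(as.data.frame(regen), as.data.frame(cells))
  # schema violations are named
  df <- read.csv(path)
  df2 <- df[df$population != "control", ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE)
  expect_error(read_cells(path2), "control")
  df3 <- df[, setdiff(names(df), "mKOrange")]
  write.csv(df3, path2, row.names = FALSE)
  expect_error(read_cells(path2), "mKOrange")
  expect_error(read_cells("/nonexistent.csv"), "not found")
})

test_that("the Gaussian sampler tracks the exact SSA sampler", {
  pb <- cerna_params(k_s = 20, k_r2 = 5, g_s = 0.2, alpha = 0.5)
  mk <- function(sampler, seed) {
    cfg <- population_config(n_cells = 250, n_replicates = 1,
                             n_control = 100, N_cherry = 4, N_cerulean = 1,
                             copy_sdlog = 0.3, sampler = sampler,
                             seed = seed)
    generate_population(cfg, pb)
  }
  ga <- mk("gaussian", 65)
  ss <- mk("ssa", 65)
  tg <- attr(ga, "truth")
  ts <- attr(ss, "truth")
  tg <- tg[tg$D1 > 0, ]
  ts <- ts[ts$D1 > 0, ]
  # same molecule scale and dispersion from both samplers
  expect_equal(mean(tg$mol_mCherry), mean(ts$mol_mCherry), tolerance = 0.25)
  expect_equal(sd(log1p(tg$mol_mCerulean)), sd(log1p(ts$mol_mCerulean)),
               tolerance = 0.3)
})
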