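# small deterministic cell table builder: two replicates whose controls
# differ, transfected intensities set explicitly
toy_cells <- function() {
  ctrl1 <- data.frame(replicate = 1, population = "control",
                      eYFP = rep(c(90, 110), 10), mCherry = rep(c(90, 110), 10),
                      mCerulean = rep(c(90, 110), 10),
                      mKOrange = rep(c(90, 110), 10))
  ctrl2 <- ctrl1
  ctrl2$replicate <- 2
  ctrl2[3:6] <- ctrl2[3:6] + 100   # shifted control: higher cutoff
  tr <- expand.grid(replicate = 1:2, i = 1:20)
  tr <- data.frame(replicate = tr$replicate, population = "transfected",
                   eYFP = 150 + 10 * tr$i, mCherry = 150 + 10 * tr$i,
                   mCerulean = 150 + 5 * tr$i, mKOrange = 300)
  structure(rbind(ctrl1, ctrl2, tr),
            class = c("cell_table", "data.frame"))
}

test_that("background correction applies the mean + 2 SD rule per replicate", {
  cells <- toy_cells()
  cc <- background_correct(cells)
  cuts <- attr(cc, "cutoffs")
  # control mean 100, sd ~10.26 (sample sd of alternating 90/110)
  sd20 <- sd(rep(c(90, 110), 10))
  expect_equal(cuts$eYFP[1], 100 + 2 * sd20)
  expect_equal(cuts$eYFP[2], 200 + 2 * sd20)   # per-replicate cutoff
  r1 <- cc[cc$replicate == 1, ]
  expect_equal(r1$eYFP, (150 + 10 * (1:20)) - (100 + 2 * sd20))
  # an intensity below the cutoff stays negative (retained for gating)
  cells2 <- cells
  cells2$eYFP[cells2$population == "transfected"][1] <- 50
  cc2 <- background_correct(cells2)
  expect_lt(cc2$eYFP[1], 0)
  expect_error(background_correct(cells[cells$population != "control", ]),
               "control")
})

test_that("gating keeps exactly the double-positive cells", {
  cc <- background_correct(toy_cells())
  cc$mKOrange[1:5] <- -1
  g <- gate_positive(cc)
  expect_equal(nrow(g), sum(cc$eYFP > 0 & cc$mKOrange > 0))
  g_y <- gate_positive(cc, channels = "eYFP")   # relaxed rule: superset
  expect_gte(nrow(g_y), nrow(g))
  cc$eYFP <- -abs(cc$eYFP)
  expect_error(gate_positive(cc), "removed all")
  expect_error(gate_positive(toy_cells()), "corrected")
})

test_that("binning conserves cells and masks thin or degenerate bins", {
  set.seed(71)
  n <- 6000
  mk_rep <- function(r) {
    y <- runif(n, 0, 1000)
    data.frame(replicate = r, population = "transfected",
               eYFP = y, mCherry = 2 * y + rnorm(n, 0, 20),
               mCerulean = 500 + rnorm(n, 0, 30), mKOrange = 400)
  }
  cells <- structure(rbind(mk_rep(1), mk_rep(2)), corrected = TRUE,
                     class = c("cell_table", "data.frame"))
  bs <- bin_and_summarize(cells, n_bins = 10, min_cells = 50)
  expect_equal(sum(bs$per_replicate$n), 2 * n - bs$n_out_of_range)
  expect_true(all(diff(bs$breaks) - diff(bs$breaks)[1] < 1e-9))  # equal width
  agg <- bs$aggregated
  expect_equal(agg$n_replicates[!agg$masked] >= 2,
               rep(TRUE, sum(!agg$masked)))
  # linear mCherry = 2 * eYFP: per-bin mean curve linear through origin
  fit <- lm(mean_mCherry ~ mean_eYFP, data = agg[!agg$masked, ])
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.02)
  # replicate-SD error bars are far smaller than within-bin dispersion:
  # the SD over replicate means vs the cell-level SD (factor ~sqrt(N_cib))
  b <- which(!agg$masked)[3]
  within_sd <- agg$mean_mCherry[b] * agg$cv_mCherry[b]
  expect_lt(agg$sd_mean_mCherry[b], within_sd / 5)
  expect_error(bin_and_summarize(cells, n_bins = 10, min_cells = 1e7),
               "populated bins")
})

test_that("identical datasets give F = 1 with zero jackknife error", {
  set.seed(72)
  n <- 3000
  mk <- function(r) data.frame(replicate = r, population = "transfected",
                               eYFP = runif(n, 0, 900),
                               mCherry = runif(n, 100, 200),
                               mCerulean = runif(n, 100, 200),
                               mKOrange = 300)
  cells <- structure(rbind(mk(1), mk(2), mk(3)), corrected = TRUE,
                     class = c("cell_table", "data.frame"))
  bs <- bin_and_summarize(cells, n_bins = 8, min_cells = 50)
  fr <- empirical_fold_repression(bs, bs)
  expect_equal(fr$F[!fr$masked], rep(1, sum(!fr$masked)))
  expect_equal(fr$se_jackknife[!fr$masked],
               rep(0, sum(!fr$masked)), tolerance = 1e-12)
  bs2 <- bin_and_summarize(cells, n_bins = 10, min_cells = 50)
  expect_error(empirical_fold_repression(bs, bs2), "edges")
})

test_that("jackknife error matches the hand-computed three-replicate case", {
  # one bin, three replicates with regulated means 10, 10, 20 and
  # unregulated means 40, 40, 40: leave-one-out F values are
  # 40/15, 40/15, 40/10, and the jackknife SE is
  # sqrt(2/3 * sum((F_i - mean(F_i))^2))
  mk <- function(r, m) data.frame(replicate = r, population = "transfected",
                                  eYFP = seq(10, 90, length.out = 200),
                                  mCherry = m, mCerulean = 1,
                                  mKOrange = 1)
  reg <- structure(rbind(mk(1, 10), mk(2, 10), mk(3, 20)), corrected = TRUE,
                   class = c("cell_table", "data.frame"))
  unreg <- structure(rbind(mk(1, 40), mk(2, 40), mk(3, 40)), corrected = TRUE,
                     class = c("cell_table", "data.frame"))
  breaks <- c(0, 33, 66, 100)
  bs_r <- bin_and_summarize(reg, breaks = breaks, min_cells = 10)
  bs_u <- bin_and_summarize(unreg, breaks = breaks, min_cells = 10)
  fr <- empirical_fold_repression(bs_r, bs_u)
  Fi <- c(40 / 15, 40 / 15, 40 / 10)
  expect_equal(fr$F[1], 40 / mean(c(10, 10, 20)))
  expect_equal(fr$se_jackknife[1],
               sqrt(2 / 3 * sum((Fi - mean(Fi))^2)))
})

test_that("pearson ratio is 1 for identical data and flags weak references", {
  set.seed(73)
  n <- 4000
  mk <- function(r) {
    y <- runif(n, 0, 900)
    z <- rnorm(n)
    data.frame(replicate = r, population = "transfected", eYFP = y,
               mCherry = 100 + 30 * z + rnorm(n, 0, 60),
               mCerulean = 100 + 30 * z + rnorm(n, 0, 60), mKOrange = 1)
  }
  cells <- structure(rbind(mk(1), mk(2), mk(3)), corrected = TRUE,
                     class = c("cell_table", "data.frame"))
  breaks <- seq(0, 900, by = 100)
  pr <- pearson_ratio(cells, cells, breaks, threshold_bin = 5)
  expect_equal(pr$ratio, rep(1, 3))
  expect_equal(pr$error, rep(0, 3), tolerance = 1e-12)
  expect_false(any(pr$unstable))  # shared-noise correlation ~0.2 > floor
  expect_true(all(c("below", "around", "above") %in% pr$region))
  # weak reference correlation: unstable flag fires at the 0.1 floor
  weak <- mk(1)
  weak$mCherry <- rnorm(n, 100, 60)  # decorrelated
  weak <- structure(rbind(weak,
                          within(mk(2), mCherry <- rnorm(n, 100, 60)),
                          within(mk(3), mCherry <- rnorm(n, 100, 60))),
                    corrected = TRUE,
                    class = c("cell_table", "data.frame"))
  pr_w <- pearson_ratio(cells, weak, breaks, threshold_bin = 5)
  expect_true(all(pr_w$unstable))
})

test_that("ratio p-values follow the normal null", {
  expect_equal(ratio_pvalue(1, 1, 0.2), 0.5)
  expect_equal(ratio_pvalue(1.6, 1, 0.2), pnorm(3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(ratio_pvalue(1.6, 1, 0.2), 5), 0.00135)
  expect_equal(ratio_pvalue(0.4, 1, 0.2, sided = "less"),
               pnorm(-3), tolerance = 1e-12)
  expect_equal(ratio_pvalue(1.6, 1, 0.2, sided = "two"),
               2 * pnorm(3, lower.tail = FALSE), tolerance = 1e-12)
  expect_warning(p <- ratio_pvalue(1.5, 1, 0), "undefined")
  expect_true(is.na(p))
})
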