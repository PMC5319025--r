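#' Background-correct a cell table
#'
#' Per replicate and channel, subtracts the background cutoff
#' `mean + 2 * sd` of the untransfected control population from every
#' cell's intensity.  Negative corrected values are retained for the
#' gating stage.
#'
#' @param cells a `cell_table` with a control population per replicate.
#' @return The corrected `cell_table` (control rows dropped), with
#'   attribute `cutoffs` (data.frame replicate x channel cutoff) and
#'   `corrected = TRUE`.
#' @export
background_correct <- function(cells) {
  need <- c("replicate", "population", CHANNELS)
  if (!all(need %in% names(cells))) {
    stop("cell table lacks required columns")
  }
  reps <- sort(unique(cells$replicate))
  out <- NULL
  cutoffs <- NULL
  for (r in reps) {
    ctrl <- cells[cells$replicate == r & cells$population == "control", ,
                  drop = FALSE]
    if (nrow(ctrl) == 0) {
      stop("no control population for replicate ", r)
    }
    tr <- cells[cells$replicate == r & cells$population == "transfected", ,
                drop = FALSE]
    cut_r <- vapply(CHANNELS, function(ch) {
      mean(ctrl[[ch]]) + 2 * sd(ctrl[[ch]])
    }, numeric(1))
    for (ch in CHANNELS) tr[[ch]] <- tr[[ch]] - cut_r[[ch]]
    out <- rbind(out, tr)
    cutoffs <- rbind(cutoffs,
                     data.frame(replicate = r, t(cut_r)))
  }
  rownames(out) <- NULL
  structure(out, cutoffs = cutoffs, corrected = TRUE,
            config = attr(cells, "config"), params = attr(cells, "params"),
            class = c("cell_table", "data.frame"))
}

#' Gate cells positive for the constitutive reporters
#'
#' Retains cells with corrected intensity above zero on the constitutive
#' channel of each plasmid (`eYFP` and `mKOrange` by default), i.e.
#' cells demonstrably carrying both constructs.
#'
#' @param cells a background-corrected `cell_table`.
#' @param channels channels that must be positive (default
#'   `c("eYFP", "mKOrange")`).
#' @return The gated `cell_table`; attribute `gate_counts` records rows
#'   before/after.  Errors if no cell passes.
#' @export
gate_positive <- function(cells, channels = c("eYFP", "mKOrange")) {
  if (!isTRUE(attr(cells, "corrected"))) {
    stop("gate_positive expects a background-corrected table")
  }
  keep <- rep(TRUE, nrow(cells))
  for (ch in channels) keep <- keep & cells[[ch]] > 0
  if (!any(keep)) {
    stop("gating removed all ", nrow(cells), " cells (rule: ",
         paste(channels, collapse = " & "), " > 0)")
  }
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            cutoffs = attr(cells, "cutoffs"), corrected = TRUE,
            config = attr(cells, "config"), params = attr(cells, "params"),
            gate_counts = c(before = nrow(cells), after = sum(keep)),
            class = c("cell_table", "data.frame"))
}

#' Bin cells on eYFP and summarise each bin
#'
#' Bins the gated, background-corrected cells into consecutive
#' equal-width intervals of corrected eYFP intensity (shared edges across
#' replicates, spanning zero to the pooled 99.5th percentile).  Per bin
#' and replicate: cell count, mean and CV of each channel, and the
#' Pearson correlation between mCherry and mCerulean.  Statistics are
#' then aggregated across replicates (reported value = mean over
#' replicates, error = SD over replicates).  Bins with fewer than
#' `min_cells` cells in a replicate are masked for that replicate; bins
#' aggregated from fewer than 2 replicates are flagged.
#'
#' @param cells gated, corrected `cell_table`.
#' @param n_bins number of equal-width bins, or `"auto"` (largest count
#'   up to 40 keeping median occupied-bin occupancy >= 1000 cells, at
#'   least 10).
#' @param breaks optional explicit bin edges (overrides `n_bins`).
#' @param min_cells per-replicate minimum bin occupancy.
#' @return A `binned_stats` object: list with `breaks`, `mid` (bin
#'   centres), `per_replicate` (long data.frame), `aggregated`
#'   (data.frame with per-bin means and SDs of each statistic, `n_total`,
#'   `n_replicates`, `masked` flag), `n_gated`, `n_out_of_range`.
#' @export
bin_and_summarize <- function(cells, n_bins = "auto", breaks = NULL,
                              min_cells = 100) {
  if (!isTRUE(attr(cells, "corrected"))) {
    stop("bin_and_summarize expects a background-corrected, gated table")
  }
  y <- cells$eYFP
  if (is.null(breaks)) {
    hi <- as.numeric(quantile(y, 0.995))
    if (identical(n_bins, "auto")) {
      n_bins <- 40
      repeat {
        edges <- seq(0, hi, length.out = n_bins + 1)
        occ <- tabulate(findInterval(y, edges, rightmost.closed = TRUE),
                        nbins = n_bins)
        if (stats::median(occ[occ > 0]) >= 1000 || n_bins <= 10) break
        n_bins <- n_bins - 5
      }
    }
    breaks <- seq(0, hi, length.out = n_bins + 1)
  }
  if (length(breaks) < 4) stop("need at least 3 bins")
  if (any(diff(breaks) <= 0)) stop("breaks must be increasing")
  bin_of <- findInterval(y, breaks, rightmost.closed = TRUE)
  in_range <- bin_of >= 1 & bin_of <= length(breaks) - 1
  nb <- length(breaks) - 1
  reps <- sort(unique(cells$replicate))
  per <- NULL
  for (r in reps) {
    sel <- cells$replicate == r & in_range
    br <- bin_of[sel]
    sub <- cells[sel, , drop = FALSE]
    for (b in seq_len(nb)) {
      rows <- sub[br == b, , drop = FALSE]
      n <- nrow(rows)
      if (n < min_cells) {
        per <- rbind(per, data.frame(
          replicate = r, bin = b, n = n, masked = TRUE,
          mean_eYFP = NA_real_, mean_mCherry = NA_real_,
          mean_mCerulean = NA_real_, cv_eYFP = NA_real_,
          cv_mCherry = NA_real_, cv_mCerulean = NA_real_,
          pearson = NA_real_))
        next
      }
      pe <- suppressWarnings(cor(rows$mCherry, rows$mCerulean))
      per <- rbind(per, data.frame(
        replicate = r, bin = b, n = n, masked = FALSE,
        mean_eYFP = mean(rows$eYFP),
        mean_mCherry = mean(rows$mCherry),
        mean_mCerulean = mean(rows$mCerulean),
        cv_eYFP = sd(rows$eYFP) / mean(rows$eYFP),
        cv_mCherry = if (mean(rows$mCherry) > 0)
          sd(rows$mCherry) / mean(rows$mCherry) else NA_real_,
        cv_mCerulean = if (mean(rows$mCerulean) > 0)
          sd(rows$mCerulean) / mean(rows$mCerulean) else NA_real_,
        pearson = if (is.finite(pe)) pe else NA_real_))
    }
  }
  stats_cols <- c("mean_eYFP", "mean_mCherry", "mean_mCerulean",
                  "cv_eYFP", "cv_mCherry", "cv_mCerulean", "pearson")
  agg <- do.call(rbind, lapply(seq_len(nb), function(b) {
    rows <- per[per$bin == b & !per$masked, , drop = FALSE]
    nrep <- nrow(rows)
    out <- data.frame(bin = b, mid = (breaks[b] + breaks[b + 1]) / 2,
                      n_total = sum(per$n[per$bin == b]),
                      n_replicates = nrep,
                      masked = nrep < 2)
    for (sc in stats_cols) {
      out[[sc]] <- if (nrep >= 1) mean(rows[[sc]], na.rm = TRUE) else NA_real_
      out[[paste0("sd_", sc)]] <- if (nrep >= 2) {
        sd(rows[[sc]], na.rm = TRUE)
      } else NA_real_
    }
    out
  }))
  if (sum(!agg$masked) < 3) {
    stop("fewer than 3 populated bins; widen the data or lower min_cells")
  }
  structure(list(breaks = breaks, mid = agg$mid, per_replicate = per,
                 aggregated = agg, n_gated = nrow(cells),
                 n_out_of_range = sum(!in_range), min_cells = min_cells),
            class = "binned_stats")
}

#' @export
print.binned_stats <- function(x, ...) {
  cat("binned_stats:", length(x$breaks) - 1, "equal-width eYFP bins, ",
      x$n_gated, "gated cells (", x$n_out_of_range, "beyond last edge)\n")
  print(head(x$aggregated[!x$aggregated$masked,
                          c("bin", "mid", "n_total", "mean_eYFP",
                            "mean_mCherry", "pearson")], 10))
  invisible(x)
}

#' Empirical fold-repression with jackknife errors
#'
#' Per-bin ratio `F = mean mCherry (unregulated) / mean mCherry
#' (regulated)`, with the error from a leave-one-replicate-out jackknife
#' (the omitted replicate is removed from both datasets).  Bins masked in
#' either input, or with non-positive regulated mean, are masked.
#'
#' @param binned_reg `binned_stats` of the regulated (MRE-bearing)
#'   population.
#' @param binned_unreg `binned_stats` of the matched `N = 0` population,
#'   binned on identical edges.
#' @return Data.frame with `bin`, `mid`, `F`, `se_jackknife`, `masked`.
#' @export
empirical_fold_repression <- function(binned_reg, binned_unreg) {
  if (length(binned_reg$breaks) != length(binned_unreg$breaks) ||
      any(abs(binned_reg$breaks - binned_unreg$breaks) >
          1e-9 * pmax(1, abs(binned_reg$breaks)))) {
    stop("bin edges differ between the two datasets")
  }
  nb <- length(binned_reg$breaks) - 1
  reps_r <- sort(unique(binned_reg$per_replicate$replicate))
  reps_u <- sort(unique(binned_unreg$per_replicate$replicate))
  if (length(reps_r) != length(reps_u)) {
    stop("replicate counts differ; jackknife requires matched replicates")
  }
  R <- length(reps_r)
  bin_mean <- function(per, b, drop_rep = NULL) {
    rows <- per[per$bin == b & !per$masked, , drop = FALSE]
    if (!is.null(drop_rep)) rows <- rows[rows$replicate != drop_rep, ,
                                         drop = FALSE]
    if (nrow(rows) == 0) return(NA_real_)
    mean(rows$mean_mCherry)
  }
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    mu_u <- bin_mean(binned_unreg$per_replicate, b)
    mu_r <- bin_mean(binned_reg$per_replicate, b)
    masked <- is.na(mu_u) || is.na(mu_r) || mu_r <= 0 ||
      binned_reg$aggregated$masked[b] || binned_unreg$aggregated$masked[b]
    Fv <- if (masked) NA_real_ else mu_u / mu_r
    se <- NA_real_
    if (!masked && R >= 2) {
      Fi <- vapply(seq_len(R), function(i) {
        mu_ui <- bin_mean(binned_unreg$per_replicate, b, reps_u[i])
        mu_ri <- bin_mean(binned_reg$per_replicate, b, reps_r[i])
        if (is.na(mu_ui) || is.na(mu_ri) || mu_ri <= 0) NA_real_
        else mu_ui / mu_ri
      }, numeric(1))
      Fi <- Fi[is.finite(Fi)]
      if (length(Fi) >= 2) {
        se <- sqrt((length(Fi) - 1) / length(Fi) *
                     sum((Fi - mean(Fi))^2))
      }
    }
    data.frame(bin = b, mid = binned_reg$mid[b], F = Fv,
               se_jackknife = se, masked = masked)
  }))
  out
}

#' Pearson-correlation ratio between regulated and reference populations
#'
#' For each region of constitutive expression relative to the threshold
#' bin (below / around / above), pools the cells of the region's bins per
#' replicate, computes the Pearson correlation between mCherry and
#' mCerulean in the regulated dataset and in the `N = 0` reference, forms
#' the per-replicate ratio regulated / reference, and reports the mean
#' and SD over replicates.  This discounts correlations induced by the
#' experimental setting (correlated plasmid co-uptake) and isolates
#' miRNA-mediated coupling.
#'
#' @param cells_reg,cells_ref gated, corrected `cell_table`s (regulated
#'   and `N = 0` reference), with matched replicate structure.
#' @param breaks shared bin edges (from [bin_and_summarize()]).
#' @param threshold_bin index of the threshold bin.
#' @param floor reference correlations below this magnitude flag the
#'   ratio as unstable (default 0.1).
#' @param around_halfwidth bins on each side of the threshold bin that
#'   count as "around" (default 1).
#' @return A `pearson_ratio_result` data.frame: one row per region with
#'   `region`, `ratio`, `error` (replicate SD), `rho_reg`, `rho_ref`
#'   (replicate means), `n_replicates`, `unstable`.
#' @export
pearson_ratio <- function(cells_reg, cells_ref, breaks, threshold_bin,
                          floor = 0.1, around_halfwidth = 1) {
  nb <- length(breaks) - 1
  if (threshold_bin < 1 || threshold_bin > nb) {
    stop("threshold_bin outside the bin range")
  }
  regions <- list(
    below = seq_len(max(threshold_bin - around_halfwidth - 1, 0)),
    around = max(threshold_bin - around_halfwidth, 1):
      min(threshold_bin + around_halfwidth, nb),
    above = if (threshold_bin + around_halfwidth + 1 <= nb)
      (threshold_bin + around_halfwidth + 1):nb else integer(0))
  reps <- sort(unique(cells_reg$replicate))
  if (!identical(reps, sort(unique(cells_ref$replicate)))) {
    stop("replicate labels differ between datasets")
  }
  region_rho <- function(cells, bins, r) {
    b <- findInterval(cells$eYFP, breaks, rightmost.closed = TRUE)
    rows <- cells[cells$replicate == r & b %in% bins, , drop = FALSE]
    if (nrow(rows) < 10) return(NA_real_)
    suppressWarnings(cor(rows$mCherry, rows$mCerulean))
  }
  out <- do.call(rbind, lapply(names(regions), function(rg) {
    bins <- regions[[rg]]
    if (length(bins) == 0) {
      return(data.frame(region = rg, ratio = NA_real_, error = NA_real_,
                        rho_reg = NA_real_, rho_ref = NA_real_,
                        n_replicates = 0L, unstable = TRUE))
    }
    rr <- vapply(reps, function(r) region_rho(cells_reg, bins, r),
                 numeric(1))
    rf <- vapply(reps, function(r) region_rho(cells_ref, bins, r),
                 numeric(1))
    keep <- is.finite(rr) & is.finite(rf) & abs(rf) > 1e-12
    ratios <- rr[keep] / rf[keep]
    data.frame(region = rg,
               ratio = if (length(ratios)) mean(ratios) else NA_real_,
               error = if (length(ratios) >= 2) sd(ratios) else NA_real_,
               rho_reg = mean(rr[is.finite(rr)]),
               rho_ref = mean(rf[is.finite(rf)]),
               n_replicates = length(ratios),
               unstable = !is.finite(mean(rf[is.finite(rf)])) ||
                 abs(mean(rf[is.finite(rf)])) < floor)
  }))
  class(out) <- c("pearson_ratio_result", "data.frame")
  out
}

#' Gaussian p-value of a Pearson ratio against the unregulated null
#'
#' Tail probability of the observed region ratio under a normal null
#' whose mean is the matched `N = 0` ratio and whose SD is the
#' biological-replicate error.  One-sided (enrichment of correlation) by
#' default.
#'
#' @param ratio observed ratio (scalar).
#' @param null_mean null ratio (the `N = 0` vs `N = 0` ratio, ~1).
#' @param sd_replicates replicate SD used as the null scale; must be > 0.
#' @param sided `"greater"` (default), `"less"`, or `"two"`.
#' @return The p-value, or `NA` with a warning when `sd_replicates` is
#'   zero/undefined.
#' @examples
#' ratio_pvalue(1, 1, 0.2)            # 0.5
#' round(ratio_pvalue(1.6, 1, 0.2), 5)  # 3 SD: 0.00135
#' @export
ratio_pvalue <- function(ratio, null_mean, sd_replicates,
                         sided = c("greater", "less", "two")) {
  sided <- match.arg(sided)
  if (!is.finite(sd_replicates) || sd_replicates <= 0) {
    warning("replicate SD is zero/undefined; p-value undefined")
    return(NA_real_)
  }
  z <- (ratio - null_mean) / sd_replicates
  switch(sided,
         greater = pnorm(z, lower.tail = FALSE),
         less = pnorm(z),
         two = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Locate the threshold bin on binned statistics
#'
#' Applies the maximal log-log-slope threshold estimator
#' ([sensitivity_threshold()]) to the binned mean mCherry vs bin-centre
#' eYFP curve, restricted to unmasked bins with positive means (bins
#' below the background floor carry no slope information).
#'
#' @param binned a `binned_stats` object.
#' @param tol slope-excess tolerance passed to [sensitivity_threshold()].
#' @return A list with `bin` (threshold bin index, `NA` if absent),
#'   `mid` (its eYFP centre), `max_slope`, `has_threshold`, `bins_used`.
#' @export
binned_threshold <- function(binned, tol = 0.05) {
  agg <- binned$aggregated
  use <- !agg$masked & is.finite(agg$mean_mCherry) &
    agg$mean_mCherry > 0 & agg$mid > 0
  if (sum(use) < 3) stop("fewer than 3 usable bins for threshold recovery")
  thr <- sensitivity_threshold(agg$mid[use], agg$mean_mCherry[use],
                               tol = tol)
  bins_used <- agg$bin[use]
  list(bin = if (thr$has_threshold) bins_used[thr$index] else NA_integer_,
       mid = thr$p0_star, max_slope = thr$max_slope,
       has_threshold = thr$has_threshold, bins_used = bins_used)
}
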