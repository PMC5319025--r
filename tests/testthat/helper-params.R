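# Shared parameter fixtures.
#
# Units: time in mRNA lifetimes (g_r = 1), molecule numbers absolute.
# The reference set puts the network in the titration regime of interest:
# strong binding on target 1, weak on target 2, stable miRNA, proteins
# ~10x longer-lived than mRNA, tens to thousands of molecules per cell.

# Fig. 1-style reference condition: sharp threshold, strong target-1
# binding, weak competitor
params_ref <- function(...) {
  base <- list(k_s = 20, k_r1 = 10, k_r2 = 5, g_s = 0.2, g_r1 = 1,
               g_r2 = 1, g_1 = 2, g_2 = 0.05, alpha = 0.5,
               k_p1 = 1, k_p2 = 1, g_p1 = 0.1, g_p2 = 0.1)
  do.call(cerna_params, utils::modifyList(base, list(...)))
}

# mild-interaction condition far from threshold: linear-noise regime
params_mild <- function(...) {
  base <- list(k_s = 10, k_r1 = 30, k_r2 = 20, g_s = 1, g_r1 = 1,
               g_r2 = 1, g_1 = 0.05, g_2 = 0.05, alpha = 0.5,
               k_p1 = 1, k_p2 = 1, g_p1 = 0.5, g_p2 = 0.5)
  do.call(cerna_params, utils::modifyList(base, list(...)))
}

# default p0 grid spanning the reference threshold (~4e2 in p0 units)
p0_grid_ref <- function(n = 40) exp(seq(log(2), log(4000), length.out = n))

# local interior maxima (indices) of a numeric curve
interior_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}
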