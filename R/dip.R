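#' Hartigan dip statistic
#'
#' Sup-norm distance between the empirical CDF of a sample and the
#' closest unimodal CDF (convex before the mode, concave after it, with a
#' jump permitted only at the mode).  Computed by bisection on the band
#' half-width within which a unimodal CDF fits, with convex-hull
#' feasibility checks on the tie-collapsed sample (see the package
#' vignette for the construction).  The dip is at least `1/(2n)` for a
#' sample of `n` distinct values and at most `1/4`; large values indicate
#' multimodality.  It is invariant under strictly increasing transforms
#' of the data.
#'
#' @param values numeric vector (NAs dropped).
#' @return The dip statistic (a single number in `[0, 0.25]`).
#' @examples
#' dip_statistic(1:100)            # equally spaced: 1/(2n)
#' dip_statistic(c(rnorm(200), rnorm(200, 8)))  # well-separated modes
#' @export
dip_statistic <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) <= 1) return(0)
  cpp_dip(sort(values))
}
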