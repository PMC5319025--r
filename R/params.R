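#' Model parameters for the miRNA-target titration network
#'
#' Constructs and validates the full rate-parameter set of the titration
#' network: one miRNA species `s` and two target mRNAs `r1`, `r2`
#' translated into proteins `p1`, `p2`.  Time is measured in units of the
#' mRNA degradation rate (so `g_r1 = 1` is the natural default) and
#' molecule numbers are absolute counts per cell.
#'
#' @param k_s miRNA transcription rate (molecules / time).
#' @param k_r1,k_r2 target transcription rates (molecules / time).
#' @param g_s free-miRNA degradation rate (1 / time), must be > 0.
#' @param g_r1,g_r2 free-target degradation rates (1 / time), must be > 0.
#' @param g_1,g_2 effective miRNA-target interaction strengths
#'   (1 / (molecules x time)).  An interaction event always removes the
#'   target; the miRNA is removed with probability `alpha`.
#' @param alpha probability in \[0, 1\] that the miRNA is degraded together
#'   with its target (recycled with probability `1 - alpha`).
#' @param k_p1,k_p2 translation rates (proteins per mRNA per time).
#' @param g_p1,g_p2 protein degradation rates (1 / time), must be > 0.
#'
#' @return An object of class `cerna_params` (a named list of the rates).
#' @examples
#' pars <- cerna_params(k_s = 10, k_r1 = 5, k_r2 = 5)
#' constitutive_levels(pars)
#' @export
cerna_params <- function(k_s = 20, k_r1 = 10, k_r2 = 5,
                         g_s = 0.2, g_r1 = 1, g_r2 = 1,
                         g_1 = 0.5, g_2 = 0.05, alpha = 0.5,
                         k_p1 = 1, k_p2 = 1, g_p1 = 0.1, g_p2 = 0.1) {
  p <- list(k_s = k_s, k_r1 = k_r1, k_r2 = k_r2,
            g_s = g_s, g_r1 = g_r1, g_r2 = g_r2,
            g_1 = g_1, g_2 = g_2, alpha = alpha,
            k_p1 = k_p1, k_p2 = k_p2, g_p1 = g_p1, g_p2 = g_p2)
  class(p) <- "cerna_params"
  validate_params(p)
}

PARAM_FIELDS <- c("k_s", "k_r1", "k_r2", "g_s", "g_r1", "g_r2",
                  "g_1", "g_2", "alpha", "k_p1", "k_p2", "g_p1", "g_p2")

#' Validate a parameter set
#'
#' Checks that every rate is a finite non-negative scalar, that the
#' degradation rates (`g_s`, `g_r1`, `g_r2`, `g_p1`, `g_p2`) are strictly
#' positive, and that `alpha` lies in \[0, 1\].
#'
#' @param params a `cerna_params` object or a named list with exactly the
#'   fields of [cerna_params()]; unknown fields are rejected.
#' @return The validated `cerna_params` object (invisibly usable in place).
#' @export
validate_params <- function(params) {
  if (!is.list(params)) stop("params must be a list or cerna_params object")
  nm <- names(params)
  unknown <- setdiff(nm, PARAM_FIELDS)
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(PARAM_FIELDS, nm)
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  for (f in PARAM_FIELDS) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(f, " must be a finite numeric scalar")
    }
  }
  if (params$alpha < 0 || params$alpha > 1) {
    stop("alpha must lie in [0,1]")
  }
  for (f in setdiff(PARAM_FIELDS, "alpha")) {
    if (params[[f]] < 0) stop(f, " must be ≥ 0")
  }
  for (f in c("g_s", "g_r1", "g_r2", "g_p1", "g_p2")) {
    if (params[[f]] <= 0) stop(f, " must be > 0")
  }
  params <- params[PARAM_FIELDS]
  class(params) <- "cerna_params"
  params
}

#' @export
print.cerna_params <- function(x, ...) {
  cat("miRNA-target titration model parameters\n")
  cat("  transcription:  k_s =", x$k_s, " k_r1 =", x$k_r1, " k_r2 =", x$k_r2, "\n")
  cat("  degradation:    g_s =", x$g_s, " g_r1 =", x$g_r1, " g_r2 =", x$g_r2,
      " g_p1 =", x$g_p1, " g_p2 =", x$g_p2, "\n")
  cat("  interaction:    g_1 =", x$g_1, " g_2 =", x$g_2,
      " alpha (miRNA co-degradation prob.) =", x$alpha, "\n")
  cat("  translation:    k_p1 =", x$k_p1, " k_p2 =", x$k_p2, "\n")
  invisible(x)
}

#' Swap the two target indices of a parameter set
#'
#' Returns the mirrored model in which target 1 and target 2 exchange all
#' of their rates.  Model outputs must be equivariant under this swap.
#'
#' @param params a `cerna_params` object.
#' @return The mirrored `cerna_params`.
#' @export
swap_targets <- function(params) {
  params <- validate_params(params)
  q <- params
  q$k_r1 <- params$k_r2; q$k_r2 <- params$k_r1
  q$g_r1 <- params$g_r2; q$g_r2 <- params$g_r1
  q$g_1  <- params$g_2;  q$g_2  <- params$g_1
  q$k_p1 <- params$k_p2; q$k_p2 <- params$k_p1
  q$g_p1 <- params$g_p2; q$g_p2 <- params$g_p1
  q
}

#' Constitutive (unregulated) expression levels
#'
#' Closed-form means each target would reach with no miRNA regulation
#' (interaction strength tending to zero): `r0_i = k_ri / g_ri` and
#' `p0_i = k_pi * k_ri / (g_ri * g_pi)`.
#'
#' @param params a `cerna_params` object.
#' @return A list with fields `r0_1`, `r0_2`, `p0_1`, `p0_2`.
#' @export
constitutive_levels <- function(params) {
  params <- validate_params(params)
  list(r0_1 = params$k_r1 / params$g_r1,
       r0_2 = params$k_r2 / params$g_r2,
       p0_1 = params$k_p1 * params$k_r1 / (params$g_r1 * params$g_p1),
       p0_2 = params$k_p2 * params$k_r2 / (params$g_r2 * params$g_p2))
}

#' Read model parameters from a YAML or JSON file
#'
#' The file must contain a flat mapping with exactly the field names of
#' [cerna_params()]; unknown keys are rejected, missing keys fall back to
#' the package defaults only when `partial = TRUE`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param partial if `TRUE`, keys absent from the file take the
#'   [cerna_params()] defaults; if `FALSE` (default) all 13 fields are
#'   required.
#' @return A validated `cerna_params` object.
#' @export
read_params <- function(path, partial = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension: .", ext)
  }
  if (!is.list(raw)) stop("parameter file must contain a mapping")
  unknown <- setdiff(names(raw), PARAM_FIELDS)
  if (length(unknown) > 0) {
    stop("unknown parameter field(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (partial) raw <- modifyList(as.list(cerna_params()), raw)
  validate_params(raw)
}

#' Write model parameters to a YAML or JSON file
#'
#' @param params a `cerna_params` object.
#' @param path destination path, extension selects the format.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(params), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported parameter file extension: .", ext)
  }
  invisible(path)
}
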