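# Instrument resolving power and peak-merging decisions.

#' Describe the instrument's resolving power
#'
#' Resolving power R = m/z / FWHM. On Orbitrap instruments R falls off as the
#' inverse square root of m/z from its value at a reference m/z (the
#' `mz_calibration` point, conventionally m/z 200); FT-free instruments are
#' modelled with a constant R. Two species are called resolved when their
#' mass difference exceeds `separation` times the local FWHM; the default
#' 1.66 is the classic baseline-separation criterion for two equal Gaussian
#' peaks.
#'
#' @param resolution Resolving power at the reference m/z (FWHM definition),
#'   e.g. 60000.
#' @param mz_ref Reference m/z at which `resolution` is specified (Da),
#'   default 200.
#' @param scaling `"orbitrap"` (inverse square root of m/z) or `"constant"`.
#' @param separation Dimensionless multiple of FWHM required to call two
#'   species resolved, default 1.66.
#' @return A `resolution_model` list.
#' @examples
#' resolution_model(60000, 200)
#' @export
resolution_model <- function(resolution, mz_ref = 200,
                             scaling = c("orbitrap", "constant"),
                             separation = 1.66) {
  scaling <- match.arg(scaling)
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0) {
    stop("resolution must be a single positive number", call. = FALSE)
  }
  if (length(mz_ref) != 1L || is.na(mz_ref) || mz_ref <= 0) {
    stop("mz_ref must be a single positive number", call. = FALSE)
  }
  if (length(separation) != 1L || is.na(separation) || separation <= 0) {
    stop("separation must be a single positive number", call. = FALSE)
  }
  structure(list(resolution = resolution, mz_ref = mz_ref,
                 scaling = scaling, separation = separation),
            class = "resolution_model")
}

#' @export
print.resolution_model <- function(x, ...) {
  cat(sprintf("<resolution model> R = %g at m/z %g (%s scaling), separation %g x FWHM\n",
              x$resolution, x$mz_ref, x$scaling, x$separation))
  invisible(x)
}

#' Resolving power at a given m/z
#'
#' @param model A [resolution_model()].
#' @param mz m/z at which to evaluate, Da.
#' @return Resolving power (dimensionless).
#' @export
resolving_power_at <- function(model, mz) {
  stopifnot(inherits(model, "resolution_model"))
  if (any(mz <= 0)) stop("mz must be positive", call. = FALSE)
  switch(model$scaling,
         constant = rep_len(model$resolution, length(mz)),
         orbitrap = model$resolution * sqrt(model$mz_ref / mz))
}

#' Smallest resolvable neutral-mass difference
#'
#' `separation * FWHM(mz) * charge`: the FWHM criterion is applied on the m/z
#' axis and converted to neutral-mass units by multiplying with the charge.
#'
#' @param model A [resolution_model()], or `NULL` for the nominal
#'   (low-resolution) limit in which everything within half a Da merges.
#' @param mz m/z of the ion species compared, Da.
#' @param charge Positive integer charge state.
#' @return Mass difference in Da (neutral-mass scale).
#' @examples
#' min_separable_mass_diff(resolution_model(60000, 200, "constant",
#'                                          separation = 1), 200, 1)  # 1/300
#' @export
min_separable_mass_diff <- function(model, mz, charge = 1L) {
  if (is.null(model)) return(0.5)
  if (charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  model$separation * (mz / resolving_power_at(model, mz)) * charge
}

#' Are two mass shifts indistinguishable at this resolution?
#'
#' @param shift_a,shift_b Exact neutral mass shifts, Da.
#' @param model A [resolution_model()] or `NULL` (nominal limit).
#' @param mz m/z at which the species are observed.
#' @param charge Positive integer charge state.
#' @return `TRUE` when `|shift_a - shift_b|` is below the resolvable
#'   difference; symmetric and reflexive.
#' @examples
#' m <- resolution_model(60000, 200)
#' # 13C2 vs 18O on a 2+ peptide ion at m/z 536.8: merged
#' is_unresolved(2.006710, 2.004246, m, mz = 536.82, charge = 2)
#' @export
is_unresolved <- function(shift_a, shift_b, model, mz, charge = 1L) {
  if (any(!is.finite(shift_a)) || any(!is.finite(shift_b))) {
    stop("shifts must be finite", call. = FALSE)
  }
  abs(shift_a - shift_b) < min_separable_mass_diff(model, mz, charge)
}
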