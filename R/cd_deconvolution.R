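## Secondary-structure estimation from far-UV CD spectra by non-negative
## least squares against a reference basis.

CD_CLASSES <- c("alpha_helix", "beta_sheet", "beta_turn", "random_coil")

gaussian_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

#' Synthetic CD reference basis
#'
#' Builds a four-class basis (alpha-helix, beta-sheet, beta-turn, random
#' coil) from Gaussian band parameterizations of the canonical far-UV CD
#' shapes: the helix with its positive pi-pi* band near 193 nm and the
#' double negative minima at 208 and 222 nm, the sheet with a positive band
#' near 196 nm and a single minimum near 218 nm, the turn with a weak
#' positive band near 205 nm, and the coil with a strong minimum near
#' 198 nm. Units are nominal mean-residue ellipticity (10^3 deg cm^2/dmol);
#' the deconvolution is scale-invariant, so only the shapes matter.
#'
#' This basis is synthetic: it reproduces textbook band positions, not any
#' proprietary reference-set, so absolute fractions from real spectra are
#' indicative rather than calibrated.
#'
#' @param wavelengths Grid in nm; must cover at least 190-240 nm
#'   (default 185-250 nm at 1 nm).
#' @return An object of class `cd_basis`: list with `wavelengths` and
#'   `basis_spectra` (named list of vectors).
#' @export
cd_basis <- function(wavelengths = seq(185, 250, by = 1)) {
  if (any(diff(wavelengths) <= 0))
    stop_invalid("wavelengths must be strictly increasing")
  if (min(wavelengths) > 190 || max(wavelengths) < 240)
    stop_invalid("basis grid must cover at least 190-240 nm")
  wl <- as.numeric(wavelengths)
  basis <- list(
    alpha_helix = gaussian_band(wl, 193, 7, 65) -
      gaussian_band(wl, 208, 8, 28) - gaussian_band(wl, 222, 10, 30),
    beta_sheet = gaussian_band(wl, 196, 7, 30) -
      gaussian_band(wl, 218, 10, 14),
    beta_turn = -gaussian_band(wl, 190, 7, 9) +
      gaussian_band(wl, 205, 9, 8) - gaussian_band(wl, 225, 12, 3),
    random_coil = -gaussian_band(wl, 198, 8, 40) +
      gaussian_band(wl, 220, 14, 2))
  structure(list(wavelengths = wl, basis_spectra = basis),
            class = "cd_basis")
}

#' @export
print.cd_basis <- function(x, ...) {
  cat(sprintf("<cd_basis> %d classes on %g-%g nm (%d points)\n",
              length(x$basis_spectra), min(x$wavelengths),
              max(x$wavelengths), length(x$wavelengths)))
  invisible(x)
}

#' CD secondary-structure deconvolution
#'
#' Estimates secondary-structure fractions by non-negative least squares of
#' the measured spectrum on the basis spectra over their common wavelength
#' range, followed by renormalization of the non-negative weights onto the
#' unit simplex. Because of that final renormalization the fractions are
#' invariant to any common positive rescaling of the spectrum (and of the
#' basis), which sidesteps mean-residue-ellipticity normalization.
#'
#' @param s A [spectrum()] of kind `"cd"`.
#' @param basis A [cd_basis()] (default: the packaged synthetic basis).
#' @return An object of class `secondary_structure`: `fractions` (named,
#'   sums to 1), `weights` (raw NNLS weights), `residual_norm` (Euclidean
#'   norm of the NNLS residual, on the spectrum's scale).
#' @examples
#' b <- cd_basis()
#' s <- gen_cd_spectrum(c(alpha_helix = 0.3, beta_sheet = 0.3,
#'                        beta_turn = 0, random_coil = 0.4), b)
#' deconvolve_cd(s, b)$fractions
#' @export
deconvolve_cd <- function(s, basis = cd_basis()) {
  stopifnot(inherits(s, "spectrum"), inherits(basis, "cd_basis"))
  if (s$kind != "cd")
    stop_invalid("spectrum kind must be 'cd'")
  lo <- max(min(s$wavelengths), min(basis$wavelengths))
  hi <- min(max(s$wavelengths), max(basis$wavelengths))
  if (hi - lo < 30)
    stop_invalid("spectrum and basis must overlap over at least 30 nm")
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  wl <- s$wavelengths[keep]
  y <- s$intensities[keep]
  A <- vapply(basis$basis_spectra, function(b)
    stats::approx(basis$wavelengths, b, xout = wl)$y, numeric(length(wl)))
  w <- pracma::lsqnonneg(A, y)$x
  names(w) <- names(basis$basis_spectra)
  total <- sum(w)
  if (total <= 1e-12)
    stop_invalid("degenerate deconvolution: all weights zero")
  frac <- w / total
  structure(list(fractions = frac, weights = w,
                 residual_norm = sqrt(sum((y - A %*% w)^2))),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure>\n")
  for (k in names(x$fractions))
    cat(sprintf("  %-12s %6.2f %%\n", k, 100 * x$fractions[[k]]))
  cat(sprintf("  residual norm %.4g\n", x$residual_norm))
  invisible(x)
}
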