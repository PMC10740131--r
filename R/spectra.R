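## Peak detection and red/blue-shift classification for emission,
## synchronous and CD spectra.

SPECTRUM_KINDS <- c("emission", "synchronous_15", "synchronous_60", "cd")

#' Spectrum container
#'
#' A wavelength grid with paired intensities and light metadata. Kinds:
#' `emission` (intrinsic fluorescence), `synchronous_15` / `synchronous_60`
#' (synchronous scans at delta-lambda = 15 nm, tyrosine microenvironment, and
#' 60 nm, tryptophan), `cd` (far-UV circular dichroism).
#'
#' @param wavelengths Strictly increasing grid in nm.
#' @param intensities Same length as `wavelengths`, finite.
#' @param kind One of `"emission"`, `"synchronous_15"`, `"synchronous_60"`,
#'   `"cd"`.
#' @param label Free-text sample id.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, intensities, kind = "emission", label = "") {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (length(wavelengths) != length(intensities))
    stop_invalid("wavelengths and intensities must have the same length")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop_invalid("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(intensities)))
    stop_invalid("intensities must be finite")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 kind = kind, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s '%s': %d points, %.4g-%.4g nm\n", x$kind,
              x$label, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Emission-maximum wavelength
#'
#' Locates the wavelength of maximum intensity, optionally within a window,
#' and refines it below grid resolution by fitting a parabola through the
#' discrete argmax and its two neighbours. Ties on the discrete grid are
#' broken toward the shorter wavelength. When the maximum sits on the window
#' boundary no refinement is possible; the raw endpoint is returned with a
#' warning (`at_boundary = TRUE`).
#'
#' @param s A [spectrum()].
#' @param window Optional `c(min_nm, max_nm)` search window.
#' @param smooth_width Optional odd moving-average width (points) applied
#'   before peak search; default no smoothing.
#' @return List with `lambda_max` (refined, nm), `lambda_raw` (grid argmax),
#'   `intensity`, `at_boundary`.
#' @examples
#' s <- gen_spectrum(center = 337, width = 20, grid = seq(300, 450, 1))
#' find_lambda_max(s)$lambda_max
#' @export
find_lambda_max <- function(s, window = NULL, smooth_width = NULL) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelengths
  y <- s$intensities
  if (!is.null(smooth_width)) {
    stopifnot(smooth_width >= 1, smooth_width %% 2 == 1)
    k <- rep(1 / smooth_width, smooth_width)
    y <- as.numeric(stats::filter(y, k, sides = 2))
    keep <- !is.na(y)
    wl <- wl[keep]; y <- y[keep]
  }
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- wl >= window[1] & wl <= window[2]
    wl <- wl[keep]; y <- y[keep]
  }
  if (length(wl) < 3L)
    stop_invalid("need at least 3 spectrum points in the search window")
  i <- which.max(y)  # first maximum: tie broken toward shorter wavelength
  at_boundary <- i == 1L || i == length(y)
  if (at_boundary) {
    warning("intensity maximum lies on the window boundary; no refinement")
    return(list(lambda_max = wl[i], lambda_raw = wl[i],
                intensity = y[i], at_boundary = TRUE))
  }
  ## parabola through (wl, y) at i-1, i, i+1; vertex is the refined peak
  x3 <- wl[(i - 1):(i + 1)]
  y3 <- y[(i - 1):(i + 1)]
  co <- solve(cbind(1, x3, x3^2), y3)
  lam <- if (co[3] < 0) -co[2] / (2 * co[3]) else wl[i]
  ## keep the vertex inside the bracketing interval (degenerate flat tops)
  if (lam < x3[1] || lam > x3[3]) lam <- wl[i]
  list(lambda_max = unname(lam), lambda_raw = wl[i],
       intensity = y[i], at_boundary = FALSE)
}

#' Red/blue-shift call between two peak wavelengths
#'
#' @param lambda_ref Reference peak position, nm.
#' @param lambda_sample Sample peak position, nm.
#' @param tol Dead band in nm; moves within `tol` are called `"none"`
#'   (default 0.5 nm, half a typical 1-nm scan step).
#' @return `"red"` (sample at longer wavelength), `"blue"`, or `"none"`.
#' @examples
#' classify_shift(337, 341)  # "red"
#' classify_shift(315, 313)  # "blue"
#' @export
classify_shift <- function(lambda_ref, lambda_sample, tol = 0.5) {
  if (!is_number(lambda_ref) || !is_number(lambda_sample))
    stop_invalid("peak positions must be single finite numbers")
  d <- lambda_sample - lambda_ref
  if (d > tol) "red" else if (d < -tol) "blue" else "none"
}
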