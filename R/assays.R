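## Deterministic calculators for the colorimetric assays and the
## urea/thiourea noncovalent-force partition.

#' Bromophenol-blue bound (surface hydrophobicity proxy)
#'
#' BPB bound (ug) = 200 ug x (A_blank - A_sample) / A_blank. Bound dye mass
#' proxies the exposed hydrophobic surface of the protein. A sample reading
#' above the blank gives a negative value; it is returned as-is with a
#' warning so downstream QC can decide.
#'
#' @param a_blank Absorbance (595 nm) of the dye blank, > 0.
#' @param a_sample Absorbance of the sample supernatant.
#' @return Bound BPB in micrograms.
#' @examples
#' bpb_bound(0.5, 0.25)  # 100
#' @export
bpb_bound <- function(a_blank, a_sample) {
  if (!is_number(a_blank) || a_blank <= 0)
    stop_invalid("a_blank must be a positive number")
  if (!is_number(a_sample))
    stop_invalid("a_sample must be a single finite number")
  out <- 200 * (a_blank - a_sample) / a_blank
  if (out < 0)
    warning("a_sample exceeds a_blank: negative BPB bound returned")
  out
}

#' Sulfhydryl content by Ellman's assay
#'
#' Beer-Lambert conversion of the 412-nm TNB absorbance to sulfhydryl
#' concentration, with explicit dilution bookkeeping, expressed per gram of
#' protein: umol SH / g = A412 / (extinction x path) x 1e6 x dilution /
#' protein (mg/mL). The default dilution factor 11 reflects 0.5 mL sample
#' + 4.5 mL buffer + 0.5 mL reagent; the default extinction 13600 M^-1 cm^-1
#' is the standard TNB value.
#'
#' @param a412 Absorbance at 412 nm (>= 0).
#' @param extinction Molar extinction coefficient, M^-1 cm^-1.
#' @param path_cm Cuvette path length in cm.
#' @param dilution_factor Total assay volume over sample volume.
#' @param protein_mg_per_ml Protein concentration of the undiluted sample.
#' @return Sulfhydryl content in umol per g protein.
#' @export
sulfhydryl_content <- function(a412, extinction = 13600, path_cm = 1,
                               dilution_factor = 11, protein_mg_per_ml = 5) {
  if (!is_number(a412) || a412 < 0)
    stop_invalid("a412 must be a non-negative number")
  for (v in list(extinction, path_cm, dilution_factor, protein_mg_per_ml))
    if (!is_number(v) || v <= 0)
      stop_invalid("extinction, path, dilution and protein conc must be > 0")
  conc_M <- a412 / (extinction * path_cm)       # mol/L in the cuvette
  conc_M * 1e6 * dilution_factor / protein_mg_per_ml  # umol per g protein
}

#' Linear standard-curve fit
#'
#' OLS fit of absorbance on concentration for a standard series; the
#' concentration range of the standards is stored so inverse predictions
#' outside it can be flagged.
#'
#' @param concentrations Standard concentrations (ug/mL), at least 3 points
#'   with at least 2 distinct values.
#' @param absorbances Paired absorbance readings.
#' @return An object of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared`, `range`.
#' @export
fit_linear_calibration <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances))
    stop_invalid("concentrations and absorbances must have the same length")
  if (length(concentrations) < 3L)
    stop_invalid("calibration needs at least 3 standards")
  if (length(unique(concentrations)) < 2L)
    stop_invalid("calibration needs at least 2 distinct concentrations")
  if (any(!is.finite(concentrations)) || any(!is.finite(absorbances)))
    stop_invalid("calibration inputs must be finite")
  fit <- ols(concentrations, absorbances)
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 range = range(concentrations)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> A = %.4g x conc + %.4g, r2 = %.4f, range %g-%g ug/mL\n",
              x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Inverse prediction from a standard curve
#'
#' Concentration = (absorbance - intercept) / slope. Predictions outside the
#' standards range are returned with a warning rather than clamped.
#'
#' @param fit A [fit_linear_calibration()] result.
#' @param absorbance Measured absorbance.
#' @return Concentration in ug/mL.
#' @export
invert_calibration <- function(fit, absorbance) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is_number(absorbance))
    stop_invalid("absorbance must be a single finite number")
  if (abs(fit$slope) <= 1e-12 * max(1, abs(fit$intercept)))
    stop_invalid("calibration slope is zero; curve not invertible")
  conc <- (absorbance - fit$intercept) / fit$slope
  if (conc < fit$range[1] || conc > fit$range[2])
    warning(sprintf("predicted concentration %.4g outside standards range [%g, %g]",
                    conc, fit$range[1], fit$range[2]))
  conc
}

#' Urea/thiourea noncovalent-force partition
#'
#' Urea preferentially breaks hydrogen bonds while thiourea preferentially
#' breaks hydrophobic contacts, so the free-ligand amounts released by each
#' agent partition the noncovalent binding. The larger release, by more than
#' a relative margin, names the dominant force.
#'
#' @param free_after_urea Free ligand (ug) after urea treatment, >= 0.
#' @param free_after_thiourea Free ligand (ug) after thiourea, >= 0.
#' @param rel_tol Relative margin below which the releases count as
#'   comparable (default 0.1).
#' @return An object of class `force_partition` with fields
#'   `hydrogen_bond_release`, `hydrophobic_release`, `dominant` (one of
#'   `"hydrogen_bond"`, `"hydrophobic"`, `"comparable"`).
#' @examples
#' partition_forces(100, 60)$dominant  # "hydrogen_bond"
#' @export
partition_forces <- function(free_after_urea, free_after_thiourea,
                             rel_tol = 0.1) {
  if (!is_number(free_after_urea) || free_after_urea < 0 ||
      !is_number(free_after_thiourea) || free_after_thiourea < 0)
    stop_invalid("released amounts must be non-negative numbers")
  u <- free_after_urea
  t <- free_after_thiourea
  dominant <- if (u > t * (1 + rel_tol)) "hydrogen_bond"
    else if (t > u * (1 + rel_tol)) "hydrophobic"
    else "comparable"
  structure(list(hydrogen_bond_release = u, hydrophobic_release = t,
                 dominant = dominant),
            class = "force_partition")
}

#' @export
print.force_partition <- function(x, ...) {
  cat(sprintf("<force_partition> urea %.4g ug vs thiourea %.4g ug -> %s\n",
              x$hydrogen_bond_release, x$hydrophobic_release, x$dominant))
  invisible(x)
}
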