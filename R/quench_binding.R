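## Fluorescence-quenching binding analysis: Stern-Volmer, double-log,
## Van't Hoff, Gibbs energy, and the two classification rules.

#' Quenching series at one temperature
#'
#' Bundles one temperature's titration: quencher molar concentrations with
#' the paired fluorescence intensities, plus the unquenched intensity F0.
#'
#' @param temperature Temperature in kelvin.
#' @param concentrations Quencher concentrations in M, non-negative and
#'   strictly increasing.
#' @param f0 Fluorescence intensity without quencher (arbitrary units, > 0).
#' @param f Intensities at each concentration, same units as `f0`, all > 0.
#'
#' @return An object of class `quenching_series`.
#' @examples
#' q <- c(1, 2, 3) * 1e-4
#' quenching_series(293, q, f0 = 1000, f = 1000 / (1 + 1000 * q))
#' @export
quenching_series <- function(temperature, concentrations, f0, f) {
  if (!is_number(temperature) || temperature <= 0)
    stop_invalid("temperature must be a positive number (kelvin)")
  if (length(f) != length(concentrations))
    stop_invalid("f and concentrations must have the same length")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop_invalid("concentrations must be finite and non-negative")
  if (any(diff(concentrations) <= 0))
    stop_invalid("concentrations must be strictly increasing")
  if (!is_number(f0) || f0 <= 0)
    stop_invalid("f0 must be a positive number")
  if (any(!is.finite(f)) || any(f <= 0))
    stop_invalid("all intensities f must be positive and finite")
  structure(
    list(temperature = temperature,
         concentrations = as.numeric(concentrations),
         f0 = f0, f = as.numeric(f)),
    class = "quenching_series")
}

#' @export
print.quenching_series <- function(x, ...) {
  cat(sprintf("<quenching_series> T = %g K, %d points, F0 = %g\n",
              x$temperature, length(x$f), x$f0))
  invisible(x)
}

#' Stern-Volmer fit
#'
#' Fits F0/F = 1 + Ksv \[Q\] by ordinary least squares and derives the
#' bimolecular quenching rate constant Kq = Ksv / tau0. By default the
#' intercept is left free (and reported), which keeps r-squared meaningful on
#' real data; `anchored = TRUE` fixes the intercept at 1 as written in the
#' Stern-Volmer relation.
#'
#' @param series A [quenching_series()].
#' @param tau0 Unquenched fluorophore lifetime in seconds (default 1e-8 s,
#'   the value implied when Kq in 1e11 units numerically equals Ksv in 1e3
#'   units).
#' @param anchored Fix the intercept of F0/F vs \[Q\] at 1 (default FALSE).
#'
#' @return An object of class `stern_volmer_fit` with fields `ksv` (M^-1),
#'   `kq` (M^-1 s^-1), `tau0`, `intercept`, `r_squared`, `temperature`.
#' @examples
#' q <- c(1, 2, 3) * 1e-4
#' s <- quenching_series(293, q, 1000, 1000 / (1 + 1000 * q))
#' fit_stern_volmer(s, tau0 = 1e-8)
#' @export
fit_stern_volmer <- function(series, tau0 = 1e-8, anchored = FALSE) {
  stopifnot(inherits(series, "quenching_series"))
  if (!is_number(tau0) || tau0 <= 0)
    stop_invalid("tau0 must be a positive number (seconds)")
  if (length(series$f) < 3L)
    stop_invalid("Stern-Volmer fit needs at least 3 concentration points")
  q <- series$concentrations
  y <- series$f0 / series$f
  fit <- if (anchored) {
    res <- ols(q, y - 1, anchored = TRUE)
    res$intercept <- 1
    ## r2 is computed on the anchored line against the raw F0/F values
    resid <- y - (1 + res$slope * q)
    ss_tot <- sum((y - mean(y))^2)
    res$r_squared <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) {
      if (sum(resid^2) <= .Machine$double.eps * max(1, sum(y^2))) 1 else 0
    } else min(1, max(0, 1 - sum(resid^2) / ss_tot))
    res
  } else {
    ols(q, y)
  }
  structure(
    list(ksv = fit$slope, kq = fit$slope / tau0, tau0 = tau0,
         intercept = fit$intercept, r_squared = fit$r_squared,
         temperature = series$temperature, anchored = anchored),
    class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<stern_volmer_fit> T = %g K: Ksv = %.4g M^-1, Kq = %.4g M^-1 s^-1, r2 = %.4f\n",
    x$temperature, x$ksv, x$kq, x$r_squared))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Fits log10((F0 - F)/F) = log10(Ka) + n log10(\[Q\]) by OLS, giving the
#' apparent binding constant Ka and the number of binding sites n. Points
#' with F >= F0 carry no quenching signal; they are dropped with a warning.
#'
#' @param series A [quenching_series()].
#' @return An object of class `double_log_fit` with fields `ka` (M^-1), `n`,
#'   `r_squared`, `temperature`, `n_points_used`.
#' @examples
#' q <- c(1, 2, 3) * 1e-4
#' s <- quenching_series(293, q, 1000, 1000 / (1 + 100 * q))
#' fit_double_log(s)  # recovers Ka = 100, n = 1
#' @export
fit_double_log <- function(series) {
  stopifnot(inherits(series, "quenching_series"))
  keep <- series$f < series$f0 & series$concentrations > 0
  if (any(!keep))
    warning(sprintf("dropping %d point(s) with F >= F0 or [Q] = 0",
                    sum(!keep)))
  if (sum(keep) < 3L)
    stop_invalid("double-log fit needs at least 3 points with F < F0")
  q <- series$concentrations[keep]
  f <- series$f[keep]
  x <- log10(q)
  y <- log10((series$f0 - f) / f)
  fit <- ols(x, y)
  structure(
    list(ka = 10^fit$intercept, n = fit$slope, r_squared = fit$r_squared,
         temperature = series$temperature, n_points_used = sum(keep)),
    class = "double_log_fit")
}

#' @export
print.double_log_fit <- function(x, ...) {
  cat(sprintf("<double_log_fit> T = %g K: Ka = %.4g M^-1, n = %.4g, r2 = %.4f\n",
              x$temperature, x$ka, x$n, x$r_squared))
  invisible(x)
}

#' Van't Hoff analysis
#'
#' Linear regression of ln(Ka) on 1/T: the slope is -dH/R and the intercept
#' dS/R. Results are reported in kJ units (dH in kJ/mol, dS in kJ/(mol K)).
#'
#' @param temperatures Temperatures in kelvin (at least 2, all distinct).
#' @param ka Apparent binding constants in M^-1, one per temperature, all > 0.
#' @return A list with `delta_h` (kJ/mol), `delta_s` (kJ/(mol K)),
#'   `r_squared`.
#' @examples
#' ka <- gen_vant_hoff_dataset(-50, -0.1, c(293, 303, 310))
#' fit_vant_hoff(c(293, 303, 310), ka)
#' @export
fit_vant_hoff <- function(temperatures, ka) {
  if (length(temperatures) != length(ka))
    stop_invalid("temperatures and ka must have the same length")
  if (length(temperatures) < 2L)
    stop_invalid("Van't Hoff fit needs at least 2 temperatures")
  if (anyDuplicated(temperatures))
    stop_invalid("temperatures must be distinct")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_invalid("temperatures must be positive (kelvin)")
  if (any(!is.finite(ka)) || any(ka <= 0))
    stop_invalid("all Ka must be positive")
  fit <- ols(1 / temperatures, log(ka))
  list(delta_h = -fit$slope * R_GAS / 1000,
       delta_s = fit$intercept * R_GAS / 1000,
       r_squared = fit$r_squared)
}

#' Gibbs free energy of binding
#'
#' dG = dH - T dS at each requested temperature.
#'
#' @param delta_h Binding enthalpy, kJ/mol.
#' @param delta_s Binding entropy, kJ/(mol K).
#' @param temperatures Temperatures in kelvin, all > 0.
#' @return Named numeric vector of dG in kJ/mol, names are the temperatures.
#' @examples
#' compute_gibbs(-164.076, -0.501, c(293, 303, 310))
#' @export
compute_gibbs <- function(delta_h, delta_s, temperatures) {
  if (!is_number(delta_h) || !is_number(delta_s))
    stop_invalid("delta_h and delta_s must be single finite numbers")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_invalid("temperatures must be positive (kelvin)")
  dg <- delta_h - temperatures * delta_s
  names(dg) <- as.character(temperatures)
  dg
}

#' Thermodynamic summary of binding
#'
#' Combines a Van't Hoff fit over Ka(T) with per-temperature Gibbs energies
#' and the driving-force classification of [classify_forces()].
#'
#' @inheritParams fit_vant_hoff
#' @param tol Enthalpy threshold (kJ/mol) passed to [classify_forces()].
#' @return An object of class `thermo_result` with fields `delta_h`,
#'   `delta_s`, `delta_g_by_temperature`, `r_squared`, `r_gas`, `force_label`.
#' @export
binding_thermodynamics <- function(temperatures, ka, tol = 1.0) {
  vh <- fit_vant_hoff(temperatures, ka)
  structure(
    list(delta_h = vh$delta_h, delta_s = vh$delta_s,
         delta_g_by_temperature = compute_gibbs(vh$delta_h, vh$delta_s,
                                                temperatures),
         r_squared = vh$r_squared, r_gas = R_GAS,
         force_label = classify_forces(vh$delta_h, vh$delta_s, tol = tol)),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.3f kJ/mol, dS = %.4f kJ/(mol K), force = %s\n",
              x$delta_h, x$delta_s, x$force_label))
  dg <- x$delta_g_by_temperature
  cat(paste(sprintf("  dG(%s K) = %.3f kJ/mol", names(dg), dg),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Quenching-mechanism classification
#'
#' Static quenching (ground-state complex) and dynamic quenching (collisional)
#' are distinguished by how Ksv moves with temperature and by whether Kq
#' exceeds the maximum diffusion-controlled collision rate constant
#' (2e10 M^-1 s^-1). A Ksv that rises with temperature while every Kq sits
#' above the diffusion limit indicates both processes at once ("combined").
#'
#' @param fits List of [fit_stern_volmer()] results at distinct temperatures
#'   (at least 2; any order, sorted internally).
#' @param diffusion_limit Maximum diffusive collision rate constant in
#'   M^-1 s^-1 (default 2e10).
#' @return An object of class `mechanism_call` with fields `label` (one of
#'   `"static"`, `"dynamic"`, `"combined"`, `"indeterminate"`), `ksv_trend`
#'   (`"increasing"`, `"decreasing"`, `"flat"`),
#'   `kq_exceeds_diffusion_limit`, `diffusion_limit`.
#' @details The trend is strict monotonicity of Ksv over temperature; values
#'   equal within a relative 1e-6 count as ties, and any non-monotone pattern
#'   is reported as `"flat"` (which yields an indeterminate label).
#' @export
classify_quenching <- function(fits, diffusion_limit = 2e10) {
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, inherits, logical(1), "stern_volmer_fit")))
    stop_invalid("need a list of >= 2 stern_volmer_fit objects")
  temps <- vapply(fits, `[[`, numeric(1), "temperature")
  if (anyDuplicated(temps))
    stop_invalid("fits must be at distinct temperatures")
  ord <- order(temps)
  ksv <- vapply(fits, `[[`, numeric(1), "ksv")[ord]
  kq <- vapply(fits, `[[`, numeric(1), "kq")[ord]
  d <- diff(ksv)
  tie <- abs(d) <= 1e-6 * pmax(abs(ksv[-1]), abs(ksv[-length(ksv)]))
  trend <- if (all(tie)) "flat"
    else if (all(d > 0 & !tie)) "increasing"
    else if (all(d < 0 & !tie)) "decreasing"
    else "flat"
  exceeds <- all(kq > diffusion_limit)
  label <- if (trend == "increasing" && exceeds) "combined"
    else if (trend == "increasing") "dynamic"
    else if (trend == "decreasing" && exceeds) "static"
    else "indeterminate"
  structure(
    list(label = label, ksv_trend = trend,
         kq_exceeds_diffusion_limit = exceeds,
         diffusion_limit = diffusion_limit),
    class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (Ksv %s with T, Kq %s diffusion limit %.3g)\n",
              x$label, x$ksv_trend,
              if (x$kq_exceeds_diffusion_limit) "above" else "not above",
              x$diffusion_limit))
  invisible(x)
}

#' Driving-force classification from binding thermodynamics
#'
#' Sign-based attribution of the dominant noncovalent force (the
#' Ross-Subramanian convention): dH < 0 with dS < 0 points to hydrogen
#' bonding / van der Waals contacts, dH > 0 with dS > 0 to hydrophobic
#' interactions, and dH near zero (or dH < 0 with dS > 0) to electrostatic
#' interactions. The rare exothermic-but-entropy-neutral leftover case
#' (dH > tol, dS <= 0) falls back to electrostatic as the residual class.
#'
#' @param delta_h Binding enthalpy, kJ/mol.
#' @param delta_s Binding entropy, kJ/(mol K).
#' @param tol Threshold (kJ/mol) below which |dH| counts as "near zero".
#' @return One of `"hydrogen_bond_vdw"`, `"hydrophobic"`, `"electrostatic"`.
#' @examples
#' classify_forces(-164.076, -0.501)  # "hydrogen_bond_vdw"
#' @export
classify_forces <- function(delta_h, delta_s, tol = 1.0) {
  if (!is_number(delta_h) || !is_number(delta_s))
    stop_invalid("delta_h and delta_s must be single finite numbers")
  if (abs(delta_h) <= tol) return("electrostatic")
  if (delta_h < -tol && delta_s < 0) return("hydrogen_bond_vdw")
  if (delta_h > tol && delta_s > 0) return("hydrophobic")
  "electrostatic"
}

#' End-to-end quenching analysis
#'
#' Runs the full binding workflow on quenching series measured at several
#' temperatures: per-temperature Stern-Volmer and double-log fits, Van't Hoff
#' thermodynamics with Gibbs energies, mechanism and driving-force calls.
#'
#' @param series_list List of [quenching_series()] at distinct temperatures.
#' @param tau0 Fluorophore lifetime in seconds (see [fit_stern_volmer()]).
#' @param diffusion_limit Diffusion-controlled rate limit, M^-1 s^-1.
#' @param anchored Anchor the Stern-Volmer intercept at 1 (default FALSE).
#' @return A list of class `quench_report` with elements `stern_volmer`,
#'   `double_log`, `thermo`, `mechanism`, `table` (a data.frame mirroring the
#'   usual per-temperature constants table).
#' @export
quench_analysis <- function(series_list, tau0 = 1e-8,
                            diffusion_limit = 2e10, anchored = FALSE) {
  stopifnot(is.list(series_list), length(series_list) >= 2L)
  sv <- lapply(series_list, fit_stern_volmer, tau0 = tau0, anchored = anchored)
  dl <- lapply(series_list, fit_double_log)
  temps <- vapply(sv, `[[`, numeric(1), "temperature")
  ka <- vapply(dl, `[[`, numeric(1), "ka")
  thermo <- binding_thermodynamics(temps, ka)
  mech <- classify_quenching(sv, diffusion_limit = diffusion_limit)
  tab <- data.frame(
    temperature_K = temps,
    ksv_M1 = vapply(sv, `[[`, numeric(1), "ksv"),
    kq_M1s1 = vapply(sv, `[[`, numeric(1), "kq"),
    r2_sv = vapply(sv, `[[`, numeric(1), "r_squared"),
    ka_M1 = ka,
    n_sites = vapply(dl, `[[`, numeric(1), "n"),
    r2_dl = vapply(dl, `[[`, numeric(1), "r_squared"),
    delta_g_kJ_mol = unname(thermo$delta_g_by_temperature))
  structure(list(stern_volmer = sv, double_log = dl, thermo = thermo,
                 mechanism = mech, table = tab),
            class = "quench_report")
}

#' @export
print.quench_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  print(x$thermo)
  print(x$mechanism)
  invisible(x)
}
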