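## Plain-text input/output: CSV readers for titrations, spectra and
## calibration standards, and a demo-dataset writer.

#' Read a quenching titration CSV
#'
#' Expects columns `conc_M` and `intensity`; the row with `conc_M == 0`
#' defines F0 (averaged if replicated). Remaining rows are sorted by
#' concentration.
#'
#' @param file Path to the CSV file.
#' @param temperature Temperature of the series in kelvin.
#' @return A [quenching_series()].
#' @export
read_quenching_csv <- function(file, temperature) {
  d <- utils::read.csv(file)
  if (!all(c("conc_M", "intensity") %in% names(d)))
    stop_invalid("quenching CSV needs columns conc_M, intensity")
  zero <- d$conc_M == 0
  if (!any(zero))
    stop_invalid("quenching CSV needs a conc_M = 0 row to define F0")
  d2 <- d[!zero, , drop = FALSE]
  d2 <- d2[order(d2$conc_M), , drop = FALSE]
  quenching_series(temperature, d2$conc_M,
                   f0 = mean(d$intensity[zero]), f = d2$intensity)
}

#' Read a spectrum CSV
#'
#' Expects columns `wavelength_nm` and `intensity` (or `ellipticity` for CD).
#'
#' @param file Path to the CSV file.
#' @param kind Spectrum kind (see [spectrum()]).
#' @param label Sample id (default the file name).
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(file, kind = "emission", label = basename(file)) {
  d <- utils::read.csv(file)
  ycol <- intersect(c("intensity", "ellipticity"), names(d))
  if (!"wavelength_nm" %in% names(d) || !length(ycol))
    stop_invalid("spectrum CSV needs columns wavelength_nm and intensity/ellipticity")
  d <- d[order(d$wavelength_nm), , drop = FALSE]
  spectrum(d$wavelength_nm, d[[ycol[1]]], kind = kind, label = label)
}

#' Read a calibration standards CSV
#'
#' Expects columns `conc_ug_ml` and `absorbance`.
#'
#' @param file Path to the CSV file.
#' @return A [fit_linear_calibration()] result.
#' @export
read_calibration_csv <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("conc_ug_ml", "absorbance") %in% names(d)))
    stop_invalid("standards CSV needs columns conc_ug_ml, absorbance")
  fit_linear_calibration(d$conc_ug_ml, d$absorbance)
}

#' Write a complete synthetic demo dataset
#'
#' Writes quenching CSVs (one per temperature), an emission spectrum CSV, a
#' CD spectrum CSV, a calibration standards CSV and a toy XYZ trajectory to
#' a directory, and returns the generating ground truth invisibly.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [gen_config()]; its temperatures, concentrations and noise
#'   level define the dataset.
#' @param ksv_true Per-temperature true Stern-Volmer constants, M^-1
#'   (default 750, 1120, 1460, matched to the worked example).
#' @return Invisibly, a list of ground-truth parameters and file paths.
#' @export
write_demo_dataset <- function(dir, cfg = gen_config(),
                               ksv_true = c(750, 1120, 1460)) {
  stopifnot(inherits(cfg, "gen_config"),
            length(ksv_true) == length(cfg$temperatures))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (i in seq_along(cfg$temperatures)) {
    cfg_i <- gen_config(cfg$seed + i, cfg$noise_sigma,
                        cfg$concentrations, cfg$temperatures)
    s <- gen_quenching_series(ksv_true[i], cfg_i,
                              temperature = cfg$temperatures[i])
    p <- file.path(dir, sprintf("quenching_%gK.csv", cfg$temperatures[i]))
    utils::write.csv(data.frame(conc_M = c(0, s$concentrations),
                                intensity = c(s$f0, s$f)),
                     p, row.names = FALSE)
    paths[[sprintf("quenching_%g", cfg$temperatures[i])]] <- p
  }
  em <- gen_spectrum(337, 20, cfg = cfg)
  p <- file.path(dir, "emission.csv")
  utils::write.csv(data.frame(wavelength_nm = em$wavelengths,
                              intensity = em$intensities), p,
                   row.names = FALSE)
  paths$emission <- p
  basis <- cd_basis()
  wts <- c(alpha_helix = 0.15, beta_sheet = 0.31, beta_turn = 0.20,
           random_coil = 0.34)
  cd <- gen_cd_spectrum(wts, basis, cfg)
  p <- file.path(dir, "cd.csv")
  utils::write.csv(data.frame(wavelength_nm = cd$wavelengths,
                              ellipticity = cd$intensities), p,
                   row.names = FALSE)
  paths$cd <- p
  conc <- seq(0, 25, by = 5)
  p <- file.path(dir, "standards.csv")
  utils::write.csv(data.frame(conc_ug_ml = conc,
                              absorbance = 0.02 * conc + 0.01), p,
                   row.names = FALSE)
  paths$standards <- p
  traj <- gen_toy_trajectory(10, 5, rigid_motion = TRUE,
                             jitter_sigma = 0.01, cfg = cfg)
  p <- file.path(dir, "trajectory.xyz")
  con <- file(p, "w")
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines("synthetic toy trajectory (Angstrom)", con)
    ## coordinates stored in Angstrom, the XYZ convention
    writeLines(sprintf("%s %.6f %.6f %.6f", fr$elements,
                       fr$coords[, 1] * 10, fr$coords[, 2] * 10,
                       fr$coords[, 3] * 10), con)
  }
  close(con)
  paths$trajectory <- p
  invisible(list(ksv_true = ksv_true, cd_weights = wts,
                 calibration = c(slope = 0.02, intercept = 0.01),
                 emission_center = 337, paths = paths))
}
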