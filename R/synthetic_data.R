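## Seeded generators for every input the pipeline consumes, with known
## ground truth, so all stages are testable without instrument data.

## Study-condition defaults: the quencher titration levels (M) and the
## incubation temperatures (K) of the motivating binding experiment.
DEFAULT_CONCENTRATIONS <- c(0, 0.760, 1.520, 2.282, 3.041, 3.802) * 1e-4
DEFAULT_TEMPERATURES <- c(293, 303, 310)

#' Generator configuration
#'
#' A single integer seed drives a named sub-stream per generator (offset
#' hashing), so the modules' random draws are decoupled but jointly
#' reproducible: the same config yields byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param noise_sigma Relative noise level (>= 0); multiplicative lognormal
#'   for fluorescence intensities, additive for spectra/absorbances.
#' @param concentrations Quencher concentrations in M (default the study's
#'   six levels, 0 to 3.802e-4 M).
#' @param temperatures Temperatures in kelvin (default 293, 303, 310).
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(seed = 1L, noise_sigma = 0,
                       concentrations = DEFAULT_CONCENTRATIONS,
                       temperatures = DEFAULT_TEMPERATURES) {
  if (!is_number(noise_sigma) || noise_sigma < 0)
    stop_invalid("noise_sigma must be >= 0")
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 concentrations = concentrations,
                 temperatures = temperatures),
            class = "gen_config")
}

## Per-generator sub-stream seed, kept inside 32-bit integer range.
substream <- function(cfg, offset) {
  as.integer((abs(as.numeric(cfg$seed)) * 97 + offset) %% 2147483647L)
}

#' Generate a Stern-Volmer-consistent quenching series
#'
#' Inverts the Stern-Volmer relation: F = F0 / (1 + Ksv \[Q\]) at the
#' config's concentrations, with multiplicative lognormal intensity noise of
#' relative magnitude `noise_sigma` applied to every measured intensity
#' (including the zero-quencher reading). A concentration of 0 in the config
#' defines the measured F0.
#'
#' @param ksv_true True Stern-Volmer constant, M^-1 (>= 0).
#' @param cfg A [gen_config()].
#' @param f0 Noise-free unquenched intensity (default 1000).
#' @param temperature Temperature tag for the series (default the config's
#'   first temperature).
#' @return A [quenching_series()].
#' @export
gen_quenching_series <- function(ksv_true, cfg = gen_config(), f0 = 1000,
                                 temperature = cfg$temperatures[1]) {
  if (!is_number(ksv_true) || ksv_true < 0)
    stop_invalid("ksv_true must be >= 0")
  stopifnot(inherits(cfg, "gen_config"))
  q <- cfg$concentrations
  withr::with_seed(substream(cfg, 11L), {
    noise <- if (cfg$noise_sigma > 0)
      exp(cfg$noise_sigma * stats::rnorm(length(q))) else rep(1, length(q))
    f_all <- f0 / (1 + ksv_true * q) * noise
  })
  nz <- q > 0
  f0_meas <- if (any(!nz)) f_all[!nz][1] else f0
  quenching_series(temperature, q[nz], f0 = f0_meas, f = f_all[nz])
}

#' Generate a Van't Hoff-consistent Ka(T) set
#'
#' Ka(T) = exp(-dH/(R T) + dS/R), with dH and dS supplied in kJ units and
#' converted to J internally (R = 8.314 J/(mol K)). Deterministic.
#'
#' @param delta_h Binding enthalpy, kJ/mol.
#' @param delta_s Binding entropy, kJ/(mol K).
#' @param temperatures Temperatures in kelvin, all > 0.
#' @return Named numeric vector of Ka (M^-1) by temperature.
#' @export
gen_vant_hoff_dataset <- function(delta_h, delta_s,
                                  temperatures = DEFAULT_TEMPERATURES) {
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_invalid("temperatures must be positive (kelvin)")
  ka <- exp(-delta_h * 1000 / (R_GAS * temperatures) +
              delta_s * 1000 / R_GAS)
  names(ka) <- as.character(temperatures)
  ka
}

#' Generate a Gaussian emission spectrum
#'
#' A Gaussian peak of the given center, width (standard deviation) and
#' amplitude on the grid, plus additive Gaussian noise with standard
#' deviation `noise_sigma * amplitude`.
#'
#' @param center Peak center, nm.
#' @param width Gaussian standard deviation, nm (> 0).
#' @param amplitude Peak height (default 100).
#' @param grid Wavelength grid, nm (default 300-450 at 1 nm).
#' @param cfg A [gen_config()].
#' @param kind Spectrum kind tag (default `"emission"`).
#' @return A [spectrum()].
#' @export
gen_spectrum <- function(center, width, amplitude = 100,
                         grid = seq(300, 450, by = 1), cfg = gen_config(),
                         kind = "emission") {
  if (!is_number(width) || width <= 0)
    stop_invalid("width must be > 0")
  stopifnot(inherits(cfg, "gen_config"))
  withr::with_seed(substream(cfg, 23L), {
    y <- amplitude * exp(-0.5 * ((grid - center) / width)^2) +
      cfg$noise_sigma * amplitude * stats::rnorm(length(grid))
  })
  spectrum(grid, y, kind = kind, label = sprintf("synthetic-%gnm", center))
}

#' Generate a CD spectrum as a basis mixture
#'
#' Weighted sum of the basis spectra plus additive Gaussian noise with
#' standard deviation `noise_sigma * max(abs(signal))`.
#'
#' @param weights Named non-negative fractions over the basis classes,
#'   summing to 1 (within 1e-6).
#' @param basis A [cd_basis()].
#' @param cfg A [gen_config()].
#' @return A [spectrum()] of kind `"cd"`.
#' @export
gen_cd_spectrum <- function(weights, basis = cd_basis(), cfg = gen_config()) {
  stopifnot(inherits(basis, "cd_basis"), inherits(cfg, "gen_config"))
  if (is.null(names(weights)) ||
      !all(names(weights) %in% names(basis$basis_spectra)))
    stop_invalid("weights must be named by basis classes")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop_invalid("weights must be non-negative and sum to 1")
  y <- Reduce(`+`, Map(function(w, k) w * basis$basis_spectra[[k]],
                       weights, names(weights)))
  withr::with_seed(substream(cfg, 37L), {
    y <- y + cfg$noise_sigma * max(abs(y)) * stats::rnorm(length(y))
  })
  spectrum(basis$wavelengths, y, kind = "cd", label = "synthetic-cd")
}

random_rotation <- function() {
  ## uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a toy trajectory
#'
#' A random base structure (Gaussian cloud, sd 0.3 nm) carried through
#' frames with optional per-frame rigid rotation+translation and per-atom
#' isotropic Gaussian jitter. With jitter alone, the expected per-atom RMSF
#' approaches `jitter_sigma * sqrt(3)` over many frames.
#'
#' @param n_atoms Number of atoms (>= 4).
#' @param n_frames Number of frames (>= 2).
#' @param rigid_motion Apply a random rigid transform per frame.
#' @param jitter_sigma Per-coordinate Gaussian jitter sd, nm.
#' @param cfg A [gen_config()].
#' @return A [trajectory()].
#' @export
gen_toy_trajectory <- function(n_atoms, n_frames, rigid_motion = FALSE,
                               jitter_sigma = 0, cfg = gen_config()) {
  if (n_atoms < 4L) stop_invalid("need at least 4 atoms")
  if (n_frames < 2L) stop_invalid("need at least 2 frames")
  if (!is_number(jitter_sigma) || jitter_sigma < 0)
    stop_invalid("jitter_sigma must be >= 0")
  stopifnot(inherits(cfg, "gen_config"))
  withr::with_seed(substream(cfg, 53L), {
    base <- matrix(stats::rnorm(n_atoms * 3, sd = 0.3), n_atoms, 3)
    elements <- sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
    frames <- lapply(seq_len(n_frames), function(i) {
      co <- base
      if (rigid_motion) {
        co <- co %*% random_rotation()
        co <- sweep(co, 2, stats::runif(3, -1, 1), `+`)
      }
      if (jitter_sigma > 0)
        co <- co + matrix(stats::rnorm(n_atoms * 3, sd = jitter_sigma),
                          n_atoms, 3)
      traj_frame(co, atom_names = paste0(elements, seq_len(n_atoms)),
                 elements = elements)
    })
  })
  trajectory(frames)
}
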