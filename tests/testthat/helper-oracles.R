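# Independent oracles used by the geometry tests. These deliberately avoid
# the package's SVD-based superposition path.

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)
rot_y <- function(b) matrix(c(cos(b), 0, sin(b),
                              0, 1, 0,
                              -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
euler_rotation <- function(a, b, c) rot_z(a) %*% rot_y(b) %*% rot_z(c)

# RMSD at a given rotation, with the optimal translation (centroid match).
rmsd_given_rotation <- function(ref, mob, R) {
  refc <- sweep(ref, 2, colMeans(ref))
  mobc <- sweep(mob, 2, colMeans(mob))
  rot <- mobc %*% t(R)
  sqrt(mean(rowSums((rot - refc)^2)))
}

# Brute-force minimal RMSD: coarse Euler-angle grid search followed by a
# Nelder-Mead polish of the best grid point (still plain RMSD evaluations).
brute_force_rmsd <- function(ref, mob, n_grid = 24) {
  alphas <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  betas <- seq(0, pi, length.out = n_grid %/% 2 + 1)
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a in alphas) for (b in betas) for (c in alphas) {
    v <- rmsd_given_rotation(ref, mob, euler_rotation(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, function(p)
    rmsd_given_rotation(ref, mob, euler_rotation(p[1], p[2], p[3])),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

# Apply a fixed rigid transform to a coordinate matrix.
rigid_transform <- function(co, a = 0.7, b = 1.1, c = -0.4,
                            shift = c(1, -2, 0.5)) {
  sweep(co %*% t(euler_rotation(a, b, c)), 2, shift, `+`)
}

# Convenience: a noiseless quenching series with known Ksv.
make_sv_series <- function(ksv, q = c(0.760, 1.520, 2.282, 3.041, 3.802) * 1e-4,
                           f0 = 1000, temperature = 293) {
  quenching_series(temperature, q, f0, f0 / (1 + ksv * q))
}
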