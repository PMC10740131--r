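test_that("Kabsch RMSD is zero for identical and rigidly moved frames", {
  set.seed(11)
  co <- matrix(rnorm(30, sd = 0.3), 10, 3)
  a <- traj_frame(co)
  expect_lt(kabsch_rmsd(a, a), 1e-12)
  b <- traj_frame(rigid_transform(co))
  expect_lt(kabsch_rmsd(a, b), 1e-10)
  expect_lt(abs(kabsch_rmsd(a, b) - kabsch_rmsd(b, a)), 1e-10)
  expect_error(kabsch_rmsd(a, traj_frame(co[1:5, ])), "atom count")
})

test_that("Kabsch RMSD matches a rotation-grid brute-force oracle", {
  ref <- matrix(c(0, 0, 0,
                  0.3, 0, 0,
                  0, 0.3, 0,
                  0, 0, 0.3), 4, 3, byrow = TRUE)
  mob <- ref
  mob[4, ] <- mob[4, ] + c(0.05, -0.03, 0.08)  # one displaced atom
  mob <- rigid_transform(mob)
  ours <- kabsch_rmsd(traj_frame(ref), traj_frame(mob))
  oracle <- brute_force_rmsd(ref, mob)
  expect_lt(abs(ours - oracle), 1e-3)
  expect_lte(ours, oracle + 1e-9)  # ours is the true minimum
})

test_that("RMSF is zero for static input and matches closed forms", {
  co <- matrix(rnorm(30, sd = 0.3), 10, 3)
  static <- trajectory(lapply(1:5, function(i) traj_frame(co)))
  expect_true(all(rmsf(static) < 1e-12))
  # two-state oscillation of one atom: RMSF = d on pre-aligned coordinates
  d <- 0.07
  frames <- lapply(1:6, function(i) {
    c2 <- co
    c2[1, 1] <- c2[1, 1] + if (i %% 2 == 0) d else -d
    traj_frame(c2)
  })
  r <- rmsf(trajectory(frames), align = FALSE)
  expect_equal(r[1], d, tolerance = 1e-12)
  expect_true(all(r[-1] < 1e-12))
  # rigid-body motion only: all ~0 after alignment
  rigid <- gen_toy_trajectory(20, 8, rigid_motion = TRUE,
                              cfg = gen_config(seed = 5))
  expect_true(all(rmsf(rigid) < 1e-10))
  expect_error(rmsf(trajectory(list(traj_frame(co)))), "2 frames")
})

test_that("jitter-only trajectories reach the Gaussian RMSF expectation", {
  sigma <- 0.02
  tr <- gen_toy_trajectory(20, 200, rigid_motion = FALSE,
                           jitter_sigma = sigma, cfg = gen_config(seed = 8))
  r <- rmsf(tr, align = FALSE)
  expect_lt(abs(mean(r) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.1)
})

test_that("SASA matches the analytic sphere and is additive when separated", {
  one <- traj_frame(matrix(0, 1, 3), elements = "O", radii = 0.15)
  s1 <- sasa(one)
  expect_lt(abs(s1$total - 4 * pi * 0.29^2) / (4 * pi * 0.29^2), 0.01)
  # coincident identical spheres expose the same surface as one
  two_same <- traj_frame(matrix(0, 2, 3), elements = c("O", "O"),
                         radii = c(0.15, 0.15))
  expect_lt(abs(sasa(two_same)$total - s1$total) / s1$total, 0.02)
  # far-apart atoms: areas add
  two_far <- traj_frame(rbind(c(0, 0, 0), c(5, 0, 0)),
                        elements = c("O", "O"), radii = c(0.15, 0.15))
  expect_lt(abs(sasa(two_far)$total - 2 * s1$total) / (2 * s1$total), 0.01)
})

test_that("SASA splits by atom class and is rigid-transform invariant", {
  set.seed(21)
  co <- matrix(rnorm(30, sd = 0.25), 10, 3)
  fr <- traj_frame(co, elements = rep(c("C", "O"), 5))
  s <- sasa(fr)
  expect_equal(s$total, s$hydrophobic + s$hydrophilic, tolerance = 1e-9)
  expect_equal(s$total, sum(s$per_atom), tolerance = 1e-12)
  fr2 <- traj_frame(rigid_transform(co), elements = rep(c("C", "O"), 5))
  expect_equal(sasa(fr2)$total, s$total, tolerance = 0.01 * s$total)
})

test_that("SASA quadrature converges in the test-point count", {
  for (seed in 1:3) {
    set.seed(seed)
    co <- matrix(rnorm(30, sd = 0.2), 10, 3)
    fr <- traj_frame(co, elements = sample(c("C", "N", "O"), 10, TRUE))
    a <- sasa(fr, n_points = 960)$total
    b <- sasa(fr, n_points = 3840)$total
    expect_lt(abs(a - b) / b, 0.01)
  }
})

test_that("hydrogen bonds obey the distance and angle criterion", {
  # idealized linear O-H...O at 0.28 nm O-O separation
  lin <- traj_frame(rbind(c(0, 0, 0), c(0.096, 0, 0), c(0.28, 0, 0)),
                    atom_names = c("O1", "H1", "O2"),
                    elements = c("O", "H", "O"))
  expect_identical(count_hbonds(lin), 1L)
  # same pair stretched past the distance cutoff
  far <- traj_frame(rbind(c(0, 0, 0), c(0.096, 0, 0), c(0.40, 0, 0)),
                    elements = c("O", "H", "O"))
  expect_identical(count_hbonds(far), 0L)
  # acceptor swung to 45 degrees off the O-H axis
  ang <- traj_frame(rbind(c(0, 0, 0), c(0.096, 0, 0),
                          0.28 * c(cos(pi / 4), sin(pi / 4), 0)),
                    elements = c("O", "H", "O"))
  expect_identical(count_hbonds(ang), 0L)
  # rigid-transform invariance of the count
  lin2 <- traj_frame(rigid_transform(lin$coords), elements = c("O", "H", "O"))
  expect_identical(count_hbonds(lin2), 1L)
  # no flagged donors/acceptors: zero with a warning
  none <- traj_frame(matrix(rnorm(12), 4, 3), elements = rep("C", 4))
  expect_warning(n0 <- count_hbonds(none), "no flagged")
  expect_identical(n0, 0L)
})

test_that("Kabsch agrees with an established superposition routine", {
  set.seed(31)
  ref <- matrix(rnorm(36, sd = 0.4), 12, 3)
  mob <- rigid_transform(ref + matrix(rnorm(36, sd = 0.03), 12, 3))
  ours <- kabsch_rmsd(traj_frame(ref), traj_frame(mob))
  # bio3d works in Angstrom and rounds RMSD to 3 decimals; compare there
  refA <- as.vector(t(ref * 10))
  mobA <- matrix(as.vector(t(mob * 10)), 1)
  fitted <- bio3d::fit.xyz(refA, mobA, fixed.inds = seq_along(refA),
                           mobile.inds = seq_along(refA))
  theirs <- bio3d::rmsd(refA, fitted)
  expect_lt(abs(ours * 10 - theirs), 2e-3)
})
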