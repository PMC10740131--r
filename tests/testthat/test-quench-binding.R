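test_that("quenching_series validates its invariants", {
  q <- c(1, 2, 3) * 1e-4
  expect_s3_class(quenching_series(293, q, 1000, c(900, 800, 700)),
                  "quenching_series")
  expect_error(quenching_series(293, rev(q), 1000, c(900, 800, 700)),
               "strictly increasing")
  expect_error(quenching_series(293, q, 1000, c(900, 800)), "same length")
  expect_error(quenching_series(293, q, -1, c(900, 800, 700)), "f0")
  expect_error(quenching_series(293, q, 1000, c(900, 0, 700)), "positive")
})

test_that("Stern-Volmer fit recovers the slope on exact data", {
  q <- c(1, 2, 3) * 1e-4
  s <- quenching_series(293, q, 1000, 1000 / (1 + 1000 * q))
  fit <- fit_stern_volmer(s, tau0 = 1e-8)
  expect_equal(fit$ksv, 1000, tolerance = 1e-9)
  expect_equal(fit$kq, 1e11, tolerance = 1e-9)
  expect_identical(fit$kq * fit$tau0, fit$ksv)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # anchored variant on the same exact data gives the same slope
  fit_a <- fit_stern_volmer(s, tau0 = 1e-8, anchored = TRUE)
  expect_equal(fit_a$ksv, 1000, tolerance = 1e-9)
  expect_identical(fit_a$intercept, 1)
})

test_that("no quenching gives Ksv = 0 and too-few points error out", {
  q <- c(1, 2, 3) * 1e-4
  s_flat <- quenching_series(293, q, 1000, rep(1000, 3))
  expect_equal(fit_stern_volmer(s_flat)$ksv, 0, tolerance = 1e-12)
  s2 <- quenching_series(293, q[1:2], 1000, c(900, 800))
  expect_error(fit_stern_volmer(s2), "at least 3")
  expect_error(fit_stern_volmer(make_sv_series(1000), tau0 = -1), "tau0")
})

test_that("Stern-Volmer round trip holds for arbitrary Ksv and tau0", {
  for (ksv in c(10, 750, 1460, 5e4)) {
    for (tau0 in c(1e-9, 1e-8, 1)) {
      s <- make_sv_series(ksv)
      fit <- fit_stern_volmer(s, tau0 = tau0)
      expect_lt(abs(fit$ksv - ksv) / ksv, 1e-9)
      expect_identical(fit$kq * tau0, fit$ksv)
    }
  }
})

test_that("double-log fit inverts its generating identity", {
  q <- c(1, 2, 3) * 1e-4
  # (F0-F)/F = Ka [Q]  =>  n = 1
  s1 <- quenching_series(293, q, 1000, 1000 / (1 + 100 * q))
  fit1 <- fit_double_log(s1)
  expect_equal(fit1$ka, 100, tolerance = 1e-9)
  expect_equal(fit1$n, 1, tolerance = 1e-9)
  # (F0-F)/F = Ka [Q]^2  =>  n = 2
  s2 <- quenching_series(293, q, 1000, 1000 / (1 + 1e4 * q^2))
  fit2 <- fit_double_log(s2)
  expect_equal(fit2$ka, 1e4, tolerance = 1e-9)
  expect_equal(fit2$n, 2, tolerance = 1e-9)
})

test_that("double-log rejects unquenched points and errors when too few remain", {
  q <- c(1, 2, 3, 4) * 1e-4
  f <- c(1000, 900, 800, 700)  # first point has F == F0
  s <- quenching_series(293, q, 1000, f)
  expect_warning(fit <- fit_double_log(s), "F >= F0")
  expect_identical(fit$n_points_used, 3L)
  s_flat <- quenching_series(293, q, 1000, rep(1000, 4))
  expect_error(suppressWarnings(fit_double_log(s_flat)), "at least 3")
})

test_that("Van't Hoff fit inverts the generating thermodynamics", {
  temps <- c(293, 303, 310)
  ka <- gen_vant_hoff_dataset(-50, -0.1, temps)
  fit <- fit_vant_hoff(temps, ka)
  expect_equal(fit$delta_h, -50, tolerance = 1e-9)
  expect_equal(fit$delta_s, -0.1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # identical Ka at two temperatures: flat line, zero enthalpy
  expect_equal(fit_vant_hoff(c(293, 310), c(500, 500))$delta_h, 0,
               tolerance = 1e-12)
  # Ka rising with 1/T (falling with T) means exothermic binding
  x <- 1 / c(293, 303, 310)
  ka_up <- 2^((x - min(x)) / diff(range(x)))
  expect_lt(fit_vant_hoff(c(293, 303, 310), ka_up)$delta_h, 0)
  expect_error(fit_vant_hoff(c(293, 293), c(1, 2)), "distinct")
  expect_error(fit_vant_hoff(c(293, 310), c(-1, 2)), "positive")
})

test_that("Gibbs energy is the exact linear combination dH - T dS", {
  dg <- compute_gibbs(-164.076, -0.501, c(293, 303, 310))
  expect_equal(unname(dg), c(-17.283, -12.273, -8.766), tolerance = 1e-9)
  expect_identical(unname(compute_gibbs(0, 0, 298)), 0)
  # linearity in dH and dS; temperature differences isolate -dS
  dh <- -20; ds <- 0.05; temps <- c(280, 300, 320)
  g <- compute_gibbs(dh, ds, temps)
  expect_equal(unname(compute_gibbs(2 * dh, ds, temps) - g), rep(dh, 3))
  expect_equal(unname(g[1] - g[2]), -(280 - 300) * ds)
  expect_error(compute_gibbs(-20, 0.05, c(300, -1)), "positive")
})

test_that("quenching mechanism classification follows trend and diffusion limit", {
  fits <- lapply(seq_along(c(293, 303, 310)), function(i)
    fit_stern_volmer(make_sv_series(c(750, 1120, 1460)[i],
                                    temperature = c(293, 303, 310)[i]),
                     tau0 = 1e-8))
  call <- classify_quenching(fits)
  expect_identical(call$label, "combined")
  expect_identical(call$ksv_trend, "increasing")
  expect_true(call$kq_exceeds_diffusion_limit)
  # slow lifetime pushes Kq below the diffusion limit: dynamic only
  fits_slow <- lapply(fits, function(f) { f$kq <- f$ksv / 1; f$tau0 <- 1; f })
  call2 <- classify_quenching(fits_slow)
  expect_false(call2$kq_exceeds_diffusion_limit)
  expect_identical(call2$label, "dynamic")
  # decreasing Ksv below the limit is indeterminate
  f1 <- fit_stern_volmer(make_sv_series(2000, temperature = 293), tau0 = 1)
  f2 <- fit_stern_volmer(make_sv_series(1000, temperature = 310), tau0 = 1)
  expect_identical(classify_quenching(list(f1, f2))$label, "indeterminate")
  # decreasing Ksv above the limit indicates a ground-state complex
  f1b <- fit_stern_volmer(make_sv_series(2000, temperature = 293), tau0 = 1e-8)
  f2b <- fit_stern_volmer(make_sv_series(1000, temperature = 310), tau0 = 1e-8)
  expect_identical(classify_quenching(list(f1b, f2b))$label, "static")
  # equal Ksv at all temperatures is a flat trend
  fe <- lapply(c(293, 310), function(t)
    fit_stern_volmer(make_sv_series(1000, temperature = t)))
  expect_identical(classify_quenching(fe)$ksv_trend, "flat")
  expect_error(classify_quenching(fits[1]), ">= 2")
})

test_that("driving-force classification follows the sign rules", {
  expect_identical(classify_forces(-164.076, -0.501), "hydrogen_bond_vdw")
  expect_identical(classify_forces(30, 0.2), "hydrophobic")
  expect_identical(classify_forces(0.0, 0.1), "electrostatic")
  expect_identical(classify_forces(-30, 0.2), "electrostatic")
  expect_identical(classify_forces(0.9, 0.2), "electrostatic")  # |dH| <= tol
})

test_that("binding_thermodynamics bundles Van't Hoff, Gibbs and force label", {
  temps <- c(293, 303, 310)
  ka <- gen_vant_hoff_dataset(-164.076, -0.501, temps)
  th <- binding_thermodynamics(temps, ka)
  expect_equal(th$delta_h, -164.076, tolerance = 1e-9)
  expect_equal(th$delta_s, -0.501, tolerance = 1e-9)
  expect_equal(unname(th$delta_g_by_temperature),
               th$delta_h - temps * th$delta_s, tolerance = 1e-12)
  expect_identical(th$force_label, "hydrogen_bond_vdw")
  expect_identical(th$r_gas, 8.314)
})

test_that("noisy Stern-Volmer recovery: median error under 5% at 1% noise", {
  errs <- vapply(seq_len(200), function(i) {
    cfg <- gen_config(seed = 1000 + i, noise_sigma = 0.01)
    s <- gen_quenching_series(1000, cfg)
    abs(fit_stern_volmer(s)$ksv - 1000) / 1000
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
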