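test_that("inlet core radius follows the size-exclusion geometry", {
  expect_equal(inlet_core_radius(30, 1.2), 0.92)
  expect_equal(inlet_core_radius(100, 0), 1)
  expect_error(inlet_core_radius(2.4, 1.2), "exceed")
  expect_error(inlet_core_radius(2.0, 1.2), "exceed")
})

test_that("annulus viscosity interpolates between plasma and core", {
  expect_equal(annulus_viscosity(3.3, 0), 1)       # Haynes cell-free layer
  expect_equal(annulus_viscosity(3.3, 1), 3.3)     # homogeneous suspension
  expect_equal(annulus_viscosity(3.3, 0.1), 1.23)
  expect_error(annulus_viscosity(0.9, 0.1), "eta_c")
  expect_error(annulus_viscosity(3.3, 1.2), "alpha")
})

test_that("closed-form core radius matches its degenerate reductions", {
  expect_equal(core_radius_closed_form(1, 3.3, 1.23), 1)
  s0 <- c(0.3, 0.7, 0.95)
  expect_equal(core_radius_closed_form(s0, 2.5, 2.5),
               s0 / sqrt(1 + sqrt(1 - s0^2)))
  expect_equal(core_radius_closed_form(0.92, 2.05, 1.105),
               REF$s_inf_example, tolerance = 1e-10)
})

test_that("closed-form and bisection core radii agree on random valid inputs", {
  tr <- random_triples(1000)
  eta_A <- annulus_viscosity(tr$eta_c, tr$alpha)
  cf <- core_radius_closed_form(tr$s0, tr$eta_c, eta_A)
  num <- core_radius_numeric(tr$s0, tr$eta_c, eta_A)
  expect_lt(max(abs(cf - num)), 1e-10)
  expect_true(all(cf > 0 & cf <= tr$s0))
})

test_that("velocity profile is no-slip, continuous, monotone and flux-normalized", {
  v <- velocity_profile(0.7, 3.3, 1.23)
  expect_equal(v(1), 0)
  eps <- 1e-9
  expect_equal(v(0.7 - eps), v(0.7 + eps), tolerance = 1e-6)
  r <- seq(0.001, 1, length.out = 400)
  expect_true(all(diff(v(r)) < 0))
  expect_equal(profile_flux(v, 0, 1), 1, tolerance = 1e-9)
  expect_error(v(1.5), "\\[0, 1\\]")
  # homogeneous limit: plain Poiseuille 2(1 - r^2)
  vh <- velocity_profile(0.5, 2.5, 2.5)
  expect_equal(vh(r), 2 * (1 - r^2), tolerance = 1e-12)
})

test_that("mass conservation ties the asymptotic profile to the inlet core flux", {
  tr <- random_triples(25, seed = 7)
  for (i in seq_len(nrow(tr))) {
    eta_A <- annulus_viscosity(tr$eta_c[i], tr$alpha[i])
    s_inf <- core_radius_closed_form(tr$s0[i], tr$eta_c[i], eta_A)
    v <- velocity_profile(s_inf, tr$eta_c[i], eta_A)
    expect_equal(profile_flux(v, 0, 1), 1, tolerance = 1e-9)
    expect_equal(profile_flux(v, 0, s_inf), tr$s0[i]^2, tolerance = 1e-9)
  }
})

test_that("apparent viscosity spans [eta_A, eta_c] and matches the example", {
  expect_equal(apparent_relative_viscosity(1, 3.3, 1.23), 3.3)
  expect_equal(apparent_relative_viscosity(0, 3.3, 1.23), 1.23)
  expect_equal(apparent_relative_viscosity(REF$s_inf_example, 2.05, 1.105),
               REF$eta_app_example, tolerance = 1e-10)
  s <- seq(0.05, 0.95, by = 0.1)
  eta <- apparent_relative_viscosity(s, 3.3, 1.23)
  expect_true(all(eta > 1.23 & eta < 3.3))
  expect_true(all(diff(eta) > 0))  # more core, more resistance
})

test_that("quadrature-based two-fluid Poiseuille oracle confirms the discharge formula", {
  # homogeneous fluid: the oracle must return the common viscosity
  expect_equal(apparent_viscosity_poiseuille_oracle(0.6, 2.5, 2.5), 2.5,
               tolerance = 1e-9)
  cases <- rbind(c(REF$s_inf_example, 2.05, 1.105), c(0.5, 3.3, 1.23))
  tr <- random_triples(40, seed = 11)
  eta_A <- annulus_viscosity(tr$eta_c, tr$alpha)
  s_inf <- core_radius_closed_form(tr$s0, tr$eta_c, eta_A)
  cases <- rbind(cases, cbind(s_inf, tr$eta_c, eta_A))
  for (i in seq_len(nrow(cases))) {
    direct <- apparent_relative_viscosity(cases[i, 1], cases[i, 2], cases[i, 3])
    oracle <- apparent_viscosity_poiseuille_oracle(cases[i, 1], cases[i, 2],
                                                   cases[i, 3])
    expect_lt(abs(direct - oracle) / direct, 1e-8)
  }
})

test_that("predict_vessel composes the chain and reports dimensional output", {
  p <- model_params(eta_c = 1.18, alpha = 0.1, a_star_um = 1.2)
  sol <- predict_vessel(30, p)
  expect_s3_class(sol, "fl_solution")
  expect_equal(sol$s0, 0.92)
  expect_equal(sol$eta_A, 1.018)
  expect_equal(sol$s_inf, core_radius_closed_form(0.92, 1.18, 1.018))
  expect_equal(sol$s_inf, core_radius_numeric(0.92, 1.18, 1.018),
               tolerance = 1e-10)
  expect_equal(sol$layer_thickness_um, 15 * (1 - sol$s_inf))
  expect_equal(sol$layer_thickness_um, 3.2, tolerance = 0.05)
  # ordering and the thicker-than-inlet-gap property
  expect_true(sol$eta_A < sol$eta_app && sol$eta_app < p$eta_c)
  expect_gt(sol$layer_thickness_um, p$a_star_um)
  # dimensional route
  pd <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2,
                     eta_p_mPas = 1.2)
  sd_ <- predict_vessel(100, pd)
  expect_equal(sd_$eta_app_mPas, sd_$eta_app * 1.2)
})

test_that("predict_vessel warns below the continuum threshold but errors on impossible geometry", {
  p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
  expect_warning(predict_vessel(10, p), "continuum")
  expect_silent(predict_vessel(100, p))
  expect_error(suppressWarnings(predict_vessel(2, p)), "exceed")
})

test_that("structural limits: alpha extremes and the wide-vessel asymptote", {
  # alpha = 1 collapses to homogeneous flow at every diameter
  p1 <- model_params(eta_c = 3.3, alpha = 1, a_star_um = 1.2)
  for (D in c(5, 30, 300)) {
    sol <- suppressWarnings(predict_vessel(D, p1))
    expect_equal(sol$eta_app, 3.3)
  }
  # alpha = 0 is the cell-free marginal layer
  p0 <- model_params(eta_c = 3.3, alpha = 0, a_star_um = 1.2)
  expect_equal(predict_vessel(100, p0)$eta_A, 1)
  # wide-vessel limit recovers the bulk viscosity; the deficit decays like
  # sqrt(a*/D), so a very large diameter is needed for tight agreement
  p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
  deficit <- vapply(10^(4:8), function(D)
    3.3 - predict_vessel(D, p)$eta_app, numeric(1))
  expect_true(all(diff(deficit) < 0) && all(deficit > 0))
  expect_equal(deficit[-1] / deficit[-5], rep(10^-0.5, 4), tolerance = 0.02)
  expect_equal(predict_vessel(1e11, p)$eta_app, 3.3, tolerance = 1e-4)
})

test_that("viscosity curves increase with diameter and preserve input order", {
  p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
  d <- exp(seq(log(35), log(2000), length.out = 40))
  cur <- viscosity_curve(d, p)
  expect_true(all(diff(cur$eta_app_rel) > 0))
  expect_true(all(diff(cur$layer_thickness_um) > 0))
  # single point agrees with predict_vessel
  expect_equal(cur$eta_app_rel[1], predict_vessel(d[1], p)$eta_app)
  # reversed grid: same values, order preserved
  rev_cur <- viscosity_curve(rev(d), p)
  expect_equal(rev_cur$eta_app_rel, rev(cur$eta_app_rel))
  expect_equal(rev_cur$diameter_um, rev(d))
  expect_error(viscosity_curve(c(100, 2, 50), p), "position 2")
})

test_that("marginal layer thins as the core viscosity rises", {
  thick <- vapply(c(1.2, 1.6, 2.05, 3.3, 6), function(ec)
    predict_vessel(60, model_params(eta_c = ec, alpha = 0.1,
                                    a_star_um = 1.2))$layer_thickness_um,
    numeric(1))
  expect_true(all(diff(thick) < 0))
})

test_that("model_params validates and routes hematocrit through Charm-Kurland", {
  p <- model_params(phi = 0.45, alpha = 0.1, a_star_um = 1.2)
  expect_equal(p$eta_c, charm_kurland_relative_viscosity(0.45))
  expect_identical(p$eta_c_source, "phi")
  expect_error(model_params(alpha = 0.1, a_star_um = 1.2), "exactly one")
  expect_error(model_params(eta_c = 3.3, phi = 0.4, alpha = 0.1,
                            a_star_um = 1.2), "exactly one")
  expect_error(model_params(eta_c = 0.9, alpha = 0.1, a_star_um = 1.2),
               "eta_c")
  expect_error(model_params(eta_c = 3.3, alpha = -0.1, a_star_um = 1.2),
               "alpha")
  expect_error(model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 0),
               "a_star_um")
})
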