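test_that("relative viscosity is the calibrated efflux-time ratio", {
  expect_equal(relative_viscosity(100, 100, 0.004, 0.004), 1.0)
  expect_equal(relative_viscosity(110, 100), 1.1)
  expect_equal(relative_viscosity(105, 100, 0.004, 0.008), 0.525)
  expect_error(relative_viscosity(-1, 100), "positive")
  expect_error(relative_viscosity(100, 0), "positive")
  s <- titration_series(c(30, 60, 90, 120), c(102, 105, 109, 114),
                        "efflux_time", temperature = 20)
  rel <- efflux_to_relative(s, efflux_solvent = 100)
  expect_identical(response_kind(rel), "relative_viscosity")
  expect_equal(rel$response, c(1.02, 1.05, 1.09, 1.14))
})

test_that("the virial fit inverts the noiseless forward model exactly", {
  p <- noiseless_params()
  s <- gen_viscosity(p, seed = NULL)
  fit <- fit_virial(s, cmc = 26.5, nu = 2.97)
  expect_equal(fit$v_shyd, 0.710, tolerance = 1e-6)
  expect_equal(fit$k1, 1.0, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$intercept, 1)
})

test_that("forward-then-fit is self-inverse over a broad parameter range", {
  withr::local_seed(17)
  for (i in 1:20) {
    p <- noiseless_params(cmc = runif(1, 5, 40), nu = runif(1, 2.5, 6),
                          v_shyd = runif(1, 0.3, 2.5), k1 = runif(1, 0.2, 3))
    s <- gen_viscosity(p, concentrations = seq(ceiling(p$cmc) + 5, 200, 15),
                       seed = NULL)
    fit <- fit_virial(s, cmc = p$cmc, nu = p$nu)
    expect_equal(fit$v_shyd, p$v_shyd, tolerance = 1e-6)
    expect_equal(fit$k1, p$k1, tolerance = 1e-4)
  }
})

test_that("flat and nonphysical viscosity curves are flagged", {
  flat <- titration_series(seq(30, 100, 10), rep(1, 8), "relative_viscosity",
                           temperature = 20)
  fit <- fit_virial(flat, cmc = 26.5)
  expect_equal(fit$p1, 0)
  expect_equal(fit$p2, 0)
  expect_true("no micellar contribution" %in% fit$flags)

  falling <- titration_series(seq(30, 100, 10),
                              1 - 0.001 * (seq(30, 100, 10) - 26.5),
                              "relative_viscosity", temperature = 20)
  expect_true(any(grepl("nonphysical", fit_virial(falling, cmc = 26.5)$flags)))

  few <- titration_series(c(30, 40, 50), c(1.01, 1.02, 1.03),
                          "relative_viscosity", temperature = 20)
  expect_error(fit_virial(few, cmc = 26.5), ">= 4")
})

test_that("shape factors: sphere limit, long-rod branch, and inversion", {
  sph <- shape_factor(1)
  expect_identical(sph$nu, 2.5)
  expect_equal(sph$j, 1)
  expect_identical(sph$regime, "sphere")

  # long-rod branch against independently written arithmetic at J = 20
  oracle_j20 <- 1.6 + (400 / 15) * (1 / (log(40) - 1.5) + 3 / (log(40) - 0.5))
  expect_equal(shape_factor_from_j(20), oracle_j20, tolerance = 1e-12)

  # nu = 2.97 corresponds to J = 2.10: root find vs closed-form inversion
  inv <- invert_shape_factor(2.97)
  closed <- 1 + ((2.97 - 2.5) / 0.407)^(1 / 1.508)
  expect_lt(abs(inv$j - 2.10), 0.01)
  expect_equal(inv$j, closed, tolerance = 1e-8)
  expect_equal(shape_factor(inv$axial_ratio)$nu, 2.97, tolerance = 1e-6)

  expect_error(shape_factor(0.9), ">= 1")
})

test_that("the shape factor is continuous at the sphere limit and increasing", {
  expect_equal(shape_factor(1 + 1e-9)$nu, 2.5, tolerance = 1e-6)
  ratios <- seq(1, 50, length.out = 120)
  nus <- vapply(ratios, function(r) shape_factor(r)$nu, numeric(1))
  expect_true(all(diff(nus) > 0))
})

test_that("hydration bookkeeping reproduces the solvation counts", {
  # APFO in plain water: 0.710 - 0.376 = 0.334 nm^3 of water -> 11 molecules
  b <- hydration_budget(0.710, apfo_spec(), solvent_spec())
  expect_equal(b$n_water, 11)
  expect_equal(b$v_water_total, 0.334)
  expect_equal(b$n_cosolvent, 0)

  # cylindrical case via the printed urea-volume intermediate (0.064 nm^3)
  bI <- hydration_budget(0.376 + 0.334 + 0.064, apfo_spec(), urea_solvent(4),
                         v_water_total_reference = 0.334,
                         scenario = "case_I_cylindrical")
  expect_equal(bI$v_cosolvent_total, 0.064)
  expect_equal(bI$n_cosolvent, 0.9)

  # spherical case: Vshyd 0.910 -> 0.200 nm^3 of urea -> 2.7 molecules
  bII <- hydration_budget(0.910, apfo_spec(), urea_solvent(4),
                          v_water_total_reference = 0.334,
                          scenario = "case_II_spherical")
  expect_equal(bII$v_cosolvent_total, 0.200)
  expect_equal(bII$n_cosolvent, 2.7)

  # SDS in 4 M urea: 2.240 - 0.410 - 1.200 = 0.630 nm^3 -> 8.4 ureas
  bS <- hydration_budget(2.240, sds_spec(), urea_solvent(4),
                         v_water_total_reference = 1.200)
  expect_equal(bS$v_cosolvent_total, 0.630)
  expect_equal(bS$n_cosolvent, 8.4)
})

test_that("the volume budget is conserved and dehydration is flagged", {
  withr::local_seed(3)
  for (i in 1:20) {
    v_mol <- runif(1, 0.2, 0.6)
    spec <- surfactant_spec("x", 7, "fluorocarbon", v_mol)
    ref <- runif(1, 0, 0.5)
    v_shyd <- v_mol + ref + runif(1, 0, 0.5)
    b <- hydration_budget(v_shyd, spec, solvent_spec(),
                          v_water_total_reference = ref)
    expect_equal(b$v_molecule + b$v_water_total + b$v_cosolvent_total,
                 v_shyd, tolerance = 1e-12)
  }
  spec <- apfo_spec()
  expect_warning(
    b <- hydration_budget(0.60, spec, urea_solvent(4),
                          v_water_total_reference = 0.334),
    "floored")
  expect_true("dehydration relative to reference" %in% b$flags)
  expect_equal(b$n_cosolvent, 0)
  expect_error(hydration_budget(0.2, spec, solvent_spec()), "molecular volume")
})

test_that("case I vs case II Vshyd scale exactly as the shape-factor ratio", {
  s <- gen_viscosity(truth_params(seed = 31))
  fI <- fit_virial(s, cmc = 26.5, nu = 2.97)
  fII <- fit_virial(s, cmc = 26.5, nu = 2.5)
  expect_equal(fI$v_shyd / fII$v_shyd, 2.5 / 2.97, tolerance = 1e-12)
})
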