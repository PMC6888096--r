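test_that("CSV titrations parse, sort, and average duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("conc_mM,kappa\n10,600\n20,1150\n30,1500", f)
  s <- read_titration(f, "conductivity")
  expect_s3_class(s, "titration_series")
  expect_equal(s$concentration, c(10, 20, 30))
  expect_equal(s$response, c(600, 1150, 1500))
  expect_identical(response_kind(s), "conductivity")

  # shuffled rows give the identical series
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("conc_mM,kappa\n30,1500\n10,600\n20,1150", f2)
  expect_equal(read_titration(f2, "conductivity"), s)

  # duplicate concentrations averaged with a warning
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("conc_mM,kappa\n10,600\n10,620\n20,1150", f3)
  expect_warning(s3 <- read_titration(f3, "conductivity"), "duplicate")
  expect_equal(s3$concentration, c(10, 20))
  expect_equal(s3$response, c(610, 1150))

  # comment lines ignored; non-numeric cells are named by row
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines("# simulated\nconc_mM,kappa\n10,600\n20,abc\n30,1500", f4)
  expect_error(read_titration(f4, "conductivity"), "row 2")
})

test_that("titration series invariants are enforced", {
  expect_error(titration_series(1:6, c(1, 2, 3, 4, 5, Inf)), "finite")
  expect_error(titration_series(1:3, 1:2), "equal length")
  expect_error(titration_series(5, 1), "at least 2")
  expect_error(titration_series(1:6, 1:6, temperature = 100), "\\[0, 100\\)")
  expect_error(titration_series(1:6, 1:6, temperature = -1), "\\[0, 100\\)")
})

test_that("unit conversions round-trip to 1 part in 1e12", {
  withr::local_seed(11)
  t <- runif(50, -200, 90)
  expect_lt(max(abs(kelvin_to_celsius(celsius_to_kelvin(t)) - t)), 1e-12)
  c_mm <- 10^runif(50, -3, 3)
  expect_lt(max(abs(molar_to_mm(mm_to_molar(c_mm)) / c_mm - 1)), 1e-12)
  expect_equal(celsius_to_kelvin(24), 297.15)
  expect_equal(celsius_to_kelvin(0), 273.15)
  expect_error(celsius_to_kelvin(-274), "absolute zero")
})

test_that("surfactant and solvent specs validate and derive the prefactor", {
  a <- apfo_spec()
  expect_equal(a$tail_volume, 333.6)
  expect_equal(a$tail_length, 11.14)
  expect_equal(a$n_prefactor, 2L)
  expect_equal(a$molecular_volume, 0.376)
  expect_equal(sds_spec()$molecular_volume, 0.410)
  expect_error(surfactant_spec("x", 0, "fluorocarbon", 0.3), "positive integer")
  expect_error(surfactant_spec("x", 7, "fluorocarbon", -1), "molecular_volume")
  expect_error(surfactant_spec("x", 7, "fluorocarbon", 0.3, c(0, 1)), "nonzero")
  expect_error(surfactant_spec("x", 12, "hydrocarbon", 0.41), "explicit")
  expect_error(solvent_spec("urea", -1), "molarity")
  expect_equal(urea_solvent(4)$cosolvent_molecular_volume, 0.075)
})

test_that("an empty or incomplete report config errors with the required keys", {
  expect_error(run_report(list()), "surfactant")
  expect_error(run_report(list(surfactant = "apfo")), "inputs")
})

test_that("a conductivity-only config yields a partial report with absent stages", {
  dir <- withr::local_tempdir()
  p <- truth_params(seed = 7)
  gen_bundle(p, seed = 7, dir = dir)
  rep <- run_report(list(surfactant = "apfo",
                         inputs = list(conductivity = file.path(dir, "conductivity.csv"))))
  expect_identical(rep$conductivity$status, "ok")
  expect_identical(rep$tension$status, "absent")
  expect_identical(rep$viscosity$status, "absent")
  expect_lt(abs(rep$conductivity$cmc_mM - 26.5), 2)
})

test_that("a full synthetic bundle round-trips to the generator truth", {
  dir <- withr::local_tempdir()
  p <- truth_params(seed = 42)
  gen_bundle(p, seed = 42, dir = dir)
  rep <- run_report(list(
    surfactant = "apfo", nu = 2.97,
    inputs = list(conductivity = file.path(dir, "conductivity.csv"),
                  tension = file.path(dir, "tension.csv"),
                  fluorescence = file.path(dir, "pyrene_ratios.csv"),
                  viscosity = file.path(dir, "viscosity.csv"))))
  expect_identical(rep$conductivity$status, "ok")
  expect_lt(abs(rep$conductivity$cmc_mM - 26.5), 1.5)
  expect_lt(abs(rep$conductivity$alpha - 0.47), 0.05)
  expect_lt(abs(rep$tension$slope_mN_m_decade - (-29.6)), 1.5)
  expect_lt(abs(rep$tension$a_min_A2 - 63.84), 3)
  expect_identical(rep$tension$packing$shape_class, "cylinder")
  expect_identical(rep$fluorescence$status, "ok")
  expect_lt(abs(rep$viscosity$v_shyd_nm3 - 0.710), 0.05)
  expect_lt(abs(rep$viscosity$hydration$n_water - 11), 2)
})

test_that("report serialization is canonical: write-read-write is byte-identical", {
  dir <- withr::local_tempdir()
  gen_bundle(truth_params(seed = 3), seed = 3, dir = dir)
  rep <- run_report(list(surfactant = "apfo", nu = 2.97,
                         inputs = list(conductivity = file.path(dir, "conductivity.csv"),
                                       viscosity = file.path(dir, "viscosity.csv"))))
  f1 <- file.path(dir, "r1.json"); f2 <- file.path(dir, "r2.json")
  write_report(rep, f1)
  write_report(read_report(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("titration CSV writer round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- gen_viscosity(truth_params(seed = 5))
  write_titration(s, f, header_comment = "seed 5")
  s2 <- read_titration(f, "relative_viscosity", temperature = 20)
  expect_equal(s2$concentration, s$concentration)
  expect_equal(s2$response, s$response, tolerance = 1e-10)
})
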