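# Spectrum container, overlap densities and emission approximation.

test_that("spectrum construction enforces its invariants", {
  expect_s3_class(spectrum_new(1:5, rep(1, 5)), "pn_spectrum")
  expect_error(spectrum_new(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(spectrum_new(1:3, c(1, -1, 1)), "non-negative")
  expect_error(spectrum_new(1, 1), "length")
})

test_that("resample interpolates linearly, preserves endpoints, rejects extrapolation", {
  s <- spectrum_new(c(400, 500), c(0, 1))
  expect_equal(resample(s, 450)$values, 0.5)
  expect_equal(resample(s, s$grid)$values, s$values)
  expect_error(resample(s, c(300, 450)), "outside")
})

test_that("wavelength to wavenumber conversion is the 1e7/lambda map", {
  s <- spectrum_new(c(400, 500, 600), c(1, 2, 1))
  w <- to_wavenumber(s)
  expect_true(all(diff(w$grid) > 0))
  expect_true(20000 %in% w$grid)  # 500 nm
  # jacobian off leaves values untouched (shape-only)
  expect_setequal(w$values, s$values)
})

test_that("jacobian conversion conserves integrals within 0.1%", {
  lam <- seq(500, 700, 1)
  s <- spectrum_new(lam, exp(-(lam - 600)^2 / 800), "wavelength_nm")
  a_nm <- spectrum_area(s)
  a_wn <- spectrum_area(to_wavenumber(s, jacobian = TRUE)) /
    # density per cm^-1 integrates to the same total as density per nm
    1
  expect_equal(a_wn, a_nm, tolerance = 1e-3)
})

test_that("normalize_area yields unit area and is idempotent", {
  s <- spectrum_new(c(0, 10), c(2, 2))
  n1 <- normalize_area(s)
  expect_equal(spectrum_area(n1), 1, tolerance = 1e-9)
  expect_equal(max(n1$values), 0.1, tolerance = 1e-12)
  n2 <- normalize_area(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
  expect_error(normalize_area(spectrum_new(1:3, rep(0, 3))), "zero area")
})

test_that("identical Gaussians self-overlap at the closed form 1/(2 sigma sqrt(pi))", {
  sigma <- 300
  g <- make_gaussian_band(660, sigma)
  expect_equal(density_of_states(g, g), 1 / (2 * sigma * sqrt(pi)),
               tolerance = 5e-3)
})

test_that("well-separated Gaussians have vanishing overlap", {
  a <- make_gaussian_band(1e7 / 20000, 300)   # 20000 cm^-1
  b <- make_gaussian_band(1e7 / 23000, 300)   # 10 sigma away
  expect_lt(suppressWarnings(density_of_states(a, b)), 1e-12)
})

test_that("rho falls monotonically with donor-acceptor peak separation", {
  seps <- c(0, 200, 400, 800, 1600)
  rhos <- vapply(seps, function(d) {
    a <- make_gaussian_band(1e7 / 15000, 300)
    f <- make_gaussian_band(1e7 / (15000 - d), 300)
    density_of_states(a, f)
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
})

test_that("rho converges under grid refinement", {
  nu <- seq(14000, 16000, 2)
  shape <- exp(-(nu - 15000)^2 / (2 * 300^2))
  coarse <- spectrum_new(nu, shape, "wavenumber_cm1")
  nu_f <- seq(14000, 16000, 1)
  fine <- spectrum_new(nu_f, exp(-(nu_f - 15000)^2 / (2 * 300^2)),
                       "wavenumber_cm1")
  r1 <- density_of_states(coarse, coarse)
  r2 <- density_of_states(fine, fine)
  expect_equal(r1, r2, tolerance = 5e-3)
})

test_that("rho is asymmetric between classes once Stokes shifts exist", {
  # donor emission is red-shifted, so a -> blue-shifted acceptor loses
  # more overlap than the reverse direction gains
  rho_ab <- density_of_states(
    spectral_library_get(fx_library, "CHL_B", "Q", "absorption"),
    spectral_library_get(fx_library, "CHL_A", "Q", "emission"))
  rho_ba <- density_of_states(
    spectral_library_get(fx_library, "CHL_A", "Q", "absorption"),
    spectral_library_get(fx_library, "CHL_B", "Q", "emission"))
  expect_gt(rho_ba, 1.5 * rho_ab)  # donation downhill in energy is favoured
})

test_that("approximate_emission translates, mirrors and renormalizes", {
  ab <- make_gaussian_band(1e7 / 23000, 400)
  em0 <- approximate_emission(ab, 0)
  expect_equal(em0$grid[which.max(em0$values)], 23000, tolerance = 1e-2)
  em <- approximate_emission(ab, 1000)
  expect_equal(em$grid[which.max(em$values)], 22000, tolerance = 1e-2)
  expect_equal(spectrum_area(em), 1, tolerance = 1e-9)
  # two-peak asymmetric shape flips order about the pivot under mirroring
  nu <- seq(20000, 26000, 4)
  two <- spectrum_new(nu, exp(-(nu - 22000)^2 / 5e4) +
                        0.5 * exp(-(nu - 24000)^2 / 5e4),
                      "wavenumber_cm1")
  m <- approximate_emission(two, 0, mirror = TRUE)
  main_pk <- m$grid[which.max(m$values)]
  side <- m$grid[which(diff(sign(diff(m$values))) == -2) + 1L]
  expect_lt(min(side), main_pk)  # minor peak now below the major one
  expect_error(approximate_emission(two, -5), ">= 0")
})

test_that("dipole strength follows the sqrt scaling law and null case", {
  ex <- make_gaussian_band(662, 320, 9e4, "extinction_M1cm1")
  w <- c(620, 700)
  d1 <- dipole_strength_from_band(ex, w, n = 1)
  ex2 <- spectrum_new(ex$grid, 2 * ex$values, ex$axis_kind, ex$value_kind)
  expect_equal(dipole_strength_from_band(ex2, w, n = 1), sqrt(2) * d1,
               tolerance = 1e-12)
  zero <- spectrum_new(ex$grid, rep(0, length(ex$grid)), ex$axis_kind,
                       ex$value_kind)
  expect_equal(dipole_strength_from_band(zero, w), 0)
  expect_error(dipole_strength_from_band(ex, c(650, 650)), "empty")
})

test_that("spectra round-trip through two-column text files", {
  s <- make_gaussian_band(500, 500)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, path, header = "fixture")
  r <- read_spectrum(path)
  expect_equal(r$grid, s$grid, tolerance = 1e-8)
  expect_equal(r$values, s$values, tolerance = 1e-8)
})

test_that("the lambda^4 diagnostic ratio sits near the overlap wavelength^4", {
  a <- make_gaussian_band(660, 300)
  r <- rho_lambda4_ratio(a, a)
  expect_gt(r, 600^4)
  expect_lt(r, 720^4)
})
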