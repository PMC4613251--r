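# Mode strengths, conservation laws, chirality properties, and the
# Lorentzian spectral synthesis.

test_that("a single oscillator has zero rotational strength", {
  one <- polarizable_unit_set(
    tibble::tibble(x = 1, y = 2, z = 3, ux = 0, uy = 0, uz = 1,
                   nu0 = 5e4, D = 2e9))
  st <- mode_moments(normal_modes(one), one)
  expect_equal(st$R_k, 0, tolerance = 1e-15)
  expect_equal(st$D_k, 2e9, tolerance = 1e-6)
})

test_that("coplanar systems carry no rotational strength", {
  withr::with_seed(51, {
    for (i in 1:5) {
      n <- sample(3:7, 1)
      pos <- cbind(runif(n, 0, 12), runif(n, 0, 12), 0)
      ang <- runif(n, 0, 2 * pi)
      ch <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = 0,
                           ux = cos(ang), uy = sin(ang), uz = 0,
                           nu0 = runif(n, 48000, 56000),
                           D = runif(n, 1e9, 3e9))
      us <- polarizable_unit_set(ch)
      st <- suppressWarnings(mode_moments(normal_modes(us), us))
      expect_lt(max(abs(st$R_k)), 1e-10 * max(st$D_k))
    }
  })
})

test_that("dipole and rotational strengths obey the sum rules", {
  withr::with_seed(53, {
    for (i in 1:20) {
      us <- random_unit_set(sample(2:10, 1), sample(0:4, 1))
      st <- mode_moments(normal_modes(us), us)
      expect_equal(sum(st$D_k), sum(us$chromophores$D),
                   tolerance = 1e-8)
      expect_lt(abs(sum(st$R_k)),
                max(1e-8 * sum(abs(st$R_k)), 1e-10))
    }
  })
})

test_that("rotational strengths are independent of the moment origin", {
  withr::with_seed(59, {
    us <- random_unit_set(6, 2)
    modes <- normal_modes(us)
    st0 <- mode_moments(modes, us)
    for (i in 1:5) {
      st <- mode_moments(modes, us, origin = rnorm(3, sd = 50))
      expect_equal(st$R_k, st0$R_k,
                   tolerance = 1e-10)
    }
  })
})

test_that("the mirror image preserves D_k and negates R_k and the CD", {
  withr::with_seed(61, {
    us <- random_unit_set(7, 3)
    mir <- mirror_image(us, normal = c(1, 2, -1), point = c(3, 0, 1))
    st <- mode_moments(normal_modes(us), us)
    stm <- mode_moments(normal_modes(mir), mir)
    expect_equal(stm$nu_k, st$nu_k, tolerance = 1e-10)
    expect_equal(stm$D_k, st$D_k, tolerance = 1e-8)
    expect_equal(stm$R_k, -st$R_k, tolerance = 1e-8)

    sp <- compute_spectra(st, Gamma = 6000, p = us$p)
    spm <- compute_spectra(stm, Gamma = 6000, p = us$p)
    expect_equal(spm$epsilon, sp$epsilon, tolerance = 1e-10)
    expect_equal(spm$delta_epsilon, -sp$delta_epsilon, tolerance = 1e-10)
  })
})

test_that("spectra are invariant under rigid motion of the system", {
  withr::with_seed(67, {
    us <- random_unit_set(6, 3)
    st <- mode_moments(normal_modes(us), us)
    sp <- compute_spectra(st, Gamma = 6000, p = us$p)
    for (i in 1:3) {
      us2 <- rigid_transform_units(us)
      st2 <- mode_moments(normal_modes(us2), us2)
      sp2 <- compute_spectra(st2, Gamma = 6000, p = us$p)
      expect_equal(sp2$epsilon, sp$epsilon, tolerance = 1e-8)
      expect_equal(sp2$delta_epsilon, sp$delta_epsilon, tolerance = 1e-8)
    }
  })
})

test_that("spectral synthesis honors its basic contract", {
  one <- polarizable_unit_set(
    tibble::tibble(x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1,
                   nu0 = 52000, D = 2e9), p = 2)
  st <- mode_moments(normal_modes(one), one)
  sp <- compute_spectra(st, Gamma = 6000, p = 2)

  # epsilon nonnegative everywhere; zero R -> identically zero CD
  expect_true(all(sp$epsilon >= 0))
  expect_equal(sp$delta_epsilon, rep(0, nrow(sp)), tolerance = 1e-15)

  # peak within one grid step of the oscillator wavelength
  lam_peak <- sp$wavelength_nm[which.max(sp$epsilon)]
  expect_lte(abs(lam_peak - 1e7 / 52000), 1)

  # wavenumber column consistent with the grid
  expect_equal(sp$wavenumber, 1e7 / sp$wavelength_nm)

  # decreasing grids and bad Gamma are refused
  expect_error(compute_spectra(st, Gamma = 6000, p = 2,
                               grid_nm = c(200, 190)),
               class = "dipolecd_input_error")
  expect_error(compute_spectra(st, Gamma = -1, p = 2),
               class = "dipolecd_param_error")
  expect_error(compute_spectra(st, Gamma = 6000, p = 1),
               class = "dipolecd_input_error")
})

test_that("isolated-oscillator extinction matches the analytic Lorentzian", {
  nu0 <- 52000; D <- 2e9; Gamma <- 6000; p <- 2
  one <- polarizable_unit_set(
    tibble::tibble(x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1,
                   nu0 = nu0, D = D), p = p)
  st <- mode_moments(normal_modes(one), one)
  sp <- compute_spectra(st, Gamma = Gamma, p = p)
  nu <- sp$wavenumber
  analytic <- 8 * pi^2 * 6.02214076e23 * 1e-24 * Gamma * nu^2 * D /
    (6909 * p * ((nu0^2 - nu^2)^2 + Gamma^2 * nu^2))
  expect_equal(sp$epsilon, analytic, tolerance = 1e-12)
})

test_that("an ideal helix yields the canonical couplet morphology", {
  helix <- ideal_helix(15)
  res <- suppressMessages(run_cdcalc(helix, synthetic_params()))
  sp <- res$spectrum
  win <- sp[sp$wavelength_nm >= 180 & sp$wavelength_nm <= 230, ]
  expect_equal(count_sign_changes(win$delta_epsilon), 1L)
  # positive lobe at short wavelength, negative at long
  expect_gt(win$delta_epsilon[1L], 0)
  expect_lt(win$delta_epsilon[nrow(win)], 0)
})

test_that("wavelength/wavenumber conversion is exact and guarded", {
  expect_equal(wavelength_to_wavenumber(200), 50000)
  expect_equal(wavelength_to_wavenumber(100), 100000)
  expect_equal(wavenumber_to_wavelength(wavelength_to_wavenumber(193.7)),
               193.7, tolerance = 1e-12)
  expect_error(wavelength_to_wavenumber(0),
               class = "dipolecd_input_error")
  expect_error(wavenumber_to_wavelength(-5),
               class = "dipolecd_input_error")
})
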