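# Dipole field tensor, block assembly, Schur reduction and the
# normal-mode eigenproblem, with the dense complex solve as oracle.

test_that("dipole field tensor has the textbook form and symmetries", {
  T1 <- dipole_field_tensor(c(0, 0, 0), c(1, 0, 0))
  expect_equal(T1, diag(c(-2, 1, 1)), tolerance = 1e-12)
  T2 <- dipole_field_tensor(c(0, 0, 0), c(2, 0, 0))
  expect_equal(T2, T1 / 8, tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:10) {
      a <- rnorm(3); b <- a + rnorm(3, sd = 3)
      Tij <- dipole_field_tensor(a, b)
      expect_equal(Tij, dipole_field_tensor(b, a), tolerance = 1e-12)
      expect_equal(Tij, t(Tij), tolerance = 1e-12)
      expect_equal(sum(diag(Tij)), 0, tolerance = 1e-12)
    }
  })
  expect_error(dipole_field_tensor(c(0, 0, 0), c(0.3, 0, 0)),
               class = "dipolecd_contact_error")
})

test_that("assembled blocks have the prescribed structure", {
  # single isotropic point: 3x3 diag(1/alpha), no dispersive rows
  us1 <- polarizable_unit_set(
    tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                   ux = numeric(), uy = numeric(), uz = numeric(),
                   nu0 = numeric(), D = numeric()),
    tibble::tibble(x = 0, y = 0, z = 0, alpha = 0.5), p = 2)
  bl1 <- assemble(us1)
  expect_equal(bl1$A22, diag(3) * 2, tolerance = 1e-12)

  # two isotropic points: off-diagonal block is exactly T12
  us2 <- polarizable_unit_set(
    us1$chromophores,
    tibble::tibble(x = c(0, 3), y = c(0, 1), z = c(0, -2),
                   alpha = c(0.5, 0.8)), p = 2)
  bl2 <- assemble(us2)
  expect_equal(bl2$A22[1:3, 4:6],
               dipole_field_tensor(c(0, 0, 0), c(3, 1, -2)),
               tolerance = 1e-12)

  # full assembled matrix is symmetric for random mixed systems
  withr::with_seed(23, {
    for (i in 1:5) {
      us <- random_unit_set(4, 4)
      bl <- assemble(us)
      Afull <- rbind(cbind(bl$A11, bl$A12),
                     cbind(t(bl$A12), bl$A22))
      expect_equal(Afull, t(Afull), tolerance = 1e-10)
      expect_equal(diag(bl$A11), us$chromophores$nu0^2 / us$chromophores$D,
                   tolerance = 1e-12)
    }
  })
})

test_that("contact violations are reported as errors", {
  ch <- tibble::tibble(x = c(0, 0.3), y = 0, z = 0, ux = 0, uy = 0,
                       uz = 1, nu0 = 5e4, D = 2e9)
  expect_error(assemble(polarizable_unit_set(ch)),
               class = "dipolecd_contact_error")
})

test_that("Schur reduction matches the dense-inverse oracle", {
  # no nondispersive units: identity on A11
  withr::with_seed(31, {
    us0 <- random_unit_set(5, 0)
    bl0 <- assemble(us0)
    expect_identical(reduce_dispersive(bl0), bl0$A11)

    # scalar case: one dispersive + one far isotropic along the u axis
    # reduces per the a - b^2/c closed form on each Cartesian component
    for (i in 1:20) {
      us <- random_unit_set(sample(2:6, 1), sample(1:5, 1))
      bl <- assemble(us)
      red <- reduce_dispersive(bl)
      expect_equal(red, dense_schur(bl), tolerance = 1e-10)
      expect_equal(red, t(red), tolerance = 1e-10)
    }
  })
})

test_that("1x1 Schur complement reproduces a - b^2/c", {
  # one dispersive oscillator along z and one isotropic point on the z
  # axis: by symmetry only the zz component couples, so the reduced
  # 1x1 matrix is a - b^2/c with a = nu0^2/D, b = T_zz, c = 1/alpha
  nu0 <- 5e4; D <- 2e9; alpha <- 0.9; Rz <- 4
  us <- polarizable_unit_set(
    tibble::tibble(x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1,
                   nu0 = nu0, D = D),
    tibble::tibble(x = 0, y = 0, z = Rz, alpha = alpha))
  bl <- assemble(us)
  b <- -2 / Rz^3
  expect_equal(drop(reduce_dispersive(bl)),
               nu0^2 / D - b^2 * alpha, tolerance = 1e-12)
})

test_that("singular nondispersive blocks are refused", {
  bl <- list(A11 = matrix(1), A12 = matrix(c(1, 0, 0), 1, 3),
             A22 = matrix(0, 3, 3), n_nd = 3L)
  expect_error(reduce_dispersive(bl), class = "dipolecd_singular_block")
})

test_that("isolated and paired oscillators give closed-form modes", {
  nu0 <- 52000; D <- 1.9e9
  one <- polarizable_unit_set(
    tibble::tibble(x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1,
                   nu0 = nu0, D = D))
  m1 <- normal_modes(one)
  expect_equal(m1$nu_k, nu0, tolerance = 1e-12)

  # two identical parallel oscillators, u perpendicular to the
  # separation axis: nu+-^2 = nu0^2 +- D/R^3
  for (R in c(4, 6, 9)) {
    two <- polarizable_unit_set(
      tibble::tibble(x = c(0, R), y = 0, z = 0, ux = 0, uy = 0, uz = 1,
                     nu0 = nu0, D = D))
    m2 <- normal_modes(two)
    expect_equal(sort(m2$nu_k_sq), nu0^2 + c(-1, 1) * D / R^3,
                 tolerance = 1e-8)
  }
})

test_that("eigenvectors are orthonormal and mode count equals q", {
  withr::with_seed(41, {
    for (i in 1:8) {
      q <- sample(2:10, 1)
      us <- random_unit_set(q, sample(0:4, 1))
      m <- normal_modes(us)
      expect_equal(length(m$nu_k_sq), q)
      expect_equal(t(m$t) %*% m$t, diag(q), tolerance = 1e-8)
      # sign convention: largest-magnitude component positive
      for (k in seq_len(q)) {
        expect_gt(m$t[which.max(abs(m$t[, k])), k], 0)
      }
    }
  })
})

test_that("eigenvalues are invariant under rigid motion", {
  withr::with_seed(43, {
    us <- random_unit_set(6, 4)
    m <- normal_modes(us)
    for (i in 1:5) {
      m2 <- normal_modes(rigid_transform_units(us))
      expect_equal(m2$nu_k_sq, m$nu_k_sq,
                   tolerance = 1e-8 * max(abs(m$nu_k_sq)))
    }
  })
})

test_that("full solve satisfies its residual and decoupled limits", {
  # infinitely separated (one unit alone): mu = alpha E exactly
  nu0 <- 5e4; D <- 2e9; Gamma <- 6000
  one <- polarizable_unit_set(
    tibble::tibble(x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1,
                   nu0 = nu0, D = D), p = 2)
  grid <- seq(180, 230, 5)
  fs <- full_solve(one, grid, Gamma = Gamma)
  nu <- 1e7 / grid
  a_exact <- D / (nu0^2 - nu^2 + 1i * Gamma * nu)
  expect_equal(fs$alpha_im, Im(a_exact), tolerance = 1e-10)
  expect_equal(fs$alpha_re, Re(a_exact), tolerance = 1e-10)
})

test_that("mode Lorentzian sum equals the complex solve on dispersive systems", {
  withr::with_seed(47, {
    Gamma <- 5000
    for (i in 1:5) {
      us <- random_unit_set(sample(3:10, 1), 0)
      fs <- full_solve(us, 175:250, Gamma = Gamma)
      modes <- normal_modes(us)
      strengths <- mode_moments(modes, us)
      sp <- compute_spectra(strengths, Gamma = Gamma, p = us$p,
                            grid_nm = 175:250)
      expect_equal(sp$epsilon, fs$epsilon,
                   tolerance = 1e-6)
    }
  })
})
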