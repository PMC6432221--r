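test_that("twist-expulsion parameter has the right algebra and scale
           invariance", {
  sys <- squeelix_system(B = 2, C = 2, omega1 = pi / 2 * 0.1, omega3 = 0.1,
                         L = 100)
  expect_equal(twist_expulsion_gamma(sys), 1, tolerance = 1e-14)
  sys2 <- squeelix_system(B = 1, C = 1, omega1 = 0.26, omega3 = 0.1, L = 100)
  expect_equal(twist_expulsion_gamma(sys2), 4 * 0.0676 / (pi^2 * 0.01),
               tolerance = 1e-14)
  # simultaneous rescaling of both intrinsic rates leaves gamma unchanged
  sys3 <- squeelix_system(B = 1, C = 1, omega1 = 0.26 * 3, omega3 = 0.1 * 3,
                          L = 100)
  expect_equal(twist_expulsion_gamma(sys3), twist_expulsion_gamma(sys2))
})

test_that("the elliptic ground-state condition m E(m) = gamma is solved on
           the physical branch", {
  expect_identical(ground_state_m(1), 1)
  expect_identical(ground_state_m(2), "circle")
  expect_error(ground_state_m(-1), "positive")
  for (g in c(0.15, 0.4, 0.52, 0.8, 0.95)) {
    m <- ground_state_m(g)
    expect_equal(m * pracma::ellipke(m)$e, g, tolerance = 1e-11)
    expect_equal(m, m_root_by_scan(g), tolerance = 1e-7)
  }
  # monotone and continuous over the dense-to-dilute range
  gs <- seq(0.05, 0.99, length.out = 40)
  ms <- vapply(gs, ground_state_m, numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_lt(max(diff(ms)), 0.15)
})

test_that("the twist profile solves the pendulum equation and has the
           homoclinic closed form at m = 1", {
  sys <- squeelix_system(B = 1, C = 1, omega1 = 0.2, omega3 = 0.08, L = 60)
  # m = 1: Gudermannian kink interpolating -pi/2 -> pi/2, psi(0) = 0
  pr <- twist_profile(sys, m = 1, n_points = 801)
  lam <- sqrt(1 / 1) / 0.2
  expect_equal(pr$psi, 2 * atan(exp(pr$s / lam)) - pi / 2, tolerance = 1e-10)
  expect_equal(pr$psi[(801 + 1) / 2], 0, tolerance = 1e-12)
  # tails approach +/- pi/2 as ~ 2 exp(-|s|/lambda)
  expect_equal(range(pr$psi), c(-pi / 2, pi / 2), tolerance = 4 * exp(-6))
  # psi(0) = 0 for all m; kappa slaved to the twist
  for (m in c(0.3, 0.7, 1)) {
    prm <- twist_profile(sys, m = m, n_points = 501)
    expect_equal(prm$psi[251], 0, tolerance = 1e-10)
    expect_equal(prm$kappa, 0.2 * sin(prm$psi))
  }
  # Jacobi amplitude against direct ODE integration of the pendulum
  skip_if_not_installed("deSolve")
  for (m in c(0.5, 0.9)) {
    u <- seq(0, 12, length.out = 200)
    psi_ode <- pendulum_ode_psi(u, m)
    expect_equal(semiflex:::jacobi_am(u, m), psi_ode, tolerance = 1e-6)
  }
})

test_that("pendulum-equation residual of the profile is tiny under
           finite-difference differentiation", {
  # in u = s/lambda units: psi'' + (m/2) sin(2 psi) = 0
  for (m in c(0.4, 0.8, 0.99)) {
    h <- 1e-3
    u <- seq(-6, 6, by = h)
    psi <- semiflex:::jacobi_am(u, m)
    i <- 3:(length(u) - 2)
    d2 <- (-psi[i - 2] + 16 * psi[i - 1] - 30 * psi[i] +
             16 * psi[i + 1] - psi[i + 2]) / (12 * h^2)
    resid <- d2 + (m / 2) * sin(2 * psi[i])
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("shape reconstruction closes circles and produces the
           twist-kink S-shape", {
  # zero curvature: straight segment of length L
  straight <- reconstruct_shape(tibble::tibble(s = seq(0, 10, length.out = 200),
                                               kappa = 0))
  expect_equal(max(straight$x), 10, tolerance = 1e-12)
  expect_equal(max(abs(straight$y)), 0)
  # constant curvature omega1: circle of radius 1/omega1 closing on itself
  om <- 0.1
  L <- 2 * pi / om
  circ <- reconstruct_shape(tibble::tibble(s = seq(0, L, length.out = 4001),
                                           kappa = om))
  expect_lt(sqrt(circ$x[4001]^2 + circ$y[4001]^2), 1e-6 * L)
  # single twist-kink: two opposite arcs of radius ~ 1/omega1
  sys <- squeelix_system(B = 1, C = 1, omega1 = 0.2, omega3 = 0.08, L = 80)
  pr <- twist_profile(sys, m = 1, n_points = 4001)
  sh <- reconstruct_shape(pr)
  far <- abs(pr$s) > 3 * sqrt(1 / 1) / 0.2
  dth <- diff(sh$theta) / diff(sh$s)
  segs <- (abs(pr$s) > 15)[-1]
  expect_equal(mean(abs(dth[segs])), 0.2, tolerance = 0.02)
  expect_equal(sort(unique(sign(round(dth[segs], 3)))), c(-1, 1))
  # non-uniform grid is resampled with a warning
  expect_warning(
    reconstruct_shape(tibble::tibble(s = c(0, 1, 3, 6), kappa = 0)),
    "resampling")
})

test_that("kink energetics and regime classification follow gamma", {
  # gamma = 1 exactly: zero kink self-energy
  s1 <- squeelix_system(B = 1, C = 1, omega1 = pi / 2 * 0.1, omega3 = 0.1,
                        L = 100)
  expect_equal(kink_energetics(s1)$DeltaE, 0, tolerance = 1e-14)
  # gamma = 2 by construction: DeltaE = pi C omega3
  s2 <- squeelix_system(B = 1, C = 1, omega1 = sqrt(2) * pi / 2 * 0.1,
                        omega3 = 0.1, L = 100)
  expect_equal(twist_expulsion_gamma(s2), 2, tolerance = 1e-12)
  expect_equal(kink_energetics(s2)$DeltaE, pi * 0.1, tolerance = 1e-12)
  expect_equal(kink_energetics(s2)$E0_per_L, 0.1^2 / 2)
  # sign(DeltaE) = sign(gamma - 1)
  for (g in c(0.3, 0.9, 1.4, 3)) {
    om1 <- sqrt(g) * pi / 2 * 0.1
    s <- squeelix_system(B = 1, C = 1, omega1 = om1, omega3 = 0.1, L = 10)
    expect_equal(sign(kink_energetics(s)$DeltaE), sign(g - 1))
  }
  # regime labels at the three reference gammas
  expect_identical(classify_regime(5.47)$regime, "circle")
  expect_identical(classify_regime(0.997)$regime, "dilute_kinks")
  expect_identical(classify_regime(0.52)$regime, "dense_kinks")
  gs <- squeelix_ground_state(s2)
  expect_identical(gs$regime, "circle")
  expect_s3_class(glance(gs), "tbl_df")
})
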