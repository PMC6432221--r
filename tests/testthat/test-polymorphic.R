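test_cs <- mt_cross_section(Ri = 8, Rm = 10.25, Ro = 12.5,
                            eps_i = 0.02, eps_o = -0.02)

block_sigma <- function(N, p) c(rep(1, p), rep(0, N - p))

test_that("the characteristic curvature is linear in the strains and
           matches the quadrature least-squares minimiser", {
  k1 <- characteristic_curvature(test_cs)
  double <- mt_cross_section(Ri = 8, Rm = 10.25, Ro = 12.5,
                             eps_i = 0.04, eps_o = -0.04)
  expect_equal(characteristic_curvature(double), 2 * k1, tolerance = 1e-14)
  # vanishing strains: kappa1 -> 0 linearly
  small <- mt_cross_section(Ri = 8, Rm = 10.25, Ro = 12.5,
                            eps_i = 2e-9, eps_o = -2e-9)
  expect_equal(characteristic_curvature(small), k1 * 1e-7, tolerance = 1e-12)
  # half-switched cross-section (N = 14, p = 7 -> phi_p = pi): the
  # minimiser curvature magnitude equals |kappa1|; oracle reconstructs the
  # quadratic form from quadrature evaluations only
  cs14 <- mt_cross_section(Ri = 8, Rm = 10.25, Ro = 12.5,
                           eps_i = 0.02, eps_o = -0.02, N = 14)
  sig <- block_sigma(14, 7)
  ora <- mt_quadrature_minimizer(cs14, sig)
  expect_equal(sqrt(sum(ora$kappa^2)), abs(characteristic_curvature(cs14)),
               tolerance = 1e-8)
  mn <- minimize_cross_section(cs14, sig)
  expect_equal(mn$kappa, ora$kappa, tolerance = 1e-7)
  expect_equal(mn$energy, ora$energy, tolerance = 1e-8)
})

test_that("closed-form and quadrature energies agree to rounding", {
  set.seed(4)
  for (i in 1:4) {
    sig <- rbinom(13, 1, 0.4)
    kap <- rnorm(2, 0, 1e-3)
    eb <- rnorm(1, 0, 1e-3)
    ec <- cross_section_energy(test_cs, kap, eb, sig)
    eq <- cross_section_energy(test_cs, kap, eb, sig, method = "quadrature")
    expect_equal(ec, eq, tolerance = 1e-10)
  }
  # unswitched, undeformed: zero energy
  expect_identical(cross_section_energy(test_cs), 0)
})

test_that("a fully switched straight tube relaxes to the area-weighted
           mean strain but stays frustrated", {
  mm <- semiflex:::mt_moments(test_cs)
  mn <- minimize_cross_section(test_cs, rep(1, 13))
  expect_equal(mn$eps_bar, mm$W2 * 2 * pi / mm$A, tolerance = 1e-12)
  expect_equal(mn$kappa, c(0, 0), tolerance = 1e-12)
  expect_gt(mn$energy, 0)
})

test_that("block curvature rises from zero, peaks in the middle and
           returns to zero at full switching", {
  kmag <- vapply(0:13, function(p) {
    sqrt(sum(minimize_cross_section(test_cs, block_sigma(13, p))$kappa^2))
  }, numeric(1))
  expect_equal(kmag[1], 0)
  expect_equal(kmag[14], 0, tolerance = 1e-12)
  expect_equal(kmag / abs(characteristic_curvature(test_cs)),
               abs(sin(pi * (0:13) / 13)), tolerance = 1e-10)
  expect_gt(max(kmag), 0)
})

test_that("switched dimers aggregate: the contiguous block minimises the
           energy at fixed switch number", {
  for (p in 1:4) {
    e_block <- minimize_cross_section(test_cs, block_sigma(13, p))$energy
    configs <- utils::combn(13, p)
    energies <- apply(configs, 2, function(idx) {
      sig <- replace(rep(0, 13), idx, 1)
      minimize_cross_section(test_cs, sig)$energy
    })
    expect_equal(min(energies), e_block, tolerance = 1e-10)
    expect_true(all(energies >= e_block - 1e-12 * abs(e_block)))
  }
})

test_that("the first-principles block potential has the rescaled
           quadratic + sine structure", {
  cs <- mt_cross_section(Ri = 8, Rm = 10.25, Ro = 12.5,
                         eps_i = 0.02, eps_o = -0.02, DeltaG = -0.05)
  Fl <- 2e-4; Ml <- 5e-3
  sc <- mt_rescaled_loads(cs, F = Fl, M = Ml)
  mm <- semiflex:::mt_moments(cs)
  e_raw <- vapply(0:13, function(p) {
    phic <- pi * p / 13
    minimize_cross_section(cs, block_sigma(13, p), F = Fl, M = Ml,
                           M_axis = c(cos(phic), sin(phic)))$energy
  }, numeric(1))
  phi <- 2 * pi * (0:13) / 13
  e_scaled <- sc$E0 * (sc$c2 / 2 * phi^2 + sc$f * phi -
                         sc$m * sin(phi / 2) - 0.5 * sin(phi / 2)^2)
  shift <- e_raw - e_scaled
  # the two constructions differ by a phi-independent constant only
  expect_lt(diff(range(shift)), 1e-12 + 1e-8 * max(abs(e_raw)))
  # and that constant is the load relaxation -g' Q^-1 g / (2Y)
  expect_equal(shift[1], -(Ml^2 / mm$Q11 + Fl^2 / mm$A) / (2 * cs$Y),
               tolerance = 1e-10)
  # the exported potential matches the same rescaled form
  expect_equal(polymorphic_potential(cs, phi, sc$f, sc$m),
               sc$c2 / 2 * phi^2 + sc$f * phi - sc$m * sin(phi / 2) -
                 0.5 * sin(phi / 2)^2)
})

test_that("the phase diagram orders L, C and S sensibly", {
  c2 <- mt_rescaled_loads(test_cs)$c2
  # symmetric point: f chosen so the two straight states are degenerate
  f_sym <- -c2 * pi
  phi <- seq(0, 2 * pi, length.out = 301)
  e <- polymorphic_potential(test_cs, phi, f_sym, 0)
  expect_equal(e[1], e[301], tolerance = 1e-10)
  expect_equal(e, rev(e), tolerance = 1e-10)
  # large torque makes the curved state the global minimum (the potential
  # is written for m > 0; negative m bends the other way)
  pd <- phase_diagram(test_cs, f_grid = c(f_sym), m_grid = c(0, 2),
                      n_phi = 401)
  expect_identical(pd$state[pd$m == 2], "C")
  # strongly negative f favours full switching (S)
  pd2 <- phase_diagram(test_cs, f_grid = c(-1), m_grid = 0, n_phi = 401)
  expect_identical(pd2$state, "S")
  # strongly positive f keeps the tube straight and long (L)
  pd3 <- phase_diagram(test_cs, f_grid = c(1), m_grid = 0, n_phi = 401)
  expect_identical(pd3$state, "L")
})

test_that("quasi-static force sweeps show hysteresis for bistable
           potentials", {
  hs <- hysteresis_sweep(test_cs, seq(-0.3, 0.3, length.out = 121), m = 0.3)
  expect_true(attr(hs, "hysteretic"))
  up <- hs$phi[hs$direction == "up"]
  down <- rev(hs$phi[hs$direction == "down"])
  # jumps occur at different forces in the two directions
  jump_up <- which.max(abs(diff(up)))
  jump_down <- which.max(abs(diff(down)))
  expect_false(jump_up == jump_down)
})
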