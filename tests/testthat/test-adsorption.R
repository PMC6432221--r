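# one moderately sized wall Monte-Carlo shared by several blocks below
wall_sys <- adsorption_system(ell = 10, S = 250)
wall_mc <- sample_wall_contacts(wall_sys, 5e4, seed = 101)

test_that("fragment weights have the four exponents and continuous
           crossovers", {
  sys <- adsorption_system(ell = 20, S = 500)
  # stiff loops: -5/2; flexible loops: -3/2
  expect_equal(fragment_weight(8, sys, "loop") / fragment_weight(4, sys, "loop"),
               2^(-2.5), tolerance = 1e-12)
  expect_equal(fragment_weight(400, sys, "loop") / fragment_weight(200, sys, "loop"),
               2^(-1.5), tolerance = 1e-12)
  # tails: -1/4 then -1/2
  expect_equal(fragment_weight(8, sys, "tail") / fragment_weight(4, sys, "tail"),
               2^(-0.25), tolerance = 1e-12)
  expect_equal(fragment_weight(400, sys, "tail") / fragment_weight(200, sys, "tail"),
               2^(-0.5), tolerance = 1e-12)
  # continuity at the crossovers (2 ell for loops, ell for tails)
  eps <- 1e-9
  expect_equal(fragment_weight(2 * 20 - eps, sys, "loop"),
               fragment_weight(2 * 20 + eps, sys, "loop"), tolerance = 1e-6)
  expect_equal(fragment_weight(20 - eps, sys, "tail"),
               fragment_weight(20 + eps, sys, "tail"), tolerance = 1e-6)
})

test_that("chemisorption scales reproduce the table values and the
           flexible fixed point", {
  expect_equal(chemisorption_scales(0.59, 0.26)$s0, 0.34, tolerance = 0.01)
  dna <- chemisorption_scales(50, 0.34)
  expect_equal(dna$s0, 1.8, tolerance = 0.01)
  expect_equal(dna$S_star, 1.4e3, tolerance = 0.01)
  fp <- chemisorption_scales(2, 2)
  expect_equal(fp$s0, 2)
  expect_equal(fp$S_star, 2)
})

test_that("contact probability is a continuous three-regime power law", {
  sys <- adsorption_system(ell = 100, S = 1e4)
  s0 <- (100)^(1 / 3)
  expect_equal(contact_probability(s0 * 0.99, sys), 1)
  expect_equal(contact_probability(4 * s0, sys), 4^(-2.5), tolerance = 1e-12)
  # both branches meet at ell
  expect_equal(contact_probability(100 - 1e-9, sys),
               (100 / s0)^(-2.5), tolerance = 1e-6)
  expect_equal(contact_probability(100 + 1e-9, sys),
               (100 / s0)^(-2.5), tolerance = 1e-6)
})

test_that("reversible-adsorption thresholds scale correctly", {
  base <- adsorption_system(ell = 100, S = 1000, Delta = 1, u = 1)
  uc1 <- adsorption_thresholds(base)$uc
  wide <- adsorption_system(ell = 100, S = 1000, Delta = 8, u = 1)
  expect_equal(adsorption_thresholds(wide)$uc, uc1 / 4, tolerance = 1e-12)
  # tau = 0 at threshold; below threshold flagged not adsorbed
  at <- adsorption_system(ell = 100, S = 1000, Delta = 1, u = uc1)
  expect_identical(adsorption_thresholds(at)$status, "not adsorbed")
  expect_equal(adsorption_thresholds(at)$tau, 0)
  # strong regime: h < ell whenever tau > (Delta/ell)^(2/3)
  for (u_rel in c(2, 5, 10)) {
    sys <- adsorption_system(ell = 100, S = 1000, Delta = 1, u = u_rel * uc1)
    th <- adsorption_thresholds(sys)
    if (th$strong) expect_lt(th$h, 100)
  }
})

test_that("crossing-angle statistics integrate to one with median pi/2", {
  sys <- adsorption_system(ell = 1000, S = 1e4)
  cr <- crossing_statistics(c(0.1, pi / 2, pi - 1e-9), sys)
  expect_equal(cr$cdf[3], 1, tolerance = 1e-9)
  expect_equal(cr$cdf[2], 0.5)
  # small-angle cumulative ~ theta^2 / 4
  expect_equal(cr$cdf[1], 0.1^2 / 4, tolerance = 1e-3)
  expect_equal(attr(cr, "theta_max"), (1 / 1000)^(1 / 3))
  expect_equal(attr(cr, "align_prob"),
               2 * (1 - cos((1 / 1000)^(1 / 3))) / 2)
  expect_error(crossing_statistics(3.2, sys), "0, pi")
})

test_that("the layered profile has the three printed regimes, continuity,
           and the grafted-tail flag", {
  sys <- adsorption_system(ell = 100, S = 4000, c2inf = 0.1)
  z1 <- 1 / 0.1
  # inner: linear growth; middle: 1/z^2; outer: 1/z
  inner <- layered_profile(c(2, 4), sys)
  expect_equal(inner$c[2] / inner$c[1], 2, tolerance = 1e-12)
  mid <- layered_profile(c(20, 40), sys)
  expect_equal(mid$c[2] / mid$c[1], 1 / 4, tolerance = 1e-12)
  outer <- layered_profile(c(150, 300), sys)
  expect_equal(outer$c[2] / outer$c[1], 1 / 2, tolerance = 1e-12)
  # continuity at z1 and ell
  eps <- 1e-9
  expect_equal(layered_profile(z1 - eps, sys)$c,
               layered_profile(z1 + eps, sys)$c, tolerance = 1e-6)
  expect_equal(layered_profile(100 - eps, sys)$c,
               layered_profile(100 + eps, sys)$c, tolerance = 1e-6)
  far <- layered_profile(sqrt(4000 * 100) + 1, sys)
  expect_identical(far$regime, "grafted_tails")
  expect_true(is.na(far$c))
})

test_that("wall Monte-Carlo recovers the loop exponents", {
  fits <- fit_loop_exponents(wall_mc)
  stiff <- fits$slope[fits$regime == "stiff_loop"]
  flex <- fits$slope[fits$regime == "flexible_loop"]
  expect_equal(stiff, -2.5, tolerance = 0.14)          # +/- 0.35 absolute
  expect_equal(flex, -1.5, tolerance = 0.27)           # +/- 0.4 absolute
  # tail (survival) exponent in the stiff window: -1/4
  surv <- vapply(2:10, function(s) {
    mean(is.na(wall_mc$returns) | wall_mc$returns > s)
  }, numeric(1))
  tail_slope <- unname(coef(lm(log(surv) ~ log(2:10)))[2])
  expect_equal(tail_slope, -0.25, tolerance = 0.3)
  # fully flexible control: single first-passage regime, slope -3/2
  flex_sys <- adsorption_system(ell = 1, S = 300, b = 1)
  fmc <- sample_wall_contacts(flex_sys, 3e4, seed = 7)
  fs <- fit_powerlaw_slope(fmc$contacts, c(10, 100))
  expect_equal(fs$slope, -1.5, tolerance = 0.17)
})

test_that("the proximal profile follows z^(-4/3) in closed form,
           quadrature and Monte-Carlo", {
  sys <- adsorption_system(ell = 50, S = 500)
  pp <- proximal_profile(c(2, 4), sys)
  expect_equal(pp$c[2] / pp$c[1], 2^(-4 / 3), tolerance = 1e-12)
  expect_true(all(pp$in_range))
  expect_false(proximal_profile(60, sys)$in_range)
  # quadrature oracle: differentiate the cumulative loop superposition
  # int^{s(z)} Zl s ds through the height map z ~ s^(3/2)/ell^(1/2)
  zg <- exp(seq(log(1), log(50), length.out = 300))
  shat <- (zg^2 * 50)^(1 / 3)
  cum <- vapply(shat, function(sh) {
    integrate(function(s) fragment_weight(s, sys, "loop") * s, 1, sh,
              rel.tol = 1e-10)$value
  }, numeric(1))
  cz <- diff(cum) / diff(zg)
  zm <- sqrt(zg[-1] * zg[-300])
  sel <- zm > 1.5 & zm < 25
  slope <- unname(coef(lm(log(cz[sel]) ~ log(zm[sel])))[2])
  expect_equal(slope, -4 / 3, tolerance = 0.01)
  # Monte-Carlo superposition: at desk-scale stiffness the flexural
  # crossover (angle spread ~ 1 rad near s ~ ell) blurs the height map,
  # so only a broad band around -4/3 is meaningful here
  wmc <- sample_wall_contacts(adsorption_system(ell = 50, S = 500),
                              3e4, seed = 5, collect_heights = TRUE)
  prof <- proximal_profile_mc(wmc)
  selmc <- prof$z >= 1 & prof$z <= 8 & prof$c > 0
  slope_mc <- unname(coef(lm(log(c) ~ log(z), data = prof[selmc, ]))[2])
  expect_lt(slope_mc, -0.9)
  expect_gt(slope_mc, -2.3)
  expect_error(proximal_profile_mc(wall_mc), "collect_heights")
})

test_that("zipping is rarely preempted for short chains and increasingly
           preempted for long ones", {
  sys <- adsorption_system(ell = 100, S = 1)
  S_star <- chemisorption_scales(100, 1)$S_star
  short <- simulate_zipping(sys, 300, seed = 21, S = S_star / 20)
  long <- simulate_zipping(sys, 300, seed = 22, S = 8 * S_star)
  expect_lt(short$fraction_preempted, 0.1)
  expect_gt(long$fraction_preempted, 0.5)
  mid <- simulate_zipping(sys, 300, seed = 23, S = S_star)
  expect_gt(mid$fraction_preempted, short$fraction_preempted)
  expect_gt(long$fraction_preempted, mid$fraction_preempted)
})

test_that("input validation catches bad systems", {
  expect_error(adsorption_system(ell = 1, S = 10, b = 2), "b <= ell")
  expect_error(adsorption_thresholds(adsorption_system(ell = 10, S = 10)),
               "Delta")
  expect_error(simulate_zipping(adsorption_system(ell = 1000, S = 5),
                                10, 1), "S > s0")
})
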