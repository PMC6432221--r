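#' Squeezed-helix ("squeelix") parameter set
#'
#' A helical filament with intrinsic curvature `omega1` and intrinsic
#' torsion `omega3`, bending modulus `B` and torsional modulus `C`,
#' confined flat onto a plane. Under confinement curvature becomes slaved
#' to the twist field and the planar ground state is selected by the
#' twist-expulsion parameter `gamma = 4 omega1^2 B / (pi^2 omega3^2 C)`.
#'
#' @param B,C Bending and torsional moduli (> 0, energy x length).
#' @param omega1 Intrinsic curvature (> 0, 1/length).
#' @param omega3 Intrinsic torsion (> 0, 1/length).
#' @param L Contour length (> 0).
#' @return An object of class `squeelix_system`.
#' @examples
#' sys <- squeelix_system(B = 1, C = 1, omega1 = 0.26, omega3 = 0.1, L = 200)
#' twist_expulsion_gamma(sys)
#' @export
squeelix_system <- function(B, C, omega1, omega3, L) {
  assert_positive(B = B, C = C, omega1 = omega1, omega3 = omega3, L = L)
  structure(list(B = B, C = C, omega1 = omega1, omega3 = omega3, L = L),
            class = "squeelix_system")
}

#' @export
print.squeelix_system <- function(x, ...) {
  cat(sprintf(
    "<squeelix_system> B = %g, C = %g, omega1 = %g, omega3 = %g, L = %g (gamma = %.4g)\n",
    x$B, x$C, x$omega1, x$omega3, x$L, twist_expulsion_gamma(x)))
  invisible(x)
}

#' Twist-expulsion parameter
#'
#' `gamma = 4 omega1^2 B / (pi^2 omega3^2 C)`. For `gamma > 1` twist-kinks
#' are expelled and the planar ground state is a circle of radius
#' `1/omega1`; for `gamma <= 1` the ground state carries a finite kink
#' density set by the elliptic condition `m E(m) = gamma`.
#'
#' @param sys A [squeelix_system()].
#' @return The dimensionless parameter gamma.
#' @export
twist_expulsion_gamma <- function(sys) {
  stopifnot(inherits(sys, "squeelix_system"))
  4 * sys$omega1^2 * sys$B / (pi^2 * sys$omega3^2 * sys$C)
}

# complete elliptic integral of the second kind, parameter convention
# (E(0) = pi/2, E(1) = 1)
ellip_E <- function(m) {
  vapply(m, function(mm) {
    if (mm >= 1) 1 else pracma::ellipke(mm)$e
  }, numeric(1))
}

ellip_K <- function(m) {
  vapply(m, function(mm) {
    if (mm >= 1) Inf else pracma::ellipke(mm)$k
  }, numeric(1))
}

#' Elliptic parameter of the squeelix ground state
#'
#' Solves `m E(m) = gamma` for the elliptic parameter `m` of the
#' ground-state twist profile, by bracketed bisection to `tol`. `E(m)` is
#' the complete elliptic integral of the second kind in the parameter
#' convention (`E(1) = 1`), so `gamma = 1` gives exactly `m = 1` (the
#' homoclinic single twist-kink). For `gamma > 1` no interior minimum
#' exists and the flag `"circle"` is returned.
#'
#' Note `m E(m)` is strictly increasing only up to an interior maximum
#' (~1.0088 near m ~ 0.97) before returning to 1 at m = 1; for
#' `gamma < 1` the physical (rising-branch) root is nevertheless unique
#' because past the maximum `m E(m)` stays above 1.
#'
#' @param gamma Twist-expulsion parameter (> 0), or a [squeelix_system()].
#' @param tol Bisection tolerance (default 1e-12).
#' @return The root `m` in (0, 1], or the character flag `"circle"`.
#' @export
ground_state_m <- function(gamma, tol = 1e-12) {
  if (inherits(gamma, "squeelix_system")) gamma <- twist_expulsion_gamma(gamma)
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be a positive finite number.")
  }
  if (gamma > 1) return("circle")
  f <- function(m) m * ellip_E(m) - gamma
  if (abs(f(1)) <= tol) return(1)
  lo <- tol
  hi <- 1
  if (f(lo) > 0) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Jacobi amplitude am(u | m), parameter convention, revolving branch
# unwrapped (am(u + 2K) = am(u) + pi). m = 1 is the Gudermannian.
jacobi_am <- function(u, m) {
  if (m >= 1) return(2 * atan(exp(u)) - pi / 2)
  K <- pracma::ellipke(m)$k
  n <- floor((u + K) / (2 * K))
  u0 <- u - 2 * n * K
  j <- lapply(u0, function(uu) pracma::ellipj(uu, m))
  sn <- vapply(j, `[[`, numeric(1), "sn")
  cn <- vapply(j, `[[`, numeric(1), "cn")
  # atan2 keeps full precision where sn -> +/-1 (cn >= 0 on [-K, K])
  n * pi + atan2(sn, cn)
}

# kink width of the profile with elliptic parameter m
squeelix_lambda <- function(sys, m = 1) {
  sqrt(m * sys$C / sys$B) / sys$omega1
}

#' Twist and curvature profile of the squeelix ground state
#'
#' The ground-state twist angle is `psi(s) = am(s / lambda | m)` with
#' `lambda = sqrt(m C / B) / omega1` (this width is the unique one for
#' which the profile solves the pendulum equation
#' `psi'' + (B omega1^2 / 2C) sin(2 psi) = 0`), and the planar curvature is
#' slaved to it, `kappa(s) = omega1 sin(psi(s))`. For `m = 1` the profile
#' is the single twist-kink `psi = 2 atan(exp(s/lambda)) - pi/2`,
#' interpolating from -pi/2 to +pi/2. The bulk solution is evaluated on a
#' grid of length `L` centred on `s = 0` (finite-length boundary layers
#' are not solved).
#'
#' @param sys A [squeelix_system()].
#' @param m Elliptic parameter in (0, 1]; default from [ground_state_m()].
#' @param n_points Grid size (>= 100).
#' @return Tibble with columns `s`, `psi`, `kappa`.
#' @export
twist_profile <- function(sys, m = NULL, n_points = 1000) {
  stopifnot(inherits(sys, "squeelix_system"))
  if (is.null(m)) {
    m <- ground_state_m(twist_expulsion_gamma(sys))
    if (identical(m, "circle")) {
      s <- seq(-sys$L / 2, sys$L / 2, length.out = n_points)
      return(tibble(s = s, psi = pi / 2, kappa = sys$omega1))
    }
  }
  if (!is.numeric(m) || m <= 0 || m > 1) abort("`m` must be in (0, 1].")
  if (n_points < 100) abort("`n_points` must be >= 100.")
  lam <- squeelix_lambda(sys, m)
  s <- seq(-sys$L / 2, sys$L / 2, length.out = n_points)
  psi <- jacobi_am(s / lam, m)
  tibble(s = s, psi = psi, kappa = sys$omega1 * sin(psi))
}

#' Reconstruct a planar shape from a curvature profile
#'
#' Integrates the tangent angle `phi(s)` from `kappa(s)` and the position
#' from `(cos phi, sin phi)`, both by cumulative trapezoids. Non-uniform
#' grids are resampled (with a warning).
#'
#' @param profile A data frame with columns `s` and `kappa` (e.g. from
#'   [twist_profile()]).
#' @return Tibble with columns `s`, `theta` (tangent angle), `x`, `y`.
#' @export
reconstruct_shape <- function(profile) {
  s <- profile$s
  kap <- profile$kappa
  ds <- diff(s)
  if (diff(range(ds)) > 1e-8 * mean(ds)) {
    warn("non-uniform arc-length grid; resampling.")
    grid <- seq(min(s), max(s), length.out = length(s))
    kap <- approx(s, kap, xout = grid)$y
    s <- grid
  }
  phi <- pracma::cumtrapz(s, kap)[, 1]
  x <- pracma::cumtrapz(s, cos(phi))[, 1]
  y <- pracma::cumtrapz(s, sin(phi))[, 1]
  tibble(s = s, theta = phi, x = x, y = y)
}

#' Twist-kink energetics
#'
#' Energy density of the circular (kink-free) state `E0/L = C omega3^2 / 2`,
#' the self-energy of a single twist-kink
#' `Delta E = pi C omega3 (gamma - 1)` (negative for `gamma < 1`: kinks
#' proliferate; positive for `gamma > 1`: kinks are expelled), and the kink
#' width `lambda = sqrt(C/B) / omega1`.
#'
#' @param sys A [squeelix_system()].
#' @return Tibble with columns `E0_per_L`, `DeltaE`, `lambda`, `gamma`.
#' @export
kink_energetics <- function(sys) {
  stopifnot(inherits(sys, "squeelix_system"))
  g <- twist_expulsion_gamma(sys)
  tibble(E0_per_L = sys$C * sys$omega3^2 / 2,
         DeltaE = pi * sys$C * sys$omega3 * (g - 1),
         lambda = squeelix_lambda(sys, 1),
         gamma = g)
}

# gamma below which twist-kinks overlap: kink spacing d = 2 K(m) lambda(m)
# falls below the kink extension pi * lambda(1), i.e. sqrt(m) K(m) = pi/2.
gamma_dense_threshold <- function() {
  m_d <- uniroot(function(m) sqrt(m) * ellip_K(m) - pi / 2,
                 c(0.2, 0.95), tol = 1e-10)$root
  m_d * ellip_E(m_d)
}

#' Classify the squeelix ground-state regime
#'
#' `gamma > 1`: circular ground state (kinks expelled). For `gamma <= 1`
#' the ground state carries kinks with spacing `d = 2 K(m) lambda(m)`;
#' when `d` exceeds the kink extension `pi lambda(1)` the kinks are dilute
#' and individually resolvable, otherwise they overlap and the twist grows
#' almost linearly (sinusoidal shape).
#'
#' @param sys A [squeelix_system()] or a bare gamma value.
#' @return A list with `regime` (one of `"circle"`, `"dilute_kinks"`,
#'   `"dense_kinks"`), `gamma`, `m`, `lambda` and (for kinked states) the
#'   kink spacing `d`.
#' @export
classify_regime <- function(sys) {
  g <- if (inherits(sys, "squeelix_system")) twist_expulsion_gamma(sys) else sys
  have_sys <- inherits(sys, "squeelix_system")
  lam1 <- if (have_sys) squeelix_lambda(sys, 1) else 1 # in units of lambda(1)
  m <- ground_state_m(g)
  if (identical(m, "circle")) {
    return(list(regime = "circle", gamma = g, m = NA_real_,
                lambda = lam1, d = Inf))
  }
  # spacing / width ratio is scale free: d / lambda(1) = 2 sqrt(m) K(m)
  ratio <- 2 * sqrt(m) * ellip_K(m)
  regime <- if (ratio > pi) "dilute_kinks" else "dense_kinks"
  list(regime = regime, gamma = g, m = m, lambda = lam1,
       d = ratio * lam1)
}

#' Squeelix ground state summary
#'
#' Convenience wrapper bundling [twist_expulsion_gamma()],
#' [ground_state_m()], [kink_energetics()] and [classify_regime()].
#'
#' @param sys A [squeelix_system()].
#' @return An object of class `squeelix_gs`.
#' @export
squeelix_ground_state <- function(sys) {
  cls <- classify_regime(sys)
  en <- kink_energetics(sys)
  structure(c(cls, list(E0_per_L = en$E0_per_L, DeltaE = en$DeltaE,
                        system = sys)),
            class = "squeelix_gs")
}

#' @export
print.squeelix_gs <- function(x, ...) {
  cat(sprintf("<squeelix ground state> gamma = %.4g -> %s\n", x$gamma, x$regime))
  if (!is.na(x$m)) {
    cat(sprintf("  m = %.6g, kink width lambda = %.4g, spacing d = %.4g\n",
                x$m, x$lambda, x$d))
  }
  cat(sprintf("  E0/L = %.4g, single-kink energy DeltaE = %.4g\n",
              x$E0_per_L, x$DeltaE))
  invisible(x)
}

#' @rdname squeelix_ground_state
#' @param x A `squeelix_gs` object.
#' @param ... Unused.
#' @export
glance.squeelix_gs <- function(x, ...) {
  tibble(gamma = x$gamma, regime = x$regime, m = x$m, lambda = x$lambda,
         d = x$d, E0_per_L = x$E0_per_L, DeltaE = x$DeltaE)
}
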