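#' Shear-coupled filament bundle ("railway track") parameters
#'
#' Two stiff filaments cross-linked by soft springs: bending energy
#' `(B/2) theta'^2` plus shear energy `(K/2) tau^2` with the shear
#' `tau = theta - theta_bar` measured from the mean orientation. The
#' competition screens imposed curvature over the length
#' `lambda = sqrt(B/K)`.
#'
#' @param B Bundle bending constant (> 0).
#' @param K Shear constant (> 0); for a simple two-filament bundle
#'   `K ~ rho_ch w^2 k` (see [bundle_shear_constant()]).
#' @param L Bundle length (> 0).
#' @return An object of class `bundle_system`.
#' @export
bundle_system <- function(B, K, L) {
  assert_positive(B = B, K = K, L = L)
  structure(list(B = B, K = K, L = L), class = "bundle_system")
}

#' Shear constant of a simple two-filament bundle
#'
#' `K = rho_ch w^2 k` for cross-link line density `rho_ch`, lateral width
#' `w` and cross-link spring constant `k` (unit prefactor).
#'
#' @param rho_ch Cross-link line density.
#' @param w Lateral width.
#' @param k Cross-link spring constant.
#' @return The shear constant.
#' @export
bundle_shear_constant <- function(rho_ch, w, k) {
  assert_positive(rho_ch = rho_ch, w = w, k = k)
  rho_ch * w^2 * k
}

#' Elastic screening length of a shear-coupled bundle
#'
#' `lambda = sqrt(B / K)`: deformations decay exponentially on this scale.
#'
#' @param sys A [bundle_system()].
#' @return The screening length.
#' @export
screening_length <- function(sys) {
  stopifnot(inherits(sys, "bundle_system"))
  sqrt(sys$B / sys$K)
}

#' Response to an imposed arc
#'
#' A preformed arc of curvature `kappa0` over a region of length `l_arc`
#' centred at `s0` induces exponentially screened counter-curvature in its
#' surroundings: outside the arc
#' `theta'(s) = -(kappa0 l_arc / (2 lambda)) exp(-|s - s_edge| / lambda)`,
#' so the two counter-arcs exactly cancel the imposed turning angle (the
#' shear is measured from the mean orientation, which forces
#' `int (theta - theta_bar) ds = 0`). Valid for `L >> lambda`.
#'
#' @param sys A [bundle_system()].
#' @param kappa0 Imposed curvature.
#' @param l_arc Arc length of the imposed region (< L).
#' @param s0 Centre of the arc (default mid-bundle `0`; the grid spans
#'   `[-L/2, L/2]`).
#' @param n Grid size (default 1001).
#' @return Tibble with columns `s`, `dtheta` (`theta'(s)`), `tau`
#'   (shear `theta - theta_bar`), `region`.
#' @export
imposed_arc_response <- function(sys, kappa0, l_arc, s0 = 0, n = 1001) {
  stopifnot(inherits(sys, "bundle_system"))
  if (l_arc >= sys$L) abort("need l_arc < L.")
  lam <- screening_length(sys)
  s <- seq(-sys$L / 2, sys$L / 2, length.out = n)
  lo <- s0 - l_arc / 2
  hi <- s0 + l_arc / 2
  A <- kappa0 * l_arc / (2 * lam)
  inside <- s >= lo & s <= hi
  dtheta <- ifelse(inside, kappa0,
                   -A * exp(-abs(ifelse(s < lo, lo - s, s - hi)) / lam))
  # shear: inside the arc theta ramps linearly about the mean; outside it
  # relaxes exponentially from +/- kappa0 l_arc / 2
  tau <- ifelse(inside, kappa0 * (s - s0),
                ifelse(s < lo, -kappa0 * l_arc / 2 * exp(-(lo - s) / lam),
                       kappa0 * l_arc / 2 * exp(-(s - hi) / lam)))
  tibble(s = s, dtheta = dtheta, tau = tau,
         region = ifelse(inside, "arc", "screened"))
}

#' Energy of an imposed (preformed) arc
#'
#' Closed form on the screened profile: the arc itself costs no bending
#' (the curvature is preferred there) but shears the bundle,
#' `E = K kappa0^2 l^3 / 12 + sqrt(B K) kappa0^2 l^2 / 4`. Short arcs
#' (`l << lambda`) grow as `l^2` (the square-root term), long arcs as
#' `l^3` (shear dominated) — very unlike the linear growth of a plain
#' WLC arc.
#'
#' @param sys A [bundle_system()].
#' @param kappa0 Imposed curvature.
#' @param l_arc Arc length(s).
#' @return Energies.
#' @export
imposed_arc_energy <- function(sys, kappa0, l_arc) {
  stopifnot(inherits(sys, "bundle_system"))
  sys$K * kappa0^2 * l_arc^3 / 12 +
    sqrt(sys$B * sys$K) * kappa0^2 * l_arc^2 / 4
}

#' Tail-bridged filament parameters
#'
#' A filament of bending modulus `B` whose backbone is bridged by
#' prestressed elastic tails spanning a distance `d` with spring constant
#' `k`. Beyond `kcrit = 12 B / d^3` the straight state buckles into
#' switchable curved sections.
#'
#' @param B Filament bending modulus (> 0).
#' @param d Tail span (> 0).
#' @param k Tail spring constant (> 0).
#' @return An object of class `tail_system`.
#' @export
tail_system <- function(B, d, k) {
  assert_positive(B = B, d = d, k = k)
  structure(list(B = B, d = d, k = k), class = "tail_system")
}

#' Buckling threshold and bistable curvature amplitude
#'
#' `kcrit = 12 B / d^3`; above threshold the filament is bistable with
#' curvature `kappa = +/- sqrt(1 - kcrit/k) / d` (unit prefactor), zero
#' below.
#'
#' @param sys A [tail_system()].
#' @return Tibble with columns `kcrit`, `buckled`, `kappa_amplitude`.
#' @export
buckling <- function(sys) {
  stopifnot(inherits(sys, "tail_system"))
  kcrit <- 12 * sys$B / sys$d^3
  buckled <- sys$k > kcrit
  tibble(kcrit = kcrit, buckled = buckled,
         kappa_amplitude = if (buckled) sqrt(1 - kcrit / sys$k) / sys$d else 0)
}

#' Landau energy density of the tail-bridged filament
#'
#' Near threshold the energy density per unit length expands as
#' `e(kappa) = (k d^3 / 2) (C1 (kcrit/k - 1) kappa^2 + C2 d^2 kappa^4)`
#' with positive constants `C1`, `C2` (defaults 1). Above threshold the
#' minima sit at `kappa^2 = C1 (1 - kcrit/k) / (2 C2 d^2)`; for
#' `C1 = 2 C2` this is the unit-prefactor amplitude of [buckling()].
#'
#' @param sys A [tail_system()].
#' @param kappa Curvature value(s).
#' @param C1,C2 Landau constants (> 0, default 1).
#' @return Energy density values.
#' @export
landau_energy <- function(sys, kappa, C1 = 1, C2 = 1) {
  stopifnot(inherits(sys, "tail_system"))
  assert_positive(C1 = C1, C2 = C2)
  kcrit <- 12 * sys$B / sys$d^3
  sys$k * sys$d^3 / 2 *
    (C1 * (kcrit / sys$k - 1) * kappa^2 + C2 * sys$d^2 * kappa^4)
}

#' Curvature domain wall under hyper-stiffness
#'
#' When the tail attachment intervals overlap, a gradient penalty
#' `(H/2) int kappa'^2 ds` with `H ~ k d^5` couples neighbouring curvature
#' states ("persistence of curvature"). This relaxes a kappa(-L/2) = -k*,
#' kappa(+L/2) = +k* boundary-value problem to a domain wall whose width
#' grows with `H`. Minimised numerically (L-BFGS-B on a discretised
#' profile with analytic gradient).
#'
#' @param sys A [tail_system()] above threshold.
#' @param H Hyper-stiffness constant; default `k d^5`.
#' @param L Domain length (default `40 d`).
#' @param n Grid size (default 201).
#' @param C1,C2 Landau constants passed to the double-well.
#' @return Tibble with columns `s`, `kappa`, plus attribute `width` (the
#'   distance over which `kappa` crosses between 10% and 90% of the
#'   asymptotic values).
#' @export
curvature_domain_wall <- function(sys, H = NULL, L = 40 * sys$d, n = 201,
                                  C1 = 1, C2 = 1) {
  stopifnot(inherits(sys, "tail_system"))
  if (is.null(H)) H <- sys$k * sys$d^5
  kcrit <- 12 * sys$B / sys$d^3
  if (sys$k <= kcrit) abort("domain walls require k > kcrit.")
  kstar <- sqrt(C1 * (1 - kcrit / sys$k) / (2 * C2)) / sys$d
  s <- seq(-L / 2, L / 2, length.out = n)
  ds <- s[2] - s[1]
  a2 <- sys$k * sys$d^3 / 2 * C1 * (kcrit / sys$k - 1)   # < 0
  a4 <- sys$k * sys$d^3 / 2 * C2 * sys$d^2
  energy <- function(kin) {
    kap <- c(-kstar, kin, kstar)
    sum(a2 * kap^2 + a4 * kap^4) * ds +
      H / 2 * sum(diff(kap)^2) / ds
  }
  grad <- function(kin) {
    kap <- c(-kstar, kin, kstar)
    g <- (2 * a2 * kap + 4 * a4 * kap^3) * ds
    lap <- c(0, diff(diff(kap)), 0)
    g <- g - H * lap / ds
    g[2:(n - 1)]
  }
  init <- kstar * tanh(s[2:(n - 1)] / (2 * sys$d))
  opt <- stats::optim(init, energy, grad, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  kap <- c(-kstar, opt$par, kstar)
  cross <- function(f) approx(kap, s, xout = f * kstar, ties = "ordered")$y
  width <- cross(0.9) - cross(-0.9)
  structure(tibble(s = s, kappa = kap), width = width, kstar = kstar)
}
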