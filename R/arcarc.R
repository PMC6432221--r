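#' Arc/arc twist-kink gas parameter set
#'
#' The arc/arc model treats thermally injected twist-kinks as an ideal gas
#' of quasi-particles separating circular arcs of alternating curvature
#' `+omega`/`-omega`. A chain of `N = S/b` monomers carries a Poisson
#' number of kinks with mean `<k> = N exp(-E)`; flexural fluctuations with
#' persistence length `ell` factor out as a Gaussian convolution.
#'
#' @param S Contour length (> 0).
#' @param omega Arc curvature magnitude (> 0, 1/length).
#' @param ell Flexural persistence length (> 0).
#' @param E_kink Kink energy in thermal units (Boltzmann weight `exp(-E)`).
#' @param b Microscopic step (> 0, default 1).
#' @return An object of class `arcarc_system`.
#' @examples
#' sys <- arcarc_system(S = 100, omega = 0.01, ell = 1000, E_kink = 4)
#' kink_statistics(sys)$mean_k
#' @export
arcarc_system <- function(S, omega, ell, E_kink, b = 1) {
  assert_positive(S = S, omega = omega, ell = ell, b = b)
  if (!is.numeric(E_kink) || !is.finite(E_kink)) abort("`E_kink` must be finite.")
  if (S / b < 1) abort("need S/b >= 1.")
  structure(list(S = S, b = b, omega = omega, ell = ell, E = E_kink),
            class = "arcarc_system")
}

#' @export
print.arcarc_system <- function(x, ...) {
  cat(sprintf(
    "<arcarc_system> S = %g, b = %g, omega = %g, ell = %g, E = %g (<k> = %.4g)\n",
    x$S, x$b, x$omega, x$ell, x$E, mean_kinks(x)))
  invisible(x)
}

mean_kinks <- function(sys) sys$S * exp(-sys$E) / sys$b

#' Kink-number statistics
#'
#' Twist-kinks do not interact, so their number is Poisson with mean
#' `<k> = (S/b) exp(-E)`.
#'
#' @param sys An [arcarc_system()].
#' @param tail Truncate the pmf where the remaining tail mass drops below
#'   this value (default 1e-12).
#' @return A list with `mean_k` and `pmf`, a tibble (`k`, `prob`).
#' @export
kink_statistics <- function(sys, tail = 1e-12) {
  stopifnot(inherits(sys, "arcarc_system"))
  mk <- mean_kinks(sys)
  kmax <- 0
  while (stats::ppois(kmax, mk, lower.tail = FALSE) > tail) kmax <- kmax + 1
  list(mean_k = mk, pmf = tibble(k = 0:kmax, prob = stats::dpois(0:kmax, mk)))
}

# continuous (excited-state) part of the bare deflection density, theta
# vectorised; even in theta, support |theta| < omega S. The I1 term has a
# removable 0/0 at theta_hat -> 1 with limit <k>/2.
arcarc_density_bare <- function(theta, sys) {
  mk <- mean_kinks(sys)
  th_max <- sys$omega * sys$S
  that <- theta / th_max
  out <- numeric(length(theta))
  ok <- abs(that) < 1
  r <- sqrt(1 - that[ok]^2)
  i1 <- ifelse(mk * r < 1e-8, mk / 2, besselI(mk * r, 1) / r)
  out[ok] <- exp(-sys$E) / (2 * sys$omega * sys$b) * exp(-mk) *
    (besselI(mk * r, 0) + i1)
  # Heaviside u(0) = 1/2 at the support edge
  edge <- abs(abs(that) - 1) < .Machine$double.eps * 8
  out[edge] <- out[edge] / 2
  out
}

#' Deflection-angle distribution of the arc/arc model
#'
#' The bare distribution has a continuous Bessel-function part on the
#' compact support `|theta| <= omega S` plus delta atoms of weight
#' `exp(-<k>)/2` at `theta = +/- omega S` (the kink-free ground states).
#' With `with_flexure = TRUE` the whole distribution is convolved with the
#' flexural Gaussian of variance `S / ell`; the atoms become shifted
#' Gaussians (handled analytically) and the continuous part is convolved
#' on the grid by FFT.
#'
#' @param sys An [arcarc_system()].
#' @param with_flexure Convolve with the flexural Gaussian? Default TRUE.
#' @param n_grid Minimum grid size; refined automatically so the Gaussian
#'   width and the Bessel ridge are resolved by at least 8 points.
#' @return A tibble (`theta`, `density`) of class `deflection_distribution`
#'   with attributes `atom_weight` (each atom, before smoothing),
#'   `theta_max`, `sigma` (flexural width or 0) and `with_flexure`.
#' @export
deflection_pdf <- function(sys, with_flexure = TRUE, n_grid = 2001) {
  stopifnot(inherits(sys, "arcarc_system"))
  mk <- mean_kinks(sys)
  th_max <- sys$omega * sys$S
  sigma <- if (with_flexure) sqrt(sys$S / sys$ell) else 0
  dth_needed <- if (with_flexure) min(sigma / 8, th_max / 500) else th_max / 1000
  L <- th_max + if (with_flexure) 8 * sigma else 0
  n <- max(n_grid, 2 * ceiling(L / dth_needed) + 1)
  theta <- seq(-L, L, length.out = n)
  dth <- theta[2] - theta[1]
  dens <- arcarc_density_bare(theta, sys)
  if (with_flexure) {
    half <- ceiling(8 * sigma / dth)
    kern <- dnorm(seq(-half, half) * dth, 0, sigma)
    kern <- kern / sum(kern)
    sm <- convolve(dens, rev(kern), type = "open")
    dens <- sm[(half + 1):(half + n)]
    dens <- dens + (exp(-mk) / 2) *
      (dnorm(theta, -th_max, sigma) + dnorm(theta, th_max, sigma))
  }
  structure(tibble(theta = theta, density = dens),
            atom_weight = exp(-mk) / 2, theta_max = th_max,
            sigma = sigma, with_flexure = with_flexure,
            class = c("deflection_distribution", class(tibble())))
}

#' Cumulative distribution of a deflection distribution
#'
#' Returns a function `F(theta)` built by trapezoidal accumulation of the
#' grid density; for a bare (unconvolved) distribution the edge atoms are
#' added as steps.
#'
#' @param dist A [deflection_pdf()] result.
#' @return A vectorised cdf function.
#' @export
deflection_cdf <- function(dist) {
  theta <- dist$theta
  dens <- dist$density
  dth <- theta[2] - theta[1]
  cdf <- cumsum(dens) * dth
  if (!attr(dist, "with_flexure")) {
    w <- attr(dist, "atom_weight")
    tm <- attr(dist, "theta_max")
    f0 <- approxfun(theta, cdf, yleft = 0, yright = max(cdf))
    return(function(x) {
      f0(x) + w * (x >= -tm) + w * (x >= tm)
    })
  }
  cdf <- cdf / max(cdf)
  approxfun(theta, cdf, yleft = 0, yright = 1)
}

#' Sample end-to-end deflection angles of the arc/arc model
#'
#' Direct Monte-Carlo realisation: Poisson kink number, kink positions
#' uniform on (0, S), initial curvature sign +/- with probability 1/2,
#' sign alternating at each kink; the kink contribution is the alternating
#' arc-length sum times `omega`, plus (optionally) a flexural Gaussian of
#' variance `S/ell`. Sorted kink positions are generated group-wise from
#' exponential spacings, so the sampler is vectorised over chains.
#'
#' @param sys An [arcarc_system()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param with_flexure Add the flexural Gaussian? Default TRUE.
#' @return Numeric vector of `n` deflection angles.
#' @export
sample_deflection <- function(sys, n, seed, with_flexure = TRUE) {
  stopifnot(inherits(sys, "arcarc_system"))
  set.seed(as.integer(seed))
  mk <- mean_kinks(sys)
  S <- sys$S
  kk <- rpois(n, mk)
  sgn0 <- sample(c(-1, 1), n, replace = TRUE)
  A <- numeric(n)
  for (kv in sort(unique(kk))) {
    idx <- which(kk == kv)
    if (kv == 0) {
      A[idx] <- S
      next
    }
    e <- matrix(rexp(length(idx) * (kv + 1)), ncol = kv + 1)
    cs <- t(apply(e, 1, cumsum))
    pos <- S * cs[, 1:kv, drop = FALSE] / cs[, kv + 1]  # sorted uniforms
    alt <- rep_len(c(1, -1), kv)
    # alternating arc sum: 2 * sum((-1)^(j-1) s_j) + (-1)^k S
    A[idx] <- 2 * as.vector(pos %*% alt) + (-1)^kv * S
  }
  th <- sys$omega * sgn0 * A
  if (with_flexure) th <- th + rnorm(n, 0, sqrt(S / sys$ell))
  th
}

#' Sample full arc/arc chains
#'
#' Discrete chains of `S/b` bonds: the curvature sign flips at Poisson
#' kink positions, the bond angle integrates the arc curvature plus
#' Gaussian flexural increments of variance `b/ell`.
#'
#' @param sys An [arcarc_system()].
#' @param n_chains Number of chains (>= 1).
#' @param seed Integer seed.
#' @return A chain tibble (`chain_id`, `s`, `theta`, `x`, `y`) as in
#'   [sample_wlc2d()].
#' @export
sample_arcarc <- function(sys, n_chains, seed) {
  stopifnot(inherits(sys, "arcarc_system"))
  if (n_chains < 1) abort("`n_chains` must be >= 1.")
  set.seed(as.integer(seed))
  N <- floor(sys$S / sys$b + 1e-9)
  mk <- mean_kinks(sys)
  mids <- (seq_len(N) - 0.5) * sys$b
  TH <- matrix(0, N, n_chains)
  for (j in seq_len(n_chains)) {
    k <- rpois(1, mk)
    sgn <- sample(c(-1, 1), 1)
    kap <- if (k == 0) rep(sgn * sys$omega, N) else {
      pos <- sort(runif(k, 0, sys$S))
      sgn * (-1)^findInterval(mids, pos) * sys$omega
    }
    dth <- kap * sys$b + rnorm(N, 0, sqrt(sys$b / sys$ell))
    # bond angle at the bond midpoint convention: integrate curvature to
    # the bond centre
    TH[, j] <- cumsum(c(0, dth[-N])) + dth / 2
  }
  x <- apply(sys$b * cos(TH), 2, cumsum)
  y <- apply(sys$b * sin(TH), 2, cumsum)
  out <- tibble(
    chain_id = rep(seq_len(n_chains), each = N + 1),
    s = rep(sys$b * (0:N), times = n_chains),
    theta = as.vector(rbind(matrix(0, 1, n_chains), TH)),
    x = as.vector(rbind(matrix(0, 1, n_chains), x)),
    y = as.vector(rbind(matrix(0, 1, n_chains), y))
  )
  structure(out, params = sys, seed = as.integer(seed),
            class = c("wlc_ensemble", class(out)))
}

# complex decay rates 1/(2 l_{1,2}) and mixing amplitude R
arcarc_rates <- function(sys) {
  R <- sqrt(as.complex(1 - sys$omega^2 * sys$b^2 * exp(2 * sys$E)))
  r1 <- exp(-sys$E) / sys$b * (1 - R) + 1 / (2 * sys$ell)
  r2 <- exp(-sys$E) / sys$b * (1 + R) + 1 / (2 * sys$ell)
  list(R = R, r1 = r1, r2 = r2, l1 = 1 / (2 * r1), l2 = 1 / (2 * r2))
}

#' Tangent correlation of the arc/arc model
#'
#' `C(s) = (1/2 + 1/2R) exp(-s/(2 l1)) + (1/2 - 1/2R) exp(-s/(2 l2))` with
#' `R = sqrt(1 - omega^2 b^2 exp(2E))` and complex rates
#' `1/(2 l_{1,2}) = exp(-E)/b (1 -/+ R) + 1/(2 ell)`. The two terms are
#' complex conjugates in the oscillatory regime (`omega b exp(E) > 1`, one
#' turn survives the kinks) so the result is always real; reality is
#' asserted, not assumed. Limits: `omega -> 0` recovers the pure 2D WLC
#' correlation; `E -> Inf` gives the damped cosine
#' `exp(-s/(2 ell)) cos(omega s)`.
#'
#' @param s Arc-length separation(s).
#' @param sys An [arcarc_system()].
#' @return Numeric vector `C(s)`.
#' @export
arcarc_correlation <- function(s, sys) {
  stopifnot(inherits(sys, "arcarc_system"))
  assert_nonnegative(s, "s")
  rt <- arcarc_rates(sys)
  v <- (0.5 + 0.5 / rt$R) * exp(-rt$r1 * s) +
    (0.5 - 0.5 / rt$R) * exp(-rt$r2 * s)
  if (max(abs(Im(v))) > 1e-9) abort("correlation failed reality check.")
  Re(v)
}

#' Chain dimensions of the arc/arc model
#'
#' `Re2` and `Rg2` as the same complex combination of 2D WLC expressions
#' evaluated at the complex persistence lengths `l1`, `l2`:
#' `Re2 = (Re2(l1) + Re2(l2))/2 + (Re2(l1) - Re2(l2))/(2R)`. Complex
#' arithmetic is kept throughout and the imaginary part (required
#' < 1e-9 relative) is asserted away at the end.
#'
#' @param sys An [arcarc_system()].
#' @param S Contour length(s); defaults to `sys$S`. Vectorised.
#' @return Tibble with columns `S`, `Re2`, `Rg2`.
#' @export
arcarc_moments <- function(sys, S = sys$S) {
  stopifnot(inherits(sys, "arcarc_system"))
  rt <- arcarc_rates(sys)
  comb <- function(f) {
    v1 <- f(rep(rt$l1, length(S)), S)
    v2 <- f(rep(rt$l2, length(S)), S)
    v <- 0.5 * (v1 + v2) + (0.5 / rt$R) * (v1 - v2)
    if (max(abs(Im(v)) / pmax(abs(v), 1e-300)) > 1e-9) {
      abort("moments failed reality check.")
    }
    Re(v)
  }
  tibble(S = S, Re2 = comb(re2_wlc2d), Rg2 = comb(rg2_wlc2d))
}

#' Linear force-extension response
#'
#' In linear response the mean extension along a small force `f` (thermal
#' units per length) is `<x> = Re2 f / 2`.
#'
#' @param sys An [arcarc_system()].
#' @param f Force(s) in thermal units / length.
#' @return Mean extension(s).
#' @export
linear_extension <- function(sys, f) {
  stopifnot(inherits(sys, "arcarc_system"))
  arcarc_moments(sys)$Re2 * f / 2
}

#' Fourier-Laplace partition function of the arc/arc model
#'
#' Closed form `Z(q, p) = (p + exp(-E)) / (p^2 + q^2 omega^2 b^2 -
#' exp(-2E))` with `q` conjugate to the deflection angle and `p` to the
#' monomer index `n = s/b`. Used as the analytic side of the
#' Laplace-domain consistency test against numerical transformation of the
#' deflection distribution.
#'
#' @param q Fourier variable (angle).
#' @param p Laplace variable (monomer index); convergence needs
#'   `p > exp(-E)`.
#' @param sys An [arcarc_system()].
#' @return Value of `Z(q, p)`.
#' @export
arcarc_partition_laplace <- function(q, p, sys) {
  stopifnot(inherits(sys, "arcarc_system"))
  (p + exp(-sys$E)) / (p^2 + q^2 * sys$omega^2 * sys$b^2 - exp(-2 * sys$E))
}
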