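# Independent numerical oracles used across the test files. Each one
# recomputes a closed form by a different route (quadrature, ODE
# integration, dense grid scan, linear algebra) so implementation and
# check never share code.

# Re^2 and Rg^2 by direct double integration of a correlation function
# C(u): Re2 = 2 int_0^S (S - u) C(u) du, Rg2 = (1/S^2) int (S - u) Re2(u).
dimensions_by_quadrature <- function(Cfun, S, rel.tol = 1e-12) {
  re2_of <- function(Supper) {
    2 * integrate(function(u) (Supper - u) * Cfun(u), 0, Supper,
                  rel.tol = rel.tol, subdivisions = 2000L)$value
  }
  re2 <- re2_of(S)
  rg2 <- integrate(function(u) {
    (S - u) * vapply(u, re2_of, numeric(1))
  }, 0, S, rel.tol = 1e-9, subdivisions = 500L)$value / S^2
  list(Re2 = re2, Rg2 = rg2)
}

# pendulum equation psi'' = -(m/2) sin(2 psi) in u = s/lambda units,
# psi(0) = 0, psi'(0) = 1 (= dn(0)), integrated with deSolve
pendulum_ode_psi <- function(u, m) {
  rhs <- function(t, y, parms) {
    list(c(y[2], -(parms$m / 2) * sin(2 * y[1])))
  }
  sol <- deSolve::ode(c(psi = 0, dpsi = 1), times = u, func = rhs,
                      parms = list(m = m), method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  sol[, "psi"]
}

# root of m E(m) = gamma by dense grid scan plus local refinement
# (independent of the package's bisection)
m_root_by_scan <- function(gamma, n_coarse = 20000L) {
  f <- function(m) m * pracma::ellipke(m)$e - gamma
  grid <- seq(1e-8, 1, length.out = n_coarse)
  vals <- grid * vapply(grid, function(m) pracma::ellipke(min(m, 1 - 1e-16))$k * 0 +
                          (if (m >= 1) 1 else pracma::ellipke(m)$e), numeric(1)) - gamma
  i <- which(vals > 0)[1]
  lo <- grid[i - 1]
  hi <- grid[i]
  fine <- seq(lo, hi, length.out = 100000L)
  fvals <- fine * vapply(fine, function(m) if (m >= 1) 1 else pracma::ellipke(m)$e,
                         numeric(1)) - gamma
  j <- which(fvals > 0)[1]
  # linear interpolation across the final bracket
  x0 <- fine[j - 1]; x1 <- fine[j]
  y0 <- fvals[j - 1]; y1 <- fvals[j]
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

# exact minimiser of the shear-coupled bundle energy with an imposed-arc
# constraint (theta' = kappa0 inside), by dense linear algebra on a grid
bundle_arc_minimizer <- function(B, K, L, l_arc, kappa0, n = 1201) {
  s <- seq(-L / 2, L / 2, length.out = n)
  ds <- s[2] - s[1]
  lo <- -l_arc / 2
  hi <- l_arc / 2
  inside <- which(s >= lo - ds / 4 & s <= hi + ds / 4)
  outside <- setdiff(seq_len(n), inside)
  nu <- length(outside) + 1
  P <- matrix(0, n, nu)
  q <- numeric(n)
  for (i in seq_along(outside)) P[outside[i], i] <- 1
  for (j in seq_along(inside)) {
    P[inside[j], nu] <- 1
    q[inside[j]] <- kappa0 * (s[inside[j]] - s[inside[1]])
  }
  D <- diff(diag(n)) / ds
  seg_in <- (s[-n] >= lo - ds / 4) & (s[-1] <= hi + ds / 4)
  Db <- D[!seg_in, ]
  A <- B * ds * t(Db) %*% Db +
    K * ds * (diag(n) - matrix(1 / n, n, n))
  H <- t(P) %*% A %*% P
  g <- -t(P) %*% (A %*% q)
  u <- solve(H + 1e-12 * mean(diag(H)) * diag(nu), g)
  th <- as.vector(P %*% u + q)
  list(s_mid = (s[-1] + s[-n]) / 2, dtheta = diff(th) / ds,
       l_eff = (length(inside) - 1) * ds)
}

# numerical Fourier-Laplace transform of the bare deflection statistics:
# the unnormalised partition sum is exp(<k>(s)) P_inf(theta, s); atoms
# contribute cos(q omega s) exactly.
numeric_partition_laplace <- function(q, p, sys, n_max = 400) {
  stopifnot(inherits(sys, "arcarc_system"))
  Ffun <- function(n) {  # n = s / b, vectorised over scalar n
    s <- n * sys$b
    if (n == 0) return(1)
    # bypass the constructor: the transform integrates down to s < b
    syss <- structure(list(S = s, b = sys$b, omega = sys$omega,
                           ell = sys$ell, E = sys$E),
                      class = "arcarc_system")
    cont <- integrate(function(th) {
      cos(q * th) * semiflex:::arcarc_density_bare(th, syss)
    }, -sys$omega * s, sys$omega * s, rel.tol = 1e-12,
    subdivisions = 2000L)$value
    mk <- s * exp(-sys$E) / sys$b
    exp(mk) * cont + cos(q * sys$omega * s)
  }
  integrate(function(nv) {
    exp(-p * nv) * vapply(nv, Ffun, numeric(1))
  }, 0, n_max, rel.tol = 1e-9, subdivisions = 2000L)$value
}

# least-squares minimiser of the quadrature cross-section energy,
# extracting the exact quadratic form by finite differences (exact for a
# quadratic) and solving the normal equations
mt_quadrature_minimizer <- function(cs, sigma) {
  f <- function(v) semiflex::cross_section_energy(cs, v[1:2], v[3], sigma,
                                                  method = "quadrature")
  e0 <- f(c(0, 0, 0))
  h <- 1e-3
  g <- numeric(3)
  Hm <- matrix(0, 3, 3)
  for (i in 1:3) {
    ei <- replace(numeric(3), i, h)
    fp <- f(ei)
    fmm <- f(-ei)
    g[i] <- (fp - fmm) / (2 * h)
    Hm[i, i] <- (fp - 2 * e0 + fmm) / h^2
  }
  for (i in 1:2) for (j in (i + 1):3) {
    eij <- replace(replace(numeric(3), i, h), j, h)
    Hm[i, j] <- Hm[j, i] <-
      (f(eij) - f(replace(numeric(3), i, h)) -
         f(replace(numeric(3), j, h)) + e0) / h^2
  }
  v <- -solve(Hm, g)
  list(kappa = v[1:2], eps_bar = v[3], energy = f(v))
}
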