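#' Polymorphic microtubule cross-section
#'
#' Two-layer annular cross-section of a microtubule whose `N`
#' protofilament sectors can switch dimer-wise from a straight to a
#' curved conformation. A switched sector gains `DeltaG` (per dimer of
#' length `b`) and acquires preferred strains `eps_i > 0` (tensile) in the
#' inner layer `Ri < rho < Rm` and `eps_o < 0` (compressive) in the outer
#' layer `Rm < rho < Ro`, reflecting preferred outward curving. The
#' elastic energy density is
#' `Y/2 int (eps(rho, phi) - eps_pref)^2 rho drho dphi` with
#' `eps = -kappa . rho + eps_bar`.
#'
#' @param Ri,Rm,Ro Inner/middle/outer radii (`Ri < Rm < Ro`).
#' @param eps_i,eps_o Preferred strains (`eps_i > 0 > eps_o`).
#' @param N Number of protofilaments (>= 9, default 13).
#' @param b Dimer length (default 8 nm).
#' @param Y Elastic modulus (default 1; sets the energy unit).
#' @param DeltaG Switching free energy per dimer (default 0).
#' @return An object of class `mt_cross_section`.
#' @examples
#' cs <- mt_cross_section(Ri = 8, Rm = 10.25, Ro = 12.5,
#'                        eps_i = 0.01, eps_o = -0.01)
#' characteristic_curvature(cs)
#' @export
mt_cross_section <- function(Ri, Rm, Ro, eps_i, eps_o, N = 13, b = 8,
                             Y = 1, DeltaG = 0) {
  assert_positive(Ri = Ri, Rm = Rm, Ro = Ro, b = b, Y = Y)
  if (!(Ri < Rm && Rm < Ro)) abort("need Ri < Rm < Ro.")
  if (!(eps_i > 0 && eps_o < 0)) abort("need eps_i > 0 > eps_o.")
  if (N < 9) abort("need N >= 9 protofilaments.")
  structure(list(Ri = Ri, Rm = Rm, Ro = Ro, eps_i = eps_i, eps_o = eps_o,
                 N = as.integer(N), b = b, Y = Y, DeltaG = DeltaG),
            class = "mt_cross_section")
}

#' @export
print.mt_cross_section <- function(x, ...) {
  cat(sprintf("<mt_cross_section> N = %d, Ri/Rm/Ro = %g/%g/%g, eps = (%g, %g), kappa1 = %.4g\n",
              x$N, x$Ri, x$Rm, x$Ro, x$eps_i, x$eps_o,
              characteristic_curvature(x)))
  invisible(x)
}

# geometric moments of the annulus and of the preferred-strain field
mt_moments <- function(cs) {
  list(A = pi * (cs$Ro^2 - cs$Ri^2),
       Q11 = pi / 4 * (cs$Ro^4 - cs$Ri^4),
       W2 = cs$eps_i * (cs$Rm^2 - cs$Ri^2) / 2 +
            cs$eps_o * (cs$Ro^2 - cs$Rm^2) / 2,
       W3 = cs$eps_i * (cs$Rm^3 - cs$Ri^3) / 3 +
            cs$eps_o * (cs$Ro^3 - cs$Rm^3) / 3,
       U  = cs$eps_i^2 * (cs$Rm^2 - cs$Ri^2) / 2 +
            cs$eps_o^2 * (cs$Ro^2 - cs$Rm^2) / 2)
}

#' Characteristic polymorphic curvature
#'
#' `kappa1 = (8 / 3 pi) (eps_i (Rm^3 - Ri^3) + eps_o (Ro^3 - Rm^3)) /
#' (Ro^4 - Ri^4)`: the curvature adopted by a half-switched cross-section
#' (block angle pi); the minimiser curvature of a block of angle `phi_p`
#' is `kappa1 sin(phi_p / 2)` in magnitude.
#'
#' @param cs An [mt_cross_section()].
#' @return The characteristic curvature (1/length).
#' @export
characteristic_curvature <- function(cs) {
  stopifnot(inherits(cs, "mt_cross_section"))
  8 / (3 * pi) *
    (cs$eps_i * (cs$Rm^3 - cs$Ri^3) + cs$eps_o * (cs$Ro^3 - cs$Rm^3)) /
    (cs$Ro^4 - cs$Ri^4)
}

# angular integrals over the switched sectors given a 0/1 state vector
sector_integrals <- function(cs, sigma) {
  if (length(sigma) != cs$N) abort("`sigma` must have length N.")
  idx <- which(sigma > 0)
  edges <- 2 * pi * (0:cs$N) / cs$N
  list(Phi = length(idx) * 2 * pi / cs$N,
       Cphi = sum(sin(edges[idx + 1]) - sin(edges[idx])),
       Sphi = sum(-cos(edges[idx + 1]) + cos(edges[idx])))
}

#' Cross-section energy at fixed curvature and stretching
#'
#' Elastic energy per unit length of the two-layer annulus for a given
#' dimer state vector `sigma`, centreline curvature `kappa = (kx, ky)`
#' and mean stretching strain `eps_bar`, plus the switching energy
#' `(DeltaG / b) sum(sigma)`. Evaluated in closed form (the integrand is
#' quadratic; sector/layer moments are analytic) or by panel-wise
#' Gauss-Legendre quadrature over each layer and sector (used as the
#' independent check; agreement is at rounding level).
#'
#' @param cs An [mt_cross_section()].
#' @param kappa Numeric length-2 curvature vector.
#' @param eps_bar Mean stretching strain.
#' @param sigma 0/1 state vector of length `N` (default all straight).
#' @param method `"closed"` or `"quadrature"`.
#' @param n_r,n_phi Quadrature nodes per layer / per sector.
#' @return Energy per unit length.
#' @export
cross_section_energy <- function(cs, kappa = c(0, 0), eps_bar = 0,
                                 sigma = rep(0, cs$N),
                                 method = c("closed", "quadrature"),
                                 n_r = 32, n_phi = 16) {
  stopifnot(inherits(cs, "mt_cross_section"))
  method <- match.arg(method)
  eswitch <- cs$DeltaG / cs$b * sum(sigma)
  if (method == "closed") {
    mm <- mt_moments(cs)
    si <- sector_integrals(cs, sigma)
    quad <- kappa[1]^2 * mm$Q11 + kappa[2]^2 * mm$Q11 + eps_bar^2 * mm$A
    cross <- 2 * kappa[1] * mm$W3 * si$Cphi + 2 * kappa[2] * mm$W3 * si$Sphi -
      2 * eps_bar * mm$W2 * si$Phi
    const <- mm$U * si$Phi
    return(cs$Y / 2 * (quad + cross + const) + eswitch)
  }
  gl_r1 <- pracma::gaussLegendre(n_r, cs$Ri, cs$Rm)
  gl_r2 <- pracma::gaussLegendre(n_r, cs$Rm, cs$Ro)
  total <- 0
  for (n in seq_len(cs$N)) {
    a <- 2 * pi * (n - 1) / cs$N
    bnd <- 2 * pi * n / cs$N
    gl_a <- pracma::gaussLegendre(n_phi, a, bnd)
    for (layer in 1:2) {
      gl <- if (layer == 1) gl_r1 else gl_r2
      ep <- if (sigma[n] > 0) {
        if (layer == 1) cs$eps_i else cs$eps_o
      } else 0
      rho <- gl$x
      wphi <- gl_a$w
      phi <- gl_a$x
      strain <- outer(-rho, kappa[1] * cos(phi) + kappa[2] * sin(phi)) +
        eps_bar - ep
      total <- total + sum((gl$w * rho) %*% t(wphi) * strain^2)
    }
  }
  cs$Y / 2 * total + eswitch
}

#' Minimise the cross-section energy over curvature and stretching
#'
#' Closed-form minimiser of the positive-definite quadratic form in
#' `(kx, ky, eps_bar)` for a given state vector, optionally under an
#' external force `F` (coupling to `eps_bar`) and torque `M` (coupling to
#' `kx`).
#'
#' @param cs An [mt_cross_section()].
#' @param sigma 0/1 state vector.
#' @param F,M External force and torque (default 0).
#' @param M_axis Unit vector giving the bending axis the torque couples
#'   to (default x).
#' @return A list with `kappa`, `eps_bar`, `energy` (includes switching
#'   and load terms).
#' @export
minimize_cross_section <- function(cs, sigma, F = 0, M = 0,
                                   M_axis = c(1, 0)) {
  stopifnot(inherits(cs, "mt_cross_section"))
  mm <- mt_moments(cs)
  si <- sector_integrals(cs, sigma)
  # e = Y/2 (v' Q v - 2 v.r + c) + g.v + eswitch, Q = diag(Q11, Q11, A)
  r <- c(-mm$W3 * si$Cphi, -mm$W3 * si$Sphi, mm$W2 * si$Phi)
  M_axis <- M_axis / sqrt(sum(M_axis^2))
  g <- c(M * M_axis, F)
  v <- (r - g / cs$Y) / c(mm$Q11, mm$Q11, mm$A)
  e <- cross_section_energy(cs, v[1:2], v[3], sigma) + sum(g * v)
  list(kappa = v[1:2], eps_bar = v[3], energy = e)
}

#' Rescaled load parameters of the polymorphic potential
#'
#' Minimising the cross-section energy over `(kappa, eps_bar)` for a
#' single contiguous switched block of angle `phi_p` under loads `(F, M)`
#' gives, in units of `E0 = 4 Y W3^2 / Q11`, the polymorphic potential
#' `e(phi_p) = (c2/2) phi_p^2 + f phi_p - m sin(phi_p/2) -
#' (1/2) sin^2(phi_p/2)` (up to a `phi_p`-independent constant). The
#' generalised force `f` collects the elastic frustration, the switching
#' free energy (linear in `DeltaG`) and the external force; the
#' generalised torque is `m = M / (2 Y W3)`; `c2 = -W2^2 Q11 / (4 W3^2 A)`
#' comes from the stretching relaxation.
#'
#' @param cs An [mt_cross_section()].
#' @param F,M External force and torque.
#' @param DeltaG Switching free energy per dimer; defaults to the value
#'   stored in `cs`.
#' @return A list with `f`, `m`, `c2`, `E0`.
#' @export
mt_rescaled_loads <- function(cs, F = 0, M = 0, DeltaG = cs$DeltaG) {
  mm <- mt_moments(cs)
  E0 <- 4 * cs$Y * mm$W3^2 / mm$Q11
  list(f = (cs$Y * mm$U / 2 + DeltaG * cs$N / (2 * pi * cs$b) +
              F * mm$W2 / mm$A) / E0,
       m = M / (2 * cs$Y * mm$W3),
       c2 = -mm$W2^2 * mm$Q11 / (4 * mm$W3^2 * mm$A),
       E0 = E0)
}

#' Polymorphic potential over the block angle
#'
#' The single-block potential in rescaled variables,
#' `e(phi_p) = (c2/2) phi_p^2 + f phi_p - m sin(phi_p/2) -
#' (1/2) sin^2(phi_p/2)`, with the geometric coefficient `c2` taken from
#' the cross-section. `phi_p = 0` is the straight long state (L),
#' `phi_p = 2 pi` the fully switched straight-but-shortened state (S);
#' interior minima are macroscopically curved states (C) with curvature
#' magnitude `kappa1 sin(phi_p/2)`.
#'
#' @param cs An [mt_cross_section()].
#' @param phi_p Block angle(s) in `[0, 2 pi]`.
#' @param f,m Rescaled generalised force and torque.
#' @return Numeric vector of rescaled energies.
#' @export
polymorphic_potential <- function(cs, phi_p, f, m) {
  stopifnot(inherits(cs, "mt_cross_section"))
  if (any(phi_p < -1e-9 | phi_p > 2 * pi + 1e-9)) {
    abort("`phi_p` must lie in [0, 2 pi].")
  }
  phi_p <- pmin(pmax(phi_p, 0), 2 * pi)
  c2 <- mt_rescaled_loads(cs)$c2
  c2 / 2 * phi_p^2 + f * phi_p - m * sin(phi_p / 2) - 0.5 * sin(phi_p / 2)^2
}

# energies and location of the three candidate states on a phi grid
candidate_states <- function(cs, f, m, phi = seq(0, 2 * pi, length.out = 721)) {
  e <- polymorphic_potential(cs, phi, f, m)
  n <- length(e)
  interior <- which(diff(sign(diff(e))) > 0) + 1
  interior <- interior[interior > 1 & interior < n]
  if (length(interior)) {
    iC <- interior[which.min(e[interior])]
    phiC <- phi[iC]
    eC <- e[iC]
  } else {
    phiC <- NA_real_
    eC <- NA_real_
  }
  list(e_L = e[1], e_S = e[n], e_C = eC, phi_C = phiC)
}

#' Phase diagram of the polymorphic microtubule
#'
#' For each point of an `(f, m)` grid, ranks the straight-long (L),
#' curved (C, interior minimum) and straight-short (S) states of the
#' polymorphic potential by energy.
#'
#' @param cs An [mt_cross_section()].
#' @param f_grid,m_grid Numeric grids (>= 20 points each recommended).
#' @param n_phi Resolution of the block-angle grid.
#' @return A tibble with columns `f`, `m`, `e_L`, `e_C`, `e_S`, `phi_C`,
#'   `state` (lowest-energy state) and `ordering` (e.g. `"C<L<S"`).
#' @export
phase_diagram <- function(cs, f_grid, m_grid, n_phi = 721) {
  stopifnot(inherits(cs, "mt_cross_section"))
  phi <- seq(0, 2 * pi, length.out = n_phi)
  grid <- tidyr::expand_grid(f = f_grid, m = m_grid)
  res <- purrr::pmap(grid, function(f, m) {
    st <- candidate_states(cs, f, m, phi)
    en <- c(L = st$e_L, C = st$e_C, S = st$e_S)
    present <- !is.na(en)
    ord <- names(sort(en[present]))
    tibble(e_L = st$e_L, e_C = st$e_C, e_S = st$e_S, phi_C = st$phi_C,
           state = ord[1], ordering = paste(ord, collapse = "<"))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Quasi-static hysteresis sweep of the generalised force
#'
#' Sweeps `f` up and then back down at fixed `m`, tracking the local
#' minimum of the polymorphic potential the system currently occupies
#' (steepest-descent to the nearest minimum on a fine block-angle grid).
#' Discontinuous jumps of the occupied `phi_p` mark mechanical
#' instabilities; differing jump locations between the two sweep
#' directions form a hysteresis loop.
#'
#' @param cs An [mt_cross_section()].
#' @param f_seq Increasing sequence of generalised forces.
#' @param m Fixed generalised torque.
#' @param n_phi Block-angle grid resolution.
#' @return A tibble (`direction`, `f`, `phi`, `energy`) with attribute
#'   `hysteretic` (TRUE if the two branches separate by more than the grid
#'   step somewhere).
#' @export
hysteresis_sweep <- function(cs, f_seq, m, n_phi = 1441) {
  stopifnot(inherits(cs, "mt_cross_section"))
  phi <- seq(0, 2 * pi, length.out = n_phi)
  descend <- function(i, e) {
    repeat {
      if (i > 1 && e[i - 1] < e[i]) i <- i - 1
      else if (i < length(e) && e[i + 1] < e[i]) i <- i + 1
      else return(i)
    }
  }
  sweep_dir <- function(fs, start_idx = NULL) {
    out <- numeric(length(fs))
    en <- numeric(length(fs))
    i <- start_idx
    for (k in seq_along(fs)) {
      e <- polymorphic_potential(cs, phi, fs[k], m)
      if (is.null(i)) i <- which.min(e)
      i <- descend(i, e)
      out[k] <- phi[i]
      en[k] <- e[i]
    }
    list(phi = out, energy = en, last = i)
  }
  up <- sweep_dir(f_seq)
  down <- sweep_dir(rev(f_seq), start_idx = up$last)
  res <- dplyr::bind_rows(
    tibble(direction = "up", f = f_seq, phi = up$phi, energy = up$energy),
    tibble(direction = "down", f = rev(f_seq), phi = down$phi,
           energy = down$energy))
  gap <- abs(up$phi - rev(down$phi))
  structure(res, hysteretic = any(gap > 4 * pi / n_phi))
}
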