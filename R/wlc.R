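#' Worm-like-chain parameter set
#'
#' Bundles the three lengths that define an ideal worm-like chain (WLC) —
#' persistence length `ell`, segment (monomer) size `b` and contour length
#' `S` — together with the spatial dimension `D`. All other WLC functions
#' take this object. Lengths share one unit (conventionally the monomer
#' size, `b = 1`).
#'
#' @param ell Persistence length (> 0). The decay length of the
#'   tangent-tangent correlation, `ell = B / kBT` with `B` the bending
#'   modulus.
#' @param S Contour length (>= 0).
#' @param b Segment size used by the discrete sampler (> 0, default 1).
#' @param D Spatial dimension, 2 or 3. The correlation decays as
#'   `exp(-s / (2 ell))` in 2D and `exp(-s / ell)` in 3D (two transverse
#'   directions decorrelate the tangent).
#' @return An object of class `wlc_params`.
#' @examples
#' p <- wlc_params(ell = 10, S = 200)
#' tangent_correlation(c(0, 10, 20), p)
#' @export
wlc_params <- function(ell, S, b = 1, D = 2) {
  assert_positive(ell = ell, b = b)
  assert_nonnegative(S, "S")
  if (!D %in% c(2L, 3L)) abort("`D` must be 2 or 3.")
  structure(list(ell = ell, b = b, S = S, D = as.integer(D)),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("<wlc_params> ell = %g, b = %g, S = %g, D = %d  (S/ell = %.3g)\n",
              x$ell, x$b, x$S, x$D, x$S / x$ell))
  invisible(x)
}

#' Tangent-tangent correlation of the WLC
#'
#' `C(s) = exp(-s / (2 ell))` in 2D and `exp(-s / ell)` in 3D.
#'
#' @param s Arc-length separation(s), >= 0.
#' @param p A [wlc_params()] object.
#' @return Numeric vector of correlations in (0, 1].
#' @export
tangent_correlation <- function(s, p) {
  stopifnot(inherits(p, "wlc_params"))
  assert_nonnegative(s, "s")
  if (p$D == 2L) exp(-s / (2 * p$ell)) else exp(-s / p$ell)
}

# Re^2 of the 2D WLC; complex-safe (used with complex ell by the arc/arc
# module). Series expansion below x = S/(2 ell) ~ 0.05 avoids cancellation.
re2_wlc2d <- function(ell, S) {
  x <- S / (2 * ell)
  small <- is.finite(abs(x)) & abs(x) < 0.05
  out <- x
  if (any(small)) {
    xs <- x[small]
    term <- xs^2 / 2
    acc <- term
    for (n in 3:12) {
      term <- -term * xs / n
      acc <- acc + term
    }
    out[small] <- 8 * ell[small]^2 * acc
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- 4 * ell[!small] * S[!small] -
      8 * ell[!small]^2 * (1 - exp(-xl))
  }
  out
}

rg2_wlc2d <- function(ell, S) {
  x <- S / (2 * ell)
  small <- is.finite(abs(x)) & abs(x) < 0.05
  out <- x
  if (any(small)) {
    # Rg^2 = 4 ell^2 (x^2/12 - x^3/60 + x^4/360 - ...), denominators
    # multiply by 5, 6, 7, ...
    xs <- x[small]
    term <- xs^2 / 12
    acc <- term
    den <- 5
    for (n in 1:10) {
      term <- -term * xs / den
      acc <- acc + term
      den <- den + 1
    }
    out[small] <- 4 * ell[small]^2 * acc
  }
  if (any(!small)) {
    xl <- x[!small]
    el <- ell[!small]
    Sl <- S[!small]
    g <- (1 - exp(-xl)) / xl
    out[!small] <- 2 * el * Sl / 3 - 4 * el^2 * (1 - (2 / xl) * (1 - g))
  }
  out
}

#' Mean-square end-to-end distance and radius of gyration of the WLC
#'
#' Closed forms obtained by double integration of the tangent correlation:
#' in 2D, `Re2 = 4 ell S - 8 ell^2 (1 - exp(-S / (2 ell)))`, with the
#' matching gyration radius; the 3D result follows by replacing `ell` with
#' `ell / 2`. The rod limit gives `Re2 -> S^2`, `Rg2 -> S^2 / 12`; the
#' flexible limit `Re2 -> 4 ell S` (2D).
#'
#' @param p A [wlc_params()] object.
#' @param S Contour length(s); defaults to `p$S`. Vectorised.
#' @return A tibble with columns `S`, `Re2`, `Rg2`.
#' @export
chain_dimensions <- function(p, S = p$S) {
  stopifnot(inherits(p, "wlc_params"))
  assert_nonnegative(S, "S")
  ell_eff <- if (p$D == 2L) p$ell else p$ell / 2
  e <- rep_len(ell_eff, length(S))
  tibble(S = S, Re2 = Re(re2_wlc2d(e, S)), Rg2 = Re(rg2_wlc2d(e, S)))
}

#' Sample discrete 2D worm-like chains
#'
#' Generates `n_chains` discrete chains of `S/b` bonds of fixed length `b`.
#' Successive bond angles differ by independent Gaussian increments of
#' variance `b / ell`, the 2D convention under which the ensemble
#' tangent correlation matches `exp(-s / (2 ell))` exactly. The first bond
#' points along x (`theta = 0`).
#'
#' @param p A [wlc_params()] object (`D` must be 2 and `S/b >= 2`).
#' @param n_chains Number of chains (>= 1).
#' @param seed Integer seed; recorded in the result's attributes.
#' @return A tibble of class `wlc_ensemble` with columns
#'   `chain_id`, `s` (arc length of the node), `theta` (angle of the bond
#'   ending at the node; 0 for the launch node), `x`, `y`. Attributes
#'   `params` and `seed` record the generation conditions.
#' @export
sample_wlc2d <- function(p, n_chains, seed) {
  stopifnot(inherits(p, "wlc_params"))
  if (p$D != 2L) abort("sample_wlc2d() samples 2D chains; use D = 2.")
  if (n_chains < 1) abort("`n_chains` must be >= 1.")
  nb <- p$S / p$b
  if (abs(nb - round(nb)) > 1e-9) {
    warn("`S/b` is not an integer; rounding down.")
  }
  N <- floor(nb + 1e-9)
  if (N < 2) abort("need S/b >= 2.")
  set.seed(as.integer(seed))
  # bond angles: theta_1 = 0, increments afterwards
  dth <- matrix(rnorm((N - 1) * n_chains, 0, sqrt(p$b / p$ell)), nrow = N - 1)
  th <- rbind(0, apply(dth, 2, cumsum))          # N x n
  x <- apply(p$b * cos(th), 2, cumsum)
  y <- apply(p$b * sin(th), 2, cumsum)
  out <- tibble(
    chain_id = rep(seq_len(n_chains), each = N + 1),
    s = rep(p$b * (0:N), times = n_chains),
    theta = as.vector(rbind(matrix(0, 1, n_chains), th)),
    x = as.vector(rbind(matrix(0, 1, n_chains), x)),
    y = as.vector(rbind(matrix(0, 1, n_chains), y))
  )
  structure(out, params = p, seed = as.integer(seed),
            class = c("wlc_ensemble", class(out)))
}

# bond-angle matrix (N x n_chains) from an ensemble tibble
bond_angle_matrix <- function(chains) {
  n <- length(unique(chains$chain_id))
  rows <- nrow(chains) / n
  th <- matrix(chains$theta, nrow = rows)
  th[-1, , drop = FALSE]                         # drop launch-node duplicate
}

#' Ensemble tangent-tangent correlation
#'
#' Estimates `C(s) = <cos(theta(s) - theta(0))>` from bond-bond angle
#' differences at integer multiples of the bond length, averaged over all
#' starting bonds and chains.
#'
#' @param chains A chain ensemble from [sample_wlc2d()] (or any tibble with
#'   `chain_id`, `s`, `theta` on a uniform grid).
#' @param max_lag Largest arc-length lag, in bonds; default half the chain.
#' @return Tibble with columns `s`, `C`, `stderr`.
#' @export
ensemble_correlation <- function(chains, max_lag = NULL) {
  p <- attr(chains, "params")
  b <- if (!is.null(p)) p$b else diff(chains$s[1:2])
  th <- bond_angle_matrix(chains)
  N <- nrow(th)
  if (is.null(max_lag)) max_lag <- floor(N / 2)
  max_lag <- min(max_lag, N - 1)
  ks <- seq_len(max_lag)
  res <- vapply(ks, function(k) {
    d <- cos(th[(1 + k):N, , drop = FALSE] - th[1:(N - k), , drop = FALSE])
    perch <- colMeans(d)
    c(mean(perch), sd(perch) / sqrt(length(perch)))
  }, numeric(2))
  tibble(s = b * ks, C = res[1, ], stderr = res[2, ])
}

#' Estimate the persistence length of a sampled ensemble
#'
#' Fits the exponential decay of the ensemble tangent correlation by least
#' squares on `log C(s)` and converts the slope with the dimension
#' convention (`ell = -1 / (2 slope)` in 2D). The fit window defaults to
#' `s` between one bond and `min(ell_guess, S/4)`, with `ell_guess` taken
#' from the first `1/e` crossing of `C(s)`; large-`s` lags are noisy and
#' excluded. Straight rods (no crossing, correlation ~ 1) are flagged
#' `rigid` with an infinite estimate.
#'
#' @param chains A chain ensemble from [sample_wlc2d()].
#' @param D Dimension convention for the conversion (default 2).
#' @param fit_window Optional numeric length-2 arc-length window overriding
#'   the default.
#' @return An object of class `plfit` with elements `ell` (estimate),
#'   `rigid` (flag), `window`, `n_chains`, `correlation` (the fitted
#'   table) and `r.squared`.
#' @export
estimate_persistence_length <- function(chains, D = 2, fit_window = NULL) {
  n <- length(unique(chains$chain_id))
  corr <- ensemble_correlation(chains)
  b <- corr$s[1]
  S <- max(chains$s)
  below <- which(corr$C < exp(-1))
  if (length(below) == 0 && min(corr$C) > 0.99) {
    # straight rods: correlation does not decay measurably
    return(structure(list(ell = Inf, rigid = TRUE, window = NULL,
                          n_chains = n, correlation = corr,
                          r.squared = NA_real_),
                     class = "plfit"))
  }
  ell_guess <- if (length(below) == 0) Inf else {
    # 1/e crossing sits at s = 2 ell in 2D, s = ell in 3D
    if (D == 2) corr$s[below[1]] / 2 else corr$s[below[1]]
  }
  win <- if (is.null(fit_window)) c(b, min(ell_guess, S / 4)) else fit_window
  sel <- corr$s >= win[1] & corr$s <= win[2]
  if (sum(sel) < 3) {  # widen for very stiff or short chains
    sel <- seq_len(min(max(3, sum(sel)), nrow(corr)))
    win <- range(corr$s[sel])
  }
  dat <- corr[sel, ]
  if (any(dat$C <= 0)) {
    warn("non-positive correlations in fit window; shrinking window.")
    keep <- seq_len(which(dat$C <= 0)[1] - 1)
    dat <- dat[keep, ]
    win[2] <- max(dat$s)
  }
  fit <- lm(log(C) ~ s, data = dat)
  slope <- coef(fit)[["s"]]
  ell <- if (D == 2) -1 / (2 * slope) else -1 / slope
  structure(list(ell = ell, rigid = FALSE, window = win, n_chains = n,
                 correlation = corr,
                 r.squared = summary(fit)$r.squared),
            class = "plfit")
}

#' @export
print.plfit <- function(x, ...) {
  if (x$rigid) {
    cat("<plfit> rigid ensemble: correlation does not decay (ell -> Inf)\n")
  } else {
    cat(sprintf("<plfit> ell = %.4g (window %.3g..%.3g, %d chains, R^2 = %.4f)\n",
                x$ell, x$window[1], x$window[2], x$n_chains, x$r.squared))
  }
  invisible(x)
}

#' @rdname estimate_persistence_length
#' @param x A `plfit` object.
#' @param ... Unused.
#' @export
tidy.plfit <- function(x, ...) {
  tibble(term = "ell", estimate = x$ell, rigid = x$rigid)
}

#' @rdname estimate_persistence_length
#' @export
glance.plfit <- function(x, ...) {
  tibble(ell = x$ell, rigid = x$rigid, n_chains = x$n_chains,
         r.squared = x$r.squared,
         window_lo = if (is.null(x$window)) NA_real_ else x$window[1],
         window_hi = if (is.null(x$window)) NA_real_ else x$window[2])
}
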