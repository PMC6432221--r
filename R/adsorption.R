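#' Wall-adsorption parameter set
#'
#' Parameters for a semiflexible chain at a flat wall: persistence length
#' `ell`, monomer size `b` (the reaction distance for chemisorption),
#' contour length `S`, and optionally the adsorption-potential range
#' `Delta` with strength `u` (reversible adsorption), the intrinsic
#' reaction frequency `q` and the final 2D monomer concentration `c2inf`
#' (irreversible layers). The semiflexible regime `b <= ell` is assumed.
#'
#' @param ell Persistence length (> 0).
#' @param S Chain length (> 0).
#' @param b Monomer size / reaction distance (> 0, default 1).
#' @param Delta Adsorption-potential range (optional).
#' @param u Adsorption strength in thermal units (optional).
#' @param q Intrinsic reaction frequency (default 1).
#' @param c2inf Final 2D monomer concentration (optional).
#' @return An object of class `adsorption_system`.
#' @examples
#' sys <- adsorption_system(ell = 10, S = 250)
#' chemisorption_scales(sys$ell, sys$b)
#' @export
adsorption_system <- function(ell, S, b = 1, Delta = NULL, u = NULL,
                              q = 1, c2inf = NULL) {
  assert_positive(ell = ell, S = S, b = b, q = q)
  if (b > ell) abort("semiflexible regime requires b <= ell.")
  if (!is.null(Delta)) assert_positive(Delta = Delta)
  if (!is.null(c2inf)) assert_positive(c2inf = c2inf)
  structure(list(ell = ell, b = b, S = S, Delta = Delta, u = u, q = q,
                 c2inf = c2inf),
            class = "adsorption_system")
}

#' @export
print.adsorption_system <- function(x, ...) {
  sc <- chemisorption_scales(x$ell, x$b)
  cat(sprintf("<adsorption_system> ell = %g, b = %g, S = %g (s0 = %.3g, S* = %.3g)\n",
              x$ell, x$b, x$S, sc$s0, sc$S_star))
  invisible(x)
}

#' Loop and tail statistical weights
#'
#' Piecewise power laws for the partition function of a chain fragment at
#' a repulsive wall: stiff loops decay as `s^(-5/2)` (crossing over to the
#' flexible first-passage law `s^(-3/2)` around `s = 2 ell`), stiff tails
#' as `s^(-1/4)` (crossing to `s^(-1/2)` around `s = ell`). Prefactors are
#' fixed by continuity at the crossover; overall normalisation is
#' arbitrary (relative weights).
#'
#' @param s Fragment size(s) (> 0).
#' @param sys An [adsorption_system()].
#' @param kind `"loop"` or `"tail"`.
#' @return Numeric vector of relative weights.
#' @export
fragment_weight <- function(s, sys, kind = c("loop", "tail")) {
  kind <- match.arg(kind)
  assert_positive(s = s)
  ell <- sys$ell
  if (kind == "loop") {
    sc <- 2 * ell
    ifelse(s <= sc, s^(-2.5), sc^(-1) * s^(-1.5))
  } else {
    ifelse(s <= ell, s^(-0.25), ell^(0.25) * s^(-0.5))
  }
}

#' Chemisorption length scales
#'
#' The zipping-loop size `s0 = (ell b^2)^(1/3)` (the longest section that
#' stays within the reaction distance of the wall) and the
#' multiple-nucleation chain length `S* = ell^(5/3) b^(-2/3)` beyond which
#' nucleation of large adsorption loops preempts single-front zipping.
#' Unit prefactors throughout; both are order-of-magnitude scales.
#'
#' @param ell Persistence length(s) (> 0).
#' @param b Monomer size(s) (> 0).
#' @return Tibble with columns `ell`, `b`, `s0`, `S_star`.
#' @export
chemisorption_scales <- function(ell, b) {
  assert_positive(ell = ell, b = b)
  tibble(ell = ell, b = b,
         s0 = (ell * b^2)^(1 / 3),
         S_star = ell^(5 / 3) * b^(-2 / 3))
}

#' Reversible-adsorption thresholds
#'
#' Critical adsorption strength `uc = (Delta^2 ell)^(-1/3)` (Odijk
#' confinement vs. binding energy balance), reduced temperature
#' `tau = (u - uc)/uc`, and, in the strong-adsorption regime
#' `tau > (Delta/ell)^(2/3)`, the layer thickness `h = Delta / tau^(3/2)`
#' (then smaller than `ell`). Unit prefactors.
#'
#' @param sys An [adsorption_system()] with `Delta` and `u` set
#'   (`Delta < ell`).
#' @return Tibble with columns `uc`, `tau`, `strong`, `h`, `status`.
#' @export
adsorption_thresholds <- function(sys) {
  stopifnot(inherits(sys, "adsorption_system"))
  if (is.null(sys$Delta) || is.null(sys$u)) {
    abort("`Delta` and `u` must be set for adsorption thresholds.")
  }
  if (sys$Delta >= sys$ell) abort("need Delta < ell.")
  uc <- (sys$Delta^2 * sys$ell)^(-1 / 3)
  if (sys$u <= uc) {
    return(tibble(uc = uc, tau = (sys$u - uc) / uc, strong = FALSE,
                  h = NA_real_, status = "not adsorbed"))
  }
  tau <- (sys$u - uc) / uc
  strong <- tau > (sys$Delta / sys$ell)^(2 / 3)
  tibble(uc = uc, tau = tau, strong = strong,
         h = if (strong) sys$Delta / tau^(3 / 2) else NA_real_,
         status = if (strong) "strongly adsorbed" else "weakly adsorbed")
}

#' Monomer-wall contact probability for chemisorption
#'
#' Probability (relative, `P = 1` on the zipped plateau) that a monomer a
#' chemical distance `s` from an existing bond lies within the reaction
#' distance: `P = 1` for `s < s0`; `(s/s0)^(-5/2)` for `s0 < s < ell`
#' (stiff loop); `(ell/s0)^(-5/2) (s/ell)^(-3/2)` beyond (flexible loop).
#' Continuous at both boundaries by construction.
#'
#' @param s Chemical distance(s) (> 0).
#' @param sys An [adsorption_system()].
#' @return Numeric vector of relative contact probabilities.
#' @export
contact_probability <- function(s, sys) {
  stopifnot(inherits(sys, "adsorption_system"))
  assert_positive(s = s)
  s0 <- (sys$ell * sys$b^2)^(1 / 3)
  ell <- sys$ell
  ifelse(s < s0, 1,
         ifelse(s < ell, (s / s0)^(-2.5),
                (ell / s0)^(-2.5) * (s / ell)^(-1.5)))
}

# mass of a wrapped normal N(0, s/ell) within |theta| < dtheta: the
# acceptance of the orientation window for a *free* flexural angle. Used
# to de-bias the flexible-window contact statistics, where the angle at
# the wall is flexurally randomised and the window acceptance still
# carries the O(exp(-s/2ell)) uniformisation transient.
wrapped_angle_mass <- function(s, ell, dtheta) {
  sig2 <- s / ell
  m <- dtheta / pi
  for (k in 1:12) {
    m <- m + (2 / pi) * exp(-k^2 * sig2 / 2) * sin(k * dtheta) / k
  }
  m
}

# antiderivative of contact_probability from 0 (closed form, piecewise)
contact_prob_integral <- function(x, s0, ell) {
  A3 <- (ell / s0)^(-2.5) * ell^1.5
  ifelse(x <= s0, x,
    ifelse(x <= ell,
      s0 + (2 / 3) * s0^2.5 * (s0^(-1.5) - x^(-1.5)),
      s0 + (2 / 3) * s0^2.5 * (s0^(-1.5) - ell^(-1.5)) +
        2 * A3 * (ell^(-0.5) - x^(-0.5))))
}

# inverse of contact_prob_integral measured from lo
contact_prob_invcdf <- function(lo, u, s0, ell) {
  v <- contact_prob_integral(lo, s0, ell) + u
  if (v <= s0) return(v)
  F2max <- s0 + (2 / 3) * s0^2.5 * (s0^(-1.5) - ell^(-1.5))
  if (v <= F2max) {
    t <- s0^(-1.5) - (v - s0) * 1.5 / s0^2.5
    return(t^(-2 / 3))
  }
  A3 <- (ell / s0)^(-2.5) * ell^1.5
  t <- ell^(-0.5) - (v - F2max) / (2 * A3)
  t^(-2)
}

#' Kinetic Monte-Carlo of chemisorption zipping vs. loop nucleation
#'
#' Gillespie-type competition, per run, between advance of the zipping
#' front (steps of size `s0` at rate `q s0 / b`) and nucleation of an
#' adsorption loop beyond the front (total rate `(q/b)` times the
#' integrated contact probability; loop size drawn by inverse CDF from the
#' piecewise `P(s)`). Rates are frozen between events; the number of zip
#' steps between nucleations is drawn geometrically from the embedded jump
#' chain. A nucleated loop of size `s` larger than both `ell` and the
#' length already zipped preempts single-front zipping (it wins the race
#' over the scale it spans); smaller loops merely advance the front.
#'
#' @param sys An [adsorption_system()].
#' @param n_runs Number of independent runs.
#' @param seed Integer seed.
#' @param S Chain length; defaults to `sys$S`.
#' @return A list with `fraction_preempted`, `n_runs`, `S` and the scale
#'   table from [chemisorption_scales()].
#' @export
simulate_zipping <- function(sys, n_runs, seed, S = sys$S) {
  stopifnot(inherits(sys, "adsorption_system"))
  set.seed(as.integer(seed))
  s0 <- (sys$ell * sys$b^2)^(1 / 3)
  ell <- sys$ell
  if (S <= s0) abort("need S > s0.")
  one_run <- function() {
    x <- sys$b      # one bound monomer to start
    Rz <- sys$q * s0 / sys$b
    while (x < S) {
      hi <- S - x
      if (hi <= s0) return(FALSE)
      Rn <- sys$q / sys$b *
        (contact_prob_integral(hi, s0, ell) - contact_prob_integral(s0, s0, ell))
      G <- rgeom(1, Rn / (Rn + Rz))
      if (x + G * s0 >= S) return(FALSE)
      x <- x + G * s0
      hi <- S - x
      if (hi <= s0) return(FALSE)
      Rn <- sys$q / sys$b *
        (contact_prob_integral(hi, s0, ell) - contact_prob_integral(s0, s0, ell))
      s <- contact_prob_invcdf(s0, runif(1) * Rn * sys$b / sys$q, s0, ell)
      if (s > ell && s > x) return(TRUE)
      x <- x + s
    }
    FALSE
  }
  frac <- mean(vapply(seq_len(n_runs), function(i) one_run(), logical(1)))
  list(fraction_preempted = frac, n_runs = n_runs, S = S,
       scales = chemisorption_scales(sys$ell, sys$b))
}

#' Zipping crossover length
#'
#' Scans chain lengths around `S* = ell^(5/3) b^(-2/3)` with
#' [simulate_zipping()] and log-interpolates the chain length at which
#' half of the runs are preempted by a distant nucleation.
#'
#' @param ell Persistence length.
#' @param b Monomer size (default 1).
#' @param n_runs Runs per chain length (default 400).
#' @param seed Integer seed.
#' @param S_factors Multiples of `S*` to scan.
#' @return A list with `S50`, `S_star` and the scan `table`.
#' @export
zipping_crossover <- function(ell, b = 1, n_runs = 400, seed = 1,
                              S_factors = c(0.25, 0.5, 1, 2, 4, 8)) {
  S_star <- ell^(5 / 3) * b^(-2 / 3)
  Ss <- S_star * S_factors
  sys <- adsorption_system(ell = ell, S = max(Ss), b = b)
  fr <- vapply(seq_along(Ss), function(i) {
    simulate_zipping(sys, n_runs, seed + i, S = Ss[i])$fraction_preempted
  }, numeric(1))
  S50 <- exp(approx(fr, log(Ss), xout = 0.5, ties = "ordered")$y)
  list(S50 = S50, S_star = S_star, table = tibble(S = Ss, fraction = fr))
}

#' Proximal concentration profile (closed form)
#'
#' In the proximal layer `b < z < ell` the stiff loops of size `s` extend
#' to heights `z ~ s^(3/2) / ell^(1/2)`; converting the loop-size
#' distribution `Zl ~ s^(-5/2)` gives `c(z) ~ z^(-4/3)`, here normalised
#' to unit integral over `[b, ell]`.
#'
#' @param z Height(s) above the wall.
#' @param sys An [adsorption_system()].
#' @return Tibble with columns `z`, `c`, `in_range`.
#' @export
proximal_profile <- function(z, sys) {
  stopifnot(inherits(sys, "adsorption_system"))
  assert_positive(z = z)
  norm <- 3 * (sys$b^(-1 / 3) - sys$ell^(-1 / 3))
  tibble(z = z, c = z^(-4 / 3) / norm,
         in_range = z > sys$b & z < sys$ell)
}

#' Loop-size to height map
#'
#' A stiff loop of size `s` extends into the solution over
#' `z ~ s^(3/2) / ell^(1/2)` (unit prefactor).
#'
#' @param s Loop size(s).
#' @param sys An [adsorption_system()].
#' @return Heights.
#' @export
loop_height_map <- function(s, sys) {
  s^(3 / 2) / sqrt(sys$ell)
}

#' Crossing-angle statistics of sequentially adsorbed stiff chains
#'
#' Two straight adsorbed lines that do cross have crossing angle
#' distributed as `P(theta) = sin(theta)/2` on `(0, pi)` (parallel lines
#' do not cross), with cumulative `(1 - cos theta)/2 ~ theta^2/4` at small
#' angles. An incoming filament aligns rather than crosses when the angle
#' is below `theta_max = (b/ell)^(1/3)` (bending penalty `ell theta^2/s0`
#' of order one); the alignment probability doubles the one-sided
#' small-angle cumulative.
#'
#' @param theta Crossing angle(s) in (0, pi).
#' @param sys An [adsorption_system()].
#' @return Tibble (`theta`, `pdf`, `cdf`) with attributes `theta_max` and
#'   `align_prob`.
#' @export
crossing_statistics <- function(theta, sys) {
  stopifnot(inherits(sys, "adsorption_system"))
  if (any(theta <= 0 | theta >= pi)) abort("`theta` must lie in (0, pi).")
  theta_max <- (sys$b / sys$ell)^(1 / 3)
  align <- 2 * (1 - cos(theta_max)) / 2
  structure(tibble(theta = theta, pdf = sin(theta) / 2,
                   cdf = (1 - cos(theta)) / 2),
            theta_max = theta_max, align_prob = align)
}

#' Layered concentration profile of an irreversibly built multi-chain film
#'
#' Three-regime profile over the final chemisorbed layer, continuous at
#' the interior boundaries: below `z1 = 1/(c2inf b)` the residual-hole
#' loops give a linearly growing `c(z)`; between `z1` and `ell` the wider
#' stiff loops give `c ~ 1/(b z^2)`; between `ell` and `sqrt(S ell)`
#' flexible loops give `c ~ 1/(b ell z)`. Beyond `sqrt(S ell)` only
#' grafted tails remain (flagged).
#'
#' @param z Height(s) above the wall (> 0).
#' @param sys An [adsorption_system()] with `c2inf` set.
#' @return Tibble with columns `z`, `c`, `regime`.
#' @export
layered_profile <- function(z, sys) {
  stopifnot(inherits(sys, "adsorption_system"))
  assert_positive(z = z)
  if (is.null(sys$c2inf)) abort("`c2inf` must be set for the layered profile.")
  b <- sys$b
  ell <- sys$ell
  z1 <- 1 / (sys$c2inf * b)
  if (z1 >= ell) abort("need 1/(c2inf b) < ell for a layered profile.")
  z_out <- sqrt(sys$S * ell)
  cvals <- ifelse(z < z1, z / (b * z1^3),
                  ifelse(z < ell, 1 / (b * z^2),
                         ifelse(z < z_out, 1 / (b * ell * z), NA_real_)))
  regime <- dplyr::case_when(
    z < z1 ~ "inner",
    z < ell ~ "stiff_loops",
    z < z_out ~ "flexible_loops",
    TRUE ~ "grafted_tails"
  )
  tibble(z = z, c = cvals, regime = regime)
}

# ---------------------------------------------------------------------------
# Monte-Carlo of wall contacts (loop statistics and proximal layer)

#' Simulate wall-contact statistics of grazing-launched chains
#'
#' Discrete 2D WLCs are launched from the wall (first node at `z = 0`,
#' initial tangent in-plane) with an absorbing wall: a chain is followed
#' until its height first goes negative. While alive, every node with
#' `0 <= z < b` whose tangent is flat within `dtheta` is recorded as a
#' contact; the loop weight requires matching in both height and
#' orientation, which is what makes the stiff-loop statistics decay as
#' `s^(-5/2)` rather than with the bare first-passage exponent. Return
#' (absorption) lengths are kept as well: their survival function decays
#' with the tail exponents (-1/4 stiff, -1/2 flexible).
#'
#' @param sys An [adsorption_system()].
#' @param n Number of chains.
#' @param seed Integer seed.
#' @param dtheta Orientation window for a contact (radians, default 0.3).
#' @param collect_heights Also accumulate node heights of completed
#'   excursions (loop-height histograms for the proximal profile)?
#' @return An object of class `wall_mc`: list with `contacts` (arc lengths
#'   in bonds), `returns` (absorption lengths, `NA` if censored), and when
#'   requested `height_hist` (size-bin x height-bin counts), `n_exc`,
#'   `s_mid`, `z_breaks`.
#' @export
sample_wall_contacts <- function(sys, n, seed, dtheta = 0.3,
                                 collect_heights = FALSE) {
  stopifnot(inherits(sys, "adsorption_system"))
  set.seed(as.integer(seed))
  N <- floor(sys$S / sys$b + 1e-9)
  ell_b <- sys$ell / sys$b
  contacts <- vector("list", 0)
  returns <- numeric(0)
  if (collect_heights) {
    s_breaks <- exp(seq(log(1.5), log(N), length.out = 25))
    z_breaks <- exp(seq(log(0.5), log(max(4, N^1.5 / sqrt(ell_b))),
                        length.out = 41))
    H <- matrix(0, length(s_breaks) - 1, length(z_breaks) - 1)
    n_exc <- numeric(length(s_breaks) - 1)
  }
  chunk <- max(1000, floor(2e6 / N))
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    done <- done + m
    dth <- matrix(rnorm(N * m, 0, sqrt(sys$b / sys$ell)), nrow = N)
    th <- apply(dth, 2, cumsum)
    z <- apply(sin(th), 2, cumsum)      # heights in units of b
    alive <- apply(z >= 0, 2, cumprod)  # 1 while above the wall
    alive_len <- colSums(alive)
    ret <- ifelse(alive_len < N, alive_len + 1, NA_real_)
    returns <- c(returns, ret)
    thw <- atan2(sin(th), cos(th))
    cmask <- alive == 1 & z < 1 & abs(thw) < dtheta
    contacts[[length(contacts) + 1]] <- row(cmask)[cmask]
    if (collect_heights) {
      retd <- which(!is.na(ret))
      if (length(retd)) {
        sbin <- findInterval(ret[retd], s_breaks)
        okc <- sbin >= 1 & sbin < length(s_breaks)
        for (jj in which(okc)) {
          j <- retd[jj]
          zi <- z[seq_len(alive_len[j]), j]
          zb <- findInterval(zi, z_breaks)
          okz <- zb >= 1 & zb < length(z_breaks)
          if (any(okz)) {
            tb <- tabulate(zb[okz], nbins = ncol(H))
            H[sbin[jj], ] <- H[sbin[jj], ] + tb
          }
          n_exc[sbin[jj]] <- n_exc[sbin[jj]] + 1
        }
      }
    }
  }
  out <- list(contacts = unlist(contacts) * sys$b,
              returns = returns * sys$b, n = n, sys = sys, dtheta = dtheta)
  if (collect_heights) {
    out$height_hist <- H
    out$n_exc <- n_exc
    out$s_mid <- sqrt(s_breaks[-1] * s_breaks[-length(s_breaks)]) * sys$b
    out$z_breaks <- z_breaks * sys$b
  }
  structure(out, class = "wall_mc")
}

#' Fit a log-log power-law slope from event data
#'
#' Log-binned histogram of the events within a window, least-squares slope
#' of `log(density)` vs. `log(s)`.
#'
#' @param x Event values (e.g. contact arc lengths).
#' @param window Length-2 numeric window.
#' @param n_bins Number of log bins (default 10).
#' @param correction Optional function of the bin midpoint; the binned
#'   density is divided by it before fitting (acceptance de-biasing).
#' @return A list with `slope`, `stderr`, `n_events`.
#' @export
fit_powerlaw_slope <- function(x, window, n_bins = 10, correction = NULL) {
  x <- x[x >= window[1] & x <= window[2]]
  if (length(x) < 50) abort("too few events in window for a slope fit.")
  br <- exp(seq(log(window[1]), log(window[2]), length.out = n_bins + 1))
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  dens <- h$density
  if (!is.null(correction)) dens <- dens / correction(h$mids)
  keep <- dens > 0
  fit <- lm(log(dens[keep]) ~ log(h$mids[keep]))
  list(slope = unname(coef(fit)[2]),
       stderr = summary(fit)$coefficients[2, 2],
       n_events = length(x))
}

#' Loop and tail exponents from a wall Monte-Carlo
#'
#' Fits the stiff-window and flexible-window slopes of the contact
#' statistics (expected -5/2 and -3/2) and, from the survival function of
#' the return lengths, the tail exponent (-1/4 stiff). Windows default to
#' `[2b, 2 ell]` (the loop crossover sits near `2 ell`) and
#' `[3 ell, 0.6 S]` (wide enough for stable statistics; the flexural
#' uniformisation transient of the orientation window is divided out
#' before fitting); if a window holds too few events it is widened with
#' a warning.
#'
#' @param wmc A [sample_wall_contacts()] result.
#' @param stiff_window,flex_window Optional length-2 windows.
#' @return Tibble with columns `regime`, `slope`, `stderr`, `n_events`,
#'   `window_lo`, `window_hi`.
#' @export
fit_loop_exponents <- function(wmc, stiff_window = NULL, flex_window = NULL) {
  stopifnot(inherits(wmc, "wall_mc"))
  sys <- wmc$sys
  if (is.null(stiff_window)) stiff_window <- c(2 * sys$b, 2 * sys$ell)
  if (is.null(flex_window)) flex_window <- c(3 * sys$ell, 0.6 * sys$S)
  fit_in <- function(win, debias = FALSE) {
    corr <- if (debias) {
      function(s) wrapped_angle_mass(s, sys$ell, wmc$dtheta)
    } else NULL
    tryCatch(fit_powerlaw_slope(wmc$contacts, win, correction = corr),
             error = function(e) {
               warn("too few contacts in window; widening.")
               fit_powerlaw_slope(wmc$contacts, c(win[1] / 2, win[2] * 1.5),
                                  correction = corr)
             })
  }
  fs <- fit_in(stiff_window)
  ff <- fit_in(flex_window, debias = TRUE)
  tibble(regime = c("stiff_loop", "flexible_loop"),
         slope = c(fs$slope, ff$slope),
         stderr = c(fs$stderr, ff$stderr),
         n_events = c(fs$n_events, ff$n_events),
         window_lo = c(stiff_window[1], flex_window[1]),
         window_hi = c(stiff_window[2], flex_window[2]))
}

#' One-call loop-statistics Monte-Carlo
#'
#' Runs [sample_wall_contacts()] and [fit_loop_exponents()].
#'
#' @inheritParams sample_wall_contacts
#' @param ... Passed to [fit_loop_exponents()].
#' @return A list with `exponents` (tibble) and `mc` (the `wall_mc`).
#' @export
sample_loop_statistics <- function(sys, n, seed, dtheta = 0.3, ...) {
  mc <- sample_wall_contacts(sys, n, seed, dtheta = dtheta)
  list(exponents = fit_loop_exponents(mc, ...), mc = mc)
}

#' Monte-Carlo proximal profile by loop superposition
#'
#' Builds the near-wall concentration by superposing the node-height
#' histograms of sampled loop excursions, each size class weighted by the
#' loop weight `Zl(s)` (the Monte-Carlo provides the loop geometry, the
#' analytic weight the ensemble frequency; a loop of size `s` contributes
#' its `~s` monomer heights to the histogram, which realises the
#' `Zl(s) s` monomer weighting of the layer integral). The log-log slope
#' over the proximal window should be -4/3.
#'
#' @param wmc A [sample_wall_contacts()] result with
#'   `collect_heights = TRUE`.
#' @return Tibble with columns `z`, `c` (relative concentration).
#' @export
proximal_profile_mc <- function(wmc) {
  stopifnot(inherits(wmc, "wall_mc"))
  if (is.null(wmc$height_hist)) {
    abort("run sample_wall_contacts() with collect_heights = TRUE.")
  }
  sys <- wmc$sys
  H <- wmc$height_hist
  dz <- diff(wmc$z_breaks)
  zmid <- sqrt(wmc$z_breaks[-1] * wmc$z_breaks[-length(wmc$z_breaks)])
  w <- fragment_weight(wmc$s_mid, sys, "loop")
  conc <- numeric(length(zmid))
  for (i in seq_len(nrow(H))) {
    if (wmc$n_exc[i] > 0) {
      conc <- conc + w[i] * (H[i, ] / wmc$n_exc[i]) / dz
    }
  }
  tibble(z = zmid, c = conc)
}
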