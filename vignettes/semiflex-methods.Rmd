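---
title: "Models and numerical methods in semiflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in semiflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiflex)
```

semiflex implements a family of coarse-grained filament models built on
and beyond the worm-like chain (WLC), together with seeded Monte-Carlo
samplers that act as independent oracles for every closed form. This
vignette records the models, their assumptions, the tunable parameters,
and the numerical choices a user or maintainer would want to know about.
Everything quantitative stated here is computed by the test suite or the
examples; nothing is quoted from elsewhere.

## 1. The worm-like chain core

The WLC penalises curvature with a bending modulus $B$; in thermal units
the only parameter is the persistence length $\ell = B/k_BT$. In 2D the
tangent-tangent correlation decays as $C(s) = e^{-s/2\ell}$, in 3D as
$e^{-s/\ell}$ (two transverse directions decorrelate the tangent). The
mean-square end-to-end distance and gyration radius follow by double
integration of $C$; `chain_dimensions()` evaluates the 2D closed forms
and maps 3D onto them by $\ell \to \ell/2$.

**Numerics.** For $S/(2\ell) < 0.05$ the closed forms suffer
catastrophic cancellation (they are differences of near-equal terms
$\sim \ell^2$); the implementation switches to a series in
$x = S/2\ell$ carried to machine precision. The same routines accept
complex $\ell$ because the arc/arc model (section 3) evaluates them at
complex decay lengths.

**Sampler.** `sample_wlc2d()` draws discrete chains of fixed bond
length $b$ whose angle increments are i.i.d. Gaussian with variance
$b/\ell$. That variance convention is stated explicitly because the 2D
and 3D conventions differ by a factor 2: with $\mathrm{var}(\delta\theta)
= b/\ell$ the sampled ensemble reproduces the 2D form of $C(s)$ exactly.
`estimate_persistence_length()` inverts the sampler by a least-squares
fit of $\log C(s)$ on $s \in [b, \min(\ell_{guess}, S/4)]$, with
$\ell_{guess}$ from the first $1/e$ crossing; when a chain is too stiff
to cross $1/e$ within its length the window falls back to $[b, S/4]$,
and ensembles whose correlation never drops below 0.99 are flagged
`rigid` rather than fitted. At $10^4$ chains ($\ell = 10b$, $S = 200b$)
the inversion is accurate to better than 3%.

## 2. The squeezed helix ("squeelix")

A filament with intrinsic curvature $\omega_1$ and intrinsic torsion
$\omega_3$ (moduli $B$, $C$) confined flat to a plane has its planar
curvature slaved to the twist angle $\psi$:
$\kappa(s) = \omega_1 \sin\psi(s)$, with $\psi$ obeying the pendulum
equation $\psi'' + (B\omega_1^2/2C)\sin 2\psi = 0$. The bulk ground
state is $\psi(s) = \mathrm{am}(s/\lambda\,|\,m)$ with
$\lambda = \sqrt{mC/B}/\omega_1$, and the elliptic parameter is selected
by $m\,E(m) = \gamma$ where
$\gamma = 4\omega_1^2 B / (\pi^2 \omega_3^2 C)$ is the twist-expulsion
parameter and $E$ the complete elliptic integral of the second kind
(parameter convention, $E(1) = 1$).

**Numerical choices.**

* The elliptic-function convention is pinned by the anchor
  $\gamma = 1 \Rightarrow m = 1$; both the modulus and the parameter
  convention are in circulation, and the unit tests fix the latter.
* $m E(m)$ is *not* globally monotone: it has a shallow interior
  maximum ($\approx 1.0088$ near $m \approx 0.97$) before returning to 1
  at $m = 1$. For $\gamma < 1$ the physically relevant rising-branch
  root is still unique because beyond the maximum $mE(m)$ stays above 1;
  `ground_state_m()` solves it by bracketed bisection to $10^{-12}$ and
  returns $m = 1$ exactly at $\gamma = 1$. A consequence worth knowing:
  $m(\gamma)$ jumps from $\approx 0.92$ to 1 as $\gamma \to 1^-$; the
  function is continuous and monotone on the interior of the kinked
  range, which is what the property tests check.
* $\lambda$ is validated not by trusting any printed inline expression
  but by requiring the profile to satisfy the pendulum equation under
  fourth-order finite differencing (residual $< 10^{-6}$); that residual
  pins $\lambda$ uniquely given $m$. The Jacobi amplitude is evaluated
  through `pracma::ellipj` with `atan2(sn, cn)` branch stitching, which
  keeps full precision where $sn \to \pm 1$; $m = 1$ uses the
  Gudermannian closed form $2\arctan e^{s/\lambda} - \pi/2$.
* Finite-length boundary layers (the boundary condition
  $\psi'(\pm L/2) = \omega_3$) are not solved; profiles are the bulk
  solution truncated to length $L$, the standard long-chain treatment.

**Regimes.** $\gamma > 1$ expels kinks (circular ground state, radius
$1/\omega_1$); for $\gamma \le 1$ the ground state carries kinks with
spacing $d = 2K(m)\lambda(m)$. The dense/dilute boundary is a judgment
call because the spacing measured in units of the $m$-dependent width is
bounded below by $2K(0) = \pi$. We take the kink *extension* to be
$\pi\lambda_1$ with $\lambda_1 = \sqrt{C/B}/\omega_1$ the homoclinic
width — the arc over which the single kink completes the bulk of its
$\pi$ swing — and call kinks dense when $d \le \pi\lambda_1$, i.e.
$\sqrt{m}K(m) \le \pi/2$, i.e. $\gamma \lesssim 0.78$. This places
$\gamma = 0.52$ in the dense and $\gamma = 0.997$ in the dilute class,
matching the reference shapes. (Defining the width as $\lambda_1$
itself would misclassify the dense example, so the extension convention
is the one we commit to and test.)

## 3. The arc/arc twist-kink gas

When $\gamma > 1$ kinks exist only as thermal excitations of energy $E$
(thermal units). Neglecting their width and interactions, a chain of
$N = S/b$ units carries $k \sim \mathrm{Poisson}(\langle k\rangle)$
kinks, $\langle k\rangle = N e^{-E}$, separating arcs of alternating
curvature $\pm\omega$. The deflection-angle distribution has a
continuous Bessel-function part on $|\theta| \le \omega S$ plus atoms of
weight $e^{-\langle k\rangle}/2$ at $\pm\omega S$ (the kink-free
states); flexural fluctuations with persistence length $\ell$ enter
exactly as a Gaussian convolution of variance $S/\ell$.

**Numerics.** The term $I_1(\langle k\rangle r)/r$,
$r = \sqrt{1-\hat\theta^2}$, has a removable $0/0$ at the support edge
handled by its limit $\langle k\rangle/2$; the Heaviside edge uses
$u(0) = 1/2$. The density has a square-root cusp at the edge, so the
normalisation is checked by adaptive quadrature ($10^{-8}$) while plain
grid sums are good to $\sim 10^{-3}$; the convolution is done by FFT on
a grid that resolves the Gaussian width by at least 8 points, with the
atoms convolved analytically as shifted Gaussians. The deflection
sampler generates *sorted* kink positions group-wise from exponential
spacings, so a $10^6$-sample run takes seconds; at that size the
Kolmogorov-Smirnov distance to the grid distribution is
$\lesssim 10^{-3}$.

The tangent correlation is a two-exponential form with complex rates
$1/2\ell_{1,2} = (e^{-E}/b)(1 \mp R) + 1/2\ell$,
$R = \sqrt{1-\omega^2b^2e^{2E}}$. The bracket placement is fixed not by
typography but by three limits enforced as tests: $C(0) = 1$ exactly,
$\omega \to 0$ reduces to the pure WLC, and $E \to \infty$ gives the
damped cosine $e^{-s/2\ell}\cos\omega s$ (oscillatory iff
$\omega b e^{E} > 1$, i.e. one turn survives the kinks). $R_e^2$ and
$R_g^2$ evaluate the WLC closed forms at the complex $\ell_{1,2}$ and
combine them; complex arithmetic is kept throughout and reality of the
result is asserted ($<10^{-9}$ relative), never assumed. The gyration
radius develops undulations in $S$ exactly when $E > -\log b\omega$
($\approx 4.6$ for $\omega = 0.01/b$), which the tests detect as
oscillations of the local log-log slope.

## 4. Adsorption at a flat wall

**Loop/tail weights.** Ideal-chain fragments at a repulsive wall carry
weights $Z_l \propto s^{-5/2}$ (stiff loop), $s^{-3/2}$ (flexible
loop), $Z_t \propto s^{-1/4}$ (stiff tail), $s^{-1/2}$ (flexible tail),
implemented as piecewise power laws continuous at the crossovers
($2\ell$ for loops, $\ell$ for tails). All scaling relations in this
module use unit prefactors and are documented as order-of-magnitude
laws; tests treat them with tolerances, never as exact.

**What the wall Monte-Carlo measures — and why.** The height of an
almost-straight chain is an *integrated* random walk (the tangent angle
diffuses, the height integrates it). For such a process the plain
first-passage density to the wall decays as $s^{-5/4}$ (the classical
persistence exponent 1/4 of the random-acceleration process, which is
also exactly the stiff-*tail* exponent: the survival function of our
simulated chains decays as $s^{-1/4}$). A naive "first return"
histogram therefore can *not* show the loop exponent $-5/2$. The loop
weight constrains the returning end in height *and* orientation, so
`sample_wall_contacts()` records *contacts*: nodes of a surviving
(never-crossed) chain that lie within the reaction slab $z < b$ *and*
whose tangent is flat within a fixed window $\delta\theta = 0.3$ rad.
This statistic decays as $s^{-5/2}$ in the stiff window and $s^{-3/2}$
in the flexible window, which we verified against the exponent algebra
before freezing the tests. In the flexible window the orientation
window's acceptance still carries the flexural uniformisation transient
$\sim e^{-s/2\ell}$; `fit_loop_exponents()` divides the binned density
by the wrapped-normal window mass (free-chain angle variance $s/\ell$ —
exact for the unconstrained part of the statistics) before fitting. At
$\ell = 10b$, $S = 250b$ and $3\times10^5$ chains the fitted slopes are
stable to $\pm 0.05$ across seeds.

**Proximal profile.** Stiff loops of size $s$ reach heights
$z \sim s^{3/2}/\ell^{1/2}$; superposing them with weight $Z_l(s)\,s$
gives $c(z) \propto z^{-4/3}$ on $b < z < \ell$. The package exposes
the closed form, a quadrature superposition (differentiating the
cumulative loop integral through the height map; slope $-4/3$ to 1%)
and a Monte-Carlo superposition that histograms actual excursion
heights weighted by $Z_l$. At desk-scale stiffness the Monte-Carlo
version is crossover-limited — the flexural angle spread reaches
$\sim1$ rad near $s \sim \ell$, blurring the height map — so its slope
is only constrained to a broad band around $-4/3$; the quadrature
superposition carries the quantitative test.

**Chemisorption.** Zipping proceeds in minimal-loop steps
$s_0 = (\ell b^2)^{1/3}$ at rate $qs_0/b$; the contact probability
$P(s)$ has the three-regime form (plateau, $-5/2$, $-3/2$) matched
continuously at $s_0$ and $\ell$. `simulate_zipping()` runs the
embedded jump chain of the Gillespie competition between front advance
and loop nucleation (rates frozen between events; the number of zip
steps between nucleations is geometric; nucleation sizes drawn by the
closed-form inverse CDF of piecewise $P$). A nucleated loop *preempts*
single-front zipping when it exceeds both $\ell$ and the length already
zipped — the race criterion underlying the multiple-nucleation length
$S^* = \ell^{5/3}b^{-2/3}$; smaller loops simply advance the front.
With these (unit-prefactor) conventions the measured 50% crossover sits
at $\approx 2.3\,S^*$ and scales with exponent $1.68$ over
$\ell \in [100, 1000]\,b$. Note that the simpler criterion "any
nucleation beyond $\ell$" would *not* reproduce the $5/3$ scaling (its
crossover scales as $\ell^{4/3}$); the race criterion is therefore the
normative one.

**Crossing statistics and layers.** Crossing angles of sequentially
adsorbed straight chains follow $P(\theta) = \sin\theta/2$ (exact
cumulative $(1-\cos\theta)/2$, median $\pi/2$); alignment instead of
crossing becomes likely below $\theta_{max} = (b/\ell)^{1/3}$, and the
alignment probability doubles the one-sided small-angle cumulative (the
only place the symmetry doubling is applied). The final chemisorbed
multi-chain film has the three-regime profile linear /$z^{-2}$/$z^{-1}$
matched continuously at $1/(c_{2\infty}b)$ and $\ell$, with heights
beyond $\sqrt{S\ell}$ flagged as the grafted-tail fringe.

## 5. Bundles and bistable filaments

The shear-coupled two-filament bundle ("railway track") adds a shear
energy $K\tau^2/2$, $\tau = \theta - \bar\theta$, to the bending energy
and screens imposed curvature over $\lambda = \sqrt{B/K}$. For a
preformed arc of length $l$ the closed-form response (counter-arcs of
amplitude $\kappa_0 l/2\lambda$ decaying as $e^{-\Delta s/\lambda}$) is
*exact* for $L \gg \lambda$, which the tests confirm against a dense
constrained quadratic minimiser to 2% (the residual being pure
discretisation). The arc energy
$K\kappa_0^2l^3/12 + \sqrt{BK}\kappa_0^2 l^2/4$ grows as $l^2$ below
$\lambda$ and $l^3$ above — the anti-cooperative signature of such
models.

The tail-bridged filament buckles at $k_{crit} = 12B/d^3$ into
bistable curvature $\pm\sqrt{1-k_{crit}/k}/d$ (unit prefactor). The
near-threshold Landau form carries constants $C_1, C_2$ (defaults 1,
exposed as inputs; its minima sit at the $\sqrt{C_1/2C_2}$ multiple of
the unit-prefactor amplitude, coinciding for $C_1 = 2C_2$). The
hyper-stiffness term $H\int\kappa'^2/2$ with default $H = kd^5$
produces curvature domain walls whose width grows monotonically with
$H$, computed by L-BFGS relaxation of the discretised profile.

## 6. The polymorphic microtubule cross-section

A two-layer annulus ($R_i < R_m < R_o$) of $N$ protofilament sectors;
a switched sector gains $\Delta G$ per dimer (length $b$) and acquires
preferred strains $\varepsilon_i > 0$ (inner) and $\varepsilon_o < 0$
(outer). The elastic energy is quadratic in
$(\kappa_x, \kappa_y, \bar\varepsilon)$, so per-state minimisation is a
closed-form $3\times3$ solve; a panel-wise Gauss-Legendre quadrature
(32 radial nodes per layer, 16 angular nodes per sector — panels are
placed at the sector and layer boundaries so the integrand is smooth on
each) provides the independent energy oracle at rounding-level
agreement. Because switched dimers attract within the lattice (verified
exhaustively: for any fixed number of switched dimers at $N = 13$ the
contiguous block minimises the energy), the model reduces to a single
block of angle $\phi_p = 2\pi p/N$. The block minimiser curvature is
$\kappa_1 \sin(\phi_p/2)$ in magnitude, with
$\kappa_1 = \tfrac{8}{3\pi}[\varepsilon_i(R_m^3-R_i^3) +
\varepsilon_o(R_o^3-R_m^3)]/(R_o^4-R_i^4)$.

Minimising over $(\kappa, \bar\varepsilon)$ under a force $F$ (coupling
to stretch) and torque $M$ (coupling to curvature) yields the
polymorphic potential, which we construct from first principles rather
than transcribing any printed rescaled form:
$$ e(\phi_p)/E_0 = \tfrac{c_2}{2}\phi_p^2 + f\,\phi_p
   - m\sin\tfrac{\phi_p}{2} - \tfrac12\sin^2\tfrac{\phi_p}{2}, $$
with energy unit $E_0 = 4YW_3^2/Q_{11}$, torque $m = M/(2YW_3)$,
quadratic coefficient $c_2 = -W_2^2Q_{11}/(4W_3^2A)$ (from stretch
relaxation; negative), and $f$ collecting the elastic frustration, the
switching gain (linear in $\Delta G$) and $F$ (moments $W_2, W_3, U$ and
$A, Q_{11}$ are the layer/annulus integrals defined in the code). The
structure — and the constant offset $-g^TQ^{-1}g/2Y$ — is verified
against the raw block-by-block minimisation. $\phi_p = 0$ and $2\pi$
are the straight long (L) and straight short (S) states; interior
minima are curved (C). `phase_diagram()` ranks the three states on an
$(f, m)$ grid and `hysteresis_sweep()` follows the occupied local
minimum through quasi-static force sweeps, detecting the discontinuous,
direction-dependent jumps of bistable parameter sets. The default
demonstration geometry ($R_i/R_m/R_o = 8/10.25/12.5$ nm,
$\varepsilon_{i,o} = \pm 0.02$) is a documented *assumption* — the
model's radii and strains are user inputs, not literature values.

## 7. What the synthetic ensembles do and do not show

The samplers generate *ideal* chains: no excluded volume, no
chain-chain interactions, no hydrodynamics, and (for the wall module)
an ideal absorbing/reflecting-free wall realised by path conditioning.
Passing tests therefore validate the statistical mechanics of the
implemented models, not the behaviour of real polymers in regimes where
self-avoidance or multi-chain crowding matters (dense 2D layers,
long swollen chains). Problem sizes in the default test run — $10^4$
chains for moment checks, $3\times10^5$ launched chains for wall
statistics, $10^6$ deflection samples, 300–400 kinetic runs per chain
length — were chosen so that statistical error sits a factor of a few
below each tolerance; they are the package's reference conditions and
are stated in the tests themselves.

## 8. Known limitations

* Finite-length squeelix boundary layers and thermally activated
  oscillatory ($m > 1$) twist branches are out of scope.
* The arc/arc model misses twist fluctuations beyond kink number and
  position, and the force response is linear only.
* All adsorption scaling laws have unit prefactors; absolute
  concentrations and rates are relative.
* The zipping simulation treats sub-$\ell$ nucleations as instantaneous
  front advances; multi-front growth after a distant nucleation is not
  followed (the run ends at the first preempting event).
* The polymorphic model keeps the single-block approximation
  (justified by the aggregation property) and a per-cross-section
  treatment; axial cooperativity along the tube is not modelled.
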