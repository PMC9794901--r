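---
title: "Discretizing a toxin-stressed plankton model: consistency, bifurcations and control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discretizing a toxin-stressed plankton model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktomaps)
```

## The continuous model and its discretizations

The package studies a planar plankton model in which phytoplankton $p$ grow
logistically, are grazed through a Holling type-II response, and additionally
die at a quadratic rate $m p^2$ from an external toxic substance, while
zooplankton $z$ gain from grazing, are poisoned by phytoplankton toxin, and
die at a constant per-capita rate:

$$\frac{dp}{dt} = r p\Big(1-\frac{p}{k}\Big) - \frac{\alpha p z}{a+p} - m p^2,
\qquad
\frac{dz}{dt} = \frac{\beta p z}{a+p} - \frac{\rho p z}{a+p} - \delta z.$$

All eight constants are strictly positive. Units: $r,\alpha,\beta,\rho,\delta$
are per unit time, $k$ and $a$ are biomasses, $m$ is per biomass per time.
Biologically the conversion rate should not exceed the capture rate
($\beta < \alpha$); the constructor warns (but does not fail) when it does,
because the bundled worked-example parameter sets themselves violate it.

A planar flow cannot be chaotic, but a planar *map* can. That is the central
consistency question here: does a discretization introduce dynamics the flow
does not have? The package implements three maps with step size $\eta$:

* **Euler**: $s_{n+1} = s_n + \eta f(s_n)$. Simple, but it does not preserve
  positivity and — as the package's flip machinery shows constructively — it
  admits period-doubling and chaos.
* **NSFD (Mickens)**: nonlinear loss terms are moved into denominators,
  $$p_{n+1} = \frac{(1+\eta r)p_n}{1+\eta\big(\tfrac{r}{k}p_n +
  \tfrac{\alpha z_n}{a+p_n} + m p_n\big)},\qquad
  z_{n+1} = \frac{\big(1+\tfrac{\eta\beta p_n}{a+p_n}\big) z_n}
  {1+\eta\big(\delta+\tfrac{\rho p_n}{a+p_n}\big)}.$$
  Every denominator exceeds 1 on the closed positive quadrant, so positive
  states map to positive states for *every* step size, and the fixed points
  coincide exactly with the continuous equilibria.
* **Hybrid-controlled**: $s_{n+1} = \Theta^3 E(s_n) + (1-\Theta^3) s_n$ with
  gain $\Theta \in (0,1]$ — a convex combination of the Euler update and the
  identity that shrinks every multiplier's distance from 1 and thereby
  suppresses bifurcations.

The continuous right-hand side is kept only as a consistency reference (shared
equilibria, Jacobian limits); the package does no ODE integration.

## Fixed points, boundedness, stability

The maps share three equilibria: extinction $(0,0)$, the zooplankton-free
boundary point $(kr/(km+r),\,0)$, and a coexistence point with
$p^* = a\delta/(\beta-\delta-\rho)$, which exists precisely when

$$\beta > \delta+\rho \quad\text{and}\quad kr(\beta-\delta-\rho) >
a\delta(km+r).$$

The interior $z^*$ is computed twice — by the closed form and by the
phytoplankton nullcline $z = (a+p)(r(1-p/k)-mp)/\alpha$ — and the two must
agree to $10^{-10}$ relative; a mismatch is treated as a hard failure, not a
tolerance issue. Under the same two conditions positive NSFD orbits are
eventually confined to the box
$[0, kr/(km+r)] \times [0, (kr(\beta-\delta-\rho)-a\delta(km+r))/(\rho(km+r))]$;
the property tests verify the $p$-bound on random admissible orbits. The
underlying derivation assumes $z_n \ge p_n$ along the orbit, a hypothesis the
map is not known to propagate; the tests deliberately do not impose it, and
the $p$-bound holds regardless because the $p$-update is dominated by a
monotone scalar comparison map with fixed point $kr/(km+r)$.

Stability of a fixed point is read off the characteristic polynomial
$F(\omega)=\omega^2-T\omega+D$ of its Jacobian through the Jury conditions
($F(1)$, $F(-1)$, $D$). Two numerical policies matter:

* **Non-hyperbolicity tolerance.** A multiplier is "on" the unit circle when
  $\big||\omega|-1\big| < 10^{-9}$. Reports carry the raw moduli so callers
  can re-threshold.
* **Hypothesis failure.** The Jury lemma assumes $F(1)>0$. When it fails
  (it does for the bundled non-reproducible flip example, whose printed
  polynomial has $F(1)<0$) classification falls back to eigenvalue moduli
  directly and the report flags the fallback.

Closed-form criteria — the boundary-point sink condition
$kr\beta < a\delta(km+r)+kr(\delta+\rho)$, the interior Jury values $U(1)$,
$U(-1)$, and the controlled map's polynomial $G(\lambda)$ — are all evaluated
*alongside* the Jacobian route and cross-checked to $10^{-8}$ in the tests,
never trusted alone.

## Neimark–Sacker analysis

At the coexistence point of either map, a complex multiplier pair crosses the
unit circle as $\eta$ grows: $D(\hat\eta)=1$ with $T^2<4D$. Criticality used
in reports is always the bisection root of $D(\eta)-1$ (to $10^{-12}$); for
the NSFD map the closed-form ratio for $\hat\eta$ is evaluated alongside. For
the bundled NSFD example the closed form and bisection agree to machine
precision at $0.409982$, about $0.4\%$ away from the digit string published
with that example — a source-internal discrepancy we document rather than
resolve.

Two design decisions shape this module:

* **Numeric path is authoritative.** The degree-3 Taylor coefficients of the
  map about the fixed point are obtained by symbolic differentiation of the
  map's closed-form expression (exact, no truncation error), then pushed
  through the similarity transform with columns $(\theta_{12}, 0)$ and
  $(\lambda-\theta_{11}, -\omega)$ to rotation normal form, from which the
  $\xi$-coefficients and the first Lyapunov quantity
  $$\digamma = -\mathrm{Re}\Big[\tfrac{(1-2\varrho_1)\varrho_2^2}{1-\varrho_1}
  \xi_{20}\xi_{11}\Big] - \tfrac12|\xi_{11}|^2 - |\xi_{02}|^2 +
  \mathrm{Re}(\varrho_2\xi_{21})$$
  follow. The very long published coefficient expressions are *not*
  transcribed: they are typo-prone, and for the bundled Euler example the
  published intermediate polynomials are internally inconsistent with the
  published Jacobian (their linear coefficient differs from the Jacobian's
  corresponding entry). Those published polynomials ship as a fixture; the
  $\xi$-layer reproduces the published $\xi$ values exactly when fed them,
  while the fully numeric path reproduces the *sign* of $\digamma$ (both
  negative: supercritical, an attracting invariant curve for
  $\eta > \hat\eta$), not its digits. Behavioral tests confirm the direction
  by iteration on both sides of criticality.
* **Transversality from the determinant.** At a complex pair
  $|\varrho(\eta)|^2 = D(\eta)$, so the crossing speed is
  $d|\varrho|/d\eta = D'(\hat\eta)/2$. The package computes $D'$ by symbolic
  differentiation of the Jacobian-entry expressions and verifies it against a
  central finite difference of the eigenvalue modulus to $10^{-4}$ relative.
  (A published closed form for this slope does not match the
  finite-difference slope even in sign; the determinant route does, to nine
  digits, and is what the package reports.)

Nondegeneracy ($\varrho^m \ne 1$, $m\le4$) is checked through
$\hat p(0) = 2\mathrm{Re}\,\varrho_1 \notin \{-2,-1,0,2\}$ with margin
$10^{-8}$. $\varrho_1$ is always the multiplier with positive imaginary part.

## Period-doubling analysis

For the Euler map, a real multiplier reaches $-1$ at parameter combinations
given in closed form (solving for the half-saturation constant $a$ at fixed
$\eta$) and located numerically by bisection on $F(-1)=0$ (default bracket
$\eta \in (10^{-3}, 1]$). At criticality the map is transformed to the
eigenbasis $S=[v_{-1}, v_{\psi_2}]$, the quadratic center manifold
$v = M_{11}u^2 + M_{12}u\bar\eta$ is attached, and the reduced scalar map
$G(u) = -u + a_{11}u^2 + a_{15}u^3 + \dots$ yields

$$L_{12} = \Big(\tfrac12 G_{uu}\Big)^2 + \tfrac16 G_{uuu} = a_{11}^2 + a_{15},$$

whose sign gives the direction (positive: stable period-two branch beyond
criticality). Matching powers in the invariance equation gives
$M_{11} = g_{20}/(1-\psi_2)$ and $M_{12} = -g_{u\bar\eta}/(1+\psi_2)$; the
second denominator differs from the published account, but it is the one the
order-$u\bar\eta$ invariance condition forces, and the tests verify the
residual of the invariance equation directly by substitution. The
transversality quantity $L_{11}$ is computed as $(S^{-1}J'(\eta)S)_{11}$,
which is exact for the Euler map because $J(\eta)=I+\eta A$ with $A$ the flow
Jacobian, and because the Euler fixed point does not move with $\eta$ (so the
reduced map has no pure-$\bar\eta$ term). A behavioral oracle iterates the
map on both sides of criticality and classifies the tail as fixed-point /
period-2 / other; tests use a $\pm 2\%$ step-size offset with a
$2\times10^4$-step transient, since the second multiplier of the worked flip
point is $0.975$ and convergence onto the branch is slow.

Since the bundled flip example's published parameters violate the
interior-existence condition, the working flip fixture is constructed from
the Euler NS example's parameters with $a$ moved to its closed-form critical
value $2.72557\ldots$ at $\eta = 0.736811\ldots$ — at which $F(-1)$ vanishes
to machine precision, $L_{12} = 0.334 > 0$, and a stable period-two orbit
indeed appears exactly for $\eta$ beyond criticality.

The NSFD contrast is a theorem, and the package treats it as a property:
$U(-1) > 0$ on every sampled admissible parameter point, and the flip
detector never fires for the NSFD map — the discretization is dynamically
consistent in this respect.

## Chaos control

The controlled map's interior Jacobian is
$\Theta^3 J_{\mathrm{euler}} + (1-\Theta^3)I$; the closed-form $G(\lambda)$
(which is free of $\alpha$, as the off-diagonal product cancels it) agrees
with this Jacobian to machine precision and both are kept, one as
implementation and one as cross-check. As $\Theta \to 0$ the map tends to the
identity, so the leading multiplier modulus starts at 1, dips below it, and
climbs back to 1 at $\Theta = 1$: the stability region is an interval
$(0, \Theta^*)$, with $\Theta^*$ found by bisection on the leading modulus
(labelled NS-type when the pair is complex with $D=1$, flip-type when
$F(-1)=0$). For the bundled control example the determinant stays below 1 on
the whole interior gain range at its stated step size, so no interior
critical gain exists there and the published critical-gain digits are shipped
as non-asserted reference values.

## Scans, exponents, and their numerical policy

* **Maximal Lyapunov exponent**: Benettin tangent-vector iteration with
  per-step renormalization; defaults $n = 2\times10^4$ with a
  $2\times10^3$-step transient, initial tangent direction drawn from a seeded
  RNG (seed 0) so results are bit-reproducible. At a sink the estimate
  matches $\log$ of the leading local multiplier (tests check to 2%); in the
  Euler map's large-step regime it is positive. Note that positive exponents
  are interspersed with periodic windows: at one of the bundled
  phase-portrait step sizes ($\eta = 0.958$) the exponent is negative
  (a window), while at $\eta = 0.998$ it is positive.
* **Bifurcation diagrams**: long-format tables (scan value, sample index,
  $p$, $z$), default transient 2000 and 200 samples per value. The default
  initial-state policy is sweep continuation; note its known hazard near a
  supercritical NS transition: the final state of a converged sweep sits
  numerically *on* the fixed point, which remains exactly invariant past
  criticality, so the diagram can show zero spread where an invariant curve
  exists. The `restart` policy (used by the package's own spread tests)
  avoids this.
* **Region scans** classify one fixed point over a 2-parameter grid, with
  cells lacking the point labelled `absent`.
* Orbit components are capped at $10^{12}$; beyond that the orbit is flagged
  `diverged` rather than raising — Euler orbits at large $\eta$ legitimately
  escape.

## What the synthetic inputs do and do not show

There are no external data; "inputs" are parameter sets. The four bundled
sets are the published worked-example values, digit for digit, and random
property-testing draws sample the admissible region (interior existence
margins strictly positive, rates in moderate ranges). Passing tests therefore
demonstrate the *mathematics* of the maps — shared equilibria, positivity,
Jury equivalence, normal-form correctness — on realistic parameter scales;
they say nothing about fitting real plankton time series, observation noise,
seasonal forcing, or spatial structure, none of which the model contains.

## Problem sizes

The test suite uses $10^4$ random draws for positivity and Jury-oracle
equivalence, $10^3$ draws for shared-equilibria, Jacobian-vs-finite-difference
and no-NSFD-flip properties, orbits of $10^4$ steps (behavioral bifurcation
checks) and $2$–$4\times10^4$ steps (flip transients, Lyapunov exponents);
the whole suite runs in well under a minute on one core.

## Known limitations

* Planar maps only; no general Jury table for higher dimensions.
* No continuation of the invariant curve itself, and no tracking of the
  period-4, 8, … cascade; both are visible only through scan output.
* The center-manifold reduction reports $a_{11}$, $a_{12}$, $a_{15}$ (the
  coefficients that decide direction and transversality); the
  $u^2\bar\eta$ and $u\bar\eta^2$ coefficients of the reduced map are not
  assembled.
* The published intermediate polynomials, one published Jacobian and the
  published critical control gains that cannot be reproduced from their own
  stated inputs are shipped as documented, non-asserted fixtures.
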