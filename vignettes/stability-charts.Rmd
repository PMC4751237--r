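---
title: "Stability charts for a neutral delay equation and the quiescence cell model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability charts for a neutral delay equation and the quiescence cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaychart)
```

## The characteristic equation and its stability region

The package centres on the characteristic equation

$$\lambda = \alpha_1 + (\alpha_2 + \alpha_3\lambda)e^{-\lambda},$$

written internally as the entire function
$\Delta(\lambda) = \lambda - \alpha_1 - (\alpha_2+\alpha_3\lambda)e^{-\lambda}$.
It arises by linearising a coupled renewal/delay system about a steady
state; the term $\alpha_3\lambda e^{-\lambda}$ is the *neutral* part
contributed by a delayed derivative (here: the renewal equation for the
division-committing rate degenerates into a difference equation in
continuous time). The steady state is asymptotically stable exactly when
$\Delta$ has no zeros with $\mathrm{Re}\,\lambda \ge 0$.

Everything hinges on the restriction $|\alpha_3| < 1$. Then any root with
$\mathrm{Re}\,\lambda \ge 0$ obeys
$|\lambda| \le (|\alpha_1|+|\alpha_2|)/(1-|\alpha_3|)$
(`modulus_bound()`), so unstable roots live in a compact half-disk and
cannot sneak in "from infinity" as coefficients vary. For $|\alpha_3| > 1$
there are infinitely many right-half-plane roots; the package rejects that
regime everywhere except plain evaluation of $\Delta$.

Roots reach the imaginary axis in two ways, and these critical loci carve
the $(\alpha_1,\alpha_2)$-plane into cells with a constant number of
unstable roots (a D-partition):

* $\lambda = 0$ on the half-line $L(\alpha_3)$:
  $\alpha_2 = -\alpha_1$, $\alpha_1 \le 1-\alpha_3$. On the rest of the
  line $\lambda = 0$ is still a root, but extra right-half-plane roots are
  already present.
* $\lambda = \pm i\omega$, $\omega > 0$, on the curves traced by
  $c_1(\omega, \alpha_3) = \frac{\omega}{\sin\omega}(\cos\omega-\alpha_3)$,
  $c_2(\omega, \alpha_3) = \frac{\omega}{\sin\omega}(\alpha_3\cos\omega-1)$:
  the Hopf curve $C_0$ for $\omega \in [0,\pi)$ and the higher branches
  $C_k^\pm$ on the later pole-free $\omega$-intervals.

$L$ and $C_0$ meet at the corner $(1-\alpha_3, \alpha_3-1)$, where
$\lambda = 0$ is a *double* root (`multiplicity_at_zero()` reports 2 there,
and 3 in the degenerate limit $\alpha_3 = -1$). The stability region is
exactly the open set between $L$ (above) and $C_0$ (below):

$$S(\alpha_3) = \{\alpha_1 < 1-\alpha_3,\ \varphi(\alpha_1) < \alpha_2 < -\alpha_1\},$$

where $\varphi$ is $C_0$ re-parameterised by $\alpha_1$ — legitimate
because $c_1$ is strictly decreasing in $\omega$ on every branch
(`c0_height()` inverts it by bisection). `classify_point()` encodes this
test literally; points with $\alpha_1 \ge 1-\alpha_3$ are unstable off the
closure of $L$ and are tagged `right_of_corner`.

## Root counting: design of the numerical oracle

The analysis gives the *geometry*; to validate it (and to label the other
D-partition cells) the package carries an independent numerical oracle,
`count_unstable_roots()`, built on the argument principle:

* Contour: the boundary of the half-disk
  $\{\mathrm{Re}\,\lambda \ge x_0,\ |\lambda| \le R\}$ with
  $R = $ `modulus_bound` $+\,1$ and $x_0$ the caller's `margin`
  (default $10^{-8}$). Zeros with $|\mathrm{Re}\,\lambda| \le$ `margin`
  are genuinely expected on boundary curves, so they are located
  separately (Newton seeded at the near-zeros of $\Delta(i\omega)$ along
  a 0.02-spaced axis scan) and reported as `marginal`, never counted.
* The winding number is read off from adaptively refined samples of
  $\Delta$ along the contour. Refinement uses two criteria: consecutive
  phase increments must stay below $\pi/2$, *and* an anti-aliasing
  condition — interval width times a local Lipschitz bound
  $2\max|\Delta'|$ must stay below $0.8$ of the endpoint modulus.
  The second condition matters: a root lying close to the contour can
  rotate the phase by a full $2\pi$ between two coarse samples while every
  sampled increment looks small, silently losing one root. With it, the
  winding number always settles on an integer (asserted to within 0.2).
* If $\Delta$ nearly vanishes on the contour itself ($< 10^{-10}$ times a
  local coefficient scale), the flat segment is moved to another candidate
  abscissa chosen as far as possible from the located near-axis roots, and
  the count is reconciled with the requested margin using those roots
  (conjugate pairs counted twice).

`find_roots()` is the companion locator: damped Newton from a 0.25-spaced
grid of seeds over the bounded window, followed by merging of converged
copies. The merge radius is $10^{-4}$, not the $10^{-6}$ a simple-root
analysis would suggest: near a double root (the corner) Newton stagnates at
a distance of order $\sqrt{\text{tol}}$ with an already-tiny residual, and
a smaller radius would report one double root as two simple ones.
Multiplicity is assigned by the closed-form derivative test
($|\Delta^{(j)}| < 10^{-8}$).

Both routes are exercised against each other across dense coefficient
grids ($41\times41$ over $[-6,6]^2$ for five values of $\alpha_3$,
boundary-adjacent points excluded at distance $10^{-2}$) and against a
deliberately naive fixed-density winding counter kept in the test helpers.
The crossing directions are checked too: $+1$ root crossing $L$ upward,
$+2$ crossing $C_0$ downward.

## The quiescence model

The scaled model tracks the division-committing rate $p(t)$, the quiescent
quantity $Q(t)$ and the environment $E(t) \in (0,1]$:

$$p(t) = 2\beta_1(E(t))e^{-\mu}p(t-1) + G(E(t))Q(t),$$
$$Q'(t) = 2(1-\beta_1(E(t)))e^{-\mu}p(t-1) - (\mu+G(E(t)))Q(t),$$
$$E(t) = \Big(1 + \theta\int_0^1 p(t-a)e^{-\mu a}\,da + (1-\theta)Q(t)\Big)^{-1}.$$

Parameters, with units in cell-cycle time: death rate $\mu \ge 0$
(dimensionless after time scaling; the nontrivial regime needs
$2e^{-\mu} > 1$, i.e. $\mu < \ln 2$); consumption weight
$\theta \in [0,1]$ of proliferating relative to quiescent cells
(the biologically plausible range is $[1/2, 1]$); and the two responses
$\beta_1(E) \in [0,1)$ (commitment probability) and $G(E) > 0$
(quiescence exit rate, per unit time).

`R0()` implements
$R_0(E) = 2e^{-\mu}(\beta_1(E)\mu + G(E))/(\mu+G(E))$, the expected number
of checkpoint arrivals produced per checkpoint arrival at frozen
environment $E$. Under $R_0(0) < 1 < R_0(1)$ and the monotonicity
hypothesis $\beta_1'(\mu+G) + G'(1-\beta_1) > 0$, the equation
$R_0(\bar E) = 1$ has a unique root, found by bisection to $10^{-12}$
(`solve_steady_state()`); the steady state
$(\bar p, \bar Q) \propto (\mu/(2e^{-\mu}-1),\, 1)$ and the derived
quantities $l = (3e^{-\mu}-2)/(2e^{-\mu}-1) < 1$, $K$, and
$A(\bar E) = \big(\tfrac{2e^{-\mu}\mu}{2e^{-\mu}-1}\beta_1'(\bar E) +
G'(\bar E)\big)\bar E(1-\bar E)$ follow in closed form. Failure modes are
typed errors: extinction ($R_0(1) \le 1$), unbounded growth
($R_0(0) \ge 1$), hypothesis violation.

The monotonicity hypothesis is an inequality along a continuum; it is
checked on a 1001-point grid rather than symbolically. One numerical
subtlety: very steep Hill responses underflow their derivative to exactly
zero far from half-saturation, so the grid check rejects only genuinely
negative values (or an identically zero profile) — a flat-by-underflow
tail does not spoil a strictly increasing response.

Linearisation produces the coefficients
$$\alpha_1 = -\mu - G(\bar E) + A\tfrac{1-2\theta}{1-l\theta},\quad
\alpha_2 = 2e^{-\mu}\big(\mu\beta_1(\bar E) + G(\bar E) +
A\tfrac{\frac32\theta-1}{1-l\theta}\big),\quad
\alpha_3 = 2e^{-\mu}\beta_1(\bar E),$$
with $0 < \alpha_3 < 1$ automatic and the transcritical identity
$\alpha_1+\alpha_2 = (1-2e^{-\mu})A(\bar E) < 0$ holding to $10^{-10}$ in
tests. `char_matrix_det()` evaluates the $2\times2$ characteristic-matrix
determinant of the linearised system directly (the factor
$(1-e^{-(\mu+\lambda)})/(\mu+\lambda)$ extended by its series at
$\lambda = -\mu$); the package asserts only that its zero set coincides
with that of the scalar $\Delta$, not any proportionality factor.

## Response families and calibration

The model leaves $\beta_1$ and $G$ free. Three differentiable families are
provided (constant; increasing Hill $g_{\max}E^n/(E^n+h^n)$; linear), plus
user functions with analytic or central-difference derivatives. Case
studies pin $(\mu, \beta_1(\bar E), \bar E)$ rather than raw parameters,
so calibration helpers solve the steady-state identity
$G(\bar E) = (1-\alpha_3)\mu/(2e^{-\mu}-1)$ (G-regulated case) or
$\beta_1(\bar E) = (1 + G\frac{1-2e^{-\mu}}{\mu})/(2e^{-\mu})$
($\beta_1$-regulated case) for the remaining degree of freedom.

The reference fixture (`make_fixture("fig4")`) uses $\mu = 0.5$, constant
$\beta_1 = 0.5$ and Hill $G$ with half-saturation at $\bar E = 0.5$; then
$g_{\max} = 2G(\bar E)$ and the local steepness is
$G'(\bar E) = nG(\bar E) \approx 0.923\,n$, so the Hill exponent is the one
steepness dial that moves neither $\bar E$ nor $\alpha_3$. In this setting
the $\theta$-line first touches the Hopf curve at
$G'(\bar E) \approx 65$ ($n \approx 70$): below that the steady state is
stable for every $\theta \in [1/2, 1]$. The packaged `shallow` ($n=2$) and
`steep` ($n=120$, $\theta_{crit} \approx 0.534$) fixtures sit on the two
sides of that threshold by construction. Such exponents are extreme as
chemistry but are simply what the feedback geometry demands at
$\bar E = 0.5$; the two-parameter map below makes the requirement visible.

## One- and two-parameter studies

Since $R_0$ is $\theta$-free, varying $\theta$ moves $(\alpha_1,\alpha_2)$
along a line of slope $-1$ ($\alpha_3$ and $\alpha_1+\alpha_2$ fixed) with
$\alpha_1$ strictly decreasing — North-West. `hopf_point()` solves
$\frac{\omega}{\sin\omega}(\cos\omega-1) =
\frac{1-2e^{-\mu}}{1+\alpha_3}A(\bar E)$ for the unique
$\omega^* \in (0,\pi)$ by bisection (left side strictly decreasing from 0
to $-\infty$, right side negative), and $\bar\alpha_1 = c_1(\omega^*,
\alpha_3)$. The $\theta$ study then reduces to comparing $\bar\alpha_1$
with the $\theta = 1/2$ abscissa $-\mu-G(\bar E)$: either stable on all of
$[1/2,1]$, or a unique $\theta_{crit} \in (1/2, 2/3)$ (bisection to
$10^{-10}$; exact because $\alpha_1(\theta)$ is monotone). $\theta \ge 2/3$
is always stable: there $\alpha_2 > 0$ while $\alpha_1+\alpha_2 < 0$, which
is inside the region.

`map_to_model_plane()` pushes any boundary curve into the
$(G'(\bar E), \theta)$- or $(\beta_1'(\bar E), \theta)$-plane through the
inverse parameter map ($\theta$ from a Möbius-type expression in
$(\alpha_1, \alpha_2)$; the slope from
$A = \text{slope}\cdot\bar E(1-\bar E)$). The two planes differ only by the
factor $(2e^{-\mu}-1)/(2e^{-\mu}\mu)$, fully determined by $\mu$ — the
package checks this to $10^{-10}$, which is the model's way of saying that
observed oscillations cannot identify *which* mechanism (initiation or
termination of quiescence) carries the feedback. Points at the pole
$\theta = 1/2$ of the slope expression (equivalently
$\alpha_1 = -\mu-G(\bar E)$) are dropped and recorded; mapped $\theta$
outside $[0,1]$ is flagged rather than discarded, since far parts of $C_0$
map outside the physical window. Instability sits at small $\theta$ and
large steepness, with the $C_1^+$ image strictly inside the unstable side.

## The simulator

The nonlinear system is integrated by the method of steps on a uniform
grid with $N$ points per unit delay, locked to integer times so the jump
discontinuities that the renewal structure propagates land on nodes and are
never smoothed. Per node, the consumption integral uses the composite
trapezoidal rule on the stored history; its $a = 0$ endpoint makes
$(p, E)$ weakly implicit, solved by fixed-point iteration (tolerance
$10^{-12}$, at most 50 iterations, damping 0.5 on non-contraction) jointly
with a trapezoidal predictor–corrector step for $Q$. The scheme is
second-order between breakpoints and at least first-order overall; the
suite asserts that doubling $N$ at least halves the error. Defaults
$N = 256$, `t_end = 200` resolve the relevant oscillation periods
($2\pi/\omega \ge 2$) with hundreds of samples per period; the test suite
uses shorter horizons ($t_{end} \le 120$) chosen to keep the full property
suite around a minute while leaving the measured rates within a few per
mil of the linear prediction.

`measure_dominant_mode()` extracts the dominant linear mode from
oscillation peaks (parabolically refined; log-height regression for the
rate, mean spacing for the frequency), or from the log-envelope when the
decay is monotone. Two practical rules make this reliable. First, the
reference level is the integrator's *own* fixed point (the tail of an
unperturbed run), not the analytic steady state — the two differ by the
$O(h^2)$ quadrature bias, which would otherwise floor the measurable
signal. Second, for an unstable steady state the mode is measured on a
window cut *before* nonlinear saturation (the orbit settles on a limit
cycle whose amplitude no longer grows and whose frequency is not
$\mathrm{Im}\,\lambda$), so growing runs start from perturbations as small
as $10^{-7}$. With these rules, measured rates and frequencies match the
dominant characteristic root to well under the 5% the cross-validation
tests demand, on both sides of the stability boundary.

## What the synthetic setups do and do not show

All validation inputs are generated in code: the named fixtures above, and
random model draws ($\mu \sim U(0.05, 0.6)$, $\theta \sim U(0,1)$,
$\bar E \sim U(0.2, 0.8)$, Hill exponents $U(1.5, 6)$, constant or gently
increasing $\beta_1$) that satisfy the steady-state conditions by
construction. They exercise the analytic structure — identities, region
geometry, bifurcation thresholds, linear/nonlinear consistency — under
exactly the assumptions of the model: a sharp cell-cycle duration, a
single well-mixed resource, quasi-steady-state environment, smooth
monotone responses. Passing tests therefore say nothing about distributed
cell-cycle times, spatial structure, measurement noise, or non-monotone
feedback; none of those are modelled.

## Numerical choices and limitations

* Bisection tolerances: $10^{-12}$ in $\omega$ and $\bar E$;
  boundary-proximity tagging at $10^{-8}$; marginal-root margin $10^{-8}$
  (caller-adjustable). Conditioning degrades at the corner (double root),
  which is why the corner is handled by closed forms wherever possible.
* Curves are sampled evenly in $\alpha_1$ (inverted by bisection), making
  them graph-like for plotting and export; $C_k$ branches are built for
  $k \le 3$ by default, enough to label every region that fits a
  reasonable plotting window.
* For $|\alpha_3| \ge 1$ the package only rejects; the infinitude of
  right-half-plane roots in that regime is not certified, and the limiting
  diagrams are only approached through $|\alpha_3| \to 1$ inside the
  admissible range. Near those limits convergence of the $C_k^\pm$
  branches to the diagonal lines is non-uniform around their
  $\alpha_2$-axis crossings (deviation of order
  $(2k+1)\pi\sqrt{1-|\alpha_3|}$), which the tests account for by
  excluding a small neighbourhood of the crossing.
* No continuation of periodic orbits past the Hopf point, no adaptive time
  stepping, and no treatment of the neutral-equation solution theory
  beyond what the linear analysis needs.
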