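---
title: "Methods: tumour-virus reaction-diffusion dynamics with radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour-virus reaction-diffusion dynamics with radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`virodyn` simulates the interaction of an aggressive tumour with a
continuously delivered oncolytic virus in the cylindrically symmetric annulus
of tissue served by one blood vessel. The vessel has radius $r_b$; the tissue
it supports extends to $r_b/\mathrm{BVF}$, where BVF is the blood volume
fraction. Three densities evolve on $r \in [r_b, r_b/\mathrm{BVF}]$:
uninfected tumour cells $x(r,t)$, infected tumour cells $y(r,t)$ and free
virus $v(r,t)$:

$$
\begin{aligned}
\partial_t x &= D_1 \nabla^2 x + r_1 x - \beta x v,\\
\partial_t y &= D_1 \nabla^2 y + \beta x v - \delta y,\\
\partial_t v &= D_2 \nabla^2 v + b \delta y - \kappa \beta x v - \alpha v,
\end{aligned}
$$

with $\nabla^2 = \tfrac1r \partial_r (r\, \partial_r)$. Tumour growth is
exponential at rate $r_1$ (no carrying capacity: the model describes an
aggressive tumour on a 30-day horizon). Infection is mass-action at rate
$\beta$; lysis at rate $\delta$ releases $b$ new virions per cell; each
infection consumes $\kappa$ virions (default 1), and free virus is cleared at
rate $\alpha$. Cells satisfy no-flux conditions at both boundaries; the virus
is held at the delivery concentration $v_0$ on the vessel wall (a Dirichlet
condition representing continuous delivery) and is no-flux at the outer rim.

In the two-phase (radiovirotherapy) protocol, virotherapy runs alone until
$t_r$; from then on radiation at dose-rate $R(t)$ removes cells into a
damaged compartment $u(r,t)$:

$$
\begin{aligned}
\partial_t x &= D_1 \nabla^2 x + r_1 x - \beta x v - a_1 R(t)\, x,\\
\partial_t y &= D_1 \nabla^2 y + \beta x v - \delta y - a_2 R(t)\, y,\\
\partial_t u &= a_1 R(t)\, x + a_2 R(t)\, y - \gamma u,\\
\partial_t v &= D_2 \nabla^2 v + b \delta y - \kappa \beta x v - \alpha v.
\end{aligned}
$$

Damaged cells are immobile: $u$ has no diffusion term and therefore needs no
boundary condition. The Phase I fields at $t_r$ become the Phase II initial
conditions, with $u(r,t_r) = 0$. As printed in its source, the
radiovirotherapy virus equation carries the consumption term $\beta x v$,
i.e. it assumes $\kappa = 1$; `virodyn` applies $\kappa$ in both phases so
that the two models coincide exactly when $R \equiv 0$.

Three radiation deliveries are provided, all measured from $t_r$:
constant $R(t) = R$ (temporary brachytherapy; default $R = 2$),
decaying $R(t) = \beta_1 e^{-\alpha_1 (t - t_r)}$ (permanent brachytherapy;
defaults $\beta_1 = 2$, $\alpha_1 = 0.01\,h^{-1}$), and periodic
$R(t) = \beta_2 + \alpha_2 \sin \omega (t - t_r)$ (external beam; defaults
$\beta_2 = \alpha_2 = 1$, $\omega = 2\,$rad/h). Measuring time since $t_r$ is
a design choice: radiation does not exist before Phase II, and only under
this reading do the constant and decaying modes agree (both equal 2) when
radiation starts, which is the behaviour the protocols are meant to compare.
The per-hour units of $\alpha_1$ and $\omega$ follow the model's overall
hour-based clock. With the defaults $a_1 R = 0.02\,h^{-1} = r_1$ for the
constant mode: the reference dose exactly cancels tumour growth, which is
what makes the constant protocol qualitatively different from the other two.

### The output functional

Treatment outcome is tracked through the normalized viable tumour mass

$$
f_x(t) = \frac{2\pi}{M_0} \int_{r_b}^{r_b/\mathrm{BVF}} x(r,t)\, r\, dr,
\qquad V = \pi\left[(r_b/\mathrm{BVF})^2 - r_b^2\right],
$$

with $M_0 = x_0 V$ in Phase I. In Phase II the baseline is reset to the
viable mass at $t_r$, so the Phase II curve restarts at 1 and measures what
radiation adds on top of the virotherapy achieved so far. The integral is
evaluated by composite trapezoid quadrature on the grid nodes; the rule is
exact for the linear integrand $x_0 r$, so $f_x(0) = 1$ holds exactly rather
than to quadrature tolerance.

## Parameters

All times are hours, lengths mm, densities per mm³. Reference values:

| symbol | meaning | default | units |
|---|---|---|---|
| $D_1$ | tumour cell diffusivity | $10^{-8}$ | mm²/h |
| $r_1$ | tumour growth rate | 0.02 | 1/h |
| $\beta$ | infection rate | $7\times10^{-10}$ | mm³/(h·virus) |
| $\delta$ | infected-cell death rate | 1/18 | 1/h |
| $D_2$ | virus diffusivity | $5\times10^{-7}$ | mm²/h |
| $b$ | burst size | 50 | virus/cell |
| $\kappa$ | consumption per infection | 1 | virus/cell |
| $\alpha$ | virus clearance | 0.008 | 1/h |
| $a_1, a_2$ | radiation damage rates | 0.01 | 1/h per dose-rate |
| $\gamma$ | damaged-cell death rate | 0.01 | 1/h |
| $r_b$ | vessel radius | 0.01 | mm |
| BVF | blood volume fraction | 0.05 | — |
| $v_0$ | wall virus density | $0.5\times10^6$ | virus/mm³ |
| $x_0$ | initial tumour density | $0.5\times10^6$ | cell/mm³ |
| $t_r$ | radiotherapy start | 120 | h |

The parameters that matter most for the qualitative outcome are $\beta$, $b$
and $\alpha$ (swept by `run_sweep()`): the spatially uniform coexistence
state of the reaction system sits at $x^* = \alpha / [\beta(b-\kappa)]
\approx 2.3\times10^5$ cells/mm³ and $v^* = r_1/\beta \approx 2.9\times10^7$
virus/mm³, and the trajectory is a damped predator-prey-like excursion
around it. Raising $\beta$ deepens and hastens the first collapse; raising
$\alpha$ starves the virus and leaves more tumour; a tiny burst size
($b = 2$) cannot sustain the virus at all and the treatment behaves like a
consumable drug, with no oscillation.

## The initial virus profile

The initial interior virus distribution is the one genuinely open modelling
choice: only the wall value $v_0$ is part of the model statement.
`initial_state()` implements two readings:

* **`"uniform"` (default)** — $v(r,0) = v_0$ everywhere: the delivery system
  (e.g. nanovectored carriers) loads the tissue at the treatment
  concentration when therapy starts.
* **`"wall"`** — $v(r,0) = 0$ except at the vessel wall: virus enters only
  by diffusion from the vessel.

The default is `"uniform"`, for a physical reason. With
$D_2 = 5\times10^{-7}$ mm²/h, the diffusion time across the 0.19 mm annulus
is $L^2/4D_2 \approx 1.8\times10^4$ h — about two years. Under the `"wall"`
reading the virus therefore never meaningfully reaches the tissue within the
30-day treatment: the infection travels as a slow front, the tumour grows
essentially unchecked for ~13 days, and adding radiation at day 5 finds an
almost virus-free tissue (the combined protocol then barely improves on
radiation alone, contradicting the reported synergy of the combination).
Under the `"uniform"` reading the model reproduces the reported behaviour of
the combined protocol — collapse of the Phase II mass to below 1% of its
baseline within six days of constant radiation, and the
constant < periodic < decaying end-of-run ordering. Spatial profiles showing
infection dynamics across the whole annulus within the first week are
likewise only possible with interior virus. Both readings remain available,
and all structural tests (oracles, conservation, convergence) are
independent of the choice.

## Numerics

* **Space.** Uniform grid of `n_nodes` (default 191, so $\Delta r = 1\,\mu$m
  on the reference geometry). The cylindrical Laplacian is discretized in
  conservative finite-volume (flux) form: second-order central differences
  in the interior, a zero discrete face flux at no-flux boundaries
  (equivalent to a mirror ghost node weighted by the face radius), and
  clamped values at Dirichlet nodes (whose own Laplacian is reported as 0 —
  a clamped node does not evolve). The flux form is chosen so that the
  discrete operator telescopes exactly against the trapezoid quadrature
  weights: with all reactions off and sealed boundaries, the measured mass
  of each species is conserved to machine precision, which the test suite
  asserts at $10^{-6}$ relative over 100 h.
* **Time.** Method of lines with classic fixed-step RK4 (default
  $\Delta t = 0.05$ h). The integrator refuses to start if $\Delta t$
  exceeds the explicit-diffusion bound
  $0.25\,\Delta r^2/\max(D_1, D_2)$, and aborts with the step index if any
  field becomes non-finite. The default step was fixed by the robustness
  rule "halving $\Delta t$ changes $f_x(720\,h)$ by well under 0.1%
  relative"; at the reference resolution the observed change is at the
  $10^{-13}$ level, i.e. the time discretization contributes nothing
  visible next to the spatial one.
* **Boundary enforcement.** The wall virus value is imposed on the incoming
  state of every RK4 stage evaluation and re-imposed after each full step,
  so the Dirichlet node is exact at stage points and snapshots alike.
* **Snapshots and summaries.** Full fields and $f_x$ are recorded every hour
  (plus $t=0$ and $t_{\mathrm{end}}$). Extremum times are reported at
  snapshot resolution without interpolation — with the 1 h cadence, timing
  claims are resolvable to the hour. Oscillation detection ignores
  turning points with prominence below 1% of the trajectory range;
  "eradicated" means $f_x < 0.01$ at the end of the run and non-increasing
  over the final 48 h.

### Verification strategy

Every structural property is checked against an independent oracle rather
than against the solver itself: the virus-free model against the exact
exponential $e^{r_1 t}$ (to $10^{-6}$); the zero-diffusion limit against an
adaptive `deSolve::lsoda` integration of the well-mixed three-species system
(to $10^{-4}$ over 240 h); the decoupled virus equation against a direct
linear solve of the same discretized operator; and the discretization order
against refinement studies. The order-of-accuracy test runs on a smooth,
grid-resolvable configuration (enhanced diffusivities $D_1 = 10^{-5}$,
$D_2 = 10^{-4}$ mm²/h, a smooth virus bump, 24 h horizon, 25/49/97 nodes)
because order of accuracy is a property of the scheme and is only measurable
where the exact solution is smooth on all grids in the study; see the
limitations below for why the full 720 h reference trajectory is not such a
configuration.

## What the defaults do and do not reproduce

The package's reference conditions reproduce, at the default resolution:

* the Phase II collapse under constant radiation (to ≈ 0.04% of the Phase II
  baseline six days after starting radiation, and decaying thereafter — the
  reference dose exactly cancels growth, so the virus does the rest);
* the end-of-run protocol ordering constant ≤ periodic ≤ decaying;
* monotone responses to $\beta$ and $\alpha$, and the non-oscillatory
  $b = 2$ regime;
* virotherapy alone failing to eradicate (deep minimum followed by
  regrowth).

They do **not** reproduce the originally reported Phase I landmark values
(minimum ≈ 7% of initial mass, ≈ 55% at day 30, peak near day 7): with the
reference constants exactly as tabulated, the computed trajectory peaks at
day 5.6, dips to ≈ 1.2% and ends near 7.5%, and no reading of the
unspecified choices we explored (interior virus level, wall-only seeding,
grid and step refinement) yields all three landmark values simultaneously.
The package reports what the stated model and constants actually produce.

## Known limitations

* **Post-collapse sensitivity.** After the first viral sweep the viable
  density falls by many orders of magnitude; the later recurrence grows out
  of those near-zero residuals at rate $r_1$ ($e^{r_1 \cdot 720} \sim
  10^6$), so late-time values such as $f_x(720\,h)$ amplify tiny
  discretization differences enormously. They are reproducible
  bit-for-bit at fixed settings (the model is deterministic) but converge
  slowly under grid refinement. Early-time quantities (the first collapse,
  the Phase II response) are robust. A continuum model is anyway a doubtful
  description of densities below one cell per domain; the eradication
  criterion (mass below 1% and not regrowing) is the intended reading of
  such tails.
* **Wall-seeded fronts.** Under `v_init = "wall"` the solution is a
  reaction-diffusion front propagating into an unstable (growing) state;
  its numerical speed converges slowly in $\Delta r$, compounding the
  previous point.
* **Model scope.** One spatial dimension (cylindrical symmetry), no immune
  response, no healthy-tissue compartment, no radiation damage to normal
  tissue, exponential (unsaturated) tumour growth, continuous virus
  delivery only — bolus or cyclic delivery is not modelled.
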