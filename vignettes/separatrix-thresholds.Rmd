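---
title: "Separatrices and spike-threshold variability: models, methods, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separatrices and spike-threshold variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepx)
```

## The problem and the model class

The voltage at which a neuron commits to firing an action potential (AP) is
not a constant: it depends on the recent stimulation history through the
state of the recovery and gating variables.  This package treats that
variability as a geometric fact about state space.  Every model in the zoo
is written in the conductance-based normal form

$$C\,\dot v = f(v, X) + i_e(t), \qquad
  \dot x = \frac{x_\infty(v) - x}{\tau_x(v)} \ \text{for each gating
  coordinate } x,$$

and the *separatrix* — the boundary of the resting state's basin of
attraction — is the set of states from which an instantaneous voltage shift
flips the outcome between AP and subthreshold relaxation.  The
*instantaneous threshold* $\theta(X; i_e)$ is the voltage coordinate of the
separatrix at a frozen gating state.  Everything else in the package
(threshold traces, clamp maps, pulse boundaries) is a projection or a
re-parameterisation of this one object.

A deliberate non-goal: the package never defines a threshold from voltage
derivatives of an already-recorded AP (the common $dV/dt$ criteria).  Those
describe an AP after the fact; the separatrix predicts one.

## The model zoo and its reference parameters

All dimensionless models use $C = 1$; the registry
(`neuron_model()`) carries the reference values and every parameter is
overridable through a config file or the `params` argument.

* **`qif`** — quadratic integrate-and-fire,
  $\dot v = (v - v_r)(v - v_t) + i_e$, reset to $v_{reset}$ at $v_{peak}$.
  The separatrix is a *point*: the larger root of $\dot v = 0$.  Defaults
  $v_r = 0$, $v_t = 30$, $v_{peak} = 40$, $v_{reset} = -5$ put the rheobase
  at $(v_t - v_r)^2/4 = 225$, so the demonstration current $I_e = 50$ is
  comfortably subthreshold.
* **`pwl2d`** — piecewise-linear voltage nullcline in three segments
  (slopes $-0.5, 0.5, -0.25$; breakpoints $1.5$ and $25$) with a linear
  recovery current ($\tau_w = 5$, $k_w = 0.45$).  The separatrix is a
  *line* through the middle-segment saddle.
* **`pwl3d`** — the same construction with two recovery currents
  ($\tau_u = 5$, $k_u = 0.45$; $\tau_w = 10$, $k_w = 0.6$; steeper middle
  segment $k_m = 0.95$, right breakpoint at $50$).  The separatrix is a
  *plane*.
* **`fhn`** and **`boltzmann-fhn`** — FitzHugh–Nagumo cubic with a linear
  ($w_\infty = k_w v + b_w$) or Boltzmann recovery nullcline.  These are
  the demonstration models for quasi-threshold (canard) behaviour; the
  Boltzmann variant is a type I cell with a genuine saddle.
* **`fhn3d`** — FitzHugh–Nagumo with two recovery variables, included for
  completeness of the zoo.
* **`hh`** — the classic Hodgkin–Huxley squid-axon equations in the modern
  voltage convention (rest near $-65$ mV), with
  $\bar g_{Na} = 120$, $\bar g_K = 36$, $\bar g_L = 0.3$ mS/cm²,
  $C_m = 1$ µF/cm² and reversal potentials $50$, $-77$, $-54.4$ mV.  Only
  the reversal potentials are fixed by the problem statement; the
  conductances are the standard published values of this convention and
  are config-overridable.

### The Boltzmann nullcline parameterisation

The Boltzmann-FHN recovery nullcline is implemented as

$$w_\infty(v) = \frac{a}{1 + b\,e^{-v/c}}, \qquad
  a = 2,\ b = 3,\ c = 0.27,\ \tau_w = 8,\ i_e \equiv 0.62 .$$

This choice is load-bearing.  The alternative reading of the same three
parameters, $a/(1+\exp((b-v)/c))$, places the sigmoid's midpoint at
$v = 3$ — outside the cubic's working range — and yields a *stable* third
equilibrium, which contradicts the required type I portrait.  With the
parameterisation above the three equilibria are a stable point
($v \approx -1.224$), a saddle ($v \approx -0.659$) and an unstable node
($v \approx 0.193$, both eigenvalues real and positive), exactly the
portrait the model is meant to demonstrate.  `neuron_model("boltzmann-fhn")`
*validates this portrait at construction* and raises a fixture-validation
error for parameter overrides that break it.

## Analytic separatrices

**QIF.** For $i_e$ below rheobase the two roots of $\dot v = 0$ are the
dynamic resting potential and the dynamic threshold;
`qif_threshold()` returns both.  Depolarising current raises the rest and
lowers the threshold until they merge in a saddle-node at rheobase
(`qif_rheobase()`), where the threshold error is raised.

**2D PWL.** The middle-segment fixed point is a saddle; its stable
direction has slope $k_\theta = k_m/C - \lambda_s$ where $\lambda_s$ is the
negative eigenvalue of the middle-region Jacobian, and the line

$$w = k_\theta v + b_\theta, \qquad
  b_\theta = \frac{(i_e + b_m)(k_w - k_\theta)}{k_w - k_m}$$

passes exactly through the saddle.  With the reference parameters
$k_\theta = 0.5302776$, $b_\theta = -2.4083269$, and
$k_\theta > k_m > k_w$, so the threshold falls as depolarising current
rises, and $i_e$ moves the line up without rotating it.  States *below*
the line fire.

**3D PWL.** The middle-region Jacobian has three real eigenvalues
($0.7920$, $0.0160$, $-0.1580$ at the defaults).  The plane spanned by the
two non-dominant eigenvectors, anchored at the middle-segment equilibrium,
is invariant under the middle-region flow and is the threshold plane; the
dominant eigenvector is the fast firing direction and fixes the firing
side.  The two smallest-magnitude eigenvalues are chosen as the spanning
pair precisely because the transverse direction must be the fast one.

**Virtual fixed points.** With the 2D reference parameters the saddle sits
at $v = 30$, *outside* its own middle region — it is a virtual fixed
point, as is the middle-region anchor of the 3D plane.  The line/plane is
still constructed from the segment algebra and is still invariant for the
flow *inside* the middle region; its validity annotation is the middle
region only, and the hyperpolarised continuation of the separatrix is
obtained by `trace_manifold()`, which integrates backward in time from the
line (or from a real saddle, offset by $\delta$ along the stable
eigenvector).

### The canard layer and what "agreement" can mean

Because the 2D saddle is virtual, the line is strictly speaking a
quasi-separatrix: trajectories that hug it closely eventually leave the
middle region near the right breakpoint and enter a region governed by a
different (spiralling) segment, where graded peaks exist.  The width of
this canard layer around the line grows toward the right breakpoint — by a
linearised growth estimate it is of order $10^{-6}$ (in $w$) for
$v \lesssim 15$, and of order $10^{-3}$ near $v = 24$.  Consequently the
package's own validation of "simulation agrees with the line side"
samples states at $v \in [2, 15]$, where the layer is far below the
sampling resolution, and the clamp-boundary comparison uses rows
$v_c \in [6, 20]$.  This is not a tolerance trick: outside the layer the
agreement is exact to bisection precision; inside it the model genuinely
has no sharp boundary, which is the quasi-threshold point the models are
built to illustrate.

## Numerics

**Integration** is fixed-step classic RK4 (compiled), default
$\Delta t = 0.01$ (time units / ms), free-evolution horizon 100.  The step
was convergence-checked: endpoint errors scale as $\Delta t^4$ (empirical
order $\ge 3.9$) and trajectories agree with the matrix-exponential
closed form inside linear regions to $10^{-13}$ at $\Delta t = 10^{-3}$.
During a voltage clamp the voltage coordinate is held exactly (the
derivative is zeroed and the coordinate pinned), matching the ideal-clamp
idealisation; impulses are exact jumps $\Delta v = q/C$ (a narrow
rectangular pulse is available through `stim_step()` when the
approximation itself is under study).  The QIF reset accepts the crossing
step, records the peak capped at a configurable value, and jumps to
$v_{reset}$ — reproducibility is preferred over resolving the exact peak
of an unbounded quadratic blow-up.

**AP criteria.** HH: $V_{max} \ge 0$ mV; piecewise-linear models:
$v_{max}$ reaches the right breakpoint of $f(v)$; FitzHugh–Nagumo family:
$v_{max} \ge 1$; QIF: a reset event.  For the PWL models "reaching the
right breakpoint" is exactly the event that separates line-side outcomes
up to the canard layer, which is why it is the criterion.

**Bisection** (`instantaneous_threshold()`, `bisect_boundary()`) is
deterministic with a 20-point pre-scan that detects graded (multi-flip)
responses; when several flips exist the one nearest rest is returned with
a warning.  Hyperpolarised brackets are legal — thresholds below rest are
physiological after inhibition.

**Threshold traces** (`threshold_trace()`) return two columns computed by
different routes: direct bisection at each node, and integration of

$$\dot\theta = \frac{\partial\theta}{\partial i_e}\frac{di_e}{dt} +
  \sum_x \frac{\partial\theta}{\partial x}\,
  \frac{x_\infty(v) - x}{\tau_x(v)} .$$

For QIF and the PWL models the partials are analytic (root formula;
line/plane coefficients) and the quadrature is exact.  For HH the partials
are central finite differences of bisection thresholds.  The error budget
that sets the comparison tolerance: with bisection tolerance $10^{-5}$ mV
and FD step $h = 5\times10^{-3}$ per gating unit, the gradient error is
$\sim 2\cdot 10^{-5}/h + O(h^2) \approx 4\times10^{-3}$, integrated over a
10 ms clamp path; the package asserts agreement within $0.02$ mV (five
times the budgeted per-node error).  The FD step is larger than naive
because the bisection noise term $2\,\mathrm{tol}/h$ dominates below
$h \approx (\mathrm{tol})^{1/3}$.  One further numerical point: the
gradient integrand contains the $m$-gate relaxation with
$\tau_m \approx 0.3$ ms, so gradient nodes are placed on a
transient-resolving schedule near $t = 0$ rather than the uniform user
grid; a uniform 1 ms schedule biases the trace by $\sim 0.3$ mV.

**First-order reduction** (`first_order_fit()`) fits
$\theta(t) = \theta_\infty + (\theta_0 - \theta_\infty)e^{-t/\tau_\theta}$
with a deterministic AR(1) initialisation (exact on a pure exponential)
polished by Nelder–Mead.  Constant traces leave $\tau_\theta$
unidentifiable and are flagged rather than fitted.

The reduction claim is about the *equation form*: for the 2D PWL model
$\dot\theta = (\theta_\infty(v) - \theta)/\tau_w$ holds identically, so
whenever $v$ is held (voltage clamp, or any $di_e/dt = 0$ situation with
$v$ pinned) the trace is a single exponential with
$\tau_\theta = \tau_w$ *exactly*.  The package demonstrates the reduction
along a clamp protocol for that reason; under a free-running DC step the
trace mixes the complex eigenmodes of the resting region
($-0.35 \pm 0.26i$) and no single time constant exists — that observation,
and the two-time-constant obstruction in the 3D model
($\tau_u = 5 \ne \tau_w = 10$ leaves a relative single-exponential
residual of $\approx 5\times10^{-3}$ versus below $10^{-9}$ for a matched
single-$\tau$ control), delimit where the classic first-order threshold
equation can be trusted.

**Eigen-plane validation horizon.** A trajectory started on the 3D plane
drifts off it at the rate at which eigenvector rounding error
($\sim 10^{-13}$) is amplified by the dominant eigenvalue,
$e^{0.79 t}$ — about $10^{-6}$ by $t \approx 20$.  The on-plane invariance
test therefore runs to $t = 15$; the off-plane *non-crossing* property has
no such limit and is checked on 50 starts for as long as each remains in
the middle region.

## Scans and boundaries

`clamp_scan()` exploits the closed-form clamp relaxation
(`clamp_relax()`): the clamp phase costs nothing, each cell is one free
evolution.  `extract_boundary()` refines per-row flips by bisection and
labels each point `separatrix` (release derivative away from zero: the
threshold border) or `zero-rate` (the $dv/dt = 0$ border in the
high-voltage region).  For the 2D model the separatrix border has the
closed form

$$\tau_c(v_c) = -\tau_w\,
  \log\!\left(1 - \frac{k_\theta v_c + b_\theta}{k_w v_c}\right),$$

(`pwl2d_clamp_boundary()`), finite for middle-region clamp voltages
between the rest-threshold ($\approx 4.54$) and the saddle voltage (30).
Scan grids are configurable; the shipped analyses use $v_c$ steps of
0.5–2 units with $\tau_c \in (0, 20]$ at step 0.1–0.5, sizes chosen to
resolve both borders at desk scale.  The Hodgkin–Huxley map on
$V_c \in [-88, -32]$ reproduces the canonical structure: long depolarised
clamps suppress APs (accommodation), long hyperpolarised clamps elicit
them on release (anode-break excitation), and the low-voltage border
satisfies the self-consistency $V_c = \theta(X(V_c, \tau_c); 0)$ to
$\sim 5\times10^{-5}$ mV.

## What the validations do and do not show

All validations run on the deterministic reference models themselves —
there is no synthetic noise, no channel stochasticity, no morphology.
Passing them shows that the package computes the separatrix objects it
defines correctly (analytic vs numerical route agreement) and that the
qualitative threshold phenomenology (accommodation, post-inhibitory
facilitation, threshold variability with stimulation history) follows
from separatrix crossing in these models.  It does not show that any of
these models quantitatively matches a biological neuron, and the
quasi-threshold analysis above marks exactly where the sharp-threshold
idealisation stops being meaningful.

## Known limitations

* No bifurcation-diagram machinery: parameter thresholds (rheobase aside)
  are out of scope, as is continuation of separatrices under parameter
  sweeps.
* No 4D hypersurface meshing for Hodgkin–Huxley; thresholds are computed
  pointwise and on clamp-plane sections.
* The 3D FitzHugh–Nagumo fold-curve/canard-surface geometry is not
  analysed; the model definition ships for completeness.
* Configs are JSON or YAML (the R ecosystem's structured-config formats);
  no TOML reader is bundled.
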