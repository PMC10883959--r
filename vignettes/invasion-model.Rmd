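---
title: "Predation, competition and the establishment of an exotic generalist predator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predation, competition and the establishment of an exotic generalist predator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasim)
```

## The model and its assumptions

`invasim` analyses the fate of an exotic generalist predator introduced
into a native prey–predator community.  The native baseline is the
classical Lotka–Volterra pair with logistic prey growth and a linear
(Holling Type-I) functional response:

$$\frac{dx}{dt} = r x\left(1-\frac{x}{K}\right) - d x y, \qquad
  \frac{dy}{dt} = p d x y - q y.$$

The native predator is a specialist: without prey it declines
exponentially at rate $q$.  Whenever $pdK > q$ the pair coexists at
$e_{xy} = \big(q/(dp),\; r(pdK-q)/(d^2Kp)\big)$, which is locally stable
whenever it exists, and globally attracting in practice — every
simulated trajectory from positive interior states reaches it.

The invaded system adds the exotic density $Z$:

$$\begin{aligned}
\frac{dX}{dt} &= r X\left(1-\frac{X}{K}\right) - d X Y - \alpha d X Z\\
\frac{dY}{dt} &= p d X Y - q Y - \beta b Y Z\\
\frac{dZ}{dt} &= s Z\left(1-\frac{Z}{\kappa(X)}\right) - b Z Y, \qquad
\kappa(X) = n\alpha d X + c.
\end{aligned}$$

Three modelling choices matter:

* **Proportional rates.** The exotic's predation rate is $\alpha d$ and
  the competitive mortality it imposes on the native predator is
  $\beta b$, both proportional to the corresponding native-side
  coefficients.  $\alpha > 1$ means the exotic out-predates the native;
  $\beta > 1$ means it out-competes it.  This makes the two axes of the
  scenario maps directly interpretable as relative predation pressure
  and relative competitive ability.
* **Generalism.** The exotic grows logistically with a prey-dependent
  carrying capacity $\kappa(X)$ that never falls below $c$: it persists
  on alternative food even with no prey, which is why the exotic-only
  state $E_Z=(0,0,c)$ always exists.
* **Linear functional response.** Consumption scales linearly with prey
  density.  Saturating (Type-II) responses are deliberately out of
  scope; they would add handling-time parameters without changing the
  questions the package answers.

## Equilibria and stability

All fixed points are closed-form (`native_equilibria()`,
`boundary_equilibria()`, `interior_equilibria()`).  The boundary states
and their stability conditions are:

| state | exists | stable |
|---|---|---|
| $E_0=(0,0,0)$ | always | never |
| $E_X=(K,0,0)$ | always | never (the exotic grows at rate $s$) |
| $E_{XY}=(x_s,y_s,0)$ | $pdK>q$ | $s - b\,y_s < 0$ |
| $E_{XZ}$ | $r > \alpha dc$ | $\alpha d^2K(cp+\alpha nq) + \big(\beta b(c+\alpha dKn)-pdK+q\big)r > 0$ |
| $E_Z=(0,0,c)$ | always | $r < \alpha cd$ |

Two of these inequalities carry the ecology of the whole analysis.  The
$E_{XY}$ condition says the exotic cannot invade when its intrinsic
growth $s$ is below the competitive mortality $b\,y_s$ exerted by the
resident native predator — biotic resistance in one line.  The $E_Z$
condition defines the predation threshold $\alpha = r/(cd)$
(`region3_boundary()`): past it, exotic predation pressure at the
guaranteed capacity $c$ exceeds the prey's intrinsic growth and the prey
cannot re-invade.

The interior (three-species) equilibrium has prey coordinate $X_s$
solving a concave-down quadratic $P(\theta)=A_0+A_1\theta+A_2\theta^2$
on $(0,K)$, with coordinates $Y_s, Z_s$ determined by $X_s$
(`interior_quadratic()`).  Candidate roots must also satisfy
$\beta b(c+n\alpha dX_s) > pdX_s - q > 0$ so that $Y_s, Z_s > 0$.  When
two roots qualify, the smaller lies on the rising limb of $P$
($P'(X_s)>0$) and is discarded as unstable; when exactly one qualifies
it is the coexistence candidate *whatever the sign of* $P'(X_s)$.  The
distinction is not cosmetic: at the reference parameter set with
$b=0.005$, $\alpha=0.7$, $\beta=0.5$ the single qualifying root has
$P'(X_s)>0$ and is nevertheless the attractor (simulation from
$(15,10,2)$ lands on it to machine precision).  A rule that required
$P'(X_s)<0$ unconditionally would erase the entire coexistence region
at that competition level.  Because no closed-form stability predicate
is available for the interior state, it is classified by the
eigenvalues of the closed-form Jacobian (`classify_numeric()`), and the
analytic predicates above are continuously cross-validated against the
same eigenvalue classifier (`stability()`): over thousands of sampled
parameter sets the two never disagree outside a $10^{-6}$ marginal
band.

One degeneracy deserves care: at exactly $r=\alpha cd$ (for the
reference set, $\alpha=1.2$) the state $E_{XZ}$ collides with $E_Z$ in
a transcritical exchange.  Points within $10^{-9}$ (relative) of such
existence boundaries are reported *marginal* rather than forced into
exists/absent, and stability margins within $10^{-6}$ are likewise
never classified — grid cells touching them carry a `marginal` flag.

## Scenarios, propagules, impact

`classify_cell()` assembles the set of simultaneously stable attractors
at a given $(\alpha,\beta)$ and maps it to a region label: I (native
resistance), II (native predator excluded), III (native collapse), IV
(coexistence), plus the bistable overlaps I+II and I+III where the
outcome genuinely depends on the initial condition.  Overlap cells are
*not* resolved to a single scenario — that resolution belongs to the
propagule analysis.  `scenario_scan()` rasterises the plane; the
default grid is $[0.05, 2.5]^2$ at $101\times101$, which covers all the
reference anchor points; classification is pointwise, so refining the
grid never flips a non-marginal cell.

In bistable cells the exotic enters the native community at its
equilibrium $(x_s, y_s)$, so establishment is a property of the
propagule size $Z_0$ alone.  `min_propagule()` finds the threshold
$Z^*$ by a 20-point ascending geometric scan of $[10^{-3}, 50]$
followed by bisection to a bracket of width $10^{-3}$.  Monotonicity of
establishment in $Z_0$ is assumed for the bisection but checked by the
scan and flagged if violated.  Two conventions differ from the
reference grayscale map: non-establishment is reported as an explicit
`NA` sentinel rather than $Z^*=0$ (a `fig7_coding` flag restores the
0-coding), because a literal $Z^*\approx 0$ means the opposite — any
positive propagule grows, which happens precisely when $E_{XY}$ is
unstable and which the package reports as $Z^* = 10^{-3}$ (the scan
floor).  The probed ceiling $z_{max}=50$ is a documented default, not a
derived quantity; bistable cells whose basin threshold exceeds it are
reported non-establishable at that ceiling.

Impact on native densities is measured by $R_1 = X/x_s$ and
$R_2 = Y/y_s$: long-run densities with the exotic present, relative to
the analytic exotic-free baseline (`impact_ratios()`).  The baseline is
not simulated — $e_{xy}$ is attracting whenever it exists, so a paired
run would only add numerical noise.  The qualitative summary
(`table5_summary()`) classes the prey as *increase* ($R_1>1$),
*collapse* (final density below 1 individual — an order of magnitude
below the baseline and bordering the extinction threshold; the value is
attached so a tiny positive equilibrium is never confused with
thresholded extinction), else *decrease*; the native predator as
*extinct* (below $10^{-4}$), *declines* ($R_2<1$), else *persists*.
At the mink-based parameter set the native predator is depressed
($R_2<1$) at every non-marginal grid cell, while the prey can profit
($R_1 > 1$) when the exotic predates little but competes hard — the
trophic-cascade signature of a superior competitor.

## Numerical choices

* **Integration.** The stiff-capable `lsoda` (deSolve) with the model's
  right-hand side compiled in C; relative tolerance $10^{-8}$, absolute
  $10^{-10}$.  Coordinate faces are exactly invariant in the compiled
  RHS, so a run started with $Z=0$ is a native-system run bit-for-bit.
  Components the solver overshoots into $(-10^{-9},0)$ are clamped to 0
  (positivity is structural); more negative values are treated as
  errors, never silently repaired.
* **Horizons.** Default $t_{end}=5000$ years with 2000 saved states:
  the slowest tested modes (margins of order $10^{-2}$/yr at $s=0.2$)
  equilibrate well within it.  Grid sweeps save 200–500 states per run
  since only the trailing window matters.  Runs cut short can leave a
  decaying component inside the band between the two outcome
  thresholds; such runs are reported `undetermined` rather than guessed.
* **Outcome thresholds.** Extinct below $10^{-4}$ individuals,
  persistent above $10^{-2}$, judged on the mean of the final 10% of
  saved states.  Attractor densities at the documented parameter sets
  are $O(1)$–$O(10)$, while decaying components head exponentially to
  zero, so the bands separate cleanly; the window mean avoids
  misreading transient dips.
* **Quadratic roots.** $A_2$ can be tiny, so roots of $P$ use the
  sign-aware stable quadratic formula and are then polished by
  bisection (`uniroot`) on a bracketing interval.
* **Sampling.** `sample_params()` draws each parameter uniformly and
  independently from its documented interval (the ranges give no
  distributional information beyond bounds), with a fixed default seed
  (20240222) purely for reproducibility.  $K$ spans $[100,200]$ in the
  ranges although every reference analysis pins $K=100$; the fixtures
  keep the pinned value, the ranges keep the printed interval.

## What the parameter generator does and does not emulate

The generator reproduces the study conditions: the "theoretical"
fixture ($c=10$, $n=2$) for scenario and propagule analyses, the "mink"
fixture ($c=0.05$, $n=3$) for impact analyses, and uniform sampling of
the documented mink-based ranges for the property suites.  It emulates
parameter *uncertainty*, not data: there is no demographic or
observation noise, no seasonality, and no spatial structure, so passing
tests establish internal consistency of the deterministic model across
its plausible parameter space — not agreement with field abundances.
Real invasions also feature repeated introduction events; the propagule
analysis treats a single event, which is the quantity $Z^*$ is defined
for.

## Known limitations

* The interior equilibrium's stability has no closed form here; the
  eigenvalue classification is exact up to numerical tolerance but
  provides no symbolic boundary in $(\alpha,\beta)$.  Region-IV
  boundaries are therefore raster boundaries, not continuation curves.
* Exactly on degeneracies ($pdK=q$, $r=\alpha cd$, zero stability
  margins) the package reports *marginal* and declines to classify;
  quantities on those sets should be read as boundary markers.
* `establishes()` judges persistence at a finite horizon with a finite
  threshold; for margins below about $10^{-3}$/yr the verdict can
  depend on the horizon.  The bisection bracket is always reported so
  such cases are auditable.
* Basin boundaries are probed only along the propagule axis
  $(x_s, y_s, Z_0)$; the full separatrix surface is out of scope.
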