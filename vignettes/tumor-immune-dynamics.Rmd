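---
title: "Modelling tumor-immune dynamics with CD4+ T cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumor-immune dynamics with CD4+ T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorimmune)
```

## The model

The package simulates a deterministic ODE model of a growing tumor under
immune surveillance.  Six populations interact in the untreated system:
tumor cells $T$, natural killer (NK) cells $N$, tumor-specific CD8$^+$ T
cells $L$, CD4$^+$ T cells $Y$, circulating lymphocytes $C$ and the
IL-2 cytokine concentration $I$.  The structural assumptions are the
ones standard in this family of models:

* the tumor grows logistically, $a T (1 - bT)$, with carrying capacity
  $1/b \approx 9.8\times10^8$ cells;
* NK cells and CD8$^+$ T cells kill tumor cells; NK kill is mass-action
  ($-cNT$) while CD8$^+$ kill acts through a saturating lysis fraction
  $$D = d\,\frac{(L/T)^l}{s + (L/T)^l},$$
  a Hill-type function of the effector-to-target ratio;
* CD4$^+$ T cells do not kill directly: they secrete IL-2
  ($\beta_2 T/(\alpha_2+T)\,Y$), and IL-2 both kills tumor cells
  ($-c_1 T/(a_1+T)\, I$) and boosts CD8$^+$ recruitment;
* circulating lymphocytes follow $\dot C = \alpha - \beta C$,
  independent of everything else, and source both NK production ($eC$)
  and naive CD8$^+$ activation ($r_2 C T$);
* both effector cell types are exhausted by tumor contact ($-pNT$,
  $-qLT$) and CD8$^+$ cells are additionally suppressed by NK cells at
  high density ($-uNL^2$).

The treated system adds a chemotherapy drug compartment
$\dot M = -\gamma M + v_M(t)$ with saturating log-kill terms
$-K_X(1-e^{-M})X$ on tumor, NK, CD8$^+$ and lymphocytes, and additive
infusion inputs $v_I, v_L, v_Y$ on IL-2, CD8$^+$ and CD4$^+$ T cells.
With all doses zero and $M = 0$ it reduces exactly to the untreated
system (`rhs_treated()` vs `rhs_untreated()`, tested).

Two reference human parameter sets ("patient1", "patient2") ship as YAML
fixtures; they differ in the CD8$^+$ lysis parameters ($d$, $l$, $s$),
CD8$^+$ turnover ($m$, $q$, $k$), NK exhaustion ($p$) and the lymphocyte
source/turnover ($\alpha$, $\beta$).  All rates are per day, populations
in cells; IL-2, drug and dose units are left abstract, consistent with
the rate constants — the package documents and does not convert them.

### The lysis fraction at vanishing populations

$D$ as written divides by $T$.  The package evaluates the algebraically
identical form $d L^l/(s T^l + L^l)$ and defines $D(0,0)=0$ and
$D(0, L>0)=d$, which preserves continuity of the product $D\,T \to 0$
and avoids a $0/0$.  `cd8_from_lysis()` inverts the relation,
$L = (sD/(d-D))^{1/l}\,T$, used by the equilibrium solvers.

## The integrator

The dose inputs switch on and off abruptly, and several interaction
terms become fast at large tumor burden, which defeated an off-the-shelf
explicit Runge-Kutta integration of this system; the package therefore
implements the fixed-step Adams predictor-corrector the analysis is
built on, with three design elements worth spelling out.

**Exact coefficients.** The Adams-Bashforth/Moulton weights for orders
1-12 are generated from the classical backward-difference recurrences in
exact rational arithmetic (numerators and denominators stay below
$2^{53}$, checked at every operation), so the tables carry no
transcription or rounding error.  They are validated in the tests
against an independent Lagrange-polynomial-integration oracle and
against the interpolatory conditions themselves.

**Pairing and order.** "Order $k$" pairs the $k$-step Bashforth
predictor with the $(k-1)$-step Moulton corrector evaluated once at the
predicted state (PECE) — the standard pairing in which both formulas
have formal order $k$, so the configured order is the observable
convergence order (measured 2/4/6 in the tests to within $\pm 0.3$).
Iterated correction is available behind a configuration flag.

**Self-starting ramp on a refined grid.** A $k$-step method needs $k$
starting values.  The integrator ramps the order up from 1 within each
smooth segment, but a plain ramp at the working step caps the global
order at 3 (the first trapezoidal step alone contributes an $O(h^3)$
error), so the ramp runs on a grid refined by `startup_substeps`
(default 64) for the first $k-1$ intervals, and while ramping the
corrector uses the full available history (order $m+1$ at history
length $m$).  Startup error is then far below the settled method's and
the nominal order is observable.  The same restart runs after every
dose discontinuity: `event_times()` lists all pulse edges and the span
is integrated segment by segment, with the piecewise-constant dose
fixed per segment (evaluated at the segment midpoint), so discontinuous
forcing never crosses a multistep history.

**Step size and the negative-state policy.** The step defaults to
$\Delta t = 2^{-9}$ day; a grid-refinement test checks that halving it
changes the untreated reference trajectory by well under 0.1%.  In
regimes where the tumor saturates its carrying capacity, the effector
equations become genuinely stiff (per-capita rates of order
$p\,T \approx 3\times10^3$/day) and an explicit method at this step
oscillates around the tiny quasi-steady NK/CD8$^+$ levels.  Two
policies keep this harmless: the right-hand side used by the solver
clamps transiently negative predictor states to the boundary of the
biologically meaningful orthant, and any component driven below zero by
an accepted step is clipped to zero and counted (`clips` in the
trajectory metadata).  The affected populations are those already at
biologically negligible levels ($N \sim 10^{-2}$-$10^1$ cells); the
tumor and lymphocyte trajectories are insensitive to the oscillation,
and all qualitative outcomes are invariant to halving the step or
switching order 8 to 12 (asserted in the tests).  Trajectories in these
regimes were additionally cross-checked against `deSolve::lsoda` at
tight tolerances.

## Equilibria and stability

Setting the untreated right-hand sides to zero splits the equilibria
into three branches, all implemented in closed form as far as the
algebra allows:

1. **Tumor-free**: $(0,\ e\alpha/(f\beta),\ 0,\ 0,\ \alpha/\beta,\ 0)$,
   with eigenvalues known in closed form; only
   $\lambda_1 = a - ce\alpha/(f\beta)$ can be positive, so the state is
   stable iff $a < a^\* = ce\alpha/(f\beta)$.  This is the recurrence
   condition: past the threshold, an eradicated tumor regrows from any
   remaining seed.  (The published linearization drops the NK
   exhaustion entry $-pN_{eq}$ from the Jacobian's (2,1) position; the
   package keeps it — the eigenvalues are unaffected because that
   column is below the diagonal.)
2. **Tumor-bearing, cytokine-free** ($I=Y=0$): at each candidate tumor
   size the NK level, the required lysis fraction and the implied
   CD8$^+$ level are closed forms; the remaining CD8$^+$ balance
   residual is scanned over $T \in (1, 1/b)$ on a 2000-point log grid
   and sign changes are bisected to machine precision.  Tumor sizes
   whose required lysis fraction leaves $[0, d)$ are branch-invalid and
   skipped, but roots squeezed against a validity boundary are still
   caught: where $D \to 0$ the residual limit is negative, and where
   $D \to d$ it diverges to $+\infty$, so an opposite-signed edge point
   guarantees a bracket.  Negative CD8$^+$ solutions are discarded.
3. **Tumor-bearing with active CD4$^+$/IL-2 loop**: the equilibrium
   tumor sizes are the positive roots of a cubic whose coefficients
   involve only the CD4$^+$/IL-2 parameters; roots come from the
   polynomial companion matrix with one Newton polish, and at each the
   remaining $(I, L)$ system is solved by the same scan-and-bisect
   residual method over $I \in [10^{-3}, 10^{12}]$.

Every returned point carries its full-system residual relative to the
largest term in each equation ($<10^{-6}$ enforced, typically
$\sim10^{-12}$), and a 2-D sign-pattern scan of the corresponding
residual surfaces — the intersection-of-curves construction —
independently reproduces the root sets in the tests.

Stability is classified from the eigenvalues of a finite-difference
Jacobian (central differences, per-component step
$\max(10^{-6}|x_i|, 10^{-3})$, second-order one-sided stencils at
domain boundaries).  A verdict is withheld ("marginal") when the
leading real part is within $10^{-8}\times\max(1,\rho(J))$ of zero,
since bifurcation sweeps pass through zero eigenvalues; the sweep
signature uses the sign of the margin itself so that switches bisect to
the actual eigenvalue crossing.

**A sixth equilibrium.** For both reference patients the cytokine-free
scan finds, in addition to the published interior point, a genuine
equilibrium just below the carrying capacity
($T \approx 9.80\times10^8$, NK and residuals checked), and it is
*stable* — it is the attractor that the untreated large-tumor
simulations converge to.  The published stability table lists only the
interior points; the package reports what the equations contain.

## Bifurcation sweeps

`bifurcation_sweep()` substitutes one parameter over a grid (400
log-spaced samples plus 100 linear samples near zero by default for the
growth-rate sweep over $[0,10]$; 400 linear samples for the NK-kill
sweep over $[0, 4\times10^{-6}]$ — grids chosen to resolve the closest
reported events with margin), enumerates and classifies all branches at
each value, and links points into curves by nearest-neighbour matching
in $\log_{10}(1+T)$ with a 0.3-decade jump threshold, numbering curves
by branch type and first appearance.  `locate_bifurcations()` bisects
every change in the per-branch (count, stable-count) signature to a
relative bracket of $10^{-4}$, labelling events as stability switches
or branch creation/destruction, and attaches the closed-form threshold
as a cross-check where one exists.  Boundary-of-range changes are not
reported as bifurcations.

For the first patient the sweep recovers the tumor-free stability
switch at $a^\* = 2.02257\times10^{-5}$ (and, sweeping $c$, at
$c^\* = a f\beta/(e\alpha) = 1.36594\times10^{-6}$; the published
grid-derived figure is 1.365e-6, and the corresponding closed form for
the second patient is 1.3660e-6 against a printed 1.356e-6 — the
package reports the closed form).  The tumor-bearing cytokine-free
branch disappears through $T \to 0$ at $a \approx 2.3397$, matching the
published upper boundary 2.33 to 0.4%.  Its *lower* boundary is
different in kind: the equations place a saddle-node fold at
$a \approx 9.8\times10^{-4}$, where the interior point and the
near-capacity point merge, whereas the published diagram reports the
branch appearing at $a = 0.01$ — consistent with a sweep grid whose
first nonzero sample was 0.01, and flagged accordingly in the
acceptance tests rather than adjusted to match.  Similarly, no
branch-count change exists over the published $c$ range for the second
patient ($c$ enters the equilibria only through $cN_{eq}$, negligible
at every admissible root), so the reported creation of a third curve at
$c = 0.4\times10^{-6}$ is not reproduced.

## The scenario workbench

`scenario_registry()` encodes the published experiment panel: three
no-treatment runs, five continuous-therapy runs and seven pulsed runs
across both patients, with the printed initial states, intensities,
pulse counts, periods and start days.  Unstated components start at
zero (IL-2, drug; CD4$^+$ cells in the predecessor-model comparison,
which has no such compartment).  Horizons are 60 days for no-treatment
and continuous runs and 100 days for pulsed runs, covering the longest
(9-pulse) regimen with margin.

**Pulse shape.** The sources state intensity, start, period and count
but not duration, nor whether doses are infusions or boluses.  Pulses
are implemented as constant-rate infusions on half-open windows
$[t_0, t_0 + \text{duration})$ with duration defaulting to one day
(the predecessor literature's convention); total delivered dose is then
intensity $\times$ 1 day, identical to a bolus of the printed size.
The stated "6 pulses of IL-2 from day 8 to day 11" is internally tense
(six pulses in four days) and is encoded as six equal sub-day infusions
evenly spaced over $[8, 11.5)$, flagged in the scenario description.

**Eradication rule.** A run counts as eradicated when the tumor burden
falls below 1 cell and stays below it to the horizon; the eradication
day is the first crossing of that sustained excursion.  The rule, the
threshold and the horizons are this package's operationalization of
"the tumor is eliminated" — the sources show figures without stating
either — and all verdicts are checked to be invariant to step halving
and to switching solver order between 8 and 12.

**What reproduces and what does not.** All seven no-treatment and
continuous-therapy verdicts reproduce, including the
combined-CD8$^+$/IL-2/CD4$^+$ success with eradication near day 9
("about 10 days" in the source), and five of the eight pulsed verdicts
reproduce, including both negative controls.  Three published pulsed
eradications — CD8$^+$/IL-2 pulses plus five CD4$^+$ pulses of $10^7$
at $T(0)=8\times10^5$; five chemotherapy pulses plus five CD4$^+$
pulses of $6\times10^6$ at $T(0)=3\times10^6$; three chemotherapy
pulses plus five CD4$^+$ pulses of $4\times10^7$ at $T(0)=10^7$ — do
not follow from the printed equations and doses.  The failures are not
numerical: an independent stiff solver reproduces the same
trajectories, and no total-dose-preserving pulse shape changes the
verdicts (keeping each dose on for its whole period does flip two of
them, but at the cost of flipping a published negative control).  An
order-of-magnitude argument shows why: at the tumor sizes reached by
treatment onset, the IL-2 kill term needs a cytokine level requiring
roughly forty times the printed total CD4$^+$ dose.  The acceptance
tests assert the published verdicts as printed and these three stay
red.

`phase_field()` evaluates the restricted $(T, Y)$ vector field with the
other four states frozen at an equilibrium's values, for streamline
plots of the local flow around each equilibrium.

## What the bundled conditions do and do not show

The two parameter sets and the scenario panel are reference inputs, not
data: passing tests demonstrates that the implementation reproduces the
published analysis of this deterministic model, not that the model fits
any patient.  The model has no stochasticity, no delays, no spatial
structure, no pharmacokinetics beyond single-compartment drug decay,
and treats dose units as abstract; conclusions about therapy design
read off these simulations inherit all of those idealizations.

## Problem sizes and runtime choices

Defaults were chosen so a full analysis runs comfortably on a laptop
core: equilibrium scans use 2000-point grids (doubling them moves no
coordinate by more than $10^{-4}$ relative, tested); sweeps use 400-500
samples; scenario integrations use $\Delta t = 2^{-9}$ day over 60-100
days (roughly $3\times10^4$-$5\times10^4$ steps).  Unit tests use
reduced grids and horizons where the full sizes add nothing; the
acceptance layer runs the full published conditions.

## Limitations

* No adaptive step or order control, no implicit (BDF) option, and no
  dense-output interpolation; stiff endgames rely on the clipping
  policy rather than an implicit method.
* No two-parameter bifurcation surfaces, Hopf/limit-cycle continuation
  or basin-of-attraction analysis.
* The Jacobian at general points is numerical; only the tumor-free case
  has an analytic form.
* Therapy optimization is out of scope: the workbench runs the printed
  regimens.
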