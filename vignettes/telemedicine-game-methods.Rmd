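---
title: "Methods: the four-population telemedicine game"
author: "telemedgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-population telemedicine game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telemedgame)
```

## The model

The package studies how a chronic-disease diagnosis-and-treatment system
organises itself when four bounded-rational populations repeatedly adjust
their strategies by payoff comparison:

* **physical medical institutions** run their online portal *self-built*
  (proportion $x$) or *relying on* a third-party platform that keeps a
  $1-\alpha$ share of the online benefit;
* **medical service platforms** staff with *part-time* ($y$) or
  *full-time* doctors — part-time is cheaper ($C_{21} < C_{22}$) but
  full-time responds faster ($\theta > \beta$, $R_{21} < R_{22}$);
* **intelligent medical device providers** offer *leasing* ($z$) or sale
  only;
* **chronic-disease patients** hold a *physical* ($p$) or *Internet*
  preference for "re-visits and drug renewal".

Payoffs for every one of the $2^4$ pure-strategy profiles are assembled in
`build_payoff_tensor()`. An Internet-preference patient visits the
commercial platform with probability $\beta$ (part-time mode) or $\theta$
(full-time mode) and the institution's portal otherwise; full-time
staffing exerts a drag $F_1$ on the institutions' portals; leasing adds
spillovers $T_1, T_2$ and Internet preference a relief effect $T_3$. All
payoffs are unitless "payoff units": the model is about orderings and
differences, not currency.

Each group follows two-strategy replicator dynamics,
$\dot v = v(1-v)\,(U_1^v - U_2^v)$. The payoff differences reduce to

$$
\begin{aligned}
\Delta_x &= (C_{12}-C_{11}) + (1-p)(R_{12}-\alpha R_{13})
            - (1-p)(1-y)F_1(1-\alpha),\\
\Delta_y &= (1-p)(R_{21}-R_{22}) + (C_{22}-C_{21}),\\
\Delta_z &= (C_{32}-C_{31}) + (R_{32}-R_{34}) + (R_{31}+R_{34}-R_{32}-R_{33})\,p,\\
\Delta_p &= (C_{46}-C_{45}) + \theta(C_{44}-C_{46}+R_{41}-R_{43})
            + y\beta(C_{43}-C_{46}+R_{41}-R_{42})\\
         &\quad + y\theta(C_{46}-C_{44}-R_{41}+R_{43}).
\end{aligned}
$$

$\Delta_x$ was re-derived from the payoff matrix rather than transcribed,
and the package requires it to agree with the tensor-expectation route to
machine precision (`payoff_deltas()` vs `group_payoffs()`) and with the
corner eigenvalues below. Two structural facts follow and are enforced as
tests: eight parameters ($R_{11}, R_{44}, R_{45}, C_{41}, C_{42}, T_1,
T_2, T_3$) cancel from every difference and are therefore dynamically
inert (they default to 0 and the validator skips the $C_{41}<C_{42}$
ordering at that inert default), and $z$ influences nobody while
$\Delta_z$ depends only on $p$ — device leasing reacts to patient
preference but feeds back on no one.

## Stability analysis

In a multi-population game an evolutionarily stable strategy must be a
pure-strategy (corner) profile, so only the 16 corners are classified. At
a corner the Jacobian is diagonal with entries $(1-2v)\Delta_v$, and the
Lyapunov first method applies: all four eigenvalues strictly negative
$\Rightarrow$ ESS; any strictly positive $\Rightarrow$ unstable; an
eigenvalue within `boundary_tol` (default $10^{-12}$) of zero leaves the
method silent and the corner is reported *inconclusive*, never silently
classified. Interior fixed points are outside scope by the same
pure-strategy argument.

The eigenvalues organise into seven reusable expressions
(`expression_values()`):
$e_1 = (R_{21}-C_{21})-(R_{22}-C_{22})$,
$e_2 = (R_{32}-C_{31})-(R_{34}-C_{32})$,
$e_3 = (R_{31}-C_{31})-(R_{33}-C_{32})$,
$e_4 = (R_{12}-F_1-C_{11})-[\alpha(R_{13}-F_1)-C_{12}]$,
$e_5 = (R_{12}-C_{11})-(\alpha R_{13}-C_{12})$,
$e_6$ and $e_7$ the patient's offline-minus-online net benefit under
full-time resp. part-time mode. Ten corners can be stable; each carries a
named condition (1–10) given by required strict signs of a subset of
$e_1 \ldots e_7$ — the remaining eigenvalues are forced negative by the
assumption inequalities. Six corners contain an assumption-forced
positive eigenvalue ($C_{22}-C_{21}$ or $C_{11}-C_{12}$) and can never be
stable. `permitted_conditions()` derives the co-occurrence logic from
sign consistency alone: conditions 1, 2, 4, 7 can pair only with 5 or 9,
while 3, 6, 8, 10 are always solitary.

Two transcription ambiguities in the source tables were resolved in
favour of internal consistency: the first eigenvalue of corner
$E_{10}$ is read as $\alpha(R_{13}-F_1)-C_{12}$ minus
$(R_{12}-F_1-C_{11})$ (i.e. $-e_4$), matching the $E_5$ row and the
derived $\Delta_x$; and the narrative labels of one unique-ESS case name
corner "(1,1,0,0)" as $E_1$ and cite expression 6 where the condition
table constrains expression 7 — the tables, which are mutually
consistent, are authoritative throughout.

As an independent numerical oracle, `numeric_jacobian()`
central-differences the *tensor-route* RHS (not the closed forms it is
checking) and must reproduce the closed-form eigenvalues at every corner
to $10^{-8}$; this dual route is exercised over hundreds of random games
in the test suite.

## Numerical integration

The RHS is a smooth polynomial, so a stiff solver is unnecessary:
`simulate_replicator()` uses `deSolve::lsodar` with `rel_tol = 1e-8`,
`abs_tol = 1e-10`, output step 0.1, default horizon 200 time units, and a
terminal root that stops integration once the RHS max-norm falls below
$10^{-10}$. The dynamics preserve the unit hypercube analytically; output
states are clamped to $[0,1]$ purely to absorb floating-point drift, and
the pre-clamp excursion is recorded (tests require it below $10^{-6}$).

Endpoint classification (`classify_endpoint()`) declares convergence to
the nearest corner when the max-norm distance is below
`epsilon = 1e-3` *and* the RHS max-norm is below `rhs_epsilon = 1e-6`.
Two failure modes of a purely positional test motivated the design, both
discovered by the random-game sweep:

* **slow transit**: a trajectory can pass within $10^{-3}$ of a saddle
  with a tiny but non-vanishing outward drift; the RHS criterion
  separates this from settlement (a genuinely settled state sits at the
  $10^{-10}$ early-stop level, orders below `rhs_epsilon`);
* **numerical absorption**: a proportion can underflow onto an invariant
  face, where the $v(1-v)$ factor freezes a linearly unstable direction
  and parks the trajectory at a saddle indefinitely. Exact replicator
  dynamics cannot converge to a corner with a strictly positive
  eigenvalue from the interior, so such endpoints are flagged
  `saddle_capture` and never counted as converged.

`convergence_time()` measures the first time after which a component
stays within `epsilon` of its pure-strategy limit; a component that has
not settled by the horizon yields an explicit `NA`, never a number.

## Scenarios and the sensitivity experiments

`load_scenario()` resolves a registry of named experiments against the
calibrated baseline (the published simulation calibration for the
cardiovascular/cerebrovascular case): `fig1` = baseline;
`fig2` $R_{32}{=}2$; `fig3` $R_{13}{=}2$; `fig4` both; `fig5`
$R_{22}{=}1.8, R_{42}{=}1.5$; `fig6`–`fig8` build on `fig5`. The
narrative chains variants ("based on ..."), so the registry stores the
fully resolved parameter sets; for the two patient-side speed experiments
the base is the `fig5` regime, the unique resolution under which the
printed $e_7$ transition $-0.1 \to -0.26$ is arithmetically consistent,
and the platform-side experiments require $R_{22}{=}1.8$ (plus
$R_{21}{=}1.3$ for the cost variant) for the printed $-0.3 \to +0.1$
values. Dual-ESS scenarios are probed from the canonical basin
representatives $(0.3,0.3,0.3,0.3)$ and $(0.7,0.7,0.7,0.7)$ (the source
states only "below 0.5" / "above 0.5"); unique-ESS scenarios must reach
the same corner from both.

Each sensitivity experiment (`fig9`–`fig15`) compares a reference and an
adjusted parameter value and asserts that the adjustment *strictly
accelerates* the named stakeholder's settling, from the same initial
state — this is the claim the experiments make, and it is the form the
package asserts. It is deliberately *not* phrased as "larger absolute
expression value is always faster": the platform-cost experiment
(`fig13`) disproves that reading, since cutting $C_{21}$ from 0.5 to 0.1
shrinks $|e_1|$ from 0.3 to 0.1 yet accelerates the platforms, because it
simultaneously raises the corner eigenvalue $C_{22}-C_{21}$ from 0.2
to 0.6. One experiment (`fig12`) is compared from the high basin
$(0.7,\ldots)$: from the low basin its two variants drive $y$ to
*different* corners (the reference variant satisfies conditions
$\{1,9\}$ and sends $y \to 0$), so a speed comparison is only well-posed
where both variants converge to the same corner ($E_{12}$). The registry
records a canonical initial state per experiment.

## The synthetic game generator

`sample_parameters()` draws random parameter sets satisfying all ten
assumption inequalities *constructively* — for each ordered pair the
smaller value is drawn uniformly and a positive gap added — rather than
by rejection, which degenerates under ten simultaneous constraints.
Default ranges (costs in $[0.1, 1.5]$, benefits in $[0.5, 3.5]$, shares
and probabilities inside $(0,1)$, effects in $[0, 0.5]$) are centred on
the calibrated baseline's magnitudes so sampled games are numerically
comparable to the studied regime. A seeded `sampling_spec()` fixes the
entire draw stream.

The generator emulates the *structure* of the studied system — the
orderings and scales of costs and benefits — and nothing else: real
institutions' cost distributions, correlations between parameters, and
any monetary calibration are out of scope. Passing property sweeps
therefore certify the internal consistency of the machinery (closed
forms vs numeric Jacobians, condition logic vs simulated endpoints) on
games *like* the calibrated one, not the empirical accuracy of any
particular parameter set.

`run_sweep()` ties the pipeline together over seeded draws: every
satisfied-condition set must be permitted by the compatibility logic,
closed-form and numeric eigenvalues must agree to $10^{-8}$, and every
converged endpoint must be a corner classified ESS. Sweep simulations
use a horizon of 600 with RHS early stopping, because random games can
have eigenvalues much closer to zero than the calibrated scenarios;
draws that still have not settled are reported unconverged rather than
guessed.

## Problem sizes and limitations

The shipped tests run the eight equilibrium scenarios from two initial
states each, the seven sensitivity pairs, a 500-draw eigenvalue-agreement
sweep and a 200-draw simulated sweep; these sizes make the suite a
desk-scale computation while leaving the property checks statistically
meaningful. Known limitations: only pure-strategy (corner) equilibria are
classified, with no centre-manifold analysis of inconclusive corners;
dynamics are deterministic infinite-population replicator equations (no
finite-population or stochastic effects); parameters are constant in
time; and the governance-mechanism policy discussion surrounding the
model is not part of the computational artifact.
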