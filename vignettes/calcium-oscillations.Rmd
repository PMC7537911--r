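---
title: "Minimal models of calcium oscillations in a cardiac release unit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal models of calcium oscillations in a cardiac release unit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caosc)
```

## The problem

A ventricular myocyte handles calcium through tens of thousands of calcium
release units (CaRUs): clusters of ryanodine receptors (RyRs) facing the
junctional sarcoplasmic reticulum (SR) across a nanoscopic dyadic space.
When a cell is neither paced nor exchanging calcium with the outside (LCC
and NCX conductances zero), its total calcium content is an exact constant,
and the question becomes purely internal: *given a total calcium load and a
complement of buffers, in what dynamical regime does the release machinery
sit?* Three regimes are possible:

* a **closed-RyR rest state** — nearly all calcium stored in the SR, the
  cytosol quiet, the unit excitable (a large enough perturbation triggers a
  calcium-induced calcium release transient, then the unit returns to rest);
* **sustained oscillations** — periodic cycles of release and SERCA-driven
  refill; at the whole-cell level these underlie periodic calcium waves and
  are pro-arrhythmic;
* a **permanently open state** — RyRs held open by elevated dyadic calcium,
  the SR depleted, cytosolic calcium high.

`caosc` implements a minimal CaRU model of this situation and the full
analysis pipeline that maps the average total calcium load
$\bar c_T$ (the bifurcation parameter, in µM per unit volume) and the
calsequestrin level $B_{SQ}$ to these regimes.

## The model

Three dynamic quantities describe one unit: dyadic free calcium $c_d$,
total SR calcium $c_{sr}^{tot}$, and the RyR open fraction $P_o$:

$$\dot c_d = g P_o (c_{sr} - c_d) - \frac{c_d - c_i}{\tau_i}, \qquad
\dot c_{sr}^{tot} = \frac{v_i}{v_{sr}} J_{up} - \frac{v_d}{v_{sr}} g P_o
(c_{sr} - c_d), \qquad
\dot P_o = k_p c_d^2 (1 - P_o) - k_m P_o,$$

with SERCA uptake $J_{up} = g_{up}\, c_i^2 / (K_s^2 + c_i^2)$. Two algebraic
closures complete the system and are the numerically load-bearing part:

* **Rapid calsequestrin buffering.** CSQ binding is fast relative to
  release, so free SR calcium follows from the total by inverting
  $c_{sr}^{tot} = c_{sr} + B_{SQ} c_{sr}/(K_{SQ} + c_{sr})$
  ([`free_sr_calcium()`]). Carrying the *total* as the state variable and
  recovering the free concentration algebraically conserves mass exactly,
  with none of the drift that finite-rate buffer ODEs accumulate.
* **Total-calcium conservation.** Cytosolic calcium $c_i$ is never
  integrated. At every state it solves the conservation quadratic
  $\bar c_T = \tfrac{v_i}{v}(c_i + \tfrac{B_b c_i}{K_b + c_i})
  + \tfrac{v_d}{v} c_d + \tfrac{v_{sr}}{v} c_{sr}^{tot}$
  ([`solve_cytosolic()`]). Mass conservation therefore holds to round-off
  on every trajectory (the test suite asserts $\le 10^{-8}$ relative; in
  practice it is $\sim 10^{-15}$).

Because the SERCA term has no reverse mode, $c_i = c_d = 0$ with all
calcium in the SR is an exact rest state at every load. Physiological
diastolic calcium is ~0.1 µM rather than 0, but at SR concentrations of
order 1 mM the simplification is immaterial for the regime structure.

Two quasi-steady reductions make the analysis two-dimensional:

* `fast_ryr` (the baseline): RyR gating is fast, $P_o = c_d^2/(K_o^2 +
  c_d^2)$; dynamic variables $(c_d, c_{sr}^{tot})$.
* `fast_dyadic` (a robustness check): dyadic diffusion is fast, $c_d =
  (\tau_i g P_o c_{sr} + c_i)/(1 + \tau_i g P_o)$; dynamic variables
  $(c_{sr}^{tot}, P_o)$, used with $B_{SQ} = 0$.

Both share the three-variable model's fixed points exactly (they share the
equilibrium equations); what changes is the stability assignment, which is
why the package classifies stability per variant
(`find_fixed_points(..., variant = )`).

## Parameters, units and calibration

Units are fixed project-wide: concentrations in µM, time in ms, volumes as
dimensionless fractions of the unit volume $v = v_i + v_{sr} + v_d$. The
control set ships in `inst/extdata/control_params.txt`; each value carries a
provenance tag ([`param_provenance()`]).

Four values are literature constants (`PAPER`): $K_o = 15$ µM, $B_b = 80$
µM, $K_b = 0.5$ µM, $K_{SQ} = 650$ µM (with $B_{SQ}$ scanned between 0 and
20 mM). The remaining rates and volumes (`DERIVED`) were fixed once by a
calibration argument and have not been revisited:

1. The closed-form onset algebra (below) pins two combinations against
   reference values of the onset: the volume ratio $v/v_{sr} = 45.6$
   (from the pre-onset SR concentration $2.28$ mM at a $50$ µM load) and
   the lumped release strength
   $\tilde g \equiv g \tau_i / K_o^2 = 1/1120$ µM$^{-2}$ (from the
   diastolic SR calcium of $0.86$ mM at onset). These three reference
   numbers are mutually consistent only to their printed rounding — exact
   simultaneous agreement would require $v_d < 0$ — so the shipped set
   reproduces them to within 1%.
2. The dyadic volume fraction is set to a realistically tiny $v_d = 10^{-3}$
   (the dyadic cleft is a nanodomain), leaving $v_i = 0.9771$.
3. In scaled time the fixed-point diagram depends only on the uptake
   parameters through $u \equiv v_i \tau_i g_{up} / v_d$ and $K_s$. These
   two were tuned so that the fold and Hopf loci of the control diagram sit
   at their reference positions ($\approx 39$ and $\approx 66$ µM);
   $u = 10.6$ µM, $K_s = 0.64$ µM. The homoclinic locus and the nullcline
   pinch-off are then predictions, not fitted quantities — they land at
   $\approx 50$ µM, consistent with the closed form.
4. The absolute time scale is set by $\tau_i = 0.1$ ms (dyad-to-cytosol
   diffusion is sub-millisecond), giving $g = 2.009$ ms$^{-1}$ and
   $g_{up} = 0.108$ µM/ms — the latter in the usual range for SERCA
   turnover. RyR gating rates $k_p = 2.1\times10^{-3}$ µM$^{-2}$ms$^{-1}$
   (the same order as detailed subcellular models use for the opening rate)
   and $k_m = K_o^2 k_p$.

## Fixed points and bifurcation structure

At equilibrium the system collapses to a scalar root problem
$f(c_i; \bar c_T) = 0$ ([`equilibrium_residual()`]): the dyad balance after
substituting $c_d(c_i)$ (uptake routed through the dyad) and
$c_{sr}^{tot}(c_i)$ (conservation). `find_fixed_points()` brackets all
roots on 2000 log-spaced points of the feasible $c_i$ interval — enough to
resolve the narrow five-root calsequestrin window — polishes them with
`uniroot` to $10^{-13}$, merges roots closer than $10^{-6}$ µM, and
classifies each root from the eigenvalues of the requested variant's
Jacobian (numeric differentiation with one-sided fallbacks at the
feasibility boundary; eigenvalue real parts within $10^{-9}$ of zero count
as neutral and resolve towards stability, which correctly handles the rest
state's structural zero along the uptake direction).

At the control parameters ($B_{SQ} = 0$) the structure as the load grows is:

* below the **fold** at $\approx 39$ µM, the rest state is the only fixed
  point;
* above it, two further fixed points exist (a saddle and an upper state,
  both initially unstable) while the rest state remains stable at *every*
  load — regime coexistence is the rule, which is why classification runs
  start from a kicked initial state ([`default_initial_state()`]);
* at the **homoclinic locus** $\approx 50$ µM a stable limit cycle is born
  with infinite period: `find_homoclinic()` bisects the sustained-
  oscillation boundary and records the period growing without bound on
  approach;
* at the **Hopf locus** $\approx 66$ µM the limit cycle dies as the upper
  state becomes stable (a complex pair crosses the axis —
  `find_hopf()` verifies the crossing pair is complex and the branch
  continuous before calling it a Hopf).

`sweep_diagram()` assembles the full picture on a load grid: per-load fixed
points with stability, limit-cycle extent and period from direct long
integration (continuation of unstable periodic orbits is deliberately out
of scope), and the three loci refined by bisection to 0.1 µM — matching the
~1 µM precision at which the reference loci are quoted.

## Nullcline geometry and the closed-form onset

In the $(c_d, c_{sr})$ plane of the fast-RyR reduction, the $\dot c_d = 0$
nullcline is the S-shaped CICR balance curve. Scanning it line-by-line in
$c_{sr}$, a connected curve shows one contiguous window of $c_{sr}$ values
carrying three $c_d$ roots. At a critical load the curve **pinches off**:
two of the three roots are lost over an interior range of $c_{sr}$, and the
3-root window splits into two disjoint windows. `nullcline_split()`
implements exactly this count-profile detector (400 $c_{sr}$ lines × 600
log-spaced points along the fast coordinate; a window must span at least
two grid lines, which suppresses tangency noise), and `pinch_off_load()`
bisects the transition. Below the Hopf locus the split is empirically
necessary *and* sufficient for sustained oscillation — the test suite
verifies the equivalence on a 20-load grid over [35, 80] µM. Above the
Hopf the geometry stays split for a few µM while the now-stable upper
state absorbs the dynamics, so the geometric criterion is an onset
criterion, not a global one.

Linearising the pinch-off condition (using $c_d \ll K_o$, $c_d \ll c_{sr}$
and bound-buffer dominance) yields a closed form
([`onset_analytic()`]):

$$\bar c_T^* = \sqrt{\frac{v_{sr} v_i B_b}{v^2 \tilde g K_b}}
- \frac{v_{sr}}{4 \tilde g K_b v}, \qquad
c_{sr}^* = \frac{v \bar c_T^*}{2 v_{sr}} - \frac{1}{8 \tilde g K_b}.$$

At control parameters $\bar c_T^* = 49.7$ µM, within 1% of the numeric
pinch-off (50.0 µM); the onset is accompanied by a drop of basal SR calcium
from 2.27 mM to 0.85 mM — less than half, i.e. the deterministic transition
to oscillation is *sudden*. Because the $\dot c_d$ nullcline contains no
SERCA term, the onset is exactly invariant to $g_{up}$ — the package tests
this at ±50%.

Two genuinely open design points were resolved as follows:

* **Buffer-affinity direction.** Intuition might suggest that a
  higher-affinity cytosolic buffer (smaller $K_b$) frees oscillations at
  lower loads. The closed form says otherwise in the control regime: both
  terms of $\bar c_T^*$ scale inversely with $K_b$, and for
  $K_b \gtrsim 0.08$ µM the onset *rises* as $K_b$ falls. We follow the
  algebra, and cross-check it with the independent numeric pinch-off
  (which agrees within 10% at $K_b = 0.25, 0.5$ and $1$ µM). Raising the
  buffer amount $B_b$ delays the onset unambiguously.
* **Fast-dyadic "appearance at ~54 µM".** Since all variants share fixed
  points, the fast-dyadic branches are *born* at the shared fold
  ($\approx 39$ µM); what is specific to the variant is where its dynamics
  first sustains a nontrivial attractor. The package measures that
  dynamical onset (by the same simulation classifier used everywhere) and
  finds it within 10% of the 54 µM reference — together with its own
  gating-nullcline pinch-off in the $(c_{sr}, P_o)$ plane, detected by the
  same count-profile method on a log-spaced $P_o$ grid.

## Calsequestrin

With $B_{SQ} > 0$ the same machinery runs through the rapid-buffer
relation. Raising $B_{SQ}$ moves the fold to higher loads (the closed state
survives longer) and narrows the oscillatory window from both sides until
it vanishes; at 20 mM no sustained oscillation exists anywhere, the upper
state instead gains stability through a saddle-node, and a narrow load
window with **five** fixed points opens just above the fold (at 20 mM CSQ:
loads ≈ 145 µM), with the lowest and uppermost points stable. In this
reconstruction one of the intermediate points is also stable in a sliver of
that window — the qualitative picture (CSQ suppresses oscillations and
produces a direct excitable-to-open transition) is unchanged.

## Stochastic gating

RyR gating noise is modelled as a bounded uniform perturbation of the open
probability, $P_o = c_d^2/(K_o^2+c_d^2) + \sigma (U - \tfrac12)$, redrawn
every integration step and clamped to $[0,1]$ (clamping is our choice; the
probability interpretation demands it). Per-step noise of this kind has no
step-size-independent continuum limit, so **the step is part of the model
specification**: stochastic runs use fixed-step Euler with $\Delta t = 0.1$
ms by default (configurable 0.01–0.1 ms), recorded in the trace metadata.
With $\sigma = 0$ the scheme reproduces a deterministic fixed-step run
sample for sample.

At $\sigma = 2\times10^{-3}$ the noise-sustained oscillatory range extends
strictly below the deterministic homoclinic load: at 54 µM the stochastic
period matches the deterministic one within a few percent; at 45 µM — where
the deterministic system only rests — the noise sustains a coherent rhythm
with a period near one second; at lower loads still, the rhythm turns into
rare noise-triggered release events whose mean interval grows extremely
steeply — kilosecond-scale by 35 µM at this $\sigma$ and step
(`count_release_events()` measures it by hysteresis event counting, since
far too few cycles occur there for inter-peak statistics). The transition
from rest to oscillation is therefore *gradual* under noise, in contrast
to the sudden deterministic onset. Two scaling points worth knowing.
First, clamping the noisy open probability at zero leaves a small positive
mean leak, so the noisy "rest" state is shifted: at 35 µM it holds
cytosolic calcium near 0.056 µM with a correspondingly reduced SR (the
value predicted by balancing the mean leak $\sigma/8$ against SERCA
uptake). Second, at rest the ratio of the maximal noise kick to the CICR
threshold is $\tilde g^2 K_o^2 (\sigma/2) c_{sr}^2$ — fixed entirely by
the calibrated $\tilde g$, $K_o$, $\sigma$ and the load — so the low-load
escape rate is not adjustable through the remaining free rates; it is a
prediction of the calibration, and it is very steep in the load.

## The lattice surrogate

`lattice_simulate()` is a deliberately qualitative, desk-scale surrogate
for spatial wave phenomenology — not a reimplementation of any detailed
subcellular model. A 1-D chain of fast-RyR units (default 50) carries
per-unit loads coupled by pairwise diffusive exchange of cytosolic free
calcium ($D_i$, default 0.5 ms$^{-1}$; optional SR exchange $D_{sr}$,
default 0). Exchange is antisymmetric per neighbour pair, so the
lattice-average load is conserved exactly while each unit keeps the exact
single-unit closure. Two emergent features deserve note: the strong
cytosolic buffering (factor ~160 at rest) makes a single kicked unit a
sub-critical nucleus — igniting a wave takes a block of about three units —
and strong coupling suppresses excitation entirely (source–sink mismatch),
so $D_i$ sits in a window. `wave_events()` thresholds the space–time
cytosolic array (default: midway between rest and maximum), labels
4-connected components, and reports per-event origin, extent and front
speed. What passing lattice tests show is the *regime logic* — quiescence
at low load, recurring propagated events at intermediate load, a persistent
high-calcium state at high load — not quantitative wave speeds or rates of
any real cell.

## Numerical choices, problem sizes and limitations

* Deterministic integration: `deSolve::lsoda` on compiled right-hand
  sides, `rtol` $10^{-8}$ / `atol` $10^{-10}$; halving tolerances moves
  final states by $<10^{-6}$ relative (tested). Stochastic and lattice
  integration: compiled fixed-step Euler.
* Sustained-oscillation classifier: after a 20 s transient (traces show
  transients well short of this), peak-to-peak $c_i$ amplitude above 5% of
  reference plus an absolute floor of 0.02 µM, at least 5 inter-peak
  intervals with CV < 20% (deterministic) or < 60% (stochastic —
  near-onset cycles are irregular), and no decay between window halves.
  Period estimation uses mid-level crossings with a hysteresis band, then
  takes the mean inter-peak interval.
* Default problem sizes (chosen to keep every analysis interactive on a
  laptop): 60 s probes for regime classification; locus bisection to
  0.1 µM; 2000-point root bracketing; 400 × 600 nullcline grids; stochastic
  period measurements pool 3 seeds (4000 s each at low loads where events
  are rare, 200 s where they are not).
* Limitations: no continuation of unstable periodic orbits (the
  limit-cycle fold segment between homoclinic and Hopf is approximated by
  direct simulation); no two-parameter continuation beyond gridded scans;
  no membrane currents, pacing, or RyR luminal regulation; the lattice is
  a surrogate, not a spatial cell model; and at loads within ~0.1 µM of
  the homoclinic, measured periods depend visibly on probe length, as they
  must near an infinite-period bifurcation.
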