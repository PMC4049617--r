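---
title: "A kinetic model of glycolytic bistability: model, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of glycolytic bistability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glycoswitch)
```

## The model

glycoswitch implements a mechanistic ODE model of mammalian glycolysis:
mass balances for twelve intermediates (intracellular glucose, G6P, F6P,
F16BP, F26BP, DHAP, GAP, 1,3-BPG, 3PG, 2PG, PEP and cytosolic pyruvate)
connected by sixteen reaction steps, from facilitated glucose transport
through lactate production, mitochondrial pyruvate export and an
alanine-linked pyruvate exchange.  Energy nucleotides (ATP, ADP, AMP), the
redox couple (NAD+/NADH), ions, mitochondrial pyruvate, extracellular
lactate and alanine are clamped (the *fixed environment*), so the model
isolates the allosteric control structure of the pathway itself.

Three enzymes carry the regulatory structure:

* **PFK** — cooperative in F6P, ATP-inhibited at high ATP, and activated
  through a single saturable allosteric factor
  $A = (\varepsilon + w)/(1 + w)$ with
  $w = (\mathrm{F16BP}/K_{a,\mathrm{fbp}})^{4} +
  (\mathrm{F26BP}/K_{a,\mathrm{f26}})^{4} + \mathrm{AMP}/K_{a,\mathrm{amp}}$.
  The F16BP term is present for PFKM ($K_a$ = 0.35 mM) and PFKL (0.65 mM)
  and structurally absent for PFKP.  Because all activators feed one
  saturable factor, saturating F26BP *occludes* the F16BP feedback: this
  is the mechanism by which a high PFKFB kinase-to-phosphatase (K/P)
  ratio abolishes F6P-node bistability.
* **PFKFB** — Michaelis–Menten kinase (F6P, ATP substrates) and
  bisphosphatase (F26BP substrate) domains.  The K/P ratio multiplies the
  kinase maximal rate relative to the phosphatase, while the expression
  *level* multiplies both equally — so K/P moves the steady-state F26BP
  concentration and the level only sets how fast the F26BP pool moves.
  The kinase is inhibited by PEP (Hill 2, $K_i$ = 0.01 mM): this is the
  sensing arm of Loop 2.
* **PK** — cooperative in PEP (Hill 2), with the apparent PEP
  half-saturation divided by $(1 + \mathrm{F16BP}/K_a)$ for the
  activatable isoforms (PKM2 0.04 mM, PKL 0.01 mM, PKR 0.04 mM; PKM1 has
  no activation), isoform-specific ATP inhibition, and a weak pyruvate
  product inhibition ($K_i$ = 20 mM) through which the downstream
  pyruvate pool back-pressures PEP.

Loop 1 (PFK's F16BP feedback plus F26BP activation) and Loop 2 (PK
activation by F16BP → PEP drop → PFKFB kinase disinhibition → F26BP rise
→ PFK activation) are toggled purely by the isozyme choice, never by
ad-hoc switches: removing a regulation means omitting its term.

The chain enzymes (GLUT, HK, PGI, ALDO, TPI, GAPDH, PGK, PGAM, ENO, LDH,
mitochondrial transport, alanine exchange) use reversible
Michaelis–Menten forms that vanish exactly at their equilibria.  HK
carries cooperative product inhibition by G6P (Hill 2.5, $K_i$ = 0.15
mM); this is the coupling that lets the F6P node's bistability express
itself against the glucose supply, because the supply flux must fall
several-fold as F6P (hence G6P) rises across the node's bistable window.

## Calibration

The supplementary rate equations this model descends from are not
transcribed here; instead the functional forms above were calibrated
against the printed behavioural anchors:

* The two-enzyme F6P node (PFK + ALDO, DHAP and GAP clamped at 0.04 and
  0.02 mM) reproduces switch-up at ≈ 0.30 mM and switch-down at ≈ 0.09 mM
  F6P.  These two anchors fix the PFK scale (Vmax 190 mM/h at reference
  level), its F6P half-saturation (0.36 mM), the basal activity
  ($\varepsilon$ = 0.016) and the ALDO scale (40 mM/h).
* The full pathway reproduces the loop-dependent steady-state structure:
  no multistability with PFKP + PKM1; a Loop-1 window opening near 1 mM
  glucose with PFKL + PKM1; a Loop-2 window at higher glucose
  (≈ 3–6 mM) with PFKP + PKM2.  These anchors fix the supply side (GLUT
  Vmax 110 mM/h, Km 10 mM; HK Vmax 400 mM/h, glucose Km 4 mM, G6P
  inhibition as above) and the PFKFB kinase scale.
* PFKFB expression level leaves every steady state unchanged by
  construction; its absolute speed (Vph = 120 mM/h) was chosen so the
  reference response time of the F26BP pool sits below the 1.5 h pulse
  of the transient protocol while a fivefold lower level does not.
* The lactate branch: LDH equilibrium constant 2.5·10^4 (the literature
  scale for pyruvate reduction), with the LDH capacity, mitochondrial
  transporter and alanine exchange scaled so that the high-flux branch
  diverts proportionally more carbon to lactate than the low-flux branch
  and the lactate-to-glucose flux ratio stays below its stoichiometric
  bound of 2.
* Cell-specific fluxes are reported through an effective conversion
  volume (16 pL per cell by default).  It is chosen so the high-flux
  branch maps near 0.3 mmol/10^9 cells/h, the scale of measured uptake
  rates in cultured proliferative cells; it is a unit mapping, not an
  anatomical volume.

All remaining constants (near-equilibrium chain enzymes, fixed
environment) are physiologically plausible choices and are recorded with
their provenance in `inst/extdata/default_config.yaml`.

## Numerical methods

Steady states are enumerated by a multistart damped-Newton iteration in
log-concentration space: initial guesses are drawn log-uniformly over
[1e-4, 10] mM per species (a standard-uniform mode is available), Newton
steps use a forward-difference Jacobian with a trust-region cap and
backtracking line search, and convergence requires max |d/dt| < 1e-8
mM/h.  Roots are deduplicated at 1e-4 relative tolerance (keeping the
lowest-residual representative), classified by the eigenvalues of a
central-difference Jacobian (stable iff every real part < −1e-9 /h;
near-zero real parts are flagged "marginal"), and sorted by flux.
Scans seed each grid point with the roots of its neighbour
(nearest-neighbour continuation) in addition to the multistart, and a
missed point retries once with a sixfold denser multistart.  Switch
points are refined by bisection on branch existence, to 0.005 mM in F6P
and 0.05 mM in glucose by default.

Transient runs use the stiff BDF integrator (deSolve's `vode`) at
rtol 1e-8 / atol 1e-10 mM.  The pathway is stiff — the 1,3-BPG pool
turns over in fractions of a second while F26BP relaxes over hours —
and the BDF family handles this cleanly where non-stiff-to-stiff
switching integrators stall.

The solver stack is validated against independent oracles: a 1-D toy
auto-activation system whose steady states are polynomial roots
(`toy_bistable()`, `toy_steady_states()`), brute-force sign-change root
scanning (`brute_force_roots()`), and the analytic Jacobian of linear
systems.

## What the test suite does and does not show

The synthetic configurations used by the tests are the model's own
study conditions: isozyme sets on the reference enzyme-level vector, a
fixed physiological environment, and randomized enzyme-level
perturbations spanning two orders of magnitude.  Passing tests show that
the implementation reproduces the calibrated switch concentrations, the
loop-dependent multistability structure, hysteresis, the PFKFB
level/timescale separation and the history-dependent flux protocol — on
this model.  They do not show that real cells carry these exact
constants; the isozyme-discriminating constants are literature values,
everything else is calibration.

## Known limitations

* **No stable intermediate branch with both loops active.**  With PFKL +
  PKM2 the model is bistable (maximum two stable plus one unstable
  state), not tri-stable.  In this rate-law family both loops' activation
  transitions map to overlapping F16BP ranges through the ALDO flux map,
  so a putative intermediate state always ignites the F16BP feedback and
  collapses onto the high branch.  Alternative geometries (a flux
  ceiling in ALDO or GAPDH, dual-action F26BP that also lowers PFK's F6P
  half-saturation) were explored and each broke one of the anchored
  behaviours; the limitation is documented rather than masked.
  For the same reason the redox scan tops out at three coexisting states
  (at NAD/NADH ≥ 9) rather than five, and one state below (NAD/NADH ≤ 1).
* **Node bistability is lost between K/P = 5 and 8** rather than just
  above 10.  Strengthening the F26BP activation constant to move this
  threshold cancels the full model's Loop-2 branch, because both scale
  with the same kinase flux.
* **The Loop-1 low-flux branch persists to high glucose** in the PFKL +
  PKM1 configuration (its fold lies above 25 mM): with only Loop 1
  active, the glucose supply saturates before it can overwhelm the
  unactivated PFK.  The Loop-2-containing configurations do fold within
  the physiological range.
* The alanine scan moves the switch-up concentration in the right
  direction but only weakly (≈ +0.1 mM over two decades of alanine):
  LDH clamps cytosolic pyruvate, so the alanine exchange has little
  leverage on PEP.
* Quasi-static protocols approximate basin structure; no exhaustive
  basin-of-attraction computation is performed.

## Problem sizes

Default grids are chosen for interactive use: node scans use 0.005 mM
F6P steps over [0.01, 0.40]; full-model scans use 22 glucose points over
[0.5, 25] with bisection refinement at the folds; the pulse protocol
runs 550 h with 0.1 h output steps; the hysteresis protocol
preconditions for 12 h and assays for 6 h, as in the cell-culture
protocol it mirrors.

```{r example}
cfg <- build_config("PFKL", "PKM1", kp = 10)
d <- scan_bifurcation(cfg, "glucose", seq(0.5, 10, by = 0.5))
switch_points(d)
```
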