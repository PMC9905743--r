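---
title: "Modeling degenerate DRN-VTA neuromodulator circuits with drnvta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling degenerate DRN-VTA neuromodulator circuits with drnvta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drnvta)
```

## The model

`drnvta` simulates a mean-field firing-rate model of the midbrain
serotonin-dopamine system: five neural populations - DRN serotonin (5-HT),
VTA dopamine (DA), DRN glutamate (Glu), DRN GABA and VTA GABA - coupled by
two kinds of interaction.

**Fast, quasi-steady synapses.** Ionotropic currents from the Glu and GABA
pools are much faster than every other timescale in the model, so they are
treated as instantaneous: the current a population receives from a fast
source is a signed coupling times the presynaptic firing rate. Each
population's rate follows a threshold-linear transfer function

$$F_p = g_p\,[I_p - I_{0,p}]_+ ,$$

with gains $g_{DA} = 0.019$ and $g_{5HT} = 0.033$ Hz/a.u., thresholds
$I_{0,DA} = -10$ and $I_{0,5HT} = 0.13$ a.u., and fixed bias currents
(99.87, 210, 100, 450, 200 a.u. for 5-HT, DA, Glu, DRN GABA, VTA GABA).
Because the fast currents depend on the rates themselves, the five rates are
the solution of a rectified linear system at every instant. The solver uses
an active-set strategy: assume a set of supra-threshold populations, solve
the linear restriction, verify the rectification conditions, and swap
violators (with an exhaustive deterministic fallback over all $2^5$ subsets).
The test suite checks this solver against both a damped relaxation oracle and
brute-force enumeration on random networks.

**Slow neuromodulator-induced currents.** Interactions sourced by 5-HT or DA
act through released transmitter. Four first-order currents follow

$$\tau\,\dot I = -I + \frac{k}{1 + e^{-a([x]-x_0)}},$$

two autoreceptor self-inhibitions (5-HT$_{1A}$: $\tau = 500$ ms; D2:
$\tau = 150$ ms; $k = 80$, slope 10 $\mu M^{-1}$, offset 0.1 $\mu$M) and two
cross-modulation currents driven by [5-HT] and [DA] ($\tau = 1200$ and
1000 ms, $k = 0.03$, slope 20 $\mu M^{-1}$). Each target population weights
the relevant cross-modulation current by its own signed connection weight.
Transmitter pools follow Michaelis-Menten release-reuptake dynamics

$$\frac{d[x]}{dt} = \frac{[x]_p F}{1000} - \frac{V_{max}[x]}{K_m + [x]},$$

with $[5HT]_p = 0.08$, $V_{max} = 0.0013\ \mu$M/ms, $K_m = 0.17\ \mu$M for
serotonin and $[DA]_p = 0.1$, $V_{max} = 0.004$, $K_m = 0.15$ for dopamine
(time in ms, concentration in model-unit $\mu$M throughout). Setting these
to zero yields the closed-form steady-state relations
$F_{5HT} = 16.25\,[5HT]/(0.17+[5HT])$ and $F_{DA} = 40\,[DA]/(0.15+[DA])$,
which anchor both the fixed-point solver and two acceptance checks.

**The DA-driven sigmoid offset.** The source literature for this model family
is internally inconsistent about the offset of the DA-driven cross-modulation
sigmoid (0.1 vs 0.3 $\mu$M appear in different displayed forms). We use
0.1 $\mu$M, matching the steady-state system in which the DA-sourced target
currents appear three times, for a decisive structural reason: with an offset
of 0.3 $\mu$M the tonic DA-sourced currents are $O(10^{-4})$ a.u. at the
calibrated baseline ([DA]$^* \approx 0.02\ \mu$M), which makes every
DA-to-target connection functionally inert at rest and - as we verified
numerically - makes the graded dose-response ordering of the D2-agonist
screen unreachable for any weight choice. With 0.1 $\mu$M the same screen
reproduces the expected ordering with moderate weights.

## Architectures, variants and calibration

The registry ships twelve architectures (A-L) built over a catalog of
admissible edges; six connection patterns with limited experimental support
are excluded outright (DRN GABA to VTA DA or VTA GABA, VTA GABA to or from
DRN Glu, Glu-GABA links within the DRN, VTA DA to DRN Glu). Architecture K
is the minimal template circuit; A is the densest; L is the only one with a
fast (ionotropic, 5-HT$_3$/co-transmission-like) 5-HT to DA link. Four edge
kinds may be excitatory or inhibitory (5-HT to Glu, 5-HT to DRN GABA, 5-HT
to DA, DA to VTA GABA); expanding each architecture over its undetermined
signs and the two serotonin phenotypes (Type I / Type II) yields exactly 84
variants (32 for A, 8 for L), enforced by registry integrity tests. The
per-architecture edge lists are reconstructions: the surviving constraints
are the counts above, the stepwise-removal narrative (e.g. C lacks the 5-HT
to DRN GABA edge that B has; D additionally lacks DA to VTA GABA), and the
restriction of the VTA GABA to DRN GABA edge to A and L.

**Baseline pinning.** The template activity profile fixes tonic pre-cue
rates in both tasks: 5-HT 3.0/4.5, DA 4.8/4.8, Glu 4.1/4.1, DRN GABA
21.5/19.4, VTA GABA 13.5/16.3 Hz (punishment/reward). At a tonic fixed
point the concentrations - and hence all four slow currents - are algebraic
functions of those rates, so each population's current balance is *linear*
in the unknown weights. Calibration is therefore deterministic: the three
unknown gains (Glu and the two GABA pools) are solved once from the template
equations, and each variant's core weights (5-HT autoreceptor, Glu to 5-HT,
Glu to DA, VTA GABA to DA, 5-HT to the GABA pools) are solved per population
from the two task equations, given the architecture's extra edges at their
fixture weights. Every variant reproduces the ten baseline rates
essentially exactly, which is why the degeneracy screen passes for all 84.
A stochastic Latin-hypercube + coordinate-refinement search (`calibrate()`)
is provided for user-supplied architectures where the linear reduction does
not apply.

**Compensatory inputs.** The reward/punishment difference in the DRN GABA
baseline (21.5 vs 19.4 Hz) forces a sizable serotonin-sourced inhibitory
current onto DRN GABA. Architectures that lack that edge (C) or carry its
excitatory version (half of A's variants) cannot supply it internally, so
calibration solves architecture-specific external inputs instead: a constant
inhibitory current to DRN GABA, an additional reward-trial component, and -
for Type II reward trials - a slow-ramp (1200 ms) cue-interval component
that mimics the template's gradual serotonin-driven GABA suppression. This
generalises the extra reward-trial inhibitory input that the dense
architectures (A, L) require in any case; amplitudes are calibration
outputs, not free parameters.

**D2 fixture weights.** The DA-sourced ("D2") edge weights are fixtures
sized so that the dose screen exhibits the expected ordering on the shipped
registry: nothing deviates at baseline ($X = 1$); at $X = 10$ every variant
deviates through its DA trace only; at $X = 40$ architecture A is singled
out by DRN GABA and 5-HT deviations; at $X = 70$ (punishment) D, E, H and L
join through 5-HT changes; at $X = 100$ five subsets of architectures are
distinguishable ({A}, {B,C}, {D,E,H}, {L}, {F,G,I,J,K}). The shipped values
are `da_gd` 480 (A) / 50 (G), `da_5ht` 150 (A) / 60 (D,E,H,L) / 10 (B,C),
`da_gv` 190. Distinguishability is operationalised as: same map from (task,
serotonin type) to violating-population set within a subset, different maps
across subsets.

## Task protocols

Cue onset is at 4.5 s (allowing the network to settle; simulations start at
the tonic fixed point of the constant inputs, making the pre-cue segment an
exact steady state) and outcome at 5.7 s, with an 8 s horizon. Reward trials
add a constant 50 a.u. to 5-HT and DA (the across-trial reward signal);
Type I reward uses a 200 a.u. VTA GABA step between cue and outcome, Type II
a 100 a.u. sustained 5-HT step; a 1000 a.u., 200 ms Glu pulse marks the cue.
Punishment delivers 1000 a.u., 200 ms pulses at outcome to VTA GABA + DRN
GABA (Type I) or DRN GABA + 5-HT (Type II). Transient events are smoothed
with 50 ms exponential edges (toggleable; constants are unsmoothed).

## Numerics

* **Integration:** classical fixed-step 4th-order Runge-Kutta, default
  $dt = 0.5$ ms, with the rate system re-solved at every stage; the slowest
  intrinsic timescale is 1.2 s, and a dt-halving test holds every recorded
  rate change below 0.1%. The compiled integrator warm-starts the active-set
  solver from the previous stage's active set, which changes nothing about
  the solution (verified against the R solver) and speeds the loop several-fold.
  Concentrations are clipped at zero only within $10^{-9}$; larger
  excursions or non-finite states abort with an error.
* **Fixed points:** damped Newton on ([5-HT], [DA]) - slow currents
  substituted by their sigmoid steady values, rates pinned to the clearance
  curves - from a deterministic $10 \times 10$ log-spaced grid of starts;
  all distinct roots are reported and the full 6-D residual must fall below
  $10^{-10}$. Concentrations are box-constrained at zero, which is itself a
  valid boundary equilibrium (e.g. DA under a frozen punishment drive).
* **Jacobians:** central finite differences of the full right-hand side
  with rates re-solved per perturbation (one-sided at the $c \ge 0$
  boundary), cross-checked to $10^{-6}$ against a closed-form Jacobian that
  differentiates the active-set solution implicitly. The four current rows
  carry the exact diagonal $-1/500, -1/150, -1/1200, -1/1000$.
* **Deviation metric:** mean over the 3.5-6.7 s window of
  $100\,|F - F_{tpl}| / \max(F_{tpl}, 0.1)$ per population; the 0.1 Hz floor
  only matters where the template itself is phasically silenced. Thresholds:
  10% (DA, 5-HT, Glu), 16% (both GABA pools). The template is always the
  denominator (a documented asymmetry of the pseudometric).

## Stability conditions and a known discrepancy

The stability battery evaluates each variant at the tonic fixed point of its
task's constant inputs and at a "phasic" quasi-static freeze with every
protocol event held at full amplitude. Two structural facts are worth
knowing. First, some frozen drives have no equilibrium at all: a frozen
reward Glu pulse pushes DA release past its maximal Michaelis-Menten uptake,
and the frozen Type II punishment pulse does the same for serotonin
(clearance caps the steady rates at 40 and 16.25 Hz). The battery records
these as `no_fixed_point`; every equilibrium that exists is stable, with
purely real spectra, and punishment-phasic equilibria are consistently more
stable than tonic ones.

Second, the *magnitude* of the leading tonic eigenvalue is pinned by the
dopamine clearance mode $-V_{max}K_m/(K_m+[DA]^*)^2$: with the calibrated
baseline DA rate of 4.8 Hz, $[DA]^* = 0.0205\ \mu$M and the mode is
$\approx -0.0207$ ms$^{-1}$ for *every* architecture (couplings into the
concentration modes are $O(10^{-6})$). Published values for this model
family (about $-0.017$ to $-0.016$ for the sparse architectures and
$\approx -0.03$ for the fast-link architecture) are not reachable from the
printed rate and uptake constants: $-0.03$ exceeds the mode's maximal
possible magnitude $-V_{max}/K_m = -0.0267$, and driving the eigenvalue
there through coupling produces complex pairs first. The package reports
what the dynamics imply; the acceptance suite keeps the corresponding
checks in place and documents them as failing.

## Scope of the synthetic conditions

All inputs are idealised constants, steps and pulses; the generator emulates
fully learned reward conditioning and unexpected punishment only - no
partial learning, reward omission, probabilistic outcomes, trial-to-trial
variability or noise. Passing the degeneracy screen on these profiles shows
that structurally different circuits reproduce the same *idealised* task
response, not that they would be indistinguishable in noisy recordings.
Membrane dynamics, spiking, receptor pharmacokinetics and plasticity are out
of scope by construction.

## Problem sizes

The shipped analyses run at desk scale: single 8 s trials at $dt = 0.5$ ms
(0.5-1 s each after compilation), the 84-variant screen and stability
battery in tens of seconds, and the full $84 \times 5$-dose D2 battery in a
few minutes; the test suite uses $dt = 1$ ms with coarser recording where
the checks tolerate it.
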