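# drnvta

Mean-field simulation and degeneracy screening of the DRN–VTA
neuromodulator circuit.

## What this is for

The dorsal raphe nucleus (DRN, the main source of forebrain serotonin) and
the ventral tegmental area (VTA, the main source of mesolimbic dopamine)
signal reward and punishment through a tangle of direct and indirect
connections among serotonin (5-HT), dopamine (DA), glutamate and GABA
populations. Structurally different wirings of these populations can produce
the same task-evoked activity — circuit *degeneracy*. `drnvta` is for
computational neuroscientists who want to simulate this circuit family,
enumerate its degenerate wirings, test their dynamical stability, and ask
which wirings a pharmacological perturbation (a D2-receptor agonist) could
tell apart.

The model is a five-population firing-rate network. Each population has a
threshold-linear transfer function `F = g·[I − I₀]₊`. Fast ionotropic
synapses from the Glu/GABA pools are quasi-steady (`I = ±J·F_pre`), so the
five rates solve a rectified linear system at every instant. Slow
neuromodulator-induced currents follow

```
τ dI/dt = −I + k / (1 + exp(−a([x] − x₀)))
```

(5-HT₁A and D2 autoreceptors, plus [5-HT]- and [DA]-driven cross-modulation
currents), and the transmitter pools obey Michaelis–Menten
release–reuptake:

```
d[x]/dt = [x]_p·F/1000 − V_max·[x]/(K_m + [x])
```

Setting these to zero yields the steady-state relations
`F_5HT = 16.25·[5-HT]/(0.17+[5-HT])` and `F_DA = 40·[DA]/(0.15+[DA])`, which
anchor the fixed-point analysis. Twelve architectures (A–L), expanded over
undetermined connection signs and two serotonin phenotypes (Type I/II),
yield 84 calibrated model variants; all of them reproduce the template
activity profile within the per-population inclusion criterion (10% for DA,
5-HT, Glu; 16% for the GABA pools, time-averaged over 1 s before cue to 1 s
after outcome).

## A worked example

```r
library(drnvta)

v  <- template_variant("I")                 # architecture K, Type I 5-HT
tc <- simulate_circuit(v, task = "reward")  # 8 s trial, dt = 0.5 ms
round(baseline_statistics(tc), 2)           # mean rates 1 s before cue
#>  HT5_DRN   DA_VTA  GLU_DRN GABA_DRN GABA_VTA
#>      4.5      4.8      4.1     19.4     16.3
```

Those are the calibrated reward-task baseline firing rates (Hz): serotonin
4.5, dopamine 4.8, glutamate 4.1, DRN GABA 19.4, VTA GABA 16.3. The
punishment task gives 3.0 / 4.8 / 4.1 / 21.5 / 13.5 — dopamine's baseline
is unchanged across tasks because the indirect 5-HT → VTA GABA → DA pathway
cancels the constant reward input to DA.

```r
s <- stability_verdict(v, "tonic", "punishment")
s$verdict
#> [1] "stable"
round(Re(s$eigenvalues), 5)
#> [1] -0.02049 -0.00682 -0.00477 -0.00231 -0.00100 -0.00083
```

All six Jacobian eigenvalues are real and negative (units: per ms): the
tonic state is dynamically stable. The leading magnitude (−0.0205) is the
dopamine clearance mode; the smallest (−1/1200) is the slow 5-HT-driven
cross-modulation current.

```r
vs  <- enumerate_variants()                       # all 84 calibrated variants
rep <- d2_screen(vs, d2_config(factors = c(1, 10, 40)))
```

`d2_screen` scales every DA-sourced connection (including the D2
autoreceptor) by each dose factor X and flags variants whose activity leaves
the inclusion criterion: at X = 1 nothing is flagged, at X = 10 every
variant deviates through its DA trace, and by X = 40 architecture A is
singled out by DRN GABA and 5-HT deviations. `d2_signatures(rep, X)` groups
architectures into distinguishable subsets (five at X = 100).

A command-line driver with the same capabilities ships in
`inst/cli/drnvta.R`:

```sh
Rscript inst/cli/drnvta.R simulate --architecture K --task punishment --type I
Rscript inst/cli/drnvta.R d2 --factors 1,10,40,70,100
```

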