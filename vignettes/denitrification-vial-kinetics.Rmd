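---
title: "Modelling and analysing denitrification kinetics in sealed batch vials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing denitrification kinetics in sealed batch vials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denitkin)
```

# The system

A denitrifying culture grows in a sealed, vigorously stirred 120 mL serum
vial: 50 mL mineral medium, 70 mL He headspace charged with ~1% O~2~,
20 °C, 2 mM (100 µmol per vial) NO~3~^-^. As O~2~ runs out the cells
switch to N-oxide respiration, reducing NO~3~^-^ stepwise to N~2~ through
NO~2~^-^, NO and N~2~O. A robot repeatedly draws 1 mL of headspace
(replacing it with He) for gas chromatography; NO~2~^-^ is measured in
small liquid samples taken from parallel replicate vials so that the
headspace-to-liquid ratio of the monitored vial is never disturbed.

Strains fall into three phenotypes by the fraction of the supplied
NO~3~^-^-N that transiently pools as NO~2~^-^: full accumulators (FNA,
≥ 89%), partial accumulators (PNA, roughly 40–60%) and low accumulators
(LNA, ≤ 20%). The package has two halves: an analysis pipeline that turns
instrument-style data into loss-corrected pools, inferred NO~3~^-^,
electron flows and a phenotype call; and a mechanistic simulator whose
shipped presets reproduce the three phenotypes, a *narG* deletion, and a
NO~3~^-^-spike electron-competition experiment, so that the analysis can
be validated end to end against known ground truth.

# The simulator

## Electron supply and allocation

The model's central idea is that respiration is a competition for a finite
electron supply. Catabolism delivers electrons to the quinone pool at a
capacity $S(t) = v_{\mathrm{supply}}\,B(t)$ proportional to biomass $B$.
Each terminal reductase $i$ places a demand

$$D_i = a_i \, v_{\max,i} \, B \, \frac{[S_i]}{K_{m,i} + [S_i]}
        \times (\text{modifiers}),$$

where $a_i \in [0,1]$ is its synthesised activity and $[S_i]$ its
substrate concentration in the liquid. Nir carries two modifiers: a
NO~3~^-^ gate $K_i/(K_i + [\mathrm{NO_3^-}])$ (the metabolic inhibition
that makes FNA strains halt NO~2~^-^ reduction whenever NO~3~^-^ is
present) and a subpopulation fraction (only part of an FNA population
expresses Nir, which is what makes the electron flow dip at the
NO~3~^-^→NO~2~^-^ transition). If the summed demand exceeds $S$, realized
flows are allocated proportionally to $w_i D_i$ with per-reductase
priority weights $w_i$, no reductase receives more than its demand, and
freed supply is re-shared (a small waterfilling iteration). Pools advance
by the standard half-reaction stoichiometry (4 e^-^ per O~2~; 2 e^-^ per N
for NO~3~^-^→NO~2~^-^; 1 e^-^ per N for each later step; 5 e^-^ per N for
the full ladder), and biomass grows as $dB/dt = Y \sum_i V_i$.

Gases partition between headspace and liquid at equilibrium — the vial is
stirred hard enough that this is the right default — using dimensionless
Henry constants at 20 °C shipped as data
(`inst/extdata/gas_table.yaml`). A finite mass-transfer coefficient is
available (`gas_props(kla = )` with `estimate_liquid_conc()`) solely to
reproduce transfer-limited liquid O~2~ estimates; published µmol-per-vial
to µM conversions imply such a sub-equilibrium estimate, and since the
underlying transfer parameters are not published we expose `kla` without
pinning a value.

## Regulation

Denitrification genes are induced when total vial O~2~ falls below a
threshold (default 14 µmol). Each reductase activity then rises first
order, $da_i/dt = r_i (1 - a_i)$, after a per-reductase delay. Three
regulatory motifs distinguish the phenotypes:

* **FNA** (defaults of `phenotype_params()`): strong NO~3~^-^ gating of
  Nir ($K_i$ = 20 µM), a Nir-expressing subpopulation of 0.3, nearly no
  first-pulse Nir synthesis (0.01 h^-1^ — the initial transcription pulse
  yields hardly any NO~2~^-^ reduction), and a *second synthesis pulse*
  (0.25 h^-1^) for Nir/Nor when NO~3~^-^ is depleted.
* **PNA**: no gating, prompt Nir synthesis, but a *small Nir capacity*
  (8 µmol e^-^ biomass^-1^ h^-1^) with high allocation priority: Nir runs
  at capacity both while NO~3~^-^ is being reduced and afterwards, so
  NO~2~^-^ accumulates at roughly the difference between production and
  that fixed consumption — about half the supplied N — and drains
  smoothly after the peak.
* **LNA**: prompt synthesis, large Nir capacity, and NO~3~^-^ reduction
  throttled early — either Nar is absent (Nap-only strains, with Nap
  intrinsically slow at 25 µmol e^-^ biomass^-1^ h^-1^) or its synthesis
  is delayed by 5 h relative to the other genes. Production never
  outruns consumption, so NO~2~^-^ stays near zero. The `dNarG` preset is
  simply the PNA parameterisation without Nar; it presents as an LNA and
  takes several times longer to finish, mirroring the deletion phenotype.

The competition presets encode the spike experiment: pre-induced cultures
(all activities 1) start anoxic on 100 µmol NO~2~^-^, and a state trigger
adds 100 µmol NO~3~^-^ at the first grid time where NO~2~^-^ has dropped
by one third. In the FNA parameterisation the gate then shuts Nir down
until the NO~3~^-^ is gone (NO~2~^-^ climbs by the full spiked amount and
N~2~ plateaus transiently); PNA reduces both at once; LNA continues
NO~2~^-^ reduction unperturbed. All three close the balance at
~200 µmol N~2~-N.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `v_supply` | µmol e^-^ biomass^-1^ h^-1^ | 80 | sets overall pace; with the yield below, runs complete in ~25–45 h, matching observed 28–78 h completion times to within a factor of two |
| `yield` | biomass (µmol e^-^)^-1^ | 0.0015 | aerobic growth rate ~0.12 h^-1^; biomass unit is OD~600~ × vial (inoculum 0.075 ≙ OD 0.075) |
| `induction_o2_threshold` | µmol O~2~ vial^-1^ | 14 | O~2~ keeps falling through the synthesis delay and the hourly sampling grid, so inducing near the top of the observed 10–15 µmol onset window places the *measured* onset mid-window |
| `km["no3"]` | µM | 1000 | an apparent, vial-scale affinity; it gives NO~3~^-^ depletion an exponential tail so measured pools are smooth on the sampling grid (a corner sharper than the NO~2~^-^ sampling interval cannot be reconstructed by any interpolant) |
| `km["no"]`, `km["n2o"]` | µM | 0.3, 3 | place the quasi-steady NO and N~2~O pools in the tens-of-nmol range |
| `vmax_e["nor"/"nos"]`, `w` nor/nos | — | 800, weight 5 | NO is toxic: Nor/Nos get high capacity and allocation priority, keeping transients below the observed ceilings (≤ 70.5 nmol NO, ≤ 89 nmol N~2~O) |
| `nir_no3_inhibition_ki` | µM | 20 (FNA); `Inf` disables | gate half-point; low enough that Nir flow is a fraction of a percent of its uninhibited value at mM NO~3~^-^ |
| `nir_subpop_fraction` | — | 0.3 (FNA); 1 otherwise | depth of the transition dip |

## The observation model

`autosample()` re-simulates the vial segment-wise between gas sampling
events; at each event it records the headspace concentrations and removes
`sample_volume`/(headspace + dissolved-equivalent) of every gas from the
ongoing state — dilution feeds back into the physics, it is not painted on
afterwards. The He replacement is treated as an exact isobaric 1 mL
exchange; no overpressure state is tracked. NO~2~^-^ is read at its own,
sparser times (default every 2 h) from the same perturbed trajectory: the
parallel NO~2~^-^ vials sit in the same incubation robot and undergo the
same gas-sampling program — their role is only to spare the monitored
vial the liquid draws. Modelling them as *unsampled* vials would
desynchronise the NO~2~^-^ and gas series by about half an hour (gas
sampling removes O~2~ and advances induction), which is an artefact of
pairing two physically different vials, not of the instrument.

Noise is measurement-only: multiplicative Gaussian per detector
(O~2~/N~2~ 1%, N~2~O 2%, NO 5%, NO~2~^-^ 3%), truncated at zero. Because
the physical trajectory is therefore deterministic, `autosample()` exposes
its `physical` record so replicate noise draws of one scenario cost one
simulation.

# The analysis

`analyze_run()` chains the stages: loss correction (the removed amount at
each sampling is the *measured* concentration times the sample volume,
mirroring instrument practice), cubic-spline interpolation of NO~2~^-^
onto the gas grid, nitrogen mass balance, rate estimation, electron-flow
partitioning, onset and dip detection. Design points worth stating:

* **NO~3~^-^ is inferred, never measured.** The balance
  $R_3 = \Delta\mathrm{NO_2^-} + R_2$ with
  $R_2 = \mathrm{NO} + \mathrm{N_2O\text{-}N} + \mathrm{N_2\text{-}N}$
  makes the full pool bookkeeping computable from gases and NO~2~^-^
  alone. Protocols that *start* with NO~2~^-^ (the competition runs) use
  the generalisation $R_3 = \max(\Delta\mathrm{NO_2^-} + R_2,\,0)$; the
  ordering $R_3 \ge R_2 \ge R_1 \ge R_0$ is an invariant of NO~3~^-^-fed
  runs only.
* **Consistency guard.** If $R_3$ exceeds the supplied N by more than 5%
  *persistently* (terminal value, or mean positive excess), the input is
  rejected as inconsistent — wrong units or wrong metadata. The check is
  deliberately not pointwise: a full accumulator holds ~100% of the
  supplied N as NO~2~^-^, so with 3% measurement noise isolated sampling
  points land above the bound in a sizeable share of perfectly ordinary
  runs.
* **Spline choice.** `stats::splinefun(method = "fmm")` — the classic
  cubic spline that reproduces cubic polynomials exactly. Natural end
  conditions were rejected: they reproduce only linear functions, and
  their end-interval bias is visible exactly where the NO~2~^-^ series
  matters.
* **Derivatives.** Centred three-point differences by default; a
  smoothing-spline derivative (`rate_method = "spline"`) is the right
  choice for single noisy runs (the source experiments average three
  replicates before computing flows). Negative rates are clipped to zero
  for the electron flows; raw signed rates are kept as diagnostics.
  Clipping biases time-integrals of noisy flows slightly upward, so
  stoichiometric identities are checked on the terminal pool values
  ($2R_3 + R_2 + R_1 + R_0$), which telescope exactly.
* **Dip definition.** Depth is $1 - V_e^{\min}/\text{plateau}$ with the
  plateau the median total flow over the 5 h before NO~3~^-^ depletion,
  and $V_e^{\min}$ the deepest *local* minimum in a ±3 h window around
  depletion whose flow later rebounds by at least 10% of the plateau.
  The rebound requirement is what separates a transition dip from the
  terminal shutdown of a finished run: smooth-transition phenotypes
  complete shortly after NO~3~^-^ depletion and would otherwise score a
  spurious full-depth "dip". Depletion is taken at 5% of supplied N
  because the interpolated NO~2~^-^ peak slightly underestimates the
  truth, which delays a 1% criterion by hours.
* **Classification.** The fraction denominator is the provided (plus
  spiked) NO~3~^-^-N, not the N reduced so far — the two differ mid-run,
  and the provided amount is the experimenter-controlled quantity.
  Boundaries: ≤ 0.20 → LNA, ≥ 0.80 → FNA, PNA between. The 0.62–0.89
  interval is unpopulated in the observations; 0.80 splits it while
  keeping the known FNA minimum inside FNA. Both thresholds are
  arguments. The borderline 11–17% accumulators are classified LNA here;
  whether they constitute a fourth class is left to the data.
* **Statistics.** The one-way ANOVA F and the Tukey–Kramer studentized
  range comparisons are computed from their defining sums of squares, with
  the compact letter display built by insert-and-absorb; `stats::aov` and
  `stats::TukeyHSD` serve as independent cross-checks in the test suite
  rather than as the implementation. Shapiro–Wilk delegates to
  `stats::shapiro.test`. α is fixed at 0.05 throughout.

# Numerical choices

The ODE system is stiff — the NO and N~2~O pools sit at nmol levels under
µmol h^-1^ throughput — so it is integrated with the BDF method
(`deSolve::ode(method = "bdf")`, rtol 10^-8^, atol 10^-10^, internal step
capped at the output step). Discrete events (induction, the second
synthesis pulse, spikes) fire at the first dense-grid time whose state
satisfies the condition; the default grid step is 0.05 h and halving it
changes the FNA NO~2~^-^ maximum by well under 0.5%. Negative pools abort
with a diagnostic rather than being silently clipped. Event latching to
the grid, not root-finding, is deliberate: it keeps trajectories exactly
reproducible across solver versions for fixed inputs.

Problem sizes throughout the test suite are the study's own: 100 µmol
NO~3~^-^-N per vial, hourly gas sampling over 40–96 h runs, 25 noise
seeds per preset for classifier robustness, and 10,000 null simulations
for the ANOVA type-I check.

# What the generator does and does not emulate

It emulates: sequential (FNA) versus simultaneous (PNA/LNA) acceptor use;
transient NO/N~2~O pools at tens-of-nmol magnitudes; the onset of
NO~3~^-^ reduction at 10–15 µmol vial O~2~; the electron-flow dip and its
absence; sampling dilution with He replacement; per-detector measurement
noise; NO~3~^-^-spike competition dynamics. It does not emulate: pH and
HNO~2~ toxicity, DNRA, aerobic denitrification, per-cell stochastic
induction (the Nir subpopulation is a fixed fraction), transcript
abundances (delays and synthesis pulses stand in for them), vial leakage
or septum back-diffusion, or CO~2~/carbonate chemistry. Passing tests
therefore show that the *analysis* is correct on data with this structure
and noise — not that real vials contain no further surprises; in
particular, real detector drift and replicate-to-replicate biological
variation are not in the noise model. The regulator-deletion strain with
*elevated* accumulation reported alongside these phenotypes is
deliberately not a preset: its mechanism is unresolved, and inventing one
would put fiction in the ground truth.

# Known limitations

The Nar:Nir competition weights and capacities are calibrated to the
printed accumulation bands, not measured; absolute growth yield is only
loosely constrained (completion times within a factor of ~2). The dip
detector is tuned for smooth or replicate-averaged flows; on single noisy
runs the centred-difference flows can hide or exaggerate it (use the
smoothing-spline rates there). The interpolated NO~2~^-^ maximum is a
measurement-limited estimate: a peak narrower than the NO~2~^-^ sampling
interval is irrecoverable by construction, which is also why the
simulator's study conditions keep transitions wider than the sampling
grid, as the real kinetics are.
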