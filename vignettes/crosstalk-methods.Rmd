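---
title: "Modelling the autophagy-apoptosis decision under ER stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the autophagy-apoptosis decision under ER stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Cells facing endoplasmic-reticulum stress first mount a pro-survival
autophagic response; if the stress is strong or lasts long enough, an
abrupt and effectively irreversible switch to apoptosis follows.  `erfate`
implements a deliberately minimal dynamical model of that decision with
three lumped tiers:

* **ERSS** — an ER stress sensor, activated by the stressor level $S$
  (arbitrary stress units) by mass action:
  $\dot E = k_{ae} S (E_T - E) - k_{ie} E$.  Its steady state
  $E^*(S) = k_{ae}S E_T/(k_{ae}S + k_{ie})$ converts the stress dose into
  an internal signal.
* **AUT** — the autophagy machinery (Beclin-1 axis), activated by the
  sensor and inactivated basally and by active apoptosis inducer, both
  through Michaelis–Menten terms:
  $$\dot A = (k_{aau} + k'_{aau} E)\frac{A_T - A}{J_{aa} + A_T - A}
           - (k_{iau} + k'_{iau} P_{act})\frac{A}{J_{ia} + A}.$$
  With small Michaelis constants this activation/inactivation pair is a
  zero-order-ultrasensitive (Goldbeter–Koshland-type) switch: AUT sits
  high or low depending on the sign of the velocity imbalance, and flips
  sharply when the balance crosses one.
* **APO** — the apoptosis inducer (caspase axis), activated by the sensor
  through a distributive chain of $n$ sequential modification steps with
  per-step forward rate $k_{aap} E$ and per-step backward rate
  $$k_b = \frac{k_{iap}}{1 + k_{fb} P_{act}} + k'_{iap} A,$$
  where $P_{act}$ is the fully modified (last) chain species and the
  unmodified pool is $P_0 = P_T - \sum_i P_i$.

Two motifs shape the decision.  The **mutual antagonism**
($k'_{iau} P_{act}$ suppressing AUT, $k'_{iap} A$ suppressing the chain)
makes survival and death mutually exclusive attractors.  The **positive
feedback** $1/(1 + k_{fb} P_{act})$, by which active apoptosis inducer
protects itself from demodification, locks the death state in place once
the chain is fully modified.

## Why three modification steps

The multistep chain is what gives apoptosis activation its threshold-like
character: at low sensor activity the chain occupancy falls off roughly
like the $n$-th power of the forward/backward ratio, so deeper chains
separate sub- and super-threshold stress levels more sharply.  During
calibration a two-step chain proved structurally too shallow: its
occupancy curve runs nearly parallel (in the stress level) to the
autophagy-suppression threshold, so the commitment boundary is
hypersensitive to rate constants and intrinsic molecular noise at the
reference system size ($\Omega = 100$) smears the dose–response window
across several stress units.  With $n = 3$ the two curves cross
transversally: the window sharpens to well under one stress unit of blur,
while low stress levels stay cleanly autophagic.  We therefore ship
$n = 3$ as the calibrated default (the constructor accepts any
$n \ge 2$ as within the multistep regime, and $n = 1$ — with a warning —
as the graded, monostable control used in the bifurcation tests).

## Stress protocols

The stressor enters as a right-continuous piecewise-constant $S(t)$ in
minutes.  Three protocol constructors cover the study designs:
`constant_stress(S0, t_end)` (the 240-min reference treatment),
`washout(S0, t_washout, t_post)` (instantaneous removal — drug washout —
followed by 120 min of observation), and `modulate_autophagy(params,
kaau_p_new)` for pharmacological autophagy modulation.  Following the
simulation design rather than the bench protocol, modulation changes
`kaau_p` for the entire run instead of mimicking a 2-h pre-incubation:
`kaau_p = 0.2` stands for 3-MA-like inhibition, `0.7` for
metyrapone-like activation, against the calibrated baseline of `0.45`.

## Stochastic engine

Single cells are simulated with an exact Gillespie (direct-method) SSA.
Every additive rate term of the ODE maps to exactly one reaction channel
($4 + 2n$ channels); propensities are $\Omega$ times the concentration
rate law evaluated at `counts / Omega`, so the summed
stoichiometry-weighted propensities recover the deterministic
right-hand side identically — the test suite asserts this at randomly
drawn integer states, which pins the engine to the ODE core by
construction rather than by convention.  Conserved pools (inactive
sensor, inactive AUT, unmodified APO) are carried as exact integer
complements.  The piecewise-constant stressor is handled by truncating
the next-reaction time at protocol boundaries and re-evaluating
propensities there; this is exact for time-homogeneous propensities
within segments.

Randomness policy: every public stochastic operation takes one seed.
Ensembles spawn per-cell seeds from the master seed via R's own RNG
(`set.seed(master)` followed by `sample.int`), which is stable across
platforms for a fixed R version; identical master seeds give
bit-identical results, and the engine draws exclusively from R's RNG so
seeds set in R govern the C++ core too.

Noise sources: intrinsic (finite-copy-number) noise at $\Omega = 100$,
plus a per-cell, mean-one lognormal factor on the stressor level
(`sigma_S`, calibrated default 0.26) modelling extrinsic variability in
perceived stress strength.  Both are part of the calibrated noise model:
intrinsic noise alone produces commitment-time dispersion of only about
ten minutes at high stress, an order of magnitude short of the washout
commitment window, whereas cell-to-cell variability of the effective
stress dose — the natural reading of population heterogeneity in stress
experiments — supplies the remainder.  Set `sigma_S = 0` to isolate the
intrinsic engine; the law-of-large-numbers checks do so, since ensemble
means converge to the deterministic solution only when cells share the
same effective stress level.

## Calibration

No reference rate constants are available for this reduced network, so
the shipped defaults were fixed by `calibrate()` against behavioural
anchors: (a1) the deterministic apoptosis threshold at 240 min lies in
the window $3 < S^* < 5$; (a2) 240-min ensembles are not
apoptosis-majority at $S_0 \le 2$ and are apoptosis-majority at
$S_0 \ge 5$; (a3) washout of $S_0 = 10$ leaves little commitment at
15–30 min, a rising committed fraction through 30–90 min, and about 95%
apoptotic cells for washout at 105 min; (a4) at $S_0 = 5$ the autophagy
transient precedes apoptosis activation.  Stochastic anchors are
evaluated with fixed sub-seeds (common random numbers), making the
calibration objective deterministic and the whole search reproducible
under its master seed.  Hard anchors are marked by infinite weight and
dominate the penalty at a large finite factor; `calibrate()` reports
per-anchor residuals and flags failure rather than silently returning a
poor fit.  The result is written to
`inst/extdata/default_params.yaml` and mirrored by the `er_params()`
defaults; `calibrate()` remains available to re-derive or refine them.

Parameter roles and units (all rates per minute, concentrations
dimensionless with totals 1):

| group | parameters | role |
|---|---|---|
| sensor | `ka_e`, `ki_e` | stress-to-signal gain and relaxation (sets the $\sim$5–15 min sensor timescale and the saturation of $E^*(S)$) |
| autophagy | `kaau`, `kaau_p`, `kiau`, `kiau_p`, `J_aa`, `J_ia` | basal and stress-driven activation, basal and APO-driven inactivation, switch sharpness |
| apoptosis chain | `kaap`, `kiap`, `kiap_p`, `n_steps` | per-step (de)modification rates, antagonism from AUT, chain depth |
| feedback | `k_fb` | self-protection of the active form; sets the lifetime of the committed state after stress removal |
| noise | `Omega`, `sigma_S` | system size (intrinsic noise), optional extrinsic stress spread |

The small difference `kiau - kaau` (0.005–0.03 across calibrations) is
deliberate: it keeps the resting autophagy level below the
classification threshold while letting activated autophagy relax only
slowly after stress removal, so briefly stressed populations still score
autophagic 120 min after washout.

## Classification, thresholds, censoring

A cell is **apoptotic** when $P_{act}/P_T > 0.5$, else **autophagic**
when $A/A_T > 0.5$, else **neither**; apoptosis takes precedence,
reflecting the mutual exclusivity of the fates with death dominant.  The
0.5/0.5 convention is symmetric and parameter-free; both thresholds are
arguments everywhere.  Fates are read from the state at the evaluation
time (240 min for dose–response scans; washout time + 120 min for
washout scans), not from the trajectory history.  Apoptosis activation
times are first crossings of the apoptotic threshold; cells that never
cross within the horizon are censored at the horizon and flagged.

## Bifurcation characterisation

`apoptosis_threshold()` bisects the stress axis on the outcome of a
240-min integration from rest (default resolution 0.01 stress units).
`hysteresis_scan()` performs a quasi-static ramp: 500 min of dwell per
level (its fixed equilibration convention), carrying the end state of
each level into the next, upward from rest and then downward from the
committed death state.  Bistability is reported when the downward branch
stays apoptotic below the upward activation level `S_on`.  Because the
chain's forward rate is proportional to sensor activity, the only true
fixed point at $S = 0$ has an unmodified chain; "irreversibility" at
$S = 0$ is therefore operationalised as the committed state surviving
the full dwell at $S = 0$ — with the calibrated `k_fb` the death state's
decay time (thousands of minutes) far exceeds both the dwell and any
experimental observation window, which is the behaviour the washout
experiments probe.  We assert the behaviour, not a specific molecular
loop, mirroring the open mechanistic question.

## Synthetic observables

`markers_from_trajectory()` maps trajectories onto blot-style
densitometry: LC3II proportional to active AUT; p62 decaying with the
time-integral of AUT (a degradation readout — blots show slow p62 loss,
not an instantaneous inverse of autophagic activity); procaspase-3 as
the unactivated APO pool; cleaved PARP proportional to $P_{act}$;
multiplicative lognormal noise with configurable CV.  All
proportionality constants default to 1 and are configurable — the
quantitative link between lumped model activities and band intensities
is a modelling convenience, not a claim.  `apoptotic_index()` scores a
binomially drawn count of `n_counted` cells (default 1000) against the
ensemble's true apoptotic fraction, emulating microscopy counting noise.

What the synthetic data do *not* emulate: blot saturation and loading
artefacts, necrotic cells, cell division and death-driven attrition of
the counted population, and any stressor-specific pharmacokinetics (the
stressor is an abstract level $S$).  Tests passing on these synthetic
readouts validate the analysis plumbing, not the biology of any
particular stressor.

## Numerical choices

* Deterministic integration: `deSolve::lsoda`, `rtol = 1e-8`,
  `atol = 1e-10`, restarted at protocol boundaries; invariants (bounds,
  chain conservation) are checked at every output point and violations
  beyond `1e-6` raise instead of being clipped.
* Resting state: integration from zero activities at $S = 0$ until the
  maximum absolute derivative falls below `1e-9`/min.
* SSA: direct method with linear channel search (the network has at most
  a dozen channels); propensity totals above `1e12`/min abort with a
  state snapshot.
* Ties and degenerate inputs: zero total propensity freezes the state
  until the next protocol boundary; `S0 = 0` protocols are valid and
  yield resting behaviour; `Omega < 10` triggers a deep-noise warning.
* Problem sizes: the shipped analyses use 50 cells per condition (the
  reference population size); the test suite uses 5–50 cells per
  ensemble and system sizes up to $\Omega = 10^4$ for the
  law-of-large-numbers checks, sizes chosen to keep the default suite
  fast while leaving the Monte-Carlo error well inside the asserted
  margins.

## Known limitations

* The network is a minimal abstraction: no explicit UPR branches
  (IRE1/PERK/ATF6), no explicit Bcl2/Beclin-1 species — the crosstalk is
  absorbed into the antagonism and feedback terms.
* Calibration targets behavioural anchors, not measured rate constants;
  the defaults are one behaviourally equivalent point in a degenerate
  parameter set, with no claim of uniqueness.
* Committed-state persistence at $S = 0$ is metastable by construction
  (see above); analyses probing far longer horizons than the washout
  design would need an explicit maintenance loop.
* Autophagy modulation shifts the apoptosis threshold strictly and in the
  expected directions, but the inhibition shift (`kaau_p = 0.2`) is modest
  in this calibration: basal autophagy activation keeps AUT partly active
  at low stress, so weak stress does not become lethal under inhibition
  alone.  Reproducing a drastic inhibition shift would require near-zero
  basal autophagy, which conflicts with the resting-state and
  washout-relaxation behaviour.
* Ensemble means converge to the ODE solution with system size everywhere
  except near the sharp autophagy-collapse edge, where commit-time jitter
  (shrinking only as $1/\sqrt{\Omega}$) smears the mean; at
  $\Omega = 10^4$ a deviation of a few percent persists there by
  construction of the zero-order switch.
* The washout analysis scores fates at a fixed 120 min after removal;
  cells still in transit at that moment (chain partially modified,
  autophagy already suppressed) score "neither", which is why the
  committed fraction can saturate slightly below 1.
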