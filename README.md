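# lhbRDP

Analysis toolkit for rebound depolarizing potentials (RDPs) in lateral
habenular (LHb) neurons — the depolarizations that follow the offset of a
hyperpolarizing current step and that chronic social stress reshapes.
LHb neurons come in *short-RDP* (< 400 ms) and *long-RDP* (seconds-long
plateau) phenotypes; the long plateau is generated by cyclic
nucleotide-gated (CNG) channels in non-neuronal cells electrically coupled
to the neuron through gap junctions, and stress-susceptible mice lose
long-RDP neurons. The package is for electrophysiologists who want a
reusable, tested implementation of that analysis chain, plus a
conductance-based simulator that stands in for the recordings.

It provides:

* **`simulateCell` / `simulatePair`** — a two-compartment
  (neuron + glial) conductance model: Wang–Buzsaki spiking with
  adaptation, a T-type Ca²⁺ rebound trigger, an SK/Ca pool that shortens
  rebounds, an H (sag) current, and a slow CNG-like glial conductance fed
  through an ohmic gap junction that produces the seconds-long plateau.
  Named drug conditions (`applyDrug`: TTX, apamin, Z944/Ni²⁺,
  L-cis-diltiazem, carbenoxolone/MFA, BAPTA, 8-bromo-cGMP) map onto fixed
  parameter transformations.
* **Feature extraction** — zero-phase 10 Hz Bessel filtering
  (`lowpass10Hz`), RDP duration by ±10 mV threshold crossing
  (`measureRdpDuration`), spike detection, frequency / amplitude
  adaptation indices, maximum spike counts, sag ratio
  `(V_peak − V_steady)/V_peak`, passive properties, spontaneous
  silent/tonic/burst classification, rebound oscillation counts.
* **Classification** — a hand-rolled variational Bayesian Gaussian
  mixture (`fitVbgmm`, Dirichlet-distribution weight prior, k ≤ 10,
  10 restarts) on (RDP duration, adaptation index), data-driven threshold
  derivation (`deriveThresholds`), four-way subtype assignment
  (`assignSubtype`: short/long × HF/LF), and behavioural phenotyping of
  defeated mice (`phenotypeMouse`, with the 19-mouse social-avoidance
  cohort in `socialAvoidanceTable()`).
* **Cohort statistics** — two-sample Kolmogorov–Smirnov (`ksTwoSample`),
  chi-squared with adjusted standardized residual post-hoc
  (`chiSquaredResiduals`), correlations, paired/group tests with
  Holm–Šidák correction.
* **Coupling analysis** — Spearman synchrony of paired recordings
  (`synchrony`), rebound/hyperpolarization amplitude ratios, neurobiotin
  dye-coupling criteria (`dyePositive`) and summaries
  (`couplingSummary`), with reference tallies in `lhbReferenceTallies()`.
* **Pipeline** — `runPipeline` drives simulate → features → classify →
  statistics deterministically from a seeded config, writing CSV/JSON
  outputs with provenance.

## Worked example

```r
library(lhbRDP)

## a long-RDP neuron, -100 pA 1 s step, and its CNG-blocked counterpart
pr  <- stepProtocol(amp_pA = -100, t_total = 12)
ctl <- measureRdpDuration(simulateCell(modelParams("long_rdp"), pr), pr)
lcd <- measureRdpDuration(simulateCell(modelParams("long_rdp"), pr,
                                       drug = "lcd"), pr)
c(control_ms = ctl$rdp_ms, lcd_ms = lcd$rdp_ms)
#> control_ms      lcd_ms
#>    4143.10      243.25
```

Blocking the CNG conductance converts the seconds-long plateau
(4143 ms > 400 ms, the long/short boundary) into a short rebound (243 ms)
while the trigger amplitude barely changes — the package's reproduction of
the L-cis-diltiazem experiment. The same conversion follows from
gap-junction block, and `applyDrug(p, "z944")` abolishes the rebound
entirely.

```r
## behavioural phenotyping of the defeated cohort
tab <- socialAvoidanceTable()
table(phenotypeMouse(tab$interaction_time_s, tab$interaction_ratio))
#> intermediate    resilient  susceptible
#>            1            9            9
```

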