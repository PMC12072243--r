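---
title: "Modelling and classifying rebound depolarizing potentials in lateral habenular neurons"
author: "lhbRDP package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and classifying rebound depolarizing potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhbRDP)
```

## The scientific problem

Lateral habenular (LHb) neurons respond to the offset of a hyperpolarizing
current step with a rebound depolarizing potential (RDP). Two qualitatively
different RDP phenotypes occur: *short* RDPs that last a few hundred
milliseconds, and *long* RDPs whose depolarized plateau persists for
seconds. The balance between the two phenotypes shifts with chronic social
stress: stress-susceptible mice lose long-RDP neurons. Pharmacology ties
the short rebound to T-type voltage-dependent Ca^2+^ channels (abolished by
Z944 or high Ni^2+^, prolonged when SK channels are blocked by apamin) and
the long plateau to cyclic nucleotide-gated (CNG) channels that sit not in
the neuron itself but in electrically coupled non-neuronal cells: both the
CNG blocker L-cis-diltiazem and gap-junction blockers (carbenoxolone,
meclofenamic acid) convert long RDPs into short ones, and dye-coupling
shows LHb neurons connected to oligodendrocyte-lineage cells.

`lhbRDP` implements this analysis end to end: a conductance-based
two-compartment simulator standing in for the recordings, the current-clamp
feature extraction, variational Bayesian Gaussian mixture (VB-GMM)
classification of firing subtypes, the cohort statistics, the
paired-recording and dye-coupling quantification, and the behavioural
phenotyping of chronically defeated mice.

## The two-compartment model

No published set of kinetic equations exists for these cells, so the
simulator is the package's own minimal mechanism able to reproduce the
phenomenology above; its constants were chosen once, by hand, to satisfy
the pharmacological conversion table, and are all user-configurable through
`modelParams()`. A neuron (membrane potential $V_n$, capacitance 40 pF) is
coupled through an ohmic gap junction ($g_\mathrm{gap}$, 2.5 nS) to one
lumped non-neuronal ("glial") compartment ($V_g$, 25 pF, leak 18 nS,
resting near −81 mV, input resistance ~50 MΩ):

$$C_n \dot V_n = -I_\mathrm{leak} - I_\mathrm{Na} - I_\mathrm{K}
  - I_\mathrm{T} - I_\mathrm{SK} - I_\mathrm{adapt} - I_\mathrm{H}
  - g_\mathrm{gap}(V_n - V_g) + I_\mathrm{inj} + I_\mathrm{hold}$$

$$C_g \dot V_g = -I_\mathrm{leak,g} - I_\mathrm{T,g} - I_\mathrm{CNG}
  + g_\mathrm{gap}(V_n - V_g)$$

* **Spiking.** Wang–Buzsaki Na^+^/K^+^ kinetics (instantaneous Na
  activation, gate rate factor $\phi = 5$). Spike-frequency adaptation is a
  K^+^ current gated by a slow sigmoid of voltage
  ($\tau_a = 150$ ms), and amplitude adaptation comes from slow Na^+^
  inactivation ($\tau \approx 0.3$–0.8 s). The *HF-firing* preset keeps
  both weak; the *LF-firing* preset deepens the slow Na^+^ inactivation so
  firing collapses during a 1 s step (frequency adaptation index near 1).
* **Rebound trigger.** A T-type Ca^2+^ current
  $I_T = g_T m_\infty(V)^2 h (V - E_\mathrm{Ca})$ with sigmoidal
  activation ($V_{1/2} = -50$ mV) and slow inactivation
  ($V_{1/2} = -75$ mV, $\tau_h$ 65–465 ms, slower when hyperpolarized).
  Holding at −60 mV leaves a modest availability, so even a −10 pA step
  evokes a rebound, while a 1 s hyperpolarization de-inactivates the
  current fully — this is what makes the short-RDP duration almost
  independent of the step amplitude, as observed.
* **SK shortening.** A first-order Ca^2+^ pool integrates $I_T$
  ($\tau_\mathrm{Ca} = 40$ ms) and gates an SK K^+^ current through a Hill
  function (coefficient 4). The pool is sized so that resting Ca^2+^ sits
  far below the half-activation and SK engages only during the rebound,
  terminating it; apamin (or intracellular BAPTA, which decouples SK from
  Ca^2+^ while leaving the pool intact) therefore prolongs both phenotypes.
* **The long plateau.** The glial compartment of a long-RDP cell carries
  its own T-type conductance (activation $V_{1/2} = -67$ mV, inactivation
  $V_{1/2} = -82$ mV, mostly *available* at the glial resting potential)
  and a CNG-like conductance ($E_\mathrm{CNG} = 0$ mV) with a slow gate
  $\dot s = \alpha\,H(\bar V_g - \theta)\,(1-s) - \beta s$, where
  $\bar V_g$ is a 10 ms low-pass of the glial voltage (so 1–2 ms
  transmitted spikes cannot re-trigger the gate), $\theta = -24$ mV,
  $\alpha = 25\,\mathrm{s^{-1}}$ and $\beta = 0.55\,\mathrm{s^{-1}}$. The
  neuronal rebound transmitted through the gap junction ignites a glial
  T-spike; only that spike reaches $\theta$, charging $s$; the CNG current
  then holds both compartments depolarized while $s$ decays over seconds.
  Because the plateau itself stays below $\theta$, the gate cannot latch:
  every plateau terminates. 8-bromo-cGMP is modelled phenomenologically as
  a halved $\beta$ (prolonged plateau).
* **Sag.** A small H-current (1.5 nS; 6 nS in the `"sag"` preset) produces
  the depolarizing sag seen during hyperpolarizing steps. It also
  guarantees that the post-offset trajectory cannot be trapped in a
  hyperpolarized stable state, which would otherwise appear when the
  holding bias is negative.

The *short-RDP phenotype* is identical except that the glial T-type and
CNG conductances are zero, which is the model's expression of reduced
post-junctional CNG activity: CNG block and gap-junction block then change
its rebound by construction only through passive loading (< 15 %).

Where the rebound originates in coupled pairs is left open by the
recordings; the model exposes the placement of the T conductance
(`g_T`, `g_T_g`) as configuration rather than asserting it, and the
default long-RDP cell generates the plateau-triggering spike
post-junctionally.

### Drugs

`applyDrug()` maps each named condition to a fixed, documented parameter
transformation: TTX sets $g_\mathrm{Na} = 0$; apamin $g_\mathrm{SK} = 0$;
Z944 and 5 mM Ni^2+^ zero both T conductances; 0.5–1 mM Ni^2+^ scales
$g_\mathrm{CNG}$ to 20 % and the T conductances to 80 %;
L-cis-diltiazem $g_\mathrm{CNG} = 0$; carbenoxolone and meclofenamic acid
$g_\mathrm{gap} = 0$; BAPTA decouples SK from Ca^2+^; 8-bromo-cGMP halves
$\beta$.

### Numerics

Fixed-step 4th-order Runge–Kutta at $dt = 0.025$ ms (halving $dt$ changes
the measured RDP duration by well under 1 %), sampled to 20 kHz output.
Holding at −60 mV is a pre-computed constant bias current obtained from
the analytic steady state (gates at their voltage equilibria, the glial
rest from a one-dimensional root solve), followed by a short settling
integration — mirroring manual current-clamp holding rather than a voltage
clamp. Spontaneous-activity runs settle 3 s at the free resting state
first. Optional Ornstein–Uhlenbeck current noise ($\tau = 5$ ms,
independent streams into the two compartments) is generated by an internal
xorshift64* generator so that a given seed yields bitwise-identical traces
on any platform; noise-free runs consume no randomness. Integration aborts
with a diagnostic if $|V|$ exceeds 200 mV.

## Feature extraction

All features are deterministic functions of (trace, protocol):

* **Filtering.** A 4th-order Bessel low-pass with −3 dB at 10 Hz, applied
  forward–backward (zero phase, so crossing times that define durations are
  not displaced) as cascaded biquads after odd-reflection padding. The
  analog prototype is computed from the reverse Bessel polynomial and
  rescaled to its −3 dB point, then discretized by bilinear transform with
  prewarping.
* **RDP duration** (`measureRdpDuration`): baseline = mean filtered
  voltage over the 500 ms before step onset (the recordings report a
  "baseline membrane potential" without a window; 500 ms is this package's
  choice); duration = first upward crossing of baseline + 10 mV after the
  step offset to the next downward crossing, 0 if none, censored at the
  trace end if the plateau never returns (censored durations carry a flag
  and enter cumulative summaries at their censored value).
* **Spike detection** (`detectSpikes`): upward crossing of −20 mV, one
  event per suprathreshold excursion at the excursion peak, 2 ms
  refractory merge; amplitudes referenced to −60 mV. The detector is
  unspecified in the source protocol; these defaults are robust for a
  −60 mV hold and are configurable.
* **Adaptation indices**: frequency adaptation index
  $(f_\mathrm{init} - f_\mathrm{final})/f_\mathrm{init}$ with
  $f_\mathrm{init} = 1/\mathrm{ISI}_1$ and $f_\mathrm{final}$ = spike
  count in the final 200 ms of the step divided by 0.2 s (the literal
  count-based reading; an ISI-based alternative was considered and
  rejected for the default because the definition cites an *average
  frequency over a window*). Amplitude adaptation index $A_2/A_1$ from
  −60 mV. Both are flagged undefined below two spikes rather than
  returning silent NaNs.
* **Maximum spikes** over the 1 s, 20–100 pA step series; **sag ratio**
  $(V_\mathrm{peak} - V_\mathrm{steady})/V_\mathrm{peak}$ with the steady
  state the mean over the last 100 ms of the step; **passive properties**
  from a −10 pA step (steady state = last 100 ms).
* **Spontaneous activity** over ≥ 20 s at rest: below 0.2 Hz silent; a
  cell showing any group of ≥ 3 spikes with ISIs < 100 ms riding on a
  filtered depolarization ≥ 5 mV is burst (cells with both tonic and burst
  patterns count as burst); otherwise tonic. The burst definition is not
  stated by the source protocol and is this package's documented,
  configurable choice.

## Classification

The classifier works on (RDP duration, frequency adaptation index). A
variational Bayesian Gaussian mixture (mean-field, full covariance,
Dirichlet *distribution* prior over weights, at most 10 components, best
of 10 seeded k-means initialisations) infers the number of effective
components (posterior weight > 1 % of the data). Design choices the
source analysis leaves open, fixed here:

* **Feature scaling.** Durations span orders of magnitude, so the duration
  axis is transformed $\log_{10}(x+1)$ and both features are standardized
  before fitting (`log_rdp = TRUE` default); component means are reported
  in original units. The Wishart scale prior is the empirical covariance
  divided by the component budget, sizing the prior to one component's
  share of the variance.
* **Thresholds.** Effective component means are merged into low/high
  groups along each axis at the largest gap between means (the duration
  axis inspected on the log scale), and each threshold is the arithmetic
  midpoint of the two means flanking the gap — on data gapped around
  400 ms this reproduces a 400 ms-style boundary deterministically. With a
  single effective component the thresholds are flagged undefined.
* **Assignment.** Short-RDP iff duration strictly below the duration
  threshold; HF-firing iff the adaptation index is ≤ the index threshold
  (the boundary cell is long, and HF). Cells with an undefined index drop
  out of four-way tables but stay in two-way RDP tables.

Behavioural phenotyping (`phenotypeMouse`) applies the stated criteria —
susceptible iff interaction ratio < 1 *and* interaction time < 40 s, else
resilient iff ratio > 1 *or* time > 60 s, else intermediate — and
reproduces all 19 printed labels of the social-avoidance cohort shipped in
`socialAvoidanceTable()`.

## Cohort statistics

`ksTwoSample` computes the exact two-sample Kolmogorov–Smirnov p-value
(network algorithm, ties respected) when $nm \le 10^4$ and the asymptotic
Kolmogorov series otherwise. `chiSquaredResiduals` runs the Pearson test
without continuity correction (a flag enables it) and the per-cell
post-hoc as adjusted standardized residuals
$r_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}(1-R_i/N)(1-C_j/N)}$ with raw
two-sided normal p-values (optional Holm adjustment), flagging increased
and decreased cells at $\alpha = 0.05$. The residual-analysis variant used
on the original tables is not printed there; this package's choice
reproduces the qualitative increase/decrease calls but printed per-cell
p-values are not guaranteed to match. Correlations and paired/group tests
wrap the standard R machinery, two-sided throughout, with a hand-rolled
Holm–Šidák step-down for post-hoc families. Cells are the unit of
analysis, as in the source design: no per-mouse random effects are
modelled, a known limitation.

## Coupling analysis

`synchrony` low-pass filters both traces of a pair and takes the Spearman
correlation from step onset to 3 s after offset; the coupling flag
defaults to $\rho > 0.5$. Neither the analysis window nor the flag
threshold is stated by the source analysis (it reports the $\rho$
distribution only); both are configuration with these defaults.
`dyePositive` applies the intensity criteria with strict inequalities
exactly as worded (NB-positive above surround mean + 2 SD, Alexa-negative
below surround mean + 0.5 SD, double-positives excluded), and
`couplingSummary` aggregates per-recording counts, incidence, marker
fractions and a Mann–Whitney comparison between conditions. Image
segmentation is out of scope: the module consumes tabular ROI statistics.

## The synthetic cohort generator

`makeCohort` draws per-cell phenotypes as Bernoulli variables
(`p_long`, `p_hf`) from a seeded stream and jitters conductances
lognormally around the presets: the excitability conductances
($g_T$, $g_\mathrm{SK}$, $g_\mathrm{Na}$, $g_\mathrm{adapt}$, leak) take
the full `jitter_sd` (default 0.1) while the coupling/plateau machinery
($g_{T,g}$, $g_\mathrm{CNG}$, $g_\mathrm{gap}$) varies at half that
spread — the labelled phenotype must be realized reliably (the plateau
survives ±15 % single-parameter perturbations) while plateau durations
still range over roughly 3–5 s. What the generator emulates: step-evoked
rebound phenomenology and its pharmacology, firing-type diversity,
spontaneous silent/tonic/burst regimes, and coupled-pair recordings with
small synchronized post-junctional signals. What it does not: morphology,
synaptic input statistics, electrode/series-resistance artefacts,
per-animal clustering of cell properties, and any fitted correspondence to
individual recorded neurons — passing recovery tests on these cohorts
demonstrates the pipeline's internal consistency, not agreement with any
particular recording.

Problem sizes used by the shipped checks (three cohorts of 50 cells,
twenty clustering seeds, 1000-replicate calibration loops) were chosen as
the smallest sizes at which the binomial recovery bands and calibration
intervals are meaningful.

## Known limitations

* The kinetic constants are plausible-by-construction, not fitted; only
  the qualitative pharmacological conversion table is constrained.
* The long-RDP plateau duration distribution is narrower than in real
  cohorts, and censoring (plateaus outliving the 10 s observation window)
  can occur under SK block or 8-bromo-cGMP.
* The glial compartment is a single lumped cell; syncytial spread,
  K^+^ buffering and second-messenger diffusion through junctions are not
  modelled (8-bromo-cGMP acts only through $\beta$).
* Spontaneous burst statistics are noise-driven and tuned for class
  separability rather than matched to recorded inter-burst distributions.
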