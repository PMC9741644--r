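---
title: "Methods: models, scoring rules and design choices in modeswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, scoring rules and design choices in modeswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modeswitch)
```

## The scientific problem

Small multidrug resistance (SMR) efflux pumps such as EmrE normally couple
downhill proton import to toxin export (antiport), conferring drug
resistance.  The same protein can in principle also run proton/drug symport,
drug uniport, or drug-gated proton uniport -- modes that poison the cell by
importing the toxin or by dissipating the transmembrane pH gradient.
`modeswitch` implements the computational chain for finding small molecules
that flip a pump from resistance into one of these susceptibility modes and
for identifying which mode is engaged:

1. differential phenotype-microarray scoring of strains expressing functional
   (WT) versus transport-dead (E14Q) transporter;
2. quadratic ligand-depletion fits of fluorescence-quench binding titrations;
3. solid-supported-membrane electrophysiology (SSME) charge analysis and
   transport-mode classification;
4. dose-response IC50 comparison and checkerboard MIC/FIC synergy analysis.

Every stage has a synthetic generator with planted ground truth, so the whole
chain is testable at desk scale without instrument data.

## Differential screen scoring

Each compound occupies four wells per plate set (one per concentration rank),
in two replicate plate sets.  For each well the kinetic respiration curve of
each strain is reduced to its area: a trapezoidal integral after subtracting
the t = 0 signal, which makes the statistic invariant to constant signal
offsets (the integrator and baseline convention are our choices; any
saturating-curve integrator gives equivalent differentials).  The well
differential is

$$\Delta = \mathrm{Area}_{WT} - \mathrm{Area}_{E14Q},$$

computed per replicate.  Within each replicate we take the 10% trimmed mean
of all well differentials (`floor(0.10 n)` values cut from *each* tail; the
total-versus-per-tail convention is exposed as `trim_fraction`) and the
standard deviation over non-hit wells -- at least 50 of them, supplied as a
known control list when available (the authoritative path), otherwise
auto-selected as the wells closest to the trimmed mean.  Central
auto-selection shrinks the SD estimate when the pool barely exceeds the
minimum, which is why supplied controls take precedence.  A well scores +1
(resistance) when its differential exceeds the trimmed mean by strictly more
than 2 SD, -1 below, else 0; the eight calls sum to a compound score in
[-8, +8], classified at the |score| >= 3 cutoff.  Chance calls at the 2-SD
level make |scores| of 1-2 common on null compounds, which is exactly why the
classification cutoff sits at 3.

The synthetic plate generator uses a Gompertz curve in instrument-like
arbitrary units (the exact saturating shape is irrelevant to the
differential), multiplicative Gaussian noise per timepoint plus a lognormal
per-well amplitude jitter at the preset's `noise_cv` (default 0.02), and
plants effects by scaling the affected strain's amplitude.  A resistance
effect raises the WT amplitude in affected wells; a susceptibility effect
symmetrically raises E14Q.  `wells_affected` (out of 8) emulates compounds
whose lower concentration ranks elicit no phenotype; the packaged
methyl-viologen-like preset affects all 8 wells (score +8) and the
harmane-like preset 6 (score -6).

## Ligand-depletion binding isotherm

At the assay's 10 uM transporter-dimer concentration the free-ligand
approximation fails, so occupancy uses the exact quadratic root of the
mass-action equilibrium:

$$[EH] = \tfrac{1}{2}\Big((E_T + H_{add} + K_d) -
  \sqrt{(E_T + H_{add} + K_d)^2 - 4\,E_T H_{add}}\Big),$$

with the discriminant clamped at zero against round-off.  Observed
fluorescence mixes the bound and free coefficients by *fractional* occupancy,
$F = F_{EH} f + F_E (1 - f)$: expressing the free-species term as a
concentration rather than a fraction would be dimensionally inconsistent with
fluorescence-unit coefficients, so the fractional form is used and documented
here.  Fitting is unweighted nonlinear least squares with data-driven
initialisation ($F_E$ from the lowest-ligand point, $F_{EH}$ from the
highest, $K_d$ from the half-quench concentration).  The packaged harmane
preset uses Kd = 29 uM, a 12-point grid to 800 uM and 1% Gaussian noise; at
the assay's triplicate design the median Kd recovery error at 2% noise is
under 5%.

## SSME simulator: a thermodynamic-relaxation model

The instrument literature gives only qualitative expected signal patterns per
transport mode, so the simulator is the minimal quantitative model that
reproduces all of them: the total transported charge is

$$Q_{ss} = \kappa \; q_{net} \; D \; g + Q_{leak},$$

* $q_{net}$: net inward elementary charge per cycle from stoichiometry
  ($n_H - n_D z_D$ for antiport, $n_H + n_D z_D$ for symport, $n_D z_D$ for
  drug uniport, $n_H$ for proton uniport);
* $D$: log-gradient thermodynamic drive restricted to the transported
  species, $n_H \ln([H^+]_{out}/[H^+]_{in}) \pm n_D
  \ln([drug]_{out}/[drug]_{in})$, with the proton ratio computed as
  $10^{pH_{in} - pH_{out}}$ (the pH 7.0/7.3 pair gives 1.995, reported as
  2-fold);
* $g$: drug-gating occupancy $d/(K_m^{gate} + d)$ for proton uniport, 1
  otherwise;
* $Q_{leak} = leak_0 \ln([H^+]_{out}/[H^+]_{in})$: a small drug-independent
  proton background present in every mode, including the transport-dead
  control.

The current relaxes as a single exponential, $I(t) = (Q_{ss}/\tau)
e^{-t/\tau}$, during the external-buffer phase of the three-stage
acquisition, on top of a constant sensor offset and Gaussian sampling noise.
Deliberately out of scope: microscopic eight-state kinetics (no rate
constants are available), membrane-potential feedback, and liposome
size/orientation heterogeneity -- the model is thermodynamic, so simulated
magnitudes are meaningful only relative to one another.

**Gating side.** The gating occupancy uses the *higher* of the internal and
external drug concentrations by default (`gating_side = "max"`, with `"min"`
available).  The choice matters: under the assay's 8/0.5 uM gradient pairs
with a 5 uM gating constant, min-side gating would make the no-gradient
signal 6.8-fold larger than the gradient signals, whereas the observed
hallmark of drug-gated proton leak is a signal *independent* of the drug
gradient.  Max-side gating (drug on either face can open the pore)
reproduces that invariance exactly; it is the package's design choice and is
what the classifier's equality test expects.

**Harmane's charge.** The harmane-like presets set $z_D = 0$ (neutral under
assay conditions, configurable), so any measured charge is proton movement; a
neutral uniported substrate is correctly electrically silent.

## Charge integration and mode classification

Measured traces are reduced by subtracting the mean current over the final
100 ms of the first internal phase and trapezoidally integrating the external
phase (nA x s = nC), with no resampling or filtering.  Classification uses
the drug-induced charges $\Delta Q_c = Q_c - Q_{no\,drug}$ across the three
drug conditions:

| pattern on (no-gradient, against, with) | call |
|---|---|
| none significant | inactive |
| (+, +, -) | antiport |
| (+, -, +) | symport |
| (0, -z, +z), needs $z_D \neq 0$ | drug uniport |
| all +, pairwise equal within 20% | proton uniport |
| anything else | ambiguous |

Significance is $|\Delta Q| > k_{sig} \cdot \max(\hat\sigma, q_{floor})$ with
$k_{sig} = 3$.  Two numerical choices here are ours, made because three
sensors give a very unstable SD estimate: $\hat\sigma$ pools the replicate
SDs over all four conditions (the noise is condition-independent sensor
noise), and $q_{floor}$ (default 0.01 nC) is an absolute charge-resolution
floor that keeps a truly inactive transporter from being flagged by a
fluke-small SD estimate.  Both are config-exposed.  The 20% equality
tolerance for the proton-uniport test matches the replicate scatter typical
of multi-sensor charge measurements.  At default noise the decision margins
are order-of-magnitude wide, which is why mode recovery over 5 modes x 50
seeds is confusion-free; at very low signal-to-noise, calls collapse to
inactive/ambiguous rather than to a wrong active mode.

Note that negating every trace (flipping electrode polarity) does not map an
antiporter onto a symporter: the sign patterns above are anchored to the
inward-positive convention, and a negated antiport pattern is reported
`ambiguous` rather than misassigned.

Gating kinetics are fit as $v = I_{max} c / (K_m + c)$ to baseline-subtracted
peak currents (the saturation analysis uses the no-gradient condition with a
no-drug control subtracted, removing the background leak offset).

## Dose-response and checkerboard analysis

Relative growth divides each replicate's endpoint OD600 by its own zero-drug
well.  IC50 fits use $g(c) = top / (1 + (c/\mathrm{ic50})^{hill})$ with the
floor fixed at 0 and $top \le 1.2$ -- on the relative-growth scale a zero
floor is the natural parameterisation of a "simple sigmoid".  Strain
comparison reports $100 (\mathrm{IC50}_{E14Q} -
\mathrm{IC50}_{WT})/\mathrm{IC50}_{E14Q}$ and flags no-difference when the
fit CIs overlap (the bicarbonate-co-treatment scenario).

The MIC is the smallest tested concentration with growth at most 10% of
background *sustained at every higher tested concentration* -- the
sustained-inhibition clause operationalises "inhibits all growth" on noisy
plates where a single well can dip by chance.  Censored MICs ("> max
tested") propagate as explicit censored values and poison FIC computation
with a clear error rather than a number.

FIC analysis finds the growth/no-growth interface: inhibited combination
wells (both drugs > 0) adjacent, at the next lower concentration of either
drug, to a growing well.  Each contributes
$\mathrm{FIC} = c_A/\mathrm{MIC}_A + c_B/\mathrm{MIC}_B$; the mean over
interface wells is the reported index, classified as synergistic (< 0.5),
indifferent ([0.5, 1), boundary inclusive) or antagonistic (>= 1).  Axis
wells are excluded from the interface: wells at zero partner drug sit at
FIC ~ 1 by identity and would swamp the mean; full precision is kept
internally and rounding happens only in display.

The checkerboard generator plants growth as a sharp sigmoid (Hill 12) in the
combined Loewe-style dose index $a + b + \alpha a b$, with $a, b$ in units of
each drug's true MIC and multiplicative OD noise (CV 3%, triplicate).  The
two packaged presets were calibrated once, on the noiseless surface, so that
the FIC analysis of the planted interface reproduces the reported
experimental indices: kanamycin x harmane ($\alpha = 20$, analysed mean FIC
0.372, synergistic -- stable to the third decimal across 200 noise seeds
because the 2-fold grids quantise the interface) and tetracycline x harmane
($\alpha = 16$ with the partner MIC at the top of the grid, mean FIC 0.577
+/- 0.006, indifferent).  The antagonist preset uses $\alpha = -0.9$
(FIC ~ 1.27).  Note a purely additive surface ($\alpha = 0$) reads as
FIC ~ 0.8--1.1 on 2-fold grids -- the discreteness of serial dilution biases
FIC upward, which is why "indifference" in practice corresponds to mild
positive $\alpha$.

The growth generator is a two-phase logistic: normal growth to the onset time
(default 5 h, when fermentable carbon runs out and the proton motive force
becomes limiting), then relaxation toward a drug-limited carrying capacity
$K \cdot \mathrm{inh}(c)$, read out at 18 h.  The endpoint therefore tracks
the planted inhibition curve and the refit recovers the planted IC50s; the
packaged harmane preset plants IC50s of 78 uM (WT) versus 130 uM (E14Q), a
40% reduction, recovered to within ~2 percentage points at the default 2%
OD noise (triplicate).

## Determinism and problem sizes

Every generator routes randomness through one seeded, restorable RNG scope;
identical seed means bit-identical output, and replicate/sensor/stage streams
are derived from a master seed by deterministic 31-bit mixing
(`derive_seed()`).  Test-suite problem sizes are chosen for desk-scale runs:
13-25 timepoint respiration curves (the AUC differential is insensitive to
grid density), 2 s SSME traces at 5 ms sampling, 50-seed classifier sweeps,
100-seed checkerboard round-trips, 200-seed titration recovery.

## What the synthetic data do not emulate

Plate-position and edge effects, day effects beyond the replicate split,
redox-dye chemistry, inner-filter and photobleaching corrections in the
fluorescence assay, capacitive artifacts and sensor drift in SSME, and
inoculum effects in the growth assays.  Passing tests demonstrate that the
analysis recovers planted truth under the stated noise models -- they are
evidence of correct implementation, not of robustness to every artifact of
real instrument data.  Multi-site binding, Bliss/Loewe response-surface
synergy modelling, and MIC interpolation between tested concentrations are
deliberately out of scope.
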