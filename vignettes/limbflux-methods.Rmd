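---
title: "Models and methods behind limbflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind limbflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbflux)
```

# Scope

limbflux implements the quantitative chain of a limb-immobilization
tracer-physiology study: brachial-artery blood flow from Doppler
ultrasound, arteriovenous (AV) forearm balance with two-pool
stable-isotope dilution kinetics, glucose disposal rate (GDR) from a
hyperinsulinaemic–euglycaemic clamp, deuterated-water fractional synthesis
rates (FSR), accelerator-mass-spectrometry (AMS) carbon-14 quantification,
and small deterministic phenotype reducers (grip strength, myofibre
cross-sectional area). Because raw subject- and animal-level data for such
studies are rarely deposited, every estimator ships with a forward
simulator of its measurement process, so the whole chain can be validated
against known truth at desk scale. Inferential statistics
(repeated-measures ANOVA and the like) are deliberately out of scope; the
pipeline emits tidy tables any statistics package can consume.

# Hemodynamics

A pulsed-wave Doppler trace is reduced to the time-averaged mean velocity
(TAMV) by trapezoidal integration of the instantaneous velocity over the
acquisition, divided by its duration. Retrograde (negative) velocities are
retained: the full signal is integrated, not its envelope. Volumetric flow
follows from the lumen diameter $d$ (duplicate acquisitions averaged
arithmetically before use):

$$Q = \mathrm{TAMV} \cdot \pi \left(\tfrac{d}{2}\right)^2 \cdot 60
\quad [\mathrm{mL\,min^{-1}}], \qquad
f = \frac{Q}{V_\mathrm{limb}} \times 100
\quad [\mathrm{mL\,min^{-1}\,(100\,mL)^{-1}}].$$

Limb volume is an explicit input (default 1000 mL for the packaged
simulations) because balance methods report exchange per 100 mL of limb
while the volume measurement itself is rig-specific; it is a parameter,
never a guess. Scans covering fewer than 8 cardiac cycles are flagged
`insufficient_cycles` and excluded unless overridden. No cardiac-cycle
gating beyond that acceptance rule is applied.

# Arteriovenous balance and two-pool kinetics

For a substrate with arterialized and deep-venous concentrations $C_a$,
$C_v$ (µmol/L, i.e. nmol/mL) and flow $f$:

$$NB = (C_a - C_v)\, f.$$

Positive values are net uptake by the forearm. Glucose uses the same form
with mmol/L inputs; since 1 mmol/L = 1 µmol/mL, the product with flow is
already in µmol·min⁻¹·100 mL⁻¹ and no further factor is applied.

Tracer enrichments are represented as tracer-to-tracee ratios (TTR), with
concentrations tracee-only; mole-percent-excess inputs should be converted
at the I/O boundary. At isotopic steady state, the two-pool model over the
limb bed gives

$$R_d = \left(C_a - C_v \frac{E_v}{E_a}\right) f, \qquad
R_a = R_d - NB.$$

$R_d$ (rate of disappearance) estimates tissue uptake; $R_a$ (rate of
appearance) estimates unlabelled efflux that dilutes venous enrichment.
Two consequences are used as exact tests: $NB = R_d - R_a$ by
construction, and $E_v = E_a$ (no venous dilution) forces $R_a = 0$. The
factored form above makes the second identity exact in floating point.
Note the direction of the enrichment effect: raising $E_v$ with everything
else fixed lowers both $R_d$ and $R_a$ (less dilution means less inferred
efflux), with $NB$ unaffected.

Steady-state windows are summarized per-sample-then-average: each of the
(typically five) paired samples is converted to $(NB, R_d, R_a)$ using the
window-mean flow, and the window statistic is the arithmetic mean with its
standard error. The alternative (average the concentrations and
enrichments first) is available via `estimator = "mean_first"`; the two
agree exactly in the noise-free case, and the default makes the
per-sample dispersion visible. Whole-blood flow is used unmodified for
both glucose and amino-acid balances; no plasma-flow haematocrit
correction is applied (an explicit choice matching bedside practice for
this protocol — the correction can be made upstream by supplying plasma
flow).

# Clamp protocol and the virtual subject

Dosing plans convert the per-kg / per-m² protocol rates into absolute pump
rates: a primed insulin sequence (128.2, then 71.8 mU·m⁻²·min⁻¹ in the
first two 5-min intervals, 50 mU·m⁻²·min⁻¹ thereafter), a primed
(0.5 mg/kg) continuous (0.5 mg/kg/h) phenylalanine tracer (the prime is
book-kept as an impulse at $t=0$; no compartmental prime modelling), a
primed (0.46 mL/kg) continuous (1.38 mL/kg/h) 10% amino-acid mixture, and
potassium chloride at 1 mL·kg⁻¹·h⁻¹. The 20% dextrose line is
controller-set.

GDR is the steady-state mean of the converted glucose infusion rate,

$$\mathrm{GIR} = \frac{\mathrm{rate}_{\mathrm{mL/h}} \times 0.2\,
\mathrm{g/mL} \times 1000}{60 \times \mathrm{mass}_{\mathrm{kg}}}
\quad [\mathrm{mg\,kg^{-1}\,min^{-1}}],$$

over the final 30 min by default. No glucose-space or urinary-loss
correction is applied — the convention is steady-state mean infusion.

The virtual clamp subject is a single well-mixed glucose pool integrated
with the Euler method at 1-min steps,

$$\frac{dG}{dt} = \frac{EGP + \mathrm{GIR} - D(G)}{V \cdot 180.156},
\qquad D(G) = D_{\mathrm{true}} \frac{G}{5.0},$$

with $V$ the glucose distribution volume (default 0.16 L/kg) and 180.156
mg/mmol the molar mass of glucose. A proportional–integral controller
updates the pump every 5 min toward the 5.0 mmol/L target, mirroring
bedside titration. Default gains ($k_p = 2.5$ mg·kg⁻¹·min⁻¹ per mmol/L,
$k_i = 0.18$ per mmol/L·min) settle a noise-free run well before minute
120 over the disposal range 2–12 mg·kg⁻¹·min⁻¹; they are arguments, not
constants. Endogenous glucose production defaults to 0 — fully suppressed
under clamp insulin — so the steady-state infusion rate identifies
$D_{\mathrm{true}}$; with $EGP > 0$ the estimator returns
$D_{\mathrm{true}} - EGP$, which is the quantity the infusion actually
replaces. Measurement noise perturbs only the glucose readings the
controller and log see, never the true state, and all noise flows from a
single seed. The run aborts with a diagnostic if glucose leaves
[2, 10] mmol/L. Cumulative bookkeeping makes the pool's mass balance an
exact invariant of the integration and it is asserted to 10⁻⁶ relative.

# Isotope turnover

**D₂O FSR.** Deuterated water equilibrates with body water; free alanine
picks up deuterium at a known hydrogen-exchange stoichiometry and carries
it into newly synthesized protein. The cumulative fraction of the protein
pool renewed over the labelling period is

$$FSR_{\mathrm{cum}} = \frac{E_{\mathrm{alanine}}}
{E_{\mathrm{body\,water}} \times F} \times 100\%,$$

with exchange factor $F = 3.7$ by default — the standard value for
alanine in this method, kept configurable because contract laboratories
differ in their precursor correction and the factor is rarely printed.
Samples whose product enrichment exceeds the precursor-equivalent are
flagged `super_precursor` and reported with a warning rather than
silently dropped. The result is invariant to the common unit of the two
enrichments.

**AMS ¹⁴C.** A ¹⁴C/¹²C isotope ratio is converted to absolute ¹⁴C via the
sample's carbon content: mol ¹²C = dry mass × carbon fraction / 12 g/mol,
total ¹⁴C = ratio × mol ¹²C, reported both as a total (extensive) and per
mg dry tissue (intensive). Dry masses outside the 3–8 mg protocol window
are flagged, not rejected. Urinary activity series are normalized per
animal to Day 0 = 100% exactly; animals with missing or non-positive
Day-0 readings are excluded with a reason, and the operation is
idempotent.

**Coupling.** In a pre-labelled animal, faster protein turnover both
raises the D₂O FSR and washes out retained ¹⁴C label, so across
animal × limb pairs the two endpoints should correlate negatively. The
package reports the signed Spearman coefficient (magnitude-only quoting
of correlations is a presentation convention, not a computation rule).
Only the sign and monotone structure of this coupling are asserted in
validation — rate constants of label washout are not modelled beyond the
generator's latent construction.

# Phenotyping reducers

Grip strength: of exactly five trials, one instance of the maximum and
one of the minimum are removed (stable semantics under tied extremes) and
the remaining three are averaged; the score is order-invariant and
bracketed by the 2nd order statistics. Myofibre CSA: half-open,
lower-inclusive 500 µm² bins, so a printed label like "500–999" means
[500, 1000) for fractional areas too; proportions are per fibre type and
sum to one within type; types with fewer than 35 fibres are flagged out
of the distributional output.

# The synthetic-data generators

The generators define the study conditions the validation suite runs
under; they are calibration inputs, not reproduction claims.

**Virtual forearm.** The two-pool equations are inverted: given true
$(f, C_a, E_a, R_d, R_a)$, the implied venous state is
$C_v = C_a - NB/f$ and $E_v = E_a (C_a f - R_d)/(C_v f)$; unphysical
implied states (non-positive $C_v$, $E_v \notin (0, E_a]$) are rejected
with the violated bound. Noise is multiplicative mean-one log-normal per
channel (concentration, enrichment, flow), independent across channels —
the simplest model consistent with assay CVs. Concentrations driven
non-positive are floored at 10⁻⁶ and flagged. The packaged study
conditions use arterialized phenylalanine ≈ 42 µmol/L postabsorptive and
≈ 91 µmol/L under the clamp, with CVs of 2% (concentration), 1.5%
(enrichment) and 8% (flow), and five paired samples per steady-state
window.

**Virtual clamp subject.** Delegated to the clamp module (above); the
packaged subjects carry disposal truths of 8.4 and 10.3 mg·kg⁻¹·min⁻¹,
spanning the range group means for such clamps typically occupy.

**Mouse cohort.** Three groups of 15 (healthy reference; caloric
restriction + unilateral immobilization; the same + salbutamol), two
limbs where applicable. Group × limb means are a healthy baseline times
cell multipliers; the shipped multipliers encode, per endpoint: −23%
(quadriceps) and −26% (gastrocnemius) caloric-restriction atrophy, an
additional −17%/−10% from immobilization, +9%/+10% salbutamol hypertrophy
in the mobile limb only; FSR at 46%/37% of healthy (mobile/immobilized)
with +27%/+146% salbutamol rescue; ¹⁴C/¹²C at +11%/+9% with −5%/−13%
under salbutamol; grip at −27%. The healthy cumulative FSR baseline is
set to 7% over the 13-day label window: it makes the multiplier table
internally consistent with an absolute salbutamol FSR effect of
≈ +0.87 percentage points in the mobile limb
(7 × 0.46 × 0.27 ≈ 0.87), which is the magnitude such studies report.
Remaining baselines (200/150 mg muscle masses, 5 × 10⁻¹² ¹⁴C/¹²C after
chow pre-loading, 1.9 N four-limb grip, 1400/1600 µm² type-I/II CSA with
0.35 log-scale spread, 40/60 type-I/II proportions) are typical values
for adult male C57BL/6J mice. Between-animal CVs (8% muscle mass, ~19%
FSR, ~6% ¹⁴C ratio, 10% grip) are chosen so simulated group SEMs sit in
the range such cohorts print; they are assumptions, documented here once.

FSR and the ¹⁴C ratio share a per-animal-limb standard-normal turnover
latent $z$: FSR is multiplied by $e^{\sigma_f z - \sigma_f^2/2}$ and the
ratio by $e^{-\sigma_r z - \sigma_r^2/2}$ (both mean-one), plus
independent channel noise, so the negative correlation is built in;
urinary excretion after Day 0 scales with the group excretion multiplier
and $e^{\sigma_u \bar z}$, so higher-turnover animals excrete more label.
D₂O enrichments are emitted by inverting the FSR formula, so the
estimator recovers each animal's simulated FSR exactly — the noise lives
on the biology, not on a second measurement layer, which keeps the
round-trip testable.

All randomness descends from one integer seed through a labelled
splitting scheme (FNV-1a hash of "label:seed", reduced modulo 2³¹−1), so
adding a channel never perturbs existing draws and every artefact is
byte-reproducible per seed.

# Pipeline and numerical choices

`run_full_pipeline()` executes flow → balance/kinetics → GDR → FSR/AMS →
urine → phenotyping → contrasts, writing one tidy CSV per stage plus
`run_log.yaml` carrying the seed and an FNV-1a fingerprint of the
analysis-relevant config (the output directory is excluded from both, so
outputs are byte-identical wherever they are written; the log carries no
timestamps for the same reason). Any missing or invalid input aborts with
the stage name. Doppler timepoints at or before minute 0 are assigned to
the postabsorptive phase, later ones to the clamp phase.

Percent change uses the absolute-denominator convention
$(post - pre)/|pre| \times 100$, labelled as such: it preserves the sign
of the change for negative baselines (net-release balances), where the
plain convention would flip it. Group contrasts are descriptive
(difference and ratio of cell means with SEs); cells with fewer than two
units yield missing contrasts rather than point estimates.

Validation problem sizes, chosen to give tight Monte-Carlo error at
interactive runtimes: 10⁵ random parameter sets for the two-pool
identities, a 6-point disposal grid for the clamp loop, 500 virtual
subjects for noisy recovery, and 200 cohort replicates at n = 15/group
for effect-multiplier recovery (each checked against 3 standard errors of
its replicate mean) and the correlation-sign rate.

# Limitations

The forearm model is two-pool: intracellular kinetics (synthesis and
breakdown separately) require a third, biopsy-derived pool and are out of
scope. The clamp simulator has no insulin pharmacokinetics and its
proportionality of disposal to glycaemia is a local linearization, not a
minimal model. The generators draw independent animals with log-normal
channel noise — no litter effects, no heteroscedasticity beyond the
multiplicative structure, no missingness mechanisms — so passing
validation demonstrates estimator correctness under these stated
conditions, not robustness to every pathology of real data. AMS
instrument calibration, mass-isotopomer modelling and image segmentation
of stained sections are out of scope; the package consumes reduced
per-sample and per-fibre tables.
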