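---
title: "Methods: pore characterization, removal kinetics and activation thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore characterization, removal kinetics and activation thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsorbkit)
```

adsorbkit quantifies how well porous polystyrene-divinylbenzene (PS-DVB)
adsorbents, used in extracorporeal blood purification, can capture
inflammatory cytokines. Three questions drive the design: which molecules can
physically reach the adsorbing inner surface (pore accessibility), how fast
the accessible molecules are depleted from recirculating plasma (removal
kinetics), and how far cytokine levels must fall before endothelial cells
stop responding (activation thresholds). This vignette describes the models
behind each stage, the parameters that matter, and the choices made where the
design was genuinely open.

## Inverse size-exclusion chromatography

In inverse SEC the roles of column and analyte are swapped: solutes of known
size (polystyrene standards plus a toluene tracer) probe the pore structure
of the packed adsorbent. For a probe with retention volume $V_R$ on a column
with interparticle void volume $V_0$ (elution volume of a fully excluded
probe) and total mobile-phase volume $V_T$ (elution volume of the tracer),
the distribution coefficient is

$$K_d = \frac{V_R - V_0}{V_T - V_0},$$

the fraction of the intraparticle mobile-phase volume the probe can access:
0 = fully excluded, 1 = fully permeating. `compute_kd()` returns the raw
value; `isec_profile()` clamps small excursions outside $[0, 1]$ (up to
`kd_tolerance`, default 0.05) with a warning, keeps the raw values alongside,
and rejects larger excursions as evidence of misassigned volume anchors. The
tolerance is an explicit argument because its correct value tracks the
measurement noise: with retention-volume noise of 2 % of $V_T - V_0$,
fully-excluded probes routinely produce raw $K_d$ near $\pm 0.05$, and a
pipeline consuming such data should widen the tolerance rather than fail.

### Stokes calibration

Probe size is expressed as the Stokes (viscosity) radius. Polystyrene coils
follow a power law $R_S = a\,M^b$; `fit_stokes_calibration()` estimates $a$
and $b$ by least squares in log-log space and reports the log-log $R^2$.
On the bundled standards the fit gives $R_S \approx 0.0122\,M^{0.588}$ nm
with $R^2 > 0.9999$, and every leave-one-out prediction lands within 0.7 %
of the recorded radius.

The toluene tracer (92 Da) is deliberately excluded from the default
calibration set (`read_standards()` separates `role = "tracer"` rows): it is
a small rigid molecule, not a polymer coil, and keeping it in the fit bends
the low-mass end of the power law enough to push leave-one-out errors of the
smallest polystyrene standards past 1 %.

### Accessible pore size

Exclusion is gradual, so "the" accessible pore size needs a convention. A
probe counts as able to pass the outer pore shell and reach the inner
adsorbing surface while $K_d \ge 0.1$; a value exactly at the threshold
counts as accessible. `accessible_pore_bracket()` reports the Stokes radii
of the last accessible and first excluded standards as a bracket — design
standards, not interpolated values — and doubles them into diameters. Noisy
profiles are first projected onto a non-increasing sequence (antitonic
regression via `stats::isoreg`), since physical exclusion cannot increase
accessibility with probe size; raw values are preserved in the per-standard
calls table. Profiles that never cross the threshold return a flagged open
bracket rather than an error, because an adsorbent whose pores pass every
probe (or none) is a legitimate measurement outcome.

Two routes turn bracketing standards into pore sizes. The default
(`route = "stokes"`) doubles the Stokes radii; it is the route that matches
the published characterization of these adsorbents. The alternative
(`route = "exclusion"`) applies the empirical polystyrene exclusion
correlation $M_W = 2.25\,\Phi^{1.7}$ ($\Phi$ in Angstrom) to the bracketing
masses. The two routes disagree systematically (the correlation asks at what
pore a coil is *excluded*, the Stokes route asks how big the coil *is*), so
reports always carry the route label.

### Porosity and pore volume

$$\varepsilon_P = \frac{V_T - V_0}{V_B - V_0} \qquad V_P = V_T - V_0$$

with $V_B$ the column bed volume. $V_B$ defaults to the cylinder volume of
the recorded column geometry (0.46 cm × 15 cm gives 2.493 mL) because only a
geometric bed volume keeps $\varepsilon_P \le 100\,\%$ with the bundled
volume anchors; a user-supplied $V_B$ is accepted but validated against
$V_T \le V_B$ and rejected loudly otherwise. Recomputing from the bundled
tables reproduces the recorded HAC porosity (86.6 %) exactly; CG161c and
CG300m recompute to 86.5 % and 82.0 % against recorded 86.2 % and 82.3 % —
sub-half-point differences consistent with the anchors being printed at two
decimals — and the CG161c pore volume recomputes to 1.24 mL against a
recorded 1.23 mL. These discrepancies are reported, not reconciled.

## Removal in the recirculating scale-down model

The bench model recirculates a 60 mL plasma reservoir at 1 mL/min
(≈55 cm/h superficial velocity) through a 5 mL adsorbent cartridge — a
60-fold scale-down (`scale_down_factor()`) of the 300 mL clinical device
operating on 4–6 L of blood. `removal_percent()` computes
$100\,(1 - C_\text{treated}/C_\text{ref})$. The reference is, by default,
the **no-adsorbent control circuit at the same endpoint**: of the two
plausible conventions (control endpoint vs. the circuit's own $t_0$), only
the control-endpoint reference reproduces all recorded TNF-α removal rates
from the endpoint table, and it also nets out losses unrelated to the
adsorbent. The $t_0$ convention remains available via
`removal_table(reference = "t0")`.

Concentrations below the limit of detection (entered as `<2` in input
files) are substituted at LOD/2 by default — the standard left-censoring
compromise — with LOD and zero substitution available; every summary built
from a substituted value is flagged. When input SDs are present a removal SD
is propagated to first order and labelled approximate: it describes
measurement uncertainty of the means, not the run-to-run variability a
replicate experiment would give.

`fit_depletion()` adds a deliberately simple kinetic layer: a well-mixed
reservoir of volume $V$ fed at flow $Q$ through a cartridge with constant
single-pass extraction efficiency $E$ gives $C(t) = C_0 e^{-QEt/V}$. The fit
is log-linear least squares; $E = kV/Q$ is derived and clipped to $[0, 1]$
with a warning. This model is a testing and exploration construct — the
analysis of laboratory endpoints never depends on it — and intentionally
omits saturation, protein competition (Vroman effect) and transport
limitation. The simulator (below) does offer a saturable-capacity variant;
the fitter does not, so fitting saturable data visibly underestimates $E$
rather than silently absorbing it.

## Activation thresholds

Plasma spiked at 0–10000 pg/mL and added to culture at 10 % produces
effective doses of one tenth the spiked values (`effective_dose()`, default
dilution 10). For a dose–response series with a zero-dose baseline,
`activation_threshold()` calls a dose active when its mean response both

* exceeds baseline mean + 3 × baseline SD (separation from baseline noise), and
* reaches at least 2 × baseline mean (a biologically meaningful fold change).

The dual rule is an explicit, configurable stand-in for the by-eye judgement
such thresholds usually receive; both sub-rule verdicts are reported per
dose so a user can see which rule was limiting. The threshold is reported as
the bracket (largest inactive dose, first active dose) in design doses;
log-linear interpolation of the crossing is available (`interpolate = TRUE`)
but never the default, since interpolated thresholds suggest precision the
replicate noise rarely supports. Flat series yield `open_high`; series
active from the first tested dose yield `open_low`. Relative expression
against a positive control is the plain ratio
$100 \times \text{sample}/\text{control}$ — no background or isotype
subtraction is built in, because no single subtraction convention is
universal across flow-cytometry setups; feed corrected values if the assay
calls for them.

## The synthetic-data generators

Each generator emulates the statistical structure one analysis stage
assumes, so the full pipeline is testable without laboratory data; equal
seeds give identical output.

* `simulate_isec()` partitions a probe of Stokes radius $r$ into a
  cylindrical pore of radius $r_p$ with $K_d = (1 - r/r_p)^2$ for $r < r_p$,
  else 0 (classical SEC partitioning), mixture-weighted over a pore set, and
  inverts the $K_d$ formula into retention volumes with additive Gaussian
  noise — additive because detector/retention noise does not scale with the
  signal. The partition law is a modelling choice of the generator alone;
  no analysis function assumes it.
* `simulate_depletion()` implements the single-compartment reservoir model
  above, with multiplicative log-normal noise (immunoassays have roughly
  constant CV). With a finite adsorbent capacity it switches to fixed-step
  Euler integration (step 0.01 h — transparency over sophistication at this
  scale) with exact mass bookkeeping: reservoir plus captured mass equals
  the initial mass to machine precision, and extraction stops when the
  capacity is exhausted. The control circuit is the special case $E = 0$.
* `simulate_dose_response()` draws replicate means around a Hill curve
  $\text{baseline} + E_\text{max} d^h / (EC_{50}^h + d^h)$ with additive
  noise; the reported per-dose SD is the generator's noise scale and the
  replicate mean is drawn with standard error $\sigma/\sqrt{n}$.

What the generators do *not* emulate: inter-donor variability, cytokine
release kinetics upstream of the reservoir, protein competition on the
adsorbent, assay calibration drift, or heteroscedastic baselines. Passing
recovery tests therefore demonstrates that the analysis correctly inverts
its own model classes at realistic noise, not that real plasma data will be
this well behaved.

### Recovery test conditions

The statistical recovery suites run at the conditions the models treat as
realistic: retention-volume noise of 2 % of $V_T - V_0$ with eight standards
spanning the pore radius (Kd tolerance widened to 0.15 to match that noise),
concentration noise at 2 % CV over seven hourly samples, and dose-response
noise of 10 % of the dynamic range with $n = 3$ replicates on the standard
spiking grid. Each suite uses 100 seeded replicates — ample for the ≥95 %
coverage and median-error checks while keeping the whole test run in
seconds.

## Numerical and degenerate-input policy

* All rounding (radii/diameters to 0.1 nm, porosity to 0.1 %, volumes to
  0.01 mL) happens at the reporting surface (`as_report()`/`write_report()`),
  never inside computations.
* Volume anchors are validated structurally: $0 < V_0 < V_T \le V_B$;
  violations are errors naming the offending values, because they indicate a
  data problem no downstream number survives.
* A Kd tie at the accessibility threshold counts as accessible.
* Antitonic smoothing resolves noise-induced non-monotonicity before
  bracketing; ties and flat stretches resolve toward the larger standard
  staying accessible.
* Exactly flat depletion series fit rate 0 silently; genuinely negative
  slopes clip to 0 with a warning.
* Empty inputs return empty outputs where a result set is the natural type
  (`removal_table()`), and errors where a scalar is promised.

## Known limitations

The pore bracket inherits the granularity of the standard grid; with the
$(1-r/r_p)^2$ partition law the $K_d = 0.1$ crossing sits near $0.68\,r_p$,
so a bracket in Stokes radii brackets the true pore radius only at the grid
coarseness typical of iSEC standard series — another reason brackets are
reported as design-standard pairs rather than point estimates. The depletion
fitter assumes constant extraction efficiency and will average over
saturation. The removal SD is a first-order approximation. None of the
modules model whole-blood matrices, only plasma.
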