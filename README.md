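# adsorbkit

Quantitative characterization of porous polymer adsorbents for
extracorporeal cytokine removal (hemoadsorption). Written for
biomaterials and blood-purification researchers who need to turn raw
inverse size-exclusion chromatography (iSEC) measurements, bench-scale
recirculation experiments and cell-activation assays into the numbers
that matter: which cytokines can reach an adsorbent's inner surface,
how fast they are removed, and how low they must be pushed to stop
endothelial activation.

## What it computes

**Pore accessibility by iSEC.** Solutes of known size probe the packed
adsorbent. From the retention volume *V<sub>R</sub>* of each standard
and the column anchors *V<sub>0</sub>* (void) and *V<sub>T</sub>*
(total mobile phase), the distribution coefficient is

    Kd = (V_R − V_0) / (V_T − V_0)

Probe sizes come from a power-law Stokes calibration *R<sub>S</sub> =
a·M<sup>b</sup>* fitted in log-log space to polystyrene standards. A
probe reaches the adsorbing inner surface while Kd ≥ 0.1; the accessible
pore size is bracketed by the Stokes radii (doubled into diameters) of
the last accessible and first excluded standards. Porosity and pore
volume follow from the column anchors:

    ε_P = (V_T − V_0) / (V_B − V_0)        V_P = V_T − V_0

with the bed volume *V<sub>B</sub>* taken from the column geometry.

**Removal in a recirculating scale-down model.** A 60 mL plasma
reservoir recirculated at 1 mL/min through a 5 mL cartridge is a
60-fold scale-down of a 300 mL clinical device. Removal is computed
against the no-adsorbent control circuit at the same endpoint,
`100·(1 − C_treated/C_control)`, with configurable substitution rules
for below-LOD values and an optional single-compartment depletion fit
(`C(t) = C0·exp(−QEt/V)`) that estimates the single-pass extraction
efficiency E.

**Activation thresholds.** Dose–response series of endothelial
activation markers are bracketed between the largest inactive and first
active design dose, where "active" means exceeding baseline + 3 SD
*and* a 2-fold change (both configurable, both reported).

**Synthetic data.** Seeded generators produce iSEC chromatograms (from
a cylindrical-pore partition model), reservoir depletion series (with
an optional saturable capacity) and sigmoid dose–response series, so
every stage is testable without laboratory data.

The characterization tables of three PS-DVB adsorbents (Amberchrom
CG161c, CG300m and a clinical hemoperfusion adsorbent, HAC) ship as
plain-CSV fixtures; see `load_fixture()`.

## Worked example

```r
library(adsorbkit)

# Stokes calibration over the bundled polystyrene standards
standards <- load_fixture("polystyrene_standards")
poly <- standards[standards$role == "standard", ]
cal <- fit_stokes_calibration(poly$molecular_mass, poly$stokes_radius)
cal
#> Stokes calibration: R_S = 0.01225 * M^0.5884 nm (n = 12, log-log R^2 = 0.999998)

# Full characterization of one adsorbent from its Kd profile
kd <- load_fixture("isec_kd")
cg161c <- kd[kd$adsorbent == "CG161c", ]
prof <- isec_profile("CG161c", fixture_column_volumes("CG161c"),
                     cg161c$molecular_mass, cg161c$kd)
characterize_adsorbent(prof, cal)
#> Accessible pore bracket 'CG161c' (Kd threshold 0.1): radius 5.0 - 8.1 nm, diameter 10.0 - 16.2 nm
#> Porosity 86.5 %, pore volume 1.24 mL (VB = 2.493 mL, route = stokes)

# Endpoint removal rates vs the control circuit
tab <- removal_table(load_fixture("cytokine_endpoints"))
tab[tab$analyte == "TNF-a", c("analyte", "adsorbent", "removal_percent", "removal_sd")]
#> # A tibble: 3 × 4
#>   analyte adsorbent removal_percent removal_sd
#>   <chr>   <chr>               <dbl>      <dbl>
#> 1 TNF-a   CG161c               94.3       1.01
#> 2 TNF-a   CG300m               63.5       6.29
#> 3 TNF-a   HAC                  53.4      10.5

# Threshold bracketing on a simulated activation marker
dr <- simulate_dose_response(baseline = 300, emax = 5000, ec50 = 22,
                             hill = 4, noise_sd = 500, n = 3, seed = 42)
activation_threshold(dr)
#> Activation threshold bracket: (10, 50) pg/mL
```

Reading the output: only CG161c removes TNF-α (94.3 %) deeply enough to
push it toward the 10–50 pg/mL window below which the activation marker
stays at baseline — its 10.0–16.2 nm accessible pore diameter admits
the 51 kDa TNF-α trimer, while the narrower-pored HAC (7.6–10.0 nm
bracket) leaves 46.6 % of it in circulation. The `removal_sd` column is
a first-order propagation of the endpoint SDs, labelled approximate.

A thin command-line wrapper over the same functions lives at
`inst/cli/adsorbkit.R` (subcommands `isec`, `removal`, `scaledown`,
`threshold`, `simulate`, `fixtures`).

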