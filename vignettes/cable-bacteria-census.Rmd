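---
title: "From pore-water profiles and qPCR to a cable-bacteria census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pore-water profiles and qPCR to a cable-bacteria census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cablecensus)
```

## The problem

Cable bacteria are centimetre-long, multicellular filaments of the family
*Desulfobulbaceae* that conduct electrons internally: sulfide is oxidized at
depth (the anodic half-reaction) while oxygen is reduced near the
sediment-water interface (the cathodic half-reaction). This electrogenic
sulfur oxidation (e-SOx) leaves a characteristic pore-water fingerprint -- a
centimetre-scale suboxic zone where both O~2~ and free sulfide are below
detection, a subsurface pH maximum at the oxygen penetration depth, and a
deep pH minimum from anodic proton production.

`cablecensus` implements the quantitative chain that turns raw measurements
from such sediments into a census of the population and its activity:

1. **Geochemistry** -- microsensor depth profiles give diffusive fluxes
   (Fick's first law with tortuosity correction), sulfide speciation and the
   zonation fingerprint.
2. **Electron balance** -- the cathodic O~2~ and anodic sulfide budgets each
   yield an areal electric current density.
3. **qPCR** -- standard curves convert Cq values into 16S rRNA gene copies
   per gram of wet sediment.
4. **Census** -- copy densities become cell, filament-length and
   filament-count densities; combined with the current densities they give
   per-filament current and per-cell oxygen consumption.
5. **Primer evaluation** -- the IUPAC-degenerate qPCR primers behind step 3
   are screened for design-rule compliance and taxonomic specificity.
6. **Amplicon cross-validation** -- qPCR relative abundances are regressed
   against 16S amplicon relative abundances.

A seeded synthetic-data generator emits every input the pipeline consumes
with planted ground truth, so the whole chain is testable offline.

## Fluxes from depth profiles

The diffusive flux of a solute through the pore water is

$$J \;=\; -\,\frac{\varphi\,D}{1 - 2\ln\varphi}\,\frac{dC}{dz},$$

with porosity $\varphi$, free-solution diffusion coefficient $D$
(m^2^ d^-1^) and the concentration gradient fitted by ordinary least squares
over a depth window. The factor $1-2\ln\varphi$ is the tortuosity
correction; it equals 1 in free solution and 1.256 at the default
$\varphi = 0.88$. We report $J$ signed positive downward, so an O~2~ profile
decreasing into the sediment gives a positive diffusive uptake; upward
sulfide and iron fluxes come out negative and enter the electron balance as
magnitudes.

Choices a user should know about:

* **Fit windows.** Microsensor practice does not fix a window, so `fickFlux()`
  accepts one explicitly. Defaults: for O~2~, interface to the oxygen
  penetration depth; for total sulfide, the first 4 points from the sulfide
  appearance depth (the base of the suboxic zone). OLS reduces to the exact
  two-point derivative on linear data and falls back to it when only two
  points are available.
* **Diffusion coefficients.** `diffusionCoefficient()` ships defaults for
  O~2~, H~2~S and Fe^2+^ at 16 °C / salinity 30 from standard seawater
  tables, but $D$ is always an explicit argument -- site conditions differ.
* **Sulfide speciation.** Total sulfide is
  $\Sigma H_2S = [H_2S]\,(1 + 10^{\,pH - pK_1})$ with $pK_1$ supplied by the
  user (default 6.6, a typical seawater value near the incubation
  conditions). pH is interpolated linearly onto the H~2~S grid.
* **Zonation.** Crossing depths (O~2~ below, sulfide above a detection
  threshold, default 1 µmol L^-1^) are located by linear interpolation
  between bracketing samples; pH extremes are reported on the measured grid.
  When O~2~ never falls below the threshold the oxygen penetration depth --
  and hence the suboxic width -- is `NA`, not zero.

## The electron balance

The cathodic rate is the difference in diffusive O~2~ uptake between a
sediment with an active population and a matched control. Its standard
deviation is combined additively by default (the conservative convention for
a two-treatment contrast); quadrature is available. With 4 electrons per
O~2~ and the Faraday constant, a rate of 13.6 mmol O~2~ m^-2^ d^-1^
corresponds to 61 mA m^-2^:

```{r}
currentFromO2(13.6)
```

The anodic side sums three sulfide sources: the upward flux from the deep
sulfidic zone, sulfate reduction inside the suboxic zone (the deep flux
scaled by the ratio of zone widths, assuming a uniform volumetric sulfate
reduction rate), and sulfide freed by net FeS dissolution, taken equal to
the *upward* Fe^2+^ flux (the downward flux is assumed to re-precipitate as
FeS and is not counted). At 8 electrons per sulfide oxidized to sulfate:

```{r}
b <- sulfideBudget(jUpSulfide = 4.8, wSuboxic = 10, wSulfidic = 59, jFeS = 2.0)
b
currentFromSulfide(b)
```

That the two independent estimates converge (61 vs 68 mA m^-2^) is the
central consistency check of the method.

## qPCR quantification

A standard curve is the OLS fit of Cq against $\log_{10}$(copies) over a
10-fold dilution series (at least three distinct levels; 4+ decades in
practice). The amplification efficiency is $10^{-1/slope} - 1$, exactly
100 % at slope $-1/\log_{10} 2 \approx -3.3219$. Samples are averaged on the
Cq scale (the noise model is log-domain), inverted through the curve, and
scaled by dilution factor, elution volume and wet sediment mass to copies
per gram of wet sediment. Elution volume and wet mass are required
arguments, never defaulted silently, because the absolute densities scale
with both. Cq values above a no-template cutoff (default 38) are flagged
below detection and excluded from layer means rather than imputed as zero.

A note on detection limits: propagating a 10 copies µl^-1^ reaction-level
floor through a 10^2^ dilution with typical elution volume (50 µl) and mass
(0.5 g) gives `detectionLimit(10, 100, 50, 0.5)` = 1e5 copies g^-1^.
Reaction-level floors quoted without their volume and mass factors can look
orders of magnitude lower; `detectionLimit()` therefore exposes every
factor explicitly.

## The census

With copy density $C$ (copies g^-1^ wet sediment), cell length $L_{cell}$,
16S copies per cell $n_{copy}$, wet bulk density $\rho_w$ and colonization
depth $L_{CB}$:

* cells cm^-3^: $C \rho_w / n_{copy}$
* filament length density: $N_{F,vol} = C\,L_{cell}\,\rho_w / n_{copy}$
  (m cm^-3^), $N_{F,area} = N_{F,vol} \times L_{CB}$ (m cm^-2^)
* filament count (straight, vertical filaments spanning $L_{CB}$):
  $N_{F,area} / L_{CB}$ per cm^2^.

Defaults are the study conditions: 3 µm cells, 2 copies per cell (the *Ca.*
Electrothrix aarhusiensis genome value), 1.32 g cm^-3^, 1.5 cm. The uniform
single-density shortcut (one $C$ over the colonized depth) is the documented
default; integrating layered profiles is available through the qPCR table
interface. Mean horizontal spacing comes from the count density under a
lattice model -- hexagonal ($d = \sqrt{2/(\sqrt3\,n)}$, the default) or
square ($d = n^{-1/2}$). Neither is canonical; for 6 × 10^4^ filaments
cm^-2^ they give 43.9 and 40.8 µm respectively, so spacing is a descriptive
output only.

```{r}
census <- filamentCensus(3e8)
census
filamentCurrent(currentFromO2(13.6), census)
cellSpecificO2(13.6, opd = 1, census)
```

The per-cell oxygen rate divides the cathodic rate by the oxic-zone cell
inventory only (cell density × oxygen penetration depth), since cells below
the oxic zone do not touch O~2~. Growth timing converts a fold increase in
copy density into doublings ($\log_2$) and days at a given doubling time.

## Degenerate-primer evaluation

Primers are IUPAC strings, 5′→3′, with reverse primers written on the
reverse strand as in any primer table. Matching is deliberately
*asymmetric*: a primer code denotes a set of bases and matches a template
base contained in that set, while template bases must be concrete -- a
template `N` counts as a mismatch even against primer `N`, because an
unknown base cannot be assumed to anneal. For degenerate primers this
equals best-variant semantics (the minimum mismatch count over expansions),
since positions are independent.

`findBindingSites()` slides the primer (or, for reverse primers, its
reverse complement) along the template and reports every window within the
mismatch allowance, with mismatch positions 1-based from the primer's own
5′ end. `inSilicoPCR()` pairs forward and reverse sites in productive
orientation under an amplicon-length cap (default 200 bp, the qPCR-suitable
limit), counting length from forward 5′ to reverse 5′ inclusive.
`specificityScreen()` runs these per reference record and tabulates
per-taxon template hits at each mismatch level -- a local, reproducible
stand-in for web probe/primer-matching services, run against any FASTA plus
two-column taxonomy sidecar.

`primerQC()` applies the standard design rules (GC 40--60 %, 5′ G/C
preferred, no GC-rich 3′ end, no hairpin/self-dimer/hetero-dimer) using
complementary-run heuristics rather than free-energy minimization -- the
rules are qualitative, and the thresholds (hairpin seed 4, dimer run 5) are
arguments. Melting temperatures use a nearest-neighbor model (unified
parameter set, Na^+^ entropy correction) supplied via `thermoConfig()`;
published primer-table Tm values computed with unstated methods are treated
as descriptive and are not reproduction targets.

## Amplicon cross-validation

`relativeAbundances()` pairs, per depth layer, the qPCR relative abundance
(target copies / total-bacteria copies) with the amplicon relative
abundance (target reads / reads classified as Bacteria; unclassified reads
are excluded from the denominator by default). `ratioRegression()` fits the
through-origin slope by default -- both quantities are ratios of the same
population, so a zero intercept is the natural model -- with the intercept
variant always reported alongside. `asvDetectionLimit()` anchors the
sequencing detection floor in absolute units: one read out of the layer's
total corresponds to (total-bacteria copy density / total reads) copies
g^-1^.

## The synthetic-data generator

`scenarioSpec()` fixes the study conditions: the electrogenic regime plants
an oxygen penetration depth of 1 mm, a 10 mm suboxic zone, O~2~ uptake of
35.1 mmol m^-2^ d^-1^, an upward sulfide flux of 4.8 mmol m^-2^ d^-1^, a
subsurface pH maximum 0.25 units above the overlying water and a deep
minimum of 6.2 at 12 mm; the non-electrogenic regime has a 1.6 mm OPD,
21.6 mmol m^-2^ d^-1^ uptake, sulfide at the OPD and no pH excursions.
Copy-density profiles default to the observed magnitudes (total bacteria
1.3 × 10^10^ copies g^-1^ in the top layer over 5.4 × 10^9^ below; cable
bacteria 3 × 10^8^ in the colonized 0--1.5 cm against a 9.1 × 10^4^
background).

Each generator is a *right inverse* of its analysis stage in the noiseless
limit, which is the package's core testing surface:

* `genPorewater()` inverts the Fick expression, so the planted O~2~ uptake
  and sulfide flux are recovered to 1 × 10^-9^ relative; the O~2~ surface
  concentration is whatever the planted flux and OPD jointly imply (exact
  invertibility is prioritized over matching a solubility table). Free
  H~2~S is back-computed from planted total sulfide and pH so speciation
  round-trips exactly. Profiles are emitted on a 50 µm grid to 30 mm.
* `genQpcr()` pushes planted layer densities through the planted log-linear
  curves, dilution (10^4^ for total bacteria, 10^2^ otherwise), elution
  volume and mass; noiseless tables quantify back exactly.
* `genReferenceDb()` plants exact primer sites (in-target) or sites with
  mismatches at chosen primer positions (off-target) into random
  16S-length sequences, with amplicon lengths drawn ≤ 200 bp.
* `genCommunityReads()` draws multinomial read counts at planted fractions
  (default 52 000 reads per layer).

All randomness flows from the scenario/function seed; identical inputs give
byte-identical outputs. What the generator does **not** emulate: curvature
and noise structure of real microsensor profiles, PCR amplification bias,
chimeras and sequencing error, or real phylogenetic sequence structure
(backgrounds are i.i.d. random nucleotides). Passing round trips therefore
demonstrate the correctness of the computational chain, not field
performance of the assay.

## Numerical choices and degenerate inputs

* Crossing depths interpolate linearly between bracketing samples; pH
  extremes are not interpolated.
* Replicate Cq values are averaged before inversion; the replicate CV is
  reported on the copies scale.
* A negative cathodic difference (control consuming more O~2~) is returned
  with a warning flag, not raised -- it is a legitimate "no signal" outcome.
* Division-by-zero guards: zero filament count, zero oxic-zone population,
  zero sulfidic-zone width and zero reads are errors; zero copy density
  yields zero densities with undefined spacing.
* Test and simulation sizes are kept at desk scale (1000-replicate
  efficiency simulations, 200 random primer/template draws, 10^5^--10^6^
  read draws), which run in seconds.

## Known limitations

* Steady-state diffusive fluxes only; no reactive-transport modelling,
  irrigation or advection.
* The suboxic-zone sulfate-reduction term assumes a uniform volumetric rate
  across zones.
* Straight, vertical filaments; no tortuosity or orientation model for the
  filament network.
* Dimer/hairpin heuristics are run-length based; borderline thermodynamic
  cases need a dedicated free-energy tool.
* qPCR enumeration inherits the usual caveats: primer-site conservation in
  the target clade and the per-cell 16S copy number set the accuracy floor.
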