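---
title: "Methods: from spring radioactivity to DNA strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spring radioactivity to DNA strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`diatomdose` estimates the external alpha-particle dose rates and the
resulting DNA damage for unicellular microorganisms — benthic diatoms in
particular — living in naturally radioactive mineral springs. The two
dominant alpha emitters in these systems are ²²²Rn dissolved in the water
(measured up to ~4600 Bq/L) and ²²⁶Ra bound to the sediments (~21–43 Bq/g
dry). The reference exposure conditions used throughout are 1000 Bq/L ²²²Rn
and 30 Bq/g ²²⁶Ra, the levels above which elevated rates of teratological
diatom forms have been reported in the field.

This vignette documents the model, its assumptions, every tunable that
matters, the calibrations, and the limits of what the package's tests can
demonstrate.

## Geometry and materials

The microorganism is a water sphere of radius 10 μm containing a concentric
0.5 μm water nucleus; a diatom additionally carries a 2 μm amorphous-silica
frustule shell (ρ = 2.40 g/cm³). The surrounding environment is a sphere of
radius

$$R_{env} = (R_{max} + r_M + F)\times 1.03,$$

where $R_{max}$ is the water range of the most energetic simulated alpha
line (43.44 μm for the 5.490 MeV ²²²Rn line), so every emission point that
can possibly reach the diatom lies inside the source region, with a 3%
margin. This gives 55 μm without and 57.1 μm with the frustule. The same
$R_{max}$ is used for every environment composition — a per-nuclide radius
would shrink the ²²⁶Ra-only environment and change the geometric
normalisation between configurations for no physical benefit.

The environment is water, dry sediment, or a water/sediment mixture
parameterised by porosity $P$ (volume percent of water,
$P = 100\,V_W/V_{tot}$): 100% for the open water column, 0% for pure dry
sediment (an upper-limit scenario), and 90% for the benthic mixture in
which benthic diatoms actually live. Mixture density is the
volume-weighted mean of the components (1.02 g/cm³ at 90%).

Alpha transport in any non-water material is treated as transport in water
over a scaled path: a geometric path $s$ becomes the water-equivalent path
$s\,\rho\,k$, where $k$ is the material's alpha mass stopping power
relative to water. Defaults:

* water: $\rho = 1.00$, $k = 1$;
* silica frustule: $\rho = 2.40$, $k = 0.90$ (typical of condensed oxides
  in stopping-power tabulations);
* dry sediment: $\rho = 1.20$, $k = 0.77$. Tabulated alpha mass-stopping
  ratios for mineral matter (Si, Ca, C, O dominated) fall around 0.75–0.90
  because water's hydrogen content gives it an unusually high mass stopping
  power; within that physical range the default is calibrated so that the
  simulated absolute dose to a microorganism embedded in pure dry sediment
  matches the reference value for that configuration. The mixture's linear
  stopping power is additive in the volume fractions, which makes the 90%
  benthic mixture almost exactly water-like (scaling 1.004).

Both $k$ values are configuration knobs (`materials:` block of the YAML
config); the calibration procedure is a single one-dimensional match to the
dry-sediment absolute dose and was performed once, before the test suite
was frozen.

The nucleus is placed at the centre of the microorganism. Nothing in the
source setup breaks spherical symmetry, so concentricity is the natural
maximal-symmetry choice; off-centre nuclei would only matter through the
~10 μm of water shielding, which varies weakly over plausible offsets.

## Alpha sources

Each decay emits exactly one alpha drawn from the evaluated line spectra
(three ²²²Rn lines, dominant 5.490 MeV at 99.92%; five ²²⁶Ra lines,
dominant 4.784 MeV at 93.84%). Daughter nuclides are excluded: their
spatial distribution around the diatom depends on unknown chemistry, and
beta/gamma contributions are negligible for these sources (order 0.01% of
the alpha dose). Emission points are uniform over the environment sphere
minus the diatom; directions are isotropic. The total source activity uses
the same region: ²²²Rn activity is concentration × water fraction × volume
in litres; ²²⁶Ra activity is mass activity × sediment fraction × dry
density × volume in cm³. Normalising over the full sphere instead (a
~1% effect) is available as `include_diatom_volume = TRUE`.

## Transport: straight-track CSDA

The range–energy relation is a Bragg–Kleeman power law $R = \alpha E^p$
fitted through two anchors for alphas in water: (5.490 MeV, 43.44 μm) and
(4.784 MeV, 35 μm), giving $p = 1.569$, $\alpha = 3.000$ μm·MeV$^{-p}$.
With two anchors the fit is exact; a user-supplied anchor table can replace
it. The inverse and the stopping power $dE/ds = 1/(\alpha p E^{p-1})$
follow in closed form; at 5.49 MeV the model gives ~81 keV/μm, in line with
tabulated alpha stopping powers in water.

Tracks are straight rays: alpha lateral deflection over ≤ 44 μm in water is
sub-micrometre, negligible against the 10 μm target. Ray–sphere
intersections are computed analytically for the nucleus, microorganism,
frustule and environment spheres; each traversed segment is converted to
its water-equivalent length, the residual energy at every boundary follows
from the closed-form inverse, and the energy difference across a segment is
deposited in that region. Energy is conserved to machine precision by
construction, and the test suite asserts it to 10⁻⁶ relative per track.

Secondary electrons are not transported at this scale: their energy stays
on the alpha path. This mirrors the observation that electron-mediated
deposits are keV-scale against MeV-scale ion ionisation in the
microorganism. There is no analogue of a condensed-history production cut;
the fidelity cost is discussed under Limitations.

Phase spaces (energy, position, direction, weight) are recorded at each
inward crossing of the microorganism and nucleus surfaces and can be
written/read as headered CSV.

Two estimator modes exist for the nucleus stage. Analog mode scores
everything but populates the 0.5 μm nucleus sparsely (a few entrants per
10⁵ decays). Nucleus-aimed mode draws the emission direction uniformly in
the cone subtended by the nucleus and attaches the cone's solid-angle
fraction as a statistical weight. Because the analog direction law is
isotropic, the conditional distribution of nucleus-crossing tracks is
unchanged — this is plain forced-detection variance reduction, and the
package cross-checks the weighted entrant fraction against an independent
solid-angle/range quadrature oracle.

The quadrature oracle itself integrates the effective cone fraction
$(1-\mu^*)/2$ over the radial emission density, with
$\mu^* = \max\!\big(\sqrt{1-(r_t/d)^2},\ (d^2+s^2-r_t^2)/(2ds)\big)$ and
$s$ the range budget expressed as a geometric path; the second argument
binds only when the tangent path exceeds the budget. It is exact for
uniform single-material environments without a frustule, which is the
setting in which it is used as an oracle.

## Dose-rate normalisation

Absolute doses scored over $N$ simulated decays convert to dose rates as
$\dot D = (D/N)\times A \times 3600 \times 10^6$ μGy/h with $A$ the Bq of
the corresponding nuclide in the source region. Rates are exactly linear in
the activity concentrations, so reference-condition rates rescale to any
measured spring by per-nuclide activity ratios. Totals are screened
against the 10 μGy/h ecosystem benchmark used by the ERICA assessment
framework. The normalisation chain accepts externally supplied absolute
doses, so its arithmetic is testable independently of the transport
engine.

## Nanodosimetry

Alphas recorded at the nucleus surface are replayed as straight residual
tracks through the 500 nm water nucleus. A full dielectric-response track
structure code is far beyond this package's scope; instead, discrete
energy-transfer points form a Poisson process along the track whose linear
density is LET$(E)/\langle\varepsilon\rangle$, with per-point energies
drawn from an exponential of mean $\langle\varepsilon\rangle$ truncated at
5 keV. The construction guarantees that summed point energies converge to
the CSDA loss in expectation (asserted to 5% in the tests). A fraction
(default 40%) of points represents energy carried off the core by secondary
electrons and is displaced isotropically by an exponential distance of mean
2 nm — this plays the role the 1 nm production cut plays in a
track-structure code. Process labels (alpha ionisation/excitation, electron
ionisation/excitation/solvation) are sampled with configurable fractions;
they drive the per-process specific-energy spectra and carry no further
physics.

Specific energies are scored in 30,000 cylinders of 10 nm diameter × 5 nm
height (one nucleosome, ≈147 bp each; ≈2.25% of the nucleus volume in
aggregate), placed uniformly (orientations isotropic, overlaps permitted —
the targets are probes, not an exclusive-volume chromatin model) in the
sphere shrunk by the cylinder half-diagonal so every cylinder fits. One eV
in such a cylinder is 408 Gy of specific energy. Each nonzero deposit is
attributed to the process with the largest summed energy; exact ties break
deterministically by a fixed process order. Since the targets are uniform
probes, the mean specific energy over all targets equals the nucleus dose —
the package tests this identity, and specific-energy rates follow by
multiplying the per-decay mean by the source decay rate.

## DNA damage: DBSCAN strand-break scoring

Every transfer point is an SSB candidate with probability
`SPointProb` × ramp(ε): the ramp is 0 up to 5 eV, linear to 1 at 37.5 eV,
and 1 above. `SPointProb` lumps the probability that a point falls in a
DNA-sensitive region (helix plus a virtual aura capturing indirect radical
damage); the adopted value is 8%, with {8, 12, 16, 20}% available in a
calibration sweep whose DSB yields are strictly ordered in `SPointProb` by
construction (nested selections via common random numbers). Selected SSBs
are clustered per track with DBSCAN at eps = 3.3 nm (≈10 bp) and
minPts = 2 — at minPts 2 every non-noise point is core, so there is no
border ambiguity — and every cluster with ≥2 SSBs counts exactly one DSB.
Yields are normalised per Gray of nucleus dose and per Mbp of a 27 Mbp
genome (the small-diatom assumption for a 1 μm nucleus).

### Calibration of the site-energy scale

$\langle\varepsilon\rangle$ is the single knob that sets the transfer-point
density at fixed LET and therefore the absolute strand-break yields. It was
calibrated once by sweeping 90–120 eV and comparing the benthic-with-
frustule yields at `SPointProb` 8% against the reference values (SSB ≈
0.15–0.16, DSB ≈ 0.03 per Gy per Mbp); 100 eV reproduces both to within a
few percent and is the default. The sweep and the choice predate the frozen
test suite; the value is exposed in the config (`ts: mean_site_energy`).

### Per-day rates

Breaks per day combine per-nuclide yields with per-nuclide microorganism
dose rates: $\sum_n y_n \,\dot D_n \times 24\times10^{-6} \times$ genome.
For mixed-source configurations the reported per-Gy yields are the sum of
the per-nuclide yields, which is the bookkeeping that reconciles the
single-nuclide rows with the benthic row of the reference damage table.
The alternative normalisation through nucleosome SE rates is deliberately
not the default: the reference per-day numbers for the single-nuclide
configurations are recovered by the dose-rate recipe within rounding,
whereas no single printed rate column reproduces the benthic per-day values
exactly from the rounded printed yields.

## Synthetic scenarios

`generate_scenarios()` emulates the measured spring table: the five
measured springs are returned as fixed fixtures (e.g. spring 5: 4594 Bq/L
²²²Rn, 31.4 Bq/g ²²⁶Ra), followed by synthetic scenarios with ²²²Rn
log-uniform over 13.7–4594 Bq/L (the measurements span nearly three
decades, so a log law is the natural spread) and ²²⁶Ra uniform over
21.4–42.5 Bq/g. These emulate activity ranges only — not inter-spring
correlations, seasonal variation, or measurement uncertainty — so tests
passing on them demonstrate the pipeline's arithmetic and scaling across
the measured envelope, not geochemical realism.

## Numerical choices and problem sizes

* Transport is vectorised over tracks and processed in batches of ≤2×10⁵;
  splitting into ≥10 batches supplies the statistical SD of the doses.
* Default desk-scale runs use 10⁶ decays per nuclide for the dose stage
  (the reference study used 10⁸; at 10⁶ the dose SD is ≈0.5–2%) and 8×10³
  nucleus-aimed emissions (≈2–4×10³ nucleus tracks) for the nano stage.
  The shipped tests use 10⁵–10⁶ and 3×10³ respectively.
* The nano stage steps tracks in 50 nm segments, ample since the LET
  varies by <1% across a segment for the relevant energies.
* All randomness flows from a single integer seed per run; derived seeds
  are small fixed offsets, and rerunning a configuration reproduces output
  tables byte for byte.
* Degenerate inputs are defined: zero-length tracks and zero energies give
  empty point sets; zero activity gives an all-zero report; zero nucleus
  dose makes per-Gy yields undefined and raises an error.

## Known limitations

* Straight-track CSDA ignores multiple scattering, energy-loss straggling
  (an optional Gaussian knob is deliberately off by default) and nuclear
  reactions. Entry fractions into the 10 μm microorganism are insensitive
  to this, but small-target quantities are more delicate: the model's
  nucleus-entry fraction in the pure water column (3.8×10⁻⁵) sits above
  the benthic value (3.0×10⁻⁵) that matches the reference 0.003%.
* The two-anchor power law is a global fit; it is exact at 4.784 and
  5.490 MeV and approximate elsewhere, which feeds into contrasts between
  the two nuclides' spectra (the frustuled Rn-over-Ra dose excess comes
  out ≈23% against a reference 26% derived from two-digit printed doses).
* The nanoscale sampler is calibrated, not derived: its site-energy scale
  and displacement parameters absorb everything a real track-structure
  code computes about delta-ray transport and radiolysis chemistry.
  Per-process spectra are therefore phenomenological decompositions.
* Materials are water-equivalent scalings, not element-resolved media;
  the sediment's measured elemental composition enters only through its
  density and one mass-stopping ratio.
* No DNA repair, base damage, chromatin geometry, radionuclide uptake or
  internal emitters; per-day break rates are raw induction rates.
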