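---
title: "Detecting mixotrophy in seston from amino-acid nitrogen isotopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mixotrophy in seston from amino-acid nitrogen isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sestonmix)
```

# The problem

Most pigmented protists in the sea are not pure photoautotrophs. They
supplement photosynthesis with the uptake of dissolved organic matter
(osmotrophy) and, in many groups, with the ingestion of prey
(phagotrophy); organisms combining all three are called mixoplankton.
Distinguishing these nutritional modes in field samples of seston —
suspended particles dominated by microalgae — is hard because every
sample is a mixture of functional groups.

Compound-specific nitrogen isotope analysis of amino acids (CSIA-AA)
offers a way in. Trophic amino acids (glutamic acid + glutamine, "Glu",
and alanine, "Ala") are enriched in ^15^N at each trophic transfer by a
trophic discrimination factor (TDF), while the source amino acid
phenylalanine ("Phe") retains the baseline signal of the nitrogen
source. Crucially, the two trophic amino acids see different
heterotrophic pathways: Glu integrates osmotrophy (DON assimilation
enriches Glu roughly like an herbivorous trophic step) but protistan
phagotrophy barely moves it, whereas Ala records protistan grazing
steps. Reading the two axes together therefore separates four modes:
photoautotrophy, osmo-photoautotrophy, phago-photoautotrophy, and
osmo-phago-photoautotrophy (the mixoplankton signature).

# Trophic positions and trophoclines

Trophic position from a trophic/source pair is

$$TP_{aa} = \frac{\delta^{15}N_{aa} - \delta^{15}N_{Phe} - \beta_{aa}}{TDF_{aa}} + 1$$

with the canonical constants $\beta_{Glu} = 3.4$ permil, $TDF_{Glu} =
7.6$ permil, $\beta_{Ala} = 3.2$ permil, $TDF_{Ala} = 5.7$ permil
(`trophic_calibration()`). In the $(\delta^{15}N_{Phe},
\delta^{15}N_{aa})$ plane, lines of constant TP — trophoclines — have
slope 1 and intercept $\beta + TDF\,(TP - 1)$: 3.4, 7.2 and 11.0 permil
for Glu at TP 1.0, 1.5, 2.0, and 3.2, 6.05 and 8.9 permil for Ala (the
mid-Ala intercept is often quoted rounded to 6.0). TP values are never
clipped; a seston value above the herbivore line is information, not an
error.

Uncertainty is propagated to first order,
$\sigma_{TP} = \sqrt{\sigma_{aa}^2 + \sigma_{Phe}^2}/TDF$
(`tp_uncertainty()`). It is reported alongside the calls but is *not*
used by the classifier: the field convention classifies on the point
estimate, and we follow it.

## Mode bands

`classify_trophic_mode()` partitions the TP plane with `mode_bands()`:

* TP_Glu below 1.4: autotroph side; within the closed band [1.4, 1.6]:
  osmotroph side; above 1.6: `heterotroph_dominated` (the literature does
  not interpret seston above the band, so we label rather than clamp).
* TP_Ala at or above 1.4 flags phagotrophy. The published criterion is
  "around or above 1.5"; we operationalize it as a band edge at 1.4,
  i.e. half-width 0.1 around the 1.5 archetype, mirroring the printed
  Glu band. Both edges are configurable.
* Band edges are inclusive on the mixotroph side ("between 1.4 and 1.6"
  read as a closed interval); whether the printed edges were meant
  inclusive is not stated anywhere, so this is a package decision.

`endmember_overlay()` assigns each record to the nearest reference
trophocline (TP 1.0, 1.5, 2.0). Distance to a slope-1 line is
perpendicular, $|\Delta\delta - b|/\sqrt{2}$, chosen for geometric
symmetry between the two delta axes; vertical distance is available as
an option, and exact midpoints tie toward the lower TP.

# Chemotaxonomic unmixing

Community structure comes from diagnostic pigments. A ratio matrix $F$
(8 classes x 15 pigments, pigment:chl-a weight ratios, Chl a column
fixed at 1) relates class chl-a contributions $c$ to expected pigment
concentrations $s \approx c^\top F$. `fit_composition()` solves, per
sample, a non-negative least-squares problem with pigment columns scaled
by their root-mean-square over samples, so that trace pigments are not
drowned out by fucoxanthin and chl a; set `weighting = "none"` to fit
raw concentrations. The solver is an active-set iteration on the normal
equations, which shares the cross-product matrix across samples — this
is what keeps the randomized search below affordable.

The ratio matrix itself is uncertain, so the full procedure
(`chemtax_run()`) follows the classic randomized protocol: three runs of
60 randomly perturbed matrices (each nonzero non-Chl-a entry scaled by
1 + Uniform(-0.35, 0.35)), each locally optimized, with the next run
seeded from the element-wise mean of the six best. Within
`optimize_ratio_matrix()` the search is a derivative-free accept-if-better
sweep of single-entry multiplicative steps, bounded to within 50% of the
starting entry; the objective (weighted RMS residual over all cells) is
non-increasing by construction, and a strict-descent tolerance makes a
perfect fit a fixed point. Structural zeros — e.g. peridinin occurring
only in dinoflagellates — are never violated by perturbation or
optimization, and the incumbent best matrix is never discarded between
runs. The 35% perturbation and 50% optimization bounds are the
conventional limits of the standard tool; its exact internals are not
public, so ranking is by final objective with ties broken by generation
index.

# Hydrographic features

Station predictors are standard upper-ocean diagnostics:

* `buoyancy_frequency()`: $N^2 = (g/\rho_0)\,d\sigma_\theta/dz$ on level
  midpoints ($g = 9.81$ m s^-2^, $\rho_0 = 1025$ kg m^-3^). When
  $\sigma_\theta$ is not supplied it is computed from T/S with the
  EOS-80 one-atmosphere polynomial — adequate for the near-surface casts
  this package targets.
* `mixed_layer_depth()`: the depth of the *global* maximum of $N^2$
  (shallowest on ties within 1e-12). Whether the original analysis
  searched the full cast or only the upper column is unstated; the full
  cast is used.
* `cline_depth()`: 0 when the surface concentration already meets the
  threshold, else the linearly interpolated first downward crossing,
  else missing. Nitracline, phosphocline and silicacline use 1, 0.1 and
  2 uM.
* `nai()`: the nitrate availability index — surface NO~x~ (uM) when at
  least 0.5 uM, else minus the 2-uM crossing depth (m), else minus the
  bottom depth. The mixed units are deliberate and the index is consumed
  raw downstream, matching its original usage. All interpolation goes
  through the same primitive as `cline_depth()`.
* `o2_saturation()`: Garcia–Gordon combined-fit solubility (umol/kg
  coefficient set), converted to mM with a 1025 kg m^-3^ reference
  density.
* `plume_thickness()`: interpolated depth of the salinity-35 horizon —
  the same salinity that bounds the plume's surface extent; the cast
  bottom is returned (flagged `censored`) when the whole cast is
  fresher.

"Surface" values are read at the topmost valid level, the bin size being
unstated in the source material.

# Community clustering and the size index

Compositions (percent of total chl a) are clustered on Manhattan
distances, which are robust to the outlier samples typical of plume
gradients, with average linkage (the linkage used originally is
unstated; complete and single are options, Ward is excluded for a
non-Euclidean distance) and a default cut at k = 4 communities.
`pca_validation()` checks the clustering tendency with a centered,
unscaled principal decomposition — percent units are commensurate so
scaling is off by default — and reports, per label pair, the centroid
distance in the PC1–PC2 plane over the mean within-cluster spread.

`mean_size_index()` computes the pigment-based community size from the
seven diagnostic pigments with the Bricaud/Uitz weights (micro: 1.41
Fuco + 1.41 Perid; nano: 1.27 HexFuco + 0.35 ButFuco + 0.60 Allo; pico:
1.01 Chl b + 0.86 Zea), the source analysis citing but not printing
them; the index is the fraction-weighted mean of tags micro = 3, nano =
2, pico = 1.

# The trophic-mode predictor

`induce_tree()` is a C4.5-family learner: binary splits on numeric
attributes chosen by information gain ratio, thresholds at the midpoint
of the straddling values, missing values handled by sending case weight
down both children in proportion to the known cases, and
pessimistic-error pruning with confidence factor `cf` (default 0.25,
`min_cases` 2). An exact replica of the commercial C5.0 heuristics
(winnowing, boosting, global pruning) is out of scope; the quantities
reported — `attribute_usage()` (percent of training case weight passing
through nodes testing an attribute; 100% at the root) and
`training_error()` (resubstitution error, the figure quoted in the kind
of analysis this package supports) — are the same. Prediction for a row
missing the tested attribute follows the majority-weight child.

# The synthetic generator

`gen_aa_profiles()` inverts the TP equations: each sample gets a true
Phe baseline from Uniform(2, 12) permil (the spread of nitrogen-source
baselines across an estuary-to-ocean gradient), Glu and Ala placed on
the generating mode's archetype trophoclines, and independent Gaussian
noise of SD 1 permil per reported delta — the typical triplicate
reproducibility of the measurement. Archetypes: photoautotroph (1.0,
1.0), osmo-photoautotroph (1.5, 1.0), phago-photoautotroph (1.0, 1.5),
mixoplankton (1.5, 1.5); end-member archetypes protozooplankton (1.2,
2.0) — the Glu value reflecting that strict grazers stay near the
autotroph end member on the Glu axis, a reading of the cited cultures,
not a printed number — and DON-grown heterotrophs (2.0, 1.5). Mixtures
of populations are approximated by arithmetic means of member deltas,
exact only for equal nitrogen pools; no mechanistic fractionation is
simulated.

A consequence worth stating plainly, because the package's own tests
compute it: with single-measurement noise of 1 permil, the TP_Glu
standard deviation is $\sqrt{2}/7.6 \approx 0.19$, nearly twice the 0.1
half-width of the mixotroph band. Band-based classification of a true
TP_Glu 1.5 sample then succeeds only ~40% of the time (the unit tests
check the simulated rates against this closed-form Gaussian
prediction). Noise-free profiles round-trip at 100%. Real studies
mitigate the noise by replicate averaging (`n_replicates` in the
generator) and by reading points against the trophocline plot rather
than a hard band; users should treat band calls near the edges with the
reported `sd_tp_*`.

`gen_pigment_samples()`, `gen_ctd_cast()` and `gen_station_set()`
likewise invert the downstream stages: pigment mixtures from a known
ratio matrix with 1% multiplicative noise; two-layer casts with a tanh
pycnocline at the prescribed mixed-layer depth and a nutrient profile
that plants any NAI branch; and station tables in which
mixotroph-dominated stations satisfy MLD <= 37 m and surface chl a >
0.171 ug/L while autotroph stations violate at least one rule (deep
mixed layers being the commoner violation, so that MLD is the dominant
predictor). Every generator is a pure function of its seed.

What the generator does *not* emulate: spatial autocorrelation along a
cruise track, co-variation of pigments and isotopes within a station,
non-Gaussian analytical error, or mechanistic isotope fractionation.
Passing tests therefore demonstrate correctness of the computations and
recoverability under the stated statistical structure, not performance
on real cruise data.

# Problem sizes and numerics

The test suite and the analysis scripts use deliberately small problem
sizes chosen to exercise every code path: 100–2000 amino-acid profiles,
12–16 pigment mixtures for the full 60 x 3 randomized search (about
two to three minutes on one core; the thin analysis driver uses a 20 x 2
search), casts on a 1-m grid, and 100-station feature tables. Numerical
choices that matter: NNLS tolerance scales with the normal-matrix
diagonal and falls back to a tiny ridge on singular active sets;
optimizer acceptance requires descent beyond 1e-10(1 + objective);
trophocline ties resolve to the lower TP within 1e-9; N^2 ties to the
shallowest depth within 1e-12; degenerate all-zero pigment rows yield a
zero composition with a warning rather than an error so whole cruises
can be processed.

# Limitations

* The four-mode classification assumes seston is dominated by the
  pigmented community; detrital or metazoan material shifts both axes.
* TDFs for true mixoplankton are unmeasured; the constants are the
  canonical culture-derived values.
* The ratio-matrix search is a local, bounded heuristic — like the
  standard tool it emulates, it can converge to a local optimum when the
  starting ratios are far from the truth.
* The tree learner reports resubstitution error only; no cross-validated
  generalization claim is made.
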