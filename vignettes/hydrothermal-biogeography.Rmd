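---
title: "Hydrothermal indexes, ensemble distribution modelling and habitat dynamics"
author: "hydrotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrothermal indexes, ensemble distribution modelling and habitat dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotherm)
```

## The scientific problem

Arid- and semi-arid-zone shrubs such as *Caragana* occupy ranges shaped by
two coupled climatic axes: accumulated growing-season warmth and moisture
availability relative to that warmth. `hydrotherm` implements the
quantitative toolkit used to analyse such ranges: hydrothermal index
surfaces interpolated from climate stations, per-species thermal profiles
with optimal ranges, a five-type moisture–temperature classification, an
ensemble species-distribution-modelling (SDM) procedure with a True Skill
Statistic (TSS) weighted consensus, and habitat-dynamics accounting
(suitability classes, latitude-corrected areas, range-change maps,
centroid migration). A synthetic world with known ground truth makes every
stage testable without external data.

## Hydrothermal indexes

For a station with monthly mean temperatures $t_1,\dots,t_{12}$ (°C) and
annual precipitation $P$ (mm):

* **Warmth index** $WI = \sum_{t_m > 5} (t_m - 5)$ (°C·month), Kira's
  accumulated warmth.
* **Coldness index** $CI = -\sum_{t_m < 5} (5 - t_m)$ (°C·month), always
  non-positive.
* **Humidity index** $HI = P / WI$ (mm/(°C·month)), Xu's moisture index.

The month conditions are the standard ones: a bare sum over all months
would make $WI$ negative in cold climates, contradicting its definition
as accumulated warmth, so `warmth_index()` sums only months above the
5 °C threshold and `coldness_index()` only months below it. They satisfy
$WI + CI = 12(\bar t - 5)$ exactly (months at exactly 5 °C contribute to
neither), which the tests use as an algebraic invariant. Where $WI \le 0$
the ratio $HI$ is undefined; `humidity_index()` returns `NA` rather than
raising an error, and the flag propagates as nodata downstream. (The HI
unit is sometimes printed inverted in the literature; every value handled
here is consistent with mm per °C·month, which is the convention this
package adopts.)

## Interpolation by ordinary kriging

Station indexes are interpolated to a regular 2.5 arc-minute
longitude/latitude grid with ordinary kriging, the best linear unbiased
predictor whose weights sum to one. Choices the method leaves open were
fixed as follows and are exposed in `kriging_config()`:

* **Variogram family**: exponential by default (spherical and Gaussian
  also available), with nugget, partial sill and range fitted by weighted
  least squares (weights = pair counts per lag bin) to the empirical
  semivariogram, or fixed by the caller.
* **Distance metric**: planar Euclidean in degrees. At the
  sub-continental extents this package targets the distortion is
  immaterial for interpolation weights, and it keeps the kriging system
  identical to the small dense linear-algebra oracle used in the tests.
* **Grid registration**: cell centers, origin at the bounding-box
  lower-left corner, rows stored north to south.
* **Degenerate (constant) fields**: a fitted variogram with zero total
  sill makes the kriging system singular although every convex weighting
  is equivalent; the predictor then returns the station mean, so a
  constant field interpolates to a constant surface.
* **Exactness**: with zero nugget the predictor honours station values
  exactly; singular neighbourhoods are reported as errors with the
  offending location rather than silently regularised.

`crossvalidate_kriging()` reports leave-one-out RMSE with the variogram
frozen at the full-data fit — refitting per fold would change the model
being validated.

## Species thermal profiles

Occurrences are spatially thinned to one record per 2.5 arc-minute cell
(`thin_occurrences()`; the first record in input order wins, making the
result reproducible without a seed), index values are extracted at the
containing cell (`extract_index_values()`; point-level interpolation
would manufacture precision the 2.5′ surfaces do not have), and species
with fewer than five records are excluded (`summarize_species()`,
`min_n = 5`). Statistics use the sample standard deviation
($n-1$ denominator).

Under a normal thermal response, the **peak width at half height** of the
warmth-index distribution is $PWH = 2.354\,S$, and the optimal range
$X \pm 0.5\,PWH$ contains about 78% of occurrences. Values are stored
unrounded; report tables round half away from zero to one decimal.

The five moisture–temperature types cross WI bins $[20,60)$, $[60,75)$,
$[75,\infty)$ with HI bins $<3.5$, $[3.5,7.5]$, $>7.5$:

| type | name | WI | HI |
|---|---|---|---|
| 1 | Cold-Temperate Humid | 20–60 | > 7.5 |
| 2 | Mesothermal Xeric | 60–75 | 3.5–7.5 |
| 3 | Mesothermal Humid | 60–75 | > 7.5 |
| 4 | Warm-Temperate Hyperxeric | ≥ 75 | < 3.5 |
| 5 | Warm-Temperate Xeric | ≥ 75 | 3.5–7.5 |

Two conventions deserve comment. The warm bin is open-ended: species with
mean WI above 90 are routinely placed in the warm-temperate types, so a
printed upper bound of 90 is treated as descriptive, not operative, and
classification is total. Ties at HI = 7.5 go to the xeric/mesic column
(the middle bin is closed on both sides). Bin combinations not realised
by any of the five types — e.g. cold and hyper-arid — return `NA` with
the raw bin pair reported, as does mean WI below 20. Classification is
always by computed, unrounded means; one published species
(*C. stenophylla*, rounded mean WI 75.0) is known to sit exactly on the
60–75 / ≥75 boundary and the package deliberately does not special-case
it — its computed bin simply differs from the published row for that one
species, and the bundled table reproduces the published column totals
(10/26/8), the cold-humid row count (7) and the grand total (44) exactly.

Aridity zones follow the HI cut points 3.5 / 5.5 / 7.5
(arid, semi-arid, semi-humid, humid; lower-inclusive).

## The ensemble SDM procedure

`run_sdm_pipeline()` reimplements the consensus-forecasting workflow:

1. **Variable screening** (`screen_variables()`): at the sample
   locations, a greedy Pearson pass removes one member of the worst
   correlated pair (the one with the larger mean $|r|$ against the rest)
   until all $|r| < 0.7$, then a VIF pass drops the largest variance
   inflation factor until all $VIF < 5$. VIF is computed from the inverse
   correlation matrix (the test oracle recomputes it independently as
   $1/(1-R^2)$ per variable); an exactly singular correlation matrix
   signals infinite VIF and the variable loading heaviest on the null
   eigenvector is dropped. Categorical layers bypass both passes. Every
   drop is logged with its statistic.
2. **Pseudo-absences** (`sample_pseudo_absences()`): two independent sets
   of 8000 cells drawn uniformly without replacement from unmasked
   non-presence cells (capped with a warning when fewer are eligible).
   Uniform random sampling is the default background strategy when no
   bias model is specified.
3. **Repeated fits** (`fit_single_model()`): each learner × PA set × run
   gets a seeded, class-stratified 80/20 split (stratification avoids
   single-class validation folds on small data); evaluation is on the
   held-out 20% only.
4. **Evaluation** (`evaluate_predictions()`): AUC as the rank statistic
   with half-credit ties; TSS as the maximum of
   sensitivity + specificity − 1 over the sorted unique score
   thresholds, reporting the smallest threshold on ties.
5. **Consensus** (`build_ensemble()`): members with held-out TSS
   strictly above 0.55 are retained with weights proportional to raw
   TSS, normalised to sum to one — the weighted-mean consensus. The
   ensemble's own evaluation pools the retained members' held-out
   predictions across runs (a definition the package states explicitly
   because consensus platforms differ here).
6. **Projection** (`project_ensemble()`): member predictions are
   computed cell-wise on a scenario stack and combined with the frozen
   weights; the result is a convex combination, so every ensemble cell
   value lies within the member range.

The learner registry ships four members: logistic regression (`glm`),
random forest (`rf`), gradient-boosted trees (`xgb`, single-threaded for
reproducibility) and `maxent_like`, an L1-regularised logistic regression
on linear, quadratic and hinge features — the feature expansion that
makes MaxEnt-style fitting expressible as penalised GLM. All run with
default settings; the contribution of the pipeline is the procedure
around the learners, not any one learner's tuning, and the registry is
pluggable. The deterministic λ choice in `maxent_like` (AIC along the
regularisation path) avoids a randomised cross-validation inside an
otherwise fully seeded pipeline. Categorical variables are one-hot
encoded inside the learners that need a numeric design.

All randomness descends from one root seed; per-fit seeds are derived
arithmetically from (learner, PA set, run), and the run manifest records
every seed, screening decision and evaluation row, so a rerun under the
same configuration is bit-identical.

## Habitat dynamics

Suitability grids in $[0,1]$ are cut at 0.2 / 0.4 / 0.6 into
non-suitable, minimally, moderately and highly suitable classes.
Published interval notation overlaps at the breaks, so one convention
must be fixed: bins are lower-inclusive ($[0.2, 0.4)$ etc.). The binary
potential-distribution mask instead uses a strict inequality
(suitability > 0.2), following the wording that defines it.

Areas use the spherical-zone formula
$R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bottom})$ with
$R = 6371.0088$ km (IUGG mean radius), so cell areas shrink with
latitude; the four class areas always sum to the unmasked study area.
Change maps cross current and future presence masks into
never/loss/gain/stable, a partition with loss and gain disjoint by
construction.

Range centroids are area-weighted means of presence-cell centers —
binary masks weighted by cell area, approximating polygon-centroid
behaviour; a suitability-weighted variant is available behind a flag
since published workflows do not always state which is used. The planar
lon/lat mean assumes the extent does not span the antimeridian (asserted,
errored otherwise). Migration vectors report haversine great-circle
distance, initial bearing in $[0, 360)$ and a 45°-sector cardinal label;
identical points return distance 0 and bearing 0 by convention.

## The synthetic world

`world_config()` defines a study region whose climate is a deterministic
function of position plus optional i.i.d. noise: monthly temperature
falls with latitude (`lat_gradient`, default 0.8 °C per degree) and
elevation (`lapse_per_100m`, default 0.6 °C per 100 m — the standard
environmental lapse rate) from a temperate continental monthly profile;
annual precipitation rises west to east (`precip_base` 400 mm,
`precip_lon_gradient` 15 mm per degree) and is floored at zero after
noise. The defaults describe a 5°×5° mid-latitude box at 2.5′ resolution
with 300 stations — hydrothermal structure of the kind found across
northern-China drylands, with WI spanning several tens of °C·month and
HI crossing the semi-arid/semi-humid boundary.

Stations are snapped to distinct DEM cell centers with elevation taken
from the DEM, so indexes computed from noise-free stations equal the
analytic surfaces at the station cells exactly — the ground-truth
consistency the kriging recovery tests rely on. Virtual species draw
occurrence cells with probability proportional to a Gaussian kernel in
(WI, HI) space — the simplest unimodal niche consistent with the
normal-curve assumption behind the PWHH range — with a uniform jitter
inside the cell. Scenario climates either perturb layers directly
(temperature +Δt, precipitation ×(1+Δp)) or, more faithfully, shift the
world's monthly profile and regenerate the index surfaces
(`scenario_config()`).

What the generator deliberately does **not** emulate: spatial
autocorrelation in the noise (kept i.i.d. so kriging recovery tests stay
interpretable), topographically complex relief, multi-year weather
variability, observation bias in occurrences, and niche shapes beyond a
symmetric unimodal kernel. Tests passing on this world therefore
demonstrate the correctness of the computations and the recoverability
of planted structure — not robustness to the sampling artefacts of real
occurrence databases.

## Numerical choices and test problem sizes

* The kernel-mean recovery tests use a world whose monthly profile stays
  above 5 °C everywhere, making WI exactly linear in latitude; the
  estimator of a planted optimum is unbiased only where the WI
  distribution over cells is locally uniform, and the test fixture is
  constructed to be in that regime.
* Kriging recovery uses a 10×10-cell world with 90 stations (about one
  per cell); the dense linear-field cross-validation example uses a
  Gaussian variogram, whose smoothness is what reproduces smooth trends
  to well under 0.1% of the field range — the exponential family levels
  off too quickly for that bar.
* The ensemble recovery run uses a 60×60-cell world, 400 presences,
  8000-point pseudo-absence sets (capped by eligibility), 3 learners ×
  2 PA sets × 10 runs = 60 fits; the determinism check reruns a smaller
  configuration (2 runs, 150-point sets) twice and compares manifests
  bit for bit.
* Oracle-equivalence suites run 1000 random AUC/TSS instances against
  exhaustive pair/threshold enumeration, and 50 random ≤5-station
  kriging systems against a hand-assembled linear solve.

## Limitations

Grids are in-memory dense matrices — appropriate for regional 2.5′
extents, not global mosaics. Kriging is isotropic and drift-free
(no co-kriging, external drift or anisotropy). The pipeline models one
occurrence table as one response; genus-level pooling of species is the
caller's choice. Raster exchange uses the plain-text ESRI ASCII grid
format with geographic WGS84 coordinates only; projected rasters are
rejected explicitly rather than reprojected.
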