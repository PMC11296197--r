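---
title: "From feather nanostructure to colour: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From feather nanostructure to colour: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongecolor)
```

## The scientific problem

Non-iridescent structural plumage colour — the UV-blue of a blue tit's crown,
for example — is produced inside feather barbs by a *spongy layer*: a
quasi-ordered network of keratin rods and air channels with a characteristic
repeat distance of roughly 100–170 nm. Coherent scattering from this
structure selectively reinforces short wavelengths, so the dominant
periodicity of the sponge should causally determine hue, its regularity
should influence spectral purity, and the amount of coherently scattering
material should influence brightness.

Small-angle X-ray scattering (SAXS) measures exactly these quantities
without slicing the feather: the sponge produces broad scattering peaks
whose position, width and height map onto periodicity, regularity and
scattering strength. `spongecolor` implements the full chain from raw
detector images to cohort-level statistical conclusions, together with a
synthetic-cohort generator so that each stage can be validated against known
ground truth.

## Reduction: from detector frames to scattering curves

A pixel at radial distance $r$ from the beam centre on a detector a distance
$D$ downstream sees the scattering half-angle $\theta = \tfrac12
\arctan(r/D)$, and the corresponding momentum transfer is

$$q = \frac{4\pi \sin\theta}{\lambda},$$

with $\lambda$ the X-ray wavelength (0.154 nm for a Cu K$\alpha$ laboratory
source; default sample–detector distance 2507 mm, pixel pitch 0.172 mm for a
Pilatus-class hybrid pixel detector). Length scales follow from Bragg's
relation $d = 2\pi/q$: the spongy-structure peaks near $q \approx 0.045$ and
$0.075\ \mathrm{nm^{-1}}$ correspond to repeat distances of roughly 140 and
84 nm.

`azimuthal_average()` bins unmasked pixels into equal-width $q$ bins
(default 256) and reports the per-bin mean intensity with the standard error
of that mean (Poisson $\sqrt{I}$ when a bin holds a single pixel). Frame
corrections (`correct_frame()`) accept dark, empty-beam, transmission,
exposure-time, flatness and absorption inputs, all defaulting to the
identity; the package deliberately does not reproduce a full instrument
calibration chain.

Matrix-mode experiments measure each sample at 21 grid positions with 6
exposures each (126 replicate curves). Two reduction decisions are not
dictated by the physics and were made as follows:

* **Outlier filtering.** A replicate is discarded when the robust z-score of
  its summed intensity over the analysis window — $(T - \mathrm{med}\,T) /
  \mathrm{MAD}(T)$ — exceeds 3.5 in either direction. Low totals catch empty
  positions (no feather in the beam), high totals catch cosmic-ray
  artefacts. A second, absolute criterion flags curves whose windowed total
  is statistically indistinguishable from zero given their own
  uncertainties; a purely relative criterion cannot flag an empty position
  when most replicates are empty.
* **Intensity normalisation.** Replicates differ by a multiplicative factor
  (amount of material in the beam), so each curve is rescaled by the
  least-squares factor matching it to a reference and the scaled curves are
  averaged. The reference is the pointwise median of the curves after each
  is brought to unit mean intensity over the window. Normalising before
  taking the median makes the whole operation exactly invariant to
  rescaling any input curve, at the cost of an arbitrary overall intensity
  scale — immaterial here, because no absolute intensity calibration exists
  and the peak-height analysis is measured relative to the fitted baseline.

## The Porod-space double-Gaussian peak model

Feather samples scatter as two broad sponge peaks on a steep $q^{-4}$
power-law background (larger objects such as melanin granules). Multiplying
by $q^4$ — the Porod plot — flattens that background. The Porod-transformed
curve is modelled as

$$y(q) = c + a_1 e^{-\ln 2\,(q - q_1)^2 / h_1^2}
       + \alpha\, a_1 e^{-\ln 2\,(q - \beta q_1)^2 / h_2^2},$$

a constant baseline plus two Gaussians parameterised by their half width at
half maximum (the $\ln 2$ factor makes $h$ exactly the HWHM). The secondary
peak is tied to the primary through the height ratio $\alpha$ ($a_2 \equiv
\alpha a_1$) and the position ratio $\beta$ ($q_2 \equiv \beta q_1$); both
ratios are fitted freely within bounds rather than fixed, since nothing
forces a single universal peak spacing.

Fitting minimises the unweighted sum of squared residuals over
$0.038 \le q \le 0.2\ \mathrm{nm^{-1}}$ (weighted fits are available via
`weighted = TRUE` but are not the default, because the Porod transform
already equalises the useful dynamic range and the per-bin uncertainties at
the lowest $q$ are the least reliable). Numerical choices:

* bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`),
  cost tolerance $10^{-12}$, at most 5000 function evaluations;
* bounds generous around the observed peak regions: $q_1 \in [0.038,
  0.07]$, $h_1, h_2 \in [10^{-4}, 0.05]$, $a_1 \ge 0$, $\alpha \in [0, 2]$,
  $\beta \in [1.3, 2.2]$, $c \ge 0$;
* data-driven starting values: smoothed minimum for $c$, highest smoothed
  local maximum in $[0.038, 0.06]$ for the primary peak (ties broken toward
  lower $q$ — the UV-side peak is the primary), half-prominence width for
  $h_1$ with a 0.007 fallback, and typical values $\beta_0 = 5/3$,
  $\alpha_0 = 0.3$, $h_{2,0} = 0.012$ for the secondary;
* degenerate inputs: a peakless curve fits with $a_1$ at its lower bound 0
  and the baseline absorbing the signal; a curve with no local maximum gets
  the fallback start $q_{1,0} = 0.045$ with a warning.

On noiseless model-generated curves the fit recovers all seven parameters
with relative error below $10^{-4}$; at 2 % amplitude noise with the full
126-replicate matrix design, the median $|q_1|$ error across seeds is well
below 1 % (both properties are asserted in the test suite).

Peak heights are strongly right-skewed across individuals, so downstream
analyses use $\log(a + 10^5)$ (natural logarithm — any base is a monotone
equivalent; the choice is recorded in the fit object metadata).

## Colorimetry

Three reflectance variables summarise a spectrum, computed on a canonical
1-nm grid from 320 to 700 nm (inclusive, linear interpolation from the
instrument grid):

* **brightness** — mean per-cent reflectance over 320–700 nm;
* **UV chroma** — UV-band (320–400 nm) reflectance relative to brightness.
  "Band reflectance divided by brightness" admits two readings: band *mean*
  over brightness (a flat spectrum scores exactly 1) or band *sum* over
  full-range sum (a flat spectrum scores $81/381 \approx 0.213$). The two
  differ by a constant factor and rank samples identically; the band-mean
  convention is the default and the choice is recorded in the output.
* **hue** — the wavelength of maximum reflectance, ties resolved to the
  lowest wavelength. No smoothing is applied before the argmax by default;
  a boxcar option exists for noisy instruments.

Replicate measurements (three per sample) are averaged at the *variable*
level: the sample hue is the mean of the replicate hues, not the argmax of
an averaged spectrum.

## Predicting hue from periodicity

Constructive interference at normal incidence in a quasi-ordered structure
of repeat distance $d = 2\pi/q_1$ reinforces
$$\lambda = 2\,d\,n_\mathrm{avg},$$
where $n_\mathrm{avg}$ is the average refractive index of the keratin–air
composite. With keratin index 1.58, air 1.0 and a keratin volume fraction of
0.57, the volume-weighted mean of the phase indices gives

```{r navg}
average_refractive_index(1.58, 0.57)
```

i.e. 1.33 at two decimals. Linear volume-weighted averaging of the indices
is the rule that reproduces this constant from those inputs and is the
default; a squared-index (low-contrast dielectric) mixing rule is exposed as
an option but changes the index only in the third decimal. The keratin
fraction is treated as sexually uniform by default, with sex-specific values
available through `optical_model()`. A primary peak at
$q_1 = 0.045\ \mathrm{nm^{-1}}$ maps to

```{r hue045}
predict_hue(0.045)
```

nanometres, and the whole observed primary-peak region (0.038–0.06) maps
into the UV–blue window (~280–440 nm).

## Cohort statistics

The inferential pipeline mirrors standard practice for dichromatism
analyses. Design choices, where a choice had to be made:

* **Sex standardisation** (`sex_standardize()`): within-sex z-scores with
  the $n-1$ sample standard deviation, because both nanostructural and
  colour variables differ between sexes in mean *and* variance.
* **Sex comparisons** (`sex_mean_variance_tests()`): pooled two-sample $t$
  for means; variance-ratio $F$ with the larger variance in the numerator
  and a two-tailed p-value (the tail convention is not forced by the
  problem; two-tailed is the conservative choice).
* **Backward elimination with reintroduction**
  (`glm_backward_reintroduce()`): ordinary least squares; at each step the
  least significant *removable* term with $p > \alpha$ (default 0.05) is
  dropped. Marginality is respected — an interaction is removable before
  its main effects, and a main effect is kept while any interaction
  containing it survives. After convergence every eliminated term is
  reintroduced alone into the final model to report the $F$ it would have
  had, so the output lists each candidate term exactly once. Retained terms
  carry type-III-style partial $F$ values computed by deleting the term's
  model-matrix columns. With $\alpha = 1$ the full model is reported;
  with $\alpha = 0$ only the intercept survives. Under a null response,
  removable terms are retained at close to the nominal 5 % rate; a main
  effect protected by marginality is retained whenever its interaction is,
  so its null retention rate is structurally $\approx \alpha +
  P(\text{interaction retained})$ — a feature of marginality, not an error.
* **Varimax orthogonalisation** (`varimax_orthogonalize()`): principal
  components of the correlation matrix, all components retained, varimax
  rotation. The returned scores are standardized rotated component scores
  (exactly uncorrelated, unit variance) and the returned loadings are the
  rotated orthonormal eigenvector basis. The textbook
  "loadings $=$ eigenvectors $\times \sqrt{\text{eigenvalues}}$" convention
  cannot simultaneously deliver orthonormal loadings and uncorrelated
  scores; whitened rotated scores satisfy both properties this package
  promises, and for the purpose at hand — decorrelating collinear
  predictors before a linear model — only the score space matters.
* **Residual dichromatism** (`male_residual_dichromatism()`): the
  structural regression is fitted on males (the larger sample), residuals
  are computed for all rows from the male coefficients, and the sexes'
  residuals are compared with a pooled $t$. Extrapolating male coefficients
  across a structural sex gap adds estimation noise proportional to the
  gap, so the test is slightly anticonservative for very large gaps; at the
  1-within-sex-sd gaps typical of crown dichromatism the null rejection
  rate stays near 5 %.
* **Estimated versus measured hue** (`paired_hue_comparison()`): a
  two-level repeated-measures design is analysed exactly through difference
  scores — the sex-by-data-type interaction is the pooled $t$ (equivalently
  $F = t^2$) on per-sample differences between sexes, and the within-sex
  effects are paired $t$-tests. Degenerate inputs (zero-variance
  differences) are handled explicitly rather than refused.
* **Repeatability** (`repeatability()`): per parameter, both measurement
  rounds are sex-standardized and correlated (Pearson); the sex difference
  in repeatability is the sex $\times$ round-1 interaction in a linear
  model for the round-2 value. This interaction test has modest power for
  contrasts between two already-high correlations (e.g. ~14 % for 0.97 vs
  0.74 at $n = 24$ per sex) — a limitation of the test itself that users
  comparing repeatabilities should keep in mind.

All p-values are two-sided and no multiple-testing correction is applied.
Year enters the models as an ordinary factor; variables are not
year-corrected.

## The synthetic-cohort generator

`cohort_config()` fixes the study conditions the generator emulates:

* 53 male and 29 female samples, from two capture years;
* per-sex truncated-normal latent parameters: primary peak position
  centred at 0.047 (M) and 0.044 (F) with sd 0.002 on [0.038, 0.06] — the
  male crown sponge tuned slightly finer (more UV) than the female;
  primary HWHM centred at 0.007 (M) and 0.008 (F); amplitude, ratio and
  baseline defaults chosen as realistic round numbers for Porod-space
  feather curves (means 110/80 for $a_1$, $\alpha = 0.3$, $\beta = 5/3$,
  $h_2 = 0.012$, $c = 2$);
* matrix-mode measurement: 21 positions $\times$ 6 exposures, additive
  Gaussian Porod-space noise of 2 % of $a_1$, a lognormal per-position
  intensity scale (log-sd 0.1), and optional artefact replicates (empty or
  spiked) with configurable probability;
* triplicate reflectance spectra: a Gaussian reflectance peak (width 45 nm)
  over a flat baseline carrying 30 % of total brightness, centred on the
  sample's realized hue, plus 0.5 % measurement noise;
* structure-to-colour links: realized hue is the periodicity prediction
  plus a sex offset (0 nm for males, $-8$ nm for females — representing
  other structural elements lowering realized female hue) and 2 nm of
  biological scatter; brightness increases by 1.5 % per within-sex sd of
  amplitude and decreases by 1.0 % per within-sex sd of peak position,
  around per-sex baselines of 22 % (M) and 18 % (F).

Every random quantity is a deterministic function of the base seed and the
sample/position/exposure indices (a private sub-seed per unit), so any
subset of a cohort is reproducible on its own and two draws with the same
seed are bit-identical.

Two simulation paths exist. The *physical* path renders detector frames
and replicate curves and pushes them through reduction and peak fitting; it
validates the measurement chain and is exercised at small sample counts in
the test suite (its per-sample cost is ~0.3 s). The *table-level* path
(`simulate_cohort_table()`) emulates the measurement-plus-fit stage by
perturbing each latent parameter with a small relative measurement error
(0.5 % for $q_1$, consistent with the physical path's measured recovery
accuracy) and simulates the spectra in full; it is used for the
calibration and effect-recovery suites, which need hundreds of cohorts
(200 cohorts and 500–1000 null replicates are the problem sizes used).

**What the generator does not emulate:** real instrument backgrounds and
calibration chains, anisotropic scattering, detector geometry distortions,
non-Gaussian reflectance peak shapes, preen-wax or abrasion effects, and
any within-sample variation in sponge parameters other than the intensity
scale and the optional `within_sample_q1_sd` periodicity jitter (default 0;
the true magnitude of within-sample periodicity variation is an open
biological question). Passing tests therefore demonstrate that the
algorithms recover what they are designed to recover under the stated noise
model — not that real feather data are free of the confounders listed
above.

## Known limitations

* The hue prediction is a first-order, normal-incidence interference
  formula; it ignores dispersion, disorder broadening and multiple
  scattering, and full optical simulation of the sponge is out of scope.
* The amplitude parameters are on an arbitrary intensity scale; only
  baseline-relative, log-transformed amplitudes are comparable across
  samples.
* The backward-elimination report inherits the usual caveats of stepwise
  inference; the package reports reintroduction $F$ values precisely so
  that dropped terms remain visible.
* Avian visual modelling (cone catches, tetrahedral colour space) is
  deliberately not included; the three reflectance variables are physical
  summaries, not perceptual ones.
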