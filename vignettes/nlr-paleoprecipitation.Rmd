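---
title: "Methods: NLR bioclimatic precipitation reconstruction and model-data comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NLR bioclimatic precipitation reconstruction and model-data comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleorain)
```

## The model

`paleorain` estimates the precipitation regime under which a fossil plant
assemblage lived, from the modern climatic tolerances of the taxa's nearest
living relatives (NLRs). The statistical model is deliberately simple and
fully explicit:

1. Each taxon's modern occurrences, after cleaning and spatial thinning,
   are reduced to six precipitation bioclim variables — MAP (mm/yr), WMP and
   DMP (mm/month), PS (%), WQP and CQP (mm/quarter) — extracted from a
   monthly reference climatology.
2. The taxon's climatic envelope is Gaussian and axis-aligned: per variable
   $c$, a sample mean $\mu_{tc}$ and sample standard deviation
   $\sigma_{tc}$ ($n-1$ denominator).
3. The likelihood of taxon $t$ at a candidate climate $x$ is
   $f_t(x) = \prod_{c=1}^{6} \mathcal{N}(x_c;\, \mu_{tc}, \sigma_{tc})$,
   and the assemblage likelihood is $f(z) = \prod_t f_t(x)$.
4. The candidate set is a large uniform sample of *extant* climate
   combinations — the bioclim vectors of distinct land cells of the
   reference climatology (default 100,000 cells, or every land cell when
   fewer exist). Restricting candidates to climates that occur on the
   modern Earth keeps the six functionally-dependent variables mutually
   consistent without modelling their covariance.
5. The candidate maximising $f(z)$ is the reconstruction; the per-variable
   min–max over candidates with $f(z) \ge$ 5% of the maximum is its
   uncertainty range.

The key assumptions are (a) envelope Gaussianity, (b) independence of the
six variables in the product — knowingly false, since MAP, WMP and DMP are
functionally related, but mitigated by the extant-candidate restriction —
and (c) niche stability between the fossil taxon and its NLR. All three are
inherited from the method itself, not artifacts of this implementation.

## Numerical choices

**Log space everywhere.** Products of $6n$ normal densities underflow
double precision for even moderate assemblages, so all likelihood
arithmetic is the row-sum of log densities,
$\log f_t = -\sum_c \log(\sigma_c\sqrt{2\pi}) - \sum_c (x_c-\mu_c)^2 / 2\sigma_c^2$,
and the 5% rule is applied as $\log f(z) \ge \log f_{max} + \ln(0.05)$.
Values stay finite for per-variable z-scores beyond 100. Tests cross-check
the log-space implementation against an independent linear-space brute
force (products of `dnorm` values) to 1e-9 relative error.

**Ties.** The likelihood maximiser takes the lowest candidate index on
exact ties. Nearest-cell point extraction breaks equidistant ties toward
the smaller longitude index, then the smaller latitude index. Quarter
identification (the 12 circular 3-month windows) picks the warmest-mean
window, resolving temperature ties toward the *wetter* window (the coldest
quarter toward the drier), then the earliest start month; without a
documented tie rule, symmetric seasonal cycles — common in idealised data —
would make WQP/CQP platform-dependent.

**Envelope sd floor.** A taxon with one occurrence, or identical
occurrences, would yield a delta-function envelope that dominates the
product. Standard deviations are floored at 5% of the per-variable sd over
all land cells of the reference grid (`sigma_floor_default()`): scale-aware
per variable, and far below any well-sampled envelope's spread.

**PS convention.** PS = 100 × population-sd(monthly)/mean(monthly), the
plain coefficient of variation, with PS = 0 when the mean is 0. The
`+1 mm` variant used by some bioclim software changes values only in
near-zero-rainfall cells; the plain convention was chosen as the simplest
and is applied uniformly to occurrences and candidates, so the choice
cancels in the likelihood comparison.

**Raw precipitation.** Envelopes are fitted on raw (untransformed)
variables. A log transform would reweight wet versus dry taxa; raw values
keep the units interpretable and match the Gaussian-envelope statement of
the model.

**Extraction and regridding.** Point extraction defaults to the nearest
land cell (within a 2-cell search radius; beyond that the point is flagged
missing, never silently dropped) because blending land and ocean cells
through interpolation contaminates coastal envelopes. Bilinear extraction
is available; it drops ocean corners and renormalises the stencil weights.
Field regridding is mask-aware bilinear with the same renormalisation;
masks regrid by majority rule (interpolated land fraction ≥ 0.5).
Multi-model statistics follow the lowest-common-resolution convention:
every member is regridded to the coarsest member's grid before the ensemble
mean or RMSE is formed.

**Regional statistics.** Box membership is by cell-center inclusion with
longitudes normalised to [-180, 180). Regional means are cos(latitude)
weighted; RMSE is unweighted by default with a weighted option, since the
convention for published model-evaluation RMSEs is rarely stated — the
choice is an explicit argument, not a hidden constant.

## The synthetic-data generator

The generator supplies every input the pipeline consumes, with known truth:

- **Climatology** (`generate_climate_grid()`): a zonally symmetric wet belt,
  Gaussian in latitude (default amplitude 200 mm/month over a 20 mm/month
  background, decay scale 15°), whose center migrates ±10° with a sinusoidal
  seasonal cycle peaking in July; temperature with a meridional gradient and
  a hemisphere-antisymmetric seasonal cycle; a smooth elliptical continent
  covering 55% of a 1°, 72 × 80-cell Africa-like domain (20°W–52°E,
  40°S–40°N). Precipitation noise is mean-one lognormal and multiplicative,
  parameterised by its approximate absolute sd at the belt peak (default
  10 mm/month); `noise_sd = 0` reproduces the smooth field exactly. The 1°
  default resolution is a modelling choice — typical of the climatologies
  used for envelope extraction — not a constraint of the method.
- **Assemblages** (`generate_assemblage()`): occurrences are sampled *in
  climate space* — each land cell weighted by a Gaussian density centered on
  the designated fossil-site cell's bioclim vector — and mapped back to cell
  centers. This is exactly the statistical structure the envelope model
  assumes, so envelope fitting and the likelihood search can be tested as
  parameter recovery. Default generating sds are 0.25 × the per-variable
  land-cell sd ("moderate" envelopes: broad enough to span many cells,
  narrow enough to carry signal).
- **Pseudo-models** (`generate_model_ensemble()`): the base climatology
  regridded to per-model resolutions, plus known constant biases and seeded
  noise, standing in for a multi-model ensemble with known errors.

What the generator does **not** emulate: orography, zonal asymmetry
(monsoon–desert contrasts), interannual variability, geographic sampling
bias in occurrence databases, and taxonomic uncertainty in NLR assignment.
Passing recovery tests therefore demonstrates the correctness of the
*statistics*, not the adequacy of the NLR method for any particular real
flora.

## The recovery study and its conditions

The acceptance study uses one 1° synthetic grid, a designated fossil site
at (25°E, 15°S) — a climatically mid-range land cell, away from the edges of
the attainable climate space where availability bias is worst — 10 taxa ×
100 occurrences per replicate, the exhaustive candidate set (~3,200 land
cells), and 50 seeded replicates. These sizes keep the full study under a
minute on one CPU while leaving each envelope's standard error per variable
near $\sigma/\sqrt{100}$.

Recovery is judged in MAP units at the resolution of the candidate set:
the MLE must fall within one *candidate-set MAP spacing* of the truth,
operationalised as the largest |ΔMAP| between the true cell and its eight
geographic neighbours among the candidates. With exhaustive candidates the
truth cell is itself a candidate, so this is the natural "one grid step"
tolerance.

## Known limitations

- **The 5%-of-max range is not a calibrated confidence interval**, although
  ranges of this kind are conventionally reported as 95% intervals in the
  NLR literature. With many taxa centered on the same climate the combined
  likelihood sharpens like $\sigma/\sqrt{n}$, while the envelope means
  retain a small availability bias (occurrence sampling happens on the
  discrete manifold of extant cell climates, where the six variables
  co-vary, so fitted marginal sds are systematically smaller than the
  generating sds). Truth coverage of the range is therefore high but not
  guaranteed, and varies between grid realizations; the ≥80% coverage used
  in the tests is a design target for the stated study conditions, not a
  general calibration claim.
- Averaging co-located reconstructions weights every record equally,
  regardless of its range width.
- The comparand for model–reconstruction RMSE (range midpoint vs
  most-likely value) is an argument; published tables of this kind rarely
  state theirs, so any comparison should report which was used.
- The rotation stage applies a single Euler rotation (or a per-site lookup
  table); it does not implement a full plate-motion model.
- Grids are exchanged as a self-describing plain-text long-format CSV with
  explicit dimensions and units (mm/month, °C) rather than a binary array
  format; the format is lossless for the grid sizes used here but not
  intended for high-resolution global archives.

## Reproducibility

Every stochastic step takes an explicit integer seed, and the pipeline
driver (`run_pipeline()`) derives deterministic per-stage substream seeds
from one top-level seed, so identical configuration plus seed yields
byte-identical tabular artifacts; the manifest records the configuration
hash and the MD5 of every artifact. Generators are bit-reproducible under a
fixed seed.
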