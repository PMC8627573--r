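---
title: "Comparative lipidomics across depth and temperature: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative lipidomics across depth and temperature: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenofa)
```

## The scientific problem

Marine ectotherms adjust the fatty acid composition of their membranes to
keep biophysical properties (fluidity, phase behavior) within a workable
range as temperature and hydrostatic pressure change — homeoviscous
adaptation. Testing whether depth (a pressure proxy) and temperature leave
*distinct* signatures in fatty acid profiles requires comparing many
species that live in different habitats, and species are not independent
observations: close relatives resemble each other for reasons of ancestry
alone. `ctenofa` implements the full chain of analysis for such a study:

1. **GC-MS relative quantitation** of fatty acid methyl esters (FAMEs) and
   fatty alcohols from external-standard calibration series;
2. **lipidome summary metrics** per specimen (double bond index, mean chain
   length, saturation classes, odd-chain and alcohol totals);
3. **phylogenetically generalized least squares (PGLS)** under an
   Ornstein–Uhlenbeck (OU) correlation structure, with specimens attached
   to a species tree, environmental slicing of the specimen set, and Holm
   familywise error control.

A synthetic-data generator produces every input with known ground truth,
so the whole pipeline is testable end to end without any external data.

## Quantitation model

Each standard compound is injected at a series of GC inlet split ratios
$s$. We take the on-column fraction to be $1/(1+s)$ and regress the
integrated signal on it **through the origin**: signal must vanish when
nothing reaches the column, and the instrument response is linear in
on-column mass over the calibrated range. The slope is the compound's
*mass ionization coefficient* $k^{\mathrm{mass}}$ (counts per unit
split-normalized mass); dividing by molar mass gives the *molar
ionization coefficient* $k$. The axis convention is isolated in
`on_column_fraction()`, so an alternative definition is a one-line change;
with noise-free data the fitted slope is exact regardless of the
convention used to generate it, because generation and fitting share the
transform's inverse relationship only through the standards table itself.

For a sample with single-ion integrals $A_i$, mole fractions follow by
closure over the calibrated ("known") compounds:

$$x_i = \frac{A_i / k_i}{\sum_j A_j / k_j}.$$

Any per-sample scale (injection volume, detector drift common to all
peaks) cancels; the tests assert this scale invariance directly.

**Quantitation ions.** Integration uses each compound's base peak unless
compounds coelute. For coeluters we pick the most intense target ion that
is at least *tenfold* more abundant (relative to each spectrum's base
peak) than in every coeluting spectrum; the equivalent share form — the
target holds at least a 0.9 share of the summed intensity, i.e. a
$\geq 9\times$ margin — is available as `rule = "share"`. Both are
implemented because the two phrasings differ slightly at the margin
($10\times$ vs $9\times$); the tenfold inequality is the default because
it is the stricter and more explicitly stated rule. Ties break toward
lower m/z for determinism. When no ion passes, the error names the pair:
that is a real analytical failure (unresolvable coelution), not a case to
paper over.

**Detection test.** A compound counts as detected when a one-tailed
one-sample t-test of mean mole fraction $> 0$ survives Holm adjustment
across compounds at $\alpha = 0.05$. Before testing, a single pass removes
observations more than six standard deviations from the mean, with mean
and SD computed leaving the observation under test out. The leave-one-out
form matters: a lone spike among $n$ observations can never sit more than
about $\sqrt{n}$ *full-sample* SDs from the mean, so a six-sigma rule
computed naively would never fire at realistic sample sizes. The pass is
simultaneous (every point judged against the others) and not iterated, so
the rule stays deterministic and order-free.

## Summary metrics

The double bond index is the mole-fraction-weighted mean number of double
bonds per chain; mean chain length is the weighted mean carbon count. By
default both are computed on the **even-chain fatty acid pool**, with the
pool renormalized to sum to one. Renormalization makes each metric a true
weighted mean of that pool — without it, a sample rich in alcohols or
odd-chain acids would see its DBI shrink for reasons unrelated to
unsaturation. Because the even-chain restriction and renormalization are a
modeling choice rather than a mathematical necessity, `basis = "all_fa"`
widens the pool to all fatty acids. Saturation classes (SFA = 0 double
bonds, MUFA = 1, PUFA ≥ 2) partition the fatty-acid fraction; odd-chain
(OCFA) and fatty-alcohol totals are reported separately. Odd-chain acids
keep their saturation class, so SFA + MUFA + PUFA + alcohols close to 1.

## The regression model

For a response $y$ (e.g. DBI) and predictor $z$ (depth in km, or
temperature in °C) over $n$ specimens:

$$y = \beta_0 + \beta_1 z + \varepsilon,\qquad
  \varepsilon \sim \mathcal{N}\!\left(0,\ \sigma^2 C(\alpha)\right),\qquad
  C_{ij} = e^{-\alpha\, d_{ij}},$$

where $d_{ij}$ is patristic distance between specimens on the
individual-expanded tree and $\alpha \ge 0$ is the OU selection strength.
Large residual disagreement between close relatives is strong evidence
about the regression line, and the GLS weighting honors that; the test
suite checks the property directionally on a fixed four-tip tree.

Implementation choices, each of which was genuinely open:

- **Individual attachment.** Specimens join the species tree as terminal
  polytomies on branches of length $\varepsilon = 10^{-3}$ × tree height
  (configurable). Exactly zero-length attachment would duplicate rows of
  $C$ and make it singular, so $\varepsilon = 0$ is rejected rather than
  regularized silently.
- **Height normalization.** $\alpha$ has units of inverse distance, so
  distances are divided by tree height before fitting; estimates are
  comparable across trees regardless of branch-length scale.
- **Profiling $\alpha$.** Per regression, $\log\alpha$ is profiled by ML
  over $[-6, 6]$ (25-point grid, then golden-section refinement of the
  best interior bracket). At the upper bound $C \approx I$, so an
  ordinary regression is reachable as a special case; on a star phylogeny
  PGLS and OLS agree to machine precision for the slope t-test because an
  equicorrelated $C$ drops out of the centered problem entirely.
- **Numerics.** $C$ is factored triangularly (Cholesky) and the model
  whitened; $C$ is never inverted explicitly. Coefficient covariance uses
  the unbiased $\hat\sigma^2 = \mathrm{RSS}_C/(n-p)$ so that the identity
  correlation reproduces `lm` exactly; the reported log-likelihood uses
  the ML $\hat\sigma^2 = \mathrm{RSS}_C/n$. Slope inference is a
  two-sided t-test on $n-2$ degrees of freedom.

### Slicing and multiplicity

Depth confounds with temperature in most of the ocean, so depth
regressions use only specimens with body temperature ≤ 7.5 °C and
temperature regressions only specimens collected at ≤ 200 m. Both
thresholds are **inclusive** by default, following the operational ≤ form
(a flag switches to strict). Specimens in neither slice are excluded from
environmental regressions but retained for summary statistics and
intercorrelations, which use the full specimen set.

Holm families are one response panel × one predictor: the five summary
metrics, the six major FAMEs, the C17 odd-chain pair (temperature only),
and the alcohol total each form a family per predictor. Within-species
ordinary regressions (species with $n \ge 6$ in the relevant slice) take
the responses within one species × predictor as a family, and the four
intercorrelation pairs form one family. Holm controls familywise type I
error *within a family*; no claim is made about the union of all families,
and the operating-characteristic simulation below measures exactly the
per-family rate for that reason.

## What the generator emulates — and what it does not

`simulate_study()` draws, in order:

- a **coalescent species tree**, rescaled to height 1 (binary, ultrametric,
  strictly positive branch lengths);
- **habitats**: each species belongs to one locale; each locale has a
  monotone temperature profile
  $T(z) = T_{\mathrm{deep}} + (T_{\mathrm{surf}} - T_{\mathrm{deep}})
  e^{-z/z_{\mathrm{scale}}}$ (Arctic: near-isothermal cold column bounded
  in $[-2, 7.5]$ °C; temperate and tropical: thermoclines). Collection
  depths are drawn shallow-biased (quadratic), and three strata
  (shallow-warm, shallow-cold, deep-cold) are forced non-empty so both
  analysis slices always exist;
- **compositions**: per compound, a latent coordinate = baseline +
  species-level OU deviation (exact multivariate-normal draw from the
  stationary covariance $\sigma^2 e^{-\alpha d}$, not a path simulation) +
  linear depth and temperature effects + individual noise; the profile is
  the softmax of the latent vector, so every profile is a valid simplex
  and environmental effects are linear on the latent (log-ratio) scale;
- **GC-MS fixtures**: an 8-point split-ratio calibration series per
  compound lying exactly on a line through the origin, per-sample peak
  integrals equal to true moles × molar coefficient × a per-sample scale,
  and reference spectra in which one designated pair (C20:5/C22:6 by
  default) shares its base peak so quantitation-ion selection is
  genuinely exercised.

The default compound panel holds the six major even-chain FAMEs plus
C15:0, C17:0, C17:1 and the C22:1(n-9) fatty alcohol, with baselines near
field-typical mole fractions (C16:0 ≈ 0.35, C22:6 ≈ 0.20, OCFAs at the
percent level). Default latent effect sizes encode the qualitative
structure under study — deeper → more C18:1 at the expense of SFAs,
warmer → C18:0 up / C14:0 down, a C17:0/C17:1 temperature exchange, polar
alcohol enrichment — at order-of-magnitude scale (0.03–0.25 latent units
per °C or per km). No published effect sizes exist in these natural
units, which is precisely why they are configuration, not constants.

Features of real data deliberately *not* emulated: chromatographic
drift and retention-time alignment, detector saturation, spectral overlap
beyond the single designated coelution, diet-driven covariance between
compounds, and ocean structure beyond a monotone temperature profile.
Passing tests therefore demonstrate that the pipeline's statistics do
what they claim under their own assumptions — not that those assumptions
hold for any particular field dataset.

## Operating characteristics

Two simulation experiments quantify the regression machinery; both run at
desk scale and are recomputed from scratch by `scripts/acceptance.R`:

- **Slope recovery** (`pgls_coverage_sim()`): 200 studies of 200
  individuals over 20 taxa, true depth slope 1 per km, residuals drawn
  from the exact stationary OU covariance on the individual-expanded tree
  ($\alpha = 3$, $\sigma = 0.5$), $\alpha$ re-profiled per fit. The 95% CI
  covers the truth in ≈ 95% of replicates and the slope sign is recovered
  in all. The experiment is run at the level of the regression model —
  not through the softmax generator — because the softmax link makes the
  induced slope of DBI on depth a nonlinear functional with no closed
  form, so "covers the true slope" is only well-posed on the latent-linear
  model. Sign recovery *through* the full compositional pipeline is
  checked separately by the battery power test (an injected C18:1–depth
  effect must surface with the right sign and survive Holm).
- **Familywise error** (`battery_fwer_sim()`): 200 null studies (species
  and individual variance on, environmental effects zero) through the
  full compositional generator, metrics, the cold-slice summary family,
  and Holm. The fraction of replicates with any rejection stays within
  the binomial band around the nominal 0.05.

Problem sizes used throughout the tests (50-sample round trips, 100
random GLS instances at $n \le 8$, 200-replicate simulations,
permutations of p-vectors to length 8) were chosen as the smallest scales
at which each property is convincingly exercised.

## Worked example

```{r example, eval = FALSE}
st <- simulate_study(sim_config(n_taxa = 8, individuals_per_taxon = 6,
                                seed = 11))
res <- run_analysis(st$tree, st$specimens,
                    standards = st$standards, peaks = st$peaks,
                    spectra = st$spectra, coelution = st$coelution)
subset(res$battery, family == "summary x depth",
       c(response, n, slope, p, p_holm, significant))
```

With this seed the default generator's depth effects surface as
significant SFA decline and MUFA increase with depth in the cold slice
(see the README for the printed output), mirroring the qualitative
structure the defaults encode.

## Known limitations

- The OU correlation assumes a single $\alpha$ per regression; individual
  noise on top of species-level OU structure is absorbed by inflating
  $\hat\alpha$ rather than modeled as a separate variance component
  (no "measurement error" / Pagel's-$\lambda$-style mixture).
- Closure (compositions summing to 1) induces negative dependence among
  fractions; intercorrelation results must be read with that in mind.
  The pipeline reports them as the field does, without a log-ratio
  transform.
- `alpha = 0` (all-ones correlation) is flagged non-invertible rather
  than fitted; the profile search therefore runs over strictly positive
  $\alpha$.
- Degrees of freedom for the slope test are $n - 2$ even though $\alpha$
  is estimated; the coverage simulation shows the effect is negligible at
  the scales used here.
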