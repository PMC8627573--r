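# ctenofa

Comparative lipidomics of marine ectotherm fatty acid profiles across
depth and temperature gradients.

Animals regulate membrane lipid composition to hold fluidity and phase
behavior in a workable range (homeoviscous adaptation). In the ocean,
low temperature and high hydrostatic pressure both order membranes, so
separating their adaptive signatures requires sampling many species
across habitats — and species are not independent data points: close
relatives resemble each other through shared ancestry. `ctenofa` is for
researchers running exactly this kind of study design on GC-MS fatty
acid data: it takes external-standard calibration series, integrated
peak tables and a species phylogeny, and produces phylogenetically
corrected regressions of lipidome properties on environmental
predictors.

## What it implements

**GC-MS relative quantitation.** The calibration signal of each standard
at split ratio *s* is regressed through the origin against the on-column
fraction 1/(1+s); the slope is the mass ionization coefficient, divided
by molar mass to give the molar coefficient *k*. Sample mole fractions
then follow by closure over calibrated compounds:

    x_i = (A_i / k_i) / Σ_j (A_j / k_j)

with single-ion integrals *A* taken on each compound's base peak, or —
for coeluting compounds — on the most intense ion at least tenfold more
abundant than in every coeluting spectrum. A one-tailed t-test with
Holm correction (after leave-one-out six-sigma outlier removal) decides
which compounds are detected at significant levels.

**Lipidome summaries.** Double bond index (DBI) and mean chain length as
mole-fraction-weighted means over the renormalized even-chain fatty acid
pool; SFA/MUFA/PUFA saturation-class totals; odd-chain (OCFA) and
fatty-alcohol totals.

**OU-PGLS regression.** Generalized least squares with residual
correlation exp(−α·d) in patristic distance d on the species tree, with
conspecific specimens attached as terminal polytomies, tree height
normalized to 1, α profiled by maximum likelihood per regression (the
ordinary-regression limit is reachable at the large-α bound), and Holm
familywise control within each response-panel × predictor family. Depth
regressions use specimens at ≤ 7.5 °C; temperature regressions use
specimens at ≤ 200 m.

**Synthetic studies.** `simulate_study()` generates trees, habitat
profiles, compositions (species-level Ornstein–Uhlenbeck traits plus
linear environmental effects, mapped to the simplex by softmax) and
GC-MS fixtures with known ground truth, so every stage of the pipeline
is testable end to end.

## Worked example

```r
library(ctenofa)

st  <- simulate_study(sim_config(n_taxa = 8, individuals_per_taxon = 6,
                                 seed = 11))
res <- run_analysis(st$tree, st$specimens,
                    standards = st$standards, peaks = st$peaks,
                    spectra = st$spectra, coelution = st$coelution)
subset(res$battery, family == "summary x depth",
       c(response, n, slope, p, p_holm, significant))
```

```
      response  n    slope        p   p_holm significant
1          dbi 41 -0.01536 7.61e-01 1.00e+00       FALSE
2 chain_length 41  0.02588 5.83e-01 1.00e+00       FALSE
3          sfa 41 -0.02861 6.93e-04 2.77e-03        TRUE
4         mufa 41  0.03675 4.19e-10 2.10e-09        TRUE
5         pufa 41 -0.00753 3.84e-01 1.00e+00       FALSE
```

This is the cold-slice (≤ 7.5 °C) depth family: 41 of the 48 simulated
specimens qualify, and after Holm adjustment within the family the SFA
fraction declines with depth (slope −0.029 per km, adjusted P = 0.0028)
while MUFA rises (+0.037 per km, adjusted P = 2.1e−9) — the default
generator injects exactly this deep-water SFA→C18:1 exchange, and the
battery recovers it. Slopes are in response units per km of depth.
Per-sample metrics look like:

```
  sample_id  dbi chain_length   sfa   mufa  pufa   ocfa alcohol
1   sp01_01 2.45         18.4 0.508 0.0776 0.396 0.0369  0.0181
2   sp01_02 2.69         18.6 0.446 0.1044 0.430 0.0327  0.0200
3   sp01_03 2.20         18.1 0.551 0.0780 0.353 0.0307  0.0187
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/ctenofa` (subcommands `simulate`, `quant`, `metrics`,
`regress`, `run`).

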