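# ctsbss — blind source separation for compositional time series

`ctsbss` decomposes strictly positive compositional time series —
wavelength-resolved absorbance records, relative-abundance series,
chemical fractions — into latent uncorrelated source series. Such data
carry only relative information, so the package first expresses the
composition in isometric log-ratio (ilr) coordinates,
`x_ilr = V' clr(x)` with a column-orthonormal, zero-column-sum contrast
matrix `V`, and assumes there the blind source separation model

    x_ilr(t) = mu + Omega z(t),

with full-rank mixing `Omega` and latent series `z` with uncorrelated
unit-variance components. The estimand is an unmixing matrix `Gamma`
with `Gamma Omega` a signed, scaled permutation. Nine estimators cover
the main identifiability regimes:

| Model assumption | Estimators | Information used |
|---|---|---|
| stationary, serially correlated | `amuse`, `sobi` | lagged autocovariances |
| stochastic volatility | `gfobi`, `gjade`, `vsobi` | fourth-order cross-moments / cumulants / nonquadratic contrasts |
| nonstationary variance | `nss_sd`, `nss_jd`, `nss_td_jd` | interval covariances (and lags) |
| unknown / mixed | `nss_sobi_gfobi` | interval autocovariances **and** fourth-moment matrices in one weighted joint diagonalization |

The combined estimator `nss_sobi_gfobi` is the workhorse for data whose
latent nature is unknown: it whitens globally, splits the range into K
intervals, stacks per-interval autocovariance matrices (lags `lags1`)
and fourth-order cross-moment matrices (lags `lags2`), applies a weight
scheme (`equal`, `kurtosis` = B-matrices / (p+2), or `maxnorm` =
1/max|entry| when that exceeds 1), and jointly diagonalizes the stack by
cyclic Jacobi rotations. Results map back to interpretable zero-sum clr
loadings (`Gamma W' V'`) and to reconstructed compositions.

Practical extras: timestamp-gap-aware moment estimation (only pairs at
exactly the declared lag enter), covariance-PCA pre-reduction for wide
compositions, the minimum distance index (MD) for benchmarking unmixing
matrices, synthetic linear-process / GARCH / log-volatility generators,
and a simulation harness.

## Worked example

```r
library(ctsbss)

# a mixed-nature scenario: 2 linear + 2 GARCH latent sources, mapped to
# a 5-part composition of length 2000
sim <- generate_scenario(scenario_spec("MIX", setting = 1, T = 2000),
                         seed = 1)
d <- cts_decompose(sim$x, method = "nss_sobi_gfobi", K = 6,
                   lags1 = 0:6, lags2 = 0:6, scheme = "maxnorm")
d
#> CTS decomposition (nss_sobi_gfobi): 5 parts -> 4 sources

md_index(d$bss$unmixing, sim$Omega)
#> Minimum distance index: 0.0847

round(d$clr_loadings, 3)
#>    part1  part2  part3  part4  part5
#> z1 0.010  0.864 -0.298 -0.300 -0.276
#> z2 0.040 -0.001 -0.051  0.709 -0.697
#> z3 0.894 -0.214 -0.244 -0.271 -0.165
#> z4 0.023  0.019  0.803 -0.355 -0.490
```

The MD index compares the estimated unmixing with the true mixing used
by the simulator: 0 is perfect separation, 1 no separation; 0.08 at
T = 2000 means the four sources are recovered nearly perfectly up to
sign and order. Each clr-loadings row sums to zero and shows which parts
a source drives against which (source z1 is essentially the log-ratio of
part2 against parts 3–5). Back-transformation of any source subset gives
the compositional signal those sources carry:

```r
rec <- cts_reconstruct(d, components = 1:2)
round(head(rec$values, 3), 4)
#>       part1  part2  part3  part4  part5
#> [1,] 0.2020 0.1942 0.1952 0.2406 0.1680
#> [2,] 0.1966 0.1302 0.2274 0.2182 0.2276
#> [3,] 0.1902 0.1040 0.2412 0.2046 0.2599
```

A command-line front end ships in `inst/exec/ctsbss`:

```sh
ctsbss decompose --input data.csv --grid "10 min" --method nss_sobi_gfobi \
    --K 6 --lags1 6,12,...,72 --lags2 78,84,...,144 --weights maxnorm \
    --pca 0.999 --seed 42 --out outdir/
ctsbss benchmark --reps 200 --setting 1 --out table1.csv
```

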