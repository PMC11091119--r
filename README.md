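# vertibelt

Cloud-model analysis of mountain vegetation vertical belts.

On a forested mountain, vegetation types succeed one another with
elevation, but the belts are not sharply bounded: each has a **core zone**
of permanent establishment plus **upper and lower extension zones** where
its stands mix with the neighbouring belts. `vertibelt` quantifies both the
macro-pattern and the fuzziness of this structure. It is written for
quantitative ecologists and biogeographers working with a DEM and a
forest-inventory stand map (species composition in tenths plus a dominant
species code per stand).

The statistical core is the **normal cloud model**. A belt's distribution
height is summarised by three numerical features estimated from sampled
elevations x₁…xₙ by the backward cloud generator:

    Ex = x̄
    En = sqrt(π/2) · (1/n) Σ |xᵢ − Ex|
    He = sqrt(S − En²),   S the sample variance (divisor n − 1)

Ex locates the belt centre, En measures the fuzziness of its height range,
and He the dispersion of that fuzziness (the randomness of the patches).
The forward generator inverts the model, drawing droplets
En′ ~ N(En, He), x ~ N(Ex, En′) with membership
C(x) = exp(−(x − Ex)² / 2En′²) for cloud maps. Around the core, the
pipeline provides: forest typing from composition tenths (the ≥7-tenths
purity rule), 50 m elevation-bin area-proportion profiles, core/extension
delineation via the mean-proportion threshold rule, 200 m grid sampling
with Horn-aspect sunny/shady stratification, per-stratum cloud fitting,
and between-type expectation differences. A synthetic single-peak mountain
generator with analytic ground truth stands in for proprietary inventory
data.

## Worked example

```r
library(vertibelt)

cfg    <- synthetic_config(seed = 42)          # 200 x 200 cells, 25 m
dem    <- generate_dem(cfg)
stands <- classify_stand_map(generate_stand_map(cfg, dem))

profile <- bin_proportions(stands, dem)        # 50 m bins
scheme  <- zone_scheme(profile)
scheme$deciduous_broadleaf
#> <zone_entry> deciduous_broadleaf: threshold 45.04%
#>   core  [450, 800) m
#>   lower (-Inf, 450) m
#>   upper [800, Inf) m

pts <- sample_points(dem, stands, scheme)      # 625 points at 200 m spacing
zc  <- zone_cloud_table(pts)
head(zc$parameters, 3)
#>           forest_type  zone   n    ex_m     en_m     he_m degenerate
#> 1 deciduous_broadleaf  core 105 614.438 102.3969  0.00000       TRUE
#> 2 deciduous_broadleaf lower  29 356.858  63.4504 12.99824      FALSE
#> 3 deciduous_broadleaf upper   8 841.410  32.1882 11.74018      FALSE
```

The deciduous belt on this synthetic mountain centres near 614 m in its
core with En ≈ 102 m of fuzziness; its lower extension centres ≈ 258 m
lower with a tighter spread. A `degenerate` flag marks strata whose
He radicand was negative (platykurtic samples — typical for the
near-uniform elevations of a plateau-shaped core) and was clamped to 0.

Between-type expectation differences, fed with the published Mount
Taishan unit cloud parameters shipped in the package:

```r
tab <- taishan_unit_clouds()
ex_differences(tab[tab$elev_class %in% c("<550", "900-1100"), ],
               c("deciduous_broadleaf", "mixed"))
#> <ex_diff_table> |Ex(deciduous_broadleaf) - Ex(mixed)| over 4 unit(s)
#>  elev_class aspect_class abs_ex_diff_m
#>        <550        shady         39.15
#>        <550        sunny         36.94
#>    900-1100        shady         22.82
#>    900-1100        sunny         28.77
#> pooled range: 22.82 - 39.15 m
```

Deciduous-vs-mixed belt centres differ by 22.82–39.15 m in these
elevation classes while conifer-vs-mixed gaps (same call with
`temperate_conifer`) span only 4.79–7.94 m — the signature of broadleaf
species encroaching on conifer habitat at low elevation.

The whole analysis also runs as one call (or from a shell via
`inst/scripts/vertibelt.R`):

```r
run_pipeline(list(simulate = list(n_rows = 500, n_cols = 500, seed = 9)),
             "out/")   # profile.csv, zone_scheme.yaml, sample_points.csv,
                       # zone/unit cloud tables, skipped_strata.csv,
                       # ex-difference tables, droplets.csv, cloud_*.png
```

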