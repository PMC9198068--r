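# pdindex

Infrastructure-based physical distancing risk mapping from clustered
household survey data.

Many households in low- and middle-income countries cannot comply with
physical distancing guidance during an epidemic: they share toilets with
other households, fetch water from public sources, sleep several people to
a room, and own no phone or vehicle. `pdindex` builds a **physical
distancing index (PDI)** that quantifies this constraint at household,
regional and pixel level, for epidemiologists and policy analysts who need
to rank subnational regions by transmission risk attributable to missing
private infrastructure.

## The model

Five deprivation-oriented indicators per household — other households
sharing the toilet (count), public water source (binary), persons per
sleeping room, no mobile phone, no vehicle — are z-scored and projected on
the first principal component of their correlation matrix:

    s_i = Σ_j v_j (x_ij − x̄_j) / σ_j,   v = leading eigenvector of R, ‖v‖ = 1,

sign-fixed so higher score = more deprived. Regional indices are weighted
means with weight `sample_weight × log(1 + population density)` and are
min-max normalized so the most deprived region scores 1. Pixel maps come
from a conjugate Gaussian penalized tensor-product B-spline fit to
cluster-level mean scores (GCV-selected smoothing, closed-form prediction
sd). A synthetic generator produces DHS-like clustered microdata — a
spatially correlated latent deprivation factor driving all five
indicators, displaced cluster GPS coordinates, sample weights, a density
raster, and regional caseloads — so the whole pipeline is testable without
restricted survey data. See `vignettes/pdi-methods.Rmd` for the full
methods account.

## Worked example

The numbered drivers under `analysis/` run the whole study and write their
tables under `results/study/` (regenerated on each run; not committed):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_index.R
Rscript analysis/03_aggregate.R
Rscript analysis/04_surface.R
Rscript analysis/05_validate.R
```

Output of the run at the committed configuration:

```
simulated 15000 households in 600 clusters, 30 regions
  sharing a toilet: 47.8% (mean 1.88 other households among sharers)
  public water source: 42.3%   persons per room: 3.22
  no mobile: 31.9%   no vehicle: 52.7%
first component explains 70.3% of the indicator variance
loadings (all positive => higher score = more deprived):
    share_toilet     public_water persons_per_room           no_ict       no_vehicle
           0.431            0.465            0.440            0.448            0.451
aggregated 30 regions (15000 households)
fitted surface on 600 clusters: lambda = 4.64, edf = 63.8, sigma = 6.406
PDI vs caseload over 30 regions: Pearson 0.65, Spearman 0.79
recovery of latent regional deprivation: Spearman 0.98
leave-one-indicator-out correlations with the full index:
    share_toilet     public_water persons_per_room           no_ict       no_vehicle
           0.986            0.988            0.987            0.987            0.987
```

Reading: the marginal indicator rates match the generator's calibration
targets (45% shared sanitation, 40% public water, 3.2 persons/room); one
principal component carries ~70% of the indicator variance with
near-uniform positive loadings, as expected under a one-factor model; the
normalized regional PDI ranks regions almost exactly like the latent
deprivation that generated them (Spearman 0.98) while correlating 0.79
with the noisy detected caseloads; and dropping any single indicator
leaves the index essentially unchanged (all correlations ≥ 0.98).

The same pipeline runs programmatically:

```r
library(pdindex)
res <- run_pipeline(synthetic_config(seed = 1), "out", surface = TRUE)
res$report$spearman$correlation   # PDI vs caseload
```

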