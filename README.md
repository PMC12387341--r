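# woodscreen

Screening woody plant species for tolerance to **sequential drought–heat
stress**: an R implementation of the physiological, histochemical and
statistical analysis layer of a dual-stress screening workflow for trees.

Urban forestry and restoration programs need tree species that survive
weeks of drought followed by acute heat.  Screening candidates combines a
handful of quantitative assays, and this package implements all of them
as tested, reproducible functions:

* **Stress indices** — relative water content
  (RWC = 100·(fresh − dry)/(turgid − dry)), electrolyte leakage
  (EL = κ_sample/κ_autoclaved) and its heat index
  (ELI = (EL_H − EL_C)/EL_C), the Evans-blue inhibition index
  (100·(A_H − A_NC)/(A_PC − A_NC)), and survival rate.
* **DAB image quantification** — hydrogen peroxide accumulation from
  8-bit RGB images of DAB-stained leaves: inverted red-channel stain
  scoring, greedy placement of three 100 × 100 px regions of interest on
  the most stained zones, HSV-saturation readout (0–255 scale) and
  background correction by the least-stained window.
* **Quadrant pre-screening** — z-standardized (RWC, ELI) scatter;
  quadrant II (high z-RWC, low z-ELI) species near validated tolerant
  references become candidates, quadrant IV species are flagged
  sensitive.
* **Recovery kinetics** — peak stress phase, sustained clearance time,
  net recovery and species ranking/clustering over a 14-phase
  stress/recovery schedule (control, H₂O₂ control, drought, 4 heat
  durations, 7 recovery durations).
* **Group statistics** — one-way ANOVA with Duncan's multiple range test
  (α = 0.05) and compact letter displays, including reconstruction from
  published mean ± SD tables.
* **Synthetic data generators** — stained-leaf images, dehydration
  series, conductivity sets, DAB kinetics and screening cohorts with
  known ground truth; every generator inverts its analysis exactly at
  zero noise.

The package also ships the published reference tables it reproduces: the
27-species screening panel, the 6-species × 14-phase DAB intensity table
and the index values printed for the validated reference species.

## Worked example

Classify the four validated species from their measured indices:

```r
library(woodscreen)
pairs <- data.frame(species = c("Co", "Qm", "Qg", "Aj"),
                    rwc = c(78.2, 76.8, 72.9, 35.6),
                    eli = c(1.78, 2.94, 2.68, 8.00))
classify(pairs, references = c("Co", "Qm", "Qg"))
#> Tolerance screen: 4 species, references Co,Qm,Qg, radius 1.00
#>   species  rwc  eli  z_rwc  z_eli quadrant     class distance_to_reference
#> 1      Co 78.2 1.78  0.607 -0.736       II  tolerant                 0.268
#> 2      Qm 76.8 2.94  0.538 -0.324       II  tolerant                 0.173
#> 3      Qg 72.9 2.68  0.346 -0.416       II  tolerant                 0.169
#> 4      Aj 35.6 8.00 -1.491  1.476       IV sensitive                 2.798
```

The three hinoki-cypress/oak references land in quadrant II (water
retaining, membrane stable); the silk tree *Albizia julibrissin* lands in
quadrant IV and is called sensitive — matching its observed 8.3 %
survival under the dual stress.

Quantify a synthetic DAB-stained leaf with programmed saturation 120:

```r
g <- gen_leaf_image(seed = 1, stain_saturation = 120)
quantify(g$image)
#> DAB quantification: 3 ROI(s) of 100x100 px (stride 25)
#>   background saturation: 0.00
#>   corrected saturation:  119.85 +/- 0.00
```

The quantifier recovers the programmed value to within 8-bit rounding.
Rank the six published species by recovery endpoint (phase N, 480 min):

```r
rank_species(load_dab_table())
#>   species endpoint_n net_recovery rank
#> 1      Tj       38.9         49.3    1
#> 2      Aj       70.7        -21.6    2
#> 3    Csin      104.9        -34.7    3
#> 4      Qs      137.9         -5.7    4
#> 5      Qp      139.6        -13.7    5
#> 6      Qa      143.0        -29.6    6
```

*Ternstroemia japonica* (Tj) clears hydrogen peroxide fastest and ranks
first — the most resilient species in the panel.

## Package layout

| Area | Files |
| --- | --- |
| Fixtures and I/O | `R/fixtures.R`, `R/io.R` |
| Stress indices | `R/indices.R` |
| DAB quantification | `R/dab.R` |
| Screening classifier | `R/screening.R` |
| Recovery kinetics | `R/kinetics.R` |
| ANOVA + Duncan letters | `R/stats.R` |
| Synthetic generators | `R/synthetic.R` |
| Workflow + reports | `R/pipeline.R`, `inst/cli/woodscreen.R` |

The methods vignette (`vignettes/methods.Rmd`) documents the model
conventions, numerical choices and the limits of what the synthetic data
can demonstrate.
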