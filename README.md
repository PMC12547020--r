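# gpcrtraffic

Quantification and statistics for yeast GPCR-trafficking experiments.

When budding yeast sense nutrient stress (or the TORC1 inhibitor rapamycin),
they remove the mating-pheromone receptors Ste2/Ste3 from the plasma membrane
and route them toward the vacuole, dampening the pheromone response. Studies
of this process rest on a handful of quantitative readouts, and this package
implements that full quantification layer as tested, reusable code:

1. **Peripheral membrane abundance** — per-cell mean receptor intensity in a
   morphological ring at the cell edge. Each cell label is eroded with a
   1-px diamond so neighbors detach, components under 5000 px are dropped,
   and the ring is the cell minus its 7-px diamond erosion. Intensities are
   measured after pseudo-flat-field correction (image minus its sigma-50
   Gaussian blur) and expressed as percentages of the control-group mean.
2. **Vacuolar cargo phenotype** — from a two-channel line scan through the
   vacuole, the two most prominent peaks of the vacuole-membrane marker
   (e.g. Vph1) and their flanking positions define the membrane; positions
   between them define the lumen. A cell is scored cargo-**full** when the
   receptor's lumen:membrane ratio exceeds 1, cargo-**empty** below 1.
3. **Dose–response** — reporter fluorescence normalized to culture density
   (A600) and per-dose means fit to a four-parameter Hill equation,
   y(d) = b + Emax · dⁿ / (EC50ⁿ + dⁿ),
   by bounded least squares (lower bounds 0). Parameter differences between
   genotypes are called significant when 95% confidence intervals do not
   overlap.
4. **Group statistics** — Welch t tests, one-way ANOVA with Tukey HSD,
   percentile-bootstrap CIs, and the rescue-category rule for mutants under
   drug: different only from untreated WT = *no rescue*; from both WT arms =
   *partial rescue*; only from treated WT = *complete rescue*.
5. **Mating efficiency** — dilution-corrected percentage of mating-competent
   cells that formed diploids, compared by a one-tailed Welch test.

Because raw microscopy of this kind is rarely public, the package ships a
synthetic-data module (`render_field`, `gen_profiles`, `gen_dose_response`,
`gen_mating_counts`) that generates every input with known ground truth —
fields of elliptical cells with bright membrane rings, illumination
gradients and Poisson/read noise; two-peak line profiles; noisy Hill plates;
binomial colony counts. Effect presets (`builtin_presets()`) encode the
relative changes under study, so every stage is validated by parameter
recovery.

## Worked example

Simulate control and *ypk1*Δ-like reporter plates, fit both Hill curves, and
compare Emax by CI overlap:

```r
library(gpcrtraffic)
tab <- rbind(gen_dose_response("control", seed = 42),
             gen_dose_response("ypk1_delta", seed = 43))
fits <- fit_hill_groups(tab)
sapply(fits, function(f) round(f$estimate, 3))
#>         control ypk1_delta
#> b        51.703     39.029
#> emax   1004.942   5476.114
#> ec50      0.985      0.669
#> hill_n    1.255      1.109
ci_overlap_significant(fits$control, fits$ypk1_delta, "emax")
#> [1] "significant"
```

The control fit recovers the generating parameters (b = 50, Emax = 1000,
EC50 = 1 µM, n = 1.2) to within the plate noise, and the mutant's fitted
Emax is 5.45× the control (generator truth 5.33×) with disjoint confidence
intervals — the fold increase in maximal mating-gene transcription.

Classify one vacuole line scan (marker channel with peaks at positions 3
and 7, receptor channel dim in the lumen):

```r
classify_vacuole(marker = c(1, 2, 10, 3, 2, 3, 10, 2, 1),
                 cargo  = c(0, 0, 5, 1, 1, 1, 5, 0, 0), min_sep = 3)
#> $peak_left:  3      $peak_right: 7
#> $mem_mean:   2      $lum_mean:   1
#> $ratio:      0.5    $klass:      "empty"
```

The lumen:membrane ratio of 0.5 marks this vacuole cargo-empty.

The numbered scripts under `analysis/` run the complete workflow on
synthetic cohorts — peripheral quantification (`01`), vacuole phenotyping
(`02`), dose–response fitting (`03`), mating assays (`04`) and rescue
classification (`05`) — each printing what it finds and writing its tables
under `results/`.

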