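# posE13C

Carbon-position-resolved ¹³C enrichment analysis of aspartate from GC-MS
in-source fragment ions.

## The problem

Photoautotrophs (cyanobacteria, algae, plants) assimilate inorganic
carbon through two carboxylases: RUBISCO, whose carbon ends up in
position 1-C of aspartate (via 3-phosphoglycerate), and PEPC, which fixes
bicarbonate directly into position 4-C (via oxaloacetate); the CBB cycle
redistributes fixed carbon into 2-C and 3-C. Whole-molecule ¹³C
enrichment after a ¹³CO₂ pulse cannot separate these fluxes. GC in-source
fragmentation can: silylated aspartic acid yields fragment ions covering
carbon subsets {1,2,3,4}, {2,3,4}, {2,3} and {3,4}, and because a
fragment's fractional enrichment E¹³C is the mean over its covered
positions, the per-position enrichments follow by carbon-number-weighted
differences:

    e1 = 4·E{1234} − 3·E{234}
    e2 = 3·E{234} − 2·E{34}
    e3 = 2·E{23} + 2·E{34} − 3·E{234}
    e4 = 3·E{234} − 2·E{23}

Upstream, each fragment MID is corrected for natural isotope abundance by
non-negative least squares against a correction matrix built from its
molecular formula (column *j* = natural pattern of the non-backbone atoms
⊗ *j*-shift ⊗ binomial natural ¹³C of the unlabeled backbone carbons).
Downstream, positional enrichments are multiplied by internal-standard
calibrated aspartate concentrations and the resulting molar ¹³C time
courses are fitted with a zero-baseline logistic
y(t) = y_max / (1 + exp(−k(t − t_mid))); the maximal assimilation rate is
k·y_max/4 at the half-max time t_mid. Position 4-C rates are an in vivo
proxy of PEPC activity, 1-C of RUBISCO activity.

The package is a library plus a thin CLI (`inst/cli/pose13c`), with a
synthetic-data generator replacing instrument data: standard-mixture
panels, day/night pulse-labeling time courses, and centroided mzML
fixtures. See the methods vignette
(`vignettes/positional-enrichment.Rmd`) for the full model description,
parameter defaults and limitations.

## Worked example

Validate accuracy and precision on the simulated 36-mixture × 4-replicate
certified-standards panel at 25 ng:

```r
library(posE13C)
report <- run_standards_validation(seed = 1)
print(report)
#> Standards validation report
#> Positional accuracy/precision (percentage points):
#>  position     mean_dev    sd_dev   n pass_accuracy pass_precision
#>         1  0.048864491 0.4926895 144          TRUE           TRUE
#>         2 -0.015935850 0.4386631 144          TRUE           TRUE
#>         3  0.129285630 0.5445907 144          TRUE           TRUE
#>         4 -0.001450503 0.4420984 144          TRUE           TRUE
#> ...
#> PASS (bounds: accuracy < 1, precision < 2.5, fragment < 1.1)
```

`mean_dev` is the accuracy (mean deviation of measured from expected
E¹³C, percentage points) and `sd_dev` the precision (SD of that
deviation) at each carbon position over all 144 panel measurements; both
sit well inside the < 1 / < 2.5 point bounds.

Analyze simulated day/night ¹³CO₂ pulse labeling:

```r
rates <- run_labeling_analysis(seed = 7)
rates$rate_summary
#>   position condition n_determined n_replicates max_slope half_max_time     status
#>          1      dark            0            4        NA            NA         ND
#>          4      dark            4            4  1.514186      43.88144 determined
#>          1     light            4            4  4.800905      22.10875 determined
#>          4     light            4            4  4.819120      21.19993 determined
```

In the dark the 1-C (RUBISCO) rate is not determined — no sigmoidal
signal exists — while the 4-C (PEPC) rate is positive but lower and later
than in the light (units: pmol · OD₇₅₀⁻¹ · mL⁻¹ · min⁻¹ for `max_slope`,
min for `half_max_time`). In the light, 1-C and 4-C rates are similar, as
generated.

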