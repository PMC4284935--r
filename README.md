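# discHb — optic disc hemoglobin colorimetry from fundus photographs

Axonal loss in the optic nerve shows up at the fundus as papillary pallor,
but an examiner's eye cannot quantify pallor — by the time it is obvious,
a large share of the nerve fibers is gone. The optic nerve head is the one
fundus structure whose color is dominated by a single pigment, hemoglobin
(Hb), so *measuring its color measures its perfusion and tissue content*.
discHb estimates the relative Hb content of optic disc tissue from an
ordinary RGB fundus photograph and provides the cohort statistics needed
to compare a patient group (e.g. Parkinson's disease) against healthy
controls. It is aimed at ophthalmic imaging researchers who want a fully
open, testable implementation of vessel-referenced disc colorimetry.

## The measurement

Hb-rich tissue reflects mainly red light; pale tissue reflects red and
green about equally. For each disc pixel with reflectances (r, g, b):

    h   = (r − g̃) / max(r, ε)          per-pixel red–green contrast
    Hb% = 100 · h_pixel / h_vessel      vessel-referenced percentage

where g̃ is the green value corrected for crystalline-lens yellowing and
`h_vessel` comes from the per-channel medians of the central retinal
vessel pixels — columns of pure blood (100% Hb by definition) that see the
same illumination and ocular media as the tissue around them, so shared
optical factors cancel. Lens yellowing is estimated from the vessels'
blue:green ratio (blue attenuated by κ, green by (1+κ)/2) and undone
multiplicatively. The disc is then partitioned into 24 sectors — eight 45°
wedges × three concentric rings at 1/3 and 2/3 of the disc radius — and
Hb is reported as a mean plus 24 sector percentages per eye. Group
comparisons use pooled-variance Student t tests with Bonferroni
correction per measurement family (0.05/25 = 0.002 for the Hb family),
a Lilliefors-style Kolmogorov–Smirnov normality gate, and Pearson
correlations against retinal nerve fiber layer (RNFL) thickness tables.

Because no public dataset pairs fundus photographs with per-sector Hb
ground truth, the package ships a synthetic fundus generator (two-endmember
optical mixing, branching vessel tree, illumination gradient, lens model,
sensor noise — deliberately *not* the estimator's inverse) with exact
ground truth, plus cohort-level draws matching published group parameter
tables, so the whole pipeline is validated end to end.

## Worked example

```r
library(discHb)

## one synthetic subject with known truth, full pipeline
r   <- renderFundus(subjectSpec(subjectId = "demo", seed = 42))
fit <- analyzeFundus(r$image)
fit$qc
#> QCReport: PASS (mean luminance 0.333; saturated 0.000/0.000/0.000)
fit$disc
#> DiscGeometry (right eye): center (256.0, 256.0), semi-axes 79.9 x 76.0 px
fit$lens
#> LensCompensation: kappaHat 0.999, greenScale 1.000
fit$profile
#> SectorProfile 'demo' (right eye, anatomical frame): mean Hb 66.4%
#>   sectors 1-24: 71.8 71.2 67 69.5 71.6 66.3 62 68.3 66.8 55.6 56.2 59.8
#>   54.8 52.5 58.1 58.1 61.9 64.5 67.9 74.3 75.1 71.9 80.9 73.3
mean(r$trueHb[r$tissue])   # generator ground truth for this subject
#> 68.1
```

The QC report gates exposure, the disc ellipse is recovered to sub-pixel
accuracy, the clear-lens image yields κ̂ ≈ 1 (compensation is the
identity), and the estimated mean Hb of 66.4% sits about 1.7 points below
this subject's true 68.1% — the known mild compressive bias of the index
against the generator's independent forward model.

```r
## a small simulated two-group cohort through the full image pipeline
cc  <- generateCohort(cohortParams(nPd = 12, nHealthy = 12,
                                   imageSize = 256, seed = 7))
tab <- analyzeCohort(cc)
rows <- compareGroups(tab, c("mean_hb", paste0("hb_", 1:24)))
formatComparison(rows)[1:2, ]
#>   variable       Healthy            PD      P significant
#> 1  mean_hb  67.14 (2.22)  56.01 (3.70) <0.001        TRUE
#> 2     hb_1 73.01 (10.01) 68.04 (14.62)  0.341       FALSE
```

Even at n = 12 per arm the mean-Hb difference clears the Bonferroni
family threshold (significance here means p < 0.05/25 = 0.002), while
single noisy sectors do not — the same qualitative picture reported for
real cohorts, where differences concentrate in the outer (neuroretinal
rim) ring.

A thin command-line wrapper over the same functions lives in
`inst/scripts/discHb-cli.R` (subcommands `qc`, `segment`, `analyze`,
`simulate`, `cohort`).

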