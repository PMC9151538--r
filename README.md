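# lesionmorph

Morphometry and statistics for radiofrequency (RF) catheter-ablation
lesions in ex vivo cardiac tissue.

In RF ablation, current delivered through the catheter tip electrode
necrotizes a patch of myocardium. How large and how deep that lesion gets
depends on the catheter **contact force** (gram-force), the **contact
angle** between catheter and tissue (0° = parallel, 90° = perpendicular),
and through them the **contact area** — the tissue footprint of the tip
electrode. `lesionmorph` is for researchers quantifying these
relationships from bench experiments: it implements the image-analysis
pipeline that turns lesion photographs into calibrated measurements, a
synthetic photograph generator with exact ground truth for validating that
pipeline, and the statistical layer relating force, angle and contact area
to lesion area and depth.

## What is inside

**Condition tables.** The published measurement grid of an ex vivo porcine
study — 5 contact angles × 8 contact forces, n = 6 ablations per cell — is
shipped as checksummed CSV fixtures: mean ± SD lesion area (mm²), mean ±
SD lesion depth (mm), and the lesion-area / contact-area ratio per cell.
The contact-area grid X is recovered by inverting the ratio,
X = Ȳ / ratio.

**Morphometry.** The pipeline follows the standard photographic workflow:
calibrate pixels to mm, segment candidate lesions, convert to grayscale
(Rec.601), threshold at 40% of the white level (resolving the graded
"reversible injury" rim), fill holes, then measure each region — area from
the pixel count, centroid and ellipse-equivalent major/minor axes from
second central moments — rotate the major axis vertical, classify the
morphology (ellipse / oval / circle), and measure maximum depth below the
tissue surface on bisected views.

**Statistics.** Pearson and Spearman correlation with exact t-distribution
p-values (df = n − 2) and Evans verbal labels; logarithmic
(y = a·ln z + b) versus linear least-squares comparison by R²; pooled
t-tests; and a balanced-design identity that reconstructs the
replicate-level Pearson correlation (n = 240) from cell means and SDs
alone:

    S_zy = m Σ (z_i − z̄)(ȳ_i − ȳ)
    S_zz = m Σ (z_i − z̄)²
    S_yy = m Σ (ȳ_i − ȳ)² + Σ (m − 1) s_i²
    r    = S_zy / √(S_zz · S_yy)

valid because the predictor (force) is constant within each cell of a
balanced design.

## Worked example

```r
library(lesionmorph)

# force-lesion area correlation at the replicate level
area <- load_lesion_area_table()
pearson_balanced_raw(area, "force_gf")
#> Pearson correlation: (+) 0.7816 (strong), n = 240, two-sided P = 1.062e-50

# contact angle is a (weak, negative) determinant of lesion area
pearson_test(area$angle_deg, area$mean)
#> Pearson correlation: (-) 0.3688 (weak), n = 40, two-sided P = 0.01919

# recover the contact-area grid and fit X = a ln(Z) + b at 90 degrees
X <- recover_contact_area_table()
x90 <- subset(X, angle_deg == 90)
fit_log(x90$force_gf, x90$mean)
#> y = 2.692 ln(z) + 0.8904   (R^2 = 0.8933, n = 8)

# validate the image pipeline on a synthetic lesion with known truth
sp <- lesion_spec("ellipse", 4, 2, orientation_deg = 37,
                  center_mm = c(10, 10), border_width_mm = 0)
fr <- generate_top_view(list(sp), mm_per_pixel = 0.05,
                        width_px = 400, height_px = 400)
measure_top_view(calibrate(fr))[[1]]
#> <lesion_region> area 25.16 mm^2, axes 8.00 x 4.01 mm,
#>   orientation 0.1 deg, class ellipse
spec_area_mm2(sp)   # analytic truth: pi * 4 * 2
#> [1] 25.13274
```

The first call says that across all 240 ablations, higher contact force
goes with larger lesions (r = 0.78, "strong"); the second that lesions
shrink as the catheter tilts toward perpendicular; the log fit quantifies
how the recovered contact area saturates with force; and the last block
shows the pipeline recovering a known ellipse's area (0.1% error), axes
and orientation.

A full in-silico replica of the study design is available through
`run_config()`, `simulate_panels()` and `measure_panels()`, and
`reproduce_tables()` recomputes every headline statistic from the fixtures
with pass/fail flags against its printed reference.

## Documentation

The methods vignette (`vignettes/lesion-morphometry.Rmd`) describes the
model assumptions, the synthetic-image generator and its limits, the
numerical conventions (thresholding, moments, rotation, depth), and the
design decisions behind the classifier and the statistics.
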