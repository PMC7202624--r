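# pcleQuant

Fully automatic quantification of alveolar elastin structure in
probe-based confocal laser endomicroscopy (pCLE) images.

pCLE produces circular-field-of-view grayscale snapshots of the
autofluorescent elastin web bounding the alveolar mouths (600 µm FOV on
the clinical probe). In diffuse parenchymal lung diseases (COP, HP,
NSIP, IPF) this web thickens and gains intricacy. pcleQuant reduces a
snapshot to three structural readouts and compares patient groups
against normal tissue:

* **T<sub>med</sub>** — median local thickness of the network (µm). At each pixel
  of the topology-preserved skeleton, the local thickness is
  T<sub>local</sub> = 2·d<sub>np</sub>, twice the Euclidean distance to the nearest
  background pixel.
* **σ<sub>T</sub>** — standard deviation of T<sub>local</sub> (µm, population convention).
* **C<sub>s</sub>** — structural connectivity (mm⁻¹): the number of enclosed
  holes of the segmented network, obtained from its Euler number,
  divided by the total skeleton length
  (C<sub>s</sub> = N<sub>holes</sub> / L<sub>skeleton</sub>).

The pipeline is: trainable pixel classification (multi-scale filter
bank → random undersampling → correlation-based feature selection →
information-gain-ratio ranking → 200-tree random forest) →
physical-unit mask cleaning (holes separated by walls thinner than 2 µm
merged, holes under 30 µm equivalent diameter filled) → skeleton
metrics → per-group two-tailed Wilcoxon rank-sum tests with Bonferroni
correction. A synthetic phantom generator (Voronoi ribbon networks with
exact mask, hole-count and width ground truth) makes every stage
testable without patient data. See the methods vignette
(`vignettes/elastin-quantification.Rmd`) for conventions and
assumptions.

## Worked example

```r
library(pcleQuant)

# a normal-like phantom at the clinical FOV scale (600 um across 192 px)
ph <- generate_phantom(phantom_spec(image_size_px = 192, n_seeds = 24,
                                    width_um_mean = 12, width_um_sd = 2,
                                    seed = 1))
ph$image
#> pcle_image 'phantom-seed1': 192 x 192 px, 3.125 um/px (FOV 192 px across)

# measure its ground-truth mask (bypassing the classifier)
quantify_mask(segmentation_mask(ph$truth$true_mask, ph$truth$spacing_um,
                                ph$truth$fov_mask))
#> structure_metrics: T_med = 12.5 um, sigma_T = 2.3 um, C_s = 2.30 /mm (8 holes, 3481 um skeleton)

# a severely disrupted phantom: more alveolar mouths, thicker, more
# variable ribbons -- all three readouts rise
sev <- generate_phantom(phantom_spec(image_size_px = 192, n_seeds = 60,
                                     width_um_mean = 20, width_um_sd = 6,
                                     seed = 2))
quantify_mask(segmentation_mask(sev$truth$true_mask, sev$truth$spacing_um,
                                sev$truth$fov_mask))
#> structure_metrics: T_med = 22.5 um, sigma_T = 12.3 um, C_s = 3.85 /mm (21 holes, 5456 um skeleton)
```

T<sub>med</sub> recovers the rendered ribbon width (12.5 vs 12 µm nominal), the
hole count equals the generator's flood-fill ground truth (8), and the
disrupted phantom scores higher on all three readouts — the same
ordering that separates DPLD from normal parenchyma clinically.

For a full cohort run (segmentation with a trained model, first-snapshot
selection, group statistics, Table-style report):

```r
res <- run_pipeline(manifest, model, pipeline_config(spacing_um = 600/576),
                    out_dir = "out")   # metrics.csv, report.csv, run_metadata.json
```

or from the shell via the CLI
(`Rscript inst/cli/pclequant.R <phantom|train|segment|quantify|cohort-stats|run> ...`).

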