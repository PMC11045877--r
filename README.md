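# biadquant

Quantification of dual-color bimolecular anchor detector (BiAD)
fluorescence microscopy.

BiAD sensors read out the chromatin-modification state of a single genomic
locus in single cells: a dCas9/sgRNA anchor marks the locus, a
modification-specific reader domain binds the local chromatin mark, and
each module carries half of a split fluorophore, so fluorescence
complementation occurs only where anchor and reader meet. In the dual-color
design a full-length marker fluorophore (YPet, recruited via MS2 hairpins
on the sgRNA) labels the locus independently of the modification signal
(reconstituted IFP2.0), which makes a ratiometric readout possible:
BiAD signal relative to marker signal, per locus, independent of the local
sgRNA binding-site copy number that sets spot brightness.

This package is for microscopists and chromatin biologists who have such
two- or three-channel nuclear images (or want to validate an analysis
against simulated ground truth before acquiring them). It implements the
full quantification chain:

1. **Projection and channel binding** — multi-page TIFF z-stacks to 2D
   maximum-intensity projections, channels bound to semantic roles
   (`MARKER`, `BIAD`, `STAIN`, `NUCSTAIN`) explicitly, never guessed from
   metadata.
2. **Two-threshold segmentation** — a low marker threshold defines the
   nucleus (the background ROI), a high threshold the brightest marker
   spots, at most six per cell; manual per-cell thresholds or automatic
   (Otsu nucleus + within-nucleus quantile spot threshold).
3. **Relative BiAD signal** — per spot *s* with nuclear background *n*:

   ```
   r_s = (BiAD_s − BiAD_n) / (Marker_s − Marker_n)
   ```

   averaged over a cell's spots to give one value per cell (the dot in the
   boxplots).
4. **Normalizations** — per-spot Xi/Xa classification against an
   immunostain territory with per-cell Xa-normalization (Xi values read as
   fold enrichment over the active X), and control-detector normalization
   of treatment arms (values read as fold change over a binding-deficient
   mutant).
5. **Statistics** — two-tailed unpaired t tests (Welch default, Student
   optional), one-way ANOVA with Tukey's post test, 1.5-IQR boxplot
   summaries with replicate-colored points.
6. **Simulation** — a generator for synthetic nuclei with
   copy-number-scaled marker spots, detector-dependent BiAD amplitudes,
   stain territories, transfection dropout and Poisson + Gaussian camera
   noise, carrying full ground truth for every stage.

## Worked example

Simulate one cell whose three loci carry a 50% modification occupancy read
by a wild-type detector, then quantify it:

```r
library(biadquant)

cfg <- simulationConfig(seed = 7, modification_fraction = 0.5)
sim <- simulateCell(cfg, cell_id = "demo")
sim
#> SimulatedCell 'demo': 3 locus/loci, true ratios 0.5, 0.5, 0.5

q <- quantifyCell(simImage(sim), simThresholds(cfg))
q$spots[, c("spot_id", "area", "corrected_marker", "corrected_biad",
            "relative_biad")]
#>  spot_id area corrected_marker corrected_biad relative_biad
#>        1   51        1915.7750      962.99029     0.5026636
#>        2   49         757.6935      382.84706     0.5052796
#>        3   51         180.0495       89.62309     0.4977693
q$cell[, c("cell_id", "mean_relative_biad", "spot_count")]
#>  cell_id mean_relative_biad spot_count
#>     demo          0.5019041          3
```

The three spots differ ~10-fold in marker brightness (copy numbers 45,
160, 392 at the default gain), yet all recover a relative BiAD signal near
the configured 0.5 — the point of the ratiometric readout. A group
comparison of 15 wild-type against 15 binding-deficient mutant cells:

```r
wt  <- lapply(1:15, function(i) simulateCell(
  simulationConfig(seed = 100 + i, modification_fraction = 0.5),
  sprintf("wt_%02d", i)))
mut <- lapply(1:15, function(i) simulateCell(
  simulationConfig(seed = 200 + i, modification_fraction = 0.5,
                   detector_efficiency = 0), sprintf("mut_%02d", i)))
cells <- c(wt, mut)
names(cells) <- vapply(cells, function(s) cellId(simImage(s)), "")
sheet <- data.frame(cell_id = names(cells),
                    condition = rep(c("WT", "W42A"), each = 15),
                    treatment = "none",
                    replicate = rep(c("rep1", "rep2", "rep3"), 10))
res <- runQuantify(cells, sample_sheet = sheet,
                   thresholds = simThresholds(simulationConfig()))
cmp <- runCompare(res$cells)
cmp$comparison
#> GroupComparison [t_test_two_tailed_unpaired]
#>   groups: WT, W42A
#>   means:  0.4996, -0.0004443
#>   statistic = 414.8, p = 1.008e-39
```

The mutant detector cannot bind the mark, so its BiAD amplitude is zero
and its per-cell signals scatter around 0; the wild-type group sits at the
configured 0.5. `runQuantify` also returns a QC ledger (`res$qc`) in which
every input cell appears exactly once, either analyzed or excluded with a
reason code, and the per-cell thresholds used (`res$thresholds`).

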