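test_that("background subtraction preserves sign and cancels offsets", {
  expect_equal(backgroundSubtract(500, 200), 300)
  expect_equal(backgroundSubtract(200, 200), 0)
  expect_equal(backgroundSubtract(150, 200), -50)  # not clamped
  expect_equal(backgroundSubtract(c(500, 150), c(200, 200)), c(300, -50))
})

test_that("per-spot ratios and per-cell means follow the ratiometric model", {
  img <- toy_cell(ratio = 0.5, amps = c(400, 200))
  q <- quantifyCell(img, toy_thresholds())
  expect_equal(q$spots$relative_biad, c(0.5, 0.5))
  expect_equal(q$cell$mean_relative_biad, 0.5)
  expect_equal(q$cell$spot_count, 2L)

  # mutant null: flat BiAD channel gives exactly zero
  img0 <- toy_cell(ratio = 0, amps = c(400, 200))
  q0 <- quantifyCell(img0, toy_thresholds())
  expect_equal(q0$spots$relative_biad, c(0, 0))

  # negatives participate in the cell mean
  expect_equal(cellMeanBiad(data.frame(
    cell_id = "x", spot_id = 1:3, area = 9,
    corrected_marker = 1, corrected_biad = c(0.2, -0.1, 0.5),
    relative_biad = c(0.2, -0.1, 0.5), valid = TRUE,
    allele = "unlabeled"))$mean_relative_biad, 0.2)
  expect_error(cellMeanBiad(data.frame(relative_biad = 1, valid = FALSE)),
               class = "biad_qc_error")
  # missing BIAD channel is a configuration error
  img_nob <- CellImage(list(MARKER = getChannel(img, "MARKER")))
  expect_error(quantifyCell(img_nob, toy_thresholds()),
               class = "biad_config_error")
})

test_that("ratios are invariant to gain and offset, linear in BiAD-only gain", {
  cfg <- wt_config(19, ratio = 0.5)
  img <- simImage(simulateCell(cfg))
  thr <- simThresholds(cfg)
  base <- quantifyCell(img, thr)$spots$relative_biad

  g <- 2.5
  both <- CellImage(list(MARKER = getChannel(img, "MARKER") * g,
                         BIAD = getChannel(img, "BIAD") * g), cell_id = "g")
  r_both <- quantifyCell(both, ThresholdPair(thr@nucleus * g,
                                             thr@spot * g))$spots$relative_biad
  expect_equal(r_both, base, tolerance = 1e-12)

  off <- CellImage(list(MARKER = getChannel(img, "MARKER") + 37,
                        BIAD = getChannel(img, "BIAD") + 81), cell_id = "o")
  r_off <- quantifyCell(off, ThresholdPair(thr@nucleus + 37,
                                           thr@spot + 37))$spots$relative_biad
  expect_equal(r_off, base, tolerance = 1e-9)

  bg <- CellImage(list(MARKER = getChannel(img, "MARKER"),
                       BIAD = getChannel(img, "BIAD") * g), cell_id = "bg")
  r_bg <- quantifyCell(bg, thr)$spots$relative_biad
  expect_equal(r_bg, base * g, tolerance = 1e-12)
})

test_that("relative BiAD is independent of copy number; marker scales with it", {
  cfgs <- lapply(c(45, 90, 180, 392, 1000), function(cn)
    simulationConfig(seed = 31, n_loci = 2L, copy_number = cn,
                     modification_fraction = 0.5, noise_poisson = FALSE,
                     read_sigma = 0))
  res <- lapply(cfgs, function(cfg) {
    q <- quantifyCell(simImage(simulateCell(cfg)), simThresholds(cfg))
    c(ratio = mean(q$spots$relative_biad),
      marker = mean(q$spots$corrected_marker))
  })
  ratios <- vapply(res, `[[`, 0, "ratio")
  markers <- vapply(res, `[[`, 0, "marker")
  expect_equal(ratios, rep(0.5, 5), tolerance = 1e-10)
  expect_true(all(diff(markers) > 0))
})

test_that("allele classification follows the inclusive 0.5 overlap rule", {
  mk_spot <- function(rows, cols) {
    m <- matrix(FALSE, 10, 10)
    m[rows, cols] <- TRUE
    new("SpotRegion", mask = m, centroid = c(mean(rows), mean(cols)),
        area = as.integer(sum(m)), meanIntensity = c(MARKER = 1),
        spotId = 1L)
  }
  stain <- matrix(FALSE, 10, 10)
  stain[1:10, 1:5] <- TRUE
  inside <- mk_spot(2:3, 2:3)       # overlap 1.0
  outside <- mk_spot(7:8, 7:8)      # overlap 0.0
  straddle <- mk_spot(2:3, 5:6)     # overlap exactly 0.5
  expect_identical(classifyAlleles(list(inside, outside, straddle), stain),
                   c("Xi", "Xa", "Xi"))
  expect_identical(classifyAlleles(list(straddle), stain,
                                   overlap_fraction_min = 0.6), "Xa")
  expect_error(classifyAlleles(list(inside), NULL),
               class = "biad_config_error")
})

test_that("Xa normalization anchors Xa spots at 1 and recovers enrichment", {
  sq <- data.frame(cell_id = "c1", spot_id = 1:3, area = 9,
                   corrected_marker = 1, corrected_biad = c(0.8, 0.4, 0.4),
                   relative_biad = c(0.8, 0.4, 0.4), valid = TRUE,
                   allele = c("Xi", "Xa", "Xa"))
  out <- normalizeToXa(sq)
  expect_equal(out$xa_normalized, c(2, 1, 1))
  # all-equal spots: no enrichment, everything 1
  sq2 <- sq
  sq2$relative_biad <- 0.4
  sq2$corrected_biad <- 0.4
  expect_equal(normalizeToXa(sq2)$xa_normalized, c(1, 1, 1))
  # within-cell Xa mean is exactly 1 even with unequal Xa spots
  sq3 <- sq
  sq3$relative_biad <- c(0.9, 0.3, 0.5)
  out3 <- normalizeToXa(sq3)
  expect_equal(mean(out3$xa_normalized[out3$allele == "Xa"]), 1,
               tolerance = 1e-12)
  # missing Xa spots or degenerate Xa mean exclude the cell
  sq4 <- sq
  sq4$allele <- c("Xi", "Xi", "Xi")
  expect_error(normalizeToXa(sq4), class = "biad_qc_error")
  sq5 <- sq
  sq5$relative_biad <- c(0.8, 0, 0)
  expect_error(normalizeToXa(sq5), class = "biad_qc_error")
})

test_that("noiseless allelic simulation recovers the configured enrichment", {
  cfg <- allelic_config(47, enrichment = 2, noise_poisson = FALSE,
                        read_sigma = 0)
  sim <- simulateCell(cfg, "al")
  q <- quantifyCell(simImage(sim), simThresholds(cfg), allelic = TRUE,
                    exclude_spots_from_background = TRUE)
  expect_setequal(q$spots$allele, c("Xi", "Xa"))
  expect_equal(sum(q$spots$allele == "Xi"), 1L)
  out <- normalizeToXa(q$spots)
  expect_equal(out$xa_normalized[out$allele == "Xi"], 2, tolerance = 1e-9)
})

test_that("control normalization anchors each arm at its own control mean", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:12),
    condition = rep(c("WT", "R44Q"), each = 3, times = 2),
    treatment = rep(c("DMSO", "DNMT1i"), each = 6),
    mean_relative_biad = c(0.6, 0.5, 0.7, 0.2, 0.25, 0.15,
                           0.3, 0.35, 0.25, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
  out <- normalizeToControl(cells, "R44Q")
  # per-arm loop oracle
  for (arm in unique(cells$treatment)) {
    sel <- cells$treatment == arm
    ctrl_mean <- mean(cells$mean_relative_biad[sel &
                                                 cells$condition == "R44Q"])
    expect_equal(out$control_normalized[sel],
                 cells$mean_relative_biad[sel] / ctrl_mean)
    expect_equal(mean(out$control_normalized[sel &
                                               out$condition == "R44Q"]), 1)
  }
  expect_equal(out$control_normalized[1L], 0.6 / 0.2)

  # too few control cells is a configuration error
  expect_error(normalizeToControl(cells[c(1:4, 7:12), ], "R44Q"),
               class = "biad_config_error")
  # degenerate control mean refuses normalization
  cells0 <- cells
  cells0$mean_relative_biad[cells0$condition == "R44Q" &
                              cells0$treatment == "DMSO"] <- 0
  expect_error(normalizeToControl(cells0, "R44Q"), class = "biad_qc_error")
})

test_that("spot QC summaries histogram counts per condition", {
  cells <- data.frame(cell_id = c("a", "b", "c"), condition = "WT",
                      spot_count = c(2L, 3L, 4L))
  qc <- spotQcSummary(cells)
  hist <- qc$WT$count_histogram
  expect_equal(as.vector(hist[as.character(2:4)]), c(1L, 1L, 1L))
  expect_equal(as.vector(hist[c("0", "1", "5", "6")]), rep(0L, 4))
  expect_identical(spotQcSummary(cells), spotQcSummary(cells))
  # area summaries come from the per-spot table
  spots <- data.frame(condition = "WT", area = c(9, 16, 25))
  qc2 <- spotQcSummary(cells, spots)
  expect_equal(unname(qc2$WT$area_summary[["Median"]]), 16)
})
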