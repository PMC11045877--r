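test_that("rendered nuclei have the configured geometry and intensities", {
  cfg <- simulationConfig(seed = 2, noise_poisson = FALSE, read_sigma = 0)
  set.seed(2)
  r <- renderNucleus(cfg)
  marker <- getChannel(r$image, "MARKER")
  expect_equal(sort(unique(as.vector(marker))), c(5, 100))
  expect_equal(unique(marker[r$nucleus_mask]), 100)
  expect_equal(unique(marker[!r$nucleus_mask]), 5)
  # area close to the ellipse area pi*a*b
  expect_equal(sum(r$nucleus_mask), pi * 40 * 30, tolerance = 0.01)
  # no stain base configured, no stain plane
  expect_false("STAIN" %in% channelRoles(r$image))
  expect_null(r$territory_mask)

  # oversized nucleus is rejected
  expect_error(simulationConfig(nucleus_axes = c(70, 70)), "exceed")
})

test_that("stain territory covers the requested nucleus fraction and Xi loci", {
  cfg <- allelic_config(5, territory_fraction = 0.2)
  set.seed(5)
  r <- renderNucleus(cfg)
  expect_false(is.null(r$territory_mask))
  frac <- sum(r$territory_mask) / sum(r$nucleus_mask)
  expect_equal(frac, 0.2, tolerance = 0.01)
  expect_true(all(r$territory_mask[r$nucleus_mask] |
                    !r$territory_mask[r$nucleus_mask]))
  # territory pixels carry the stain amplitude over the base
  stain <- getChannel(r$image, "STAIN")
  expect_equal(unique(stain[r$territory_mask]), 30 + 150)
  expect_equal(unique(stain[r$nucleus_mask & !r$territory_mask]), 30)

  # Xi loci land inside the territory, Xa outside
  sp <- renderSpots(r, cfg)
  for (i in seq_len(nrow(sp$truth))) {
    inside <- r$territory_mask[round(sp$truth$row[i]),
                               round(sp$truth$col[i])]
    expect_identical(inside, sp$truth$allele[i] == "Xi")
  }
})

test_that("spot amplitudes follow the linear copy-number and detector model", {
  cfg <- simulationConfig(seed = 8, n_loci = 2L, copy_number = c(100, 200),
                          marker_gain = 5, modification_fraction = 0.5,
                          noise_poisson = FALSE, read_sigma = 0)
  set.seed(8)
  sp <- renderSpots(renderNucleus(cfg), cfg)
  marker <- getChannel(sp$image, "MARKER")
  biad <- getChannel(sp$image, "BIAD")
  for (i in 1:2) {
    ri <- round(sp$truth$row[i]); ci <- round(sp$truth$col[i])
    expect_equal(marker[ri, ci], 100 + 5 * cfg@copyNumber[i])
    expect_equal(biad[ri, ci], 40 + 5 * cfg@copyNumber[i] * 0.5)
  }
  # doubling copy number doubles marker amplitude, leaves the ratio at 0.5
  expect_equal(sp$truth$true_ratio, c(0.5, 0.5))

  # mutant detector: zero BiAD amplitude everywhere
  cfg0 <- mutant_config(8, noise_poisson = FALSE, read_sigma = 0)
  sim0 <- simulateCell(cfg0)
  biad0 <- getChannel(simImage(sim0), "BIAD")
  expect_equal(unique(biad0[sim0@nucleusMask]), 40)   # flat despite spots
  expect_equal(unique(biad0[!sim0@nucleusMask]), 5)
  expect_equal(simTruth(sim0)$true_ratio, rep(0, 3))
})

test_that("noise model is identity when off, additive offset, Poisson mean", {
  cfg_off <- simulationConfig(seed = 3, noise_poisson = FALSE,
                              read_sigma = 0, offset = 0)
  img <- CellImage(list(MARKER = matrix(100, 20, 20),
                        BIAD = matrix(40, 20, 20)))
  expect_identical(getChannel(applyNoise(img, cfg_off), "MARKER"),
                   getChannel(img, "MARKER"))

  cfg_offset <- simulationConfig(seed = 3, noise_poisson = FALSE,
                                 read_sigma = 0, offset = 50)
  expect_equal(getChannel(applyNoise(img, cfg_offset), "MARKER"),
               matrix(150, 20, 20))

  cfg_p <- simulationConfig(seed = 3, noise_poisson = TRUE, read_sigma = 0)
  flat <- CellImage(list(MARKER = matrix(100, 100, 100)))
  set.seed(99)
  noisy <- getChannel(applyNoise(flat, cfg_p), "MARKER")
  se <- sqrt(100 / 1e4)
  expect_lt(abs(mean(noisy) - 100), 3 * se)
  expect_gt(stats::var(as.vector(noisy)), 50)  # shot noise present
})

test_that("a fixed seed fixes the full simulated output", {
  cfg <- wt_config(123, dropout_probability = 0.5)
  a <- simulateCell(cfg, "d")
  b <- simulateCell(cfg, "d")
  expect_identical(getChannel(simImage(a), "MARKER"),
                   getChannel(simImage(b), "MARKER"))
  expect_identical(simTruth(a), simTruth(b))
  # different seed, different field
  c2 <- simulateCell(wt_config(124, dropout_probability = 0.5), "d")
  expect_false(identical(getChannel(simImage(a), "MARKER"),
                         getChannel(simImage(c2), "MARKER")))
})

test_that("dropout zeroes BiAD amplitudes at the configured rate", {
  cfg1 <- wt_config(17, dropout_probability = 1)
  sim1 <- simulateCell(cfg1)
  expect_true(all(simTruth(sim1)$dropped_out))
  expect_equal(simTruth(sim1)$true_ratio, rep(0, 3))

  # rate check over cells (binomial 99% interval)
  n <- 200L
  p <- 0.3
  dropped <- vapply(seq_len(n), function(i) {
    cfg <- simulationConfig(seed = 1000L + i, n_loci = 1L,
                            image_size = c(48L, 48L),
                            nucleus_axes = c(14, 12), copy_number = 100,
                            noise_poisson = FALSE, read_sigma = 0,
                            dropout_probability = p)
    any(simTruth(simulateCell(cfg))$dropped_out)
  }, TRUE)
  ci <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(sum(dropped), ci[1L])
  expect_lte(sum(dropped), ci[2L])
})

test_that("simulated experiments write a coherent dataset to disk", {
  dir <- withr::local_tempdir()
  configs <- list(WT = wt_config(1, n_loci = 2L,
                                 image_size = c(96L, 96L),
                                 nucleus_axes = c(28, 22)),
                  W42A = mutant_config(2, image_size = c(96L, 96L),
                                       nucleus_axes = c(28, 22)))
  sim <- runSimulate(configs, n_cells = 3L, dir = dir)
  expect_length(sim$cells, 6L)
  expect_equal(nrow(sim$sample_sheet), 6L)
  expect_setequal(unique(sim$sample_sheet$condition), c("WT", "W42A"))
  expect_setequal(unique(sim$sample_sheet$replicate),
                  c("rep1", "rep2", "rep3"))
  expect_true(all(file.exists(sim$sample_sheet$path)))
  expect_true(file.exists(file.path(dir, "sample_sheet.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # determinism: regenerating gives identical ground truth and images
  dir2 <- withr::local_tempdir()
  sim2 <- runSimulate(configs, n_cells = 3L, dir = dir2)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(readBin(sim$sample_sheet$path[1L], "raw", 1e6),
                   readBin(sim2$sample_sheet$path[1L], "raw", 1e6))

  # written images reload and quantify to the same values as in memory
  sheet <- read.csv(file.path(dir, "sample_sheet.csv"),
                    stringsAsFactors = FALSE)
  res_disk <- runQuantify(sheet,
                          thresholds = simThresholds(configs$WT))
  res_mem <- runQuantify(sim$cells, sample_sheet = sheet,
                         thresholds = simThresholds(configs$WT))
  expect_equal(res_disk$cells$mean_relative_biad,
               res_mem$cells$mean_relative_biad, tolerance = 5e-3)
})

test_that("per-pixel spot SNR reflects the noise configuration", {
  expect_equal(simSpotSNR(wt_config(1, ratio = 0.5)), 10, tolerance = 0.01)
  expect_gt(simSpotSNR(allelic_config(1)), 10)
  noiseless <- wt_config(1, noise_poisson = FALSE, read_sigma = 0)
  expect_identical(simSpotSNR(noiseless), Inf)
})
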