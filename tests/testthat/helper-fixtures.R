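# Shared fixture builders. Simulation settings follow the study regime:
# nuclei of ~40 x 30 px semi-axes at 128 px frames for full-fidelity cases,
# 96 px frames with 2 loci where many cells are simulated.

# two-channel image with a rectangular "nucleus" and hand-placed square
# spots; everything about it is analytically known
toy_cell <- function(base_marker = 100, base_biad = 40, background = 5,
                     ratio = 0.5, amps = c(400, 200), cell_id = "toy") {
  m <- matrix(background, 40, 40)
  b <- matrix(background, 40, 40)
  m[6:35, 6:35] <- base_marker
  b[6:35, 6:35] <- base_biad
  centers <- list(c(12, 12), c(26, 26))
  for (i in seq_along(amps)) {
    rr <- centers[[i]][1L] + (-1:1)
    cc <- centers[[i]][2L] + (-1:1)
    m[rr, cc] <- m[rr, cc] + amps[i]
    b[rr, cc] <- b[rr, cc] + amps[i] * ratio
  }
  CellImage(list(MARKER = m, BIAD = b), cell_id = cell_id)
}

toy_thresholds <- function() ThresholdPair(50, 250)

# wild-type detector configuration at a per-pixel BiAD spot SNR of ~10
# (dimmest locus); true per-spot ratio set by modification_fraction
wt_config <- function(seed, ratio = 0.5, n_loci = 3L, ...) {
  simulationConfig(seed = seed, n_loci = n_loci,
                   copy_number = c(58, 160, 392)[seq_len(n_loci)],
                   modification_fraction = ratio,
                   detector_efficiency = 1, ...)
}

# binding-pocket mutant detector: zero BiAD amplitude at every locus
mutant_config <- function(seed, ...) {
  simulationConfig(seed = seed, n_loci = 3L,
                   copy_number = c(58, 160, 392),
                   modification_fraction = 0.5,
                   detector_efficiency = 0, ...)
}

# allelic configuration: one Xi locus (2x BiAD enrichment) + two Xa loci,
# stain channel with a territory over the Xi locus
allelic_config <- function(seed, enrichment = 2, ...) {
  simulationConfig(seed = seed, n_loci = 3L, copy_number = 160,
                   modification_fraction = 0.5,
                   base_intensity = c(MARKER = 100, BIAD = 40, STAIN = 30),
                   xi_loci = 1L, biad_enrichment = enrichment, ...)
}

# quantify a batch of simulated cells with config-derived manual thresholds
quantify_sim_batch <- function(config_fn, seeds, ...) {
  cells <- lapply(seq_along(seeds), function(i) {
    simulateCell(config_fn(seeds[i]), cell_id = sprintf("c%03d", i))
  })
  names(cells) <- vapply(cells, function(s) cellId(simImage(s)), "")
  runQuantify(cells, thresholds = simThresholds(config_fn(seeds[1L])), ...)
}
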