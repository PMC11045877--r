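#' @include AllClasses.R
NULL

#' Simulation configuration for synthetic BiAD microscopy
#'
#' Describes one simulated cell population: nucleus geometry, channel base
#' intensities, marker loci (copy numbers, modification occupancy, Xi
#' membership), detector behavior, transfection dropout and the camera
#' noise model. All intensities are in expected-photon units; images are
#' written as 16-bit.
#'
#' @slot imageSize Integer (rows, cols).
#' @slot nucleusAxes Numeric semi-axes (row, col) of the elliptical nucleus
#'   in pixels.
#' @slot background Intensity outside the nucleus (all channels).
#' @slot baseIntensity Named intensities inside the nucleus; the names
#'   (\code{MARKER}, \code{BIAD}, optionally \code{STAIN}) define which
#'   channels are rendered.
#' @slot nLoci Number of marker loci (polyploidy; 2--4 typical).
#' @slot copyNumber Local sgRNA binding-site copy number per locus
#'   (recycled to \code{nLoci}).
#' @slot markerGain Marker intensity per repeat copy: the marker spot
#'   amplitude is \code{markerGain * copyNumber}, a linear brightness model.
#' @slot modificationFraction Chromatin-modification occupancy per locus in
#'   [0, 1] (recycled).
#' @slot detectorEfficiency Reader binding efficiency in [0, 1]; 0 models a
#'   binding-pocket mutant detector.
#' @slot biadGain BiAD-to-marker gain ratio of the optical setup.
#' @slot xiLoci Integer indices of loci on the inactive X.
#' @slot biadEnrichment Multiplicative BiAD enrichment of Xi loci.
#' @slot territoryFraction Stain-territory area as a fraction of the
#'   nucleus area (used when a STAIN base intensity is present).
#' @slot stainAmplitude Stain intensity added over the territory.
#' @slot dropoutProbability Probability that a cell lacks non-fluorescent
#'   sensor components and stays BiAD-negative despite visible marker
#'   spots.
#' @slot spotShape \code{"tophat"} (flat disc; exact analytic recovery) or
#'   \code{"gaussian"} (PSF-like).
#' @slot spotRadius Top-hat radius in pixels.
#' @slot spotSigma Gaussian sigma in pixels.
#' @slot minSeparation Minimum center-to-center distance between loci.
#' @slot noisePoisson Poisson (shot) noise on or off.
#' @slot readSigma Gaussian read-noise standard deviation.
#' @slot offset Constant camera offset added after noise.
#' @slot seed Integer seed; fixes the full output.
#' @export
setClass("SimulationConfig",
         representation(imageSize = "integer", nucleusAxes = "numeric",
                        background = "numeric", baseIntensity = "numeric",
                        nLoci = "integer", copyNumber = "numeric",
                        markerGain = "numeric",
                        modificationFraction = "numeric",
                        detectorEfficiency = "numeric", biadGain = "numeric",
                        xiLoci = "integer", biadEnrichment = "numeric",
                        territoryFraction = "numeric",
                        stainAmplitude = "numeric",
                        dropoutProbability = "numeric", spotShape = "character",
                        spotRadius = "numeric", spotSigma = "numeric",
                        minSeparation = "numeric", noisePoisson = "logical",
                        readSigma = "numeric", offset = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  p <- c(object@modificationFraction, object@detectorEfficiency,
         object@dropoutProbability, object@territoryFraction)
  if (any(p < 0 | p > 1)) return("probabilities/fractions must lie in [0, 1]")
  if (any(object@copyNumber < 1)) return("copy numbers must be >= 1")
  if (object@readSigma < 0) return("read_sigma must be non-negative")
  if (!object@spotShape %in% c("tophat", "gaussian"))
    return("spot shape must be 'tophat' or 'gaussian'")
  if (!"MARKER" %in% names(object@baseIntensity))
    return("a MARKER base intensity is required")
  if (length(object@xiLoci) &&
      any(object@xiLoci < 1L | object@xiLoci > object@nLoci))
    return("xi_loci indices out of range")
  if (any(2 * object@nucleusAxes + 2 * object@spotRadius + 4 >
          object@imageSize))
    return("nucleus axes exceed the image size")
  TRUE
})

#' @rdname SimulationConfig-class
#'
#' @param image_size,nucleus_axes,background,base_intensity,n_loci,copy_number
#'   See the corresponding slots.
#' @param marker_gain,modification_fraction,detector_efficiency,biad_gain
#'   See slots.
#' @param xi_loci,biad_enrichment,territory_fraction,stain_amplitude See
#'   slots.
#' @param dropout_probability,spot_shape,spot_radius,spot_sigma,min_separation
#'   See slots.
#' @param noise_poisson,read_sigma,offset,seed See slots.
#' @return A validated \linkS4class{SimulationConfig}.
#' @details Defaults emulate the published experimental regime: diploid to
#'   tetraploid cells with 2--4 marker loci, local repeat copy numbers
#'   spanning tens to hundreds (45--392 by default, the low end of the
#'   45 to >1,000 range seen at real target loci), fully modified loci read
#'   by a wild-type detector, and shot plus read noise of a scientific
#'   camera. Set \code{detector_efficiency = 0} for a binding-deficient
#'   mutant detector and \code{dropout_probability > 0} for
#'   transfection-incomplete cells.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' sim <- simulateCell(cfg)
#' sim
#' @export
simulationConfig <- function(image_size = c(128L, 128L),
                             nucleus_axes = c(40, 30),
                             background = 5,
                             base_intensity = c(MARKER = 100, BIAD = 40),
                             n_loci = 3L,
                             copy_number = c(45, 160, 392),
                             marker_gain = 5,
                             modification_fraction = 1,
                             detector_efficiency = 1,
                             biad_gain = 1,
                             xi_loci = integer(0),
                             biad_enrichment = 2,
                             territory_fraction = 0.2,
                             stain_amplitude = 150,
                             dropout_probability = 0,
                             spot_shape = c("tophat", "gaussian"),
                             spot_radius = 4,
                             spot_sigma = 2,
                             min_separation = NULL,
                             noise_poisson = TRUE,
                             read_sigma = 5,
                             offset = 0,
                             seed = 1L) {
  spot_shape <- match.arg(spot_shape)
  n_loci <- as.integer(n_loci)
  if (is.null(min_separation)) min_separation <- 2 * spot_radius + 4
  new("SimulationConfig",
      imageSize = as.integer(rep_len(image_size, 2L)),
      nucleusAxes = as.numeric(rep_len(nucleus_axes, 2L)),
      background = background, baseIntensity = base_intensity,
      nLoci = n_loci,
      copyNumber = rep_len(as.numeric(copy_number), n_loci),
      markerGain = marker_gain,
      modificationFraction = rep_len(modification_fraction, n_loci),
      detectorEfficiency = detector_efficiency, biadGain = biad_gain,
      xiLoci = as.integer(xi_loci), biadEnrichment = biad_enrichment,
      territoryFraction = territory_fraction,
      stainAmplitude = stain_amplitude,
      dropoutProbability = dropout_probability, spotShape = spot_shape,
      spotRadius = spot_radius, spotSigma = spot_sigma,
      minSeparation = min_separation, noisePoisson = noise_poisson,
      readSigma = read_sigma, offset = offset, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %dx%d px, %d loci (copies %s), detector eff %.2g\n",
    object@imageSize[1L], object@imageSize[2L], object@nLoci,
    paste(object@copyNumber, collapse = "/"), object@detectorEfficiency))
  cat(sprintf("  channels: %s | shape: %s | dropout: %.2g | seed: %d\n",
              paste(names(object@baseIntensity), collapse = ", "),
              object@spotShape, object@dropoutProbability, object@seed))
})

#' Simulated cell with ground truth
#'
#' @slot image The rendered \linkS4class{CellImage}.
#' @slot truth Per-locus data frame: \code{locus}, \code{row}, \code{col},
#'   \code{copy_number}, \code{allele}, \code{modification_fraction},
#'   \code{dropped_out}, \code{true_ratio} (the relative BiAD signal the
#'   pipeline should recover).
#' @slot nucleusMask Logical ground-truth nucleus mask.
#' @slot territoryMask Logical stain-territory mask, or \code{NULL}.
#' @export
setClass("SimulatedCell",
         representation(image = "CellImage", truth = "data.frame",
                        nucleusMask = "matrix", territoryMask = "ANY"))

setMethod("show", "SimulatedCell", function(object) {
  cat(sprintf("SimulatedCell '%s': %d locus/loci, true ratios %s\n",
              cellId(object@image), nrow(object@truth),
              paste(signif(object@truth$true_ratio, 3), collapse = ", ")))
})

#' Ground-truth accessor for simulated cells
#' @param x A \linkS4class{SimulatedCell}.
#' @return The per-locus truth data frame.
#' @export
simTruth <- function(x) {
  stopifnot(is(x, "SimulatedCell"))
  x@truth
}

#' Image accessor for simulated cells
#' @param x A \linkS4class{SimulatedCell}.
#' @return The rendered \linkS4class{CellImage}.
#' @export
simImage <- function(x) {
  stopifnot(is(x, "SimulatedCell"))
  x@image
}

# per-locus true relative BiAD ratio implied by a config (before dropout)
.trueRatios <- function(config) {
  r <- config@detectorEfficiency * config@modificationFraction *
    config@biadGain
  if (length(config@xiLoci))
    r[config@xiLoci] <- r[config@xiLoci] * config@biadEnrichment
  r
}

#' Render the noiseless nucleus
#'
#' An elliptical nucleus at the per-channel base intensities over a dark
#' background. When the configuration carries a \code{STAIN} base
#' intensity, a connected stain territory — the \code{territory_fraction}
#' of nucleus pixels closest to the territory center — receives an
#' additional \code{stain_amplitude}. The territory center is drawn inside
#' the nucleus (uses the RNG; seed under caller control).
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param cell_id Identifier for the rendered image.
#' @return List: \code{image} (noiseless \linkS4class{CellImage}),
#'   \code{nucleus_mask}, \code{territory_mask} (\code{NULL} without a
#'   STAIN channel), \code{territory_center}.
#' @export
renderNucleus <- function(config, cell_id = "cell") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nr <- config@imageSize[1L]; nc <- config@imageSize[2L]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ay <- config@nucleusAxes[1L]; ax <- config@nucleusAxes[2L]
  rowd <- (seq_len(nr) - cy) / ay
  cold <- (seq_len(nc) - cx) / ax
  nucleus <- outer(rowd^2, cold^2, `+`) <= 1
  channels <- lapply(config@baseIntensity, function(base) {
    plane <- matrix(config@background, nr, nc)
    plane[nucleus] <- base
    plane
  })
  territory <- NULL
  center <- NULL
  territory_radius <- NA_real_
  if ("STAIN" %in% names(config@baseIntensity) &&
      config@territoryFraction > 0) {
    # center drawn at moderate eccentricity so the territory stays connected
    # and leaves room for Xa loci outside it
    theta <- stats::runif(1L, 0, 2 * pi)
    rho <- 0.45
    center <- c(cy + rho * ay * sin(theta), cx + rho * ax * cos(theta))
    idx <- which(nucleus)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    d2 <- (rows - center[1L])^2 + (cols - center[2L])^2
    k <- max(1L, round(config@territoryFraction * length(idx)))
    sel <- order(d2)[seq_len(k)]
    territory <- matrix(FALSE, nr, nc)
    territory[idx[sel]] <- TRUE
    territory_radius <- sqrt(max(d2[sel]))
    channels$STAIN[territory] <- channels$STAIN[territory] +
      config@stainAmplitude
  }
  img <- new("CellImage", channels = channels, cellId = as.character(cell_id),
             pixelSize = NA_real_, bitDepth = 16L,
             metadata = list(simulated = TRUE))
  list(image = img, nucleus_mask = nucleus, territory_mask = territory,
       territory_center = center, territory_radius = territory_radius)
}

.placeLoci <- function(config, nucleus_mask, territory_mask,
                       territory_center, territory_radius = NA_real_,
                       max_tries = 2000L) {
  nr <- nrow(nucleus_mask); nc <- ncol(nucleus_mask)
  margin <- config@spotRadius + 2
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ay <- config@nucleusAxes[1L] - margin
  ax <- config@nucleusAxes[2L] - margin
  is_xi <- seq_len(config@nLoci) %in% config@xiLoci
  pos <- matrix(NA_real_, config@nLoci, 2L)
  # Xi loci first (inside the territory), then Xa (outside it)
  ord <- order(!is_xi)
  for (i in ord) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (is_xi[i] && !is.null(territory_center)) {
        rmax <- 2.5 * config@spotRadius
        if (is.finite(territory_radius))
          rmax <- max(1, min(rmax,
                             territory_radius - config@spotRadius - 1))
        ang <- stats::runif(1L, 0, 2 * pi)
        rad <- sqrt(stats::runif(1L)) * rmax
        cand <- territory_center + rad * c(sin(ang), cos(ang))
      } else {
        ang <- stats::runif(1L, 0, 2 * pi)
        u <- sqrt(stats::runif(1L))
        cand <- c(cy + u * ay * sin(ang), cx + u * ax * cos(ang))
      }
      ri <- round(cand[1L]); ci <- round(cand[2L])
      if (ri < 1L || ri > nr || ci < 1L || ci > nc) next
      if (!nucleus_mask[ri, ci]) next
      if (((ri - cy) / ay)^2 + ((ci - cx) / ax)^2 > 1) next
      if (!is.null(territory_mask)) {
        if (is_xi[i] && !territory_mask[ri, ci]) next
        if (!is_xi[i]) {
          # Xa spots must clear the territory edge so their overlap stays
          # well below the Xi classification rule
          dter <- sqrt(sum((cand - territory_center)^2))
          if (is.finite(territory_radius) &&
              dter < territory_radius + config@spotRadius + 1) next
        }
      }
      ok <- TRUE
      for (j in seq_len(config@nLoci))
        if (j != i && !is.na(pos[j, 1L]) &&
            sqrt(sum((cand - pos[j, ])^2)) < config@minSeparation) {
          ok <- FALSE
          break
        }
      if (!ok) next
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      .cfgStop(sprintf(
        "could not place locus %d with separation %.1f after %d tries",
        i, config@minSeparation, max_tries))
  }
  pos
}

#' Render marker and BiAD spots onto a nucleus
#'
#' Samples locus positions inside the nucleus (Xi loci inside the stain
#' territory, Xa loci outside; minimum pairwise separation enforced by
#' rejection) and adds, per locus, a marker amplitude of
#' \code{marker_gain * copy_number} and a BiAD amplitude of marker
#' amplitude times the locus's true ratio
#' (\code{detector_efficiency * modification_fraction * biad_gain}, times
#' \code{biad_enrichment} for Xi loci). Shapes are flat discs (top-hat,
#' exact-recovery mode) or Gaussians (realistic mode); amplitudes add to
#' the base.
#'
#' @param rendered Output of \code{\link{renderNucleus}}.
#' @param config A \linkS4class{SimulationConfig}.
#' @param dropped_out If \code{TRUE} the cell lacks sensor components: all
#'   BiAD amplitudes are zero.
#' @return List: \code{image} (noiseless \linkS4class{CellImage} with
#'   spots) and \code{truth} (per-locus data frame).
#' @export
renderSpots <- function(rendered, config, dropped_out = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  img <- rendered$image
  nucleus_mask <- rendered$nucleus_mask
  pos <- .placeLoci(config, nucleus_mask, rendered$territory_mask,
                    rendered$territory_center, rendered$territory_radius)
  ratios <- .trueRatios(config)
  marker_amp <- config@markerGain * config@copyNumber
  biad_amp <- if (dropped_out) rep(0, config@nLoci) else marker_amp * ratios
  nr <- nrow(nucleus_mask); nc <- ncol(nucleus_mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  marker <- getChannel(img, "MARKER")
  biad <- if ("BIAD" %in% channelRoles(img)) getChannel(img, "BIAD") else NULL
  for (i in seq_len(config@nLoci)) {
    d2 <- (rows - pos[i, 1L])^2 + (cols - pos[i, 2L])^2
    if (config@spotShape == "tophat") {
      fp <- (d2 <= config@spotRadius^2) * 1
    } else {
      fp <- exp(-d2 / (2 * config@spotSigma^2))
      fp[fp < 1e-8] <- 0
    }
    fp <- fp * nucleus_mask
    marker <- marker + marker_amp[i] * fp
    if (!is.null(biad)) biad <- biad + biad_amp[i] * fp
  }
  img@channels$MARKER <- marker
  if (!is.null(biad)) img@channels$BIAD <- biad
  truth <- data.frame(
    locus = seq_len(config@nLoci), row = pos[, 1L], col = pos[, 2L],
    copy_number = config@copyNumber,
    allele = ifelse(seq_len(config@nLoci) %in% config@xiLoci, "Xi", "Xa"),
    modification_fraction = config@modificationFraction,
    dropped_out = dropped_out,
    true_ratio = if (dropped_out) rep(0, config@nLoci) else ratios,
    stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Apply the camera noise model
#'
#' Per pixel: Poisson resampling of the expected intensity (if enabled),
#' then additive Gaussian read noise, then a constant offset; the result is
#' clipped at zero. With all noise off and zero offset this is the
#' identity. Deterministic under the caller's RNG state.
#'
#' @param image Noiseless \linkS4class{CellImage}.
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{CellImage} with noise applied.
#' @export
applyNoise <- function(image, config) {
  stopifnot(is(image, "CellImage"), is(config, "SimulationConfig"))
  if (config@readSigma < 0) .cfgStop("read_sigma must be non-negative")
  img <- image
  img@channels <- lapply(image@channels, function(ch) {
    d <- dim(ch)
    x <- as.numeric(ch)
    if (config@noisePoisson) x <- stats::rpois(length(x), x)
    if (config@readSigma > 0)
      x <- x + stats::rnorm(length(x), 0, config@readSigma)
    x <- x + config@offset
    x[x < 0] <- 0
    matrix(x, d[1L], d[2L])
  })
  img
}

#' Simulate one cell
#'
#' Composes \code{\link{renderNucleus}}, \code{\link{renderSpots}} and
#' \code{\link{applyNoise}} under the configuration's seed; with
#' probability \code{dropout_probability} the cell is transfection
#' incomplete and all BiAD amplitudes are zeroed (recorded in the truth).
#' A fixed seed fixes the full output.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param cell_id Identifier for the cell.
#' @return A \linkS4class{SimulatedCell}.
#' @export
simulateCell <- function(config, cell_id = "cell") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  dropped <- stats::runif(1L) < config@dropoutProbability
  rendered <- renderNucleus(config, cell_id = cell_id)
  spotted <- renderSpots(rendered, config, dropped_out = dropped)
  noisy <- applyNoise(spotted$image, config)
  new("SimulatedCell", image = noisy, truth = spotted$truth,
      nucleusMask = rendered$nucleus_mask,
      territoryMask = rendered$territory_mask)
}

#' Manual threshold pair implied by a simulation configuration
#'
#' The deterministic analogue of the per-cell manual thresholds of the
#' original workflow: the nucleus threshold halfway between background and
#' the marker base intensity, the spot threshold halfway up the dimmest
#' spot's amplitude above the base.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ThresholdPair} (method \code{"manual"}).
#' @export
simThresholds <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  base <- config@baseIntensity[["MARKER"]]
  min_amp <- min(config@markerGain * config@copyNumber)
  ThresholdPair((config@background + base) / 2, base + 0.5 * min_amp,
                method = "manual")
}

#' Per-pixel BiAD spot signal-to-noise ratio of a configuration
#'
#' For the dimmest locus: BiAD spot amplitude divided by the per-pixel
#' noise standard deviation at that spot
#' (\code{sqrt(base + amplitude)} shot noise if Poisson is enabled, plus
#' read noise in quadrature).
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return Numeric SNR (Inf for a noiseless configuration).
#' @export
simSpotSNR <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  ratios <- .trueRatios(config)
  amp <- min(config@markerGain * config@copyNumber * ratios)
  base <- if ("BIAD" %in% names(config@baseIntensity))
    config@baseIntensity[["BIAD"]] else 0
  var_shot <- if (config@noisePoisson) base + amp else 0
  sd_tot <- sqrt(var_shot + config@readSigma^2)
  if (sd_tot == 0) return(Inf)
  amp / sd_tot
}

#' Simulate a multi-condition experiment
#'
#' Generates \code{n_cells} cells per condition with deterministic per-cell
#' seeds derived from each configuration's seed, assigns replicate ids
#' round-robin (default 3 replicates, mirroring triplicate independent
#' experiments), and optionally writes per-cell multi-page TIFFs, a sample
#' sheet and the ground-truth table.
#'
#' @param configs Named list: condition label to
#'   \linkS4class{SimulationConfig}.
#' @param n_cells Cells per condition.
#' @param dir Output directory for images and CSVs; \code{NULL} keeps
#'   everything in memory.
#' @param replicates Number of replicate ids to cycle through.
#' @param treatment Treatment-arm label recorded for all cells (vectorized
#'   over conditions).
#' @return List: \code{cells} (named list of \linkS4class{SimulatedCell}),
#'   \code{sample_sheet} (cell_id, path, condition, treatment, replicate),
#'   \code{truth} (per-locus long table with cell ids).
#' @export
simulateExperiment <- function(configs, n_cells, dir = NULL, replicates = 3L,
                               treatment = "none") {
  stopifnot(length(configs) >= 1L, !is.null(names(configs)))
  treatment <- rep_len(treatment, length(configs))
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  cells <- list()
  sheet <- list()
  truth <- list()
  global <- 0L
  for (ci in seq_along(configs)) {
    cond <- names(configs)[ci]
    config <- configs[[ci]]
    for (i in seq_len(n_cells)) {
      global <- global + 1L
      cell_id <- sprintf("%s_%03d", cond, i)
      cfg_i <- config
      cfg_i@seed <- as.integer((config@seed + 7919 * global) %%
                                 .Machine$integer.max)
      sim <- simulateCell(cfg_i, cell_id = cell_id)
      cells[[cell_id]] <- sim
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, paste0(cell_id, ".tif"))
        writeCellImage(sim@image, path)
      }
      sheet[[cell_id]] <- data.frame(
        cell_id = cell_id, path = path, condition = cond,
        treatment = treatment[ci],
        replicate = sprintf("rep%d", ((i - 1L) %% replicates) + 1L),
        channels = paste(channelRoles(sim@image), collapse = ";"),
        stringsAsFactors = FALSE)
      tr <- sim@truth
      tr$cell_id <- cell_id
      tr$condition <- cond
      truth[[cell_id]] <- tr
    }
  }
  sample_sheet <- do.call(rbind, sheet)
  rownames(sample_sheet) <- NULL
  truth_tab <- do.call(rbind, truth)
  rownames(truth_tab) <- NULL
  if (!is.null(dir)) {
    utils::write.csv(sample_sheet, file.path(dir, "sample_sheet.csv"),
                     row.names = FALSE)
    writeQuantTable(truth_tab, file.path(dir, "ground_truth.csv"))
  }
  list(cells = cells, sample_sheet = sample_sheet, truth = truth_tab)
}
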