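#' @include AllClasses.R segmentation.R
NULL

.qcStop <- function(msg, reason = "qc") {
  stop(errorCondition(msg, reason = reason,
                      class = c("biad_qc_error", "error", "condition")))
}

#' Nuclear background subtraction
#'
#' Subtracts the mean nuclear intensity from a spot's mean intensity.
#' Negative results are preserved, not clamped: a BiAD spot dimmer than the
#' nuclear BiAD background is a real observation, and clamping would bias
#' the null (binding-deficient detector) upward.
#'
#' @param spot_mean,nuclear_mean Mean ROI intensities (same channel).
#' @return \code{spot_mean - nuclear_mean}; vectorized.
#' @export
backgroundSubtract <- function(spot_mean, nuclear_mean) {
  stopifnot(all(is.finite(spot_mean)), all(is.finite(nuclear_mean)),
            all(spot_mean >= 0), all(nuclear_mean >= 0))
  spot_mean - nuclear_mean
}

#' Relative BiAD signal of one spot
#'
#' The core ratiometric quantity: the background-corrected BiAD spot
#' intensity divided by the background-corrected marker spot intensity,
#' \deqn{r = \frac{I_{BiAD}^{spot} - I_{BiAD}^{nuc}}
#'                {I_{marker}^{spot} - I_{marker}^{nuc}}.}
#' Normalizing to the marker removes the dependence on local sgRNA binding
#' site copy number, which sets the marker spot brightness. The ratio may
#' be negative (BiAD spot dimmer than the nuclear BiAD background).
#'
#' Spots whose corrected marker intensity falls below \code{eps} are marked
#' invalid (\code{valid = FALSE}, ratio \code{NA}) and excluded from
#' per-cell aggregation rather than producing unstable ratios.
#'
#' @param spot A \linkS4class{SpotRegion} measured in MARKER and BIAD.
#' @param nucleus The cell's \linkS4class{NucleusRegion}.
#' @param eps Denominator guard; callers should scale it to the marker
#'   channel's dynamic range (the pipeline uses \code{1e-6} of the range).
#' @param cell_id Identifier recorded in the output row.
#' @return One-row data frame: \code{cell_id}, \code{spot_id}, \code{area},
#'   \code{corrected_marker}, \code{corrected_biad}, \code{relative_biad},
#'   \code{valid}, \code{allele} (initially \code{"unlabeled"}).
#' @export
spotRelativeBiad <- function(spot, nucleus, eps = 1e-9, cell_id = "cell") {
  stopifnot(is(spot, "SpotRegion"), is(nucleus, "NucleusRegion"))
  for (role in c("MARKER", "BIAD"))
    if (!role %in% names(spot@meanIntensity) ||
        !role %in% names(nucleus@meanIntensity))
      .cfgStop(paste0("relative BiAD signal requires a measured ", role,
                      " channel"))
  cm <- backgroundSubtract(spot@meanIntensity[["MARKER"]],
                           nucleus@meanIntensity[["MARKER"]])
  cb <- backgroundSubtract(spot@meanIntensity[["BIAD"]],
                           nucleus@meanIntensity[["BIAD"]])
  valid <- cm >= eps
  data.frame(cell_id = cell_id, spot_id = spot@spotId,
             area = spot@area, corrected_marker = cm, corrected_biad = cb,
             relative_biad = if (valid) cb / cm else NA_real_,
             valid = valid, allele = "unlabeled",
             stringsAsFactors = FALSE)
}

#' Per-cell aggregate of spot ratios
#'
#' Averages the relative BiAD signal over a cell's valid spots; each cell
#' contributes one value (one dot in the boxplots) to group statistics.
#' Negative spot ratios participate in the mean.
#'
#' @param spot_quants Data frame of per-spot rows
#'   (\code{\link{spotRelativeBiad}}).
#' @param cell_id,condition,treatment,replicate Labels attached to the row.
#' @return One-row data frame: \code{cell_id}, \code{condition},
#'   \code{treatment}, \code{replicate}, \code{mean_relative_biad},
#'   \code{spot_count} (number of valid spots), \code{mean_spot_area}.
#'   Errors with a QC condition when no valid spot remains.
#' @export
cellMeanBiad <- function(spot_quants, cell_id = "cell",
                         condition = NA_character_,
                         treatment = NA_character_,
                         replicate = NA_character_) {
  stopifnot(is.data.frame(spot_quants))
  keep <- spot_quants[spot_quants$valid, , drop = FALSE]
  if (!nrow(keep))
    .qcStop(sprintf("cell '%s': no valid spot for aggregation", cell_id),
            reason = "invalid_denominator")
  data.frame(cell_id = cell_id, condition = condition, treatment = treatment,
             replicate = replicate,
             mean_relative_biad = mean(keep$relative_biad),
             spot_count = nrow(keep),
             mean_spot_area = mean(keep$area),
             stringsAsFactors = FALSE)
}

#' Classify spots as Xi or Xa by stain-territory overlap
#'
#' A spot is labeled \code{Xi} when the fraction of its pixels inside the
#' immunostain territory (e.g. the H3K27me3-dense Xi domain) reaches
#' \code{overlap_fraction_min}; the boundary is inclusive, so a spot with
#' exactly half its pixels in the territory is Xi. All other spots are
#' \code{Xa}.
#'
#' @param spots List of \linkS4class{SpotRegion}.
#' @param stain_mask Logical matrix: the segmented stain territory.
#' @param overlap_fraction_min Minimum overlap fraction for an Xi call.
#' @return Character vector of labels, one per spot.
#' @export
classifyAlleles <- function(spots, stain_mask, overlap_fraction_min = 0.5) {
  if (is.null(stain_mask))
    .cfgStop("allelic analysis requires a STAIN channel territory mask")
  stopifnot(is.logical(stain_mask))
  vapply(spots, function(s) {
    frac <- sum(s@mask & stain_mask) / s@area
    if (frac >= overlap_fraction_min) "Xi" else "Xa"
  }, character(1L))
}

#' Segment the immunostain territory
#'
#' Otsu threshold on the STAIN channel restricted to the nucleus (or a
#' manual threshold), keeping all components: the territory is the set of
#' stain-positive nuclear pixels.
#'
#' @param image A \linkS4class{CellImage} with a STAIN channel.
#' @param nucleus The cell's \linkS4class{NucleusRegion}.
#' @param threshold Manual stain threshold; \code{NULL} for Otsu within the
#'   nucleus.
#' @return Logical matrix.
#' @export
segmentStainTerritory <- function(image, nucleus, threshold = NULL) {
  stopifnot(is(image, "CellImage"), is(nucleus, "NucleusRegion"))
  if (!"STAIN" %in% channelRoles(image))
    .cfgStop("no STAIN channel in this image")
  stain <- getChannel(image, "STAIN")
  if (is.null(threshold)) {
    vals <- stain[nucleus@mask]
    rng <- range(vals)
    if (diff(rng) <= 0)
      .segStop(sprintf("cell '%s': constant stain channel within nucleus",
                       image@cellId))
    threshold <- EBImage::otsu(EBImage::Image(matrix(vals)), range = rng,
                               levels = 256L)
  }
  (stain >= threshold) & nucleus@mask
}

#' Normalize a cell's spot ratios to its mean Xa signal
#'
#' Divides every spot's relative BiAD signal by the mean over the cell's
#' Xa-labeled spots, so Xa spots average to exactly 1 within each cell and
#' Xi values read directly as fold enrichment over the active X.
#'
#' @param spot_quants Per-spot data frame of one cell with \code{allele}
#'   labels assigned.
#' @param eps Guard: cells whose mean Xa signal is at or below \code{eps}
#'   are excluded from allelic analysis (QC condition).
#' @return The data frame with an added \code{xa_normalized} column.
#' @export
normalizeToXa <- function(spot_quants, eps = 1e-6) {
  stopifnot(is.data.frame(spot_quants), "allele" %in% names(spot_quants))
  keep <- spot_quants$valid
  xa <- keep & spot_quants$allele == "Xa"
  xi <- keep & spot_quants$allele == "Xi"
  cid <- spot_quants$cell_id[1L]
  if (!any(xa) || !any(xi))
    .qcStop(sprintf(
      "cell '%s': allelic normalization needs at least one Xa and one Xi spot",
      cid), reason = "missing_allele")
  xa_mean <- mean(spot_quants$relative_biad[xa])
  if (xa_mean <= eps)
    .qcStop(sprintf("cell '%s': degenerate mean Xa signal (%.3g)", cid,
                    xa_mean), reason = "degenerate_xa")
  spot_quants$xa_normalized <- ifelse(keep,
                                      spot_quants$relative_biad / xa_mean,
                                      NA_real_)
  spot_quants
}

#' Normalize per-cell signals to a control detector
#'
#' Within each treatment arm, divides every cell's mean relative BiAD
#' signal by the arithmetic mean over that arm's control-condition cells
#' (e.g. a binding-pocket mutant detector), so control cells average to 1
#' per arm and treatment effects read as fold changes over the control.
#'
#' @param cells Experiment table (per-cell data frame with
#'   \code{condition}, \code{treatment}, \code{mean_relative_biad}).
#' @param control_condition Label of the control detector.
#' @param eps Guard against a degenerate (near-zero) control mean.
#' @param min_control Minimum control cells required per arm.
#' @return \code{cells} with an added \code{control_normalized} column.
#' @export
normalizeToControl <- function(cells, control_condition, eps = 1e-6,
                               min_control = 3L) {
  stopifnot(is.data.frame(cells),
            all(c("condition", "treatment", "mean_relative_biad") %in%
                  names(cells)))
  arms <- unique(cells$treatment)
  out <- cells
  out$control_normalized <- NA_real_
  for (arm in arms) {
    in_arm <- cells$treatment %in% arm
    ctrl <- in_arm & cells$condition == control_condition
    if (sum(ctrl) < min_control)
      .cfgStop(sprintf(
        "treatment arm '%s': %d control cell(s) of '%s', need >= %d",
        arm, sum(ctrl), control_condition, min_control))
    m <- mean(cells$mean_relative_biad[ctrl])
    if (m <= eps)
      .qcStop(sprintf(
        "treatment arm '%s': degenerate control mean (%.3g), normalization refused",
        arm, m), reason = "degenerate_control")
    out$control_normalized[in_arm] <- cells$mean_relative_biad[in_arm] / m
  }
  out
}

#' Spot-count and spot-area QC summaries per condition
#'
#' Companion QC for BiAD comparisons: differences between conditions should
#' show in the BiAD signal, not in spot count or area.
#'
#' @param cells Experiment table (per-cell rows with \code{condition} and
#'   \code{spot_count}).
#' @param spots Optional per-spot long table (with \code{condition} and
#'   \code{area}) for area statistics.
#' @return Named list per condition: \code{count_histogram} (counts 0..6)
#'   and, when \code{spots} is given, \code{area_summary}
#'   (five-number summary plus mean).
#' @export
spotQcSummary <- function(cells, spots = NULL) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L)
  conds <- unique(cells$condition)
  out <- lapply(conds, function(cond) {
    counts <- cells$spot_count[cells$condition == cond]
    hist <- table(factor(counts, levels = 0:6))
    res <- list(count_histogram = hist)
    if (!is.null(spots) && "condition" %in% names(spots)) {
      a <- spots$area[spots$condition == cond]
      res$area_summary <- c(summary(a))
    }
    res
  })
  names(out) <- conds
  out
}

#' Quantify one cell end to end
#'
#' Convenience wrapper: segments the nucleus and spots, measures ROIs,
#' computes per-spot relative BiAD signals and the per-cell mean, and
#' optionally classifies alleles against the stain territory.
#'
#' @param image A \linkS4class{CellImage} with MARKER and BIAD channels.
#' @param thresholds A \linkS4class{ThresholdPair}, or \code{NULL} for
#'   \code{\link{autoThresholds}}.
#' @param max_spots,min_spot_area Passed to \code{\link{detectSpots}}.
#' @param allelic If \code{TRUE}, segment the STAIN territory and label
#'   spots Xi/Xa.
#' @param stain_threshold Manual stain threshold for allelic mode.
#' @param overlap_fraction_min Xi overlap rule
#'   (\code{\link{classifyAlleles}}).
#' @param exclude_spots_from_background If \code{TRUE}, recompute the
#'   nuclear background means over the nucleus mask minus all spot masks
#'   before background subtraction (off by default: the standard workflow
#'   measures the whole nucleus as one ROI).
#' @param condition,treatment,replicate Labels copied to the output rows.
#' @return List with \code{cell} (one-row per-cell data frame),
#'   \code{spots} (per-spot data frame), \code{nucleus}, \code{spot_regions}
#'   and \code{thresholds}. Segmentation or QC failures raise classed
#'   conditions that \code{\link{runQuantify}} converts to QC exclusions.
#' @examples
#' cfg <- simulationConfig(seed = 7, noise_poisson = FALSE, read_sigma = 0)
#' sim <- simulateCell(cfg)
#' q <- quantifyCell(sim$image, simThresholds(cfg))
#' q$cell$mean_relative_biad
#' @export
quantifyCell <- function(image, thresholds = NULL, max_spots = 6L,
                         min_spot_area = 4L, allelic = FALSE,
                         stain_threshold = NULL, overlap_fraction_min = 0.5,
                         exclude_spots_from_background = FALSE,
                         condition = NA_character_, treatment = NA_character_,
                         replicate = NA_character_) {
  stopifnot(is(image, "CellImage"))
  if (!"BIAD" %in% channelRoles(image))
    .cfgStop("BiAD quantification requires a BIAD channel")
  if (is.null(thresholds)) thresholds <- autoThresholds(image)
  nucleus <- segmentNucleus(image, thresholds)
  spots <- detectSpots(image, nucleus, thresholds, max_spots = max_spots,
                       min_spot_area = min_spot_area)
  if (!length(spots))
    .qcStop(sprintf("cell '%s': no marker spot above threshold",
                    image@cellId), reason = "no_spots")

  bg_region <- nucleus
  if (exclude_spots_from_background) {
    bg_mask <- nucleus@mask
    for (s in spots) bg_mask <- bg_mask & !s@mask
    if (!any(bg_mask))
      .segStop(sprintf("cell '%s': spots cover the whole nucleus",
                       image@cellId), reason = "empty_background")
    bg_region <- new("NucleusRegion", mask = bg_mask,
                     area = as.integer(sum(bg_mask)),
                     meanIntensity = measureRegion(image, bg_mask))
  }

  marker <- getChannel(image, "MARKER")
  eps <- 1e-6 * max(diff(range(marker)), .Machine$double.eps)
  sq <- do.call(rbind, lapply(spots, spotRelativeBiad, nucleus = bg_region,
                              eps = eps, cell_id = cellId(image)))
  if (allelic) {
    territory <- segmentStainTerritory(image, nucleus,
                                       threshold = stain_threshold)
    sq$allele <- classifyAlleles(spots, territory,
                                 overlap_fraction_min = overlap_fraction_min)
  }
  cell <- cellMeanBiad(sq, cell_id = cellId(image), condition = condition,
                       treatment = treatment, replicate = replicate)
  sq$condition <- condition
  sq$treatment <- treatment
  sq$replicate <- replicate
  list(cell = cell, spots = sq, nucleus = nucleus, spot_regions = spots,
       thresholds = thresholds)
}
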