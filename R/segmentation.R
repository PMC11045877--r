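#' @include AllClasses.R AllGenerics.R
NULL

# condition helpers so the pipeline can catch per-cell failures and turn them
# into QC exclusions instead of aborting a batch
.segStop <- function(msg, reason = "segmentation_failure") {
  stop(errorCondition(msg, reason = reason,
                      class = c("biad_segmentation_error", "error",
                                "condition")))
}
.cfgStop <- function(msg) {
  stop(errorCondition(msg, reason = "configuration",
                      class = c("biad_config_error", "error", "condition")))
}

# 8-connected relabeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]     # down-right diagonal
  c_ <- lab[-nr, -1L]; d <- lab[-1L, -nc]    # down-left diagonal
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c_[c_ > 0 & d > 0 & c_ != d],
                       d[c_ > 0 & d > 0 & c_ != d]))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n), find, 1L)
    remap <- match(roots, sort(unique(roots)))
    pos <- lab > 0
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Mean ROI intensity in every channel
#'
#' Arithmetic mean of the pixel intensities under \code{mask}, computed
#' independently per channel.
#'
#' @param image A \linkS4class{CellImage}.
#' @param mask Logical matrix with the image extent.
#' @return Named numeric vector, one mean per channel role.
#' @examples
#' img <- CellImage(list(MARKER = matrix(1:9, 3)))
#' measureRegion(img, matrix(c(TRUE, rep(FALSE, 8)), 3))
#' @export
measureRegion <- function(image, mask) {
  stopifnot(is(image, "CellImage"), is.logical(mask))
  if (!identical(dim(mask), dim(image@channels[[1L]])))
    stop("mask extent does not match the image", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  vapply(image@channels, function(ch) mean(ch[mask]), numeric(1L))
}

#' Segment the nucleus with the low marker threshold
#'
#' Thresholds the marker channel at the nucleus (low) threshold, keeps the
#' largest 4-connected component, fills interior holes, and measures the
#' mean intensity of the resulting nuclear ROI in every channel. The
#' nuclear mean is the per-channel background subtracted from spot
#' intensities downstream. Spot pixels are included in the nuclear mean
#' (the whole nucleus is measured as one ROI); see
#' \code{\link{quantifyCell}} for the option to exclude them.
#'
#' @param image A \linkS4class{CellImage} with a MARKER channel.
#' @param thresholds A \linkS4class{ThresholdPair}.
#' @return A \linkS4class{NucleusRegion}.
#' @seealso \code{\link{detectSpots}}, \code{\link{autoThresholds}}
#' @export
segmentNucleus <- function(image, thresholds) {
  stopifnot(is(image, "CellImage"), is(thresholds, "ThresholdPair"))
  marker <- getChannel(image, "MARKER")
  mask0 <- marker >= thresholds@nucleus
  if (!any(mask0))
    .segStop(sprintf("cell '%s': no pixel reaches the nucleus threshold %g",
                     image@cellId, thresholds@nucleus),
             reason = "no_nucleus")
  lab <- EBImage::bwlabel(mask0)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(mask) > 0
  new("NucleusRegion", mask = mask, area = as.integer(sum(mask)),
      meanIntensity = measureRegion(image, mask))
}

#' Detect the brightest marker spots with the high threshold
#'
#' Connected components (8-connected) of marker pixels at or above the spot
#' threshold, restricted to the nucleus mask and filtered by a minimum
#' area. Components are ranked by mean marker intensity (descending, ties
#' broken by larger area, then by earlier raster order) and at most
#' \code{max_spots} are retained, mirroring the analysis convention of at
#' most six spots per cell.
#'
#' @param image A \linkS4class{CellImage}.
#' @param nucleus The cell's \linkS4class{NucleusRegion}.
#' @param thresholds A \linkS4class{ThresholdPair}.
#' @param max_spots Maximum number of spots retained per cell.
#' @param min_spot_area Minimum component area in pixels; suppresses
#'   shot-noise singletons.
#' @return List of \linkS4class{SpotRegion}, brightest first; empty list if
#'   no component qualifies (the cell then carries no spots and is excluded
#'   from BiAD statistics, but counted in QC).
#' @export
detectSpots <- function(image, nucleus, thresholds, max_spots = 6L,
                        min_spot_area = 4L) {
  stopifnot(is(image, "CellImage"), is(nucleus, "NucleusRegion"),
            is(thresholds, "ThresholdPair"), max_spots >= 1L)
  marker <- getChannel(image, "MARKER")
  cand <- (marker >= thresholds@spot) & nucleus@mask
  if (!any(cand)) return(list())
  lab <- .label8(cand)
  ncomp <- max(lab)
  stats <- lapply(seq_len(ncomp), function(k) {
    idx <- which(lab == k)
    list(idx = idx, area = length(idx), mean_marker = mean(marker[idx]))
  })
  stats <- stats[vapply(stats, function(s) s$area >= min_spot_area, TRUE)]
  if (!length(stats)) return(list())
  ord <- order(-vapply(stats, `[[`, 0, "mean_marker"),
               -vapply(stats, `[[`, 0L, "area"))
  stats <- stats[ord[seq_len(min(max_spots, length(stats)))]]
  nr <- nrow(marker)
  lapply(seq_along(stats), function(i) {
    s <- stats[[i]]
    m <- matrix(FALSE, nr, ncol(marker))
    m[s$idx] <- TRUE
    rows <- ((s$idx - 1L) %% nr) + 1L
    cols <- ((s$idx - 1L) %/% nr) + 1L
    new("SpotRegion", mask = m, centroid = c(mean(rows), mean(cols)),
        area = as.integer(s$area), meanIntensity = measureRegion(image, m),
        spotId = i)
  })
}

#' Automatic threshold pair for batch operation
#'
#' The original workflow sets both thresholds manually per cell; this
#' automatic mode enables reproducible batch runs. The nucleus threshold is
#' Otsu's threshold on the marker channel; the spot threshold is a
#' configurable quantile of the marker intensities within the provisional
#' nucleus mask (default 0.995, i.e. the 99.5th percentile).
#'
#' @param image A \linkS4class{CellImage}.
#' @param spot_quantile Quantile of within-nucleus marker intensity used as
#'   the spot threshold.
#' @param levels Histogram resolution for Otsu's method.
#' @return A \linkS4class{ThresholdPair} with method
#'   \code{"percentile_spot"}.
#' @export
autoThresholds <- function(image, spot_quantile = 0.995, levels = 256L) {
  stopifnot(is(image, "CellImage"), spot_quantile > 0, spot_quantile < 1)
  marker <- getChannel(image, "MARKER")
  rng <- range(marker)
  if (diff(rng) <= 0)
    .segStop(sprintf("cell '%s': constant marker channel, cannot threshold",
                     image@cellId))
  # clip the rare ultra-bright spot pixels before Otsu so the
  # background-vs-nucleus bimodality, not the spots, drives the threshold
  clipped <- pmin(marker, stats::quantile(marker, 0.98, type = 7L))
  crng <- range(clipped)
  if (diff(crng) <= 0) {
    clipped <- marker
    crng <- rng
  }
  nuc_thr <- EBImage::otsu(EBImage::Image(clipped), range = crng,
                           levels = levels)
  mask0 <- marker >= nuc_thr
  lab <- EBImage::bwlabel(mask0)
  mask <- lab == which.max(tabulate(lab[lab > 0]))
  spot_thr <- as.numeric(stats::quantile(marker[mask], spot_quantile,
                                         type = 7L))
  if (spot_thr <= nuc_thr)
    spot_thr <- nuc_thr + 1e-9 * diff(rng)   # degenerate: flat nucleus
  ThresholdPair(nuc_thr, spot_thr, method = "percentile_spot")
}
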