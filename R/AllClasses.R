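# Central S4 classes for the BiAD quantification pipeline.

#' Valid semantic channel roles
#'
#' The pipeline binds image channels to semantic roles rather than acquisition
#' order: \code{MARKER} is the locus marker (YPet on the sgRNA scaffold),
#' \code{BIAD} the reconstituted split-fluorophore modification signal
#' (IFP2.0), \code{STAIN} an optional immunostain (e.g. H3K27me3 for Xi
#' identification), \code{NUCSTAIN} an optional nuclear counterstain (DAPI).
#'
#' @return Character vector of the four recognized roles.
#' @export
channelRoleNames <- function() c("MARKER", "BIAD", "STAIN", "NUCSTAIN")

.checkRoles <- function(roles) {
  if (anyDuplicated(roles))
    return("channel roles must be unique")
  bad <- setdiff(roles, channelRoleNames())
  if (length(bad))
    return(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")))
  if (sum(roles == "MARKER") != 1L)
    return("exactly one MARKER channel is required")
  NULL
}

.checkPlanes <- function(planes, ndim) {
  if (!length(planes)) return("at least one channel is required")
  dims <- lapply(planes, dim)
  if (any(vapply(dims, length, 1L) != ndim))
    return(sprintf("every channel must be a %d-dimensional array", ndim))
  if (length(unique(lapply(dims, as.integer))) != 1L)
    return("all channels must share identical dimensions")
  for (p in planes) {
    if (!is.numeric(p)) return("intensities must be numeric")
    if (anyNA(p)) return("intensities must not contain NA")
    if (min(p) < 0) return("intensities must be non-negative")
  }
  NULL
}

#' Multi-channel z-stack
#'
#' Holds one 3D intensity grid (row, column, z) per semantic channel role.
#' Intensities are stored as doubles after load to avoid overflow in
#' downstream background subtraction; the acquisition bit depth is carried
#' as metadata only.
#'
#' @slot channels Named list of 3D numeric arrays, names are channel roles.
#' @slot zSpacing Z-plane spacing in micrometers.
#' @slot bitDepth Acquisition bit depth (8 or 16).
#' @slot metadata Free-form acquisition record.
#' @seealso \code{\link{loadStack}}, \code{\link{maxIntensityProjection}}
#' @export
setClass("ZStack",
         representation(channels = "list", zSpacing = "numeric",
                        bitDepth = "integer", metadata = "list"),
         prototype(zSpacing = NA_real_, bitDepth = 16L, metadata = list()))

setValidity("ZStack", function(object) {
  msg <- .checkRoles(names(object@channels))
  if (is.null(msg)) msg <- .checkPlanes(object@channels, 3L)
  if (is.null(msg) && !(object@bitDepth %in% c(8L, 16L)))
    msg <- "bitDepth must be 8 or 16"
  if (is.null(msg)) TRUE else msg
})

#' Per-cell multi-channel 2D image
#'
#' The working unit of segmentation and quantification: one 2D plane per
#' semantic channel role (typically a maximum-intensity projection of a
#' z-stack through the nucleus). Pixel coordinates are (row, column),
#' 1-based as native R matrices.
#'
#' @slot channels Named list of numeric matrices, names are channel roles.
#' @slot pixelSize Pixel edge length in micrometers (NA if unknown).
#' @slot cellId Cell identifier.
#' @slot bitDepth Acquisition bit depth (metadata only).
#' @slot metadata Free-form acquisition record.
#' @export
setClass("CellImage",
         representation(channels = "list", pixelSize = "numeric",
                        cellId = "character", bitDepth = "integer",
                        metadata = "list"),
         prototype(pixelSize = NA_real_, cellId = "cell", bitDepth = 16L,
                   metadata = list()))

setValidity("CellImage", function(object) {
  msg <- .checkRoles(names(object@channels))
  if (is.null(msg)) msg <- .checkPlanes(object@channels, 2L)
  if (is.null(msg) && length(object@cellId) != 1L)
    msg <- "cellId must be a single string"
  if (is.null(msg)) TRUE else msg
})

#' Construct a CellImage from channel matrices
#'
#' @param channels Named list of numeric matrices; names are channel roles
#'   (exactly one \code{MARKER}, at most one each of \code{BIAD},
#'   \code{STAIN}, \code{NUCSTAIN}).
#' @param cell_id Cell identifier.
#' @param pixel_size Pixel edge length in micrometers.
#' @param bit_depth Acquisition bit depth.
#' @param metadata Optional list of acquisition metadata.
#' @return A \linkS4class{CellImage}.
#' @examples
#' img <- CellImage(list(MARKER = matrix(1, 8, 8), BIAD = matrix(0, 8, 8)))
#' channelRoles(img)
#' @export
CellImage <- function(channels, cell_id = "cell", pixel_size = NA_real_,
                      bit_depth = 16L, metadata = list()) {
  new("CellImage", channels = lapply(channels, .asNumericArray),
      cellId = as.character(cell_id), pixelSize = as.numeric(pixel_size),
      bitDepth = as.integer(bit_depth), metadata = metadata)
}

.asNumericArray <- function(x) {
  storage.mode(x) <- "double"
  x
}

#' Nucleus / spot intensity threshold pair
#'
#' Two intensity thresholds on the marker channel: a low one defining the
#' nucleus (the nuclear-background ROI) and a high one defining the
#' brightest marker spots. The spot threshold must exceed the nucleus
#' threshold.
#'
#' @slot nucleus Nucleus (low) threshold intensity.
#' @slot spot Spot (high) threshold intensity.
#' @slot method How the pair was obtained: \code{"manual"},
#'   \code{"otsu_nucleus"} or \code{"percentile_spot"}.
#' @export
setClass("ThresholdPair",
         representation(nucleus = "numeric", spot = "numeric",
                        method = "character"),
         prototype(method = "manual"))

setValidity("ThresholdPair", function(object) {
  if (length(object@nucleus) != 1L || length(object@spot) != 1L)
    return("thresholds must be scalar")
  if (!is.finite(object@nucleus) || !is.finite(object@spot))
    return("thresholds must be finite")
  if (object@spot <= object@nucleus)
    return("spot threshold must exceed nucleus threshold")
  if (!object@method %in% c("manual", "otsu_nucleus", "percentile_spot"))
    return("unknown threshold method")
  TRUE
})

#' @rdname ThresholdPair-class
#' @param nucleus,spot Threshold intensities (spot > nucleus).
#' @param method Provenance label for the pair.
#' @return A \linkS4class{ThresholdPair}.
#' @export
ThresholdPair <- function(nucleus, spot, method = "manual") {
  new("ThresholdPair", nucleus = as.numeric(nucleus),
      spot = as.numeric(spot), method = method)
}

#' Segmented nucleus region
#'
#' The largest 4-connected component above the nucleus threshold, holes
#' filled. Its per-channel mean intensity is the nuclear background used
#' for spot background subtraction.
#'
#' @slot mask Logical matrix (image extent).
#' @slot area Pixel count.
#' @slot meanIntensity Named numeric vector: mean intensity per channel
#'   role over the mask.
#' @export
setClass("NucleusRegion",
         representation(mask = "matrix", area = "integer",
                        meanIntensity = "numeric"))

setValidity("NucleusRegion", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@area <= 0L || sum(object@mask) != object@area)
    return("area must equal the number of TRUE mask pixels and be > 0")
  if (any(object@meanIntensity < 0)) return("mean intensities must be >= 0")
  TRUE
})

#' Segmented marker spot region
#'
#' One 8-connected component above the spot threshold, restricted to the
#' nucleus.
#'
#' @slot mask Logical matrix (image extent), subset of the nucleus mask.
#' @slot centroid Numeric (row, col) centroid in pixels.
#' @slot area Pixel count.
#' @slot meanIntensity Named numeric vector of per-channel means.
#' @slot spotId Integer rank of the spot within its cell (1 = brightest
#'   marker spot).
#' @export
setClass("SpotRegion",
         representation(mask = "matrix", centroid = "numeric",
                        area = "integer", meanIntensity = "numeric",
                        spotId = "integer"))

setValidity("SpotRegion", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@area <= 0L || sum(object@mask) != object@area)
    return("area must equal the number of TRUE mask pixels and be > 0")
  if (length(object@centroid) != 2L) return("centroid must be (row, col)")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "ZStack", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("ZStack: %d channel(s) [%s], %d x %d x %d (row x col x z)\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1L], d[2L], d[3L]))
  cat(sprintf("  z-spacing: %s um | bit depth: %d\n",
              format(object@zSpacing), object@bitDepth))
})

setMethod("show", "CellImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("CellImage '%s': %d channel(s) [%s], %d x %d px\n",
              object@cellId, length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1L], d[2L]))
  rng <- vapply(object@channels, function(ch) range(ch), numeric(2L))
  for (nm in colnames(rng))
    cat(sprintf("  %-8s [%g, %g]\n", nm, rng[1L, nm], rng[2L, nm]))
})

setMethod("show", "ThresholdPair", function(object) {
  cat(sprintf("ThresholdPair (%s): nucleus %g, spot %g\n",
              object@method, object@nucleus, object@spot))
})

setMethod("show", "NucleusRegion", function(object) {
  cat(sprintf("NucleusRegion: %d px | means: %s\n", object@area,
              paste(sprintf("%s=%.3g", names(object@meanIntensity),
                            object@meanIntensity), collapse = ", ")))
})

setMethod("show", "SpotRegion", function(object) {
  cat(sprintf("SpotRegion #%d: %d px at (%.1f, %.1f) | means: %s\n",
              object@spotId, object@area, object@centroid[1L],
              object@centroid[2L],
              paste(sprintf("%s=%.3g", names(object@meanIntensity),
                            object@meanIntensity), collapse = ", ")))
})
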