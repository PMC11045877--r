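#' @include AllClasses.R
NULL

#' Channel roles present in an image or stack
#'
#' @param x A \linkS4class{ZStack} or \linkS4class{CellImage}.
#' @return Character vector of semantic channel roles.
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' Extract one channel by semantic role
#'
#' @param x A \linkS4class{ZStack} or \linkS4class{CellImage}.
#' @param role One of \code{"MARKER"}, \code{"BIAD"}, \code{"STAIN"},
#'   \code{"NUCSTAIN"}.
#' @return For a \code{CellImage}, a numeric matrix; for a \code{ZStack},
#'   a 3D numeric array (row, column, z).
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))

#' Cell identifier accessor
#' @param x A \linkS4class{CellImage}.
#' @return Character scalar.
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' Pixel size accessor (micrometers per pixel)
#' @param x A \linkS4class{CellImage}.
#' @return Numeric scalar.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Acquisition bit depth accessor
#' @param x A \linkS4class{ZStack} or \linkS4class{CellImage}.
#' @return Integer scalar (8 or 16). Intensities are held as doubles
#'   internally; the bit depth is retained as metadata only.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Region mask accessor
#' @param x A \linkS4class{NucleusRegion} or \linkS4class{SpotRegion}.
#' @return Logical matrix with the image extent.
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))

#' Region area accessor (pixel count)
#' @param x A \linkS4class{NucleusRegion} or \linkS4class{SpotRegion}.
#' @return Integer scalar.
#' @export
setGeneric("regionArea", function(x) standardGeneric("regionArea"))

#' Per-channel mean intensities of a region
#' @param x A \linkS4class{NucleusRegion} or \linkS4class{SpotRegion}.
#' @return Named numeric vector (one entry per measured channel role).
#' @export
setGeneric("meanIntensities", function(x) standardGeneric("meanIntensities"))

#' Maximum-intensity projection of a z-stack
#'
#' Collapses the z dimension of every channel independently: each output
#' pixel is the maximum over z of the corresponding input pixels. Applied
#' to a single-plane stack it is the identity.
#'
#' @param stack A \linkS4class{ZStack}.
#' @param cell_id Identifier attached to the resulting image.
#' @return A \linkS4class{CellImage}.
#' @export
setGeneric("maxIntensityProjection",
           function(stack, cell_id = "cell") {
             standardGeneric("maxIntensityProjection")
           })
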