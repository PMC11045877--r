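#' @include AllClasses.R AllGenerics.R
NULL

.getRole <- function(channels, role) {
  if (!role %in% names(channels))
    stop("channel role '", role, "' not present in this image", call. = FALSE)
  channels[[role]]
}

#' @rdname channelRoles
#' @export
setMethod("channelRoles", "ZStack", function(x) names(x@channels))

#' @rdname channelRoles
#' @export
setMethod("channelRoles", "CellImage", function(x) names(x@channels))

#' @rdname getChannel
#' @export
setMethod("getChannel", "ZStack",
          function(x, role) .getRole(x@channels, role))

#' @rdname getChannel
#' @export
setMethod("getChannel", "CellImage",
          function(x, role) .getRole(x@channels, role))

#' @rdname cellId
#' @export
setMethod("cellId", "CellImage", function(x) x@cellId)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CellImage", function(x) x@pixelSize)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "ZStack", function(x) x@bitDepth)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "CellImage", function(x) x@bitDepth)

#' @rdname regionMask
#' @export
setMethod("regionMask", "NucleusRegion", function(x) x@mask)

#' @rdname regionMask
#' @export
setMethod("regionMask", "SpotRegion", function(x) x@mask)

#' @rdname regionArea
#' @export
setMethod("regionArea", "NucleusRegion", function(x) x@area)

#' @rdname regionArea
#' @export
setMethod("regionArea", "SpotRegion", function(x) x@area)

#' @rdname meanIntensities
#' @export
setMethod("meanIntensities", "NucleusRegion", function(x) x@meanIntensity)

#' @rdname meanIntensities
#' @export
setMethod("meanIntensities", "SpotRegion", function(x) x@meanIntensity)

#' Spot rank accessor
#' @param x A \linkS4class{SpotRegion}.
#' @return Integer spot id (1 = brightest marker spot of the cell).
#' @export
spotId <- function(x) {
  stopifnot(is(x, "SpotRegion"))
  x@spotId
}

#' Spot centroid accessor
#' @param x A \linkS4class{SpotRegion}.
#' @return Numeric (row, col) centroid in pixel coordinates.
#' @export
spotCentroid <- function(x) {
  stopifnot(is(x, "SpotRegion"))
  x@centroid
}
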