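#' @include AllClasses.R AllGenerics.R
NULL

.readPages <- function(path) {
  if (!file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("failed to parse TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages)
    if (length(dim(p)) != 2L)
      stop("only single-sample (grayscale) TIFF pages are supported: ",
           path, call. = FALSE)
  lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  })
}

#' Load a multi-channel microscopy stack
#'
#' Reads single- or multi-page grayscale TIFF / OME-TIFF data and binds
#' pages to semantic channel roles. Channel binding is always explicit via
#' \code{channel_map} and never inferred from file metadata, since
#' acquisition metadata conventions vary between instruments.
#'
#' Two channel layout dialects are supported. With a single \code{path} and
#' \code{layout = "interleaved"} (default), pages cycle through the channels
#' within each z-plane (c1z1, c2z1, ..., c1z2, ...); with
#' \code{layout = "blocks"}, all z-planes of channel 1 precede those of
#' channel 2, and so on. With one \code{path} per channel, each file holds
#' the z-planes of a single channel.
#'
#' @param path Character vector: one TIFF path (multi-channel file) or one
#'   path per channel role.
#' @param channel_map Character vector of channel roles in acquisition
#'   order; exactly one \code{"MARKER"} is required.
#' @param layout Page layout for a single multi-channel file.
#' @param z_spacing Z-plane spacing in micrometers (metadata only).
#' @param bit_depth Acquisition bit depth (8 or 16, metadata only).
#' @return A \linkS4class{ZStack}. A 2D file yields a single-plane stack.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(list(matrix(runif(64), 8), matrix(runif(64), 8)), f,
#'                 bits.per.sample = 16)
#' stk <- loadStack(f, c("MARKER", "BIAD"))
#' dim(getChannel(stk, "MARKER"))
#' @export
loadStack <- function(path, channel_map, layout = c("interleaved", "blocks"),
                      z_spacing = NA_real_, bit_depth = 16L) {
  layout <- match.arg(layout)
  msg <- .checkRoles(channel_map)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  nch <- length(channel_map)

  if (length(path) > 1L) {
    if (length(path) != nch)
      stop("got ", length(path), " files for ", nch,
           " channel roles", call. = FALSE)
    per_channel <- lapply(path, .readPages)
    nz <- length(per_channel[[1L]])
    if (!all(vapply(per_channel, length, 1L) == nz))
      stop("per-channel files hold different z-plane counts", call. = FALSE)
    channels <- lapply(per_channel, function(pp)
      array(unlist(pp), dim = c(dim(pp[[1L]]), length(pp))))
  } else {
    pages <- .readPages(path)
    if (length(pages) %% nch != 0L)
      stop("file holds ", length(pages), " page(s), not a multiple of the ",
           nch, " mapped channel(s)", call. = FALSE)
    nz <- length(pages) %/% nch
    idx <- if (layout == "interleaved") {
      function(ch) seq(ch, by = nch, length.out = nz)
    } else {
      function(ch) seq((ch - 1L) * nz + 1L, length.out = nz)
    }
    channels <- lapply(seq_len(nch), function(ch) {
      pp <- pages[idx(ch)]
      array(unlist(pp), dim = c(dim(pp[[1L]]), nz))
    })
  }
  names(channels) <- channel_map
  new("ZStack", channels = channels, zSpacing = as.numeric(z_spacing),
      bitDepth = as.integer(bit_depth),
      metadata = list(source = path, layout = layout))
}

#' @rdname maxIntensityProjection
#' @export
setMethod("maxIntensityProjection", "ZStack", function(stack, cell_id = "cell") {
  planes <- lapply(stack@channels, function(arr) {
    nz <- dim(arr)[3L]
    if (nz < 1L) stop("empty stack", call. = FALSE)
    out <- arr[, , 1L, drop = TRUE]
    dim(out) <- dim(arr)[1:2]
    if (nz > 1L)
      for (z in 2:nz) out <- pmax(out, arr[, , z])
    out
  })
  new("CellImage", channels = planes, cellId = as.character(cell_id),
      pixelSize = NA_real_, bitDepth = stack@bitDepth,
      metadata = stack@metadata)
})

#' Write a CellImage as a multi-page 16-bit TIFF
#'
#' Pages are written in the image's channel order (one page per channel);
#' intensities are rounded and clamped to the unsigned integer range of
#' \code{bit_depth}. The matching reader is
#' \code{loadStack(path, channelRoles(image), layout = "interleaved")}.
#'
#' @param image A \linkS4class{CellImage}.
#' @param path Output file path.
#' @param bit_depth Bits per sample (8 or 16).
#' @return Invisibly, \code{path}.
#' @export
writeCellImage <- function(image, path, bit_depth = 16L) {
  stopifnot(is(image, "CellImage"), bit_depth %in% c(8L, 16L))
  maxval <- 2^bit_depth - 1
  pages <- lapply(image@channels, function(ch)
    pmin(pmax(round(ch), 0), maxval) / maxval)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bit_depth),
                 error = function(e)
                   stop("failed to write TIFF '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Export segmentation masks as an 8-bit label image
#'
#' For visual QC: background 0, nucleus 1, spots numbered from 2 in spot-id
#' order (spot 1 of the cell gets label 2, etc.).
#'
#' @param nucleus A \linkS4class{NucleusRegion}.
#' @param spots List of \linkS4class{SpotRegion}.
#' @param path Optional TIFF output path; if \code{NULL} the label matrix is
#'   returned without writing.
#' @return Integer label matrix, invisibly when \code{path} is given.
#' @export
writeMaskLabels <- function(nucleus, spots = list(), path = NULL) {
  lab <- matrix(0L, nrow(nucleus@mask), ncol(nucleus@mask))
  lab[nucleus@mask] <- 1L
  for (s in spots) lab[s@mask] <- s@spotId + 1L
  if (is.null(path)) return(lab)
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  invisible(lab)
}

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write per-cell (and optionally per-spot) quantification tables
#'
#' CSV with a header row, UTF-8, comma-delimited. Numeric columns are
#' serialized with 17 significant digits so the table round-trips through
#' \code{\link{readQuantTable}} without loss; missing values (e.g. allele
#' labels outside allelic mode) become empty fields.
#'
#' @param rows Data frame of per-cell rows (an experiment table).
#' @param path Output CSV path.
#' @param spots Optional per-spot long-format data frame.
#' @param spots_path Output path for \code{spots}.
#' @return Invisibly, \code{path}.
#' @export
writeQuantTable <- function(rows, path, spots = NULL, spots_path = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0L)
  .writeOne <- function(df, p) {
    out <- df
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
    utils::write.csv(out, p, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  .writeOne(rows, path)
  if (!is.null(spots)) {
    if (is.null(spots_path))
      spots_path <- sub("(\\.csv)?$", "_spots.csv", path)
    .writeOne(spots, spots_path)
  }
  invisible(path)
}

#' Read back a quantification table written by writeQuantTable
#'
#' @param path CSV path.
#' @return Data frame; empty fields become \code{NA}.
#' @export
readQuantTable <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path, call. = FALSE)
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}
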