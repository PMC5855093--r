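# File-format glue: TIFF images and masks, ROI/polygon JSON.

# Normalize tiff::readTIFF output (matrix, array, or list of frames) to a
# list of numeric matrices.
tiff_frames <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(x)) x <- list(x)
  lapply(x, function(fr) {
    if (length(dim(fr)) == 3L) {
      lapply(seq_len(dim(fr)[3L]), function(k) fr[, , k])
    } else list(as.matrix(fr))
  }) |> unlist(recursive = FALSE)
}

#' Read a two-channel tract image from TIFF
#'
#' Accepts either a two-frame TIFF or a single frame with two samples per
#' pixel. The pixel size must be supplied explicitly: it is never assumed to
#' be 1 um/px.
#'
#' @param path TIFF file path.
#' @param pixel_size um/px (required).
#' @param orientation see [tract_image()].
#' @param channel_order order of the channels in the file (default dorsal
#'   then ventral).
#' @return a [tract_image()].
#' @export
read_tract_tiff <- function(path, pixel_size, orientation = "dorsal_high",
                            channel_order = c("dorsal", "ventral")) {
  if (missing(pixel_size) || is.null(pixel_size))
    abort("pixel_size is required; it is never assumed to be 1 um/px")
  frames <- tiff_frames(path)
  if (length(frames) != 2L)
    abort("%s: expected exactly 2 channels, found %d", path, length(frames))
  names(frames) <- channel_order
  tract_image(frames[["dorsal"]], frames[["ventral"]], pixel_size, orientation)
}

#' Write a two-channel tract image to TIFF
#'
#' Channels are written as two frames (dorsal then ventral), rescaled to the
#' unit range TIFF stores.
#'
#' @param image a [tract_image()].
#' @param path output path.
#' @return `path`, invisibly. The scale factor used is attached as an
#'   attribute of the return value.
#' @export
write_tract_tiff <- function(image, path) {
  hi <- max(image$dorsal, image$ventral, 1)
  tiff::writeTIFF(list(image$dorsal / hi, image$ventral / hi), path,
                  bits.per.sample = 16L)
  out <- path
  attr(out, "scale") <- hi
  invisible(out)
}

#' Read a binary mask (stack) from TIFF
#'
#' @param path TIFF file path.
#' @param pixel_size um/px (required; never assumed).
#' @return list with `masks` (list of binary matrices) and `pixel_size`.
#' @export
read_mask_tiff <- function(path, pixel_size) {
  if (missing(pixel_size) || is.null(pixel_size))
    abort("pixel_size is required; it is never assumed to be 1 um/px")
  list(masks = lapply(tiff_frames(path), function(m) (m > 0.5) * 1),
       pixel_size = pixel_size)
}

#' Read a reference line from ROI JSON
#'
#' Expects `{x1, y1, x2, y2}` in pixels, optionally `offset_from_chiasm`.
#'
#' @param path JSON file path.
#' @return a [reference_line()].
#' @export
read_roi_line <- function(path) {
  j <- jsonlite::fromJSON(path)
  for (k in c("x1", "y1", "x2", "y2"))
    if (is.null(j[[k]])) abort("%s: missing field %s", path, k)
  reference_line(j$x1, j$y1, j$x2, j$y2,
                 offset_from_chiasm = j$offset_from_chiasm %||% 70)
}

#' Read a polygon from JSON
#'
#' Expects a list of `[x, y]` pairs in um.
#'
#' @param path JSON file path.
#' @return n x 2 matrix.
#' @export
read_polygon_json <- function(path) {
  as_poly(as.matrix(jsonlite::fromJSON(path)), path)
}

#' Write a polygon to JSON
#'
#' @param poly n x 2 matrix (um).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygon_json <- function(poly, path) {
  jsonlite::write_json(unname(as.matrix(poly)), path, digits = NA)
  invisible(path)
}
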