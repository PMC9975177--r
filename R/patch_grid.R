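#' Construct a PatchSpec
#'
#' @param sizePx patch side length in pixels; must divide `imageSidePx`.
#' @param imageSidePx side of the square image the spec tiles.
#' @return a [PatchSpec-class] object.
#' @examples
#' spec <- patchSpec(128, 1024)
#' gridDim(spec)  # 8
#' @export
patchSpec <- function(sizePx, imageSidePx) {
  new("PatchSpec", sizePx = as.integer(sizePx),
      imageSidePx = as.integer(imageSidePx))
}

#' Resize a grayscale image to a square side
#'
#' Bilinear resampling to `targetSide` x `targetSide`. Intensities are
#' interpolated but never rescaled or standardized, so the output lives on
#' the same intensity scale as the input.
#'
#' @param image 2-D numeric matrix (single-channel).
#' @param targetSide output side in pixels.
#' @return numeric `targetSide` x `targetSide` matrix.
#' @examples
#' resizeImage(matrix(7, 2048, 2048), 8)[1, 1]  # still 7
#' @export
resizeImage <- function(image, targetSide) {
  .check(is.numeric(image) && is.matrix(image) && length(image) > 0,
         "image must be a non-empty 2-D numeric matrix (single channel)")
  .check(all(is.finite(image)), "image contains non-finite intensities")
  targetSide <- as.integer(targetSide)
  .check(targetSide >= 1L, "targetSide must be >= 1")
  if (nrow(image) == targetSide && ncol(image) == targetSide) return(image)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                            w = targetSide, h = targetSide,
                                            filter = "bilinear"))
  matrix(as.numeric(out), targetSide, targetSide)
}

#' Tile a square image into non-overlapping patches
#'
#' Splits `image` into `gridDim(spec)^2` disjoint square patches covering
#' the image exactly, returned in row-major order (gy varying slowest).
#' Grid coordinates are 0-based; patch (gx, gy) holds pixel rows
#' `[gy*s, (gy+1)*s)` and columns `[gx*s, (gx+1)*s)` (half-open).
#'
#' Each patch is a plain list with elements `spec`, `gx`, `gy`, `pixels`
#' (class `"mrpadPatch"`); individual patches are deliberately lightweight
#' because an image yields thousands of them.
#'
#' @param image square numeric matrix whose side `spec` divides.
#' @param spec a [PatchSpec-class].
#' @return list of patches, length `gridDim(spec)^2`.
#' @export
tileImage <- function(image, spec) {
  .check(is.matrix(image) && nrow(image) == ncol(image),
         "image must be a square matrix")
  .check(nrow(image) == imageSide(spec),
         sprintf("image side (%d) does not match spec imageSidePx (%d)",
                 nrow(image), imageSide(spec)))
  s <- patchSize(spec)
  if (nrow(image) %% s != 0L)
    stop(sprintf("patch size %d does not divide image side %d: cannot tile",
                 s, nrow(image)))
  g <- gridDim(spec)
  out <- vector("list", g * g)
  k <- 1L
  for (gy in 0:(g - 1L)) {
    rows <- (gy * s + 1L):((gy + 1L) * s)
    for (gx in 0:(g - 1L)) {
      cols <- (gx * s + 1L):((gx + 1L) * s)
      out[[k]] <- structure(
        list(spec = spec, gx = gx, gy = gy,
             pixels = image[rows, cols, drop = FALSE]),
        class = "mrpadPatch")
      k <- k + 1L
    }
  }
  out
}

#' Reassemble tiles into the original image
#'
#' Inverse of [tileImage()]: places each patch's pixel block back at its
#' grid location. Used mainly to assert the disjoint-cover invariant.
#'
#' @param patches list of patches from [tileImage()].
#' @return numeric matrix of side `imageSidePx`.
#' @export
reassembleTiles <- function(patches) {
  .check(length(patches) > 0, "no patches to reassemble")
  spec <- patches[[1L]]$spec
  s <- patchSize(spec)
  side <- imageSide(spec)
  out <- matrix(NA_real_, side, side)
  for (p in patches) {
    out[(p$gy * s + 1L):((p$gy + 1L) * s),
        (p$gx * s + 1L):((p$gx + 1L) * s)] <- p$pixels
  }
  .check(!anyNA(out), "patches do not cover the image")
  out
}
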