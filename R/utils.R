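#' @importFrom EBImage Image imageData readImage resize rotate
#' @importFrom stats quantile rnorm runif setNames cov
#' @importFrom utils read.csv write.csv tail head
NULL

# internal: coerce an EBImage read to a plain 2-D numeric matrix
.asGrayMatrix <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) return(x[, , drop = TRUE])
  if (length(d) == 3L) {
    # accept a trivially replicated grayscale stack, reject true color
    ch <- lapply(seq_len(d[3]), function(i) x[, , i])
    if (d[3] == 1L) return(ch[[1L]])
    same <- all(vapply(ch[-1L], function(m)
      isTRUE(all.equal(m, ch[[1L]], tolerance = 1e-12)), logical(1)))
    if (same) return(ch[[1L]])
  }
  stop("input must be a single-channel (grayscale) image")
}

#' Read a grayscale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale PNG/TIFF into a plain numeric matrix
#' (intensities as stored by the reader, typically scaled to [0, 1]; no
#' further normalization is applied). A color image with genuinely distinct
#' channels is rejected.
#'
#' @param path file path (.png, .tif or .tiff).
#' @return numeric matrix.
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  # EBImage stores x (image column) in the first dimension; transpose to
  # the usual R matrix convention m[row, col] used by the writers
  m <- t(.asGrayMatrix(EBImage::imageData(img)))
  storage.mode(m) <- "double"
  m
}

#' Write a grayscale image
#'
#' Writes a numeric matrix as 16-bit TIFF (`.tif`/`.tiff`) or 8-bit PNG
#' (`.png`). Values are clipped to [0, 1] for encoding.
#'
#' @param image numeric matrix.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
writeImageGray <- function(image, path) {
  m <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop("unsupported image extension: .", ext)
  invisible(path)
}

# internal: md5 of an R object via canonical serialization (version 2 for
# stability across sessions)
.objectChecksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

# internal: clip helper
.clip01 <- function(x) pmin(pmax(x, 0), 1)

# internal: stopifnot-style check with a clean message
.check <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)
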