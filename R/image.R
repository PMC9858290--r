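#' Construct a single-cell image sample
#'
#' An image sample is an `H x W x 3` numeric array of intensities on the
#' `[0, 1]` scale with an optional class label and source identifier. The
#' canonical crop is square; the default edge of 224 pixels is chosen so
#' that three 2x down-samplings in the encoder land exactly on a 28 x 28
#' latent grid.
#'
#' @param pixels numeric array, `H x W x 3` (or `H x W`, replicated to 3
#'   channels), values in `[0, 1]`.
#' @param label class label or `NULL`.
#' @param source_id identifier string or `NULL`.
#' @return an object of class `wbc_image` (the pixel array with `label`
#'   and `source_id` attributes).
#' @examples
#' img <- image_sample(array(0.5, c(8, 8, 3)), label = "myeloblast")
#' image_label(img)
#' @export
image_sample <- function(pixels, label = NULL, source_id = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    abort("pixels must be an H x W x 3 array")
  if (d[1] != d[2]) abort("image must be a square crop (H = W)")
  if (anyNA(pixels) || min(pixels) < -1e-8 || max(pixels) > 1 + 1e-8)
    abort("pixel values must lie in [0, 1]")
  structure(pmin(pmax(unclass(pixels), 0), 1),
            label = label, source_id = source_id, class = "wbc_image")
}

#' @rdname image_sample
#' @param img a `wbc_image`.
#' @export
image_label <- function(img) attr(img, "label", exact = TRUE)

#' @rdname image_sample
#' @export
image_source_id <- function(img) attr(img, "source_id", exact = TRUE)

# Rebuild a wbc_image around a raw pixel array, carrying metadata over.
rewrap_image <- function(pixels, template, label = image_label(template),
                         source_id = image_source_id(template)) {
  structure(pmin(pmax(unclass(pixels), 0), 1),
            label = label, source_id = source_id, class = "wbc_image")
}

#' @export
print.wbc_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<wbc_image %dx%dx%d label=%s source=%s>\n", d[1], d[2], d[3],
              image_label(x) %||% "<none>", image_source_id(x) %||% "<none>"))
  invisible(x)
}

#' Read and write single-cell images
#'
#' PNG (preferred, lossless 8-bit) and TIFF files are supported. Grayscale
#' images are replicated to three channels; an alpha channel, if present,
#' is dropped. A write followed by a read reproduces the pixels within the
#' 8-bit quantization bound of 1/255 per channel.
#'
#' @param path file path; the format is chosen by extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param label,source_id metadata attached to the returned sample;
#'   `source_id` defaults to the file name.
#' @param resize if non-`NULL`, bilinearly resize to this square edge
#'   length after reading.
#' @return `read_image()` returns a [image_sample()]; `write_image()`
#'   returns `path` invisibly.
#' @examples
#' img <- image_sample(array(runif(16 * 16 * 3), c(16, 16, 3)))
#' p <- tempfile(fileext = ".png")
#' write_image(img, p)
#' round_trip <- read_image(p)
#' max(abs(round_trip - img)) <= 1 / 255
#' @export
read_image <- function(path, label = NULL, source_id = NULL, resize = NULL) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format '.", ext, "' for ", path))
  )
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1) px <- array(rep(px, 3L), c(dim(px)[1:2], 3L))
  if (!is.null(resize) && !all(dim(px)[1:2] == resize))
    px <- .resize_bilinear(px, as.integer(resize), as.integer(resize))
  image_sample(px, label = label,
               source_id = source_id %||% basename(path))
}

#' @rdname read_image
#' @param img the image sample to write.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  px <- unclass(img)
  attributes(px) <- list(dim = dim(img))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    abort(paste0("unsupported image format '.", ext, "'"))
  )
  invisible(path)
}

#' Bilinearly resize an image sample
#'
#' @param img a [image_sample()] or plain `H x W x C` array.
#' @param size target square edge length in pixels.
#' @return resized image; metadata is preserved for `wbc_image` input.
#' @export
resize_image <- function(img, size) {
  out <- .resize_bilinear(unclass(img), as.integer(size), as.integer(size))
  if (inherits(img, "wbc_image")) rewrap_image(out, img) else out
}

# Stack a list of images (or one image) into an H x W x C x N array.
stack_images <- function(images) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

unstack_images <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(i) array(x[, , , i], d[1:3]))
}
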