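#' Read an image file as an RGB image
#'
#' PNG, JPEG, TIFF and BMP are supported via EBImage. Grayscale files are
#' replicated across the three channels.
#'
#' @param path file path.
#' @return RGB image (`h x w x 3`, values 0-255).
#' @export
read_image <- function(path) {
  x <- EBImage::readImage(path)
  d <- dim(x)                      # EBImage stores (x = col, y = row[, ch])
  a <- as.array(x)
  if (length(d) == 2L) a <- array(rep(a, 3), c(d[1], d[2], 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  rgb_image(clip8(aperm(a, c(2, 1, 3)) * 255))
}

#' Read a binary mask from an image file
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path file path.
#' @return binary mask.
#' @export
read_mask <- function(path) {
  x <- EBImage::readImage(path)
  a <- as.array(x)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  binary_mask(t(a) > 0.5)
}

#' Write an RGB image as PNG
#' @param img RGB image.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(aperm(rgb_image(img), c(1, 2, 3)) / 255, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit 0/255 PNG
#' @param mask binary mask.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(binary_mask(mask) * 1, path)
  invisible(path)
}

# 1-pixel-wide outer contour of a mask
mask_outline <- function(mask) mask & !erode_mask(mask, 1L)

#' Overlay prediction (blue) and ground truth (red) contours on an image
#'
#' @param img RGB image.
#' @param pred predicted mask (blue contour), or `NULL`.
#' @param gt ground-truth mask (red contour), or `NULL`.
#' @return RGB image with contours drawn.
#' @export
overlay_contours <- function(img, pred = NULL, gt = NULL) {
  img <- rgb_image(img)
  paint <- function(im, mask, color) {
    o <- mask_outline(dilate_mask(mask, 1L))
    for (ch in 1:3) {
      plane <- im[, , ch]
      plane[o] <- color[ch]
      im[, , ch] <- plane
    }
    im
  }
  if (!is.null(gt) && any(gt)) img <- paint(img, binary_mask(gt), c(255, 0, 0))
  if (!is.null(pred) && any(pred)) img <- paint(img, binary_mask(pred), c(0, 80, 255))
  img
}
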