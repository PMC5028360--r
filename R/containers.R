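#' @title Image and mask containers
#' @description
#' dermseg uses plain base-R containers throughout: an RGB image is a
#' `height x width x 3` numeric array with values in `[0, 255]` (channel
#' order red, green, blue); a gray image is a numeric matrix carrying a
#' declared value range in its `"range"` attribute; a binary mask is a
#' logical matrix with `TRUE` marking foreground. Pixels are indexed
#' `[row, col]`, 1-based; row 1 is the top image row.
#' @name containers
NULL

#' Construct / validate an RGB image
#'
#' @param pixels numeric `h x w x 3` array, values in `[0, 255]`.
#' @return the validated array (invisibly unchanged).
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_image: `pixels` must be a height x width x 3 array")
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L)
    stop("rgb_image: image must be at least 8 x 8 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("rgb_image: values must be finite and within [0, 255]")
  storage.mode(pixels) <- "double"
  pixels
}

#' Construct a gray image with a declared value range
#'
#' @param pixels numeric matrix.
#' @param range length-2 numeric `(lo, hi)` declared value range; defaults to
#'   `c(0, 255)`.
#' @return numeric matrix with a `"range"` attribute.
#' @export
gray_image <- function(pixels, range = c(0, 255)) {
  if (!is.matrix(pixels)) stop("gray_image: `pixels` must be a matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("gray_image: all values must be finite")
  if (length(range) != 2L || range[2] <= range[1])
    stop("gray_image: `range` must be (lo, hi) with hi > lo")
  if (min(pixels) < range[1] || max(pixels) > range[2])
    stop("gray_image: values fall outside the declared range")
  storage.mode(pixels) <- "double"
  attr(pixels, "range") <- as.numeric(range)
  pixels
}

#' @rdname gray_image
#' @param img gray image.
#' @return declared `(lo, hi)` range (defaults to `c(0, 255)` if undeclared).
#' @export
gray_range <- function(img) {
  r <- attr(img, "range")
  if (is.null(r)) c(0, 255) else r
}

#' Validate a binary mask
#'
#' @param pixels logical matrix, `TRUE` = foreground.
#' @return the logical matrix.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("binary_mask: `pixels` must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("binary_mask: values must be logical or 0/1")
    pixels <- array(as.logical(pixels), dim(pixels))
  }
  if (anyNA(pixels)) stop("binary_mask: NA not allowed")
  pixels
}

# strip dermseg attributes, returning a bare matrix
bare <- function(m) {
  attr(m, "range") <- NULL
  m
}

# clip to [0,255]
clip8 <- function(x) pmin(pmax(x, 0), 255)

# run code with a local RNG stream; global .Random.seed is restored on exit
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# reflective (half-sample symmetric) index vector: positions (1-p):(n+p)
reflect_idx <- function(n, p) {
  pos <- (1L - p):(n + p)
  # period-2n half-sample reflection
  m <- ((pos - 1L) %% (2L * n))
  m <- ifelse(m < 0L, m + 2L * n, m)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# pad a matrix reflectively by (pr, pc)
pad_reflect <- function(m, pr, pc = pr) {
  ri <- reflect_idx(nrow(m), pr)
  ci <- reflect_idx(ncol(m), pc)
  m[ri, ci, drop = FALSE]
}
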