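#' Luminance of an RGB image
#'
#' Combines the three channels linearly with the ITU-R BT.601 weights
#' `R*0.2989 + G*0.5870 + B*0.1140`. Values are kept as reals (no rounding).
#'
#' @param img RGB image (see [rgb_image()]).
#' @return gray image with declared range `c(0, 255)`.
#' @export
luminance <- function(img) {
  img <- rgb_image(img)
  gray_image(img[, , 1] * 0.2989 + img[, , 2] * 0.5870 + img[, , 3] * 0.1140)
}

#' Shannon entropy of each color channel
#'
#' Each channel is histogrammed over the 256 8-bit levels; the entropy is
#' `-sum(p * log2(p))` over non-empty bins, in bits. The winning channel is
#' the one with the highest entropy; ties break toward blue, then green,
#' since the blue channel is the segmentation default.
#'
#' @param img RGB image.
#' @return list with `per_channel` (named numeric, bits) and
#'   `argmax_channel` (one of `"red"`, `"green"`, `"blue"`).
#' @export
channel_entropy <- function(img) {
  img <- rgb_image(img)
  ent1 <- function(ch) {
    counts <- tabulate(pmin(255L, as.integer(floor(ch * 256 / 255))) + 1L, 256L)
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  e <- c(red = ent1(img[, , 1]), green = ent1(img[, , 2]), blue = ent1(img[, , 3]))
  pref <- c("blue", "green", "red")                       # tie-break order
  winner <- pref[pref %in% names(e)[e >= max(e) - 1e-12]][1]
  list(per_channel = e, argmax_channel = winner)
}

#' Split an RGB image into CIE L*a*b* channels
#'
#' sRGB companding, D65 white point. Declared ranges are `L` in `[0, 100]`,
#' `a` and `b` in `[-128, 127]`.
#'
#' @param img RGB image.
#' @return list of gray images `L`, `a`, `b`.
#' @export
split_lab <- function(img) {
  img <- rgb_image(img)
  d <- dim(img)
  srgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3])) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  shape <- function(v, rng) gray_image(matrix(pmin(pmax(v, rng[1]), rng[2]), d[1], d[2]), rng)
  list(L = shape(lab[, 1], c(0, 100)),
       a = shape(lab[, 2], c(-128, 127)),
       b = shape(lab[, 3], c(-128, 127)))
}

#' Extract a single-channel image
#'
#' @param img RGB image.
#' @param which one of `"red"`, `"green"`, `"blue"` (the pipeline default),
#'   `"luminance"`, `"max_entropy"` (channel of highest entropy), `"L"`,
#'   `"a"`, `"b"` (CIE L*a*b*).
#' @return gray image.
#' @export
extract_channel <- function(img, which = "blue") {
  img <- rgb_image(img)
  valid <- c("red", "green", "blue", "luminance", "max_entropy", "L", "a", "b")
  if (!is.character(which) || length(which) != 1L || !(which %in% valid))
    stop("extract_channel: `which` must be one of: ", paste(valid, collapse = ", "))
  switch(which,
    red = gray_image(img[, , 1]),
    green = gray_image(img[, , 2]),
    blue = gray_image(img[, , 3]),
    luminance = luminance(img),
    max_entropy = extract_channel(img, channel_entropy(img)$argmax_channel),
    L = split_lab(img)$L,
    a = split_lab(img)$a,
    b = split_lab(img)$b)
}

# quantize a gray image to integer levels 0..255 over its declared range
quantize256 <- function(img) {
  r <- gray_range(img)
  pmin(255L, as.integer(floor((bare(img) - r[1]) * 256 / (r[2] - r[1]))))
}

#' Otsu threshold by exhaustive intra-class variance minimization
#'
#' The image is quantized to 256 uniform bins over its declared range and
#' every candidate threshold `t` in `0..254` is scored by the within-class
#' variance `w1(t)*var1(t) + w2(t)*var2(t)` of the two classes
#' `{0..t}` and `{t+1..255}`; the smallest minimizer with both classes
#' non-empty is returned. `value` is the threshold mapped back to the
#' image's value scale, such that `pixel <= value` reproduces the low class
#' exactly.
#'
#' @param img gray image with at least two distinct quantized levels.
#' @return object of class `"otsu_result"`: list with `threshold` (bin index
#'   in 0..254), `value` (gray-level threshold on the declared range),
#'   `class_weights`, `class_variances`, `objective`.
#' @export
otsu <- function(img) {
  q <- quantize256(img)
  counts <- tabulate(q + 1L, 256L)
  if (sum(counts > 0) < 2L) stop("otsu: degenerate histogram (single gray level)")
  n <- sum(counts)
  lev <- 0:255
  p <- counts / n
  w1 <- cumsum(p)                       # P(class {0..t}), t = 0..255
  m1 <- cumsum(p * lev)                 # first moments
  s1 <- cumsum(p * lev^2)
  wtot <- w1[256]; mtot <- m1[256]; stot <- s1[256]
  t <- 0:254
  w1t <- w1[t + 1L]; w2t <- wtot - w1t
  ok <- w1t > 0 & w2t > 0
  mu1 <- ifelse(ok, m1[t + 1L] / w1t, 0)
  mu2 <- ifelse(ok, (mtot - m1[t + 1L]) / w2t, 0)
  v1 <- ifelse(ok, s1[t + 1L] / w1t - mu1^2, 0)
  v2 <- ifelse(ok, (stot - s1[t + 1L]) / w2t - mu2^2, 0)
  obj <- ifelse(ok, w1t * v1 + w2t * v2, Inf)
  best <- which.min(obj) - 1L           # smallest minimizer (which.min ties -> first)
  r <- gray_range(img)
  structure(list(
    threshold = best,
    value = r[1] + (best + 1) * (r[2] - r[1]) / 256,
    class_weights = c(w1t[best + 1L], w2t[best + 1L]),
    class_variances = c(v1[best + 1L], v2[best + 1L]),
    objective = obj[best + 1L]
  ), class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("Otsu threshold: level %d (value %.4f)\n", x$threshold, x$value))
  cat(sprintf("  class weights %.4f / %.4f, within-class variance %.4f\n",
              x$class_weights[1], x$class_weights[2], x$objective))
  invisible(x)
}

#' Threshold a gray image into a binary mask
#'
#' @param img gray image.
#' @param t threshold on the image's value scale (within the declared range).
#' @param dark_foreground if `TRUE` (default) the mask is `pixel <= t`
#'   (lesions are darker than skin); otherwise `pixel > t`.
#' @return binary mask.
#' @export
binarize <- function(img, t, dark_foreground = TRUE) {
  r <- gray_range(img)
  if (!is.numeric(t) || length(t) != 1L || t < r[1] || t > r[2])
    stop("binarize: `t` must lie within the declared range [", r[1], ", ", r[2], "]")
  m <- if (dark_foreground) bare(img) <= t else bare(img) > t
  binary_mask(m)
}

#' Dark-corner mask
#'
#' Otsu-binarizes the image with dark pixels as foreground and keeps only
#' connected components that touch at least one of the four image corner
#' pixels — the signature of the unilluminated rounded lens corners of a
#' dermatoscope. The kept components are additionally clipped to the
#' near-corner zone (pixels within `max_dist_frac * min(h, w)` of their
#' nearest image corner): a lens corner cannot physically reach the image
#' center, so a dark artifact bridging a corner to the lesion (an
#' undetected hair, say) cannot drag the lesion into the corner mask. A
#' centered dark lesion never touches a corner and is excluded outright. A
#' contrast-free image yields an empty mask with a warning.
#'
#' @param img gray image.
#' @param max_dist_frac fraction of the shorter image side bounding how far
#'   from its corner a corner pixel may lie (default 0.5).
#' @return binary mask of the dark corner regions (possibly empty).
#' @export
corner_mask <- function(img, max_dist_frac = 0.5) {
  res <- tryCatch(otsu(img), error = function(e) {
    warning("corner_mask: degenerate histogram; returning empty mask")
    NULL
  })
  empty <- matrix(FALSE, nrow(img), ncol(img))
  if (is.null(res)) return(binary_mask(empty))
  dark <- binarize(img, res$value, dark_foreground = TRUE)
  lab <- EBImage::bwlabel(dark)
  h <- nrow(lab); w <- ncol(lab)
  hit <- unique(c(lab[1, 1], lab[1, w], lab[h, 1], lab[h, w]))
  hit <- hit[hit > 0]
  if (length(hit) == 0) return(binary_mask(empty))
  m <- matrix(lab %in% hit, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- pmin((rows - 1)^2 + (cols - 1)^2, (rows - 1)^2 + (cols - w)^2,
             (rows - h)^2 + (cols - 1)^2, (rows - h)^2 + (cols - w)^2)
  binary_mask(m & d2 <= (max_dist_frac * min(h, w))^2)
}
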