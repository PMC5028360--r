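#' Directional difference-of-Gaussians parameters
#'
#' The hair matched filter is an anisotropic difference of two Gaussians,
#' `g(x, y) = k1 exp(-(x^2/2s_x1^2 + y^2/2s_y1^2)) -
#'            k2 exp(-(x^2/2s_x2^2 + y^2/2s_y2^2))`,
#' mean-subtracted so it sums to zero, evaluated on the integer grid
#' `[-half_size, half_size]^2` and rotated to a bank of orientations. `x` is
#' the across-line axis and `y` the along-line axis: the first Gaussian is
#' narrow across the line and elongated along it, the second is broader and
#' acts as the local background estimate.
#'
#' @param k1,k2 gains of the two Gaussians.
#' @param sigma_x1,sigma_y1 std. dev. (pixels) of the first Gaussian.
#' @param sigma_x2,sigma_y2 std. dev. (pixels) of the second Gaussian.
#' @param half_size kernel half-width in pixels; default
#'   `ceiling(3 * max(sigmas))`.
#' @param angles orientation bank in degrees, each in `[0, 180)`; default 12
#'   orientations at 15 degree steps.
#' @return object of class `"dog_params"`.
#' @export
dog_params <- function(k1 = 1, k2 = 0.4,
                       sigma_x1 = 1.5, sigma_y1 = 6,
                       sigma_x2 = 3, sigma_y2 = 9,
                       half_size = NULL,
                       angles = seq(0, 165, by = 15)) {
  sig <- c(sigma_x1, sigma_y1, sigma_x2, sigma_y2)
  if (any(sig <= 0)) stop("dog_params: all sigmas must be > 0")
  if (is.null(half_size)) half_size <- ceiling(3 * max(sig))
  if (half_size < ceiling(3 * max(sig)))
    stop("dog_params: half_size must be >= 3 * max(sigma)")
  if (length(angles) == 0 || any(angles < 0 | angles >= 180))
    stop("dog_params: angles must be non-empty, each in [0, 180)")
  structure(list(k1 = k1, k2 = k2,
                 sigma_x1 = sigma_x1, sigma_y1 = sigma_y1,
                 sigma_x2 = sigma_x2, sigma_y2 = sigma_y2,
                 half_size = as.integer(half_size), angles = as.numeric(angles)),
            class = "dog_params")
}

#' Base (unrotated) difference-of-Gaussians kernel
#'
#' At angle 0 the kernel is elongated along the column axis, i.e. it matches
#' a horizontal line. The kernel is mean-subtracted so its response to a
#' constant image is exactly zero.
#'
#' @param p [dog_params()].
#' @return square numeric matrix of side `2 * half_size + 1`.
#' @export
dog_kernel <- function(p) {
  if (!inherits(p, "dog_params")) p <- do.call(dog_params, p)
  g <- seq(-p$half_size, p$half_size)
  x <- matrix(g, length(g), length(g))         # across-line axis = rows
  y <- t(x)                                    # along-line axis = cols
  k <- p$k1 * exp(-(x^2 / (2 * p$sigma_x1^2) + y^2 / (2 * p$sigma_y1^2))) -
       p$k2 * exp(-(x^2 / (2 * p$sigma_x2^2) + y^2 / (2 * p$sigma_y2^2)))
  k - mean(k)
}

#' Rotate a kernel by bicubic resampling
#'
#' The output at rotated coordinates equals the input at the original
#' coordinates; support is unchanged and samples falling outside are zero.
#' Resampling is bicubic (Catmull-Rom), so repeated rotations compose with
#' little smoothing loss. The result is re-centered to zero mean so
#' rotation preserves the zero-response-to-constant property.
#'
#' @param kernel square numeric matrix (odd side).
#' @param angle rotation in degrees, `[0, 180)`.
#' @return rotated kernel, same dimensions.
#' @export
rotate_kernel <- function(kernel, angle) {
  if (angle < 0 || angle >= 180) stop("rotate_kernel: angle must be in [0, 180)")
  if (angle == 0) return(kernel)
  n <- nrow(kernel); c0 <- (n + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  # output grid (xr = row offset, yc = col offset); source = rotate by -angle
  xr <- matrix(seq_len(n) - c0, n, n)
  yc <- t(xr)
  sx <- xr * co - yc * si + c0
  sy <- yc * co + xr * si + c0
  at <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    v <- numeric(length(i))
    v[ok] <- kernel[cbind(i[ok], j[ok])]
    v
  }
  # Catmull-Rom weights for fractional offset t at taps -1, 0, 1, 2
  cr_w <- function(t) list(
    w0 = ((-t + 2) * t - 1) * t / 2,
    w1 = ((3 * t - 5) * t * t + 2) / 2,
    w2 = ((-3 * t + 4) * t + 1) * t / 2,
    w3 = (t - 1) * t * t / 2)
  i0 <- floor(sx); j0 <- floor(sy)
  wi <- cr_w(sx - i0); wj <- cr_w(sy - j0)
  v <- 0
  for (a in 0:3) {
    rowv <- wj$w0 * at(i0 - 1 + a, j0 - 1) + wj$w1 * at(i0 - 1 + a, j0) +
            wj$w2 * at(i0 - 1 + a, j0 + 1) + wj$w3 * at(i0 - 1 + a, j0 + 2)
    v <- v + rowv * wi[[a + 1]]
  }
  out <- matrix(v, n, n)
  out - mean(out)
}

# FFT-based 2-D convolution with reflective boundary handling
conv2_reflect <- function(img, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  p <- pad_reflect(img, kh, kw)
  ph <- nrow(p); pw <- ncol(p)
  kp <- matrix(0, ph, pw)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  # center the kernel at (1,1) modulo the padded grid
  kp <- kp[c((kh + 1):ph, seq_len(kh)), c((kw + 1):pw, seq_len(kw))]
  out <- Re(stats::fft(stats::fft(p) * stats::fft(kp), inverse = TRUE)) / (ph * pw)
  out[(kh + 1):(kh + nrow(img)), (kw + 1):(kw + ncol(img)), drop = FALSE]
}

#' Directional matched-filter response
#'
#' Convolves the image with the rotated difference-of-Gaussians bank
#' (reflective boundary). Hairs are dark against skin, so the per-
#' orientation response is the negated matched-filter output: dark
#' curvilinear structure yields a large positive response at the matching
#' orientation. Returns the pixelwise maximum over orientations and the
#' orientation attaining it.
#'
#' @param img gray image (larger than the kernel support).
#' @param p [dog_params()].
#' @return object of class `"hair_detection"`: list with `response` (gray
#'   image), `best_angle` (numeric matrix, degrees), `angles`.
#' @export
directional_response <- function(img, p = dog_params()) {
  if (!inherits(p, "dog_params")) p <- do.call(dog_params, p)
  x <- bare(img)
  side <- 2L * p$half_size + 1L
  if (nrow(x) < side || ncol(x) < side)
    stop("directional_response: image smaller than the kernel support")
  base <- dog_kernel(p)
  resp <- matrix(-Inf, nrow(x), ncol(x))
  best <- matrix(p$angles[1], nrow(x), ncol(x))
  for (a in p$angles) {
    r <- conv2_reflect(x, -rotate_kernel(base, a))
    upd <- r > resp
    resp[upd] <- r[upd]
    best[upd] <- a
  }
  rng <- range(resp)
  if (rng[2] <= rng[1]) rng <- c(rng[1] - 0.5, rng[1] + 0.5)
  # matched-filter gain for a nominal 3-px dark line of unit contrast:
  # the response equals the (negated) kernel mass over the line's footprint
  c0 <- p$half_size + 1L
  unit <- sum(base[(c0 - 1L):(c0 + 1L), ])
  structure(list(response = gray_image(resp, rng), best_angle = best,
                 angles = p$angles, unit_response = unit),
            class = "hair_detection")
}

#' @export
print.hair_detection <- function(x, ...) {
  cat(sprintf("directional response over %d orientations; response range [%.3f, %.3f]\n",
              length(x$angles), min(x$response), max(x$response)))
  invisible(x)
}

#' Threshold the hair response into a binary hair mask
#'
#' Three cleaning steps follow the raw threshold. (1) A component shape
#' filter keeps only line-like structure: a component survives if its
#' major-axis length reaches `min_length` and it is either elongated
#' (major/minor ratio at least `min_elongation`) or everywhere thin
#' (maximal inscribed radius at most `max_halfwidth` — this accepts the
#' low-elongation webs formed by crossing hairs while still rejecting
#' compact blobs). (2) If an intensity image is supplied, the surviving
#' regions — which are smooth halos around the shafts at the scale of the
#' matched filter — are trimmed to pixels actually darker than their local
#' (15 x 15 median) background by at least `dark_margin`. (3) The mask is
#' closed by 1 px to bridge noise gaps and dilated by `grow` px to cover
#' antialiased shaft borders.
#'
#' @param det_response a `"hair_detection"` object from
#'   [directional_response()], or a bare response gray image (then the
#'   `"contrast"` strategy is unavailable); for `strategy = "raw_dark"`,
#'   the raw intensity image instead.
#' @param strategy threshold strategy:
#'   * `"contrast"` (default): response above the matched-filter gain times
#'     `min_contrast`, i.e. the response a dark line of `min_contrast` gray
#'     levels would produce — an absolute, calibrated floor;
#'   * `"otsu"`: Otsu on the response map, keep above;
#'   * `"fixed"`: keep response `> value`;
#'   * `"quantile"`: keep above quantile `q`;
#'   * `"raw_dark"`: keep raw intensity `<= value` (the literal dark-hair
#'     reading; `value` defaults to the intensity Otsu threshold).
#' @param value threshold for `"fixed"` / `"raw_dark"`.
#' @param q upper-tail probability for `"quantile"` (default 0.9).
#' @param min_contrast minimum detectable line contrast in gray levels for
#'   `"contrast"` (default 20 — below typical lesion/skin contrast, well
#'   above the noise floor).
#' @param min_elongation minimum major/minor axis ratio (default 3).
#' @param min_length minimum major-axis length in pixels (default 15).
#' @param max_halfwidth maximal inscribed radius (pixels) for the thinness
#'   alternative of the shape filter (default 12).
#' @param intensity optional gray image (e.g. the luminance) for the
#'   local-darkness verification; `NULL` skips it.
#' @param dark_margin gray levels a verified hair pixel must lie below its
#'   local median background (default `min_contrast / 2`).
#' @param grow final dilation radius in pixels (default 1).
#' @return binary hair mask.
#' @export
segment_hairs <- function(det_response, strategy = "contrast", value = NULL,
                          q = 0.9, min_contrast = 20,
                          min_elongation = 3, min_length = 15,
                          max_halfwidth = 12, intensity = NULL,
                          dark_margin = min_contrast / 2, grow = 1L) {
  det <- NULL
  if (inherits(det_response, "hair_detection")) {
    det <- det_response
    det_response <- det$response
  }
  x <- bare(det_response)
  if (!(is.character(strategy) && length(strategy) == 1L &&
        strategy %in% c("contrast", "otsu", "fixed", "quantile", "raw_dark")))
    stop("segment_hairs: strategy must be one of contrast, otsu, fixed, quantile, raw_dark")
  m <- switch(strategy,
    contrast = {
      if (is.null(det))
        stop("segment_hairs: `contrast` strategy needs the hair_detection object")
      x > det$unit_response * min_contrast
    },
    otsu = {
      res <- tryCatch(otsu(det_response), error = function(e) NULL)
      if (is.null(res)) matrix(FALSE, nrow(x), ncol(x)) else x > res$value
    },
    fixed = {
      if (is.null(value)) stop("segment_hairs: `value` required for fixed strategy")
      x > value
    },
    quantile = x > stats::quantile(x, q),
    raw_dark = {
      if (is.null(value)) {
        res <- tryCatch(otsu(det_response), error = function(e) NULL)
        value <- if (is.null(res)) -Inf else res$value
      }
      x <= value
    })
  m <- binary_mask(matrix(m, nrow(x), ncol(x)))
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))
  major <- mom[, "m.majoraxis"]
  minor <- major * sqrt(pmax(0, 1 - mom[, "m.eccentricity"]^2))
  dm <- EBImage::distmap(m * 1)
  maxr <- vapply(seq_len(max(lab)), function(k) max(dm[lab == k]), 0)
  keep <- which(major >= min_length &
                  (major / pmax(minor, 1e-6) >= min_elongation |
                     maxr <= max_halfwidth))
  m <- matrix(lab %in% keep, nrow(x), ncol(x))
  if (!any(m)) return(binary_mask(m))
  if (!is.null(intensity)) {
    iv <- bare(intensity)
    if (!all(dim(iv) == dim(m)))
      stop("segment_hairs: intensity shape mismatch")
    bg <- local_median_background(iv, 7L)
    m <- m & (iv <= bg - dark_margin)
    m <- close_mask(m, 1L)
  }
  if (grow > 0 && any(m)) m <- dilate_mask(m, grow)
  binary_mask(m)
}

# fast local median (window 2*size+1) via EBImage's constant-time filter,
# reflective boundary
local_median_background <- function(x, size) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(x)
  p <- pad_reflect(x, size)
  f <- matrix(as.numeric(EBImage::medianFilter((p - lo) / (hi - lo), size)),
              nrow(p), ncol(p))
  n <- nrow(x); m <- ncol(x)
  f[(size + 1):(size + n), (size + 1):(size + m), drop = FALSE] * (hi - lo) + lo
}

# one Jacobi sweep of the 4-neighbor mean restricted to `sel`
diffuse_step <- function(x, sel) {
  p <- pad_reflect(x, 1L)
  n <- nrow(x); m <- ncol(x)
  nb <- (p[1:n, 2:(m + 1)] + p[3:(n + 2), 2:(m + 1)] +
         p[2:(n + 1), 1:m] + p[2:(n + 1), 3:(m + 2)]) / 4
  x[sel] <- nb[sel]
  x
}

# central differences with reflective boundary
grad_c <- function(x) {
  p <- pad_reflect(x, 1L)
  n <- nrow(x); m <- ncol(x)
  list(dr = (p[3:(n + 2), 2:(m + 1)] - p[1:n, 2:(m + 1)]) / 2,
       dc = (p[2:(n + 1), 3:(m + 2)] - p[2:(n + 1), 1:m]) / 2)
}

lap_c <- function(x) {
  p <- pad_reflect(x, 1L)
  n <- nrow(x); m <- ncol(x)
  p[1:n, 2:(m + 1)] + p[3:(n + 2), 2:(m + 1)] +
    p[2:(n + 1), 1:m] + p[2:(n + 1), 3:(m + 2)] - 4 * x
}

# isophote transport inpainting of one channel; sel = pixels to fill
inpaint_channel <- function(x, sel, iterations, dt = 0.1) {
  # harmonic initialization: propagate boundary values into the hole
  x[sel] <- mean(x[!sel])
  for (i in seq_len(200)) x <- diffuse_step(x, sel)
  # transport the smoothness estimate (Laplacian) along isophotes,
  # interleaved with light diffusion for stability
  for (i in seq_len(iterations)) {
    gl <- grad_c(lap_c(x))
    g <- grad_c(x)
    nrm <- sqrt(g$dr^2 + g$dc^2) + 1e-8
    # isophote direction = gradient rotated 90 degrees
    upd <- (gl$dr * (-g$dc) + gl$dc * g$dr) / nrm
    x[sel] <- x[sel] + dt * upd[sel]
    if (i %% 5 == 0) x <- diffuse_step(x, sel)
  }
  x
}

#' Inpaint masked pixels by isophote-guided PDE propagation
#'
#' Pixels under the mask (dilated by `dilate_radius` so halos around hair
#' shafts are also refilled) are replaced by values propagated from the
#' surrounding image along isophotes (level lines): after a harmonic
#' initialization, the image smoothness (Laplacian) is transported in the
#' direction perpendicular to the gradient, with light interleaved
#' diffusion, in the style of Bertalmio et al. Pixels outside the dilated
#' mask are returned bit-exact.
#'
#' @param img gray image or RGB image.
#' @param mask binary mask of pixels to replace.
#' @param iterations transport iterations (default 50).
#' @param dilate_radius extra pixels filled around the mask (default 2).
#' @return image of the same kind.
#' @export
inpaint <- function(img, mask, iterations = 50L, dilate_radius = 2L) {
  mask <- binary_mask(mask)
  d <- dim(img)
  if (!all(d[1:2] == dim(mask))) stop("inpaint: mask shape mismatch")
  if (iterations < 1L) stop("inpaint: iterations must be >= 1")
  sel <- if (dilate_radius > 0 && any(mask))
    dilate_mask(mask, dilate_radius) else mask
  if (all(sel)) stop("inpaint: nothing to inpaint from (mask covers the image)")
  if (!any(sel)) return(img)
  if (length(d) == 3L) {
    out <- img
    for (ch in 1:3) out[, , ch] <- inpaint_channel(img[, , ch], sel, iterations)
    out[, , 1][!sel] <- img[, , 1][!sel]  # guard bit-exactness off the mask
    out[, , 2][!sel] <- img[, , 2][!sel]
    out[, , 3][!sel] <- img[, , 3][!sel]
    out
  } else {
    out <- inpaint_channel(bare(img), sel, iterations)
    out[!sel] <- bare(img)[!sel]
    rng <- gray_range(img)
    gray_image(pmin(pmax(out, rng[1]), rng[2]), rng)
  }
}

# disc-brush morphology helpers (odd brush side 2r+1)
disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  binary_mask(EBImage::dilate(mask * 1, disc_brush(radius)) > 0.5)
}

erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  binary_mask(EBImage::erode(mask * 1, disc_brush(radius)) > 0.5)
}

#' Median smoothing
#'
#' Each pixel is replaced by the median of its `window x window`
#' neighborhood (reflective boundary).
#'
#' @param img gray image.
#' @param window odd window side, >= 3 (default 3).
#' @return gray image.
#' @export
median_smooth <- function(img, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("median_smooth: `window` must be odd and >= 3")
  x <- bare(img)
  r <- (window - 1L) %/% 2L
  p <- pad_reflect(x, r)
  n <- nrow(x); m <- ncol(x)
  stack <- array(0, c(n * m, window * window))
  k <- 0L
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L)) {
    k <- k + 1L
    stack[, k] <- p[(1 + dr):(n + dr), (1 + dc):(m + dc)]
  }
  med <- apply(stack, 1L, stats::median)
  rng <- gray_range(img)
  gray_image(matrix(med, n, m), rng)
}

#' Full hair removal: enhance, segment, inpaint, smooth
#'
#' Runs [directional_response()] on the luminance, thresholds it with
#' [segment_hairs()], inpaints each color channel under the hair mask, and
#' median-smooths the repaired region (the median filter is applied only
#' under the dilated hair mask so untouched skin stays bit-exact).
#'
#' @param img RGB image.
#' @param p [dog_params()].
#' @param strategy threshold strategy, see [segment_hairs()].
#' @param iterations inpainting iterations (default 50).
#' @param window median window (default 3).
#' @param dilate_radius mask dilation before inpainting (default 2).
#' @return list with `image` (cleaned RGB image) and `hair_mask`.
#' @export
remove_hairs <- function(img, p = dog_params(), strategy = "contrast",
                         iterations = 50L, window = 3L, dilate_radius = 2L) {
  img <- rgb_image(img)
  lum <- luminance(img)
  det <- directional_response(lum, p)
  hair <- if (strategy == "raw_dark") segment_hairs(lum, strategy = "raw_dark")
          else segment_hairs(det, strategy = strategy, intensity = lum)
  if (!any(hair)) return(list(image = img, hair_mask = hair))
  filled <- inpaint(img, hair, iterations = iterations,
                    dilate_radius = dilate_radius)
  sel <- dilate_mask(hair, dilate_radius + (window - 1L) %/% 2L)
  out <- filled
  for (ch in 1:3) {
    sm <- bare(median_smooth(gray_image(clip8(filled[, , ch])), window))
    plane <- filled[, , ch]
    plane[sel] <- sm[sel]
    out[, , ch] <- plane
  }
  list(image = rgb_image(clip8(out)), hair_mask = hair)
}
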