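#' Specification of a synthetic dermoscopy phantom
#'
#' The phantom emulates the structures that matter to the segmentation
#' pipeline: a darker, soft-edged elliptical lesion on lighter skin, dark
#' curved hair strokes crossing lesion and skin, bright gel/water bubbles
#' with darker rims, dark rounded lens corners, and additive Gaussian pixel
#' noise. Default canvas is 256 x 192 (the 768 x 560 dermoscope frame scaled
#' down; the full size is available by request).
#'
#' @param height,width canvas size in pixels.
#' @param skin_color,lesion_color,hair_color RGB triples in `[0, 255]`.
#' @param lesion_center `(row, col)` of the lesion ellipse.
#' @param lesion_axes `(semi-axis-rows, semi-axis-cols)` in pixels; the
#'   ellipse must fit inside the canvas.
#' @param edge_softness Gaussian blur sigma (pixels) of the lesion boundary.
#' @param n_hairs number of hair strokes.
#' @param hair_thickness stroke thickness in pixels.
#' @param n_bubbles number of bright bubbles.
#' @param corner_radius radius (pixels) of the rounded illuminated field;
#'   0 disables dark corners.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param seed integer RNG seed; the same spec always renders bit-identically.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(height = 192L, width = 256L,
                         skin_color = c(224, 172, 150),
                         lesion_center = c(round(height / 2), round(width / 2)),
                         lesion_axes = c(round(height * 0.23), round(width * 0.23)),
                         lesion_color = c(122, 84, 66),
                         edge_softness = 4,
                         n_hairs = 0L, hair_thickness = 3L,
                         hair_color = c(52, 42, 36),
                         n_bubbles = 0L,
                         corner_radius = 0L,
                         noise_sd = 5,
                         seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               skin_color = as.numeric(skin_color),
               lesion_center = as.numeric(lesion_center),
               lesion_axes = as.numeric(lesion_axes),
               lesion_color = as.numeric(lesion_color),
               edge_softness = as.numeric(edge_softness),
               n_hairs = as.integer(n_hairs),
               hair_thickness = as.integer(hair_thickness),
               hair_color = as.numeric(hair_color),
               n_bubbles = as.integer(n_bubbles),
               corner_radius = as.numeric(corner_radius),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  chk <- function(cond, field, msg)
    if (!cond) stop("phantom_spec: invalid `", field, "`: ", msg)
  chk(s$height >= 16 && s$width >= 16, "height/width", "canvas must be at least 16 x 16")
  for (f in c("skin_color", "lesion_color", "hair_color"))
    chk(length(s[[f]]) == 3 && all(s[[f]] >= 0 & s[[f]] <= 255), f,
        "must be an RGB triple in [0, 255]")
  chk(s$edge_softness >= 0, "edge_softness", "must be >= 0")
  chk(s$n_hairs >= 0, "n_hairs", "must be >= 0")
  chk(s$n_bubbles >= 0, "n_bubbles", "must be >= 0")
  chk(s$hair_thickness >= 1, "hair_thickness", "must be >= 1")
  chk(s$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(s$corner_radius >= 0, "corner_radius", "must be >= 0")
  chk(all(s$lesion_axes > 0), "lesion_axes", "must be positive")
  chk(s$lesion_center[1] - s$lesion_axes[1] >= 1 &&
      s$lesion_center[1] + s$lesion_axes[1] <= s$height &&
      s$lesion_center[2] - s$lesion_axes[2] >= 1 &&
      s$lesion_center[2] + s$lesion_axes[2] <= s$width,
      "lesion_center/lesion_axes", "lesion ellipse must fit inside the image")
  invisible(s)
}

# quadratic Bezier through seeded random endpoints/control point, returning
# a skeleton mask of the curve
render_hair_skeleton <- function(h, w) {
  # endpoints on opposite-ish sides so strokes cross the frame
  p0 <- c(runif(1, 1, h), runif(1, 1, w))
  p2 <- c(runif(1, 1, h), runif(1, 1, w))
  while (sum((p0 - p2)^2) < (min(h, w) / 2)^2) p2 <- c(runif(1, 1, h), runif(1, 1, w))
  mid <- (p0 + p2) / 2
  bend <- c(runif(1, -h / 4, h / 4), runif(1, -w / 4, w / 4))
  p1 <- pmin(pmax(mid + bend, 1), c(h, w))
  tt <- seq(0, 1, length.out = 4L * as.integer(ceiling(sqrt(sum((p0 - p2)^2)))))
  pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  sk <- matrix(FALSE, h, w)
  ij <- cbind(pmin(pmax(round(pts[, 1]), 1), h), pmin(pmax(round(pts[, 2]), 1), w))
  sk[ij] <- TRUE
  sk
}

corner_mask_gt <- function(h, w, r) {
  if (r <= 0) return(matrix(FALSE, h, w))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(FALSE, h, w)
  for (cc in list(c(1, 1), c(1, w), c(h, 1), c(h, w))) {
    # quarter-disc of radius r centered r pixels inside the corner
    ctr <- c(if (cc[1] == 1) r else h - r + 1, if (cc[2] == 1) r else w - r + 1)
    inside_sq <- abs(rows - cc[1]) < r & abs(cols - cc[2]) < r
    beyond <- (rows - ctr[1])^2 + (cols - ctr[2])^2 > r^2
    m <- m | (inside_sq & beyond)
  }
  m
}

#' Render a synthetic dermoscopy phantom
#'
#' Deterministic for a fixed spec (the spec's `seed` drives independent RNG
#' substreams per artifact class, so e.g. switching hairs off leaves the
#' noise field and bubbles of the twin phantom unchanged).
#'
#' @param spec [phantom_spec()].
#' @return object of class `"phantom_case"`: list with `image` (RGB image),
#'   `lesion_mask`, `hair_mask`, `corner_mask` (binary masks), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  # lesion alpha: hard ellipse blurred by edge_softness; GT = alpha >= 0.5
  alpha <- ((rows - spec$lesion_center[1]) / spec$lesion_axes[1])^2 +
           ((cols - spec$lesion_center[2]) / spec$lesion_axes[2])^2 <= 1
  alpha <- alpha * 1
  if (spec$edge_softness > 0)
    alpha <- EBImage::gblur(alpha, sigma = spec$edge_softness)
  alpha <- matrix(pmin(pmax(as.numeric(alpha), 0), 1), h, w)
  lesion_mask <- alpha >= 0.5

  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- spec$skin_color[ch] * (1 - alpha) + spec$lesion_color[ch] * alpha

  # bubbles: bright discs with darker rims (gel artifact proxy)
  if (spec$n_bubbles > 0) {
    with_seed(spec$seed + 1013L, {
      for (b in seq_len(spec$n_bubbles)) {
        r <- runif(1, 4, 10)
        ctr <- c(runif(1, r + 1, h - r), runif(1, r + 1, w - r))
        d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
        core <- d <= r - 1.5
        rim <- d > r - 1.5 & d <= r
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[core] <- clip8(plane[core] + 55)
          plane[rim] <- clip8(plane[rim] - 35)
          img[, , ch] <- plane
        }
      }
    })
  }

  # hairs: dark curved strokes, dilated to the requested thickness
  hair_mask <- matrix(FALSE, h, w)
  if (spec$n_hairs > 0) {
    with_seed(spec$seed + 2029L, {
      for (k in seq_len(spec$n_hairs))
        hair_mask <- hair_mask | render_hair_skeleton(h, w)
    })
    if (spec$hair_thickness > 1)
      hair_mask <- dilate_mask(hair_mask, (spec$hair_thickness - 1) / 2)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[hair_mask] <- spec$hair_color[ch]
      img[, , ch] <- plane
    }
  }

  # dark rounded lens corners
  cmask <- corner_mask_gt(h, w, spec$corner_radius)
  if (any(cmask)) {
    dark <- c(26, 22, 22)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cmask] <- dark[ch]
      img[, , ch] <- plane
    }
  }

  # additive Gaussian noise, clipped to [0, 255]
  if (spec$noise_sd > 0) {
    with_seed(spec$seed + 4057L, {
      img <- clip8(img + array(rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3)))
    })
  }

  structure(list(image = rgb_image(clip8(img)),
                 lesion_mask = binary_mask(lesion_mask),
                 hair_mask = binary_mask(hair_mask),
                 corner_mask = binary_mask(cmask),
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  s <- x$spec
  cat(sprintf("phantom %d x %d (seed %d): lesion %d px, hair %d px, corners %d px\n",
              s$height, s$width, s$seed, sum(x$lesion_mask), sum(x$hair_mask),
              sum(x$corner_mask)))
  invisible(x)
}

#' Generate a suite of jittered phantoms
#'
#' Reproducibly draws `n` phantoms around `base_spec`: lesion center, axes
#' and lesion color (contrast) are jittered; each case gets its own derived
#' seed, recorded in its spec.
#'
#' @param n number of cases, >= 1.
#' @param base_spec [phantom_spec()] template.
#' @param seed suite-level seed.
#' @return list of `phantom_case` objects.
#' @export
generate_suite <- function(n, base_spec = phantom_spec(), seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("generate_suite: `n` must be >= 1")
  if (!inherits(base_spec, "phantom_spec")) base_spec <- do.call(phantom_spec, base_spec)
  h <- base_spec$height; w <- base_spec$width
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- unclass(base_spec)
      s$lesion_axes <- pmax(4, round(s$lesion_axes * runif(2, 0.8, 1.2)))
      maxoff <- c(h, w) * 0.08
      ctr <- s$lesion_center + round(runif(2, -1, 1) * maxoff)
      s$lesion_center <- c(
        min(max(ctr[1], s$lesion_axes[1] + 1), h - s$lesion_axes[1]),
        min(max(ctr[2], s$lesion_axes[2] + 1), w - s$lesion_axes[2]))
      s$lesion_color <- clip8(s$lesion_color + round(runif(1, -15, 15)))
      s$seed <- as.integer(s$seed + i * 7919L)
      do.call(phantom_spec, s)
    })
  })
  lapply(specs, generate_phantom)
}
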