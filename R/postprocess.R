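#' Morphological post-processing configuration
#'
#' @param fill_holes fill enclosed background holes (default `TRUE`).
#' @param min_island_area minimum area (pixels) for the dominant component
#'   to count as a lesion at all (default 100).
#' @param merge_distance maximum gap (pixels) between a satellite component
#'   and the dominant component for the satellite to be kept and bridged
#'   (default 20).
#' @param erosion_radius,dilation_radius radii of the final opening
#'   (default 3 each; 0 disables).
#' @param smooth_window odd boundary moving-average window `W` (default 15;
#'   1 disables smoothing).
#' @return object of class `"morphology_config"`.
#' @export
morphology_config <- function(fill_holes = TRUE, min_island_area = 100,
                              merge_distance = 20, erosion_radius = 3,
                              dilation_radius = 3, smooth_window = 15) {
  if (erosion_radius < 0 || dilation_radius < 0 || merge_distance < 0)
    stop("morphology_config: radii must be >= 0")
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("morphology_config: smooth_window must be odd and >= 1")
  structure(list(fill_holes = isTRUE(fill_holes),
                 min_island_area = min_island_area,
                 merge_distance = merge_distance,
                 erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius,
                 smooth_window = as.integer(smooth_window)),
            class = "morphology_config")
}

#' Fill enclosed holes in a mask
#'
#' Background components (4-connectivity) not connected to the image border
#' become foreground. Idempotent.
#'
#' @param mask binary mask.
#' @return binary mask.
#' @export
fill_holes <- function(mask) {
  mask <- binary_mask(mask)
  bg <- EBImage::bwlabel(!mask)
  h <- nrow(mask); w <- ncol(mask)
  border <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  border <- border[border > 0]
  binary_mask(mask | !(bg %in% c(0, border)) |
                matrix(FALSE, h, w))  # keep matrix shape
}

#' Keep the dominant lesion component, merge near satellites
#'
#' The largest connected component is the lesion candidate. Satellite
#' components whose minimal boundary distance to it is at most
#' `merge_distance` are kept and bridged by a morphological closing with a
#' disc of radius `merge_distance / 2`; all farther components are removed.
#' A final opening (erosion then dilation) with the configured radii cleans
#' thin spurs. If the dominant component is smaller than `min_island_area`,
#' an empty mask is returned with a warning.
#'
#' @param mask binary mask.
#' @param cfg [morphology_config()].
#' @return binary mask with at most one connected component.
#' @export
manage_islands <- function(mask, cfg = morphology_config()) {
  mask <- binary_mask(mask)
  if (!any(mask)) {
    warning("manage_islands: no lesion found (empty mask)")
    return(mask)
  }
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  main <- which.max(areas)
  if (areas[main] < cfg$min_island_area) {
    warning("manage_islands: no lesion found (dominant component below min_island_area)")
    return(binary_mask(matrix(FALSE, nrow(mask), ncol(mask))))
  }
  main_mask <- lab == main
  keep <- main_mask
  if (length(areas) > 1L && cfg$merge_distance > 0) {
    dm <- EBImage::distmap(1 - main_mask * 1)    # distance to the main component
    for (k in seq_along(areas)) {
      if (k == main) next
      if (min(dm[lab == k]) <= cfg$merge_distance) keep <- keep | (lab == k)
    }
    if (!identical(sum(keep), sum(main_mask)))
      keep <- close_mask(keep, max(1L, round(cfg$merge_distance / 2)))
  }
  out <- keep
  if (cfg$erosion_radius > 0) out <- erode_mask(out, cfg$erosion_radius)
  if (cfg$dilation_radius > 0) out <- dilate_mask(out, cfg$dilation_radius)
  # the opening may split or erase; retain the largest surviving component
  if (!any(out)) {
    warning("manage_islands: no lesion found (opening removed all components)")
    return(binary_mask(out))
  }
  lab2 <- EBImage::bwlabel(out)
  if (max(lab2) > 1L) {
    areas2 <- tabulate(lab2[lab2 > 0])
    out <- lab2 == which.max(areas2)
  }
  binary_mask(matrix(as.logical(out), nrow(mask), ncol(mask)))
}

close_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  erode_mask(dilate_mask(mask, radius), radius)
}

# ordered outer boundary of a single-component mask, as an n x 2 matrix of
# (row, col) coordinates (8-connected tracing via EBImage::ocontour)
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  xy <- oc[[1]]
  cbind(xy[, 1] + 1L, xy[, 2] + 1L)
}

# even-odd scanline rasterization of a closed polygon given as (row, col)
# vertices; returns a logical matrix of the given dim
rasterize_polygon <- function(poly, dims) {
  out <- matrix(FALSE, dims[1], dims[2])
  n <- nrow(poly)
  if (n < 3) {
    out[cbind(pmin(pmax(round(poly[, 1]), 1), dims[1]),
              pmin(pmax(round(poly[, 2]), 1), dims[2]))] <- TRUE
    return(out)
  }
  r1 <- poly[, 1]; c1 <- poly[, 2]
  r2 <- poly[c(2:n, 1), 1]; c2 <- poly[c(2:n, 1), 2]
  for (row in seq_len(dims[1])) {
    y <- row
    cross <- ((r1 <= y & r2 > y) | (r2 <= y & r1 > y))
    if (!any(cross)) next
    xs <- c1[cross] + (y - r1[cross]) / (r2[cross] - r1[cross]) * (c2[cross] - c1[cross])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      # half-pixel band compensates the half-pixel erosion a strict
      # center-inside rule would apply along the whole contour
      lo <- ceiling(xs[k] - 0.5); hi <- floor(xs[k + 1] + 0.5 - 1e-9)
      lo <- max(1L, lo); hi <- min(dims[2], hi)
      if (hi >= lo) out[row, lo:hi] <- TRUE
    }
  }
  out
}

#' Smooth a mask boundary by a circular moving average
#'
#' The closed boundary of the (single-component) mask is extracted as an
#' ordered coordinate sequence; a circular moving average of window `W` is
#' applied independently to the row and column sequences; the smoothed
#' closed polygon is re-rasterized (even-odd scanline fill).
#'
#' @param mask binary mask with exactly one connected component.
#' @param W odd averaging window (1 returns the mask unchanged).
#' @return binary mask.
#' @export
smooth_boundary <- function(mask, W = 15L) {
  mask <- binary_mask(mask)
  W <- as.integer(W)
  if (W %% 2L == 0L || W < 1L) stop("smooth_boundary: W must be odd and >= 1")
  if (W == 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1L)
    stop("smooth_boundary: mask must have exactly one component (run manage_islands first)")
  b <- trace_boundary(mask)
  n <- nrow(b)
  if (n <= W) return(mask)
  half <- (W - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, j) ((i + j - 1L) %% n) + 1L)
  sm <- cbind(rowMeans(matrix(b[idx, 1], n)), rowMeans(matrix(b[idx, 2], n)))
  ras <- rasterize_polygon(sm, dim(mask))
  if (!any(ras)) mask else binary_mask(ras)
}

#' Full post-processing of a raw wavelet mask
#'
#' Removes corner pixels, fills holes, manages islands, and smooths the
#' boundary. The result never intersects `corner_mask` and has at most one
#' connected component.
#'
#' @param mask raw binary lesion mask.
#' @param corner_mask binary mask of dark lens corners (or `NULL`).
#' @param cfg [morphology_config()].
#' @return final binary lesion mask.
#' @export
postprocess_mask <- function(mask, corner_mask = NULL, cfg = morphology_config()) {
  mask <- binary_mask(mask)
  if (!is.null(corner_mask)) {
    corner_mask <- binary_mask(corner_mask)
    if (!all(dim(corner_mask) == dim(mask)))
      stop("postprocess_mask: corner_mask shape mismatch")
    mask <- mask & !corner_mask
  }
  if (cfg$fill_holes) mask <- fill_holes(mask)
  mask <- manage_islands(mask, cfg)
  if (any(mask) && cfg$smooth_window > 1L)
    mask <- smooth_boundary(mask, cfg$smooth_window)
  if (!is.null(corner_mask)) mask <- mask & !corner_mask
  binary_mask(mask)
}
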