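# Orthogonal / biorthogonal filter banks for the separable 2-D DWT.
# Analysis low/high pass (dec_lo, dec_hi) and synthesis pair (rec_lo,
# rec_hi). haar/db4/sym4 are the standard Daubechies constructions;
# bior6.8 is the Cohen-Daubechies-Feauveau 6/8 biorthogonal spline pair;
# cdf97 is the CDF 9/7 pair used by JPEG2000 (Antonini et al. filter bank).
.wavelet_banks <- local({
  h <- 1 / sqrt(2)
  db4_lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
              -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
              0.7148465705529157, 0.2303778133088965)
  sym4_lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
               0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
               -0.012603967262037833, 0.0322231006040427)
  # quadrature mirror: hi[k] = (-1)^k lo[n-1-k]; synthesis = time-reverse
  qmf <- function(lo) {
    hi <- rev(lo) * (-1)^seq_along(lo)
    list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
  }
  bior68 <- list(
    dec_lo = c(0, 0.0019088317364812906, -0.0019142861290887667,
               -0.016990639867602342, 0.01193456527972926, 0.04973290349094079,
               -0.07726317316720414, -0.09405920349573646, 0.4207962846098268,
               0.8259229974584023, 0.4207962846098268, -0.09405920349573646,
               -0.07726317316720414, 0.04973290349094079, 0.01193456527972926,
               -0.016990639867602342, -0.0019142861290887667, 0.0019088317364812906),
    dec_hi = c(0, 0, 0, 0.014426282505624435, -0.014467504896790148,
               -0.07872200106262882, 0.04036797903033992, 0.41784910915027457,
               -0.7589077294536541, 0.41784910915027457, 0.04036797903033992,
               -0.07872200106262882, -0.014467504896790148, 0.014426282505624435,
               0, 0, 0, 0),
    rec_lo = c(0, 0, 0, 0.014426282505624435, 0.014467504896790148,
               -0.07872200106262882, -0.04036797903033992, 0.41784910915027457,
               0.7589077294536541, 0.41784910915027457, -0.04036797903033992,
               -0.07872200106262882, 0.014467504896790148, 0.014426282505624435,
               0, 0, 0, 0),
    rec_hi = c(0, -0.0019088317364812906, -0.0019142861290887667,
               0.016990639867602342, 0.01193456527972926, -0.04973290349094079,
               -0.07726317316720414, 0.09405920349573646, 0.4207962846098268,
               -0.8259229974584023, 0.4207962846098268, 0.09405920349573646,
               -0.07726317316720414, -0.04973290349094079, 0.01193456527972926,
               0.016990639867602342, -0.0019142861290887667, -0.0019088317364812906))
  cdf97 <- list(
    dec_lo = c(0, 0.03782845550726404, -0.023849465019556843,
               -0.11062440441843718, 0.37740285561283066, 0.8526986790088938,
               0.37740285561283066, -0.11062440441843718, -0.023849465019556843,
               0.03782845550726404),
    dec_hi = c(0, -0.06453888262869706, 0.04068941760916406,
               0.41809227322161724, -0.7884856164055829, 0.41809227322161724,
               0.04068941760916406, -0.06453888262869706, 0, 0),
    rec_lo = c(0, -0.06453888262869706, -0.04068941760916406,
               0.41809227322161724, 0.7884856164055829, 0.41809227322161724,
               -0.04068941760916406, -0.06453888262869706, 0, 0),
    rec_hi = c(0, -0.03782845550726404, -0.023849465019556843,
               0.11062440441843718, 0.37740285561283066, -0.8526986790088938,
               0.37740285561283066, 0.11062440441843718, -0.023849465019556843,
               -0.03782845550726404))
  list(haar = qmf(c(h, h)), db1 = qmf(c(h, h)), db4 = qmf(db4_lo),
       sym4 = qmf(sym4_lo), bior6.8 = bior68, cdf97 = cdf97)
})

#' Supported mother wavelets
#' @return character vector of wavelet names usable in [dwt2()].
#' @export
wavelet_families <- function() setdiff(names(.wavelet_banks), "db1")

wavelet_bank <- function(name) {
  bank <- .wavelet_banks[[name]]
  if (is.null(bank))
    stop("unsupported wavelet '", name, "'; supported: ",
         paste(names(.wavelet_banks), collapse = ", "))
  bank
}

# --- single-level 1-D transforms applied to every column of a matrix -------
# Analysis: half-sample symmetric extension by (flen-1), full convolution,
# downsample keeping floor((n + flen - 1)/2) coefficients. Synthesis:
# zero-upsample, full convolution with the synthesis filters, keep the
# central 2*la - flen + 2 samples, trim to the recorded length. This
# convention is perfect-reconstruction for arbitrary signal lengths.

dwt_cols <- function(x, filt) {
  n <- nrow(x); flen <- length(filt)
  ext <- x[reflect_idx(n, flen - 1L), , drop = FALSE]
  la <- (n + flen - 1L) %/% 2L
  out <- matrix(0, la, ncol(x))
  base <- flen + 2L * seq_len(la)       # full-conv row = base - j
  for (j in seq_len(flen))
    if (filt[j] != 0) out <- out + filt[j] * ext[base - j, , drop = FALSE]
  out
}

idwt_cols <- function(a, d, filt_lo, filt_hi, n_out) {
  la <- nrow(a); flen <- length(filt_lo)
  odd <- seq(1L, 2L * la, by = 2L)
  ua <- matrix(0, 2L * la, ncol(a)); ua[odd, ] <- a
  ud <- matrix(0, 2L * la, ncol(d)); ud[odd, ] <- d
  conv_full <- function(up_mat, filt) {
    nf <- nrow(up_mat)
    acc <- matrix(0, nf + flen - 1L, ncol(up_mat))
    for (j in seq_len(flen))
      if (filt[j] != 0)
        acc[j:(j + nf - 1L), ] <- acc[j:(j + nf - 1L), ] + filt[j] * up_mat
    acc
  }
  full <- conv_full(ua, filt_lo) + conv_full(ud, filt_hi)
  start <- flen - 1L                    # synthesis window (full length 2la-flen+2)
  full[start:(start + n_out - 1L), , drop = FALSE]
}

#' 2-D multilevel discrete wavelet transform
#'
#' Separable analysis (columns then rows) with half-sample symmetric
#' boundary extension. The approximation band of level `l` is re-decomposed
#' to produce level `l + 1`. Band sizes follow `floor((n + flen - 1)/2)` per
#' level, where `flen` is the analysis filter length, so the transform is
#' perfect-reconstruction for any input size.
#'
#' @param img gray image (or bare numeric matrix).
#' @param wavelet one of [wavelet_families()] (plus alias `"db1"` for haar).
#' @param levels number of decomposition levels (default 2).
#' @return object of class `"wavelet_pyramid"`: list with `levels`,
#'   `wavelet`, `boundary` (`"symmetric"`), `input_dim`, and `bands` — a list
#'   of per-level lists with matrices `A`, `H`, `V`, `D`.
#' @export
dwt2 <- function(img, wavelet = "bior6.8", levels = 2L) {
  bank <- wavelet_bank(wavelet)
  x <- bare(img)
  if (!is.matrix(x)) stop("dwt2: input must be a matrix")
  levels <- as.integer(levels)
  if (levels < 1L) stop("dwt2: `levels` must be >= 1")
  if (min(dim(x)) < 2^levels)
    stop("dwt2: image dimensions must be at least 2^levels")
  bands <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    lo_c <- dwt_cols(a, bank$dec_lo)        # filter the row index (vertical)
    hi_c <- dwt_cols(a, bank$dec_hi)
    A <- t(dwt_cols(t(lo_c), bank$dec_lo))  # then the column index (horizontal)
    V <- t(dwt_cols(t(lo_c), bank$dec_hi))  # vertical edges: high-pass horizontally
    H <- t(dwt_cols(t(hi_c), bank$dec_lo))  # horizontal edges: high-pass vertically
    D <- t(dwt_cols(t(hi_c), bank$dec_hi))
    bands[[l]] <- list(A = A, H = H, V = V, D = D, input_dim = dim(a))
    a <- A
  }
  structure(list(levels = levels, wavelet = wavelet, boundary = "symmetric",
                 input_dim = dim(x), bands = bands),
            class = "wavelet_pyramid")
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("%d-level '%s' wavelet pyramid of a %d x %d image (%s extension)\n",
              x$levels, x$wavelet, x$input_dim[1], x$input_dim[2], x$boundary))
  for (l in seq_len(x$levels))
    cat(sprintf("  level %d: bands %d x %d\n", l,
                nrow(x$bands[[l]]$A), ncol(x$bands[[l]]$A)))
  invisible(x)
}

#' Inverse 2-D multilevel DWT
#'
#' @param pyr pyramid from [dwt2()].
#' @return reconstructed matrix, equal to the input of [dwt2()] up to
#'   floating-point round-off.
#' @export
idwt2 <- function(pyr) {
  bank <- wavelet_bank(pyr$wavelet)
  a <- pyr$bands[[pyr$levels]]$A
  for (l in rev(seq_len(pyr$levels))) {
    b <- pyr$bands[[l]]
    dims <- b$input_dim
    lo_c <- t(idwt_cols(t(a), t(b$V), bank$rec_lo, bank$rec_hi, dims[2]))
    hi_c <- t(idwt_cols(t(b$H), t(b$D), bank$rec_lo, bank$rec_hi, dims[2]))
    a <- idwt_cols(lo_c, hi_c, bank$rec_lo, bank$rec_hi, dims[1])
  }
  a
}

#' Extract an approximation band
#'
#' Level 0 is defined as the original image.
#'
#' @param pyr pyramid from [dwt2()].
#' @param level requested level, `0..pyr$levels`.
#' @return gray image (declared range = observed band range).
#' @export
approximation <- function(pyr, level = pyr$levels) {
  level <- as.integer(level)
  if (level < 0L || level > pyr$levels)
    stop("approximation: `level` must be in 0..", pyr$levels)
  a <- if (level == 0L) {
    # level 0 not stored; reconstruct the original
    idwt2(pyr)
  } else pyr$bands[[level]]$A
  rng <- range(a)
  if (rng[2] <= rng[1]) rng <- c(rng[1], rng[1] + 1)
  gray_image(a, rng)
}

# filter half-delay used to align coefficient i with input position
# 2^L * i - d * (2^L - 1): the energy centroid of the analysis low-pass
# (equals (flen - 1)/2 for linear-phase banks, and the group delay for
# asymmetric ones like db4)
filter_delay <- function(wavelet) {
  h <- wavelet_bank(wavelet)$dec_lo
  sum((seq_along(h) - 1) * h^2) / sum(h^2)
}

#' Segment a lesion mask from a wavelet approximation band
#'
#' Otsu-binarizes the approximation band with dark pixels as foreground and
#' maps the low-resolution mask back to full resolution by nearest-neighbor
#' lookup under the transform's coefficient-to-pixel alignment
#' (`pos = 2^L * i - d (2^L - 1)` with `d` the filter half-delay).
#'
#' @param a2 gray image: approximation band (typically level 2).
#' @param original_shape integer `(rows, cols)` of the full-resolution image.
#' @param level decomposition level of `a2` (default 2).
#' @param delay filter half-delay `d` (default: bior6.8's, see
#'   [dwt2()]; [segment_lesion()] passes the right value automatically).
#' @return full-resolution binary mask (raw, pre-post-processing).
#' @export
segment_from_approximation <- function(a2, original_shape, level = 2L,
                                       delay = filter_delay("bior6.8")) {
  res <- tryCatch(otsu(a2), error = function(e)
    stop("segment_from_approximation: no contrast at level ", level))
  small <- binarize(a2, res$value, dark_foreground = TRUE)
  f <- 2^level
  # half-up rounding keeps the map exactly shift-covariant at stride f
  map <- function(pos, n) pmin(pmax(as.integer(floor((pos + delay * (f - 1)) / f + 0.5)), 1L), n)
  ri <- map(seq_len(original_shape[1]), nrow(small))
  ci <- map(seq_len(original_shape[2]), ncol(small))
  binary_mask(small[ri, ci, drop = FALSE])
}

# DC gain of the 2-D low-pass path after `level` decompositions
lowpass_gain <- function(wavelet, level) sum(wavelet_bank(wavelet)$dec_lo)^(2 * level)

#' Wavelet lesion segmentation of a preprocessed channel image
#'
#' Pixels under `corner_mask` are first replaced by the median intensity of
#' the remaining skin, so dark lens corners cannot dominate the Otsu
#' threshold of the approximation band. The image is then decomposed
#' (`dwt2`), the requested approximation band extracted, and thresholded via
#' [segment_from_approximation()]. Corner pixels are removed from the
#' returned mask. The approximation band is quantized over the fixed range
#' `input range x low-pass DC gain` (clipping rare boundary ringing), so the
#' threshold grid does not depend on boundary content and interior results
#' are shift-stable.
#'
#' @param channel_img gray image (hair removal already applied upstream).
#' @param corner_mask binary mask of dark lens corners (may be empty);
#'   `NULL` for none.
#' @param wavelet mother wavelet (default `"bior6.8"`).
#' @param level approximation level used for segmentation (default 2).
#' @return full-resolution raw lesion mask.
#' @export
segment_lesion <- function(channel_img, corner_mask = NULL,
                           wavelet = "bior6.8", level = 2L) {
  x <- bare(channel_img)
  rng <- gray_range(channel_img)
  if (!is.null(corner_mask) && any(corner_mask)) {
    if (!all(dim(corner_mask) == dim(x)))
      stop("segment_lesion: corner_mask shape mismatch")
    x[corner_mask] <- stats::median(x[!corner_mask])
  }
  pyr <- dwt2(gray_image(x, rng), wavelet = wavelet, levels = level)
  a <- approximation(pyr, level)
  g <- lowpass_gain(wavelet, level)
  arng <- sort(rng * g)
  a <- gray_image(pmin(pmax(bare(a), arng[1]), arng[2]), arng)
  mask <- segment_from_approximation(a, dim(x), level = level,
                                     delay = filter_delay(wavelet))
  if (!is.null(corner_mask)) mask <- mask & !corner_mask
  binary_mask(mask)
}
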