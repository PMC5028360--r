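make_rgb <- function(r, g, b, h = 8, w = 8) {
  a <- array(0, c(h, w, 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  rgb_image(a)
}

test_that("luminance applies the BT.601 weights without rounding", {
  expect_equal(luminance(make_rgb(0, 0, 0))[1, 1], 0)
  expect_equal(luminance(make_rgb(255, 0, 0))[1, 1], 76.2195)
  expect_equal(luminance(make_rgb(100, 100, 100))[1, 1], 99.99)
  # monotone in every channel
  base <- luminance(make_rgb(40, 80, 120))[1, 1]
  expect_gt(luminance(make_rgb(41, 80, 120))[1, 1], base)
  expect_gt(luminance(make_rgb(40, 81, 120))[1, 1], base)
  expect_gt(luminance(make_rgb(40, 80, 121))[1, 1], base)
})

test_that("channel entropy matches closed forms and prefers blue on ties", {
  e <- channel_entropy(make_rgb(7, 7, 7))
  expect_equal(unname(e$per_channel), c(0, 0, 0))
  expect_identical(e$argmax_channel, "blue")
  # two equally frequent intensities -> 1 bit
  half <- matrix(c(10, 200), 8, 8)
  img <- make_rgb(0, 0, 0); img[, , 1] <- half
  expect_equal(channel_entropy(img)$per_channel[["red"]], 1)
  # uniform blue over all 256 levels -> 8 bits, blue wins
  a <- array(0, c(16, 16, 3)); a[, , 3] <- matrix(0:255, 16, 16)
  e2 <- channel_entropy(rgb_image(a))
  expect_equal(e2$per_channel[["blue"]], 8)
  expect_identical(e2$argmax_channel, "blue")
})

test_that("entropy is invariant to pixel permutation", {
  set.seed(7)
  a <- array(sample(0:255, 3 * 256, replace = TRUE), c(16, 16, 3))
  perm <- sample(256)
  b <- array(0, c(16, 16, 3))
  for (ch in 1:3) b[, , ch] <- matrix(as.vector(a[, , ch])[perm], 16, 16)
  expect_equal(channel_entropy(rgb_image(a))$per_channel,
               channel_entropy(rgb_image(b))$per_channel)
})

test_that("L*a*b split hits the white point and neutral axis", {
  lab_w <- split_lab(make_rgb(255, 255, 255))
  expect_equal(lab_w$L[1, 1], 100, tolerance = 1e-4)
  lab_k <- split_lab(make_rgb(0, 0, 0))
  expect_equal(lab_k$L[1, 1], 0, tolerance = 0.01)
  expect_equal(lab_k$a[1, 1], 0, tolerance = 0.01)
  expect_equal(lab_k$b[1, 1], 0, tolerance = 0.01)
  lab_g <- split_lab(make_rgb(119, 119, 119))
  expect_lt(abs(lab_g$a[1, 1]), 0.5)
  expect_lt(abs(lab_g$b[1, 1]), 0.5)
})

test_that("extract_channel returns the named channel and validates the selector", {
  img <- make_rgb(10, 20, 30)
  expect_equal(extract_channel(img, "blue")[1, 1], 30)
  expect_equal(extract_channel(img, "red")[1, 1], 10)
  expect_equal(extract_channel(img, "luminance"), luminance(img))
  a <- array(0, c(16, 16, 3)); a[, , 3] <- matrix(0:255, 16, 16)
  expect_equal(extract_channel(rgb_image(a), "max_entropy"),
               extract_channel(rgb_image(a), "blue"))
  expect_error(extract_channel(img, "chartreuse"), "one of")
})

test_that("otsu returns the smallest brute-force minimizer", {
  # two-value image: any threshold separating them has objective 0;
  # the smallest is the low value's bin
  v <- c(rep(10, 32), rep(200, 32))
  img <- gray_image(matrix(v, 8, 8))
  res <- otsu(img)
  expect_identical(res$threshold, 10L)
  expect_equal(res$objective, 0)
  expect_equal(sum(res$class_weights), 1, tolerance = 1e-9)
  # perfectly separable 0/255
  img2 <- gray_image(matrix(c(rep(0, 40), rep(255, 24)), 8, 8))
  expect_equal(otsu(img2)$objective, 0)
  # two Gaussian modes: threshold lands between them and matches brute force
  set.seed(11)
  v3 <- pmin(pmax(c(rnorm(5000, 60, 10), rnorm(5000, 180, 10)), 0), 255)
  img3 <- gray_image(matrix(v3, 100, 100))
  res3 <- otsu(img3)
  expect_gt(res3$threshold, 70)     # between the two modes
  expect_lt(res3$threshold, 170)
  bf <- otsu_bruteforce(pmin(255L, as.integer(floor(v3 * 256 / 255))))
  expect_identical(res3$threshold, bf$threshold)
  expect_identical(res3$threshold, 97L)   # frozen: independently cross-checked
  expect_error(otsu(gray_image(matrix(5, 8, 8))), "degenerate")
})

test_that("binarize respects polarity and range checks", {
  img <- gray_image(matrix(c(5, 5, 250, 250), 2, 2))
  expect_identical(binarize(img, 100), matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_identical(binarize(img, 100, dark_foreground = FALSE),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_true(all(binarize(img, 255)))
  expect_error(binarize(img, -1), "range")
})

test_that("corner_mask keeps only dark components touching a corner", {
  p <- generate_phantom(phantom_spec(seed = 2))
  expect_false(any(corner_mask(luminance(p$image))))
  pc <- generate_phantom(phantom_spec(corner_radius = 55, seed = 2))
  cm <- corner_mask(luminance(pc$image))
  d <- evaluate_masks(cm, pc$corner_mask)$dice
  expect_gte(d, 0.9)
  # the dark centered lesion is excluded even though it is below threshold
  expect_equal(sum(cm & pc$lesion_mask), 0)
  expect_warning(corner_mask(gray_image(matrix(7, 16, 16))), "degenerate")
})
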