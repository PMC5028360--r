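test_that("1-D analysis matches the frozen independent reference", {
  x <- matrix(dwt_reference$x, ncol = 1)
  for (w in wavelet_families()) {
    bank <- dermseg:::wavelet_bank(w)
    cA <- dermseg:::dwt_cols(x, bank$dec_lo)
    cD <- dermseg:::dwt_cols(x, bank$dec_hi)
    expect_equal(as.numeric(cA), dwt_reference[[w]]$cA, tolerance = 1e-10,
                 info = w)
    expect_equal(as.numeric(cD), dwt_reference[[w]]$cD, tolerance = 1e-10,
                 info = w)
  }
})

test_that("constant image under haar gives A = 2c and zero details", {
  p <- dwt2(matrix(3.5, 16, 16), "haar", 1)
  expect_equal(max(abs(p$bands[[1]]$A - 7)), 0)
  expect_equal(max(abs(p$bands[[1]]$H)), 0)
  expect_equal(max(abs(p$bands[[1]]$V)), 0)
  expect_equal(max(abs(p$bands[[1]]$D)), 0)
})

test_that("band size bookkeeping follows floor((n + flen - 1)/2) per level", {
  p <- dwt2(matrix(0:4095 / 16, 64, 64), "haar", 2)
  expect_equal(dim(p$bands[[2]]$A), c(16, 16))
  pb <- dwt2(matrix(0:4095 / 16, 64, 64), "bior6.8", 2)
  expect_equal(dim(pb$bands[[1]]$A), c(40, 40))   # (64 + 17) %/% 2
  expect_equal(dim(pb$bands[[2]]$A), c(28, 28))   # (40 + 17) %/% 2
  expect_error(dwt2(matrix(0, 4, 4), "haar", 3), "2\\^levels")
  expect_error(dwt2(matrix(0, 16, 16), "not_a_wavelet"), "supported")
})

test_that("decompose/reconstruct round trips below 1e-8 for every family", {
  set.seed(101)
  for (w in wavelet_families()) {
    for (i in 1:5) {
      d <- sample(24:48, 2)
      m <- matrix(runif(prod(d)) * 255, d[1], d[2])
      expect_lt(max(abs(idwt2(dwt2(m, w, 2)) - m)), 1e-8)
    }
  }
})

test_that("approximation band access and level-0 identity convention", {
  m <- matrix(runif(32 * 32, 0, 255), 32, 32)
  p <- dwt2(m, "bior6.8", 2)
  expect_equal(dim(approximation(p, 2)), dim(p$bands[[2]]$A))
  expect_equal(unclass(dermseg:::bare(approximation(p, 0))), m,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(approximation(p, 3), "level")
  # approximation carries more energy than any level-2 detail band on a lesion image
  ph <- generate_phantom(phantom_spec(seed = 4))
  p2 <- dwt2(extract_channel(ph$image, "blue"), "bior6.8", 2)
  eA <- mean(p2$bands[[2]]$A^2)
  expect_gt(eA, mean(p2$bands[[2]]$H^2))
  expect_gt(eA, mean(p2$bands[[2]]$V^2))
  expect_gt(eA, mean(p2$bands[[2]]$D^2))
})

test_that("segment_from_approximation upsamples to the original shape", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  chan <- extract_channel(ph$image, "blue")
  pyr <- dwt2(chan, "bior6.8", 2)
  m <- segment_from_approximation(approximation(pyr, 2), dim(chan))
  expect_identical(dim(m), dim(dermseg:::bare(chan)))
  expect_error(
    segment_from_approximation(gray_image(matrix(4, 16, 16), c(0, 255)), c(64, 64)),
    "no contrast")
})

test_that("segment_lesion recovers phantom lesions across wavelet families", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  chan <- extract_channel(ph$image, "blue")
  for (w in c("bior6.8", "haar")) {
    m <- segment_lesion(chan, NULL, wavelet = w)
    d <- evaluate_masks(m, ph$lesion_mask)$dice
    expect_gte(d, if (w == "bior6.8") 0.85 else 0.8)
  }
})

test_that("corner pixels are filled before the DWT and absent from the mask", {
  pc <- generate_phantom(phantom_spec(corner_radius = 55, seed = 6))
  chan <- extract_channel(pc$image, "blue")
  m <- segment_lesion(chan, pc$corner_mask)
  expect_equal(sum(m & pc$corner_mask), 0)
  expect_gte(evaluate_masks(m, pc$lesion_mask)$dice, 0.85)
})

test_that("raw mask is shift-covariant at the level-2 stride in the interior", {
  p <- generate_phantom(phantom_spec(noise_sd = 0, seed = 8))
  img <- extract_channel(p$image, "blue")
  n <- nrow(img)
  img2 <- gray_image(rbind(dermseg:::bare(img)[5:n, ],
                           dermseg:::bare(img)[rep(n, 4), ]))
  m1 <- segment_lesion(img, NULL)
  m2 <- segment_lesion(img2, NULL)
  margin <- 64  # beyond the bior6.8 level-2 boundary influence
  inner <- margin:(n - margin)
  expect_identical(m1[inner + 4, ], m2[inner, ])
})

test_that("segmentation is deterministic", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  chan <- extract_channel(ph$image, "blue")
  expect_identical(segment_lesion(chan, NULL), segment_lesion(chan, NULL))
})
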