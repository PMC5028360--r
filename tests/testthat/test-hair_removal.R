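test_that("DoG kernel is zero-sum, symmetric, with the expected center", {
  p <- dog_params()
  k <- dog_kernel(p)
  expect_equal(sum(k), 0, tolerance = 1e-12)
  # evaluate the closed form at a few grid points (tiny oracle), including
  # the center where the raw value is k1 - k2
  c0 <- p$half_size + 1
  raw <- function(x, y)
    p$k1 * exp(-(x^2 / (2 * p$sigma_x1^2) + y^2 / (2 * p$sigma_y1^2))) -
    p$k2 * exp(-(x^2 / (2 * p$sigma_x2^2) + y^2 / (2 * p$sigma_y2^2)))
  shift <- k[c0, c0] - raw(0, 0)            # the subtracted mean
  expect_equal(raw(0, 0), p$k1 - p$k2)
  for (pt in list(c(0, 3), c(2, -5), c(-4, 4)))
    expect_equal(k[c0 + pt[1], c0 + pt[2]], raw(pt[1], pt[2]) + shift,
                 tolerance = 1e-12)
  # point symmetry under (x, y) -> (-x, -y)
  expect_equal(k, k[nrow(k):1, ncol(k):1])
  # identical Gaussians cancel exactly
  k0 <- dog_kernel(dog_params(k1 = 1, k2 = 1, sigma_x1 = 2, sigma_y1 = 5,
                              sigma_x2 = 2, sigma_y2 = 5))
  expect_equal(max(abs(k0)), 0)
  expect_error(dog_params(sigma_x1 = -1), "sigma")
})

test_that("kernel rotation: identity at 0, transpose at 90, composition at 45+45", {
  k <- dog_kernel(dog_params())
  expect_identical(rotate_kernel(k, 0), k)
  r90 <- rotate_kernel(k, 90)
  expect_lt(max(abs(r90 - t(k))), 1e-6 * max(abs(k)) + 1e-12)
  r45twice <- rotate_kernel(rotate_kernel(k, 45), 45)
  expect_lt(max(abs(r45twice - r90)), 0.02 * max(abs(k)))
  expect_error(rotate_kernel(k, 180), "angle")
})

test_that("constant images give exactly zero directional response", {
  det <- directional_response(gray_image(matrix(128, 80, 80)),
                              dog_params(sigma_y1 = 4, sigma_x2 = 2, sigma_y2 = 6,
                                         angles = c(0, 45, 90)))
  expect_lt(max(abs(dermseg:::bare(det$response))), 1e-9)
})

test_that("the filter bank is orientation selective on rendered lines", {
  p <- dog_params()
  for (a in c(0, 60, 120)) {
    img <- render_line_image(angle = a)
    det <- directional_response(img, p)
    line_px <- dermseg:::bare(img) < 100
    modal <- as.numeric(names(which.max(table(det$best_angle[line_px]))))
    expect_equal(modal, a)
  }
  # rotation equivariance of the peak response
  m0 <- max(dermseg:::bare(directional_response(render_line_image(angle = 0), p)$response))
  m90 <- max(dermseg:::bare(directional_response(render_line_image(angle = 90), p)$response))
  expect_lt(abs(m0 - m90) / m0, 0.05)
})

test_that("segment_hairs thresholds and validates strategies", {
  resp <- gray_image(matrix(runif(64 * 64, 0, 10), 64, 64), c(0, 100))
  expect_false(any(segment_hairs(resp, strategy = "fixed", value = 50)))
  expect_error(segment_hairs(resp, strategy = "sorcery"), "strategy")
  ph <- generate_phantom(phantom_spec(n_hairs = 10, seed = 3))
  det <- directional_response(luminance(ph$image))
  hm <- segment_hairs(det, intensity = luminance(ph$image))
  cc <- confusion_counts(hm, ph$hair_mask)
  expect_gte(cc$tp / cc$gt_area, 0.7)
  # hair-free phantom: under 1% of pixels flagged
  p0 <- generate_phantom(phantom_spec(seed = 3))
  det0 <- directional_response(luminance(p0$image))
  expect_lt(mean(segment_hairs(det0, intensity = luminance(p0$image))), 0.01)
})

test_that("inpainting fills from the surroundings and never touches the rest", {
  img <- gray_image(matrix(77, 48, 48))
  empty <- matrix(FALSE, 48, 48)
  expect_identical(inpaint(img, empty), img)
  disc <- outer(1:48, 1:48, function(i, j) (i - 24)^2 + (j - 24)^2 <= 36)
  filled <- inpaint(img, disc, iterations = 10)
  expect_lt(max(abs(dermseg:::bare(filled) - 77)), 1e-6)
  # off-(dilated-)mask pixels are bit-exact
  set.seed(5)
  noisy <- gray_image(matrix(runif(48 * 48, 0, 255), 48, 48))
  out <- inpaint(noisy, disc, iterations = 5, dilate_radius = 2)
  sel <- dermseg:::dilate_mask(disc, 2)
  expect_identical(dermseg:::bare(out)[!sel], dermseg:::bare(noisy)[!sel])
  expect_error(inpaint(img, matrix(TRUE, 48, 48)), "nothing to inpaint")
})

test_that("median smoothing removes impulses but keeps constants and steps", {
  img <- gray_image(matrix(50, 32, 32))
  expect_equal(dermseg:::bare(median_smooth(img)), matrix(50, 32, 32))
  imp <- matrix(50, 32, 32); imp[16, 16] <- 250
  sm <- median_smooth(gray_image(imp), 3)
  expect_equal(sm[16, 16], 50)
  step <- matrix(rep(c(20, 220), each = 16 * 32), 32, 32)
  sms <- median_smooth(gray_image(step), 3)
  expect_equal(dermseg:::bare(sms), step)   # median preserves straight steps
  expect_error(median_smooth(img, 4), "odd")
})

test_that("remove_hairs leaves hairless images untouched and is nearly idempotent", {
  p0 <- generate_phantom(phantom_spec(seed = 12))
  hr0 <- remove_hairs(p0$image)
  expect_lt(mean(hr0$image != p0$image), 0.02)
  ph <- generate_phantom(phantom_spec(n_hairs = 6, seed = 12))
  hr1 <- remove_hairs(ph$image)
  hr2 <- remove_hairs(hr1$image)
  expect_lt(mean(hr2$image != hr1$image), 0.05)
})

test_that("inpainting restores the hair-free twin inside the hair region", {
  ph <- generate_phantom(phantom_spec(n_hairs = 8, seed = 14))
  pf <- generate_phantom(phantom_spec(n_hairs = 0, seed = 14))
  hr <- remove_hairs(ph$image)
  gm <- rep(ph$hair_mask, 3)
  mae_before <- mean(abs(ph$image[gm] - pf$image[gm]))
  mae_after <- mean(abs(hr$image[gm] - pf$image[gm]))
  expect_lt(mae_after, 0.5 * mae_before)
})
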