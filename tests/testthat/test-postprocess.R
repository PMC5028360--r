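disc_mask <- function(h, w, ctr, r)
  outer(1:h, 1:w, function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2 <= r^2)

test_that("fill_holes fills enclosed holes only, and is idempotent", {
  d <- disc_mask(40, 40, c(20, 20), 10)
  expect_identical(fill_holes(d), d)
  ann <- d & !disc_mask(40, 40, c(20, 20), 5)
  expect_identical(fill_holes(ann), d)
  expect_identical(fill_holes(fill_holes(ann)), d)
  # C-shape: slot open to the border stays open
  cs <- matrix(FALSE, 40, 40); cs[10:30, 10:30] <- TRUE; cs[1:20, 19:21] <- FALSE
  expect_identical(fill_holes(cs), cs)
})

test_that("manage_islands merges near satellites and drops far specks", {
  cfg <- morphology_config(merge_distance = 10, erosion_radius = 0,
                           dilation_radius = 0)
  big <- disc_mask(120, 160, c(60, 60), 25)
  sat <- disc_mask(120, 160, c(60, 93), 5)    # 3 px gap from the big disc
  spk <- disc_mask(120, 160, c(15, 150), 3)   # far away
  m <- manage_islands(big | sat | spk, cfg)
  expect_equal(max(EBImage::bwlabel(m)), 1)   # merged into one component
  expect_true(all(m[sat]))                    # satellite kept and bridged
  expect_false(any(m & spk))                  # far speck removed
  # single component passes through an opening-only path unchanged in count
  m2 <- manage_islands(big, morphology_config())
  expect_equal(max(EBImage::bwlabel(m2)), 1)
  expect_warning(manage_islands(matrix(FALSE, 20, 20)), "no lesion")
  expect_warning(
    manage_islands(disc_mask(60, 60, c(30, 30), 3),
                   morphology_config(min_island_area = 100)), "no lesion")
})

test_that("boundary smoothing rounds corners but preserves area and circles", {
  sq <- matrix(FALSE, 100, 100); sq[30:70, 30:70] <- TRUE
  expect_identical(smooth_boundary(sq, 1), sq)
  sm <- smooth_boundary(sq, 15)
  expect_lt(abs(sum(sm) - sum(sq)) / sum(sq), 0.05)
  expect_lt(sum(sm & !sq) + 0, sum(sq))        # stays in the neighborhood
  # corners are actually rounded
  expect_false(sm[30, 30] && sm[30, 70] && sm[70, 30] && sm[70, 70])
  circ <- disc_mask(100, 100, c(50, 50), 30)
  smc <- smooth_boundary(circ, 15)
  expect_gte(evaluate_masks(smc, circ)$dice, 0.98)
  # near-idempotence at W = 15
  expect_lt(mean(smooth_boundary(sm, 15) != sm), 0.01)
  two <- sq; two[80:90, 80:90] <- TRUE
  expect_error(smooth_boundary(two, 15), "one component")
})

test_that("postprocess_mask output avoids corners and has at most one component", {
  pc <- generate_phantom(phantom_spec(corner_radius = 50, seed = 3))
  gt <- pc$lesion_mask
  out <- postprocess_mask(gt, pc$corner_mask)
  expect_gte(evaluate_masks(out, gt)$dice, 0.98)
  expect_equal(sum(out & pc$corner_mask), 0)
  expect_lte(max(EBImage::bwlabel(out)), 1)
  # a mask overlapping the corners is clipped
  all_on <- matrix(TRUE, nrow(gt), ncol(gt))
  out2 <- postprocess_mask(all_on, pc$corner_mask,
                           morphology_config(smooth_window = 1))
  expect_equal(sum(out2 & pc$corner_mask), 0)
})

test_that("post-processing does not degrade raw wavelet masks in the pipeline", {
  suite <- generate_suite(6, phantom_spec(n_hairs = 8, noise_sd = 5), seed = 77)
  improved <- vapply(suite, function(p) {
    res <- dermseg_run(p$image)
    raw_d <- evaluate_masks(res$wavelet_mask, p$lesion_mask)$dice
    fin_d <- evaluate_masks(res$lesion_mask, p$lesion_mask)$dice
    fin_d >= raw_d
  }, logical(1))
  expect_gte(mean(improved), 0.8)
})
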