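test_that("a perfectly static noiseless scene has motility index zero", {
  px <- array(0L, c(8, 2, 24, 24))
  px[, 1, 6:12, 6:18] <- 90L
  px[, 2, 6:12, 6:18] <- 90L
  s <- image_series(px, 8L, 0.1, 4, t_act = 1L,
                    act_rois = list(c(4, 4, 10, 10)))
  mo <- motility_index(s)
  expect_equal(mo$index, 0)
  expect_true(all(mo$diff_counts == 0))
})

test_that("an object whose every pixel flips by more than the threshold has index one", {
  nT <- 9; px <- array(0L, c(nT, 2, 20, 20))
  for (i in 2:nT) px[i, 1, 5:12, 5:12] <- if (i %% 2) 100L else 200L
  s <- image_series(px, 8L, 0.1, 4, t_act = 1L,
                    act_rois = list(c(4, 4, 8, 8)))
  mo <- motility_index(s)
  expect_equal(mo$index, 1)
})

test_that("the motility index is invariant under swapping the channels", {
  r <- simulate_mito(sim_params(n_segments = 15, field_um = 9.6,
                                n_pre_frames = 2, n_post_frames = 12,
                                diffusion_um2_s = 0.02, seed = 21))
  s <- r$series
  s_sw <- s
  s_sw$pixels <- s$pixels[, 2:1, , , drop = FALSE]
  m1 <- motility_index(s)
  m2 <- motility_index(s_sw)
  expect_identical(m1$index, m2$index)
  expect_identical(m1$diff_counts, m2$diff_counts)
})

test_that("vectorized counts equal the naive double-loop recount", {
  r <- simulate_mito(sim_params(n_segments = 10, field_um = 6.4,
                                n_pre_frames = 2, n_post_frames = 8,
                                diffusion_um2_s = 0.02, seed = 22))
  mo <- motility_index(r$series)
  br <- motility_counts_brute(r$series)
  expect_identical(mo$sum_counts, br$sum_counts)
  expect_identical(mo$diff_counts, br$diff_counts)
})

test_that("an empty summed series is refused", {
  px <- array(2L, c(6, 2, 10, 10))
  s <- image_series(px, 8L, 0.1, 4, t_act = 1L,
                    act_rois = list(c(2, 2, 5, 5)))
  expect_error(motility_index(s), "below threshold")
})

test_that("colocalization percentages follow the mask overlap", {
  img <- matrix(10L, 30, 30)
  img[5:14, 5:14] <- 200L               # 100-pixel object
  expect_equal(coloc_percent(img, img)$percent_A_in_B, 100)
  imgB <- matrix(10L, 30, 30)
  imgB[20:27, 20:27] <- 200L            # disjoint object
  expect_equal(coloc_percent(img, imgB)$percent_A_in_B, 0)
  # 29 of 100 object pixels overlap -> 29%
  imgC <- matrix(10L, 30, 30)
  imgC[5:14, 12:14] <- 200L             # rows 5..14 x cols 12..14 = 30 px
  imgC[5, 12] <- 10L                    # minus one -> 29 in-mask overlaps
  expect_equal(coloc_percent(img, imgC)$percent_A_in_B, 29)
})

test_that("coloc is monotone under dilation of the second mask and rejects flat images", {
  img <- matrix(5L, 26, 26); img[8:17, 8:17] <- 180L
  prev <- -1
  for (grow in 0:3) {
    imgB <- matrix(5L, 26, 26)
    imgB[(10 - grow):(13 + grow), (10 - grow):(13 + grow)] <- 180L
    pc <- coloc_percent(img, imgB)$percent_A_in_B
    expect_gte(pc, prev)
    prev <- pc
  }
  expect_error(coloc_percent(matrix(7L, 5, 5), img[1:5, 1:5]),
               "single gray level")
})
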