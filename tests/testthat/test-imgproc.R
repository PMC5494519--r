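test_that("despeckle matches the per-pixel sorted-neighborhood median", {
  set.seed(42)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    expect_identical(despeckle(img), median3x3_brute(img))
  }
  # non-square and tiny images
  img <- matrix(sample(0:255, 7 * 13, replace = TRUE), 7, 13)
  expect_identical(despeckle(img), median3x3_brute(img))
})

test_that("despeckle removes isolated speckles and keeps constants", {
  img <- matrix(0L, 9, 9)
  expect_identical(despeckle(img), img)
  img2 <- matrix(7L, 5, 5)
  expect_identical(despeckle(img2), img2)
  img3 <- matrix(0L, 9, 9); img3[5, 5] <- 255L
  expect_identical(despeckle(img3), matrix(0L, 9, 9))
  expect_error(despeckle(array(0, c(2, 2, 2))), "2-D")
})

test_that("despeckle never raises the maximum; smooth images are median-stable", {
  set.seed(7)
  for (rep in 1:10) {
    img <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
    expect_lte(max(despeckle(img)), max(img))
  }
  # a monotone ramp is its own 3x3 median
  ramp <- matrix(rep(0:11, each = 12), 12, 12)
  expect_identical(despeckle(ramp), ramp)
})

test_that("pooled Otsu equals exhaustive between-class-variance search", {
  set.seed(1)
  for (rep in 1:20) {
    # bimodal-ish random stack
    nT <- sample(2:4, 1); H <- 12; W <- 12
    px <- array(0L, c(nT, 2, H, W))
    v <- c(pmin(pmax(round(rnorm(nT * H * W / 2, 30, 12)), 0), 255),
           pmin(pmax(round(rnorm(nT * H * W / 2, 170, 25)), 0), 255))
    px[, 1, , ] <- sample(v)
    px[, 2, , ] <- sample(v)
    s <- mk_series(px, t_act = 0L)
    thr <- otsu_threshold_series(s, channel = 1, frames = 1:nT)
    vals <- as.vector(px[, 1, , ])
    expect_identical(as.integer(thr), as.integer(otsu_brute(vals, 8)))
  }
})

test_that("Otsu separates a two-level histogram and rejects flat images", {
  px <- mk_const_stack(2, 8, 8)
  px[, 1, , ] <- c(array(10L, c(2, 8, 4)), array(200L, c(2, 8, 4)))
  s <- mk_series(px, t_act = 0L)
  thr <- otsu_threshold_series(s, channel = 1, frames = 1:2)
  expect_gt(thr, 10)
  expect_lte(thr, 200)
  flat <- mk_series(mk_const_stack(2, 8, 8, gfp = 50), t_act = 0L)
  expect_error(otsu_threshold_series(flat, channel = 1, frames = 1:2),
               "single gray level")
})

test_that("pooled Otsu is invariant under frame permutation and moves down with empty frames", {
  set.seed(3)
  nT <- 6; H <- 10; W <- 10
  px <- array(sample(0:255, nT * 2 * H * W, replace = TRUE),
              c(nT, 2, H, W))
  s <- mk_series(px, t_act = 0L)
  t1 <- otsu_threshold_series(s, 1, frames = 1:nT)
  t2 <- otsu_threshold_series(s, 1, frames = sample(1:nT))
  expect_identical(t1, t2)
  # appending an all-background frame can only lower (or keep) the split
  px2 <- array(0L, c(nT + 1, 2, H, W))
  px2[1:nT, , , ] <- px
  s2 <- mk_series(px2, t_act = 0L)
  t3 <- otsu_threshold_series(s2, 1, frames = 1:(nT + 1))
  expect_lte(t3, t1)
})

test_that("noise-ratio threshold implements the 0.1% rule", {
  # identically zero pre-activation channel -> threshold 1
  s <- mk_series(mk_const_stack(4, 10, 10), t_act = 3L)
  expect_identical(noise_ratio_threshold(s, 1), 1L)
  # 1,000 pixels with one at 50: t = 1 qualifies (1/1000 = 0.1%)
  px <- mk_const_stack(2, 25, 40)
  px[1, 1, 1, 1] <- 50L
  s2 <- mk_series(px, t_act = 1L)
  expect_identical(noise_ratio_threshold(s2, 1), 1L)
  expect_error(noise_ratio_threshold(mk_series(px, t_act = 0L), 1),
               "no pre-activation")

})

test_that("noise-ratio threshold equals the order-statistic oracle on Gaussian noise", {
  set.seed(99)
  H <- 250; W <- 200; nT <- 3   # 1e5 pre-activation pixels
  px <- array(0L, c(nT, 2, H, W))
  noise <- pmin(pmax(round(rnorm(2 * H * W, 10, 3)), 0), 255)
  px[1, 1, , ] <- noise[1:(H * W)]
  px[2, 1, , ] <- noise[(H * W + 1):(2 * H * W)]
  s <- mk_series(px, t_act = 2L)
  thr <- noise_ratio_threshold(s, 1)
  expect_identical(as.integer(thr), as.integer(noise_thr_brute(noise)))
})

test_that("noise-ratio threshold is non-decreasing in the noise scale", {
  set.seed(5)
  base <- abs(rnorm(4000))
  prev <- -Inf
  for (scale in c(5, 10, 20, 40)) {
    px <- array(0L, c(3, 2, 50, 40))
    px[1, 1, , ] <- pmin(round(base[1:2000] * scale), 255)
    px[2, 1, , ] <- pmin(round(base[2001:4000] * scale), 255)
    s <- mk_series(px, t_act = 2L)
    thr <- noise_ratio_threshold(s, 1)
    expect_gte(thr, prev)
    prev <- thr
  }
})
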