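test_that("a constant fluorescence ratio yields zero decay", {
  nT <- 14; H <- W <- 20
  px <- array(0L, c(nT, 2, H, W))
  px[2:nT, 1, 6:15, 6:15] <- 100L      # GFP appears at activation
  px[, 2, 6:15, 6:15] <- 150L
  s <- image_series(px, 8L, 0.1, frame_interval_s = 50, t_act = 1L,
                    act_rois = list(c(5, 5, 10, 10)))
  rd <- rpa_decay(s)
  expect_equal(rd$ratio[1], 1)
  expect_equal(rd$decay_500s, 0, tolerance = 1e-12)
  expect_true(rd$at_500s)
})

test_that("a ratio of 0.65 at 500 s gives a decay of 0.35", {
  # GFP declines linearly to 65% of its start by 500 s; DsRed constant
  nT <- 13; H <- W <- 20
  t_act <- 1L
  times <- (0:(nT - 2)) * 50               # analysis frames, 0..550 s
  gfp <- as.integer(200 - 0.14 * times)    # 200 -> 130 at 500 s
  px <- array(0L, c(nT, 2, H, W))
  for (i in seq_along(times)) px[i + 1, 1, 6:15, 6:15] <- gfp[i]
  px[, 2, 6:15, 6:15] <- 200L
  s <- image_series(px, 8L, 0.1, frame_interval_s = 50, t_act = t_act,
                    act_rois = list(c(5, 5, 10, 10)))
  rd <- rpa_decay(s)
  expect_equal(rd$decay_500s, 0.35, tolerance = 1e-9)
})

test_that("image-based decay matches the content-ledger dilution on a chain", {
  con <- simulate_chain(chain_params(k_fuse = 2, n_chain = 8,
                                     n_post_frames = 30))
  led <- rpa_from_ledger(con)
  img <- rpa_decay(con$series)
  expect_false(img$at_500s)                 # short probe run
  expect_gt(led$decay_500s, 0.5)            # strong dilution when connected
  expect_equal(img$decay_500s, led$decay_500s, tolerance = 0.1)
  frag <- simulate_chain(chain_params(k_fuse = 0, n_chain = 8,
                                      n_post_frames = 30))
  expect_lt(abs(rpa_decay(frag$series)$decay_500s), 0.05)
  expect_equal(rpa_from_ledger(frag)$decay_500s, 0, tolerance = 1e-12)
})

test_that("the ratio decay is invariant to a global linear intensity rescale", {
  con <- simulate_chain(chain_params(k_fuse = 2, n_chain = 6,
                                     n_post_frames = 20))
  s <- con$series
  s2 <- s
  s2$pixels <- s$pixels * 3L
  s2$bit_depth <- 16L
  expect_equal(rpa_decay(s2)$decay_500s, rpa_decay(s)$decay_500s,
               tolerance = 1e-6)
})

test_that("spreading stays at baseline for a frozen fragmented network", {
  frag <- simulate_chain(chain_params(k_fuse = 0, n_chain = 8,
                                      n_post_frames = 30))
  sp <- spreading_curve(frag$series)
  # nothing can leave the ROI: only PSF bleed, constant over time
  expect_lt(max(sp$outside_pixels) - min(sp$outside_pixels), 20)
  con <- simulate_chain(chain_params(k_fuse = 2, n_chain = 8,
                                     n_post_frames = 30))
  sp2 <- spreading_curve(con$series)
  expect_gt(sp2$outside_pixels[nrow(sp2)], sp2$outside_pixels[1] + 100)
})

test_that("an all-zero GFP channel gives an all-zero spreading curve", {
  px <- array(0L, c(6, 2, 16, 16))
  px[, 2, 5:12, 5:12] <- 120L
  s <- image_series(px, 8L, 0.1, 4, t_act = 2L,
                    act_rois = list(c(4, 4, 8, 8)))
  sp <- spreading_curve(s)
  expect_true(all(sp$outside_pixels == 0))
})

test_that("a bleached-out ROI is refused", {
  px <- array(0L, c(8, 2, 16, 16))
  px[, 1, 5:12, 5:12] <- 100L            # GFP present, DsRed zero
  s <- image_series(px, 8L, 0.1, 4, t_act = 1L,
                    act_rois = list(c(4, 4, 8, 8)))
  expect_warning(expect_error(rpa_decay(s, dsred_floor = 1), "noise floor"),
                 "bleached out")
})
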