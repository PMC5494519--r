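test_that("the exponential fit recovers noiseless parameters to 1e-6", {
  x <- (0:119) * 4
  y <- 400 * exp(-0.002 * x)
  fit <- exp_decay_fit(x, y)
  expect_lt(abs(fit$a - 400) / 400, 1e-6)
  expect_lt(abs(fit$b - 0.002) / 0.002, 1e-6)
  expect_equal(fit$half_time_s, log(2) / 0.002, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)
  expect_true(fit$converged)
})

test_that("the fit agrees with the closed-form log-linear solution on clean data", {
  x <- (0:59) * 4
  y <- 180 * exp(-0.0035 * x)
  fit <- exp_decay_fit(x, y)
  ll <- lm(log(y) ~ x)
  expect_equal(fit$a, exp(unname(coef(ll)[1])), tolerance = 1e-7)
  expect_equal(fit$b, -unname(coef(ll)[2]), tolerance = 1e-7)
})

test_that("constant counts give a zero rate and an infinite flagged half-time", {
  fit <- exp_decay_fit((0:20) * 4, rep(100, 21))
  expect_equal(fit$b, 0, tolerance = 1e-10)
  expect_identical(fit$half_time_s, Inf)
  expect_error(exp_decay_fit((0:5) * 4, rep(0, 6)), "all counts are zero")
})

test_that("half-times convert as ln(2)/b", {
  # the decay-constant scale reported for control cells: b ~ 9.72e-4 /s
  fit_b <- 9.72e-4
  expect_equal(log(2) / fit_b, 713, tolerance = 0.001)
})

test_that("green-only decay is invariant to distant pure-RFP objects", {
  mk_states <- function(extra_red) {
    n <- if (extra_red) 6L else 4L
    st <- data.frame(
      id = seq_len(n),
      x = c(2, 4, 2, 4, 10, 11)[seq_len(n)],
      y = c(2, 2, 4, 4, 10, 11)[seq_len(n)],
      angle = 0, len = 1.2, comp = seq_len(n),
      dsred = c(24, 24, 144, 144, 144, 144)[seq_len(n)],
      dark = 0,
      bright = c(144, 144, 0, 0, 0, 0)[seq_len(n)])
    lapply(1:14, function(i) st)
  }
  p <- sim_params(n_segments = 4, field_um = 12.8, n_pre_frames = 2,
                  n_post_frames = 12, psf_sigma_um = 0,
                  photons_per_unit = Inf, background = 2,
                  act_rois = list(c(1, 1, 4.5)), seed = 1)
  s1 <- render_series(mk_states(FALSE), p)
  p2 <- p; p2$n_segments <- 6L
  s2 <- render_series(mk_states(TRUE), p2)
  f1 <- gfp_only_decay(s1)
  f2 <- gfp_only_decay(s2)
  expect_identical(f1$counts$count, f2$counts$count)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
})

test_that("simulated fusion shortens the fitted half-time", {
  r_hi <- simulate_mito(benchmark_params(0.016, seed = 601,
                                         n_post_frames = 40))
  r_no <- simulate_mito(benchmark_params(0, seed = 601,
                                         n_post_frames = 40))
  f_hi <- gfp_only_decay(r_hi$series)
  f_no <- gfp_only_decay(r_no$series)
  expect_lt(f_hi$half_time_s, f_no$half_time_s)
})

test_that("too few post-activation frames are refused", {
  px <- array(10L, c(6, 2, 12, 12))
  s <- image_series(px, 8L, 0.1, 4, t_act = 3L,
                    act_rois = list(c(3, 3, 6, 6)))
  expect_error(gfp_only_decay(s), "at least 10")
})
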