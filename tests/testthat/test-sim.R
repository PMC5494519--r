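test_that("zero fusion rate produces no fusion records", {
  p <- sim_params(n_segments = 15, field_um = 12.8, n_pre_frames = 2,
                  n_post_frames = 20, k_fuse_per_contact_s = 0, seed = 1)
  r <- simulate_mito(p, render = FALSE)
  expect_identical(sum(r$truth_events$event == "fusion"), 0L)
})

test_that("total DsRed is constant except for the activation bleach step", {
  p <- sim_params(n_segments = 20, field_um = 12.8, n_pre_frames = 3,
                  n_post_frames = 25, k_fuse_per_contact_s = 0.1,
                  k_fiss_per_junction_s = 0.05, seed = 2)
  r <- simulate_mito(p, render = FALSE)
  tot <- vapply(r$states, function(st) sum(st$dsred), numeric(1))
  t_act <- p$n_pre_frames
  expect_equal(tot[seq_len(t_act)], rep(tot[1], t_act))     # pre
  expect_equal(tot[(t_act + 1):length(tot)],
               rep(tot[t_act + 1], length(tot) - t_act))    # post
  expect_lt(tot[t_act + 1], tot[1])                         # bleach happened
})

test_that("per-component fluorophore totals survive fusion, fission and mixing", {
  for (seed in 1:4) {
    p <- sim_params(n_segments = 20, field_um = 12.8, n_pre_frames = 2,
                    n_post_frames = 30, k_fuse_per_contact_s = 0.08,
                    k_fiss_per_junction_s = 0.05, seed = seed)
    r <- simulate_mito(p, render = FALSE)
    t_act <- p$n_pre_frames
    dev_gfp <- 0; dev_red <- 0
    for (f in seq_len(length(r$states) - 1L)) {
      st0 <- r$states[[f]]; st1 <- r$states[[f + 1]]
      # group by the NEW component structure: mixing and fusion move content
      # only within these groups, so their totals must carry over exactly
      for (cc in unique(st1$comp)) {
        m <- st1$comp == cc
        dev_gfp <- max(dev_gfp, abs(sum(st1$dark[m] + st1$bright[m]) -
                                      sum(st0$dark[m] + st0$bright[m])))
        if (f != t_act) {   # dsred changes only at the activation transition
          dev_red <- max(dev_red, abs(sum(st1$dsred[m]) -
                                        sum(st0$dsred[m])))
        }
      }
    }
    expect_lt(dev_gfp, 1e-8)
    expect_lt(dev_red, 1e-8)
  }
})

test_that("activated GFP stays confined until mixing with an activated component", {
  p <- sim_params(n_segments = 25, field_um = 12.8, n_pre_frames = 2,
                  n_post_frames = 30, k_fuse_per_contact_s = 0.1,
                  diffusion_um2_s = 0.01, seed = 3)
  r <- simulate_mito(p, render = FALSE)
  t_act <- p$n_pre_frames
  for (f in seq_len(t_act)) {
    expect_true(all(r$states[[f]]$bright == 0))   # dark before activation
  }
  st_act <- r$states[[t_act + 1]]
  tainted <- st_act$id[st_act$bright > 0]
  for (f in (t_act + 1):length(r$states)) {
    st <- r$states[[f]]
    tainted <- st$id[st$comp %in% unique(st$comp[st$id %in% tainted])]
    expect_true(all(st$id[st$bright > 1e-9] %in% tainted))
  }
})

test_that("identical seed and params give an identical run", {
  p <- sim_params(n_segments = 10, field_um = 9.6, n_pre_frames = 2,
                  n_post_frames = 10, k_fuse_per_contact_s = 0.05, seed = 9)
  r1 <- simulate_mito(p)
  r2 <- simulate_mito(p)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$truth_events, r2$truth_events)
  expect_identical(r1$series$pixels, r2$series$pixels)
})

test_that("held-pair fusion timing follows the per-frame Bernoulli hazard", {
  # p = 1 - exp(-k dt); first-fusion frame is geometric(p)
  k <- 0.25; dt <- 4
  pfr <- 1 - exp(-k * dt)
  n_seeds <- 100
  first <- vapply(seq_len(n_seeds), function(s) {
    r <- simulate_held_pair(k, seed = s, n_post_frames = 50)
    ev <- r$truth_events[r$truth_events$event == "fusion", ]
    if (nrow(ev)) min(ev$frame) else NA_real_
  }, numeric(1))
  expect_true(all(is.finite(first)))    # q = 1 - (1-p)^50 ~ 1
  geo_mean <- 1 / pfr                   # frames count from 1
  geo_se <- sqrt((1 - pfr) / pfr^2) / sqrt(n_seeds)
  expect_lt(abs(mean(first) - geo_mean), 3 * geo_se + 1e-12)
})

test_that("transient fusions carry their fused duration, complete ones do not", {
  p <- sim_params(n_segments = 20, field_um = 12.8, n_pre_frames = 2,
                  n_post_frames = 40, k_fuse_per_contact_s = 0.1,
                  k_fiss_per_junction_s = 0.1, seed = 4)
  r <- simulate_mito(p, render = FALSE)
  ev <- r$truth_events
  fus <- ev[ev$event == "fusion", ]
  expect_gt(nrow(fus), 0)
  expect_true(any(fus$type == "transient"))
  expect_true(all(fus$duration_s[fus$type == "transient"] > 0))
  expect_true(all(is.na(fus$duration_s[fus$type == "complete"])))
  expect_true(all(fus$orientation %in%
                    c("end_to_end", "end_to_side", "side_to_side")))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(n_segments = 0), "n_segments")
  expect_error(sim_params(act_rois = list(c(100, 100, 5))), "outside field")
  expect_error(sim_params(bleach_survival = 1.5), "bleach_survival")
  expect_error(sim_params(k_fuse_per_contact_s = -1), "rates")
})
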