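#' Desk-scale benchmark scene for the fusion decay measure
#'
#' The validation conditions used throughout the package's tests and
#' reproduction script: a 16 um field at 0.1 um/px (160 px), 60 uniform
#' 1.2 um segments, slow motility (5e-4 um^2/s, the scale of constrained
#' interphase mitochondrial wiggling; faster drift makes unfused red
#' mitochondria slide over green-only pixels and mimics fusion at zero
#' rate), four dispersed 3.5 x
#' 3.5 um activation squares (as in recordings with several photoactivated
#' areas per cell; dispersing the activated population keeps the green-only
#' loss in the exponential regime instead of shielding a single activated
#' block), 3 pre-activation frames and a 100-frame (400 s) post window at
#' the standard 4 s interval. Only the fusion rate and the seed vary
#' between runs.
#'
#' @param k_fuse fusion hazard per contacting pair, 1/s.
#' @param seed integer seed.
#' @param n_post_frames post-activation frames (default 100).
#' @return a [sim_params].
#' @export
benchmark_params <- function(k_fuse, seed, n_post_frames = 100L) {
  sim_params(n_segments = 60L, field_um = 16, pixel_um = 0.1,
             n_pre_frames = 3L, n_post_frames = as.integer(n_post_frames),
             seg_len_um_mean = 1.2, seg_len_um_sd = 0,
             diffusion_um2_s = 5e-4, k_fuse_per_contact_s = k_fuse,
             k_fiss_per_junction_s = 0.002,
             act_rois = list(c(1.5, 1.5, 3.5), c(11, 2, 3.5),
                             c(2, 11, 3.5), c(10.5, 10.5, 3.5)),
             photons_per_unit = 20, background = 5, seed = seed)
}

#' Static chain scene for the continuity measure
#'
#' A deterministic, noise-free scene probing matrix continuity: `n_chain`
#' equal segments laid end-to-end within mutual contact distance across the
#' field, immobile, with the activation square covering the first few
#' segments. With a high fusion rate the chain zips into a single component
#' within a few frames and the activated GFP dilutes into the whole chain
#' (the connected case); with `k_fuse = 0` the segments never exchange
#' content (the fragmented case). Rendering is noiseless so the image-based
#' ratio can be compared to the content-ledger oracle.
#'
#' @param k_fuse fusion hazard, 1/s (use 0 for the fragmented control).
#' @param seed integer seed (motion and noise are off, so this only fixes
#'   the RNG contract).
#' @param n_chain chain length in segments.
#' @param n_post_frames post-activation frames; the default covers > 500 s.
#' @return a [sim_params] describing the chain scene.
#' @export
chain_params <- function(k_fuse, seed = 1L, n_chain = 15L,
                         n_post_frames = 130L) {
  seg_len <- 1.2
  gap <- 0.1                       # within the 0.3 um contact distance
  pitch <- seg_len + gap
  field <- ceiling((n_chain * pitch + 2) / 0.15) * 0.15
  # square ROI covering exactly the first two segments of the chain
  x1 <- (field - n_chain * pitch) / 2 + pitch / 2
  roi_size <- pitch + 2 * 0.65
  sim_params(n_segments = as.integer(n_chain), field_um = field,
             pixel_um = 0.15, n_pre_frames = 2L,
             n_post_frames = as.integer(n_post_frames),
             seg_len_um_mean = seg_len, seg_len_um_sd = 0,
             diffusion_um2_s = 0, k_fuse_per_contact_s = k_fuse,
             k_fiss_per_junction_s = 0, contact_dist_um = 0.3,
             act_rois = list(c(x1 - 0.65, field / 2 - roi_size / 2,
                               roi_size)),
             psf_sigma_um = 0.1, photons_per_unit = Inf, background = 0,
             seed = seed)
}

#' Two static segments held in permanent contact
#'
#' The elementary scene for calibrating the fusion hazard: two parallel,
#' overlapping, immobile segments, so the pair is fusion-eligible at every
#' frame and the number of runs with a fusion follows the per-frame
#' Bernoulli hazard `p = 1 - exp(-k_fuse * dt)` exactly.
#'
#' @param k_fuse fusion hazard, 1/s.
#' @param seed integer seed.
#' @param n_post_frames post-activation frames (default 50).
#' @param render render the image series (default `FALSE`; the calibration
#'   uses only the event log).
#' @return a `sim_run`.
#' @export
simulate_held_pair <- function(k_fuse, seed, n_post_frames = 50L,
                               render = FALSE) {
  p <- sim_params(n_segments = 2L, field_um = 8, n_pre_frames = 1L,
                  n_post_frames = as.integer(n_post_frames),
                  seg_len_um_mean = 1.5, seg_len_um_sd = 0,
                  diffusion_um2_s = 0, k_fuse_per_contact_s = k_fuse,
                  k_fiss_per_junction_s = 0, act_rois = list(c(2.5, 2.5, 3)),
                  photons_per_unit = Inf, background = 0, seed = seed)
  init <- data.frame(
    id = 1:2, x = 4, y = c(3.9, 4.1), angle = 0, len = 1.5, comp = 1:2,
    dsred = p$amount_per_um * 1.5, dark = p$amount_per_um * 1.5, bright = 0)
  run_simulation(init, p, render = render)
}

#' Deterministic initial layout for the chain scene
#'
#' [simulate_mito] places segments at random; the chain scene needs them on
#' a line. This runs the simulation with the chain layout substituted as the
#' initial state.
#'
#' @param params a [sim_params] from [chain_params].
#' @param render render the image series.
#' @return a `sim_run`.
#' @export
simulate_chain <- function(params, render = TRUE) {
  p <- params
  n <- p$n_segments
  seg_len <- p$seg_len_um_mean
  pitch <- seg_len + 0.1
  x0 <- (p$field_um - n * pitch) / 2 + pitch / 2
  init <- data.frame(
    id = seq_len(n),
    x = x0 + (seq_len(n) - 1L) * pitch,
    y = p$field_um / 2, angle = 0, len = seg_len, comp = seq_len(n),
    dsred = p$amount_per_um * seg_len,
    dark = p$amount_per_um * seg_len,
    bright = 0)
  run_simulation(init, p, render = render)
}
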