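# Small fixture builders used across test files.

# an image_series built directly from a T x 2 x H x W array with sensible
# defaults: one centered ROI, 4 s frames, 8-bit
mk_series <- function(pixels, t_act = 1L, act_rois = NULL,
                      bit_depth = 8L, pixel_um = 0.1,
                      frame_interval_s = 4) {
  H <- dim(pixels)[3]; W <- dim(pixels)[4]
  if (is.null(act_rois)) {
    act_rois <- list(c(H %/% 4, W %/% 4, H %/% 2, W %/% 2))
  }
  image_series(pixels, bit_depth = bit_depth, pixel_um = pixel_um,
               frame_interval_s = frame_interval_s, t_act = t_act,
               act_rois = act_rois)
}

# constant-valued two-channel stack
mk_const_stack <- function(nT, H, W, gfp = 0, dsred = 0) {
  px <- array(0L, c(nT, 2, H, W))
  px[, 1, , ] <- gfp
  px[, 2, , ] <- dsred
  px
}

# scripted detector scene with high SNR used by several tests
scripted_scene <- function(n_pairs = 5, seed = 11, n_frames = 40, ...) {
  p <- sim_params(photons_per_unit = 200, psf_sigma_um = 0.1,
                  background = 5, field_um = 12.8, seed = seed)
  scripted_fusion_run(n_pairs = n_pairs, n_pre_frames = 3,
                      n_frames = n_frames, params = p, ...)
}
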