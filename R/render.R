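# add one capsule (rectangle + end caps) to an intensity matrix; intensity
# per pixel is the fluorophore amount per unit length
draw_capsule <- function(img, x, y, angle, len, width, value, pixel_um) {
  H <- nrow(img); W <- ncol(img)
  hx <- cos(angle) * len / 2; hy <- sin(angle) * len / 2
  p1 <- c(x - hx, y - hy); p2 <- c(x + hx, y + hy)
  r <- width / 2
  r0 <- max(1L, floor((min(p1[2], p2[2]) - r) / pixel_um) + 1L)
  r1 <- min(H, ceiling((max(p1[2], p2[2]) + r) / pixel_um))
  c0 <- max(1L, floor((min(p1[1], p2[1]) - r) / pixel_um) + 1L)
  c1 <- min(W, ceiling((max(p1[1], p2[1]) + r) / pixel_um))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  py <- (rows - 0.5) * pixel_um
  px <- (cols - 0.5) * pixel_um
  PX <- matrix(px, length(rows), length(cols), byrow = TRUE)
  PY <- matrix(py, length(rows), length(cols))
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  l2 <- dx * dx + dy * dy
  if (l2 < 1e-12) {
    D2 <- (PX - p1[1])^2 + (PY - p1[2])^2
  } else {
    tt <- pmin(pmax(((PX - p1[1]) * dx + (PY - p1[2]) * dy) / l2, 0), 1)
    D2 <- (PX - (p1[1] + tt * dx))^2 + (PY - (p1[2] + tt * dy))^2
  }
  inside <- D2 <= r * r
  sub <- img[rows, cols, drop = FALSE]
  sub[inside] <- sub[inside] + value
  img[rows, cols] <- sub
  img
}

roi_um_to_px <- function(roi, pixel_um) {
  # c(x0, y0, size) in um -> c(r0, c0, nr, nc), 0-based half-open pixels
  c(round(roi[2] / pixel_um), round(roi[1] / pixel_um),
    round(roi[3] / pixel_um), round(roi[3] / pixel_um))
}

#' Render simulated network states to an image series
#'
#' Draws every segment as a capsule of width `seg_width_um` with per-pixel
#' intensity equal to its fluorophore amount per unit length (channel 1 from
#' activated PA-GFP, channel 2 from DsRed), then applies a Gaussian PSF of
#' `psf_sigma_um`, adds the background level, samples Poisson shot noise at
#' `photons_per_unit` photons per intensity unit (`Inf` = noiseless), and
#' quantizes to `bit_depth`.
#'
#' @param states list of per-frame segment data frames (as in a `sim_run`).
#' @param params the [sim_params] used to generate them.
#' @param seed optional seed for the noise draws; by default rendering
#'   consumes the current RNG stream (as inside [simulate_mito]).
#' @return an [image_series].
#' @export
render_series <- function(states, params, seed = NULL) {
  p <- params
  if (!length(states)) stop("states must be nonempty")
  if (!p$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.null(seed)) set.seed(seed)
  H <- W <- as.integer(round(p$field_um / p$pixel_um))
  nT <- length(states)
  maxv <- 2^p$bit_depth - 1
  sigma_px <- p$psf_sigma_um / p$pixel_um
  arr <- array(0L, c(nT, 2L, H, W))
  for (i in seq_len(nT)) {
    st <- states[[i]]
    for (ch in 1:2) {
      amt <- if (ch == 1L) st$bright else st$dsred
      img <- matrix(0, H, W)
      for (k in seq_len(nrow(st))) {
        if (amt[k] <= 0) next
        img <- draw_capsule(img, st$x[k], st$y[k], st$angle[k], st$len[k],
                            p$seg_width_um, amt[k] / st$len[k], p$pixel_um)
      }
      if (sigma_px > 0)
        img <- EBImage::imageData(EBImage::gblur(img, sigma = sigma_px))
      lambda <- img + p$background
      if (is.finite(p$photons_per_unit)) {
        img <- stats::rpois(length(lambda), lambda * p$photons_per_unit) /
          p$photons_per_unit
      } else {
        img <- lambda
      }
      q <- round(pmin(pmax(img, 0), maxv))
      arr[i, ch, , ] <- as.integer(q)
    }
  }
  image_series(arr, bit_depth = p$bit_depth, pixel_um = p$pixel_um,
               frame_interval_s = p$frame_interval_s,
               t_act = p$n_pre_frames,
               act_rois = lapply(p$act_rois, roi_um_to_px,
                                 pixel_um = p$pixel_um))
}

#' Deterministic scene with scripted, well-separated fusion events
#'
#' Builds a `sim_run` whose fusion times are prescribed rather than
#' stochastic: `n_pairs` donor/acceptor segment pairs are laid out in
#' horizontal strips, the donor of each pair sits inside its own activation
#' square (so it is bright in GFP and bleached in DsRed after the activation
#' frame), and at each pair's `fuse_frame` the acceptor translates into
#' end-to-end contact and the pair's matrix content mixes proportionally to
#' length. Optional `fiss_frames` separate a pair again, making its event
#' transient. Used to grade the event detector against unambiguous ground
#' truth.
#'
#' @param n_pairs number of pairs.
#' @param fuse_frames 0-based frames (> activation frame) of the fusions,
#'   length `n_pairs`.
#' @param fiss_frames optional 0-based separation frames (`NA` = stays
#'   fused), length `n_pairs`.
#' @param n_pre_frames,n_frames pre-activation frames and total frames.
#' @param params a [sim_params] supplying geometry/optics; its segment
#'   counts and ROIs are overridden by the constructed scene.
#' @return a `sim_run` with `truth_events` and a rendered `series`.
#' @export
scripted_fusion_run <- function(n_pairs = 5L,
                                fuse_frames = NULL,
                                fiss_frames = NULL,
                                n_pre_frames = 3L, n_frames = 40L,
                                params = sim_params()) {
  p <- params
  if (is.null(fuse_frames))
    fuse_frames <- n_pre_frames + 4L + 6L * (seq_len(n_pairs) - 1L)
  stopifnot(length(fuse_frames) == n_pairs,
            all(fuse_frames > n_pre_frames),
            all(fuse_frames < n_frames))
  if (is.null(fiss_frames)) fiss_frames <- rep(NA_integer_, n_pairs)
  seg_len <- 1.2; gap_apart <- 1.6; overlap <- 0.15
  strip <- 2.4
  field <- max(p$field_um, (n_pairs + 0.5) * strip)
  t_act <- n_pre_frames
  ids_a <- seq_len(n_pairs) * 2L - 1L
  ids_b <- ids_a + 1L
  ax <- 2.2; ay <- strip * (seq_len(n_pairs) - 0.5)
  amt <- p$amount_per_um * seg_len
  mk_state <- function(f) {
    fused <- f >= fuse_frames & !(is.finite(fiss_frames) & f >= fiss_frames)
    was_fused <- f >= fuse_frames
    # acceptor x: approaches in two steps so frame-to-frame mask overlap is
    # never lost (a track must not jump farther than its own length)
    x_contact <- ax + seg_len - overlap
    x_apart <- ax + seg_len + gap_apart
    x_mid <- (x_contact + x_apart) / 2
    bx <- ifelse(fused, x_contact,
          ifelse(f == fuse_frames - 1L & f >= 0L, x_mid,
          ifelse(is.finite(fiss_frames) & f == fiss_frames, x_mid,
                 x_apart)))
    act <- f >= t_act
    dsred_a <- ifelse(rep(act, n_pairs), amt * p$bleach_survival, amt)
    dark_a <- ifelse(rep(act, n_pairs), 0, amt)
    bright_a <- ifelse(rep(act, n_pairs), amt, 0)
    dsred_b <- rep(amt, n_pairs); dark_b <- rep(amt, n_pairs)
    bright_b <- rep(0, n_pairs)
    # proportional mixing once fused (equal lengths -> simple average)
    mixd <- (dsred_a + dsred_b) / 2
    mixk <- (dark_a + dark_b) / 2
    mixb <- (bright_a + bright_b) / 2
    dsred_a <- ifelse(was_fused, mixd, dsred_a)
    dsred_b <- ifelse(was_fused, mixd, dsred_b)
    dark_a <- ifelse(was_fused, mixk, dark_a)
    dark_b <- ifelse(was_fused, mixk, dark_b)
    bright_a <- ifelse(was_fused, mixb, bright_a)
    bright_b <- ifelse(was_fused, mixb, bright_b)
    data.frame(
      id = c(rbind(ids_a, ids_b)),
      x = c(rbind(rep(ax, n_pairs), bx)),
      y = c(rbind(ay, ay)),
      angle = 0, len = seg_len,
      comp = c(rbind(ids_a, ifelse(fused, ids_a, ids_b))),
      dsred = c(rbind(dsred_a, dsred_b)),
      dark = c(rbind(dark_a, dark_b)),
      bright = c(rbind(bright_a, bright_b)))
  }
  states <- lapply(0:(n_frames - 1L), mk_state)
  roi_sz <- seg_len + 1.2
  rois <- lapply(seq_len(n_pairs), function(k) {
    c(ax - roi_sz / 2, ay[k] - roi_sz / 2, roi_sz)
  })
  p2 <- p
  p2$field_um <- field
  p2$n_pre_frames <- as.integer(n_pre_frames)
  p2$n_post_frames <- as.integer(n_frames - n_pre_frames)
  p2$act_rois <- rois
  p2$n_segments <- 2L * n_pairs
  dt <- p$frame_interval_s
  truth <- data.frame(
    event = "fusion", frame = fuse_frames,
    time_s = (fuse_frames - t_act) * dt,
    id_a = ids_a, id_b = ids_b,
    type = ifelse(is.finite(fiss_frames), "transient", "complete"),
    duration_s = ifelse(is.finite(fiss_frames),
                        (fiss_frames - fuse_frames) * dt, NA_real_),
    orientation = "end_to_end")
  set.seed(p$seed)
  structure(list(params = p2, states = states, truth_events = truth,
                 series = render_series(states, p2)),
            class = "sim_run")
}
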