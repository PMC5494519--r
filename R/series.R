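#' Two-channel photoactivation image series
#'
#' The common currency of all analysis stages: a `T x 2 x H x W` array of
#' unsigned integer pixel values (channel 1 = photoactivatable GFP, channel 2
#' = DsRed/RFP) together with its physical calibration and activation
#' metadata.
#'
#' Frame indices are 0-based throughout: `t_act` is the index of the first
#' frame acquired after the activation pulse ("immediately after
#' photoactivation"), frames `< t_act` are pre-activation, and quantitative
#' analysis starts at `t_act`. ROIs are axis-aligned rectangles in
#' 0-based `(row, col)` pixel coordinates with half-open extents,
#' `c(r0, c0, nrow, ncol)`.
#'
#' @param pixels numeric or integer array, `T x 2 x H x W`, values in
#'   `[0, 2^bit_depth)`.
#' @param bit_depth 8 or 16.
#' @param pixel_um physical pixel size, micrometers.
#' @param frame_interval_s frame interval, seconds.
#' @param t_act 0-based activation frame index.
#' @param act_rois list of photoactivation squares, each `c(r0, c0, nr, nc)`
#'   (0-based, half-open).
#' @param cell_roi optional logical `H x W` mask restricting analysis to the
#'   cell footprint; `NULL` means the whole frame.
#' @return an object of class `image_series`.
#' @export
image_series <- function(pixels, bit_depth, pixel_um, frame_interval_s,
                         t_act, act_rois, cell_roi = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4L, dim(pixels)[2] == 2L)
  stopifnot(bit_depth %in% c(8L, 16L))
  stopifnot(pixel_um > 0, frame_interval_s > 0)
  nT <- dim(pixels)[1]
  if (t_act < 0 || t_act >= nT)
    stop("t_act must satisfy 0 <= t_act < T")
  if (min(pixels) < 0 || max(pixels) >= 2^bit_depth)
    stop("pixel values out of range for bit_depth")
  H <- dim(pixels)[3]; W <- dim(pixels)[4]
  for (roi in act_rois) check_roi(roi, H, W)
  if (!is.null(cell_roi))
    stopifnot(is.logical(cell_roi), all(dim(cell_roi) == c(H, W)))
  structure(list(
    pixels = pixels, bit_depth = as.integer(bit_depth),
    pixel_um = pixel_um, frame_interval_s = frame_interval_s,
    t_act = as.integer(t_act), act_rois = act_rois, cell_roi = cell_roi
  ), class = "image_series")
}

check_roi <- function(roi, H, W) {
  if (length(roi) != 4L) stop("ROI must be c(r0, c0, nr, nc)")
  if (any(roi[3:4] <= 0)) stop("ROI extents must be positive")
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > H || roi[2] + roi[4] > W)
    stop("ROI outside image bounds")
  invisible(roi)
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "image_series: %d frames x 2 ch x %dx%d px (%d-bit), %.3g um/px, %.3g s/frame\n",
    d[1], d[3], d[4], x$bit_depth, x$pixel_um, x$frame_interval_s))
  cat(sprintf("  activation at frame %d; %d ROI(s); cell_roi: %s\n",
              x$t_act, length(x$act_rois),
              if (is.null(x$cell_roi)) "whole frame" else "set"))
  invisible(x)
}

n_frames <- function(series) dim(series$pixels)[1]

# 1-based pixel-array indices of pre-activation frames (0-based f < t_act)
pre_idx <- function(series) seq_len(series$t_act)

# 1-based indices of the analysis window: frame t_act (the first image after
# the activation pulse, "immediately after photoactivation") onwards
post_idx <- function(series) {
  nT <- n_frames(series)
  (series$t_act + 1L):nT
}

# seconds since the first analysis frame for 1-based pixel index i
frame_time_s <- function(series, i) {
  (i - (series$t_act + 1L)) * series$frame_interval_s
}

channel_frame <- function(series, i, channel) {
  series$pixels[i, channel, , ]
}

roi_mask <- function(roi, H, W) {
  m <- matrix(FALSE, H, W)
  m[(roi[1] + 1L):(roi[1] + roi[3]), (roi[2] + 1L):(roi[2] + roi[4])] <- TRUE
  m
}

all_roi_mask <- function(series) {
  H <- dim(series$pixels)[3]; W <- dim(series$pixels)[4]
  m <- matrix(FALSE, H, W)
  for (roi in series$act_rois) m <- m | roi_mask(roi, H, W)
  m
}

cell_mask <- function(series) {
  H <- dim(series$pixels)[3]; W <- dim(series$pixels)[4]
  if (is.null(series$cell_roi)) matrix(TRUE, H, W) else series$cell_roi
}
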