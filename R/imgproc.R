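#' 3x3 median despeckle filter
#'
#' The standard "despeckle" step applied to every frame before thresholding:
#' each pixel is replaced by the median of its 3x3 neighborhood. Borders are
#' handled by edge replication, so the output has the same shape (and storage
#' mode) as the input.
#'
#' Implemented as a 19-comparator median-of-9 exchange network applied to the
#' nine shifted copies of the padded image, so the filter is exact and fully
#' vectorized.
#'
#' @param frame a 2-D numeric or integer matrix.
#' @return the filtered matrix.
#' @export
despeckle <- function(frame) {
  if (!is.matrix(frame)) stop("despeckle expects a 2-D image matrix")
  H <- nrow(frame); W <- ncol(frame)
  if (H < 1L || W < 1L) stop("empty image")
  p <- frame[c(1L, seq_len(H), H), c(1L, seq_len(W), W), drop = FALSE]
  n <- vector("list", 9L)
  k <- 0L
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1L
    n[[k]] <- as.vector(p[(1L + dr):(H + dr), (1L + dc):(W + dc)])
  }
  swp <- function(a, b) {
    lo <- pmin(n[[a]], n[[b]]); hi <- pmax(n[[a]], n[[b]])
    n[[a]] <<- lo; n[[b]] <<- hi
  }
  # median-of-9 exchange network (indices 1..9)
  swp(2, 3); swp(5, 6); swp(8, 9); swp(1, 2); swp(4, 5); swp(7, 8)
  swp(2, 3); swp(5, 6); swp(8, 9); swp(1, 4); swp(6, 9); swp(5, 8)
  swp(4, 7); swp(2, 5); swp(3, 6); swp(5, 8); swp(5, 3); swp(7, 5)
  swp(5, 3)
  out <- matrix(n[[5]], H, W)
  if (is.integer(frame)) storage.mode(out) <- "integer"
  out
}

# Exhaustive Otsu threshold on a vector of non-negative integers.
# Threshold t splits values into classes {v < t} and {v >= t}; returns the
# lowest t in 1..(2^bit_depth - 1) maximizing between-class variance.
otsu_from_values <- function(v, bit_depth) {
  if (length(v) == 0L) stop("no pixels to threshold")
  if (length(unique(v)) < 2L)
    stop("image has a single gray level; no separable classes")
  L <- 2L^as.integer(bit_depth)
  h <- as.numeric(tabulate(as.integer(v) + 1L, nbins = L))
  N <- as.numeric(length(v))
  cw <- cumsum(h)                       # pixels with value <= level
  cm <- cumsum(h * (0:(L - 1)))         # intensity mass with value <= level
  M <- cm[L]
  # candidate thresholds t = 1..L-1: class 0 holds values 0..t-1
  w0 <- cw[1:(L - 1)]
  m0 <- cm[1:(L - 1)]
  valid <- w0 > 0 & w0 < N
  sb <- rep(-Inf, L - 1L)
  sb[valid] <- (m0[valid] * N - M * w0[valid])^2 /
    (w0[valid] * (N - w0[valid]))
  which.max(sb)  # ties broken toward the lowest level
}

#' Series-level Otsu threshold
#'
#' Computes a single threshold for an image series the way the automated
#' fusion analysis requires: one pooled histogram over the selected frames
#' of one channel (restricted to the cell ROI if set), then an exhaustive
#' search for the gray level maximizing between-class variance. Ties are
#' broken toward the lowest level. The returned threshold `t` separates the
#' classes `value < t` (background) and `value >= t` (object).
#'
#' The search is exact at native gray-level resolution for both 8- and
#' 16-bit data (the cumulative-histogram search is linear in the number of
#' levels, so no coarse binning is needed).
#'
#' @param series an [image_series].
#' @param channel 1 (GFP) or 2 (DsRed/RFP).
#' @param frames 1-based frame indices to pool; defaults to the
#'   post-activation analysis window.
#' @param prefilter optional per-frame function applied before pooling
#'   (e.g. [despeckle]); `NULL` for raw pixels.
#' @return integer threshold.
#' @export
otsu_threshold_series <- function(series, channel, frames = post_idx(series),
                                  prefilter = NULL) {
  if (length(frames) == 0L) stop("no frames selected")
  cm <- cell_mask(series)
  vals <- unlist(lapply(frames, function(i) {
    f <- channel_frame(series, i, channel)
    if (!is.null(prefilter)) f <- prefilter(f)
    f[cm]
  }), use.names = FALSE)
  otsu_from_values(vals, series$bit_depth)
}

#' Noise-ratio threshold from pre-activation frames
#'
#' Before activation the GFP channel carries no signal, so any suprathreshold
#' pre-activation pixel is a false positive. This returns the smallest
#' threshold `t` such that at most `max_frac` (default 0.1%) of the in-cell
#' pixels in the pre-activation frames of the given channel satisfy
#' `value >= t` -- i.e. the series is "thresholded to reach a 0.1%
#' noise-to-signal ratio".
#'
#' @param series an [image_series] with at least one pre-activation frame.
#' @param channel channel index (default 1, GFP).
#' @param max_frac maximum tolerated suprathreshold fraction.
#' @return integer threshold.
#' @export
noise_ratio_threshold <- function(series, channel = 1L, max_frac = 0.001) {
  pre <- pre_idx(series)
  if (length(pre) == 0L) stop("no pre-activation frames")
  cm <- cell_mask(series)
  v <- unlist(lapply(pre, function(i) channel_frame(series, i, channel)[cm]),
              use.names = FALSE)
  n <- length(v)
  k <- floor(max_frac * n)              # allowed suprathreshold count
  vs <- sort(v, decreasing = TRUE)
  as.integer(vs[k + 1L] + 1L)
}
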