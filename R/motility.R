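#' Frame-differencing motility index
#'
#' Combines the two channels by addition, thresholds both the summed series
#' and the successive-difference series at the constant 32 (defined on an
#' 8-bit scale), and reports the median suprathreshold pixel count of the
#' difference series normalized by that of the summed series, over the
#' post-activation period. 16-bit input is linearly rescaled to 8-bit
#' (max-normalized over the summed post-activation series) before the
#' constant threshold is applied. "Above the threshold" is strict
#' (`value > 32`). Differences are absolute by default.
#'
#' @param series an [image_series] with at least 2 post-activation frames.
#' @param threshold the constant threshold (default 32).
#' @param signed use signed-positive differences instead of absolute.
#' @return a `motility_result`: `index`, `diff_counts`, `sum_counts`,
#'   `mean_intensity_above` (QC: mean summed intensity above threshold).
#' @export
motility_index <- function(series, threshold = 32, signed = FALSE) {
  idx <- post_idx(series)
  if (length(idx) < 2L) stop("need at least 2 post-activation frames")
  cm <- cell_mask(series)
  summed <- lapply(idx, function(i) {
    s <- channel_frame(series, i, 1L) + channel_frame(series, i, 2L)
    pmin(s, 2^series$bit_depth - 1)
  })
  if (series$bit_depth > 8L) {
    mx <- max(vapply(summed, max, 0))
    if (mx > 0) summed <- lapply(summed, function(s) s * (255 / mx))
  } else {
    summed <- lapply(summed, function(s) pmin(s, 255))
  }
  sum_counts <- vapply(summed, function(s) sum(s[cm] > threshold),
                       numeric(1))
  diff_counts <- vapply(seq_len(length(summed) - 1L), function(k) {
    d <- summed[[k + 1L]] - summed[[k]]
    if (!signed) d <- abs(d) else d <- pmax(d, 0)
    sum(d[cm] > threshold)
  }, numeric(1))
  if (stats::median(sum_counts) == 0)
    stop("summed series entirely below threshold; no cell signal")
  above <- unlist(lapply(summed, function(s) s[cm][s[cm] > threshold]),
                  use.names = FALSE)
  structure(list(
    index = stats::median(diff_counts) / stats::median(sum_counts),
    diff_counts = diff_counts, sum_counts = sum_counts,
    mean_intensity_above = mean(above)
  ), class = "motility_result")
}

#' @export
print.motility_result <- function(x, ...) {
  cat(sprintf(
    "motility_result: index = %.4f (median diff %g / median sum %g), mean intensity above threshold %.1f\n",
    x$index, stats::median(x$diff_counts), stats::median(x$sum_counts),
    x$mean_intensity_above))
  invisible(x)
}

#' Binary-mask colocalization percentage
#'
#' Otsu-thresholds each single-frame image independently and reports the
#' percentage of mask-A pixels that also lie in mask B (object-pixel
#' co-occurrence on binary masks, Manders-style without intensity
#' weighting).
#'
#' @param imgA,imgB same-shape single-frame images.
#' @param bit_depth gray-level depth of the inputs (default 8).
#' @return a `coloc_result`: `percent_A_in_B`, `threshold_A`, `threshold_B`.
#' @export
coloc_percent <- function(imgA, imgB, bit_depth = 8L) {
  stopifnot(is.matrix(imgA), is.matrix(imgB), all(dim(imgA) == dim(imgB)))
  tA <- otsu_from_values(as.vector(imgA), bit_depth)
  tB <- otsu_from_values(as.vector(imgB), bit_depth)
  mA <- imgA >= tA; mB <- imgB >= tB
  if (!any(mA)) stop("mask A is empty")
  structure(list(percent_A_in_B = 100 * sum(mA & mB) / sum(mA),
                 threshold_A = tA, threshold_B = tB),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: %.1f%% of A in B (thresholds %d / %d)\n",
              x$percent_A_in_B, x$threshold_A, x$threshold_B))
  invisible(x)
}
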