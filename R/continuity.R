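#' Ratio decay in the region of photoactivation
#'
#' Computes, per activation ROI and frame, the ratio of mean GFP to mean
#' DsRed fluorescence over the ROI pixels, normalized to the first frame
#' acquired after the activation pulse, and the decay of that ratio at 500 s
#' (`decay_500s = 1 - ratio(500 s)`, linearly interpolated between the
#' bracketing frames). Larger decay means faster equilibration of activated
#' PA-GFP out of the ROI, i.e. a more connected / more actively fusing
#' network. Multiple ROIs are averaged per cell.
#'
#' The DsRed ROI mean must stay above a noise floor (default: mean + 3 sd of
#' the pre-activation GFP channel, the only pure-noise data in the series):
#' a bleached-out ROI has an undefined ratio. Such ROIs are skipped with a
#' warning (multi-ROI recordings are curated the same way in practice); if
#' every ROI fails the floor, the cell errors.
#'
#' @param series an [image_series] with at least one activation ROI.
#' @param dsred_floor noise floor for the DsRed ROI mean; `NULL` = estimate
#'   from pre-activation frames (0 when there are none).
#' @return an `rpa_timecourse`: list with `time_s`, `ratio` (normalized,
#'   ROI-averaged), `decay_500s`, `at_500s` (FALSE when the series ends
#'   before 500 s and the last frame was used instead).
#' @export
rpa_decay <- function(series, dsred_floor = NULL) {
  if (length(series$act_rois) == 0L) stop("series has no activation ROI")
  idx <- post_idx(series)
  if (length(idx) < 2L) stop("need at least 2 post-activation frames")
  H <- dim(series$pixels)[3]; W <- dim(series$pixels)[4]
  if (is.null(dsred_floor)) {
    pre <- pre_idx(series)
    dsred_floor <- if (length(pre)) {
      v <- unlist(lapply(pre, function(i)
        channel_frame(series, i, 1L)[cell_mask(series)]), use.names = FALSE)
      mean(v) + 3 * stats::sd(v)
    } else 0
  }
  time_s <- frame_time_s(series, idx)
  curves <- lapply(seq_along(series$act_rois), function(ri) {
    m <- roi_mask(series$act_rois[[ri]], H, W)
    ratio <- vapply(idx, function(i) {
      mg <- mean(channel_frame(series, i, 1L)[m])
      mr <- mean(channel_frame(series, i, 2L)[m])
      if (mr <= dsred_floor) return(NA_real_)
      mg / mr
    }, numeric(1))
    if (anyNA(ratio)) {
      warning("ROI ", ri,
              " skipped: DsRed mean at/below noise floor (bleached out)")
      return(NULL)
    }
    ratio / ratio[1]
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (!length(curves))
    stop("DsRed ROI mean at/below noise floor in every ROI; ",
         "ratio undefined")
  ratio <- rowMeans(do.call(cbind, curves))
  at_500 <- max(time_s) >= 500
  r500 <- if (at_500) {
    stats::approx(time_s, ratio, xout = 500)$y
  } else {
    ratio[length(ratio)]
  }
  structure(list(time_s = time_s, ratio = ratio,
                 decay_500s = 1 - r500, at_500s = at_500),
            class = "rpa_timecourse")
}

#' @export
print.rpa_timecourse <- function(x, ...) {
  cat(sprintf("rpa_timecourse: %d frames, decay at 500 s = %.3f%s\n",
              length(x$time_s), x$decay_500s,
              if (x$at_500s) "" else " (series ends before 500 s)"))
  invisible(x)
}

#' Spreading of activated GFP outside the photoactivated areas
#'
#' Thresholds the GFP channel at the 0.1% noise-to-signal level (from the
#' pre-activation frames, see [noise_ratio_threshold]), masks out the
#' photoactivation squares, and counts the remaining suprathreshold GFP
#' pixels per post-activation frame.
#'
#' @param series an [image_series] with pre-activation frames.
#' @return data frame with `time_s` and `outside_pixels`.
#' @export
spreading_curve <- function(series) {
  thr <- noise_ratio_threshold(series, channel = 1L)
  idx <- post_idx(series)
  if (length(idx) == 0L) stop("no post-activation frames")
  keep <- cell_mask(series) & !all_roi_mask(series)
  outside <- vapply(idx, function(i) {
    sum(channel_frame(series, i, 1L)[keep] >= thr)
  }, numeric(1))
  data.frame(time_s = frame_time_s(series, idx), outside_pixels = outside)
}

#' Closed-form continuity oracle from the simulator's content ledger
#'
#' Recomputes the RPA ratio time course directly from ground-truth segment
#' amounts (sum of activated GFP over ROI segments divided by sum of DsRed,
#' normalized like [rpa_decay]), bypassing rendering entirely. Segments are
#' attributed to a ROI by centroid. This is the dilution law the image-based
#' measurement must reproduce on noise-free renders.
#'
#' @param run a `sim_run`.
#' @return list with `time_s`, `ratio`, `decay_500s`, `at_500s`.
#' @export
rpa_from_ledger <- function(run) {
  p <- run$params
  t_act <- p$n_pre_frames
  frames <- t_act:(length(run$states) - 1L)          # 0-based analysis frames
  dt <- p$frame_interval_s
  time_s <- (frames - t_act) * dt
  ratio <- vapply(frames, function(f) {
    st <- run$states[[f + 1L]]
    m <- rep(FALSE, nrow(st))
    for (r in p$act_rois) {
      m <- m | (st$x >= r[1] & st$x < r[1] + r[3] &
                st$y >= r[2] & st$y < r[2] + r[3])
    }
    if (!any(m)) return(NA_real_)
    sum(st$bright[m]) / sum(st$dsred[m])
  }, numeric(1))
  ratio <- ratio / ratio[1]
  at_500 <- max(time_s) >= 500
  r500 <- if (at_500) stats::approx(time_s, ratio, xout = 500)$y else
    ratio[length(ratio)]
  list(time_s = time_s, ratio = ratio, decay_500s = 1 - r500,
       at_500s = at_500)
}
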