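#' Single-exponential fit of a pixel-count decay
#'
#' Fits `y = a * exp(-b * x)` by unweighted nonlinear least squares,
#' initialized from a log-linear regression on the positive counts. The
#' half-time is `ln(2)/b`, reported as `Inf` (with `converged` unaffected)
#' when the fitted decay constant is not positive.
#'
#' @param time_s sample times, seconds.
#' @param counts non-negative counts (zeros are allowed in the objective;
#'   the log-linear initialization uses only positive counts).
#' @return a `decay_fit`: list with `a`, `b`, `half_time_s`, `r2`, `counts`
#'   (data frame of `time_s`, `count`, `fitted`) and `converged`.
#' @export
exp_decay_fit <- function(time_s, counts) {
  stopifnot(length(time_s) == length(counts), length(counts) >= 3L)
  if (all(counts == 0)) stop("all counts are zero; no activated signal")
  if (length(unique(counts)) == 1L) {
    # degenerate flat series: the zero-rate fit is exact
    return(structure(list(
      a = counts[1], b = 0, half_time_s = Inf, r2 = NA_real_,
      counts = data.frame(time_s = time_s, count = counts,
                          fitted = counts),
      converged = TRUE), class = "decay_fit"))
  }
  pos <- counts > 0
  ll <- stats::lm(log(counts[pos]) ~ time_s[pos])
  a0 <- exp(unname(stats::coef(ll)[1]))
  b0 <- -unname(stats::coef(ll)[2])
  converged <- TRUE
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ a * exp(-b * time_s),
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    converged <- FALSE
    a <- a0; b <- b0
  } else {
    cf <- stats::coef(fit)
    a <- unname(cf["a"]); b <- unname(cf["b"])
  }
  yhat <- a * exp(-b * time_s)
  sst <- sum((counts - mean(counts))^2)
  r2 <- if (sst > 0) 1 - sum((counts - yhat)^2) / sst else NA_real_
  structure(list(a = a, b = b,
                 half_time_s = if (b > 0) log(2) / b else Inf,
                 r2 = r2,
                 counts = data.frame(time_s = time_s, count = counts,
                                     fitted = yhat),
                 converged = converged),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: a = %.4g, b = %.4g /s, half-time = %.4g s, R^2 = %.3f%s\n",
    x$a, x$b, x$half_time_s, x$r2,
    if (x$converged) "" else " (log-linear fallback)"))
  invisible(x)
}

#' GFP-only pixel loss as an automated fusion measure
#'
#' The unbiased fusion statistic of the assay: after simultaneous
#' photoactivation of PA-GFP and photobleaching of DsRed, activated
#' mitochondria are green-only; every fusion with an unbleached mitochondrion
#' re-reddens them, so the count of green-only pixels decays with fusion
#' activity. Per post-activation frame (within the cell ROI) each channel is
#' despeckled, one pooled Otsu threshold per channel series is applied, and
#' the green-only mask is `GFP mask AND NOT RFP mask`. The per-frame counts
#' are fit by [exp_decay_fit]; `ln(2)/b` is the half-time used as the fusion
#' measure.
#'
#' @param series an [image_series]; `cell_roi`, when set, restricts the
#'   analysis to the cell footprint (recommended for real recordings).
#' @param min_post minimum number of post-activation frames.
#' @return a `decay_fit` (see [exp_decay_fit]) with an extra element
#'   `thresholds = c(gfp, rfp)`.
#' @export
gfp_only_decay <- function(series, min_post = 10L) {
  idx <- post_idx(series)
  if (length(idx) < min_post)
    stop("need at least ", min_post, " post-activation frames")
  cm <- cell_mask(series)
  dG <- lapply(idx, function(i) despeckle(channel_frame(series, i, 1L)))
  dR <- lapply(idx, function(i) despeckle(channel_frame(series, i, 2L)))
  thrG <- otsu_from_values(unlist(lapply(dG, function(f) f[cm])),
                           series$bit_depth)
  thrR <- otsu_from_values(unlist(lapply(dR, function(f) f[cm])),
                           series$bit_depth)
  counts <- vapply(seq_along(idx), function(k) {
    sum((dG[[k]] >= thrG) & (dR[[k]] < thrR) & cm)
  }, numeric(1))
  fit <- exp_decay_fit(frame_time_s(series, idx), counts)
  fit$thresholds <- c(gfp = thrG, rfp = thrR)
  fit
}
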