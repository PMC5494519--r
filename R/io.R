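#' Write an image series as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored frame-major, channel within frame (page = 2*(t-1) + c);
#' the sidecar records the axis sizes and all calibration and activation
#' metadata so that [read_series] round-trips losslessly.
#'
#' @param series an [image_series].
#' @param tiff_path output TIFF path.
#' @param sidecar_path output JSON path; default `<tiff_path>.json`.
#' @export
write_series <- function(series, tiff_path,
                         sidecar_path = paste0(tiff_path, ".json")) {
  d <- dim(series$pixels)
  maxv <- 2^series$bit_depth - 1
  pages <- vector("list", d[1] * 2L)
  for (t in seq_len(d[1])) for (ch in 1:2) {
    pages[[(t - 1L) * 2L + ch]] <- series$pixels[t, ch, , ] / maxv
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = series$bit_depth)
  meta <- list(
    n_frames = d[1], n_channels = 2L, height = d[3], width = d[4],
    bit_depth = series$bit_depth, pixel_um = series$pixel_um,
    frame_interval_s = series$frame_interval_s, t_act = series$t_act,
    act_rois = series$act_rois,
    cell_roi = if (is.null(series$cell_roi)) NULL else
      which(series$cell_roi) - 1L,
    axes = "TCYX")
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tiff_path, sidecar = sidecar_path))
}

#' Read an image series written by [write_series]
#'
#' @param tiff_path multi-page TIFF (frame-major, channel within frame).
#' @param sidecar_path JSON sidecar with calibration and activation
#'   metadata; missing required fields raise an error naming the field.
#' @return an [image_series].
#' @export
read_series <- function(tiff_path, sidecar_path = paste0(tiff_path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("bit_depth", "pixel_um", "frame_interval_s", "t_act")) {
    if (is.null(meta[[field]]))
      stop("sidecar is missing required field \"", field, "\"")
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  n_pages <- length(pages)
  nC <- if (!is.null(meta$n_channels)) meta$n_channels else 2L
  if (is.null(meta$n_frames)) {
    if (n_pages %% nC != 0L)
      stop("ambiguous axes: ", n_pages, " pages not divisible by ", nC,
           " channels; candidates: ",
           paste(paste0("T=", seq_len(n_pages), ",C=1"), collapse = " "))
    meta$n_frames <- n_pages %/% nC
  }
  if (meta$n_frames * nC != n_pages)
    stop("ambiguous axes: sidecar says T=", meta$n_frames, ", C=", nC,
         " but TIFF has ", n_pages, " pages")
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  maxv <- 2^meta$bit_depth - 1
  arr <- array(0L, c(meta$n_frames, nC, H, W))
  for (t in seq_len(meta$n_frames)) for (ch in seq_len(nC)) {
    arr[t, ch, , ] <- as.integer(round(pages[[(t - 1L) * nC + ch]] * maxv))
  }
  rois <- meta$act_rois
  if (is.matrix(rois)) rois <- lapply(seq_len(nrow(rois)), function(i) rois[i, ])
  if (is.null(rois)) rois <- list()
  cell_roi <- NULL
  if (!is.null(meta$cell_roi) && length(meta$cell_roi)) {
    cell_roi <- matrix(FALSE, H, W)
    cell_roi[meta$cell_roi + 1L] <- TRUE
  }
  image_series(arr, bit_depth = meta$bit_depth, pixel_um = meta$pixel_um,
               frame_interval_s = meta$frame_interval_s, t_act = meta$t_act,
               act_rois = rois, cell_roi = cell_roi)
}

#' Write a complete simulation run to disk
#'
#' Emits the rendered series (TIFF + JSON sidecar, see [write_series]) and
#' the ground-truth event table as CSV.
#'
#' @param run a `sim_run` with a rendered `series`.
#' @param dir output directory (created if needed).
#' @param stem file stem, default `"simrun"`.
#' @return named character vector of the written paths.
#' @export
write_simrun <- function(run, dir, stem = "simrun") {
  if (is.null(run$series)) stop("run has no rendered series")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff_path <- file.path(dir, paste0(stem, ".tif"))
  paths <- write_series(run$series, tiff_path)
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(run$truth_events, truth_path, row.names = FALSE)
  invisible(c(paths, truth = truth_path))
}
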