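#' Simulation parameters for a synthetic photoactivation experiment
#'
#' Defines the conditions of a simulated two-channel recording: a population
#' of mobile mitochondrial segments carrying two matrix fluorophores
#' (constitutive DsRed and initially dark photoactivatable GFP), stochastic
#' fusion/fission with instantaneous matrix-content mixing, a photoactivation
#' step that switches PA-GFP on and photobleaches DsRed inside square ROIs,
#' and rendering with PSF blur and shot noise.
#'
#' Defaults emulate the acquisition used in the assay this package
#' quantifies: 512x512 px at 0.1 um/px, 0.25 frames/s (4 s interval), 5x5 um
#' (25 um^2) activation squares, and a 120-frame (8 min) post-activation
#' window. The bleach depth is not an experimentally reported constant;
#' `bleach_survival = 0.2` (80% bleach) is a configuration choice.
#'
#' @param n_segments number of mitochondrial segments.
#' @param field_um side of the square field, micrometers.
#' @param pixel_um pixel size, micrometers.
#' @param frame_interval_s frame interval, seconds.
#' @param n_pre_frames,n_post_frames frames before/from activation. The
#'   activation pulse is applied at 0-based frame `n_pre_frames`.
#' @param seg_len_um_mean,seg_len_um_sd segment length distribution, um.
#' @param seg_width_um drawn capsule width, um.
#' @param diffusion_um2_s center-of-mass diffusion coefficient, um^2/s;
#'   connected components move rigidly.
#' @param k_fuse_per_contact_s fusion hazard per contacting pair, 1/s.
#' @param k_fiss_per_junction_s fission hazard per junction, 1/s.
#' @param contact_dist_um capsule-boundary gap below which two segments are
#'   fusion-eligible, um.
#' @param bleach_survival fraction of DsRed surviving the activation pulse
#'   inside the ROI, in `[0, 1]`.
#' @param act_rois list of activation squares in micrometers, each
#'   `c(x0, y0, size)`; default one centered 5x5 um square (`roi_um`).
#' @param roi_um side of the default centered activation square, um.
#' @param psf_sigma_um Gaussian PSF sigma, um (0 disables blur).
#' @param photons_per_unit photons per intensity unit for shot noise;
#'   `Inf` renders noiselessly.
#' @param background additive background level, intensity units.
#' @param bit_depth 8 or 16.
#' @param amount_per_um initial fluorophore amount per um of segment length
#'   (sets the drawn per-pixel intensity, since intensity is amount per unit
#'   length).
#' @param seed integer seed; one seeded generator drives motion, fission,
#'   fusion and rendering in a fixed documented order.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_segments = 40L, field_um = 51.2, pixel_um = 0.1,
                       frame_interval_s = 4, n_pre_frames = 5L,
                       n_post_frames = 120L, seg_len_um_mean = 1.5,
                       seg_len_um_sd = 0.4, seg_width_um = 0.5,
                       diffusion_um2_s = 0.01, k_fuse_per_contact_s = 0.02,
                       k_fiss_per_junction_s = 0.002, contact_dist_um = 0.3,
                       bleach_survival = 0.2, act_rois = NULL, roi_um = 5,
                       psf_sigma_um = 0.15, photons_per_unit = 20,
                       background = 5, bit_depth = 8L, amount_per_um = 120,
                       seed = 1L) {
  if (is.null(act_rois)) {
    x0 <- (field_um - roi_um) / 2
    act_rois <- list(c(x0, x0, roi_um))
  }
  p <- list(n_segments = as.integer(n_segments), field_um = field_um,
            pixel_um = pixel_um, frame_interval_s = frame_interval_s,
            n_pre_frames = as.integer(n_pre_frames),
            n_post_frames = as.integer(n_post_frames),
            seg_len_um_mean = seg_len_um_mean, seg_len_um_sd = seg_len_um_sd,
            seg_width_um = seg_width_um, diffusion_um2_s = diffusion_um2_s,
            k_fuse_per_contact_s = k_fuse_per_contact_s,
            k_fiss_per_junction_s = k_fiss_per_junction_s,
            contact_dist_um = contact_dist_um,
            bleach_survival = bleach_survival, act_rois = act_rois,
            psf_sigma_um = psf_sigma_um, photons_per_unit = photons_per_unit,
            background = background, bit_depth = as.integer(bit_depth),
            amount_per_um = amount_per_um, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$n_segments >= 1L)
  if (p$field_um <= 0 || p$pixel_um <= 0 || p$frame_interval_s <= 0)
    stop("field/pixel/frame values must be positive")
  if (p$k_fuse_per_contact_s < 0 || p$k_fiss_per_junction_s < 0 ||
      p$diffusion_um2_s < 0)
    stop("rates must be >= 0")
  if (p$bleach_survival < 0 || p$bleach_survival > 1)
    stop("bleach_survival must lie in [0, 1]")
  if (!p$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  for (r in p$act_rois) {
    if (length(r) != 3L || r[3] <= 0) stop("act_roi must be c(x0, y0, size)")
    if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > p$field_um ||
        r[2] + r[3] > p$field_um)
      stop("act_roi outside field")
  }
  invisible(p)
}

# union-find connected components from a 2-column edge matrix; returns the
# component label (smallest member id) per segment
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

seg_endpoints <- function(st) {
  hx <- cos(st$angle) * st$len / 2
  hy <- sin(st$angle) * st$len / 2
  list(p1x = st$x - hx, p1y = st$y - hy, p2x = st$x + hx, p2y = st$y + hy)
}

# closest approach of two 2-D segments; returns squared distance and the
# normalized parameters (s, t) of the closest points on each axis
seg_closest <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) {
    s <- 0; t <- 0
  } else if (a <= eps) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(max((b * f - c1 * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(max(-c1 / a, 0), 1)
      } else if (t > 1) {
        t <- 1; s <- min(max((b - c1) / a, 0), 1)
      }
    }
  }
  ca <- p1 + s * d1; cb <- p2 + t * d2
  list(d2 = sum((ca - cb)^2), s = s, t = t)
}

# orientation class of a contact from closest-point parameters
orientation_class <- function(s, t, len_a, len_b, end_tol_um = 0.3) {
  end_a <- min(s, 1 - s) * len_a <= end_tol_um
  end_b <- min(t, 1 - t) * len_b <= end_tol_um
  if (end_a && end_b) "end_to_end"
  else if (end_a || end_b) "end_to_side"
  else "side_to_side"
}

apply_activation <- function(st, p) {
  in_roi <- rep(FALSE, nrow(st))
  for (r in p$act_rois) {
    in_roi <- in_roi | (st$x >= r[1] & st$x < r[1] + r[3] &
                        st$y >= r[2] & st$y < r[2] + r[3])
  }
  st$bright[in_roi] <- st$bright[in_roi] + st$dark[in_roi]
  st$dark[in_roi] <- 0
  st$dsred[in_roi] <- st$dsred[in_roi] * p$bleach_survival
  st
}

# proportional-to-length re-equilibration of all fluorophore pools within
# the given components (instantaneous matrix mixing)
mix_components <- function(st, comps) {
  for (cc in comps) {
    m <- st$comp == cc
    tl <- sum(st$len[m])
    for (col in c("dsred", "dark", "bright")) {
      st[[col]][m] <- sum(st[[col]][m]) * st$len[m] / tl
    }
  }
  st
}

#' Simulate a photoactivation experiment with ground truth
#'
#' Runs the stochastic network simulation defined by `params` and (optionally)
#' renders it to an [image_series]. Per frame transition the generator, in
#' fixed order: (1) moves each connected component rigidly by a Gaussian
#' displacement with per-axis variance `2 D dt` (clamped so all members stay
#' in the field); (2) breaks each junction independently with probability
#' `1 - exp(-k_fiss dt)`; (3) tests fusion-eligible pairs (different
#' components whose capsule boundaries are within `contact_dist_um`) in
#' ascending `(id_a, id_b)` order, each fusing with probability
#' `1 - exp(-k_fuse dt)`, a segment at most once per frame; (4) instantly
#' re-equilibrates all fluorophore pools proportionally to segment length
#' within every connected component (matrix content is a soluble, rapidly
#' diffusing pool, so mixing is complete at frame resolution; fission
#' partitions nothing beyond the amounts segments already hold); (5) in the
#' transition into the activation frame moves `pagfp_dark` entirely to
#' `pagfp_bright` and multiplies DsRed by `bleach_survival` for segments
#' whose centroid lies in an activation ROI -- so frame `t_act` is the first
#' image showing activated GFP, before any post-activation mixing.
#'
#' Every fusion is logged with frame, partner ids and contact-geometry
#' orientation; a fusion whose junction breaks again within the recording is
#' classified `transient` with its fused duration, otherwise `complete`.
#'
#' @param params a [sim_params] object.
#' @param render render the image series (set `FALSE` for dynamics-only
#'   studies, which is much faster).
#' @return a `sim_run` list with elements `params`, `states` (one data frame
#'   of segments per frame), `truth_events` (fusion and fission records) and
#'   `series` (an [image_series], or `NULL` when `render = FALSE`).
#' @export
simulate_mito <- function(params, render = TRUE) {
  p <- validate_sim_params(params)
  set.seed(p$seed)
  n <- p$n_segments
  margin <- min(p$seg_len_um_mean / 2 + p$seg_width_um, p$field_um / 4)
  len <- pmax(0.3, stats::rnorm(n, p$seg_len_um_mean, p$seg_len_um_sd))
  st <- data.frame(
    id = seq_len(n),
    x = stats::runif(n, margin, p$field_um - margin),
    y = stats::runif(n, margin, p$field_um - margin),
    angle = stats::runif(n, 0, pi),
    len = len, comp = seq_len(n),
    dsred = p$amount_per_um * len,
    dark = p$amount_per_um * len,
    bright = 0)
  run_simulation(st, p, render = render, reseed = FALSE)
}

# simulation engine over a caller-supplied initial state; reseed = FALSE
# when the caller has already seeded the stream (simulate_mito does, so the
# layout draws and the dynamics share one stream)
run_simulation <- function(st, params, render = TRUE, reseed = TRUE) {
  p <- validate_sim_params(params)
  if (reseed) set.seed(p$seed)
  n <- nrow(st)
  if (n < 1L) stop("zero segments")
  dt <- p$frame_interval_s
  nT <- p$n_pre_frames + p$n_post_frames
  if (nT < 1L) stop("no frames to simulate")
  t_act <- p$n_pre_frames
  margin <- min(p$seg_len_um_mean / 2 + p$seg_width_um, p$field_um / 4)
  edges <- matrix(integer(0), ncol = 2)
  p_fuse <- 1 - exp(-p$k_fuse_per_contact_s * dt)
  p_fiss <- 1 - exp(-p$k_fiss_per_junction_s * dt)
  sd_step <- sqrt(2 * p$diffusion_um2_s * dt)
  fusions <- list(); fissions <- list()
  states <- vector("list", nT)
  if (t_act == 0L) st <- apply_activation(st, p)
  states[[1]] <- st

  for (f in seq_len(nT - 1L)) {  # f is the 0-based index of the new frame
    # --- motion (rigid per component, ascending component label) ---
    if (sd_step > 0) {
      for (cc in sort(unique(st$comp))) {
        m <- st$comp == cc
        d <- stats::rnorm(2L, 0, sd_step)
        dx <- min(max(d[1], margin - min(st$x[m])),
                  (p$field_um - margin) - max(st$x[m]))
        dy <- min(max(d[2], margin - min(st$y[m])),
                  (p$field_um - margin) - max(st$y[m]))
        if (is.finite(dx)) st$x[m] <- st$x[m] + dx
        if (is.finite(dy)) st$y[m] <- st$y[m] + dy
      }
    }
    # --- fission (independent per junction, in edge order) ---
    if (nrow(edges) && p_fiss > 0) {
      br <- stats::runif(nrow(edges)) < p_fiss
      if (any(br)) {
        for (k in which(br)) {
          fissions[[length(fissions) + 1L]] <-
            list(frame = f, a = edges[k, 1], b = edges[k, 2])
        }
        edges <- edges[!br, , drop = FALSE]
        st$comp <- components_from_edges(n, edges)
      }
    }
    # --- fusion (eligible pairs in ascending id order) ---
    if (p_fuse > 0 && n >= 2L) {
      ep <- seg_endpoints(st)
      reach <- (st$len + p$seg_width_um) / 2 + p$contact_dist_um
      used <- logical(n)
      for (i in seq_len(n - 1L)) {
        if (used[i]) next
        for (j in (i + 1L):n) {
          if (used[i] || used[j] || st$comp[i] == st$comp[j]) next
          cd <- sqrt((st$x[i] - st$x[j])^2 + (st$y[i] - st$y[j])^2)
          if (cd > reach[i] + reach[j]) next
          cl <- seg_closest(c(ep$p1x[i], ep$p1y[i]), c(ep$p2x[i], ep$p2y[i]),
                            c(ep$p1x[j], ep$p1y[j]), c(ep$p2x[j], ep$p2y[j]))
          gap <- sqrt(cl$d2) - p$seg_width_um - p$contact_dist_um
          if (gap > 0) next
          if (stats::runif(1L) < p_fuse) {
            edges <- rbind(edges, c(i, j))
            used[i] <- TRUE; used[j] <- TRUE
            fusions[[length(fusions) + 1L]] <- list(
              frame = f, a = i, b = j,
              orientation = orientation_class(cl$s, cl$t, st$len[i],
                                              st$len[j]))
            st$comp <- components_from_edges(n, edges)
          }
        }
      }
    }
    # --- instantaneous matrix mixing within every connected component ---
    multi <- unique(st$comp[duplicated(st$comp)])
    if (length(multi)) st <- mix_components(st, multi)
    # --- photoactivation / photobleach ---
    if (f == t_act) st <- apply_activation(st, p)
    states[[f + 1L]] <- st
  }

  truth <- truth_event_table(fusions, fissions, t_act, dt)
  run <- structure(list(params = p, states = states, truth_events = truth,
                        series = NULL), class = "sim_run")
  if (render) run$series <- render_series(states, p)
  run
}

truth_event_table <- function(fusions, fissions, t_act, dt) {
  fis <- if (length(fissions)) {
    data.frame(frame = vapply(fissions, `[[`, 0, "frame"),
               a = vapply(fissions, `[[`, 0, "a"),
               b = vapply(fissions, `[[`, 0, "b"))
  } else data.frame(frame = numeric(0), a = numeric(0), b = numeric(0))
  rows <- lapply(fusions, function(ev) {
    later <- fis$frame > ev$frame &
      ((fis$a == ev$a & fis$b == ev$b) | (fis$a == ev$b & fis$b == ev$a))
    if (any(later)) {
      f2 <- min(fis$frame[later])
      type <- "transient"; dur <- (f2 - ev$frame) * dt
    } else {
      type <- "complete"; dur <- NA_real_
    }
    data.frame(event = "fusion", frame = ev$frame,
               time_s = (ev$frame - t_act) * dt,
               id_a = ev$a, id_b = ev$b, type = type, duration_s = dur,
               orientation = ev$orientation)
  })
  fus_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = character(0), frame = numeric(0), time_s = numeric(0),
               id_a = numeric(0), id_b = numeric(0), type = character(0),
               duration_s = numeric(0), orientation = character(0))
  if (nrow(fis)) {
    fis_df <- data.frame(event = "fission", frame = fis$frame,
                         time_s = (fis$frame - t_act) * dt,
                         id_a = fis$a, id_b = fis$b, type = NA_character_,
                         duration_s = NA_real_, orientation = NA_character_)
    fus_df <- rbind(fus_df, fis_df)
  }
  fus_df[order(fus_df$frame), , drop = FALSE]
}

#' @export
print.sim_run <- function(x, ...) {
  nf <- sum(x$truth_events$event == "fusion")
  cat(sprintf("sim_run: %d segments, %d frames, %d fusion event(s)\n",
              x$params$n_segments, length(x$states), nf))
  invisible(x)
}

#' Count ground-truth fusions that mix activated and unactivated content
#'
#' A fusion is only visible in the two-channel recording when it transfers
#' fluorophore between partners of different content -- one carrying
#' activated (bright) PA-GFP and the other not. Fusions between two
#' activated or two unactivated partners exchange nothing detectable (this
#' is also what manual counting of inter-mitochondrial transfer scores).
#' This counts such content-mixing fusions from the ground-truth log, using
#' the partners' bright densities in the frame before each event.
#'
#' @param run a `sim_run`.
#' @param min_frac a partner is "bright" when its PA-GFP (bright) amount per
#'   um exceeds this fraction of `amount_per_um`.
#' @return integer count.
#' @export
mixing_fusion_count <- function(run, min_frac = 0.05) {
  ev <- run$truth_events
  ev <- ev[ev$event == "fusion", , drop = FALSE]
  if (!nrow(ev)) return(0L)
  thr <- min_frac * run$params$amount_per_um
  n <- 0L
  for (r in seq_len(nrow(ev))) {
    st <- run$states[[ev$frame[r]]]          # frame before the event
    da <- st$bright[st$id == ev$id_a[r]] / st$len[st$id == ev$id_a[r]]
    db <- st$bright[st$id == ev$id_b[r]] / st$len[st$id == ev$id_b[r]]
    if (xor(da > thr, db > thr)) n <- n + 1L
  }
  n
}

#' Total fluorophore amounts per component and frame
#'
#' Ground-truth content ledger used by the conservation checks and the
#' closed-form continuity oracle.
#'
#' @param run a `sim_run`.
#' @return data frame with frame (0-based), component, total dsred, dark,
#'   bright and length.
#' @export
component_totals <- function(run) {
  out <- lapply(seq_along(run$states), function(i) {
    st <- run$states[[i]]
    agg <- stats::aggregate(st[c("dsred", "dark", "bright", "len")],
                            by = list(comp = st$comp), FUN = sum)
    agg$frame <- i - 1L
    agg
  })
  do.call(rbind, out)
}
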