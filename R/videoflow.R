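#' Construct a bead-video object
#'
#' A time-lapse stack of fluorescence images of tracer beads, stored as an
#' array `[y, x, t]` with the dorso-ventral axis on rows (row 1 = ventral
#' wall after alignment) and the rostro-caudal axis on columns (caudal to the
#' right).
#'
#' @param stack numeric array `[ny, nx, nt]` (a matrix is treated as a single
#'   frame).
#' @param pixel_size_um pixel size in micrometres (default 0.189).
#' @param frame_interval_s frame interval in seconds (default 0.1, i.e.
#'   10 Hz).
#' @return An object of class `bead_video`.
#' @export
bead_video <- function(stack, pixel_size_um = 0.189, frame_interval_s = 0.1) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 2 || dim(stack)[3] >= 1)
  if (!(pixel_size_um > 0) || !(frame_interval_s > 0)) {
    stop("pixel size and frame interval must be positive", call. = FALSE)
  }
  structure(list(stack = stack, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "bead_video")
}

#' @export
print.bead_video <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Bead video: %d x %d px, %d frames, %.0f nm/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size_um * 1000, x$frame_interval_s))
  invisible(x)
}

# estimate canal tilt (degrees from horizontal) from the time-mean image
estimate_tilt <- function(video) {
  mean_img <- apply(video$stack, c(1, 2), mean)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(mean_img), sigma = 2))
  smn <- pmin(pmax(sm / max(sm), 0), 1)     # otsu needs [0, 1]
  thr <- EBImage::otsu(EBImage::Image(smn))
  mask <- smn > thr
  lab <- label8(mask)
  if (max(lab) == 0) return(0)
  sizes <- tabulate(lab[lab > 0])
  coords <- which(lab == which.max(sizes), arr.ind = TRUE)
  mom <- region_moments(coords)
  v <- mom$axis                                # (row, col) components
  atan2(v[1], v[2]) * 180 / pi                 # angle from the x (col) axis
}

#' Align and crop a bead video
#'
#' Rotates the stack so the canal axis is horizontal and optionally crops to
#' the canal. Right-angle rotations are exact array operations; arbitrary
#' angles use bilinear interpolation. With `rotate = NULL` the tilt is
#' estimated from the principal axis of the thresholded time-mean image.
#'
#' @param video a `bead_video`.
#' @param rotate rotation to apply in degrees (positive = counter-clockwise
#'   in standard image display, i.e. it removes a clockwise canal tilt), or
#'   `NULL` to auto-estimate.
#' @param crop `NULL`, or `list(rows =, cols =)` index vectors applied after
#'   rotation.
#' @return The aligned `bead_video`.
#' @export
preprocess_video <- function(video, rotate = NULL, crop = NULL) {
  stopifnot(inherits(video, "bead_video"))
  if (is.null(rotate)) rotate <- -estimate_tilt(video)
  stack <- video$stack
  if (abs(rotate %% 360) > 1e-9) {
    r <- rotate %% 360
    if (abs(r - round(r / 90) * 90) < 1e-9) {
      q <- (round(r / 90) %% 4)
      for (i in seq_len(q)) stack <- rot90_stack(stack)
    } else {
      frames <- lapply(seq_len(dim(stack)[3]), function(f) {
        img <- EBImage::Image(t(stack[, , f]))
        t(as.matrix(EBImage::rotate(img, rotate, bg.col = 0)))
      })
      stack <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
    }
  }
  if (!is.null(crop)) {
    if (max(crop$rows) > dim(stack)[1] || max(crop$cols) > dim(stack)[2] ||
        min(crop$rows) < 1 || min(crop$cols) < 1) {
      stop("crop box outside the frame", call. = FALSE)
    }
    stack <- stack[crop$rows, crop$cols, , drop = FALSE]
  }
  bead_video(stack, video$pixel_size_um, video$frame_interval_s)
}

# counter-clockwise quarter turn of an [y, x, t] stack (in display
# orientation with row 1 on top)
rot90_stack <- function(stack) {
  d <- dim(stack)
  out <- array(0, c(d[2], d[1], d[3]))
  for (f in seq_len(d[3])) out[, , f] <- t(stack[, , f])[d[2]:1, ]
  out
}

#' Wavelet-denoise a bead video
#'
#' Per-frame 2D Haar decomposition (level 6 on frames large enough to
#' support it) with soft thresholding of every detail subband at the
#' universal threshold `sigma sqrt(2 log N)`, where `sigma` is a robust MAD
#' noise estimate from the finest diagonal subband. Improves the
#' signal-to-noise ratio of dim beads before kymograph slicing.
#'
#' @param video a `bead_video`; frames smaller than 64 px in either dimension
#'   are returned unchanged with a warning.
#' @param levels decomposition depth.
#' @return The denoised `bead_video`.
#' @export
denoise <- function(video, levels = 6) {
  stopifnot(inherits(video, "bead_video"))
  d <- dim(video$stack)
  if (d[1] < 64 || d[2] < 64) {
    warning("frames smaller than 64 px: denoising skipped")
    return(video)
  }
  out <- video$stack
  for (f in seq_len(d[3])) {
    out[, , f] <- haar_denoise_frame(video$stack[, , f], levels)
  }
  bead_video(out, video$pixel_size_um, video$frame_interval_s)
}

#' Build a kymograph at one dorso-ventral position
#'
#' Re-slices the stack at row `row`: the signal is averaged over `window`
#' adjacent dorso-ventral rows (moving-window average; Brownian wandering is
#' partially averaged out, which is what makes bead traces long enough to
#' segment). Normalization then removes the two nuisance intensity factors:
#' each time sample is divided by its spatial mean (global flicker and
#' photobleaching -- a per-position normalization alone cannot remove a
#' temporal decay), and each spatial column by its temporal mean
#' (inhomogeneous illumination).
#'
#' @param video a `bead_video`.
#' @param row dorso-ventral row index.
#' @param window odd number of adjacent rows to average (default 3).
#' @return An object of class `kymograph`: matrix `[time, x]` plus metadata.
#' @export
build_kymograph <- function(video, row, window = 3) {
  stopifnot(inherits(video, "bead_video"))
  d <- dim(video$stack)
  if (row < 1 || row > d[1]) stop("`row` outside the stack", call. = FALSE)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  half <- (window - 1) / 2
  rows <- (row - half):(row + half)
  if (any(rows < 1 | rows > d[1])) {
    warning("row at the border: averaging window shrunk")
    rows <- rows[rows >= 1 & rows <= d[1]]
  }
  km <- t(vapply(seq_len(d[3]),
                 function(f) colMeans(video$stack[rows, , f, drop = FALSE]),
                 numeric(d[2])))                       # nt x nx
  rm_ <- rowMeans(km)
  rm_[rm_ == 0] <- 1
  km <- sweep(km, 1, rm_, `/`)                         # per-frame: bleaching
  cm <- colMeans(km)
  cm[cm == 0] <- 1
  km <- sweep(km, 2, cm, `/`)                          # per-position: gain
  structure(list(data = km, row = row, window = window,
                 pixel_size_um = video$pixel_size_um,
                 frame_interval_s = video$frame_interval_s),
            class = "kymograph")
}

#' Extract bead traces from a kymograph
#'
#' Pixels above the (per-column) average are segmented into 8-connected
#' regions; each region's ellipse-equivalent moments give its area,
#' eccentricity and orientation. Four filters keep only straight tilted lines
#' corresponding to moving beads: area >= `min_px` (rejects noise specks),
#' eccentricity > `min_ecc` (rejects blobs/aggregates), and |cos theta| and
#' |sin theta| >= 0.1 (reject stuck beads -- vertical lines -- and global
#' illumination flickers -- horizontal lines). The velocity of a surviving
#' trace is the tangent of its orientation measured from the time axis,
#' scaled by pixel size over frame interval; positive = caudal.
#'
#' @param kym a `kymograph`.
#' @param min_px minimum region area in pixels (default 15).
#' @param min_ecc minimum eccentricity (default 0.9).
#' @param min_trig minimum |cos theta| and |sin theta| (default 0.1).
#' @return A data.frame of trace events: `velocity_um_s`, `row`, `time_s`
#'   (centroid), `n_px`, `eccentricity`, `theta_deg`.
#' @export
extract_traces <- function(kym, min_px = 15, min_ecc = 0.9, min_trig = 0.1) {
  stopifnot(inherits(kym, "kymograph"))
  mask <- kym$data > 1                       # columns are normalized to mean 1
  empty <- data.frame(velocity_um_s = numeric(), row = integer(),
                      time_s = numeric(), n_px = integer(),
                      eccentricity = numeric(), theta_deg = numeric())
  if (!any(mask)) return(empty)
  lab <- label8(mask)
  regions <- label_coords(lab)
  out <- lapply(regions, function(co) {
    co <- as.matrix(co)
    if (nrow(co) < min_px) return(NULL)
    mom <- region_moments(co)
    if (mom$eccentricity <= min_ecc) return(NULL)
    theta <- atan2(mom$axis[2], mom$axis[1])  # from time axis, (-pi/2, pi/2]
    if (abs(cos(theta)) < min_trig || abs(sin(theta)) < min_trig) return(NULL)
    vel <- tan(theta) * kym$pixel_size_um / kym$frame_interval_s
    data.frame(velocity_um_s = vel, row = kym$row,
               time_s = (mom$centroid[1] - 1) * kym$frame_interval_s,
               n_px = mom$area, eccentricity = mom$eccentricity,
               theta_deg = theta * 180 / pi)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Scan all dorso-ventral rows of a video for trace events
#'
#' Convenience wrapper running [build_kymograph()] + [extract_traces()] for
#' every interior row.
#'
#' @param video a `bead_video`.
#' @param rows rows to scan (default all that admit the full window).
#' @param window,... passed to [build_kymograph()] / [extract_traces()].
#' @return Combined event data.frame.
#' @export
scan_video_events <- function(video, rows = NULL, window = 3, ...) {
  d <- dim(video$stack)
  half <- (window - 1) / 2
  if (is.null(rows)) rows <- (1 + half):(d[1] - half)
  ev <- lapply(rows, function(r) {
    extract_traces(build_kymograph(video, r, window), ...)
  })
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Aggregate trace events into a dorso-ventral velocity profile
#'
#' @param events event data.frame (from [extract_traces()] /
#'   [scan_video_events()]).
#' @param pixel_size_um pixel size, to report row positions in micrometres.
#' @return An object of class `velocity_profile`: data.frame with `row`,
#'   `y_um`, `mean_v`, `sem` (NA where fewer than 2 events), `n`, ordered
#'   ventral to dorsal.
#' @export
velocity_profile <- function(events, pixel_size_um = 0.189) {
  if (nrow(events) == 0 || length(unique(events$row)) < 3) {
    stop("need events from at least 3 dorso-ventral rows", call. = FALSE)
  }
  sp <- split(events$velocity_um_s, events$row)
  out <- data.frame(
    row = as.integer(names(sp)),
    mean_v = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_, numeric(1)),
    n = vapply(sp, length, integer(1)))
  out <- out[order(out$row), ]
  out$y_um <- (out$row - 1) * pixel_size_um
  rownames(out) <- NULL
  structure(out[, c("row", "y_um", "mean_v", "sem", "n")],
            class = c("velocity_profile", "data.frame"))
}

#' Normalized landmarks of a measured velocity profile
#'
#' The canal boundaries are located by the event-support rule: position 0 is
#' the most ventral row with at least `min_events` events and mean velocity
#' above `+v_thresh`; position 1 the most dorsal row with at least
#' `min_events` events and mean velocity below `-v_thresh` (threshold applied
#' symmetrically on both sides). Between them, the positions of the caudal
#' maximum, the zero crossing (linear interpolation between the rows
#' bracketing the sign change between the two extrema) and the rostral
#' minimum are reported on the normalized [0, 1] scale.
#'
#' @param profile a `velocity_profile`.
#' @param min_events minimum event count for a boundary row (default 5).
#' @param v_thresh boundary velocity threshold, um/s (default 0.4).
#' @return A list with `rel_vmax`, `rel_zero`, `rel_vmin`, the boundary rows,
#'   and `defined` (FALSE with NA landmarks when the rule is never met or no
#'   sign change exists).
#' @export
profile_landmarks <- function(profile, min_events = 5, v_thresh = 0.4) {
  stopifnot(inherits(profile, "velocity_profile"))
  vent_ok <- profile$n >= min_events & profile$mean_v > v_thresh
  dors_ok <- profile$n >= min_events & profile$mean_v < -v_thresh
  undef <- list(rel_vmax = NA_real_, rel_zero = NA_real_, rel_vmin = NA_real_,
                row0 = NA_integer_, row1 = NA_integer_, defined = FALSE)
  if (!any(vent_ok) || !any(dors_ok)) return(undef)
  r0 <- min(profile$row[vent_ok])
  r1 <- max(profile$row[dors_ok])
  if (r1 <= r0) return(undef)
  inside <- profile$row >= r0 & profile$row <= r1
  p <- profile[inside, ]
  rel <- function(row) (row - r0) / (r1 - r0)
  i_max <- which.max(p$mean_v); i_min <- which.min(p$mean_v)
  # zero crossing between the extrema
  lo <- min(i_max, i_min); hi <- max(i_max, i_min)
  zc <- NA_real_
  for (i in lo:(hi - 1)) {
    v1 <- p$mean_v[i]; v2 <- p$mean_v[i + 1]
    if (v1 == 0) { zc <- p$row[i]; break }
    if (v1 * v2 < 0) {
      zc <- p$row[i] + (p$row[i + 1] - p$row[i]) * v1 / (v1 - v2)
      break
    }
  }
  if (is.na(zc)) return(undef)
  list(rel_vmax = rel(p$row[i_max]), rel_zero = rel(zc),
       rel_vmin = rel(p$row[i_min]), row0 = r0, row1 = r1, defined = TRUE)
}

#' Section-averaged flow versus time
#'
#' Averages event velocities from all dorso-ventral positions in time bins.
#' For a steady bidirectional flow the average is close to zero; transient
#' unidirectional flow (e.g. after a muscle contraction) shows as an
#' excursion.
#'
#' @param events event data.frame with `time_s` and `velocity_um_s`.
#' @param bin_width_s time bin width, s.
#' @param t_range optional c(start, end) of the series, s.
#' @return data.frame `t` (bin centre), `v` (mean, NA for empty bins), `n`,
#'   `low_confidence` (fewer than 3 events).
#' @export
flow_vs_time <- function(events, bin_width_s = 1, t_range = NULL) {
  if (nrow(events) == 0) {
    return(data.frame(t = numeric(), v = numeric(), n = integer(),
                      low_confidence = logical()))
  }
  if (is.null(t_range)) t_range <- c(0, max(events$time_s))
  breaks <- seq(t_range[1], t_range[2] + bin_width_s, by = bin_width_s)
  bins <- cut(events$time_s, breaks, right = FALSE, labels = FALSE)
  nb <- length(breaks) - 1
  v <- rep(NA_real_, nb); n <- integer(nb)
  for (b in unique(bins[!is.na(bins)])) {
    sel <- which(bins == b)
    v[b] <- mean(events$velocity_um_s[sel])
    n[b] <- length(sel)
  }
  data.frame(t = breaks[-length(breaks)] + bin_width_s / 2, v = v, n = n,
             low_confidence = n < 3)
}

#' Detect muscle-contraction artifacts in an intensity series
#'
#' Contractions displace the whole field of view, producing bursts in the
#' absolute frame-to-frame derivative of the mean canal intensity. Runs of
#' supra-threshold derivative values are grouped into events; the strength of
#' an event is the sum of its supra-threshold derivative values (mixing
#' amplitude and duration).
#'
#' @param intensity numeric vector of mean canal intensity per frame.
#' @param threshold derivative threshold (default 4, dimensionless on the
#'   normalized-intensity derivative).
#' @param frame_interval_s frame interval, s.
#' @return data.frame `onset_s`, `duration_s`, `strength`.
#' @export
detect_contractions <- function(intensity, threshold = 4,
                                frame_interval_s = 0.1) {
  dI <- abs(diff(intensity))
  supra <- dI > threshold
  if (!any(supra)) {
    return(data.frame(onset_s = numeric(), duration_s = numeric(),
                      strength = numeric()))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  data.frame(
    onset_s = (starts[sel] - 1) * frame_interval_s,
    duration_s = r$lengths[sel] * frame_interval_s,
    strength = vapply(sel, function(i) sum(dI[starts[i]:ends[i]]), numeric(1)))
}

#' Integrated flow following each contraction
#'
#' Integrates the section-averaged flow over a window after each contraction
#' onset (trapezoid over the binned series); pairs the integral with the
#' event strength for correlation analysis.
#'
#' @param flow data.frame with `t` and `v` (as from [flow_vs_time()], or any
#'   time series of mean velocity).
#' @param events contraction events from [detect_contractions()].
#' @param window_s integration window, s (default 2.5).
#' @return data.frame `onset_s`, `strength`, `flow_integral` (um/s * s),
#'   `truncated`.
#' @export
post_contraction_flux <- function(flow, events, window_s = 2.5) {
  if (nrow(events) == 0) {
    return(data.frame(onset_s = numeric(), strength = numeric(),
                      flow_integral = numeric(), truncated = logical()))
  }
  t_max <- max(flow$t)
  out <- lapply(seq_len(nrow(events)), function(i) {
    t0 <- events$onset_s[i]; t1 <- t0 + window_s
    truncated <- t1 > t_max
    sel <- which(flow$t >= t0 & flow$t <= min(t1, t_max) & !is.na(flow$v))
    integral <- if (length(sel) >= 2) {
      sum(diff(flow$t[sel]) * (flow$v[sel][-1] + flow$v[sel][-length(sel)]) / 2)
    } else if (length(sel) == 1) {
      flow$v[sel] * min(window_s, t_max - t0)
    } else 0
    data.frame(onset_s = t0, strength = events$strength[i],
               flow_integral = integral, truncated = truncated)
  })
  do.call(rbind, out)
}

#' Extrema of a measured velocity profile
#'
#' Estimates the extremal velocities and their positions from a measured
#' (noisy) dorso-ventral profile: row means are first smoothed with a
#' count-weighted running mean over `smooth` rows, which suppresses the
#' upward bias that taking a plain maximum over many noisy rows would
#' introduce.
#'
#' @param profile a `velocity_profile`.
#' @param smooth odd window length in rows (default 5).
#' @param min_n rows with fewer events are ignored (default 5).
#' @return A list: `vmax`, `y_vmax_um`, `vmin`, `y_vmin_um`.
#' @export
measured_profile_extrema <- function(profile, smooth = 5, min_n = 5) {
  stopifnot(inherits(profile, "velocity_profile"))
  p <- profile[profile$n >= min_n, ]
  if (nrow(p) < 3) stop("too few well-supported rows", call. = FALSE)
  half <- (smooth - 1) %/% 2
  sm <- vapply(seq_len(nrow(p)), function(i) {
    sel <- max(1, i - half):min(nrow(p), i + half)
    sum(p$mean_v[sel] * p$n[sel]) / sum(p$n[sel])
  }, numeric(1))
  list(vmax = max(sm), y_vmax_um = p$y_um[which.max(sm)],
       vmin = min(sm), y_vmin_um = p$y_um[which.min(sm)])
}
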