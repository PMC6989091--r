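#' Minimal particle tracking velocimetry
#'
#' Detects beads in every frame (threshold at mean + 2 sd, 8-connected
#' segmentation, Gaussian subpixel localization by 3-point log-parabola
#' interpolation of each region's peak) and links detections between frames
#' with an exact optimal assignment minimizing the total squared
#' displacement, gated at `gate_px` per frame. Trajectories may bridge a
#' single missing frame; shorter gaps terminate the track. Only trajectories
#' longer than `min_len` points are kept.
#'
#' @param video a `bead_video`.
#' @param gate_px maximum displacement per frame, px (default 5).
#' @param min_len minimum trajectory length in time points (default 6,
#'   i.e. more than 5).
#' @param min_area minimum detection area, px (default 3).
#' @param threshold_k detection threshold in frame-sd units above the mean.
#' @return A list of class `ptv_tracks`: `tracks` (list of data.frames with
#'   `frame`, `x_px`, `y_px`), and `velocities` (data.frame per track:
#'   `vx_um_s`, `vy_um_s`, `n`).
#' @export
track_particles <- function(video, gate_px = 5, min_len = 6, min_area = 3,
                            threshold_k = 2) {
  stopifnot(inherits(video, "bead_video"))
  d <- dim(video$stack)
  detections <- lapply(seq_len(d[3]), function(f) {
    detect_beads(video$stack[, , f], min_area, threshold_k)
  })

  # active track bookkeeping: position, frames missed, history
  tracks <- list()
  active <- list()
  for (f in seq_len(d[3])) {
    det <- detections[[f]]
    if (length(active)) {
      pos <- do.call(rbind, lapply(active, function(a) a$pos))
      link <- if (nrow(det)) {
        gated_match(pos, as.matrix(det[, c("y_px", "x_px")]), gate_px)
      } else rep(NA_integer_, nrow(pos))
      new_active <- list()
      used <- integer(0)
      for (i in seq_along(active)) {
        a <- active[[i]]
        j <- link[i]
        if (!is.na(j)) {
          a$pos <- c(det$y_px[j], det$x_px[j])
          a$hist <- rbind(a$hist, c(f, det$x_px[j], det$y_px[j]))
          a$missed <- 0
          new_active[[length(new_active) + 1]] <- a
          used <- c(used, j)
        } else if (a$missed < 1) {
          a$missed <- a$missed + 1            # bridge one missing frame
          new_active[[length(new_active) + 1]] <- a
        } else {
          tracks[[length(tracks) + 1]] <- a$hist
        }
      }
      if (nrow(det)) {
        for (j in setdiff(seq_len(nrow(det)), used)) {
          new_active[[length(new_active) + 1]] <-
            list(pos = c(det$y_px[j], det$x_px[j]),
                 hist = matrix(c(f, det$x_px[j], det$y_px[j]), 1),
                 missed = 0)
        }
      }
      active <- new_active
    } else if (nrow(det)) {
      active <- lapply(seq_len(nrow(det)), function(j) {
        list(pos = c(det$y_px[j], det$x_px[j]),
             hist = matrix(c(f, det$x_px[j], det$y_px[j]), 1),
             missed = 0)
      })
    }
  }
  for (a in active) tracks[[length(tracks) + 1]] <- a$hist

  tracks <- Filter(function(h) nrow(h) >= min_len, tracks)
  tracks <- lapply(tracks, function(h) {
    df <- as.data.frame(h); names(df) <- c("frame", "x_px", "y_px"); df
  })
  px <- video$pixel_size_um; dt <- video$frame_interval_s
  velocities <- do.call(rbind, lapply(tracks, function(tr) {
    tt <- tr$frame * dt
    data.frame(vx_um_s = unname(stats::coef(stats::lm(tr$x_px ~ tt))[2]) * px,
               vy_um_s = unname(stats::coef(stats::lm(tr$y_px ~ tt))[2]) * px,
               n = nrow(tr))
  }))
  structure(list(tracks = tracks, velocities = velocities),
            class = "ptv_tracks")
}

# single-frame bead detection with Gaussian subpixel refinement
detect_beads <- function(frame, min_area = 3, threshold_k = 2) {
  thr <- mean(frame) + threshold_k * stats::sd(frame)
  mask <- frame > thr
  empty <- data.frame(x_px = numeric(), y_px = numeric(), area = integer())
  if (!any(mask)) return(empty)
  lab <- label8(mask)
  out <- lapply(label_coords(lab), function(co) {
    co <- as.matrix(co)
    if (nrow(co) < min_area) return(NULL)
    vals <- frame[co]
    pk <- co[which.max(vals), ]
    data.frame(x_px = subpixel_peak(frame, pk[1], pk[2], 2),
               y_px = subpixel_peak(frame, pk[1], pk[2], 1),
               area = nrow(co))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else out
}

# 3-point Gaussian (log-parabola) interpolation of a peak along one axis
subpixel_peak <- function(frame, r, c, axis) {
  idx <- if (axis == 1) r else c
  n <- if (axis == 1) nrow(frame) else ncol(frame)
  if (idx <= 1 || idx >= n) return(idx)
  g <- function(o) {
    v <- if (axis == 1) frame[r + o, c] else frame[r, c + o]
    max(v, 1e-12)
  }
  l1 <- log(g(-1)); l2 <- log(g(0)); l3 <- log(g(1))
  den <- l1 - 2 * l2 + l3
  if (abs(den) < 1e-12) return(idx)
  idx + 0.5 * (l1 - l3) / den
}

#' Measure the canal diameter from a dye-filled z-stack
#'
#' Maximum-intensity projection, smoothing, Otsu threshold, and a
#' rotated-rectangle fit to the largest connected component: the width is
#' derived from the variance of the pixel coordinates across the canal's
#' principal axis (for a uniform band of width W the transverse variance is
#' W^2/12). This automates the manual rotated-rectangle measurement used on
#' maximum projections.
#'
#' @param zstack array `[y, x, z]` (or a matrix, e.g. a time-average image).
#' @param pixel_size_um pixel size, um.
#' @return A list: `diameter_um`, `tilt_deg` of the canal axis, `reliable`
#'   (FALSE when the width is below 3 px, the resolution floor).
#' @export
measure_canal_diameter <- function(zstack, pixel_size_um = 0.189) {
  if (is.matrix(zstack)) zstack <- array(zstack, c(dim(zstack), 1))
  mip <- apply(zstack, c(1, 2), max)
  if (max(mip) <= 0 || stats::sd(as.numeric(mip)) == 0) {
    stop("no canal-like region found (empty projection)", call. = FALSE)
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(mip / max(mip)), sigma = 1))
  sm <- pmin(pmax(sm, 0), 1)                # otsu needs [0, 1]
  thr <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > thr
  lab <- label8(mask)
  if (max(lab) == 0) stop("no canal-like region found", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  coords <- which(lab == which.max(sizes), arr.ind = TRUE)
  mom <- region_moments(coords)
  lambda_minor <- (mom$minor / 4)^2
  width_px <- sqrt(12 * lambda_minor)
  list(diameter_um = width_px * pixel_size_um,
       tilt_deg = atan2(mom$axis[1], mom$axis[2]) * 180 / pi,
       reliable = width_px >= 3)
}

#' Track an injected bead front on widefield images
#'
#' Low-pass filters each image, averages over the canal rows, and reports the
#' most caudal position along the canal where the intensity still exceeds
#' `threshold_frac` of the instantaneous peak. Distances are measured from
#' the injection site; a log-log slope of distance versus time is fitted
#' where at least 10 points are available.
#'
#' @param series array `[y, x, t]` of widefield frames.
#' @param times_min acquisition times, minutes post injection.
#' @param canal_rows row indices of the canal in the images.
#' @param x0_px injection-site column (default: peak of the first frame).
#' @param pixel_size_um pixel size, um.
#' @param threshold_frac front threshold (default 0.05 of peak).
#' @param blur_sigma low-pass Gaussian sigma, px.
#' @param fit_t_min earliest time (minutes) included in the slope fit;
#'   `NULL` uses all times. Early frames, where the front still reflects the
#'   initial bolus width rather than spreading, flatten the fitted exponent.
#' @return A list of class `bead_front`: data.frame `track`
#'   (`t_min`, `front_um`, NA where no front was detected), and `slope`
#'   (log-log, NA if too few points).
#' @export
track_bead_front <- function(series, times_min, canal_rows,
                             x0_px = NULL, pixel_size_um = 1,
                             threshold_frac = 0.05, blur_sigma = 2,
                             fit_t_min = NULL) {
  stopifnot(length(dim(series)) == 3, dim(series)[3] == length(times_min))
  nt <- dim(series)[3]
  profiles <- vapply(seq_len(nt), function(f) {
    img <- EBImage::Image(series[, , f])
    sm <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
    colMeans(sm[canal_rows, , drop = FALSE])
  }, numeric(dim(series)[2]))                 # nx x nt
  if (is.null(x0_px)) x0_px <- which.max(profiles[, 1])
  front <- vapply(seq_len(nt), function(f) {
    p <- profiles[, f]
    pk <- max(p)
    if (!(pk > 0)) return(NA_real_)
    above <- which(p >= threshold_frac * pk)
    above <- above[above >= x0_px]
    if (!length(above)) return(NA_real_)
    (max(above) - x0_px) * pixel_size_um
  }, numeric(1))
  ok <- !is.na(front) & front > 0 & times_min > 0
  if (!is.null(fit_t_min)) ok <- ok & times_min >= fit_t_min
  slope <- if (sum(ok) >= 10) {
    unname(stats::coef(stats::lm(log(front[ok]) ~ log(times_min[ok])))[2])
  } else NA_real_
  structure(list(track = data.frame(t_min = times_min, front_um = front),
                 slope = slope),
            class = "bead_front")
}
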