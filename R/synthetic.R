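#' Specification for a synthetic bead video
#'
#' Defaults emulate the study's acquisition settings: 10 Hz for 30 s at
#' 189 nm/px, an ~8.9 um canal carrying the bidirectional biparabolic flow
#' with ~5 um/s extrema, and 20 nm-radius tracer beads whose Brownian
#' diffusivity follows from the Stokes-Einstein relation at 301 K.
#'
#' @param seed mandatory random seed (reproducibility is byte-exact given the
#'   seed).
#' @param d_um canal diameter, um.
#' @param length_um rostro-caudal field of view, um.
#' @param pixel_size_um pixel size, um.
#' @param frame_rate_hz frame rate, Hz.
#' @param duration_s recording duration, s.
#' @param profile a `flow_profile`, or `NULL` for the default two-region
#'   solution with `fv = 4000 N/m^3` in this geometry.
#' @param bead_radius_m bead radius, m (diffusivity via [stokes_einstein()]).
#' @param D_m2_s override for the Brownian diffusivity (NULL = Stokes-Einstein).
#' @param n_beads number of beads in the field of view.
#' @param brightness peak bead intensity above background.
#' @param psf_sigma_px Gaussian point-spread sigma, px.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param margin_um image margin beyond each canal wall, um.
#' @param temperature_k temperature for the Stokes-Einstein relation, K.
#' @return A list of class `bead_video_spec`.
#' @export
bead_video_spec <- function(seed, d_um = 8.9, length_um = 30,
                            pixel_size_um = 0.189, frame_rate_hz = 10,
                            duration_s = 30, profile = NULL,
                            bead_radius_m = 20e-9, D_m2_s = NULL,
                            n_beads = 60, brightness = 40, psf_sigma_px = 1.2,
                            noise_sd = 2, margin_um = 2,
                            temperature_k = 301) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(profile)) {
    profile <- solve_two_region(model_params(d = d_um * 1e-6,
                                             h = d_um * 1e-6 / 2, fv = 4000))
  }
  if (is.null(D_m2_s)) D_m2_s <- stokes_einstein(bead_radius_m, temperature_k)
  structure(as.list(environment()), class = "bead_video_spec")
}

#' Generate a synthetic bead video with planted ground truth
#'
#' Beads advect with the planted velocity profile `v(y) dt` and take Gaussian
#' Brownian steps `N(0, 2 D dt)` per axis; the canal walls are reflective and
#' the field of view periodic along x. Frames are rendered as Gaussian spots
#' over a dark background with additive Gaussian read noise.
#'
#' @param spec a [bead_video_spec()].
#' @return A list: `video` (a [bead_video()]), `truth` (data.frame of
#'   per-frame true bead positions: `frame`, `bead`, `x_um`, `y_um`,
#'   `v_um_s` -- the planted local flow speed at the bead), `spec`.
#' @export
make_bead_video <- function(spec) {
  stopifnot(inherits(spec, "bead_video_spec"))
  set.seed(spec$seed)
  d <- spec$d_um; Lx <- spec$length_um
  dt <- 1 / spec$frame_rate_hz
  nt <- round(spec$duration_s * spec$frame_rate_hz)
  D_um <- spec$D_m2_s * 1e12                  # um^2/s
  step_sd <- sqrt(2 * D_um * dt)
  nb <- spec$n_beads

  # coverage check: warn when spots overlap heavily (velocimetry degrades)
  spot_area <- pi * (2 * spec$psf_sigma_px * spec$pixel_size_um)^2
  if (nb * spot_area / (Lx * d) > 0.5) {
    warning("bead density high enough that spots overlap substantially")
  }

  xb <- stats::runif(nb, 0, Lx)
  yb <- stats::runif(nb, 0, d)
  vfun <- function(y) evaluate_profile(spec$profile, pmin(pmax(y, 0), d) * 1e-6) * 1e6

  px <- spec$pixel_size_um
  ny_px <- round((d + 2 * spec$margin_um) / px)
  nx_px <- round(Lx / px)
  y_off <- spec$margin_um                      # canal wall y=0 at this image y
  stack <- array(0, c(ny_px, nx_px, nt))
  truth <- vector("list", nt)

  # gaussian kernel footprint
  ks <- ceiling(4 * spec$psf_sigma_px)
  for (f in seq_len(nt)) {
    truth[[f]] <- data.frame(frame = f, bead = seq_len(nb),
                             x_um = xb, y_um = yb, v_um_s = vfun(yb))
    frame <- matrix(0, ny_px, nx_px)
    cx <- xb / px + 0.5
    cy <- (yb + y_off) / px + 0.5
    for (b in seq_len(nb)) {
      r0 <- max(1, floor(cy[b] - ks)); r1 <- min(ny_px, ceiling(cy[b] + ks))
      c0 <- max(1, floor(cx[b] - ks)); c1 <- min(nx_px, ceiling(cx[b] + ks))
      if (r1 < r0 || c1 < c0) next
      rr <- r0:r1; cc <- c0:c1
      frame[rr, cc] <- frame[rr, cc] + spec$brightness *
        exp(-((rr - cy[b])^2) / (2 * spec$psf_sigma_px^2)) %o%
        exp(-((cc - cx[b])^2) / (2 * spec$psf_sigma_px^2))
    }
    frame <- frame + matrix(stats::rnorm(ny_px * nx_px, 10, spec$noise_sd),
                            ny_px, nx_px)
    stack[, , f] <- frame

    # advance beads: advection + Brownian step, reflective walls, periodic x
    xb <- (xb + vfun(yb) * dt + stats::rnorm(nb, 0, step_sd)) %% Lx
    yb <- reflect(yb + stats::rnorm(nb, 0, step_sd), 0, d)
  }
  list(video = bead_video(stack, px, dt),
       truth = do.call(rbind, truth), spec = spec)
}

# reflect positions into [lo, hi]
reflect <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

#' Generate a synthetic oscillating-cilia video
#'
#' Each cilium is rendered as a bright segment anchored at its base point,
#' swinging about its mean orientation at its beat frequency. Defaults
#' emulate the cilia acquisition settings (100 Hz for 3 s).
#'
#' @param seed random seed.
#' @param cilia data.frame with columns `x_um`, `y_um` (base point),
#'   `length_um`, `theta_deg` (mean tilt from the dorso-ventral axis, signed
#'   toward caudal), `freq_hz`, `phase` (rad), `side` ("ventral"/"dorsal").
#' @param fov_um c(width, height) of the field of view, um.
#' @param midline_row_um y position of the canal midline, um.
#' @param pixel_size_um pixel size, um.
#' @param frame_rate_hz frame rate, Hz (default 100).
#' @param duration_s duration, s (default 3).
#' @param swing_deg half-amplitude of the angular swing (default 12).
#' @param brightness,psf_sigma_px,noise_sd rendering parameters.
#' @return A list: `video` (class `cilia_video`: `stack`, `frame_rate_hz`,
#'   `pixel_size_um`, `midline_row`), `truth` (the cilia table), `seed`.
#' @export
make_cilia_video <- function(seed, cilia, fov_um = c(40, 25),
                             midline_row_um = 12.5, pixel_size_um = 0.189,
                             frame_rate_hz = 100, duration_s = 3,
                             swing_deg = 12, brightness = 30,
                             psf_sigma_px = 1, noise_sd = 1.5) {
  set.seed(seed)
  if (any(cilia$freq_hz >= frame_rate_hz / 2)) {
    warning("planted frequencies at or above Nyquist will alias")
  }
  px <- pixel_size_um
  nx <- round(fov_um[1] / px); ny <- round(fov_um[2] / px)
  nt <- round(duration_s * frame_rate_hz)
  stack <- array(0, c(ny, nx, nt))
  tvec <- (seq_len(nt) - 1) / frame_rate_hz
  nseg <- 40
  for (f in seq_len(nt)) {
    frame <- matrix(0, ny, nx)
    for (i in seq_len(nrow(cilia))) {
      ci <- cilia[i, ]
      ang <- (ci$theta_deg + swing_deg * sin(2 * pi * ci$freq_hz * tvec[f] +
                                               ci$phase)) * pi / 180
      # theta measured from the dorso-ventral (y) axis, positive toward
      # caudal; ventral cilia are anchored near the bottom wall (large y) and
      # extend upward into the canal, dorsal ones the opposite
      s <- seq(0, ci$length_um, length.out = nseg)
      ys <- ci$y_um + s * cos(ang) * (if (identical(ci$side, "ventral")) -1 else 1)
      xs <- ci$x_um + s * sin(ang)
      rr <- round(ys / px + 0.5); cc <- round(xs / px + 0.5)
      ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
      frame[cbind(rr[ok], cc[ok])] <- brightness
    }
    frame <- as.matrix(EBImage::gblur(EBImage::Image(frame),
                                      sigma = psf_sigma_px))
    stack[, , f] <- frame + matrix(stats::rnorm(ny * nx, 5, noise_sd), ny, nx)
  }
  video <- structure(list(stack = stack, frame_rate_hz = frame_rate_hz,
                          pixel_size_um = px,
                          midline_row = round(midline_row_um / px)),
                     class = "cilia_video")
  list(video = video, truth = cilia, seed = seed)
}

#' Generate a dye-filled canal phantom z-stack
#'
#' A bright band of the given width and tilt over a dark background, with
#' per-slice intensity falling away from the focal plane and Gaussian noise.
#'
#' @param seed random seed.
#' @param d_um planted canal width, um.
#' @param tilt_deg band tilt from horizontal, degrees.
#' @param fov_um c(width, height), um.
#' @param nz number of z slices.
#' @param pixel_size_um pixel size, um.
#' @param noise_sd Gaussian noise sd.
#' @param brightness in-focus band intensity.
#' @return A list: `stack` (`[y, x, z]`), `truth` (d_um), parameters.
#' @export
make_canal_phantom <- function(seed, d_um = 8.9, tilt_deg = 0,
                               fov_um = c(50, 30), nz = 30,
                               pixel_size_um = 0.189, noise_sd = 2,
                               brightness = 50) {
  set.seed(seed)
  px <- pixel_size_um
  nx <- round(fov_um[1] / px); ny <- round(fov_um[2] / px)
  yc <- fov_um[2] / 2
  th <- tilt_deg * pi / 180
  xg <- ((seq_len(nx)) - 0.5) * px
  yg <- ((seq_len(ny)) - 0.5) * px
  # signed distance of each pixel from the band mid-line
  dist <- outer(yg, xg, function(y, x) (y - yc) * cos(th) - (x - fov_um[1] / 2) * sin(th))
  band <- abs(dist) <= d_um / 2
  stack <- array(0, c(ny, nx, nz))
  for (z in seq_len(nz)) {
    focus <- exp(-((z - (nz + 1) / 2)^2) / (2 * (nz / 4)^2))
    stack[, , z] <- band * brightness * focus +
      matrix(stats::rnorm(ny * nx, 5, noise_sd), ny, nx)
  }
  list(stack = stack, truth = d_um, tilt_deg = tilt_deg,
       pixel_size_um = px, seed = seed)
}

#' Generate a transmitted-light intensity series with contraction artifacts
#'
#' The mean-intensity series carries planted bursts of absolute derivative
#' (the imaging signature of a muscle contraction); an accompanying
#' section-averaged flow series shows, for each event, a fast pulse in the
#' contraction direction followed by a slower exponential counter-flow of
#' opposite sign.
#'
#' @param seed random seed.
#' @param duration_s series duration, s.
#' @param frame_rate_hz sampling rate, Hz.
#' @param events data.frame with `onset_s`, `derivative` (planted |dI/dt| per
#'   frame), `duration_s`, `pulse_v_um_s` (peak flow during the event),
#'   `counter_tau_s` (decay time of the counter-flow).
#' @param noise_sd intensity noise (default 0, so planted strengths are
#'   recovered exactly).
#' @return A list: `intensity` (vector), `flow` (data.frame `t`, `v`),
#'   `events`, `frame_rate_hz`, `seed`.
#' @export
make_contraction_series <- function(seed, duration_s = 60, frame_rate_hz = 10,
                                    events = NULL, noise_sd = 0) {
  set.seed(seed)
  nt <- round(duration_s * frame_rate_hz)
  dt <- 1 / frame_rate_hz
  tvec <- (seq_len(nt) - 1) * dt
  if (is.null(events)) {
    events <- data.frame(onset_s = c(15, 40), derivative = c(10, 8),
                         duration_s = c(0.5, 0.3), pulse_v_um_s = c(12, 8),
                         counter_tau_s = c(2, 2))
  }
  if (any(events$onset_s + events$duration_s > duration_s)) {
    warning("events extending beyond the series are truncated")
  }
  dI <- numeric(nt - 1)
  flow <- numeric(nt)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    i0 <- floor(ev$onset_s / dt) + 1
    i1 <- min(i0 + round(ev$duration_s / dt) - 1, nt - 1)
    sgn <- rep_len(c(1, -1), i1 - i0 + 1)     # shaking: alternating sign
    dI[i0:i1] <- ev$derivative * sgn
    # flow: pulse during the event, then exponential counter-flow
    during <- seq_len(nt) >= i0 & seq_len(nt) <= i1
    flow[during] <- flow[during] + ev$pulse_v_um_s
    after <- which(seq_len(nt) > i1)
    ta <- (after - i1 - 1) * dt
    amp <- ev$pulse_v_um_s * ev$duration_s / ev$counter_tau_s
    flow[after] <- flow[after] - amp * exp(-ta / ev$counter_tau_s)
  }
  intensity <- cumsum(c(100, dI))
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(nt, 0, noise_sd)
  list(intensity = intensity, flow = data.frame(t = tvec, v = flow),
       events = events, frame_rate_hz = frame_rate_hz, seed = seed)
}

#' Render transport snapshots as a widefield image series
#'
#' Draws the x-marginal concentration of a transport simulation along a
#' horizontal canal in low-resolution widefield-like images, for validating
#' the bead-front tracker against the simulation it came from.
#'
#' @param cf a `conc_field` from [simulate_transport()].
#' @param seed random seed for the added noise.
#' @param ny_im,nx_im image size, px.
#' @param canal_rows rows occupied by the canal.
#' @param noise_sd Gaussian noise sd relative to unit peak (default 0.01).
#' @return A list: `series` (`[y, x, t]`), `times_min`, `x0_px`,
#'   `pixel_size_um`, `canal_rows`.
#' @export
make_front_series <- function(cf, seed = 1, ny_im = 32, nx_im = 256,
                              canal_rows = 14:18, noise_sd = 0.01) {
  stopifnot(inherits(cf, "conc_field"))
  set.seed(seed)
  nt <- length(cf$times)
  series <- array(0, c(ny_im, nx_im, nt))
  # resample marginals onto the image grid
  xi <- seq(min(cf$x), max(cf$x), length.out = nx_im)
  pk <- max(cf$marginals)
  for (f in seq_len(nt)) {
    prof <- stats::approx(cf$x, cf$marginals[f, ], xout = xi)$y / pk
    img <- matrix(0, ny_im, nx_im)
    img[canal_rows, ] <- matrix(prof, length(canal_rows), nx_im, byrow = TRUE)
    series[, , f] <- img + matrix(stats::rnorm(ny_im * nx_im, 0, noise_sd),
                                  ny_im, nx_im)
  }
  x0_px <- which.min(abs(xi - cf$x0))
  list(series = series, times_min = cf$times / 60, x0_px = x0_px,
       pixel_size_um = (xi[2] - xi[1]) * 1e6, canal_rows = canal_rows)
}
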