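#' Per-pixel beat-frequency map of a cilia video
#'
#' A 4 x 4 spatial sliding average raises the local signal-to-noise ratio,
#' then the temporal Fourier transform of every averaged pixel is computed
#' and the dominant non-DC peak extracted. Bins below `f_min` (slow drift)
#' and above Nyquist are excluded; signals above Nyquist alias in the usual
#' way (a 60 Hz beat sampled at 100 Hz appears at 40 Hz).
#'
#' @param video a `cilia_video` (fields `stack` `[y, x, t]`, `frame_rate_hz`,
#'   `pixel_size_um`, `midline_row`).
#' @param f_min lowest reportable frequency, Hz (default 2).
#' @param box spatial averaging box size, px (default 4).
#' @return An object of class `freq_map`: matrices `freq` (Hz; NA where no
#'   non-DC power) and `amp` (spectral amplitude of the dominant peak), the
#'   frequency resolution `df`, `nyquist`, and video metadata.
#' @export
frequency_map <- function(video, f_min = 2, box = 4) {
  stk <- video$stack
  d <- dim(stk)
  if (d[3] < 32) {
    stop("need at least 32 frames for a usable frequency resolution",
         call. = FALSE)
  }
  sm <- array(0, d)
  for (f in seq_len(d[3])) sm[, , f] <- box_mean(stk[, , f], box)
  mat <- matrix(sm, d[1] * d[2], d[3])        # pixels x time
  sp <- Mod(stats::mvfft(t(mat)))             # time-FFT per pixel: nt x npix
  nt <- d[3]
  freqs <- (seq_len(nt) - 1) * video$frame_rate_hz / nt
  nyq <- video$frame_rate_hz / 2
  keep <- which(freqs > f_min & freqs <= nyq)
  sub <- sp[keep, , drop = FALSE]
  imax <- max.col(t(sub))                     # dominant bin per pixel
  amp <- 2 * sub[cbind(imax, seq_len(ncol(sub)))] / nt
  fr <- freqs[keep][imax]
  fr[amp <= 0] <- NA_real_
  structure(list(freq = matrix(fr, d[1], d[2]),
                 amp = matrix(amp, d[1], d[2]),
                 df = video$frame_rate_hz / nt, nyquist = nyq,
                 frame_rate_hz = video$frame_rate_hz,
                 pixel_size_um = video$pixel_size_um,
                 midline_row = video$midline_row),
            class = "freq_map")
}

# sliding k x k box mean with edge clamping (integral-image based)
box_mean <- function(m, k = 4) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  lo <- -(k %/% 2); hi <- lo + k - 1
  r0 <- pmax(seq_len(nr) + lo, 1); r1 <- pmin(seq_len(nr) + hi, nr)
  c0 <- pmax(seq_len(nc) + lo, 1); c1 <- pmin(seq_len(nc) + hi, nc)
  A <- ii[r1 + 1, c1 + 1, drop = FALSE]
  B <- ii[r0, c1 + 1, drop = FALSE]
  C <- ii[r1 + 1, c0, drop = FALSE]
  D <- ii[r0, c0, drop = FALSE]
  cnt <- outer(r1 - r0 + 1, c1 - c0 + 1)
  (A - B - C + D) / cnt
}

#' Segment constant-frequency cilia regions
#'
#' Pixels whose dominant-peak amplitude clears a robust noise floor
#' (median + `amp_k` x MAD of the amplitude map) are binned into 5 Hz
#' frequency bands (5-10, 10-15, ... up to Nyquist); 8-connected components
#' with at least `min_area` pixels are kept as individual cilia sweep
#' regions.
#'
#' @param fmap a `freq_map`.
#' @param min_area minimum region area, px (default 200, about 3 um across).
#' @param band_hz band width, Hz (default 5).
#' @param band_start first band edge, Hz (default 5).
#' @param amp_k robust amplitude-mask factor (default 3).
#' @return A list of regions, each with `coords` (pixel indices), `freq_hz`
#'   (mean in-region dominant frequency), `band` = c(lo, hi).
#' @export
segment_cilia_regions <- function(fmap, min_area = 200, band_hz = 5,
                                  band_start = 5, amp_k = 3) {
  stopifnot(inherits(fmap, "freq_map"))
  amp <- fmap$amp
  noise <- stats::median(amp, na.rm = TRUE) +
    amp_k * stats::mad(amp, na.rm = TRUE)
  good <- !is.na(fmap$freq) & amp > noise
  regions <- list()
  lo_edges <- seq(band_start, fmap$nyquist - band_hz, by = band_hz)
  for (lo in lo_edges) {
    hi <- lo + band_hz
    mask <- good & fmap$freq >= lo & fmap$freq < hi
    if (!any(mask)) next
    lab <- label8(mask)
    for (co in label_coords(lab)) {
      co <- as.matrix(co)
      if (nrow(co) < min_area) next
      regions[[length(regions) + 1]] <-
        list(coords = co, freq_hz = mean(fmap$freq[co]), band = c(lo, hi))
    }
  }
  regions
}

#' Geometric properties of a segmented cilium region
#'
#' Fits the ellipse-equivalent second moments of the swept region: the major
#' axis approximates the cilium length `L`, the orientation `theta` is the
#' signed angle between the major axis and the dorso-ventral axis (positive =
#' tilted toward caudal), and the beating height is `L |cos theta|` -- the
#' dorso-ventral extent the beating cilium occupies. The side is assigned by
#' comparing the centroid with the canal midline (rows below the midline in
#' the image, i.e. larger row indices, are ventral).
#'
#' @param region one region from [segment_cilia_regions()].
#' @param pixel_size_um pixel size, um.
#' @param midline_row midline row index.
#' @return A one-row data.frame: `freq_hz`, `theta_deg`, `length_um`,
#'   `height_um`, `side`, `area_px`, `row`, `col` (centroid).
#' @export
cilium_properties <- function(region, pixel_size_um, midline_row) {
  mom <- region_moments(region$coords)
  L <- mom$major * pixel_size_um
  theta <- atan2(mom$axis[2], mom$axis[1])    # from the D-V (row) axis
  side <- if (mom$centroid[1] > midline_row) "ventral" else "dorsal"
  # sign convention: positive theta = tilted toward caudal, for a cilium
  # extending from its base wall into the canal; the canonical image-plane
  # angle (row component >= 0) points toward the ventral wall, so it is
  # negated for ventral cilia
  theta_deg <- theta * 180 / pi * (if (side == "ventral") -1 else 1)
  data.frame(freq_hz = region$freq_hz,
             theta_deg = theta_deg,
             length_um = L,
             height_um = L * abs(cos(theta)),
             side = side,
             area_px = mom$area,
             row = mom$centroid[1], col = mom$centroid[2])
}

#' Full cilia analysis of a video
#'
#' [frequency_map()] + [segment_cilia_regions()] + [cilium_properties()].
#'
#' @param video a `cilia_video`.
#' @param ... passed to [segment_cilia_regions()].
#' @return A data.frame of per-cilium properties (possibly 0 rows).
#' @export
map_cilia <- function(video, ...) {
  fmap <- frequency_map(video)
  regions <- segment_cilia_regions(fmap, ...)
  if (!length(regions)) {
    return(data.frame(freq_hz = numeric(), theta_deg = numeric(),
                      length_um = numeric(), height_um = numeric(),
                      side = character(), area_px = integer(),
                      row = numeric(), col = numeric()))
  }
  out <- do.call(rbind, lapply(regions, cilium_properties,
                               pixel_size_um = video$pixel_size_um,
                               midline_row = video$midline_row))
  rownames(out) <- NULL
  out
}

#' Cohort summary of cilia properties
#'
#' Medians per side of frequency, |theta|, length and beating height, with
#' dispersion reported both as 0.5 sd (the reporting convention used for
#' cohort medians here) and plain sd, plus the ventral:dorsal count ratio.
#'
#' @param regions data.frame from [map_cilia()].
#' @return A list: `per_side` (data.frame) and `ventral_dorsal_ratio`.
#' @export
summarize_cilia <- function(regions) {
  if (nrow(regions) == 0) {
    return(list(per_side = data.frame(), ventral_dorsal_ratio = NA_real_))
  }
  per_side <- do.call(rbind, lapply(split(regions, regions$side), function(g) {
    s <- if (nrow(g) >= 2) stats::sd(g$freq_hz) else 0
    data.frame(side = g$side[1], n = nrow(g),
               freq_hz = stats::median(g$freq_hz),
               abs_theta_deg = stats::median(abs(g$theta_deg)),
               length_um = stats::median(g$length_um),
               height_um = stats::median(g$height_um),
               freq_half_sd = 0.5 * s,
               freq_sd = s)
  }))
  rownames(per_side) <- NULL
  nv <- sum(regions$side == "ventral"); nd <- sum(regions$side == "dorsal")
  list(per_side = per_side,
       ventral_dorsal_ratio = if (nd > 0) nv / nd else Inf)
}
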