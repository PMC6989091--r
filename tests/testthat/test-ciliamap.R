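# Cilia beat-frequency mapping: planted sinusoids, banding, properties.

# a minimal cilia_video with a block oscillating at each requested frequency
oscillating_video <- function(freqs, rate = 100, dur = 3, block = 12,
                              ny = 64, nx = 96, amp = 8, noise = 0.3,
                              seed = 1) {
  set.seed(seed)
  nt <- round(rate * dur)
  tt <- (seq_len(nt) - 1) / rate
  stack <- array(stats::rnorm(ny * nx * nt, 10, noise), c(ny, nx, nt))
  for (i in seq_along(freqs)) {
    r0 <- 8 + (i - 1) * (block + 10)
    rows <- r0:(r0 + block - 1); cols <- 20:(20 + block - 1)
    osc <- amp * sin(2 * pi * freqs[i] * tt)
    for (f in seq_len(nt)) stack[rows, cols, f] <- stack[rows, cols, f] + osc[f]
  }
  structure(list(stack = stack, frame_rate_hz = rate, pixel_size_um = 0.189,
                 midline_row = ny / 2), class = "cilia_video")
}

test_that("planted single-frequency signals are recovered within one bin", {
  vid <- oscillating_video(38.1)
  fm <- frequency_map(vid)
  region_freqs <- fm$freq[10:16, 22:28]
  expect_lt(max(abs(region_freqs - 38.1)), fm$df + 1e-9)
})

test_that("constant pixels carry no reportable frequency power", {
  vid <- oscillating_video(numeric(0), noise = 0)
  vid$stack[] <- 7
  fm <- frequency_map(vid)
  expect_true(all(fm$amp < 1e-10))
})

test_that("too-short recordings are refused", {
  vid <- oscillating_video(20, dur = 0.31)
  expect_error(frequency_map(vid), "32 frames")
})

test_that("signals above Nyquist alias as sampling theory dictates", {
  vid <- oscillating_video(60)                 # 60 Hz at 100 Hz -> 40 Hz
  fm <- frequency_map(vid)
  expect_equal(stats::median(fm$freq[10:16, 22:28]), 40, tolerance = 0.5)
  # nothing ever exceeds Nyquist
  expect_lte(max(fm$freq, na.rm = TRUE), fm$nyquist)
})

test_that("banded segmentation isolates planted cilia with correct bands", {
  vid <- oscillating_video(c(20, 40), block = 16)
  fm <- frequency_map(vid)
  regions <- segment_cilia_regions(fm)
  expect_equal(length(regions), 2)
  bands <- t(vapply(regions, `[[`, numeric(2), "band"))
  freqs <- sort(vapply(regions, `[[`, numeric(1), "freq_hz"))
  expect_equal(freqs, c(20, 40), tolerance = 0.5)
  expect_true(any(bands[, 1] == 20) && any(bands[, 1] == 40))
})

test_that("small regions are rejected by the area filter", {
  # a 9 x 9 block dilates to ~144 px under the 4 x 4 sliding average:
  # below the 200 px default, above a 100 px threshold
  vid <- oscillating_video(20, block = 9)
  fm <- frequency_map(vid)
  expect_equal(length(segment_cilia_regions(fm)), 0)
  expect_equal(length(segment_cilia_regions(fm, min_area = 100)), 1)
})

test_that("frequencies straddling a band edge split by dominant frequency", {
  vid <- oscillating_video(c(24.4, 25.6), block = 16)
  fm <- frequency_map(vid)
  regions <- segment_cilia_regions(fm)
  expect_equal(length(regions), 2)
  bands <- sort(vapply(regions, function(r) r$band[1], numeric(1)))
  expect_equal(bands, c(20, 25))
})

test_that("region geometry gives length, orientation, height and side", {
  # vertical (D-V-aligned) strip: theta = 0, height = length
  vert <- list(coords = cbind(10:49, rep(5, 40)), freq_hz = 20,
               band = c(20, 25))
  pv <- cilium_properties(vert, pixel_size_um = 0.189, midline_row = 60)
  expect_equal(abs(pv$theta_deg), 0, tolerance = 1e-9)
  expect_equal(pv$height_um, pv$length_um)
  expect_equal(pv$side, "dorsal")              # centroid above the midline
  # horizontal strip: |theta| = 90, height ~ 0
  horiz <- list(coords = cbind(rep(80, 40), 10:49), freq_hz = 20,
                band = c(20, 25))
  ph <- cilium_properties(horiz, 0.189, midline_row = 60)
  expect_equal(abs(ph$theta_deg), 90)
  expect_lt(ph$height_um / ph$length_um, 1e-6)
  expect_equal(ph$side, "ventral")
  # single-pixel degenerate region falls back to a defined orientation
  single <- list(coords = cbind(5, 5), freq_hz = 20, band = c(20, 25))
  ps <- cilium_properties(single, 0.189, 60)
  expect_false(is.na(ps$theta_deg))
})

test_that("planted cilia recover frequency, angle, length class and side", {
  cilia <- data.frame(
    x_um = c(6, 14, 22, 30, 10, 26), y_um = c(rep(23, 4), 3, 3),
    length_um = c(5.8, 5, 4.5, 6, 4.5, 5),
    theta_deg = c(30, 45, 62.6, 20, -25, 35),
    freq_hz = c(38.1, 20, 30, 45, 15, 12), phase = c(0, 1, 2, 3, 4, 5),
    side = c(rep("ventral", 4), "dorsal", "dorsal"))
  gen <- make_cilia_video(seed = 3, cilia = cilia)
  reg <- map_cilia(gen$video)
  expect_equal(nrow(reg), 6)
  reg <- reg[order(reg$col), ]
  truth <- cilia[order(cilia$x_um), ]
  df <- 1 / 3                                  # 3 s recording: 1/3 Hz bins
  expect_true(all(abs(reg$freq_hz - truth$freq_hz) <= df + 0.05))
  expect_equal(reg$side, truth$side)           # 100% side classification
  expect_true(all(abs(reg$theta_deg - truth$theta_deg) < 10))
  expect_true(all(reg$height_um <= reg$length_um + 1e-9))
  expect_true(all(reg$freq_hz <= 50))
  # beating height consistency: L |cos theta| within the swept-region excess
  expect_true(all(abs(reg$height_um -
                        reg$length_um * abs(cos(reg$theta_deg * pi / 180)))
                  < 1e-9))
})

test_that("side classification flips under midline reflection", {
  cilia <- data.frame(x_um = c(10, 28), y_um = c(22, 3),
                      length_um = c(5.8, 4.5), theta_deg = c(30, -25),
                      freq_hz = c(20, 40), phase = c(0, 1),
                      side = c("ventral", "dorsal"))
  gen <- make_cilia_video(seed = 3, cilia = cilia)
  reg <- map_cilia(gen$video)
  flipped <- gen$video
  flipped$stack <- flipped$stack[dim(flipped$stack)[1]:1, , , drop = FALSE]
  flipped$midline_row <- dim(flipped$stack)[1] - flipped$midline_row
  reg_f <- map_cilia(flipped)
  expect_equal(sort(reg$side), sort(ifelse(reg_f$side == "ventral",
                                           "dorsal", "ventral")))
})

test_that("detection is invariant under global intensity scaling", {
  vid <- oscillating_video(c(20, 40), block = 16)
  n1 <- length(segment_cilia_regions(frequency_map(vid)))
  vid5 <- vid; vid5$stack <- vid$stack * 5
  n5 <- length(segment_cilia_regions(frequency_map(vid5)))
  expect_equal(n1, n5)
})

test_that("cohort summaries report side medians and the count ratio", {
  reg <- data.frame(freq_hz = c(38, 40, 36, 12),
                    theta_deg = c(30, -32, 31, -25),
                    length_um = c(5, 6, 5.5, 4), height_um = c(4, 5, 4.5, 3.5),
                    side = c("ventral", "ventral", "ventral", "dorsal"),
                    area_px = 300, row = 1, col = 1)
  sm <- summarize_cilia(reg)
  v <- sm$per_side[sm$per_side$side == "ventral", ]
  expect_equal(v$freq_hz, 38)
  expect_equal(v$abs_theta_deg, 31)
  expect_equal(sm$ventral_dorsal_ratio, 3)
  # single region: medians are its values, dispersion 0
  s1 <- summarize_cilia(reg[4, ])
  expect_equal(s1$per_side$freq_hz, 12)
  expect_equal(s1$per_side$freq_sd, 0)
  # mixed-sign symmetric angles: median |theta| equals median of positives
  regs <- reg; regs$theta_deg <- c(30, -30, 31, -31)
  smx <- summarize_cilia(regs)
  expect_equal(smx$per_side[smx$per_side$side == "ventral", "abs_theta_deg"],
               30.5, tolerance = 1)
  # empty input
  expect_equal(nrow(summarize_cilia(reg[0, ])$per_side), 0)
})

test_that("videos without cilia yield an empty region table", {
  gen <- make_cilia_video(seed = 4, cilia = data.frame(
    x_um = numeric(), y_um = numeric(), length_um = numeric(),
    theta_deg = numeric(), freq_hz = numeric(), phase = numeric(),
    side = character()))
  expect_equal(nrow(map_cilia(gen$video)), 0)
})
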