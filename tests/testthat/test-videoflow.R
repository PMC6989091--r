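# Kymograph velocimetry: constructed-line oracles, the four trace filters,
# profiles, landmarks, contractions, and preprocessing.

test_that("a blank kymograph yields no events", {
  expect_equal(nrow(extract_traces(blank_kymograph())), 0)
})

test_that("constructed lines give exact slope-derived velocities", {
  # unit-slope single-pixel lines have exact second moments: velocity to
  # machine precision
  for (slope in c(1, -1)) {
    m <- draw_line(matrix(1, 100, 200), t0 = 10, x0 = 100, slope = slope,
                   len = 40)
    ev <- extract_traces(as_kymograph(m))
    expect_equal(nrow(ev), 1)
    expect_equal(ev$velocity_um_s, slope * 0.189 / 0.1, tolerance = 1e-9)
  }
  # steeper lines must be drawn wider to stay 8-connected; the finite width
  # perturbs the ellipse orientation only in the 4th decimal
  for (slope in c(2, 3)) {
    m <- draw_line(matrix(1, 100, 200), t0 = 10, x0 = 20, slope = slope,
                   len = 40, width = slope)
    ev <- extract_traces(as_kymograph(m))
    expect_equal(nrow(ev), 1)
    expect_equal(ev$velocity_um_s, slope * 0.189 / 0.1, tolerance = 1e-2)
  }
  # the canonical example: 2 px/frame -> 3.78 um/s, caudal-positive
  m <- draw_line(matrix(1, 100, 200), 10, 20, 2, 40, width = 2)
  expect_equal(extract_traces(as_kymograph(m))$velocity_um_s, 3.78,
               tolerance = 1e-2)
  # mirror image is negative
  m <- draw_line(matrix(1, 100, 200), 10, 150, -2, 40, width = 2)
  ev <- extract_traces(as_kymograph(m))
  expect_equal(ev$velocity_um_s, -2 * 0.189 / 0.1, tolerance = 1e-2)
})

test_that("the four filters reject distractors and keep exactly k lines", {
  m <- matrix(1, 120, 220)
  m <- draw_line(m, 5, 10, 2, 40, width = 2)   # valid
  m <- draw_line(m, 60, 120, 1, 30)            # valid
  m <- draw_line(m, 10, 200, 0, 40)            # stuck bead: vertical in time
  m[80, 30:70] <- 10                           # global flicker: horizontal
  m <- draw_line(m, 100, 40, 1, 8)             # too short (< 15 px)
  m[30:39, 150:159] <- 10                      # low-eccentricity blob
  ev <- extract_traces(as_kymograph(m))
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$velocity_um_s), c(1, 2) * 0.189 / 0.1, tolerance = 1e-2)
})

test_that("kymograph construction normalizes columns and encodes motion", {
  # constant video -> all-ones kymograph
  vid <- bead_video(array(7, c(20, 50, 30)))
  km <- build_kymograph(vid, 10)
  expect_equal(km$data, matrix(1, 30, 50))
  # a single bead drifting 1 px/frame appears as a unit-slope line
  stack <- array(1, c(21, 120, 40))
  for (f in 1:40) stack[10, 10 + f, f] <- 30
  ev <- extract_traces(build_kymograph(bead_video(stack), 10))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$velocity_um_s, 1 * 0.189 / 0.1, tolerance = 1e-6)
})

test_that("column normalization removes linear photobleaching", {
  stack <- array(0, c(21, 120, 40))
  decay <- seq(1, 0.4, length.out = 40)
  for (f in 1:40) {
    stack[, , f] <- 1 * decay[f]
    stack[10, 10 + f, f] <- 30 * decay[f]
  }
  km <- build_kymograph(bead_video(stack), 10)
  # line contrast against the same-time background is time-independent
  line_vals <- vapply(1:40, function(f) km$data[f, 10 + f], numeric(1))
  bg_vals <- vapply(1:40, function(f) km$data[f, 80 + f], numeric(1))
  contrast <- line_vals / bg_vals
  expect_lt(stats::sd(contrast) / mean(contrast), 0.02)
  # and the bleaching no longer floods the threshold mask: the trace is
  # still extracted with its exact velocity
  ev <- extract_traces(km)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$velocity_um_s, 1 * 0.189 / 0.1, tolerance = 1e-6)
})

test_that("border rows shrink the averaging window with a warning", {
  vid <- bead_video(array(1, c(10, 64, 5)))
  expect_warning(build_kymograph(vid, 1), "border")
  expect_error(build_kymograph(vid, 11), "row")
  expect_error(build_kymograph(vid, 5, window = 4), "odd")
})

test_that("velocity profiles aggregate events with correct SEM and order", {
  ev <- data.frame(velocity_um_s = c(2, 2, 2, -1, -3, 5),
                   row = c(3, 3, 3, 7, 7, 5),
                   time_s = 1:6, n_px = 20, eccentricity = 0.95,
                   theta_deg = 45)
  pr <- velocity_profile(ev, 0.189)
  expect_equal(pr$row, c(3, 5, 7))
  expect_equal(pr$mean_v, c(2, 5, -2))
  expect_equal(pr$sem[1], 0)                   # identical velocities
  expect_true(is.na(pr$sem[2]))                # single event
  expect_error(velocity_profile(ev[ev$row == 3, ]), "3 dorso-ventral rows")
})

test_that("landmarks normalize positions by the event-support rule", {
  ev <- synthetic_events(rows = 1:41, n_per_row = 10, vmax = 5)
  pr <- velocity_profile(ev, 0.189)
  lm <- profile_landmarks(pr)
  expect_true(lm$defined)
  expect_equal(lm$rel_zero, 0.5, tolerance = 0.05)
  expect_lt(lm$rel_vmax, lm$rel_zero)
  expect_gt(lm$rel_vmin, lm$rel_zero)
  # all-positive profile: no zero crossing, flagged undefined
  ev_pos <- ev; ev_pos$velocity_um_s <- abs(ev_pos$velocity_um_s) + 1
  expect_false(profile_landmarks(velocity_profile(ev_pos, 0.189))$defined)
  # support rule: rows with too few events cannot set the boundary
  ev_thin <- ev[ev$row > 3 | seq_len(nrow(ev)) %% 10 == 0, ]
  lm_thin <- profile_landmarks(velocity_profile(ev_thin, 0.189))
  expect_gte(lm_thin$row0, 4)
})

test_that("flow versus time is near zero for steady bidirectional flow", {
  ev <- synthetic_events(rows = 1:41, n_per_row = 20, vmax = 5)
  fl <- flow_vs_time(ev, bin_width_s = 5)
  expect_lt(max(abs(fl$v), na.rm = TRUE), 0.3)
  # planted unidirectional pulse shows as an excursion
  pulse <- data.frame(velocity_um_s = 8, row = 20,
                      time_s = seq(10, 12, by = 0.1), n_px = 20,
                      eccentricity = 0.95, theta_deg = 45)
  fl2 <- flow_vs_time(rbind(ev, pulse), bin_width_s = 5)
  expect_gt(fl2$v[fl2$t == 12.5], 0.5)
  expect_equal(nrow(flow_vs_time(ev[0, ], 1)), 0)
})

test_that("contraction detection recovers planted events exactly", {
  expect_equal(nrow(detect_contractions(rep(5, 100))), 0)
  # planted square artifact: derivative 10 for 5 frames -> strength 50
  I <- cumsum(c(100, rep(0, 19), rep(10, 5), rep(0, 30)))
  ev <- detect_contractions(I, threshold = 4, frame_interval_s = 0.1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$strength, 50)
  expect_equal(ev$duration_s, 0.5)
  # two pulses separated by a sub-threshold gap stay two events
  I2 <- cumsum(c(100, rep(0, 10), rep(10, 3), rep(1, 5), rep(-8, 3), rep(0, 20)))
  expect_equal(nrow(detect_contractions(I2, 4, 0.1)), 2)
})

test_that("post-contraction flux integrates the right window", {
  flow0 <- data.frame(t = seq(0, 30, 0.5), v = 0)
  evs <- data.frame(onset_s = 10, duration_s = 0.5, strength = 50)
  expect_equal(post_contraction_flux(flow0, evs)$flow_integral, 0)
  # planted counter-flow after the pulse: integral sign follows the flow
  cs <- make_contraction_series(seed = 1, events = data.frame(
    onset_s = 10, derivative = 10, duration_s = 0.5, pulse_v_um_s = 10,
    counter_tau_s = 2))
  det <- detect_contractions(cs$intensity, 4, 0.1)
  fx <- post_contraction_flux(cs$flow, det, window_s = 2.5)
  expect_equal(nrow(fx), 1)
  expect_false(fx$truncated)
  # window only over the decaying counter-flow: negative integral
  fx_late <- post_contraction_flux(cs$flow,
                                   transform(det, onset_s = onset_s + 1), 2.5)
  expect_lt(fx_late$flow_integral, 0)
  # event at the end of the recording is truncated
  fx_end <- post_contraction_flux(cs$flow,
                                  transform(det, onset_s = 59), 2.5)
  expect_true(fx_end$truncated)
})

test_that("preprocessing aligns, rotates exactly at right angles, and crops", {
  ph <- make_canal_phantom(seed = 6, d_um = 8.9, tilt_deg = 10,
                           fov_um = c(40, 30))
  stk <- array(rep(ph$stack[, , 15], 3), c(dim(ph$stack)[1:2], 3))
  bv <- bead_video(stk, ph$pixel_size_um, 0.1)
  # identity
  expect_identical(preprocess_video(bv, rotate = 0)$stack, bv$stack)
  # auto-alignment brings a 10-degree tilt below 1 degree
  aligned <- preprocess_video(bv)
  expect_lt(abs(csfflow:::estimate_tilt(aligned)), 1)
  # two quarter turns equal a half turn
  b2 <- preprocess_video(preprocess_video(bv, rotate = 90), rotate = 90)
  expect_identical(b2$stack, preprocess_video(bv, rotate = 180)$stack)
  # crop validation
  expect_error(preprocess_video(bv, rotate = 0,
                                crop = list(rows = 1:10, cols = 1:10000)),
               "crop")
})

test_that("denoising leaves clean frames intact and contracts pure noise", {
  set.seed(5)
  # noise-free frame: correlation > 0.99 after denoising
  spec <- bead_video_spec(seed = 3, n_beads = 20, noise_sd = 1e-9,
                          duration_s = 0.3)
  gen <- make_bead_video(spec)
  dn <- denoise(gen$video)
  f <- 1
  expect_gt(stats::cor(as.numeric(gen$video$stack[, , f]),
                       as.numeric(dn$stack[, , f])), 0.99)
  # pure-noise frame: variance shrinks
  noise <- array(stats::rnorm(96 * 96 * 2), c(96, 96, 2))
  dn2 <- denoise(bead_video(noise))
  expect_lt(stats::var(as.numeric(dn2$stack)), stats::var(as.numeric(noise)))
  # planted dim beads gain signal-to-noise
  spec3 <- bead_video_spec(seed = 9, n_beads = 15, brightness = 24,
                           noise_sd = 3, duration_s = 0.3)
  gen3 <- make_bead_video(spec3)
  tr <- gen3$truth[gen3$truth$frame == 1, ]
  px <- spec3$pixel_size_um
  rr <- round((tr$y_um + spec3$margin_um) / px + 0.5)
  cc <- round(tr$x_um / px + 0.5)
  ok <- rr >= 3 & rr <= nrow(gen3$video$stack[, , 1]) - 2 & cc >= 3 &
    cc <= ncol(gen3$video$stack[, , 1]) - 2
  snr <- function(m) (mean(m[cbind(rr[ok], cc[ok])]) - stats::median(m)) /
    stats::sd(m[1:6, ])                        # margin rows are background
  before <- snr(gen3$video$stack[, , 1])
  after <- snr(denoise(gen3$video)$stack[, , 1])
  expect_gt(after, before)
  # too-small frames skip with a warning
  expect_warning(denoise(bead_video(array(1, c(20, 20, 2)))), "64 px")
})

test_that("determinism: the same seed reproduces stacks and events exactly", {
  g1 <- make_bead_video(bead_video_spec(seed = 123, n_beads = 10,
                                        duration_s = 2))
  g2 <- make_bead_video(bead_video_spec(seed = 123, n_beads = 10,
                                        duration_s = 2))
  expect_identical(g1$video$stack, g2$video$stack)
  expect_identical(g1$truth, g2$truth)
  e1 <- scan_video_events(g1$video, rows = 20:25)
  e2 <- scan_video_events(g2$video, rows = 20:25)
  expect_identical(e1, e2)
})

test_that("end-to-end recovery is accurate when traces are resolvable", {
  # planted biparabolic profile with slow beads (trace displacement below
  # the PSF footprint per frame): the full pipeline recovers the extrema
  # within 15% and the zero crossing at mid-height
  spec <- bead_video_spec(seed = 1, D_m2_s = 0.05e-12, n_beads = 60)
  gen <- make_bead_video(spec)
  px <- spec$pixel_size_um
  wall0 <- round(spec$margin_um / px)
  wall1 <- round((spec$margin_um + spec$d_um) / px)
  vid <- preprocess_video(denoise(gen$video), rotate = 0,
                          crop = list(rows = (wall0 + 1):wall1,
                                      cols = seq_len(dim(gen$video$stack)[2])))
  ev <- scan_video_events(vid)
  pr <- velocity_profile(ev, px)
  ex <- measured_profile_extrema(pr)
  expect_equal(ex$vmax, 4.95, tolerance = 0.15)
  expect_equal(abs(ex$vmin), 4.95, tolerance = 0.15)
  lm <- profile_landmarks(pr)
  expect_true(lm$defined)
  expect_equal(lm$rel_zero, 0.5, tolerance = 0.12)
  # planted caudal ventral flow -> positive ventral means (sign convention)
  expect_gt(pr$mean_v[which.min(abs(pr$y_um - 2.2))], 0)
  expect_lt(abs(mean(ev$velocity_um_s)), 0.5)
})
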