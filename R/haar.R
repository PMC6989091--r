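# 2D Haar wavelet transform and level-dependent soft-threshold denoising.
# Used to raise the signal-to-noise ratio of dim fluorescent beads before
# kymograph slicing. Frames are reflect-padded to a multiple of 2^levels.

haar_step <- function(m) {
  odd <- seq(1, nrow(m), by = 2); even <- odd + 1
  a <- (m[odd, , drop = FALSE] + m[even, , drop = FALSE]) / sqrt(2)
  d <- (m[odd, , drop = FALSE] - m[even, , drop = FALSE]) / sqrt(2)
  list(a = a, d = d)
}

haar_unstep <- function(a, d) {
  out <- matrix(0, 2 * nrow(a), ncol(a))
  odd <- seq(1, nrow(out), by = 2)
  out[odd, ] <- (a + d) / sqrt(2)
  out[odd + 1, ] <- (a - d) / sqrt(2)
  out
}

# returns list of levels, each with detail subbands LH, HL, HH; plus final LL
haar_dwt2 <- function(m, levels) {
  out <- vector("list", levels)
  ll <- m
  for (l in seq_len(levels)) {
    r <- haar_step(ll)
    ra <- haar_step(t(r$a)); rd <- haar_step(t(r$d))
    out[[l]] <- list(LH = t(ra$d), HL = t(rd$a), HH = t(rd$d))
    ll <- t(ra$a)
  }
  list(details = out, LL = ll)
}

haar_idwt2 <- function(dec) {
  ll <- dec$LL
  for (l in rev(seq_along(dec$details))) {
    dd <- dec$details[[l]]
    a <- t(haar_unstep(t(ll), t(dd$LH)))
    d <- t(haar_unstep(t(dd$HL), t(dd$HH)))
    ll <- haar_unstep(a, d)
  }
  ll
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

# Haar denoising, decomposition level `levels`, with level-dependent soft
# thresholds. The noise scale is estimated once, robustly (MAD), from the
# finest diagonal subband -- which is essentially pure noise -- and the
# universal threshold sigma * sqrt(2 log N) is applied to every detail
# subband (an orthonormal transform keeps white-noise sigma constant across
# levels, while coherent image structure grows, so coarse-scale structure
# survives).
haar_denoise_frame <- function(frame, levels = 6) {
  nr <- nrow(frame); nc <- ncol(frame)
  # cap the depth so the coarsest scale still resolves structure smaller
  # than the frame (a level-6 decomposition needs frames of a few hundred
  # pixels; small crops use fewer levels)
  levels <- min(levels, max(1, floor(log2(min(nr, nc))) - 2))
  blk <- 2^levels
  pr <- (blk - nr %% blk) %% blk
  pc <- (blk - nc %% blk) %% blk
  padded <- frame
  if (pr > 0) padded <- rbind(padded, padded[nr:(nr - pr + 1), , drop = FALSE])
  if (pc > 0) padded <- cbind(padded, padded[, ncol(padded):(ncol(padded) - pc + 1), drop = FALSE])
  N <- length(padded)
  dec <- haar_dwt2(padded, levels)
  sigma <- stats::median(abs(dec$details[[1]]$HH)) / 0.6745
  thr <- sigma * sqrt(2 * log(N))
  for (l in seq_along(dec$details)) {
    for (b in c("LH", "HL", "HH")) {
      dec$details[[l]][[b]] <- soft_threshold(dec$details[[l]][[b]], thr)
    }
  }
  rec <- haar_idwt2(dec)
  rec[seq_len(nr), seq_len(nc), drop = FALSE]
}
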