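# Shared fixtures for the test suite. Everything is generated in code.

# canonical central-canal profile: d = 8.9 um, h = d/2, fv = 4000 N/m^3
canonical_profile <- function() {
  solve_two_region(model_params(d = 8.9e-6, h = 8.9e-6 / 2, fv = 4000))
}

# draw a straight line of given slope (columns per row) into a kymograph
# matrix; width broadens the line across columns
draw_line <- function(m, t0, x0, slope, len, width = 1, value = 10) {
  for (k in 0:(len - 1)) {
    r <- t0 + k
    c0 <- round(x0 + slope * k)
    for (w in 0:(width - 1)) {
      cc <- c0 + w
      if (r >= 1 && r <= nrow(m) && cc >= 1 && cc <= ncol(m)) m[r, cc] <- value
    }
  }
  m
}

# wrap a raw matrix as a kymograph object (already "normalized": background
# 1, lines above it)
as_kymograph <- function(mat, pixel_size_um = 0.189, frame_interval_s = 0.1) {
  structure(list(data = mat, row = 1L, window = 3L,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "kymograph")
}

blank_kymograph <- function(nt = 100, nx = 120) as_kymograph(matrix(1, nt, nx))

# brute-force optimal assignment by permutation enumeration (small n)
brute_force_assign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    cst <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (cst < best_cost) { best_cost <- cst; best <- p[seq_len(n)] }
  }
  list(assignment = best, cost = best_cost)
}

# events table for a planted symmetric bidirectional profile across rows
synthetic_events <- function(rows = 1:30, n_per_row = 10, vmax = 5) {
  d <- max(rows) - min(rows)
  do.call(rbind, lapply(rows, function(r) {
    xi <- (r - min(rows)) / d
    v <- if (xi <= 0.5) vmax * (8 * xi - 16 * xi^2) else
      -vmax * (8 * (1 - xi) - 16 * (1 - xi)^2)
    data.frame(velocity_um_s = rep(v, n_per_row), row = r,
               time_s = seq(0, 29, length.out = n_per_row),
               n_px = 20L, eccentricity = 0.95, theta_deg = 45)
  }))
}
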