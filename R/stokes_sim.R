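#' Describe a spatial pattern of ciliary forcing
#'
#' A periodic arrangement of ciliated patches along the ventral wall: each
#' period of length `w` carries one active segment of width `a` (centred in
#' the period) in which the fluid below `y = h` is pushed caudally with volume
#' force density `fv`. Per-period amplitudes may differ (`fv` recycled over
#' periods), which models neighbouring cilia beating at different frequencies.
#' The force profile across the ciliated layer is either constant in y or
#' decreasing linearly from `2 fv` at the wall to 0 at `y = h` (same total
#' force).
#'
#' @param w pattern period along the canal axis, m.
#' @param a active-segment width, m (`0 <= a <= w`); `a = w` is uniform
#'   forcing.
#' @param fv force amplitude(s), N/m^3; a vector is recycled over successive
#'   periods.
#' @param h ciliated-layer height, m.
#' @param shape `"constant"` or `"linear"` force profile in y.
#' @return An object of class `cilia_pattern`.
#' @export
cilia_pattern <- function(w, a = w, fv = 4000, h, shape = c("constant", "linear")) {
  shape <- match.arg(shape)
  stopifnot(w > 0, a >= 0, a <= w, h > 0, all(fv >= 0))
  structure(list(w = w, a = a, fv = fv, h = h, shape = shape),
            class = "cilia_pattern")
}

# Volume force fx(x, y) on the grid for a pattern (matrix ny x nx).
pattern_force <- function(pattern, x, y, Lx) {
  nx <- length(x); ny <- length(y)
  w <- pattern$w; a <- pattern$a; h <- pattern$h
  n_per <- as.integer(round(Lx / w))
  period_idx <- pmin(floor(x / w), n_per - 1L)           # 0-based period
  xin <- x - period_idx * w                              # position in period
  # fraction of each grid cell [x - dx/2, x + dx/2] covered by the active
  # segment, so the discrete pattern carries the exact active fraction a/w
  dxg <- x[2] - x[1]
  lo <- (w - a) / 2; hi <- (w + a) / 2
  cover <- function(xc) {
    l <- pmax(xc - dxg / 2, lo); r <- pmin(xc + dxg / 2, hi)
    pmax(r - l, 0) / dxg
  }
  active <- cover(xin) + cover(xin + w) + cover(xin - w)  # wrap neighbours
  amp <- rep_len(pattern$fv, n_per)[period_idx + 1L] * active
  # constant shape: half-weight a node sitting exactly on the interface so
  # the discrete force step is centred at y = h (keeps the solver 2nd order)
  dy <- y[2] - y[1]
  yprof <- if (pattern$shape == "constant") {
    ifelse(abs(y - h) < dy / 4, 0.5, as.numeric(y < h))
  } else {
    ifelse(y <= h, 2 * (1 - y / h), 0)
  }
  outer(yprof, amp)                                      # ny x nx
}

#' Solve 2D Stokes flow driven by a ciliary force pattern
#'
#' Steady incompressible Stokes flow in a channel `0 <= y <= d`, periodic in
#' x over `n_periods` repetitions of the forcing pattern, with no-slip walls
#' and zero net axial flux through every cross-section (the closed-canal
#' condition). The solver expands the force in Fourier modes along x. The
#' mean (k = 0) mode is a 1D two-point problem for the mean axial velocity
#' with a free global pressure gradient fixed by the flux constraint; each
#' k != 0 mode solves the streamfunction biharmonic equation
#' `mu (D^2 - k^2)^2 psi_k = -d f_k/dy` with clamped walls
#' (`psi = psi' = 0`). Pressure is recovered from the axial momentum balance.
#'
#' @param d channel diameter, m.
#' @param pattern a [cilia_pattern()].
#' @param mu dynamic viscosity, Pa.s.
#' @param n_periods number of pattern repetitions in the periodic domain
#'   (>= 3 recommended).
#' @param ny number of grid nodes across the diameter (wall to wall). Odd
#'   values place the mid-plane on a node; the default resolves `d` with 64
#'   intervals.
#' @param nx_per_period grid columns per pattern period (>= 48 recommended).
#' @return An object of class `flow_field`: grids `x`, `y`; matrices
#'   (ny x nx) `u`, `v`, `P`, `psi`; the global pressure gradient `dPdx`;
#'   and the geometry/pattern metadata.
#' @export
solve_stokes <- function(d, pattern, mu = 1e-3, n_periods = 3,
                         ny = 65, nx_per_period = 48) {
  stopifnot(inherits(pattern, "cilia_pattern"), d > 0, pattern$h < d)
  if (ny < 17) stop("grid must resolve the diameter with >= 16 intervals", call. = FALSE)
  if ((ny - 1) * pattern$h / d < 8) {
    warning("fewer than 8 grid cells across the ciliated layer; ",
            "solution may be under-resolved")
  }
  Lx <- n_periods * pattern$w
  nx <- n_periods * nx_per_period
  dx <- Lx / nx
  x <- (seq_len(nx) - 1) * dx
  y <- seq(0, d, length.out = ny)
  dy <- y[2] - y[1]

  fx <- pattern_force(pattern, x, y, Lx)                 # ny x nx

  # FFT along x (rows of t(fx)): f_hat[k+1, j] for mode k at height y_j
  f_hat <- t(stats::mvfft(t(fx))) / nx                   # ny x nx complex

  # --- k = 0 mean-flow mode: mu u0'' = G - f0(y), no slip, zero net flux ----
  f0 <- Re(f_hat[, 1])
  n_i <- ny - 2
  D2 <- diag(-2, n_i)
  if (n_i > 1) {
    idx <- seq_len(n_i - 1)
    D2[cbind(idx, idx + 1)] <- 1
    D2[cbind(idx + 1, idx)] <- 1
  }
  D2 <- D2 / dy^2
  up <- solve(D2, -f0[2:(ny - 1)] / mu)                  # particular: G = 0
  u1 <- solve(D2, rep(1 / mu, n_i))                      # response to unit G
  wts <- rep(dy, ny); wts[c(1, ny)] <- dy / 2            # trapezoid
  int_up <- sum(wts[2:(ny - 1)] * up)
  int_u1 <- sum(wts[2:(ny - 1)] * u1)
  G <- -int_up / int_u1
  u0 <- c(0, up + G * u1, 0)

  # --- k != 0 modes: biharmonic streamfunction solve ------------------------
  psi_hat <- matrix(0 + 0i, ny, nx)
  u_hat <- matrix(0 + 0i, ny, nx)
  u_hat[, 1] <- u0

  # discrete d/dy of f_hat (central interior, one-sided ends)
  dfdy <- function(fk) {
    g <- complex(length.out = ny)
    g[2:(ny - 1)] <- (fk[3:ny] - fk[1:(ny - 2)]) / (2 * dy)
    g[1] <- (fk[2] - fk[1]) / dy
    g[ny] <- (fk[ny] - fk[ny - 1]) / dy
    g
  }

  kmax <- nx %/% 2
  f_scale <- max(abs(f_hat))
  for (k in seq_len(kmax)) {
    fk <- f_hat[, k + 1]
    if (max(abs(fk)) < 1e-14 * f_scale) next             # empty harmonic
    kap <- 2 * pi * k / Lx
    # interior operator for (D^2 - kap^2)^2 with psi=0 at walls, psi'=0 ghosts
    M <- matrix(0, n_i, n_i)
    for (i in seq_len(n_i)) {
      # 4th derivative 5-point stencil on interior index i (global i+1)
      st <- c(1, -4, 6, -4, 1) / dy^4
      cols <- (i - 2):(i + 2)
      for (s in seq_along(cols)) {
        j <- cols[s]
        if (j >= 1 && j <= n_i) M[i, j] <- M[i, j] + st[s]
      }
      if (i == 1) M[i, 1] <- M[i, 1] + 1 / dy^4          # ghost psi_0 = psi_2
      if (i == n_i) M[i, n_i] <- M[i, n_i] + 1 / dy^4    # ghost at top wall
      # -2 kap^2 D2 + kap^4 I
      M[i, i] <- M[i, i] + 2 * kap^2 * 2 / dy^2 + kap^4
      if (i > 1) M[i, i - 1] <- M[i, i - 1] - 2 * kap^2 / dy^2
      if (i < n_i) M[i, i + 1] <- M[i, i + 1] - 2 * kap^2 / dy^2
    }
    rhs <- -dfdy(fk)[2:(ny - 1)] / mu
    pk <- solve(M, rhs)
    psik <- c(0 + 0i, pk, 0 + 0i)
    psi_hat[, k + 1] <- psik
    if (k < nx - k) psi_hat[, nx - k + 1] <- Conj(psik)
    # u = d psi / dy (central; one-sided at walls is 0 by clamping)
    uk <- complex(length.out = ny)
    uk[2:(ny - 1)] <- (psik[3:ny] - psik[1:(ny - 2)]) / (2 * dy)
    u_hat[, k + 1] <- uk
    if (k < nx - k) u_hat[, nx - k + 1] <- Conj(uk)
  }

  # streamfunction of the mean mode: cumulative trapezoid of u0
  psi0 <- cumsum(c(0, (u0[-1] + u0[-ny]) / 2 * dy))
  psi_hat[, 1] <- psi0

  inv_x <- function(m_hat) Re(t(stats::mvfft(t(m_hat), inverse = TRUE)))
  u <- inv_x(u_hat)
  psi <- inv_x(psi_hat)

  # v = -d psi/dx  -> v_hat = -i kap psi_hat
  kvec <- c(0:(nx %/% 2), -rev(seq_len(nx - nx %/% 2 - 1)))
  kapv <- 2 * pi * kvec / Lx
  v_hat <- sweep(psi_hat, 2, -1i * kapv, `*`)
  v <- inv_x(v_hat)

  # pressure: ik P = mu (u'' - k^2 u) + f  (k != 0); k = 0 carries G x
  P_hat <- matrix(0 + 0i, ny, nx)
  for (k in seq_len(kmax)) {
    uk <- u_hat[, k + 1]
    if (all(uk == 0)) next
    kap <- 2 * pi * k / Lx
    upp <- complex(length.out = ny)
    upp[2:(ny - 1)] <- (uk[3:ny] - 2 * uk[2:(ny - 1)] + uk[1:(ny - 2)]) / dy^2
    upp[1] <- upp[2]; upp[ny] <- upp[ny - 1]
    Pk <- (mu * (upp - kap^2 * uk) + f_hat[, k + 1]) / (1i * kap)
    P_hat[, k + 1] <- Pk
    if (k < nx - k) P_hat[, nx - k + 1] <- Conj(Pk)
  }
  P <- inv_x(P_hat) + matrix(G, ny, nx) * matrix(x, ny, nx, byrow = TRUE)

  structure(list(x = x, y = y, u = u, v = v, P = P, psi = psi,
                 dPdx = G, d = d, h = pattern$h, mu = mu,
                 pattern = pattern, Lx = Lx, n_periods = n_periods),
            class = "flow_field")
}

#' Section-averaged pressure along the canal axis
#'
#' Averages the pressure over the cross-section at each axial station and
#' fits a straight line; for uniform forcing with `h = d/2` the slope is
#' `fv/2`, and for sparse patterns it is reduced in proportion to the active
#' fraction `a/w` (linearity of the Stokes equation).
#'
#' @param field a `flow_field` from [solve_stokes()].
#' @return A list with `x`, `P` (section-averaged), and the fitted `slope`
#'   (N/m^3).
#' @export
pressure_profile <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  wts <- rep(1, length(field$y)); wts[c(1, length(field$y))] <- 0.5
  Pbar <- as.numeric(crossprod(wts, field$P)) / sum(wts)
  # mean slope via exact one-period differencing: the periodic pressure
  # component cancels, leaving the global gradient (a plain straight-line fit
  # would be biased by the sawtooth-like within-period pressure variation)
  npp <- length(field$x) %/% field$n_periods
  if (npp >= 1 && length(field$x) > npp) {
    i <- seq_len(length(field$x) - npp)
    slope <- mean((Pbar[i + npp] - Pbar[i])) / (field$pattern$w)
  } else {
    slope <- unname(stats::coef(stats::lm(Pbar ~ field$x))[2])
  }
  list(x = field$x, P = Pbar, slope = slope)
}

#' Detect recirculation regions (vortices) in a flow field
#'
#' A vortex is a closed-streamline region: an interior local extremum of the
#' streamfunction whose enclosing level set does not traverse the whole
#' periodic domain nor touch the walls. Candidate extrema are located on the
#' discrete grid (8-connectivity, periodic in x); for each, the most extreme
#' level whose enclosing component is still closed is found by bisection, and
#' the prominence (extremum minus that level, as a fraction of the global
#' streamfunction range) measures how developed the vortex is. Extrema with
#' prominence below `min_prominence` (numerical ripples on the open-streamline
#' ridge of a uniform flow) are discarded.
#'
#' @param field a `flow_field`.
#' @param min_prominence minimum prominence fraction for a reported vortex.
#' @return A list of class `vortex_report`: `count`, a data.frame `vortices`
#'   (x, y, psi, prominence), and `through_flow` — the maximum `|u|` on the
#'   mid-cross-section of a passive stretch (NA when the pattern has no
#'   passive region).
#' @export
detect_recirculation <- function(field, min_prominence = 0.02) {
  stopifnot(inherits(field, "flow_field"))
  psi <- field$psi
  ny <- nrow(psi); nx <- ncol(psi)
  rng <- diff(range(psi))
  if (rng <= 0) {
    return(structure(list(count = 0L,
                          vortices = data.frame(x = numeric(), y = numeric(),
                                                psi = numeric(), prominence = numeric()),
                          through_flow = through_flow_metric(field)),
                     class = "vortex_report"))
  }

  # regional extrema (plateau-tolerant) over the 8-neighbourhood, periodic in
  # x, interior in y: cells not dominated by any neighbour, grouped into
  # connected plateaus. Piecewise-uniform forcing produces genuinely flat
  # streamfunction tops, so strict point extrema would be missed.
  shift_x <- function(m, s) m[, ((seq_len(nx) - 1 + s) %% nx) + 1, drop = FALSE]
  neigh_max <- matrix(-Inf, ny, nx)
  neigh_min <- matrix(Inf, ny, nx)
  for (sy in -1:1) for (sx in -1:1) {
    if (sy == 0 && sx == 0) next
    rows <- pmin(pmax(seq_len(ny) + sy, 1), ny)
    m <- shift_x(psi, sx)[rows, , drop = FALSE]
    neigh_max <- pmax(neigh_max, m)
    neigh_min <- pmin(neigh_min, m)
  }
  tol <- 1e-12 * rng
  interior <- matrix(FALSE, ny, nx); interior[3:(ny - 2), ] <- TRUE
  cand_blobs <- function(mask, is_max) {
    lab <- label8(mask & interior)
    out <- list()
    for (co in label_coords(lab)) {
      co <- as.matrix(co)
      vals <- psi[co]
      rep_i <- co[if (is_max) which.max(vals) else which.min(vals), ]
      out[[length(out) + 1]] <- list(iy = rep_i[1], ix = rep_i[2],
                                     pe = psi[rep_i[1], rep_i[2]], is_max = is_max)
    }
    out
  }
  cands <- c(cand_blobs(psi >= neigh_max - tol, TRUE),
             cand_blobs(psi <= neigh_min + tol, FALSE))

  vort <- list()
  claimed <- matrix(FALSE, ny, nx)
  med <- stats::median(psi)
  ord <- order(-vapply(cands, function(cc) abs(cc$pe - med), numeric(1)))
  for (ci in ord) {
    cc <- cands[[ci]]
    if (claimed[cc$iy, cc$ix]) next
    prom <- vortex_prominence(psi, cc$iy, cc$ix, cc$is_max)
    if (is.null(prom)) next
    if (prom$prominence / rng < min_prominence) next
    claimed <- claimed | prom$region
    vort[[length(vort) + 1]] <- data.frame(
      x = field$x[cc$ix], y = field$y[cc$iy], psi = cc$pe,
      prominence = prom$prominence / rng)
  }
  vortices <- if (length(vort)) do.call(rbind, vort) else
    data.frame(x = numeric(), y = numeric(), psi = numeric(), prominence = numeric())
  structure(list(count = nrow(vortices), vortices = vortices,
                 through_flow = through_flow_metric(field)),
            class = "vortex_report")
}

# Largest level excursion from extremum (iy, ix) whose enclosing superlevel
# (sublevel) component stays closed: does not span all x columns (periodic
# through-flow) nor touch a wall. Returns prominence and the closed region.
vortex_prominence <- function(psi, iy, ix, is_max, iters = 24) {
  ny <- nrow(psi); nx <- ncol(psi)
  pe <- psi[iy, ix]
  lo <- if (is_max) min(psi) else max(psi)              # fully open level
  closed_at <- function(t) {
    mask <- if (is_max) psi >= t else psi <= t
    # periodic x: duplicate domain, take the component containing the seed
    m2 <- cbind(mask, mask)
    lab <- label8(m2)
    comp <- lab == lab[iy, ix]
    cols <- unique(((which(comp, arr.ind = TRUE)[, 2] - 1) %% nx) + 1)
    touches_wall <- any(comp[1, ]) || any(comp[ny, ])
    spans_all_x <- length(cols) == nx
    if (touches_wall || spans_all_x) return(NULL)
    comp[, seq_len(nx)] | comp[, nx + seq_len(nx)]
  }
  # must be closed just below/above the extremum
  t_hi <- pe - (if (is_max) 1 else -1) * 1e-9 * (abs(pe - lo) + 1e-300)
  region <- closed_at(t_hi)
  if (is.null(region)) return(NULL)
  t_closed <- t_hi
  t_open <- lo
  for (i in seq_len(iters)) {
    t_mid <- (t_closed + t_open) / 2
    r <- closed_at(t_mid)
    if (is.null(r)) t_open <- t_mid else { t_closed <- t_mid; region <- r }
  }
  list(prominence = abs(pe - t_closed), region = region)
}

# max |u| on the mid cross-section of a passive stretch (between active
# segments); NA for a fully active pattern.
through_flow_metric <- function(field) {
  pat <- field$pattern
  if (pat$a >= pat$w) return(NA_real_)
  # active segment is centred in each period: passive mid-point is the period
  # boundary x = m*w (mod Lx)
  ix <- which.min(abs(field$x - 0))
  max(abs(field$u[, ix]))
}

#' Flow field for spatially heterogeneous beat amplitudes
#'
#' Convenience wrapper: neighbouring full-width ciliated segments pushing
#' with different force densities (as produced by cilia beating at different
#' frequencies). Segments of width `w` carry the amplitudes in `fv_values`,
#' recycled along the canal.
#'
#' @param d channel diameter, m.
#' @param w segment width, m.
#' @param fv_values vector of per-segment force densities, N/m^3 (at least
#'   two values; all equal reduces to the uniform case).
#' @param h ciliated height, m.
#' @param ... passed to [solve_stokes()] (`mu`, `ny`, `nx_per_period`, ...).
#' @param n_segments number of segments in the periodic domain (a multiple of
#'   `length(fv_values)`).
#' @return A `flow_field`.
#' @export
heterogeneous_frequency_field <- function(d, w, fv_values, h = d / 2,
                                          n_segments = 2 * length(fv_values), ...) {
  if (length(fv_values) < 2) stop("need at least two segment amplitudes", call. = FALSE)
  pat <- cilia_pattern(w = w, a = w, fv = fv_values, h = h)
  solve_stokes(d, pat, n_periods = n_segments, ...)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Stokes flow field: %d x %d grid, Lx = %.3g um, d = %.3g um\n",
              ncol(x$u), nrow(x$u), x$Lx * 1e6, x$d * 1e6))
  cat(sprintf("  max |u| = %.3g um/s, global dP/dx = %.4g N/m^3\n",
              max(abs(x$u)) * 1e6, x$dPdx))
  invisible(x)
}

#' @export
print.vortex_report <- function(x, ...) {
  cat(sprintf("Vortex report: %d recirculation region(s)\n", x$count))
  if (x$count > 0) print(x$vortices)
  cat(sprintf("  through-flow metric (max |u| mid-passive): %s\n",
              ifelse(is.na(x$through_flow), "NA (no passive region)",
                     sprintf("%.3g um/s", x$through_flow * 1e6))))
  invisible(x)
}
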