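#' Stokes-Einstein diffusivity of a spherical particle
#'
#' `D = kB T / (6 pi r mu)` with the CODATA Boltzmann constant.
#'
#' @param r particle radius, m.
#' @param T_k temperature, K (default 301 K, the 28 C rearing temperature).
#' @param mu dynamic viscosity, Pa.s.
#' @return Diffusion coefficient in m^2/s.
#' @examples
#' stokes_einstein(20e-9)  # ~1.1e-11 m^2/s for a 20 nm-radius particle
#' @export
stokes_einstein <- function(r, T_k = 301, mu = 1e-3) {
  if (any(r <= 0) || T_k <= 0 || mu <= 0) {
    stop("`r`, `T_k` and `mu` must all be positive", call. = FALSE)
  }
  kB <- 1.380649e-23
  kB * T_k / (6 * pi * r * mu)
}

#' Taylor-Aris geometric constant of a velocity profile
#'
#' The shear-dispersion constant `C` in `Deff = D (1 + C Pe^2)`, computed by
#' quadrature as `C = int_0^1 G(xi)^2 dxi` with
#' `G(xi) = int_0^xi v(s d)/V ds`, where `V = max |v|` and the flow has zero
#' section-average. For the symmetric bidirectional (biparabolic) profile the
#' exact value is 13/315, i.e. `1/C = 315/13 ~ 24.2`.
#'
#' @param profile a `flow_profile` from [solve_two_region()], or a function
#'   `v(y)` on `[0, d]` (zero net flux assumed).
#' @param d diameter, m (taken from the profile if missing).
#' @param n quadrature points (Simpson; must be odd).
#' @return The dimensionless constant `C`.
#' @export
taylor_aris_constant <- function(profile, d = NULL, n = 4001) {
  if (inherits(profile, "flow_profile")) {
    d <- profile$d
    vfun <- function(y) evaluate_profile(profile, y)
  } else {
    stopifnot(is.function(profile), !is.null(d))
    vfun <- profile
  }
  if (n %% 2 == 0) n <- n + 1
  xi <- seq(0, 1, length.out = n)
  v <- vfun(xi * d)
  V <- max(abs(v))
  if (V == 0) return(0)
  hstep <- xi[2] - xi[1]
  # cumulative integral of v/V (trapezoid), then Simpson for int G^2
  G <- c(0, cumsum((v[-1] + v[-n]) / 2 * hstep)) / V
  w <- rep(c(4, 2), length.out = n - 2)
  sum(c(1, w, 1) * G^2) * hstep / 3
}

#' Shear-enhanced effective diffusivity
#'
#' `Deff = D (1 + C Pe^2)` with `Pe = V d / D`; the dispersion constant `C`
#' defaults to the exact biparabolic value computed by quadrature (13/315,
#' conventionally rounded as `Deff ~ D (1 + Pe^2/24)`).
#'
#' @param D Brownian diffusivity, m^2/s.
#' @param V maximal flow speed, m/s.
#' @param d channel diameter, m.
#' @param C dispersion constant; `NULL` uses the biparabolic value.
#' @return Effective diffusivity, m^2/s.
#' @export
effective_diffusivity <- function(D, V, d, C = NULL) {
  stopifnot(D > 0, V >= 0, d >= 0)
  if (is.null(C)) C <- biparabolic_C()
  Pe <- V * d / D
  D * (1 + C * Pe^2)
}

# memoized exact-profile constant
.csfflow_env <- new.env(parent = emptyenv())
biparabolic_C <- function() {
  if (is.null(.csfflow_env$C)) {
    prof <- solve_two_region(model_params(d = 1e-5, h = 5e-6, fv = 4000))
    .csfflow_env$C <- taylor_aris_constant(prof)
  }
  .csfflow_env$C
}

#' Simulate advection-diffusion transport in the canal
#'
#' Integrates `dc/dt + v(y) dc/dx = D (d2c/dy2 + d2c/dx2)` in a channel of
#' diameter `d`, periodic in x (domain chosen long enough that the boundary
#' stays empty), no-flux walls. The initial condition is a Gaussian plug in x
#' (standard deviation `sigma0`, centred at `x0`), uniform across the
#' section.
#'
#' Scheme: Strang splitting. Advection and axial diffusion are applied
#' exactly in Fourier space per dorso-ventral row (the velocity depends on y
#' only, so each x-harmonic is multiplied by `exp(-(i k v_j + D k^2) dt)`,
#' with no numerical dispersion or axial numerical diffusion); transverse
#' diffusion uses Crank-Nicolson with conservative no-flux walls. Mass is
#' conserved to machine precision; the time step is bounded for splitting
#' accuracy.
#'
#' @param profile a `flow_profile`, a function `v(y)`, or `NULL` for pure
#'   diffusion. A profile/function is scaled to maximal speed `V` if `V`
#'   is given.
#' @param D Brownian diffusivity, m^2/s.
#' @param d channel diameter, m (from the profile if available).
#' @param t_end simulation end time, s.
#' @param V optional maximal speed override, m/s.
#' @param sigma0 initial plug width, m (default `d/2`).
#' @param x0 plug centre, m (default domain centre).
#' @param Lx domain length, m (default sized so that boundaries stay below
#'   1e-6 of the peak at `t_end`).
#' @param nx,ny grid sizes (defaults resolve `sigma0` and the diameter).
#' @param dt time step, s; must satisfy `dt <= 0.05 d^2/D` (accuracy bound;
#'   refused with a suggestion otherwise).
#' @param snap_times times at which to record the solution (default 60 points
#'   geometrically spaced over `[t_end/100, t_end]`).
#' @return An object of class `conc_field`: grids, snapshot times, x-marginal
#'   matrix (`length(times)` x `nx`), a few full fields, mass history, and
#'   the physical parameters.
#' @export
simulate_transport <- function(profile, D, t_end, d = NULL, V = NULL,
                               sigma0 = NULL, x0 = NULL, Lx = NULL,
                               nx = NULL, ny = 32, dt = NULL,
                               snap_times = NULL) {
  stopifnot(D > 0, t_end > 0)
  if (inherits(profile, "flow_profile")) {
    d <- profile$d
    vfun <- function(y) evaluate_profile(profile, y)
  } else if (is.function(profile)) {
    stopifnot(!is.null(d))
    vfun <- profile
  } else {
    stopifnot(!is.null(d))
    vfun <- function(y) rep(0, length(y))
  }
  dy <- d / ny
  yc <- (seq_len(ny) - 0.5) * dy            # cell centres
  vy <- vfun(yc)
  if (!is.null(V)) {
    vm <- max(abs(vy))
    vy <- if (vm > 0) vy * (V / vm) else vy
  }
  Vmax <- max(abs(vy))
  if (is.null(sigma0)) sigma0 <- d / 2

  tau <- d^2 / D
  Deff <- effective_diffusivity(D, Vmax, d)
  if (is.null(Lx)) {
    Lx <- 2 * (5.5 * sqrt(2 * Deff * t_end + sigma0^2)) + 10 * sigma0
  }
  if (is.null(nx)) {
    dx_target <- min(d / 2, sigma0 / 2)
    nx <- max(64, 2^ceiling(log2(Lx / dx_target)))
  }
  dx <- Lx / nx
  x <- (seq_len(nx) - 1) * dx
  if (is.null(x0)) x0 <- Lx / 2

  dt_max <- 0.05 * tau
  if (is.null(dt)) dt <- min(0.01 * tau, t_end / 50)
  if (dt > dt_max) {
    stop(sprintf(paste0("time step %.3g s too coarse to resolve the ",
                        "shear-dispersion coupling; use dt <= %.3g s"),
                 dt, dt_max), call. = FALSE)
  }

  if (is.null(snap_times)) {
    snap_times <- exp(seq(log(t_end / 100), log(t_end), length.out = 60))
  }
  snap_times <- sort(unique(pmin(snap_times, t_end)))

  # initial condition: Gaussian plug, mass 1 (per unit depth)
  gx <- exp(-0.5 * ((x - x0) / sigma0)^2)
  # include periodic images so the plug is exactly periodic
  gx <- gx + exp(-0.5 * ((x - x0 - Lx) / sigma0)^2) +
    exp(-0.5 * ((x - x0 + Lx) / sigma0)^2)
  C0 <- matrix(gx, ny, nx, byrow = TRUE)
  C0 <- C0 / (sum(C0) * dx * dy)
  mass0 <- sum(C0) * dx * dy

  # exact x-step multipliers per (row, mode)
  kvec <- c(0:(nx %/% 2), -rev(seq_len(nx - nx %/% 2 - 1)))
  kap <- 2 * pi * kvec / Lx
  Ex <- exp(outer(vy, kap, function(v, k) -(1i * k * v + D * k^2) * dt))

  # Crank-Nicolson half-step operators for y-diffusion (no-flux walls)
  Ly <- diag(-2, ny)
  Ly[cbind(seq_len(ny - 1), seq_len(ny - 1) + 1)] <- 1
  Ly[cbind(seq_len(ny - 1) + 1, seq_len(ny - 1))] <- 1
  Ly[1, 1] <- -1; Ly[ny, ny] <- -1
  Ly <- Ly / dy^2
  th <- D * dt / 4                          # half step, CN => dt/2 * 1/2
  Aimp <- diag(ny) - th * Ly
  Aexp <- diag(ny) + th * Ly

  half_diffuse <- function(C) solve(Aimp, Aexp %*% C)
  x_step <- function(C) {
    Ch <- t(stats::mvfft(t(C)))             # FFT along x for each row
    Ch <- Ch * Ex
    Re(t(stats::mvfft(t(Ch), inverse = TRUE))) / nx
  }

  C <- C0
  t_now <- 0
  marg <- matrix(NA_real_, length(snap_times), nx)
  mass <- numeric(length(snap_times))
  field_idx <- unique(round(seq(1, length(snap_times), length.out = min(8, length(snap_times)))))
  fields <- vector("list", length(field_idx))
  names(fields) <- as.character(field_idx)

  for (si in seq_along(snap_times)) {
    t_target <- snap_times[si]
    while (t_now < t_target - 1e-12 * t_end) {
      step <- min(dt, t_target - t_now)
      if (abs(step - dt) > 1e-12 * dt) {
        # partial step: recompute multipliers for this step only
        Exs <- exp(outer(vy, kap, function(v, k) -(1i * k * v + D * k^2) * step))
        ths <- D * step / 4
        Ai <- diag(ny) - ths * Ly; Ae <- diag(ny) + ths * Ly
        C <- solve(Ai, Ae %*% C)
        Ch <- t(stats::mvfft(t(C))) * Exs
        C <- Re(t(stats::mvfft(t(Ch), inverse = TRUE))) / nx
        C <- solve(Ai, Ae %*% C)
      } else {
        C <- half_diffuse(C)
        C <- x_step(C)
        C <- half_diffuse(C)
      }
      t_now <- t_now + step
    }
    mass[si] <- sum(C) * dx * dy
    marg[si, ] <- pmax(colSums(C) * dy, 0)
    if (si %in% field_idx) fields[[as.character(si)]] <- pmax(C, 0)
  }

  drift <- max(abs(mass - mass0)) / mass0
  if (drift > 1e-3) {
    stop(sprintf("mass-conservation drift %.2g exceeds 0.1%%", drift),
         call. = FALSE)
  }

  structure(list(x = x, y = yc, times = snap_times, marginals = marg,
                 fields = fields, field_times = snap_times[field_idx],
                 mass = mass, mass0 = mass0, D = D, d = d, v = vy, V = Vmax,
                 x0 = x0, sigma0 = sigma0, dt = dt, Lx = Lx,
                 Deff_analytic = Deff),
            class = "conc_field")
}

#' Fit the effective diffusivity from a transport simulation
#'
#' Linear fit of the x-marginal variance against time over the asymptotic
#' window `t >= t_min` (default `3 d^2/D`, after the cross-channel diffusion
#' time); the effective diffusivity is half the slope.
#'
#' @param cf a `conc_field`.
#' @param t_min start of the asymptotic window, s.
#' @return Fitted `Deff` in m^2/s.
#' @export
fit_effective_diffusivity <- function(cf, t_min = NULL) {
  stopifnot(inherits(cf, "conc_field"))
  tau <- cf$d^2 / cf$D
  if (is.null(t_min)) t_min <- 3 * tau
  sel <- cf$times >= t_min
  if (sum(sel) < 5) {
    stop("insufficient asymptotic window: simulation must run well past ",
         "3 d^2/D with >= 5 recorded snapshots beyond it", call. = FALSE)
  }
  v2 <- marginal_variance(cf)[sel]
  tt <- cf$times[sel]
  unname(stats::coef(stats::lm(v2 ~ tt))[2]) / 2
}

marginal_variance <- function(cf) {
  apply(cf$marginals, 1, function(m) {
    s <- sum(m)
    mu <- sum(m * cf$x) / s
    sum(m * (cf$x - mu)^2) / s
  })
}

#' Track the concentration front
#'
#' The front is the furthest distance from the source at which the x-marginal
#' still exceeds `threshold_frac` of its instantaneous peak. Its position
#' grows as `t^0.5` for a diffusive process (with or without flow; the flow
#' only enlarges the prefactor through `Deff`).
#'
#' @param cf a `conc_field`.
#' @param threshold_frac fraction of the instantaneous peak (default 0.05).
#' @param t_min start of the window used for the log-log slope fit (default
#'   `1.5 d^2/D`).
#' @return An object of class `front_track`: data.frame `track` (`t`, `x_f`),
#'   fitted log-log `slope`, and `truncated` flag if the front approached the
#'   domain boundary (those times are dropped from the fit with a warning).
#' @export
track_front <- function(cf, threshold_frac = 0.05, t_min = NULL) {
  stopifnot(inherits(cf, "conc_field"))
  tau <- cf$d^2 / cf$D
  if (is.null(t_min)) t_min <- 1.5 * tau
  nT <- length(cf$times)
  xf <- numeric(nT)
  for (i in seq_len(nT)) {
    m <- cf$marginals[i, ]
    pk <- max(m)
    above <- which(m >= threshold_frac * pk & cf$x >= cf$x0)
    xf[i] <- if (length(above)) max(cf$x[above]) - cf$x0 else NA_real_
  }
  edge <- max(cf$x) - cf$x0 - 3 * (cf$x[2] - cf$x[1])
  truncated <- any(xf >= edge, na.rm = TRUE)
  ok <- !is.na(xf) & xf > 0 & xf < edge
  if (truncated) {
    warning("front reached the domain boundary; truncating the fit window")
  }
  fit_sel <- ok & cf$times >= t_min
  slope <- NA_real_
  if (sum(fit_sel) >= 10 &&
      diff(range(log10(cf$times[fit_sel]))) >= 0.9) {
    fit <- stats::lm(log(xf[fit_sel]) ~ log(cf$times[fit_sel]))
    slope <- unname(stats::coef(fit)[2])
  }
  structure(list(track = data.frame(t = cf$times, x_f = xf),
                 slope = slope, truncated = truncated,
                 threshold_frac = threshold_frac, t_min = t_min),
            class = "front_track")
}

#' Propagation time over a distance, with and without flow
#'
#' For particles of radius `r`, the time for the concentration front to cover
#' a distance `L` is modelled as `t = L^2 / (4 Deff)` with flow and
#' `L^2 / (4 D)` without. With flow, the Peclet number (and so `Deff`) falls
#' with particle size more slowly than `1/D`, giving transport a weaker size
#' dependence than pure diffusion.
#'
#' @param r particle radius (vectorized), m.
#' @param L transport distance, m.
#' @param V maximal flow speed, m/s.
#' @param d channel diameter, m.
#' @param T_k temperature, K.
#' @param mu viscosity, Pa.s.
#' @return A data.frame with `r`, `D`, `Deff`, `t_flow`, `t_noflow` (s).
#' @export
propagation_time <- function(r, L, V, d, T_k = 301, mu = 1e-3) {
  stopifnot(all(r > 0), L > 0)
  D <- stokes_einstein(r, T_k, mu)
  Deff <- vapply(D, function(Di) effective_diffusivity(Di, V, d), numeric(1))
  data.frame(r = r, D = D, Deff = Deff,
             t_flow = L^2 / (4 * Deff), t_noflow = L^2 / (4 * D))
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("Transport simulation: %d x %d grid, Lx = %.3g um, d = %.3g um\n",
              length(x$x), length(x$y), x$Lx * 1e6, x$d * 1e6))
  cat(sprintf("  D = %.3g m^2/s, V = %.3g um/s, Pe = %.3g, Deff(analytic) = %.3g m^2/s\n",
              x$D, x$V * 1e6, x$V * x$d / x$D, x$Deff_analytic))
  cat(sprintf("  %d snapshots to t = %.3g s; mass drift %.2g\n",
              length(x$times), max(x$times), max(abs(x$mass - x$mass0)) / x$mass0))
  invisible(x)
}

#' @export
print.front_track <- function(x, ...) {
  cat(sprintf("Front track: %d times, threshold %.0f%% of peak\n",
              nrow(x$track), 100 * x$threshold_frac))
  cat(sprintf("  log-log slope (t >= %.3g s): %.3f%s\n", x$t_min, x$slope,
              if (x$truncated) " [window truncated at boundary]" else ""))
  invisible(x)
}
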