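#' Parameters of the two-region cilia-driven flow model
#'
#' Bundles the physical parameters of the homogenized two-region model of
#' cilia-driven flow in a narrow channel: a ventral layer of height `h`
#' (0 < y < h) in which beating cilia exert a constant volume force density
#' `fv` on the fluid, and a passive dorsal layer (h < y < d). If `fv` is not
#' supplied it is derived from dimensional analysis as `fv = alpha * mu * f / h`.
#'
#' All quantities are SI internally (m, s, Pa.s, N/m^3); reporting helpers
#' convert to micrometres where convenient.
#'
#' @param alpha dimensionless force factor of order unity (default 0.5).
#' @param mu dynamic viscosity in Pa.s (default 1e-3, water-like CSF).
#' @param f mean cilia beat frequency in Hz (default 40).
#' @param d channel (central canal) diameter in m (default 8.9e-6).
#' @param h ciliated-layer height in m; must lie strictly inside (0, d)
#'   (default `d/2`).
#' @param fv volume force density in N/m^3, or `NULL` to derive it.
#' @return An object of class `model_params`.
#' @examples
#' # canonical central-canal parameters; fv = 4000 N/m^3 uses h = 5 um
#' p <- model_params(h = 5e-6)
#' p$fv
#' @export
model_params <- function(alpha = 0.5, mu = 1e-3, f = 40, d = 8.9e-6,
                         h = d / 2, fv = NULL) {
  stopifnot(is.numeric(mu), is.numeric(d), is.numeric(h))
  if (!(mu > 0)) stop("`mu` must be positive", call. = FALSE)
  if (!(d > 0)) stop("`d` must be positive", call. = FALSE)
  eps <- 1e-6 * d
  if (!(h > eps && h < d - eps)) {
    stop("`h` must lie strictly inside (0, d) (margin 1e-6*d): the two-region ",
         "model loses meaning at the limits", call. = FALSE)
  }
  if (is.null(fv)) {
    fv <- cilia_force_density(alpha, mu, f, h)
  } else {
    if (!(is.numeric(fv) && fv >= 0)) stop("`fv` must be >= 0", call. = FALSE)
  }
  structure(list(alpha = alpha, mu = mu, f = f, d = d, h = h, fv = fv),
            class = "model_params")
}

#' Ciliary volume force density from dimensional analysis
#'
#' The homogenized force density exerted by the ciliated layer,
#' `fv = alpha * mu * f / h` (N/m^3): viscous stress `mu * f` generated over
#' the layer height `h`, scaled by a dimensionless factor `alpha`.
#'
#' @param alpha dimensionless factor (> 0).
#' @param mu dynamic viscosity, Pa.s (> 0).
#' @param f cilia beat frequency, Hz (>= 0).
#' @param h ciliated-layer height, m (> 0).
#' @return Volume force density in N/m^3.
#' @examples
#' cilia_force_density(0.5, 1e-3, 40, 5e-6)  # 4000 N/m^3
#' @export
cilia_force_density <- function(alpha, mu, f, h) {
  if (!(is.numeric(h) && h > 0)) stop("`h` must be positive", call. = FALSE)
  if (!(is.numeric(mu) && mu > 0)) stop("`mu` must be positive", call. = FALSE)
  if (!(is.numeric(alpha) && alpha > 0)) stop("`alpha` must be positive", call. = FALSE)
  if (!(is.numeric(f) && f >= 0)) stop("`f` must be non-negative", call. = FALSE)
  alpha * mu * f / h
}

#' Solve the two-region Stokes model with zero-net-flux closure
#'
#' In each region the Stokes equation reduces to a balance between the axial
#' pressure gradient, the ciliary force and viscous diffusion:
#' \deqn{dP/dx - fv = \mu v_v''(y) \quad (0 < y < h), \qquad
#'       dP/dx = \mu v_d''(y) \quad (h < y < d),}
#' with no slip at both walls. The solution is a pair of parabolas
#' \deqn{v_v(y) = \frac{dP/dx - fv}{\mu}\left(y^2/2 - y_A y\right), \qquad
#'       v_d(y) = \frac{dP/dx}{\mu}\left(y^2/2 - y_B y - d^2/2 + y_B d\right),}
#' whose constants \eqn{y_A, y_B} and the pressure gradient are fixed by three
#' conditions: continuity of velocity and of shear rate at `y = h`, and zero
#' net flux across the section (the canal is closed, so the ventral caudal
#' stream must be exactly returned dorsally). Although the unknowns enter
#' nonlinearly as written, the substitution `A = (dP/dx - fv) yA`,
#' `B = (dP/dx) yB` makes the system linear; it is solved exactly as a 3x3
#' linear system for any `h` in (0, d). For the symmetric case `h = d/2` this
#' reduces to `yA = d/4`, `yB = 3d/4`, `dP/dx = fv/2`.
#'
#' @param params a [model_params()] object.
#' @return An object of class `flow_profile` with elements `yA`, `yB`, `dPdx`,
#'   the parabola prefactors `kv = (dPdx - fv)/mu` and `kd = dPdx/mu`, and the
#'   geometry (`d`, `h`, `mu`, `fv`). For `fv = 0` the flow is identically
#'   zero and `yA`, `yB` are `NA`.
#' @seealso [evaluate_profile()], [profile_features()], [net_flux()]
#' @export
solve_two_region <- function(params) {
  stopifnot(inherits(params, "model_params"))
  d <- params$d; h <- params$h; mu <- params$mu; fv <- params$fv

  if (fv == 0) {
    prof <- list(yA = NA_real_, yB = NA_real_, dPdx = 0,
                 kv = 0, kd = 0, d = d, h = h, mu = mu, fv = 0)
    class(prof) <- "flow_profile"
    return(prof)
  }

  # Linear system in (A, B, G) with A = (G - fv) yA, B = G yB, G = dP/dx:
  #   velocity continuity at h, shear continuity at h, zero net flux.
  # Nondimensionalized (lengths by d, forces by fv) to keep it well scaled.
  hh <- h / d
  M <- rbind(
    c(-hh,        -(1 - hh),        1 / 2),
    c(-1,          1,               0),
    c(-hh^2 / 2,  (1 - hh)^2 / 2,   hh / 2 - 1 / 3)
  )
  rhs <- c(hh^2 / 2, hh, hh^3 / 6)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular two-region system (degenerate geometry): ",
         conditionMessage(e), call. = FALSE)
  })
  A <- sol[1] * fv * d; B <- sol[2] * fv * d; G <- sol[3] * fv

  prof <- list(yA = A / (G - fv), yB = B / G, dPdx = G,
               kv = (G - fv) / mu, kd = G / mu,
               d = d, h = h, mu = mu, fv = fv)
  class(prof) <- "flow_profile"
  prof
}

#' Evaluate the analytical velocity profile
#'
#' Piecewise-parabolic axial velocity at dorso-ventral positions `y`
#' (y = 0 ventral wall, y = d dorsal wall). Positive velocity is directed
#' rostral-to-caudal; with `fv > 0` the ventral region flows caudally and the
#' dorsal region returns rostrally.
#'
#' @param profile a `flow_profile` from [solve_two_region()].
#' @param y numeric vector of positions in m, all within `[0, d]`.
#' @return Velocities in m/s, same length as `y`.
#' @export
evaluate_profile <- function(profile, y) {
  stopifnot(inherits(profile, "flow_profile"))
  d <- profile$d; h <- profile$h
  if (any(y < 0 | y > d)) {
    stop("`y` must lie within [0, d] = [0, ", format(d), "]", call. = FALSE)
  }
  if (profile$fv == 0) return(rep(0, length(y)))
  v <- numeric(length(y))
  ventral <- y <= h
  v[ventral] <- profile$kv * (y[ventral]^2 / 2 - profile$yA * y[ventral])
  yd <- y[!ventral]
  v[!ventral] <- profile$kd * (yd^2 / 2 - profile$yB * yd - d^2 / 2 + profile$yB * d)
  v
}

#' Landmark features of the analytical profile
#'
#' Closed-form extrema (parabola vertices) and zero crossing of the
#' bidirectional profile, in absolute position and relative to the diameter.
#' The ventral parabola peaks (caudal maximum) at `y = yA`; the dorsal one
#' dips (rostral minimum) at `y = yB`; the interior zero crossing is the root
#' `2 yA` (if it falls in the ventral region) or `2 yB - d` (dorsal region).
#'
#' @param profile a `flow_profile`.
#' @return A list with `vmax`, `y_vmax`, `vmin`, `y_vmin`, `y_zero`, the
#'   relative positions `rel_vmax`, `rel_zero`, `rel_vmin` (in `[0, 1]`), and
#'   `defined` (FALSE with all-NaN features when `fv = 0`).
#' @export
profile_features <- function(profile) {
  stopifnot(inherits(profile, "flow_profile"))
  d <- profile$d; h <- profile$h
  if (profile$fv == 0) {
    nan <- NaN
    return(list(vmax = nan, y_vmax = nan, vmin = nan, y_vmin = nan,
                y_zero = nan, rel_vmax = nan, rel_zero = nan, rel_vmin = nan,
                defined = FALSE))
  }
  y_vmax <- profile$yA
  y_vmin <- profile$yB
  vmax <- evaluate_profile(profile, y_vmax)
  vmin <- evaluate_profile(profile, y_vmin)
  # interior zero crossing: ventral root 2*yA, else dorsal root 2*yB - d
  y_zero <- if (2 * profile$yA > 0 && 2 * profile$yA <= h) {
    2 * profile$yA
  } else {
    2 * profile$yB - d
  }
  list(vmax = vmax, y_vmax = y_vmax, vmin = vmin, y_vmin = y_vmin,
       y_zero = y_zero,
       rel_vmax = y_vmax / d, rel_zero = y_zero / d, rel_vmin = y_vmin / d,
       defined = TRUE)
}

#' Net flux of a solved profile
#'
#' Analytic integral of the piecewise-parabolic velocity across the section
#' (per unit depth, m^2/s). For any profile produced by [solve_two_region()]
#' this is zero to machine precision; it is exposed so the closure can be
#' checked, and so that perturbed profiles show a non-zero flux.
#'
#' @param profile a `flow_profile`.
#' @return Net flux in m^2/s.
#' @export
net_flux <- function(profile) {
  stopifnot(inherits(profile, "flow_profile"))
  d <- profile$d; h <- profile$h
  if (profile$fv == 0 && profile$dPdx == 0) return(0)
  # int_0^h kv (y^2/2 - yA y) dy + int_h^d kd (y^2/2 - yB y - d^2/2 + yB d) dy
  iv <- profile$kv * (h^3 / 6 - profile$yA * h^2 / 2)
  id <- profile$kd * ((d^3 - h^3) / 6 - profile$yB * (d^2 - h^2) / 2 -
                        d^2 * (d - h) / 2 + profile$yB * d * (d - h))
  iv + id
}

#' @export
print.flow_profile <- function(x, ...) {
  cat("Two-region bidirectional flow profile\n")
  cat(sprintf("  d = %.3g um, h = %.3g um, fv = %.4g N/m^3, mu = %.3g Pa.s\n",
              x$d * 1e6, x$h * 1e6, x$fv, x$mu))
  cat(sprintf("  dP/dx = %.6g N/m^3, yA = %.4g um, yB = %.4g um\n",
              x$dPdx, x$yA * 1e6, x$yB * 1e6))
  if (x$fv > 0) {
    ft <- profile_features(x)
    cat(sprintf("  vmax = %+.3g um/s at y/d = %.3f; vmin = %+.3g um/s at y/d = %.3f; zero at y/d = %.3f\n",
                ft$vmax * 1e6, ft$rel_vmax, ft$vmin * 1e6, ft$rel_vmin, ft$rel_zero))
  }
  invisible(x)
}

#' Export a profile as a two-column table (micrometre units)
#'
#' @param profile a `flow_profile`.
#' @param n number of equally spaced sample points across the diameter.
#' @return A data.frame with `y_um` and `v_um_per_s`.
#' @export
profile_table <- function(profile, n = 201) {
  y <- seq(0, profile$d, length.out = n)
  data.frame(y_um = y * 1e6,
             v_um_per_s = evaluate_profile(profile, y) * 1e6)
}
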