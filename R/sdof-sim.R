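# Forward model of the tissue-contact-sensor (TCS) stack as a base-excited
# single-degree-of-freedom oscillator.  The arterial wall displacement y(t)
# and the motion-artifact displacement drive the same second-order system
#   m0 x'' + (c0 + cs) x' + (k0 + ks) x = k_f u + c_f u'
# and motion makes the parameters drift: m(t), c(t), k(t) follow the
# baseline displacement, turning the artifact into multiplicative
# distortion x_tvsp riding on each pulse harmonic.
#
# Nominal parameters are never identified in practice, so the defaults put
# the stack's natural frequency (10 Hz) well above the <=15 Hz pulse band:
# the stack is then a near-unity transmitter and distortion is dominated
# by the parameter drift, not by resonance.

#' Oscillator constants of the tissue-contact-sensor stack
#'
#' @param m0 Equivalent mass (a.u., > 0).
#' @param f_natural Undamped natural frequency of the stack in Hz;
#'   sets `k0 = (2 pi f_natural)^2 m0`.
#' @param zeta Damping ratio; sets `c0 = 2 zeta sqrt(k0 m0)`.
#' @param ks_ratio,cs_ratio Sensor stiffness/damping as fractions of
#'   `k0`/`c0`.  A PPG sensor has no deformable microstructure, so both
#'   are forced to zero for `sensor_kind = "ppg"`.
#' @param sensor_kind `"tactile"` or `"ppg"`.
#' @return An `sdof_params` list with elements `m0`, `c0`, `k0`, `ks`,
#'   `cs`, `sensor_kind`.
#' @export
sdof_params <- function(m0 = 1, f_natural = 10, zeta = 0.3,
                        ks_ratio = 0.2, cs_ratio = 0.2,
                        sensor_kind = c("tactile", "ppg")) {
  sensor_kind <- match.arg(sensor_kind)
  vals <- c(m0 = m0, f_natural = f_natural, zeta = zeta,
            ks_ratio = ks_ratio, cs_ratio = cs_ratio)
  if (!all(is.finite(vals))) {
    stop("SDOF parameters must all be finite", call. = FALSE)
  }
  if (m0 <= 0 || f_natural <= 0 || zeta < 0 ||
      ks_ratio < 0 || cs_ratio < 0) {
    stop("need m0 > 0, f_natural > 0, zeta >= 0, ks_ratio >= 0, ",
         "cs_ratio >= 0", call. = FALSE)
  }
  if (sensor_kind == "ppg" && (ks_ratio != 0 || cs_ratio != 0)) {
    stop("a PPG sensor has ks = cs = 0; drop ks_ratio/cs_ratio",
         call. = FALSE)
  }
  k0 <- (2 * pi * f_natural)^2 * m0
  c0 <- 2 * zeta * sqrt(k0 * m0)
  structure(
    list(m0 = m0, c0 = c0, k0 = k0,
         ks = ks_ratio * k0, cs = cs_ratio * c0,
         sensor_kind = sensor_kind),
    class = "sdof_params"
  )
}

#' Artifact-to-parameter coupling
#'
#' Baseline motion modulates each nominal parameter fractionally:
#' `m(t) = alpha_m m0 xhat_b(t)` (and likewise for c, k), where `xhat_b`
#' is the baseline displacement normalized to unit peak.  Each `|alpha|`
#' must stay below 1 so the instantaneous coefficients remain positive;
#' all zeros reduce the model to linear time-invariant.
#'
#' The defaults are deliberately unequal.  When `ks = cs = 0` (a PPG
#' sensor) and all three coefficients are equal, the common factor
#' `(1 + alpha xhat_b)` multiplies both sides of the equation of motion
#' and cancels exactly, so equal coupling produces *no* distortion at
#' all -- a degenerate direction of the model.  Physically the three
#' parameters have no reason to track contact pressure identically
#' (stiffness responds most strongly), so the defaults stagger them.
#'
#' @param alpha_m,alpha_c,alpha_k Dimensionless modulation coefficients
#'   (defaults 0.2, 0.3, 0.4).
#' @return A `tvsp_coupling` list.
#' @export
tvsp_coupling <- function(alpha_m = 0.2, alpha_c = 0.3, alpha_k = 0.4) {
  a <- c(alpha_m = alpha_m, alpha_c = alpha_c, alpha_k = alpha_k)
  if (!all(is.finite(a))) stop("coupling must be finite", call. = FALSE)
  if (any(abs(a) >= 1)) {
    stop("TVSP coupling too large: each |alpha| must be < 1 so the ",
         "system parameters stay positive", call. = FALSE)
  }
  structure(as.list(a), class = "tvsp_coupling")
}

#' Closed-form frequency response of the LTI stack
#'
#' Complex gain from base excitation to mass displacement,
#' `G(w) = (k0 + j w c0) / (-m0 w^2 + j w (c0 + cs) + k0 + ks)`,
#' i.e. the steady-state response when the parameters do not drift.
#'
#' @param params An [sdof_params()].
#' @param omega Angular frequency in rad/s (vectorized, >= 0).
#' @return Tibble with columns `omega`, `gain` (magnitude `G0`) and
#'   `phase` (rad).
#' @export
sdof_frequency_response <- function(params, omega) {
  stopifnot(inherits(params, "sdof_params"))
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("`omega` must be finite and >= 0", call. = FALSE)
  }
  g <- (params$k0 + 1i * omega * params$c0) /
    (-params$m0 * omega^2 + 1i * omega * (params$c0 + params$cs) +
       params$k0 + params$ks)
  tibble::tibble(omega = omega, gain = Mod(g), phase = Arg(g))
}

# spline interpolants of a base excitation (value + derivative); analytic
# derivatives are used when the generator supplied them
.base_funs <- function(base, fs) {
  u <- sig_values(base, "value")
  du <- if ("deriv" %in% names(base)) base$deriv else numeric_deriv(u, fs)
  list(
    u = stats::splinefun(base$time, u, method = "fmm"),
    du = stats::splinefun(base$time, du, method = "fmm")
  )
}

.run_rk4 <- function(rhs, times, oversample) {
  fine <- seq(times[1], times[length(times)],
              by = diff(times[1:2]) / oversample)
  sol <- deSolve::ode(c(x = 0, v = 0), fine, rhs, NULL, method = "rk4")
  x <- sol[, "x"]
  if (any(!is.finite(x))) {
    bad <- fine[which(!is.finite(x))[1]]
    stop("SDOF integration diverged at t = ", signif(bad, 4), " s",
         call. = FALSE)
  }
  # the coarse grid is every `oversample`-th fine point by construction
  x[seq(1L, by = oversample, length.out = length(times))]
}

#' Solve the forced LTI oscillator
#'
#' Time-steps `m0 x'' + (c0+cs) x' + (k0+ks) x = k_f u + c_f u'` from zero
#' initial displacement and velocity (the static preload is excluded from
#' the analysis), using fixed-step 4th-order Runge-Kutta on a grid
#' `oversample` times finer than the input, then returns the solution on
#' the input grid.
#'
#' @param params An [sdof_params()].
#' @param base Base excitation tibble (`time`, `value`, optional `deriv`).
#' @param forcing Which gains multiply the excitation: `"pulse"` uses
#'   `(k0, c0)` (arterial drive), `"sensor"` uses `(ks, cs)` (artifact at
#'   the substrate of a tactile sensor).
#' @param forcing_stiffness,forcing_damping Explicit gains overriding
#'   `forcing`.
#' @param oversample Integration refinement factor (default 5).
#' @return Tibble with columns `time`, `value` on the input grid.
#' @export
sdof_solve <- function(params, base, forcing = c("pulse", "sensor"),
                       forcing_stiffness = NULL, forcing_damping = NULL,
                       oversample = 5) {
  stopifnot(inherits(params, "sdof_params"))
  fs <- sig_fs(base)
  if (is.null(forcing_stiffness)) {
    forcing <- match.arg(forcing)
    forcing_stiffness <- if (forcing == "pulse") params$k0 else params$ks
    forcing_damping <- if (forcing == "pulse") params$c0 else params$cs
  }
  if (is.null(forcing_damping)) forcing_damping <- 0
  bf <- .base_funs(base, fs)
  m <- params$m0; ct <- params$c0 + params$cs; kt <- params$k0 + params$ks
  rhs <- function(t, s, p) {
    f <- forcing_stiffness * bf$u(t) + forcing_damping * bf$du(t)
    list(c(s[2], (f - ct * s[2] - kt * s[1]) / m))
  }
  tibble::tibble(time = base$time,
                 value = .run_rk4(rhs, base$time, oversample))
}

#' Solve the oscillator with drifting parameters
#'
#' Time-steps the variable-coefficient equation
#' `(m0+m(t)) x'' + (c0+c(t)+cs) x' + (k0+k(t)+ks) x =
#'  (k0+k(t)) y + (c0+c(t)) y'`
#' where `m(t) = alpha_m m0 xhat_b(t)` etc., and `xhat_b` is the baseline
#' displacement normalized to unit peak.  With zero coupling this reduces
#' exactly to [sdof_solve()] with pulse forcing.
#'
#' @param params An [sdof_params()].
#' @param coupling A [tvsp_coupling()].
#' @param xb Baseline displacement at the mass (tibble `time`, `value`).
#' @param y True pulse excitation (tibble `time`, `value`, opt. `deriv`).
#' @param oversample Integration refinement factor (default 5).
#' @return Tibble with columns `time`, `value`.
#' @export
sdof_solve_tvsp <- function(params, coupling, xb, y, oversample = 5) {
  stopifnot(inherits(params, "sdof_params"),
            inherits(coupling, "tvsp_coupling"))
  fs <- sig_fs(y)
  xbv <- sig_values(xb, "value")
  peak <- max(abs(xbv))
  xhat <- if (peak > 0) xbv / peak else xbv * 0
  # instantaneous coefficients must stay strictly positive
  worst <- max(abs(c(coupling$alpha_m, coupling$alpha_c, coupling$alpha_k)))
  if (worst * max(abs(xhat)) >= 1) {
    stop("TVSP coupling too large", call. = FALSE)
  }
  xhat_f <- stats::splinefun(xb$time, xhat, method = "fmm")
  bf <- .base_funs(y, fs)
  rhs <- function(t, s, p) {
    h <- xhat_f(t)
    m <- params$m0 * (1 + coupling$alpha_m * h)
    cc <- params$c0 * (1 + coupling$alpha_c * h)
    kk <- params$k0 * (1 + coupling$alpha_k * h)
    f <- kk * bf$u(t) + cc * bf$du(t)
    list(c(s[2], (f - (cc + params$cs) * s[2] -
                    (kk + params$ks) * s[1]) / m))
  }
  tibble::tibble(time = y$time,
                 value = .run_rk4(rhs, y$time, oversample))
}

#' Simulate an artifact-corrupted pulse measurement
#'
#' Produces the full measurement bundle for one record: the clean LTI
#' response `x_c`, the drifting-parameter response `x_m`, the
#' multiplicative distortion `x_tvsp = x_m - x_c`, the additive baseline,
#' and the sensor output `measured`.
#'
#' For a tactile sensor the artifact `ma` is the substrate displacement
#' `z_b`; it is transmitted to the mass through the sensor gains
#' `(ks, cs)` to give `x_b`, the baseline is `x_b - z_b` (the sensor reads
#' the substrate-to-mass distance), and `measured = x_m + baseline`.
#' For a PPG sensor `ma` is the sensor displacement `x_b` itself
#' (`ks = cs = 0` leaves nothing to transmit) and
#' `measured = y + x_tvsp + x_b`.
#'
#' @param sensor_kind `"tactile"` or `"ppg"`; must match `params`.
#' @param params An [sdof_params()].
#' @param coupling A [tvsp_coupling()].
#' @param y True pulse excitation (tibble `time`, `value`, opt. `deriv`).
#' @param ma Motion-artifact excitation on the same grid (or `NULL` for
#'   none).
#' @param oversample Integration refinement factor (default 5).
#' @return An `sdof_bundle` tibble with columns `time`, `measured`,
#'   `x_c`, `x_m`, `x_tvsp`, `baseline`; `sensor_kind` is attached as an
#'   attribute.
#' @export
simulate_measurement <- function(sensor_kind = c("tactile", "ppg"),
                                 params = sdof_params(sensor_kind = sensor_kind),
                                 coupling = tvsp_coupling(),
                                 y, ma = NULL, oversample = 5) {
  sensor_kind <- match.arg(sensor_kind)
  stopifnot(inherits(params, "sdof_params"))
  if (sensor_kind == "ppg" && (params$ks != 0 || params$cs != 0)) {
    stop("PPG simulation requires ks = cs = 0 in `params`", call. = FALSE)
  }
  fs <- sig_fs(y)
  if (is.null(ma)) {
    ma <- tibble::tibble(time = y$time, value = 0, deriv = 0)
  }
  if (nrow(ma) != nrow(y)) {
    stop("`y` and `ma` must share the sampling grid", call. = FALSE)
  }

  if (sensor_kind == "tactile") {
    xb <- sdof_solve(params, ma, forcing = "sensor", oversample = oversample)
    baseline <- xb$value - ma$value
  } else {
    xb <- ma[c("time", "value")]
    baseline <- xb$value
  }
  x_c <- sdof_solve(params, y, forcing = "pulse", oversample = oversample)
  x_m <- sdof_solve_tvsp(params, coupling, xb, y, oversample = oversample)
  x_tvsp <- x_m$value - x_c$value
  measured <- if (sensor_kind == "tactile") {
    x_m$value + baseline
  } else {
    y$value + x_tvsp + baseline
  }
  out <- tibble::tibble(
    time = y$time, measured = measured,
    x_c = x_c$value, x_m = x_m$value,
    x_tvsp = x_tvsp, baseline = baseline
  )
  attr(out, "sensor_kind") <- sensor_kind
  class(out) <- c("sdof_bundle", class(out))
  out
}
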