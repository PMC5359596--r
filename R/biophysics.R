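#' Induced local membrane potential under a current pulse
#'
#' Lumped passive model of field stimulation. A uniform extracellular current
#' pulse polarizes the membrane along the field axis: the local potential
#' change at a membrane element whose outward normal makes angle `theta` with
#' the field direction is
#'
#' `dV(theta, t) = k * A * (r_rel / g) * cos(theta) * (1 - exp(-t * g / tau_m))`
#'
#' where `A` is the pulse drive (arbitrary current units), `g` the total
#' conductance fold relative to control, and `k` the simulator's calibration
#' constant (mV of plateau polarization at the cell pole per unit drive per
#' unit relative resistance). The cathode-facing side (`cos(theta) > 0`)
#' depolarizes, the anode-facing side hyperpolarizes; the whole-cell average
#' is zero. At the plateau of a constant-current pulse the relation is Ohm's
#' law: halving membrane resistance halves the potential change. The charging
#' time constant scales inversely with total conductance
#' (`tau_eff = tau_m / g`), as for a passive RC membrane.
#'
#' For a symmetric biphasic pulse, `t` beyond `phase_duration` falls in the
#' second phase: polarity flips and charging restarts from the phase onset
#' (the brief discharge transient between phases is not modeled).
#'
#' @param cell A [cell_model()].
#' @param field A [field_geometry()] (orientation only; the model is
#'   axisymmetric, so only `theta` enters).
#' @param pulse A [pulse_protocol()].
#' @param membrane_angle Angle(s) in radians between the outward membrane
#'   normal and the field direction.
#' @param g_fold Conductance fold(s) relative to control: a scalar for an
#'   ohmic membrane, or length-2 `c(depol, hyper)` for hemisphere-specific
#'   folds (rectification).
#' @param t Time(s) since pulse onset, ms. Must be nonnegative and within the
#'   pulse duration.
#' @param k Calibration constant, mV per unit drive (config parameter of the
#'   simulator; default gives ~3.5% peak dF/F with the default dye).
#' @return Potential change(s) in mV, vectorized over `membrane_angle`/`t`.
#' @export
#' @examples
#' cc <- cell_model()
#' fd <- field_geometry()
#' pp <- pulse_protocol()
#' induced_delta_v(cc, fd, pp, membrane_angle = c(0, pi / 2, pi), t = 90)
induced_delta_v <- function(cell, field, pulse, membrane_angle, g_fold = 1,
                            t, k = 35) {
  stopifnot(inherits(cell, "cell_model"), inherits(pulse, "pulse_protocol"))
  if (any(t < 0)) abort("`t` must be nonnegative")
  if (any(g_fold <= 0)) abort("`g_fold` must be > 0")
  dv_from_cos(cell, cos(membrane_angle), pulse, g_fold, t, k)
}

# Core of the forward model, on cos(theta) directly so that pixels with an
# exactly perpendicular normal give an exact 0.
dv_from_cos <- function(cell, costh, pulse, g_fold, t, k) {
  tmax <- if (pulse$shape == "biphasic") 2 * pulse$phase_duration else
    pulse$phase_duration
  if (any(t > tmax)) abort("`t` exceeds the pulse duration")
  phase_sign <- ifelse(t <= pulse$phase_duration, 1, -1)
  t_phase <- ifelse(phase_sign > 0, t, t - pulse$phase_duration)
  # Depolarized hemisphere = where the signed polarization is positive.
  if (length(g_fold) == 2) {
    g <- ifelse(phase_sign * costh >= 0, g_fold[[1]], g_fold[[2]])
  } else {
    g <- g_fold
  }
  k * pulse$amplitude * (cell$r_rel / g) * phase_sign * costh *
    (1 - exp(-t_phase * g / cell$tau_m))
}

#' Membrane-averaged induced potential
#'
#' Average of [induced_delta_v()] over the membrane, sampled uniformly in
#' angle. For a centrally symmetric (circular) cell over the full membrane
#' this is zero to numerical precision - the positive and negative
#' polarizations cancel, which is why whole-cell fluorescence shows no
#' stimulus response. Restricting `arc` to the cathode-facing hemisphere
#' (`c(-pi/2, pi/2)`) gives a strictly positive mean depolarization.
#'
#' @inheritParams induced_delta_v
#' @param arc Angular interval (radians, relative to the field direction)
#'   over which to average; default the full membrane.
#' @param n Number of uniform angular samples (midpoint rule).
#' @return Mean potential change in mV.
#' @export
whole_cell_mean_dv <- function(cell, field, pulse, t, g_fold = 1,
                               arc = c(-pi, pi), n = 3600, k = 35) {
  stopifnot(length(arc) == 2, arc[2] > arc[1])
  h <- (arc[2] - arc[1]) / n
  ang <- arc[1] + h * (seq_len(n) - 0.5)
  mean(induced_delta_v(cell, field, pulse, membrane_angle = ang,
                       g_fold = g_fold, t = t, k = k))
}
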