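#' Passive electrical and optical model of one cell
#'
#' A cell is modeled as a membrane annulus (ring) over a dim interior, with
#' lumped passive electrical properties. The membrane-localized
#' voltage-sensitive dye responds linearly to the local transmembrane
#' potential: a membrane pixel at potential change `dv` (mV) emits
#' `f_rest * (1 + dye_sens * dv)` expected camera counts.
#'
#' @param center Numeric length-2, image coordinates `(row, col)` of the cell
#'   center in pixels (1-based, matching R matrix indexing).
#' @param radius Outer membrane radius in pixels. Must be positive.
#' @param tau_m Membrane time constant in ms (RC charging constant). Must be
#'   positive.
#' @param r_rel Baseline relative membrane resistance (dimensionless;
#'   1 = control). Must be positive.
#' @param f_rest Resting fluorescence of a membrane pixel in camera counts.
#'   Must be positive.
#' @param dye_sens Fractional fluorescence change per mV of membrane potential
#'   (1/mV). Negative for fast styryl dyes imaged at red-shifted emission,
#'   where depolarization dims the dye.
#' @param ring_width Membrane ring thickness in pixels (annulus between
#'   `radius - ring_width` and `radius`).
#' @param interior_frac Interior fluorescence as a fraction of `f_rest`
#'   (cytosolic background from out-of-focus membrane and residual dye).
#'
#' @return An object of class `cell_model`.
#' @seealso [induced_delta_v()], [render_frame()]
#' @export
#' @examples
#' cell_model(center = c(64, 64), radius = 22)
cell_model <- function(center = c(64, 64), radius = 22, tau_m = 5,
                       r_rel = 1, f_rest = 40000, dye_sens = -0.001,
                       ring_width = 3.5, interior_frac = 0.25) {
  stopifnot(length(center) == 2, is.numeric(center))
  if (radius <= 0) abort("`radius` must be > 0")
  if (tau_m <= 0) abort("`tau_m` must be > 0")
  if (r_rel <= 0) abort("`r_rel` must be > 0")
  if (f_rest <= 0) abort("`f_rest` must be > 0")
  if (ring_width <= 0 || ring_width > radius) {
    abort("`ring_width` must be in (0, radius]")
  }
  structure(
    list(center = as.numeric(center), radius = radius, tau_m = tau_m,
         r_rel = r_rel, f_rest = f_rest, dye_sens = dye_sens,
         ring_width = ring_width, interior_frac = interior_frac),
    class = "cell_model"
  )
}

#' Current-pulse stimulation protocol
#'
#' Describes the test current pulse delivered by the field electrodes. The
#' drive `amplitude` is in arbitrary units proportional to the injected
#' current; the simulator's calibration constant converts drive to peak mV
#' (see [induced_delta_v()]). The plateau frame is captured at
#' `plateau_sample_time` ms into the (first) phase, which should be several
#' membrane time constants so the RC charging is complete.
#'
#' @param shape `"monophasic"` or `"biphasic"` (symmetric biphasic: second
#'   phase of equal duration and opposite polarity).
#' @param phase_duration Duration of one phase in ms.
#' @param amplitude Current drive in arbitrary units (proportional to I).
#' @param plateau_sample_time Time into the phase, in ms, at which the plateau
#'   frame is captured. Must not exceed `phase_duration`.
#' @param inter_pulse_interval Recovery interval between successive pulses, ms.
#'
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(shape = c("monophasic", "biphasic"),
                           phase_duration = 100, amplitude = 1,
                           plateau_sample_time = 90,
                           inter_pulse_interval = 100) {
  shape <- match.arg(shape)
  if (phase_duration <= 0) abort("`phase_duration` must be > 0")
  if (plateau_sample_time < 0 || plateau_sample_time > phase_duration) {
    abort("`plateau_sample_time` must lie in [0, phase_duration]")
  }
  if (inter_pulse_interval < 0) abort("`inter_pulse_interval` must be >= 0")
  structure(
    list(shape = shape, phase_duration = phase_duration,
         amplitude = amplitude, plateau_sample_time = plateau_sample_time,
         inter_pulse_interval = inter_pulse_interval),
    class = "pulse_protocol"
  )
}

#' Extracellular field geometry
#'
#' Direction of the (uniform) stimulation field in the image plane, as a
#' `(row, col)` vector; it is normalized to unit length. The side of a cell
#' whose outward membrane normal is aligned with `direction` depolarizes
#' (faces the cathode); the opposite side hyperpolarizes.
#'
#' @param direction Numeric length-2 `(row, col)` vector; need not be unit
#'   length, must be nonzero.
#' @return An object of class `field_geometry` with a unit `direction` and a
#'   `uniform = TRUE` flag.
#' @export
field_geometry <- function(direction = c(0, 1)) {
  stopifnot(length(direction) == 2, is.numeric(direction))
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) abort("`direction` must be a nonzero vector")
  structure(list(direction = as.numeric(direction) / nrm, uniform = TRUE),
            class = "field_geometry")
}

#' Hill-type drug conductance model
#'
#' Ground-truth pharmacology for the simulator: an agonist opens channels so
#' that total membrane conductance scales by a Hill function of concentration,
#' from 1 (control) to `g_max_fold` at saturation. `rectification` models
#' voltage-dependent channel conductance: the drug-added conductance on the
#' hyperpolarized hemisphere is scaled by `rectification` relative to the
#' depolarized hemisphere (1 = ohmic; < 1 reproduces outward rectification,
#' i.e. a stronger drug effect under depolarization).
#'
#' @param ec50 Half-maximal activating concentration (M). Must be positive.
#' @param hill Hill coefficient (dimensionless, > 0).
#' @param g_max_fold Maximal conductance fold change at saturation (> 0;
#'   > 1 for agonist-opened channels).
#' @param rectification Ratio of hyperpolarizing-side to depolarizing-side
#'   drug-added conductance (> 0; 1 = ohmic).
#' @return An object of class `drug_model`.
#' @export
#' @examples
#' capsaicin_like <- drug_model(ec50 = 1e-6, hill = 1, g_max_fold = 5,
#'                              rectification = 0.5)
#' conductance_fold(capsaicin_like, c(0, 1e-6, 1))
drug_model <- function(ec50, hill = 1, g_max_fold = 5, rectification = 1) {
  if (ec50 <= 0) abort("`ec50` must be > 0")
  if (hill <= 0) abort("`hill` must be > 0")
  if (g_max_fold <= 0) abort("`g_max_fold` must be > 0")
  if (rectification <= 0) abort("`rectification` must be > 0")
  structure(
    list(ec50 = ec50, hill = hill, g_max_fold = g_max_fold,
         rectification = rectification),
    class = "drug_model"
  )
}

#' Antagonist acting against a fixed agonist dose
#'
#' Wraps an agonist [drug_model()] together with a fixed agonist
#' concentration and an inhibitory Hill term: the drug-added conductance of
#' the agonist is scaled by `1 / (1 + (c_ant / ic50)^hill)`, so the response
#' window closes as antagonist concentration rises (competitive-style
#' scaling of the maximal effect at a fixed agonist challenge).
#'
#' @param agonist A [drug_model()].
#' @param agonist_conc Fixed agonist challenge concentration (M, > 0).
#' @param ic50 Antagonist half-inhibitory concentration (M, > 0).
#' @param hill Inhibition Hill coefficient (> 0).
#' @return An object of class `antagonist_model` (also a `drug_model`
#'   subtype for dispatch in the simulator; "concentration" then refers to
#'   the antagonist).
#' @export
antagonist_model <- function(agonist, agonist_conc, ic50, hill = 1) {
  stopifnot(inherits(agonist, "drug_model"))
  if (agonist_conc <= 0) abort("`agonist_conc` must be > 0")
  if (ic50 <= 0) abort("`ic50` must be > 0")
  if (hill <= 0) abort("`hill` must be > 0")
  structure(
    list(agonist = agonist, agonist_conc = agonist_conc, ic50 = ic50,
         hill = hill, rectification = agonist$rectification),
    class = c("antagonist_model", "drug_model")
  )
}

#' Drug-dependent conductance fold change
#'
#' Total membrane conductance relative to control at a given concentration.
#' For an agonist ([drug_model()]):
#' `1 + (g_max_fold - 1) * conc^hill / (conc^hill + ec50^hill)` - monotone
#' nondecreasing, 1 at zero concentration, `g_max_fold` at saturation. For an
#' [antagonist_model()], `conc` is the antagonist concentration and the
#' agonist's drug-added conductance at the fixed agonist challenge is scaled
#' by the inhibition factor.
#'
#' @param drug A [drug_model()] or [antagonist_model()].
#' @param conc Concentration(s) in M; must be nonnegative.
#' @return Numeric vector of conductance folds, same length as `conc`.
#' @export
conductance_fold <- function(drug, conc) {
  UseMethod("conductance_fold", drug)
}

#' @export
conductance_fold.antagonist_model <- function(drug, conc) {
  if (any(conc < 0)) abort("`conc` must be nonnegative")
  g_ag <- conductance_fold(drug$agonist, drug$agonist_conc)
  inhib <- 1 / (1 + (conc / drug$ic50)^drug$hill)
  1 + (g_ag - 1) * inhib
}

#' @export
conductance_fold.drug_model <- function(drug, conc) {
  if (any(conc < 0)) abort("`conc` must be nonnegative")
  ch <- conc^drug$hill
  1 + (drug$g_max_fold - 1) * ch / (ch + drug$ec50^drug$hill)
}

# Hemisphere-specific conductance folds c(depolarized, hyperpolarized).
# Rectification scales only the drug-added conductance, so both sides are 1
# at zero dose.
hemisphere_folds <- function(drug, conc) {
  g <- conductance_fold(drug, conc)
  c(depol = g, hyper = 1 + (g - 1) * drug$rectification)
}

#' Camera noise model
#'
#' Generic monochrome scientific camera: optional Poisson shot noise on the
#' expected counts, additive Gaussian read noise, rounding to integer counts
#' and clipping to the bit depth.
#'
#' @param read_noise_sd Read noise standard deviation in counts (>= 0).
#' @param shot_noise Logical; apply Poisson noise on expected counts.
#' @param bit_depth Bits per pixel; one of 8, 12, 16.
#' @param binning_native On-chip binning factor (1 = none; kept for
#'   provenance, frames are rendered at the delivered resolution).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(read_noise_sd = 3, shot_noise = TRUE,
                         bit_depth = 16, binning_native = 1) {
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0")
  if (!bit_depth %in% c(8, 12, 16)) abort("`bit_depth` must be 8, 12 or 16")
  structure(
    list(read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
         bit_depth = as.integer(bit_depth),
         binning_native = as.integer(binning_native)),
    class = "camera_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> center (%g, %g), radius %g px, ring %g px, tau %g ms, F0 %g\n",
    x$center[1], x$center[2], x$radius, x$ring_width, x$tau_m, x$f_rest))
  invisible(x)
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf(
    "<drug_model> EC50 %.3g M, hill %.2f, g_max_fold %.2f, rectification %.2f\n",
    x$ec50, x$hill, x$g_max_fold, x$rectification))
  invisible(x)
}

#' @export
print.antagonist_model <- function(x, ...) {
  cat(sprintf(
    "<antagonist_model> IC50 %.3g M (hill %.2f) vs agonist at %.3g M\n",
    x$ic50, x$hill, x$agonist_conc))
  invisible(x)
}
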