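#' @import methods
#' @importFrom stats coef lm mad median nlminb optim predict quantile rnorm
#'   rpois runif sd setNames t.test ks.test vcov complete.cases rexp rbinom
#' @importFrom utils read.csv write.csv head tail
NULL

#' Gompertz growth-schedule parameters
#'
#' Parameter container for the asymmetric sigmoid
#' \deqn{y(t) = y_0 + (A - y_0)\exp(-\exp(-k(t - t_i)))}
#' used both to prescribe the population growth-rate schedule in the
#' synthetic-scene simulator and to hold fitted population curves of
#' GR(t) or L(t).  The inflection \code{t_i} is the transition time
#' from the post-binding lag phase to the growth phase.
#'
#' @slot coef named numeric: \code{y0} (baseline), \code{A} (plateau),
#'   \code{k} (1/min), \code{t_i} (min).
#' @slot vcov covariance matrix of the estimates (zero matrix when the
#'   object holds prescribed rather than fitted parameters).
#' @slot residual residual standard deviation of the fit (NA when prescribed).
#' @slot data data.frame with columns \code{t}, \code{y} used for the fit
#'   (empty when prescribed).
#' @slot degenerate logical; TRUE when the data had no usable sigmoidal
#'   rise (A ~ y0) and \code{t_i} is undefined.
#' @export
setClass("GompertzFit",
  representation(coef = "numeric", vcov = "matrix", residual = "numeric",
                 data = "data.frame", degenerate = "logical"),
  prototype(coef = c(y0 = NA_real_, A = NA_real_, k = NA_real_, t_i = NA_real_),
            vcov = matrix(0, 4, 4), residual = NA_real_,
            data = data.frame(), degenerate = FALSE),
  validity = function(object) {
    if (!all(c("y0", "A", "k", "t_i") %in% names(object@coef)))
      return("coef must contain y0, A, k, t_i")
    if (!object@degenerate && !anyNA(object@coef) && object@coef[["k"]] <= 0)
      return("rate k must be positive")
    TRUE
  })

#' Synthetic-scene configuration
#'
#' Full parameterization of the agent-based colonization simulator and the
#' brightfield renderer.  Defaults describe the study conditions: a 3 h
#' time-lapse at 2 fps of E. coli binding to a functionalized channel floor
#' under laminar flow, with Poisson arrivals during a 20-min injection
#' window, a Gompertz population growth-rate schedule, exponential surface
#' detachment, slow flow-normal realignment and small angular wiggle about a
#' per-cell pivot.
#'
#' @slot duration_min movie duration, minutes.
#' @slot frame_rate_fps acquisition rate, frames per second.
#' @slot pixel_size_um physical pixel size, µm/px.
#' @slot image_shape integer (nx, ny) in pixels; x is the flow axis.
#' @slot injection_window_min arrivals occur only during the first this-many
#'   minutes.
#' @slot arrival_rate_per_min Poisson binding rate during injection, cells/min.
#' @slot n_initial_cells cells already bound at t = 0.
#' @slot initial_length_um numeric (mean, sd) of length at binding, µm.
#' @slot cell_width_um rod width, µm.
#' @slot gr_schedule [GompertzFit] prescribing population GR(t), µm/min.
#' @slot division_length_um division threshold, µm.
#' @slot division_asymmetry daughter split is 0.5 ± this fraction, in [0, 0.5).
#' @slot daughter_detach_prob probability a newborn daughter is washed away.
#' @slot detach_halflife_min surface residence half-life T1/2, minutes
#'   (detachment rate ln2 / T1/2); Inf disables detachment.
#' @slot realign_rate_per_min rate of exponential relaxation of the median
#'   axis from flow-aligned (0°) toward flow-normal (90°), 1/min.
#' @slot wiggle_amplitude_deg stationary sd of the angular wiggle ∂θ, degrees.
#' @slot wiggle_relax_time_s correlation time of the wiggle
#'   (Ornstein–Uhlenbeck), seconds.
#' @slot pivot_offset_frac signed pivot position as a fraction of cell length
#'   in [-0.5, 0.5]; 0 = rocking about the center, negative = upstream
#'   twisting pivot.
#' @slot noise_sd additive Gaussian intensity noise sd (images live in [0, 1]).
#' @slot illumination_coeffs named numeric polynomial coefficients
#'   (x, y, xx, xy, yy) of the multiplicative illumination field on
#'   normalized [-1, 1] coordinates.
#' @slot blur_sigma_px optical blur sigma, px.
#' @slot focus_drift_amp fractional slow modulation of the blur sigma over
#'   the movie (0 disables focus drift).
#' @slot nanoparticle_rate_per_min arrival rate of small round confounder
#'   spots, spots/min.
#' @slot seed integer RNG seed; identical (config, seed) gives bit-identical
#'   truth tables and rendered stacks.
#' @export
setClass("SceneConfig",
  representation(duration_min = "numeric", frame_rate_fps = "numeric",
    pixel_size_um = "numeric", image_shape = "integer",
    injection_window_min = "numeric", arrival_rate_per_min = "numeric",
    n_initial_cells = "integer", initial_length_um = "numeric",
    cell_width_um = "numeric", gr_schedule = "GompertzFit",
    division_length_um = "numeric", division_asymmetry = "numeric",
    daughter_detach_prob = "numeric", detach_halflife_min = "numeric",
    realign_rate_per_min = "numeric", wiggle_amplitude_deg = "numeric",
    wiggle_relax_time_s = "numeric", pivot_offset_frac = "numeric",
    noise_sd = "numeric", illumination_coeffs = "numeric",
    blur_sigma_px = "numeric", focus_drift_amp = "numeric",
    nanoparticle_rate_per_min = "numeric", seed = "integer"),
  validity = function(object) {
    pos <- c(duration_min = object@duration_min,
             frame_rate_fps = object@frame_rate_fps,
             pixel_size_um = object@pixel_size_um,
             initial_length_mean_um = object@initial_length_um[[1]],
             cell_width_um = object@cell_width_um,
             division_length_um = object@division_length_um,
             detach_halflife_min = object@detach_halflife_min,
             wiggle_relax_time_s = object@wiggle_relax_time_s)
    bad <- names(pos)[!(pos > 0)]
    if (length(bad)) return(paste0("field must be strictly positive: ", bad[1]))
    nn <- c(injection_window_min = object@injection_window_min,
            arrival_rate_per_min = object@arrival_rate_per_min,
            realign_rate_per_min = object@realign_rate_per_min,
            wiggle_amplitude_deg = object@wiggle_amplitude_deg,
            noise_sd = object@noise_sd, blur_sigma_px = object@blur_sigma_px,
            focus_drift_amp = object@focus_drift_amp,
            nanoparticle_rate_per_min = object@nanoparticle_rate_per_min)
    bad <- names(nn)[!is.finite(nn) | nn < 0]
    if (length(bad)) return(paste0("field must be finite and >= 0: ", bad[1]))
    if (!is.finite(object@division_asymmetry) ||
        object@division_asymmetry < 0 || object@division_asymmetry >= 0.5)
      return("division_asymmetry must lie in [0, 0.5)")
    if (!is.finite(object@daughter_detach_prob) ||
        object@daughter_detach_prob < 0 || object@daughter_detach_prob > 1)
      return("daughter_detach_prob must lie in [0, 1]")
    if (!is.finite(object@pivot_offset_frac) ||
        abs(object@pivot_offset_frac) > 0.5)
      return("pivot_offset_frac must lie in [-0.5, 0.5]")
    if (length(object@image_shape) != 2L || any(object@image_shape < 8L))
      return("image_shape must be two pixel dimensions >= 8")
    if (length(object@initial_length_um) != 2L ||
        object@initial_length_um[[2]] < 0)
      return("initial_length_um must be (mean, sd) with sd >= 0")
    if (object@n_initial_cells < 0L)
      return("n_initial_cells must be >= 0")
    TRUE
  })

#' Ground-truth tracks and event log of a simulated scene
#'
#' @slot tracks data.frame, one row per bound cell per rendered frame:
#'   cell_id, parent_id, frame, t_min, x_um, y_um, length_um, theta_deg
#'   (signed axis angle vs flow), pivot_frac, bound.
#' @slot events data.frame, one row per cell: cell_id, parent_id, t_bind_min,
#'   t_detach_min (continuous exponential draw, NA if censored), t_divide_min
#'   (NA if none), fate in {divided, detached, censored, washed}.
#' @slot config the [SceneConfig] that produced the scene.
#' @export
setClass("TruthTable",
  representation(tracks = "data.frame", events = "data.frame",
                 config = "SceneConfig"),
  validity = function(object) {
    need <- c("cell_id", "parent_id", "frame", "t_min", "x_um", "y_um",
              "length_um", "theta_deg", "pivot_frac", "bound")
    if (nrow(object@tracks) && !all(need %in% names(object@tracks)))
      return("tracks is missing required columns")
    TRUE
  })

#' Brightfield time-lapse stack
#'
#' Ordered grayscale frames with physical calibration.  The first array
#' dimension is x (the flow axis, by convention), the second y, the third
#' time, matching the EBImage spatial convention.
#'
#' @slot frames numeric array (nx, ny, n_frames), intensities in [0, 1].
#' @slot frame_rate_fps frames per second.
#' @slot pixel_size_um µm per pixel.
#' @export
setClass("MovieStack",
  representation(frames = "array", frame_rate_fps = "numeric",
                 pixel_size_um = "numeric"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L) return("frames must be a 3-D array")
    if (!all(is.finite(object@frames))) return("intensities must be finite")
    if (object@frame_rate_fps <= 0 || object@pixel_size_um <= 0)
      return("frame_rate_fps and pixel_size_um must be positive")
    TRUE
  })

#' Per-frame segmentation result for a stack
#'
#' @slot observations data.frame, one row per gated object: frame, t_min,
#'   label, x_um, y_um, length_um, width_um, theta_deg (folded to [0, 90]),
#'   theta_axis_deg (signed axis angle in (-90, 90]), area_um2, solidity,
#'   mean_intensity.
#' @slot labels list of integer label matrices, one per frame (0 = background).
#' @slot frame_rate_fps effective frame rate of the segmented stack.
#' @slot pixel_size_um µm per pixel.
#' @export
setClass("SegmentationStack",
  representation(observations = "data.frame", labels = "list",
                 frame_rate_fps = "numeric", pixel_size_um = "numeric"))

#' Stitched single-cell trajectories with lineage
#'
#' @slot observations data.frame: traj_id, parent_id, frame, t_min, x_um,
#'   y_um, length_um, width_um, theta_deg, theta_axis_deg, area_um2,
#'   gr_eligible (set by [filterForGrowth]).
#' @slot lineage data.frame: traj_id, parent_id, start_min, end_min, fate in
#'   {divided, detached, censored}.
#' @slot params the linking parameter list used.
#' @export
setClass("TrajectorySet",
  representation(observations = "data.frame", lineage = "data.frame",
                 params = "list"))

#' Fit of the colonization-curve model
#'
#' Holds the reconstructed net growth–release exponential
#' \deqn{N(t) = N_0 \exp\!\Big(\int_{t_0}^{t} \big[\ln 2 / T_2(s) -
#'   \ln 2 / T_{1/2}\big]\, ds\Big), \qquad t \ge t_0,}
#' fitted to log N with Poisson weights, where \eqn{t_0} is the transition
#' time (Gompertz inflection of GR(t)) at which division starts.
#'
#' @slot N0 bacteria on the surface at t0.
#' @slot t0 start of the division phase, minutes.
#' @slot T_half mean binding (surface residence half-life) time, minutes;
#'   Inf when the fitted detachment rate is <= 0.
#' @slot net_rate net exponential rate of N(t) after t0, 1/min.
#' @slot residual residual sd of the weighted log-linear fit.
#' @slot data data.frame of the points used (t, N).
#' @export
setClass("BindingFit",
  representation(N0 = "numeric", t0 = "numeric", T_half = "numeric",
                 net_rate = "numeric", residual = "numeric",
                 data = "data.frame"),
  validity = function(object) {
    if (is.finite(object@N0) && object@N0 <= 0) return("N0 must be positive")
    if (is.finite(object@T_half) && object@T_half <= 0)
      return("T_half must be positive")
    TRUE
  })
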