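# circular median axis angle for direction-free (period-180) axis data,
# via angle doubling; returns degrees in (-90, 90]
.axisMedianAngle <- function(theta_deg) {
  th2 <- 2 * theta_deg * pi / 180
  a <- atan2(median(sin(th2)), median(cos(th2))) / 2 * 180 / pi
  if (a <= -90) a <- a + 180
  if (a > 90) a <- a - 180
  a
}

#' Orientation statistics over a short full-rate window
#'
#' For one bound cell observed at the original frame rate over a short
#' window (default 2 min), computes the time-median major axis M (median
#' centroid plus circular-median axis angle), the median binding angle
#' \eqn{\theta_M} (median of the folded angle between the instantaneous
#' axis and the flow direction), its spread STD(\eqn{\theta}), and the
#' signed instantaneous deviation \eqn{\partial\theta} of the axis from M
#' (axis direction fixed within the window so small deviations do not
#' flip sign).
#'
#' @param traj data.frame of one cell's full-rate observations: columns
#'   \code{t_min}, \code{x_um}, \code{y_um}, \code{theta_axis_deg} (signed
#'   axis angle vs flow in (-90, 90]), \code{length_um}.
#' @param window_start_min window start, minutes.
#' @param duration_min window length, minutes (default 2; ~240 samples at
#'   2 fps).
#' @param min_valid_frac reject the window when fewer than this fraction
#'   of the expected samples are present.
#' @return an object of class \code{motion_window} (list with theta_M,
#'   theta_std, dtheta, median axis, centroids, median length), or NULL
#'   (with a warning) for a window with too few valid frames.
#' @export
computeMotionWindow <- function(traj, window_start_min, duration_min = 2,
                                min_valid_frac = 0.5) {
  stopifnot(all(c("t_min", "x_um", "y_um", "theta_axis_deg",
                  "length_um") %in% names(traj)))
  w <- traj[traj$t_min >= window_start_min &
              traj$t_min < window_start_min + duration_min, , drop = FALSE]
  if (nrow(w) < 3L) {
    warning("window rejected: fewer than 3 observations")
    return(NULL)
  }
  dt <- min(diff(sort(unique(traj$t_min))))
  expected <- duration_min / dt
  if (nrow(w) < min_valid_frac * expected) {
    warning(sprintf("window rejected: %d of ~%.0f expected frames",
                    nrow(w), expected))
    return(NULL)
  }
  # canonicalize to (-90, 90]: a rod's axis is direction-free
  w$theta_axis_deg <- ((w$theta_axis_deg + 90) %% 180) - 90
  w$theta_axis_deg[w$theta_axis_deg == -90] <- 90
  m_angle <- .axisMedianAngle(w$theta_axis_deg)
  dtheta <- (w$theta_axis_deg - m_angle + 90) %% 180 - 90
  structure(list(
    traj_id = if ("traj_id" %in% names(w)) w$traj_id[1] else NA_integer_,
    window_start_min = window_start_min, duration_min = duration_min,
    t_min = w$t_min, theta_axis_deg = w$theta_axis_deg,
    theta_M = median(abs(w$theta_axis_deg)),
    theta_std = sd(abs(w$theta_axis_deg)),
    m_angle = m_angle,
    m0 = c(x = median(w$x_um), y = median(w$y_um)),
    centroids = cbind(x = w$x_um, y = w$y_um),
    dtheta_deg = dtheta,
    length_um = median(w$length_um)),
    class = "motion_window")
}

#' Wiggle profile and pivot localization
#'
#' For each sampled position l along the cell's median axis (l = 0 at the
#' cell center), the instantaneous lateral separation between the point at
#' l on the instantaneous axis and the median axis M is evaluated per
#' frame, and its standard deviation over the window gives the profile
#' sep_std(l).  For a rigid rotation about a pivot at position p the
#' profile is V-shaped with its vertex at p: the pivot estimate is the
#' (quadratically refined) argmin.  The classical pure-rotation expression
#' l x sin(dtheta) — which ignores the correlated lateral translation that
#' an off-axis pivot produces — is reported alongside as
#' \code{sep_std_rot}.
#'
#' The binding mode is \code{rocking} when the pivot sits within
#' 0.15 L of the center and the profile is approximately symmetric
#' (end-point sep_std ratio < 1.5), \code{twisting} otherwise, and
#' \code{undetermined} (flagged) when there is essentially no wiggle.
#'
#' @param window a \code{motion_window} from [computeMotionWindow()].
#' @param L cell length, µm (default: the window's median length).
#' @param n_positions sampled positions along the axis.
#' @return data.frame of class \code{wiggle_profile} with columns
#'   \code{l_um}, \code{sep_std_um}, \code{sep_std_rot_um}; attributes
#'   \code{pivot_um}, \code{pivot_frac}, \code{mode}, \code{confidence}.
#' @export
wiggleProfile <- function(window, L = NULL, n_positions = 21L) {
  stopifnot(inherits(window, "motion_window"))
  if (is.null(L)) L <- window$length_um
  if (!is.finite(L) || L <= 0) stop("degenerate cell length")
  th <- window$m_angle * pi / 180
  u <- c(cos(th), sin(th)); nv <- c(-sin(th), cos(th))
  dx <- window$centroids[, 1] - window$m0[1]
  dy <- window$centroids[, 2] - window$m0[2]
  c_perp <- dx * nv[1] + dy * nv[2]          # lateral centroid offset
  sdth <- sin(window$dtheta_deg * pi / 180)
  l <- seq(-L / 2, L / 2, length.out = n_positions)
  sep <- outer(sdth, l) + c_perp             # frames x positions
  sep_rot <- outer(sdth, l)
  sep_std <- apply(sep, 2, sd)
  sep_std_rot <- apply(sep_rot, 2, sd)
  # quadratic refinement of the argmin
  i <- which.min(sep_std)
  pivot <- l[i]
  if (i > 1L && i < length(l)) {
    y <- sep_std[(i - 1L):(i + 1L)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom > 0)
      pivot <- l[i] + (l[2] - l[1]) * 0.5 * (y[1] - y[3]) / denom
  }
  pivot <- min(max(pivot, -L / 2), L / 2)
  amp <- max(sep_std)
  if (amp < 1e-3) {
    mode <- "undetermined"; conf <- 0
    warning("no measurable wiggle; binding mode undetermined")
  } else {
    ends_ratio <- max(sep_std[1], sep_std[length(l)]) /
      max(min(sep_std[1], sep_std[length(l)]), 1e-12)
    mode <- if (abs(pivot) <= 0.15 * L && ends_ratio < 1.5) "rocking"
            else "twisting"
    conf <- 1 - min(sep_std) / amp
  }
  out <- data.frame(l_um = l, sep_std_um = sep_std,
                    sep_std_rot_um = sep_std_rot)
  attr(out, "pivot_um") <- pivot
  attr(out, "pivot_frac") <- pivot / L
  attr(out, "mode") <- mode
  attr(out, "confidence") <- conf
  class(out) <- c("wiggle_profile", class(out))
  out
}

#' Motion windows for all cells at a given time point
#'
#' @param obs full-rate observation data.frame with a \code{traj_id} (or
#'   \code{cell_id}) column.
#' @param window_start_min,duration_min,min_valid_frac see
#'   [computeMotionWindow()].
#' @return list of \code{motion_window} objects (rejected windows omitted).
#' @export
motionWindows <- function(obs, window_start_min, duration_min = 2,
                          min_valid_frac = 0.5) {
  idcol <- if ("traj_id" %in% names(obs)) "traj_id" else "cell_id"
  if (!"theta_axis_deg" %in% names(obs) && "theta_deg" %in% names(obs))
    obs$theta_axis_deg <- obs$theta_deg
  ws <- lapply(split(obs, obs[[idcol]]), function(tro) {
    tro$traj_id <- tro[[idcol]]
    suppressWarnings(computeMotionWindow(tro, window_start_min,
                                         duration_min, min_valid_frac))
  })
  ws[!vapply(ws, is.null, TRUE)]
}

#' Population orientation/wiggle summary at two time points
#'
#' Collects per-cell (theta_M, STD(theta)) pairs at an early and a late
#' time point, pools the wiggle profiles into relative-position bins
#' (the bar-plot analog), and tests the early/late theta_M distributions
#' with a two-sample Kolmogorov–Smirnov test.
#'
#' @param windows_early,windows_late lists of \code{motion_window}
#'   objects (one may be empty; a partial summary is then returned with a
#'   warning).
#' @param n_bins relative-position bins for the pooled profiles.
#' @return list with \code{angles} (per cell: time, theta_M, theta_std,
#'   pivot_frac, mode), \code{profiles} (pooled sep_std per l/L bin per
#'   time), and \code{ks} (KS tests comparing time points, NULL if one is
#'   missing).
#' @export
populationMotionSummary <- function(windows_early, windows_late,
                                    n_bins = 10L) {
  one <- function(ws, label) {
    if (!length(ws)) return(NULL)
    rows <- lapply(ws, function(w) {
      pr <- wiggleProfile(w)
      list(ang = data.frame(time = label, traj_id = w$traj_id,
                            theta_M = w$theta_M, theta_std = w$theta_std,
                            pivot_frac = attr(pr, "pivot_frac"),
                            mode = attr(pr, "mode")),
           prof = data.frame(time = label, rel_pos = pr$l_um /
                               w$length_um, sep_std_um = pr$sep_std_um))
    })
    list(ang = do.call(rbind, lapply(rows, `[[`, "ang")),
         prof = do.call(rbind, lapply(rows, `[[`, "prof")))
  }
  e <- suppressWarnings(one(windows_early, "early"))
  l <- suppressWarnings(one(windows_late, "late"))
  if (is.null(e) || is.null(l))
    warning("missing time point; returning partial summary")
  angles <- rbind(if (!is.null(e)) e$ang, if (!is.null(l)) l$ang)
  prof <- rbind(if (!is.null(e)) e$prof, if (!is.null(l)) l$prof)
  if (!is.null(prof) && nrow(prof)) {
    prof$bin <- cut(prof$rel_pos, breaks = seq(-0.5, 0.5,
                                               length.out = n_bins + 1L),
                    include.lowest = TRUE)
    profiles <- do.call(rbind, lapply(split(prof,
                                            list(prof$time, prof$bin),
                                            drop = TRUE), function(p)
      data.frame(time = p$time[1], bin = p$bin[1],
                 rel_pos_mid = mean(p$rel_pos),
                 sep_std_um = mean(p$sep_std_um), n = nrow(p))))
    rownames(profiles) <- NULL
  } else profiles <- data.frame()
  ks <- if (!is.null(e) && !is.null(l) && nrow(e$ang) >= 2L &&
            nrow(l$ang) >= 2L)
    list(theta_M = suppressWarnings(ks.test(e$ang$theta_M, l$ang$theta_M)),
         theta_std = suppressWarnings(ks.test(e$ang$theta_std,
                                              l$ang$theta_std)))
  else NULL
  list(angles = angles, profiles = profiles, ks = ks)
}
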