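#' Build a synthetic-scene configuration
#'
#' Defaults describe the study conditions: bacteria are injected during the
#' first 20 min and bind at random positions as a Poisson process; each
#' bound cell elongates at the population growth-rate schedule GR(t)
#' (a Gompertz sigmoid rising from 0.01 to 0.025 µm/min with inflection at
#' 60 min), linearly over the first two thirds of its cycle and near-
#' exponentially thereafter; division occurs at 4.5 µm with a small
#' asymmetry and daughters may be washed away; cells detach with an
#' exponential residence half-life of 60 min; the median axis slowly
#' realigns from flow-aligned toward flow-normal while a small
#' mean-reverting wiggle rocks the cell about its pivot.
#'
#' @param duration_min,frame_rate_fps,pixel_size_um,image_shape movie
#'   geometry; see [SceneConfig-class].
#' @param injection_window_min,arrival_rate_per_min,n_initial_cells arrival
#'   model.
#' @param initial_length_um,cell_width_um,gr_schedule,division_length_um,division_asymmetry,daughter_detach_prob
#'   growth/division model.
#' @param detach_halflife_min surface residence half-life T1/2 (min).
#' @param realign_rate_per_min,wiggle_amplitude_deg,wiggle_relax_time_s,pivot_offset_frac
#'   orientation model.
#' @param noise_sd,illumination_coeffs,blur_sigma_px,focus_drift_amp,nanoparticle_rate_per_min
#'   rendering model.
#' @param seed RNG seed.
#' @return a validated [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(duration_min = 5, frame_rate_fps = 0.5, seed = 7)
#' cfg
#' @export
sceneConfig <- function(duration_min = 180, frame_rate_fps = 2,
                        pixel_size_um = 0.2, image_shape = c(400L, 400L),
                        injection_window_min = 20, arrival_rate_per_min = 3,
                        n_initial_cells = 0L,
                        initial_length_um = c(2.8, 0.3), cell_width_um = 1,
                        gr_schedule = gompertzParams(y0 = 0.01, A = 0.025,
                                                     k = 0.05, t_i = 60),
                        division_length_um = 4.5, division_asymmetry = 0.05,
                        daughter_detach_prob = 0.1,
                        detach_halflife_min = 60,
                        realign_rate_per_min = 0.012,
                        wiggle_amplitude_deg = 3, wiggle_relax_time_s = 5,
                        pivot_offset_frac = 0, noise_sd = 0.01,
                        illumination_coeffs = c(x = 0.05, y = -0.04,
                                                xx = -0.03, xy = 0.02,
                                                yy = -0.02),
                        blur_sigma_px = 1, focus_drift_amp = 0,
                        nanoparticle_rate_per_min = 0, seed = 1L) {
  ic <- setNames(rep(0, 5), c("x", "y", "xx", "xy", "yy"))
  ic[names(illumination_coeffs)] <- illumination_coeffs
  new("SceneConfig", duration_min = duration_min,
      frame_rate_fps = frame_rate_fps, pixel_size_um = pixel_size_um,
      image_shape = as.integer(image_shape),
      injection_window_min = injection_window_min,
      arrival_rate_per_min = arrival_rate_per_min,
      n_initial_cells = as.integer(n_initial_cells),
      initial_length_um = initial_length_um, cell_width_um = cell_width_um,
      gr_schedule = gr_schedule, division_length_um = division_length_um,
      division_asymmetry = division_asymmetry,
      daughter_detach_prob = daughter_detach_prob,
      detach_halflife_min = detach_halflife_min,
      realign_rate_per_min = realign_rate_per_min,
      wiggle_amplitude_deg = wiggle_amplitude_deg,
      wiggle_relax_time_s = wiggle_relax_time_s,
      pivot_offset_frac = pivot_offset_frac, noise_sd = noise_sd,
      illumination_coeffs = ic, blur_sigma_px = blur_sigma_px,
      focus_drift_amp = focus_drift_amp,
      nanoparticle_rate_per_min = nanoparticle_rate_per_min,
      seed = as.integer(seed))
}

# population GR schedule (um/min) at time t (min)
.grAt <- function(config, t) gompertzValue(config@gr_schedule, t)

#' Simulate ground-truth colonization dynamics
#'
#' Event-driven agent simulation sampled at the rendered frame times.
#' Arrivals are Poisson during the injection window only; each cell's length
#' follows the population GR schedule, linear over the first two thirds of
#' the cycle and accelerating in proportion to length thereafter; division
#' splits the mother 0.5 ± asymmetry with daughters appearing in the next
#' frame; detachment times are drawn from an exponential with rate
#' ln2 / detach_halflife_min at binding; the median axis relaxes from
#' flow-aligned toward flow-normal at realign_rate while the instantaneous
#' axis carries a mean-reverting (Ornstein–Uhlenbeck) angular wiggle, the
#' rigid rotation being centered on the cell's pivot.
#'
#' @param config a [SceneConfig-class]; the simulation is seeded from
#'   \code{sceneSeed(config)} and is bit-reproducible.
#' @return a [TruthTable-class] with per-frame tracks and a per-cell event
#'   log carrying the continuous binding/detachment/division times.
#' @examples
#' tt <- simulateTruth(sceneConfig(duration_min = 10, frame_rate_fps = 0.2,
#'                                 arrival_rate_per_min = 1, seed = 3))
#' head(truthTracks(tt))
#' @export
simulateTruth <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  set.seed(config@seed)
  fps <- config@frame_rate_fps
  n_frames <- floor(config@duration_min * 60 * fps + 1e-9)
  dt_min <- 1 / (fps * 60)
  fov_um <- config@image_shape * config@pixel_size_um
  rate_det <- log(2) / config@detach_halflife_min   # ln2 / T1/2
  margin <- min(config@division_length_um / 2, min(fov_um) / 4)

  # per-cell state: (qx, qy) anchors one pole (the birth septum); the cell
  # elongates from there in direction sgn along its median axis, so sibling
  # cells push apart as they grow
  st <- list(id = integer(0), parent = integer(0), qx = numeric(0),
             qy = numeric(0), sgn = numeric(0), L = numeric(0),
             Lb = numeric(0), thetaM = numeric(0), dtheta = numeric(0),
             t_bind = numeric(0), t_det = numeric(0))
  ev <- list()
  rows <- vector("list", n_frames)
  next_id <- 1L

  new_cells <- function(n, parent, t, L, qx, qy, sgn, thetaM, st) {
    ids <- next_id + seq_len(n) - 1L
    next_id <<- next_id + n
    t_det <- t + rexp(n, rate = rate_det)
    dth <- rnorm(n, 0, config@wiggle_amplitude_deg)
    for (i in seq_len(n))
      ev[[length(ev) + 1L]] <<- data.frame(
        cell_id = ids[i], parent_id = parent[i], t_bind_min = t,
        t_detach_min = t_det[i], t_divide_min = NA_real_,
        fate = "censored", stringsAsFactors = FALSE)
    list(id = c(st$id, ids), parent = c(st$parent, parent),
         qx = c(st$qx, qx), qy = c(st$qy, qy), sgn = c(st$sgn, sgn),
         L = c(st$L, L), Lb = c(st$Lb, L), thetaM = c(st$thetaM, thetaM),
         dtheta = c(st$dtheta, dth), t_bind = c(st$t_bind, t),
         t_det = c(st$t_det, t_det))
  }
  drop_cells <- function(st, keep) lapply(st, function(v) v[keep])
  mark_fate <- function(ids, fate, t, col) {
    for (id in ids) {
      j <- which(vapply(ev, function(e) e$cell_id, 0L) == id)
      ev[[j]][[col]] <<- t
      ev[[j]]$fate <<- fate
    }
  }

  # place a cell: draw centroid/axis with volume exclusion (a bacterium
  # cannot bind on top of an already bound one), anchor one pole
  min_sep <- 1.5 * config@initial_length_um[1]
  draw_cells <- function(n, t, st) {
    L <- pmax(0.5, rnorm(n, config@initial_length_um[1],
                         config@initial_length_um[2]))
    cx <- cy <- numeric(n)
    for (i in seq_len(n)) {
      ox <- st$qx; oy <- st$qy
      if (i > 1L) { ox <- c(ox, cx[seq_len(i - 1L)])
                    oy <- c(oy, cy[seq_len(i - 1L)]) }
      for (try in 1:25) {
        cx[i] <- runif(1, margin, fov_um[1] - margin)
        cy[i] <- runif(1, margin, fov_um[2] - margin)
        if (!length(ox) ||
            min(sqrt((ox - cx[i])^2 + (oy - cy[i])^2)) >= min_sep) break
      }
    }
    thetaM <- abs(rnorm(n, 0, 5))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    uM <- cbind(cos(thetaM * pi / 180), sin(thetaM * pi / 180))
    new_cells(n, rep(NA_integer_, n), t, L,
              cx - sgn * (L / 2) * uM[, 1], cy - sgn * (L / 2) * uM[, 2],
              sgn, thetaM, st)
  }

  # seed cells at t = 0
  if (config@n_initial_cells > 0L)
    st <- draw_cells(config@n_initial_cells, 0, st)

  ou_a <- exp(-dt_min * 60 / config@wiggle_relax_time_s)
  ou_s <- config@wiggle_amplitude_deg * sqrt(1 - ou_a^2)

  for (f in seq_len(n_frames)) {
    t <- (f - 1L) * dt_min

    # Poisson arrivals during the injection window
    if (t < config@injection_window_min && config@arrival_rate_per_min > 0) {
      n_arr <- rpois(1L, config@arrival_rate_per_min * dt_min)
      if (n_arr > 0L) st <- draw_cells(n_arr, t, st)
    }

    # detachment: cells whose exponential residence time has elapsed
    gone <- st$t_det <= t
    if (any(gone)) {
      mark_fate(st$id[gone], "detached", NA, "t_divide_min")
      st <- drop_cells(st, !gone)
    }

    n <- length(st$id)
    if (n > 0L) {
      # orientation: relax median axis toward 90 deg; OU wiggle about it
      st$thetaM <- 90 - (90 - st$thetaM) *
        exp(-config@realign_rate_per_min * dt_min)
      st$dtheta <- st$dtheta * ou_a + ou_s * rnorm(n)

      # growth: linear at GR(t) for first 2/3 of cycle, length-
      # proportional acceleration after
      g <- .grAt(config, t)
      Lsw <- st$Lb + (2 / 3) * (config@division_length_um - st$Lb)
      rate <- ifelse(st$L < Lsw, g, g * st$L / Lsw)
      st$L <- st$L + rate * dt_min

      # record bound cells: centroid = pole anchor + half length along the
      # median axis, displaced by the rigid wiggle rotation about the pivot
      theta <- st$thetaM + st$dtheta
      p_um <- config@pivot_offset_frac * st$L
      uM <- cbind(cos(st$thetaM * pi / 180), sin(st$thetaM * pi / 180))
      u <- cbind(cos(theta * pi / 180), sin(theta * pi / 180))
      cx <- st$qx + st$sgn * (st$L / 2) * uM[, 1] +
        p_um * (uM[, 1] - u[, 1])
      cy <- st$qy + st$sgn * (st$L / 2) * uM[, 2] +
        p_um * (uM[, 2] - u[, 2])
      rows[[f]] <- data.frame(
        cell_id = st$id, parent_id = st$parent, frame = f, t_min = t,
        x_um = cx, y_um = cy, length_um = st$L, theta_deg = theta,
        pivot_frac = config@pivot_offset_frac, bound = TRUE)

      # division at threshold; daughters appear next frame
      div <- st$L >= config@division_length_um
      if (any(div)) {
        snap <- lapply(st, function(v) v[div])   # mothers, frozen
        mother_ids <- snap$id
        t_next <- f * dt_min
        for (i in seq_along(mother_ids)) {
          Lm <- snap$L[i]
          asym <- config@division_asymmetry * sample(c(-1, 1), 1L)
          Ld <- Lm * c(0.5 + asym, 0.5 - asym)
          thM <- snap$thetaM[i]
          uM <- c(cos(thM * pi / 180), sin(thM * pi / 180))
          s <- snap$sgn[i]
          # septum on the median axis; each daughter is anchored there and
          # elongates outward, away from its sibling
          septum <- c(snap$qx[i], snap$qy[i]) + s * Ld[1] * uM
          keep_d <- runif(2) >= config@daughter_detach_prob
          d_sgn <- c(-s, s)
          jit <- rnorm(2, 0, 2)   # small post-division axis jitter, deg
          cleft <- 0.8            # um; septum cleft between daughters
          for (d in 1:2) {
            anch <- septum + d_sgn[d] * (cleft / 2) * uM
            st <- new_cells(1L, mother_ids[i], t_next, Ld[d],
                            anch[1], anch[2], d_sgn[d], thM + jit[d], st)
            if (!keep_d[d]) {
              washed_id <- st$id[length(st$id)]
              st <- drop_cells(st, st$id != washed_id)
              mark_fate(washed_id, "washed", t_next, "t_detach_min")
            }
          }
        }
        mark_fate(mother_ids, "divided", t, "t_divide_min")
        st <- drop_cells(st, !(st$id %in% mother_ids))
      }
    }
  }

  tracks <- if (length(rows)) do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
            else NULL
  if (is.null(tracks))
    tracks <- data.frame(cell_id = integer(0), parent_id = integer(0),
                         frame = integer(0), t_min = numeric(0),
                         x_um = numeric(0), y_um = numeric(0),
                         length_um = numeric(0), theta_deg = numeric(0),
                         pivot_frac = numeric(0), bound = logical(0))
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(cell_id = integer(0), parent_id = integer(0),
                            t_bind_min = numeric(0), t_detach_min = numeric(0),
                            t_divide_min = numeric(0),
                            fate = character(0))
  # censor detach times past movie end for cells never seen to leave
  still <- events$fate == "censored"
  events$t_detach_min[still] <- NA_real_
  new("TruthTable", tracks = tracks, events = events, config = config)
}

#' Near-wall flow speed in a square microfluidic duct
#'
#' Laminar pressure-driven flow in a square duct, evaluated close to the
#' midpoint of one wall using the analytic Fourier-series velocity profile.
#' Terms are added until the relative change falls below \code{tol}.
#' At the study geometry (0.8 x 0.8 mm duct, 100 µL/min) the speed 1 µm
#' above the floor midpoint is about 31 µm/s.
#'
#' @param flow_rate_ul_min volumetric flow rate, µL/min.
#' @param channel_side_mm inner side of the square duct, mm.
#' @param distance_um distance from the midpoint of one wall, µm.
#' @param tol series truncation tolerance (relative).
#' @return speed in µm/s, with attribute \code{n_terms} = series terms kept.
#' @examples
#' nearWallSpeed(100, 0.8, 1)
#' @export
nearWallSpeed <- function(flow_rate_ul_min, channel_side_mm, distance_um,
                          tol = 1e-6) {
  if (any(c(flow_rate_ul_min, channel_side_mm, distance_um) <= 0))
    stop("all arguments must be strictly positive")
  a <- channel_side_mm * 1e-3           # side, m
  z <- distance_um * 1e-6               # distance from wall, m
  if (z >= a / 2)
    stop("distance must be smaller than half the channel side")
  Q <- flow_rate_ul_min * 1e-9 / 60     # m^3/s
  # duct cross-section: y in [-a/2, a/2], z in [0, a]; evaluate at y = 0
  u_term <- function(i) (1 / i^3) *
    (1 - 1 / cosh(i * pi / 2)) * sin(i * pi * z / a)
  q_term <- function(i) (1 / i^4) * (2 * a / pi) *
    (a - (2 * a / (i * pi)) * tanh(i * pi / 2))
  u <- q <- 0; i <- 1
  repeat {
    du <- u_term(i); dq <- q_term(i)
    u <- u + du; q <- q + dq
    if (i > 1 && abs(du) <= tol * abs(u) && abs(dq) <= tol * abs(q)) break
    if (i > 4001) break
    i <- i + 2
  }
  speed <- Q * u / q * 1e6
  attr(speed, "n_terms") <- (i + 1) / 2
  speed
}
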