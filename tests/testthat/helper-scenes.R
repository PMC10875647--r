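# shared fixtures: small scenes, rasterization and matching utilities

# binary capsule mask on an nx x ny grid (pixel units)
capsuleMask <- function(nx, ny, cx, cy, L_px, r_px, theta_deg) {
  img <- BacFlow:::.drawCapsule(matrix(1, nx, ny), cx, cy, L_px, r_px,
                                theta_deg, depth = 1, edge_px = 1e-6)$img
  img < 0.5
}

# static scene: n non-dividing, non-detaching cells, default-style imaging
staticScene <- function(n_cells = 8, duration_min = 2, fps = 1 / 30,
                        shape = c(300L, 300L), noise_sd = 0.01,
                        seed = 1, ...) {
  sceneConfig(duration_min = duration_min, frame_rate_fps = fps,
              image_shape = shape, n_initial_cells = n_cells,
              arrival_rate_per_min = 0, detach_halflife_min = 1e9,
              division_length_um = 50,
              gr_schedule = gompertzParams(1e-4, 2e-4, 0.05, 60),
              noise_sd = noise_sd, seed = seed, ...)
}

# colony scene used for division/lineage tests: cells start near the
# division threshold and grow fast enough to divide within the movie
divisionScene <- function(n_cells = 3, duration_min = 40, seed = 21,
                          noise_sd = 0, ...) {
  sceneConfig(duration_min = duration_min, frame_rate_fps = 1 / 30,
              n_initial_cells = n_cells, arrival_rate_per_min = 0,
              detach_halflife_min = 1e9, daughter_detach_prob = 0,
              initial_length_um = c(3.8, 0.1), division_length_um = 4.5,
              gr_schedule = gompertzParams(0.05, 0.051, 0.1, 0),
              noise_sd = noise_sd, image_shape = c(300L, 300L),
              seed = seed, ...)
}

# match segmented objects in one frame to truth cells by footprint IoU
matchFrame <- function(seg, truth_tracks, frame, config, iou_min = 0.5) {
  labs <- frameLabels(seg)[[frame]]
  obs <- observations(seg)
  obs <- obs[obs$frame == frame, , drop = FALSE]
  tf <- truth_tracks[truth_tracks$frame == frame, , drop = FALSE]
  px <- pixelSize(seg)
  d <- dim(labs)
  matches <- data.frame(cell_id = integer(0), label = integer(0),
                        iou = numeric(0), len_err_um = numeric(0))
  used <- integer(0)
  for (i in seq_len(nrow(tf))) {
    tm <- capsuleMask(d[1], d[2], tf$x_um[i] / px, tf$y_um[i] / px,
                      tf$length_um[i] / px,
                      config@cell_width_um / 2 / px, tf$theta_deg[i])
    cand <- labs[tm]
    cand <- cand[cand > 0L]
    if (!length(cand)) next
    lb <- as.integer(names(sort(table(cand), decreasing = TRUE)[1]))
    if (lb %in% used) next
    inter <- sum(labs[tm] == lb)
    uni <- sum(tm) + sum(labs == lb) - inter
    iou <- inter / uni
    if (iou < iou_min) next
    used <- c(used, lb)
    li <- obs$length_um[obs$label == lb]
    matches[nrow(matches) + 1L, ] <-
      list(tf$cell_id[i], lb, iou, li - tf$length_um[i])
  }
  list(matches = matches, n_truth = nrow(tf), n_pred = nrow(obs))
}

# detection precision/recall and length MAE over a set of frames
detectionStats <- function(seg, truth_tracks, config, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(seg))
  tp <- npred <- ntruth <- 0
  len_err <- numeric(0)
  for (f in frames) {
    m <- matchFrame(seg, truth_tracks, f, config)
    tp <- tp + nrow(m$matches)
    npred <- npred + m$n_pred
    ntruth <- ntruth + m$n_truth
    len_err <- c(len_err, m$matches$len_err_um)
  }
  list(precision = tp / max(npred, 1), recall = tp / max(ntruth, 1),
       length_mae_um = mean(abs(len_err)))
}

# build a SegmentationStack directly from specified cells per frame,
# bypassing rendering (footprints rasterized as capsules)
makeSyntheticSeg <- function(cells_per_frame, shape = c(120L, 120L),
                             px = 0.2, fps = 1 / 30, width_um = 1) {
  n <- length(cells_per_frame)
  labs <- vector("list", n)
  obs <- vector("list", n)
  for (f in seq_len(n)) {
    lab <- matrix(0L, shape[1], shape[2])
    cf <- cells_per_frame[[f]]
    if (!is.null(cf) && nrow(cf)) {
      for (i in seq_len(nrow(cf))) {
        m <- capsuleMask(shape[1], shape[2], cf$x_um[i] / px,
                         cf$y_um[i] / px, cf$length_um[i] / px,
                         width_um / 2 / px, cf$theta_deg[i])
        lab[m] <- i
      }
    }
    labs[[f]] <- lab
    fe <- BacFlow:::.regionFeatures(lab, lab * 0 + 0.4, px)
    if (nrow(fe)) {
      fe$frame <- f
      fe$t_min <- (f - 1) / fps / 60
    } else {
      fe$frame <- integer(0); fe$t_min <- numeric(0)
    }
    obs[[f]] <- fe
  }
  new("SegmentationStack", observations = do.call(rbind, obs),
      labels = labs, frame_rate_fps = fps, pixel_size_um = px)
}

# fraction of frame-to-frame links that disagree with the ground truth
# (wrong links within predicted trajectories + truth links that were
# broken, over the number of truth links between detected observations)
lineageLinkErrors <- function(trajset, seg, truth_tracks, config) {
  obs <- observations(trajset)
  px <- pixelSize(seg)
  # map each tracked observation to the nearest truth cell in its frame
  obs$truth_id <- NA_integer_
  for (f in unique(obs$frame)) {
    tf <- truth_tracks[truth_tracks$frame == f, , drop = FALSE]
    oi <- which(obs$frame == f)
    for (i in oi) {
      d <- sqrt((tf$x_um - obs$x_um[i])^2 + (tf$y_um - obs$y_um[i])^2)
      if (length(d) && min(d) < 1.5) obs$truth_id[i] <- tf$cell_id[which.min(d)]
    }
  }
  wrong <- 0L; total_pred <- 0L
  for (sp in split(obs, obs$traj_id)) {
    sp <- sp[order(sp$frame), ]
    if (nrow(sp) < 2L) next
    a <- sp$truth_id[-nrow(sp)]; b <- sp$truth_id[-1L]
    ok <- !is.na(a) & !is.na(b)
    wrong <- wrong + sum(a[ok] != b[ok])
    total_pred <- total_pred + sum(ok)
  }
  # truth links between consecutive detected observations of one cell
  missed <- 0L; total_truth <- 0L
  for (sp in split(obs, obs$truth_id)) {
    sp <- sp[order(sp$frame), ]
    if (nrow(sp) < 2L) next
    consec <- diff(sp$frame) == 1L
    total_truth <- total_truth + sum(consec)
    missed <- missed + sum(consec &
                             sp$traj_id[-nrow(sp)] != sp$traj_id[-1L])
  }
  (wrong + missed) / max(total_truth, 1L)
}
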