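#' Trajectory-stitching parameters
#'
#' @param max_length_change maximal fractional length change between
#'   consecutive observations of one cell (default 0.25).
#' @param gap_tolerance_min a cell may vanish from the mask (e.g. focus
#'   drift) for up to this long and still resume its trajectory.
#' @param reappearance_similarity "unaltered appearance" for gap bridging:
#'   length within this fraction and centroid within one cell length.
#' @return a named list of class \code{bacflow_track_params}.
#' @export
trackingParams <- function(max_length_change = 0.25, gap_tolerance_min = 1,
                           reappearance_similarity = 0.15) {
  stopifnot(max_length_change > 0, max_length_change < 1,
            gap_tolerance_min >= 0, reappearance_similarity > 0,
            reappearance_similarity < 1)
  structure(list(max_length_change = max_length_change,
                 gap_tolerance_min = gap_tolerance_min,
                 reappearance_similarity = reappearance_similarity),
            class = "bacflow_track_params")
}

#' Stitch per-frame observations into trajectories with lineage
#'
#' Greedy frame-to-frame assignment by footprint overlap: candidate links
#' are processed in order of decreasing overlap area (ties by minimal
#' fractional length change) and accepted when the length changed by less
#' than \code{max_length_change}.  A trajectory whose footprint maps onto
#' two unclaimed footprints whose lengths sum to the mother's (within the
#' same fraction) is closed as divided and spawns two child trajectories
#' carrying its id as \code{parent_id}.  An unmatched trajectory is held
#' open for \code{gap_tolerance_min} and resumed if an observation
#' reappears near its last position with similar length; otherwise it is
#' closed as detached (censored when it reaches the movie end).  Unclaimed
#' observations start new parentless trajectories.
#'
#' @param seg a [SegmentationStack-class].
#' @param params a [trackingParams()] list.
#' @return a [TrajectorySet-class].
#' @export
linkTrajectories <- function(seg, params = trackingParams()) {
  stopifnot(is(seg, "SegmentationStack"))
  if (!length(seg@pixel_size_um) || seg@pixel_size_um <= 0)
    stop("segmentation input is not calibrated")
  obs <- observations(seg)
  n_frames <- nFrames(seg)
  fps <- frameRate(seg)
  gap_frames <- floor(params$gap_tolerance_min * 60 * fps)
  if (nrow(obs) && anyDuplicated(obs[, c("frame", "label")]))
    stop("duplicate labels within one frame")

  # active-trajectory registry; `matched` and `miss` are per-frame state
  # (miss = -1 flags a mother closed by division, removed at frame end)
  act <- data.frame(tid = integer(0), pid = integer(0),
                    last_frame = integer(0), last_label = integer(0),
                    last_len = numeric(0), last_x = numeric(0),
                    last_y = numeric(0), miss = integer(0),
                    start_min = numeric(0), matched = logical(0))
  next_tid <- 1L
  out_rows <- list()
  closed <- list()

  emit <- function(tid, pid, o) {
    out_rows[[length(out_rows) + 1L]] <<- cbind(
      data.frame(traj_id = tid, parent_id = pid), o)
  }
  open_traj <- function(pid, o) {
    tid <- next_tid; next_tid <<- next_tid + 1L
    act[nrow(act) + 1L, ] <<- list(tid, pid, o$frame, o$label, o$length_um,
                                   o$x_um, o$y_um, 0L, o$t_min, TRUE)
    emit(tid, pid, o)
    tid
  }
  resume_traj <- function(ti, o) {
    emit(act$tid[ti], act$pid[ti], o)
    act$last_frame[ti] <<- o$frame; act$last_label[ti] <<- o$label
    act$last_len[ti] <<- o$length_um
    act$last_x[ti] <<- o$x_um; act$last_y[ti] <<- o$y_um
    act$miss[ti] <<- 0L; act$matched[ti] <<- TRUE
  }
  close_traj <- function(i, fate, end_min) {
    closed[[length(closed) + 1L]] <<- data.frame(
      traj_id = act$tid[i], parent_id = act$pid[i],
      start_min = act$start_min[i], end_min = end_min, fate = fate)
  }

  for (f in seq_len(n_frames)) {
    of <- obs[obs$frame == f, , drop = FALSE]
    assigned_obs <- rep(FALSE, nrow(of))
    act$matched <- rep(FALSE, nrow(act))

    if (nrow(act) && nrow(of)) {
      lab_prev <- frameLabels(seg)[[f - 1L]]
      lab_cur <- frameLabels(seg)[[f]]
      both <- lab_prev > 0L & lab_cur > 0L
      cand <- act$miss == 0L & act$last_frame == f - 1L
      if (any(both) && any(cand)) {
        ov <- table(prev = lab_prev[both], cur = lab_cur[both])
        pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$Freq > 0L, , drop = FALSE]
        pairs$prev <- as.integer(pairs$prev)
        pairs$cur <- as.integer(pairs$cur)
        pairs$ti <- match(pairs$prev, ifelse(cand, act$last_label, NA))
        pairs <- pairs[!is.na(pairs$ti), , drop = FALSE]
        pairs$oi <- match(pairs$cur, of$label)
        pairs <- pairs[!is.na(pairs$oi), , drop = FALSE]
        if (nrow(pairs)) {
          pairs$dlen <- abs(of$length_um[pairs$oi] - act$last_len[pairs$ti]) /
            act$last_len[pairs$ti]
          pairs <- pairs[order(-pairs$Freq, pairs$dlen), , drop = FALSE]
          # one-to-one greedy pass
          for (r in seq_len(nrow(pairs))) {
            ti <- pairs$ti[r]; oi <- pairs$oi[r]
            if (act$matched[ti] || assigned_obs[oi]) next
            if (pairs$dlen[r] >= params$max_length_change) next
            resume_traj(ti, of[oi, ])
            assigned_obs[oi] <- TRUE
          }
          # division pass: one mother footprint over two unclaimed children
          for (ti in unique(pairs$ti)) {
            if (act$matched[ti]) next
            pr <- pairs[pairs$ti == ti & !assigned_obs[pairs$oi], ,
                        drop = FALSE]
            if (nrow(pr) < 2L) next
            pr <- pr[order(-pr$Freq), , drop = FALSE][1:2, ]
            lsum <- sum(of$length_um[pr$oi])
            if (abs(lsum - act$last_len[ti]) / act$last_len[ti] >=
                params$max_length_change) next
            close_traj(ti, "divided", of$t_min[pr$oi[1]])
            mother <- act$tid[ti]
            act$matched[ti] <- TRUE
            act$miss[ti] <- -1L
            for (oi in pr$oi) {
              open_traj(mother, of[oi, ])
              assigned_obs[oi] <- TRUE
            }
          }
        }
      }
    }

    # gap bridging: resume held trajectories on similar reappearances
    if (nrow(of) && any(!assigned_obs)) {
      held <- which(!act$matched & act$miss >= 0L & act$last_frame < f)
      for (oi in which(!assigned_obs)) {
        if (!length(held)) break
        o <- of[oi, ]
        d <- sqrt((act$last_x[held] - o$x_um)^2 +
                    (act$last_y[held] - o$y_um)^2)
        sim <- abs(act$last_len[held] - o$length_um) / act$last_len[held]
        okh <- d <= act$last_len[held] & sim <= params$reappearance_similarity
        if (!any(okh)) next
        ti <- held[okh][which.min(d[okh])]
        resume_traj(ti, o)
        assigned_obs[oi] <- TRUE
        held <- setdiff(held, ti)
      }
    }

    # unclaimed observations start new parentless trajectories
    for (oi in which(!assigned_obs))
      open_traj(NA_integer_, of[oi, ])

    # age unmatched trajectories; close the ones past gap tolerance
    remove <- act$miss == -1L
    stale <- which(!act$matched & !remove)
    if (length(stale)) {
      act$miss[stale] <- act$miss[stale] + 1L
      over <- stale[act$miss[stale] > gap_frames]
      for (i in over)
        close_traj(i, "detached", (act$last_frame[i] - 1) / fps / 60)
      remove[over] <- TRUE
    }
    if (any(remove)) {
      act <- act[!remove, , drop = FALSE]
      rownames(act) <- NULL
    }
  }
  # movie end: censored if seen in the final frame, else detached
  for (i in seq_len(nrow(act)))
    close_traj(i, if (act$last_frame[i] == n_frames) "censored"
                  else "detached",
               (act$last_frame[i] - 1) / fps / 60)

  obs_out <- if (length(out_rows)) do.call(rbind, out_rows)
             else data.frame(traj_id = integer(0), parent_id = integer(0))
  lin <- if (length(closed)) do.call(rbind, closed)
         else data.frame(traj_id = integer(0), parent_id = integer(0),
                         start_min = numeric(0), end_min = numeric(0),
                         fate = character(0))
  lin <- lin[order(lin$traj_id), , drop = FALSE]
  rownames(lin) <- NULL
  obs_out <- obs_out[order(obs_out$traj_id, obs_out$frame), , drop = FALSE]
  rownames(obs_out) <- NULL
  obs_out$gr_eligible <- TRUE
  new("TrajectorySet", observations = obs_out, lineage = lin,
      params = unclass(params))
}

#' Filter trajectories for growth-rate analysis
#'
#' Drops trajectories shorter than \code{min_duration_min} and marks the
#' first and last \code{trim_min} minutes of the survivors as ineligible
#' for growth-rate estimation (those edges are noise-prone); the trimmed
#' observations are retained for counting.
#'
#' @param trajs a [TrajectorySet-class].
#' @param min_duration_min minimal trajectory span, minutes (default 10).
#' @param trim_min minutes trimmed from each end for GR eligibility.
#' @return a [TrajectorySet-class] with an updated \code{gr_eligible}
#'   column.
#' @export
filterForGrowth <- function(trajs, min_duration_min = 10, trim_min = 5) {
  stopifnot(is(trajs, "TrajectorySet"))
  obs <- observations(trajs)
  lin <- lineage(trajs)
  if (!nrow(obs)) return(trajs)
  span <- tapply(obs$t_min, obs$traj_id, function(t) diff(range(t)))
  keep_ids <- as.integer(names(span))[span >= min_duration_min]
  obs <- obs[obs$traj_id %in% keep_ids, , drop = FALSE]
  lin <- lin[lin$traj_id %in% keep_ids, , drop = FALSE]
  t0 <- tapply(obs$t_min, obs$traj_id, min)
  t1 <- tapply(obs$t_min, obs$traj_id, max)
  key <- as.character(obs$traj_id)
  obs$gr_eligible <- obs$t_min >= t0[key] + trim_min &
    obs$t_min <= t1[key] - trim_min
  rownames(obs) <- rownames(lin) <- NULL
  new("TrajectorySet", observations = obs, lineage = lin,
      params = trajs@params)
}
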