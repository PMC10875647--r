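# per-experiment initial/final GR metrics given the transition time
.experimentMetrics <- function(pop, t_i, bin_min = 20) {
  s <- pop$samples
  pre <- s$mean_gr_um_per_min[s$bin_start_min + bin_min <= t_i]
  post <- s$mean_gr_um_per_min[s$bin_start_min >= t_i]
  list(initial_gr = if (length(pre)) median(pre) else NA_real_,
       final_gr = if (length(post)) median(post) else NA_real_)
}

#' Run the full analysis pipeline on a scene or movie
#'
#' Executes the whole chain: (simulate and render when given a
#' [SceneConfig-class]) -> frame averaging -> illumination correction and
#' segmentation -> trajectory stitching -> growth-rate binning and
#' Gompertz fits -> duplication time -> colonization curve and mean
#' binding time -> full-rate orientation/wiggle windows; returns a result
#' bundle and optionally writes all tables plus a machine-readable
#' summary.  Any stage failure aborts with the stage name; already
#' computed artifacts are kept in the partial bundle attached to the
#' error condition.
#'
#' @param x a [SceneConfig-class] (synthetic run) or [MovieStack-class].
#' @param seg_params [segmentationParams()].
#' @param track_params [trackingParams()].
#' @param motion_windows_min window start times for the full-rate motion
#'   analysis, minutes; NULL skips motion analysis.
#' @param bin_min growth-rate bin width, minutes.
#' @param t2_time_varying logical; use time-varying T2(t) from the fits in
#'   the binding fit (default uses the constant end-of-experiment T2).
#' @param condition label stored in the summary.
#' @param out_dir optional directory for result tables and summary.json.
#' @return list (result bundle): truth (or NULL), seg, trajectories, pop,
#'   gr_fit, len_fit, T2_end, curve, binding (or NULL), motion (or NULL),
#'   summary (one-row data.frame).
#' @export
runPipeline <- function(x, seg_params = segmentationParams(),
                        track_params = trackingParams(),
                        motion_windows_min = NULL, bin_min = 20,
                        t2_time_varying = FALSE, condition = "control",
                        out_dir = NULL) {
  bundle <- list(condition = condition)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$bundle <- bundle
      stop(cond)
    })
  }
  truth <- NULL
  if (is(x, "SceneConfig")) {
    truth <- stage("simulate", simulateTruth(x))
    stack <- stage("render", renderMovie(truth, x))
    injection_end <- x@injection_window_min
  } else if (is(x, "MovieStack")) {
    stack <- x
    injection_end <- NULL
  } else stop("x must be a SceneConfig or a MovieStack")
  bundle$truth <- truth

  block <- seg_params$averaging_block
  avg <- if (block > 1L && block <= nFrames(stack))
    stage("average", averageFrames(stack, block)) else stack
  seg <- stage("segment", segmentStack(avg, seg_params))
  bundle$seg <- seg
  trajs <- stage("track", linkTrajectories(seg, track_params))
  filt <- stage("filter", filterForGrowth(trajs))
  bundle$trajectories <- filt
  pop <- stage("growth", binPopulation(filt, bin_min = bin_min))
  bundle$pop <- pop
  gr_fit <- stage("gompertz", fitGompertz(pop$bins$t_mid_min,
                                          pop$bins$gr_median))
  len_fit <- stage("gompertz", fitGompertz(pop$bins$t_mid_min,
                                           pop$bins$len_median))
  bundle$gr_fit <- gr_fit; bundle$len_fit <- len_fit
  t_i <- transitionTime(gr_fit)
  t_end <- max(pop$bins$t_mid_min)
  T2_end <- stage("t2", duplicationTime(len_fit, gr_fit, t_end, t_end))
  bundle$T2_end <- T2_end
  curve <- stage("curve", buildColonizationCurve(seg, injection_end))
  bundle$curve <- curve
  binding <- tryCatch({
    T2_arg <- if (t2_time_varying)
      function(s) duplicationTime(len_fit, gr_fit, s, t_end)
    else T2_end
    fitBindingTime(curve, T2_arg, t_i)
  }, error = function(e) {
    warning("binding fit skipped: ", conditionMessage(e))
    NULL
  })
  bundle$binding <- binding

  motion <- NULL
  if (!is.null(motion_windows_min)) {
    motion <- stage("motion", {
      ws <- lapply(motion_windows_min, function(w0) {
        f0 <- max(1L, floor(w0 * 60 * frameRate(stack)) + 1L)
        f1 <- min(nFrames(stack),
                  ceiling((w0 + 2) * 60 * frameRate(stack)))
        if (f1 - f0 < 2L) return(list())
        sub <- new("MovieStack",
                   frames = stack@frames[, , f0:f1, drop = FALSE],
                   frame_rate_fps = frameRate(stack),
                   pixel_size_um = pixelSize(stack))
        ss <- segmentStack(sub, seg_params)
        tw <- linkTrajectories(ss, track_params)
        ob <- observations(tw)
        if (!nrow(ob)) return(list())
        ob$t_min <- ob$t_min + (f0 - 1L) / frameRate(stack) / 60
        motionWindows(ob, w0)
      })
      names(ws) <- paste0("t", motion_windows_min)
      ws
    })
  }
  bundle$motion <- motion

  met <- .experimentMetrics(pop, t_i, bin_min)
  mode_frac <- function(ws) {
    if (is.null(ws) || !length(ws)) return(NA_real_)
    md <- vapply(ws, function(w)
      attr(suppressWarnings(wiggleProfile(w)), "mode"), "")
    mean(md == "rocking")
  }
  summary <- data.frame(
    condition = condition,
    n_trajectories = nrow(lineage(trajs)),
    initial_gr_um_min = met$initial_gr, final_gr_um_min = met$final_gr,
    transition_min = t_i, T2_end_min = T2_end,
    T_half_min = if (!is.null(binding)) binding@T_half else NA_real_,
    net_rate_per_min = if (!is.null(binding)) binding@net_rate
                       else NA_real_,
    N_final = curve$N[nrow(curve)],
    rocking_frac_early = if (!is.null(motion) && length(motion) >= 1L)
      mode_frac(motion[[1L]]) else NA_real_,
    rocking_frac_late = if (!is.null(motion) && length(motion) >= 2L)
      mode_frac(motion[[length(motion)]]) else NA_real_)
  bundle$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(observations(seg), file.path(out_dir, "observations.csv"),
              row.names = FALSE)
    write.csv(observations(filt), file.path(out_dir, "trajectories.csv"),
              row.names = FALSE)
    write.csv(lineage(filt), file.path(out_dir, "lineage.csv"),
              row.names = FALSE)
    write.csv(pop$bins, file.path(out_dir, "gr_bins.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(
      gr = as.list(gr_fit@coef), length = as.list(len_fit@coef),
      T2_end_min = T2_end),
      file.path(out_dir, "gompertz_fits.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(binding))
      jsonlite::write_json(list(N0 = binding@N0, t0 = binding@t0,
                                T_half_min = binding@T_half,
                                net_rate_per_min = binding@net_rate,
                                residual = binding@residual),
                           file.path(out_dir, "binding_fit.json"),
                           auto_unbox = TRUE, digits = NA)
    write.csv(summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
  }
  bundle
}

#' Render report figures for one or more result bundles
#'
#' Emits the standard panel set as figure files: colonization curve N(t)
#' with phases and binding-fit overlay, per-bin GR and length boxplots,
#' the Gompertz fit over the bin medians, the theta_M versus STD(theta)
#' scatter, and the pooled wiggle-profile bars.  With several bundles a
#' condition-grouped summary with SE whiskers is added.
#'
#' @param bundles a single bundle from [runPipeline()] or a list of them.
#' @param out_dir output directory.
#' @param device figure device, "pdf" or "png".
#' @return invisibly, the vector of files written.
#' @export
renderReport <- function(bundles, out_dir, device = c("pdf", "png")) {
  device <- match.arg(device)
  if (!is.null(bundles$summary)) bundles <- list(bundles)
  if (!length(bundles)) stop("no result bundles given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  b <- bundles[[1L]]
  files <- character(0)
  emit <- function(p, name, w = 6, h = 4) {
    f <- file.path(out_dir, paste0(name, ".", device))
    ggplot2::ggsave(f, p, width = w, height = h)
    files <<- c(files, f)
  }
  # N(t) with phases and, when available, the fitted exponential
  cv <- b$curve
  p1 <- ggplot2::ggplot(cv, ggplot2::aes(t_min, N, color = phase)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "bound bacteria N(t)") +
    ggplot2::theme_minimal()
  if (!is.null(b$binding)) {
    bf <- b$binding
    tt <- seq(bf@t0, max(cv$t_min), length.out = 100)
    ov <- data.frame(t_min = tt,
                     N = bf@N0 * exp(bf@net_rate * (tt - bf@t0)))
    p1 <- p1 + ggplot2::geom_line(data = ov,
                                  ggplot2::aes(t_min, N),
                                  inherit.aes = FALSE, linetype = 2,
                                  color = "red")
  } else warning("no binding fit; N(t) plotted without overlay")
  emit(p1, "colonization_curve")

  s <- b$pop$samples
  s$bin <- factor(s$bin_start_min)
  p2 <- ggplot2::ggplot(s, ggplot2::aes(bin, mean_gr_um_per_min)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "time bin (min)", y = "mean GR (um/min)") +
    ggplot2::theme_minimal()
  emit(p2, "gr_boxplots")
  p3 <- ggplot2::ggplot(s, ggplot2::aes(bin, mean_length_um)) +
    ggplot2::geom_boxplot(fill = "darkseagreen", alpha = 0.7) +
    ggplot2::labs(x = "time bin (min)", y = "mean length (um)") +
    ggplot2::theme_minimal()
  emit(p3, "length_boxplots")

  bins <- b$pop$bins
  tt <- seq(min(bins$t_mid_min), max(bins$t_mid_min), length.out = 100)
  fitln <- data.frame(t = tt, y = gompertzValue(b$gr_fit, tt))
  p4 <- ggplot2::ggplot(bins, ggplot2::aes(t_mid_min, gr_median)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitln, ggplot2::aes(t, y), color = "red") +
    ggplot2::geom_vline(xintercept = transitionTime(b$gr_fit),
                        linetype = 3) +
    ggplot2::labs(x = "time (min)", y = "median GR (um/min)") +
    ggplot2::theme_minimal()
  emit(p4, "gompertz_fit")

  ang <- prof <- NULL
  if (!is.null(b$motion) && length(b$motion) >= 1L) {
    labs <- names(b$motion)
    ms <- suppressWarnings(populationMotionSummary(
      b$motion[[1L]], if (length(b$motion) >= 2L)
        b$motion[[length(b$motion)]] else list()))
    ang <- ms$angles; prof <- ms$profiles
  }
  if (!is.null(ang) && nrow(ang)) {
    p5 <- ggplot2::ggplot(ang, ggplot2::aes(theta_std, theta_M,
                                            color = time)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "STD(theta) (deg)", y = "theta_M (deg)") +
      ggplot2::theme_minimal()
  } else {
    p5 <- ggplot2::ggplot() + ggplot2::theme_void() +
      ggplot2::annotate("text", 0, 0, label = "no motion windows")
  }
  emit(p5, "orientation_scatter")
  if (!is.null(prof) && nrow(prof)) {
    p6 <- ggplot2::ggplot(prof, ggplot2::aes(rel_pos_mid, sep_std_um,
                                             fill = time)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "position l / L", y = "sep std (um)") +
      ggplot2::theme_minimal()
  } else {
    p6 <- ggplot2::ggplot() + ggplot2::theme_void() +
      ggplot2::annotate("text", 0, 0, label = "no wiggle profiles")
  }
  emit(p6, "wiggle_profiles")

  if (length(bundles) > 1L) {
    summ <- do.call(rbind, lapply(bundles, `[[`, "summary"))
    long <- do.call(rbind, lapply(c("initial_gr_um_min", "final_gr_um_min",
                                    "transition_min"), function(m)
      data.frame(condition = summ$condition, metric = m,
                 value = summ[[m]])))
    agg <- do.call(rbind, lapply(split(long,
                                       list(long$condition, long$metric),
                                       drop = TRUE), function(g)
      data.frame(condition = g$condition[1], metric = g$metric[1],
                 mean = mean(g$value, na.rm = TRUE),
                 se = sd(g$value, na.rm = TRUE) /
                   sqrt(sum(is.finite(g$value))))))
    p7 <- ggplot2::ggplot(agg, ggplot2::aes(condition, mean,
                                            fill = condition)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se,
                                          ymax = mean + se), width = 0.3) +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::theme_minimal()
    emit(p7, "condition_summary", w = 8)
  }
  invisible(files)
}

#' @importFrom ggplot2 aes
NULL
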