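#' Momentaneous growth rate along a trajectory
#'
#' At each GR-eligible time point of a trajectory, the momentaneous growth
#' rate is the ordinary-least-squares slope of cell length versus time over
#' a window extending \code{half_window_min} on either side.  Points whose
#' window sticks out past the trajectory ends, or with fewer than three
#' observations in the window, are skipped.
#'
#' @param traj data.frame of one trajectory's observations (columns
#'   \code{t_min}, \code{length_um}, and optionally \code{gr_eligible}).
#' @param half_window_min half window, minutes (default 5).
#' @return data.frame with \code{t_min}, \code{gr_um_per_min},
#'   \code{length_um}, \code{n_window}.
#' @examples
#' tr <- data.frame(t_min = 0:30, length_um = 2 + 0.02 * (0:30))
#' head(momentaneousGR(tr))   # slope 0.02 everywhere
#' @export
momentaneousGR <- function(traj, half_window_min = 5) {
  stopifnot(all(c("t_min", "length_um") %in% names(traj)))
  traj <- traj[order(traj$t_min), , drop = FALSE]
  t <- traj$t_min; L <- traj$length_um
  elig <- if ("gr_eligible" %in% names(traj)) traj$gr_eligible
          else rep(TRUE, nrow(traj))
  t0 <- min(t); t1 <- max(t)
  out <- lapply(which(elig), function(i) {
    if (t[i] - half_window_min < t0 - 1e-9 ||
        t[i] + half_window_min > t1 + 1e-9) return(NULL)
    w <- which(t >= t[i] - half_window_min & t <= t[i] + half_window_min)
    if (length(w) < 3L) return(NULL)
    tw <- t[w] - t[i]
    slope <- sum(tw * (L[w] - mean(L[w]))) / sum(tw * (tw - mean(tw)))
    data.frame(t_min = t[i], gr_um_per_min = slope, length_um = L[i],
               n_window = length(w))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(t_min = numeric(0), gr_um_per_min = numeric(0),
                      length_um = numeric(0), n_window = integer(0)))
  do.call(rbind, out)
}

#' Bin per-cell growth rates over the experimental time axis
#'
#' Divides the time axis into fixed bins (default 20 min), computes the
#' mean momentaneous GR and mean length of each trajectory within each bin,
#' and summarizes the across-trajectory distribution per bin (median and
#' quartiles — the boxplot data of population GR(t) and L(t)).
#'
#' @param trajs a [TrajectorySet-class] (after [filterForGrowth()]).
#' @param bin_min bin width, minutes.
#' @param half_window_min passed to [momentaneousGR()].
#' @return list with \code{samples} (per trajectory per bin: traj_id,
#'   bin_start_min, mean_gr_um_per_min, mean_length_um, n_points) and
#'   \code{bins} (per bin: t_mid_min, n_cells, gr quartiles, length
#'   quartiles).
#' @export
binPopulation <- function(trajs, bin_min = 20, half_window_min = 5) {
  stopifnot(is(trajs, "TrajectorySet"))
  obs <- observations(trajs)
  empty <- list(
    samples = data.frame(traj_id = integer(0), bin_start_min = numeric(0),
                         mean_gr_um_per_min = numeric(0),
                         mean_length_um = numeric(0), n_points = integer(0)),
    bins = data.frame(t_mid_min = numeric(0), n_cells = integer(0),
                      gr_q1 = numeric(0), gr_median = numeric(0),
                      gr_q3 = numeric(0), len_q1 = numeric(0),
                      len_median = numeric(0), len_q3 = numeric(0)))
  if (!nrow(obs)) return(empty)
  gr_all <- lapply(split(obs, obs$traj_id), function(tro) {
    g <- momentaneousGR(tro, half_window_min)
    if (nrow(g)) g$traj_id <- tro$traj_id[1]
    g
  })
  gr_all <- do.call(rbind, gr_all[vapply(gr_all, nrow, 0L) > 0])
  if (is.null(gr_all) || !nrow(gr_all)) return(empty)
  gr_all$bin_start_min <- floor(gr_all$t_min / bin_min) * bin_min
  sp <- split(gr_all, list(gr_all$traj_id, gr_all$bin_start_min),
              drop = TRUE)
  samples <- do.call(rbind, lapply(sp, function(g)
    data.frame(traj_id = g$traj_id[1], bin_start_min = g$bin_start_min[1],
               mean_gr_um_per_min = mean(g$gr_um_per_min),
               mean_length_um = mean(g$length_um), n_points = nrow(g))))
  rownames(samples) <- NULL
  samples <- samples[order(samples$bin_start_min, samples$traj_id), ]
  bins <- do.call(rbind, lapply(split(samples, samples$bin_start_min),
    function(s) {
      qg <- quantile(s$mean_gr_um_per_min, c(0.25, 0.5, 0.75), names = FALSE)
      ql <- quantile(s$mean_length_um, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(t_mid_min = s$bin_start_min[1] + bin_min / 2,
                 n_cells = nrow(s), gr_q1 = qg[1], gr_median = qg[2],
                 gr_q3 = qg[3], len_q1 = ql[1], len_median = ql[2],
                 len_q3 = ql[3])
    }))
  rownames(bins) <- NULL
  list(samples = samples, bins = bins)
}

#' Duplication time from fitted population curves
#'
#' \eqn{T_2(t) = (2/3) \times L(t_{end}) / GR(t)}: the characteristic
#' division interval implied by the fitted final length and the fitted
#' growth rate at time \code{t}.  A non-positive GR yields an infinite
#' duplication time with a warning.
#'
#' @param L_fit [GompertzFit-class] of population length L(t).
#' @param GR_fit [GompertzFit-class] of population growth rate GR(t).
#' @param t time(s) at which to evaluate, minutes.
#' @param t_end end of the analyzed interval (default: last data point of
#'   the GR fit; the center of the last populated bin).
#' @return duplication time(s) in minutes.
#' @examples
#' Lf <- gompertzParams(3, 4.5, 0.05, 60)    # length plateaus at 4.5 um
#' Gf <- gompertzParams(0.1, 0.1001, 0.05, 60)
#' duplicationTime(Lf, Gf, t = 180, t_end = 180)   # (2/3)*4.5/0.1 = 30 min
#' @export
duplicationTime <- function(L_fit, GR_fit, t, t_end = NULL) {
  stopifnot(is(L_fit, "GompertzFit"), is(GR_fit, "GompertzFit"))
  if (is.null(t_end)) {
    if (!nrow(GR_fit@data))
      stop("t_end must be given when the GR fit carries no data")
    t_end <- max(GR_fit@data$t)
  }
  L_end <- gompertzValue(L_fit, t_end)
  gr <- gompertzValue(GR_fit, t)
  T2 <- (2 / 3) * L_end / gr
  if (any(gr <= 0)) {
    warning("non-positive GR: infinite duplication time")
    T2[gr <= 0] <- Inf
  }
  T2
}

#' Summarize replicate experiments and test condition contrasts
#'
#' For each experiment, the initial (final) GR is the median of the
#' per-cell mean GRs pooled over the bins strictly before (after) the
#' experiment's transition time — the inflection of its Gompertz GR(t)
#' fit.  Replicate summaries are the mean and standard error across the
#' experiments of each condition, per bin and per metric; condition pairs
#' are compared with Welch two-sample t-tests.
#'
#' @param experiments list; each element is one experiment's
#'   [binPopulation()] result (needs \code{$samples}).
#' @param condition character vector, one condition label per experiment.
#' @param transition_times optional numeric vector of per-experiment
#'   transition times (minutes); when NULL each experiment's GR(t) bin
#'   medians are fitted with [fitGompertz()] to obtain them.
#' @param bin_min bin width used, minutes.
#' @return list with \code{per_experiment} (condition, initial_gr,
#'   final_gr, transition_min), \code{summary} (per condition and metric:
#'   mean, se, n; se is NA for a single experiment), \code{bin_summary}
#'   (per condition per bin: mean and SE of the bin medians) and
#'   \code{tests} (per condition pair and metric: Welch t statistic, df,
#'   p value).
#' @export
summarizeReplicates <- function(experiments, condition,
                                transition_times = NULL, bin_min = 20) {
  stopifnot(length(experiments) == length(condition))
  n_exp <- length(experiments)
  per <- lapply(seq_len(n_exp), function(i) {
    s <- experiments[[i]]$samples
    b <- experiments[[i]]$bins
    ti <- if (!is.null(transition_times)) transition_times[i]
          else transitionTime(fitGompertz(b$t_mid_min, b$gr_median))
    pre <- s$mean_gr_um_per_min[s$bin_start_min + bin_min <= ti]
    post <- s$mean_gr_um_per_min[s$bin_start_min >= ti]
    data.frame(experiment = i, condition = condition[i],
               initial_gr = if (length(pre)) median(pre) else NA_real_,
               final_gr = if (length(post)) median(post) else NA_real_,
               transition_min = ti)
  })
  per <- do.call(rbind, per)
  metrics <- c("initial_gr", "final_gr", "transition_min")
  summ <- do.call(rbind, lapply(split(per, per$condition), function(p)
    do.call(rbind, lapply(metrics, function(m) {
      v <- p[[m]][is.finite(p[[m]])]
      data.frame(condition = p$condition[1], metric = m,
                 mean = mean(v), se = if (length(v) >= 2L)
                   sd(v) / sqrt(length(v)) else NA_real_,
                 n = length(v))
    }))))
  rownames(summ) <- NULL
  # per-bin mean +/- SE of the experiments' bin medians
  binrows <- do.call(rbind, lapply(seq_len(n_exp), function(i) {
    b <- experiments[[i]]$bins
    if (!nrow(b)) return(NULL)
    data.frame(condition = condition[i], t_mid_min = b$t_mid_min,
               gr_median = b$gr_median, len_median = b$len_median)
  }))
  bin_summary <- if (!is.null(binrows))
    do.call(rbind, lapply(split(binrows,
                                list(binrows$condition, binrows$t_mid_min),
                                drop = TRUE), function(b)
      data.frame(condition = b$condition[1], t_mid_min = b$t_mid_min[1],
                 gr_mean = mean(b$gr_median),
                 gr_se = if (nrow(b) >= 2L)
                   sd(b$gr_median) / sqrt(nrow(b)) else NA_real_,
                 len_mean = mean(b$len_median),
                 len_se = if (nrow(b) >= 2L)
                   sd(b$len_median) / sqrt(nrow(b)) else NA_real_,
                 n = nrow(b))))
  else data.frame()
  rownames(bin_summary) <- NULL
  conds <- unique(condition)
  tests <- if (length(conds) >= 2L) {
    prs <- utils::combn(conds, 2L, simplify = FALSE)
    do.call(rbind, lapply(prs, function(pr)
      do.call(rbind, lapply(metrics, function(m) {
        a <- per[[m]][per$condition == pr[1]]
        b <- per[[m]][per$condition == pr[2]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2L || length(b) < 2L)
          return(data.frame(condition_a = pr[1], condition_b = pr[2],
                            metric = m, t = NA_real_, df = NA_real_,
                            p_value = NA_real_))
        tt <- tryCatch(t.test(a, b), error = function(e) NULL)
        if (is.null(tt))   # e.g. both groups essentially constant
          return(data.frame(condition_a = pr[1], condition_b = pr[2],
                            metric = m, t = NA_real_, df = NA_real_,
                            p_value = NA_real_))
        data.frame(condition_a = pr[1], condition_b = pr[2], metric = m,
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
      }))))
  } else data.frame()
  rownames(tests) <- NULL
  list(per_experiment = per, summary = summ, bin_summary = bin_summary,
       tests = tests)
}
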