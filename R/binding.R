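#' Build a colonization curve from segmented observations
#'
#' Counts gated objects per (averaged) frame to give N(t), the number of
#' surface-bound bacteria versus time, and annotates the three phases of
#' surface colonization: binding (arrivals during the injection window),
#' plateau (lag with little net change), and exponential (division-driven
#' increase).  Phase boundaries are found by slope changes of the smoothed
#' curve: the binding phase ends at the injection end (or where the initial
#' rise flattens), and the exponential phase starts at the last sustained
#' upturn of log N.
#'
#' @param seg a [SegmentationStack-class] (or a data.frame of observations
#'   with \code{frame}/\code{t_min} columns plus \code{n_frames} and
#'   \code{frame_rate_fps} attributes supplied via arguments).
#' @param injection_end_min end of the injection window, minutes (used to
#'   seed the phase annotation); NULL to infer from the first flattening.
#' @return data.frame of class \code{colonization_curve} with columns
#'   \code{t_min}, \code{N}, \code{phase} (factor binding/plateau/
#'   exponential) and attribute \code{injection_end_min}.
#' @export
buildColonizationCurve <- function(seg, injection_end_min = NULL) {
  stopifnot(is(seg, "SegmentationStack"))
  n_frames <- nFrames(seg)
  fps <- frameRate(seg)
  obs <- observations(seg)
  N <- integer(n_frames)
  if (nrow(obs)) {
    tab <- table(factor(obs$frame, levels = seq_len(n_frames)))
    N <- as.integer(tab)
  }
  t_min <- (seq_len(n_frames) - 1) / fps / 60
  # smooth with a short running mean for slope detection
  k <- max(1L, min(5L, n_frames %/% 4L))
  Ns <- as.numeric(stats::filter(N, rep(1 / k, k), sides = 2))
  Ns[is.na(Ns)] <- N[is.na(Ns)]
  slope <- c(0, diff(Ns)) * fps * 60            # counts per minute
  inj <- if (!is.null(injection_end_min)) injection_end_min
         else {
    flat <- which(t_min > min(t_min) & slope <= 0)
    if (length(flat)) t_min[flat[1]] else max(t_min)
  }
  # exponential onset: last time log N starts a sustained rise
  phase <- rep("plateau", n_frames)
  phase[t_min < inj] <- "binding"
  pos <- slope > 0 & t_min >= inj
  expo_start <- NA_real_
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths >= max(2L, k))
    if (length(runs)) {
      i0 <- ends[runs[length(runs)]] - r$lengths[runs[length(runs)]] + 1L
      expo_start <- t_min[i0]
      phase[t_min >= expo_start] <- "exponential"
    }
  }
  out <- data.frame(t_min = t_min, N = N,
                    phase = factor(phase, levels = c("binding", "plateau",
                                                     "exponential")))
  attr(out, "injection_end_min") <- inj
  attr(out, "exponential_start_min") <- expo_start
  class(out) <- c("colonization_curve", class(out))
  out
}

#' Estimate the mean binding time from a colonization curve
#'
#' After division starts (at \eqn{t_0}, taken as the inflection of the
#' Gompertz GR(t) fit), the bound count follows a net growth–release
#' exponential
#' \deqn{N(t) = N_0 \exp\!\Big(\int_{t_0}^{t}\big[\ln 2 / T_2(s) -
#'   \ln 2 / T_{1/2}\big]\,ds\Big),}
#' where \eqn{T_2} is the duplication time and \eqn{T_{1/2}} the mean
#' binding (surface residence half-life) time.  The fit is linear least
#' squares on \eqn{\log N} with weights proportional to N
#' (variance-stabilizing for Poisson counts): the division contribution
#' \eqn{\int \ln 2 / T_2} is computed from the supplied duplication time
#' (constant, or time-varying via a function) and subtracted, and the
#' remaining slope gives the detachment rate \eqn{\ln 2 / T_{1/2}}.
#' A non-positive fitted detachment rate (no resolvable detachment) gives
#' \code{T_half = Inf}.  Works equally for detachment-dominated curves
#' (net rate < 0), as for weakly adherent mutants.
#'
#' @param curve a \code{colonization_curve} from [buildColonizationCurve()]
#'   (or any data.frame with \code{t_min}, \code{N}).
#' @param T2 duplication time: a single number (minutes), a function of
#'   time t (minutes), or \code{Inf} for no division.
#' @param t0 start of the division phase, minutes (the transition time).
#' @return a [BindingFit-class].
#' @examples
#' t <- seq(60, 180, by = 10)
#' N <- 100 * exp((log(2) / 30 - log(2) / 60) * (t - 60))
#' fitBindingTime(data.frame(t_min = t, N = N), T2 = 30, t0 = 60)
#' @export
fitBindingTime <- function(curve, T2, t0) {
  stopifnot(all(c("t_min", "N") %in% names(curve)))
  d <- curve[curve$t_min >= t0 & curve$N > 0, , drop = FALSE]
  if (nrow(d) < 6L)
    stop("fewer than 6 positive-count points after t0")
  # cumulative division contribution D(t) = int_{t0}^{t} ln2 / T2(s) ds
  Dt <- if (is.function(T2)) {
    vapply(d$t_min, function(tt) {
      if (tt <= t0) return(0)
      stats::integrate(function(s) log(2) / vapply(s, T2, 0), t0, tt,
                       rel.tol = 1e-8)$value
    }, 0)
  } else if (is.infinite(T2)) {
    rep(0, nrow(d))
  } else {
    log(2) / T2 * (d$t_min - t0)
  }
  y <- log(d$N) - Dt
  fit <- lm(y ~ I(t_min - t0), data = d, weights = d$N)
  r_det <- -unname(coef(fit)[2])          # detachment rate, 1/min
  net_fit <- lm(log(N) ~ I(t_min - t0), data = d, weights = d$N)
  T_half <- if (r_det > 1e-9) log(2) / r_det else Inf
  new("BindingFit", N0 = exp(unname(coef(fit)[1])), t0 = t0,
      T_half = T_half, net_rate = unname(coef(net_fit)[2]),
      residual = summary(fit)$sigma,
      data = data.frame(t = d$t_min, N = d$N))
}
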