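#' Construct a prescribed Gompertz parameter set
#'
#' Builds a [GompertzFit-class] object from known parameters, e.g. to
#' prescribe the population growth-rate schedule of a synthetic scene.
#'
#' @param y0 baseline value (same units as the fitted quantity).
#' @param A plateau value; must exceed \code{y0} for a growth-phase schedule.
#' @param k rate constant, 1/min.
#' @param t_i inflection (transition) time, minutes.
#' @return a [GompertzFit-class] object.
#' @examples
#' sched <- gompertzParams(y0 = 0.01, A = 0.025, k = 0.05, t_i = 60)
#' gompertzValue(sched, c(0, 60, 180))
#' @export
gompertzParams <- function(y0, A, k, t_i) {
  new("GompertzFit", coef = c(y0 = y0, A = A, k = k, t_i = t_i),
      vcov = matrix(0, 4, 4,
                    dimnames = list(c("y0", "A", "k", "t_i"),
                                    c("y0", "A", "k", "t_i"))),
      residual = NA_real_, data = data.frame(), degenerate = FALSE)
}

#' Evaluate a Gompertz curve
#'
#' @param object a [GompertzFit-class].
#' @param t time(s), minutes.
#' @return \eqn{y_0 + (A - y_0)\exp(-\exp(-k(t - t_i)))} at \code{t}.
#' @rdname gompertz
#' @export
gompertzValue <- function(object, t) {
  stopifnot(is(object, "GompertzFit"))
  if (object@degenerate)
    stop("degenerate Gompertz fit: curve undefined")
  co <- object@coef
  co[["y0"]] + (co[["A"]] - co[["y0"]]) *
    exp(-exp(-co[["k"]] * (t - co[["t_i"]])))
}

#' @describeIn gompertz transition time = the sigmoid's inflection
#'   \code{t_i}; errors for degenerate fits.
#' @export
setMethod("transitionTime", "GompertzFit", function(object) {
  if (object@degenerate)
    stop("degenerate Gompertz fit: transition time undefined")
  object@coef[["t_i"]]
})

#' Fit a Gompertz function to binned population medians
#'
#' Least-squares fit of \eqn{y(t) = y_0 + (A - y_0)\exp(-\exp(-k(t - t_i)))}
#' to (t, y) pairs, typically the per-bin medians of GR or length.  Uses
#' multi-start Levenberg–Marquardt (\code{minpack.lm::nlsLM}): y0 and A from
#' the data extremes, t_i over a coarse grid across the time span, k over a
#' decade grid, keeping the lowest residual sum of squares.
#'
#' Data with no usable rise (range below \code{degenerate_tol} of |median|,
#' or below machine noise) yield a degenerate fit whose transition time is
#' undefined; downstream accessors raise an error for such fits.
#'
#' @param t time of each bin (center), minutes.
#' @param y response (median GR in µm/min, or median length in µm).
#' @param degenerate_tol relative range below which the data are declared
#'   flat.
#' @return a [GompertzFit-class] with coefficients, covariance and residual sd.
#' @examples
#' t <- seq(10, 170, by = 20)
#' y <- gompertzValue(gompertzParams(0.01, 0.025, 0.05, 60), t)
#' fitGompertz(t, y)
#' @export
fitGompertz <- function(t, y, degenerate_tol = 0.02) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 5L)
    stop("need at least 5 bins to fit a Gompertz function")
  rng <- diff(range(y))
  if (rng <= degenerate_tol * max(abs(median(y)), .Machine$double.eps)) {
    fit <- new("GompertzFit",
               coef = c(y0 = median(y), A = median(y), k = NA_real_,
                        t_i = NA_real_),
               vcov = matrix(NA_real_, 4, 4), residual = sd(y),
               data = data.frame(t = t, y = y), degenerate = TRUE)
    return(fit)
  }
  span <- diff(range(t))
  starts <- expand.grid(
    t_i = quantile(t, c(0.2, 0.35, 0.5, 0.65, 0.8), names = FALSE),
    k = c(0.5, 1, 2, 5, 10) / span)
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + (A - y0) * exp(-exp(-k * (t - t_i))),
        start = list(y0 = min(y), A = max(y), k = starts$k[i],
                     t_i = starts$t_i[i]),
        lower = c(y0 = -Inf, A = -Inf, k = 1e-6, t_i = min(t) - 2 * span),
        upper = c(y0 = Inf, A = Inf, k = Inf, t_i = max(t) + 2 * span),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.finite(rss) && rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("Gompertz fit failed to converge from any start (best residual Inf)")
  co <- coef(best)
  vc <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, 4, 4))
  new("GompertzFit",
      coef = c(y0 = unname(co["y0"]), A = unname(co["A"]),
               k = unname(co["k"]), t_i = unname(co["t_i"])),
      vcov = vc, residual = sqrt(best_rss / max(1L, length(t) - 4L)),
      data = data.frame(t = t, y = y), degenerate = FALSE)
}

#' @importFrom stats residuals
NULL
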