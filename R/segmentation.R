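#' Segmentation parameters
#'
#' Parameters of the mask-construction chain: offset subtraction, two
#' rounds of median filtering, marker-controlled watershed, and shape/size
#' gating.  Gates default to area 1–15 µm², aspect ratio >= 1.4 and
#' solidity >= 0.85, which pass rod-shaped bacteria while rejecting round
#' nanoparticle confounders and debris.
#'
#' @param averaging_block frames averaged together before segmentation to
#'   suppress unbound (moving) cells; 20 reduces 2 fps footage to 0.1 fps.
#' @param intensity_offset user-set constant subtracted from the
#'   illumination-corrected image (foreground magnitude scale, cells ~0.45).
#' @param median_radius radius (px) of each of the two median-filter passes.
#' @param min_area_um2,max_area_um2 area gate, µm².
#' @param min_aspect_ratio length/width gate (>= 1).
#' @param max_aspect_ratio upper aspect gate to drop filamentous debris.
#' @param min_solidity solidity (area / convex area) gate.
#' @param watershed_tolerance h-maxima depth (intensity units of the
#'   corrected image) for watershed marker suppression; object seams
#'   deeper than this split.
#' @return a named list of class \code{bacflow_seg_params}.
#' @export
segmentationParams <- function(averaging_block = 20L, intensity_offset = 0.22,
                               median_radius = 1L, min_area_um2 = 1,
                               max_area_um2 = 15, min_aspect_ratio = 1.4,
                               max_aspect_ratio = 15, min_solidity = 0.85,
                               watershed_tolerance = 0.08) {
  stopifnot(averaging_block >= 1L, min_area_um2 > 0,
            max_area_um2 > min_area_um2, min_aspect_ratio >= 1)
  structure(list(averaging_block = as.integer(averaging_block),
                 intensity_offset = intensity_offset,
                 median_radius = as.integer(median_radius),
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_aspect_ratio = min_aspect_ratio,
                 max_aspect_ratio = max_aspect_ratio,
                 min_solidity = min_solidity,
                 watershed_tolerance = watershed_tolerance),
            class = "bacflow_seg_params")
}

#' Average consecutive frames
#'
#' Replaces every block of consecutive frames by their arithmetic mean,
#' dividing the effective frame rate by the block size (20-frame averaging
#' turns 2 fps footage into 0.1 fps).  Bound cells, which barely move, stay
#' sharp while unbound cells advected by the flow are blurred into the
#' background.  A trailing remainder that does not fill a block is dropped
#' with a message.
#'
#' @param stack a [MovieStack-class].
#' @param block number of consecutive frames per average.
#' @return a [MovieStack-class] with \code{frameRate(stack) / block}.
#' @examples
#' arr <- array(runif(16 * 16 * 40), c(16, 16, 40))
#' mv <- new("MovieStack", frames = arr, frame_rate_fps = 2,
#'           pixel_size_um = 0.2)
#' frameRate(averageFrames(mv, 20))   # 0.1
#' @export
averageFrames <- function(stack, block) {
  stopifnot(is(stack, "MovieStack"))
  block <- as.integer(block)
  n <- nFrames(stack)
  if (block < 1L) stop("block must be >= 1")
  if (block > n) stop("block exceeds stack length")
  if (block == 1L) return(stack)
  n_out <- n %/% block
  if (n %% block != 0L)
    message(sprintf("dropping %d trailing frame(s) not filling a block",
                    n %% block))
  d <- dim(stack@frames)
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (i in seq_len(n_out)) {
    idx <- ((i - 1L) * block + 1L):(i * block)
    out[, , i] <- rowMeans(stack@frames[, , idx, drop = FALSE], dims = 2)
  }
  new("MovieStack", frames = out,
      frame_rate_fps = stack@frame_rate_fps / block,
      pixel_size_um = stack@pixel_size_um)
}

#' Correct uneven illumination and subtract the background
#'
#' Fits a low-order (quadratic) polynomial surface to the background of a
#' brightfield frame by iteratively reweighted least squares in which
#' pixels much darker than the surface (the cells) are excluded, divides
#' the frame by the fitted field, and subtracts the residual background
#' level.  The result has background ~ 0 with cells as positive-going
#' magnitudes (fractional attenuation).
#'
#' @param frame numeric matrix (one movie frame, intensities in [0, 1]).
#' @param subsample fit the surface on every n-th pixel for speed.
#' @param n_iter robust reweighting iterations.
#' @return corrected matrix, with the fitted illumination surface attached
#'   as attribute \code{background}.
#' @export
correctIllumination <- function(frame, subsample = 4L, n_iter = 3L) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (sd(frame) < 1e-12) {
    warning("degenerate constant frame; returning zeros")
    out <- frame * 0
    attr(out, "background") <- frame
    return(out)
  }
  d <- dim(frame)
  ix <- seq(1L, d[1], by = subsample); jy <- seq(1L, d[2], by = subsample)
  X <- (ix - 0.5) / d[1] * 2 - 1; Y <- (jy - 0.5) / d[2] * 2 - 1
  g <- expand.grid(x = X, y = Y)
  z <- as.vector(frame[ix, jy])
  keep <- rep(TRUE, length(z))
  for (it in seq_len(n_iter)) {
    fit <- lm(z ~ x + y + I(x^2) + I(x * y) + I(y^2),
              data = g, subset = keep)
    r <- z - predict(fit, g)
    s <- mad(r[keep])
    if (s < 1e-12) break
    keep <- r > -2.5 * s      # cells are darker than the surface
  }
  Xf <- (seq_len(d[1]) - 0.5) / d[1] * 2 - 1
  Yf <- (seq_len(d[2]) - 0.5) / d[2] * 2 - 1
  co <- coef(fit)
  bg <- outer(Xf, Yf, function(x, y)
    co[1] + co[2] * x + co[3] * y + co[4] * x^2 + co[5] * x * y +
      co[6] * y^2)
  corr <- 1 - frame / pmax(bg, 1e-6)
  corr <- corr - median(corr)
  attr(corr, "background") <- bg
  corr
}

# vectorized 3x3 median via a 19-exchange selection network
# (edges handled by replication); much faster than a histogram median
.median3x3 <- function(img) {
  d <- dim(img)
  pad <- matrix(0, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- img
  pad[1L, ] <- pad[2L, ]; pad[d[1] + 2L, ] <- pad[d[1] + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, d[2] + 2L] <- pad[, d[2] + 1L]
  a <- vector("list", 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    a[[k]] <- pad[(1L + di):(d[1] + di), (1L + dj):(d[2] + dj)]
  }
  cx <- function(i, j) {
    lo <- pmin(a[[i]], a[[j]]); hi <- pmax(a[[i]], a[[j]])
    a[[i]] <<- lo; a[[j]] <<- hi
  }
  net <- list(c(2,3), c(5,6), c(8,9), c(1,2), c(4,5), c(7,8), c(2,3),
              c(5,6), c(8,9), c(1,4), c(6,9), c(5,8), c(4,7), c(2,5),
              c(3,6), c(5,8), c(3,5), c(7,5), c(3,5))
  for (p in net) cx(p[1], p[2])
  a[[5]]
}

# per-region shape/intensity features from a label matrix
.regionFeatures <- function(labels, intensity, pixel_size_um) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), length_um = numeric(0),
                      width_um = numeric(0), theta_deg = numeric(0),
                      theta_axis_deg = numeric(0), area_um2 = numeric(0),
                      solidity = numeric(0), mean_intensity = numeric(0)))
  lab <- labels[idx]
  ivals <- intensity[idx]
  groups <- split(seq_len(nrow(idx)), lab)
  rows <- lapply(names(groups), function(lb) {
    g <- groups[[lb]]
    x <- idx[g, 1] - 0.5; y <- idx[g, 2] - 0.5   # pixel centers
    n <- length(g)
    wt <- pmax(ivals[g], 0); if (sum(wt) <= 0) wt <- rep(1, n)
    wt <- wt / sum(wt)
    cx <- sum(wt * x); cy <- sum(wt * y)
    if (n >= 3L) {
      # intensity-weighted second moments give sub-pixel orientation
      cv <- matrix(c(sum(wt * (x - cx)^2), sum(wt * (x - cx) * (y - cy)),
                     sum(wt * (x - cx) * (y - cy)), sum(wt * (y - cy)^2)),
                   2, 2) + diag(1 / 12, 2)
      eg <- eigen(cv, symmetric = TRUE)
      v <- eg$vectors[, 1]
      theta_axis <- atan2(v[2], v[1]) * 180 / pi
      if (theta_axis <= -90) theta_axis <- theta_axis + 180
      if (theta_axis > 90) theta_axis <- theta_axis - 180
      pr_major <- (x - cx) * v[1] + (y - cy) * v[2]
      ext_px <- diff(range(pr_major)) + 1
      # area / length: a rod-width estimator insensitive to the small
      # axis errors that inflate the minor-axis extent of short cells
      wid_px <- min(n / ext_px, ext_px)
      # sub-pixel length: integrated attenuation divided by the plateau
      # of the axial line-density profile, over the footprint dilated by
      # 2 px (the corrected background is ~0, and blur preserves the
      # integral, so the dilated sums are rotation- and quantization-
      # smooth where the raw footprint extent is not); the spherocylinder
      # cap correction W (1 - pi/4) completes the area inversion
      d1 <- nrow(labels); d2 <- ncol(labels)
      i0 <- max(1L, min(idx[g, 1]) - 2L); i1 <- min(d1, max(idx[g, 1]) + 2L)
      j0 <- max(1L, min(idx[g, 2]) - 2L); j1 <- min(d2, max(idx[g, 2]) + 2L)
      sub_lab <- labels[i0:i1, j0:j1]
      keep <- sub_lab == 0L | sub_lab == as.integer(lb)
      sub_int <- intensity[i0:i1, j0:j1]
      xs <- (matrix(i0:i1, i1 - i0 + 1L, j1 - j0 + 1L) - 0.5)[keep]
      ys <- (matrix(j0:j1, i1 - i0 + 1L, j1 - j0 + 1L,
                    byrow = TRUE) - 0.5)[keep]
      wd <- sub_int[keep]                  # signed: background averages 0
      sd_ <- (xs - cx) * v[1] + (ys - cy) * v[2]
      s0 <- sd_ - min(sd_)
      b0 <- floor(s0); frc <- s0 - b0
      nb <- max(b0) + 2L
      line_mass <- vapply(seq_len(nb) - 1L, function(b)
        sum(wd[b0 == b] * (1 - frc[b0 == b])) +
          sum(wd[b0 == b - 1L] * frc[b0 == b - 1L]), 0)
      core <- line_mass[seq.int(max(1L, floor(nb * 0.35)),
                                ceiling(nb * 0.65))]
      plateau <- median(core)
      len_px <- if (is.finite(plateau) && plateau > 0)
        sum(wd) / plateau + wid_px * (1 - pi / 4)
      else ext_px
      if (!is.finite(len_px) || len_px < wid_px ||
          abs(len_px - ext_px) > 3) len_px <- ext_px
    } else {
      theta_axis <- 0; len_px <- wid_px <- sqrt(n)
    }
    sol <- if (n >= 4L) {
      h <- grDevices::chull(x, y)
      hx <- x[h]; hy <- y[h]
      ha <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
      hp <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
      min(1, n / (ha + hp / 2 + 1))   # Pick-style pixel-count estimate
    } else 1
    data.frame(label = as.integer(lb), x_um = cx * pixel_size_um,
               y_um = cy * pixel_size_um,
               length_um = len_px * pixel_size_um,
               width_um = wid_px * pixel_size_um,
               theta_deg = abs(theta_axis), theta_axis_deg = theta_axis,
               area_um2 = n * pixel_size_um^2, solidity = sol,
               mean_intensity = mean(ivals[g]))
  })
  do.call(rbind, rows)
}

#' Segment one illumination-corrected frame
#'
#' Applies, in order: subtraction of the user-set constant intensity offset
#' (clamped at zero), two rounds of median filtering, marker-controlled
#' watershed on the Euclidean distance transform of the foreground mask
#' (markers = regional maxima surviving h-maxima suppression at
#' \code{watershed_tolerance}), and the shape/size gates.  Each surviving
#' region is reported with centroid, axis-projected length and width,
#' moment-based orientation (signed in (-90, 90] and folded to [0, 90]),
#' area, solidity and mean corrected intensity.
#'
#' @param frame illumination-corrected matrix (see [correctIllumination()]).
#' @param params a [segmentationParams()] list.
#' @param pixel_size_um µm per pixel.
#' @return list with \code{observations} (data.frame) and \code{labels}
#'   (integer matrix, 0 = background); an empty foreground yields an empty
#'   observation table, not an error.
#' @export
segmentFrame <- function(frame, params = segmentationParams(),
                         pixel_size_um) {
  img <- pmax(frame - params$intensity_offset, 0)
  img <- pmin(img, 1)
  for (pass in 1:2)
    img <- if (params$median_radius == 1L) .median3x3(img)
           else as.matrix(EBImage::medianFilter(EBImage::Image(img),
                                                size = params$median_radius))
  mask <- img > 1e-4
  if (!any(mask))
    return(list(observations = .regionFeatures(matrix(0L, nrow(frame),
                                                      ncol(frame)),
                                               frame, pixel_size_um),
                labels = matrix(0L, nrow(frame), ncol(frame))))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  # elevation = filtered attenuation magnitude: touching cells keep a
  # brighter seam (shallower attenuation) that forms the watershed line,
  # which a distance transform of the solid mask would miss
  elev <- img
  elev[mask == 0] <- 0
  labels <- EBImage::watershed(EBImage::Image(elev),
                               tolerance = params$watershed_tolerance,
                               ext = 1)
  labels <- matrix(as.integer(labels), nrow(frame), ncol(frame))
  feats <- .regionFeatures(labels, frame, pixel_size_um)
  keep <- feats$area_um2 >= params$min_area_um2 &
    feats$area_um2 <= params$max_area_um2 &
    feats$length_um / feats$width_um >= params$min_aspect_ratio &
    feats$length_um / feats$width_um <= params$max_aspect_ratio &
    feats$solidity >= params$min_solidity
  drop <- feats$label[!keep]
  if (length(drop)) labels[labels %in% drop] <- 0L
  feats <- feats[keep, , drop = FALSE]
  # renumber labels 1..n for downstream overlap bookkeeping
  if (nrow(feats)) {
    remap <- integer(max(feats$label))
    remap[feats$label] <- seq_len(nrow(feats))
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    feats$label <- seq_len(nrow(feats))
  }
  rownames(feats) <- NULL
  list(observations = feats, labels = labels)
}

#' Segment a whole stack
#'
#' Runs illumination correction and [segmentFrame()] on every frame of a
#' (typically frame-averaged) movie and collects the per-frame observation
#' tables and label matrices.
#'
#' @param stack a [MovieStack-class].
#' @param params a [segmentationParams()] list.
#' @param correct logical; apply [correctIllumination()] per frame.
#' @return a [SegmentationStack-class].
#' @export
segmentStack <- function(stack, params = segmentationParams(),
                         correct = TRUE) {
  stopifnot(is(stack, "MovieStack"))
  n <- nFrames(stack)
  obs <- vector("list", n); labs <- vector("list", n)
  for (f in seq_len(n)) {
    fr <- stack@frames[, , f]
    if (correct) fr <- correctIllumination(fr)
    sf <- segmentFrame(fr, params, pixelSize(stack))
    if (nrow(sf$observations)) {
      sf$observations$frame <- f
      sf$observations$t_min <- (f - 1) / frameRate(stack) / 60
    } else {
      sf$observations$frame <- integer(0)
      sf$observations$t_min <- numeric(0)
    }
    obs[[f]] <- sf$observations
    labs[[f]] <- sf$labels
  }
  new("SegmentationStack", observations = do.call(rbind, obs),
      labels = labs, frame_rate_fps = frameRate(stack),
      pixel_size_um = pixelSize(stack))
}
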