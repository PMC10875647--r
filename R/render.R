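# evaluate the multiplicative illumination polynomial on the pixel grid,
# coordinates normalized to [-1, 1]
.illumField <- function(shape, coeffs) {
  X <- matrix(seq(-1, 1, length.out = shape[1]), shape[1], shape[2])
  Y <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
              byrow = TRUE)
  1 + coeffs[["x"]] * X + coeffs[["y"]] * Y + coeffs[["xx"]] * X^2 +
    coeffs[["xy"]] * X * Y + coeffs[["yy"]] * Y^2
}

# multiply a projected spherocylinder (capsule) attenuation into `img`;
# px coordinates of the centroid, half-length/radius in px.  Returns TRUE
# when the capsule had to be clipped at the image border.
.drawCapsule <- function(img, cx, cy, L_px, r_px, theta_deg, depth,
                         edge_px = 1) {
  d1 <- nrow(img); d2 <- ncol(img)
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  hl <- max(L_px / 2 - r_px, 0)           # half-length of the cylinder axis
  ex <- abs(u[1]) * hl + r_px + edge_px; ey <- abs(u[2]) * hl + r_px + edge_px
  i0 <- floor(cx - ex) + 1L; i1 <- ceiling(cx + ex)
  j0 <- floor(cy - ey) + 1L; j1 <- ceiling(cy + ey)
  clipped <- i0 < 1L || j0 < 1L || i1 > d1 || j1 > d2
  i0 <- max(i0, 1L); j0 <- max(j0, 1L); i1 <- min(i1, d1); j1 <- min(j1, d2)
  if (i0 > i1 || j0 > j1) return(list(img = img, clipped = TRUE))
  ix <- i0:i1; jy <- j0:j1
  px <- matrix(ix - 0.5 - cx, length(ix), length(jy))
  py <- matrix(jy - 0.5 - cy, length(ix), length(jy), byrow = TRUE)
  # distance from pixel center to the axis segment
  s <- pmin(pmax(px * u[1] + py * u[2], -hl), hl)
  d <- sqrt((px - s * u[1])^2 + (py - s * u[2])^2)
  fac <- depth * pmin(1, pmax(0, (r_px + edge_px / 2 - d) / edge_px))
  img[ix, jy] <- img[ix, jy] * (1 - fac)
  list(img = img, clipped = clipped)
}

#' Render a simulated scene as a brightfield movie
#'
#' Draws each bound cell as a projected spherocylinder darker than the
#' background, multiplies by the uneven-illumination field, applies Gaussian
#' optical blur (optionally slowly modulated to emulate focus drift), adds
#' Gaussian read-out noise, and sprinkles small round nanoparticle spots at
#' the configured rate.  Rendering is deterministic under a fixed config
#' seed.  Cells extending past the image border are clipped with a warning.
#'
#' @param truth a [TruthTable-class] from [simulateTruth()] (or a tracks
#'   data.frame with the same columns).
#' @param config the [SceneConfig-class] used for the simulation.
#' @param background background intensity level in [0, 1].
#' @param cell_depth fractional attenuation at the cell midline.
#' @return a [MovieStack-class].
#' @examples
#' cfg <- sceneConfig(duration_min = 2, frame_rate_fps = 0.1,
#'                    n_initial_cells = 3, arrival_rate_per_min = 0,
#'                    image_shape = c(120L, 120L), seed = 5)
#' mv <- renderMovie(simulateTruth(cfg), cfg)
#' mv
#' @export
renderMovie <- function(truth, config, background = 0.75, cell_depth = 0.45) {
  stopifnot(is(config, "SceneConfig"))
  tracks <- if (is(truth, "TruthTable")) truthTracks(truth) else truth
  fps <- config@frame_rate_fps
  n_frames <- floor(config@duration_min * 60 * fps + 1e-9)
  if (nrow(tracks) && max(tracks$frame) > n_frames)
    stop("tracks extend past the configured frame count")
  shape <- config@image_shape
  px_um <- config@pixel_size_um
  illum <- .illumField(shape, config@illumination_coeffs)
  set.seed(config@seed + 7919L)   # independent stream from the simulator
  arr <- array(0, dim = c(shape[1], shape[2], n_frames))
  dt_min <- 1 / (fps * 60)
  np <- matrix(numeric(0), ncol = 2)   # accumulated nanoparticle positions
  r_np_px <- 0.25 / px_um              # ~0.5 um round spots
  by_frame <- if (nrow(tracks)) split(tracks, tracks$frame) else list()
  n_clipped <- 0L
  for (f in seq_len(n_frames)) {
    img <- matrix(background, shape[1], shape[2])
    tf <- by_frame[[as.character(f)]]
    if (!is.null(tf) && nrow(tf)) {
      for (i in seq_len(nrow(tf))) {
        res <- .drawCapsule(img, tf$x_um[i] / px_um, tf$y_um[i] / px_um,
                            tf$length_um[i] / px_um,
                            config@cell_width_um / 2 / px_um,
                            tf$theta_deg[i], cell_depth)
        img <- res$img
        if (res$clipped) n_clipped <- n_clipped + 1L
      }
    }
    if (config@nanoparticle_rate_per_min > 0) {
      n_new <- rpois(1L, config@nanoparticle_rate_per_min * dt_min)
      if (n_new > 0L)
        np <- rbind(np, cbind(runif(n_new, 1, shape[1] - 1),
                              runif(n_new, 1, shape[2] - 1)))
      if (nrow(np))
        for (i in seq_len(nrow(np)))
          img <- .drawCapsule(img, np[i, 1], np[i, 2], 2 * r_np_px,
                              r_np_px, 0, 0.35)$img
    }
    img <- img * illum
    sigma <- config@blur_sigma_px *
      (1 + config@focus_drift_amp * sin(2 * pi * (f - 1) / max(n_frames, 2)))
    if (sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
    if (config@noise_sd > 0)
      img <- img + rnorm(length(img), 0, config@noise_sd)
    arr[, , f] <- pmin(pmax(img, 0), 1)
  }
  if (n_clipped > 0L)
    warning(sprintf("%d cell renderings clipped at the image border",
                    n_clipped))
  new("MovieStack", frames = arr, frame_rate_fps = fps,
      pixel_size_um = px_um)
}
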