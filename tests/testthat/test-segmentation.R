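test_that("frame averaging reduces the frame rate and preserves means", {
  arr <- array(runif(16 * 16 * 45), c(16, 16, 45))
  mv <- new("MovieStack", frames = arr, frame_rate_fps = 2,
            pixel_size_um = 0.2)
  expect_message(av <- averageFrames(mv, 20), "trailing")
  expect_equal(frameRate(av), 0.1)
  expect_equal(nFrames(av), 2L)
  expect_equal(av@frames[, , 1], rowMeans(arr[, , 1:20], dims = 2))
  # block 1 is the identity
  expect_identical(frames(averageFrames(mv, 1)), arr)
  # a constant stack is unchanged in value
  cn <- new("MovieStack", frames = array(0.4, c(8, 8, 40)),
            frame_rate_fps = 2, pixel_size_um = 0.2)
  expect_true(all(abs(frames(averageFrames(cn, 20)) - 0.4) < 1e-12))
  expect_error(averageFrames(mv, 100), "exceeds")
})

test_that("illumination correction recovers a known polynomial field", {
  cfg <- staticScene(n_cells = 6, duration_min = 0.5, fps = 1 / 30,
                     noise_sd = 0.005, seed = 13)
  mv <- renderMovie(simulateTruth(cfg), cfg)
  fr <- mv@frames[, , 1]
  co <- correctIllumination(fr)
  truth_field <- BacFlow:::.illumField(dim(fr),
                                       cfg@illumination_coeffs) * 0.75
  rec <- attr(co, "background")
  rel_rms <- sqrt(mean((rec - truth_field)^2)) / mean(truth_field)
  expect_lt(rel_rms, 0.02)
  # background of the corrected frame sits near zero
  expect_lt(abs(median(co)), 0.01)
})

test_that("a flat frame corrects to zeros and a constant frame warns", {
  flat <- matrix(0.6, 80, 80) + matrix(rnorm(6400, 0, 1e-3), 80)
  co <- correctIllumination(flat)
  expect_lt(max(abs(co)), 0.02)
  expect_warning(z <- correctIllumination(matrix(0.5, 40, 40)),
                 "degenerate")
  expect_true(all(z == 0))
})

test_that("segmented lengths are invariant to the illumination field", {
  mk <- function(coeffs, seed) {
    cfg <- staticScene(n_cells = 6, duration_min = 0.5, fps = 1 / 30,
                       noise_sd = 0, seed = seed,
                       illumination_coeffs = coeffs)
    list(cfg = cfg, mv = renderMovie(simulateTruth(cfg), cfg))
  }
  a <- mk(c(x = 0), 13)
  b <- mk(c(x = 0.1, y = -0.08, xx = -0.05), 13)
  sa <- segmentStack(a$mv)
  sb <- segmentStack(b$mv)
  oa <- observations(sa); ob <- observations(sb)
  expect_equal(nrow(oa), nrow(ob))
  oa <- oa[order(oa$x_um), ]; ob <- ob[order(ob$x_um), ]
  expect_true(all(abs(oa$length_um - ob$length_um) <= pixelSize(sa)))
})

test_that("rendered rods are recovered with sub-pixel length accuracy", {
  cfg <- staticScene(n_cells = 10, duration_min = 0.5, fps = 1 / 30,
                     shape = c(400L, 400L), seed = 31)
  tt <- simulateTruth(cfg)
  seg <- segmentStack(renderMovie(tt, cfg))
  st <- detectionStats(seg, truthTracks(tt), cfg)
  expect_equal(st$precision, 1)
  expect_equal(st$recall, 1)
  expect_lt(st$length_mae_um, pixelSize(seg))   # 1 px
})

test_that("orientation is accurate and folded to [0, 90] for rods", {
  px <- 0.2
  for (ang in c(0, 23, 45, 67, 90, -30, -75)) {
    tracks <- data.frame(cell_id = 1L, parent_id = NA_integer_, frame = 1L,
                         t_min = 0, x_um = 20, y_um = 20, length_um = 4,
                         theta_deg = ang, pivot_frac = 0, bound = TRUE)
    cfg <- sceneConfig(duration_min = 1 / 60, frame_rate_fps = 1,
                       image_shape = c(200L, 200L), noise_sd = 0,
                       arrival_rate_per_min = 0, seed = 1)
    mv <- renderMovie(tracks, cfg)
    o <- observations(segmentStack(mv))
    expect_equal(nrow(o), 1L)
    fold <- abs(ang)
    if (fold > 90) fold <- 180 - fold
    expect_true(o$theta_deg >= 0 && o$theta_deg <= 90)
    expect_lt(abs(o$theta_deg - fold), 2)
  }
})

test_that("round nanoparticles are rejected by the shape/size gates", {
  cfg <- sceneConfig(duration_min = 1, frame_rate_fps = 0.5,
                     arrival_rate_per_min = 0, n_initial_cells = 0L,
                     nanoparticle_rate_per_min = 30,
                     image_shape = c(200L, 200L), noise_sd = 0.005,
                     seed = 17)
  mv <- renderMovie(simulateTruth(cfg), cfg)
  o <- observations(segmentStack(mv))
  expect_equal(nrow(o), 0L)
})

test_that("the watershed splits two touching rods along their seam", {
  # side-by-side pair at 30 deg to the flow, touching along their flanks
  th <- 30 * pi / 180
  c2 <- c(20, 20) + 1.4 * c(-sin(th), cos(th))
  tracks <- data.frame(cell_id = 1:2, parent_id = NA_integer_, frame = 1L,
                       t_min = 0,
                       x_um = c(20, c2[1]), y_um = c(20, c2[2]),
                       length_um = c(4, 4), theta_deg = 30,
                       pivot_frac = 0, bound = TRUE)
  cfg <- sceneConfig(duration_min = 1 / 60, frame_rate_fps = 1,
                     image_shape = c(220L, 220L), noise_sd = 0,
                     arrival_rate_per_min = 0, seed = 1)
  mv <- renderMovie(tracks, cfg)
  # the pair forms one connected blob in the thresholded mask
  fr <- correctIllumination(frames(mv)[, , 1])
  mask <- BacFlow:::.median3x3(BacFlow:::.median3x3(
    pmin(pmax(fr - 0.22, 0), 1))) > 1e-4
  expect_equal(max(EBImage::bwlabel(EBImage::Image(mask * 1))), 1)
  o <- observations(segmentStack(mv))
  expect_equal(nrow(o), 2L)
  expect_equal(o$theta_deg, c(30, 30), tolerance = 0.1)
  expect_equal(o$length_um, c(4, 4), tolerance = 0.15)
})

test_that("an empty foreground yields an empty observation table", {
  o <- segmentFrame(matrix(0, 60, 60), segmentationParams(),
                    pixel_size_um = 0.2)
  expect_equal(nrow(o$observations), 0L)
  expect_true(all(o$labels == 0L))
})
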