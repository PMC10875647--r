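test_that("identical config and seed give bit-identical truth and stacks", {
  cfg <- staticScene(n_cells = 4, duration_min = 1, seed = 9)
  t1 <- simulateTruth(cfg); t2 <- simulateTruth(cfg)
  expect_identical(truthTracks(t1), truthTracks(t2))
  expect_identical(truthEvents(t1), truthEvents(t2))
  m1 <- renderMovie(t1, cfg); m2 <- renderMovie(t2, cfg)
  expect_identical(frames(m1), frames(m2))
})

test_that("no arrivals and no seed cells yield an empty track list", {
  cfg <- sceneConfig(duration_min = 2, frame_rate_fps = 0.5,
                     arrival_rate_per_min = 0, n_initial_cells = 0L,
                     seed = 1)
  tt <- simulateTruth(cfg)
  expect_equal(nrow(truthTracks(tt)), 0L)
  expect_equal(nrow(truthEvents(tt)), 0L)
})

test_that("without detachment or division the cell count is conserved", {
  cfg <- sceneConfig(duration_min = 30, frame_rate_fps = 1 / 30,
                     injection_window_min = 10, arrival_rate_per_min = 2,
                     detach_halflife_min = 1e9, division_length_um = 50,
                     gr_schedule = gompertzParams(1e-4, 2e-4, 0.05, 60),
                     seed = 4)
  tr <- truthTracks(simulateTruth(cfg))
  counts <- table(tr$frame)
  post <- counts[as.numeric(names(counts)) / (cfg@frame_rate_fps * 60) >= 10]
  expect_true(length(unique(post)) == 1L)
  expect_equal(unname(post[1]), nrow(truthEvents(simulateTruth(cfg))))
})

test_that("config validation names the offending field", {
  expect_error(sceneConfig(duration_min = -1), "duration_min")
  expect_error(sceneConfig(division_asymmetry = 0.7), "division_asymmetry")
  expect_error(sceneConfig(pivot_offset_frac = 0.9), "pivot_offset_frac")
  expect_error(sceneConfig(noise_sd = -0.1), "noise_sd")
})

test_that("per-frame bound counts balance arrivals, detachments and divisions", {
  cfg <- sceneConfig(duration_min = 60, frame_rate_fps = 1 / 30,
                     injection_window_min = 15, arrival_rate_per_min = 1,
                     n_initial_cells = 10L, detach_halflife_min = 40,
                     initial_length_um = c(3.6, 0.2),
                     division_length_um = 4.5, daughter_detach_prob = 0.2,
                     gr_schedule = gompertzParams(0.03, 0.04, 0.1, 10),
                     seed = 12)
  tt <- simulateTruth(cfg)
  tr <- truthTracks(tt); ev <- truthEvents(tt)
  for (f in sort(unique(tr$frame))) {
    t <- (f - 1) / (cfg@frame_rate_fps * 60)
    # divided cells carry their pre-division detach draw; only the
    # detached fate uses it
    expected <- sum(ev$t_bind_min <= t & ev$fate != "washed" &
                      !(ev$fate == "detached" & ev$t_detach_min <= t) &
                      (is.na(ev$t_divide_min) | ev$t_divide_min >= t))
    expect_equal(sum(tr$frame == f), expected)
  }
})

test_that("surface residence of non-dividing cells is exponential with the configured half-life", {
  cfg <- sceneConfig(duration_min = 300, frame_rate_fps = 1 / 60,
                     n_initial_cells = 1000L, arrival_rate_per_min = 0,
                     detach_halflife_min = 30, division_length_um = 100,
                     gr_schedule = gompertzParams(1e-4, 2e-4, 0.05, 60),
                     image_shape = c(600L, 600L), seed = 7)
  ev <- truthEvents(simulateTruth(cfg))
  res <- ev$t_detach_min[ev$fate == "detached"] - ev$t_bind_min[ev$fate == "detached"]
  expect_gt(length(res), 900)
  ks <- suppressWarnings(ks.test(res, "pexp", rate = log(2) / 30))
  expect_gt(ks$p.value, 0.01)
  # fraction remaining at one half-life within binomial error
  frac <- mean(is.na(ev$t_detach_min) | ev$t_detach_min - ev$t_bind_min > 30)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("daughter lengths sum to the mother length and appear one frame later", {
  cfg <- divisionScene(n_cells = 3, seed = 21)
  tt <- simulateTruth(cfg)
  tr <- truthTracks(tt); ev <- truthEvents(tt)
  moms <- ev$cell_id[ev$fate == "divided"]
  expect_gte(length(moms), 3L)
  for (m in moms) {
    kids <- ev[!is.na(ev$parent_id) & ev$parent_id == m, ]
    expect_equal(nrow(kids), 2L)
    m_last <- max(tr$frame[tr$cell_id == m])
    mL <- tr$length_um[tr$cell_id == m & tr$frame == m_last]
    kid_first <- vapply(kids$cell_id,
                        function(k) min(tr$frame[tr$cell_id == k]), 0)
    expect_true(all(kid_first == m_last + 1L))
    kL <- vapply(kids$cell_id, function(k)
      tr$length_um[tr$cell_id == k & tr$frame == m_last + 1L][1], 0)
    # daughters split the mother's length at the division threshold;
    # one frame of growth separates the records
    expect_equal(sum(kL), mL, tolerance = 0.05)
  }
  # frames of one cell are consecutive while bound
  for (sp in split(tr$frame, tr$cell_id))
    expect_true(all(diff(sort(sp)) == 1L))
})

test_that("rendered stacks behave physically", {
  # zero cells, zero noise, flat illumination: constant frames
  cfg0 <- sceneConfig(duration_min = 0.5, frame_rate_fps = 0.2,
                      arrival_rate_per_min = 0, n_initial_cells = 0L,
                      noise_sd = 0, illumination_coeffs = c(x = 0),
                      image_shape = c(60L, 60L), seed = 1)
  mv0 <- renderMovie(simulateTruth(cfg0), cfg0)
  expect_lt(diff(range(frames(mv0))), 1e-10)

  # doubling noise_sd doubles the per-pixel residual sd within 5%
  base <- sceneConfig(duration_min = 1, frame_rate_fps = 1,
                      arrival_rate_per_min = 0, n_initial_cells = 0L,
                      noise_sd = 0.01, image_shape = c(120L, 120L),
                      seed = 5)
  dbl <- sceneConfig(duration_min = 1, frame_rate_fps = 1,
                     arrival_rate_per_min = 0, n_initial_cells = 0L,
                     noise_sd = 0.02, image_shape = c(120L, 120L),
                     seed = 5)
  r1 <- sd(frames(renderMovie(simulateTruth(base), base)) -
             frames(renderMovie(simulateTruth(base),
                                sceneConfig(duration_min = 1,
                                            frame_rate_fps = 1,
                                            arrival_rate_per_min = 0,
                                            n_initial_cells = 0L,
                                            noise_sd = 0,
                                            image_shape = c(120L, 120L),
                                            seed = 5))))
  r2 <- sd(frames(renderMovie(simulateTruth(dbl), dbl)) -
             frames(renderMovie(simulateTruth(dbl),
                                sceneConfig(duration_min = 1,
                                            frame_rate_fps = 1,
                                            arrival_rate_per_min = 0,
                                            n_initial_cells = 0L,
                                            noise_sd = 0,
                                            image_shape = c(120L, 120L),
                                            seed = 5))))
  expect_lt(abs(r2 / r1 - 2), 0.05 * 2)
})

test_that("near-wall speed matches the analytic duct solution and its limits", {
  v <- nearWallSpeed(100, 0.8, 1)
  expect_equal(as.numeric(v), 30, tolerance = 0.15)
  # linear in Q
  expect_equal(as.numeric(nearWallSpeed(200, 0.8, 1)), 2 * as.numeric(v),
               tolerance = 1e-9)
  # linear in distance close to the wall
  v5 <- as.numeric(nearWallSpeed(100, 0.8, 5))
  expect_equal(v5, 5 * as.numeric(v), tolerance = 0.01)
  # parallel-plate closed form is a lower bound at the wall midpoint
  plate <- 6 * (100e-9 / 60) / (0.8e-3 * (0.8e-3)^2) * 1e-6 * 1e6
  expect_equal(plate, 19.5, tolerance = 0.01)
  expect_gt(as.numeric(v), plate)
  expect_error(nearWallSpeed(100, 0.8, 500), "distance")
  expect_error(nearWallSpeed(-1, 0.8, 1), "positive")
})
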