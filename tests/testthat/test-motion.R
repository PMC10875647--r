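# analytic rigid-wiggle observation series: rotation of a rod about a
# pivot at signed position p (um from center), OU angle with sd amp_deg
rigidWiggleTraj <- function(n = 240, amp_deg = 3, p_um = 0, L = 3,
                            theta0 = 20, fps = 2, tau_s = 5) {
  a <- exp(-1 / (fps * tau_s))
  dth <- numeric(n)
  dth[1] <- rnorm(1, 0, amp_deg)
  for (i in 2:n) dth[i] <- a * dth[i - 1] +
      amp_deg * sqrt(1 - a^2) * rnorm(1)
  th <- theta0 + dth
  pivot <- c(10, 10)
  u <- cbind(cos(th * pi / 180), sin(th * pi / 180))
  data.frame(t_min = (seq_len(n) - 1) / fps / 60,
             x_um = pivot[1] - p_um * u[, 1],
             y_um = pivot[2] - p_um * u[, 2],
             theta_axis_deg = th, length_um = L)
}

test_that("a rigid immobile cell has zero spread and a flagged flat profile", {
  tr <- data.frame(t_min = (0:239) / 120, x_um = 10, y_um = 10,
                   theta_axis_deg = 35, length_um = 3)
  w <- computeMotionWindow(tr, 0)
  expect_equal(w$theta_M, 35)
  expect_equal(w$theta_std, 0)
  expect_warning(pr <- wiggleProfile(w), "undetermined")
  expect_true(all(pr$sep_std_um == 0))
  expect_equal(attr(pr, "mode"), "undetermined")
})

test_that("the wiggle amplitude is recovered from a 2-min window", {
  set.seed(21)
  devs <- replicate(20, {
    tr <- rigidWiggleTraj(amp_deg = 3, p_um = 0)
    sd(computeMotionWindow(tr, 0)$dtheta_deg)
  })
  expect_lt(abs(mean(devs) - 3) / 3, 0.10)
})

test_that("pure center rotation gives a V profile matching the kinematic oracle", {
  set.seed(7)
  tr <- rigidWiggleTraj(amp_deg = 3, p_um = 0, L = 3)
  w <- computeMotionWindow(tr, 0)
  pr <- wiggleProfile(w)
  # vertex at the center, maxima at the poles
  expect_lt(abs(attr(pr, "pivot_um")), 0.15 * 3)
  expect_equal(attr(pr, "mode"), "rocking")
  mid <- ceiling(nrow(pr) / 2)
  expect_true(all(pr$sep_std_um[mid] <= pr$sep_std_um))
  # oracle: sd of l * sin(dtheta) at the poles from the raw series
  oracle <- sd((3 / 2) * sin((w$dtheta_deg) * pi / 180))
  expect_equal(pr$sep_std_um[nrow(pr)], oracle, tolerance = 0.15)
  # V shape: unimodal descent to the vertex from both sides
  expect_true(all(diff(pr$sep_std_um[1:mid]) <= 1e-9))
  expect_true(all(diff(pr$sep_std_um[mid:nrow(pr)]) >= -1e-9))
})

test_that("an offset pivot is localized and classified as twisting", {
  set.seed(8)
  res <- t(replicate(25, {
    L <- 3
    tr <- rigidWiggleTraj(amp_deg = 5, p_um = -0.3 * L, L = L)
    pr <- wiggleProfile(computeMotionWindow(tr, 0))
    c(err = abs(attr(pr, "pivot_frac") - (-0.3)),
      twist = attr(pr, "mode") == "twisting")
  }))
  expect_lt(mean(res[, "err"]), 0.10)
  expect_gte(mean(res[, "twist"]), 0.95)
})

test_that("theta_M is invariant under axis direction flips", {
  set.seed(9)
  tr <- rigidWiggleTraj(amp_deg = 3, theta0 = 80)
  # same axis represented with flipped directions: theta -> theta - 180
  tr2 <- tr
  flip <- seq(1, nrow(tr2), by = 2)
  tr2$theta_axis_deg[flip] <- tr2$theta_axis_deg[flip] - 180
  w1 <- computeMotionWindow(tr, 0)
  w2 <- computeMotionWindow(tr2, 0)
  expect_equal(w1$theta_M, w2$theta_M, tolerance = 1e-9)
  # deviations stay small across the +/-90 wrap
  tr3 <- rigidWiggleTraj(amp_deg = 3, theta0 = 89)
  w3 <- computeMotionWindow(tr3, 0)
  expect_lt(max(abs(w3$dtheta_deg)), 25)
})

test_that("sparse windows are rejected with a warning", {
  set.seed(12)
  tr <- rigidWiggleTraj()[sort(sample(240, 70)), ]   # ~30% of frames
  expect_warning(w <- computeMotionWindow(tr, 0), "rejected")
  expect_null(w)
})

test_that("population summaries separate identical and realigned states", {
  set.seed(10)
  early <- lapply(1:12, function(i)
    computeMotionWindow(rigidWiggleTraj(amp_deg = 4,
                                        theta0 = rnorm(1, 15, 5)), 0))
  early2 <- lapply(1:12, function(i)
    computeMotionWindow(rigidWiggleTraj(amp_deg = 4,
                                        theta0 = rnorm(1, 15, 5)), 0))
  late <- lapply(1:12, function(i)
    computeMotionWindow(rigidWiggleTraj(amp_deg = 1.5,
                                        theta0 = rnorm(1, 75, 5)), 0))
  null_sum <- populationMotionSummary(early, early2)
  expect_gt(null_sum$ks$theta_M$p.value, 0.05)
  shift <- populationMotionSummary(early, late)
  a <- shift$angles
  expect_gt(median(a$theta_M[a$time == "late"]),
            median(a$theta_M[a$time == "early"]))
  expect_lt(median(a$theta_std[a$time == "late"]),
            median(a$theta_std[a$time == "early"]))
  expect_lt(shift$ks$theta_M$p.value, 0.05)
  expect_warning(populationMotionSummary(early, list()), "partial")
})

test_that("simulated realignment reproduces the early/late orientation contrast", {
  cfg <- sceneConfig(duration_min = 170, frame_rate_fps = 1 / 30,
                     n_initial_cells = 15, arrival_rate_per_min = 0,
                     detach_halflife_min = 1e9, division_length_um = 50,
                     gr_schedule = gompertzParams(1e-4, 2e-4, 0.05, 60),
                     realign_rate_per_min = 0.012, seed = 30)
  tu <- truthTracks(simulateTruth(cfg))
  tu$theta_axis_deg <- tu$theta_deg
  tu$traj_id <- tu$cell_id
  w30 <- motionWindows(tu, 30, duration_min = 2)
  w160 <- motionWindows(tu, 160, duration_min = 2)
  m30 <- median(vapply(w30, `[[`, 0, "theta_M"))
  m160 <- median(vapply(w160, `[[`, 0, "theta_M"))
  expect_gt(m160, m30 + 20)
})
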