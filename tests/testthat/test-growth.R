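test_that("momentaneous GR equals the slope for exact data", {
  tr <- data.frame(t_min = seq(0, 30, 0.5), length_um = 3)
  expect_true(all(momentaneousGR(tr)$gr_um_per_min == 0))
  tr$length_um <- 2 + 0.02 * tr$t_min
  g <- momentaneousGR(tr)
  expect_equal(g$gr_um_per_min, rep(0.02, nrow(g)), tolerance = 1e-12)
  # windows sticking out past the ends are skipped
  expect_equal(range(g$t_min), c(5, 25))
})

test_that("GR noise matches the analytic OLS slope variance", {
  t <- seq(-5, 5, by = 0.5)
  sd_theory <- 0.1 / sqrt(sum((t - mean(t))^2))
  set.seed(11)
  est <- replicate(200, {
    tr <- data.frame(t_min = seq(0, 10, 0.5),
                     length_um = 2 + 0.02 * seq(0, 10, 0.5) +
                       rnorm(21, 0, 0.1))
    momentaneousGR(tr)$gr_um_per_min[1]   # single eligible point at t = 5
  })
  expect_lt(abs(mean(est) - 0.02), 3 * sd_theory / sqrt(200))  # unbiased
  expect_lt(abs(sd(est) / sd_theory - 1), 0.1)
})

test_that("binning reduces to the obvious summaries in small cases", {
  mkTraj <- function(id, slope) data.frame(
    traj_id = id, parent_id = NA_integer_, frame = 1:41,
    t_min = seq(0, 20, 0.5), x_um = 5, y_um = 5,
    length_um = 2 + slope * seq(0, 20, 0.5), width_um = 1,
    theta_deg = 0, theta_axis_deg = 0, area_um2 = 3, gr_eligible = TRUE)
  ts <- new("TrajectorySet",
            observations = rbind(mkTraj(1L, 0.01), mkTraj(2L, 0.03)),
            lineage = data.frame(traj_id = 1:2, parent_id = NA_integer_,
                                 start_min = 0, end_min = 20,
                                 fate = "censored"),
            params = list())
  pop <- binPopulation(ts, bin_min = 20)
  expect_equal(nrow(pop$bins), 1L)
  expect_equal(pop$bins$gr_median, 0.02, tolerance = 1e-10)
  expect_equal(pop$bins$n_cells, 2L)
  # one trajectory alone: median equals its mean GR
  pop1 <- binPopulation(new("TrajectorySet",
                            observations = mkTraj(1L, 0.01),
                            lineage = data.frame(), params = list()),
                        bin_min = 20)
  expect_equal(pop1$bins$gr_median,
               mean(pop1$samples$mean_gr_um_per_min))
})

test_that("Gompertz parameters are recovered from noisy sigmoids", {
  t <- seq(10, 170, by = 20)
  truth <- c(y0 = 0.01, A = 0.025, k = 0.05, t_i = 60)
  set.seed(42)
  errs <- t(replicate(20, {
    y <- gompertzValue(gompertzParams(0.01, 0.025, 0.05, 60), t) *
      (1 + rnorm(length(t), 0, 0.05))
    co <- fitGompertz(t, y)@coef
    abs(co - truth) / abs(truth)
  }))
  expect_lt(median(errs[, "t_i"] * 60), 20)   # within one bin
  expect_lt(median(errs[, "y0"]), 0.10)
  expect_lt(median(errs[, "A"]), 0.10)
})

test_that("degenerate flat data are flagged and refuse a transition time", {
  f <- fitGompertz(seq(10, 170, 20), rep(0.02, 9))
  expect_true(f@degenerate)
  expect_error(transitionTime(f), "degenerate")
  expect_error(gompertzValue(f, 10), "degenerate")
  expect_error(fitGompertz(1:3, 1:3), "at least 5")
})

test_that("duplication time follows the printed formula and its scalings", {
  Lf <- gompertzParams(3, 4.5, 0.05, 60)
  Gf <- gompertzParams(0.099, 0.1, 0.05, 60)
  T2 <- duplicationTime(Lf, Gf, t = 300, t_end = 300)
  expect_equal(T2, (2 / 3) * 4.5 / 0.1, tolerance = 1e-3)   # 30 min
  # doubling GR halves T2
  Gf2 <- gompertzParams(0.198, 0.2, 0.05, 60)
  expect_equal(duplicationTime(Lf, Gf2, 300, 300), T2 / 2,
               tolerance = 1e-3)
  # simultaneous rescaling of L and GR leaves T2 unchanged
  Lf2 <- gompertzParams(6, 9, 0.05, 60)
  expect_equal(duplicationTime(Lf2, Gf2, 300, 300), T2, tolerance = 1e-3)
  # non-positive GR flags an infinite duplication time
  Gneg <- gompertzParams(-0.2, -0.1, 0.05, 60)
  expect_warning(T2i <- duplicationTime(Lf, Gneg, 300, 300),
                 "non-positive")
  expect_true(is.infinite(T2i))
})

test_that("replicate summaries: identical experiments give SE zero", {
  t <- seq(10, 170, 20)
  y <- gompertzValue(gompertzParams(0.01, 0.025, 0.05, 60), t)
  mk <- function() list(
    samples = data.frame(traj_id = 1, bin_start_min = t - 10,
                         mean_gr_um_per_min = y, mean_length_um = 3,
                         n_points = 5),
    bins = data.frame(t_mid_min = t, n_cells = 1, gr_q1 = y,
                      gr_median = y, gr_q3 = y, len_q1 = 3,
                      len_median = 3, len_q3 = 3))
  s <- summarizeReplicates(list(mk(), mk()), c("control", "control"),
                           transition_times = c(60, 60))
  expect_true(all(s$summary$se == 0))
  expect_equal(nrow(s$tests), 0L)
})

test_that("the Welch test detects a 30% GR shift and holds its size", {
  sim_exp <- function(mu) {
    y <- mu * (1 + rnorm(1, 0, 0.05))
    list(samples = data.frame(traj_id = 1, bin_start_min = 0,
                              mean_gr_um_per_min = y,
                              mean_length_um = 3, n_points = 5),
         bins = data.frame())
  }
  run <- function(mu_b) {
    s <- summarizeReplicates(
      c(lapply(1:5, function(i) sim_exp(0.02)),
        lapply(1:5, function(i) sim_exp(mu_b))),
      rep(c("a", "b"), each = 5), transition_times = rep(100, 10))
    s$tests$p_value[s$tests$metric == "initial_gr"]
  }
  set.seed(3)
  power <- mean(replicate(100, run(0.014)) < 0.01)
  expect_gte(power, 0.95)
  set.seed(4)
  size <- mean(replicate(1000, run(0.02)) < 0.05)
  expect_lt(abs(size - 0.05), 0.025)
})
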