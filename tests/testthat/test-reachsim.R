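test_that("target schedules follow the width rules", {
  f <- make_schedule("Fixed")
  expect_equal(f$width_cm, rep(1, 4))

  # LS: block 1 = interquartile span, block 2 = halfway to the final width
  base <- c(rep(-6.78, 25), rep(6.78, 25))  # IQR span 13.56
  ls <- make_schedule("LS", baseline_pd = base, final_width_cm = 0.8)
  expect_equal(ls$width_cm[1], 13.56)
  expect_equal(ls$width_cm[2], (13.56 + 0.8) / 2)  # 7.18
  expect_equal(ls$width_cm[3:4], c(0.8, 0.8))

  expect_error(make_schedule("LS"), "baseline_pd")
  expect_warning(
    degen <- make_schedule("LS", baseline_pd = rep(1.5, 20)),
    "no spread"
  )
  expect_equal(degen$width_cm[1], 0.1)
})

test_that("a zero-noise reach has the closed-form geometry", {
  withr::local_seed(5)
  pol <- reach_policy(mode_angles_deg = c(-4, 0, 4), motor_noise_sd_deg = 0,
                      curvature_sd_deg = 0)
  tr <- simulate_trial(pol, mode = 3, width_cm = 1)
  # endpoint on the 15 cm stripe, lateral deviation = 15*sin(angle)
  s <- tr$samples[[1]]
  endpoint <- c(tail(s$x_cm, 1), tail(s$y_cm, 1))
  expect_equal(sqrt(sum(endpoint^2)), 15, tolerance = 1e-9)
  expect_equal(tr$pd_end, 15 * sin(4 * pi / 180), tolerance = 1e-9)
  # straight path: mid-flight PD is the endpoint PD scaled by the mean
  # minimum-jerk position fraction over normalized points 11..20
  tau <- (10:19) / 29
  # linear resampling of the 400 Hz grid leaves only O(dt^2) curvature error
  expect_equal(tr$pd_mid, tr$pd_end * mean(mj(tau)), tolerance = 1e-3)
  # durations live in the instructed 500-700 ms window at 400 Hz
  expect_true(tr$duration_ms >= 500 && tr$duration_ms <= 700)
  expect_equal(diff(s$t_ms)[1], 2.5)
})

test_that("reward is the closed interval |pd_end| <= width/2", {
  pol <- reach_policy(mode_angles_deg = c(0, 2), motor_noise_sd_deg = 0,
                      curvature_sd_deg = 0)
  withr::local_seed(1)
  on_target <- simulate_trial(pol, mode = 1, width_cm = 1)
  expect_true(on_target$reward)
  off <- simulate_trial(pol, mode = 2, width_cm = 1)  # pd ~ 0.52 cm
  expect_false(off$reward)
  # exactly at the boundary: width = 2*|pd| rewards (closed interval)
  at_boundary <- simulate_trial(pol, mode = 2, width_cm = 2 * abs(off$pd_end))
  expect_true(at_boundary$reward)
})

test_that("sessions have the block layout and respond to switch settings", {
  sch <- make_schedule("Fixed")
  stay <- reach_policy(p_switch_given_reward = 0, p_switch_given_fail = 0)
  s1 <- simulate_session(stay, sch, seed = 7)
  expect_equal(nrow(s1), 200)
  expect_equal(unique(table(s1$block)), 50L)
  expect_equal(length(unique(s1$mode)), 1)         # never switches
  expect_equal(eer(s1$mode)$eer, 0)

  # always-fail width + certain switch => alternation between modes
  alt <- reach_policy(mode_angles_deg = c(-6, 6), motor_noise_sd_deg = 0,
                      p_switch_given_reward = 1, p_switch_given_fail = 1)
  s2 <- simulate_session(alt, make_schedule("Fixed", fixed_width_cm = 1e-6),
                         seed = 8)
  expect_true(all(diff(s2$mode) != 0))
  # reproducibility under a fixed seed
  expect_identical(simulate_session(stay, sch, seed = 7), s1)
})

test_that("EER on true modes recovers the switch probability q/(1-q)", {
  q <- 0.3
  pol <- reach_policy(p_switch_given_reward = q, p_switch_given_fail = q)
  sch <- make_schedule("Fixed", trials_per_block = 250)
  s <- simulate_session(pol, sch, seed = 9)
  n <- nrow(s) - 1
  se <- sqrt(q * (1 - q) / n) / (1 - q)^2
  expect_lt(abs(eer(s$mode)$eer - q / (1 - q)), 3 * se)
})

test_that("narrower target width never increases the reward count", {
  # reward-independent switching keeps the trajectory stream identical
  pol <- reach_policy(p_switch_given_reward = 0.3, p_switch_given_fail = 0.3)
  sch_wide <- make_schedule("Fixed", fixed_width_cm = 2)
  sch_narrow <- make_schedule("Fixed", fixed_width_cm = 0.8)
  wide <- simulate_session(pol, sch_wide, seed = 13)
  narrow <- simulate_session(pol, sch_narrow, seed = 13)
  expect_identical(wide$pd_end, narrow$pd_end)
  expect_true(all(wide$reward >= narrow$reward))
})

test_that("session CSV round-trips through write_session/read_trajectories", {
  pol <- reach_policy()
  s <- simulate_session(pol, make_schedule("Fixed"), seed = 2)[1:5, ]
  stem <- file.path(withr::local_tempdir(), "ses")
  write_session(s, stem)
  back <- read_trajectories(paste0(stem, "_samples.csv"))
  expect_equal(nrow(back), 5)
  expect_equal(back$samples[[3]]$x_cm, s$samples[[3]]$x_cm, tolerance = 1e-9)
})
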