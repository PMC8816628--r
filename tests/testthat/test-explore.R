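test_that("transitions are flagged explore iff the cluster changes", {
  tr <- classify_transitions(c(2, 2, 2, 3))
  expect_equal(tr$explore, c(FALSE, FALSE, TRUE))
  expect_equal(tr$trial, 2:4)
  expect_true(all(!classify_transitions(rep(5, 10))$explore))
  expect_true(all(classify_transitions(rep(1:2, 10))$explore))
  expect_warning(empty <- classify_transitions(3L), "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("eer counts and ratio behave across scopes and sentinels", {
  # 100 explorations and 100 exploitations balance at 1.0
  lab <- c(rep(1, 101), rep(2:1, 50))
  e <- eer(lab)
  expect_equal(e$n_exploit, 100)
  expect_equal(e$n_explore, 100)
  expect_equal(e$eer, 1)
  # the classic exploration-heavy switching pattern gives eer > 1
  seq_hi <- c(1, 2, 3, 2, 1, 3, 2, 3, 1, 2, 3, 2, 1, 2, 3, 2, 1, 2, 3, 1, 2)
  expect_gt(eer(seq_hi)$eer, 1)
  # a block-repetitive pattern gives eer < 1 with many visited clusters
  seq_lo <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 5, 5, 5, 5, 6, 6, 6, 7, 7, 7)
  expect_lt(eer(seq_lo)$eer, 1)
  expect_equal(visited_clusters(seq_lo), 7)
  # strictly alternating: no exploitation => Inf sentinel, not an error
  expect_equal(eer(rep(1:2, 10))$eer, Inf)
  # per-block scope drops exactly the between-block transitions
  blocks <- rep(1:2, each = 5)
  lab10 <- c(1, 1, 2, 2, 2, 3, 3, 1, 1, 1)
  per_block <- eer(lab10, blocks, scope = "block")
  expect_equal(nrow(per_block), 2)
  whole <- eer(lab10)
  expect_equal(sum(per_block$n_explore) + sum(per_block$n_exploit),
               whole$n_explore + whole$n_exploit - 1)
})

test_that("mean EER of i.i.d. sequences approaches the closed form", {
  withr::local_seed(41)
  p <- c(0.25, 0.25, 0.25, 0.25)
  vals <- replicate(400, eer(sample(4, 200, TRUE, p))$eer)
  # finite-sequence mean sits slightly above the infinite-length ratio
  expect_equal(mean(vals), eer_closed_form(p), tolerance = 0.05)
  p2 <- c(0.8, 0.2)
  vals2 <- replicate(400, eer(sample(2, 200, TRUE, p2))$eer)
  expect_equal(mean(vals2), eer_closed_form(p2), tolerance = 0.05)
})

test_that("cumulative curves end at the session EER counts", {
  lab <- c(1, 2, 2, 3, 3, 3, 1)
  cc <- cumulative_curves(lab)
  e <- eer(lab)
  expect_equal(tail(cc$n_explore_cum, 1), e$n_explore)
  expect_equal(tail(cc$n_exploit_cum, 1), e$n_exploit)
  expect_equal(tail(cc$n_explore_cum + cc$n_exploit_cum, 1), length(lab) - 1)
  # constant sequence: exploit curve linear, explore flat
  cc2 <- cumulative_curves(rep(4, 6))
  expect_equal(cc2$n_exploit_cum, 1:5)
  expect_equal(cc2$n_explore_cum, rep(0, 5))
})

test_that("transition matrices tally counts with conserved marginals", {
  M <- transition_matrix(c(1, 1, 2), K = 2)
  expect_equal(M[1, 1], 1L, ignore_attr = TRUE)
  expect_equal(M[1, 2], 1L, ignore_attr = TRUE)
  expect_equal(sum(M), 2L)

  withr::local_seed(43)
  lab <- sample(4, 300, TRUE)
  M2 <- transition_matrix(lab, K = 4)
  e <- eer(lab)
  expect_equal(sum(diag(M2)), e$n_exploit)
  expect_equal(sum(M2) - sum(diag(M2)), e$n_explore)
  # marginals reproduce the label histogram excluding the endpoints
  expect_equal(unname(rowSums(M2)), unname(table(factor(lab[-300], 1:4))),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(M2)), unname(table(factor(lab[-1], 1:4))),
               ignore_attr = TRUE)
  # long format agrees with the matrix
  tc <- transition_counts(lab, K = 4)
  expect_equal(sum(tc$count), 299)
  expect_equal(tc$count[tc$from == 2 & tc$to == 3], M2[2, 3], ignore_attr = TRUE)
})

test_that("reward-conditioned measures match exhaustive enumeration", {
  # hand-built 6-trial session
  lab <- c(1, 1, 3, 3, 2, 2)
  rew <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  m <- reward_conditioned_measures(lab, rew)
  get <- function(name) m$value[m$measure == name]
  # transitions preceded by reward: 1->1 (exploit), 3->3 (exploit), 3->2 (explore)
  expect_equal(get("p_exploit_given_reward"), 2 / 3)
  # preceded by failure: 1->3 (explore), 2->2 (exploit)
  expect_equal(get("p_exploit_given_fail"), 1 / 2)
  # rewarded after reward: trials 2 (F), 4 (T), 5 (F) following rewarded 1,3,4
  expect_equal(get("p_reward_given_reward"), 1 / 3)
  expect_equal(get("mean_shift_after_reward"), mean(c(0, 0, 1)))
  expect_equal(get("mean_shift_after_fail"), mean(c(2, 0)))
  # complement identity holds by construction
  expect_equal(1 - get("p_exploit_given_reward"), 2 / 3 * 0 + 1 / 3)
  # degenerate conditioning set is NA-flagged with n = 0
  m2 <- reward_conditioned_measures(c(1, 1, 1), c(TRUE, TRUE, TRUE))
  expect_equal(m2$value[m2$measure == "p_exploit_given_reward"], 1)
  expect_true(is.na(m2$value[m2$measure == "p_exploit_given_fail"]))
  expect_equal(m2$n[m2$measure == "p_exploit_given_fail"], 0L)
})

test_that("reward-independent switching equalizes the two exploit rates", {
  q <- 0.35
  pol <- reach_policy(p_switch_given_reward = q, p_switch_given_fail = q)
  s <- simulate_session(pol, make_schedule("Fixed", trials_per_block = 250),
                        seed = 31)
  m <- reward_conditioned_measures(s$mode, s$reward)
  p_r <- m$value[m$measure == "p_exploit_given_reward"]
  p_f <- m$value[m$measure == "p_exploit_given_fail"]
  expect_equal(p_r, 1 - q, tolerance = 0.08)
  expect_equal(p_f, 1 - q, tolerance = 0.08)
})

test_that("delta_m reproduces direct subtraction with the prior outcome", {
  trials <- tibble::tibble(
    pd_end = c(0, 0.5, 0.5, -1),
    pd_mid = c(0, 0.2, 0.1, 0.1),
    reward = c(TRUE, TRUE, FALSE, FALSE)
  )
  dm <- delta_m(trials)
  expect_equal(dm$d_pd_end, c(0.5, 0, -1.5))
  expect_equal(dm$d_pd_mid, c(0.2, -0.1, 0))
  expect_equal(dm$prev_reward, c(TRUE, TRUE, FALSE))
  sm <- summarize_delta_m(dm)
  expect_equal(sm$mean_abs_d_pd_end[sm$prev_reward], mean(c(0.5, 0)))
  expect_equal(sm$mean_abs_d_pd_end[!sm$prev_reward], 1.5)
  # identical consecutive trials give zero change
  same <- tibble::tibble(pd_end = c(1, 1), pd_mid = c(2, 2), reward = c(TRUE, TRUE))
  expect_equal(delta_m(same)$d_pd_end, 0)
  # simulator sessions: differences match direct subtraction
  s <- simulate_session(reach_policy(), make_schedule("Fixed"), seed = 33)
  dm2 <- delta_m(s)
  expect_equal(dm2$d_pd_end, diff(s$pd_end))
})

test_that("sensitivity analysis reruns the metrics across K", {
  pol <- reach_policy(mode_angles_deg = c(-5, 0, 5), motor_noise_sd_deg = 0.3,
                      curvature_sd_deg = 0.5)
  sessions <- dplyr::bind_rows(
    simulate_session(pol, make_schedule("Fixed", blocks = 4,
                                        trials_per_block = 15),
                     participant = "P01", seed = 51),
    simulate_session(pol, make_schedule("Fixed", blocks = 4,
                                        trials_per_block = 15),
                     participant = "P02", seed = 52)
  )
  tm <- build_trial_matrix(sessions)
  sa <- suppressWarnings(sensitivity_analysis(tm, K_range = 2:4, n_restarts = 3, seed = 5))
  expect_equal(sort(unique(sa$K)), 2:4)
  expect_equal(nrow(sa), 3 * 2)  # K values x participants
  expect_true(all(sa$visited <= sa$K))
  # a single-K range reproduces the single-K analysis
  sa3 <- suppressWarnings(sensitivity_analysis(tm, K_range = 3, n_restarts = 3, seed = 5))
  expect_equal(nrow(sa3), 2)
})
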