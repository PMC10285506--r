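test_that("direction schedule balances front/behind starts for any seed", {
  for (seed in 1:10) {
    set.seed(seed)
    sched <- make_direction_schedule(75)
    expect_length(sched, 75)
    expect_equal(sum(sched == "front"), 38)
    expect_equal(sum(sched == "behind"), 37)
  }
  set.seed(1)
  expect_equal(sum(make_direction_schedule(10) == "front"), 5)
  expect_equal(sum(make_direction_schedule(11) == "front"), 6)
  expect_identical(direction_from_start(c("front", "behind")),
                   c("backward", "forward"))
})

test_that("start positions respect the movement direction by rejection sampling", {
  cfg <- protocol_config()
  set.seed(71)
  for (r in 1:200) {
    s_fwd <- sample_start_position("forward", 90, cfg)
    expect_lt(s_fwd, 90)
    expect_lt(abs(s_fwd + 100), 25)  # within 5 SD of the -100 centre
    s_bwd <- sample_start_position("backward", -90, cfg)
    expect_gt(s_bwd, -90)
  }
  # hardest case: backward to +100 accepts with probability one half
  draws <- replicate(200, sample_start_position("backward", 100, cfg))
  expect_true(all(draws > 100))
  # an exhausted cap signals a degenerate configuration
  cfg0 <- protocol_config(resample_cap = 0)
  expect_error(sample_start_position("forward", 0, cfg0), "resample_cap")
})

test_that("preselected far/near insertions follow the block rule", {
  cfg <- protocol_config()
  for (seed in 1:20) {
    set.seed(seed)
    src <- assign_preselected_trials(75, cfg)
    expect_length(src, 75)
    expect_true(all(src[1:5] == "psi"))
    expect_equal(sum(src == "far"), 7)    # complete 10-blocks 1..70
    expect_equal(sum(src == "near"), 14)  # complete 5-blocks, first excluded
    # one far per complete 10-block, one near per eligible 5-block
    for (b in 0:6) expect_equal(sum(src[(10 * b + 1):(10 * b + 10)] == "far"), 1)
    for (b in 1:14) expect_equal(sum(src[(5 * b + 1):(5 * b + 5)] == "near"), 1)
  }
})

test_that("preselected stimuli come from the stated sets, snapped to the grid", {
  cfg <- protocol_config()
  set.seed(81)
  far <- replicate(100, preselected_stimulus("far", 0, cfg))
  expect_true(all(far %in% c(-100, -90, 90, 100)))
  expect_equal(sort(unique(far)), c(-100, -90, 90, 100))
  near <- replicate(200, preselected_stimulus("near", 12, cfg))
  expect_true(all(near %in% seq(-100, 100, 10)))
  expect_true(all(near %in% c(-20, -10, 0, 20, 30, 40)))
  # forced single offsets pin down rounding and clipping
  expect_equal(preselected_stimulus("near", 12, protocol_config(near_offsets = 20)), 30)
  expect_equal(preselected_stimulus("near", 95, protocol_config(near_offsets = 30)), 100)
  expect_equal(preselected_stimulus("near", -95, protocol_config(near_offsets = -30)), -100)
})

test_that("baseline offset rounds half away from zero", {
  expect_identical(baseline_offset(1003.4, 1001.2), 2L)
  expect_identical(baseline_offset(500, 500), 0L)
  expect_identical(baseline_offset(0, 2.5), -3L)
  expect_identical(baseline_offset(2.5, 0), 3L)
  expect_error(baseline_offset(NA, 0), "finite")
})

test_that("a full session satisfies the trial-level invariants and is reproducible", {
  obs <- observer_spec(12, 18)
  s <- run_session(make_responder(obs), seed = 123)
  expect_s3_class(s, "psi_session")
  expect_equal(nrow(s$trials), 75)
  expect_true(all(s$trials$stimulus_mm %in% seq(-100, 100, 10)))
  fwd <- s$trials$direction == "forward"
  expect_true(all(s$trials$start_mm[fwd] < s$trials$stimulus_mm[fwd]))
  expect_true(all(s$trials$start_mm[!fwd] > s$trials$stimulus_mm[!fwd]))
  expect_equal(sum(fwd), 37)  # behind starts move forward
  # checkpoint bookkeeping is consistent with the final posterior
  est <- marginal_estimates(s$posterior)
  expect_equal(s$checkpoints$alpha_hat_mm[s$checkpoints$checkpoint == 75],
               est$alpha_hat)
  expect_equal(s$trials$alpha_hat_mm[75], est$alpha_hat)
  # bit-identical replication under the same seed
  s2 <- run_session(make_responder(obs), seed = 123)
  expect_identical(s$trials, s2$trials)
  # shortened sessions keep working and checkpoint at the final trial
  s10 <- run_session(make_responder(obs), protocol_config(n_trials = 10), seed = 5)
  expect_equal(nrow(s10$trials), 10)
  expect_equal(s10$checkpoints$checkpoint, 10L)
})

test_that("a deterministic threshold responder pins the PSE estimate near its threshold", {
  responder <- function(stimulus, direction) if (stimulus > 0) "left" else "right"
  s <- run_session(responder, seed = 9)
  final <- s$trials[75, ]
  # the stimulus grid only resolves 10 mm, so the estimate lands within one
  # stimulus step of the true threshold at 0
  expect_lt(abs(final$alpha_hat_mm), 10)
  expect_lt(final$beta_hat_mm, 10)
})

test_that("preselection rates hold on average outside the opening trials", {
  set.seed(91)
  cfg <- protocol_config()
  counts <- matrix(0, 20, 2)
  for (r in 1:20) {
    src <- assign_preselected_trials(75, cfg)
    counts[r, ] <- c(sum(src == "far"), sum(src == "near"))
  }
  expect_equal(mean(counts[, 1]) / 70, 1 / 10, tolerance = 0.01)
  expect_equal(mean(counts[, 2]) / 70, 1 / 5, tolerance = 0.01)
})
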