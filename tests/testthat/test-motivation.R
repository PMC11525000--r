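# Curiosity wiring, continue/stop gating, round and run limits.

test_that("instrumentation assigns triggers by structural classification", {
  mz <- tiny_maze()
  mcfg <- motivation_config(curiosity_reward = 14, boredom_reward = 0)
  ag <- attach_curiosity(build_agent("dfs_ibl", mz), mcfg)
  ps <- ag$productions
  harvest_names <- names(Filter(curiomaze:::is_harvest_production, ps))
  expect_true(all(c("take-path-west", "pop-frame", "follow-route",
                    "label-store") %in% harvest_names))
  for (nm in harvest_names)
    expect_equal(ps[[nm]]$reward, 14)
  ## round-end recognizers carry the boredom trigger
  expect_equal(ps[["goal-reached"]]$reward, 0)
  expect_equal(ps[["round-timeout"]]$reward, 0)
  ## request productions carry no trigger
  expect_true(is.na(ps[["find-path"]]$reward))
  ## continue/stop present with their initial utilities
  expect_equal(ps$continue$utility, 10)
  expect_equal(ps$stop$utility, 5)
  ## idempotent
  expect_identical(attach_curiosity(ag, mcfg), ag)
})

test_that("a production classified both ways is a configuration error", {
  mz <- tiny_maze()
  ag <- build_agent("random", mz)
  bad <- ag$productions[["take-path"]]
  bad$round_end <- TRUE
  ag$productions[["take-path"]] <- bad
  expect_error(attach_curiosity(ag, motivation_config()), "both")
})

test_that("the first continue/stop decision follows the stated probability", {
  ## U = (10, 5), 2s = 1: P(continue) = 1 / (1 + exp(5 - 10))
  p <- selection_probs(c(10, 5), egs = 0.5)
  expect_equal(p[1], 1 / (1 + exp(-5)), tolerance = 1e-12)
  ## simulated: over seeded runs the first decision is continue almost always
  mz <- tiny_maze()
  first <- vapply(1:60, function(s) {
    rec <- quick_run("random", mz, curiosity = 10, seed = s,
                     trace = FALSE, max_rounds = 1)
    rec$rounds_started > 0
  }, logical(1))
  expect_gte(mean(first), 0.9)            # 3 SE below 0.9933 at n = 60
})

test_that("stopping at the first decision yields an empty run", {
  mz <- tiny_maze()
  mcfg <- motivation_config(curiosity_reward = 10, u0_continue = -1e9)
  rec <- run_task(build_agent("random", mz), mz, motivation = mcfg, seed = 1,
                  trace = FALSE)
  expect_identical(rec$termination_reason, "stopped")
  expect_identical(rec$rounds_started, 0L)
  expect_lt(up_time_ratio(rec), 0.001)
})

test_that("the run terminates exactly at the run limit mid-round", {
  mz <- maze_generate(5, 3)
  mcfg <- motivation_config(curiosity_reward = 18, u0_stop = -1e9,
                            round_limit = 30, run_limit = 100)
  rec <- run_task(build_agent("random", mz), mz, motivation = mcfg, seed = 2,
                  trace = FALSE)
  expect_identical(rec$termination_reason, "run_limit")
  expect_equal(rec$termination_time, 100)
  expect_equal(up_time_ratio(rec), 1)
})

test_that("round timeouts close rounds and are counted as non-goal", {
  mz <- maze_generate(9, 5)                   # big map, short rounds
  mcfg <- motivation_config(curiosity_reward = 18, u0_stop = -1e9,
                            round_limit = 20, run_limit = 200)
  rec <- run_task(build_agent("dfs", mz), mz, motivation = mcfg, seed = 2,
                  trace = TRUE)
  ends <- rec$events[rec$events$kind == "round-end", ]
  expect_gt(nrow(ends), 3)
  expect_true(all(ends$a == "timeout"))
  expect_identical(rec$rounds_goal, 0L)
  ## every round lasted at most the limit plus one firing's slack
  begins <- rec$events$time[rec$events$kind == "round-begin"]
  durations <- ends$time - begins[seq_len(nrow(ends))]
  expect_true(all(durations <= 20 + 2))
})

test_that("without curiosity the task is abandoned before the time limit", {
  mz <- maze_generate(5, 17)
  stops <- vapply(1:25, function(s) {
    rec <- run_task(build_agent("random", mz), mz,
                    motivation = motivation_config(curiosity_reward = 0),
                    seed = s, trace = FALSE)
    rec$termination_time
  }, numeric(1))
  expect_lt(mean(stops), 3600)
  expect_gt(mean(stops < 3600), 0.8)
})

test_that("no reward event is ever emitted by a compiled production", {
  mz <- maze_generate(5, 23)
  rec <- quick_run("random", mz, curiosity = 10, seed = 11, trace = TRUE)
  rw <- rec$events[rec$events$kind == "reward", ]
  expect_gt(nrow(rw), 0)
  expect_false(any(startsWith(rw$production, "compiled")))
})

test_that("the reward grid spans 2 to 18 in five equal steps", {
  expect_equal(curiosity_reward_grid(), c(2, 6, 10, 14, 18))
})
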