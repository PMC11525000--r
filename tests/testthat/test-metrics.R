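# Outcome indicators and aggregation.

fake_record <- function(visits, rounds_started = 10L, rounds_goal = 3L,
                        termination_time = 1800, run_limit = 3600,
                        n_states = length(visits)) {
  structure(list(events = NULL, visit_histogram = visits, moves = sum(visits),
                 rounds_started = rounds_started, rounds_goal = rounds_goal,
                 rounds_completed = rounds_started,
                 compiled_productions_created = 5L,
                 termination_time = termination_time,
                 termination_reason = "stopped", run_limit = run_limit,
                 n_states = n_states, strategy = "random", maze_size = 5,
                 maze_seed = 1, curiosity_reward = 10, seed = 1),
            class = "cm_run_record")
}

test_that("up-time ratio is the terminated fraction of the run limit", {
  expect_equal(up_time_ratio(fake_record(1, termination_time = 3600)), 1)
  expect_equal(up_time_ratio(fake_record(1, termination_time = 1800)), 0.5)
  expect_lt(up_time_ratio(fake_record(1, termination_time = 0.35)), 0.001)
})

test_that("normalized entropy hits its analytic anchors", {
  expect_equal(normalized_entropy(rep(7, 10), 10), 1)
  expect_equal(normalized_entropy(c(12, 0, 0, 0), 4), 0)
  expect_equal(normalized_entropy(c(1, 1), 4), log(2) / log(4))
  expect_equal(normalized_entropy(integer(0), 25), 0)      # convention
  expect_equal(normalized_entropy(c(0, 0, 0), 25), 0)
})

test_that("entropy stays within [0, 1] for arbitrary histograms", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    h <- stats::rpois(n, lambda = sample(1:20, 1))
    H <- normalized_entropy(h, n)
    expect_gte(H, 0)
    expect_lte(H, 1 + 1e-12)
  }
})

test_that("goal rate is goals over started rounds with a zero convention", {
  expect_equal(goal_rate(fake_record(1, rounds_started = 10L,
                                     rounds_goal = 3L)), 0.3)
  expect_equal(goal_rate(fake_record(1, rounds_started = 0L,
                                     rounds_goal = 0L)), 0)
  expect_equal(goal_rate(fake_record(1, rounds_started = 6L,
                                     rounds_goal = 6L)), 1)
})

test_that("indicators recompute purely from the record", {
  mz <- maze_generate(5, 2)
  rec <- quick_run("random", mz, seed = 3, trace = FALSE)
  i1 <- indicators(rec)
  i2 <- indicators(rec)
  expect_identical(i1, i2)
  expect_equal(i1$entropy,
               normalized_entropy(rec$visit_histogram, rec$n_states))
  expect_true(i1$up_time_ratio >= 0 && i1$up_time_ratio <= 1)
  expect_true(i1$goal_rate >= 0 && i1$goal_rate <= 1)
})

test_that("aggregation is permutation invariant with per-map spread", {
  set.seed(4)
  tab <- do.call(rbind, lapply(1:3, function(map) {
    data.frame(strategy = "random", size = 5, reward = 10, map_seed = map,
               rep_seed = 1:4, up_time_ratio = stats::runif(4),
               n_rounds = sample(1:30, 4), entropy = stats::runif(4),
               goal_rate = stats::runif(4), n_new_productions = sample(1:9, 4),
               termination_reason = "stopped", map_index = map)
  }))
  a1 <- aggregate_indicators(tab)
  a2 <- aggregate_indicators(tab[sample(nrow(tab)), ])
  expect_equal(a1, a2)
  expect_identical(a1$n, 12L)
  expect_equal(a1$mean_up_time_ratio, mean(tab$up_time_ratio))
  ## spread: mean over maps of the within-map standard deviation
  expect_equal(a1$sd_up_time_ratio,
               mean(tapply(tab$up_time_ratio, tab$map_seed, sd)))
  ## a single run aggregates to itself with zero spread
  a3 <- aggregate_indicators(tab[1, ])
  expect_equal(a3$mean_n_rounds, tab$n_rounds[1])
  expect_equal(a3$sd_n_rounds, 0)
})

test_that("trajectory summaries conserve visits and tag compiled jumps", {
  mz <- maze_generate(5, 6)
  rec <- quick_run("random", mz, curiosity = 18, seed = 8, trace = TRUE)
  tr <- render_trajectory(rec, mz)
  expect_setequal(tr$nodes$node, mz$nodes)
  ## unvisited nodes carry zero weight
  expect_true(all(tr$nodes$visits >= 0))
  ## conservation: visit mass equals logged moves plus the initial placement
  expect_identical(sum(tr$nodes$visits), rec$moves + 1L)
  expect_identical(sum(tr$segments$count),
                   sum(rec$events$kind == "move"))
  ## any non-adjacent segment is either a compiled jump or the round-start
  ## reset of the continue production
  jumps <- tr$segments[!tr$segments$adjacent, ]
  if (nrow(jumps) > 0)
    expect_true(all(startsWith(jumps$production, "compiled") |
                      jumps$production == "continue"))
})
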