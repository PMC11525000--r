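# Core production-system primitives: pattern matching, softmax selection,
# utility updates, noisy retrieval, compilation.

buffers_with_goal <- function(goal, retrieval = NULL,
                              status = if (is.null(retrieval)) "empty" else "full") {
  list(goal = goal, imaginal = NULL, retrieval = retrieval,
       retrieval_status = status)
}

test_that("matching unifies variables against buffer contents", {
  goal <- chunk("g", "nav", location = "nodeA")
  p <- production("p",
                  lhs = list(cond_buffer("goal", location = "?v")),
                  rhs = list(act_modify("goal", location = "?v")))
  m <- match_productions(list(p), buffers_with_goal(goal))
  expect_length(m, 1)
  expect_equal(m[[1]]$bindings[["?v"]], "nodeA")

  ## repeated variable must unify across slots
  p2 <- production("p2",
                   lhs = list(cond_buffer("goal", location = "?x", target = "?x")),
                   rhs = list(act_clear("goal")))
  goal2 <- chunk("g2", "nav", location = "a", target = "b")
  expect_length(match_productions(list(p2), buffers_with_goal(goal2)), 0)
  goal3 <- chunk("g3", "nav", location = "a", target = "a")
  expect_length(match_productions(list(p2), buffers_with_goal(goal3)), 1)
})

test_that("a production requiring a retrieval chunk cannot match an empty buffer", {
  p <- production("h",
                  lhs = list(cond_buffer("goal", state = "wait"),
                             cond_buffer("retrieval", type = "path", to = "?t")),
                  rhs = list(act_modify("goal", loc = "?t")))
  goal <- chunk("g", "nav", state = "wait")
  expect_length(match_productions(list(p), buffers_with_goal(goal)), 0)
  ## and both members of a genuine conflict set are returned
  q <- production("q", lhs = list(cond_buffer("goal", state = "wait")),
                  rhs = list(act_clear("retrieval")))
  ch <- chunk("r", "path", to = "nodeB")
  m <- match_productions(list(p, q), buffers_with_goal(goal, ch))
  expect_setequal(vapply(m, function(i) i$production$name, character(1)),
                  c("h", "q"))
})

test_that("negated tests reject equal values, bound or constant", {
  p <- production("n",
                  lhs = list(cond_buffer("goal", loc = "?l", target = "?g",
                                         negs = list(loc = "?g"))),
                  rhs = list(act_clear("goal")))
  at_goal <- chunk("g", "nav", loc = "x", target = "x")
  away <- chunk("g", "nav", loc = "x", target = "y")
  expect_length(match_productions(list(p), buffers_with_goal(at_goal)), 0)
  expect_length(match_productions(list(p), buffers_with_goal(away)), 1)
})

test_that("softmax selection follows the stated probability law", {
  ## U = (10, 5), s = 0.5: P(first) = 1 / (1 + exp(-5))
  p <- selection_probs(c(10, 5), egs = 0.5)
  expect_equal(p[1], 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  ## equal utilities: uniform over k
  expect_equal(selection_probs(rep(3, 4), 0.5), rep(0.25, 4))

  ## Monte-Carlo firing frequencies match within 3 standard errors
  goal <- chunk("g", "nav", state = "s")
  mk <- function(nm) production(nm,
                                lhs = list(cond_buffer("goal", state = "s")),
                                rhs = list(act_clear("goal")))
  insts <- match_productions(list(mk("a"), mk("b")),
                             buffers_with_goal(goal))
  n <- 1e5
  set.seed(42)
  picks <- vapply(seq_len(n), function(i)
    select_instantiation(insts, c(10, 5), 0.5)$production$name, character(1))
  phat <- mean(picks == "a")
  p0 <- 1 / (1 + exp(-5))
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(phat - p0), 3 * se)

  ## single candidate is deterministic
  expect_identical(select_instantiation(insts[1], 10, 0.5)$production$name, "a")
  expect_error(select_instantiation(list(), numeric(0), 0.5), "quiescence")
})

test_that("utility updates follow the delta rule and its closed form", {
  cfg <- engine_config(discount_rewards_by_time = FALSE)
  u <- c(p = 10)
  w <- list(production = "p", time = 0)
  expect_equal(apply_reward(u, w, R = 0, time = 1, cfg)[["p"]], 8)
  ## fixed point
  expect_equal(apply_reward(c(p = 7), w, R = 7, time = 1, cfg)[["p"]], 7)
  ## |U_n - R| = (1 - alpha)^n |U_0 - R| under constant reward
  u0 <- 10; R <- 2
  u <- c(p = u0)
  for (n in 1:25) {
    u <- apply_reward(u, w, R = R, time = n, cfg)
    expect_equal(abs(u[["p"]] - R), (1 - cfg$alpha)^n * abs(u0 - R),
                 tolerance = 1e-10)
  }
  ## time discounting subtracts the elapsed time from the reward
  cfg_d <- engine_config(discount_rewards_by_time = TRUE)
  u <- apply_reward(c(p = 0), list(production = "p", time = 2),
                    R = 10, time = 5, cfg_d)
  expect_equal(u[["p"]], 0.2 * (10 - 3))
})

test_that("retrieval returns matching chunks, fails cleanly, and is seeded", {
  dm <- curiomaze:::new_dm()
  curiomaze:::dm_add(dm, chunk("p1", "path", from = "a", to = "b", dir = "east"))
  curiomaze:::dm_add(dm, chunk("p2", "path", from = "a", to = "c", dir = "south"))
  curiomaze:::dm_add(dm, chunk("p3", "path", from = "z", to = "a", dir = "west"))
  cfg <- engine_config(retrieval_threshold = -1e6)

  set.seed(1)
  res <- retrieve_chunk(list(type = "path", tests = c(from = "z")), dm, cfg)
  expect_identical(res$outcome, "success")
  expect_identical(res$chunk$name, "p3")
  expect_gt(res$latency, 0)

  ## no candidate matches the constants
  res <- retrieve_chunk(list(type = "path", tests = c(from = "q")), dm, cfg)
  expect_identical(res$outcome, "failure")
  expect_equal(res$latency,
               min(cfg$retrieval_latency_factor *
                     exp(-cfg$retrieval_threshold),
                   cfg$retrieval_latency_cap))

  ## negations restrict the candidate set
  set.seed(2)
  res <- retrieve_chunk(list(type = "path", tests = c(from = "a"),
                             negs = list(dir = "east")), dm, cfg)
  expect_identical(res$chunk$name, "p2")

  ## seeded winner is reproducible
  pick <- function(s) {
    set.seed(s)
    retrieve_chunk(list(type = "path", tests = c(from = "a")), dm,
                   engine_config())$chunk$name
  }
  expect_identical(pick(7), pick(7))
})

test_that("compiling a request/harvest pair yields a retrieval-free rule", {
  req <- production("req",
                    lhs = list(cond_buffer("goal", type = "nav", state = "check",
                                           loc = "?l", target = "?g",
                                           negs = list(loc = "?g"))),
                    rhs = list(act_request("path", from = "?l"),
                               act_modify("goal", state = "wait")))
  harv <- production("harv",
                     lhs = list(cond_buffer("goal", type = "nav", state = "wait",
                                            loc = "?l"),
                                cond_buffer("retrieval", type = "path",
                                            from = "?l", to = "?t")),
                     rhs = list(act_modify("goal", loc = "?t", state = "check"),
                                act_clear("retrieval")),
                     reward = 10)
  bind <- c("?l" = "n0_0", "?t" = "n0_1", "?g" = "n2_2")
  cp <- compile_productions(req, harv, bind)
  expect_true(cp$compiled)
  expect_true(is.na(cp$reward))           # triggers are never inherited
  expect_identical(cp$parents, c("req", "harv"))
  ## no retrieval access remains
  expect_false(any(vapply(cp$rhs, function(a) a$op == "request", logical(1))))
  expect_false(any(vapply(cp$lhs, function(cd) cd$buffer == "retrieval",
                          logical(1))))
  ## retrieval-bound variables became constants; the goal end state matches
  tests <- cp$lhs[[1]]$tests
  expect_identical(unname(tests[["loc"]]), "n0_0")
  mods <- curiomaze:::goal_modify_slots(cp)
  expect_identical(unname(mods[["loc"]]), "n0_1")
  expect_identical(unname(mods[["state"]]), "check")

  ## an ineligible pair (no request) is a no-op
  expect_null(compile_productions(harv, harv, bind))
})

test_that("compiled productions never carry a reward trigger", {
  expect_error(production("bad", lhs = list(cond_buffer("goal", a = "1")),
                          rhs = list(act_clear("goal")),
                          reward = 5, compiled = TRUE),
               "reward trigger")
})

test_that("actions referencing unbound variables are construction errors", {
  expect_error(
    production("oops",
               lhs = list(cond_buffer("goal", loc = "?l")),
               rhs = list(act_modify("goal", loc = "?nowhere"))),
    "unbound variable")
})
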