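# The three search strategies as production sets.

test_that("all strategies share the path-retrieval interface", {
  mz <- tiny_maze()
  for (s in c("random", "dfs", "dfs_ibl")) {
    ag <- build_agent(s, mz)
    reqs <- Filter(function(p) any(vapply(p$rhs, function(a)
      a$op == "request" && identical(a$type, "path"), logical(1))),
      ag$productions)
    expect_gte(length(reqs), 1)
    harvests <- Filter(curiomaze:::is_harvest_production, ag$productions)
    expect_gte(length(harvests), 1)
    expect_identical(ag$goal$slots[["loc"]], mz$start)
    expect_identical(ag$goal$slots[["target"]], mz$goal)
  }
})

test_that("the random walker moves along edges and can re-enter dead ends", {
  mz <- tiny_maze()
  rec <- run_task(build_agent("random", mz), mz,
                  motivation = eager_motivation(run_limit = 400),
                  seed = 5, trace = TRUE, max_rounds = 1)
  mv <- rec$events[rec$events$kind == "move", ]
  mv <- mv[mv$production != "continue", ]
  expect_gt(nrow(mv), 10)
  edge_set <- c(paste(mz$edges$from, mz$edges$to),
                paste(mz$edges$to, mz$edges$from))
  plain <- !startsWith(mv$production, "compiled")
  expect_true(all(paste(mv$a, mv$b)[plain] %in% edge_set))
  ## memoryless: at least one immediate return a -> b -> a among plain moves
  pm <- mv[plain, ]
  back <- pm$a[-1] == pm$b[-nrow(pm)] & pm$b[-1] == pm$a[-nrow(pm)]
  expect_true(any(back))
})

test_that("retrieval failure leaves the random walker's location unchanged", {
  mz <- tiny_maze()
  rec <- run_task(build_agent("random", mz), mz,
                  motivation = eager_motivation(run_limit = 200),
                  seed = 5, trace = TRUE, max_rounds = 1)
  ev <- rec$events
  fails <- which(ev$kind == "retrieve-fail")
  moves <- which(ev$kind == "move")
  for (i in fails) {
    loc_before <- ev$b[max(moves[moves < i], na.rm = TRUE)]
    nxt <- moves[moves > i]
    if (!length(nxt)) next
    after <- ev$a[nxt[1]]
    expect_identical(after, loc_before)
  }
})

test_that("depth-first search sets the reverse flag and backtracks at dead ends", {
  mz <- maze_generate(5, 13)
  ag <- build_agent("dfs", mz)
  ## structural: each directional harvest marks the arrival's reverse flag
  for (d in c("west", "north", "east", "south")) {
    p <- ag$productions[[paste0("take-path-", d)]]
    mods <- curiomaze:::goal_modify_slots(p)
    rev <- curiomaze:::opposite_dir[[d]]
    expect_identical(unname(mods[[substr(rev, 1, 1)]]), rev)
    others <- setdiff(c("w", "n", "e", "s"), substr(rev, 1, 1))
    expect_true(all(mods[others] == "clear"))
  }
  ## behavioural: backtracking pops restore previously visited locations
  rec <- run_task(ag, mz, motivation = eager_motivation(run_limit = 2000),
                  seed = 3, trace = TRUE, max_rounds = 1)
  mv <- rec$events[rec$events$kind == "move", ]
  pops <- mv[mv$production == "pop-frame", ]
  expect_gt(nrow(pops), 0)
  visited_before <- function(k) {
    prior <- mv[mv$time < pops$time[k], ]
    pops$b[k] %in% c(prior$a, prior$b)
  }
  expect_true(all(vapply(seq_len(nrow(pops)), visited_before, logical(1))))
})

test_that("depth-first search reaches the goal when limits are disabled", {
  for (seed in 1:6) {
    mz <- maze_generate(5, seed + 100)
    rec <- run_task(build_agent("dfs", mz), mz,
                    motivation = eager_motivation(), seed = seed,
                    trace = FALSE, max_rounds = 1)
    expect_identical(rec$termination_reason, "max_rounds")
    expect_identical(rec$rounds_goal, 1L)
  }
})

test_that("stack frames form an acyclic chain from top to bottom", {
  mz <- maze_generate(5, 21)
  rec <- run_task(build_agent("dfs", mz), mz,
                  motivation = eager_motivation(run_limit = 600),
                  seed = 9, trace = TRUE, max_rounds = 1)
  ## every successful frame retrieval during backtracking names a chunk
  ## created earlier by a push (audit via the trace)
  ev <- rec$events
  created <- ev$a[ev$kind == "move"]      # proxy: pushes accompany moves
  frames <- ev$a[ev$kind == "retrieve-success" &
                   grepl("^im", ev$a)]
  expect_true(all(grepl("^im", frames)))
  expect_gt(length(frames), 0)
})

test_that("instance learning follows labeled routes and shortens rounds", {
  mz <- maze_generate(5, 31)
  rec <- run_task(build_agent("dfs_ibl", mz), mz,
                  motivation = eager_motivation(), seed = 2,
                  trace = TRUE, max_rounds = 3)
  expect_gte(rec$rounds_goal, 1L)
  expect_gt(nrow(rec$instances), 0)
  ## every instance lies on the unique start->goal tree path
  g <- maze_igraph(mz)
  path_nodes <- names(igraph::shortest_paths(g, mz$start, mz$goal)$vpath[[1]])
  expect_true(all(rec$instances$from %in% path_nodes))
  expect_true(all(rec$instances$to %in% path_nodes))
  ## consecutive instances chain towards the goal
  expect_true(all(rec$instances$to != mz$start))
  ## concatenating a fully-instanced route reaches the goal
  if (nrow(rec$instances) == length(path_nodes) - 1) {
    route <- rec$instances
    cur <- mz$start
    for (k in seq_len(nrow(route))) {
      nxt <- route$to[route$from == cur]
      expect_length(nxt, 1)
      cur <- nxt
    }
    expect_identical(cur, mz$goal)
  }
})

test_that("before the first goal the instance memory is empty and unused", {
  mz <- maze_generate(5, 41)
  rec <- run_task(build_agent("dfs_ibl", mz), mz,
                  motivation = eager_motivation(run_limit = 120),
                  seed = 4, trace = TRUE, max_rounds = 1)
  if (rec$rounds_goal == 0) {
    ev <- rec$events
    expect_false(any(ev$production == "follow-route" & ev$kind == "fire"))
    expect_identical(nrow(rec$instances), 0L)
  } else succeed()
})
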