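## The three internal-environment models, expressed purely as production
## sets over the topological map chunks. All three share the same
## path-retrieval interface (request a "path" chunk at the current
## location, harvest it with variables), so curiosity instrumentation is
## uniform across strategies.
##
## Goal-buffer state machine (slot "state"):
##   decide -> continue/stop conflict (added by attach_curiosity)
##   check  -> goal test or path search          (random, dfs)
##   icheck -> goal test or route-instance recall (dfs_ibl)
##   wait   -> harvest / failure of a path retrieval
##   bwait  -> harvest / retry of a stack-frame retrieval (backtracking)
##   iwait  -> harvest / failure of an instance retrieval
##   label / lwait -> stack unwinding after a goal round (dfs_ibl)

FLAG_CLEAR <- "clear"

#' Build a maze-search agent
#'
#' Constructs the production set and initial goal chunk for one of the three
#' search strategies:
#'
#' * `"random"` — memoryless random walk: retrieve any path chunk adjacent
#'   to the current location and take it; on retrieval failure, retry.
#' * `"dfs"` — stochastic depth-first search: the path request excludes
#'   already-searched directions (tracked as four flag slots in the goal
#'   buffer); each move pushes a stack frame chunk (built in the imaginal
#'   buffer, linked by name) recording the previous location and flags; on
#'   failure the stack is popped to backtrack. The stack is realized purely
#'   with chunks.
#' * `"dfs_ibl"` — depth-first search plus instance-based learning: before
#'   each move the agent first tries to recall a "correct path" instance
#'   chunk for its current location and follows it when found; after a
#'   goal-reaching round the stack is unwound one frame at a time, creating
#'   one instance chunk per route step (this labeling consumes simulated
#'   time like any other processing).
#'
#' The returned specification is uninstrumented: reward triggers and the
#' continue/stop productions are attached by [attach_curiosity()], which
#' [run_task()] applies automatically.
#'
#' @param strategy One of `"random"`, `"dfs"`, `"dfs_ibl"`.
#' @param maze A [maze_generate()] object.
#' @return An object of class `cm_agent`: `strategy`, `productions`,
#'   `goal` (initial goal chunk), `round_start_slots` (goal-buffer reset
#'   applied by the continue production at each round start).
#' @export
build_agent <- function(strategy = c("random", "dfs", "dfs_ibl"), maze) {
  strategy <- match.arg(strategy)
  switch(strategy,
         random = build_random(maze),
         dfs = build_dfs(maze),
         dfs_ibl = build_dfs_ibl(maze))
}

#' @rdname build_agent
#' @export
build_random <- function(maze) {
  prods <- list(
    production(
      "find-path",
      lhs = list(cond_buffer("goal", type = "nav", state = "check",
                             loc = "?l", target = "?g",
                             negs = list(loc = "?g"))),
      rhs = list(act_request("path", from = "?l"),
                 act_modify("goal", state = "wait"))),
    production(
      "take-path",
      lhs = list(cond_buffer("goal", type = "nav", state = "wait",
                             loc = "?l"),
                 cond_buffer("retrieval", type = "path",
                             from = "?l", to = "?t")),
      rhs = list(act_modify("goal", loc = "?t", state = "check"),
                 act_clear("retrieval"))),
    production(
      "path-miss",
      lhs = list(cond_buffer("goal", type = "nav", state = "wait"),
                 cond_buffer("retrieval", status = "failure")),
      rhs = list(act_clear("retrieval"),
                 act_modify("goal", state = "check"))),
    goal_reached_production("check", labeling = FALSE),
    round_timeout_production()
  )
  new_agent("random", prods, maze,
            round_start_slots = c(state = "check", loc = maze$start),
            goal_slots = c(state = "decide", loc = maze$start,
                           target = maze$goal))
}

#' @rdname build_agent
#' @export
build_dfs <- function(maze) {
  new_agent("dfs",
            c(dfs_core_productions(resume = "check"),
              list(goal_reached_production("check", labeling = FALSE),
                   round_timeout_production())),
            maze,
            round_start_slots = c(state = "check", loc = maze$start,
                                  w = FLAG_CLEAR, n = FLAG_CLEAR,
                                  e = FLAG_CLEAR, s = FLAG_CLEAR,
                                  stack = "none"),
            goal_slots = c(state = "decide", loc = maze$start,
                           target = maze$goal,
                           w = FLAG_CLEAR, n = FLAG_CLEAR,
                           e = FLAG_CLEAR, s = FLAG_CLEAR,
                           stack = "none"))
}

#' @rdname build_agent
#' @export
build_dfs_ibl <- function(maze) {
  prods <- c(
    dfs_core_productions(resume = "icheck"),
    list(
      ## strategy decision: try to recall a labeled route step first
      production(
        "recall-route",
        lhs = list(cond_buffer("goal", type = "nav", state = "icheck",
                               loc = "?l", target = "?g",
                               negs = list(loc = "?g"))),
        rhs = list(act_request("instance", from = "?l"),
                   act_modify("goal", state = "iwait"))),
      production(
        "follow-route",
        lhs = list(cond_buffer("goal", type = "nav", state = "iwait",
                               loc = "?l"),
                   cond_buffer("retrieval", type = "instance",
                               from = "?l", to = "?t")),
        rhs = list(act_modify("goal", loc = "?t", state = "icheck"),
                   act_clear("retrieval"))),
      production(           # fall through to the DFS machinery
        "no-route",
        lhs = list(cond_buffer("goal", type = "nav", state = "iwait"),
                   cond_buffer("retrieval", status = "failure")),
        rhs = list(act_clear("retrieval"),
                   act_modify("goal", state = "check"))),
      goal_reached_production("icheck", labeling = TRUE),
      ## unwind the stack, one instance chunk per frame (request + harvest)
      production(
        "label-next",
        lhs = list(cond_buffer("goal", type = "nav", state = "label",
                               stack = "?k", negs = list(stack = "none"))),
        rhs = list(act_request("frame", name = "?k"),
                   act_modify("goal", state = "lwait"))),
      production(
        "label-store",
        lhs = list(cond_buffer("goal", type = "nav", state = "lwait"),
                   cond_buffer("retrieval", type = "frame",
                               loc = "?fl", to = "?ft", link = "?fk")),
        rhs = list(act_create("instance", label = "correct-path",
                              from = "?fl", to = "?ft"),
                   act_modify("goal", stack = "?fk", state = "label"),
                   act_clear("retrieval"))),
      production(
        "label-retry",
        lhs = list(cond_buffer("goal", type = "nav", state = "lwait",
                               stack = "?k"),
                   cond_buffer("retrieval", status = "failure")),
        rhs = list(act_clear("retrieval"),
                   act_request("frame", name = "?k"))),
      round_end_production("label-done", "label",
                           extra_tests = c(stack = "none"),
                           outcome = "goal"),
      round_timeout_production()
    ))
  new_agent("dfs_ibl", prods, maze,
            round_start_slots = c(state = "icheck", loc = maze$start,
                                  w = FLAG_CLEAR, n = FLAG_CLEAR,
                                  e = FLAG_CLEAR, s = FLAG_CLEAR,
                                  stack = "none"),
            goal_slots = c(state = "decide", loc = maze$start,
                           target = maze$goal,
                           w = FLAG_CLEAR, n = FLAG_CLEAR,
                           e = FLAG_CLEAR, s = FLAG_CLEAR,
                           stack = "none"))
}

## DFS path search, four directional harvests, stack push/pop.
## `resume` is the state entered after a completed move or backtrack
## ("check" for plain DFS, "icheck" for DFS+IBL so that instance recall is
## attempted after every move, as in the printed loop).
dfs_core_productions <- function(resume) {
  search <- production(
    "find-path",
    lhs = list(cond_buffer("goal", type = "nav", state = "check",
                           loc = "?l", target = "?g",
                           w = "?fw", n = "?fn", e = "?fe", s = "?fs",
                           negs = list(loc = "?g"))),
    ## exclude already-searched directions: a flag holds the direction name
    ## once searched ("clear" otherwise, which never matches a path chunk)
    rhs = list(act_request("path", from = "?l",
                           negs = list(dir = c("?fw", "?fn", "?fe", "?fs"))),
               act_modify("goal", state = "wait")))

  move <- function(d) {
    rev <- opposite_dir[[d]]
    reset <- c(w = FLAG_CLEAR, n = FLAG_CLEAR, e = FLAG_CLEAR, s = FLAG_CLEAR)
    reset[substr(rev, 1, 1)] <- rev        # arrival: only the return
    production(                            # direction is marked searched
      paste0("take-path-", d),
      lhs = list(cond_buffer("goal", type = "nav", state = "wait",
                             loc = "?l",
                             w = "?fw", n = "?fn", e = "?fe", s = "?fs",
                             stack = "?k"),
                 cond_buffer("retrieval", type = "path",
                             from = "?l", to = "?t", dir = d)),
      rhs = c(list(act_create("frame", loc = "?l", to = "?t",
                              w = if (d == "west") "west" else "?fw",
                              n = if (d == "north") "north" else "?fn",
                              e = if (d == "east") "east" else "?fe",
                              s = if (d == "south") "south" else "?fs",
                              link = "?k")),
              list(do.call(act_modify,
                           c(list("goal"), as.list(c(loc = "?t",
                                                     stack = "@new",
                                                     reset,
                                                     state = resume))))),
              list(act_clear("retrieval"))))
  }

  list(
    search,
    move("west"), move("north"), move("east"), move("south"),
    production(
      "path-exhausted",
      lhs = list(cond_buffer("goal", type = "nav", state = "wait",
                             stack = "?k", negs = list(stack = "none")),
                 cond_buffer("retrieval", status = "failure")),
      rhs = list(act_clear("retrieval"),
                 act_request("frame", name = "?k"),
                 act_modify("goal", state = "bwait"))),
    production(                 # nothing left to pop: the whole search
      "path-exhausted-root",    # context is lost, start the search afresh
      lhs = list(cond_buffer("goal", type = "nav", state = "wait",
                             stack = "none"),
                 cond_buffer("retrieval", status = "failure")),
      rhs = list(act_clear("retrieval"),
                 act_modify("goal", w = FLAG_CLEAR, n = FLAG_CLEAR,
                            e = FLAG_CLEAR, s = FLAG_CLEAR,
                            state = resume))),
    production(
      "pop-frame",
      lhs = list(cond_buffer("goal", type = "nav", state = "bwait"),
                 cond_buffer("retrieval", type = "frame",
                             loc = "?pl", w = "?pw", n = "?pn",
                             e = "?pe", s = "?ps", link = "?pk")),
      rhs = list(act_modify("goal", loc = "?pl", w = "?pw", n = "?pn",
                            e = "?pe", s = "?ps", stack = "?pk",
                            state = resume),
                 act_clear("retrieval"))),
    production(                 # noisy frame retrieval missed: re-request
      "pop-retry",
      lhs = list(cond_buffer("goal", type = "nav", state = "bwait",
                             stack = "?k"),
                 cond_buffer("retrieval", status = "failure")),
      rhs = list(act_clear("retrieval"),
                 act_request("frame", name = "?k")))
  )
}

## round-end recognizers -------------------------------------------------

goal_reached_production <- function(state, labeling) {
  if (labeling) {
    p <- production(
      "goal-reached",
      lhs = list(cond_buffer("goal", type = "nav", state = state,
                             loc = "?g", target = "?g")),
      rhs = list(act_signal("goal-reached"),
                 act_modify("goal", state = "label")))
  } else {
    p <- production(
      "goal-reached",
      lhs = list(cond_buffer("goal", type = "nav", state = state,
                             loc = "?g", target = "?g")),
      rhs = list(act_signal("round-end", outcome = "goal"),
                 act_modify("goal", state = "decide")))
  }
  p$round_end <- TRUE
  p
}

round_end_production <- function(name, state, extra_tests = NULL,
                                 outcome = "goal") {
  cd <- cond_buffer("goal", type = "nav", state = state)
  if (!is.null(extra_tests)) cd$tests <- c(cd$tests, extra_tests)
  p <- production(name, lhs = list(cd),
                  rhs = list(act_signal("round-end", outcome = outcome),
                             act_modify("goal", state = "decide")))
  p$round_end <- TRUE
  p
}

round_timeout_production <- function() {
  p <- production(
    "round-timeout",
    lhs = list(cond_buffer("goal", type = "nav")),
    rhs = list(act_signal("round-end", outcome = "timeout"),
               act_clear("retrieval"),
               act_modify("goal", state = "decide")))
  p$round_end <- TRUE
  p$forced_only <- TRUE                     # fired by the clock, never by
  p                                         # conflict resolution
}

new_agent <- function(strategy, productions, maze, round_start_slots,
                      goal_slots) {
  names(productions) <- vapply(productions, `[[`, character(1), "name")
  goal <- chunk("task-goal", "nav")
  goal$slots <- goal_slots
  structure(list(strategy = strategy, productions = productions,
                 goal = goal, round_start_slots = round_start_slots,
                 maze_size = maze$size, maze_seed = maze$seed,
                 start = maze$start, target = maze$goal,
                 instrumented = FALSE),
            class = "cm_agent")
}

#' @export
print.cm_agent <- function(x, ...) {
  cat(sprintf("<agent %s: %d productions%s, start=%s goal=%s>\n",
              x$strategy, length(x$productions),
              if (x$instrumented) " (instrumented)" else "",
              x$start, x$target))
  invisible(x)
}
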