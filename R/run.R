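## The engine run loop: simulated clock, conflict resolution, firing,
## retrieval latencies, reward windows, compilation, round control.
## Hot-path notes: productions are immutable after insertion (utilities
## live in a separate environment), so index buckets hold the production
## objects themselves; compiled "pure move" productions match through a
## precomputed fast path; compilation outcomes are cached per firing pair.

## conflict-set index: productions bucketed by the constant parts of their
## goal condition (state, loc), with "*" wildcards for variable/absent
## tests. Productions that additionally test all four searched flags as
## constants (the compiled depth-first-search moves, which proliferate)
## get a finer bucket keyed on the flag configuration as well, so a cycle
## only scans the variants applicable to the current flag state.
index_key <- function(p) {
  g <- goal_cond(p)
  st <- "*"; lc <- "*"
  if (!is.null(g)) {
    t <- g$tests
    if (!is.na(t["state"]) && !is_var(t[["state"]])) st <- t[["state"]]
    if (!is.na(t["loc"]) && !is_var(t[["loc"]])) lc <- t[["loc"]]
    if (st != "*" && lc != "*") {
      fl <- t[c("w", "n", "e", "s")]
      if (!anyNA(fl) && !any(is_var(fl)))
        return(paste(st, lc, fl[1], fl[2], fl[3], fl[4], sep = "|"))
    }
    ## compiled backtrack / labeling rules: constant stack, no location
    if (st != "*" && lc == "*" &&
        !is.na(t["stack"]) && !is_var(t[["stack"]]))
      return(paste("stk", st, t[["stack"]], sep = "|"))
  }
  paste0(st, "|", lc)
}

## precompute matching metadata. A "fast move" is a compiled pure-move
## production whose single goal condition tests only constants plus a
## variable target with constant negations; given its index bucket already
## guarantees state and loc, matching reduces to one %in% test.
prepare_production <- function(p) {
  p$is_harvest_lhs <- any(vapply(p$lhs, function(cd)
    cd$buffer == "retrieval" && cd$status == "full", logical(1)))
  p$fast_move <- NULL
  if (!is.null(p$pure_move) && length(p$lhs) == 1L) {
    cd <- p$lhs[[1L]]
    t <- cd$tests
    vt <- is_var(t)
    ok <- sum(vt) == 1L && identical(names(t)[vt], "target") &&
      all(c("state", "loc") %in% names(t)[!vt]) &&
      (is.null(cd$negs) ||
         (identical(names(cd$negs), "target") &&
            !any(is_var(cd$negs[["target"]]))))
    if (ok)
      p$fast_move <- list(
        blocked = if (is.null(cd$negs)) character(0) else cd$negs[["target"]],
        var = t[vt][[1L]])
  }
  p
}

bucket_add <- function(st, p) {
  key <- index_key(p)
  b <- get0(key, envir = st$idx, inherits = FALSE)
  if (is.null(b)) b <- list()
  b[[length(b) + 1L]] <- p
  assign(key, b, envir = st$idx)
}

#' Run one task session
#'
#' Executes the full task-continuation loop for one agent on one maze: at
#' each round start the continue and stop productions compete by softmax
#' conflict resolution; on continue, the agent searches until it reaches the
#' goal or the round time limit elapses, a round-end production fires
#' (emitting the boredom reward), and a new round begins; on stop the run
#' terminates. The run also terminates at the run time limit. All events
#' are simulated-clock driven; the seed fully determines the trace.
#'
#' @param agent A `cm_agent` (instrumented or not; [attach_curiosity()] is
#'   applied with `motivation` if needed).
#' @param maze The maze whose chunks populate declarative memory.
#' @param engine An [engine_config()].
#' @param motivation A [motivation_config()].
#' @param seed Integer seed for all stochastic draws of the run.
#' @param trace Keep the full event trace (data frame) in the record?
#'   Disable for large sweeps.
#' @param max_rounds Optional cap on completed rounds (useful with
#'   `run_limit = Inf`); the run terminates with reason `"max_rounds"`.
#' @return An object of class `cm_run_record`; see [indicators()].
#' @export
run_task <- function(agent, maze, engine = engine_config(),
                     motivation = motivation_config(), seed = 1,
                     trace = TRUE, max_rounds = Inf) {
  if (!isTRUE(agent$instrumented)) agent <- attach_curiosity(agent, motivation)
  with_seed(seed, {
    st <- engine_init(agent, maze, engine, motivation, trace)
    engine_loop(st, max_rounds)
    build_record(st, agent, maze, seed)
  })
}

engine_init <- function(agent, maze, ecfg, mcfg, trace) {
  st <- new.env(parent = emptyenv())
  st$cfg <- ecfg; st$mcfg <- mcfg
  st$clock <- 0
  st$dm <- new_dm()
  topo <- maze_to_chunks(maze)
  for (ch in topo$nodes) dm_add(st$dm, ch)
  for (ch in topo$paths) dm_add(st$dm, ch)
  st$prods <- new.env(parent = emptyenv())
  st$util <- new.env(parent = emptyenv())
  st$idx <- new.env(parent = emptyenv())
  st$sig2name <- new.env(parent = emptyenv())
  st$pair_cache <- new.env(parent = emptyenv())
  st$pair_rv <- new.env(parent = emptyenv())
  for (p in agent$productions) {
    p <- prepare_production(p)
    assign(p$name, p, envir = st$prods)
    assign(p$name, p$utility, envir = st$util)
    if (!isTRUE(p$forced_only)) bucket_add(st, p)
  }
  st$gensym <- 0L
  st$ncomp <- 0L
  ## buffers
  st$goal <- agent$goal
  st$imaginal <- NULL
  st$retrieval <- NULL
  st$retrieval_status <- "empty"
  st$busy_until <- Inf
  st$pending <- NULL
  st$retrieval_source <- NA_character_
  st$retrieval_req_idx <- NA_integer_
  ## reward window
  st$win_p <- character(256); st$win_t <- numeric(256); st$win_n <- 0L
  ## bookkeeping
  st$fire_idx <- 0L
  st$last <- NULL
  st$harvest_source_ok <- FALSE
  st$rounds_started <- 0L; st$rounds_goal <- 0L; st$rounds_completed <- 0L
  st$in_round <- FALSE; st$round_ongoing <- FALSE; st$round_start <- 0
  st$stopped <- FALSE; st$reason <- NA_character_
  st$visits <- stats::setNames(integer(length(maze$nodes)), maze$nodes)
  st$visits[agent$start] <- 1L
  st$moves <- 0L
  ## trace
  st$trace_on <- isTRUE(trace)
  cap <- 1024L
  st$ev_time <- numeric(cap); st$ev_kind <- character(cap)
  st$ev_p1 <- character(cap); st$ev_a <- character(cap)
  st$ev_b <- character(cap); st$ev_val <- numeric(cap); st$ev_n <- 0L
  st
}

ev_log <- function(st, time, kind, p1 = NA_character_, a = NA_character_,
                   b = NA_character_, val = NA_real_) {
  if (!st$trace_on) return(invisible())
  n <- st$ev_n + 1L
  if (n > length(st$ev_time)) {
    grow <- function(x) { length(x) <- 2L * length(x); x }
    st$ev_time <- grow(st$ev_time); st$ev_kind <- grow(st$ev_kind)
    st$ev_p1 <- grow(st$ev_p1); st$ev_a <- grow(st$ev_a)
    st$ev_b <- grow(st$ev_b); st$ev_val <- grow(st$ev_val)
  }
  st$ev_time[n] <- time; st$ev_kind[n] <- kind; st$ev_p1[n] <- p1
  st$ev_a[n] <- a; st$ev_b[n] <- b; st$ev_val[n] <- val
  st$ev_n <- n
  invisible()
}

deliver_retrieval <- function(st) {
  res <- st$pending
  st$pending <- NULL
  if (res$outcome == "success") {
    st$retrieval <- res$chunk
    st$retrieval_status <- "full"
    ev_log(st, st$clock, "retrieve-success", st$retrieval_source,
           res$chunk$name, val = res$activation)
  } else {
    st$retrieval <- NULL
    st$retrieval_status <- "failure"
    ev_log(st, st$clock, "retrieve-fail", st$retrieval_source)
  }
  st$busy_until <- Inf
}

emit_reward <- function(st, R, source) {
  cfg <- st$cfg
  n <- st$win_n
  if (n > 0L) {
    now <- st$clock
    disc <- cfg$discount_rewards_by_time
    a <- cfg$alpha
    util <- st$util
    for (k in seq_len(n)) {
      nm <- st$win_p[k]
      r_eff <- if (disc) R - (now - st$win_t[k]) else R
      u <- get(nm, envir = util)
      assign(nm, u + a * (r_eff - u), envir = util)
    }
  }
  st$win_n <- 0L
  ev_log(st, st$clock, "reward", source, val = R)
}

## recompilation strengthening: the compiled rule inherits the higher of
## its parents' utilities as the Eq. 2 reward, so with practice it can
## overtake the parents and come to represent the routine
strengthen_compiled <- function(st, child, parent1, parent2) {
  u_parent <- get(parent1, envir = st$util)
  if (!is.null(parent2)) {
    u2 <- get0(parent2, envir = st$util)
    if (!is.null(u2)) u_parent <- max(u_parent, u2)
  }
  u <- get(child, envir = st$util)
  assign(child, u + st$cfg$alpha * (u_parent - u), envir = st$util)
  ev_log(st, st$clock, "recompile", child)
}

## register a freshly compiled production, or strengthen an existing
## identical one; returns its name
add_compiled <- function(st, newp, parent1, parent2) {
  sig <- newp$signature
  existing <- get0(sig, envir = st$sig2name, inherits = FALSE)
  if (!is.null(existing)) {
    strengthen_compiled(st, existing, parent1, parent2)
    return(existing)
  }
  st$ncomp <- st$ncomp + 1L
  newp$name <- sprintf("compiled-%04d", st$ncomp)
  newp <- prepare_production(newp)
  assign(sig, newp$name, envir = st$sig2name)
  assign(newp$name, newp, envir = st$prods)
  assign(newp$name, 0, envir = st$util)
  bucket_add(st, newp)
  ev_log(st, st$clock, "compile", newp$name,
         newp$parents[1], newp$parents[2])
  newp$name
}

## retrieval-involved variables of a request/harvest pair (cached)
pair_retrieval_vars <- function(st, p1, p2, key) {
  rv <- get0(key, envir = st$pair_rv, inherits = FALSE)
  if (!is.null(rv)) return(rv)
  rv <- character(0)
  for (a in p1$rhs)
    if (a$op == "request") {
      rv <- c(rv, a$slots[is_var(a$slots)])
      if (!is.null(a$negs)) { u <- unlist(a$negs); rv <- c(rv, u[is_var(u)]) }
    }
  for (cd in p2$lhs)
    if (cd$buffer == "retrieval") {
      rv <- c(rv, cd$tests[is_var(cd$tests)])
      if (!is.null(cd$negs)) { u <- unlist(cd$negs); rv <- c(rv, u[is_var(u)]) }
    }
  rv <- unique(unname(rv))
  assign(key, rv, envir = st$pair_rv)
  rv
}

## compilation bookkeeping for the pair (previous firing, current firing)
try_compile <- function(st, prev, p, bind) {
  if (prev$requested && st$harvest_source_ok && p$is_harvest_lhs) {
    pkey <- paste0(prev$p$name, "|", p$name)
    rv <- pair_retrieval_vars(st, prev$p, p, pkey)
    allb <- c(prev$bind, bind)
    ckey <- paste0(pkey, "|", paste(allb[rv], collapse = ","))
    hit <- get0(ckey, envir = st$pair_cache, inherits = FALSE)
    if (!is.null(hit)) {
      if (nzchar(hit)) strengthen_compiled(st, hit, prev$p$name, p$name)
      return(invisible())
    }
    cp <- compile_productions(prev$p, p, allb)
    nm <- if (is.null(cp)) "" else add_compiled(st, cp, prev$p$name, p$name)
    assign(ckey, nm, envir = st$pair_cache)
  } else if (!is.null(prev$p$pure_move) && !is.null(p$pure_move) &&
             (prev$p$pure_move$hops %||% 1L) + (p$pure_move$hops %||% 1L) <=
               st$cfg$max_move_chain) {
    ckey <- paste0(prev$p$name, "|", p$name)
    hit <- get0(ckey, envir = st$pair_cache, inherits = FALSE)
    if (!is.null(hit)) {
      if (nzchar(hit)) strengthen_compiled(st, hit, prev$p$name, p$name)
      return(invisible())
    }
    cp <- compose_goal_moves(prev$p, p)
    nm <- if (is.null(cp)) "" else add_compiled(st, cp, prev$p$name, p$name)
    assign(ckey, nm, envir = st$pair_cache)
  }
  invisible()
}

fire_production <- function(st, p, bind, forced = FALSE) {
  t0 <- st$clock
  st$clock <- t0 + st$cfg$production_time
  ev_log(st, t0, "fire", p$name)
  loc_before <- st$goal$slots[["loc"]]

  new_name <- NULL
  signals <- NULL
  had_request <- FALSE
  for (a in p$rhs) {
    op <- a$op
    if (op == "modify") {
      s <- subst(a$slots, bind, new_name)
      ch <- st[[a$buffer]]
      ch$slots[names(s)] <- s
      st[[a$buffer]] <- ch
    } else if (op == "request") {
      pattern <- list(type = a$type, tests = subst(a$slots, bind))
      if (!is.null(a$negs)) {
        ng <- lapply(a$negs, function(v) {
          v <- subst(v, bind)
          v[v != FLAG_CLEAR]               # unsearched flags impose nothing
        })
        ng <- ng[vapply(ng, length, integer(1)) > 0L]
        if (length(ng)) pattern$negs <- ng
      }
      res <- retrieve_chunk(pattern, st$dm, st$cfg)
      st$retrieval <- NULL
      st$retrieval_status <- "busy"
      st$busy_until <- st$clock + res$latency
      st$pending <- res
      st$retrieval_source <- p$name
      st$retrieval_req_idx <- st$fire_idx + 1L
      had_request <- TRUE
    } else if (op == "create") {
      st$gensym <- st$gensym + 1L
      nm <- sprintf("im%05d", st$gensym)
      ch <- chunk(nm, a$type, ctime = st$clock)
      ch$slots <- subst(a$slots, bind)
      new_name <- dm_add(st$dm, ch)
      st$imaginal <- ch
    } else if (op == "clear") {
      if (a$buffer == "retrieval") {
        st$retrieval <- NULL
        st$retrieval_status <- "empty"
        st$busy_until <- Inf
        st$pending <- NULL
      } else st[[a$buffer]] <- NULL
    } else if (op == "signal") {
      signals <- c(signals, list(a))
    }
  }
  st$fire_idx <- st$fire_idx + 1L

  ## movement bookkeeping
  loc_after <- st$goal$slots[["loc"]]
  if (!identical(loc_before, loc_after)) {
    st$moves <- st$moves + 1L
    st$visits[[loc_after]] <- st$visits[[loc_after]] + 1L
    ev_log(st, st$clock, "move", p$name, loc_before, loc_after)
  }

  ## production compilation: consecutive eligible pairs
  prev <- st$last
  if (!forced && st$cfg$enable_compilation &&
      !is.null(prev) && prev$idx == st$fire_idx - 1L)
    try_compile(st, prev, p, bind)
  st$last <- list(p = p, bind = bind, idx = st$fire_idx,
                  requested = had_request)

  ## reward window entry, then any triggered reward event
  n <- st$win_n + 1L
  if (n > length(st$win_p)) {
    length(st$win_p) <- 2L * length(st$win_p)
    length(st$win_t) <- 2L * length(st$win_t)
  }
  st$win_p[n] <- p$name; st$win_t[n] <- t0; st$win_n <- n

  if (!is.na(p$reward)) emit_reward(st, p$reward, p$name)

  ## task-control signals
  if (!is.null(signals)) for (sg in signals) {
    if (sg$kind == "stop") {
      st$stopped <- TRUE
      st$reason <- "stopped"
    } else if (sg$kind == "goal-reached") {
      if (st$round_ongoing) st$rounds_goal <- st$rounds_goal + 1L
      st$round_ongoing <- FALSE            # labeling is not clocked
      ev_log(st, st$clock, "goal", p$name)
    } else if (sg$kind == "round-end") {
      if (st$round_ongoing && identical(sg$outcome, "goal"))
        st$rounds_goal <- st$rounds_goal + 1L
      st$round_ongoing <- FALSE
      st$in_round <- FALSE
      st$rounds_completed <- st$rounds_completed + 1L
      ev_log(st, st$clock, "round-end", p$name, sg$outcome)
    }
  }
  if (isTRUE(p$is_continue)) {
    st$rounds_started <- st$rounds_started + 1L
    st$in_round <- TRUE
    st$round_ongoing <- TRUE
    st$round_start <- st$clock
    ev_log(st, st$clock, "round-begin", p$name, val = st$rounds_started)
  }
  invisible()
}

engine_loop <- function(st, max_rounds = Inf) {
  mcfg <- st$mcfg
  run_limit <- mcfg$run_limit
  round_limit <- mcfg$round_limit
  egs <- st$cfg$egs
  idx <- st$idx
  util <- st$util
  empty_bind <- character(0)
  repeat {
    if (st$stopped) break
    if (st$clock >= run_limit) {
      st$reason <- "run_limit"; st$clock <- run_limit; break
    }
    if (st$rounds_completed >= max_rounds) { st$reason <- "max_rounds"; break }
    ## round timeout pre-empts conflict resolution
    if (st$in_round && st$round_ongoing &&
        st$clock - st$round_start >= round_limit) {
      p <- get("round-timeout", envir = st$prods)
      st$harvest_source_ok <- FALSE
      fire_production(st, p, empty_bind, forced = TRUE)
      next
    }
    if (st$retrieval_status == "busy" && st$clock >= st$busy_until - 1e-9)
      deliver_retrieval(st)
    gs <- st$goal$slots
    gstate <- gs[["state"]]; gloc <- gs[["loc"]]
    gtarget <- gs[["target"]]
    gnames <- names(gs)
    flagged <- if (!is.na(match("w", gnames)))
      get0(paste(gstate, gloc, gs[["w"]], gs[["n"]], gs[["e"]], gs[["s"]],
                 sep = "|"), envir = idx, inherits = FALSE)
    stacked <- if (!is.na(match("stack", gnames)))
      get0(paste("stk", gstate, gs[["stack"]], sep = "|"),
           envir = idx, inherits = FALSE)
    cands <- c(flagged, stacked,
               get0(paste0(gstate, "|", gloc), envir = idx, inherits = FALSE),
               get0(paste0(gstate, "|*"), envir = idx, inherits = FALSE),
               get0(paste0("*|", gloc), envir = idx, inherits = FALSE),
               get0("*|*", envir = idx, inherits = FALSE))
    nin <- 0L
    insts <- NULL
    if (length(cands)) {
      insts <- vector("list", length(cands))
      buffers <- list(goal = st$goal, imaginal = st$imaginal,
                      retrieval = st$retrieval,
                      retrieval_status = st$retrieval_status)
      for (p in cands) {
        fm <- p$fast_move
        if (!is.null(fm)) {                  # bucket guarantees state & loc
          if (!(gtarget %in% fm$blocked)) {
            nin <- nin + 1L
            b <- gtarget; names(b) <- fm$var
            insts[[nin]] <- list(production = p, bindings = b)
          }
        } else {
          b <- match_bindings(p, buffers)
          if (!is.null(b)) {
            nin <- nin + 1L
            insts[[nin]] <- list(production = p, bindings = b)
          }
        }
      }
    }
    if (nin == 0L) {
      if (st$retrieval_status == "busy") {
        st$clock <- min(st$busy_until, run_limit)
        if (st$clock >= st$busy_until - 1e-9) deliver_retrieval(st)
        next
      }
      st$reason <- "quiescent"              # no rule matches, nothing pending
      break
    }
    if (nin == 1L) {
      sel <- insts[[1L]]
    } else {
      insts <- insts[seq_len(nin)]
      u <- vapply(insts, function(i) get(i$production$name, envir = util),
                  numeric(1))
      sel <- select_instantiation(insts, u, egs)
    }
    ## was the retrieval in the buffer produced by the immediately
    ## preceding firing's request? (needed for compilation eligibility)
    st$harvest_source_ok <- !is.null(st$last) &&
      identical(st$retrieval_source, st$last$p$name) &&
      identical(st$retrieval_req_idx, st$fire_idx)
    fire_production(st, sel$production, sel$bindings)
  }
  if (is.na(st$reason)) st$reason <- "run_limit"
  st$termination_time <- min(st$clock, run_limit)
  invisible(st)
}

build_record <- function(st, agent, maze, seed) {
  events <- NULL
  if (st$trace_on && st$ev_n > 0L) {
    i <- seq_len(st$ev_n)
    events <- data.frame(time = st$ev_time[i], kind = st$ev_kind[i],
                         production = st$ev_p1[i], a = st$ev_a[i],
                         b = st$ev_b[i], value = st$ev_val[i],
                         stringsAsFactors = FALSE)
  }
  util <- mget(ls(st$util), envir = st$util)
  inst_names <- get0("instance", envir = st$dm$by_type, inherits = FALSE)
  instances <- if (length(inst_names)) {
    data.frame(
      from = vapply(inst_names, function(nm)
        dm_get(st$dm, nm)$slots[["from"]], character(1)),
      to = vapply(inst_names, function(nm)
        dm_get(st$dm, nm)$slots[["to"]], character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(from = character(0), to = character(0))
  structure(list(
    events = events,
    instances = instances,
    visit_histogram = st$visits,
    moves = st$moves,
    rounds_started = st$rounds_started,
    rounds_goal = st$rounds_goal,
    rounds_completed = st$rounds_completed,
    compiled_productions_created = st$ncomp,
    termination_time = st$termination_time,
    termination_reason = st$reason,
    run_limit = st$mcfg$run_limit,
    n_states = length(maze$nodes),
    strategy = agent$strategy,
    maze_size = maze$size, maze_seed = maze$seed,
    curiosity_reward = if (!is.null(agent$motivation))
      agent$motivation$curiosity_reward else NA_real_,
    seed = seed,
    final_utilities = unlist(util)),
    class = "cm_run_record")
}

#' @export
print.cm_run_record <- function(x, ...) {
  cat(sprintf(
    "<run %s %dx%d R=%s: %s at %.1f s | rounds %d (goal %d) | moves %d | compiled %d>\n",
    x$strategy, x$maze_size, x$maze_size,
    format(x$curiosity_reward), x$termination_reason, x$termination_time,
    x$rounds_started, x$rounds_goal, x$moves,
    x$compiled_productions_created))
  invisible(x)
}

#' Write a run's event trace as JSON lines
#'
#' One JSON object per event (`time`, `kind`, payload), the engine's
#' serialized test surface.
#'
#' @param record A `cm_run_record` produced with `trace = TRUE`.
#' @param path Output file path.
#' @export
write_trace_jsonl <- function(record, path) {
  if (is.null(record$events)) stop("record has no trace (trace = FALSE)")
  con <- file(path, "w")
  on.exit(close(con))
  ev <- record$events
  for (k in seq_len(nrow(ev))) {
    row <- as.list(ev[k, ])
    row <- row[!vapply(row, function(v) is.na(v) || identical(v, ""), logical(1))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
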