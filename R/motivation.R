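#' Motivation configuration
#'
#' Parameters of the task-continuation mechanism: intrinsic (curiosity)
#' reward magnitude, boredom reward at round ends, initial utilities of the
#' continue/stop productions, and the round/run time limits.
#'
#' @param curiosity_reward Magnitude of the positive reward emitted by every
#'   pattern-matching (retrieval-harvesting) production. The study design
#'   samples it at five equal intervals over \[2, 18\]:
#'   `curiosity_reward_grid()`.
#' @param boredom_reward Reward emitted by productions recognizing the end
#'   of a round (goal reached or round time limit).
#' @param u0_continue,u0_stop Initial utilities of the continue and stop
#'   productions.
#' @param round_limit,run_limit Simulated-seconds limits of one round and of
#'   the whole run.
#' @return A list of class `cm_motivation_config`.
#' @export
motivation_config <- function(curiosity_reward = 10, boredom_reward = 0,
                              u0_continue = 10, u0_stop = 5,
                              round_limit = 180, run_limit = 3600) {
  stopifnot(round_limit > 0, run_limit > 0)
  structure(list(curiosity_reward = curiosity_reward,
                 boredom_reward = boredom_reward,
                 u0_continue = u0_continue, u0_stop = u0_stop,
                 round_limit = round_limit, run_limit = run_limit),
            class = "cm_motivation_config")
}

#' The five curiosity-reward intensities of the study design
#'
#' Five equal intervals over the range 2 to 18, endpoints inclusive.
#'
#' @return `c(2, 6, 10, 14, 18)`.
#' @export
curiosity_reward_grid <- function() seq(2, 18, by = 4)

is_harvest_production <- function(p) {
  if (isTRUE(p$compiled)) return(FALSE)
  for (cd in p$lhs)
    if (cd$buffer == "retrieval" && cd$status == "full" &&
        any(is_var(cd$tests)))
      return(TRUE)
  FALSE
}

#' Attach curiosity and boredom wiring to an agent
#'
#' Instruments a [build_agent()] specification: every non-compiled
#' production that harvests a declarative retrieval with at least one
#' variable binding (i.e. performs pattern matching) receives a positive
#' reward trigger of magnitude `curiosity_reward`; every production that
#' recognizes the end of a round (goal reached, round timeout) receives the
#' boredom trigger; and the continue/stop productions that gate each round
#' are added with their initial utilities. A production classified both
#' ways is a configuration error.
#'
#' @param agent A `cm_agent`.
#' @param config A [motivation_config()].
#' @return The instrumented agent.
#' @export
attach_curiosity <- function(agent, config = motivation_config()) {
  stopifnot(inherits(agent, "cm_agent"))
  if (isTRUE(agent$instrumented)) return(agent)
  prods <- agent$productions
  for (nm in names(prods)) {
    p <- prods[[nm]]
    harv <- is_harvest_production(p)
    rend <- isTRUE(p$round_end)
    if (harv && rend)
      stop("production ", nm,
           " classified as both pattern-matching and round-end")
    if (harv) p$reward <- config$curiosity_reward
    if (rend) p$reward <- config$boredom_reward
    prods[[nm]] <- p
  }
  continue <- production(
    "continue",
    lhs = list(cond_buffer("goal", type = "nav", state = "decide")),
    rhs = list(do.call(act_modify,
                       c(list("goal"), as.list(agent$round_start_slots)))),
    utility = config$u0_continue)
  continue$is_continue <- TRUE
  stop_p <- production(
    "stop",
    lhs = list(cond_buffer("goal", type = "nav", state = "decide")),
    rhs = list(act_signal("stop")),
    utility = config$u0_stop)
  prods$continue <- continue
  prods$stop <- stop_p
  agent$productions <- prods
  agent$instrumented <- TRUE
  agent$motivation <- config
  agent
}
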