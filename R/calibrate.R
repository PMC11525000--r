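## Calibration of the retrieval latency factor F.
##
## The only timing anchor available for the declarative module is the rule
## transition time of 1.15 s per step of the uncompiled random-walk agent.
## F is chosen so that the mean simulated time between location changes of
## that agent (compilation disabled by measuring the first moves of fresh
## runs) matches the anchor; the resulting default is recorded in
## engine_config().

#' Mean per-step transition time of the uncompiled random-walk agent
#'
#' Measures the mean simulated time between consecutive location changes
#' during the early, uncompiled phase of random-walk runs (the first round,
#' before compiled moves can dominate).
#'
#' @param latency_factor Retrieval latency factor `F` to evaluate.
#' @param n_mazes Number of 5x5 mazes to average over.
#' @param steps_per_maze Number of transitions measured per maze.
#' @param seed Integer seed.
#' @return Mean transition time in simulated seconds.
#' @export
mean_transition_time <- function(latency_factor, n_mazes = 8,
                                 steps_per_maze = 120, seed = 1) {
  total <- 0; count <- 0L
  for (i in seq_len(n_mazes)) {
    mz <- maze_generate(5, mix_seed(seed, 7001, i))
    ag <- build_agent("random", mz)
    ## generous limits, stop never competitive: one long uncompiled round
    mcfg <- motivation_config(curiosity_reward = 0, u0_stop = -1e6,
                              round_limit = Inf,
                              run_limit = steps_per_maze * 4)
    ecfg <- engine_config(retrieval_latency_factor = latency_factor,
                          enable_compilation = FALSE)
    rec <- run_task(ag, mz, ecfg, mcfg, seed = mix_seed(seed, 7002, i),
                    trace = TRUE)
    mv <- rec$events[rec$events$kind == "move", , drop = FALSE]
    mv <- mv[mv$production != "continue", , drop = FALSE]
    mv <- utils::head(mv, steps_per_maze)
    if (nrow(mv) >= 2) {
      total <- total + (mv$time[nrow(mv)] - mv$time[1])
      count <- count + nrow(mv) - 1L
    }
  }
  total / count
}

#' Calibrate the retrieval latency factor
#'
#' Bisection on `F` so that [mean_transition_time()] matches `target`
#' (1.15 s, the per-step equivalence used to align the step-based baseline
#' with the clocked agents).
#'
#' @param target Target mean transition time in seconds.
#' @param lower,upper Bracketing interval for `F`.
#' @param tol Acceptable absolute deviation from the target.
#' @param seed Integer seed.
#' @param ... Passed on to [mean_transition_time()].
#' @return The calibrated latency factor.
#' @export
calibrate_latency_factor <- function(target = 1.15, lower = 0.2, upper = 2,
                                     tol = 0.01, seed = 1, ...) {
  f <- function(x) mean_transition_time(x, seed = seed, ...) - target
  lo <- lower; hi <- upper
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) stop("target not bracketed by [lower, upper]")
  for (k in 1:20) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
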