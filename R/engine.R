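#' Engine configuration
#'
#' Parameters of the production-system runtime. Times are simulated seconds;
#' the engine has no wall-clock dependence and a seed fully determines a run.
#'
#' @param ans Activation noise: scale of the logistic noise added to chunk
#'   activations during retrieval.
#' @param egs Utility noise `s` of the softmax conflict resolution
#'   (probabilities proportional to `exp(U / (2 s))`).
#' @param alpha Utility learning rate in (0, 1].
#' @param production_time Seconds consumed by one production firing.
#' @param retrieval_latency_factor Latency factor `F`: a successful
#'   retrieval takes `F * exp(-A')` seconds at noisy activation `A'`. The
#'   default is calibrated so the uncompiled random-walk agent's mean
#'   per-step transition time is about 1.15 s (see
#'   [calibrate_latency_factor()]).
#' @param retrieval_threshold Minimum noisy activation for a retrieval to
#'   succeed.
#' @param base_activation Fixed base activation shared by all stored chunks
#'   (no base-level decay or spreading activation is modelled).
#' @param retrieval_latency_cap Upper bound on any retrieval latency in
#'   seconds, applied to successes and failures alike: memory search is
#'   abandoned or resolved within a bounded time regardless of how low the
#'   noisy activation falls.
#' @param discount_rewards_by_time If `TRUE` (default), a reward of
#'   magnitude `R` reaching a production fired `dt` seconds earlier is
#'   applied as `R - dt`, the architecture's temporal credit assignment:
#'   as compilation pushes the first pattern-match reward of a round later,
#'   the continue production's effective reward decays — the graded boredom
#'   dynamics. `FALSE` applies the plain update with `R` itself.
#' @param enable_compilation Master switch for production compilation
#'   (disabled for calibration and for isolating the uncompiled dynamics).
#' @param max_move_chain Longest hop chain a compiled move production may
#'   cover: two consecutive compiled single-edge moves compose into one
#'   two-hop jump (the diagonal / through-wall moves of automatized
#'   behavior); longer chains are not composed further.
#' @return A list of class `cm_engine_config`.
#' @export
engine_config <- function(ans = 0.4, egs = 0.5, alpha = 0.2,
                          production_time = 0.050,
                          retrieval_latency_factor = 16.6,
                          retrieval_threshold = 1.2,
                          base_activation = 2.4,
                          retrieval_latency_cap = 1.5,
                          discount_rewards_by_time = TRUE,
                          enable_compilation = TRUE,
                          max_move_chain = 2) {
  stopifnot(ans > 0, egs > 0, alpha > 0, alpha <= 1,
            production_time > 0, retrieval_latency_factor > 0)
  structure(list(ans = ans, egs = egs, alpha = alpha,
                 production_time = production_time,
                 retrieval_latency_factor = retrieval_latency_factor,
                 retrieval_threshold = retrieval_threshold,
                 base_activation = base_activation,
                 retrieval_latency_cap = retrieval_latency_cap,
                 discount_rewards_by_time = discount_rewards_by_time,
                 enable_compilation = enable_compilation,
                 max_move_chain = max_move_chain),
            class = "cm_engine_config")
}

#' Softmax selection probabilities over a conflict set
#'
#' `P(i) = exp(U_i / (2 s)) / sum_j exp(U_j / (2 s))`.
#'
#' @param utilities Numeric vector of utilities.
#' @param egs Noise parameter `s` (> 0).
#' @return Probabilities summing to 1.
#' @export
selection_probs <- function(utilities, egs) {
  z <- utilities / (2 * egs)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Select one instantiation by softmax conflict resolution
#'
#' Samples one instantiation with the probabilities of [selection_probs()],
#' using the current RNG stream (deterministic under a fixed seed).
#'
#' @param instantiations Non-empty list of instantiations as returned by
#'   [match_productions()].
#' @param utilities Numeric vector of the matching productions' utilities,
#'   in the same order.
#' @param egs Noise parameter `s`.
#' @return The selected instantiation.
#' @export
select_instantiation <- function(instantiations, utilities, egs) {
  n <- length(instantiations)
  if (n == 0L) stop("empty conflict set: quiescence")
  if (n == 1L) return(instantiations[[1L]])
  p <- selection_probs(utilities, egs)
  i <- findInterval(stats::runif(1), cumsum(p)) + 1L
  if (i > n) i <- n
  instantiations[[i]]
}

#' Apply a reward event to the fired-production window
#'
#' Every production firing recorded since the previous reward event receives
#' one update `U <- U + alpha * (R_eff - U)` in firing order, where `R_eff`
#' is the raw magnitude (default) or the magnitude minus the elapsed time
#' since that firing when time discounting is enabled. The window is then
#' cleared.
#'
#' @param utilities Named numeric vector of production utilities.
#' @param window Data frame or list with `production` (names) and `time`
#'   (firing times) of the firings since the last event.
#' @param R Reward magnitude.
#' @param time Event time (simulated seconds).
#' @param config An [engine_config()].
#' @return The updated utility vector.
#' @export
apply_reward <- function(utilities, window, R, time, config) {
  prods <- window$production
  times <- window$time
  for (k in seq_along(prods)) {
    r_eff <- if (config$discount_rewards_by_time) R - (time - times[[k]]) else R
    u <- utilities[[prods[[k]]]]
    utilities[[prods[[k]]]] <- u + config$alpha * (r_eff - u)
  }
  utilities
}

## ---- production compilation --------------------------------------------

## deterministic content signature for compiled-production identity
prod_signature <- function(lhs, rhs) {
  fmt_cond <- function(cd) {
    t <- cd$tests
    if (length(t)) t <- t[order(names(t))]
    ng <- if (is.null(cd$negs)) "" else
      paste(vapply(names(cd$negs)[order(names(cd$negs))], function(k)
        paste0(k, "!", paste(sort(cd$negs[[k]]), collapse = ",")),
        character(1)), collapse = ";")
    paste(cd$buffer, cd$status, cd$type %||% "",
          paste(names(t), t, sep = "=", collapse = ","), ng, sep = "|")
  }
  fmt_act <- function(a) {
    s <- a$slots
    if (length(s)) s <- s[order(names(s))]
    paste(a$op, a$buffer %||% "", a$type %||% "", a$kind %||% "",
          a$outcome %||% "",
          paste(names(s), s, sep = "=", collapse = ","), sep = "|")
  }
  paste(paste(vapply(lhs, fmt_cond, character(1)), collapse = "&"),
        paste(vapply(rhs, fmt_act, character(1)), collapse = "&"),
        sep = " => ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subst_cond <- function(cd, bind) {
  if (length(cd$tests)) {
    v <- is_var(cd$tests) & cd$tests %in% names(bind)
    cd$tests[v] <- bind[cd$tests[v]]
  }
  if (!is.null(cd$negs))
    cd$negs <- lapply(cd$negs, function(vals) {
      v <- is_var(vals) & vals %in% names(bind)
      vals[v] <- bind[vals[v]]
      vals
    })
  cd
}

subst_act <- function(a, bind) {
  if (!is.null(a$slots) && length(a$slots)) {
    v <- is_var(a$slots) & a$slots %in% names(bind)
    a$slots[v] <- bind[a$slots[v]]
  }
  if (!is.null(a$negs))
    a$negs <- lapply(a$negs, function(vals) {
      v <- is_var(vals) & vals %in% names(bind)
      vals[v] <- bind[vals[v]]
      vals
    })
  a
}

## merge consecutive goal-modify actions; later writes win
merge_modifies <- function(actions) {
  out <- list(); pend <- NULL
  for (a in actions) {
    if (a$op == "modify" && a$buffer == "goal") {
      if (is.null(pend)) pend <- a
      else pend$slots[names(a$slots)] <- a$slots
    } else {
      out[[length(out) + 1L]] <- a
    }
  }
  if (!is.null(pend)) out[[length(out) + 1L]] <- pend
  out
}

goal_cond <- function(p) {
  for (cd in p$lhs) if (cd$buffer == "goal") return(cd)
  NULL
}

goal_modify_slots <- function(p, bind = NULL) {
  out <- character(0)
  for (a in p$rhs)
    if (a$op == "modify" && a$buffer == "goal") {
      s <- if (is.null(bind)) a$slots else subst(a$slots, bind)
      out[names(s)] <- s
    }
  out
}

is_goal_only <- function(p) {
  all(vapply(p$lhs, function(cd) cd$buffer == "goal", logical(1))) &&
    all(vapply(p$rhs, function(a)
      a$op == "modify" && a$buffer == "goal", logical(1)))
}

#' Compile a retrieval request/harvest production pair
#'
#' Combines a production `p1` that issued a declarative retrieval request
#' with the production `p2` that harvested its result in the next firing
#' into a single production that no longer touches declarative memory.
#' Every variable that took part in the retrieval (in the request pattern or
#' in `p2`'s retrieval-buffer tests) is replaced by the constant it was
#' bound to in the firing; variables untouched by the retrieval remain
#' variables. The compiled production carries no reward trigger regardless
#' of its parents and starts at utility 0.
#'
#' @param p1,p2 The parent productions.
#' @param bindings Named character vector: the union of the variable
#'   bindings of the two firings.
#' @return A compiled [production()], or `NULL` when the pair is not an
#'   eligible request/harvest sequence.
#' @export
compile_productions <- function(p1, p2, bindings) {
  req <- NULL
  for (a in p1$rhs) if (a$op == "request") req <- a
  harvests <- any(vapply(p2$lhs, function(cd)
    cd$buffer == "retrieval" && cd$status == "full", logical(1)))
  if (is.null(req) || !harvests) return(NULL)

  ## variables touched by the retrieval become constants
  rv <- character(0)
  rv <- c(rv, req$slots[is_var(req$slots)])
  if (!is.null(req$negs)) { u <- unlist(req$negs); rv <- c(rv, u[is_var(u)]) }
  for (cd in p2$lhs)
    if (cd$buffer == "retrieval") {
      rv <- c(rv, cd$tests[is_var(cd$tests)])
      if (!is.null(cd$negs)) { u <- unlist(cd$negs); rv <- c(rv, u[is_var(u)]) }
    }
  rv <- unique(unname(rv))
  bind <- bindings[intersect(rv, names(bindings))]

  g1 <- goal_cond(p1); g2 <- goal_cond(p2)
  mod1 <- goal_modify_slots(p1, bindings)
  tests <- g1$tests
  negs <- g1$negs %||% list()
  if (!is.null(g2)) {
    for (k in seq_along(g2$tests)) {
      sl <- names(g2$tests)[k]
      if (sl %in% names(mod1)) {
        want <- g2$tests[[k]]
        want_v <- if (startsWith(want, "?")) unname(bindings[want]) else want
        if (!is.na(want_v) && want_v != mod1[[sl]]) return(NULL)
      } else if (!sl %in% names(tests)) {
        tests[sl] <- g2$tests[[k]]
      }
    }
    if (!is.null(g2$negs))
      for (sl in names(g2$negs))
        negs[[sl]] <- unique(c(negs[[sl]], g2$negs[[sl]]))
  }
  gcd <- cond_buffer("goal", type = g1$type, status = "full",
                     negs = if (length(negs)) negs else NULL)
  gcd$tests <- tests
  lhs <- list(subst_cond(gcd, bind))
  ## p1's own non-goal conditions survive (e.g. a retrieval-failure test on
  ## a backtracking production): the compiled rule must not fire in states
  ## its first parent could not have fired in
  for (cd in p1$lhs)
    if (cd$buffer != "goal")
      lhs[[length(lhs) + 1L]] <- subst_cond(cd, bind)

  keep1 <- Filter(function(a) a$op != "request", p1$rhs)
  keep2 <- Filter(function(a)
    !(a$op == "clear" && a$buffer == "retrieval"), p2$rhs)
  rhs <- merge_modifies(lapply(c(keep1, keep2), subst_act, bind = bind))

  cp <- make_compiled_production(lhs, rhs, c(p1$name, p2$name))
  if (!is.null(cp) && !is.null(cp$pure_move)) cp$pure_move$hops <- 1L
  cp
}

## compose two consecutive pure goal-move productions (both compiled);
## models chained automatized moves, which can traverse several cells in a
## single 50 ms firing (the "through-wall jump" phenomenon).
compose_goal_moves <- function(p1, p2) {
  if (!is_goal_only(p1) || !is_goal_only(p2)) return(NULL)
  g1 <- p1$lhs[[1L]]; g2 <- p2$lhs[[1L]]
  if (!identical(g1$type, g2$type)) return(NULL)
  mod1 <- goal_modify_slots(p1)
  tests <- g1$tests
  for (k in seq_along(g2$tests)) {
    sl <- names(g2$tests)[k]
    want <- g2$tests[[k]]
    if (sl %in% names(mod1)) {
      if (want != mod1[[sl]]) return(NULL)   # p2 incompatible with p1 output
    } else if (sl %in% names(tests)) {
      if (want != tests[[sl]]) return(NULL)
    } else tests[sl] <- want
  }
  negs <- g1$negs %||% list()
  if (!is.null(g2$negs))
    for (sl in names(g2$negs))
      negs[[sl]] <- unique(c(negs[[sl]], g2$negs[[sl]]))
  cd <- cond_buffer("goal", type = g1$type,
                    negs = if (length(negs)) negs else NULL)
  cd$tests <- tests
  mod <- mod1
  mod2 <- goal_modify_slots(p2)
  mod[names(mod2)] <- mod2
  rhs <- list(list(op = "modify", buffer = "goal", slots = mod))
  cp <- make_compiled_production(list(cd), rhs, c(p1$name, p2$name))
  if (!is.null(cp) && !is.null(cp$pure_move))
    cp$pure_move$hops <- (p1$pure_move$hops %||% 1L) + (p2$pure_move$hops %||% 1L)
  cp
}

## Rewrite negated tests after constant substitution: a negation
## "slot S (now constant C) != ?v" where ?v is bound by slot T's test is
## equivalent to "slot T != C". Keeping the constraint on the binding slot
## preserves its meaning when compiled moves are composed (a chained move
## must not jump across the node a parent's negation protected).
normalize_negs <- function(cd) {
  if (is.null(cd$negs)) return(cd)
  tests <- cd$tests
  out <- cd$negs
  for (sl in names(cd$negs)) {
    tv <- tests[sl]
    if (is.na(tv) || is_var(tv)) next           # slot not constant: keep
    vals <- cd$negs[[sl]]
    keep <- character(0)
    for (v in vals) {
      if (is_var(v)) {
        tgt <- names(tests)[tests == v & names(tests) != sl]
        if (length(tgt)) {
          out[[tgt[1]]] <- unique(c(out[[tgt[1]]], unname(tv)))
        }                                        # else: unresolvable, drop
      } else if (v == tv) {
        return(NULL)                             # condition can never hold
      }                                          # constant != constant: drop
    }
    out[[sl]] <- keep
  }
  out <- out[vapply(out, length, integer(1)) > 0L]
  cd$negs <- if (length(out)) out else NULL
  cd
}

make_compiled_production <- function(lhs, rhs, parents) {
  lhs2 <- lapply(lhs, normalize_negs)
  if (any(vapply(lhs2, is.null, logical(1)))) return(NULL)
  lhs <- lhs2
  sig <- prod_signature(lhs, rhs)
  p <- structure(
    list(name = paste0("c", utf8_hash(sig)),
         lhs = lhs, rhs = rhs, utility = 0, reward = NA_real_,
         compiled = TRUE, parents = parents, forced_only = FALSE,
         pure_move = NULL, signature = sig),
    class = "cm_production")
  if (is_goal_only(p)) {
    fr <- p$lhs[[1L]]$tests["loc"]
    to <- goal_modify_slots(p)["loc"]
    if (!is.na(fr) && !is.na(to) && !is_var(fr) && !is_var(to))
      p$pure_move <- list(from = unname(fr), to = unname(to))
  }
  p
}

## small stable string hash (djb2), kept below 2^31
utf8_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}
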