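## Productions: IF (buffer tests, possibly with ?variables) / THEN (buffer
## actions). Conditions and actions are plain lists so models are fully
## serializable; variables are strings prefixed with "?".

is_var <- function(x) !is.na(x) & startsWith(x, "?")

#' Buffer condition for a production
#'
#' @param buffer One of `"goal"`, `"retrieval"`, `"imaginal"`.
#' @param type Required chunk type, or `NULL`.
#' @param ... Named slot tests; each value is a constant or a `"?var"`.
#' @param status For the retrieval buffer: `"full"` (default when slot tests
#'   are given) or `"failure"` to test a failed retrieval.
#' @param negs Named list of negated slot tests: the condition fails when the
#'   buffer chunk's slot equals the (resolved) value. Values may be constants
#'   or variables bound earlier in the condition list.
#' @return A condition object used in [production()].
#' @export
cond_buffer <- function(buffer, type = NULL, ..., status = NULL, negs = NULL) {
  tests <- list(...)
  tests <- if (length(tests)) vapply(tests, as.character, character(1)) else character(0)
  if (is.null(status)) status <- "full"
  if (!is.null(negs)) negs <- lapply(negs, as.character)
  list(buffer = buffer, type = type, tests = tests, status = status,
       negs = negs)
}

#' Production actions
#'
#' `act_modify()` writes slot values into a buffer chunk; `act_request()`
#' issues a declarative retrieval request (slot values must be constants or
#' bound variables; `negs` lists excluded values per slot); `act_create()`
#' creates a fresh chunk through the imaginal buffer and stores it in
#' declarative memory (the generated name can be referenced as `"@new"` in a
#' later `act_modify()` of the same production); `act_clear()` empties a
#' buffer; `act_signal()` emits a task-control signal interpreted by the run
#' loop (`"round-end"`, `"goal-reached"`, `"stop"`).
#'
#' @param buffer Target buffer id.
#' @param ... Named slot values (constants or `"?var"` / `"@new"`).
#' @param type Chunk type for requests and created chunks.
#' @param negs Named list of negated slot values for requests.
#' @param kind,outcome Signal kind and optional round outcome.
#' @return An action object used in [production()].
#' @name actions
NULL

#' @rdname actions
#' @export
act_modify <- function(buffer, ...) {
  list(op = "modify", buffer = buffer,
       slots = vapply(list(...), as.character, character(1)))
}

#' @rdname actions
#' @export
act_request <- function(type, ..., negs = NULL) {
  if (!is.null(negs)) negs <- lapply(negs, as.character)
  slots <- list(...)
  slots <- if (length(slots)) vapply(slots, as.character, character(1)) else character(0)
  list(op = "request", buffer = "retrieval", type = type,
       slots = slots, negs = negs)
}

#' @rdname actions
#' @export
act_create <- function(type, ...) {
  list(op = "create", buffer = "imaginal", type = type,
       slots = vapply(list(...), as.character, character(1)))
}

#' @rdname actions
#' @export
act_clear <- function(buffer) list(op = "clear", buffer = buffer)

#' @rdname actions
#' @export
act_signal <- function(kind, outcome = NA_character_) {
  list(op = "signal", kind = kind, outcome = outcome)
}

#' Define a production
#'
#' @param name Identifier, unique within a model.
#' @param lhs List of [cond_buffer()] conditions (the IF clause). Conditions
#'   are evaluated in order; variables bind on first occurrence and must
#'   unify on later occurrences.
#' @param rhs List of actions (the THEN clause), see [actions].
#' @param utility Initial utility.
#' @param reward Reward trigger magnitude, or `NA` for none. A production
#'   carrying a trigger emits a reward event of this magnitude each time it
#'   completes.
#' @param compiled Whether this production was produced by compilation.
#'   Compiled productions never carry reward triggers.
#' @param parents For compiled productions, the `c(p1, p2)` parent names.
#' @return An object of class `cm_production`.
#' @export
production <- function(name, lhs, rhs, utility = 0, reward = NA_real_,
                       compiled = FALSE, parents = NULL) {
  if (compiled && !is.na(reward))
    stop("compiled productions cannot carry a reward trigger")
  p <- structure(
    list(name = name, lhs = lhs, rhs = rhs, utility = utility,
         reward = reward, compiled = compiled, parents = parents,
         forced_only = FALSE, pure_move = NULL),
    class = "cm_production")
  validate_production(p)
  p
}

## every variable used in an action must be bound somewhere in the lhs
validate_production <- function(p) {
  bound <- character(0)
  for (cd in p$lhs) {
    tv <- cd$tests[is_var(cd$tests)]
    bound <- union(bound, tv)
  }
  used <- character(0)
  for (a in p$rhs) {
    if (!is.null(a$slots)) used <- c(used, a$slots[is_var(a$slots)])
    if (!is.null(a$negs)) used <- c(used, unlist(a$negs)[is_var(unlist(a$negs))])
  }
  miss <- setdiff(unique(used), bound)
  if (length(miss))
    stop("production ", p$name, ": unbound variable(s) in actions: ",
         paste(miss, collapse = ", "))
  ## negated condition tests may only use bound variables
  for (cd in p$lhs) {
    if (!is.null(cd$negs)) {
      nv <- unlist(cd$negs)
      nv <- nv[is_var(nv)]
      if (length(setdiff(nv, bound)))
        stop("production ", p$name, ": unbound variable in negated test")
    }
  }
  invisible(p)
}

#' @export
print.cm_production <- function(x, ...) {
  cat(sprintf("<production %s%s%s U=%.3g%s>\n", x$name,
              if (x$compiled) " [compiled]" else "",
              if (!is.na(x$reward)) sprintf(" [trigger R=%g]", x$reward) else "",
              x$utility,
              if (!is.null(x$parents))
                paste0(" <- ", paste(x$parents, collapse = " + ")) else ""))
  invisible(x)
}

## ---- pattern matching ---------------------------------------------------

## Unify one production against the current buffers. Returns a named
## character vector of bindings, or NULL when the production does not match.
match_bindings <- function(p, buffers) {
  b <- character(0)
  for (cd in p$lhs) {
    if (cd$buffer == "retrieval") {
      if (cd$status == "failure") {
        if (!identical(buffers$retrieval_status, "failure")) return(NULL)
        next
      }
      if (!identical(buffers$retrieval_status, "full")) return(NULL)
      ch <- buffers$retrieval
    } else {
      ch <- buffers[[cd$buffer]]
      if (is.null(ch)) return(NULL)
    }
    if (!is.null(cd$type) && ch$type != cd$type) return(NULL)
    tests <- cd$tests
    sl <- ch$slots
    sn <- names(sl)
    tn <- names(tests)
    bn <- names(b)
    for (k in seq_along(tests)) {
      want <- tests[[k]]
      i <- match(tn[k], sn)
      if (is.na(i)) return(NULL)
      have <- sl[[i]]
      if (startsWith(want, "?")) {
        j <- match(want, bn)
        if (is.na(j)) { b[[want]] <- have; bn <- names(b) }
        else if (b[[j]] != have) return(NULL)
      } else if (want != have) return(NULL)
    }
    if (!is.null(cd$negs)) {
      gn <- names(cd$negs)
      for (k in seq_along(cd$negs)) {
        i <- match(gn[k], sn)
        if (is.na(i)) next
        have <- sl[[i]]
        for (nv in cd$negs[[k]]) {
          if (startsWith(nv, "?")) {
            j <- match(nv, bn)
            if (!is.na(j) && b[[j]] == have) return(NULL)
          } else if (nv == have) return(NULL)
        }
      }
    }
  }
  b
}

#' Match productions against the current buffer contents
#'
#' Returns every production whose conditions unify with the buffers, each
#' paired with a consistent variable binding (an *instantiation*). Partial
#' matches are never returned; an empty list is a valid result.
#'
#' @param productions List of [production()] objects.
#' @param buffers A buffer-state list with elements `goal`, `imaginal`,
#'   `retrieval` (chunks or `NULL`) and `retrieval_status` (`"empty"`,
#'   `"busy"`, `"full"`, `"failure"`).
#' @return A list of instantiations: `list(production=, bindings=)`.
#' @export
match_productions <- function(productions, buffers) {
  out <- vector("list", length(productions))
  n <- 0L
  for (p in productions) {
    if (isTRUE(p$forced_only)) next
    b <- match_bindings(p, buffers)
    if (!is.null(b)) {
      n <- n + 1L
      out[[n]] <- list(production = p, bindings = b)
    }
  }
  out[seq_len(n)]
}

## substitute bindings into a named character vector of slot values
subst <- function(slots, bindings, new_name = NULL) {
  if (!length(slots)) return(slots)
  v <- is_var(slots)
  if (any(v)) slots[v] <- bindings[slots[v]]
  if (!is.null(new_name)) slots[slots == "@new"] <- new_name
  slots
}
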