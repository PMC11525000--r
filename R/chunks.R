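#' Create a chunk
#'
#' A chunk is the unit of symbolic knowledge in the engine: a typed frame of
#' slot--value pairs. Chunks live in declarative memory and in the module
#' buffers (goal, retrieval, imaginal), and are what productions pattern-match
#' against.
#'
#' @param name Unique identifier within a memory store.
#' @param type Chunk type identifier (e.g. `"path"`, `"node"`, `"nav"`).
#' @param ... Named slot values. Values are stored as character scalars;
#'   numbers are formatted with `as.character()`.
#' @param ctime Simulated creation time in seconds.
#' @return An object of class `cm_chunk`.
#' @examples
#' chunk("p1", "path", from = "n0_0", to = "n0_1", dir = "east")
#' @export
chunk <- function(name, type, ..., ctime = 0) {
  slots <- list(...)
  if (length(slots)) {
    if (is.null(names(slots)) || any(names(slots) == ""))
      stop("all slots must be named")
    if (anyDuplicated(names(slots)))
      stop("slot names must be unique within a chunk")
  }
  structure(
    list(name = name, type = type,
         slots = vapply(slots, as.character, character(1)),
         ctime = ctime),
    class = "cm_chunk")
}

#' @export
print.cm_chunk <- function(x, ...) {
  cat(sprintf("<chunk %s : %s>\n", x$name, x$type))
  if (length(x$slots))
    cat(paste0("  ", names(x$slots), " = ", x$slots, collapse = "\n"), "\n")
  invisible(x)
}

## ---- declarative memory -------------------------------------------------
## A store is an environment holding chunks by name plus two retrieval
## indices: by type, and by (type, from) for the maze path / instance /
## frame chunks that dominate retrieval traffic. A content signature set
## guards against duplicate knowledge (identical type + slots).

new_dm <- function() {
  dm <- new.env(parent = emptyenv())
  dm$chunks <- new.env(parent = emptyenv())
  dm$by_type <- new.env(parent = emptyenv())
  dm$by_type_from <- new.env(parent = emptyenv())
  dm$sigs <- new.env(parent = emptyenv())
  dm$n <- 0L
  dm
}

chunk_signature <- function(ch) {
  sl <- ch$slots
  if (length(sl)) sl <- sl[order(names(sl))]
  paste(ch$type, paste(names(sl), sl, sep = "=", collapse = ";"), sep = "|")
}

#' Add a chunk to a declarative memory store
#'
#' Duplicate content (same type and slots) is merged: the store keeps the
#' first copy and `dm_add()` returns its name. Names must be unique.
#'
#' @param dm A store created by [new_dm()] (exposed mainly for tests).
#' @param ch A [chunk()].
#' @return The name under which the chunk content is stored.
#' @keywords internal
dm_add <- function(dm, ch) {
  sig <- chunk_signature(ch)
  prior <- get0(sig, envir = dm$sigs, inherits = FALSE)
  if (!is.null(prior)) return(prior)
  if (!is.null(get0(ch$name, envir = dm$chunks, inherits = FALSE)))
    stop("chunk name already present in store: ", ch$name)
  assign(ch$name, ch, envir = dm$chunks)
  assign(sig, ch$name, envir = dm$sigs)
  tkey <- ch$type
  assign(tkey, c(get0(tkey, envir = dm$by_type, inherits = FALSE), ch$name),
         envir = dm$by_type)
  from <- unname(ch$slots["from"])
  if (!is.na(from)) {
    fkey <- paste0(ch$type, "|", from)
    assign(fkey,
           c(get0(fkey, envir = dm$by_type_from, inherits = FALSE), ch$name),
           envir = dm$by_type_from)
  }
  dm$n <- dm$n + 1L
  ch$name
}

dm_get <- function(dm, name) get0(name, envir = dm$chunks, inherits = FALSE)

## Candidate chunks for a retrieval pattern. The pattern is a list with
## $type, $tests (named character, constants only at request time) and
## optionally $negs (named list of excluded constants).
dm_candidates <- function(dm, pattern) {
  tests <- pattern$tests
  nm <- unname(tests["name"])
  if (!is.na(nm)) {                         # direct name lookup
    ch <- dm_get(dm, nm)
    if (is.null(ch) || (!is.null(pattern$type) && ch$type != pattern$type))
      return(list())
    cand <- list(ch)
  } else {
    from <- unname(tests["from"])
    names_vec <- if (!is.na(from)) {
      get0(paste0(pattern$type, "|", from), envir = dm$by_type_from,
           inherits = FALSE)
    } else {
      get0(pattern$type, envir = dm$by_type, inherits = FALSE)
    }
    if (is.null(names_vec)) return(list())
    cand <- lapply(names_vec, dm_get, dm = dm)
  }
  keep <- vapply(cand, function(ch) {
    for (sl in names(tests)) {
      if (sl == "name") next
      v <- unname(ch$slots[sl])
      if (is.na(v) || v != tests[[sl]]) return(FALSE)
    }
    if (!is.null(pattern$negs)) {
      for (sl in names(pattern$negs)) {
        v <- unname(ch$slots[sl])
        if (!is.na(v) && v %in% pattern$negs[[sl]]) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  cand[keep]
}

#' Noisy declarative retrieval
#'
#' Among the chunks matching every constant slot of `pattern`, each candidate
#' receives a noisy activation `A + eps`, with `eps` drawn from a logistic
#' distribution with scale `ans` around the fixed base activation. The
#' highest-scoring candidate at or above the retrieval threshold is returned,
#' with a latency of `F * exp(-A')` (noisy activation `A'` clamped so the
#' latency stays positive and bounded). If no candidate clears the threshold
#' the retrieval fails after the latency implied by the threshold itself.
#'
#' Uses the current RNG stream, so results are reproducible under a fixed
#' seed.
#'
#' @param pattern A list with elements `type`, `tests` (named character
#'   vector of constant slot values) and optionally `negs` (named list of
#'   excluded values per slot).
#' @param dm Declarative memory store.
#' @param config An [engine_config()].
#' @return A list with `outcome` (`"success"` or `"failure"`), `chunk`
#'   (or `NULL`), `latency` in simulated seconds, and `activation`.
#' @export
retrieve_chunk <- function(pattern, dm, config) {
  cand <- dm_candidates(dm, pattern)
  thr <- config$retrieval_threshold
  cap <- config$retrieval_latency_cap
  fail_lat <- min(config$retrieval_latency_factor * exp(-thr), cap)
  if (!length(cand)) {
    return(list(outcome = "failure", chunk = NULL, latency = fail_lat,
                activation = -Inf))
  }
  act <- config$base_activation +
    stats::rlogis(length(cand), location = 0, scale = config$ans)
  best <- which.max(act)
  a <- act[best]
  if (a < thr) {
    return(list(outcome = "failure", chunk = NULL, latency = fail_lat,
                activation = a))
  }
  lat <- min(config$retrieval_latency_factor * exp(-a), cap)
  list(outcome = "success", chunk = cand[[best]], latency = lat,
       activation = a)
}
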