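## The five per-run outcome indicators and aggregation helpers.

#' Up-time ratio
#'
#' Fraction of the run time limit elapsed before the run terminated.
#'
#' @param record A `cm_run_record`.
#' @param run_limit Run limit in simulated seconds; defaults to the limit
#'   the run was executed with.
#' @return A value in \[0, 1\].
#' @export
up_time_ratio <- function(record, run_limit = record$run_limit) {
  record$termination_time / run_limit
}

#' Normalized state-visit entropy
#'
#' Shannon entropy of the visit distribution over the `n` states of the
#' environment, normalized by `log(n)` so the value lies in \[0, 1\]:
#' uniform visiting gives 1, visiting a single state gives 0. States with
#' zero visits contribute nothing; an empty histogram returns 0 by
#' convention.
#'
#' @param visit_histogram Named or unnamed vector of per-state visit counts.
#' @param n_states Total number of states in the environment (all corner
#'   points of the map).
#' @return Normalized entropy in \[0, 1\].
#' @export
normalized_entropy <- function(visit_histogram, n_states) {
  tot <- sum(visit_histogram)
  if (tot <= 0 || n_states < 2) return(0)
  p <- visit_histogram[visit_histogram > 0] / tot
  -sum(p * log(p)) / log(n_states)
}

#' Goal achievement rate
#'
#' Goal-reaching rounds divided by started rounds; 0 when no round started.
#'
#' @param record A `cm_run_record`.
#' @return A value in \[0, 1\].
#' @export
goal_rate <- function(record) {
  if (record$rounds_started == 0L) return(0)
  record$rounds_goal / record$rounds_started
}

#' The five outcome indicators of one run
#'
#' @param record A `cm_run_record`.
#' @return A one-row data frame: `up_time_ratio`, `n_rounds` (continue
#'   firings), `entropy` (normalized state-visit entropy), `goal_rate`,
#'   `n_new_productions` (unique compiled productions created), plus the
#'   run's identifying columns.
#' @export
indicators <- function(record) {
  data.frame(
    strategy = record$strategy,
    size = record$maze_size,
    reward = record$curiosity_reward,
    map_seed = record$maze_seed,
    rep_seed = record$seed,
    up_time_ratio = up_time_ratio(record),
    n_rounds = record$rounds_started,
    entropy = normalized_entropy(record$visit_histogram, record$n_states),
    goal_rate = goal_rate(record),
    n_new_productions = record$compiled_productions_created,
    termination_reason = record$termination_reason,
    stringsAsFactors = FALSE)
}

#' Aggregate an indicator table by condition cell
#'
#' Means over all runs of each (strategy, size, reward) cell, with the
#' spread computed as in the study design: the standard deviation over the
#' repetitions of each map, averaged across maps.
#'
#' @param tab An indicator table (rows from [indicators()], e.g. from
#'   [run_sweep()]).
#' @return A data frame with per-cell `n`, means (`mean_` prefix) and
#'   averaged per-map standard deviations (`sd_` prefix) of the five
#'   indicators.
#' @export
aggregate_indicators <- function(tab) {
  vars <- c("up_time_ratio", "n_rounds", "entropy", "goal_rate",
            "n_new_productions")
  key <- interaction(tab$strategy, tab$size, tab$reward, drop = TRUE)
  out <- lapply(split(tab, key), function(cell) {
    res <- data.frame(strategy = cell$strategy[1], size = cell$size[1],
                      reward = cell$reward[1], n = nrow(cell))
    for (v in vars) {
      res[[paste0("mean_", v)]] <- mean(cell[[v]])
      per_map <- tapply(cell[[v]], cell$map_seed, stats::sd)
      per_map[is.na(per_map)] <- 0
      res[[paste0("sd_", v)]] <- mean(per_map)
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$strategy, out$size, out$reward), ]
}

#' Trajectory summary for heat-map rendering
#'
#' Node visit frequencies and traversed segments of one run. Segments
#' produced by compiled productions may connect non-adjacent corner points
#' (chained automatized moves); these are tagged so a renderer can draw the
#' characteristic jumps.
#'
#' @param record A `cm_run_record` produced with `trace = TRUE`.
#' @param maze The maze of the run.
#' @return A list with `nodes` (data frame `node`, `row`, `col`, `visits`)
#'   and `segments` (data frame `from`, `to`, `count`, `production`,
#'   `adjacent`).
#' @export
render_trajectory <- function(record, maze) {
  if (is.null(record$events)) stop("record has no trace (trace = FALSE)")
  co <- t(vapply(maze$nodes, node_coords, integer(2)))
  nodes <- data.frame(node = maze$nodes,
                      row = co[, "row"], col = co[, "col"],
                      visits = as.integer(record$visit_histogram[maze$nodes]),
                      stringsAsFactors = FALSE)
  mv <- record$events[record$events$kind == "move", , drop = FALSE]
  segments <- data.frame(from = character(0), to = character(0),
                         count = integer(0), production = character(0),
                         adjacent = logical(0), stringsAsFactors = FALSE)
  if (nrow(mv)) {
    key <- paste(mv$a, mv$b, mv$production)
    agg <- mv[!duplicated(key), c("a", "b", "production")]
    agg$count <- as.integer(table(key)[paste(agg$a, agg$b, agg$production)])
    edge_set <- c(paste(maze$edges$from, maze$edges$to),
                  paste(maze$edges$to, maze$edges$from))
    agg$adjacent <- paste(agg$a, agg$b) %in% edge_set
    names(agg)[names(agg) == "a"] <- "from"
    names(agg)[names(agg) == "b"] <- "to"
    segments <- agg[, c("from", "to", "count", "production", "adjacent")]
    rownames(segments) <- NULL
  }
  list(nodes = nodes, segments = segments)
}
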