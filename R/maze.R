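## Loop-less (perfect) grid mazes: spanning trees of the n x n grid graph,
## carved with a seeded recursive backtracker. Coordinates are 0-based and
## row-major; node names are "n<row>_<col>". Directions follow the grid:
## north = row-1, south = row+1, west = col-1, east = col+1.

node_name <- function(r, c) paste0("n", r, "_", c)

node_coords <- function(nm) {
  m <- regmatches(nm, regexec("^n(\\d+)_(\\d+)$", nm))[[1]]
  if (length(m) != 3) stop("not a node name: ", nm)
  c(row = as.integer(m[2]), col = as.integer(m[3]))
}

DIRS <- list(west  = c(0L, -1L), north = c(-1L, 0L),
             east  = c(0L,  1L), south = c( 1L, 0L))

opposite_dir <- c(west = "east", north = "south",
                  east = "west", south = "north")

## evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a perfect maze on an n x n grid
#'
#' Carves a uniform-interface perfect maze (a spanning tree of the grid
#' graph, hence loop-less: exactly one path between any two corner points)
#' with a seeded recursive backtracker. The start is fixed at the top-left
#' corner `(0,0)`; the goal is the corner point at maximal hop distance from
#' the start (ties broken in row-major order).
#'
#' @param size Odd integer >= 3; grid side length (5, 7 and 9 in the study
#'   design).
#' @param seed Integer seed; fully determines the maze.
#' @return An object of class `cm_maze` with fields `size`, `seed`, `nodes`,
#'   `edges` (data frame `from`, `to`, `dir`, one row per undirected edge,
#'   direction given from `from`), `adj` (adjacency list of
#'   `list(to=, dir=)`), `start`, `goal`, `hops` (hop distance of every node
#'   from the start).
#' @export
maze_generate <- function(size, seed) {
  if (!is.numeric(size) || size < 3 || size %% 2 != 1)
    stop("size must be an odd integer >= 3")
  size <- as.integer(size)
  n <- size * size
  idx <- function(r, c) r * size + c + 1L
  visited <- logical(n)
  edges_from <- character(n - 1L); edges_to <- character(n - 1L)
  edges_dir <- character(n - 1L); ne <- 0L

  with_seed(seed, {
    stack_r <- integer(n); stack_c <- integer(n); top <- 1L
    stack_r[1] <- 0L; stack_c[1] <- 0L
    visited[idx(0L, 0L)] <- TRUE
    while (top > 0L) {
      r <- stack_r[top]; c <- stack_c[top]
      ## unvisited neighbours
      cand <- list()
      for (d in names(DIRS)) {
        rr <- r + DIRS[[d]][1]; cc <- c + DIRS[[d]][2]
        if (rr >= 0L && rr < size && cc >= 0L && cc < size &&
            !visited[idx(rr, cc)])
          cand[[length(cand) + 1L]] <- c(rr, cc, d)
      }
      if (!length(cand)) { top <- top - 1L; next }
      pick <- cand[[sample.int(length(cand), 1L)]]
      rr <- as.integer(pick[1]); cc <- as.integer(pick[2]); d <- pick[3]
      ne <- ne + 1L
      edges_from[ne] <- node_name(r, c)
      edges_to[ne] <- node_name(rr, cc)
      edges_dir[ne] <- d
      visited[idx(rr, cc)] <- TRUE
      top <- top + 1L
      stack_r[top] <- rr; stack_c[top] <- cc
    }
  })

  coords <- expand.grid(col = 0:(size - 1L), row = 0:(size - 1L))
  nodes <- node_name(coords$row, coords$col)       # row-major order
  edges <- data.frame(from = edges_from, to = edges_to, dir = edges_dir,
                      stringsAsFactors = FALSE)
  adj <- maze_adjacency(nodes, edges)
  hops <- bfs_hops(adj, node_name(0L, 0L))
  goal <- nodes[which.max(hops[nodes])]            # row-major tie-break
  structure(list(size = size, seed = seed, nodes = nodes, edges = edges,
                 adj = adj, start = node_name(0L, 0L), goal = goal,
                 hops = hops),
            class = "cm_maze")
}

maze_adjacency <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nm in nodes) adj[[nm]] <- list(to = character(0), dir = character(0))
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]; d <- edges$dir[k]
    adj[[f]]$to <- c(adj[[f]]$to, t); adj[[f]]$dir <- c(adj[[f]]$dir, d)
    adj[[t]]$to <- c(adj[[t]]$to, f)
    adj[[t]]$dir <- c(adj[[t]]$dir, opposite_dir[[d]])
  }
  adj
}

bfs_hops <- function(adj, from) {
  hops <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  hops[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character(0)
    for (nm in frontier) {
      for (t in adj[[nm]]$to)
        if (is.na(hops[t])) { hops[t] <- d; nxt <- c(nxt, t) }
    }
    frontier <- nxt
  }
  hops
}

#' Hop distance between two corner points
#'
#' Shortest-path edge count on the maze graph (unique path on a tree).
#'
#' @param maze A [maze_generate()] object.
#' @param a,b Node names.
#' @return Integer hop count.
#' @export
maze_hop_distance <- function(maze, a, b) {
  stopifnot(a %in% maze$nodes, b %in% maze$nodes)
  h <- bfs_hops(maze$adj, a)
  if (is.na(h[b])) stop("nodes are not connected")
  unname(h[b])
}

#' Encode a maze as declarative chunks
#'
#' One `node` chunk per corner point and, per undirected edge, one `path`
#' chunk for each traversal direction, so path knowledge is retrievable from
#' either endpoint with its outbound direction.
#'
#' @param maze A [maze_generate()] object.
#' @return A list of class `cm_topo_chunks` with elements `nodes` and
#'   `paths` (lists of [chunk()]s).
#' @export
maze_to_chunks <- function(maze) {
  nodes <- lapply(maze$nodes, function(nm)
    chunk(paste0("node-", nm), "node", id = nm))
  paths <- vector("list", 2L * nrow(maze$edges))
  k <- 0L
  for (i in seq_len(nrow(maze$edges))) {
    f <- maze$edges$from[i]; t <- maze$edges$to[i]; d <- maze$edges$dir[i]
    k <- k + 1L
    paths[[k]] <- chunk(paste0("path-", f, "-", t), "path",
                        from = f, to = t, dir = d)
    k <- k + 1L
    paths[[k]] <- chunk(paste0("path-", t, "-", f), "path",
                        from = t, to = f, dir = opposite_dir[[d]])
  }
  structure(list(nodes = nodes, paths = paths), class = "cm_topo_chunks")
}

#' Recover the undirected edge list from topological chunks
#'
#' Round-trip companion of [maze_to_chunks()].
#'
#' @param topo A `cm_topo_chunks` object.
#' @return Data frame with columns `from`, `to` (lexicographically ordered
#'   within a row), one row per undirected edge.
#' @export
chunks_to_edges <- function(topo) {
  fr <- vapply(topo$paths, function(ch) ch$slots[["from"]], character(1))
  to <- vapply(topo$paths, function(ch) ch$slots[["to"]], character(1))
  a <- pmin(fr, to); b <- pmax(fr, to)
  unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
}

#' Generate the full study map suite
#'
#' Ten distinct mazes per size, reproducible from one master seed;
#' duplicate edge sets (possible at small sizes) are re-drawn.
#'
#' @param master_seed Integer master seed.
#' @param sizes Grid sizes.
#' @param n_per_size Maps per size.
#' @return A list of `cm_maze` objects with attributes `size` and
#'   `map_index` recorded in each element's position.
#' @export
maze_suite <- function(master_seed, sizes = c(5, 7, 9), n_per_size = 10) {
  out <- list()
  for (s in sizes) {
    seen <- character(0)
    for (i in seq_len(n_per_size)) {
      bump <- 0L
      repeat {
        sd <- mix_seed(master_seed, s, i, bump)
        mz <- maze_generate(s, sd)
        sig <- paste(mz$edges$from, mz$edges$to, collapse = ";")
        if (!sig %in% seen) break
        bump <- bump + 1L
      }
      seen <- c(seen, sig)
      out[[length(out) + 1L]] <- mz
    }
  }
  out
}

## deterministic integer mixing for derived seeds; stays below 2^31
mix_seed <- function(...) {
  xs <- unlist(list(...))
  h <- 17
  for (x in xs) {
    x <- if (is.character(x)) utf8_hash(x) else as.integer(x)
    h <- (h * 69069 + x + 1) %% 2147483629   # stays within exact double range
  }
  as.integer(h)
}

#' @export
print.cm_maze <- function(x, ...) {
  cat(sprintf("<maze %dx%d seed=%d start=%s goal=%s (hops %d)>\n",
              x$size, x$size, x$seed, x$start, x$goal,
              x$hops[[x$goal]]))
  invisible(x)
}

#' Serialize / restore a maze as JSON
#'
#' @param maze A `cm_maze` object.
#' @param path File path; for `maze_to_json` with `path = NULL` the JSON
#'   string is returned.
#' @return `maze_from_json` returns a `cm_maze`.
#' @export
maze_to_json <- function(maze, path = NULL) {
  x <- list(size = maze$size, seed = maze$seed,
            edges = maze$edges[c("from", "to", "dir")],
            start = maze$start, goal = maze$goal)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname maze_to_json
#' @export
maze_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  size <- as.integer(x$size)
  coords <- expand.grid(col = 0:(size - 1L), row = 0:(size - 1L))
  nodes <- node_name(coords$row, coords$col)
  edges <- as.data.frame(x$edges, stringsAsFactors = FALSE)
  adj <- maze_adjacency(nodes, edges)
  structure(list(size = size, seed = as.integer(x$seed), nodes = nodes,
                 edges = edges, adj = adj, start = x$start, goal = x$goal,
                 hops = bfs_hops(adj, x$start)),
            class = "cm_maze")
}

#' ASCII rendering of a maze
#'
#' Corner points are `.` (start `S`, goal `G`); carved passages are drawn,
#' walls left blank.
#'
#' @param maze A `cm_maze` object.
#' @return A character vector of lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print Print to the console?
#' @export
maze_ascii <- function(maze, print = TRUE) {
  n <- maze$size
  H <- matrix(" ", nrow = 2L * n - 1L, ncol = 2L * n - 1L)
  for (r in 0:(n - 1L)) for (c in 0:(n - 1L)) H[2 * r + 1, 2 * c + 1] <- "."
  for (k in seq_len(nrow(maze$edges))) {
    a <- node_coords(maze$edges$from[k]); b <- node_coords(maze$edges$to[k])
    H[a["row"] + b["row"] + 1L, a["col"] + b["col"] + 1L] <-
      if (a["row"] == b["row"]) "-" else "|"
  }
  sc <- node_coords(maze$start); gc <- node_coords(maze$goal)
  H[2 * sc["row"] + 1, 2 * sc["col"] + 1] <- "S"
  H[2 * gc["row"] + 1, 2 * gc["col"] + 1] <- "G"
  lines <- apply(H, 1, paste, collapse = "")
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
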