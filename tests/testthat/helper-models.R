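## shared fixtures: tiny mazes and quiet run settings

tiny_maze <- function(seed = 11) maze_generate(3, seed)

## motivation settings that keep a run in one long round: the stop
## production can never win and no time limit interferes
eager_motivation <- function(curiosity = 10, run_limit = Inf) {
  motivation_config(curiosity_reward = curiosity, u0_stop = -1e9,
                    round_limit = Inf, run_limit = run_limit)
}

quick_run <- function(strategy, maze, curiosity = 10, seed = 1, ...) {
  run_task(build_agent(strategy, maze), maze,
           motivation = motivation_config(curiosity_reward = curiosity),
           seed = seed, ...)
}

## host-language oracle: edge list -> igraph
maze_igraph <- function(maze) {
  igraph::graph_from_data_frame(maze$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = maze$nodes))
}
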