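## Curiosity-driven reinforcement-learning baseline: the maze as a 42x42
## grayscale raster, a learned feature encoder, a forward model whose
## prediction error is the intrinsic reward, and a one-step advantage
## actor-critic policy. The networks are deliberately small multilayer
## perceptrons implemented directly in matrix algebra (forward and backward
## passes are a dozen lines each), sized to train on one CPU core.

#' ICM baseline configuration
#'
#' @param eta Intrinsic-reward weight; the study grid spans 0.1 to 0.9 in
#'   five equal steps ([icm_eta_grid()]).
#' @param th Termination threshold on the scaled intrinsic reward.
#' @param egs_noise Scale of the logistic noise added in the termination
#'   comparison.
#' @param round_step_limit,run_step_limit Step limits per round and per run
#'   (156 and 3130, the step equivalents of the 180 s / 3600 s limits at
#'   1.15 s per step).
#' @param step_time_equiv Simulated seconds one step is worth when an ICM
#'   run is converted into the common run-record schema.
#' @param printed_termination If `TRUE`, use the termination inequality
#'   exactly as printed (terminate when `th < r_i * 500 + noise`, i.e. when
#'   curiosity is *high*); the default follows the prose (terminate when the
#'   scaled intrinsic reward falls below the threshold).
#' @param n_features Feature dimension of the encoder.
#' @param n_hidden Hidden width of all three heads.
#' @param lr Learning rate of the plain SGD updates.
#' @param gamma Discount factor of the actor-critic.
#' @param beta_forward Weight of the forward-model loss against the
#'   actor-critic loss.
#' @return A list of class `cm_icm_config`.
#' @export
icm_config <- function(eta = 0.5, th = 5, egs_noise = 0.5,
                       round_step_limit = 156, run_step_limit = 3130,
                       step_time_equiv = 1.15,
                       printed_termination = FALSE,
                       n_features = 16, n_hidden = 32,
                       lr = 1e-3, gamma = 0.95, beta_forward = 0.5) {
  stopifnot(eta > 0, eta < 1, th > 0, round_step_limit > 0,
            run_step_limit > 0)
  structure(list(eta = eta, th = th, egs_noise = egs_noise,
                 round_step_limit = as.integer(round_step_limit),
                 run_step_limit = as.integer(run_step_limit),
                 step_time_equiv = step_time_equiv,
                 printed_termination = printed_termination,
                 n_features = as.integer(n_features),
                 n_hidden = as.integer(n_hidden),
                 lr = lr, gamma = gamma, beta_forward = beta_forward),
            class = "cm_icm_config")
}

#' The five intrinsic-reward intensities of the baseline design
#'
#' @return `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @export
icm_eta_grid <- function() seq(0.1, 0.9, by = 0.2)

#' Render a maze state as a 42 x 42 grayscale image
#'
#' Walls are black (0), carved passages and corner points white (1), and
#' the player mid-gray (0.5). The underlying `(2n-1) x (2n-1)` cell grid is
#' upsampled to the fixed 42 x 42 raster by nearest neighbour, so the
#' raster size is independent of the maze size. Rendering is deterministic
#' in the state.
#'
#' @param maze A [maze_generate()] object.
#' @param player Node name of the player's position.
#' @return A 42 x 42 numeric matrix with values in \[0, 1\].
#' @export
icm_render <- function(maze, player) {
  n <- maze$size
  H <- matrix(0, 2L * n - 1L, 2L * n - 1L)          # walls
  for (r in 0:(n - 1L)) for (c in 0:(n - 1L)) H[2 * r + 1, 2 * c + 1] <- 1
  for (k in seq_len(nrow(maze$edges))) {
    a <- node_coords(maze$edges$from[k]); b <- node_coords(maze$edges$to[k])
    H[a[["row"]] + b[["row"]] + 1L, a[["col"]] + b[["col"]] + 1L] <- 1
  }
  pc <- node_coords(player)
  H[2 * pc[["row"]] + 1L, 2 * pc[["col"]] + 1L] <- 0.5
  i <- ceiling(seq_len(42L) * nrow(H) / 42L)        # nearest-neighbour scale
  H[i, i, drop = FALSE]
}

#' Forward-model intrinsic reward
#'
#' `r_i = (eta / 2) * || phihat - phi ||^2`: half the squared Euclidean
#' distance between the predicted and the actual feature encoding of the
#' next state, weighted by the curiosity intensity. Non-negative; zero
#' exactly at perfect prediction.
#'
#' @param phihat Predicted feature vector of the next state.
#' @param phi Actual feature vector of the next state.
#' @param eta Curiosity intensity.
#' @return A non-negative scalar.
#' @export
icm_intrinsic_reward <- function(phihat, phi, eta) {
  if (length(phihat) != length(phi))
    stop("feature dimension mismatch: ", length(phihat), " vs ", length(phi))
  d <- phihat - phi
  (eta / 2) * sum(d * d)
}

#' External reward of one move attempt
#'
#' -1 for a blocked move (chosen direction has no passage), 0 for an
#' ordinary move, +10 on reaching the goal (which also ends the round).
#'
#' @param outcome One of `"blocked"`, `"moved"`, `"goal"`.
#' @return The scalar external reward.
#' @export
icm_external_reward <- function(outcome) {
  switch(outcome, blocked = -1, moved = 0, goal = 10,
         stop("unknown outcome: ", outcome))
}

#' Termination test of the baseline
#'
#' Following the prose semantics, the run terminates when the scaled
#' intrinsic reward (plus logistic selection noise) falls below the
#' threshold: `r_i * 500 + noise < th`. The printed inequality (terminate
#' when `th < r_i * 500 + noise`) is available behind
#' `printed_termination`; the noise draw comes from the current RNG stream
#' either way.
#'
#' @param r_i Current intrinsic reward.
#' @param config An [icm_config()].
#' @return `TRUE` when the run should terminate.
#' @export
icm_should_terminate <- function(r_i, config) {
  noise <- stats::rlogis(1, 0, config$egs_noise)
  if (config$printed_termination) config$th < r_i * 500 + noise
  else r_i * 500 + noise < config$th
}

## ---- tiny MLP machinery -------------------------------------------------

mlp_new <- function(n_in, n_hidden, n_out, scale = 0.1) {
  list(W1 = matrix(stats::rnorm(n_in * n_hidden, 0, scale), n_in, n_hidden),
       b1 = numeric(n_hidden),
       W2 = matrix(stats::rnorm(n_hidden * n_out, 0, scale), n_hidden, n_out),
       b2 = numeric(n_out))
}

mlp_forward <- function(m, x) {
  h_lin <- drop(x %*% m$W1) + m$b1
  h <- pmax(h_lin, 0)
  list(x = x, h = h, out = drop(h %*% m$W2) + m$b2)
}

## gradient step given dL/dout; returns dL/dx for chaining
mlp_backward <- function(m, fw, dout, lr) {
  dW2 <- outer(fw$h, dout)
  dh <- drop(m$W2 %*% dout) * (fw$h > 0)
  dW1 <- outer(drop(fw$x), dh)
  dx <- drop(m$W1 %*% dh)
  m$W1 <- m$W1 - lr * dW1
  m$b1 <- m$b1 - lr * dh
  m$W2 <- m$W2 - lr * dW2
  m$b2 <- m$b2 - lr * dout
  list(model = m, dx = dx)
}

softmax <- function(z) { z <- z - max(z); e <- exp(z); e / sum(e) }

#' Run one curiosity-driven reinforcement-learning session
#'
#' An advantage actor-critic agent explores the maze from the start node,
#' one of four direction actions per step, maximizing `r = r_i + r_e`: the
#' forward model predicts the feature encoding of the next rendered state,
#' its prediction error (weighted by `eta`) is the intrinsic reward, and
#' the external reward follows [icm_external_reward()]. Reaching the goal
#' ends the round and resets the player; the run ends when the termination
#' test fires, or at the step limits. The result is expressed in the same
#' run-record schema as the production-system agents (steps converted to
#' simulated seconds), so all indicator computations apply unchanged.
#'
#' @param maze A [maze_generate()] object.
#' @param config An [icm_config()].
#' @param seed Integer seed for all stochastic draws.
#' @param trace Keep per-step events in the record?
#' @return A `cm_run_record`.
#' @export
icm_run <- function(maze, config = icm_config(), seed = 1, trace = FALSE) {
  with_seed(seed, icm_run_impl(maze, config, seed, trace))
}

icm_run_impl <- function(maze, config, seed, trace) {
  n_px <- 42L * 42L
  enc <- mlp_new(n_px, config$n_hidden, config$n_features)
  fwd <- mlp_new(config$n_features + 4L, config$n_hidden, config$n_features)
  pol <- mlp_new(config$n_features, config$n_hidden, 5L)  # 4 logits + value
  dirs <- c("west", "north", "east", "south")

  visits <- stats::setNames(integer(length(maze$nodes)), maze$nodes)
  pos <- maze$start
  visits[pos] <- 1L
  rounds <- 1L; rounds_goal <- 0L
  round_steps <- 0L; max_round_steps <- 0L
  reason <- "run_limit"
  steps <- 0L
  ev <- if (trace) list() else NULL
  img <- as.vector(icm_render(maze, pos))

  while (steps < config$run_step_limit) {
    steps <- steps + 1L
    round_steps <- round_steps + 1L
    if (round_steps > max_round_steps) max_round_steps <- round_steps
    enc_t <- mlp_forward(enc, img)
    phi_t <- enc_t$out
    pv <- mlp_forward(pol, phi_t)
    logits <- pv$out[1:4]; value <- pv$out[5]
    probs <- softmax(logits)
    act <- findInterval(stats::runif(1), cumsum(probs)) + 1L
    if (act > 4L) act <- 4L

    adj <- maze$adj[[pos]]
    hit <- match(dirs[act], adj$dir)
    if (is.na(hit)) {
      outcome <- "blocked"; new_pos <- pos
    } else {
      new_pos <- adj$to[hit]
      outcome <- if (new_pos == maze$goal) "goal" else "moved"
    }
    r_e <- icm_external_reward(outcome)

    img_next <- as.vector(icm_render(maze, new_pos))
    enc_n <- mlp_forward(enc, img_next)
    phi_next <- enc_n$out
    a_onehot <- numeric(4L); a_onehot[act] <- 1
    fw <- mlp_forward(fwd, c(phi_t, a_onehot))
    r_i <- icm_intrinsic_reward(fw$out, phi_next, config$eta)
    r <- r_i + r_e

    ## forward-model loss (1/2)||phihat - phi(s')||^2 trains the forward
    ## model and, through phi(s'), the encoder
    diff <- fw$out - phi_next
    bf <- config$beta_forward
    upd <- mlp_backward(fwd, fw, bf * diff, config$lr)
    fwd <- upd$model
    enc <- mlp_backward(enc, enc_n, -bf * diff, config$lr)$model

    ## one-step advantage actor-critic on the (detached) features
    v_next <- if (outcome == "goal") 0 else
      mlp_forward(pol, phi_next)$out[5]
    adv <- r + config$gamma * v_next - value
    dlogits <- probs
    dlogits[act] <- dlogits[act] - 1       # -d log pi(a) / d logits
    dout <- c(adv * dlogits, -adv)         # policy gradient + value MSE
    pol <- mlp_backward(pol, pv, dout, config$lr)$model
    if (!all(is.finite(pol$W2)) || !is.finite(r_i)) {
      reason <- "diverged"
      break
    }

    if (trace)
      ev[[length(ev) + 1L]] <- data.frame(
        time = steps * config$step_time_equiv, kind = "step",
        production = dirs[act], a = pos, b = new_pos, value = r_i,
        stringsAsFactors = FALSE)

    pos <- new_pos
    img <- img_next
    if (outcome != "blocked") visits[pos] <- visits[pos] + 1L
    if (outcome == "goal") {
      rounds_goal <- rounds_goal + 1L
      pos <- maze$start
      img <- as.vector(icm_render(maze, pos))
      visits[pos] <- visits[pos] + 1L
      round_steps <- 0L
      if (steps < config$run_step_limit) rounds <- rounds + 1L
    } else if (round_steps >= config$round_step_limit) {
      pos <- maze$start
      img <- as.vector(icm_render(maze, pos))
      visits[pos] <- visits[pos] + 1L
      round_steps <- 0L
      if (steps < config$run_step_limit) rounds <- rounds + 1L
    }
    if (icm_should_terminate(r_i, config)) { reason <- "stopped"; break }
  }

  run_limit_s <- config$run_step_limit * config$step_time_equiv
  structure(list(
    events = if (trace) do.call(rbind, ev) else NULL,
    max_round_steps = max_round_steps,
    visit_histogram = visits,
    moves = steps,
    rounds_started = rounds,
    rounds_goal = rounds_goal,
    rounds_completed = rounds_goal,
    compiled_productions_created = 0L,
    termination_time = min(steps * config$step_time_equiv, run_limit_s),
    termination_reason = reason,
    run_limit = run_limit_s,
    n_states = length(maze$nodes),
    strategy = "icm",
    maze_size = maze$size, maze_seed = maze$seed,
    curiosity_reward = config$eta,
    seed = seed,
    final_utilities = numeric(0)),
    class = "cm_run_record")
}
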