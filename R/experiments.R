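## Factorial simulation driver: (strategies + baseline) x map sizes x maps
## x reward intensities x repetitions, with per-cell seeds derived
## deterministically from the master seed so any single run can be
## reconstructed from its table row alone.

#' Sweep configuration
#'
#' The full study design is 3 strategies x 3 sizes x 10 maps x 5 rewards x
#' 10 repetitions (4500 production-system runs) plus the baseline at 100
#' repetitions; `smoke = TRUE` reduces this to a desk-scale factorial
#' (2 sizes, 3 maps, rewards at the grid endpoints, 5 repetitions) that
#' preserves every compared contrast.
#'
#' @param strategies Agent strategies to run (any of `"random"`, `"dfs"`,
#'   `"dfs_ibl"`, `"icm"`).
#' @param sizes Map sizes.
#' @param n_maps Maps per size.
#' @param rewards Curiosity-reward grid for the production-system agents.
#' @param etas Intrinsic-reward grid for the baseline.
#' @param reps,icm_reps Repetitions per cell.
#' @param master_seed Master seed; every run seed is a deterministic hash
#'   of (master seed, strategy, size, map index, reward, repetition).
#' @param engine,motivation Shared configuration blocks.
#' @param icm Baseline configuration block (`eta` is overridden per cell).
#' @param smoke Reduced factorial?
#' @param out_dir Optional directory: per-cell CSV fragments are written
#'   there and cells whose fragment already exists are skipped (resume).
#' @return A list of class `cm_sweep_config`.
#' @export
sweep_config <- function(strategies = c("random", "dfs", "dfs_ibl"),
                         sizes = c(5, 7, 9), n_maps = 10,
                         rewards = curiosity_reward_grid(),
                         etas = icm_eta_grid(),
                         reps = 10, icm_reps = 100,
                         master_seed = 1,
                         engine = engine_config(),
                         motivation = motivation_config(),
                         icm = icm_config(),
                         smoke = FALSE,
                         out_dir = NULL) {
  if (smoke) {
    sizes <- c(5, 9); n_maps <- 3
    rewards <- range(rewards); etas <- range(etas)
    reps <- 5; icm_reps <- 10
  }
  structure(list(strategies = strategies, sizes = sizes, n_maps = n_maps,
                 rewards = rewards, etas = etas, reps = reps,
                 icm_reps = icm_reps, master_seed = master_seed,
                 engine = engine, motivation = motivation, icm = icm,
                 out_dir = out_dir),
            class = "cm_sweep_config")
}

#' Execute one cell repetition
#'
#' Reconstructs and runs the single simulation identified by the cell
#' coordinates, exactly as [run_sweep()] would.
#'
#' @param config A [sweep_config()].
#' @param strategy,size,map_index,reward,rep Cell coordinates (for
#'   `strategy = "icm"`, `reward` is the `eta` value).
#' @return A `cm_run_record`.
#' @export
run_cell <- function(config, strategy, size, map_index, reward, rep) {
  map_seed <- mix_seed(config$master_seed, size, map_index, 0L)
  mz <- maze_generate(size, map_seed)
  run_seed <- mix_seed(config$master_seed, strategy, size, map_index,
                       round(reward * 10), rep)
  if (strategy == "icm") {
    icfg <- config$icm
    icfg$eta <- reward
    icm_run(mz, icfg, seed = run_seed)
  } else {
    mcfg <- config$motivation
    mcfg$curiosity_reward <- reward
    ag <- build_agent(strategy, mz)
    run_task(ag, mz, config$engine, mcfg, seed = run_seed, trace = FALSE)
  }
}

#' Run the factorial sweep
#'
#' One run per (strategy, size, map, reward, repetition) cell; indicator
#' rows are collected into one table (and, when `out_dir` is set, written
#' as per-cell CSV fragments that allow interrupted sweeps to resume).
#' Failures of individual runs are recorded as `termination_reason =
#' "error"` rows and the sweep continues.
#'
#' @param config A [sweep_config()].
#' @param progress Print one line per completed cell?
#' @return The indicator table (see [indicators()] for columns).
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "cm_sweep_config"))
  out <- list()
  for (strategy in config$strategies) {
    grid <- if (strategy == "icm") config$etas else config$rewards
    nrep <- if (strategy == "icm") config$icm_reps else config$reps
    for (size in config$sizes) for (map_index in seq_len(config$n_maps))
      for (reward in grid) {
        cell_id <- sprintf("cell_%d_%s_%d_m%d_r%s", config$master_seed,
                           strategy, size, map_index,
                           gsub("[.]", "p", format(reward)))
        cell_path <- if (!is.null(config$out_dir))
          file.path(config$out_dir, paste0(cell_id, ".csv"))
        if (!is.null(cell_path) && file.exists(cell_path)) {
          out[[cell_id]] <- utils::read.csv(cell_path,
                                            stringsAsFactors = FALSE)
          next
        }
        rows <- lapply(seq_len(nrep), function(rep) {
          tryCatch(indicators(run_cell(config, strategy, size, map_index,
                                       reward, rep)),
                   error = function(e) data.frame(
                     strategy = strategy, size = size, reward = reward,
                     map_seed = mix_seed(config$master_seed, size,
                                         map_index, 0L),
                     rep_seed = NA_integer_, up_time_ratio = NA_real_,
                     n_rounds = NA_integer_, entropy = NA_real_,
                     goal_rate = NA_real_, n_new_productions = NA_integer_,
                     termination_reason = "error",
                     stringsAsFactors = FALSE))
        })
        cell <- do.call(rbind, rows)
        cell$map_index <- map_index
        if (!is.null(cell_path)) {
          dir.create(dirname(cell_path), showWarnings = FALSE,
                     recursive = TRUE)
          utils::write.csv(cell, cell_path, row.names = FALSE)
        }
        if (progress)
          message(sprintf("%s done (%d runs)", cell_id, nrow(cell)))
        out[[cell_id]] <- cell
      }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## per-map means for one (strategy, size, reward) cell
per_map_means <- function(tab, strategy, size, reward, var) {
  sel <- tab$strategy == strategy & tab$size == size & tab$reward == reward
  tapply(tab[[var]][sel], tab$map_index[sel], mean)
}

#' Directional findings report
#'
#' Evaluates the study's directional claims on an indicator table by
#' comparing per-map means between condition cells; a claim passes when the
#' stated direction holds for at least the given fraction of maps (weak
#' inequality on ties).
#'
#' * `uptime_reward`: mean up-time ratio at the highest reward exceeds the
#'   lowest, per strategy.
#' * `uptime_size`: up-time ratio larger on the largest than the smallest
#'   map size at the highest reward, per strategy.
#' * `rounds_size`: rounds larger on the smallest than the largest size
#'   (random and dfs_ibl, highest reward).
#' * `goal_random_down` / `goal_ibl_up`: goal rate non-increasing (random)
#'   and non-decreasing (dfs_ibl) from the lowest to the highest reward.
#'
#' @param tab Indicator table from [run_sweep()] (needs a `map_index`
#'   column).
#' @param min_frac Minimum fraction of maps that must agree in sign.
#' @return Data frame with one row per claim: `claim`, `strategy`,
#'   `frac_maps` agreeing, `mean_low`, `mean_high`, `pass`.
#' @export
trend_report <- function(tab, min_frac = 2 / 3) {
  stopifnot("map_index" %in% names(tab))
  strategies <- setdiff(unique(tab$strategy), "icm")
  sizes <- sort(unique(tab$size))
  s_lo <- sizes[1]; s_hi <- sizes[length(sizes)]
  rewards <- sort(unique(tab$reward[tab$strategy %in% strategies]))
  r_lo <- rewards[1]; r_hi <- rewards[length(rewards)]
  rows <- list()
  ## sign test over per-map means: a "higher" claim needs a strict majority
  ## of maps in the stated direction; the monotone goal-rate claims accept
  ## ties (non-increasing / non-decreasing)
  add <- function(claim, strategy, lo, hi) {
    frac <- mean(hi > lo)
    rows[[length(rows) + 1L]] <<- data.frame(
      claim = claim, strategy = strategy, frac_maps = frac,
      mean_low = mean(lo), mean_high = mean(hi),
      pass = frac >= min_frac,
      stringsAsFactors = FALSE)
  }
  add_weak <- function(claim, strategy, lo, hi) {
    frac <- mean(hi >= lo)
    rows[[length(rows) + 1L]] <<- data.frame(
      claim = claim, strategy = strategy, frac_maps = frac,
      mean_low = mean(lo), mean_high = mean(hi),
      pass = frac >= min_frac,
      stringsAsFactors = FALSE)
  }
  for (sg in strategies) {
    for (sz in sizes)
      add(paste0("uptime_reward_", sz), sg,
          per_map_means(tab, sg, sz, r_lo, "up_time_ratio"),
          per_map_means(tab, sg, sz, r_hi, "up_time_ratio"))
    add("uptime_size", sg,
        per_map_means(tab, sg, s_lo, r_hi, "up_time_ratio"),
        per_map_means(tab, sg, s_hi, r_hi, "up_time_ratio"))
  }
  for (sg in intersect(c("random", "dfs_ibl"), strategies))
    add("rounds_size", sg,
        per_map_means(tab, sg, s_hi, r_hi, "n_rounds"),
        per_map_means(tab, sg, s_lo, r_hi, "n_rounds"))
  if ("random" %in% strategies)
    add_weak("goal_random_down", "random",
             per_map_means(tab, "random", s_lo, r_hi, "goal_rate"),
             per_map_means(tab, "random", s_lo, r_lo, "goal_rate"))
  if ("dfs_ibl" %in% strategies)
    add_weak("goal_ibl_up", "dfs_ibl",
             per_map_means(tab, "dfs_ibl", s_lo, r_lo, "goal_rate"),
             per_map_means(tab, "dfs_ibl", s_lo, r_hi, "goal_rate"))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
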