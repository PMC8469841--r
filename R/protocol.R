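#' Desk-scale reference experiment
#'
#' A reduced end-to-end protocol sized so that training, held-out
#' localization and the dueling-vs-plain comparison run in minutes on one
#' CPU: 16-voxel patches with three past frames on the default 64^3
#' phantoms, 150 episodes of at most 200 moves, replay capacity 2e4, batch
#' 32, epsilon annealed over 4000 steps, ADAM at 3e-4, target sync every
#' 500 steps, a gradient step every 4th move (the classic DQN cadence),
#' the bounded plain-distance reward, and training step sizes
#' `c(3, 3, 3, 1)` so one episode in four runs at the fine step size the
#' localization procedure later uses. The vignette explains each of these
#' desk-scale choices. The phantom suite keeps the 24 train / 8 test
#' layout of the full-scale study (32 volumes, 75% training).
#'
#' @param seed Root seed; drives phantom generation, initialization and
#'   training.
#' @param head_mode `"dueling"` or `"plain"`.
#' @param episodes Number of episodes (default 150).
#' @return A list with `spec` ([obs_spec]), `train` ([train_config]),
#'   `loc` ([loc_config]), `phantom` ([phantom_config]) and `n_phantoms`.
#' @export
desk_protocol <- function(seed = 1L, head_mode = c("dueling", "plain"),
                          episodes = 150L) {
  head_mode <- match.arg(head_mode)
  list(spec = obs_spec(N = 16L, H = 3L),
       train = train_config(episodes = episodes, max_episode_steps = 200L,
                            capacity = 2e4, batch_size = 32L,
                            eps_decay_steps = 4000, learning_rate = 3e-4,
                            target_sync_every = 500L, update_every = 4L,
                            reward_metric = "plain", rho = c(3L, 3L, 3L, 1L),
                            head_mode = head_mode, seed = seed),
       loc = loc_config(seed = seed),
       phantom = phantom_config(),
       n_phantoms = 32L)
}

#' Run the desk-scale experiment end to end
#'
#' Generates the phantom suite, trains an agent on the training split, and
#' localizes the landmark on every held-out phantom from the volume-center
#' start. Reports the per-episode log, the held-out errors, and the
#' first/last-quartile means of the 30-episode moving-average reward (the
#' learning-progress summary).
#'
#' @inheritParams desk_protocol
#' @param verbose Report training progress?
#' @return A list with `run` (the `"train_run"`), `errors_vox`,
#'   `errors_mm`, `median_error_vox`, `reward_ma_first_quartile`,
#'   `reward_ma_last_quartile`, and `protocol`.
#' @export
run_desk_experiment <- function(seed = 1L, head_mode = c("dueling", "plain"),
                                episodes = 150L, verbose = FALSE) {
  proto <- desk_protocol(seed = seed, head_mode = head_mode,
                         episodes = episodes)
  suite <- generate_suite(proto$n_phantoms,
                          base_seed = derive_seed(seed, "suite") %% 100000L,
                          cfg = proto$phantom)
  train_idx <- which(suite$manifest$split == "train")
  test_idx <- which(suite$manifest$split == "test")
  run <- run_training(suite$volumes[train_idx], suite$landmarks[train_idx],
                      proto$train, proto$spec, verbose = verbose)
  errors_vox <- numeric(length(test_idx))
  errors_mm <- numeric(length(test_idx))
  for (i in seq_along(test_idx)) {
    ti <- test_idx[i]
    res <- localize(suite$volumes[[ti]], run$params, proto$loc, proto$spec,
                    gt = suite$landmarks[[ti]])
    errors_vox[i] <- res$error_vox
    errors_mm[i] <- res$error_mm
  }
  ma <- moving_average(run$log$total_reward, 30L)
  q <- max(1L, floor(length(ma) / 4))
  list(run = run, errors_vox = errors_vox, errors_mm = errors_mm,
       median_error_vox = median(errors_vox),
       reward_ma_first_quartile = mean(ma[seq_len(q)]),
       reward_ma_last_quartile = mean(ma[seq.int(length(ma) - q + 1L, length(ma))]),
       protocol = proto)
}
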