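#' Training configuration
#'
#' Hyperparameters of the experience-replay DQN training loop. Defaults
#' follow the full-scale study protocol: discount `gamma = 0.9`,
#' epsilon-greedy exploration annealed linearly from 0.9 to 0.1, batch size
#' 48, replay capacity `1.5e5`, step size `rho = 3` voxels, and at most 1500
#' moves per episode. Quantities the protocol leaves open take documented
#' package defaults: linear epsilon decay over `5e4` environment steps,
#' ADAM with learning rate `1e-4`, target-network sync every 2500 steps,
#' warm-up of `max(batch_size, 1000)` stored transitions with one gradient
#' step per environment step thereafter, and gradient-norm clipping at 10.
#'
#' @param episodes Number of training episodes.
#' @param gamma Discount factor in `[0, 1]`.
#' @param eps_start,eps_end,eps_decay_steps Linear epsilon schedule (see
#'   [epsilon_at()]).
#' @param batch_size Replay minibatch size.
#' @param learning_rate ADAM learning rate.
#' @param target_sync_every Environment steps between target-network syncs.
#' @param max_episode_steps Per-episode move cap.
#' @param rho Training step size in voxels; a vector means one value is
#'   drawn uniformly per episode, so the policy sees every step size it
#'   will be rolled out with (e.g. `c(3, 3, 3, 1)` mixes coarse and fine).
#' @param capacity Replay memory capacity.
#' @param warmup Stored transitions required before gradient steps begin.
#' @param update_every Environment steps per gradient step (1 = a gradient
#'   step after every move; 4 is the classic DQN cadence).
#' @param reach_tol Termination radius in voxels.
#' @param reward_metric `"squared"` or `"plain"` (see [compute_reward()]).
#' @param head_mode `"dueling"` or `"plain"`.
#' @param grad_clip Global gradient-norm clip (`Inf` to disable).
#' @param seed Root seed for all randomness of the run.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(episodes = 1000L, gamma = 0.9, eps_start = 0.9,
                         eps_end = 0.1, eps_decay_steps = 5e4,
                         batch_size = 48L, learning_rate = 1e-4,
                         target_sync_every = 2500L, max_episode_steps = 1500L,
                         rho = 3L, capacity = 1.5e5,
                         warmup = max(batch_size, 1000L), update_every = 1L,
                         reach_tol = 3,
                         reward_metric = c("squared", "plain"),
                         head_mode = c("dueling", "plain"), grad_clip = 10,
                         seed = 1L) {
  reward_metric <- match.arg(reward_metric)
  head_mode <- match.arg(head_mode)
  cfg <- list(episodes = as.integer(episodes), gamma = gamma,
              eps_start = eps_start, eps_end = eps_end,
              eps_decay_steps = as.numeric(eps_decay_steps),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              target_sync_every = as.integer(target_sync_every),
              max_episode_steps = as.integer(max_episode_steps),
              rho = as.integer(rho), capacity = as.numeric(capacity),
              warmup = as.integer(warmup),
              update_every = as.integer(update_every), reach_tol = reach_tol,
              reward_metric = reward_metric, head_mode = head_mode,
              grad_clip = grad_clip, seed = as.integer(seed))
  if (cfg$gamma < 0 || cfg$gamma > 1)
    stop("'gamma' must be in [0, 1]", call. = FALSE)
  if (cfg$eps_end > cfg$eps_start)
    stop("'eps_end' must not exceed 'eps_start'", call. = FALSE)
  if (cfg$batch_size > cfg$capacity)
    stop("'batch_size' must not exceed the replay capacity", call. = FALSE)
  if (cfg$episodes < 1 || cfg$max_episode_steps < 1 || any(cfg$rho < 1) ||
      cfg$update_every < 1)
    stop("'episodes', 'max_episode_steps', 'rho' and 'update_every' must be >= 1",
         call. = FALSE)
  structure(cfg, class = "train_config")
}

#' Epsilon schedule
#'
#' Linear interpolation from `eps_start` to `eps_end` over
#' `eps_decay_steps` environment steps, constant afterwards.
#'
#' @param step Environment step counter (0-based).
#' @param cfg A [train_config].
#' @return The exploration rate at `step`.
#' @export
epsilon_at <- function(step, cfg) {
  stopifnot(step >= 0)
  frac <- pmin(step / cfg$eps_decay_steps, 1)
  cfg$eps_start + frac * (cfg$eps_end - cfg$eps_start)
}

#' Epsilon-greedy action selection
#'
#' With probability `eps` a uniformly random action; otherwise the action
#' with the highest Q-value, ties broken by the lowest action index in the
#' fixed order `+x, -x, +y, -y, +z, -z, stay`. Draws come from R's global
#' RNG.
#'
#' @param Q Numeric vector of action values.
#' @param eps Exploration rate in `[0, 1]`.
#' @return Integer action index.
#' @export
select_action <- function(Q, eps) {
  stopifnot(eps >= 0, eps <= 1)
  if (eps > 0 && runif(1) < eps) sample.int(length(Q), 1L)
  else which.max(Q)
}

#' TD target arithmetic
#'
#' `y = r + gamma * max_q_next` for non-terminal transitions and `y = r`
#' for terminal ones (bootstrapping masked).
#'
#' @param r Reward vector.
#' @param max_q_next `max_a' Q(s', a')` under the target network.
#' @param terminal Logical vector.
#' @param gamma Discount factor.
#' @return Target vector `y`.
#' @export
td_target_values <- function(r, max_q_next, terminal, gamma) {
  r + gamma * ifelse(terminal, 0, max_q_next)
}

batch_field <- function(batch, field, fun = as.numeric)
  fun(vapply(batch, function(t) t[[field]], numeric(1)))

#' TD targets for a batch of transitions
#'
#' Evaluates the frozen target network on the successor states and applies
#' [td_target_values()]. Transitions are lists with fields `s` and `s_next`
#' (observation stacks), `a` (action index), `r` and `terminal`.
#'
#' @param batch List of transitions.
#' @param target_params Frozen `"essenet_params"` copy.
#' @param gamma Discount factor.
#' @return Numeric target vector, one per transition.
#' @export
td_targets <- function(batch, target_params, gamma) {
  spec <- obs_spec(N = target_params$arch$N, H = target_params$arch$frames - 1L)
  planes <- stack_to_planes(lapply(batch, function(t) t$s_next), spec)
  Q <- net_forward_planes(target_params, planes)$Q
  td_target_values(batch_field(batch, "r"), apply(Q, 2, max),
                   vapply(batch, function(t) isTRUE(t$terminal), logical(1)),
                   gamma)
}

#' DQN loss on a batch
#'
#' Mean squared error between the prediction network's Q-value of the taken
#' action and the TD target computed under the frozen target network.
#' Targets are treated as constants: gradients flow only through the
#' prediction parameters.
#'
#' @param batch List of transitions (see [td_targets()]).
#' @param params Prediction network parameters.
#' @param target_params Frozen target network parameters.
#' @param gamma Discount factor.
#' @return Scalar loss.
#' @export
dqn_loss <- function(batch, params, target_params, gamma) {
  stopifnot(length(batch) >= 1)
  y <- td_targets(batch, target_params, gamma)
  spec <- obs_spec(N = params$arch$N, H = params$arch$frames - 1L)
  planes <- stack_to_planes(lapply(batch, function(t) t$s), spec)
  Q <- net_forward_planes(params, planes)$Q
  a <- vapply(batch, function(t) action_index(t$a), integer(1))
  q_taken <- Q[cbind(a, seq_along(batch))]
  mean((q_taken - y)^2)
}

#' Snapshot the prediction network as the target network
#'
#' Returns an independent copy: R's value semantics guarantee that
#' subsequent updates to the prediction parameters leave the returned copy
#' unchanged.
#'
#' @param params An `"essenet_params"` object.
#' @return The frozen copy.
#' @export
sync_target <- function(params) params

# ---- ADAM ----------------------------------------------------------------

adam_init <- function() list(m = NULL, v = NULL, t = 0L)

model_parts <- function(params)
  intersect(c("theta", "omega", "global", "value", "adv", "out"), names(params))

# one ADAM update with optional global gradient-norm clipping; the heavy
# lifting (moment updates, bias correction) runs compiled over the nested
# tensor lists. The moment buffers in `state` are updated in place.
adam_step <- function(params, grads, state, lr, grad_clip = Inf,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  parts <- model_parts(params)
  pm <- unclass(params)[parts]
  gm <- grads[parts]
  if (is.null(state$m)) {
    state$m <- rapply(gm, function(x) x * 0, how = "replace")
    state$v <- rapply(gm, function(x) x * 0, how = "replace")
  }
  state$t <- state$t + 1L
  new_pm <- cpp_adam_step(pm, gm, state$m, state$v, lr, grad_clip, beta1,
                          beta2, state$t, eps)
  for (part in parts) params[[part]] <- new_pm[[part]]
  list(params = params, state = state)
}

# subtract flat updates from the model leaves, in param_leaves order
apply_param_update <- function(params, upd) {
  i <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (j in seq_along(x)) x[[j]] <- walk(x[[j]])
      x
    } else if (is.numeric(x)) {
      i <<- i + 1L
      x - upd[[i]]
    } else x
  }
  for (part in intersect(c("theta", "omega", "global", "value", "adv", "out"),
                         names(params)))
    params[[part]] <- walk(params[[part]])
  params
}

#' Trailing moving average
#'
#' Element `t` is the mean of the most recent `min(window, t)` values, the
#' smoothing used when plotting per-episode rewards.
#'
#' @param x Numeric series.
#' @param window Window size (default 30).
#' @return Numeric series of the same length.
#' @export
moving_average <- function(x, window = 30L) {
  window <- as.integer(window)
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0) return(numeric(0))
  cs <- cumsum(x)
  t <- seq_len(n)
  lead <- cs
  full <- t > window
  lead[full] <- cs[full] - cs[t[full] - window]
  lead / pmin(t, window)
}

# ---- training loop -------------------------------------------------------

sample_start <- function(d) {
  margin <- floor(0.1 * d)
  vapply(seq_len(3), function(i)
    sample(seq.int(margin[i], d[i] - 1L - margin[i]), 1L), numeric(1))
}

#' Train a landmark-localization agent
#'
#' Episodic DQN training over a pool of volumes with one ground-truth
#' landmark each. Every episode picks a volume uniformly at random and
#' starts the agent at a uniformly random voxel within the central 80% of
#' each dimension. Actions are epsilon-greedy on the prediction network;
#' transitions (stored compactly as position histories, with observations
#' re-extracted on demand) go to the replay memory; after warm-up one ADAM
#' gradient step on the DQN loss follows every environment step, and the
#' target network is re-synced every `target_sync_every` steps. Fully
#' reproducible given `cfg$seed`.
#'
#' @param volumes List of [volume] objects.
#' @param landmarks List of [landmark] objects, parallel to `volumes`.
#' @param cfg A [train_config].
#' @param spec An [obs_spec].
#' @param verbose Print a line every `report_every` episodes?
#' @param report_every Episode interval for progress reporting.
#' @return An object of class `"train_run"`: `params` (trained network),
#'   `log` (per-episode data.frame with episode, volume, steps, total
#'   reward, terminal cause, final distance in voxels and mm, epsilon),
#'   `cfg`, `spec`.
#' @export
run_training <- function(volumes, landmarks, cfg, spec, verbose = FALSE,
                         report_every = 25L) {
  stopifnot(inherits(cfg, "train_config"), inherits(spec, "obs_spec"))
  if (!is.list(volumes) || length(volumes) == 0 ||
      !all(vapply(volumes, inherits, logical(1), "volume")))
    stop("'volumes' must be a non-empty list of volume objects", call. = FALSE)
  if (length(landmarks) != length(volumes))
    stop(sprintf("configuration error: %d volumes but %d landmarks",
                 length(volumes), length(landmarks)), call. = FALSE)
  for (i in seq_along(landmarks)) {
    if (!inherits(landmarks[[i]], "landmark"))
      stop(sprintf("configuration error: no landmark for volume %d", i),
           call. = FALSE)
    if (!in_bounds(volumes[[i]], landmarks[[i]]$voxel))
      stop(sprintf("configuration error: landmark '%s' lies outside volume %d",
                   landmarks[[i]]$name, i), call. = FALSE)
  }
  frames <- spec$H + 1L
  arch <- arch_spec(N = spec$N, frames = frames, head_mode = cfg$head_mode)
  params <- essenet_init(arch, seed = cfg$seed)
  target <- sync_target(params)
  opt <- adam_init()
  buf <- replay_buffer(cfg$capacity)
  set.seed(derive_seed(cfg$seed, "train"))
  n_vol <- length(volumes)
  global_step <- 0L
  log_rows <- vector("list", cfg$episodes)
  for (ep in seq_len(cfg$episodes)) {
    vi <- sample.int(n_vol, 1L)
    v <- volumes[[vi]]
    gt_vox <- landmarks[[vi]]$voxel
    d <- dim(v$data)
    rho_ep <- if (length(cfg$rho) > 1) sample(cfg$rho, 1L) else cfg$rho
    pos <- as.integer(sample_start(d))
    pf <- matrix(rep(pos, each = frames), frames, 3)
    step_count <- 0L
    total_r <- 0
    cause <- "max_steps"
    repeat {
      eps <- epsilon_at(global_step, cfg)
      if (runif(1) < eps) {
        a <- sample.int(N_ACTIONS, 1L)
      } else {
        planes <- build_planes(volumes, vi, list(pf), spec)
        a <- which.max(net_forward_planes(params, planes)$Q[, 1])
      }
      p_next <- apply_action(pos, a, rho_ep)
      r <- compute_reward(pos, p_next, gt_vox, metric = cfg$reward_metric)
      step_count <- step_count + 1L
      reached <- sqrt(sum((p_next - gt_vox)^2)) <= cfg$reach_tol
      oob <- !in_bounds(v, p_next)
      capped <- step_count >= cfg$max_episode_steps
      terminal <- reached || oob || capped
      pf_next <- rbind(p_next, pf[seq_len(frames - 1L), , drop = FALSE])
      replay_push(buf, list(vol = vi, ph = pf, ph2 = pf_next, a = a, r = r,
                            terminal = terminal))
      total_r <- total_r + r
      global_step <- global_step + 1L
      if (replay_size(buf) >= max(cfg$warmup, cfg$batch_size) &&
          global_step %% cfg$update_every == 0L) {
        batch <- replay_sample(buf, cfg$batch_size)
        vols_b <- vapply(batch, function(t) t$vol, integer(1))
        planes_next <- build_planes(volumes, vols_b,
                                    lapply(batch, function(t) t$ph2), spec)
        qn <- net_forward_planes(target, planes_next)$Q
        y <- td_target_values(batch_field(batch, "r"), apply(qn, 2, max),
                              vapply(batch, function(t) t$terminal, logical(1)),
                              cfg$gamma)
        planes_s <- build_planes(volumes, vols_b,
                                 lapply(batch, function(t) t$ph), spec)
        gr <- net_grad_planes(params, planes_s,
                              vapply(batch, function(t) t$a, integer(1)), y)
        res <- adam_step(params, gr$grads, opt, cfg$learning_rate,
                         grad_clip = cfg$grad_clip)
        params <- res$params
        opt <- res$state
      }
      if (global_step %% cfg$target_sync_every == 0L)
        target <- sync_target(params)
      pos <- p_next
      pf <- pf_next
      if (terminal) {
        cause <- if (reached) "reached_target"
        else if (oob) "out_of_bounds" else "max_steps"
        break
      }
    }
    final_vox <- sqrt(sum((pos - gt_vox)^2))
    final_mm <- sqrt(sum(((pos - gt_vox) * v$spacing)^2))
    log_rows[[ep]] <- data.frame(
      episode = ep, volume = vi, steps = step_count, total_reward = total_r,
      cause = cause, final_dist_vox = final_vox, final_dist_mm = final_mm,
      epsilon = eps)
    if (verbose && ep %% report_every == 0L) {
      recent <- vapply(log_rows[max(1, ep - report_every + 1):ep],
                       function(r) r$total_reward, numeric(1))
      message(sprintf("episode %d/%d: mean reward %.1f, eps %.2f, buffer %d",
                      ep, cfg$episodes, mean(recent), eps, replay_size(buf)))
    }
  }
  structure(list(params = params, log = do.call(rbind, log_rows),
                 cfg = cfg, spec = spec),
            class = "train_run")
}

#' @export
print.train_run <- function(x, ...) {
  n <- nrow(x$log)
  last <- x$log[max(1, n - 29):n, ]
  cat(sprintf("<train_run> %d episodes, %s head\n", n, x$cfg$head_mode))
  cat(sprintf("  last 30 episodes: mean reward %.1f, reached target %.0f%%\n",
              mean(last$total_reward),
              100 * mean(last$cause == "reached_target")))
  invisible(x)
}
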