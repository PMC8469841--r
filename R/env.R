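#' Action set
#'
#' Seven discrete actions in fixed order: `+x, -x, +y, -y, +z, -z, stay`.
#' The first six are unit displacement vectors along the axes; `stay` is the
#' zero vector. The order is also the deterministic tie-break order used by
#' greedy action selection.
#'
#' @format `ACTIONS` is a 7 x 3 integer matrix of displacement vectors with
#'   rownames `ACTION_NAMES`.
#' @export
ACTIONS <- matrix(c(1, 0, 0,
                    -1, 0, 0,
                    0, 1, 0,
                    0, -1, 0,
                    0, 0, 1,
                    0, 0, -1,
                    0, 0, 0), nrow = 7, byrow = TRUE,
                  dimnames = list(c("+x", "-x", "+y", "-y", "+z", "-z", "stay"),
                                  c("x", "y", "z")))

#' @rdname ACTIONS
#' @export
ACTION_NAMES <- rownames(ACTIONS)

#' @rdname ACTIONS
#' @export
N_ACTIONS <- 7L

action_index <- function(a) {
  if (is.character(a)) a <- match(a, ACTION_NAMES)
  a <- as.integer(a)
  if (is.na(a) || a < 1 || a > N_ACTIONS)
    stop("unknown action (expected one of +x, -x, +y, -y, +z, -z, stay, or 1:7)",
         call. = FALSE)
  a
}

#' Apply an action to a voxel position
#'
#' Moves `p` by `rho` voxels along the action's displacement vector
#' (`p + rho * a`). No bounds clamping is performed here; the environment
#' step decides what leaving the grid means.
#'
#' @param p Integer length-3 voxel position.
#' @param a Action name or index (see [ACTIONS]).
#' @param rho Integer step size in voxels (>= 1).
#' @return Integer length-3 position.
#' @export
apply_action <- function(p, a, rho = 3L) {
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 1) stop("'rho' must be an integer >= 1", call. = FALSE)
  unname(as.integer(p) + rho * ACTIONS[action_index(a), ])
}

#' Distance-based reward
#'
#' The per-step reward is the decrease in (by default squared) Euclidean
#' distance to the target:
#' `R = ||p_i - p_GT||^2 - ||p_next - p_GT||^2` in voxel units. Positive
#' means the agent moved closer. With `metric = "plain"` the un-squared
#' distances are differenced instead. Squared rewards telescope exactly over
#' a trajectory (integer arithmetic): their sum equals
#' `d^2(p_0, GT) - d^2(p_T, GT)`.
#'
#' @param p_i,p_next Positions before and after the step (voxels).
#' @param p_gt Target voxel (or a [landmark]).
#' @param metric `"squared"` (default) or `"plain"`.
#' @return Scalar reward.
#' @export
compute_reward <- function(p_i, p_next, p_gt, metric = c("squared", "plain")) {
  metric <- match.arg(metric)
  if (inherits(p_gt, "landmark")) p_gt <- p_gt$voxel
  d0 <- sum((as.numeric(p_i) - as.numeric(p_gt))^2)
  d1 <- sum((as.numeric(p_next) - as.numeric(p_gt))^2)
  if (metric == "squared") d0 - d1 else sqrt(d0) - sqrt(d1)
}

#' Reset the environment
#'
#' @param v A [volume].
#' @param start Integer length-3, 0-based starting voxel (must be inside the
#'   grid).
#' @param spec An [obs_spec] (fixes the history length).
#' @return An object of class `"env_state"` with fields `position`,
#'   `history` (up to `H` past positions, most recent first), `step_count`,
#'   `terminal` and `cause` (`"none"`, `"reached_target"`, `"out_of_bounds"`
#'   or `"max_steps"`).
#' @export
env_reset <- function(v, start, spec) {
  stopifnot(inherits(v, "volume"), inherits(spec, "obs_spec"))
  start <- as.integer(start)
  if (!is_int3(start) || !in_bounds(v, start))
    stop("'start' must be an integer voxel inside the volume", call. = FALSE)
  structure(list(position = start,
                 history = matrix(integer(0), 0, 3),
                 H = spec$H,
                 step_count = 0L,
                 terminal = FALSE,
                 cause = "none"),
            class = "env_state")
}

#' @export
print.env_state <- function(x, ...) {
  cat(sprintf("<env_state> position (%s), step %d%s\n",
              paste(x$position, collapse = ", "), x$step_count,
              if (x$terminal) sprintf(", terminal (%s)", x$cause) else ""))
  invisible(x)
}

#' Step the environment
#'
#' Applies the action, computes the reward against the ground-truth
#' landmark, and updates the termination status: `reached_target` when the
#' new position is within `reach_tol` voxels (Euclidean) of the target,
#' `out_of_bounds` when it leaves the grid, `max_steps` when the episode
#' step cap is hit. Stepping an already-terminal environment is a usage
#' error. The returned state is a fresh value; the input `env` is not
#' modified.
#'
#' @param v A [volume].
#' @param env Current `"env_state"`.
#' @param a Action (name or index).
#' @param rho Step size in voxels.
#' @param gt Target [landmark] (or voxel vector).
#' @param spec An [obs_spec].
#' @param max_steps Episode step cap (default 1500).
#' @param reach_tol Termination radius in voxels (default 3, one coarse
#'   step).
#' @param reward_metric `"squared"` or `"plain"`.
#' @return A list with `obs` (the new observation stack), `reward`, and
#'   `env` (the new state).
#' @export
env_step <- function(v, env, a, rho = 3L, gt, spec, max_steps = 1500L,
                     reach_tol = 3, reward_metric = "squared") {
  stopifnot(inherits(env, "env_state"))
  if (env$terminal)
    stop(sprintf("cannot step a terminal environment (cause: %s)", env$cause),
         call. = FALSE)
  gt_vox <- if (inherits(gt, "landmark")) gt$voxel else as.integer(gt)
  p_i <- env$position
  p_next <- apply_action(p_i, a, rho)
  reward <- compute_reward(p_i, p_next, gt_vox, metric = reward_metric)
  new_hist <- rbind(p_i, env$history)
  if (nrow(new_hist) > env$H) new_hist <- new_hist[seq_len(env$H), , drop = FALSE]
  env2 <- env
  env2$position <- p_next
  env2$history <- new_hist
  env2$step_count <- env$step_count + 1L
  if (sqrt(sum((p_next - gt_vox)^2)) <= reach_tol) {
    env2$terminal <- TRUE; env2$cause <- "reached_target"
  } else if (!in_bounds(v, p_next)) {
    env2$terminal <- TRUE; env2$cause <- "out_of_bounds"
  } else if (env2$step_count >= max_steps) {
    env2$terminal <- TRUE; env2$cause <- "max_steps"
  }
  list(obs = observe(v, env2, spec), reward = reward, env = env2)
}
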