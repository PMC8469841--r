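#' Localization configuration
#'
#' Settings for the coarse-to-fine multi-agent localization procedure: a
#' greedy rollout with coarse step size `rho_coarse` for `n_coarse_steps`
#' moves, then `n_agents` agents spawned with a random displacement of at
#' most `spawn_radius` voxels around the coarse endpoint, each refined with
#' step size `rho_fine` for `n_fine_steps` moves, and finally a weighted
#' average of the fine endpoints.
#'
#' @param rho_coarse Coarse step size in voxels (default 3).
#' @param n_coarse_steps Coarse rollout length (default 100).
#' @param n_agents Number of fine agents (default 5).
#' @param spawn_radius Spawn displacement radius in voxels (default 6, two
#'   coarse steps).
#' @param rho_fine Fine step size (default 1; must not exceed
#'   `rho_coarse`).
#' @param n_fine_steps Fine rollout length (default 50).
#' @param weighting `"uniform"` (default) or `"value_softmax"` (softmax of
#'   each agent's final state value under the dueling head).
#' @param seed Seed for the spawn displacements.
#' @return An object of class `"loc_config"`.
#' @export
loc_config <- function(rho_coarse = 3L, n_coarse_steps = 100L, n_agents = 5L,
                       spawn_radius = 6, rho_fine = 1L, n_fine_steps = 50L,
                       weighting = c("uniform", "value_softmax"), seed = 1L) {
  weighting <- match.arg(weighting)
  cfg <- list(rho_coarse = as.integer(rho_coarse),
              n_coarse_steps = as.integer(n_coarse_steps),
              n_agents = as.integer(n_agents),
              spawn_radius = as.numeric(spawn_radius),
              rho_fine = as.integer(rho_fine),
              n_fine_steps = as.integer(n_fine_steps),
              weighting = weighting, seed = as.integer(seed))
  if (cfg$rho_coarse < 1 || cfg$rho_fine < 1 || cfg$n_agents < 1)
    stop("'rho_coarse', 'rho_fine' and 'n_agents' must be >= 1", call. = FALSE)
  if (cfg$n_coarse_steps < 0 || cfg$n_fine_steps < 0 || cfg$spawn_radius < 0)
    stop("step counts and 'spawn_radius' must be non-negative", call. = FALSE)
  if (cfg$rho_fine > cfg$rho_coarse)
    stop("'rho_fine' must not exceed 'rho_coarse'", call. = FALSE)
  structure(cfg, class = "loc_config")
}

# Q-values at a given position-frame matrix under either trained network
# parameters or a stub policy function(volume, pos_frames) -> 7-vector
policy_q <- function(v, params, pf, spec) {
  if (is.function(params)) return(params(v, pf))
  planes <- build_planes(list(v), 1L, list(pf), spec)
  net_forward_planes(params, planes)$Q[, 1]
}

#' Greedy policy rollout
#'
#' Pure-greedy (epsilon = 0) rollout of exactly `n_steps` moves from
#' `start`. At inference, moves that would leave the grid are clamped to
#' the boundary instead of terminating, so fixed-length rollouts always
#' complete. Ties in the Q-values are broken by the lowest action index.
#'
#' @param v A [volume].
#' @param params Trained `"essenet_params"`, or a stub policy
#'   `function(volume, pos_frames)` returning a 7-vector of action values
#'   (`pos_frames` is the `(H+1) x 3` matrix of current and past
#'   positions).
#' @param start Integer length-3 starting voxel.
#' @param rho Step size in voxels.
#' @param n_steps Number of moves.
#' @param spec An [obs_spec].
#' @return `(n_steps + 1) x 3` integer matrix of visited positions
#'   (including `start`).
#' @export
greedy_rollout <- function(v, params, start, rho, n_steps, spec) {
  stopifnot(inherits(v, "volume"), inherits(spec, "obs_spec"))
  frames <- spec$H + 1L
  d <- dim(v$data)
  pos <- as.integer(start)
  pf <- matrix(rep(pos, each = frames), frames, 3)
  traj <- matrix(0L, n_steps + 1L, 3)
  traj[1, ] <- pos
  if (n_steps == 0) return(traj)
  for (s in seq_len(n_steps)) {
    q <- policy_q(v, params, pf, spec)
    a <- which.max(q)
    pos <- pmin(pmax(apply_action(pos, a, rho), 0L), d - 1L)
    pf <- rbind(pos, pf[seq_len(frames - 1L), , drop = FALSE])
    traj[s + 1L, ] <- pos
  }
  traj
}

#' Spawn fine agents around a point
#'
#' Draws `n` displacement vectors uniformly from the L2 ball of the given
#' radius (rejection sampling from the enclosing cube), rounds to voxels,
#' and clamps into the grid.
#'
#' @param center Integer length-3 voxel.
#' @param n Number of agents.
#' @param radius Displacement radius in voxels.
#' @param dims Volume dimensions used for clamping (optional; no clamping
#'   when `NULL`).
#' @return `n x 3` integer matrix of starting voxels.
#' @export
spawn_agents <- function(center, n, radius, dims = NULL) {
  center <- as.numeric(center)
  out <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    if (radius == 0) {
      disp <- c(0, 0, 0)
    } else {
      repeat {
        disp <- runif(3, -radius, radius)
        if (sum(disp^2) <= radius^2) break
      }
    }
    p <- as.integer(round_half_away(center + disp))
    if (!is.null(dims)) p <- pmin(pmax(p, 0L), as.integer(dims) - 1L)
    out[i, ] <- p
  }
  out
}

#' Weighted average of voxel positions
#'
#' Component-wise weighted mean, rounded half-away-from-zero to an integer
#' voxel.
#'
#' @param points `n x 3` matrix of voxel positions.
#' @param weights Non-negative weights summing to 1.
#' @return Integer length-3 voxel.
#' @export
weighted_average <- function(points, weights) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, length(weights) == nrow(points))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be non-negative and sum to 1", call. = FALSE)
  as.integer(round_half_away(colSums(points * weights)))
}

#' Coarse-to-fine multi-agent localization
#'
#' The test-time search: a coarse greedy rollout from `start` (default the
#' volume center), then `n_agents` fine agents spawned at random
#' displacements around the coarse endpoint, each refined with a short
#' fine-step rollout, and the weighted average of their endpoints as the
#' final prediction. Deterministic given `cfg$seed`. Untrained parameters
#' are accepted without complaint; prediction quality is the caller's
#' concern.
#'
#' @param v A [volume].
#' @param params Trained `"essenet_params"` or a stub policy function (see
#'   [greedy_rollout()]).
#' @param cfg A [loc_config].
#' @param spec An [obs_spec].
#' @param start Starting voxel; defaults to the volume center
#'   `floor(dim / 2)`.
#' @param gt Optional ground-truth [landmark]; when supplied the result
#'   carries `error_mm` (and `error_vox`).
#' @return An object of class `"localization_result"`: `start`,
#'   `coarse_end`, `agent_starts`, `agent_ends`, `weights`, `predicted`
#'   (voxel), `predicted_world_mm`, and optionally the errors.
#' @export
localize <- function(v, params, cfg = loc_config(), spec, start = NULL,
                     gt = NULL) {
  stopifnot(inherits(v, "volume"), inherits(cfg, "loc_config"),
            inherits(spec, "obs_spec"))
  d <- dim(v$data)
  if (is.null(start)) start <- d %/% 2L
  start <- as.integer(start)
  coarse <- greedy_rollout(v, params, start, cfg$rho_coarse,
                           cfg$n_coarse_steps, spec)
  coarse_end <- coarse[nrow(coarse), ]
  set.seed(derive_seed(cfg$seed, "spawn"))
  starts <- spawn_agents(coarse_end, cfg$n_agents, cfg$spawn_radius, d)
  ends <- matrix(0L, cfg$n_agents, 3)
  final_pf <- vector("list", cfg$n_agents)
  frames <- spec$H + 1L
  for (i in seq_len(cfg$n_agents)) {
    traj <- greedy_rollout(v, params, starts[i, ], cfg$rho_fine,
                           cfg$n_fine_steps, spec)
    ends[i, ] <- traj[nrow(traj), ]
    k <- nrow(traj)
    final_pf[[i]] <- traj[pmax(k - 0:(frames - 1L), 1L), , drop = FALSE]
  }
  if (cfg$weighting == "uniform") {
    w <- rep(1 / cfg$n_agents, cfg$n_agents)
  } else {
    if (is.function(params) || params$arch$head_mode != "dueling")
      stop("weighting = \"value_softmax\" requires dueling-head network parameters",
           call. = FALSE)
    vals <- vapply(seq_len(cfg$n_agents), function(i) {
      planes <- build_planes(list(v), 1L, final_pf[i], spec)
      as.numeric(net_forward_planes(params, planes)$V[1, 1])
    }, numeric(1))
    e <- exp(vals - max(vals))
    w <- e / sum(e)
  }
  predicted <- weighted_average(ends, w)
  res <- list(start = start, coarse_end = coarse_end, agent_starts = starts,
              agent_ends = ends, weights = w, predicted = predicted,
              predicted_world_mm = voxel_to_world(v, predicted))
  if (!is.null(gt)) {
    res$error_vox <- sqrt(sum((predicted - gt$voxel)^2))
    res$error_mm <- evaluate_error(predicted, gt, v$spacing)
  }
  structure(res, class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> predicted voxel (%s), world (%s) mm\n",
              paste(x$predicted, collapse = ", "),
              paste(format(x$predicted_world_mm, digits = 5), collapse = ", ")))
  if (!is.null(x$error_mm))
    cat(sprintf("  error: %.3f voxels, %.3f mm\n", x$error_vox, x$error_mm))
  invisible(x)
}

#' Euclidean localization error in mm
#'
#' `|| (predicted - gt) * spacing ||_2`, the evaluation metric reported for
#' landmark identification.
#'
#' @param predicted Integer length-3 predicted voxel.
#' @param gt Ground-truth [landmark] (or voxel vector).
#' @param spacing Per-axis voxel size in mm.
#' @return Error in mm.
#' @export
evaluate_error <- function(predicted, gt, spacing) {
  gt_vox <- if (inherits(gt, "landmark")) gt$voxel else as.numeric(gt)
  sqrt(sum(((as.numeric(predicted) - gt_vox) * as.numeric(spacing))^2))
}
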