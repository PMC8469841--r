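test_that("a stay-preferring stub policy yields a constant trajectory", {
  v <- make_test_volume(c(20, 20, 20), seed = 14)
  spec <- obs_spec(N = 6, H = 1)
  stay <- function(v, pf) c(rep(0, 6), 1)
  traj <- greedy_rollout(v, stay, c(9, 9, 9), rho = 3, n_steps = 10, spec)
  expect_equal(nrow(traj), 11)
  expect_true(all(traj[, 1] == 9 & traj[, 2] == 9 & traj[, 3] == 9))
  expect_equal(greedy_rollout(v, stay, c(4, 5, 6), 3, 0, spec),
               matrix(c(4L, 5L, 6L), 1))
})

test_that("the greedy-descent stub reaches the target from any start", {
  v <- make_test_volume(c(24, 24, 24), seed = 15)
  spec <- obs_spec(N = 6, H = 1)
  gt <- c(15, 8, 11)
  pol <- make_descent_policy(gt)
  set.seed(51)
  for (rep in 1:10) {
    start <- sample(0:23, 3, TRUE)
    traj <- greedy_rollout(v, pol, start, rho = 1, n_steps = 60, spec)
    expect_equal(traj[nrow(traj), ], gt, ignore_attr = TRUE)
  }
})

test_that("rollouts clamp at the boundary instead of terminating", {
  v <- make_test_volume(c(10, 10, 10), seed = 16)
  spec <- obs_spec(N = 4, H = 0)
  minus_x <- function(v, pf) c(0, 1, rep(0, 5))
  traj <- greedy_rollout(v, minus_x, c(4, 4, 4), rho = 3, n_steps = 5, spec)
  expect_equal(nrow(traj), 6)
  expect_true(all(traj[, 1] >= 0))
  expect_equal(traj[6, ], c(0, 4, 4), ignore_attr = TRUE)
})

test_that("agent spawning is radius-bounded, seedable and degenerate at 0", {
  set.seed(52)
  pts0 <- spawn_agents(c(5, 5, 5), 4, 0)
  expect_true(all(pts0 == 5))
  set.seed(52)
  pts <- spawn_agents(c(10, 10, 10), 50, 6)
  d <- sqrt(rowSums((pts - 10)^2))
  expect_true(all(d <= 6 + sqrt(3) / 2 + 1e-9))  # rounding can add half a voxel per axis
  set.seed(99); a <- spawn_agents(c(8, 8, 8), 5, 4)
  set.seed(99); b <- spawn_agents(c(8, 8, 8), 5, 4)
  expect_identical(a, b)
  clamped <- spawn_agents(c(0, 0, 0), 20, 5, dims = c(8, 8, 8))
  expect_true(all(clamped >= 0))
})

test_that("weighted averaging of endpoints follows the arithmetic", {
  expect_equal(weighted_average(rbind(c(3, 4, 5), c(3, 4, 5)), c(0.5, 0.5)),
               c(3, 4, 5))
  expect_equal(weighted_average(rbind(c(0, 0, 0), c(2, 0, 0)), c(0.5, 0.5)),
               c(1, 0, 0))
  expect_equal(weighted_average(rbind(c(9, 1, 2), c(0, 0, 0)), c(1, 0)),
               c(9, 1, 2))
  expect_error(weighted_average(rbind(c(0, 0, 0)), 2), "sum to 1")
})

test_that("localization with the oracle policy recovers the landmark exactly", {
  for (s in 1:5) {
    ph <- generate_phantom(small_phantom_config(seed = 200 + s))
    spec <- obs_spec(N = 8, H = 1)
    pol <- make_descent_policy(ph$landmark$voxel)
    cfg <- loc_config(n_coarse_steps = 60, n_fine_steps = 30, seed = s)
    res <- localize(ph$volume, pol, cfg, spec, gt = ph$landmark)
    expect_equal(res$error_vox, 0)
    expect_equal(nrow(res$agent_ends), 5)
    expect_equal(sum(res$weights), 1)
  }
})

test_that("localization is deterministic and degenerates to the coarse endpoint", {
  ph <- generate_phantom(small_phantom_config(seed = 300))
  spec <- obs_spec(N = 8, H = 1)
  pol <- make_descent_policy(ph$landmark$voxel)
  cfg <- loc_config(seed = 5)
  r1 <- localize(ph$volume, pol, cfg, spec)
  r2 <- localize(ph$volume, pol, cfg, spec)
  expect_identical(r1$predicted, r2$predicted)
  expect_identical(r1$agent_starts, r2$agent_starts)

  cfg0 <- loc_config(spawn_radius = 0, n_fine_steps = 0, seed = 5)
  r0 <- localize(ph$volume, pol, cfg0, spec)
  expect_equal(r0$predicted, r0$coarse_end, ignore_attr = TRUE)

  # fine phase never hurts under the oracle policy
  err_full <- sqrt(sum((r1$predicted - ph$landmark$voxel)^2))
  err_coarse <- sqrt(sum((r0$coarse_end - ph$landmark$voxel)^2))
  expect_lte(err_full, err_coarse)
})

test_that("value-softmax weighting needs a dueling network", {
  ph <- generate_phantom(small_phantom_config(seed = 301))
  spec <- obs_spec(N = 8, H = 2)
  pol <- make_descent_policy(ph$landmark$voxel)
  cfg <- loc_config(weighting = "value_softmax", seed = 1)
  expect_error(localize(ph$volume, pol, cfg, spec), "dueling")
  p <- essenet_init(tiny_arch(), seed = 20)
  res <- localize(ph$volume, p, cfg, spec)
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)
  expect_true(all(res$weights >= 0))
})

test_that("evaluation reports Euclidean mm error with symmetry", {
  expect_equal(evaluate_error(c(5, 5, 5), c(5, 5, 5), c(0.33, 0.33, 0.33)), 0)
  expect_equal(evaluate_error(c(8, 5, 5), c(5, 5, 5), rep(0.33, 3)), 0.99)
  p <- c(3, 7, 2); g <- c(5, 1, 0); sp <- c(0.5, 0.7, 1.1)
  perm <- c(3, 1, 2)
  expect_equal(evaluate_error(p[perm], g[perm], sp[perm]),
               evaluate_error(p, g, sp))
})
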