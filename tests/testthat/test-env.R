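test_that("actions displace by exactly rho along one axis", {
  expect_equal(apply_action(c(0, 0, 0), "+x", 3), c(3, 0, 0))
  expect_equal(apply_action(c(5, 5, 5), "stay", 3), c(5, 5, 5))
  expect_equal(apply_action(c(2, 3, 4), "-z", 1), c(2, 3, 3))
  for (a in 1:6)
    expect_equal(sqrt(sum((apply_action(c(9, 9, 9), a, 4) - c(9, 9, 9))^2)), 4)
  expect_identical(nrow(ACTIONS), 7L)
  expect_equal(rowSums(abs(ACTIONS[1:6, ])), rep(1, 6), ignore_attr = TRUE)
  expect_equal(sum(abs(ACTIONS[7, ])), 0)
})

test_that("squared-distance reward matches hand evaluation and antisymmetry", {
  expect_equal(compute_reward(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0)), 51)
  expect_equal(compute_reward(c(4, 4, 4), c(4, 4, 4), c(1, 2, 3)), 0)
  expect_equal(compute_reward(c(3, 0, 0), c(0, 0, 0), c(10, 0, 0)), -51)
  expect_equal(compute_reward(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0),
                              metric = "plain"), 3)
})

test_that("rewards telescope exactly over random trajectories", {
  set.seed(21)
  for (rep in 1:50) {
    gt <- sample(0:40, 3, replace = TRUE)
    pos <- sample(0:40, 3, replace = TRUE)
    total <- 0
    p0 <- pos
    for (s in 1:30) {
      a <- sample(7, 1)
      nxt <- apply_action(pos, a, sample(1:3, 1))
      total <- total + compute_reward(pos, nxt, gt)
      pos <- nxt
    }
    expect_identical(total, as.numeric(sum((p0 - gt)^2) - sum((pos - gt)^2)))
  }
})

test_that("reward is invariant to translation and axis permutation", {
  set.seed(22)
  for (rep in 1:20) {
    p <- sample(0:30, 3, TRUE); q <- sample(0:30, 3, TRUE); g <- sample(0:30, 3, TRUE)
    base <- compute_reward(p, q, g)
    t <- sample(-20:20, 3, TRUE)
    expect_equal(compute_reward(p + t, q + t, g + t), base)
    perm <- sample(3)
    expect_equal(compute_reward(p[perm], q[perm], g[perm]), base)
  }
})

test_that("episodes terminate on target, boundary and step cap", {
  v <- make_test_volume(c(20, 20, 20), seed = 9)
  spec <- obs_spec(N = 6, H = 1)
  gt <- landmark("t", c(10, 10, 10), volume = v)

  env <- env_reset(v, c(10, 10, 12), spec)
  out <- env_step(v, env, "-z", rho = 3, gt, spec, reach_tol = 3)
  expect_true(out$env$terminal)
  expect_equal(out$env$cause, "reached_target")

  far <- landmark("far", c(19, 19, 19), volume = v)
  env <- env_reset(v, c(0, 0, 0), spec)
  out <- env_step(v, env, "-x", rho = 3, far, spec)
  expect_true(out$env$terminal)
  expect_equal(out$env$cause, "out_of_bounds")

  env <- env_reset(v, c(4, 4, 4), spec)
  for (i in 1:5) {
    out <- env_step(v, env, if (i %% 2) "+x" else "-x", rho = 1, far, spec,
                    max_steps = 5)
    env <- out$env
  }
  expect_true(env$terminal)
  expect_equal(env$cause, "max_steps")
  expect_error(env_step(v, env, "+x", 1, far, spec), "terminal")
})

test_that("stepping returns fresh state values (no aliasing)", {
  v <- make_test_volume(c(20, 20, 20), seed = 10)
  spec <- obs_spec(N = 6, H = 2)
  gt <- landmark("t", c(2, 2, 2), volume = v)
  env <- env_reset(v, c(10, 10, 10), spec)
  out <- env_step(v, env, "+x", 1, gt, spec)
  expect_equal(env$position, c(10, 10, 10))
  expect_equal(env$step_count, 0L)
  expect_equal(out$env$position, c(11, 10, 10))
  # mutating the returned observation cannot touch the environment
  obs <- out$obs
  obs[1, 1, 1, 1] <- 99
  expect_true(all(observe(v, out$env, spec) <= 1))
})
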