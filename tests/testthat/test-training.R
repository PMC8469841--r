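test_that("replay buffer is a FIFO ring with uniform sampling", {
  buf <- replay_buffer(3)
  for (i in 1:4) replay_push(buf, i)
  expect_equal(replay_size(buf), 3L)
  expect_equal(unlist(replay_contents(buf)), c(2, 3, 4))
  expect_equal(replay_sample(replay_buffer(5) |> replay_push("only"), 1)[[1]],
               "only")
  expect_error(replay_sample(buf, 5), "cannot sample")

  # empirical uniformity of single draws
  buf4 <- replay_buffer(4)
  for (i in 1:4) replay_push(buf4, i)
  set.seed(91)
  draws <- replicate(10000, replay_sample(buf4, 1)[[1]])
  p <- chisq.test(table(draws))$p.value
  expect_gt(p, 0.01)
})

test_that("epsilon anneals linearly from 0.9 to 0.1", {
  cfg <- train_config(eps_decay_steps = 1000)
  expect_equal(epsilon_at(0, cfg), 0.9)
  expect_equal(epsilon_at(500, cfg), 0.5)
  expect_equal(epsilon_at(1000, cfg), 0.1)
  expect_equal(epsilon_at(10000, cfg), 0.1)
})

test_that("greedy selection takes the argmax with lowest-index tie-breaking", {
  expect_equal(select_action(c(0, 0, 0, 0, 0, 0, 1), eps = 0), 7L)
  expect_equal(select_action(rep(0.3, 7), eps = 0), 1L)   # tie -> +x
  set.seed(92)
  draws <- replicate(10000, select_action(rep(0, 7), eps = 1))
  expect_gt(chisq.test(table(draws))$p.value, 0.01)
})

test_that("TD target arithmetic follows the Bellman backup with terminal mask", {
  expect_equal(td_target_values(1, 99, TRUE, 0.9), 1)
  expect_equal(td_target_values(1, 2, FALSE, 0.9), 2.8)
  expect_equal(td_target_values(c(0.5, -1), c(3, 3), c(FALSE, FALSE), 0), c(0.5, -1))
})

test_that("network TD targets and DQN loss reproduce hand-computed values", {
  arch <- tiny_arch()
  spec <- obs_spec(N = 8, H = 2)
  zero <- zero_params(essenet_init(arch, seed = 11))
  target <- zero
  target$value$b <- 2        # all target Q = V = 2
  pred <- zero
  pred$adv$b <- rep(1.75, 7) # advantages cancel; Q = 0 still
  st <- random_stack(spec, seed = 80)
  batch <- list(list(s = st, a = 3L, r = 1, s_next = st, terminal = FALSE))

  expect_equal(td_targets(batch, target, gamma = 0.9), 2.8)
  expect_equal(td_targets(batch, target, gamma = 0), 1)
  batch_term <- list(list(s = st, a = 3L, r = 1, s_next = st, terminal = TRUE))
  expect_equal(td_targets(batch_term, target, gamma = 0.9), 1)

  # prediction Q(s, a) = 0 for the zeroed net: loss = y^2 = 7.84
  expect_equal(dqn_loss(batch, zero, target, 0.9), 7.84)
  # prediction with a 1.75 state-value bias: Q(s, a) = 1.75, loss = 1.1025
  pred2 <- zero
  pred2$value$b <- 1.75
  expect_equal(dqn_loss(batch, pred2, target, 0.9), (2.8 - 1.75)^2)
  # perfect prediction gives zero loss
  pred3 <- zero
  pred3$value$b <- 2.8
  expect_equal(dqn_loss(batch, pred3, target, 0.9), 0)
  # duplicating batch items leaves the mean loss unchanged
  expect_equal(dqn_loss(c(batch, batch), zero, target, 0.9),
               dqn_loss(batch, zero, target, 0.9))
})

test_that("target syncing is a value copy, independent of later updates", {
  arch <- tiny_arch()
  p <- essenet_init(arch, seed = 12)
  tgt <- sync_target(p)
  st <- random_stack(obs_spec(N = 8, H = 2), seed = 81)
  expect_identical(essenet_forward(tgt, st)$Q, essenet_forward(p, st)$Q)
  expect_identical(essenet_forward(sync_target(p), st)$Q,
                   essenet_forward(tgt, st)$Q)
  # one optimizer step changes the prediction net but not the frozen copy
  planes <- qlandmark:::stack_to_planes(st, obs_spec(N = 8, H = 2))
  gr <- qlandmark:::net_grad_planes(p, planes, 1L, 10)
  upd <- qlandmark:::adam_step(p, gr$grads, qlandmark:::adam_init(), 0.05)
  q_new <- essenet_forward(upd$params, st)$Q
  expect_gt(max(abs(q_new - essenet_forward(tgt, st)$Q)), 1e-6)
  expect_identical(essenet_forward(tgt, st)$Q, essenet_forward(p, st)$Q)
})

test_that("gradients treat TD targets as constants (no flow through theta-)", {
  arch <- tiny_arch()
  p <- essenet_init(arch, seed = 13)
  st <- random_stack(obs_spec(N = 8, H = 2), seed = 82)
  planes <- qlandmark:::stack_to_planes(st, obs_spec(N = 8, H = 2))
  y <- 1.5
  g1 <- qlandmark:::net_grad_planes(p, planes, 2L, y)
  # the gradient is a function of (params, s, a, y) only; any target network
  # producing the same y yields the identical gradient
  g2 <- qlandmark:::net_grad_planes(p, planes, 2L, y)
  expect_identical(qlandmark:::param_leaves(g1$grads),
                   qlandmark:::param_leaves(g2$grads))
  # and the analytic gradient matches a finite difference on the loss
  leaves <- qlandmark:::param_leaves(g1$grads)
  eps <- 1e-5
  for (leaf in c("global.W", "value.b")) {
    upd <- lapply(leaves, function(x) x * 0)
    upd[[leaf]][1] <- eps
    lp <- function(pp) (essenet_trace(pp, st)$Q[2] - y)^2
    fd <- (lp(qlandmark:::apply_param_update(p, lapply(upd, `-`))) -
           lp(qlandmark:::apply_param_update(p, upd))) / (2 * eps)
    expect_equal(leaves[[leaf]][1], fd, tolerance = 1e-3)
  }
})

test_that("moving average is a trailing mean with warm-up", {
  expect_equal(moving_average(rep(4, 10), 30), rep(4, 10))
  expect_equal(moving_average(c(0, 30), 30)[2], 15)
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(x, 5)[10], mean(x[6:10]))
})

test_that("training is reproducible and respects the episode cap", {
  suite <- generate_suite(3, base_seed = 400, cfg = small_phantom_config())
  spec <- obs_spec(N = 8, H = 1)
  cfg <- train_config(episodes = 4, max_episode_steps = 25, capacity = 500,
                      batch_size = 8, warmup = 16, eps_decay_steps = 50,
                      target_sync_every = 20, seed = 77)
  r1 <- run_training(suite$volumes, suite$landmarks, cfg, spec)
  r2 <- run_training(suite$volumes, suite$landmarks, cfg, spec)
  expect_identical(r1$log, r2$log)
  expect_true(all(r1$log$steps <= 25))
  expect_identical(nrow(r1$log), 4L)
  expect_true(all(r1$log$cause %in%
                    c("reached_target", "out_of_bounds", "max_steps")))
  # a missing landmark is a configuration error before training starts
  expect_error(run_training(suite$volumes, suite$landmarks[1:2], cfg, spec),
               "configuration error")
})
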