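test_that("the annealed learning rate follows alpha0 / (1 + visits)", {
  expect_equal(anneal_alpha(0, 0.5), 0.5)
  expect_equal(anneal_alpha(9, 0.5), 0.05)
  a <- anneal_alpha(0:100, 0.3)
  expect_true(all(diff(a) < 0))
  expect_lt(anneal_alpha(1e6, 0.5), 1e-6)
})

test_that("epsilon-greedy selection has the right exploration frequencies", {
  q <- q_table(n_states = 3, n_actions = 4)
  q$q[1, ] <- c(0, 0, 1, 0)
  # greedy limit: always the argmax
  p0 <- agent_params(epsilon = 0)
  set.seed(1)
  expect_true(all(replicate(200, select_action(q, 1, p0)) == 3))
  # full exploration: each non-argmax action about 1/3 of the time
  p1 <- agent_params(epsilon = 1)
  set.seed(2)
  draws <- replicate(3e4, select_action(q, 1, p1))
  expect_false(any(draws == 3))
  freq <- table(factor(draws, levels = 1:4)) / 3e4
  ci <- qbinom(c(0.0005, 0.9995), 3e4, 1 / 3) / 3e4
  for (a in c(1, 2, 4)) {
    expect_gte(freq[[a]], ci[1])
    expect_lte(freq[[a]], ci[2])
  }
  # all-equal row: uniform over the 4 actions regardless of epsilon
  set.seed(3)
  draws <- replicate(3e4, select_action(q, 2, agent_params(epsilon = 0.05)))
  freq <- table(factor(draws, levels = 1:4)) / 3e4
  ci <- qbinom(c(0.0005, 0.9995), 3e4, 1 / 4) / 3e4
  for (a in 1:4) {
    expect_gte(freq[[a]], ci[1])
    expect_lte(freq[[a]], ci[2])
  }
})

test_that("a single terminal update moves Q by alpha * delta", {
  p <- agent_params(epsilon = 0, lambda_trace = 0, gamma = 1, alpha0 = 0.5)
  q <- q_table(n_states = 3, n_actions = 4)
  q <- sarsa_update(q, s = 2, a = 1, r = 1, s2 = 2, a2 = 1,
                    terminal = TRUE, params = p)
  expect_equal(q$q[2, 1], 0.5)
  expect_equal(sum(q$q != 0), 1)
  expect_equal(q$visits[2, 1], 1L)
  # zero TD error leaves the table untouched
  q2 <- sarsa_update(q, s = 1, a = 2, r = 0, s2 = 1, a2 = 2,
                     terminal = FALSE, params = p)
  expect_equal(q2$q, q$q)
})

test_that("updates match a hand-rolled reference on a scripted 3-state chain", {
  p <- agent_params(epsilon = 0.1, lambda_trace = 0.7, gamma = 0.9,
                    alpha0 = 0.4)
  script <- data.frame(
    s  = c(1, 2, 3, 1, 2, 1, 3, 2, 1, 2),
    a  = c(1, 2, 1, 2, 1, 1, 2, 2, 1, 1),
    r  = c(0, 0, 1, 0, -0.2, 0, 1, 0, 0.5, -0.2),
    s2 = c(2, 3, 1, 2, 1, 3, 2, 1, 2, 3),
    a2 = c(2, 1, 2, 1, 1, 2, 2, 1, 1, 2),
    terminal = c(F, F, T, F, F, F, T, F, F, T))

  q <- q_table(n_states = 3, n_actions = 2)
  # independent reference: explicit loops over every table entry
  Qr <- matrix(0, 3, 2); Er <- matrix(0, 3, 2); Vr <- matrix(0, 3, 2)
  for (k in seq_len(nrow(script))) {
    tr <- script[k, ]
    q <- sarsa_update(q, tr$s, tr$a, tr$r, tr$s2, tr$a2, tr$terminal, p)
    target <- if (tr$terminal) 0 else Qr[tr$s2, tr$a2]
    delta <- tr$r + p$gamma * target - Qr[tr$s, tr$a]
    Er[tr$s, tr$a] <- 1
    for (i in 1:3) for (j in 1:2) {
      Qr[i, j] <- Qr[i, j] + p$alpha0 / (1 + Vr[i, j]) * delta * Er[i, j]
      Er[i, j] <- Er[i, j] * p$gamma * p$lambda_trace
    }
    Vr[tr$s, tr$a] <- Vr[tr$s, tr$a] + 1
  }
  expect_equal(q$q, Qr, tolerance = 1e-12)
  expect_equal(q$visits, Vr, ignore_attr = TRUE)
})

test_that("accumulating traces add rather than replace", {
  p <- agent_params(lambda_trace = 0.5, gamma = 1,
                    trace_kind = "accumulating")
  q <- q_table(n_states = 2, n_actions = 2)
  q <- sarsa_update(q, 1, 1, 0, 2, 1, FALSE, p)
  q <- sarsa_update(q, 1, 1, 0, 2, 1, FALSE, p)
  expect_equal(q$trace[1, 1], (1 * 0.5 + 1) * 0.5)
})

test_that("the compiled trainer replays exactly through sarsa_update", {
  set.seed(7)
  run <- run_training(n_steps = 1500, accuracy = 0.8, seed = 7,
                      log_transitions = TRUE)
  tr <- run$transitions
  q <- q_table()
  p <- agent_params()
  for (k in seq_len(nrow(tr))) {
    if (tr$terminal[k]) {
      q <- sarsa_update(q, tr$s[k], tr$a[k], tr$r[k], tr$s[k], tr$a[k],
                        terminal = TRUE, params = p)
    } else {
      q <- sarsa_update(q, tr$s[k], tr$a[k], tr$r[k], tr$s2[k], tr$a2[k],
                        params = p)
    }
    if (tr$reset_after[k]) q$trace[] <- 0
  }
  expect_lt(max(abs(q$q - run$q$q)), 1e-8)
  expect_equal(q$visits, run$q$visits, ignore_attr = TRUE)
  # trial log is consistent with the transition log (the log may end with
  # a partial episode that the trial table does not count)
  expect_equal(sum(run$trials$steps), max(which(tr$reset_after)))
  expect_equal(sum(tr$terminal), sum(!run$trials$truncated))
})

test_that("run_episode with a perfect channel delivers the true reward", {
  set.seed(11)
  env <- rake_env()
  q <- q_table()
  out <- run_episode(env, q, channel = reward_channel(1.0))
  expect_equal(out$record$delivered_reward,
               out$record$true_reward)
  expect_false(is.na(out$record$steps))
  # number of updates equals the number of steps: visit counts sum to steps
  expect_equal(sum(out$q$visits), out$record$steps)
})

test_that("training with a perfect channel converges to reliable success", {
  run <- run_training(n_steps = 50000, accuracy = 1.0, seed = 3)
  conv <- detect_convergence(run$trials$true_success)
  expect_true(conv$converged)
  post <- run$trials$true_success[conv$trial:nrow(run$trials)]
  expect_gt(mean(post), 0.95)
  # the greedy policy from reset reaches the front edge
  env <- rake_env()
  s <- rake_reset(env)
  greedy <- agent_params(epsilon = 0)
  set.seed(4)
  for (k in 1:100) {
    a <- select_action(run$q, state_index(s[1], s[2], s[3]), greedy)
    out <- rake_step(s, a, env)
    if (out$terminal) break
    s <- out$state
  }
  expect_true(out$terminal)
  expect_equal(out$reward, 1.0)
})

test_that("training runs are bit-identical for identical seeds", {
  a <- run_training(n_steps = 5000, accuracy = 0.7, seed = 21)
  b <- run_training(n_steps = 5000, accuracy = 0.7, seed = 21)
  expect_identical(a$trials, b$trials)
  expect_identical(a$q$q, b$q$q)
  c <- run_training(n_steps = 5000, accuracy = 0.7, seed = 22)
  expect_false(identical(a$trials, c$trials))
})

test_that("annealing stabilizes the value function over training", {
  run <- run_training(n_steps = 20000, accuracy = 0.75, seed = 5,
                      log_transitions = TRUE)
  tr <- run$transitions
  # reconstruct Q(s0, a) over time for the start state via replay
  s0 <- state_index(4, 0, 3)
  q <- q_table()
  p <- agent_params()
  snap <- numeric(0)
  for (k in seq_len(nrow(tr))) {
    if (tr$terminal[k]) {
      q <- sarsa_update(q, tr$s[k], tr$a[k], tr$r[k], tr$s[k], tr$a[k],
                        terminal = TRUE, params = p)
    } else {
      q <- sarsa_update(q, tr$s[k], tr$a[k], tr$r[k], tr$s2[k], tr$a2[k],
                        params = p)
    }
    if (tr$reset_after[k]) {
      q$trace[] <- 0
      snap <- c(snap, max(q$q[s0, ]))
    }
  }
  n <- length(snap)
  early <- snap[seq_len(ceiling(n / 10))]
  late <- snap[(n - ceiling(n / 10)):n]
  expect_lt(var(late), var(early))
})
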