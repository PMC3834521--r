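test_that("initialisation is deterministic and respects its contract", {
  cfg <- tiny_net_config()
  n1 <- init_network(cfg)
  n2 <- init_network(cfg)
  expect_identical(n1$w, n2$w)
  n3 <- init_network(tiny_net_config(seed = 43L))
  expect_false(identical(n1$w$w_ah, n3$w$w_ah))
  for (nm in c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr")) {
    expect_true(all(abs(n1$w[[nm]]) <= cfg$init_range))
  }
  expect_equal(n1$w$b_h, -2)
  expect_equal(n1$w$b_a, numeric(cfg$n_first_role))
})

test_that("zero-weight settling converges to the logistic of the bias", {
  cfg <- tiny_net_config(n_ticks = 60L)
  net <- init_network(cfg)
  for (nm in c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr")) {
    net$w[[nm]][] <- 0
  }
  tr <- run_settle(net, clamps = list(A = c(1, 0)))
  expect_equal(tr$H[61, ], rep(1 / (1 + exp(2)), 3), tolerance = 1e-10)
  # visible unclamped pools sit at logistic(0) = 0.5 throughout
  expect_true(all(abs(tr$B - 0.5) < 1e-12))
})

test_that("clamped pools are held fixed and activations stay in [0, 1]", {
  net <- init_network(tiny_net_config())
  clampA <- c(1, 0)
  relp <- c(1, 0, 1, 0)
  tr <- run_settle(net, clamps = list(A = clampA, R = relp))
  expect_true(all(apply(tr$A, 1, identical, clampA)))
  expect_true(all(apply(tr$R, 1, function(r) all(r == relp))))
  for (p in names(tr)) {
    expect_true(all(tr[[p]] >= 0 & tr[[p]] <= 1))
  }
  expect_error(run_settle(net, clamps = list(Q = 1)),
               class = "analogynet_invalid_config")
  expect_error(run_settle(net, clamps = list(A = c(2, 0))),
               class = "analogynet_invalid_config")
})

test_that("BPTT loss matches an independent scalar-level settle", {
  net <- init_network(tiny_net_config())
  relp <- c(1, 0, 1, 0)
  for (combo in 0:2) {
    g <- analogynet:::cpp_bptt_grad(net$w, 0L, 1L, relp, combo,
                                    net$cfg$lambda, net$cfg$n_ticks,
                                    net$cfg$target_ticks, net$cfg$target_margin,
                                    net$cfg$readout_margin)
    expect_equal(g$loss, reference_trial_loss(net, 0L, 1L, relp, combo),
                 tolerance = 1e-10)
  }
})

test_that("BPTT gradients match central finite differences to 1e-4", {
  # 2 + 2 + 4 + 3 = 11 units, well under the oracle's tractable size
  net <- init_network(tiny_net_config())
  relp <- c(1, 0, 1, 0)
  for (combo in 0:2) {
    g <- analogynet:::cpp_bptt_grad(net$w, 0L, 1L, relp, combo,
                                    net$cfg$lambda, net$cfg$n_ticks,
                                    net$cfg$target_ticks, net$cfg$target_margin,
                                    net$cfg$readout_margin)
    fd <- reference_fd_grads(net, 0L, 1L, relp, combo)
    for (nm in names(fd)) {
      an <- as.numeric(g$grads[[nm]])
      ref <- as.numeric(fd[[nm]])
      live <- abs(ref) > 1e-8 | abs(an) > 1e-8
      if (any(live)) {
        rel_err <- abs(an - ref)[live] / pmax(abs(ref[live]), 1e-6)
        expect_lt(max(rel_err), 1e-4)
      }
    }
  }
})

test_that("a zero learning rate leaves weights untouched", {
  net <- init_network(tiny_net_config())
  trial <- list(item1 = 1, item2 = 2, combo = "AB",
                rel_pattern = c(1, 0, 1, 0))
  res <- bptt_update(net, trial, lr = 0)
  expect_identical(res$network$w, net$w)
  expect_gt(res$loss, 0)
})

test_that("repeated updates on one trial drive the loss down", {
  net <- init_network(tiny_net_config())
  trial <- list(item1 = 1, item2 = 2, combo = "AB",
                rel_pattern = c(1, 0, 1, 0))
  losses <- numeric(100)
  for (k in 1:100) {
    res <- bptt_update(net, trial, lr = 0.2)
    net <- res$network
    losses[k] <- res$loss
  }
  expect_lt(losses[100], 0.1 * losses[1])
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("training is reproducible and spares the hidden bias", {
  env <- small_env(seed = 21)
  cfg <- network_config_for(env, seed = 5, n_hidden = 16L)
  n1 <- train_network(init_network(cfg), env, epochs = 3, seed = 99)
  n2 <- train_network(init_network(cfg), env, epochs = 3, seed = 99)
  expect_identical(n1$w, n2$w)
  expect_equal(n1$w$b_h, cfg$hidden_bias)
  expect_false(identical(n1$w$w_ah, init_network(cfg)$w$w_ah))
  expect_equal(nrow(n1$history), 3)
  # chunked training equals one straight run
  n3 <- train_network(init_network(cfg), env, epochs = 2, seed = 99,
                      eval_every = 10)
  n3 <- train_network(n3, env, epochs = 1, seed = 99, eval_every = 10)
  expect_equal(n3$w, n1$w, tolerance = 1e-12)
})

test_that("training completes trained propositions in the relation pool", {
  env <- small_env(seed = 31)
  net <- init_network(network_config_for(env, seed = 6))
  net <- train_network(net, env, epochs = 60, seed = 17)
  losses <- net$history$mean_loss
  expect_lt(losses[length(losses)], losses[1] / 2)
  # A,B clamped for a trained proposition: final R activation nearest (by
  # cosine) to that proposition's own relation prototype
  p <- env$propositions[env$propositions$freq == 9, ][1, ]
  tr <- run_settle(net, clamps = list(
    A = one_hot_vec(env$n_first_role, p$item1),
    B = one_hot_vec(env$n_second_role, p$item2)))
  rfinal <- tr$R[nrow(tr$R), ]
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  own <- env$instances$meta$prototype_id[p$rel]
  sims <- vapply(seq_len(8), function(q) {
    cosine(rfinal, env$protoset$patterns[q, ])
  }, numeric(1))
  expect_equal(which.max(sims), own)
})
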