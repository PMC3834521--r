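test_that("frontal lesion changes exactly one scalar", {
  env <- small_env(seed = 51)
  net <- train_network(init_network(network_config_for(env, seed = 14)),
                       env, epochs = 5, seed = 7)
  twin <- build_twin(net)
  lesioned <- frontal_lesion(twin, lesion_spec("frontal"))
  expect_equal(lesioned$h1_bias, -6.5)
  expect_equal(lesioned$network$w$b_h, -2)
  checksum <- function(tw) sum(vapply(
    tw$network$w[c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr")],
    sum, numeric(1)))
  expect_identical(checksum(lesioned), checksum(twin))
  expect_error(frontal_lesion(net), class = "analogynet_invalid_config")
})

test_that("an identity frontal lesion leaves behaviour unchanged", {
  env <- small_env(seed = 51)
  net <- train_network(init_network(network_config_for(env, seed = 14)),
                       env, epochs = 5, seed = 7)
  twin <- build_twin(net)
  identity_lesion <- frontal_lesion(twin, lesion_spec("frontal",
                                                      frontal_bias = -2))
  res0 <- probe_questions(twin, env$questions)
  res1 <- probe_questions(identity_lesion, env$questions)
  expect_equal(res1$echo_d1, res0$echo_d1, tolerance = 1e-14)
  expect_equal(res1$echo_d2, res0$echo_d2, tolerance = 1e-14)
})

test_that("a frontal lesion suppresses H1 activation", {
  env <- small_env(seed = 52)
  net <- train_network(init_network(network_config_for(env, seed = 15)),
                       env, epochs = 20, seed = 8)
  q <- env$questions[1, ]
  control <- twin_settle(build_twin(net), q$a, q$b, q$c, q$d1)
  lesioned <- twin_settle(frontal_lesion(build_twin(net)),
                          q$a, q$b, q$c, q$d1)
  expect_lt(mean(lesioned$H1[nrow(lesioned$H1), ]),
            mean(control$H1[nrow(control$H1), ]))
  # H2 dynamics receive the lesion only indirectly (through the shared R
  # pool), not through their own bias
  expect_equal(lesioned$H2[2, ], control$H2[2, ], tolerance = 1e-12)
})

test_that("temporal lesion removes the expected fraction of connections", {
  env <- small_env(seed = 53)
  net <- init_network(network_config_for(env, seed = 16))
  res <- temporal_lesion(net, lesion_spec("temporal", p_remove = 0.42,
                                          seed = 5))
  n_total <- sum(vapply(res$mask, length, numeric(1)))
  n_removed <- sum(vapply(res$mask, function(m) sum(m == 0), numeric(1)))
  sd3 <- 3 * sqrt(n_total * 0.42 * 0.58)
  expect_lt(abs(n_removed - 0.42 * n_total), sd3)
  # zeroed entries are exactly the masked ones; biases untouched
  for (nm in names(res$mask)) {
    expect_true(all(res$network$w[[nm]][res$mask[[nm]] == 0] == 0))
    expect_equal(res$network$w[[nm]][res$mask[[nm]] == 1],
                 net$w[[nm]][res$mask[[nm]] == 1])
  }
  expect_identical(res$network$w$b_r, net$w$b_r)
  expect_identical(res$network$w$b_h, net$w$b_h)
})

test_that("temporal lesion edge cases behave as limits", {
  env <- small_env(seed = 53)
  net <- init_network(network_config_for(env, seed = 16))
  none <- temporal_lesion(net, lesion_spec("temporal", p_remove = 0))
  expect_identical(none$network$w, net$w)
  expect_true(all(vapply(none$mask, function(m) all(m == 1), logical(1))))
  all_gone <- temporal_lesion(net, lesion_spec("temporal", p_remove = 1))
  expect_true(all(vapply(
    all_gone$network$w[c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr")],
    function(m) all(m == 0), logical(1))))
  # bias-only dynamics: every echo trial collapses to the same value
  twin <- build_twin(all_gone$network)
  q <- env$questions[1:6, ]
  e <- echo_trial(twin, q$a, q$b, q$c, q$d1)
  expect_equal(diff(range(e)), 0, tolerance = 1e-12)
})

test_that("the lesion mask is mirrored across the twin halves", {
  env <- small_env(seed = 54)
  net <- train_network(init_network(network_config_for(env, seed = 17)),
                       env, epochs = 5, seed = 9)
  twin <- temporal_lesion(build_twin(net),
                          lesion_spec("temporal", p_remove = 0.5, seed = 3))
  p <- env$propositions[1, ]
  # identical inputs on both halves settle identically under the lesion,
  # which can only happen if both halves see the same removal pattern
  tr <- twin_settle(twin, p$item1, p$item2, p$item1, p$item2,
                    probe_config(10, 1))
  expect_equal(tr$H1[1:11, ], tr$H2[1:11, ], tolerance = 1e-12)
  # and lesioned networks refuse further training
  expect_error(train_network(twin$network, env, epochs = 1),
               class = "analogynet_invalid_config")
})

test_that("independent draws give different masks, same seed the same mask", {
  env <- small_env(seed = 55)
  net <- init_network(network_config_for(env, seed = 18))
  m1 <- temporal_lesion(net, lesion_spec("temporal", seed = 1))$mask
  m2 <- temporal_lesion(net, lesion_spec("temporal", seed = 2))$mask
  m1b <- temporal_lesion(net, lesion_spec("temporal", seed = 1))$mask
  expect_identical(m1, m1b)
  expect_false(identical(m1, m2))
})

test_that("lesion specs validate their parameters", {
  expect_error(lesion_spec("temporal", p_remove = 1.2),
               class = "analogynet_invalid_config")
  expect_error(lesion_spec("sideways"))
})
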