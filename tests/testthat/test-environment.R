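test_that("the default environment has the expected structure", {
  env <- build_environment(environment_config(seed = 2))
  expect_equal(nrow(env$cells), 40)
  expect_equal(nrow(env$questions), 120)
  expect_equal(env$n_first_role, 40)
  expect_equal(env$n_second_role, 40)
  expect_equal(nrow(env$propositions), 200)
  expect_equal(sum(env$propositions$freq), 19 * 40)
})

test_that("item training frequency is equal within each role class", {
  env <- build_environment(environment_config(seed = 2))
  p <- env$propositions
  first <- tapply(p$freq, p$item1, sum)
  second <- tapply(p$freq, p$item2, sum)
  expect_length(first, 40)
  expect_length(second, 40)
  expect_true(all(first == 19))
  expect_true(all(second == 19))
})

test_that("no item pair carries two different relations", {
  env <- build_environment(environment_config(seed = 13))
  p <- env$propositions
  expect_equal(anyDuplicated(paste(p$item1, p$item2)), 0)
})

test_that("prototype roles rotate so every 8-cell window is balanced", {
  env <- build_environment(environment_config(seed = 2))
  roles <- env$cells[, c("proto_target", "proto_weak", "proto_moderate",
                         "proto_strong")]
  for (start in 1:(40 - 7)) {
    win <- roles[start:(start + 7), ]
    for (col in names(win)) {
      expect_setequal(win[[col]], 1:8)
    }
  }
  # equal total training frequency per prototype
  meta <- env$instances$meta
  p <- env$propositions
  proto <- meta$prototype_id[p$rel]
  tot <- tapply(p$freq, proto, sum)
  expect_true(all(tot == tot[1]))
})

test_that("cells satisfy the relational-structure invariants", {
  env <- build_environment(environment_config(seed = 7))
  meta <- env$instances$meta
  pid <- function(i) meta$prototype_id[i]
  for (k in seq_len(nrow(env$cells))) {
    cell <- env$cells[k, ]
    # source and target share a prototype with disjoint off-pairs
    expect_equal(pid(cell$rel_source), pid(cell$rel_target))
    off_s <- meta$off_pair[[cell$rel_source]]
    off_t <- meta$off_pair[[cell$rel_target]]
    expect_length(intersect(off_s, off_t), 0)
    # foils from three distinct other prototypes
    foils <- pid(c(cell$rel_weak, cell$rel_moderate, cell$rel_strong))
    expect_length(unique(foils), 3)
    expect_false(pid(cell$rel_target) %in% foils)
    # foil propositions share the C item; one second-role item per role
    expect_length(unique(c(cell$b, cell$d1, cell$d2, cell$d3, cell$d4)), 5)
    expect_false(cell$a == cell$c)
  }
})

test_that("each cell yields one question of each SFI type", {
  env <- build_environment(environment_config(seed = 7))
  q <- questions_from_cell(env, 5)
  expect_equal(nrow(q), 3)
  expect_setequal(q$sfi_label, c("positive", "zero", "negative"))
  expect_equal(length(unique(q$a)), 1)
  expect_equal(length(unique(q$d1)), 1)
  expect_equal(q$d1[1], env$cells$d1[env$cells$cell == 5])
  # label definition: foil frequency below/equal/above the target's
  cfg <- env$cfg
  cell <- env$cells[env$cells$cell == 5, ]
  foil_freq <- c(cfg$freq_weak, cfg$freq_moderate, cfg$freq_strong)
  names(foil_freq) <- c("positive", "zero", "negative")
  expect_equal(q$d2, c(cell$d2, cell$d3, cell$d4))
  expect_true(foil_freq["positive"] < cfg$freq_moderate)
  expect_true(foil_freq["zero"] == cfg$freq_moderate)
  expect_true(foil_freq["negative"] > cfg$freq_moderate)
  # full bank covers every cell
  expect_equal(nrow(env$questions), 3 * nrow(env$cells))
  expect_equal(unname(table(env$questions$sfi_label)["negative"]),
               nrow(env$cells))
})

test_that("a single-group environment is the minimal 5-cell design", {
  env <- build_environment(environment_config(n_groups = 1, seed = 3))
  expect_equal(nrow(env$cells), 5)
  expect_equal(env$n_first_role, 5)
  expect_equal(env$n_second_role, 5)
  expect_equal(nrow(env$questions), 15)
})

test_that("expand_epoch conserves the trial multiset", {
  env <- build_environment(environment_config(n_groups = 2, seed = 4))
  trials <- expand_epoch(env, seed = 1)
  expect_equal(nrow(trials), 3 * sum(env$propositions$freq))
  expect_equal(as.vector(table(trials$combo)),
               rep(sum(env$propositions$freq), 3))
  # each proposition contributes freq trials per combination
  p1 <- env$propositions[1, ]
  n1 <- sum(trials$item1 == p1$item1 & trials$item2 == p1$item2 &
              trials$combo == "AB")
  expect_equal(n1, p1$freq)
  # target pool is the one absent from the input combination
  expect_true(all(trials$target[trials$combo == "AB"] == "R"))
  expect_true(all(trials$target[trials$combo == "AR"] == "B"))
  expect_true(all(trials$target[trials$combo == "BR"] == "A"))
  # seeds permute but do not change the multiset
  t2 <- expand_epoch(env, seed = 2)
  key <- function(x) sort(paste(x$item1, x$rel, x$item2, x$combo))
  expect_equal(key(trials), key(t2))
  expect_false(identical(paste(trials$item1, trials$combo),
                         paste(t2$item1, t2$combo)))
})

test_that("environment generation is deterministic given the seed", {
  e1 <- build_environment(environment_config(n_groups = 2, seed = 9))
  e2 <- build_environment(environment_config(n_groups = 2, seed = 9))
  expect_identical(e1$cells, e2$cells)
  expect_identical(e1$instances$patterns, e2$instances$patterns)
})

test_that("frequency ordering is enforced", {
  expect_error(environment_config(freq_weak = 3, freq_moderate = 3),
               class = "analogynet_invalid_config")
  expect_error(environment_config(freq_strong = 2),
               class = "analogynet_invalid_config")
})
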