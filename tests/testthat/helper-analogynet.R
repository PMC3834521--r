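# Shared fixtures and independent oracles, built in code.

one_hot_vec <- function(n, i) replace(numeric(n), i, 1)

withr_local_tempfile <- function(ext = ".json") tempfile(fileext = ext)

tiny_net_config <- function(...) {
  args <- utils::modifyList(
    list(n_first_role = 2L, n_second_role = 2L, n_relation = 4L,
         n_hidden = 3L, n_ticks = 8L, target_ticks = 3L, seed = 42L),
    list(...))
  do.call(network_config, args)
}

small_env <- function(seed = 1L, n_groups = 2L) {
  build_environment(environment_config(n_groups = n_groups, seed = seed))
}

# Independent reference: settle the four pools by explicit scalar-level
# recursion and return the cross-entropy completion loss. Written against the
# dynamics definition, not against the package's settle/BPTT code paths.
reference_trial_loss <- function(net, a_idx, b_idx, rel_pattern, combo) {
  cfg <- net$cfg
  w <- net$w
  lam <- cfg$lambda
  sg <- function(x) 1 / (1 + exp(-x))
  act <- list(
    A = if (combo %in% c(0L, 1L)) {
      replace(numeric(cfg$n_first_role), a_idx + 1L, 1)
    } else sg(w$b_a),
    B = if (combo %in% c(0L, 2L)) {
      replace(numeric(cfg$n_second_role), b_idx + 1L, 1)
    } else sg(w$b_b),
    R = if (combo %in% c(1L, 2L)) rel_pattern else sg(w$b_r),
    H = rep(sg(w$b_h), cfg$n_hidden))
  target <- c("R", "B", "A")[combo + 1L]
  y <- switch(target,
              R = rel_pattern,
              B = replace(numeric(cfg$n_second_role), b_idx + 1L, 1),
              A = replace(numeric(cfg$n_first_role), a_idx + 1L, 1))
  clamped <- setdiff(c("A", "B", "R"), target)
  loss <- 0
  for (t in seq_len(cfg$n_ticks)) {
    nets <- list(
      A = colSums(w$w_ha * act$H) + w$b_a,
      B = colSums(w$w_hb * act$H) + w$b_b,
      R = colSums(w$w_hr * act$H) + w$b_r,
      H = colSums(w$w_ah * act$A) + colSums(w$w_bh * act$B) +
        colSums(w$w_rh * act$R) + w$b_h)
    for (p in c("A", "B", "R", "H")) {
      if (!(p %in% clamped)) {
        act[[p]] <- act[[p]] + lam * (sg(nets[[p]]) - act[[p]])
      }
    }
    if (t > cfg$n_ticks - cfg$target_ticks) {
      hinge_sq <- function(a, y, m) {
        d <- a - y
        sum(pmax(abs(d) - m, 0)^2)
      }
      loss <- loss + hinge_sq(act[[target]], y, cfg$target_margin)
      # readout loss on the clamped pools: the logistic of their
      # hidden-driven net input must reproduce the clamp pattern
      for (p in clamped) {
        loss <- loss + hinge_sq(sg(nets[[p]]), act[[p]], cfg$readout_margin)
      }
    }
  }
  loss
}

# Central finite differences of the reference loss with respect to every
# learnable parameter.
reference_fd_grads <- function(net, a_idx, b_idx, rel_pattern, combo,
                               h = 1e-5) {
  nms <- c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr", "b_a", "b_b", "b_r")
  out <- list()
  for (nm in nms) {
    g <- net$w[[nm]]
    g[] <- 0
    for (k in seq_along(g)) {
      up <- net; up$w[[nm]][k] <- up$w[[nm]][k] + h
      dn <- net; dn$w[[nm]][k] <- dn$w[[nm]][k] - h
      g[k] <- (reference_trial_loss(up, a_idx, b_idx, rel_pattern, combo) -
                 reference_trial_loss(dn, a_idx, b_idx, rel_pattern, combo)) /
        (2 * h)
    }
    out[[nm]] <- g
  }
  out
}
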