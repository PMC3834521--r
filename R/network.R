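#' Configure the triple-completion network
#'
#' Pools: localist first-role items (A), localist second-role items (B), a
#' distributed relation pool (R) and a hidden integrating pool (H), with
#' independent directional weight matrices in both directions between each
#' visible pool and H. Units are logistic; unclamped activations relax toward
#' the logistic of their net input with step size `lambda` per tick. The
#' hidden bias is a fixed shared scalar (default -2) that training never
#' updates; visible-pool biases are learned.
#'
#' @param n_first_role,n_second_role Sizes of the localist item pools.
#' @param n_relation Relation units.
#' @param n_hidden Hidden units.
#' @param hidden_bias Fixed shared hidden bias.
#' @param lr Learning rate for mini-batch gradient steps.
#' @param n_ticks Settling ticks per trial.
#' @param target_ticks Final ticks over which the completion loss applies.
#' @param target_margin Zero-error margin for the completed pool: a unit
#'   whose activation is within this distance of its target contributes no
#'   error or gradient, so training stops deepening an attractor once
#'   completion is reliable and activations stay graded.
#' @param readout_margin Zero-error margin for the clamped pools' readout
#'   (the logistic of their hidden-driven net input against the clamp).
#'   A larger value than `target_margin` keeps the self-supporting loop of
#'   a clamped item moderate relative to the completion pathway, preserving
#'   the graded echo differences the forced choice depends on.
#' @param lambda Activation step size in (0, 1].
#' @param init_range Half-width of the uniform weight initialisation.
#' @param batch_size Trials per weight update during training.
#' @param tie_weights Keep each visible-hidden projection pair symmetric
#'   (`W(H->X) = t(W(X->H))`), so settling is constraint satisfaction on a
#'   single consistent set of pairwise constraints. Recommended: mutual
#'   constraint between the two halves of the testing architecture relies on
#'   the same knowledge driving completion in both directions.
#' @param seed RNG seed for weight initialisation.
#' @return A `network_config` list.
#' @export
network_config <- function(n_first_role = 40L, n_second_role = 40L,
                           n_relation = 128L, n_hidden = 96L, hidden_bias = -2,
                           lr = 0.05, n_ticks = 20L, target_ticks = 5L,
                           target_margin = 0.1, readout_margin = 0.1,
                           lambda = 0.2,
                           init_range = 0.25, batch_size = 16L,
                           tie_weights = TRUE, seed = 1L) {
  check_counts(n_first_role = n_first_role, n_second_role = n_second_role,
               n_relation = n_relation, n_hidden = n_hidden,
               n_ticks = n_ticks, target_ticks = target_ticks,
               batch_size = batch_size)
  if (!(lambda > 0 && lambda <= 1)) {
    abort("lambda must be in (0, 1]", class = "analogynet_invalid_config")
  }
  if (target_ticks > n_ticks) {
    abort("target_ticks must not exceed n_ticks",
          class = "analogynet_invalid_config")
  }
  for (m in list(target_margin = target_margin,
                 readout_margin = readout_margin)) {
    if (!(is.numeric(m) && length(m) == 1 && m >= 0 && m < 0.5)) {
      abort("error margins must be in [0, 0.5)",
            class = "analogynet_invalid_config")
    }
  }
  structure(
    list(n_first_role = as.integer(n_first_role),
         n_second_role = as.integer(n_second_role),
         n_relation = as.integer(n_relation), n_hidden = as.integer(n_hidden),
         hidden_bias = hidden_bias, lr = lr, n_ticks = as.integer(n_ticks),
         target_ticks = as.integer(target_ticks),
         target_margin = target_margin, readout_margin = readout_margin,
         lambda = lambda,
         init_range = init_range, batch_size = as.integer(batch_size),
         tie_weights = isTRUE(tie_weights), seed = as.integer(seed)),
    class = "network_config")
}

#' Convenience: network configuration sized for an environment
#'
#' @param env An `analogy_environment`.
#' @param ... Overrides passed to [network_config()].
#' @export
network_config_for <- function(env, ...) {
  network_config(n_first_role = env$n_first_role,
                 n_second_role = env$n_second_role,
                 n_relation = env$cfg$relation$n_units, ...)
}

#' Initialise network weights
#'
#' Weights are drawn uniformly in `[-init_range, init_range]`; visible biases
#' start at 0 and the hidden bias at `cfg$hidden_bias`. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [network_config()].
#' @return An `analogy_network`.
#' @export
init_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  nA <- cfg$n_first_role; nB <- cfg$n_second_role
  nR <- cfg$n_relation; nH <- cfg$n_hidden
  w <- with_seed(cfg$seed, {
    rm_ <- function(nr, nc) {
      matrix(runif(nr * nc, -cfg$init_range, cfg$init_range), nr, nc)
    }
    list(w_ah = rm_(nA, nH), w_ha = rm_(nH, nA),
         w_bh = rm_(nB, nH), w_hb = rm_(nH, nB),
         w_rh = rm_(nR, nH), w_hr = rm_(nH, nR))
  })
  if (cfg$tie_weights) {
    w$w_ha <- t(w$w_ah)
    w$w_hb <- t(w$w_bh)
    w$w_hr <- t(w$w_rh)
  }
  structure(
    list(cfg = cfg,
         w = c(w, list(b_a = numeric(nA), b_b = numeric(nB), b_r = numeric(nR),
                       b_h = cfg$hidden_bias)),
         epochs_trained = 0L,
         history = tibble::tibble()),
    class = "analogy_network")
}

#' @export
print.analogy_network <- function(x, ...) {
  cat(sprintf(paste0(
    "<analogy_network> pools A=%d B=%d R=%d H=%d, hidden bias %.2f\n",
    "  trained %d epochs\n"),
    x$cfg$n_first_role, x$cfg$n_second_role, x$cfg$n_relation, x$cfg$n_hidden,
    x$w$b_h, x$epochs_trained))
  invisible(x)
}

pool_sizes <- function(net) {
  c(A = net$cfg$n_first_role, B = net$cfg$n_second_role,
    R = net$cfg$n_relation, H = net$cfg$n_hidden)
}

#' Run the settling dynamics with arbitrary clamps
#'
#' Unclamped units start at the logistic of their bias and follow
#' `a(t) = a(t-1) + lambda * (logistic(net(t)) - a(t-1))` with synchronous
#' updates; clamped pools are held at their clamp pattern throughout.
#'
#' @param net An `analogy_network`.
#' @param clamps Named list of clamp patterns; names among `"A"`, `"B"`,
#'   `"R"`, `"H"`, values in `[0, 1]` of the pool's size.
#' @param n_ticks Number of ticks (default `cfg$n_ticks`).
#' @return An `activation_trace`: list of `(n_ticks + 1) x size` matrices for
#'   pools A, B, R, H (row 1 is the initial state).
#' @export
run_settle <- function(net, clamps = list(), n_ticks = NULL) {
  stopifnot(inherits(net, "analogy_network"))
  n_ticks <- n_ticks %||% net$cfg$n_ticks
  sizes <- pool_sizes(net)
  bad <- setdiff(names(clamps), names(sizes))
  if (length(bad)) {
    abort(paste0("unknown pool in clamps: ", paste(bad, collapse = ", ")),
          class = "analogynet_invalid_config")
  }
  for (p in names(clamps)) {
    if (length(clamps[[p]]) != sizes[[p]] ||
        any(clamps[[p]] < 0 | clamps[[p]] > 1)) {
      abort(sprintf("clamp for pool %s must be %d values in [0, 1]",
                    p, sizes[[p]]),
            class = "analogynet_invalid_config")
    }
  }
  w <- net$w
  biases <- list(A = w$b_a, B = w$b_b, R = w$b_r, H = rep(w$b_h, sizes[["H"]]))
  act <- lapply(names(sizes), function(p) {
    if (p %in% names(clamps)) as.numeric(clamps[[p]]) else logistic(biases[[p]])
  })
  names(act) <- names(sizes)
  trace <- lapply(names(sizes), function(p) {
    m <- matrix(NA_real_, n_ticks + 1L, sizes[[p]])
    m[1L, ] <- act[[p]]
    m
  })
  names(trace) <- names(sizes)
  for (t in seq_len(n_ticks)) {
    nets <- list(
      A = drop(act$H %*% w$w_ha) + w$b_a,
      B = drop(act$H %*% w$w_hb) + w$b_b,
      R = drop(act$H %*% w$w_hr) + w$b_r,
      H = drop(act$A %*% w$w_ah + act$B %*% w$w_bh + act$R %*% w$w_rh) + w$b_h)
    for (p in names(sizes)) {
      if (!(p %in% names(clamps))) {
        act[[p]] <- act[[p]] + net$cfg$lambda * (logistic(nets[[p]]) - act[[p]])
      }
      trace[[p]][t + 1L, ] <- act[[p]]
    }
  }
  structure(trace, class = "activation_trace")
}

# Resolve a trial (row of expand_epoch() or a plain list) into the arguments
# the C++ gradient routine expects.
resolve_trial <- function(trial, env = NULL) {
  combo <- match(trial$combo, c("AB", "AR", "BR")) - 1L
  if (is.na(combo)) {
    abort("trial$combo must be one of AB, AR, BR",
          class = "analogynet_invalid_config")
  }
  rel_pattern <- if (!is.null(trial$rel_pattern)) {
    as.numeric(trial$rel_pattern)
  } else if (!is.null(env)) {
    as.numeric(env$instances$patterns[trial$rel, ])
  } else {
    abort("supply trial$rel_pattern or an environment to look up trial$rel",
          class = "analogynet_invalid_config")
  }
  list(a = as.integer(trial$item1) - 1L, b = as.integer(trial$item2) - 1L,
       rel = rel_pattern, combo = combo)
}

#' One backpropagation-through-time update on a single trial
#'
#' Unrolls the settling dynamics for `n_ticks`, applies cross-entropy loss on
#' the target pool over the final `target_ticks` ticks, backpropagates through
#' the unrolled dynamics and takes one gradient step of size `lr`. The hidden
#' bias receives no update.
#'
#' @param net An `analogy_network`.
#' @param trial A row of [expand_epoch()] (with `env` supplied) or a list with
#'   `item1`, `item2`, `combo` and `rel_pattern`.
#' @param env Environment used to look up the relation pattern.
#' @param lr Learning rate (default `cfg$lr`); `lr = 0` returns the loss with
#'   weights untouched.
#' @return List with the updated `network` and the trial `loss`.
#' @export
bptt_update <- function(net, trial, env = NULL, lr = net$cfg$lr) {
  stopifnot(inherits(net, "analogy_network"))
  tr <- resolve_trial(trial, env)
  res <- cpp_bptt_grad(net$w, tr$a, tr$b, tr$rel, tr$combo,
                       net$cfg$lambda, net$cfg$n_ticks, net$cfg$target_ticks,
                       net$cfg$target_margin, net$cfg$readout_margin)
  if (!is.finite(res$loss)) {
    abort("non-finite BPTT loss", class = "analogynet_numerical_error")
  }
  if (lr != 0) {
    for (nm in names(res$grads)) {
      net$w[[nm]] <- net$w[[nm]] - lr * res$grads[[nm]]
    }
  }
  list(network = net, loss = res$loss)
}

# Proposition table in the 0-based integer form the C++ trainer consumes.
prop_matrix <- function(env) {
  cbind(as.integer(env$propositions$item1) - 1L,
        as.integer(env$propositions$item2) - 1L,
        as.integer(env$propositions$rel) - 1L,
        as.integer(env$propositions$freq))
}

#' Train the network on an environment
#'
#' Each epoch presents every proposition's three input combinations, each
#' `freq` times, in a shuffled order derived from `seed` and the absolute
#' epoch index; weights are updated from mini-batch mean gradients. If
#' `questions` is supplied, analogy performance is evaluated with the twin
#' echo probe every `eval_every` epochs (and, optionally, before training).
#' Training in several calls is identical to one long call.
#'
#' @param net An `analogy_network` (fresh or partially trained).
#' @param env The `analogy_environment` to train on.
#' @param epochs Number of additional epochs.
#' @param questions Optional question tibble (see [question_bank()]).
#' @param eval_every Evaluation cadence in epochs.
#' @param probe A [probe_config()] for the evaluations.
#' @param seed Master seed for epoch shuffles (default `cfg$seed`).
#' @param eval_epoch0 Evaluate before the first epoch of this call?
#' @return The trained network; `$history` gains one row per epoch
#'   (`epoch`, `mean_loss`) with per-SFI accuracies on evaluated epochs.
#' @export
train_network <- function(net, env, epochs = 350L, questions = NULL,
                          eval_every = 10L, probe = probe_config(),
                          seed = net$cfg$seed, eval_epoch0 = TRUE) {
  stopifnot(inherits(net, "analogy_network"),
            inherits(env, "analogy_environment"))
  if (!is.null(net$lesion_mask)) {
    abort("lesioned networks are evaluated, not retrained",
          class = "analogynet_invalid_config")
  }
  check_counts(epochs = epochs, eval_every = eval_every)
  props <- prop_matrix(env)
  relpat <- env$instances$patterns
  cfg <- net$cfg

  history <- list()
  evals <- list()
  eval_now <- function(epoch) {
    acc <- evaluate_analogies(build_twin(net), questions, probe)
    evals[[length(evals) + 1L]] <<- tibble::tibble(
      epoch = epoch,
      accuracy_positive = acc$accuracy[acc$sfi_label == "positive"],
      accuracy_zero = acc$accuracy[acc$sfi_label == "zero"],
      accuracy_negative = acc$accuracy[acc$sfi_label == "negative"],
      accuracy_overall = acc$accuracy[acc$sfi_label == "overall"])
  }
  if (!is.null(questions) && eval_epoch0 && net$epochs_trained == 0L) {
    eval_now(0L)
  }

  done <- 0L
  while (done < epochs) {
    chunk <- min(eval_every - (net$epochs_trained %% eval_every),
                 epochs - done)
    res <- cpp_train_epochs(net$w, props, relpat, cfg$lr, cfg$lambda,
                            cfg$n_ticks, cfg$target_ticks, cfg$target_margin,
                            cfg$readout_margin, cfg$batch_size,
                            net$epochs_trained, chunk, as.double(seed),
                            cfg$tie_weights)
    net$w <- res$weights
    history[[length(history) + 1L]] <- tibble::tibble(
      epoch = net$epochs_trained + seq_len(chunk), mean_loss = res$mean_loss)
    net$epochs_trained <- net$epochs_trained + chunk
    done <- done + chunk
    if (!is.null(questions) && net$epochs_trained %% eval_every == 0L) {
      eval_now(net$epochs_trained)
    }
  }

  hist <- dplyr::bind_rows(history)
  if (length(evals)) {
    hist <- dplyr::full_join(hist, dplyr::bind_rows(evals), by = "epoch") |>
      dplyr::arrange(.data$epoch)
  }
  net$history <- dplyr::bind_rows(net$history, hist)
  net
}
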