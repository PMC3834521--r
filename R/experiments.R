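#' Simulation 1: the developmental relational shift
#'
#' Trains `n_networks` independently seeded networks, each on its own
#' independently generated default environment, and evaluates every analogy
#' question with the twin echo probe before training and every `eval_every`
#' epochs. Early in training, accuracy orders by SFI (positive > zero >
#' negative, the last below chance); with continued training all three
#' converge toward ceiling — the relational shift.
#'
#' @param n_networks Number of (environment, network) replicates.
#' @param epochs Training epochs per network.
#' @param eval_every Evaluation cadence in epochs.
#' @param seed Master seed; per-replicate environment and network seeds are
#'   derived from it.
#' @param env_config Function `(seed) -> environment_config`; defaults to the
#'   standard configuration.
#' @param net_config Function `(env, seed) -> network_config`; defaults to
#'   the standard configuration sized for the environment.
#' @param probe A [probe_config()].
#' @param progress Print per-network progress lines?
#' @return An `analogy_sim1` list: `records` (tidy per-network, per-epoch
#'   accuracies), `histories` (per-epoch losses), `networks`, `environments`.
#' @export
simulation1 <- function(n_networks = 5L, epochs = 350L, eval_every = 10L,
                        seed = 1L,
                        env_config = function(s) environment_config(seed = s),
                        net_config = function(env, s) network_config_for(env, seed = s),
                        probe = probe_config(), progress = FALSE) {
  check_counts(n_networks = n_networks, epochs = epochs,
               eval_every = eval_every)
  networks <- vector("list", n_networks)
  environments <- vector("list", n_networks)
  records <- vector("list", n_networks)
  histories <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    env <- build_environment(env_config(derive_seed(seed, 1L, i)))
    net <- init_network(net_config(env, derive_seed(seed, 2L, i)))
    net <- train_network(net, env, epochs = epochs,
                         questions = env$questions, eval_every = eval_every,
                         probe = probe, seed = derive_seed(seed, 3L, i))
    environments[[i]] <- env
    networks[[i]] <- net
    histories[[i]] <- dplyr::mutate(
      net$history[, c("epoch", "mean_loss")], network_id = i,
      .before = 1L) |> dplyr::filter(!is.na(.data$mean_loss))
    records[[i]] <- net$history |>
      dplyr::filter(!is.na(.data$accuracy_overall)) |>
      dplyr::transmute(network_id = i, epoch = .data$epoch,
                       condition = "control", draw = NA_integer_,
                       accuracy_positive = .data$accuracy_positive,
                       accuracy_zero = .data$accuracy_zero,
                       accuracy_negative = .data$accuracy_negative,
                       accuracy_overall = .data$accuracy_overall,
                       mean_loss = .data$mean_loss)
    if (progress) {
      message(sprintf("network %d/%d: final overall accuracy %.3f",
                      i, n_networks,
                      records[[i]]$accuracy_overall[nrow(records[[i]])]))
    }
  }
  structure(
    list(records = dplyr::bind_rows(records),
         histories = dplyr::bind_rows(histories),
         networks = networks, environments = environments,
         probe = probe, seed = seed),
    class = "analogy_sim1")
}

#' @export
print.analogy_sim1 <- function(x, ...) {
  fin <- developmental_curve(x)
  fin <- fin[fin$epoch == max(fin$epoch), ]
  cat(sprintf(paste0(
    "<analogy_sim1> %d networks, %d epochs\n",
    "  final accuracy: positive %.3f, zero %.3f, negative %.3f\n",
    "  negative-SFI sustained above chance from epoch %s\n"),
    length(x$networks), max(x$records$epoch),
    fin$accuracy[fin$sfi_label == "positive"],
    fin$accuracy[fin$sfi_label == "zero"],
    fin$accuracy[fin$sfi_label == "negative"],
    format(relational_shift_epoch(x))))
  invisible(x)
}

#' Mean developmental curve by SFI type
#'
#' @param x An `analogy_sim1` or its `records` tibble.
#' @return A tibble `epoch`, `sfi_label`, `accuracy` averaged over networks.
#' @export
developmental_curve <- function(x) {
  records <- if (inherits(x, "analogy_sim1")) x$records else x
  records |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(positive = mean(.data$accuracy_positive),
                     zero = mean(.data$accuracy_zero),
                     negative = mean(.data$accuracy_negative),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"epoch", names_to = "sfi_label",
                        values_to = "accuracy")
}

#' Epoch at which responding becomes relational
#'
#' The earliest sampled epoch at which mean negative-SFI accuracy exceeds
#' chance (0.5) and stays above it at every later sampled epoch.
#'
#' @param x An `analogy_sim1` or its `records` tibble.
#' @param chance Chance level.
#' @return The epoch, or `NA` if accuracy never stays above chance.
#' @export
relational_shift_epoch <- function(x, chance = 0.5) {
  curve <- developmental_curve(x)
  neg <- curve[curve$sfi_label == "negative", ]
  neg <- neg[order(neg$epoch), ]
  above <- neg$accuracy > chance
  sustained <- rev(cumprod(rev(above))) == 1
  if (!any(sustained)) return(NA_real_)
  neg$epoch[which(sustained)[1]]
}

#' Simulation 2: frontal and temporal lesions at end of training
#'
#' Evaluates each trained network of a [simulation1()] run under three
#' conditions: control (intact twin), frontal (H1 bias replaced, default
#' -6.5), and temporal (`n_draws` independent random connection-removal
#' draws at `p_remove`, default 0.42, giving `n_networks * n_draws` lesioned
#' networks).
#'
#' @param sim1 An `analogy_sim1` result (trained networks + environments).
#' @param frontal_bias Replacement H1 bias for the frontal condition.
#' @param p_remove Removal probability for the temporal condition.
#' @param n_draws Independent temporal lesion draws per network.
#' @param seed Master seed for the removal draws.
#' @param probe A [probe_config()]; defaults to the one used in `sim1`.
#' @return An `analogy_sim2` list: `records` (per network x condition x draw
#'   accuracies) and `summary` (condition means with the SFI effect
#'   positive - negative).
#' @export
simulation2 <- function(sim1, frontal_bias = -6.5, p_remove = 0.42,
                        n_draws = 5L, seed = 1L, probe = NULL) {
  stopifnot(inherits(sim1, "analogy_sim1"))
  if (!length(sim1$networks)) {
    abort("sim1 carries no trained networks", class = "analogynet_invalid_config")
  }
  probe <- probe %||% sim1$probe
  check_counts(n_draws = n_draws)
  rows <- list()
  add_row <- function(i, condition, draw, twin, questions) {
    acc <- evaluate_analogies(twin, questions, probe)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      network_id = i, condition = condition, draw = draw,
      accuracy_positive = acc$accuracy[acc$sfi_label == "positive"],
      accuracy_zero = acc$accuracy[acc$sfi_label == "zero"],
      accuracy_negative = acc$accuracy[acc$sfi_label == "negative"],
      accuracy_overall = acc$accuracy[acc$sfi_label == "overall"])
  }
  for (i in seq_along(sim1$networks)) {
    net <- sim1$networks[[i]]
    questions <- sim1$environments[[i]]$questions
    add_row(i, "control", NA_integer_, build_twin(net), questions)
    add_row(i, "frontal", NA_integer_,
            frontal_lesion(build_twin(net),
                           lesion_spec("frontal", frontal_bias = frontal_bias)),
            questions)
    for (j in seq_len(n_draws)) {
      spec <- lesion_spec("temporal", p_remove = p_remove,
                          seed = derive_seed(seed, 4L, i, j))
      add_row(i, "temporal", j, temporal_lesion(build_twin(net), spec),
              questions)
    }
  }
  records <- dplyr::bind_rows(rows)
  summary <- records |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("accuracy_"), mean),
                     .groups = "drop") |>
    dplyr::mutate(sfi_effect = .data$accuracy_positive - .data$accuracy_negative)
  structure(list(records = records, summary = summary,
                 frontal_bias = frontal_bias, p_remove = p_remove,
                 n_draws = n_draws),
            class = "analogy_sim2")
}

#' @export
print.analogy_sim2 <- function(x, ...) {
  cat("<analogy_sim2> condition means:\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}
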