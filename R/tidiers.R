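#' Tidy a relational-shift simulation
#'
#' @param x An `analogy_sim1`.
#' @param ... Unused.
#' @return The per-network, per-epoch record tibble.
#' @export
tidy.analogy_sim1 <- function(x, ...) x$records

#' Tidy a lesion simulation
#'
#' @param x An `analogy_sim2`.
#' @param ... Unused.
#' @return The per-network, per-condition record tibble.
#' @export
tidy.analogy_sim2 <- function(x, ...) x$records

#' Tidy an environment into its proposition table
#'
#' @param x An `analogy_environment`.
#' @param ... Unused.
#' @return The proposition tibble (cell, role, item1, rel, item2, freq).
#' @export
tidy.analogy_environment <- function(x, ...) x$propositions

#' One-row summary of a network
#'
#' @param x An `analogy_network`.
#' @param ... Unused.
#' @return A tibble with sizes, trained epochs and final mean training loss.
#' @export
glance.analogy_network <- function(x, ...) {
  loss <- if (nrow(x$history)) {
    h <- x$history[!is.na(x$history$mean_loss), ]
    if (nrow(h)) h$mean_loss[nrow(h)] else NA_real_
  } else NA_real_
  tibble::tibble(
    n_first_role = x$cfg$n_first_role, n_second_role = x$cfg$n_second_role,
    n_relation = x$cfg$n_relation, n_hidden = x$cfg$n_hidden,
    hidden_bias = x$w$b_h, epochs_trained = x$epochs_trained,
    final_mean_loss = loss)
}
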