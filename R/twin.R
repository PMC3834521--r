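#' Configure the echo probe
#'
#' @param phase1_ticks Ticks with the candidate D clamped (with A, B, C).
#' @param phase2_ticks Ticks after the D clamp is released (A, B, C stay
#'   clamped; D keeps its state and evolves freely).
#' @return A `probe_config` list.
#' @export
probe_config <- function(phase1_ticks = 12L, phase2_ticks = 24L) {
  check_counts(phase1_ticks = phase1_ticks, phase2_ticks = phase2_ticks)
  structure(list(phase1_ticks = as.integer(phase1_ticks),
                 phase2_ticks = as.integer(phase2_ticks)),
            class = "probe_config")
}

#' Build the twin testing architecture
#'
#' Two copies of the network (A,B,H1 and C,D,H2) share one set of weight
#' values and a common relation pool: A and C are read through the same
#' item-to-hidden matrices, B and D likewise, and both hidden pools project
#' to R through the same matrix. Because clamping A:B::A:B would then deliver
#' twice the trained net input to R, the hidden-to-relation contribution of
#' each half is scaled by `h_to_r_scale` (default 0.5); the R-to-hidden
#' direction keeps full strength.
#'
#' @param net A trained (or untrained) `analogy_network`.
#' @param h_to_r_scale Multiplier on each half's H-to-R drive.
#' @return A `twin_network`.
#' @export
build_twin <- function(net, h_to_r_scale = 0.5) {
  stopifnot(inherits(net, "analogy_network"))
  structure(
    list(network = net, h_to_r_scale = h_to_r_scale,
         h1_bias = net$w$b_h, lesion = NULL),
    class = "twin_network")
}

#' @export
print.twin_network <- function(x, ...) {
  cat(sprintf(
    "<twin_network> shared weights, H->R scale %.2f, H1 bias %.2f, H2 bias %.2f%s\n",
    x$h_to_r_scale, x$h1_bias, x$network$w$b_h,
    if (is.null(x$lesion)) "" else paste0(", lesion: ", x$lesion$kind)))
  invisible(x)
}

twin_weights <- function(twin) {
  w <- twin$network$w
  if (!is.null(twin$network$lesion_mask)) {
    for (nm in names(twin$network$lesion_mask)) {
      w[[nm]] <- w[[nm]] * twin$network$lesion_mask[[nm]]
    }
  }
  w
}

check_items <- function(twin, a, b, c, d) {
  nA <- twin$network$cfg$n_first_role
  nB <- twin$network$cfg$n_second_role
  ok <- all(a >= 1 & a <= nA) && all(c >= 1 & c <= nA) &&
    all(b >= 1 & b <= nB) && all(d >= 1 & d <= nB)
  if (!ok) abort("item id out of range", class = "analogynet_invalid_config")
}

#' Echo of one candidate completion
#'
#' Clamps a, b, c and the candidate d for `phase1_ticks`, releases the D clamp
#' (keeping its state) for `phase2_ticks` while a, b, c remain clamped, and
#' returns the final activation of d's unit: the echo.
#'
#' @param twin A [build_twin()] result.
#' @param a,c First-role item ids; `b`, `d` second-role item ids.
#' @param b,d Second-role item ids.
#' @param probe A [probe_config()].
#' @return The echo in `[0, 1]` (vectorised over equal-length id vectors).
#' @export
echo_trial <- function(twin, a, b, c, d, probe = probe_config()) {
  stopifnot(inherits(twin, "twin_network"))
  check_items(twin, a, b, c, d)
  w <- twin_weights(twin)
  as.numeric(cpp_echo_batch(
    w, as.integer(a) - 1L, as.integer(b) - 1L, as.integer(c) - 1L,
    as.integer(d) - 1L, probe$phase1_ticks, probe$phase2_ticks,
    twin$network$cfg$lambda, twin$h1_bias, w$b_h, twin$h_to_r_scale))
}

#' Full activation trace of a twin echo trial
#'
#' Pure-R reference implementation of the twin settling dynamics, returning
#' every pool's activations at every tick. Used for inspecting hidden-pool
#' dynamics (e.g. under lesions); [echo_trial()] computes the same dynamics.
#'
#' @inheritParams echo_trial
#' @return A list of `(ticks + 1) x size` matrices for pools A, B, C, D, H1,
#'   H2, R, plus the tick index at which D was released.
#' @export
twin_settle <- function(twin, a, b, c, d, probe = probe_config()) {
  stopifnot(inherits(twin, "twin_network"))
  check_items(twin, a, b, c, d)
  w <- twin_weights(twin)
  cfg <- twin$network$cfg
  lambda <- cfg$lambda
  nA <- cfg$n_first_role; nB <- cfg$n_second_role
  nR <- cfg$n_relation; nH <- cfg$n_hidden
  scale <- twin$h_to_r_scale
  h1b <- twin$h1_bias; h2b <- w$b_h

  act <- list(A = one_hot(nA, a), B = one_hot(nB, b), C = one_hot(nA, c),
              D = one_hot(nB, d), H1 = rep(logistic(h1b), nH),
              H2 = rep(logistic(h2b), nH), R = logistic(w$b_r))
  total <- probe$phase1_ticks + probe$phase2_ticks
  trace <- lapply(act, function(v) {
    m <- matrix(NA_real_, total + 1L, length(v)); m[1L, ] <- v; m
  })
  for (t in seq_len(total)) {
    d_free <- t > probe$phase1_ticks
    nets <- list(
      H1 = drop(act$A %*% w$w_ah + act$B %*% w$w_bh + act$R %*% w$w_rh) + h1b,
      H2 = drop(act$C %*% w$w_ah + act$D %*% w$w_bh + act$R %*% w$w_rh) + h2b,
      R = drop(scale * (act$H1 + act$H2) %*% w$w_hr) + w$b_r,
      D = drop(act$H2 %*% w$w_hb) + w$b_b)
    new <- act
    for (p in c("H1", "H2", "R")) {
      new[[p]] <- act[[p]] + lambda * (logistic(nets[[p]]) - act[[p]])
    }
    if (d_free) new$D <- act$D + lambda * (logistic(nets$D) - act$D)
    act <- new
    for (p in names(trace)) trace[[p]][t + 1L, ] <- act[[p]]
  }
  c(trace, list(release_tick = probe$phase1_ticks))
}

# Deterministic pseudo-random coin for exact echo ties, derived from the
# question's item ids so reruns pick the same alternative.
tie_coin <- function(a, b, c, d1, d2) {
  (a * 7L + b * 11L + c * 13L + d1 * 17L + d2 * 19L) %% 2L == 0L
}

#' Answer one analogy question
#'
#' Runs two echo trials from identical initial conditions, one per candidate,
#' and picks the alternative with the stronger echo (deterministic coin on an
#' exact tie).
#'
#' @param twin A `twin_network`.
#' @param question A one-row tibble or list with `a`, `b`, `c`, `d1`, `d2`
#'   (and optionally `cell`, `sfi_label`).
#' @param probe A [probe_config()].
#' @return A one-row tibble: `echo_d1`, `echo_d2`, `choice`, `correct`.
#' @export
answer_question <- function(twin, question, probe = probe_config()) {
  q <- question
  e1 <- echo_trial(twin, q$a, q$b, q$c, q$d1, probe)
  e2 <- echo_trial(twin, q$a, q$b, q$c, q$d2, probe)
  pick_d1 <- if (e1 == e2) tie_coin(q$a, q$b, q$c, q$d1, q$d2) else e1 > e2
  tibble::tibble(
    cell = q$cell %||% NA_integer_, sfi_label = q$sfi_label %||% NA_character_,
    echo_d1 = e1, echo_d2 = e2,
    choice = if (pick_d1) q$d1 else q$d2, correct = pick_d1)
}

#' Echo results for a whole question set
#'
#' Batched equivalent of [answer_question()] over every row of `questions`.
#'
#' @param x A `twin_network` or an `analogy_network` (a default twin is built).
#' @param questions Question tibble (see [question_bank()]).
#' @param probe A [probe_config()].
#' @return A tibble with one row per question: `cell`, `sfi_label`,
#'   `echo_d1`, `echo_d2`, `choice`, `correct`.
#' @export
probe_questions <- function(x, questions, probe = probe_config()) {
  twin <- if (inherits(x, "analogy_network")) build_twin(x) else x
  stopifnot(inherits(twin, "twin_network"))
  if (is.null(questions) || nrow(questions) == 0L) {
    abort("empty question set", class = "analogynet_invalid_config")
  }
  e1 <- echo_trial(twin, questions$a, questions$b, questions$c, questions$d1,
                   probe)
  e2 <- echo_trial(twin, questions$a, questions$b, questions$c, questions$d2,
                   probe)
  tie <- e1 == e2
  pick_d1 <- e1 > e2
  if (any(tie)) {
    pick_d1[tie] <- tie_coin(questions$a[tie], questions$b[tie],
                             questions$c[tie], questions$d1[tie],
                             questions$d2[tie])
  }
  tibble::tibble(
    cell = questions$cell, sfi_label = questions$sfi_label,
    echo_d1 = e1, echo_d2 = e2,
    choice = ifelse(pick_d1, questions$d1, questions$d2), correct = pick_d1)
}

#' Accuracy by SFI type
#'
#' @inheritParams probe_questions
#' @return A tibble with rows `positive`, `zero`, `negative`, `overall` and
#'   columns `sfi_label`, `n`, `accuracy`.
#' @export
evaluate_analogies <- function(x, questions, probe = probe_config()) {
  res <- probe_questions(x, questions, probe)
  by_label <- res |>
    dplyr::group_by(sfi_label = .data$sfi_label) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop")
  overall <- tibble::tibble(sfi_label = "overall", n = nrow(res),
                            accuracy = mean(res$correct))
  out <- dplyr::bind_rows(by_label, overall)
  out[order(match(out$sfi_label, c("positive", "zero", "negative", "overall"))), ]
}
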