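#' Export a question bank to CSV
#'
#' Columns: `cell`, `a`, `b`, `c`, `d1`, `d2`, `sfi_label`.
#'
#' @param env An `analogy_environment` (or a question tibble).
#' @param path Output CSV path.
#' @return The questions tibble, invisibly.
#' @export
write_question_bank <- function(env, path) {
  q <- if (inherits(env, "analogy_environment")) env$questions else env
  readr::write_csv(q[, c("cell", "a", "b", "c", "d1", "d2", "sfi_label")],
                   path)
  invisible(q)
}

#' Serialize a prototype set to JSON
#'
#' Stores unit indices, not dense vectors.
#'
#' @param protoset A `prototype_set`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
prototypes_to_json <- function(protoset, path = NULL) {
  obj <- list(cfg = unclass(protoset$cfg),
              active_units = protoset$active)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a prototype set from JSON
#'
#' @param path File path or JSON string from [prototypes_to_json()].
#' @return A `prototype_set`.
#' @export
prototypes_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(relation_space_config, obj$cfg)
  active <- lapply(seq_len(nrow(obj$active_units)), function(i) {
    as.integer(obj$active_units[i, ])
  })
  patterns <- matrix(0, cfg$n_prototypes, cfg$n_units)
  for (p in seq_along(active)) patterns[p, active[[p]]] <- 1
  structure(list(patterns = patterns, active = active, cfg = cfg),
            class = "prototype_set")
}

#' Serialize an environment to JSON
#'
#' Records the configuration, the prototype active-unit indices, the
#' instance table (prototype and off-pair indices) and the cell table, from
#' which patterns and propositions are reconstructable.
#'
#' @param env An `analogy_environment`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
environment_to_json <- function(env, path = NULL) {
  cfg <- unclass(env$cfg)
  cfg$relation <- unclass(cfg$relation)
  obj <- list(
    cfg = cfg,
    active_units = env$protoset$active,
    instances = list(prototype_id = env$instances$meta$prototype_id,
                     off_pair = env$instances$meta$off_pair),
    cells = env$cells)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore an environment from JSON
#'
#' @param path File path or JSON string from [environment_to_json()].
#' @return An `analogy_environment`.
#' @export
environment_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rel_cfg <- do.call(relation_space_config, obj$cfg$relation)
  cfg_args <- obj$cfg
  cfg_args$relation <- rel_cfg
  cfg <- do.call(environment_config, cfg_args)

  active <- lapply(seq_len(nrow(obj$active_units)), function(i) {
    as.integer(obj$active_units[i, ])
  })
  patterns <- matrix(0, rel_cfg$n_prototypes, rel_cfg$n_units)
  for (p in seq_along(active)) patterns[p, active[[p]]] <- 1
  protoset <- structure(list(patterns = patterns, active = active,
                             cfg = rel_cfg),
                        class = "prototype_set")

  pid <- as.integer(obj$instances$prototype_id)
  offs <- obj$instances$off_pair
  inst_pat <- t(vapply(seq_along(pid), function(i) {
    v <- patterns[pid[i], ]
    v[as.integer(offs[i, ])] <- 0
    v
  }, numeric(rel_cfg$n_units)))
  meta <- tibble::tibble(
    instance = seq_along(pid), prototype_id = pid,
    off_pair = lapply(seq_along(pid), function(i) as.integer(offs[i, ])))

  cells <- tibble::as_tibble(obj$cells)
  env <- structure(
    list(cfg = cfg, protoset = protoset,
         instances = list(meta = meta, patterns = inst_pat), cells = cells,
         propositions = NULL,
         n_first_role = 5L * cfg$n_groups, n_second_role = 5L * cfg$n_groups),
    class = "analogy_environment")
  env$propositions <- rebuild_propositions(env)
  env$questions <- question_bank(env)
  env
}

rebuild_propositions <- function(env) {
  cfg <- env$cfg
  cells <- env$cells
  dplyr::bind_rows(
    dplyr::transmute(cells, cell = .data$cell, role = "source",
                     item1 = .data$a, rel = .data$rel_source, item2 = .data$b,
                     freq = cfg$freq_moderate),
    dplyr::transmute(cells, cell = .data$cell, role = "target",
                     item1 = .data$c, rel = .data$rel_target, item2 = .data$d1,
                     freq = cfg$freq_moderate),
    dplyr::transmute(cells, cell = .data$cell, role = "weak",
                     item1 = .data$c, rel = .data$rel_weak, item2 = .data$d2,
                     freq = cfg$freq_weak),
    dplyr::transmute(cells, cell = .data$cell, role = "moderate",
                     item1 = .data$c, rel = .data$rel_moderate,
                     item2 = .data$d3, freq = cfg$freq_moderate),
    dplyr::transmute(cells, cell = .data$cell, role = "strong",
                     item1 = .data$c, rel = .data$rel_strong, item2 = .data$d4,
                     freq = cfg$freq_strong)) |>
    dplyr::arrange(.data$cell, match(.data$role, c("source", "target", "weak",
                                                   "moderate", "strong")))
}

#' Export network weights to JSON
#'
#' Documented named-array layout: each directional matrix stored row-major
#' with its dimensions, plus bias vectors, the fixed hidden bias and the
#' configuration.
#'
#' @param net An `analogy_network`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
weights_to_json <- function(net, path = NULL) {
  obj <- list(cfg = unclass(net$cfg), epochs_trained = net$epochs_trained,
              weights = net$w)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore network weights from JSON
#'
#' @param path File path or JSON string from [weights_to_json()].
#' @return An `analogy_network`.
#' @export
weights_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$cfg)
  w <- obj$weights
  for (nm in c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr")) {
    w[[nm]] <- as.matrix(w[[nm]])
  }
  for (nm in c("b_a", "b_b", "b_r")) w[[nm]] <- as.numeric(w[[nm]])
  w$b_h <- as.numeric(w$b_h)
  structure(list(cfg = cfg, w = w,
                 epochs_trained = as.integer(obj$epochs_trained),
                 history = tibble::tibble()),
            class = "analogy_network")
}

#' Export a training/evaluation history to CSV
#'
#' @param net An `analogy_network` with a history, or a history tibble.
#' @param path Output CSV path.
#' @export
write_history <- function(net, path) {
  h <- if (inherits(net, "analogy_network")) net$history else net
  readr::write_csv(h, path)
  invisible(h)
}
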