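#' Configure the training environment
#'
#' The environment is a set of proposition *cells*, each holding one source
#' proposition A:R1:B, one relational target C:R1':D1 (same prototype as the
#' source, disjoint off-pair), and three foil propositions C:R2:D2, C:R3:D3,
#' C:R4:D4 (each from a distinct other prototype) trained at weak, moderate
#' and strong frequency. Target (and source) propositions are trained at the
#' moderate frequency, so each cell yields one positive-, one zero- and one
#' negative-SFI analogy question.
#'
#' Cells come in counterbalancing groups of five. Each group owns five
#' first-role and five second-role items; across its cells every second-role
#' item serves once in each of the roles B, D1, weak, moderate, strong (a
#' Latin square), every first-role item serves once as A, and the C items are
#' the next group's first-role items (each of which therefore serves once as
#' C). This equates total training frequency within each role class while
#' keeping every (item1, item2) pair bound to a single relation, so the
#' completion task stays well-posed. Prototype roles rotate cyclically over
#' consecutive cells so every prototype fills every frequency role once per
#' window of `n_prototypes` cells.
#'
#' @param n_groups Number of counterbalancing groups (5 cells each).
#' @param freq_weak,freq_moderate,freq_strong Presentations per epoch per
#'   input combination for weak/moderate/strong foil propositions (the target
#'   and source use `freq_moderate`). Must be strictly increasing.
#' @param seed RNG seed for item assignment and instance draws.
#' @param relation A [relation_space_config()] for the relation code.
#' @return An `environment_config` list.
#' @export
environment_config <- function(n_groups = 8L, freq_weak = 1L, freq_moderate = 3L,
                               freq_strong = 9L, seed = 1L,
                               relation = relation_space_config(seed = derive_seed(seed, 7L))) {
  check_counts(n_groups = n_groups, freq_weak = freq_weak,
               freq_moderate = freq_moderate, freq_strong = freq_strong)
  if (!(freq_weak < freq_moderate && freq_moderate < freq_strong)) {
    abort("need freq_weak < freq_moderate < freq_strong",
          class = "analogynet_invalid_config")
  }
  if (relation$n_prototypes < 4) {
    abort("environment needs at least 4 relational prototypes",
          class = "analogynet_invalid_config")
  }
  structure(
    list(n_groups = as.integer(n_groups), freq_weak = as.integer(freq_weak),
         freq_moderate = as.integer(freq_moderate),
         freq_strong = as.integer(freq_strong), seed = as.integer(seed),
         relation = relation),
    class = "environment_config")
}

#' Build a counterbalanced training environment
#'
#' Generates the prototype set, assigns items and relation instances to
#' 5 x `n_groups` cells, and derives the proposition table and question bank.
#' Each prototype's instances cycle through a fixed random partition of its
#' active units into disjoint off-pairs, so a cell's source and target
#' instances never share turned-off units and instance patterns recur across
#' propositions (with different items) once the partition is exhausted.
#'
#' @param cfg An [environment_config()].
#' @return An `analogy_environment` with elements `cells`, `propositions`,
#'   `questions` (tibbles), `protoset`, `instances` (meta tibble + pattern
#'   matrix), and the role vocabulary sizes.
#' @export
build_environment <- function(cfg = environment_config()) {
  stopifnot(inherits(cfg, "environment_config"))
  protoset <- generate_prototypes(cfg$relation)
  np <- cfg$relation$n_prototypes
  offsets <- if (np == 8L) c(0L, 2L, 4L, 6L) else 0:3

  inst_patterns <- list()
  inst_meta <- list()
  cells <- vector("list", 5L * cfg$n_groups)

  with_seed(cfg$seed, {
    # Each prototype's instances come from a fixed random partition of its
    # active units into n_active / n_off disjoint off-pairs, cycled across
    # draws. Off-pairs are therefore always different across the instances
    # of a scope, consecutive draws (a cell's source and target) never
    # overlap, and instance patterns recur across propositions with
    # different items, so completion must use item and relation jointly.
    n_off <- cfg$relation$n_off
    off_pools <- lapply(protoset$active, function(act) {
      perm <- act[sample.int(length(act))]
      n_pairs <- length(act) %/% n_off
      lapply(seq_len(n_pairs), function(k) {
        sort(perm[((k - 1L) * n_off + 1L):(k * n_off)])
      })
    })
    draw_count <- integer(np)
    a_items <- lapply(seq_len(cfg$n_groups), function(g) {
      (g - 1L) * 5L + sample.int(5L)
    })
    b_items <- lapply(seq_len(cfg$n_groups), function(g) {
      (g - 1L) * 5L + sample.int(5L)
    })
    for (g in seq_len(cfg$n_groups)) {
      items1 <- a_items[[g]]
      items2 <- b_items[[g]]
      # C items come from the next group's first-role items so that no
      # (item1, item2) pair ever carries two different relations; with a
      # single group the next group is itself and C is the cyclically next
      # A item.
      c_items <- if (cfg$n_groups == 1L) {
        items1[c(2:5, 1L)]
      } else {
        a_items[[g %% cfg$n_groups + 1L]][sample.int(5L)]
      }
      draw <- function(pid) {
        pool <- off_pools[[pid]]
        slot <- (draw_count[pid] %% length(pool)) + 1L
        draw_count[pid] <<- draw_count[pid] + 1L
        off <- pool[[slot]]
        pattern <- protoset$patterns[pid, ]
        pattern[off] <- 0
        id <- length(inst_patterns) + 1L
        inst_patterns[[id]] <<- pattern
        inst_meta[[id]] <<- tibble::tibble(
          instance = id, prototype_id = pid, off_pair = list(off))
        id
      }

      for (i in 1:5) {
        k <- (g - 1L) * 5L + i
        protos <- ((k - 1L + offsets) %% np) + 1L  # target, weak, moderate, strong
        lat <- function(r) items2[((i + r - 2L) %% 5L) + 1L]
        cells[[k]] <- tibble::tibble(
          cell = k, group = g,
          a = items1[i], c = c_items[i],
          b = lat(1L), d1 = lat(2L), d2 = lat(3L), d3 = lat(4L), d4 = lat(5L),
          proto_target = protos[1], proto_weak = protos[2],
          proto_moderate = protos[3], proto_strong = protos[4],
          rel_source = draw(protos[1]), rel_target = draw(protos[1]),
          rel_weak = draw(protos[2]), rel_moderate = draw(protos[3]),
          rel_strong = draw(protos[4]))
      }
    }
  })

  cells <- dplyr::bind_rows(cells)
  patterns <- do.call(rbind, inst_patterns)
  instances <- list(meta = dplyr::bind_rows(inst_meta), patterns = patterns)

  propositions <- dplyr::bind_rows(
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
                     item1 = .data$c, rel = .data$rel_moderate, item2 = .data$d3,
                     freq = cfg$freq_moderate),
    dplyr::transmute(cells, cell = .data$cell, role = "strong",
                     item1 = .data$c, rel = .data$rel_strong, item2 = .data$d4,
                     freq = cfg$freq_strong)) |>
    dplyr::arrange(.data$cell, match(.data$role, c("source", "target", "weak",
                                                   "moderate", "strong")))

  env <- structure(
    list(cfg = cfg, protoset = protoset, instances = instances, cells = cells,
         propositions = propositions,
         n_first_role = 5L * cfg$n_groups, n_second_role = 5L * cfg$n_groups),
    class = "analogy_environment")
  env$questions <- question_bank(env)
  env
}

#' @export
print.analogy_environment <- function(x, ...) {
  cat(sprintf(paste0(
    "<analogy_environment> %d cells in %d groups\n",
    "  %d first-role and %d second-role items, %d relation instances\n",
    "  %d propositions (%d trials/epoch), %d analogy questions\n"),
    nrow(x$cells), x$cfg$n_groups, x$n_first_role, x$n_second_role,
    nrow(x$instances$meta), nrow(x$propositions), 3L * sum(x$propositions$freq),
    nrow(x$questions)))
  invisible(x)
}

#' Analogy questions defined by one cell
#'
#' Each cell yields three questions sharing a, b, c and the correct
#' alternative d1, and differing in the foil: the weak foil gives a
#' positive-SFI question (foil trained less often than the target), the
#' moderate foil a zero-SFI question (equal frequency), and the strong foil a
#' negative-SFI question (foil trained more often).
#'
#' @param env An `analogy_environment`.
#' @param cell Cell id.
#' @return A three-row tibble with columns `cell`, `a`, `b`, `c`, `d1`, `d2`,
#'   `sfi_label`.
#' @export
questions_from_cell <- function(env, cell) {
  row <- env$cells[env$cells$cell == cell, ]
  if (nrow(row) != 1) abort("unknown cell id", class = "analogynet_invalid_config")
  tibble::tibble(
    cell = row$cell, a = row$a, b = row$b, c = row$c, d1 = row$d1,
    d2 = c(row$d2, row$d3, row$d4),
    sfi_label = c("positive", "zero", "negative"))
}

#' Full question bank of an environment
#'
#' @param env An `analogy_environment`.
#' @return A tibble with three SFI-labelled questions per cell.
#' @export
question_bank <- function(env) {
  purrr::map_dfr(env$cells$cell, \(k) questions_from_cell(env, k))
}

#' Expand one training epoch into shuffled trials
#'
#' Every proposition of frequency f contributes f trials of each of the three
#' input combinations (AB completing R, AR completing B, BR completing A).
#' The trial multiset is fixed by the environment; `seed` only shuffles the
#' order.
#'
#' @param env An `analogy_environment`.
#' @param seed Shuffle seed.
#' @return A tibble with columns `item1`, `rel` (instance id), `item2`,
#'   `combo` (`"AB"`, `"AR"`, `"BR"`) and `target` (the completed pool).
#' @export
expand_epoch <- function(env, seed = 1L) {
  props <- env$propositions
  idx <- rep(seq_len(nrow(props)), props$freq)
  base <- props[idx, c("item1", "rel", "item2")]
  trials <- dplyr::bind_rows(
    dplyr::mutate(base, combo = "AB", target = "R"),
    dplyr::mutate(base, combo = "AR", target = "B"),
    dplyr::mutate(base, combo = "BR", target = "A"))
  ord <- with_seed(seed, sample.int(nrow(trials)))
  tibble::as_tibble(trials[ord, ])
}
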