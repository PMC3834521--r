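#' Configure the distributed relation code
#'
#' Relations are represented as binary patterns over `n_units` units. The code
#' is built from `n_prototypes` mutually disjoint prototype patterns with
#' `n_active` active units each; a relation *instance* is a prototype with
#' `n_off` of its active units turned off. Under the defaults (8 prototypes of
#' 16 active units over 128 units, 2 units off per instance) the prototypes
#' exactly tile the unit set, instances carry 14 active units, and two
#' same-prototype instances with disjoint off-pairs share 12 active units.
#'
#' @param n_units Number of relation units.
#' @param n_prototypes Number of relational prototypes.
#' @param n_active Active units per prototype.
#' @param n_off Units turned off to derive an instance from its prototype.
#' @param seed RNG seed controlling the unit-to-prototype assignment.
#' @return A `relation_space_config` list.
#' @export
relation_space_config <- function(n_units = 128L, n_prototypes = 8L,
                                  n_active = 16L, n_off = 2L, seed = 1L) {
  check_counts(n_units = n_units, n_prototypes = n_prototypes,
               n_active = n_active, n_off = n_off)
  if (n_prototypes * n_active > n_units) {
    abort("disjoint prototypes need n_prototypes * n_active <= n_units",
          class = "analogynet_invalid_config")
  }
  if (n_off >= n_active) {
    abort("n_off must be smaller than n_active",
          class = "analogynet_invalid_config")
  }
  structure(
    list(n_units = as.integer(n_units), n_prototypes = as.integer(n_prototypes),
         n_active = as.integer(n_active), n_off = as.integer(n_off),
         seed = as.integer(seed)),
    class = "relation_space_config")
}

#' Generate disjoint relational prototypes
#'
#' Draws a random permutation of the unit indices and chunks it into
#' `n_prototypes` blocks of `n_active` units, so prototypes are pairwise
#' disjoint by construction. Deterministic given `cfg$seed`.
#'
#' @param cfg A [relation_space_config()].
#' @return A `prototype_set` with a 0/1 `patterns` matrix
#'   (`n_prototypes` x `n_units`) and the per-prototype active unit indices.
#' @export
generate_prototypes <- function(cfg = relation_space_config()) {
  stopifnot(inherits(cfg, "relation_space_config"))
  perm <- with_seed(cfg$seed, sample.int(cfg$n_units))
  active <- lapply(seq_len(cfg$n_prototypes), function(p) {
    sort(perm[((p - 1) * cfg$n_active + 1):(p * cfg$n_active)])
  })
  patterns <- matrix(0, cfg$n_prototypes, cfg$n_units)
  for (p in seq_len(cfg$n_prototypes)) patterns[p, active[[p]]] <- 1
  structure(list(patterns = patterns, active = active, cfg = cfg),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> %d disjoint prototypes, %d/%d active units each\n",
              x$cfg$n_prototypes, x$cfg$n_active, x$cfg$n_units))
  invisible(x)
}

#' Derive a relation instance from a prototype
#'
#' An instance is the prototype pattern with `n_off` of its active units turned
#' off. The off-units must be disjoint from every off-pair already used
#' (`used_pairs`), so that instances drawn under one bookkeeping scope differ
#' in which units they lose. Uses the current RNG state; seed the caller for
#' reproducibility.
#'
#' @param protoset A [generate_prototypes()] result.
#' @param prototype_id Prototype index (1-based).
#' @param used_pairs List of integer vectors: off-pairs already taken for this
#'   prototype within the current scope.
#' @param cfg Relation-space configuration (defaults to the set's own).
#' @return A `relation_instance` with fields `prototype_id`, `off_pair`,
#'   `pattern`.
#' @export
generate_instance <- function(protoset, prototype_id, used_pairs = list(),
                              cfg = protoset$cfg) {
  stopifnot(inherits(protoset, "prototype_set"))
  if (!is_count(prototype_id) || prototype_id > cfg$n_prototypes) {
    abort("invalid prototype_id", class = "analogynet_invalid_config")
  }
  act <- protoset$active[[prototype_id]]
  available <- setdiff(act, unlist(used_pairs))
  if (length(available) < cfg$n_off) {
    abort(sprintf(
      "off-pair exhaustion for prototype %d: %d unused active units left, need %d",
      prototype_id, length(available), cfg$n_off),
      class = "analogynet_exhaustion")
  }
  off <- sort(available[sample.int(length(available), cfg$n_off)])
  pattern <- protoset$patterns[prototype_id, ]
  pattern[off] <- 0
  structure(list(prototype_id = as.integer(prototype_id),
                 off_pair = as.integer(off), pattern = pattern),
            class = "relation_instance")
}

#' Number of shared active units between two relation patterns
#'
#' @param r1,r2 `relation_instance` objects or 0/1 pattern vectors of equal
#'   length.
#' @return Integer count of jointly active units.
#' @export
relation_overlap <- function(r1, r2) {
  p1 <- if (inherits(r1, "relation_instance")) r1$pattern else r1
  p2 <- if (inherits(r2, "relation_instance")) r2$pattern else r2
  if (length(p1) != length(p2)) {
    abort("relation patterns have different lengths",
          class = "analogynet_dimension_error")
  }
  as.integer(sum(p1 > 0 & p2 > 0))
}
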