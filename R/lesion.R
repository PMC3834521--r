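#' Specify a lesion
#'
#' Two lesion operators model the frontal and temporal variants of
#' frontotemporal lobar degeneration. A *frontal* lesion reduces the fixed
#' bias of the H1 pool (the half maintaining the A:B context) from its
#' trained value to `frontal_bias`, weakening context maintenance while
#' leaving every weight untouched. A *temporal* lesion removes learned
#' connections at random (each entry of the six directional matrices zeroed
#' independently with probability `p_remove`); because the twin's halves share
#' weights, the removal pattern is identical in both halves.
#'
#' @param kind `"frontal"` or `"temporal"`.
#' @param frontal_bias Replacement H1 bias for frontal lesions.
#' @param p_remove Connection-removal probability for temporal lesions.
#' @param seed RNG seed for the removal draw.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(kind = c("frontal", "temporal"), frontal_bias = -6.5,
                        p_remove = 0.42, seed = 1L) {
  kind <- match.arg(kind)
  if (!(is.numeric(p_remove) && length(p_remove) == 1 &&
        p_remove >= 0 && p_remove <= 1)) {
    abort("p_remove must be a probability in [0, 1]",
          class = "analogynet_invalid_config")
  }
  structure(list(kind = kind, frontal_bias = frontal_bias,
                 p_remove = p_remove, seed = as.integer(seed)),
            class = "lesion_spec")
}

#' Apply a frontal lesion to a twin
#'
#' Sets the H1 bias to `spec$frontal_bias`; H2 and all weights are untouched.
#' Reversible: re-applying with the trained bias restores control behaviour.
#'
#' @param twin A [build_twin()] result.
#' @param spec A `lesion_spec` with `kind = "frontal"`.
#' @return The lesioned `twin_network`.
#' @export
frontal_lesion <- function(twin, spec = lesion_spec("frontal")) {
  if (!inherits(twin, "twin_network")) {
    abort("frontal_lesion() applies to a built twin",
          class = "analogynet_invalid_config")
  }
  stopifnot(inherits(spec, "lesion_spec"), spec$kind == "frontal")
  twin$h1_bias <- spec$frontal_bias
  twin$lesion <- spec
  twin
}

#' Apply a temporal lesion to a network
#'
#' Zeroes each entry of the six directional weight matrices independently
#' with probability `spec$p_remove` (biases are not projections and are
#' spared). The removal mask is returned for auditing and kept on the
#' network; a twin built from the lesioned network sees the identical
#' removal in both halves because the halves share weights. Lesioned
#' networks are evaluated, not retrained.
#'
#' @param x An `analogy_network` or `twin_network`.
#' @param spec A `lesion_spec` with `kind = "temporal"`.
#' @return For a network: list with the lesioned `network` and the 0/1
#'   `mask` matrices. For a twin: the lesioned twin (mask stored on its
#'   network).
#' @export
temporal_lesion <- function(x, spec = lesion_spec("temporal")) {
  stopifnot(inherits(spec, "lesion_spec"), spec$kind == "temporal")
  if (inherits(x, "twin_network")) {
    res <- temporal_lesion(x$network, spec)
    x$network <- res$network
    x$lesion <- spec
    return(x)
  }
  stopifnot(inherits(x, "analogy_network"))
  mats <- c("w_ah", "w_ha", "w_bh", "w_hb", "w_rh", "w_hr")
  mask <- with_seed(spec$seed, {
    lapply(stats::setNames(mats, mats), function(nm) {
      m <- x$w[[nm]]
      matrix(as.numeric(runif(length(m)) >= spec$p_remove), nrow(m), ncol(m))
    })
  })
  for (nm in mats) x$w[[nm]] <- x$w[[nm]] * mask[[nm]]
  x$lesion_mask <- mask
  list(network = x, mask = mask)
}
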