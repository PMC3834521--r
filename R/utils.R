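# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never clobbers user RNG streams.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fold (seed, stream indices) into a single reproducible 31-bit seed.
derive_seed <- function(seed, ...) {
  x <- as.double(seed)
  for (k in c(...)) x <- (x * 69069 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(x)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 1 && x == as.integer(x)
}

check_counts <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    if (!is_count(vals[[nm]])) {
      abort(sprintf("`%s` must be a single positive integer", nm),
            class = "analogynet_invalid_config")
    }
  }
  invisible(TRUE)
}

logistic <- function(x) 1 / (1 + exp(-x))

one_hot <- function(n, i) {
  v <- numeric(n)
  v[i] <- 1
  v
}
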