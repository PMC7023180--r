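#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so seeded helpers never perturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible stream of sub-seeds from a root seed; all values stay
# below .Machine$integer.max so they are valid set.seed() inputs.
derive_seeds <- function(root_seed, n) {
  with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Adjusted Rand index with the degenerate case handled: identical set
# partitions score 1 even where the chance-corrected form is 0/0 (e.g. two
# all-singleton partitions).
ari_score <- function(a, b) {
  comembership <- function(x) outer(as.vector(x), as.vector(x), "==")
  if (identical(comembership(a), comembership(b))) return(1)
  mclust::adjustedRandIndex(a, b)
}

stop_csa <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "csaclust_error")))
}
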