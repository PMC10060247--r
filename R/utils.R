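# Internal helpers shared across modules.

# Structured error with a machine-readable code as condition class.
rsError <- function(code, message) {
  stop(errorCondition(message, class = c(code, "rshte_error", "error", "condition")))
}

rsWarning <- function(code, message) {
  warning(warningCondition(message, class = c(code, "rshte_warning", "warning", "condition")))
}

# Clip probabilities away from {0, 1} so logits stay finite.
clipProb <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

# Named RNG substreams derived from a single user seed: changing e.g. the
# number of negative controls must not perturb covariate or cohort draws.
.streamOffsets <- c(
  covariates = 101L, unmeasured = 163L, assignment = 211L,
  censoring = 307L, outcomes = 401L, controls = 503L,
  folds = 601L, match = 701L, oracle = 811L
)

substreamSeed <- function(seed, stream, index = 0L) {
  if (!stream %in% names(.streamOffsets)) {
    rsError("unknown_stream", paste0("unknown RNG substream: ", stream))
  }
  off <- .streamOffsets[[stream]]
  # keep the derived seed inside 32-bit integer range
  as.integer((abs(as.numeric(seed)) * 977 + off + 13 * index) %% 2147483647)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
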