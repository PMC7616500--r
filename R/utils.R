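# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
# All generators are pure functions of (arguments, seed); no hidden state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Small deterministic string hash (for per-section seed offsets), kept
# below 2^31 so seed arithmetic stays in R integer range.
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 31 + cp) %% 1000003
  as.integer(h)
}

# Format a double so that as.numeric() recovers it bit-exactly.
format_double <- function(x) sprintf("%.17g", x)

# Coerce any numeric matrix-like to a general dgCMatrix, keeping dimnames.
as_dgc <- function(m) {
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "CsparseMatrix"),
              "generalMatrix")
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
}
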