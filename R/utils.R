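# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent (byte order) sort, so vocabularies are reproducible
# across machines regardless of collation settings.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(x) order(x, method = "radix")

# Row-wise L2 normalization; zero rows are left untouched.
l2_normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Cosine distance between the rows of a matrix, clamped to [0, 2] and with
# an exactly zero diagonal.
cosine_distance_rows <- function(m) {
  u <- l2_normalize_rows(m)
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
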