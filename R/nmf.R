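#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative documents x terms matrix V as V ~ W H with
#' W (documents x k) and H (k x terms) nonnegative, minimizing the
#' Frobenius reconstruction error with the classical multiplicative
#' update rules. Factors are initialized from a seeded uniform random
#' draw, so different seeds explore different local minima — the source
#' of diversity the ensemble relies on — while a fixed seed makes the fit
#' fully deterministic.
#'
#' @param x a `"tfidf"` object or a nonnegative numeric matrix.
#' @param k number of topics; at most `min(nrow, ncol)`.
#' @param seed integer RNG seed for the initialization.
#' @param max_iter maximum number of update sweeps (default 200).
#' @param tol stop when the relative improvement of the Frobenius error
#'   falls below this value (default 1e-4).
#' @return An object of class `"nmf_run"`: `W`, `H`, `seed`, `k`,
#'   `error_trace` (Frobenius error after initialization and after each
#'   sweep), `final_error`, `iterations`, `converged`.
#' @export
fit_nmf <- function(x, k, seed, max_iter = 200L, tol = 1e-4) {
  v <- if (inherits(x, "tfidf")) x$weights else as.matrix(x)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
    stop("input matrix must be finite and nonnegative")
  n <- nrow(v); m <- ncol(v)
  k <- as.integer(k)
  if (k < 1L || k > min(n, m))
    stop("k must be between 1 and min(#documents, #terms) = ", min(n, m))
  eps <- 1e-9
  res <- with_seed(seed, {
    w <- matrix(stats::runif(n * k), n, k)
    h <- matrix(stats::runif(k * m), k, m)
    err <- sqrt(sum((v - w %*% h)^2))
    trace <- err
    it <- 0L
    converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      h <- h * crossprod(w, v) / (crossprod(w) %*% h + eps)
      w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
      e <- sqrt(sum((v - w %*% h)^2))
      trace <- c(trace, e)
      if ((err - e) / max(err, eps) < tol) { converged <- TRUE; break }
      err <- e
    }
    list(w = w, h = h, trace = trace, it = it, converged = converged)
  })
  dimnames(res$w) <- list(rownames(v), NULL)
  dimnames(res$h) <- list(NULL, colnames(v))
  if (any(!is.finite(res$w)) || any(!is.finite(res$h)))
    stop("NMF produced non-finite values")
  structure(
    list(W = res$w, H = res$h, seed = as.integer(seed), k = k,
         error_trace = res$trace,
         final_error = res$trace[length(res$trace)],
         iterations = res$it, converged = res$converged),
    class = "nmf_run"
  )
}

#' @export
print.nmf_run <- function(x, ...) {
  cat(sprintf(
    "<nmf_run: k = %d, seed = %d, %d iterations, Frobenius error %.4g%s>\n",
    x$k, x$seed, x$iterations, x$final_error,
    if (x$converged) "" else " (max_iter reached)"))
  invisible(x)
}
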