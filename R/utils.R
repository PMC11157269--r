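# shared internal helpers

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' One master seed drives every stochastic component; substreams are
#' derived deterministically so independent draws (e.g. the two
#' conditions of a simulated pair) never share a random state. The
#' result is always a positive 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param k substream index (integer).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + as.numeric(k) * 104729
  as.integer(s %% 2147483646) + 1L
}

# summed-area table with a zero-padded first row/column:
# S[i+1, j+1] = sum(M[1:i, 1:j])
sat2 <- function(M) {
  S <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
  S[-1L, -1L] <- apply(M, 2L, cumsum)
  S[-1L, -1L] <- t(apply(S[-1L, -1L, drop = FALSE], 1L, cumsum))
  S
}

# vectorized rectangle sums over a sat2() table; bounds 1-based inclusive
sat_query <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}

# per-position count of TRUE within a centered window of half-width w
win_counts <- function(v, w) {
  cs <- c(0, cumsum(as.numeric(v)))
  n <- length(v)
  idx <- seq_len(n)
  lo <- pmax(idx - w, 1L)
  hi <- pmin(idx + w, n)
  cs[hi + 1L] - cs[lo]
}

stop_if_not_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (positive && x <= 0)) {
    stop(sprintf("'%s' must be a single %snumber", name,
                 if (positive) "positive " else ""), call. = FALSE)
  }
  invisible(x)
}
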