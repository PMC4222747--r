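# Classical algorithms on the uncompressed sequence: the scaled forward
# recursion (used as the oracle for the compressed algorithm), an exact
# path-enumeration likelihood for tiny instances, Viterbi decoding and
# posterior decoding.

.check_seq_hmm <- function(x, hmm) {
  stopifnot(inherits(x, "obs_seq"), inherits(hmm, "hmm"))
  if (x$alphabet_size != hmm$n_observables)
    stop("sequence alphabet (", x$alphabet_size,
         ") does not match model alphabet (", hmm$n_observables, ")",
         call. = FALSE)
}

#' Classical scaled forward algorithm
#'
#' Computes the forward table column by column, renormalising each column by
#' its sum; the log likelihood is the accumulated sum of log column sums.
#' Returns `-Inf` for sequences with probability zero.
#'
#' @param x an object of class `"obs_seq"`.
#' @param hmm an object of class `"hmm"` with matching alphabet.
#' @return the natural-log likelihood `log Pr(Y | lambda)`.
#' @examples
#' h <- hmm(c(0.5, 0.5), diag(2), diag(2))
#' forward_scaled(obs_seq(c(0, 0), 2), h)   # log 0.5
#' @export
forward_scaled <- function(x, hmm) {
  .check_seq_hmm(x, hmm)
  y <- x$tokens
  at <- t(hmm$trans)
  v <- hmm$emit[, y[1L] + 1L] * hmm$pi
  s <- sum(v)
  if (s <= 0) return(-Inf)
  ll <- log(s)
  v <- v / s
  for (t in seq_along(y)[-1L]) {
    v <- hmm$emit[, y[t] + 1L] * (at %*% v)
    s <- sum(v)
    if (s <= 0) return(-Inf)
    ll <- ll + log(s)
    v <- v / s
  }
  ll
}

#' Unscaled forward likelihood (underflow demonstration)
#'
#' The forward recursion without any rescaling, returning the raw probability
#' `Pr(Y | lambda)`. On long sequences the product of probabilities drops
#' below the smallest representable double and the result underflows to 0 —
#' the failure mode the scaled algorithms exist to avoid.
#'
#' @inheritParams forward_scaled
#' @return the raw probability (often exactly 0 for large `T`).
#' @export
forward_naive <- function(x, hmm) {
  .check_seq_hmm(x, hmm)
  y <- x$tokens
  at <- t(hmm$trans)
  v <- hmm$emit[, y[1L] + 1L] * hmm$pi
  for (t in seq_along(y)[-1L])
    v <- hmm$emit[, y[t] + 1L] * (at %*% v)
  sum(v)
}

#' Exact likelihood by hidden-path enumeration
#'
#' Sums the joint probability of the observation sequence and every possible
#' hidden path. Exponential in `T`; guarded to instances with
#' `N^T <= 1e6`. Serves as an independent oracle for the dynamic-programming
#' implementations.
#'
#' @inheritParams forward_scaled
#' @return the natural-log likelihood.
#' @export
likelihood_bruteforce <- function(x, hmm) {
  .check_seq_hmm(x, hmm)
  y <- x$tokens
  n <- hmm$n_states
  tt <- length(y)
  if (n^tt > 1e6)
    stop("instance too large for enumeration: N^T = ", n^tt, call. = FALSE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), tt)))
  p <- hmm$pi[paths[, 1L]] * hmm$emit[cbind(paths[, 1L], y[1L] + 1L)]
  for (t in seq_len(tt)[-1L])
    p <- p * hmm$trans[cbind(paths[, t - 1L], paths[, t])] *
      hmm$emit[cbind(paths[, t], y[t] + 1L)]
  total <- sum(p)
  if (total <= 0) -Inf else log(total)
}

#' Viterbi decoding
#'
#' Most probable hidden path, computed in log space. Ties are broken
#' deterministically toward the lower state index. When every path has
#' probability zero the score is `-Inf` and the lexicographically smallest
#' path (all zeros) is returned.
#'
#' @inheritParams forward_scaled
#' @return an object of class `"hmm_decoding"`: list with `path` (0-based
#'   state indices) and `score` (log joint probability of path and
#'   observations).
#' @export
viterbi <- function(x, hmm) {
  .check_seq_hmm(x, hmm)
  y <- x$tokens
  n <- hmm$n_states
  tt <- length(y)
  log_a <- log(hmm$trans)
  log_b <- log(hmm$emit)
  delta <- log(hmm$pi) + log_b[, y[1L] + 1L]
  psi <- matrix(1L, n, tt)
  for (t in seq_len(tt)[-1L]) {
    scores <- delta + log_a             # scores[i, j] = delta_i + log a_ij
    best <- apply(scores, 2L, which.max)  # ties -> first (lowest index)
    delta <- scores[cbind(best, seq_len(n))] + log_b[, y[t] + 1L]
    psi[, t] <- best
  }
  path <- integer(tt)
  path[tt] <- which.max(delta)
  for (t in rev(seq_len(tt)[-1L]))
    path[t - 1L] <- psi[path[t], t]
  structure(list(path = path - 1L, score = delta[path[tt]],
                 mode = "viterbi"),
            class = "hmm_decoding")
}

#' Posterior decoding
#'
#' Forward-backward with per-column scaling (the backward pass reuses the
#' forward column scale factors). Returns both the per-position posterior
#' table `Pr(x_t = i | Y, lambda)` and the per-position argmax path (ties
#' toward the lower state index).
#'
#' @inheritParams forward_scaled
#' @return an object of class `"hmm_decoding"`: list with `path` (0-based),
#'   `posterior` (`N x T` matrix, columns summing to 1) and `loglik`.
#' @export
posterior_decode <- function(x, hmm) {
  .check_seq_hmm(x, hmm)
  y <- x$tokens
  n <- hmm$n_states
  tt <- length(y)
  at <- t(hmm$trans)
  alpha <- matrix(0, n, tt)
  scales <- numeric(tt)
  v <- hmm$emit[, y[1L] + 1L] * hmm$pi
  scales[1L] <- sum(v)
  if (scales[1L] <= 0)
    stop("sequence has zero likelihood under the model", call. = FALSE)
  alpha[, 1L] <- v / scales[1L]
  for (t in seq_len(tt)[-1L]) {
    v <- hmm$emit[, y[t] + 1L] * (at %*% alpha[, t - 1L])
    scales[t] <- sum(v)
    if (scales[t] <= 0)
      stop("sequence has zero likelihood under the model", call. = FALSE)
    alpha[, t] <- v / scales[t]
  }
  beta <- matrix(0, n, tt)
  beta[, tt] <- 1
  for (t in rev(seq_len(tt - 1L)))
    beta[, t] <- (hmm$trans %*% (hmm$emit[, y[t + 1L] + 1L] * beta[, t + 1L])) /
      scales[t + 1L]
  post <- alpha * beta
  post <- sweep(post, 2L, colSums(post), "/")
  path <- apply(post, 2L, which.max) - 1L
  structure(list(path = path, posterior = post, loglik = sum(log(scales)),
                 mode = "posterior"),
            class = "hmm_decoding")
}

#' @export
print.hmm_decoding <- function(x, ...) {
  cat(sprintf("HMM decoding (%s), %d positions\n", x$mode, length(x$path)))
  if (!is.null(x$score)) cat(sprintf("  score: %.12g\n", x$score))
  if (!is.null(x$loglik)) cat(sprintf("  log likelihood: %.12g\n", x$loglik))
  head_n <- min(length(x$path), 30L)
  cat("  path: ", paste(x$path[seq_len(head_n)], collapse = " "),
      if (length(x$path) > head_n) " ..." else "", "\n", sep = "")
  invisible(x)
}
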