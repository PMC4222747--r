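# Synthetic data: generative sampling from an HMM and i.i.d. binary
# sequences of controlled complexity (the frequency of 1s tunes how
# compressible the sequence is).

#' Sample a hidden path and observation sequence from an HMM
#'
#' Generative sampling: `x_1 ~ pi`, `x_t ~ trans[x_{t-1}, ]`,
#' `y_t ~ emit[x_t, ]`. Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param hmm an object of class `"hmm"`.
#' @param length sequence length `T >= 1`.
#' @param seed integer seed.
#' @return a list with `hidden` (0-based state indices) and `obs` (an
#'   `"obs_seq"`).
#' @export
sample_sequence <- function(hmm, length, seed) {
  stopifnot(inherits(hmm, "hmm"), length >= 1L)
  viol <- validate_hmm(hmm)
  if (length(viol) > 0L) stop("invalid HMM: ", viol[[1L]], call. = FALSE)
  n <- hmm$n_states
  tt <- as.integer(length)
  withr::with_seed(as.integer(seed), {
    hidden <- integer(tt)
    hidden[1L] <- sample.int(n, 1L, prob = hmm$pi)
    for (t in seq_len(tt)[-1L])
      hidden[t] <- sample.int(n, 1L, prob = hmm$trans[hidden[t - 1L], ])
    # emissions drawn column-wise given the hidden path
    u <- stats::runif(tt)
    m <- hmm$n_observables
    cum <- hmm$emit %*% (outer(seq_len(m), seq_len(m), `<=`) * 1)
    obs <- integer(tt)
    for (t in seq_len(tt))
      obs[t] <- findInterval(u[t], cum[hidden[t], ], left.open = TRUE)
    list(hidden = hidden - 1L,
         obs = obs_seq(pmin(obs, hmm$n_observables - 1L),
                       hmm$n_observables))
  })
}

#' Random i.i.d. binary sequence of controlled complexity
#'
#' Tokens are i.i.d. Bernoulli over the alphabet `{0, 1}` with
#' `Pr(1) = one_frequency`. Lower frequencies give longer runs of zeros and
#' hence more compressible sequences.
#'
#' @param length sequence length `T >= 1`.
#' @param one_frequency probability of symbol 1, in `[0, 1]`.
#' @param seed integer seed.
#' @return an object of class `"obs_seq"` with `alphabet_size = 2`.
#' @export
random_binary_sequence <- function(length, one_frequency, seed) {
  if (one_frequency < 0 || one_frequency > 1)
    stop("one_frequency must be in [0, 1]", call. = FALSE)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    obs_seq(stats::rbinom(as.integer(length), 1L, one_frequency), 2L)
  })
}

#' Softmax parameterization of an HMM
#'
#' Maps an unconstrained parameter vector to a valid HMM: the transition and
#' emission rows are softmax-transformed blocks of the vector (each row's
#' first logit pinned at 0 for identifiability) and `pi` is fixed uniform.
#' Intended as the default search space for [train_nelder_mead()];
#' applications with structured models supply their own map.
#'
#' @param n_states number of states.
#' @param n_observables alphabet size.
#' @return a function mapping a numeric vector of length
#'   `N*(N-1) + N*(M-1)` to an `"hmm"` object, with a `"n_par"` attribute.
#' @export
softmax_parameterization <- function(n_states, n_observables) {
  n <- as.integer(n_states)
  m <- as.integer(n_observables)
  n_par <- n * (n - 1L) + n * (m - 1L)
  softmax_rows <- function(theta, ncol) {
    mat <- cbind(0, matrix(theta, nrow = n, ncol = ncol - 1L))
    e <- exp(mat - apply(mat, 1L, max))
    e / rowSums(e)
  }
  f <- function(par) {
    stopifnot(length(par) == n_par)
    a <- if (n > 1L) softmax_rows(par[seq_len(n * (n - 1L))], n)
         else matrix(1, 1L, 1L)
    b <- if (m > 1L) softmax_rows(par[n * (n - 1L) + seq_len(n * (m - 1L))], m)
         else matrix(1, n, 1L)
    hmm(rep(1 / n, n), a, b)
  }
  attr(f, "n_par") <- n_par
  f
}

#' Maximum-likelihood training by Nelder-Mead search
#'
#' Maximises the compressed-forward log likelihood over a user-supplied
#' parameterization: a function mapping an unconstrained parameter vector to
#' an `"hmm"` object. Parameter vectors yielding invalid models, or models
#' under which the sequence is impossible, score as effectively `-Inf`. The
#' preprocessing is computed once and reused at every evaluation — the reuse
#' pattern the `e` parameter of [compression_calibration()] anticipates.
#'
#' @param pre an object of class `"compressed_obs"`.
#' @param parameterization function mapping a numeric vector to an `"hmm"`.
#' @param start numeric start vector; the objective must be finite there.
#' @param control passed to [stats::optim()] (`maxit`, `reltol`, ...).
#' @return an object of class `"hmm_fit"`: list with `par`, `loglik`,
#'   `evaluations` (number of likelihood computations), `convergence`
#'   (0 means converged) and `hmm` (the model at the optimum). `coef()` and
#'   `logLik()` methods are provided.
#' @examples
#' h <- hmm(c(0.5, 0.5),
#'          matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'          matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE))
#' sim <- sample_sequence(h, 500, seed = 42)
#' fit <- train_nelder_mead(preprocess(sim$obs),
#'                          softmax_parameterization(2, 2),
#'                          start = rep(0, 4))
#' fit
#' @export
train_nelder_mead <- function(pre, parameterization, start,
                              control = list()) {
  stopifnot(inherits(pre, "compressed_obs"), is.function(parameterization))
  n_eval <- 0L
  objective <- function(par) {
    n_eval <<- n_eval + 1L
    h <- tryCatch(parameterization(par), error = function(e) NULL)
    if (is.null(h) || length(validate_hmm(h)) > 0L)
      return(-.Machine$double.xmax / 2)
    ll <- forward_compressed(pre, h)$loglik
    if (!is.finite(ll)) -.Machine$double.xmax / 2 else ll
  }
  if (!is.finite(objective(start)) ||
      objective(start) <= -.Machine$double.xmax / 4)
    stop("objective is not finite at the start vector", call. = FALSE)
  n_eval <- 0L
  ctl <- utils::modifyList(list(fnscale = -1, maxit = 500L), control)
  opt <- stats::optim(start, objective, method = "Nelder-Mead", control = ctl)
  structure(list(par = opt$par, loglik = opt$value, evaluations = n_eval,
                 convergence = opt$convergence,
                 hmm = parameterization(opt$par)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("HMM maximum-likelihood fit (Nelder-Mead)\n")
  cat(sprintf("  log likelihood: %.12g\n", x$loglik))
  cat(sprintf("  likelihood evaluations: %d\n", x$evaluations))
  cat(sprintf("  converged: %s\n", if (x$convergence == 0L) "yes" else "no"))
  cat("  parameters: ", paste(sprintf("%.6g", x$par), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.hmm_fit <- function(object, ...) object$par

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}
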