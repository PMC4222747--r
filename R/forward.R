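# Two-stage numerically stable forward algorithm on a compressed sequence.
#
# The forward recursion is a right-to-left matrix chain
#   alpha_T = C_{y_T} C_{y_{T-1}} ... C_{y_2} C_1,
# where C_o = B_o A* (B_o the diagonal emission matrix of symbol o, A* the
# transposed transition matrix) and C_1 = B_{y_1} pi. A composite symbol
# standing for the in-sequence pair (l then r) therefore gets the matrix
# C_r C_l, computed once and reused at every occurrence.
#
# Every matrix is normalised by its entry sum and every stage-2 product by
# its vector sum; the log likelihood is recovered as the sum of the
# per-symbol log scales over the compressed sequence plus the per-step log
# scales.

#' Per-symbol forward matrix
#'
#' Returns `C_o = B_o A*`, i.e. entry `(j, k) = b[j, o] * a[k, j]`. Applying
#' `C_o` to the previous forward column vector advances the forward recursion
#' by one observation of symbol `o`.
#'
#' @param hmm an object of class `"hmm"`.
#' @param symbol 0-based original observable symbol (`< M`).
#' @return an `N x N` matrix.
#' @export
symbol_matrix <- function(hmm, symbol) {
  stopifnot(inherits(hmm, "hmm"))
  symbol <- as.integer(symbol)
  if (symbol < 0L || symbol >= hmm$n_observables)
    stop("symbol ", symbol, " outside alphabet [0, ", hmm$n_observables, ")",
         call. = FALSE)
  hmm$emit[, symbol + 1L] * t(hmm$trans)
}

#' Initial forward vector
#'
#' Returns `C_1 = B_{y_1} pi`, entry `i = b[i, y_1] * pi[i]` — the first
#' column `alpha_1` of the classical forward table.
#'
#' @param hmm an object of class `"hmm"`.
#' @param first_symbol 0-based first observed symbol.
#' @return a numeric vector of length `N`.
#' @export
init_vector <- function(hmm, first_symbol) {
  stopifnot(inherits(hmm, "hmm"))
  first_symbol <- as.integer(first_symbol)
  if (first_symbol < 0L || first_symbol >= hmm$n_observables)
    stop("symbol ", first_symbol, " outside alphabet [0, ",
         hmm$n_observables, ")", call. = FALSE)
  hmm$emit[, first_symbol + 1L] * hmm$pi
}

# Select the stored threshold to evaluate with: the largest N_min <= n_states,
# falling back to the smallest stored one with a warning.
.select_threshold <- function(pre, n_states) {
  ths <- as.integer(names(pre$per_threshold))
  ok <- ths[ths <= n_states]
  sel <- if (length(ok) > 0L) max(ok) else {
    warning("no stored threshold <= ", n_states,
            "; using smallest stored threshold ", min(ths))
    min(ths)
  }
  as.character(sel)
}

#' Stage 1: normalised per-symbol matrices with log scales
#'
#' For each original symbol `o` computes `C_o`, its entry sum `c`, the
#' normalised matrix `C_o / c` and the log scale `log(c)`. For each composite
#' symbol `(l, r)` (pair `l` then `r` in the sequence) it computes, in rule
#' order, the product of the constituents' normalised matrices oriented as
#' `Cbar_r %*% Cbar_l` (the chain applies right-to-left), its entry sum `c`,
#' the normalised product, and the log scale `log(c) + s_l + s_r`. A zero
#' entry sum flags the symbol degenerate (`-Inf` scale): any sequence using
#' it is impossible under the model.
#'
#' @param hmm an object of class `"hmm"`; its alphabet must match the
#'   preprocessing's original alphabet.
#' @param pre an object of class `"compressed_obs"`.
#' @param threshold stored threshold to build tables for; by default the
#'   largest stored `N_min <= hmm$n_states`.
#' @return an object of class `"scaled_symbol_set"`: list with `matrices`
#'   (list of `N x N` matrices, entry sums 1), `log_scales`, `init_vector`
#'   (raw `C_1`), `degenerate` (logical), `n_original`, `alphabet_size` and
#'   `stage1_products` (number of matrix-matrix multiplications performed).
#' @export
scaled_symbol_set <- function(hmm, pre, threshold = NULL) {
  stopifnot(inherits(hmm, "hmm"), inherits(pre, "compressed_obs"))
  if (hmm$n_observables != pre$original_alphabet_size)
    stop("model alphabet (", hmm$n_observables,
         ") does not match preprocessing alphabet (",
         pre$original_alphabet_size, ")", call. = FALSE)
  sel <- if (is.null(threshold)) .select_threshold(pre, hmm$n_states)
         else as.character(threshold)
  if (!sel %in% names(pre$per_threshold))
    stop("no stored threshold ", sel, call. = FALSE)
  extent <- pre$per_threshold[[sel]]$alphabet_size
  m <- pre$original_alphabet_size
  mats <- vector("list", extent)
  scales <- numeric(extent)
  degen <- logical(extent)
  for (o in seq_len(m)) {
    cm <- symbol_matrix(hmm, o - 1L)
    cs <- sum(cm)
    if (cs == 0) {
      mats[[o]] <- cm
      scales[o] <- -Inf
      degen[o] <- TRUE
    } else {
      mats[[o]] <- cm / cs
      scales[o] <- log(cs)
    }
  }
  if (extent > m) {
    for (i in seq_len(extent - m)) {
      l <- pre$table$rules[i, "left"]
      r <- pre$table$rules[i, "right"]
      if (degen[l + 1L] || degen[r + 1L]) {
        mats[[m + i]] <- matrix(0, hmm$n_states, hmm$n_states)
        scales[m + i] <- -Inf
        degen[m + i] <- TRUE
        next
      }
      p <- mats[[r + 1L]] %*% mats[[l + 1L]]
      cs <- sum(p)
      if (cs == 0) {
        mats[[m + i]] <- p
        scales[m + i] <- -Inf
        degen[m + i] <- TRUE
      } else {
        mats[[m + i]] <- p / cs
        scales[m + i] <- log(cs) + scales[l + 1L] + scales[r + 1L]
      }
    }
  }
  structure(list(matrices = mats, log_scales = scales,
                 init_vector = init_vector(hmm, pre$first_symbol),
                 degenerate = degen, n_original = m,
                 alphabet_size = extent,
                 stage1_products = extent - m,
                 threshold = sel),
            class = "scaled_symbol_set")
}

#' Log likelihood via the compressed forward algorithm
#'
#' Stage 1 builds the normalised per-symbol matrices ([scaled_symbol_set()]);
#' stage 2 starts from the raw initial vector `C_1` and, for each compressed
#' token, multiplies by that token's normalised matrix, records the entry sum
#' `d` of the result, and renormalises. The log likelihood is the sum of the
#' per-token log scales plus the sum of the `log d` terms. A length-1
#' sequence is evaluated from the initial vector alone. Impossible sequences
#' yield `-Inf`, never an error.
#'
#' @param pre an object of class `"compressed_obs"`.
#' @param hmm an object of class `"hmm"`.
#' @param n_blocks number of contiguous stage-2 blocks; `1` (the default)
#'   runs the sequential matrix-vector chain, larger values evaluate each
#'   block as a normalised matrix product before combining with `C_1`
#'   (numerically equal within `1e-9`; blocks could be processed
#'   concurrently, the contract here is value equality). Values exceeding the
#'   compressed length are clamped with a warning.
#' @param threshold stored threshold to use (default: largest `N_min <=`
#'   `hmm$n_states`).
#' @return an object of class `"forward_result"`: list with `loglik`
#'   (natural log), `stage2_steps` (compressed remainder length, the number
#'   of matrix-vector multiplications), `stage1_products` (matrix-matrix
#'   multiplications, one per composite symbol) and `log_scale_sum` (the sum
#'   of the per-step `log d` terms).
#' @examples
#' h <- random_hmm(2, 2, seed = 1)
#' s <- obs_seq(c(1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1), 2)
#' forward_compressed(preprocess(s), h)
#' @seealso [forward_scaled()] for the classical algorithm on the raw
#'   sequence.
#' @export
forward_compressed <- function(pre, hmm, n_blocks = 1L, threshold = NULL) {
  tabs <- scaled_symbol_set(hmm, pre, threshold)
  tokens <- pre$per_threshold[[tabs$threshold]]$tokens
  n_tok <- length(tokens)
  res <- list(loglik = -Inf, stage2_steps = n_tok,
              stage1_products = tabs$stage1_products,
              log_scale_sum = NA_real_)
  class(res) <- "forward_result"
  v <- tabs$init_vector
  if (n_tok == 0L) {                      # T = 1: alpha_1 alone
    s <- sum(v)
    res$loglik <- if (s > 0) log(s) else -Inf
    res$log_scale_sum <- 0
    return(res)
  }
  if (any(tabs$degenerate[tokens + 1L]))  # impossible symbol in use
    return(res)
  s_sum <- sum(tabs$log_scales[tokens + 1L])
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  if (n_blocks > n_tok) {
    warning("n_blocks (", n_blocks, ") exceeds compressed length (", n_tok,
            "); clamped")
    n_blocks <- n_tok
  }
  d_sum <- 0
  if (n_blocks == 1L) {
    for (t in seq_len(n_tok)) {
      v <- tabs$matrices[[tokens[t] + 1L]] %*% v
      d <- sum(v)
      if (d <= 0) return(res)
      d_sum <- d_sum + log(d)
      v <- v / d
    }
  } else {
    bounds <- floor(seq(0L, n_tok, length.out = n_blocks + 1L))
    for (b in seq_len(n_blocks)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      p <- tabs$matrices[[tokens[idx[1L]] + 1L]]
      for (t in idx[-1L]) {
        p <- tabs$matrices[[tokens[t] + 1L]] %*% p
        d <- sum(p)
        if (d <= 0) return(res)
        d_sum <- d_sum + log(d)
        p <- p / d
      }
      v <- p %*% v
      d <- sum(v)
      if (d <= 0) return(res)
      d_sum <- d_sum + log(d)
      v <- v / d
    }
  }
  res$loglik <- s_sum + d_sum
  res$log_scale_sum <- d_sum
  res
}

#' @export
print.forward_result <- function(x, ...) {
  cat(sprintf("log Pr(Y | lambda) = %.12g\n", x$loglik))
  cat(sprintf("  stage 2 matrix-vector steps: %d\n", x$stage2_steps))
  cat(sprintf("  stage 1 matrix-matrix products: %d\n", x$stage1_products))
  invisible(x)
}

#' Convenience: compressed-forward log likelihood of a raw sequence
#'
#' Preprocesses `x` (stopping when the pair count stops decreasing) and
#' evaluates [forward_compressed()]. For repeated evaluations of the same
#' sequence, preprocess once with [preprocess()] and reuse the result.
#'
#' @param x an object of class `"obs_seq"`.
#' @param hmm an object of class `"hmm"`.
#' @param ... passed to [forward_compressed()].
#' @return an object of class `"forward_result"`.
#' @export
forward <- function(x, hmm, ...) {
  forward_compressed(preprocess(x), hmm, ...)
}
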