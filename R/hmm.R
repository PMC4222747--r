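#' Construct a discrete hidden Markov model
#'
#' A hidden Markov model over a finite hidden-state alphabet of size `N` and a
#' finite observable alphabet of size `M` is parameterised by an initial
#' distribution `pi` (`pi[i] = Pr(x_1 = i)`), an `N x N` row-stochastic
#' transition matrix `trans` (`trans[i, j] = Pr(x_t = j | x_{t-1} = i)`) and an
#' `N x M` row-stochastic emission matrix `emit`
#' (`emit[i, o] = Pr(y_t = o | x_t = i)`).
#'
#' Observable symbols and hidden states are referred to by 0-based integer
#' codes everywhere in this package (symbol `o` selects column `o + 1` of
#' `emit`), matching the on-disk sequence format.
#'
#' @param pi numeric initial state distribution of length `N`.
#' @param trans `N x N` row-stochastic transition matrix.
#' @param emit `N x M` row-stochastic emission matrix.
#' @param validate if `TRUE` (default), reject invalid parameters. Set to
#'   `FALSE` to build a deliberately invalid model, e.g. to feed
#'   [validate_hmm()].
#' @return an object of class `"hmm"`: a list with elements `n_states`,
#'   `n_observables`, `pi`, `trans`, `emit`.
#' @examples
#' h <- hmm(c(0.5, 0.5),
#'          matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'          matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE))
#' h
#' @seealso [validate_hmm()], [read_hmm()], [write_hmm()], [random_hmm()]
#' @export
hmm <- function(pi, trans, emit, validate = TRUE) {
  pi <- as.numeric(pi)
  trans <- as.matrix(trans)
  emit <- as.matrix(emit)
  storage.mode(trans) <- "double"
  storage.mode(emit) <- "double"
  x <- structure(
    list(n_states = length(pi), n_observables = ncol(emit),
         pi = pi, trans = trans, emit = emit),
    class = "hmm")
  if (validate) {
    bad <- validate_hmm(x)
    if (length(bad) > 0L)
      stop("invalid HMM: ", bad[[1L]], call. = FALSE)
  }
  x
}

# absolute tolerance on row sums of pi / trans / emit
.hmm_tol <- 1e-9

#' Validate HMM parameters
#'
#' Checks the stochasticity invariants of an HMM: `pi` entries in \[0, 1\]
#' summing to 1, each row of the transition and emission matrices summing to 1
#' (absolute tolerance `1e-9`), and all entries non-negative. Zero entries are
#' allowed everywhere, including in `pi`.
#'
#' @param x an object of class `"hmm"`, or any list with elements `pi`,
#'   `trans` and `emit`.
#' @return a character vector of violation messages (naming the offending row
#'   or entry); a valid model yields `character(0)`.
#' @examples
#' h <- hmm(c(1, 0), diag(2), diag(2))
#' validate_hmm(h)                       # character(0)
#' bad <- hmm(c(0.6, 0.6), diag(2), diag(2), validate = FALSE)
#' validate_hmm(bad)
#' @export
validate_hmm <- function(x) {
  out <- character(0)
  pi <- x$pi; trans <- x$trans; emit <- x$emit
  n <- length(pi)
  if (n < 1L)
    return("pi is empty: a model needs at least one state")
  if (!is.matrix(trans) || nrow(trans) != n || ncol(trans) != n)
    out <- c(out, sprintf("trans must be %d x %d, got %d x %d",
                          n, n, NROW(trans), NCOL(trans)))
  if (!is.matrix(emit) || nrow(emit) != n || ncol(emit) < 1L)
    out <- c(out, sprintf("emit must have %d rows, got %d", n, NROW(emit)))
  if (length(out) > 0L) return(out)

  if (any(!is.finite(pi)) || any(!is.finite(trans)) || any(!is.finite(emit)))
    out <- c(out, "non-finite entries in parameters")
  neg <- which(pi < 0)
  if (length(neg) > 0L)
    out <- c(out, sprintf("pi entry %d is negative", neg[1L]))
  if (any(pi > 1 + .hmm_tol))
    out <- c(out, sprintf("pi entry %d exceeds 1", which(pi > 1 + .hmm_tol)[1L]))
  if (abs(sum(pi) - 1) > .hmm_tol)
    out <- c(out, sprintf("pi sums to %.12g, not 1", sum(pi)))
  bad <- which(apply(trans, 1L, function(r) any(r < 0)))
  if (length(bad) > 0L)
    out <- c(out, sprintf("trans row %d has a negative entry", bad[1L]))
  rs <- rowSums(trans)
  bad <- which(abs(rs - 1) > .hmm_tol)
  if (length(bad) > 0L)
    out <- c(out, sprintf("trans row %d sums to %.12g, not 1", bad[1L], rs[bad[1L]]))
  bad <- which(apply(emit, 1L, function(r) any(r < 0)))
  if (length(bad) > 0L)
    out <- c(out, sprintf("emit row %d has a negative entry", bad[1L]))
  rs <- rowSums(emit)
  bad <- which(abs(rs - 1) > .hmm_tol)
  if (length(bad) > 0L)
    out <- c(out, sprintf("emit row %d sums to %.12g, not 1", bad[1L], rs[bad[1L]]))
  out
}

#' @export
print.hmm <- function(x, ...) {
  cat(sprintf("Hidden Markov model: %d states, %d observables\n",
              x$n_states, x$n_observables))
  cat("pi:\n"); print(x$pi)
  cat("transition matrix:\n"); print(x$trans)
  cat("emission matrix:\n"); print(x$emit)
  invisible(x)
}

#' Read an HMM from a plain-text file
#'
#' Parses the line-oriented text format written by [write_hmm()]: a header
#' line `cfhmm_hmm 1`, lines `N <int>` and `M <int>`, then labelled blocks
#' `pi` (one line of `N` numbers), `A` (`N` lines of `N` numbers) and `B`
#' (`N` lines of `M` numbers). `#` starts a comment; numbers may use decimal
#' or scientific notation.
#'
#' @param path path to an HMM file.
#' @return a validated object of class `"hmm"`.
#' @seealso [write_hmm()]
#' @export
read_hmm <- function(path) {
  if (!file.exists(path)) stop("HMM file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(lines)))
  toks <- lapply(keep, function(i) strsplit(trimws(lines[[i]]), "\\s+")[[1L]])
  lineno <- keep
  bad <- function(i, msg) stop(sprintf("%s: line %d: %s", path, i, msg),
                               call. = FALSE)
  if (length(toks) < 1L || !identical(toks[[1L]][1:2], c("cfhmm_hmm", "1")))
    bad(if (length(lineno)) lineno[1L] else 1L, "missing 'cfhmm_hmm 1' header")
  cursor <- 2L
  expect_kv <- function(key) {
    if (cursor > length(toks) || toks[[cursor]][1L] != key)
      bad(if (cursor <= length(lineno)) lineno[cursor] else length(raw),
          sprintf("expected '%s <value>'", key))
    v <- suppressWarnings(as.integer(toks[[cursor]][2L]))
    if (is.na(v)) bad(lineno[cursor], sprintf("'%s' is not an integer", key))
    cursor <<- cursor + 1L
    v
  }
  n <- expect_kv("N")
  m <- expect_kv("M")
  if (n < 1L || m < 1L) bad(lineno[cursor - 1L], "N and M must be positive")
  read_block <- function(label, nrows, ncols) {
    if (cursor > length(toks) || toks[[cursor]][1L] != label)
      bad(if (cursor <= length(lineno)) lineno[cursor] else length(raw),
          sprintf("expected block '%s'", label))
    cursor <<- cursor + 1L
    rows <- matrix(NA_real_, nrows, ncols)
    for (r in seq_len(nrows)) {
      if (cursor > length(toks))
        bad(length(raw), sprintf("block '%s': expected %d rows, file ended at row %d",
                                 label, nrows, r - 1L))
      vals <- suppressWarnings(as.numeric(toks[[cursor]]))
      if (length(vals) != ncols || anyNA(vals))
        bad(lineno[cursor], sprintf("block '%s' row %d: expected %d numbers",
                                    label, r, ncols))
      rows[r, ] <- vals
      cursor <<- cursor + 1L
    }
    rows
  }
  pi <- as.numeric(read_block("pi", 1L, n))
  a <- read_block("A", n, n)
  b <- read_block("B", n, m)
  x <- hmm(pi, a, b, validate = FALSE)
  viol <- validate_hmm(x)
  if (length(viol) > 0L)
    stop(sprintf("%s: model fails validation: %s", path, viol[[1L]]),
         call. = FALSE)
  x
}

#' Write an HMM to a plain-text file
#'
#' Serialises the model in the format read by [read_hmm()]. Numbers are
#' printed with 17 significant digits so that the round trip reproduces every
#' entry to within `1e-12` relative error (in practice exactly).
#'
#' @param x an object of class `"hmm"`.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_hmm <- function(x, path) {
  stopifnot(inherits(x, "hmm"))
  viol <- validate_hmm(x)
  if (length(viol) > 0L) stop("refusing to write invalid HMM: ", viol[[1L]],
                              call. = FALSE)
  fmt_row <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c("cfhmm_hmm 1",
             sprintf("N %d", x$n_states),
             sprintf("M %d", x$n_observables),
             "pi", fmt_row(x$pi),
             "A", apply(x$trans, 1L, fmt_row),
             "B", apply(x$emit, 1L, fmt_row))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Generate a random HMM
#'
#' Draws each row of `pi`, the transition matrix and the emission matrix from
#' a flat Dirichlet distribution (i.i.d. Exp(1) entries normalised to sum 1).
#' Deterministic for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n_states number of hidden states (`N >= 1`).
#' @param n_observables number of observable symbols (`M >= 1`).
#' @param seed integer seed.
#' @return a valid object of class `"hmm"`.
#' @examples
#' random_hmm(3, 4, seed = 1)
#' @export
random_hmm <- function(n_states, n_observables, seed) {
  if (n_states < 1L || n_observables < 1L)
    stop("n_states and n_observables must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    simplex <- function(k) {
      g <- stats::rgamma(k, shape = 1)
      if (sum(g) == 0) g <- rep(1, k)
      g / sum(g)
    }
    pi <- simplex(n_states)
    a <- t(vapply(seq_len(n_states), function(i) simplex(n_states),
                  numeric(n_states)))
    b <- t(vapply(seq_len(n_states), function(i) simplex(n_observables),
                  numeric(n_observables)))
    if (n_states == 1L) a <- matrix(a, 1L)
    b <- matrix(b, nrow = n_states)
    hmm(pi, a, b)
  })
}
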