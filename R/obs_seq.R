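#' Construct an observed symbol sequence
#'
#' An observation sequence is a vector of 0-based integer symbol codes over a
#' declared alphabet. The alphabet size is declared explicitly rather than
#' inferred from the data, because the symbols present in a sequence need not
#' exhaust the symbols an HMM can emit.
#'
#' @param tokens integer vector of symbols, each in `[0, alphabet_size)`.
#' @param alphabet_size declared number of observable symbols (`M >= 1`).
#' @return an object of class `"obs_seq"`: a list with elements `tokens`,
#'   `alphabet_size` and `length`.
#' @examples
#' obs_seq(c(1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1), alphabet_size = 2)
#' @export
obs_seq <- function(tokens, alphabet_size) {
  tokens <- as.integer(tokens)
  alphabet_size <- as.integer(alphabet_size)
  if (length(alphabet_size) != 1L || is.na(alphabet_size) || alphabet_size < 1L)
    stop("alphabet_size must be a positive integer", call. = FALSE)
  if (length(tokens) < 1L)
    stop("sequence must contain at least one token", call. = FALSE)
  if (anyNA(tokens))
    stop("sequence contains non-integer tokens", call. = FALSE)
  bad <- which(tokens < 0L | tokens >= alphabet_size)
  if (length(bad) > 0L)
    stop(sprintf("token %d at position %d is outside alphabet [0, %d)",
                 tokens[bad[1L]], bad[1L], alphabet_size), call. = FALSE)
  structure(list(tokens = tokens, alphabet_size = alphabet_size,
                 length = length(tokens)),
            class = "obs_seq")
}

#' @export
print.obs_seq <- function(x, ...) {
  cat(sprintf("Observed sequence: %d tokens over alphabet of size %d\n",
              x$length, x$alphabet_size))
  head_n <- min(x$length, 30L)
  cat(paste(x$tokens[seq_len(head_n)], collapse = " "))
  if (x$length > head_n) cat(" ...")
  cat("\n")
  invisible(x)
}

#' Read an observed sequence from a text file
#'
#' The file contains whitespace/newline-separated base-10 integers. The
#' alphabet size must be supplied by the caller.
#'
#' @param path path to a sequence file.
#' @param alphabet_size declared alphabet size.
#' @return an object of class `"obs_seq"`.
#' @seealso [write_obs_seq()]
#' @export
read_obs_seq <- function(path, alphabet_size) {
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  tokens <- scan(path, what = integer(), quiet = TRUE)
  obs_seq(tokens, alphabet_size)
}

#' Write an observed sequence to a text file
#'
#' @param x an object of class `"obs_seq"`, or a bare integer vector.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_obs_seq <- function(x, path) {
  tokens <- if (inherits(x, "obs_seq")) x$tokens else as.integer(x)
  writeLines(paste(tokens, collapse = " "), path)
  invisible(path)
}
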