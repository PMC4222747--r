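# Most-frequent-pair sequence compression.
#
# The preprocessing repeatedly replaces the most frequent non-overlapping
# adjacent symbol pair by a fresh symbol (digram / re-pair style). The result
# depends only on the sequence, never on a model, so it can be saved and
# reused across likelihood evaluations.

# Vectorised non-overlapping pair counts, returned as a flat count vector over
# keys left * k + right + 1 (k = current alphabet extent). Greedy left-to-right
# semantics: for left != right adjacent matches can never overlap; for a pair
# of identical symbols a run of length L contributes floor(L / 2).
.pair_counts_vec <- function(tokens, k) {
  n <- length(tokens)
  cnt <- integer(k * k)
  if (n < 2L) return(cnt)
  l <- tokens[-n]
  r <- tokens[-1L]
  ne <- l != r
  if (any(ne)) {
    keys <- l[ne] * k + r[ne] + 1L
    cnt <- cnt + tabulate(keys, nbins = k * k)
  }
  rl <- rle(tokens)
  long <- rl$lengths >= 2L
  if (any(long)) {
    syms <- rl$values[long]
    add <- rl$lengths[long] %/% 2L
    keys <- syms * k + syms + 1L
    agg <- rowsum(add, keys)
    idx <- as.integer(rownames(agg))
    cnt[idx] <- cnt[idx] + as.integer(agg[, 1L])
  }
  cnt
}

#' Count non-overlapping adjacent symbol pairs
#'
#' Counts, for every adjacent pair of symbols, its number of non-overlapping
#' occurrences under a greedy left-to-right scan: after a counted occurrence
#' at positions `(t, t+1)` the next candidate for that pair starts at `t+2`.
#' A pair of identical symbols therefore counts `floor(run length / 2)` per
#' run. Pairs of distinct symbols cannot overlap, so their count is the plain
#' number of adjacent matches.
#'
#' @param tokens integer vector of symbols (0-based), or an `"obs_seq"`.
#' @return a data frame with columns `left`, `right`, `count` (only pairs
#'   with positive count), ordered lexicographically by `(left, right)`.
#' @examples
#' count_pairs(c(1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1))
#' @seealso [select_pair()], [replace_pair()]
#' @export
count_pairs <- function(tokens) {
  if (inherits(tokens, "obs_seq")) tokens <- tokens$tokens
  tokens <- as.integer(tokens)
  if (length(tokens) < 2L)
    return(data.frame(left = integer(0), right = integer(0),
                      count = integer(0)))
  k <- max(tokens) + 1L
  cnt <- .pair_counts_vec(tokens, k)
  pos <- which(cnt > 0L)
  data.frame(left = (pos - 1L) %/% k,
             right = (pos - 1L) %% k,
             count = cnt[pos])
}

#' Select the most frequent pair
#'
#' Returns a pair with maximal count; ties are broken deterministically by the
#' lexicographically smallest `(left, right)`.
#'
#' @param counts a pair-count data frame as returned by [count_pairs()].
#' @return `NULL` when the table is empty, otherwise a list with elements
#'   `pair` (length-2 integer vector) and `count`.
#' @examples
#' select_pair(count_pairs(c(1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1)))
#' @export
select_pair <- function(counts) {
  if (is.null(counts) || nrow(counts) == 0L) return(NULL)
  ord <- order(-counts$count, counts$left, counts$right)
  best <- counts[ord[1L], ]
  list(pair = c(best$left, best$right), count = best$count)
}

#' Replace all non-overlapping occurrences of a pair by a new symbol
#'
#' Greedy left-to-right replacement, consistent with the counting semantics of
#' [count_pairs()]: the output length is the input length minus the pair's
#' non-overlapping occurrence count.
#'
#' @param tokens integer vector of symbols.
#' @param pair length-2 integer vector `(left, right)`.
#' @param new_symbol fresh symbol code; must not already occur in `tokens`.
#' @return the rewritten integer vector.
#' @examples
#' replace_pair(c(1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1), c(1, 0), 2)
#' @export
replace_pair <- function(tokens, pair, new_symbol) {
  tokens <- as.integer(tokens)
  new_symbol <- as.integer(new_symbol)
  if (new_symbol %in% tokens)
    stop("new_symbol ", new_symbol, " already occurs in the sequence",
         call. = FALSE)
  keep <- .pair_positions(tokens, pair[1L], pair[2L])
  if (length(keep) == 0L) return(tokens)
  tokens[keep] <- new_symbol
  tokens[-(keep + 1L)]
}

# Positions (left index) of the greedily kept occurrences of (l, r).
.pair_positions <- function(tokens, l, r) {
  n <- length(tokens)
  if (n < 2L) return(integer(0))
  m <- which(tokens[-n] == l & tokens[-1L] == r)
  if (length(m) == 0L || l != r) return(m)
  # identical symbols: within each maximal stretch of consecutive candidate
  # positions keep every other one, starting from the leftmost
  grp <- cumsum(c(TRUE, diff(m) != 1L))
  first <- m[!duplicated(grp)]
  m[(m - first[grp]) %% 2L == 0L]
}

#' Measure matrix-multiplication unit costs
#'
#' Times an `(n_min x n_min) . vector` multiply (`t_mv`) and an
#' `(n_min x n_min) . (n_min x n_min)` multiply (`t_mm`), taking the median
#' over `repetitions` timed batches. These unit costs feed the compression
#' stopping criterion: a substitution round is worthwhile while the expected
#' saving `e * (t_mv * p - t_mm)` exceeds the round's own cost.
#'
#' @param n_min smallest state-space size the preprocessing will be reused
#'   for.
#' @param repetitions number of timed batches (`>= 1`).
#' @return a list with strictly positive elements `t_mv` and `t_mm`, in
#'   seconds per multiplication.
#' @seealso [compression_calibration()], [should_stop()]
#' @export
calibrate <- function(n_min, repetitions = 5L) {
  if (n_min < 1L) stop("n_min must be >= 1", call. = FALSE)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  a <- matrix(stats::runif(n_min * n_min), n_min, n_min)
  v <- stats::runif(n_min)
  inner <- max(50L, as.integer(2e5 / max(1, n_min * n_min)))
  time_op <- function(op) {
    med <- stats::median(vapply(seq_len(repetitions), function(i) {
      t0 <- proc.time()[["elapsed"]]
      for (j in seq_len(inner)) op()
      (proc.time()[["elapsed"]] - t0) / inner
    }, numeric(1)))
    max(med, 1e-12)
  }
  list(t_mv = time_op(function() a %*% v),
       t_mm = time_op(function() a %*% a))
}

#' Compression calibration and stopping configuration
#'
#' Bundles everything the stopping criterion needs: the state-space sizes the
#' preprocessing should be saved for (`thresholds`), the expected number of
#' reuses `e`, and the unit costs `t_mv` / `t_mm` per threshold. When
#' `thresholds` is non-empty and unit costs are not supplied, they are
#' measured per threshold with [calibrate()]. When `thresholds` is empty, no
#' timings are needed: compression stops the first time two consecutive
#' rounds find the same maximal pair count.
#'
#' @param thresholds integer vector of `N_min` values (possibly empty).
#' @param e expected number of reuses of the preprocessing (`>= 1`);
#'   default 1.
#' @param t_mv,t_mm optional explicit unit costs (seconds), recycled across
#'   thresholds; supplying them bypasses measurement and makes the stopping
#'   behaviour reproducible.
#' @param fixed_round_time optional fixed value (seconds) to use as every
#'   round's recorded duration instead of wall-clock measurement; useful for
#'   fully deterministic stopping in tests and examples.
#' @param repetitions timing batches passed to [calibrate()].
#' @return an object of class `"compression_calibration"`.
#' @export
compression_calibration <- function(thresholds = integer(0), e = 1,
                                    t_mv = NULL, t_mm = NULL,
                                    fixed_round_time = NULL,
                                    repetitions = 5L) {
  thresholds <- as.integer(thresholds)
  if (anyNA(thresholds) || any(thresholds < 1L))
    stop("thresholds must be positive integers", call. = FALSE)
  if (anyDuplicated(thresholds))
    stop("thresholds must be distinct", call. = FALSE)
  if (!is.numeric(e) || length(e) != 1L || e < 1)
    stop("e must be a number >= 1", call. = FALSE)
  k <- length(thresholds)
  if (k > 0L) {
    if (is.null(t_mv) != is.null(t_mm))
      stop("supply both t_mv and t_mm or neither", call. = FALSE)
    if (is.null(t_mv)) {
      timed <- lapply(thresholds, calibrate, repetitions = repetitions)
      t_mv <- vapply(timed, `[[`, numeric(1), "t_mv")
      t_mm <- vapply(timed, `[[`, numeric(1), "t_mm")
    } else {
      t_mv <- rep_len(as.numeric(t_mv), k)
      t_mm <- rep_len(as.numeric(t_mm), k)
    }
    if (any(t_mv <= 0) || any(t_mm <= 0))
      stop("t_mv and t_mm must be strictly positive", call. = FALSE)
  } else {
    t_mv <- numeric(0)
    t_mm <- numeric(0)
  }
  ord <- order(thresholds, decreasing = TRUE)
  structure(list(thresholds = thresholds[ord], e = as.numeric(e),
                 t_mv = t_mv[ord], t_mm = t_mm[ord],
                 fixed_round_time = fixed_round_time),
            class = "compression_calibration")
}

#' Compression stopping criterion
#'
#' A further substitution round is no longer worthwhile when the expected
#' saving across `e` reuses no longer covers the round's cost:
#' `e * (t_mv * p_prev - t_mm) - pre_prev <= 0`, where `p_prev` is the pair
#' count found in the previous round and `pre_prev` its duration (the
#' estimate for the coming round's cost).
#'
#' @param calib a [compression_calibration()] object.
#' @param p_prev occurrence count of the pair found in the previous round.
#' @param pre_prev previous round's duration in seconds.
#' @param threshold_index which stored threshold's unit costs to use
#'   (default 1).
#' @return `TRUE` when compression should stop before the next round.
#' @export
should_stop <- function(calib, p_prev, pre_prev, threshold_index = 1L) {
  stopifnot(inherits(calib, "compression_calibration"),
            p_prev >= 0, pre_prev >= 0)
  if (length(calib$thresholds) < threshold_index)
    stop("calibration has no threshold ", threshold_index, call. = FALSE)
  tmv <- calib$t_mv[threshold_index]
  tmm <- calib$t_mm[threshold_index]
  calib$e * (tmv * p_prev - tmm) - pre_prev <= 0
}

#' Compress an observed sequence by most-frequent-pair substitution
#'
#' The first symbol `y_1` is stored separately (its forward-algorithm term is
#' the initial vector, not a square matrix) and never participates in
#' substitution. Positions `2..T` are then compressed round by round: each
#' round counts all adjacent pairs, selects the most frequent one
#' (lexicographic tie-break) and replaces its non-overlapping occurrences by
#' the next fresh symbol.
#'
#' With saved-state thresholds in `calib`, thresholds are processed from
#' largest to smallest; a snapshot of the sequence and alphabet is taken for
#' each threshold when its own stopping criterion ([should_stop()]) fires,
#' and compression continues for the smaller thresholds. Without thresholds,
#' compression stops the first time a round's maximal pair count equals the
#' previous round's, and the single snapshot is stored under threshold 1.
#'
#' @param x an object of class `"obs_seq"`.
#' @param calib a [compression_calibration()] object; the default compresses
#'   until the pair count stops decreasing.
#' @param verbose if `TRUE`, log each round's pair, count and duration to
#'   standard error.
#' @return an object of class `"compressed_obs"`: a list with
#'   `first_symbol`, `original_length`, `original_alphabet_size`,
#'   `table` (a `"substitution_table"`), `per_threshold` (named list keyed by
#'   `N_min`, each entry holding `alphabet_size` and `tokens`), `rounds` (a
#'   data frame of per-round statistics: pair, count `p_i`, seconds `pre_i`)
#'   and `e`.
#' @examples
#' s <- obs_seq(c(1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1), 2)
#' p <- preprocess(s)
#' p$rounds
#' @seealso [expand_symbol()], [save_preprocessing()], [forward_compressed()]
#' @export
preprocess <- function(x, calib = compression_calibration(),
                       verbose = FALSE) {
  stopifnot(inherits(x, "obs_seq"),
            inherits(calib, "compression_calibration"))
  first <- x$tokens[1L]
  tokens <- x$tokens[-1L]
  m <- x$alphabet_size
  k <- m                      # current alphabet extent
  n_th <- length(calib$thresholds)
  ti <- 1L                    # next threshold (largest first) awaiting snapshot
  per <- list()
  rules <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("new", "left", "right")))
  stats_rows <- list()
  prev_p <- NA_integer_
  prev_pre <- NA_real_
  round_i <- 0L
  snapshot <- function() list(alphabet_size = k, tokens = tokens)

  repeat {
    # threshold-mode stop checks, before starting the next round
    if (n_th > 0L && !is.na(prev_p)) {
      while (ti <= n_th && should_stop(calib, prev_p, prev_pre, ti)) {
        per[[as.character(calib$thresholds[ti])]] <- snapshot()
        ti <- ti + 1L
      }
      if (ti > n_th) break
    }
    t0 <- proc.time()[["elapsed"]]
    cnt <- .pair_counts_vec(tokens, k)
    if (length(cnt) == 0L) break
    best <- which.max(cnt)           # first max = lexicographically smallest
    p <- cnt[best]
    if (p == 0L) break               # no adjacent pair left
    if (n_th == 0L && !is.na(prev_p) && p == prev_p) break
    l <- (best - 1L) %/% k
    r <- (best - 1L) %% k
    keep <- .pair_positions(tokens, l, r)
    tokens[keep] <- k
    tokens <- tokens[-(keep + 1L)]
    rules <- rbind(rules, c(k, l, r))
    k <- k + 1L
    pre_i <- if (!is.null(calib$fixed_round_time)) calib$fixed_round_time
             else proc.time()[["elapsed"]] - t0
    stats_rows[[length(stats_rows) + 1L]] <-
      c(round_i, l, r, p, pre_i)
    if (verbose)
      message(sprintf("round %d: pair (%d,%d) x %d -> symbol %d (%.3gs)",
                      round_i, l, r, p, k - 1L, pre_i))
    prev_p <- p
    prev_pre <- pre_i
    round_i <- round_i + 1L
  }
  # natural stop: snapshot anything still pending
  if (n_th > 0L) {
    while (ti <= n_th) {
      per[[as.character(calib$thresholds[ti])]] <- snapshot()
      ti <- ti + 1L
    }
  } else {
    per[["1"]] <- snapshot()
  }
  rounds <- if (length(stats_rows) > 0L) {
    df <- as.data.frame(do.call(rbind, stats_rows))
    names(df) <- c("round", "left", "right", "pair_count", "seconds")
    df
  } else {
    data.frame(round = integer(0), left = integer(0), right = integer(0),
               pair_count = integer(0), seconds = numeric(0))
  }
  structure(list(first_symbol = first,
                 original_length = x$length,
                 original_alphabet_size = m,
                 table = substitution_table(rules, m),
                 per_threshold = per,
                 rounds = rounds,
                 e = calib$e),
            class = "compressed_obs")
}

#' @export
print.compressed_obs <- function(x, ...) {
  cat(sprintf(
    "Compressed sequence: T = %d, original alphabet %d, %d substitution rules\n",
    x$original_length, x$original_alphabet_size, nrow(x$table$rules)))
  for (nm in names(x$per_threshold)) {
    th <- x$per_threshold[[nm]]
    cat(sprintf("  threshold N_min = %s: alphabet %d, compressed length %d (from %d)\n",
                nm, th$alphabet_size, length(th$tokens) + 1L,
                x$original_length))
  }
  invisible(x)
}

#' Substitution table mapping composite symbols to their constituents
#'
#' Rule `i` defines composite symbol `M + i - 1` (0-based original alphabet
#' `0..M-1`) as the pair `(left, right)`; constituents always predate the
#' composite, so the table is acyclic by construction.
#'
#' @param rules integer matrix with columns `new`, `left`, `right`, one row
#'   per rule in creation order (may have zero rows).
#' @param original_alphabet_size size `M` of the original alphabet.
#' @return an object of class `"substitution_table"`.
#' @export
substitution_table <- function(rules, original_alphabet_size) {
  rules <- matrix(as.integer(rules), ncol = 3L,
                  dimnames = list(NULL, c("new", "left", "right")))
  m <- as.integer(original_alphabet_size)
  if (nrow(rules) > 0L) {
    expected <- m + seq_len(nrow(rules)) - 1L
    if (!all(rules[, "new"] == expected))
      stop("rules must define symbols consecutively from ", m, call. = FALSE)
    if (any(rules[, "left"] >= rules[, "new"]) ||
        any(rules[, "right"] >= rules[, "new"]))
      stop("rule constituents must predate the composite symbol",
           call. = FALSE)
  }
  structure(list(rules = rules, original_alphabet_size = m),
            class = "substitution_table")
}

# Expansions of all symbols < extent as a list of original-alphabet vectors.
.expansions <- function(table, extent = NULL) {
  m <- table$original_alphabet_size
  n_rules <- nrow(table$rules)
  if (is.null(extent)) extent <- m + n_rules
  exp <- vector("list", extent)
  for (o in seq_len(min(m, extent))) exp[[o]] <- o - 1L
  if (extent > m) {
    for (i in seq_len(extent - m)) {
      l <- table$rules[i, "left"]
      r <- table$rules[i, "right"]
      exp[[m + i]] <- c(exp[[l + 1L]], exp[[r + 1L]])
    }
  }
  exp
}

#' Expand a symbol back to the original alphabet
#'
#' Original symbols expand to themselves; a composite symbol expands to the
#' concatenated expansions of its two constituents, recursively.
#'
#' @param symbol integer symbol code.
#' @param table a [substitution_table()].
#' @return integer vector of original-alphabet symbols.
#' @examples
#' tb <- substitution_table(rbind(c(2, 0, 0), c(3, 2, 2)), 2)
#' expand_symbol(3, tb)   # 0 0 0 0
#' @export
expand_symbol <- function(symbol, table) {
  stopifnot(inherits(table, "substitution_table"))
  symbol <- as.integer(symbol)
  extent <- table$original_alphabet_size + nrow(table$rules)
  if (symbol < 0L || symbol >= extent)
    stop("unknown symbol ", symbol, " (alphabet extent ", extent, ")",
         call. = FALSE)
  .expansions(table, symbol + 1L)[[symbol + 1L]]
}

#' Reconstruct the original sequence from a compressed snapshot
#'
#' Expands every compressed token through the substitution table and prepends
#' the separately stored first symbol.
#'
#' @param pre an object of class `"compressed_obs"`.
#' @param threshold which stored threshold to expand (defaults to the first).
#' @return an object of class `"obs_seq"` equal to the original input.
#' @export
expand_compressed <- function(pre, threshold = NULL) {
  stopifnot(inherits(pre, "compressed_obs"))
  sel <- if (is.null(threshold)) 1L else {
    i <- match(as.character(threshold), names(pre$per_threshold))
    if (is.na(i)) stop("no stored threshold ", threshold, call. = FALSE)
    i
  }
  th <- pre$per_threshold[[sel]]
  exp <- .expansions(pre$table, th$alphabet_size)
  suffix <- if (length(th$tokens) > 0L) unlist(exp[th$tokens + 1L]) else integer(0)
  obs_seq(c(pre$first_symbol, suffix), pre$original_alphabet_size)
}

#' Save a preprocessing to a directory
#'
#' Writes an all-text directory layout: `metadata.txt` (format version, `T`,
#' `M`, first symbol, `e`, thresholds with their alphabet sizes), `rules.txt`
#' (one `new left right` triple per line in creation order) and one
#' `seq_<N_min>.txt` token file per stored threshold.
#'
#' @param pre an object of class `"compressed_obs"`.
#' @param directory output directory (created if missing).
#' @return `invisible(directory)`.
#' @seealso [load_preprocessing()]
#' @export
save_preprocessing <- function(pre, directory) {
  stopifnot(inherits(pre, "compressed_obs"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  ths <- names(pre$per_threshold)
  meta <- c("cfhmm_prep 1",
            sprintf("T %d", pre$original_length),
            sprintf("M %d", pre$original_alphabet_size),
            sprintf("first_symbol %d", pre$first_symbol),
            sprintf("e %.17g", pre$e),
            sprintf("thresholds %s", paste(ths, collapse = " ")),
            vapply(ths, function(nm)
              sprintf("alphabet %s %d", nm,
                      pre$per_threshold[[nm]]$alphabet_size),
              character(1)))
  writeLines(meta, file.path(directory, "metadata.txt"))
  rl <- pre$table$rules
  writeLines(if (nrow(rl) > 0L)
               apply(rl, 1L, paste, collapse = " ") else character(0),
             file.path(directory, "rules.txt"))
  for (nm in ths) {
    writeLines(paste(pre$per_threshold[[nm]]$tokens, collapse = " "),
               file.path(directory, sprintf("seq_%s.txt", nm)))
  }
  invisible(directory)
}

#' Load a preprocessing, restricted to the best stored threshold
#'
#' Selects the stored threshold with the largest `N_min <= n_states`; when
#' none qualifies, falls back to the smallest stored threshold with a
#' warning.
#'
#' @param directory directory written by [save_preprocessing()].
#' @param n_states number of states of the model the preprocessing will be
#'   used with (`>= 1`).
#' @return an object of class `"compressed_obs"` containing the selected
#'   threshold only.
#' @export
load_preprocessing <- function(directory, n_states) {
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  meta_path <- file.path(directory, "metadata.txt")
  if (!file.exists(meta_path))
    stop("missing file: ", meta_path, call. = FALSE)
  lines <- readLines(meta_path, warn = FALSE)
  if (length(lines) < 1L || !startsWith(lines[[1L]], "cfhmm_prep"))
    stop(meta_path, ": not a preprocessing directory (bad header)",
         call. = FALSE)
  fields <- strsplit(lines, "\\s+")
  get1 <- function(key) {
    i <- which(vapply(fields, function(f) f[1L] == key, logical(1)))
    if (length(i) == 0L)
      stop(meta_path, ": missing field '", key, "'", call. = FALSE)
    fields[[i[1L]]][-1L]
  }
  tt <- as.integer(get1("T"))
  m <- as.integer(get1("M"))
  first <- as.integer(get1("first_symbol"))
  e <- as.numeric(get1("e"))
  ths <- as.integer(get1("thresholds"))
  if (length(ths) == 0L || anyNA(ths))
    stop(meta_path, ": no stored thresholds", call. = FALSE)
  alpha <- integer(length(ths))
  names(alpha) <- as.character(ths)
  for (f in fields[vapply(fields, function(f) f[1L] == "alphabet", logical(1))])
    alpha[[f[2L]]] <- as.integer(f[3L])
  ok <- ths[ths <= n_states]
  sel <- if (length(ok) > 0L) max(ok) else {
    warning("no stored threshold <= ", n_states,
            "; falling back to smallest stored threshold ", min(ths))
    min(ths)
  }
  rules_path <- file.path(directory, "rules.txt")
  if (!file.exists(rules_path))
    stop("missing file: ", rules_path, call. = FALSE)
  rl <- scan(rules_path, what = integer(), quiet = TRUE)
  rules <- matrix(rl, ncol = 3L, byrow = TRUE,
                  dimnames = list(NULL, c("new", "left", "right")))
  seq_path <- file.path(directory, sprintf("seq_%d.txt", sel))
  if (!file.exists(seq_path))
    stop("missing file: ", seq_path, call. = FALSE)
  raw <- readLines(seq_path, warn = FALSE)
  tokens <- if (all(!nzchar(trimws(raw)))) integer(0)
            else scan(text = raw, what = integer(), quiet = TRUE)
  per <- list()
  per[[as.character(sel)]] <- list(alphabet_size = alpha[[as.character(sel)]],
                                   tokens = tokens)
  structure(list(first_symbol = first,
                 original_length = tt,
                 original_alphabet_size = m,
                 table = substitution_table(rules, m),
                 per_threshold = per,
                 rounds = NULL,
                 e = e),
            class = "compressed_obs")
}
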