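#' Number of fixed-length windows in a series
#'
#' @param series_len Length of the source series in samples.
#' @param window_len Window length `T` in samples.
#' @param stride Hop between consecutive window starts, in samples.
#' @return `floor((series_len - window_len) / stride) + 1` when the series
#'   holds at least one window, else 0. Trailing partial windows are
#'   discarded.
#' @export
count_windows <- function(series_len, window_len, stride) {
  stopifnot(window_len >= 1, stride >= 1)
  if (series_len < window_len) return(0L)
  as.integer(floor((series_len - window_len) / stride) + 1L)
}

#' Labeled window set
#'
#' The packaged classifier input: an `n x T x F` array of `n` windows of
#' `T` consecutive scalar samples over `F` feature channels, with one
#' integer subject label per window. Labels are 0-based indices into
#' `label_names`.
#'
#' @param windows `n x T x F` numeric array.
#' @param labels Integer vector of length `n`, values in `[0, K)`.
#' @param label_names Character vector of the `K` distinct subject ids.
#' @param feature_names Character vector of the `F` channel names.
#' @param stride Stride used at extraction (bookkeeping).
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, label_names, feature_names,
                       stride = dim(windows)[2L]) {
  if (length(dim(windows)) != 3L)
    stop("`windows` must be an n x T x F array")
  labels <- as.integer(labels)
  if (length(labels) != dim(windows)[1L])
    stop("one label per window required")
  if (anyNA(windows) || any(!is.finite(windows)))
    stop("windows must contain only finite values")
  K <- length(label_names)
  if (anyDuplicated(label_names))
    stop("identity error: duplicated subject ids in label_names")
  if (length(labels) > 0L && (min(labels) < 0L || max(labels) >= K))
    stop("labels must lie in [0, K)")
  if (length(feature_names) != dim(windows)[3L])
    stop("one feature name per channel required")
  structure(list(windows = windows, labels = labels,
                 label_names = as.character(label_names),
                 feature_names = as.character(feature_names),
                 window_len = dim(windows)[2L], stride = as.integer(stride)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x %d (%s), %d subject(s), stride %d\n",
              dim(x$windows)[1L], x$window_len, length(x$feature_names),
              paste(x$feature_names, collapse = ", "),
              length(x$label_names), x$stride))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A [window_set()].
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1L]

# internal: subset a window_set by window index, keeping all class slots
ws_subset <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$label_names, ws$feature_names, stride = ws$stride)
}

# internal: concatenate feature channels of aligned window sets (same
# windows/labels, different sensors)
ws_bind_features <- function(a, b) {
  stopifnot(inherits(a, "window_set"), inherits(b, "window_set"))
  if (n_windows(a) != n_windows(b) || a$window_len != b$window_len)
    stop("alignment error: window sets differ in shape")
  if (!identical(a$labels, b$labels) || !identical(a$label_names, b$label_names))
    stop("alignment error: window sets differ in labels")
  da <- dim(a$windows); db <- dim(b$windows)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a$windows
  out[, , da[3L] + seq_len(db[3L])] <- b$windows
  window_set(out, a$labels, a$label_names,
             c(a$feature_names, b$feature_names), stride = a$stride)
}

#' Package scalar series into fixed-length windows
#'
#' Cuts one or more time-aligned scalar channels of the same subject into
#' windows of `window_len` consecutive samples taken every `stride` samples,
#' in start-time order. Window `i` (0-based) covers source indices
#' `[i * stride, i * stride + window_len)`.
#'
#' @param series A [scalar_series()] or a list of equal-length, time-aligned
#'   `scalar_series` of the same subject (one per feature channel).
#' @param window_len Window length `T` in samples; default 150 (3 s at
#'   50 Hz).
#' @param stride Hop between window starts; default `floor(window_len / 2)`
#'   (half-segment overlap). Use `stride = window_len` for disjoint windows.
#' @param label 0-based integer class label assigned to every window.
#' @param label_names Subject ids indexed by `label`; defaults to the
#'   subject of `series`.
#' @return A [window_set()]. A series shorter than `window_len` yields an
#'   empty set with a warning.
#' @export
make_windows <- function(series, window_len = 150L,
                         stride = max(1L, floor(window_len / 2)),
                         label = 0L, label_names = NULL) {
  if (inherits(series, "scalar_series")) series <- list(series)
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1L), "scalar_series")))
  window_len <- as.integer(window_len); stride <- as.integer(stride)
  stopifnot(window_len >= 1L, stride >= 1L)
  lens <- vapply(series, function(s) length(s$values), integer(1L))
  if (length(unique(lens)) != 1L)
    stop("alignment error: feature series have unequal lengths")
  subj <- unique(vapply(series, function(s) s$subject_id, character(1L)))
  if (length(subj) != 1L)
    stop("alignment error: feature series belong to different subjects")
  if (is.null(label_names)) {
    label_names <- character(label + 1L)
    label_names[label + 1L] <- subj
    if (label > 0L) label_names[seq_len(label)] <- paste0("<unset-", seq_len(label), ">")
  }
  L <- lens[1L]
  n <- count_windows(L, window_len, stride)
  F_ <- length(series)
  feats <- vapply(series, function(s) s$quantity, character(1L))
  if (n == 0L) {
    warning(sprintf("series of length %d holds no window of length %d", L, window_len))
    return(window_set(array(0, dim = c(0L, window_len, F_)), integer(0L),
                      label_names, feats, stride = stride))
  }
  starts <- (seq_len(n) - 1L) * stride
  w <- array(0, dim = c(n, window_len, F_))
  off <- outer(starts, seq_len(window_len), `+`)  # n x T matrix of indices
  for (f in seq_len(F_)) w[, , f] <- series[[f]]$values[off]
  window_set(w, rep.int(as.integer(label), n), label_names, feats,
             stride = stride)
}

#' One-hot encode integer class labels
#'
#' @param labels Integer vector with values in `[0, K)`.
#' @param K Number of classes.
#' @return An `n x K` binary matrix of class `one_hot_labels`; row `i` has a
#'   single 1 in column `labels[i] + 1`.
#' @export
encode_one_hot <- function(labels, K) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  stopifnot(K >= 1L)
  if (length(labels) > 0L && (min(labels) < 0L || max(labels) >= K))
    stop(sprintf("domain error: labels must lie in [0, %d)", K))
  m <- matrix(0, nrow = length(labels), ncol = K)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  structure(m, class = c("one_hot_labels", "matrix", "array"))
}

#' Invert a one-hot encoding
#'
#' @param one_hot A binary `n x K` matrix as produced by [encode_one_hot()].
#' @return The 0-based integer labels (column index of each row's 1).
#' @export
decode_one_hot <- function(one_hot) {
  max.col(unclass(one_hot), ties.method = "first") - 1L
}

#' Random train/test split of a window set
#'
#' Splits windows into disjoint, exhaustive train and test subsets by a
#' uniform random permutation driven solely by `seed`. The test size is
#' `round(n * test_fraction)` (round-half-even).
#'
#' @param ws A [window_set()] with at least 2 windows.
#' @param test_fraction Fraction of windows held out, in (0, 1);
#'   default 0.3.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return An object of class `split_result`: list with `train` and `test`
#'   window sets, the `train_idx`/`test_idx` used, `seed` and
#'   `test_fraction`.
#' @export
split_train_test <- function(ws, test_fraction = 0.3, seed = 10L) {
  stopifnot(inherits(ws, "window_set"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  n <- n_windows(ws)
  if (n < 2L) stop("split error: need at least 2 windows")
  n_test <- as.integer(round(n * test_fraction))
  if (n_test < 1L || n_test >= n)
    stop("split error: one side of the split would be empty")
  perm <- with_local_seed(seed, sample.int(n))
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[(n_test + 1L):n])
  structure(list(train = ws_subset(ws, train_idx),
                 test = ws_subset(ws, test_idx),
                 train_idx = train_idx, test_idx = test_idx,
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "split_result")
}

#' Merge window sets of disjoint subject cohorts
#'
#' Concatenates window sets recorded from different subjects into one set
#' with a contiguous 0-based label space: the first set keeps its labels,
#' each following set is offset by the number of subjects seen so far (so
#' appending 2 subjects to a 15-subject cohort yields ids 15 and 16).
#'
#' @param sets List of [window_set()]s with identical window length,
#'   feature channels and stride, and pairwise-disjoint subject ids.
#' @return The merged `window_set`.
#' @export
merge_cohorts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "window_set")))
  if (length(sets) == 1L) return(sets[[1L]])
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (s$window_len != ref$window_len ||
        !identical(s$feature_names, ref$feature_names))
      stop("alignment error: window sets differ in window length or features")
  }
  all_names <- unlist(lapply(sets, `[[`, "label_names"))
  if (anyDuplicated(all_names))
    stop(sprintf("identity error: subject id '%s' appears in more than one set",
                 all_names[anyDuplicated(all_names)]))
  offsets <- cumsum(c(0L, vapply(sets, function(s) length(s$label_names),
                                 integer(1L))))
  labels <- unlist(lapply(seq_along(sets),
                          function(i) sets[[i]]$labels + offsets[i]))
  n_tot <- sum(vapply(sets, n_windows, integer(1L)))
  w <- array(0, dim = c(n_tot, ref$window_len, length(ref$feature_names)))
  at <- 0L
  for (s in sets) {
    n <- n_windows(s)
    if (n > 0L) w[at + seq_len(n), , ] <- s$windows
    at <- at + n
  }
  window_set(w, labels, all_names, ref$feature_names, stride = ref$stride)
}

# internal: evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
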