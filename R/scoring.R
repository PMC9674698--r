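#' Describe a model head
#'
#' A head kind bundles the output type of a severity model with its number of
#' classes `k`. Four kinds are supported: `"binary"` (one sigmoid unit),
#' `"multiclass"` (`k` softmax units), `"ordinal"` (`k - 1` cumulative sigmoid
#' units) and `"regression"` (one linear unit).
#'
#' @param kind One of `"binary"`, `"multiclass"`, `"ordinal"`, `"regression"`.
#' @param k Number of ordinal classes (`k = 2` for binary; `k >= 3` for
#'   multiclass and ordinal heads, which are otherwise indistinguishable from
#'   the binary head).
#' @return An object of class `head_kind` with fields `kind` and `k`.
#' @examples
#' head_kind("multiclass", 5)
#' head_kind("ordinal", 3)
#' @export
head_kind <- function(kind = c("binary", "multiclass", "ordinal", "regression"),
                      k = 2L) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) abort("`k` must be an integer >= 2.")
  if (kind == "binary" && k != 2L) abort("binary heads have k = 2.")
  if (kind %in% c("multiclass", "ordinal") && k < 3L) {
    abort(sprintf("%s heads require k >= 3 (use a binary head for k = 2).", kind))
  }
  structure(list(kind = kind, k = k), class = "head_kind")
}

#' @exportS3Method base::print
print.head_kind <- function(x, ...) {
  cat(sprintf("<head_kind> %s, k = %d (output width %d)\n",
              x$kind, x$k, head_width(x)))
  invisible(x)
}

# Number of raw output units of a head.
head_width <- function(head) {
  switch(head$kind,
         binary = 1L, regression = 1L,
         multiclass = head$k, ordinal = head$k - 1L)
}

# Score range (lo, hi) of a classification head on its severity scale.
score_range <- function(head) {
  switch(head$kind,
         binary = c(0, 1),
         multiclass = c(0, head$k - 1),
         ordinal = c(0, head$k - 1),
         regression = c(0, head$k - 1))
}

check_prob_vector <- function(p, tol = 1e-6) {
  if (anyNA(p) || any(p < -tol) || any(p > 1 + tol)) {
    abort("probabilities must lie in [0, 1].")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("probability vector must sum to 1 (got %.8f).", sum(p)))
  }
  invisible(p)
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' Continuous severity score from class probabilities
#'
#' Maps a `k`-class probability vector to the expected class index,
#' `score = sum_i p_i * (i - 1)` with one-based `i`, i.e. the probability-
#' weighted average of the zero-based class indices. The score lies in
#' `[0, k - 1]` and is linear in `p`, so the score of an average of
#' probability vectors equals the average of their scores.
#'
#' @param p A probability vector of length `k`, or a matrix with one vector
#'   per row.
#' @param tol Tolerance for the simplex check.
#' @return A numeric score (one per row of `p`).
#' @examples
#' score_from_probs(c(0, 0, 0, 0, 1)) # 4: all mass on the highest of 5 classes
#' score_from_probs(c(1, 1, 1) / 3)   # 1: uniform over 3 classes
#' @export
score_from_probs <- function(p, tol = 1e-6) {
  m <- as_row_matrix(p)
  apply(m, 1L, check_prob_vector, tol = tol)
  drop(m %*% (seq_len(ncol(m)) - 1))
}

#' Continuous severity score from ordinal (cumulative) outputs
#'
#' An ordinal head for `k` classes emits `k - 1` sigmoid outputs, the j-th
#' estimating `P(class > j - 1)`. The severity score is their sum, lying in
#' `[0, k - 1]`.
#'
#' @param q A vector of `k - 1` values in `[0, 1]`, or a matrix with one
#'   output vector per row.
#' @return A numeric score (one per row of `q`).
#' @examples
#' score_from_ordinal(c(1, 1))        # 2: saturated 3-class ordinal output
#' score_from_ordinal(c(0.9, 0.5, 0.1))
#' @export
score_from_ordinal <- function(q) {
  m <- as_row_matrix(q)
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    abort("ordinal outputs must lie in [0, 1].")
  }
  rowSums(m)
}

#' Severity score of a binary head
#'
#' The positive-class probability is used directly as the severity score.
#'
#' @param p_pos Positive-class probability (vectorized).
#' @return `p_pos`, validated to lie in `[0, 1]`.
#' @export
score_from_binary <- function(p_pos) {
  if (anyNA(p_pos) || any(p_pos < 0) || any(p_pos > 1)) {
    abort("binary probabilities must lie in [0, 1].")
  }
  as.numeric(p_pos)
}

#' Cumulative (ordinal) encoding of a class label
#'
#' Encodes a zero-based class `c` of a `k`-class ordinal problem as `k - 1`
#' binary targets, a prefix of `c` ones followed by zeros: for `k = 3`,
#' class 0 -> (0, 0), class 1 -> (1, 0), class 2 -> (1, 1).
#'
#' @param c Zero-based class label(s) in `0..k-1`.
#' @param k Number of classes.
#' @return An integer vector of length `k - 1`, or a matrix with one encoding
#'   per row when `c` has length > 1.
#' @export
encode_ordinal_label <- function(c, k) {
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  if (anyNA(c) || any(c < 0L) || any(c > k - 1L) || any(c != floor(c))) {
    abort("class labels must be integers in 0..k-1.")
  }
  enc <- outer(as.integer(c), seq_len(k - 1L), function(ci, j) as.integer(j <= ci))
  if (length(c) == 1L) drop(enc) else enc
}

#' Equal-range decision thresholds
#'
#' Splits the score range `[lo, hi]` into `k` equal-width intervals and
#' returns the `k - 1` interior cut points `lo + j * (hi - lo) / k`. Used to
#' discretize regression (and other continuous) severity scores into classes;
#' e.g. a 3-class problem on `[0, 2]` yields cuts at 0.67 and 1.33 (2 d.p.).
#'
#' @param k Number of classes (`>= 2`).
#' @param lo,hi Score range endpoints, `lo < hi`.
#' @return Numeric vector of `k - 1` strictly increasing thresholds.
#' @export
equal_range_thresholds <- function(k, lo, hi) {
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("degenerate score range: need lo < hi.")
  }
  lo + seq_len(k - 1L) * (hi - lo) / k
}

#' Discrete class decision from a head output
#'
#' Deterministic decision rules per head kind:
#' \itemize{
#'   \item multiclass: argmax of the probability vector, ties broken toward
#'     the lower class index;
#'   \item binary: positive iff `p_pos >= 0.5`;
#'   \item ordinal: number of cumulative outputs `>= 0.5`;
#'   \item regression: interval index under [equal_range_thresholds()] on the
#'     head's score range, interior intervals left-open/right-closed
#'     (`s <= t_1` -> class 0; `t_1 < s <= t_2` -> class 1; ...;
#'     `s > t_{k-1}` -> class `k - 1`), so the whole real line is covered and
#'     unclamped regression scores always decide a class.
#' }
#'
#' @param output The raw head output: probability vector/matrix (multiclass),
#'   scalar/vector `p_pos` (binary), `k - 1` vector/matrix (ordinal), or
#'   numeric score(s) (regression).
#' @param head A [head_kind()].
#' @param thresholds Optional thresholds for the regression rule; defaults to
#'   [equal_range_thresholds()] on the head's score range.
#' @return Integer class decision(s) in `0..k-1`.
#' @export
decide_class <- function(output, head, thresholds = NULL) {
  stopifnot(inherits(head, "head_kind"))
  switch(head$kind,
    multiclass = {
      m <- as_row_matrix(output)
      if (ncol(m) != head$k) abort("multiclass output must have k columns.")
      apply(m, 1L, check_prob_vector)
      as.integer(max.col(m, ties.method = "first") - 1L)
    },
    binary = {
      as.integer(score_from_binary(output) >= 0.5)
    },
    ordinal = {
      m <- as_row_matrix(output)
      if (ncol(m) != head$k - 1L) abort("ordinal output must have k - 1 columns.")
      as.integer(rowSums(m >= 0.5))
    },
    regression = {
      s <- as.numeric(output)
      if (is.null(thresholds)) {
        r <- score_range(head)
        thresholds <- equal_range_thresholds(head$k, r[1], r[2])
      }
      # class = number of thresholds strictly below s (left-open, right-closed)
      vapply(s, function(si) sum(si > thresholds), integer(1))
    })
}

#' Severity score for any head output
#'
#' Dispatches to the per-head score mapping: [score_from_probs()]
#' (multiclass), [score_from_ordinal()] (ordinal), [score_from_binary()]
#' (binary) or the identity (regression, unconstrained).
#'
#' @inheritParams decide_class
#' @return Numeric severity score(s).
#' @export
severity_score <- function(output, head) {
  stopifnot(inherits(head, "head_kind"))
  switch(head$kind,
         multiclass = score_from_probs(output),
         ordinal = score_from_ordinal(output),
         binary = score_from_binary(output),
         regression = as.numeric(output))
}

#' Score and classify a table of head outputs
#'
#' Convenience wrapper used by the evaluation pipeline: takes a matrix of raw
#' head outputs (one row per image) and returns a tibble of severity scores
#' and class decisions.
#'
#' @param outputs Matrix of head outputs, one row per image.
#' @param head A [head_kind()].
#' @return A tibble with columns `score` and `decision`.
#' @export
score_outputs <- function(outputs, head) {
  tibble(score = severity_score(outputs, head),
         decision = decide_class(outputs, head))
}
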