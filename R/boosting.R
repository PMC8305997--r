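# Binary AdaBoost with decision stumps on a two-attribute training view.
# The stump weights (alpha) are what later drive BPA voting, so they are
# stored explicitly rather than folded into a prediction rule.

#' Create a two-attribute training view for one class pair
#'
#' @param x Numeric N x 2 matrix: values of the two selected attributes.
#' @param y Numeric/integer vector of labels in \{-1, +1\}.
#' @param attrs Integer pair: indices of the two attributes in the source
#'   table (provenance only).
#' @param classes Character pair: (positive class, negative class)
#'   (provenance only).
#' @return An object of class `pair_view`.
#' @export
pair_view <- function(x, y, attrs = c(1L, 2L), classes = c("pos", "neg")) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("a pair view holds exactly two attributes")
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  if (nrow(x) < 2) stop("need at least two training samples")
  if (anyNA(x)) stop("missing values must be filtered before training")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2) stop("both labels must be present")
  structure(list(x = x, y = y, attrs = as.integer(attrs),
                 classes = as.character(classes)),
            class = "pair_view")
}

#' Candidate stump thresholds for one attribute column
#'
#' Midpoints between consecutive sorted distinct values, plus one guard below
#' the minimum and one above the maximum (offset: half the smallest gap
#' between distinct values; fixed at 1 for a constant column). This grid
#' exhausts every distinct 0/1 labeling a single-threshold stump can produce
#' on the column, so a search over it is globally optimal.
#'
#' @param column Numeric vector (non-empty).
#' @return Increasing numeric vector of thresholds.
#' @examples
#' candidate_thresholds(c(1, 2, 4)) # 0.5 1.5 3.0 4.5
#' @export
candidate_thresholds <- function(column) {
  if (length(column) == 0) stop("empty column")
  v <- sort(unique(column))
  if (length(v) == 1) return(c(v - 1, v + 1))
  g <- min(diff(v)) / 2
  c(v[1] - g, (v[-length(v)] + v[-1]) / 2, v[length(v)] + g)
}

# predictions of a stump on an N x 2 matrix: +1 iff dir * x > dir * theta
.stump_outputs <- function(attr, threshold, direction, x) {
  ifelse(direction * x[, attr] > direction * threshold, 1, -1)
}

#' Fit the optimal decision stump under sample weights
#'
#' Exhaustive search over both attributes, all candidate thresholds and both
#' directions for the stump minimizing the weighted zero-one error
#' (weights are assumed normalized, so the error is a plain weighted sum).
#' Ties are broken deterministically: lowest attribute index, then lowest
#' threshold, then direction +1 before -1. Because the flipped direction of
#' any stump has error 1 - eps, the minimum never exceeds 0.5.
#'
#' @param view A [pair_view()].
#' @param w Numeric weight vector summing to 1.
#' @return List with `stump` (fields `attr`, `threshold`, `direction`),
#'   `error` (weighted error), and `pred` (stump outputs on the view).
#' @export
fit_stump <- function(view, w) {
  stopifnot(inherits(view, "pair_view"))
  if (length(w) != nrow(view$x)) stop("weight length mismatch")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  pos <- view$y > 0
  best <- NULL
  for (d in 1:2) {
    col <- view$x[, d]
    th <- candidate_thresholds(col)
    # +1 direction: h = +1 iff x > theta; -1 direction: h = +1 iff x < theta
    err_p <- colSums(w * (outer(col, th, ">") != pos))
    err_m <- colSums(w * (outer(col, th, "<") != pos))
    # interleave so the scan order is: threshold asc, +1 before -1
    errs <- as.vector(rbind(err_p, err_m))
    i <- which.min(errs)
    cand <- list(attr = d, threshold = th[(i + 1) %/% 2],
                 direction = if (i %% 2 == 1) 1 else -1,
                 error = errs[i])
    if (is.null(best) || cand$error < best$error) best <- cand
  }
  pred <- .stump_outputs(best$attr, best$threshold, best$direction, view$x)
  list(stump = best[c("attr", "threshold", "direction")],
       error = best$error, pred = pred)
}

#' Stump (weak classifier) weight from its weighted error
#'
#' alpha = 0.5 * ln((1 - eps) / eps), with eps clipped to
#' \[1e-10, 1 - 1e-10\] so that a perfect stump gets a large finite weight
#' instead of a divergent one.
#'
#' @param eps Weighted zero-one error of the stump.
#' @return The stump weight alpha.
#' @export
stump_weight <- function(eps) {
  eps <- min(max(eps, 1e-10), 1 - 1e-10)
  0.5 * log((1 - eps) / eps)
}

#' AdaBoost sample-weight update
#'
#' Each weight is multiplied by exp(-alpha * y * h(x)) and the vector is
#' renormalized to sum 1: misclassified samples gain relative weight when
#' alpha > 0.
#'
#' @param w Current weights (sum 1).
#' @param alpha Stump weight.
#' @param pred Stump outputs (+/-1) on the training samples.
#' @param y True labels (+/-1).
#' @return Updated weight vector summing to 1.
#' @export
update_weights <- function(w, alpha, pred, y) {
  if (length(w) != length(pred) || length(w) != length(y)) {
    stop("length mismatch")
  }
  u <- w * exp(-alpha * y * pred)
  s <- sum(u)
  if (!is.finite(s) || s <= 0) stop("degenerate weight update")
  u / s
}

#' Train a strong classifier by boosting decision stumps
#'
#' Runs up to `T` rounds of stump fitting, stump weighting and sample-weight
#' updating. Training stops early when a round produces a perfect stump
#' (weighted error below 1e-10: the weight update would collapse) or, after
#' the first round, an uninformative one (error >= 0.5, alpha <= 0). The
#' procedure is fully deterministic for a fixed view.
#'
#' @param view A [pair_view()].
#' @param T Maximum number of boosting rounds (weak classifiers), >= 1.
#' @return An object of class `strong_classifier` with parallel vectors
#'   `attr`, `threshold`, `direction`, `alpha` (one entry per recorded
#'   stump) and the `class_pair`.
#' @export
train_strong <- function(view, T = 20) {
  stopifnot(inherits(view, "pair_view"), T >= 1)
  n <- nrow(view$x)
  w <- rep(1 / n, n)
  attr <- integer(0); threshold <- numeric(0)
  direction <- numeric(0); alpha <- numeric(0)
  for (t in seq_len(T)) {
    fs <- fit_stump(view, w)
    eps <- fs$error
    if (eps >= 0.5 - 1e-12) {
      # no stump beats chance (e.g. XOR-like data): keep one near-zero-weight
      # stump so the classifier is non-empty, then stop
      if (t == 1) {
        attr <- fs$stump$attr; threshold <- fs$stump$threshold
        direction <- fs$stump$direction
        alpha <- stump_weight(0.5 - 1e-10)
      }
      break
    }
    a <- stump_weight(eps)
    attr <- c(attr, fs$stump$attr)
    threshold <- c(threshold, fs$stump$threshold)
    direction <- c(direction, fs$stump$direction)
    alpha <- c(alpha, a)
    if (eps < 1e-10) break # perfect stump: the weight update degenerates
    w <- update_weights(w, a, fs$pred, view$y)
  }
  structure(list(class_pair = view$classes, attrs = view$attrs,
                 attr = attr, threshold = threshold,
                 direction = direction, alpha = alpha),
            class = "strong_classifier")
}

#' @export
print.strong_classifier <- function(x, ...) {
  cat(sprintf("Strong classifier %s (+1) vs %s (-1): %d stumps\n",
              x$class_pair[1], x$class_pair[2], length(x$alpha)))
  invisible(x)
}

# per-stump +/-1 votes of a strong classifier on a single 2-vector
.stump_votes <- function(clf, sample) {
  ifelse(clf$direction * sample[clf$attr] > clf$direction * clf$threshold,
         1, -1)
}

#' Weighted margin of a strong classifier on one sample
#'
#' The margin is `sum(alpha_t * h_t(sample))`; its sign is the plain
#' AdaBoost prediction.
#'
#' @param clf A `strong_classifier`.
#' @param sample Numeric 2-vector in the classifier's attribute pair space.
#' @return Scalar margin.
#' @export
strong_margin <- function(clf, sample) {
  stopifnot(inherits(clf, "strong_classifier"))
  sum(clf$alpha * .stump_votes(clf, sample))
}

#' Sign prediction of a strong classifier
#'
#' A zero margin (tied vote) is mapped to -1; this convention only matters
#' for the plain-AdaBoost baseline, not for BPA generation, which uses the
#' per-stump votes via [vote_fraction()].
#'
#' @inheritParams strong_margin
#' @return +1 or -1.
#' @export
strong_predict <- function(clf, sample) {
  if (strong_margin(clf, sample) > 0) 1 else -1
}

#' Fraction of stump weight voting for the positive class
#'
#' The share of total alpha carried by stumps that output +1 on the sample.
#' This is the singleton mass the classifier contributes to its positive
#' class; the complement is the negative class's share.
#'
#' @inheritParams strong_margin
#' @return Scalar in \[0, 1\].
#' @export
vote_fraction <- function(clf, sample) {
  stopifnot(inherits(clf, "strong_classifier"))
  v <- .stump_votes(clf, sample)
  sum(clf$alpha[v > 0]) / sum(clf$alpha)
}
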