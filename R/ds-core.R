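# Mass-function algebra over a closed-world frame of discernment.
#
# Propositions are non-empty subsets of the frame and are keyed by a
# canonical string: member labels in frame order, joined with ",".
# {Ve,Se} and {Se,Ve} therefore share one key.

#' Create a frame of discernment
#'
#' A frame of discernment is the exhaustive, mutually exclusive set of class
#' hypotheses over which belief is distributed. Label order is fixed and
#' defines the canonical encoding of subsets (and the tie-break order used by
#' [ds_decide()]).
#'
#' @param labels Character vector of distinct class identifiers, length >= 1.
#' @return An object of class `ds_frame`.
#' @examples
#' ds_frame(c("Se", "Ve", "Vi"))
#' @export
ds_frame <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1) stop("a frame needs at least one label")
  if (anyDuplicated(labels)) stop("frame labels must be unique")
  if (any(!nzchar(labels))) stop("frame labels must be non-empty strings")
  structure(list(labels = labels), class = "ds_frame")
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("Frame of discernment with", length(x$labels), "hypotheses:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

.as_frame <- function(frame) {
  if (inherits(frame, "ds_frame")) frame else ds_frame(frame)
}

# canonical key for a set of labels: frame order, comma-joined
.canon_key <- function(labels, frame) {
  idx <- match(labels, frame$labels)
  if (anyNA(idx)) {
    stop("labels not in frame: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  paste(frame$labels[sort(unique(idx))], collapse = ",")
}

.key_labels <- function(key) strsplit(key, ",", fixed = TRUE)[[1]]

# all non-empty subset keys of the frame, by increasing cardinality
.all_subset_keys <- function(frame) {
  n <- length(frame$labels)
  masks <- seq_len(2^n - 1)
  keys <- vapply(masks, function(m) {
    paste(frame$labels[bitwAnd(m, bitwShiftL(1, seq_len(n) - 1)) != 0],
          collapse = ",")
  }, character(1))
  keys[order(nchar(gsub("[^,]", "", keys)))]
}

.key_intersect <- function(k1, k2, frame) {
  common <- intersect(.key_labels(k1), .key_labels(k2))
  if (length(common) == 0) return("")
  .canon_key(common, frame)
}

#' Construct a mass function (basic probability assignment)
#'
#' A mass function assigns non-negative belief masses to non-empty subsets of
#' the frame of discernment; masses must total 1. The empty set is never a
#' focal element (closed world). Proposition keys are comma-joined label
#' strings in any member order, e.g. `"Se,Ve"`.
#'
#' @param frame A [ds_frame()] or character vector of labels.
#' @param masses Named numeric vector or list mapping proposition keys to
#'   non-negative masses.
#' @param renormalize If `TRUE`, masses are rescaled to total 1 (used for
#'   internally produced masses where rounding drift is expected). If `FALSE`
#'   (the default, suited to user input), a total deviating from 1 by more
#'   than `1e-6` is rejected.
#' @return An object of class `mass_function` with fields `frame` and `m`
#'   (named numeric vector on canonical keys, zero-mass entries dropped).
#' @examples
#' fr <- ds_frame(c("A", "B", "C"))
#' mass_function(fr, c(A = 0.6, B = 0.4))
#' mass_function(fr, c("A,B,C" = 1)) # vacuous
#' @export
mass_function <- function(frame, masses, renormalize = FALSE) {
  frame <- .as_frame(frame)
  masses <- unlist(masses)
  if (length(masses) == 0) stop("no masses supplied")
  if (is.null(names(masses)) || any(!nzchar(names(masses)))) {
    stop("masses must be named by proposition keys")
  }
  if (any(!is.finite(masses))) stop("masses must be finite numbers")
  if (any(masses < 0)) stop("masses must be non-negative")
  keys <- vapply(names(masses), function(k) {
    labs <- .key_labels(k)
    if (length(labs) == 0) stop("the empty set cannot carry mass")
    .canon_key(labs, frame)
  }, character(1))
  m <- vapply(split(unname(masses), keys), sum, numeric(1))
  total <- sum(m)
  if (renormalize) {
    if (total <= 0) stop("total mass is zero; cannot renormalize")
    m <- m / total
  } else if (abs(total - 1) > 1e-6) {
    stop(sprintf("masses total %.8f, not 1 (set renormalize = TRUE?)", total))
  } else if (total != 1) {
    m <- m / total # absorb tolerated drift so downstream sums are exact
  }
  m <- m[m > 0]
  if (length(m) == 0) stop("no positive mass")
  structure(list(frame = frame, m = m), class = "mass_function")
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  cat("Mass function on {", paste(x$frame$labels, collapse = ", "), "}\n",
      sep = "")
  ord <- order(match(names(x$m), .all_subset_keys(x$frame)))
  for (k in names(x$m)[ord]) {
    cat(sprintf("  m({%s}) = %.*f\n", k, digits, x$m[[k]]))
  }
  invisible(x)
}

#' Focal elements of a mass function
#'
#' @param m A `mass_function`.
#' @return Character vector of canonical proposition keys with positive mass.
#' @export
focal_elements <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  names(m$m)
}

.check_same_frame <- function(m1, m2) {
  if (!identical(m1$frame$labels, m2$frame$labels)) {
    stop("mass functions are defined on different frames")
  }
}

#' Conflict coefficient between two mass functions
#'
#' The conflict coefficient k is the total product mass the two bodies of
#' evidence place on focal-element pairs with empty intersection. k = 1 means
#' complete conflict and forbids Dempster combination.
#'
#' @param m1,m2 `mass_function` objects on the same frame.
#' @return Scalar k in \[0, 1\].
#' @export
ds_conflict <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  .check_same_frame(m1, m2)
  k <- 0
  for (a in names(m1$m)) {
    for (b in names(m2$m)) {
      if (.key_intersect(a, b, m1$frame) == "") {
        k <- k + m1$m[[a]] * m2$m[[b]]
      }
    }
  }
  min(k, 1)
}

#' Combine two mass functions with Dempster's rule
#'
#' Conjunctive combination: product masses of intersecting focal elements are
#' accumulated on the intersection and renormalized by 1 - k, where k is the
#' conflict coefficient. Combination is undefined for completely conflicting
#' evidence (1 - k below `1e-12`), which raises an error rather than dividing
#' by (near) zero.
#'
#' @param m1,m2 `mass_function` objects on the same frame.
#' @return The combined `mass_function`.
#' @examples
#' fr <- ds_frame(c("A", "B"))
#' ds_combine(mass_function(fr, c(A = 0.7, "A,B" = 0.3)),
#'            mass_function(fr, c(B = 0.5, "A,B" = 0.5)))
#' @export
ds_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  .check_same_frame(m1, m2)
  acc <- new.env(parent = emptyenv())
  k <- 0
  for (a in names(m1$m)) {
    for (b in names(m2$m)) {
      key <- .key_intersect(a, b, m1$frame)
      p <- m1$m[[a]] * m2$m[[b]]
      if (key == "") {
        k <- k + p
      } else {
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
      }
    }
  }
  if (1 - k < 1e-12) {
    stop("complete conflict (k = 1): Dempster's rule is undefined")
  }
  keys <- ls(acc)
  m <- vapply(keys, function(x) acc[[x]], numeric(1)) / (1 - k)
  mass_function(m1$frame, m, renormalize = TRUE)
}

#' Combine a sequence of mass functions
#'
#' Sequential left fold of [ds_combine()]. Dempster's rule is associative and
#' commutative, so the result is independent of input order up to floating
#' tolerance.
#'
#' @param masses List of `mass_function` objects on a common frame (>= 1).
#' @return The combined `mass_function`.
#' @export
ds_combine_all <- function(masses) {
  if (!is.list(masses) || length(masses) == 0) {
    stop("need at least one mass function")
  }
  Reduce(ds_combine, masses)
}

#' Decide a class label from a mass function
#'
#' Returns the label of the singleton proposition carrying maximal mass.
#' Composite propositions are ignored; they express ambiguity, not support
#' for a single class. Ties (including the vacuous mass, where every
#' singleton carries zero) are broken toward the lowest frame index.
#'
#' @param m A `mass_function`.
#' @return A class label (character scalar).
#' @export
ds_decide <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  labs <- m$frame$labels
  singleton <- vapply(labs, function(l) {
    v <- m$m[l]
    if (is.na(v)) 0 else v
  }, numeric(1))
  labs[which.max(singleton)] # which.max: first maximum = lowest frame index
}

#' Serialize a mass function to JSON
#'
#' The JSON document holds the ordered frame labels and a mapping of
#' comma-joined proposition keys to masses; [mass_from_json()] inverts it.
#'
#' @param m A `mass_function`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
mass_to_json <- function(m, path = NULL) {
  stopifnot(inherits(m, "mass_function"))
  doc <- list(frame = m$frame$labels, masses = as.list(m$m))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a mass function from JSON
#'
#' @param x JSON string or path to a JSON file produced by [mass_to_json()].
#' @return A `mass_function`.
#' @export
mass_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  mass_function(ds_frame(doc$frame), unlist(doc$masses))
}
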