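# End-to-end evidential classifier: one-vs-one boosted stumps per attribute
# pair generate singleton BPAs by weighted voting, the area-ratio rule moves
# mass onto composite propositions, and Dempster's rule fuses the per-pair
# evidence into one mass function per sample.

#' Fit an evidential boosting model
#'
#' For every unordered attribute pair (i, j) the rows complete on both
#' attributes are selected; one strong classifier is boosted per unordered
#' class pair (the class with the lower frame index is coded +1), and the
#' region lattice is fitted from each class's bounding box on that plane.
#' Training is deterministic for a fixed table and `T`.
#'
#' @param table A [labeled_table()] with >= 2 classes and >= 2 attributes.
#' @param T Boosting rounds per strong classifier (default 20).
#' @param realloc Reallocation mode: `"per_classifier"` (default) applies the
#'   area-ratio rule to each one-vs-one mass before averaging;
#'   `"post_average"` averages singleton masses first and then reallocates
#'   level by level (comparison variant, see the vignette).
#' @return An object of class `evidential_model`.
#' @examples
#' tab <- synth_classes(n_classes = 3, n_attr = 4, samples_per_class = 20,
#'                      overlap = 0.5, seed = 1)
#' model <- evidential_fit(tab, T = 5)
#' predict(model, tab$values[1, ])
#' @export
evidential_fit <- function(table, T = 20,
                           realloc = c("per_classifier", "post_average")) {
  stopifnot(inherits(table, "labeled_table"))
  realloc <- match.arg(realloc)
  frame <- ds_frame(levels(table$labels))
  nc <- length(frame$labels)
  if (nc < 2) stop("need at least two classes")
  n_attr <- ncol(table$values)
  if (n_attr < 2) stop("need at least two attributes")
  attr_pairs <- utils::combn(n_attr, 2)
  class_pairs <- utils::combn(frame$labels, 2)
  pairs <- vector("list", ncol(attr_pairs))
  for (p in seq_len(ncol(attr_pairs))) {
    i <- attr_pairs[1, p]; j <- attr_pairs[2, p]
    ok <- stats::complete.cases(table$values[, c(i, j), drop = FALSE])
    xy <- table$values[ok, c(i, j), drop = FALSE]
    lab <- as.character(table$labels[ok])
    boxes <- lapply(frame$labels, function(cl) {
      rows <- xy[lab == cl, , drop = FALSE]
      if (nrow(rows) == 0) {
        stop(sprintf("class '%s' has no usable rows on attribute pair (%d,%d)",
                     cl, i, j))
      }
      fit_region(rows)
    })
    names(boxes) <- frame$labels
    lattice <- region_lattice(boxes, frame)
    classifiers <- vector("list", ncol(class_pairs))
    for (q in seq_len(ncol(class_pairs))) {
      ca <- class_pairs[1, q]; cb <- class_pairs[2, q]
      sel <- lab %in% c(ca, cb)
      view <- pair_view(xy[sel, , drop = FALSE],
                        ifelse(lab[sel] == ca, 1, -1),
                        attrs = c(i, j), classes = c(ca, cb))
      classifiers[[q]] <- train_strong(view, T = T)
    }
    names(classifiers) <- paste(class_pairs[1, ], class_pairs[2, ], sep = "|")
    pairs[[p]] <- list(i = i, j = j, classifiers = classifiers,
                       lattice = lattice)
  }
  structure(list(frame = frame, attr_names = table$attr_names,
                 pairs = pairs, T = T, realloc = realloc),
            class = "evidential_model")
}

#' @export
print.evidential_model <- function(x, ...) {
  cat(sprintf(paste0("Evidential boosting model: %d classes, %d attributes,",
                     " %d attribute pairs x %d one-vs-one classifiers",
                     " (T = %d, reallocation: %s)\n"),
              length(x$frame$labels), length(x$attr_names),
              length(x$pairs), length(x$pairs[[1]]$classifiers),
              x$T, x$realloc))
  invisible(x)
}

# ---- dense fast path -------------------------------------------------------
# Prediction over many samples is dominated by subset-key string handling, so
# the default pipeline runs on plain numeric vectors indexed by canonical
# subset order, with bitmask set algebra and a precomputed intersection table.
# The object API (mass_function / reallocate) remains the reference route and
# the test suite checks the two agree.

.frame_tables <- function(frame) {
  labels <- frame$labels
  n <- length(labels)
  keys <- .all_subset_keys(frame)
  masks <- vapply(keys, function(k) {
    sum(bitwShiftL(1, match(.key_labels(k), labels) - 1))
  }, numeric(1))
  idx_of_mask <- integer(2^n - 1)
  idx_of_mask[masks] <- seq_along(keys)
  K <- length(keys)
  inter <- matrix(0L, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      m <- bitwAnd(masks[i], masks[j])
      if (m > 0) inter[i, j] <- idx_of_mask[m]
    }
  }
  list(labels = labels, keys = keys, masks = masks,
       idx_of_mask = idx_of_mask, inter = inter,
       singleton_idx = idx_of_mask[bitwShiftL(1, seq_len(n) - 1)])
}

.lattice_dense <- function(lattice, ft) {
  areas <- unname(lattice$areas[ft$keys])
  bounds <- NULL
  if (!is.null(lattice$regions)) {
    bounds <- vapply(lattice$regions[ft$keys], function(r) {
      if (r$empty) rep(NA_real_, 4) else c(r$xmin, r$xmax, r$ymin, r$ymax)
    }, numeric(4))
  }
  list(areas = areas, bounds = bounds)
}

.dense_contains <- function(ld, idx, point) {
  if (is.null(ld$bounds)) return(ld$areas[idx] > 0)
  b <- ld$bounds[, idx]
  !is.na(b[1]) && point[1] >= b[1] && point[1] <= b[2] &&
    point[2] >= b[3] && point[2] <= b[4]
}

# area-ratio chain for one one-vs-one vote (va on singleton ia, 1 - va on ib)
.dense_realloc <- function(ft, ld, va, ia, ib, point) {
  out <- numeric(length(ft$keys))
  u2 <- ft$idx_of_mask[bitwOr(ft$masks[ia], ft$masks[ib])]
  if (ld$areas[u2] <= 0 || !.dense_contains(ld, u2, point)) {
    out[ia] <- va; out[ib] <- 1 - va
    return(out)
  }
  sa <- if (ld$areas[ia] > 0) min(ld$areas[u2] / ld$areas[ia], 1) else 0
  sb <- if (ld$areas[ib] > 0) min(ld$areas[u2] / ld$areas[ib], 1) else 0
  out[ia] <- (1 - sa) * va
  out[ib] <- (1 - sb) * (1 - va)
  mcur <- sa * va + sb * (1 - va)
  cur <- u2
  curmask <- bitwOr(ft$masks[ia], ft$masks[ib])
  for (s in ft$singleton_idx) {
    sm <- ft$masks[s]
    if (bitwAnd(sm, curmask) > 0) next
    candmask <- bitwOr(curmask, sm)
    cand <- ft$idx_of_mask[candmask]
    if (ld$areas[cand] > 0 && .dense_contains(ld, cand, point)) {
      S <- if (ld$areas[cur] > 0) min(ld$areas[cand] / ld$areas[cur], 1) else 0
      out[cur] <- (1 - S) * mcur
      mcur <- S * mcur
      cur <- cand
      curmask <- candmask
    }
  }
  out[cur] <- out[cur] + mcur
  out
}

.dense_combine <- function(ft, a, b) {
  ia <- which(a > 0); ib <- which(b > 0)
  out <- numeric(length(a))
  k <- 0
  for (i in ia) {
    for (j in ib) {
      t <- ft$inter[i, j]
      p <- a[i] * b[j]
      if (t == 0) k <- k + p else out[t] <- out[t] + p
    }
  }
  if (1 - k < 1e-12) {
    stop("complete conflict (k = 1): Dempster's rule is undefined")
  }
  out / (1 - k)
}

# precompute the dense companion of a model (per predict/evaluate call)
.model_dense <- function(model) {
  ft <- .frame_tables(model$frame)
  lds <- lapply(model$pairs, function(p) .lattice_dense(p$lattice, ft))
  ab <- lapply(model$pairs[[1]]$classifiers, function(clf)
    match(clf$class_pair, model$frame$labels))
  list(ft = ft, lds = lds,
       cls_idx = lapply(ab, function(x) ft$singleton_idx[x]))
}

.pair_bpa_dense <- function(model, md, p, sample) {
  entry <- model$pairs[[p]]
  p2 <- as.numeric(sample[c(entry$i, entry$j)])
  if (anyNA(p2)) return(NULL)
  ft <- md$ft; ld <- md$lds[[p]]
  acc <- numeric(length(ft$keys))
  clfs <- entry$classifiers
  for (q in seq_along(clfs)) {
    va <- vote_fraction(clfs[[q]], p2)
    ii <- md$cls_idx[[q]]
    acc <- acc + .dense_realloc(ft, ld, va, ii[1], ii[2], p2)
  }
  acc / length(clfs)
}

.predict_bpa_dense <- function(model, md, sample) {
  out <- NULL
  for (p in seq_along(model$pairs)) {
    mp <- .pair_bpa_dense(model, md, p, sample)
    if (is.null(mp)) next
    out <- if (is.null(out)) mp else {
      tryCatch(.dense_combine(md$ft, out, mp), error = function(e) {
        stop(sprintf("combination failed at attribute pair (%d,%d): %s",
                     model$pairs[[p]]$i, model$pairs[[p]]$j,
                     conditionMessage(e)), call. = FALSE)
      })
    }
  }
  if (is.null(out)) stop("no usable attribute pair for this sample")
  out
}

.dense_to_mass <- function(ft, v, frame) {
  keep <- v > 0
  mass_function(frame, stats::setNames(v[keep], ft$keys[keep]),
                renormalize = FALSE)
}

# level-by-level area-ratio reallocation of an averaged singleton mass
# (comparison variant). At each cardinality step every proposition feeds all
# its qualifying one-class extensions; when the outgoing shares would exceed
# the available mass they are scaled down proportionally so mass is conserved.
.post_reallocate <- function(mass, lattice, point) {
  frame <- mass$frame
  nc <- length(frame$labels)
  keys <- .all_subset_keys(frame)
  card <- vapply(keys, function(k) length(.key_labels(k)), integer(1))
  m <- stats::setNames(numeric(length(keys)), keys)
  m[names(mass$m)] <- mass$m
  for (l in seq_len(nc - 1)) {
    for (p in keys[card == l]) {
      if (m[[p]] <= 0) next
      ext <- setdiff(frame$labels, .key_labels(p))
      children <- vapply(ext, function(cl)
        .canon_key(c(.key_labels(p), cl), frame), character(1))
      ok <- vapply(children, function(ch)
        lattice_area(lattice, ch) > 0 && lattice_contains(lattice, ch, point),
        logical(1))
      children <- children[ok]
      if (length(children) == 0) next
      s <- vapply(children, function(ch) area_ratio(lattice, ch, p),
                  numeric(1))
      scale <- if (sum(s) > 1) 1 / sum(s) else 1
      moved <- scale * s * m[[p]]
      m[children] <- m[children] + moved
      m[p] <- m[[p]] - sum(moved)
    }
  }
  mass_function(frame, m[m > 0], renormalize = FALSE)
}

#' Pair-level BPA for one attribute pair
#'
#' Each of the C(Nc, 2) one-vs-one classifiers contributes a two-singleton
#' mass: the positive class gets its [vote_fraction()], the negative class
#' the complement. In the default mode each such mass is reallocated through
#' the pair's region lattice at the sample point before the C(Nc, 2) masses
#' are averaged with equal weight. Classes a classifier does not involve
#' contribute zero to its mass, so with three classes the averaged BPA has
#' at most seven focal elements.
#'
#' @param model An `evidential_model`.
#' @param pair Index of the attribute pair in the model (1-based), or an
#'   integer 2-vector of attribute indices.
#' @param sample Full numeric attribute vector (length = number of model
#'   attributes).
#' @return A `mass_function`, or `NULL` if the sample is missing a value on
#'   either attribute of the pair ("pair unavailable").
#' @export
pair_bpa <- function(model, pair, sample) {
  stopifnot(inherits(model, "evidential_model"))
  if (length(pair) == 2) {
    hit <- which(vapply(model$pairs, function(p)
      p$i == min(pair) && p$j == max(pair), logical(1)))
    if (length(hit) != 1) stop("no such attribute pair in the model")
    pair <- hit
  }
  entry <- model$pairs[[pair]]
  p2 <- as.numeric(sample[c(entry$i, entry$j)])
  if (anyNA(p2)) return(NULL)
  frame <- model$frame
  if (model$realloc == "per_classifier") {
    md <- .model_dense(model)
    return(.dense_to_mass(md$ft, .pair_bpa_dense(model, md, pair, sample),
                          frame))
  }
  ncp <- length(entry$classifiers)
  acc <- stats::setNames(numeric(0), character(0))
  for (clf in entry$classifiers) {
    va <- vote_fraction(clf, p2)
    m_t <- mass_function(frame,
                         stats::setNames(c(va, 1 - va), clf$class_pair)[
                           c(va, 1 - va) > 0],
                         renormalize = FALSE)
    for (k in names(m_t$m)) {
      acc[k] <- (if (is.na(acc[k])) 0 else acc[[k]]) + m_t$m[[k]] / ncp
    }
  }
  out <- mass_function(frame, acc, renormalize = FALSE)
  .post_reallocate(out, entry$lattice, p2)
}

#' Fused BPA for one sample
#'
#' Computes [pair_bpa()] for every attribute pair with complete sample
#' values and folds them with Dempster's rule. Pairs touching a missing
#' attribute are skipped, so samples with gaps are still classifiable from
#' the remaining evidence.
#'
#' @inheritParams pair_bpa
#' @return The combined `mass_function`.
#' @export
predict_bpa <- function(model, sample) {
  stopifnot(inherits(model, "evidential_model"))
  if (length(sample) != length(model$attr_names)) {
    stop("sample length does not match the model's attribute count")
  }
  if (model$realloc == "per_classifier") {
    md <- .model_dense(model)
    return(.dense_to_mass(md$ft, .predict_bpa_dense(model, md, sample),
                          model$frame))
  }
  out <- NULL
  for (p in seq_along(model$pairs)) {
    mp <- pair_bpa(model, p, sample)
    if (is.null(mp)) next
    if (is.null(out)) {
      out <- mp
    } else {
      out <- tryCatch(ds_combine(out, mp), error = function(e) {
        stop(sprintf("combination failed at attribute pair (%d,%d): %s",
                     model$pairs[[p]]$i, model$pairs[[p]]$j,
                     conditionMessage(e)), call. = FALSE)
      })
    }
  }
  if (is.null(out)) stop("no usable attribute pair for this sample")
  out
}

#' Predict class labels
#'
#' Decision by maximal combined singleton mass ([ds_decide()]).
#'
#' @param object An `evidential_model`.
#' @param newdata Numeric matrix or data frame of samples (rows), or a
#'   single attribute vector.
#' @param type `"class"` (default) for labels, `"mass"` for the list of
#'   fused mass functions.
#' @param ... Unused.
#' @return Character vector of labels, or a list of `mass_function`s.
#' @export
predict.evidential_model <- function(object, newdata, type = c("class", "mass"),
                                     ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (object$realloc == "per_classifier") {
    md <- .model_dense(object) # shared across rows: the expensive precompute
    dense <- lapply(seq_len(nrow(newdata)), function(r)
      .predict_bpa_dense(object, md, newdata[r, ]))
    if (type == "mass") {
      return(lapply(dense, .dense_to_mass, ft = md$ft, frame = object$frame))
    }
    si <- md$ft$singleton_idx
    return(vapply(dense, function(v)
      object$frame$labels[which.max(v[si])], character(1)))
  }
  masses <- lapply(seq_len(nrow(newdata)), function(r)
    predict_bpa(object, newdata[r, ]))
  if (type == "mass") return(masses)
  vapply(masses, ds_decide, character(1))
}

#' Plain-AdaBoost baseline prediction
#'
#' Majority vote of the sign predictions of all one-vs-one strong
#' classifiers across attribute pairs, ignoring regions and evidence
#' fusion. Used as the baseline the evidential pipeline is compared with.
#'
#' @inheritParams pair_bpa
#' @return A class label.
#' @export
predict_adaboost <- function(model, sample) {
  stopifnot(inherits(model, "evidential_model"))
  votes <- stats::setNames(numeric(length(model$frame$labels)),
                           model$frame$labels)
  for (entry in model$pairs) {
    p2 <- as.numeric(sample[c(entry$i, entry$j)])
    if (anyNA(p2)) next
    for (clf in entry$classifiers) {
      winner <- if (strong_predict(clf, p2) > 0) clf$class_pair[1]
                else clf$class_pair[2]
      votes[winner] <- votes[winner] + 1
    }
  }
  if (all(votes == 0)) stop("no usable attribute pair for this sample")
  names(votes)[which.max(votes)]
}

#' Monte-Carlo evaluation across training fractions
#'
#' For each training fraction and repeat, the table is split (seeded), a
#' model is fitted on the training part and accuracy is scored on the
#' training set, the test set and the whole table. Splits that leave a class
#' without training rows are resampled up to `retry_cap` times.
#'
#' @param table A [labeled_table()].
#' @param fractions Numeric vector of training fractions in (0, 1).
#' @param repeats Repeats per fraction (>= 1).
#' @param T Boosting rounds per strong classifier.
#' @param seed Integer seed; every split derives from it reproducibly.
#' @param stratified Draw the training fraction per class instead of from
#'   the pooled rows.
#' @param realloc Passed to [evidential_fit()].
#' @param retry_cap Maximum resampling attempts for degenerate splits.
#' @return A data frame of class `evaluation_report` with one row per
#'   fraction: mean train/test/overall accuracy over repeats.
#' @export
evaluate_classifier <- function(table, fractions, repeats = 10, T = 20,
                                seed = 1, stratified = FALSE,
                                realloc = "per_classifier", retry_cap = 100) {
  stopifnot(inherits(table, "labeled_table"),
            all(fractions > 0 & fractions < 1), repeats >= 1)
  rows <- lapply(seq_along(fractions), function(fi) {
    fr <- fractions[fi]
    accs <- matrix(NA_real_, nrow = repeats, ncol = 3)
    for (r in seq_len(repeats)) {
      base <- (seed + 7919 * (fi - 1) + 104729 * (r - 1)) %% 2147483647L
      sp <- NULL
      for (try in 0:retry_cap) {
        cand <- split_table(table, fraction = fr, stratified = stratified,
                            seed = (base + try) %% 2147483647L)
        if (nlevels(droplevels(cand$train$labels)) ==
              nlevels(table$labels) && nrow(cand$test$values) > 0) {
          sp <- cand
          break
        }
      }
      if (is.null(sp)) {
        stop(sprintf("no valid split at fraction %g after %d retries",
                     fr, retry_cap))
      }
      model <- evidential_fit(sp$train, T = T, realloc = realloc)
      acc <- function(tab) {
        mean(predict(model, tab$values) == as.character(tab$labels))
      }
      tr <- acc(sp$train); te <- acc(sp$test)
      n_tr <- nrow(sp$train$values); n_te <- nrow(sp$test$values)
      accs[r, ] <- c(tr, te, (tr * n_tr + te * n_te) / (n_tr + n_te))
    }
    data.frame(fraction = fr,
               train_accuracy = mean(accs[, 1]),
               test_accuracy = mean(accs[, 2]),
               overall_accuracy = mean(accs[, 3]),
               repeats = repeats)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Serialize a fitted model to JSON
#'
#' @param model An `evidential_model`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "evidential_model"))
  doc <- list(
    frame = model$frame$labels,
    attr_names = model$attr_names,
    T = model$T,
    realloc = model$realloc,
    pairs = lapply(model$pairs, function(p) list(
      i = p$i, j = p$j,
      lattice = lapply(p$lattice$regions, function(r)
        if (r$empty) list() else c(r$xmin, r$xmax, r$ymin, r$ymax)),
      classifiers = lapply(p$classifiers, function(clf) list(
        class_pair = clf$class_pair, attrs = clf$attrs, attr = clf$attr,
        threshold = clf$threshold, direction = clf$direction,
        alpha = clf$alpha))))
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a fitted model from JSON
#'
#' @param x JSON string or file path produced by [model_to_json()].
#' @return An `evidential_model`.
#' @export
model_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  frame <- ds_frame(doc$frame)
  pairs <- lapply(doc$pairs, function(p) {
    singles <- p$lattice[frame$labels]
    boxes <- lapply(singles, function(b) {
      if (length(b) == 0) empty_region()
      else rect_region(b[1], b[2], b[3], b[4])
    })
    classifiers <- lapply(p$classifiers, function(clf) {
      structure(list(class_pair = clf$class_pair,
                     attrs = as.integer(clf$attrs),
                     attr = as.integer(clf$attr),
                     threshold = as.numeric(clf$threshold),
                     direction = as.numeric(clf$direction),
                     alpha = as.numeric(clf$alpha)),
                class = "strong_classifier")
    })
    list(i = as.integer(p$i), j = as.integer(p$j),
         classifiers = classifiers, lattice = region_lattice(boxes, frame))
  })
  structure(list(frame = frame, attr_names = doc$attr_names, pairs = pairs,
                 T = doc$T, realloc = doc$realloc),
            class = "evidential_model")
}
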