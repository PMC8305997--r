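# Independent brute-force oracles. These deliberately share no code with the
# package internals they check: set algebra is done on plain label vectors,
# stump search by full enumeration.

oracle_key <- function(labs, frame_labels) {
  paste(frame_labels[sort(match(labs, frame_labels))], collapse = ",")
}

# all non-empty subset keys of a label vector
oracle_subsets <- function(frame_labels) {
  unlist(lapply(seq_along(frame_labels), function(k) {
    utils::combn(frame_labels, k, paste, collapse = ",")
  }), use.names = FALSE)
}

# Dempster combination by explicit double loop over every focal pair.
# Returns the conflict k, the unnormalized intersection masses, and the
# normalized combined masses.
oracle_combine <- function(m1, m2) {
  fl <- m1$frame$labels
  s1 <- strsplit(names(m1$m), ",", fixed = TRUE)
  s2 <- strsplit(names(m2$m), ",", fixed = TRUE)
  k <- 0
  acc <- list()
  for (i in seq_along(s1)) {
    for (j in seq_along(s2)) {
      inter <- intersect(s1[[i]], s2[[j]])
      p <- unname(m1$m[i] * m2$m[j])
      if (length(inter) == 0) {
        k <- k + p
      } else {
        key <- oracle_key(inter, fl)
        acc[[key]] <- if (is.null(acc[[key]])) p else acc[[key]] + p
      }
    }
  }
  unnorm <- unlist(acc)
  list(k = k, unnorm = unnorm, m = unnorm / (1 - k))
}

# random mass function: a few random focal elements, exponential weights
random_mass <- function(frame, max_focal = 4) {
  keys <- oracle_subsets(frame$labels)
  pick <- sample(keys, sample.int(min(max_focal, length(keys)), 1))
  w <- stats::rexp(length(pick)) + 1e-3
  mass_function(frame, stats::setNames(w, pick), renormalize = TRUE)
}

# minimal weighted stump error by full enumeration of (attr, threshold,
# direction); thresholds derived here from scratch
oracle_best_stump_error <- function(x, y, w) {
  best <- Inf
  for (d in 1:2) {
    v <- sort(unique(x[, d]))
    ths <- c(v[1] - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
             v[length(v)] + 1)
    for (th in ths) {
      for (b in c(1, -1)) {
        h <- ifelse(b * x[, d] > b * th, 1, -1)
        best <- min(best, sum(w[h != y]))
      }
    }
  }
  best
}

# random geometric lattice on a frame: unit-scale boxes with random offsets
random_lattice <- function(frame) {
  boxes <- lapply(frame$labels, function(l) {
    x0 <- stats::runif(1, 0, 3); y0 <- stats::runif(1, 0, 3)
    rect_region(x0, x0 + stats::runif(1, 0.5, 2),
                y0, y0 + stats::runif(1, 0.5, 2))
  })
  names(boxes) <- frame$labels
  region_lattice(boxes, frame)
}
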