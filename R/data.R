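# Tabular I/O, train/test splitting, synthetic cluster generation and the
# small in-package fixtures used by the worked examples and tests.

#' Construct a labeled table
#'
#' @param values Numeric matrix (N x n, n >= 2); `NA` marks missing values.
#' @param labels Class labels (factor or coercible); the factor level order
#'   defines the frame order used throughout.
#' @param attr_names Optional attribute names (default from `values`
#'   columns, else `x1..xn`).
#' @return An object of class `labeled_table`.
#' @export
labeled_table <- function(values, labels, attr_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2) stop("need at least two attributes")
  if (nrow(values) != length(labels)) stop("values and labels lengths differ")
  labels <- if (is.factor(labels)) labels else factor(labels)
  if (is.null(attr_names)) {
    attr_names <- colnames(values)
    if (is.null(attr_names)) attr_names <- paste0("x", seq_len(ncol(values)))
  }
  colnames(values) <- attr_names
  structure(list(values = values, labels = labels, attr_names = attr_names),
            class = "labeled_table")
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf("Labeled table: %d samples, %d attributes, %d classes (%s)",
              nrow(x$values), ncol(x$values), nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf(", %d missing values", nmiss))
  cat("\n")
  invisible(x)
}

#' Read a labeled table from CSV
#'
#' Reads an RFC-4180 CSV with a header row. All non-label columns must be
#' numeric except for cells equal to a missing-value marker, which become
#' `NA`. Headerless UCI-style layouts (`iris.data` etc.) can be read by
#' setting `header = FALSE`; columns are then named `x1..xn`.
#'
#' @param path CSV file path.
#' @param label_column Column name (or index) holding the class label;
#'   default: the last column.
#' @param missing_markers Character vector of markers treated as missing
#'   (default `"?"`, the UCI convention; empty cells always count).
#' @param header Does the file have a header row?
#' @return A [labeled_table()].
#' @export
read_labeled_table <- function(path, label_column = NULL,
                               missing_markers = "?", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = header, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (!header) names(df) <- paste0("x", seq_along(df))
  if (nrow(df) == 0) stop("empty table: ", path)
  if (is.null(label_column)) label_column <- ncol(df)
  lab_idx <- if (is.character(label_column)) match(label_column, names(df))
             else as.integer(label_column)
  if (is.na(lab_idx) || lab_idx < 1 || lab_idx > ncol(df)) {
    stop("label column not found: ", label_column)
  }
  labels <- df[[lab_idx]]
  attr_df <- df[-lab_idx]
  values <- matrix(NA_real_, nrow(df), ncol(attr_df),
                   dimnames = list(NULL, names(attr_df)))
  for (cc in seq_along(attr_df)) {
    cell <- attr_df[[cc]]
    miss <- cell %in% missing_markers | !nzchar(cell) | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   cell[bad[1]], bad[1], names(attr_df)[cc]))
    }
    num[miss] <- NA_real_
    values[, cc] <- num
  }
  labeled_table(values, labels)
}

#' Write a labeled table to CSV
#'
#' Missing values are written as the first missing marker. Inverse of
#' [read_labeled_table()].
#'
#' @param table A [labeled_table()].
#' @param path Output path.
#' @param missing_marker Marker written for `NA` cells (default `"?"`).
#' @param label_name Name of the label column in the output.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(table, path, missing_marker = "?",
                                label_name = "class") {
  stopifnot(inherits(table, "labeled_table"))
  df <- as.data.frame(table$values)
  for (cc in seq_along(df)) {
    col <- format(df[[cc]], digits = 15, trim = TRUE, scientific = FALSE)
    col[is.na(df[[cc]])] <- missing_marker
    df[[cc]] <- col
  }
  df[[label_name]] <- as.character(table$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a labeled table into training and test sets
#'
#' Either a pooled `fraction` of all rows (`floor(N * fraction)`, at least
#' 1), a per-class `fraction` (`stratified = TRUE`), or an exact
#' `per_class` count drawn from every class. The two parts partition the
#' rows; a seed makes the draw reproducible.
#'
#' @param table A [labeled_table()].
#' @param fraction Training fraction in (0, 1).
#' @param per_class Exact per-class training count (overrides `fraction`;
#'   implies stratification).
#' @param stratified Draw the fraction within each class.
#' @param seed Optional integer seed.
#' @return List with `train` and `test` labeled tables.
#' @export
split_table <- function(table, fraction = NULL, per_class = NULL,
                        stratified = FALSE, seed = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table$values)
  idx <- seq_len(n)
  if (!is.null(per_class)) {
    take <- unlist(lapply(levels(table$labels), function(cl) {
      rows <- idx[table$labels == cl]
      if (per_class > length(rows)) {
        stop(sprintf("class '%s' has only %d rows, cannot take %d",
                     cl, length(rows), per_class))
      }
      sample(rows, per_class)
    }))
  } else {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      stop("need fraction in (0,1) or per_class")
    }
    if (stratified) {
      take <- unlist(lapply(levels(table$labels), function(cl) {
        rows <- idx[table$labels == cl]
        sample(rows, max(1L, floor(length(rows) * fraction)))
      }))
    } else {
      take <- sample(idx, max(1L, floor(n * fraction)))
    }
  }
  take <- sort(take)
  rest <- setdiff(idx, take)
  sub <- function(rows) {
    labeled_table(table$values[rows, , drop = FALSE], table$labels[rows],
                  table$attr_names)
  }
  list(train = sub(take), test = sub(rest))
}

# truncated normal draws on [center - halfwidth, center + halfwidth],
# sd = halfwidth / 2.5, via inverse-CDF sampling (no rejection loop)
.rtruncnorm <- function(n, center, halfwidth) {
  sd <- halfwidth / 2.5
  lo <- stats::pnorm(-halfwidth / sd)
  hi <- stats::pnorm(halfwidth / sd)
  center + sd * stats::qnorm(stats::runif(n, lo, hi))
}

#' Generate synthetic multi-class clusters with controllable overlap
#'
#' Each class is a truncated-Gaussian cluster (support exactly
#' `center +/- halfwidth` per attribute, sd = halfwidth / 2.5), so class
#' bounding boxes are controlled exactly. Default centers place class c at
#' `4 * (c - 1)` on every attribute and the half-width is
#' `1.5 * (1 + overlap)`: with `overlap = 0` adjacent class boxes are
#' disjoint with margin 1; boxes of adjacent classes intersect once
#' `overlap > 1/3`.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_attr Number of attributes (>= 2).
#' @param samples_per_class Rows per class.
#' @param overlap Non-negative spread multiplier (see above).
#' @param centers Optional `n_classes x n_attr` matrix of cluster centers.
#' @param halfwidths Optional per-class support half-widths (recycled).
#' @param seed Optional integer seed.
#' @return A [labeled_table()] with classes `c1..cK`.
#' @examples
#' synth_classes(3, 4, samples_per_class = 10, overlap = 0, seed = 1)
#' @export
synth_classes <- function(n_classes = 3, n_attr = 4, samples_per_class = 50,
                          overlap = 0.5, centers = NULL, halfwidths = NULL,
                          seed = NULL) {
  stopifnot(n_classes >= 2, n_attr >= 2, samples_per_class >= 1, overlap >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centers)) {
    centers <- matrix(rep(4 * (seq_len(n_classes) - 1), n_attr),
                      nrow = n_classes)
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != n_classes || ncol(centers) != n_attr) {
    stop("centers must be n_classes x n_attr")
  }
  if (is.null(halfwidths)) halfwidths <- 1.5 * (1 + overlap)
  halfwidths <- rep_len(halfwidths, n_classes)
  values <- matrix(NA_real_, n_classes * samples_per_class, n_attr)
  labels <- rep(paste0("c", seq_len(n_classes)), each = samples_per_class)
  for (c in seq_len(n_classes)) {
    rows <- (c - 1) * samples_per_class + seq_len(samples_per_class)
    for (a in seq_len(n_attr)) {
      values[rows, a] <- .rtruncnorm(samples_per_class, centers[c, a],
                                     halfwidths[c])
    }
  }
  labeled_table(values, factor(labels, levels = paste0("c", seq_len(n_classes))))
}

#' Iris-like synthetic preset
#'
#' Three classes, four attributes: class `c1` well separated, classes `c2`
#' and `c3` overlapping on every attribute — the structure of the Iris data
#' (Setosa separable; Versicolour and Virginica entangled) that motivates
#' composite-proposition mass. Bounding boxes: c1 support `0 +/- 1.5`, c2
#' `5 +/- 1.8`, c3 `7 +/- 2.2`, so the c2/c3 boxes share `[4.8, 6.8]` on
#' every attribute while c1 is disjoint from both.
#'
#' @param samples_per_class Rows per class (default 50, as in Iris).
#' @param seed Optional integer seed.
#' @return A [labeled_table()].
#' @export
synth_iris_like <- function(samples_per_class = 50, seed = NULL) {
  n_attr <- 4
  centers <- rbind(rep(0, n_attr), rep(5, n_attr), rep(7, n_attr))
  synth_classes(3, n_attr, samples_per_class, centers = centers,
                halfwidths = c(1.5, 1.8, 2.2), seed = seed)
}

#' In-package worked-example fixtures
#'
#' Small published reference inputs used by the worked examples, the CLI
#' `worked-example` command and the acceptance tests:
#' \describe{
#'   \item{toy_lattice}{Three-class area-only lattice (classes A, B, C) with
#'     areas A 4.5, B 4, C 7, AB 1.25, AC 1.5, BC 1.25, ABC 0.5 (arbitrary
#'     units); built with [area_lattice()] since only areas are published.}
#'   \item{toy_mass}{The two-singleton mass m(A) = 0.6, m(B) = 0.4 the toy
#'     reallocation starts from.}
#'   \item{iris_lattice}{Geometric lattice from the published per-class
#'     sepal-length x sepal-width ranges of the three Iris species
#'     (Se \[4.3, 5.8\] x \[2.3, 4.4\]; Ve \[4.9, 7.0\] x \[2.0, 3.4\];
#'     Vi \[4.9, 7.9\] x \[2.5, 3.8\], cm).}
#'   \item{iris_sample}{The Virginica test sample (SL 5.6, SW 2.8, PL 4.9,
#'     PW 2.0).}
#'   \item{iris_pair_masses}{The six published per-attribute-pair BPAs for
#'     that sample (frame Se, Ve, Vi), whose Dempster fusion decides
#'     Virginica. The SL,SW row totals 0.9999 in print and is renormalized.}
#' }
#'
#' @return A named list with the elements above.
#' @export
fixtures <- function() {
  toy_frame <- ds_frame(c("A", "B", "C"))
  toy_lattice <- area_lattice(toy_frame, c(
    "A" = 4.5, "B" = 4, "C" = 7,
    "A,B" = 1.25, "A,C" = 1.5, "B,C" = 1.25, "A,B,C" = 0.5))
  toy_mass <- mass_function(toy_frame, c(A = 0.6, B = 0.4))

  iris_frame <- ds_frame(c("Se", "Ve", "Vi"))
  iris_lattice <- region_lattice(list(
    Se = rect_region(4.3, 5.8, 2.3, 4.4),
    Ve = rect_region(4.9, 7.0, 2.0, 3.4),
    Vi = rect_region(4.9, 7.9, 2.5, 3.8)), iris_frame)
  iris_sample <- c(SL = 5.6, SW = 2.8, PL = 4.9, PW = 2.0)

  rows <- list(
    "SL,SW" = c(Se = 0.0872, Ve = 0.2680, Vi = 0.2267, "Se,Ve" = 0.0201,
                "Se,Vi" = 0.0321, "Ve,Vi" = 0.1160, "Se,Ve,Vi" = 0.2498),
    "SL,PL" = c(Ve = 0.4195, Vi = 0.5035, "Ve,Vi" = 0.0770),
    "SL,PW" = c(Ve = 0.3533, Vi = 0.6467),
    "SW,PL" = c(Ve = 0.4331, Vi = 0.5027, "Ve,Vi" = 0.0642),
    "SW,PW" = c(Ve = 0.3333, Vi = 0.6667),
    "PL,PW" = c(Ve = 0.3631, Vi = 0.6369))
  iris_pair_masses <- lapply(rows, function(r)
    mass_function(iris_frame, r, renormalize = TRUE))

  list(toy_lattice = toy_lattice, toy_mass = toy_mass,
       iris_lattice = iris_lattice, iris_sample = iris_sample,
       iris_pair_masses = iris_pair_masses)
}

#' Serialize a region lattice to JSON
#'
#' Geometric lattices store `[xmin, xmax, ymin, ymax]` per singleton (the
#' composites are recomputed on read); area-only lattices store the areas.
#'
#' @param lattice A `region_lattice`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
lattice_to_json <- function(lattice, path = NULL) {
  stopifnot(inherits(lattice, "region_lattice"))
  doc <- if (is.null(lattice$regions)) {
    list(frame = lattice$frame$labels, areas = as.list(lattice$areas))
  } else {
    singles <- lattice$regions[lattice$frame$labels]
    list(frame = lattice$frame$labels,
         regions = lapply(singles, function(r)
           c(r$xmin, r$xmax, r$ymin, r$ymax)))
  }
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a region lattice from JSON
#'
#' @param x JSON string or file path produced by [lattice_to_json()].
#' @return A `region_lattice`.
#' @export
lattice_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  frame <- ds_frame(doc$frame)
  if (!is.null(doc$regions)) {
    boxes <- lapply(doc$regions, function(b)
      rect_region(b[1], b[2], b[3], b[4]))
    region_lattice(boxes[frame$labels], frame)
  } else {
    area_lattice(frame, unlist(doc$areas))
  }
}
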