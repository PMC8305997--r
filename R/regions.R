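# Axis-aligned class bounding boxes in a two-attribute plane, their
# intersection lattice, and the recursive area-ratio reallocation that moves
# singleton mass onto composite propositions for samples in overlap regions.

#' Create an axis-aligned rectangular region
#'
#' @param xmin,xmax,ymin,ymax Box bounds in the attribute pair's units.
#' @return An object of class `rect_region`.
#' @export
rect_region <- function(xmin, xmax, ymin, ymax) {
  if (any(!is.finite(c(xmin, xmax, ymin, ymax)))) stop("bounds must be finite")
  if (xmin > xmax || ymin > ymax) stop("inverted bounds; use empty_region()")
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 empty = FALSE), class = "rect_region")
}

#' The empty region
#'
#' Marks an empty box intersection: zero area, contains no point.
#'
#' @return A `rect_region` flagged empty.
#' @export
empty_region <- function() {
  structure(list(xmin = NA_real_, xmax = NA_real_, ymin = NA_real_,
                 ymax = NA_real_, empty = TRUE), class = "rect_region")
}

#' @export
print.rect_region <- function(x, ...) {
  if (x$empty) cat("Empty region\n")
  else cat(sprintf("Region [%g, %g] x [%g, %g], area %g\n",
                   x$xmin, x$xmax, x$ymin, x$ymax, region_area(x)))
  invisible(x)
}

#' Area of a rectangular region
#'
#' @param region A `rect_region`.
#' @return Non-negative scalar; 0 for the empty region.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "rect_region"))
  if (region$empty) return(0)
  (region$xmax - region$xmin) * (region$ymax - region$ymin)
}

#' Bounding box of a point cloud
#'
#' Coordinate-wise min/max box of a class's training samples in the
#' attribute pair plane. Boundaries are closed, so every input point is
#' contained in the returned box.
#'
#' @param points Numeric matrix with two columns (>= 1 row), or a 2-vector.
#' @return A `rect_region`.
#' @export
fit_region <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 1) stop("need at least one point")
  if (anyNA(points)) stop("points must be complete")
  rect_region(min(points[, 1]), max(points[, 1]),
              min(points[, 2]), max(points[, 2]))
}

#' Intersection of two rectangular regions
#'
#' @param a,b `rect_region` objects.
#' @return A `rect_region` (possibly empty).
#' @export
region_intersect <- function(a, b) {
  stopifnot(inherits(a, "rect_region"), inherits(b, "rect_region"))
  if (a$empty || b$empty) return(empty_region())
  xmin <- max(a$xmin, b$xmin); xmax <- min(a$xmax, b$xmax)
  ymin <- max(a$ymin, b$ymin); ymax <- min(a$ymax, b$ymax)
  if (xmin > xmax || ymin > ymax) return(empty_region())
  rect_region(xmin, xmax, ymin, ymax)
}

#' Closed-interval point membership
#'
#' @param region A `rect_region`.
#' @param point Numeric 2-vector.
#' @return `TRUE` iff the point lies in the (closed) box; always `FALSE`
#'   for the empty region.
#' @export
region_contains <- function(region, point) {
  stopifnot(inherits(region, "rect_region"), length(point) == 2)
  if (region$empty) return(FALSE)
  point[1] >= region$xmin && point[1] <= region$xmax &&
    point[2] >= region$ymin && point[2] <= region$ymax
}

#' Build the full intersection lattice from per-class boxes
#'
#' Every non-empty subset of the frame gets a region: singletons keep their
#' fitted boxes, composites are the geometric intersection of their members'
#' boxes (interval intersection per axis; empty intersections have area 0).
#' By construction areas are monotone non-increasing along subset inclusion.
#'
#' @param singleton_regions Named list of `rect_region`, one per frame label.
#' @param frame A [ds_frame()] or character vector of labels; defaults to the
#'   names of `singleton_regions` in their given order.
#' @return An object of class `region_lattice` with fields `frame`,
#'   `regions` (named list over canonical subset keys) and `areas`.
#' @examples
#' boxes <- list(A = rect_region(0, 2, 0, 2), B = rect_region(1, 3, 1, 3))
#' region_lattice(boxes)
#' @export
region_lattice <- function(singleton_regions, frame = NULL) {
  if (is.null(frame)) frame <- names(singleton_regions)
  frame <- .as_frame(frame)
  if (!setequal(names(singleton_regions), frame$labels)) {
    stop("need exactly one region per frame label")
  }
  keys <- .all_subset_keys(frame)
  regions <- lapply(keys, function(k) {
    Reduce(region_intersect, singleton_regions[.key_labels(k)])
  })
  names(regions) <- keys
  areas <- vapply(regions, region_area, numeric(1))
  structure(list(frame = frame, regions = regions, areas = areas),
            class = "region_lattice")
}

#' Build a lattice from areas alone (synthetic fixture form)
#'
#' Some published examples state region areas without coordinates. An
#' area-only lattice carries no geometry: membership queries treat any
#' positive-area region as containing the query point, which matches the
#' fixture's premise that the sample lies in every stated intersection. Use
#' only for such fixtures; fitted models always carry real geometry.
#'
#' @param frame A [ds_frame()] or character vector of labels.
#' @param areas Named numeric vector over subset keys; missing keys get 0.
#' @return A `region_lattice` with `regions = NULL`.
#' @export
area_lattice <- function(frame, areas) {
  frame <- .as_frame(frame)
  keys <- .all_subset_keys(frame)
  full <- stats::setNames(numeric(length(keys)), keys)
  canon <- vapply(names(areas), function(k) .canon_key(.key_labels(k), frame),
                  character(1))
  full[canon] <- as.numeric(areas)
  if (any(full < 0)) stop("areas must be non-negative")
  structure(list(frame = frame, regions = NULL, areas = full),
            class = "region_lattice")
}

#' @export
print.region_lattice <- function(x, ...) {
  cat("Region lattice on {", paste(x$frame$labels, collapse = ", "), "}",
      if (is.null(x$regions)) " (areas only)" else "", "\n", sep = "")
  for (k in names(x$areas)) cat(sprintf("  area({%s}) = %g\n", k, x$areas[k]))
  invisible(x)
}

#' Area of a lattice region
#'
#' @param lattice A `region_lattice`.
#' @param key Proposition key (any member order).
#' @return Non-negative scalar area.
#' @export
lattice_area <- function(lattice, key) {
  stopifnot(inherits(lattice, "region_lattice"))
  unname(lattice$areas[.canon_key(.key_labels(key), lattice$frame)])
}

#' Point membership in a lattice region
#'
#' For geometric lattices this is closed-interval box membership; for
#' area-only fixtures ([area_lattice()]) any positive-area region is deemed
#' to contain the point.
#'
#' @inheritParams lattice_area
#' @param point Numeric 2-vector.
#' @return Logical.
#' @export
lattice_contains <- function(lattice, key, point) {
  stopifnot(inherits(lattice, "region_lattice"))
  k <- .canon_key(.key_labels(key), lattice$frame)
  if (is.null(lattice$regions)) return(lattice$areas[[k]] > 0)
  region_contains(lattice$regions[[k]], point)
}

#' Area ratio between a region and an immediate super-proposition's region
#'
#' S = area(child) / area(parent), where `parent` is a proposition and
#' `child` adds exactly one class to it; lattice monotonicity guarantees
#' S <= 1. A zero-area parent yields S = 0 (no reallocation flows through a
#' degenerate region).
#'
#' @param lattice A `region_lattice`.
#' @param child Key of the larger proposition (one extra member).
#' @param parent Key of the sub-proposition.
#' @return Scalar in \[0, 1\].
#' @export
area_ratio <- function(lattice, child, parent) {
  stopifnot(inherits(lattice, "region_lattice"))
  cl <- .key_labels(.canon_key(.key_labels(child), lattice$frame))
  pl <- .key_labels(.canon_key(.key_labels(parent), lattice$frame))
  if (!all(pl %in% cl) || length(cl) != length(pl) + 1) {
    stop("parent must be the child minus exactly one class")
  }
  pa <- lattice_area(lattice, parent)
  if (pa <= 0) return(0)
  min(lattice_area(lattice, child) / pa, 1)
}

#' Reallocate a two-singleton mass onto composite propositions
#'
#' Implements the recursive area-ratio rule for the mass produced by one
#' one-vs-one classifier: starting from masses on \{A\} and \{B\}, a share
#' S of each singleton mass (the area ratio of the AB intersection to that
#' singleton's box) moves onto \{A,B\}; the chain then extends one class at
#' a time — each extension moves a share S of the current composite mass
#' onto the enlarged composite — as long as the enlarged intersection has
#' positive area and contains the sample point. Total mass is conserved
#' exactly. If the point is outside the AB intersection (or that
#' intersection is degenerate) the input is returned unchanged.
#'
#' When more than one class could extend the chain (frames larger than 3),
#' candidates are absorbed one at a time in ascending frame-index order,
#' applying the discount sequentially; for three-class frames this reduces
#' to the single published chain A,B -> AB -> ABC.
#'
#' @param pair_mass A `mass_function` with singleton focal elements drawn
#'   from one class pair.
#' @param lattice A `region_lattice` on the same frame.
#' @param point Numeric 2-vector: the sample in the pair's attribute space.
#' @param classes Optional character pair naming the two singletons; needed
#'   when one of them carries zero mass (a unanimous classifier vote) and so
#'   is absent from the focal set. Defaults to the two focal elements.
#' @param max_cardinality Truncate the recursion: no composite larger than
#'   this cardinality receives mass (default: the frame size, i.e. the full
#'   chain). `max_cardinality = 2` returns the state after the initial
#'   two-singleton step.
#' @return A `mass_function` (sums to 1).
#' @export
reallocate <- function(pair_mass, lattice, point, classes = NULL,
                       max_cardinality = NULL) {
  stopifnot(inherits(pair_mass, "mass_function"),
            inherits(lattice, "region_lattice"))
  if (!identical(pair_mass$frame$labels, lattice$frame$labels)) {
    stop("mass and lattice are on different frames")
  }
  frame <- pair_mass$frame
  fe <- focal_elements(pair_mass)
  if (is.null(classes)) {
    if (length(fe) != 2 || any(vapply(fe, function(k)
      length(.key_labels(k)), integer(1)) != 1)) {
      stop("pair mass must have exactly two singleton focal elements")
    }
    classes <- fe
  } else {
    classes <- as.character(classes)
    if (length(classes) != 2 || !all(fe %in% classes)) {
      stop("focal elements must lie within the stated class pair")
    }
  }
  a <- classes[1]; b <- classes[2]
  ma <- if (is.na(pair_mass$m[a])) 0 else pair_mass$m[[a]]
  mb <- if (is.na(pair_mass$m[b])) 0 else pair_mass$m[[b]]
  u2 <- .canon_key(c(a, b), frame)
  if (!lattice_contains(lattice, u2, point) || lattice_area(lattice, u2) <= 0) {
    return(pair_mass)
  }
  sa <- area_ratio(lattice, u2, a)
  sb <- area_ratio(lattice, u2, b)
  m <- stats::setNames(numeric(3), c(a, b, u2))
  m[a] <- (1 - sa) * ma
  m[b] <- (1 - sb) * mb
  m[u2] <- sa * ma + sb * mb
  if (is.null(max_cardinality)) max_cardinality <- length(frame$labels)
  cur <- u2
  for (lab in frame$labels) {
    if (length(.key_labels(cur)) >= max_cardinality) break
    if (lab %in% .key_labels(cur)) next
    cand <- .canon_key(c(.key_labels(cur), lab), frame)
    if (lattice_area(lattice, cand) > 0 &&
        lattice_contains(lattice, cand, point)) {
      s <- area_ratio(lattice, cand, cur)
      m[cand] <- s * m[[cur]]
      m[cur] <- (1 - s) * m[[cur]]
      cur <- cand
    }
  }
  mass_function(frame, m[m > 0], renormalize = FALSE)
}
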