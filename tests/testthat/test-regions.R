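test_that("bounding boxes fit point clouds with closed boundaries", {
  r <- fit_region(matrix(c(1, 1), ncol = 2))
  expect_equal(region_area(r), 0)
  expect_true(region_contains(r, c(1, 1)))

  pts <- rbind(c(1, 1), c(3, 2), c(2, 5))
  r2 <- fit_region(pts)
  expect_equal(c(r2$xmin, r2$xmax, r2$ymin, r2$ymax), c(1, 3, 1, 5))
  expect_equal(region_area(r2), 8)
  for (i in seq_len(nrow(pts))) expect_true(region_contains(r2, pts[i, ]))

  expect_error(fit_region(matrix(numeric(0), ncol = 2)), "at least one")
})

test_that("region intersection handles disjoint and nested boxes", {
  a <- rect_region(0, 2, 0, 2)
  b <- rect_region(5, 6, 5, 6)
  expect_true(region_intersect(a, b)$empty)
  expect_equal(region_area(region_intersect(a, b)), 0)
  expect_false(region_contains(region_intersect(a, b), c(0, 0)))

  inner <- rect_region(0.5, 1, 0.5, 1)
  expect_equal(region_intersect(a, inner), inner)

  # boundary membership is closed
  expect_true(region_contains(a, c(2, 2)))
  expect_false(region_contains(a, c(2.0001, 2)))
})

test_that("the lattice reproduces the published sepal ranges and areas", {
  lat <- fixtures()$iris_lattice
  expect_equal(unname(lat$areas["Se"]), 3.15, tolerance = 1e-12)
  seve <- lat$regions[["Se,Ve"]]
  expect_equal(c(seve$xmin, seve$xmax, seve$ymin, seve$ymax),
               c(4.9, 5.8, 2.3, 3.4))
  expect_equal(unname(lat$areas["Se,Ve"]), 0.99, tolerance = 1e-12)
  full <- lat$regions[["Se,Ve,Vi"]]
  expect_equal(c(full$xmin, full$xmax, full$ymin, full$ymax),
               c(4.9, 5.8, 2.5, 3.4))
  expect_equal(unname(lat$areas["Se,Ve,Vi"]), 0.81, tolerance = 1e-12)
})

test_that("lattice areas are monotone along subset inclusion", {
  set.seed(21)
  for (i in 1:20) {
    fr <- ds_frame(LETTERS[1:sample(2:4, 1)])
    lat <- random_lattice(fr)
    for (key in names(lat$areas)) {
      labs <- strsplit(key, ",")[[1]]
      singles <- lat$areas[labs]
      expect_lte(lat$areas[[key]], min(singles) + 1e-12)
      # composite region is contained in every member's box
      reg <- lat$regions[[key]]
      if (!reg$empty) {
        for (l in labs) {
          s <- lat$regions[[l]]
          expect_gte(reg$xmin, s$xmin); expect_lte(reg$xmax, s$xmax)
          expect_gte(reg$ymin, s$ymin); expect_lte(reg$ymax, s$ymax)
        }
      }
    }
  }
})

test_that("lattice areas agree with Monte-Carlo point sampling", {
  set.seed(22)
  fr <- ds_frame(c("A", "B", "C"))
  lat <- random_lattice(fr)
  xs <- range(unlist(lapply(lat$regions[fr$labels], function(r)
    c(r$xmin, r$xmax))))
  ys <- range(unlist(lapply(lat$regions[fr$labels], function(r)
    c(r$ymin, r$ymax))))
  box_area <- diff(xs) * diff(ys)
  n <- 40000
  px <- stats::runif(n, xs[1], xs[2])
  py <- stats::runif(n, ys[1], ys[2])
  for (key in c("A", "A,B", "A,B,C")) {
    reg <- lat$regions[[key]]
    inside <- if (reg$empty) rep(FALSE, n) else {
      px >= reg$xmin & px <= reg$xmax & py >= reg$ymin & py <= reg$ymax
    }
    est <- mean(inside) * box_area
    se <- stats::sd(inside) * box_area / sqrt(n)
    expect_lt(abs(est - lat$areas[[key]]), max(4 * se, 1e-9))
  }
})

test_that("area ratios follow the published examples and guard degeneracy", {
  fx <- fixtures()
  expect_equal(area_ratio(fx$toy_lattice, "A,B", "A"), 1.25 / 4.5,
               tolerance = 1e-12)
  expect_equal(area_ratio(fx$iris_lattice, "Se,Ve", "Se"), 0.99 / 3.15,
               tolerance = 1e-12)
  # empty child
  lat <- region_lattice(list(A = rect_region(0, 1, 0, 1),
                             B = rect_region(5, 6, 5, 6)))
  expect_equal(area_ratio(lat, "A,B", "A"), 0)
  # zero-area parent: ratio defined as 0
  lat0 <- region_lattice(list(A = rect_region(1, 1, 0, 1),
                              B = rect_region(0, 2, 0, 2)))
  expect_equal(area_ratio(lat0, "A,B", "A"), 0)
  expect_error(area_ratio(fx$toy_lattice, "A,B,C", "A"), "exactly one")
})

test_that("reallocation reproduces the worked three-class example", {
  fx <- fixtures()
  out <- reallocate(fx$toy_mass, fx$toy_lattice, c(0, 0),
                    classes = c("A", "B"))
  sab_a <- 1.25 / 4.5; sab_b <- 1.25 / 4; sabc <- 0.5 / 1.25
  ab1 <- sab_a * 0.6 + sab_b * 0.4
  expect_equal(unname(out$m["A"]), (1 - sab_a) * 0.6, tolerance = 1e-12)
  expect_equal(unname(out$m["B"]), (1 - sab_b) * 0.4, tolerance = 1e-12)
  expect_equal(unname(out$m["A,B"]), (1 - sabc) * ab1, tolerance = 1e-12)
  expect_equal(unname(out$m["A,B,C"]), sabc * ab1, tolerance = 1e-12)
  expect_equal(sum(out$m), 1, tolerance = 1e-12)

  # truncating the recursion yields the first-step state
  step1 <- reallocate(fx$toy_mass, fx$toy_lattice, c(0, 0),
                      classes = c("A", "B"), max_cardinality = 2)
  expect_equal(unname(step1$m["A,B"]), ab1, tolerance = 1e-12)
  expect_false("A,B,C" %in% focal_elements(step1))
})

test_that("reallocation is a no-op outside the pair intersection", {
  fr <- ds_frame(c("A", "B", "C"))
  lat <- region_lattice(list(A = rect_region(0, 2, 0, 2),
                             B = rect_region(1, 3, 1, 3),
                             C = rect_region(10, 11, 10, 11)), fr)
  m <- mass_function(fr, c(A = 0.6, B = 0.4))
  # point in A only, outside AB
  out <- reallocate(m, lat, c(0.2, 0.2))
  expect_equal(out$m, m$m)
  # disjoint boxes: reallocation inert everywhere
  lat0 <- region_lattice(list(A = rect_region(0, 1, 0, 1),
                              B = rect_region(5, 6, 0, 1),
                              C = rect_region(10, 11, 0, 1)), fr)
  expect_equal(reallocate(m, lat0, c(0.5, 0.5))$m, m$m)
})

test_that("reallocation conserves mass and keeps it in [0,1]", {
  set.seed(23)
  for (i in 1:100) {
    fr <- ds_frame(LETTERS[1:sample(2:4, 1)])
    lat <- random_lattice(fr)
    ab <- sample(fr$labels, 2)
    va <- stats::runif(1)
    m <- mass_function(fr, stats::setNames(c(va, 1 - va), ab)[c(va, 1 - va) > 0],
                       renormalize = FALSE)
    pt <- c(stats::runif(1, 0, 5), stats::runif(1, 0, 5))
    out <- reallocate(m, lat, pt, classes = ab)
    expect_equal(sum(out$m), 1, tolerance = 1e-12)
    expect_true(all(out$m >= 0 & out$m <= 1))
    # mass on a larger composite never exceeds its pre-discount source
    u2 <- paste(fr$labels[sort(match(ab, fr$labels))], collapse = ",")
    if (u2 %in% focal_elements(out) && !setequal(focal_elements(out),
                                                 focal_elements(m))) {
      expect_lte(unname(out$m[u2]), sum(m$m) + 1e-12)
    }
  }
})

test_that("lattices round-trip through JSON in both forms", {
  fx <- fixtures()
  p1 <- withr::local_tempfile(fileext = ".json")
  lattice_to_json(fx$iris_lattice, p1)
  back <- lattice_from_json(p1)
  expect_equal(back$areas, fx$iris_lattice$areas, tolerance = 1e-12)

  p2 <- withr::local_tempfile(fileext = ".json")
  lattice_to_json(fx$toy_lattice, p2)
  back2 <- lattice_from_json(p2)
  expect_null(back2$regions)
  expect_equal(back2$areas, fx$toy_lattice$areas, tolerance = 1e-12)
})
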