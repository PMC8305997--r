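test_that("fitting produces the expected pair/classifier combinatorics", {
  tab <- synth_classes(3, 4, samples_per_class = 15, overlap = 0.5, seed = 31)
  model <- evidential_fit(tab, T = 3)
  expect_length(model$pairs, choose(4, 2))
  for (p in model$pairs) expect_length(p$classifiers, choose(3, 2))

  tab2 <- synth_classes(2, 2, samples_per_class = 10, overlap = 0, seed = 32)
  model2 <- evidential_fit(tab2, T = 3)
  expect_length(model2$pairs, 1)
  expect_length(model2$pairs[[1]]$classifiers, 1)

  # deterministic: identical serialized models
  expect_identical(as.character(model_to_json(model)),
                   as.character(model_to_json(evidential_fit(tab, T = 3))))
})

test_that("a class with no usable rows on a pair is reported by name", {
  tab <- synth_classes(3, 3, samples_per_class = 8, overlap = 0, seed = 33)
  vals <- tab$values
  vals[tab$labels == "c2", 1] <- NA # c2 unusable wherever attribute 1 appears
  bad <- labeled_table(vals, tab$labels)
  expect_error(evidential_fit(bad, T = 2), "c2.*\\(1,2\\)")
})

test_that("pair-level BPAs are valid and respect the focal-support structure", {
  tab <- synth_iris_like(samples_per_class = 25, seed = 34)
  model <- evidential_fit(tab, T = 5)
  keys7 <- c("c1", "c2", "c3", "c1,c2", "c1,c3", "c2,c3", "c1,c2,c3")
  set.seed(34)
  for (r in sample(nrow(tab$values), 10)) {
    for (p in seq_along(model$pairs)) {
      m <- pair_bpa(model, p, tab$values[r, ])
      expect_equal(sum(m$m), 1, tolerance = 1e-12)
      expect_true(all(focal_elements(m) %in% keys7))
    }
  }
})

test_that("without region overlap BPAs are singleton-only and confident", {
  tab <- synth_classes(3, 4, samples_per_class = 20, overlap = 0, seed = 35)
  model <- evidential_fit(tab, T = 5)
  singles <- c("c1", "c2", "c3")
  # sample deep inside class c1's box
  s <- as.numeric(tab$values[3, ])
  for (p in seq_along(model$pairs)) {
    m <- pair_bpa(model, p, s)
    expect_true(all(focal_elements(m) %in% singles))
    # the two classifiers involving c1 vote for it in full; the third splits
    # its unit mass between c2 and c3
    expect_gte(unname(m$m["c1"]), 2 / 3 - 1e-9)
  }
  # evidential pipeline and plain-AdaBoost baseline agree deep inside a class
  expect_identical(predict(model, s), predict_adaboost(model, s))
  expect_identical(predict(model, s), "c1")
})

test_that("the dense pipeline equals the object-route primitives", {
  # reference route: vote_fraction -> mass_function -> reallocate -> average
  # -> ds_combine_all, built from the public primitives only
  tab <- synth_iris_like(samples_per_class = 20, seed = 30)
  model <- evidential_fit(tab, T = 5)
  set.seed(30)
  for (r in sample(nrow(tab$values), 8)) {
    s <- as.numeric(tab$values[r, ])
    ref_pairs <- lapply(model$pairs, function(entry) {
      p2 <- s[c(entry$i, entry$j)]
      parts <- lapply(entry$classifiers, function(clf) {
        va <- vote_fraction(clf, p2)
        m_t <- mass_function(model$frame,
                             stats::setNames(c(va, 1 - va), clf$class_pair)[
                               c(va, 1 - va) > 0])
        reallocate(m_t, entry$lattice, p2, classes = clf$class_pair)
      })
      acc <- stats::setNames(numeric(0), character(0))
      for (m_t in parts) {
        for (k in names(m_t$m)) {
          acc[k] <- (if (is.na(acc[k])) 0 else acc[[k]]) +
            m_t$m[[k]] / length(parts)
        }
      }
      mass_function(model$frame, acc)
    })
    ref <- ds_combine_all(ref_pairs)
    got <- predict_bpa(model, s)
    expect_equal(got$m[names(ref$m)], ref$m, tolerance = 1e-9)
    expect_identical(predict(model, s), ds_decide(ref))
  }
})

test_that("single-pair models fuse to their only pair BPA", {
  tab <- synth_classes(3, 2, samples_per_class = 15, overlap = 0.6, seed = 36)
  model <- evidential_fit(tab, T = 4)
  s <- tab$values[1, ]
  expect_equal(predict_bpa(model, s), pair_bpa(model, 1, s))
})

test_that("missing attributes drop pairs but keep the sample classifiable", {
  tab <- synth_classes(3, 3, samples_per_class = 20, overlap = 0.3, seed = 37)
  model <- evidential_fit(tab, T = 4)
  s <- as.numeric(tab$values[5, ])
  s[3] <- NA
  expect_null(pair_bpa(model, 2, s)) # pair (1,3) unavailable
  m <- predict_bpa(model, s) # falls back to pair (1,2)
  expect_s3_class(m, "mass_function")
  expect_identical(ds_decide(m), "c1")
  expect_error(predict_bpa(model, c(NA, NA, NA)), "no usable")
})

test_that("the post-averaging reallocation variant emits valid masses", {
  tab <- synth_iris_like(samples_per_class = 20, seed = 38)
  model <- evidential_fit(tab, T = 4, realloc = "post_average")
  set.seed(38)
  for (r in sample(nrow(tab$values), 5)) {
    m <- predict_bpa(model, tab$values[r, ])
    expect_equal(sum(m$m), 1, tolerance = 1e-9)
    expect_true(all(m$m >= 0))
  }
})

test_that("evaluation reports are reproducible and sane", {
  tab <- synth_classes(3, 3, samples_per_class = 12, overlap = 0, seed = 39)
  rep1 <- evaluate_classifier(tab, fractions = c(0.3, 0.6), repeats = 2,
                              T = 3, seed = 5)
  rep2 <- evaluate_classifier(tab, fractions = c(0.3, 0.6), repeats = 2,
                              T = 3, seed = 5)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_true(all(rep1$train_accuracy >= 0 & rep1$train_accuracy <= 1))
  # trivially separable data: perfect accuracy at every fraction
  expect_equal(rep1$overall_accuracy, c(1, 1))

  strat <- evaluate_classifier(tab, fractions = 0.5, repeats = 1, T = 3,
                               seed = 6, stratified = TRUE)
  expect_equal(strat$overall_accuracy, 1)
})

test_that("models round-trip through JSON with identical predictions", {
  tab <- synth_iris_like(samples_per_class = 15, seed = 40)
  model <- evidential_fit(tab, T = 3)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  back <- model_from_json(path)
  s <- tab$values[7, ]
  m1 <- predict_bpa(model, s)
  m2 <- predict_bpa(back, s)
  expect_equal(m2$m[names(m1$m)], m1$m, tolerance = 1e-12)
  expect_identical(predict(back, tab$values[1:5, ]),
                   predict(model, tab$values[1:5, ]))
})
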