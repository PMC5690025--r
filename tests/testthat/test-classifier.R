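# CV error, sequential forward selection, one-vs-all training surface.

test_that("linearly separable toy problem gives zero CV error", {
  toy <- make_separable_toy(n = 40)
  expect_equal(kfold_cv_error(toy$X, toy$y, k = 10, seed = 0), 0)
})

test_that("label-independent features give chance-level error", {
  withr::with_seed(77, {
    X <- cbind(noise = stats::rnorm(200))
    y <- rep(c(TRUE, FALSE), each = 100)
  })
  err <- kfold_cv_error(X, y, k = 10, seed = 0)
  expect_gt(err, 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(err, 0.5 + 3 * sqrt(0.25 / 200))
})

test_that("CV is deterministic in the seed and validates its inputs", {
  toy <- make_separable_toy(n = 40)
  expect_identical(kfold_cv_error(toy$X, toy$y, k = 10, seed = 3),
                   kfold_cv_error(toy$X, toy$y, k = 10, seed = 3))
  expect_error(kfold_cv_error(toy$X, rep(TRUE, 40)), "both classes")
  expect_error(kfold_cv_error(toy$X, toy$y, k = 41), "exceed")
  expect_error(kfold_cv_error(toy$X, toy$y, k = 25), "class count")
})

test_that("CV error equals a hand-rolled leak-free fold loop", {
  # includes gross outliers so any standardization leak would change folds'
  # scalers and hence predictions
  withr::with_seed(11, {
    X <- cbind(a = stats::rnorm(40), b = stats::rnorm(40, sd = 100))
    X[1:4, "b"] <- 1e4
    y <- rep(c(TRUE, FALSE), 20)
    X[y, "a"] <- X[y, "a"] + 1.2
  })
  for (seed in c(0, 1, 7)) {
    expect_equal(kfold_cv_error(X, y, k = 10, seed = seed),
                 oracle_cv_error(X, y, k = 10, seed = seed))
  }
})

test_that("SFS finds a single separating feature and stops on noise", {
  withr::with_seed(21, {
    X <- cbind(matrix(stats::rnorm(40 * 5), 40, 5), sep = rep(c(-1, 1), 20))
    colnames(X) <- c(paste0("n", 1:5), "sep")
    y <- rep(c(FALSE, TRUE), 20)
  })
  sfs <- sequential_forward_select(X, y, k = 10, seed = 0)
  expect_identical(sfs$features, "sep")
  expect_equal(sfs$cv_error, 0)
  # brute force over single features confirms the greedy first step
  singles <- vapply(colnames(X), function(f) {
    kfold_cv_error(X, y, feature_subset = f, k = 10, seed = 0)
  }, numeric(1))
  expect_equal(min(singles), 0)
  expect_identical(names(which.min(singles)), "sep")

  # pure-noise features: no strict improvement after the first forced pick
  Xn <- X[, 1:5]
  sfs_n <- sequential_forward_select(Xn, y, k = 10, seed = 0)
  expect_length(sfs_n$features, 1)

  expect_length(sequential_forward_select(X, y, k = 10, seed = 0,
                                          max_features = 1)$features, 1)
})

test_that("SFS agrees with exhaustive search on small instances", {
  # when the greedy path is optimal at sizes 1-2, SFS must equal exhaustive
  withr::with_seed(33, {
    X <- matrix(stats::rnorm(40 * 6), 40, 6)
    colnames(X) <- paste0("f", 1:6)
    y <- rep(c(FALSE, TRUE), each = 20)
    X[y, 2] <- X[y, 2] + 1.1
    X[y, 5] <- X[y, 5] + 0.9
  })
  sfs <- sequential_forward_select(X, y, k = 10, seed = 0, max_features = 2)
  singles <- vapply(colnames(X), function(f)
    kfold_cv_error(X, y, f, k = 10, seed = 0), numeric(1))
  best1 <- names(which.min(singles))
  expect_identical(sfs$features[1], best1)
  if (length(sfs$features) == 2) {
    pairs_err <- vapply(setdiff(colnames(X), best1), function(f)
      kfold_cv_error(X, y, c(best1, f), k = 10, seed = 0), numeric(1))
    expect_equal(sfs$cv_error, min(min(pairs_err), min(singles)))
  }
})

test_that("one-vs-all heads honour multi-label positives and serialize", {
  ds <- generate_dataset(
    n_per_class = 6,
    classes = list("regular", "rings", "scatter", c("rings", "scatter")),
    section_kinds = "uniformity", noise_sigma = 15, master_seed = 4
  )
  ft <- extract_features(ds)
  mod <- train_artifact_classifier(
    ft, classes = c("rings", "scatter", "regular"), k = 5, seed = 0,
    max_features = 3
  )
  td <- tidy(mod)
  expect_true(all(td$cv_error >= 0 & td$cv_error <= 1))
  # the double-artifact images must fire both heads
  preds <- predict(mod, ft)
  both <- ft$id[vapply(ft$labels, function(l) setequal(l, c("rings", "scatter")),
                       logical(1))]
  for (cls in c("rings", "scatter")) {
    hit <- preds[preds$id %in% both & preds$class == cls, ]
    expect_true(all(hit$positive))
  }
  # clean images classified regular
  cl <- classify_artifacts(mod, ft)
  clean_ids <- ft$id[vapply(ft$labels, length, integer(1)) == 0]
  for (i in clean_ids) {
    expect_identical(cl$detected[[which(cl$id == i)]], "regular")
  }
  # round trip: identical margins and decisions
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(mod, path)
  mod2 <- read_classifier(path)
  p2 <- predict(mod2, ft)
  expect_equal(preds$margin, p2$margin, tolerance = 1e-9)
  expect_identical(preds$positive, p2$positive)
  # margins flip sign when the head weights are negated (linearity contract)
  mod3 <- mod2
  mod3$heads$weights <- lapply(mod3$heads$weights, function(w) -w)
  mod3$heads$bias <- -mod3$heads$bias
  expect_equal(predict(mod3, ft)$margin, -p2$margin, tolerance = 1e-12)
})

test_that("missing features and unknown sections are reported by name", {
  ds <- generate_dataset(n_per_class = 3, classes = list("regular", "scatter"),
                         section_kinds = "uniformity", noise_sigma = 10,
                         master_seed = 5)
  ft <- extract_features(ds)
  mod <- train_artifact_classifier(ft, classes = c("scatter"), k = 3, seed = 0,
                                   max_features = 2)
  used <- mod$heads$features[[1]][1]
  broken <- ft[, setdiff(names(ft), used)]
  expect_error(predict(mod, broken), used, fixed = TRUE)
  other <- dplyr::mutate(ft, section_kind = "high_contrast")
  expect_error(predict(mod, other), "high_contrast")
})
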