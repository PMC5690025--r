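# One-vs-all linear SVM artifact classification with sequential forward
# feature selection under stratified k-fold cross-validation. Fold-wise
# standardization is computed on the training split only, so test-fold
# statistics never leak into the scaler.

as_feature_matrix <- function(X, feature_subset = NULL) {
  if (inherits(X, "data.frame")) {
    num <- vapply(X, is.numeric, logical(1))
    X <- as.matrix(X[, num, drop = FALSE])
  }
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(X))
    if (length(missing) > 0) {
      rlang::abort(paste0("Missing feature(s): ", paste(missing, collapse = ", ")))
    }
    X <- X[, feature_subset, drop = FALSE]
  }
  X
}

as_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lv <- unique(as.character(y))
    if (length(lv) > 2) rlang::abort("`y` must be binary.")
    y <- as.character(y) == sort(lv)[1]
  }
  as.logical(y)
}

# Stratified fold assignment: each class is shuffled and dealt round-robin.
make_stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

train_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}

fit_linear_svm <- function(Xs, y, cost) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  e1071::svm(Xs, yf, type = "C-classification", kernel = "linear",
             cost = cost, scale = FALSE)
}

#' Stratified k-fold cross-validation error of a linear SVM
#'
#' For each fold the remaining folds are standardized (mean/SD computed on
#' the training split only), a linear SVM (`C = cost`) is fitted, and the
#' held-out fold is standardized with the training scaler and scored. The
#' error is the total misclassification count divided by `n`. Deterministic
#' given `seed`.
#'
#' @param X Feature table (tibble/data frame with numeric feature columns, or
#'   a numeric matrix).
#' @param y Binary labels: logical, or a 2-level factor/character vector.
#' @param feature_subset Optional character vector restricting the columns
#'   used.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM regularization parameter C (default 1).
#' @return Error rate in \[0, 1\].
#' @export
kfold_cv_error <- function(X, y, feature_subset = NULL, k = 10, seed = 0,
                           cost = 1) {
  X <- as_feature_matrix(X, feature_subset)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) rlang::abort("`y` must contain both classes.")
  if (k > length(y)) rlang::abort("`k` cannot exceed the number of samples.")
  if (k < 2) rlang::abort("`k` must be at least 2.")
  if (k > min(table(y))) {
    rlang::abort("`k` cannot exceed the smaller class count (stratified folds).")
  }
  folds <- make_stratified_folds(y, k, seed)
  wrong <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- train_scaler(X[tr, , drop = FALSE])
    m <- fit_linear_svm(apply_scaler(X[tr, , drop = FALSE], sc), y[tr], cost)
    pred <- predict(m, apply_scaler(X[!tr, , drop = FALSE], sc)) == "pos"
    wrong <- wrong + sum(pred != y[!tr])
  }
  wrong / length(y)
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: at each step the candidate feature whose
#' addition minimizes [kfold_cv_error()] is added (ties broken by lowest
#' column index, i.e. registry order); selection stops when no addition
#' strictly reduces the error, when the error reaches 0, or when
#' `max_features` is reached.
#'
#' @inheritParams kfold_cv_error
#' @param max_features Maximum number of features to select (default 5).
#' @return A list with `features` (ordered character vector), `cv_error`
#'   (the final error) and `trace` (tibble `step`, `feature`, `cv_error`).
#' @export
sequential_forward_select <- function(X, y, k = 10, seed = 0, cost = 1,
                                      max_features = 5) {
  Xm <- as_feature_matrix(X)
  if (ncol(Xm) < 1) rlang::abort("At least one candidate feature is required.")
  candidates <- colnames(Xm)
  selected <- character(0)
  best <- Inf
  trace <- list()
  while (length(selected) < max_features && length(candidates) > 0) {
    errs <- vapply(candidates, function(f) {
      kfold_cv_error(Xm, y, feature_subset = c(selected, f), k = k,
                     seed = seed, cost = cost)
    }, numeric(1))
    i <- which.min(errs)                 # first minimum = lowest registry index
    if (errs[i] >= best) break
    best <- unname(errs[i])
    selected <- c(selected, candidates[i])
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(selected), feature = candidates[i], cv_error = best
    )
    candidates <- candidates[-i]
    if (best == 0) break
  }
  list(features = selected, cv_error = best, trace = dplyr::bind_rows(trace))
}

# Positivity rule of each one-vs-all head. Multi-label images count as
# positive for every artifact they carry.
head_is_positive <- function(labels_list, class_name) {
  if (class_name == "regular") {
    vapply(labels_list, function(l) length(l) == 0, logical(1))
  } else if (class_name == "regular_or_crescent") {
    vapply(labels_list, function(l) all(l %in% "crescent"), logical(1))
  } else {
    vapply(labels_list, function(l) class_name %in% l, logical(1))
  }
}

default_head_classes <- function() {
  c("scatter", "beam_hardening", "rings", "crescent", "regular",
    "regular_or_crescent")
}

#' Train one-vs-all artifact classifiers per phantom section
#'
#' For every section kind present in `features` and every class head, runs
#' [sequential_forward_select()] over the finite feature columns and refits
#' the linear SVM on all data with the selected features (features z-scored
#' with the full-data scaler, which is stored with the model). Feature
#' columns that are not finite for every image of a section (e.g. an MTF50
#' that never crossed) are excluded from that section's pool.
#'
#' @param features Wide feature tibble from [extract_features()]: columns
#'   `id`, `section_kind`, `labels` (list-column of label sets) and one
#'   numeric column per feature.
#' @param classes Head names; artifact kinds are positive when the kind is in
#'   the label set, `"regular"` when the set is empty,
#'   `"regular_or_crescent"` when the set is empty or crescent-only.
#' @inheritParams kfold_cv_error
#' @inheritParams sequential_forward_select
#' @return An object of class `artifact_classifier` with one head per
#'   (section, class): selected features, weights, bias, scaler, CV error.
#' @export
train_artifact_classifier <- function(features,
                                      classes = default_head_classes(),
                                      k = 10, seed = 0, cost = 1,
                                      max_features = 5) {
  stopifnot(all(c("section_kind", "labels") %in% names(features)))
  heads <- list()
  for (kind in unique(features$section_kind)) {
    sec <- features[features$section_kind == kind, ]
    num <- vapply(sec, is.numeric, logical(1))
    finite <- vapply(sec[, num, drop = FALSE],
                     function(v) all(is.finite(v)), logical(1))
    Xs <- as.matrix(sec[, names(finite)[finite], drop = FALSE])
    for (cls in classes) {
      y <- head_is_positive(sec$labels, cls)
      if (sum(y) < 2 || sum(!y) < 2) {
        rlang::warn(sprintf(
          "Section %s: class %s has fewer than 2 examples per side; skipped.",
          kind, cls))
        next
      }
      sfs <- sequential_forward_select(Xs, y, k = k, seed = seed, cost = cost,
                                       max_features = max_features)
      Xf <- Xs[, sfs$features, drop = FALSE]
      sc <- train_scaler(Xf)
      m <- fit_linear_svm(apply_scaler(Xf, sc), y, cost)
      w <- drop(crossprod(m$coefs, m$SV))
      b <- -m$rho
      dv <- drop(apply_scaler(Xf, sc) %*% w) + b
      if (mean(dv[y]) < mean(dv[!y])) { w <- -w; b <- -b }
      heads[[length(heads) + 1]] <- tibble::tibble(
        section_kind = kind, class = cls,
        features = list(sfs$features),
        mu = list(unname(sc$mu)), sd = list(unname(sc$sd)),
        weights = list(unname(w)), bias = b,
        cv_error = sfs$cv_error, trace = list(sfs$trace)
      )
    }
  }
  structure(
    list(heads = dplyr::bind_rows(heads),
         config = list(k = k, seed = seed, cost = cost,
                       max_features = max_features)),
    class = "artifact_classifier"
  )
}

#' @export
print.artifact_classifier <- function(x, ...) {
  cat(sprintf("<artifact_classifier> %d head(s), k = %d, C = %g, seed = %d\n",
              nrow(x$heads), x$config$k, x$config$cost, x$config$seed))
  print(tidy(x))
  invisible(x)
}

#' Tidy a trained artifact classifier
#'
#' @param x An `artifact_classifier`.
#' @param ... Unused.
#' @return One row per (section, class) head with `cv_error`, `n_features`
#'   and the collapsed selected-feature list.
#' @method tidy artifact_classifier
#' @export
tidy.artifact_classifier <- function(x, ...) {
  dplyr::mutate(
    x$heads[, c("section_kind", "class", "cv_error")],
    n_features = vapply(x$heads$features, length, integer(1)),
    features = vapply(x$heads$features, paste, character(1), collapse = ", ")
  )
}

#' @rdname tidy.artifact_classifier
#' @method glance artifact_classifier
#' @export
glance.artifact_classifier <- function(x, ...) {
  tibble::tibble(
    n_heads = nrow(x$heads),
    mean_cv_error = mean(x$heads$cv_error),
    k = x$config$k, cost = x$config$cost, seed = x$config$seed
  )
}

#' Per-head decision margins for new feature vectors
#'
#' Each one-vs-all head votes independently: the margin is the signed linear
#' decision value in standardized feature space (positive = head fires), so
#' an image may receive several artifact labels.
#'
#' @param object An [artifact_classifier][train_artifact_classifier].
#' @param features Wide feature tibble (as from [extract_features()] or a
#'   single [extract_feature_vector()] row). Section kinds absent from the
#'   model are an error, as are missing feature columns (named in the error).
#' @param ... Unused.
#' @return Long tibble: `id`, `section_kind`, `class`, `margin`, `positive`.
#' @method predict artifact_classifier
#' @export
predict.artifact_classifier <- function(object, features, ...) {
  if (!"id" %in% names(features)) {
    features <- dplyr::mutate(features, id = sprintf("img_%03d", dplyr::row_number()))
  }
  out <- list()
  for (kind in unique(features$section_kind)) {
    heads <- object$heads[object$heads$section_kind == kind, ]
    if (nrow(heads) == 0) {
      rlang::abort(sprintf("Model has no heads for section kind '%s'.", kind))
    }
    sec <- features[features$section_kind == kind, ]
    for (h in seq_len(nrow(heads))) {
      fts <- heads$features[[h]]
      missing <- setdiff(fts, names(sec))
      if (length(missing) > 0) {
        rlang::abort(paste0("Missing feature(s): ", paste(missing, collapse = ", ")))
      }
      Xf <- as.matrix(sec[, fts, drop = FALSE])
      sc <- list(mu = heads$mu[[h]], sd = heads$sd[[h]])
      margin <- drop(apply_scaler(Xf, sc) %*% heads$weights[[h]]) + heads$bias[h]
      out[[length(out) + 1]] <- tibble::tibble(
        id = sec$id, section_kind = kind, class = heads$class[h],
        margin = margin, positive = margin > 0
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Classify images by the artifacts their heads detect
#'
#' Summarizes [predict.artifact_classifier()]: every artifact head that fires
#' contributes its label; an image whose artifact heads all stay silent is
#' reported as `"regular"`.
#'
#' @inheritParams predict.artifact_classifier
#' @param model An [artifact_classifier][train_artifact_classifier].
#' @return Tibble `id`, `section_kind`, `detected` (list-column of labels).
#' @export
classify_artifacts <- function(model, features) {
  margins <- predict(model, features)
  margins <- margins[margins$class %in% artifact_kinds(), ]
  margins |>
    dplyr::group_by(.data$id, .data$section_kind) |>
    dplyr::summarise(
      detected = list({
        pos <- .data$class[.data$positive]
        if (length(pos) == 0) "regular" else sort(pos)
      }),
      .groups = "drop"
    )
}

#' Persist / restore a trained classifier as JSON
#'
#' The JSON captures selected features, weights, standardization parameters,
#' per-head CV errors and the training config; a restored model produces
#' identical predictions.
#'
#' @param model An [artifact_classifier][train_artifact_classifier].
#' @param path File path.
#' @return `write_classifier()` returns `path` invisibly; `read_classifier()`
#'   returns the model.
#' @export
write_classifier <- function(model, path) {
  heads <- lapply(seq_len(nrow(model$heads)), function(i) {
    h <- model$heads[i, ]
    list(section_kind = h$section_kind, class = h$class,
         features = h$features[[1]], mu = h$mu[[1]], sd = h$sd[[1]],
         weights = h$weights[[1]], bias = h$bias, cv_error = h$cv_error)
  })
  jsonlite::write_json(list(heads = heads, config = model$config), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  heads <- dplyr::bind_rows(lapply(raw$heads, function(h) {
    tibble::tibble(
      section_kind = h$section_kind, class = h$class,
      features = list(unlist(h$features)),
      mu = list(unlist(h$mu)), sd = list(unlist(h$sd)),
      weights = list(unlist(h$weights)), bias = h$bias,
      cv_error = h$cv_error, trace = list(NULL)
    )
  }))
  structure(list(heads = heads, config = raw$config),
            class = "artifact_classifier")
}
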