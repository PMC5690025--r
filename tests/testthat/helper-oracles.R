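# Independent oracles used across test files. These deliberately use naive
# loop-based implementations so they share no code path with the package.

# Brute-force symmetric normalized co-occurrence matrix by explicit pair
# enumeration over every pixel and offset.
oracle_glcm_matrix <- function(q, drow, dcol, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(q[r, c]) && !is.na(q[r2, c2])) {
        counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
        counts[q[r2, c2], q[r, c]] <- counts[q[r2, c2], q[r, c]] + 1
      }
    }
  }
  counts / sum(counts)
}

# Direct formulas for a handful of GLCM scalars, written independently.
oracle_glcm_scalars <- function(P) {
  L <- nrow(P)
  contrast <- 0; dissim <- 0; energy <- 0; entropy <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      contrast <- contrast + (i - j)^2 * P[i, j]
      dissim <- dissim + abs(i - j) * P[i, j]
      energy <- energy + P[i, j]^2
      if (P[i, j] > 0) entropy <- entropy - P[i, j] * log2(P[i, j])
    }
  }
  c(contrast = contrast, dissimilarity = dissim, energy = energy,
    entropy = entropy, `maximum probability` = max(P))
}

# Hand-rolled stratified k-fold CV loop with leak-free standardization,
# mirroring the contract but none of the package code.
oracle_cv_error <- function(X, y, k, seed, cost = 1) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  wrong <- 0
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    mu <- colMeans(X[tr, , drop = FALSE])
    s <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    s[s < 1e-12] <- 1
    scale_with <- function(M) sweep(sweep(M, 2, mu, "-"), 2, s, "/")
    yf <- factor(ifelse(y[tr], "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(scale_with(X[tr, , drop = FALSE]), yf,
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
    pred <- predict(m, scale_with(X[te, , drop = FALSE])) == "pos"
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / length(y)
}

# Separable 1D toy problem: classes centred at -1 and +1 with spread 0.1.
make_separable_toy <- function(n = 40, seed = 42) {
  withr::with_seed(seed, {
    x <- c(stats::runif(n / 2, -1.1, -0.9), stats::runif(n / 2, 0.9, 1.1))
    X <- cbind(feat = x)
    y <- rep(c(FALSE, TRUE), each = n / 2)
    list(X = X, y = y)
  })
}
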