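# Gaussian-kernel C-SVM, solved as the dual QP with quadprog.
# No SVM package ships in the target environment, so the classifier is
# implemented here: binary soft-margin dual, one-vs-one multiclass voting,
# and stratified k-fold cross-validated grid search over (C, gamma).

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

# binary C-SVM dual:
#   min 1/2 a' Q a - 1'a,  Q = (y y') * K,  s.t. y'a = 0, 0 <= a <= C
svm_binary_fit <- function(X, y, C, gamma) {
  stopifnot(all(y %in% c(-1, 1)), length(unique(y)) == 2)
  n <- length(y)
  K <- rbf_kernel(X, X, gamma)
  Q <- (y %o% y) * K + diag(1e-8, n)
  sol <- quadprog::solve.QP(Dmat = Q, dvec = rep(1, n),
                            Amat = cbind(y, diag(n), -diag(n)),
                            bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  g <- as.vector(K %*% (a * y))
  margin <- which(a > 1e-6 * C & a < C * (1 - 1e-6))
  b <- if (length(margin) > 0) {
    mean(y[margin] - g[margin])
  } else {
    -(max(g[y == -1]) + min(g[y == 1])) / 2
  }
  list(X = X, y = y, alpha = a, b = b, C = C, gamma = gamma)
}

svm_binary_decision <- function(model, Xnew) {
  as.vector(rbf_kernel(Xnew, model$X, model$gamma) %*%
              (model$alpha * model$y)) + model$b
}

# one-vs-one multiclass wrapper. `y` is a factor.
svm_fit <- function(X, y, C, gamma) {
  lev <- levels(droplevels(y))
  y <- droplevels(y)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    sel <- y %in% p
    yy <- ifelse(y[sel] == p[2], 1, -1)   # +1 = second level of the pair
    svm_binary_fit(X[sel, , drop = FALSE], yy, C, gamma)
  })
  structure(list(models = models, pairs = pairs, levels = lev,
                 C = C, gamma = gamma),
            class = "mpus_svm")
}

#' @export
predict.mpus_svm <- function(object, newdata, ...) {
  n <- nrow(newdata)
  votes <- matrix(0, n, length(object$levels),
                  dimnames = list(NULL, object$levels))
  score <- votes
  for (i in seq_along(object$models)) {
    d <- svm_binary_decision(object$models[[i]], newdata)
    p <- object$pairs[[i]]
    win <- ifelse(d > 0, p[2], p[1])
    for (k in seq_len(n)) votes[k, win[k]] <- votes[k, win[k]] + 1
    score[, p[2]] <- score[, p[2]] + d
    score[, p[1]] <- score[, p[1]] - d
  }
  # majority vote; ties broken by summed decision values
  pick <- vapply(seq_len(n), function(k) {
    best <- which(votes[k, ] == max(votes[k, ]))
    if (length(best) > 1) best <- best[which.max(score[k, best])]
    object$levels[best]
  }, "")
  factor(pick, levels = object$levels)
}

# stratified fold assignment (1..k) for a factor y
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# grid search over (C, gamma) by stratified k-fold CV accuracy.
svm_grid_search <- function(X, y, C_grid = 10^(-1:3), gamma_grid = 10^(-3:1),
                            n_folds = 5) {
  n_folds <- min(n_folds, min(table(y)))
  fold <- stratified_folds(y, n_folds)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      m <- svm_fit(X[tr, , drop = FALSE], y[tr], grid$C[i], grid$gamma[i])
      correct <- correct +
        sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, 0)
  best <- which.max(acc)
  list(C = grid$C[best], gamma = grid$gamma[best], cv_accuracy = acc[best],
       grid = cbind(grid, cv_accuracy = acc))
}
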