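#' Z-score standardization of a feature table
#'
#' Centers and scales each of the six mpUS feature columns to mean 0 and
#' unit sample SD (n - 1 convention), so that features measured on very
#' different scales (m/s, Np/m, a.u., ratios) carry equal weight in PCA and
#' the SVM kernel. The fitted centers and scales are attached as attributes
#' so held-out rows can be standardized with the training parameters.
#'
#' @param table a `feature_table` (see [gen_feature_table()]).
#' @param center,scale optional previously fitted parameters (named
#'   6-vectors) to apply instead of fitting new ones.
#' @return the standardized `feature_table`, with attributes `center` and
#'   `scale`.
#' @export
zscore <- function(table, center = NULL, scale = NULL) {
  stopifnot(all(mpus_feature_names %in% names(table)))
  X <- as.matrix(table[, mpus_feature_names])
  if (is.null(center)) {
    sds <- apply(X, 2, sd)
    zero <- sds < 1e-12
    if (any(zero)) {
      stop("zero-variance feature column(s): ",
           paste(mpus_feature_names[zero], collapse = ", "))
    }
    center <- colMeans(X)
    scale <- sds
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  table[, mpus_feature_names] <- Xs
  attr(table, "center") <- center
  attr(table, "scale") <- scale
  table
}

#' PCA with per-feature contribution percentages
#'
#' Runs PCA on the standardized feature matrix and attributes the variance
#' captured by the retained components back to the original features:
#' the contribution of feature `j` is
#' `100 * sum_k lambda_k w_jk^2 / sum_k lambda_k` over the retained
#' components `k`, i.e. eigenvalue-weighted squared loadings. Contributions
#' sum to 100. With all components retained on standardized data every
#' feature contributes exactly `100/6` (each standardized feature has unit
#' variance), so a reduced set -- typically the first three components, as
#' used for decision-plane visualization -- is what makes the ranking
#' informative. Component signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param table a standardized `feature_table` (see [zscore()]).
#' @param n_components number of leading components to retain (1-6).
#' @return list with `scores` (rows x retained components), `loadings`
#'   (6 x retained), `explained_variance` (percent per retained component,
#'   out of the total variance), `contributions` (named percent 6-vector),
#'   and `eigenvalues`.
#' @export
pca_contributions <- function(table, n_components = 3) {
  stopifnot(all(mpus_feature_names %in% names(table)))
  X <- as.matrix(table[, mpus_feature_names])
  stopifnot(n_components >= 1, n_components <= ncol(X))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > 1e-10 * p$sdev[1])
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds matrix rank (", rank, ")")
  }
  flip <- apply(p$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  rot <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  lambda <- p$sdev^2
  keep <- seq_len(n_components)
  contrib <- 100 * as.vector(rot[, keep, drop = FALSE]^2 %*% lambda[keep]) /
    sum(lambda[keep])
  names(contrib) <- mpus_feature_names
  list(scores = scores[, keep, drop = FALSE],
       loadings = rot[, keep, drop = FALSE],
       explained_variance = 100 * lambda[keep] / sum(lambda),
       contributions = contrib,
       eigenvalues = lambda)
}

#' Train and evaluate the Gaussian-kernel SVM on a feature table
#'
#' Stratified seeded 80/20 (by default) split; Z-scoring and (optionally)
#' PCA are fitted on the training split only and applied to the test split;
#' hyperparameters are chosen by grid search over `C` in `10^(-1..3)` and
#' `gamma` in `10^(-3..1)` with stratified 5-fold cross-validation on the
#' training split. Multiclass problems use one-vs-one voting.
#'
#' Three accuracies are reported: `train_accuracy` (training split),
#' `test_accuracy` (held-out split), and `overall_accuracy` (the same
#' trained model's predictions over all rows). The two-category mode drops
#' the low-fat cohort and separates normal from high-fat livers; the
#' three-category mode keeps all cohorts.
#'
#' @param table a `feature_table` (raw units; standardization happens
#'   inside the split).
#' @param mode `"two_category"` or `"three_category"`.
#' @param input_space `"raw_features"` (6 standardized features),
#'   `"first_3_pcs"`, or `"all_pcs"`.
#' @param split training fraction (default 0.8).
#' @param seed integer seed controlling the split, fold assignment, and any
#'   RNG inside the search.
#' @param C_grid,gamma_grid hyperparameter grids.
#' @return an object of class `classification_report`.
#' @export
svm_train_eval <- function(table,
                           mode = c("two_category", "three_category"),
                           input_space = c("raw_features", "first_3_pcs",
                                           "all_pcs"),
                           split = 0.8, seed = 1,
                           C_grid = 10^(-1:3), gamma_grid = 10^(-3:1)) {
  mode <- match.arg(mode)
  input_space <- match.arg(input_space)
  stopifnot(split > 0, split < 1)
  tab <- as.data.frame(table)
  if (mode == "two_category") {
    tab <- tab[tab$cohort %in% c("normal", "high_fat"), , drop = FALSE]
  }
  tab$cohort <- factor(tab$cohort,
                       levels = intersect(c("normal", "low_fat", "high_fat"),
                                          unique(tab$cohort)))
  counts <- base::table(tab$cohort)
  if (any(counts < 2)) {
    stop("every cohort needs at least 2 rows; got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }

  res <- with_seed_maybe(seed, {
    # stratified split
    test_idx <- unlist(lapply(levels(tab$cohort), function(lev) {
      idx <- which(tab$cohort == lev)
      n_test <- max(1, round(length(idx) * (1 - split)))
      sample(idx, n_test)
    }))
    train_idx <- setdiff(seq_len(nrow(tab)), test_idx)
    if (length(unique(tab$cohort[test_idx])) < nlevels(tab$cohort)) {
      stop("split left an empty test class; stratification counts: ",
           paste(levels(tab$cohort), tabulate(tab$cohort[test_idx]),
                 sep = "=", collapse = ", "))
    }
    train <- tab[train_idx, ]
    ztrain <- zscore(structure(train, class = c("feature_table", "data.frame")))
    zfull <- zscore(structure(tab, class = c("feature_table", "data.frame")),
                    center = attr(ztrain, "center"),
                    scale = attr(ztrain, "scale"))
    pca <- NULL
    n_pc <- switch(input_space, raw_features = 0L, first_3_pcs = 3L,
                   all_pcs = 6L)
    if (n_pc > 0) {
      pca <- pca_contributions(ztrain, n_components = n_pc)
      Xfull <- as.matrix(as.data.frame(zfull)[, mpus_feature_names])
      Xfull <- sweep(Xfull, 2, colMeans(as.matrix(
        as.data.frame(ztrain)[, mpus_feature_names])))
      Xall <- Xfull %*% pca$loadings
    } else {
      Xall <- as.matrix(as.data.frame(zfull)[, mpus_feature_names])
    }
    Xtr <- Xall[train_idx, , drop = FALSE]
    ytr <- tab$cohort[train_idx]
    search <- svm_grid_search(Xtr, ytr, C_grid, gamma_grid)
    model <- svm_fit(Xtr, ytr, search$C, search$gamma)
    pred_all <- predict(model, Xall)
    list(test_idx = test_idx, train_idx = train_idx, model = model,
         search = search, pca = pca, pred_all = pred_all,
         center = attr(ztrain, "center"), scale = attr(ztrain, "scale"),
         scores = Xall)
  })

  acc <- function(idx) {
    100 * mean(res$pred_all[idx] == tab$cohort[idx])
  }
  structure(list(mode = mode, input_space = input_space,
                 train_accuracy = acc(res$train_idx),
                 test_accuracy = acc(res$test_idx),
                 overall_accuracy = acc(seq_len(nrow(tab))),
                 pca_contributions = if (!is.null(res$pca)) res$pca$contributions,
                 explained_variance = if (!is.null(res$pca)) res$pca$explained_variance,
                 hyperparameters = c(C = res$search$C, gamma = res$search$gamma),
                 cv_accuracy = 100 * res$search$cv_accuracy,
                 n_train = length(res$train_idx), n_test = length(res$test_idx),
                 cohort_counts = as.list(counts),
                 model = res$model, scores = res$scores,
                 labels = tab$cohort, test_idx = res$test_idx,
                 center = res$center, scale = res$scale,
                 seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s / %s\n", x$mode, x$input_space))
  cat(sprintf("  accuracy: train %.1f%% | test %.1f%% | overall %.1f%%\n",
              x$train_accuracy, x$test_accuracy, x$overall_accuracy))
  cat(sprintf("  SVM: C = %g, gamma = %g (CV %.1f%%); n = %d train / %d test\n",
              x$hyperparameters["C"], x$hyperparameters["gamma"],
              x$cv_accuracy, x$n_train, x$n_test))
  if (!is.null(x$pca_contributions)) {
    cat("  PCA contributions (%):",
        paste(sprintf("%s %.1f", names(x$pca_contributions),
                      x$pca_contributions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample the SVM decision surface on a 3D grid
#'
#' Evaluates the trained classifier of a `classification_report` built in a
#' PC input space on a regular grid spanning the observed range of the first
#' three PC scores, for decision-plane rendering.
#'
#' @param report a `classification_report` with `input_space` using PCs.
#' @param n grid points per axis.
#' @return data.frame with `pc1`, `pc2`, `pc3` and the predicted `label`.
#' @export
decision_surface <- function(report, n = 12) {
  stopifnot(inherits(report, "classification_report"))
  if (report$input_space == "raw_features") {
    stop("decision_surface needs a report trained in a PC input space")
  }
  S <- report$scores[, 1:3, drop = FALSE]
  axes <- lapply(1:3, function(j) seq(min(S[, j]), max(S[, j]), length.out = n))
  grid <- as.matrix(expand.grid(pc1 = axes[[1]], pc2 = axes[[2]],
                                pc3 = axes[[3]]))
  full <- cbind(grid, matrix(0, nrow(grid),
                             ncol(report$scores) - 3))[, seq_len(ncol(report$scores)), drop = FALSE]
  out <- as.data.frame(grid)
  out$label <- predict(report$model, full)
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic is
#' `U = min(U_x, U_y)` with midranks for ties. The two-sided p-value is
#' exact -- computed from the full null distribution of U by dynamic
#' programming -- whenever `n_x * n_y <= 400` and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections is
#' used.
#'
#' @param x,y numeric samples.
#' @param alpha significance level for the `significant` flag.
#' @return list with `U`, `p`, `method` (`"exact"` or `"normal"`), and
#'   `significant` (`p < alpha`).
#' @export
mann_whitney_u <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) > 0, length(y) > 0,
            all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx * ny <= 400) {
    cnt <- u_null_counts(nx, ny)           # counts of U = 0..nx*ny
    total <- sum(cnt)
    # two-sided: both tails at least as extreme as u (distribution symmetric)
    p <- min(1, 2 * sum(cnt[seq_len(u + 1)]) / total)
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- max(abs(u - mu) - 0.5, 0) / sqrt(sig2)
    p <- 2 * pnorm(-z)
    method <- "normal"
  }
  list(U = u, p = p, method = method, significant = p < alpha)
}

# Null distribution of the Mann-Whitney U statistic (no ties): counts of
# arrangements with U_x = 0..nx*ny. Recurrence on the last element of the
# pooled ordering: if it is an x it sees all n y's (u -> u - n), else it is
# a y (n -> n - 1):  c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u).
u_null_counts <- function(nx, ny) {
  umax <- nx * ny
  prev <- matrix(0, ny + 1, umax + 1)   # m = 0 layer: U must be 0
  prev[, 1] <- 1
  for (m in seq_len(nx)) {
    cur <- matrix(0, ny + 1, umax + 1)
    cur[1, 1] <- 1                      # n = 0: only U = 0
    for (n in seq_len(ny)) {
      shifted <- c(rep(0, n), prev[n + 1, seq_len(umax + 1 - n)])
      cur[n + 1, ] <- shifted + cur[n, ]
    }
    prev <- cur
  }
  prev[ny + 1, ]
}
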