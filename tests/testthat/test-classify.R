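test_that("Z-scoring standardizes every feature with the sample-SD convention", {
  tab <- gen_feature_table(seed = 71)
  z <- zscore(tab)
  X <- as.matrix(as.data.frame(z)[, mpusliver:::mpus_feature_names])
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-10))
  # {1, 2, 3} -> {-1, 0, 1} under sample SD
  small <- tab[1:3, ]
  small$sws <- c(1, 2, 3)
  zs <- zscore(structure(small, class = c("feature_table", "data.frame")))
  expect_equal(zs$sws, c(-1, 0, 1), tolerance = 1e-12)
  # idempotence
  z2 <- zscore(z)
  expect_equal(as.data.frame(z2)[, 4:9], as.data.frame(z)[, 4:9],
               tolerance = 1e-10)
  # constant column rejected by name
  tab$hscan <- 0.5
  expect_error(zscore(tab), "hscan")
})

test_that("PCA contributions sum to 100 and collapse to 100/6 with all components", {
  z <- zscore(gen_feature_table(seed = 72))
  pc3 <- pca_contributions(z, 3)
  expect_equal(sum(pc3$contributions), 100, tolerance = 1e-8)
  pc6 <- pca_contributions(z, 6)
  expect_equal(unname(pc6$contributions), rep(100 / 6, 6), tolerance = 1e-8)
  expect_error(pca_contributions(z, 7))
})

test_that("PCA matches a brute-force eigendecomposition of the sample covariance", {
  z <- zscore(gen_feature_table(three_cohort_hscan_dominant(), seed = 73))
  X <- as.matrix(as.data.frame(z)[, mpusliver:::mpus_feature_names])
  eig <- eigen(cov(X), symmetric = TRUE)
  pc <- pca_contributions(z, 3)
  expect_equal(pc$eigenvalues, eig$values, tolerance = 1e-8)
  for (k in 1:3) {
    expect_equal(abs(pc$loadings[, k]), abs(eig$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  manual <- 100 * (eig$vectors[, 1:3]^2 %*% eig$values[1:3]) /
    sum(eig$values[1:3])
  expect_equal(unname(pc$contributions), as.vector(manual), tolerance = 1e-8)
})

test_that("a dominant-separation feature yields the maximum contribution over 3 PCs", {
  # median over seeds: the hscan feature carries 6 pooled-SD shifts vs 1.5
  ranks <- vapply(1:10, function(s) {
    z <- zscore(gen_feature_table(three_cohort_hscan_dominant(), seed = s))
    pc <- pca_contributions(z, 3)
    rank(pc$contributions)["hscan"]
  }, 0)
  expect_gte(median(ranks), 5)   # hscan among the top contributions
})

test_that("widely separated cohorts classify perfectly; conflicting duplicates cannot", {
  tab <- gen_feature_table(two_cohort_sep3(), seed = 74)
  rep <- svm_train_eval(tab, "two_category", "raw_features", seed = 74)
  expect_equal(rep$test_accuracy, 100)
  expect_equal(rep$train_accuracy, 100)

  # identical rows with conflicting labels are inseparable
  dup <- tab[rep(1:6, 2), ]
  dup$cohort <- rep(c("normal", "high_fat"), each = 6)
  dup <- structure(dup, class = c("feature_table", "data.frame"))
  rep2 <- svm_train_eval(dup, "two_category", "raw_features", seed = 74,
                         C_grid = 10, gamma_grid = 0.1)
  expect_lt(rep2$overall_accuracy, 100)
})

test_that("permuted labels score near the majority-class rate", {
  tab <- gen_feature_table(two_cohort_sep3(), seed = 75)
  maj <- max(table(tab$cohort)) / nrow(tab)
  accs <- vapply(1:20, function(s) {
    perm <- tab
    perm$cohort <- withr::with_seed(s, sample(perm$cohort))
    r <- svm_train_eval(structure(perm, class = class(tab)), "two_category",
                        "raw_features", seed = s,
                        C_grid = c(1, 100), gamma_grid = c(0.01, 0.1))
    r$test_accuracy / 100
  }, 0)
  # mean permuted accuracy within binomial noise of the majority rate
  se <- sqrt(maj * (1 - maj) / (11 * 20))   # ~11 test rows per split
  expect_lt(abs(mean(accs) - maj), 4 * se + 0.05)
})

test_that("reports are split-deterministic and leakage-free", {
  tab <- gen_feature_table(seed = 76)
  r1 <- svm_train_eval(tab, "three_category", "first_3_pcs", seed = 7)
  r2 <- svm_train_eval(tab, "three_category", "first_3_pcs", seed = 7)
  expect_equal(r1$test_accuracy, r2$test_accuracy)
  expect_equal(r1$pca_contributions, r2$pca_contributions)
  expect_identical(r1$test_idx, r2$test_idx)
  # shuffling held-out rows' features must not touch the training-set
  # standardization parameters
  tab2 <- tab
  tab2[r1$test_idx, mpusliver:::mpus_feature_names] <-
    tab2[sample(r1$test_idx), mpusliver:::mpus_feature_names]
  r3 <- svm_train_eval(structure(tab2, class = class(tab)),
                       "three_category", "first_3_pcs", seed = 7)
  expect_equal(r3$center, r1$center, tolerance = 1e-12)
  expect_equal(r3$scale, r1$scale, tolerance = 1e-12)
})

test_that("svm_train_eval validates cohort availability", {
  tab <- gen_feature_table(seed = 77)
  tiny <- tab[c(1, 40), ]                 # one row per class
  expect_error(svm_train_eval(structure(tiny, class = class(tab)),
                              "two_category"), "at least 2")
})

test_that("decision surface export labels a 3D PC grid", {
  tab <- gen_feature_table(seed = 78)
  r <- svm_train_eval(tab, "three_category", "first_3_pcs", seed = 8)
  surf <- decision_surface(r, n = 5)
  expect_equal(nrow(surf), 125)
  expect_true(all(c("pc1", "pc2", "pc3", "label") %in% names(surf)))
  expect_true(all(levels(surf$label) %in% c("normal", "low_fat", "high_fat")))
  r_raw <- svm_train_eval(tab, "two_category", "raw_features", seed = 8)
  expect_error(decision_surface(r_raw), "PC input space")
})

test_that("Mann-Whitney exact p-values match hand enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  expect_false(r$significant)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))   # ties -> normal path
  expect_equal(same$p, 1)

  far <- mann_whitney_u(1:6, 101:106)
  expect_lt(far$p, 0.05)
  expect_true(far$significant)
  expect_equal(far$p, mwu_p_enumerate(1:6, 101:106), tolerance = 1e-12)
})

test_that("exact Mann-Whitney p equals full enumeration for all n <= 8", {
  set.seed(79)
  for (nx in 2:8) {
    for (ny in 2:8) {
      x <- rnorm(nx)
      y <- rnorm(ny, mean = runif(1, -1, 1))
      r <- mann_whitney_u(x, y)
      expect_equal(r$method, "exact")
      expect_equal(r$p, mwu_p_enumerate(x, y), tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("Mann-Whitney agrees with the base R implementation", {
  set.seed(80)
  x <- rnorm(10); y <- rnorm(12, 0.8)
  ours <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                             correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(min(ours$U, length(x) * length(y) - ours$U),
               min(ref$statistic, length(x) * length(y) - ref$statistic),
               ignore_attr = TRUE)
})
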