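test_that("k-NN imputation matches the exhaustive-search oracle", {
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("s", 1:3), paste0("a", 1:4)))
  expect_identical(knn_impute(m, k = 2), m + 0)   # complete: unchanged

  # k = 1 with an identical-on-observed-columns neighbour copies its value
  m2 <- rbind(s1 = c(1, 2, 3, NA), s2 = c(1, 2, 3, 7), s3 = c(9, 9, 9, 0))
  colnames(m2) <- paste0("a", 1:4)
  expect_equal(knn_impute(m2, k = 1)["s1", "a4"], 7)

  # 6x4 toy with 2 missing cells against the brute-force oracle
  set.seed(3)
  m3 <- matrix(round(runif(24, 0, 100), 1), 6, 4,
               dimnames = list(paste0("s", 1:6), paste0("a", 1:4)))
  m3[2, 3] <- NA; m3[5, 1] <- NA
  expect_equal(knn_impute(m3, k = 2), brute_knn_impute(m3, k = 2))
  # larger random missingness patterns, several k
  for (k in c(1, 3, 10)) {
    m4 <- matrix(runif(80, 0, 100), 8, 10,
                 dimnames = list(paste0("s", 1:8), paste0("a", 1:10)))
    m4[sample(80, 12)] <- NA
    if (any(colSums(!is.na(m4)) == 0)) next
    imp <- knn_impute(m4, k = k)
    expect_equal(imp, brute_knn_impute(m4, k = k))
    # imputed values stay inside the observed range of their column
    for (cc in 1:10) {
      obs <- m4[!is.na(m4[, cc]), cc]
      expect_true(all(imp[, cc] >= min(obs) & imp[, cc] <= max(obs)))
    }
  }

  bad <- m2; bad[, 2] <- NA
  expect_error(knn_impute(bad), "fully missing.*a2")
})

test_that("mean centering zeroes column means and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 0, 50))
  cm <- mean_center(m)
  expect_equal(cm[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(all(abs(colMeans(cm)) < 1e-12))
  expect_equal(mean_center(cm), cm)
})

test_that("Pearson distance matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 5)
  m <- rbind(a = x, b = 2 * x + 3, c = -x + 10, d = c(4, 1, 8, 2))
  d <- pearson_distance(m)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d["a", "b"], 0)   # perfect correlation
  expect_equal(d["a", "c"], 2)   # perfect anticorrelation
  hand <- function(u, v) {
    1 - sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(d["a", "d"], hand(x, m["d", ]))
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))

  expect_error(pearson_distance(rbind(a = c(1, 1, 1), b = x[1:3])),
               "constant row.*a")
})

test_that("complete-linkage agglomeration matches naive and stats oracles", {
  # two samples: a single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- hcluster(d2)
  expect_equal(t2$height, 0.3)
  expect_equal(t2$merge, matrix(c(-2L, -1L), 1))

  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(7 * 5), 7, dimnames = list(paste0("s", 1:7), NULL))
    d <- pearson_distance(m)
    tree <- hcluster(d)
    expect_equal(tree$height, naive_complete_linkage_heights(d))
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    expect_equal(tree$height, hc$height)
    # heights are non-decreasing (ultrametric property of complete linkage)
    expect_true(all(diff(tree$height) >= -1e-12))
  }

  expect_error(hcluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("clustering is invariant to row permutation and recovers planted groups", {
  set.seed(21)
  # two planted groups share distinct column signatures; noise is small
  sig1 <- runif(10, 0, 100); sig2 <- runif(10, 0, 100)
  base <- rbind(matrix(rep(sig1, each = 4), 4),
                matrix(rep(sig2, each = 4), 4)) + rnorm(80, sd = 1)
  rownames(base) <- paste0("s", 1:8)
  tree <- hcluster(pearson_distance(base))
  labels <- cut_tree(tree, 2)
  expect_equal(unname(labels[1:4]), rep(labels[["s1"]], 4))
  expect_equal(unname(labels[5:8]), rep(labels[["s5"]], 4))

  perm <- sample(8)
  tree_p <- hcluster(pearson_distance(base[perm, ]))
  labels_p <- cut_tree(tree_p, 2)[rownames(base)]
  # same partition up to label swap
  agree <- outer(labels, labels, "==") == outer(labels_p, labels_p, "==")
  expect_true(all(agree))
  expect_equal(sort(tree_p$height), sort(tree$height))
})

test_that("tree cutting covers the edge cases and orders labels by appearance", {
  set.seed(5)
  m <- matrix(rnorm(30), 6, dimnames = list(paste0("s", 1:6), NULL))
  tree <- hcluster(pearson_distance(m))
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 6))
  expect_equal(length(unique(cut_tree(tree, 6))), 6L)
  expect_error(cut_tree(tree, 0), "out of range")
  expect_error(cut_tree(tree, 7), "out of range")
  k3 <- cut_tree(tree, 3)
  expect_equal(k3[[1]], 1L)                 # first leaf's cluster is 1
  expect_equal(sort(unique(k3)), 1:3)
})

test_that("PCA matches an explicit eigendecomposition and handles degeneracy", {
  # collinear data: one component carries all variance
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  p <- pca_profiles(line)
  expect_equal(p$explained_variance[1], 1)

  # isotropic 2-D toy: near-equal explained variances
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  iso <- cbind(cos(th), sin(th))
  pi2 <- pca_profiles(iso)
  expect_equal(pi2$explained_variance[1], pi2$explained_variance[2],
               tolerance = 1e-9)

  # 5x3 toy against eigen() of the covariance of centered data
  set.seed(9)
  m <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- pca_profiles(m)
  eg <- eigen(stats::cov(m))
  expect_equal(fit$explained_variance,
               eg$values / sum(eg$values))
  for (j in 1:3) {
    v <- eg$vectors[, j]
    big <- which.max(abs(v))
    if (v[big] < 0) v <- -v      # same sign convention as the package
    expect_equal(unname(fit$loadings[, j]), v)
    expect_equal(unname(fit$scores[, j]),
                 as.numeric(scale(m, scale = FALSE) %*% v))
  }
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_warning(pca_profiles(line, n_components = 3), "rank")
})

test_that("Newick export follows the half-height convention and round-trips", {
  skip_if_not_installed("ape")
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(newick_string(hcluster(d2)), "(B:0.2,A:0.2);")

  set.seed(13)
  m <- matrix(rnorm(50), 5, dimnames = list(paste0("s", 1:5), NULL))
  tree <- hcluster(pearson_distance(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(tree, path,
                    order_path = withr::local_tempfile(fileext = ".csv"))
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tree$labels)
  # leaf depths equal half the root merge height (ultrametric)
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(depths, rep(max(tree$height) / 2, 5), tolerance = 1e-9)
  # cophenetic distances from the exported tree reproduce merge heights
  coph <- ape::cophenetic.phylo(phy)[tree$labels, tree$labels]
  expect_equal(max(coph), max(tree$height), tolerance = 1e-9)
})
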