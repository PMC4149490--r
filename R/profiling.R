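# Profile analytics: k-NN imputation, mean centering, Pearson correlation
# distance, complete-linkage agglomeration with deterministic tie-breaks,
# tree cutting, PCA, and Newick export.

#' k-nearest-neighbour imputation of a profile matrix
#'
#' Each missing cell is replaced by the mean of its column's values among
#' the k rows nearest to the target row. Row distance is the root mean
#' squared difference over mutually observed columns (i.e. squared
#' Euclidean distance scaled by the proportion of columns observed), so
#' rows with different missingness patterns are comparable. Only rows with
#' the cell's column observed are eligible neighbours; k is truncated to
#' the available rows.
#'
#' @param matrix Numeric matrix, possibly with `NA`s; every row needs at
#'   least one observed value.
#' @param k Neighbour count (default 10).
#' @return The matrix with all `NA`s imputed.
#' @export
knn_impute <- function(matrix, k = 10) {
  m <- base::as.matrix(matrix)
  storage.mode(m) <- "double"
  stopifnot(k >= 1)
  if (!anyNA(m)) return(m)
  full_miss <- colSums(!is.na(m)) == 0L
  if (any(full_miss)) {
    stop("column(s) fully missing, cannot impute: ",
         paste(colnames(m)[full_miss], collapse = ", "))
  }
  if (any(rowSums(!is.na(m)) == 0L)) stop("row with no observed values")
  obs <- !is.na(m)
  out <- m
  for (i in which(rowSums(!obs) > 0L)) {
    d <- rep(NA_real_, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i) next
      sh <- obs[i, ] & obs[j, ]
      if (!any(sh)) next
      d[j] <- sqrt(mean((m[i, sh] - m[j, sh])^2))
    }
    for (cc in which(!obs[i, ])) {
      cand <- which(obs[, cc] & !is.na(d))
      if (!length(cand)) {
        stop("no neighbour observes column ",
             if (!is.null(colnames(m))) colnames(m)[cc] else cc,
             " for row ", i)
      }
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      out[i, cc] <- mean(m[nb, cc])
    }
  }
  out
}

#' Column mean-centering
#'
#' @param matrix Complete numeric matrix.
#' @return Matrix with each column shifted to mean zero.
#' @export
mean_center <- function(matrix) {
  m <- base::as.matrix(matrix)
  stopifnot(!anyNA(m))
  sweep(m, 2L, colMeans(m))
}

#' Pearson correlation distance between matrix rows
#'
#' d(i, j) = 1 - r(row i, row j); range \[0, 2\], diagonal 0. Not a metric
#' (the triangle inequality can fail); used as the dissimilarity for
#' complete-linkage clustering of percent-positive profiles.
#'
#' @param matrix Complete numeric matrix with >= 2 rows; rows must be
#'   non-constant.
#' @return Symmetric distance matrix.
#' @export
pearson_distance <- function(matrix) {
  m <- base::as.matrix(matrix)
  stopifnot(nrow(m) >= 2L, !anyNA(m))
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    lab <- rownames(m)[sds == 0]
    if (is.null(lab)) lab <- which(sds == 0)
    stop("constant row (correlation undefined): ", paste(lab, collapse = ", "))
  }
  d <- 1 - stats::cor(t(m))
  diag(d) <- 0
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomeration: start from singletons, repeatedly merge the pair
#' of clusters at minimal inter-cluster distance, where complete linkage
#' defines that distance as the maximum pairwise member distance. Ties are
#' broken deterministically by the lexicographically smallest pair of
#' smallest member leaf indices. Merge heights are non-decreasing
#' (complete linkage is reducible, hence ultrametric-compatible).
#'
#' @param distances Symmetric distance matrix with zero diagonal.
#' @param method Linkage; only `"complete"` is implemented.
#' @return An object of class `cluster_tree`: `merge` (hclust-style n-1 x 2
#'   matrix, negatives = leaves), `height`, `labels`, `method`.
#' @export
hcluster <- function(distances, method = "complete") {
  d <- base::as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  method <- match.arg(method, "complete")
  n <- nrow(d)
  stopifnot(n >= 2L)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  members <- lapply(seq_len(n), identity)  # leaf indices per active cluster
  ids <- -seq_len(n)                       # hclust coding: -leaf, +merge
  active <- rep(TRUE, n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    best_d <- Inf
    act <- which(active)
    for (ai in seq_along(act)) {
      for (bi in seq_along(act)) {
        if (bi <= ai) next
        i <- act[ai]; j <- act[bi]
        dij <- D[i, j]
        key <- sort(c(min(members[[i]]), min(members[[j]])))
        if (dij < best_d - 1e-12 ||
            (abs(dij - best_d) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best_d <- dij
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[s, ] <- sort(c(ids[i], ids[j]))
    height[s] <- D[i, j]
    # complete linkage: distance to the union is the max of the parts
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- max(D[i, k], D[j, k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- s
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = method),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %s linkage, heights [%.3g, %.3g]\n",
              length(x$labels), x$method, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a cluster tree to a `stats::hclust` object
#'
#' @param tree A `cluster_tree`.
#' @return An `hclust` object (enables `plot()`, `stats::cutree()`, etc.).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  # build a valid ordering of leaves (left-to-right traversal)
  order_of <- function(node) {
    if (node < 0) return(-node)
    c(order_of(tree$merge[node, 1]), order_of(tree$merge[node, 2]))
  }
  structure(list(merge = tree$merge, height = tree$height,
                 order = order_of(n - 1L), labels = tree$labels,
                 method = tree$method, call = match.call(),
                 dist.method = "pearson"),
            class = "hclust")
}

#' Cut a cluster tree into k groups
#'
#' Removes the k - 1 highest merges; cluster labels are integers ordered by
#' first leaf appearance (leaf 1's cluster is 1, the next new cluster is 2,
#' and so on).
#'
#' @param tree A `cluster_tree`.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector of cluster labels per leaf.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  raw <- stats::cutree(as_hclust(tree), k = k)
  relabel <- match(raw, unique(raw))
  names(relabel) <- tree$labels
  relabel
}

#' Principal components analysis of a profile matrix
#'
#' Spectral decomposition of the covariance of (column-)centered data; the
#' sign convention fixes each component so its largest-magnitude loading is
#' positive.
#'
#' @param matrix Complete numeric matrix (samples x antigens).
#' @param center Mean-center columns first (default `TRUE`, the analysis
#'   mode used for profile PCA).
#' @param n_components Components to keep; truncated to the matrix rank
#'   with a warning if more are requested.
#' @return List (class `pca_result`): `loadings` (antigen x component),
#'   `scores` (sample x component), `explained_variance` (fractions).
#' @export
pca_profiles <- function(matrix, center = TRUE, n_components = NULL) {
  m <- base::as.matrix(matrix)
  stopifnot(!anyNA(m), nrow(m) >= 2L)
  fit <- stats::prcomp(m, center = center, scale. = FALSE)
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-10)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    n_components <- rank
  }
  idx <- seq_len(n_components)
  load <- fit$rotation[, idx, drop = FALSE]
  scores <- fit$x[, idx, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(load))) {
    big <- which.max(abs(load[, j]))
    if (load[big, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = load, scores = scores,
                 explained_variance = ev[idx]),
            class = "pca_result")
}

#' Newick serialization of a cluster tree
#'
#' Ultrametric convention: a leaf merged at height h sits at depth h / 2,
#' so a two-leaf tree is `(A:h/2,B:h/2);`. Internal branch lengths are half
#' the difference of successive merge heights.
#'
#' @param tree A `cluster_tree`.
#' @return Newick string.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%.10g", gsub("[,;:() ]", "_", tree$labels[-node]),
              parent_h / 2)
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%.10g",
              node_str(tree$merge[node, 1], h),
              node_str(tree$merge[node, 2], h),
              (parent_h - h) / 2)
    }
  }
  root_h <- tree$height[n - 1L]
  sprintf("(%s,%s);",
          node_str(tree$merge[n - 1L, 1], root_h),
          node_str(tree$merge[n - 1L, 2], root_h))
}

#' Export a dendrogram (Newick) and leaf order (CSV)
#'
#' @param tree A `cluster_tree`.
#' @param path Output path for the Newick file.
#' @param order_path Optional CSV path for the heatmap leaf order.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(tree, path, order_path = NULL) {
  writeLines(newick_string(tree), path)
  if (!is.null(order_path)) {
    hc <- as_hclust(tree)
    utils::write.csv(data.frame(position = seq_along(hc$order),
                                label = tree$labels[hc$order]),
                     order_path, row.names = FALSE)
  }
  invisible(path)
}
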