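#' Movement phenotyping: PCA + k-means
#'
#' Dimensionality reduction of standardized swim-parameter profiles,
#' k-means clustering on the retained components with elbow / silhouette
#' / gap-statistic diagnostics, and identification of the parameters that
#' discriminate the clusters.
#'
#' @name phenotyping
NULL

#' PCA with a cumulative-explained-variance cut
#'
#' Runs PCA on an already-standardized subjects x parameters matrix and
#' retains the smallest number of components whose cumulative explained
#' variance reaches `target_variance`. Constant columns are dropped with
#' a warning before the decomposition.
#'
#' @param X numeric matrix, subjects in rows, standardized parameters in
#'   columns.
#' @param target_variance cumulative explained-variance target, fraction
#'   (default 0.70).
#' @return list `scores` (retained components), `loadings`,
#'   `explained_variance` (cumulative, all components), `n_components`.
#' @export
pca_reduce <- function(X, target_variance = 0.70) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, target_variance > 0, target_variance <= 1)
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= target_variance)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = cum,
       n_components = k)
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(X, 1, function(p) min(colSums((t(centers) - p)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, X[sample.int(n, 1), , drop = FALSE])
    } else {
      centers <- rbind(centers, X[sample.int(n, 1, prob = d2), , drop = FALSE])
    }
  }
  centers
}

# best-of-n_init k-means with k-means++ seeding
kmeans_best <- function(X, k, n_init) {
  best <- NULL
  for (i in seq_len(n_init)) {
    km <- suppressWarnings(
      stats::kmeans(X, centers = kmeanspp_centers(X, k), iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

# gap statistic for one k: E*[log(W)] - log(W) with B uniform reference
# draws over the data's bounding box
gap_statistic <- function(X, k, wss, B = 50) {
  rng <- apply(X, 2, range)
  logW_ref <- vapply(seq_len(B), function(b) {
    Xr <- apply(rng, 2, function(r) stats::runif(nrow(X), r[1], r[2]))
    log(kmeans_best(Xr, k, n_init = 5)$tot.withinss)
  }, numeric(1))
  list(gap = mean(logW_ref) - log(wss),
       se = stats::sd(logW_ref) * sqrt(1 + 1 / B))
}

#' k-means clustering with model-order diagnostics
#'
#' Runs k-means (k-means++ seeding, `n_init` restarts) for every k in
#' `k_range` and reports within-cluster sum of squares, mean silhouette
#' width and the gap statistic (uniform reference over the data's
#' bounding box, B reference sets). The chosen k is the elbow of the WSS
#' curve (maximum second difference, including the k = 1 total sum of
#' squares); ties break toward smaller k. All diagnostics are exposed so
#' the choice can be overridden.
#'
#' @param X numeric matrix (e.g. retained PCA scores), subjects in rows.
#' @param k_range integer candidate cluster counts (default 2:6),
#'   within \[2, n_subjects - 1\].
#' @param n_init number of k-means restarts per k (default 50).
#' @param seed integer RNG seed; fixed for reproducibility.
#' @param B number of gap-statistic reference sets (default 50).
#' @return list of class `cluster_result`: `k`, `assignments`,
#'   `centers`, `diagnostics` (data frame: k, wss, silhouette, gap,
#'   gap_se).
#' @export
kmeans_select <- function(X, k_range = 2:6, n_init = 50, seed = 1, B = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects to cluster")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  stopifnot(length(k_range) >= 1)
  set.seed(seed)
  fits <- lapply(k_range, function(k) kmeans_best(X, k, n_init))
  wss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  sil <- vapply(seq_along(k_range), function(i) {
    mean(cluster::silhouette(fits[[i]]$cluster, stats::dist(X))[, 3])
  }, numeric(1))
  gaps <- lapply(seq_along(k_range), function(i) {
    gap_statistic(X, k_range[i], wss[i], B = B)
  })
  # elbow on the WSS curve including k = 1 (total SS about the grand mean)
  wss1 <- sum(scale(X, scale = FALSE)^2)
  curve <- c(wss1, wss)
  ks <- c(1L, k_range)
  if (length(curve) >= 3) {
    d2 <- diff(diff(curve))            # second difference at interior ks
    cand_ks <- ks[seq_along(d2) + 1L]
    k_best <- cand_ks[which.max(d2)]   # which.max: first max = smaller k
  } else {
    k_best <- k_range[which.max(sil)]
  }
  i <- match(k_best, k_range)
  structure(list(
    k = k_best,
    assignments = fits[[i]]$cluster,
    centers = fits[[i]]$centers,
    diagnostics = data.frame(
      k = k_range, wss = wss, silhouette = sil,
      gap = vapply(gaps, `[[`, numeric(1), "gap"),
      gap_se = vapply(gaps, `[[`, numeric(1), "se"))
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d; sizes: %s\n", x$k,
              paste(table(x$assignments), collapse = ", ")))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Parameters that discriminate the clusters
#'
#' Candidates are the `top_n` parameters by absolute loading on each
#' retained principal component (deduplicated). Each candidate is tested
#' across clusters with the Kruskal-Wallis test, Holm-Bonferroni
#' corrected over the candidate set; parameters significant at `alpha`
#' are returned with pairwise post hoc Mann-Whitney comparisons.
#'
#' @param pca result of [pca_reduce()].
#' @param profiles subjects x parameters matrix the PCA was fit on.
#' @param assignments integer cluster labels per subject.
#' @param alpha significance level (default 0.05).
#' @param top_n loadings per component to consider (default 5).
#' @return list `selected` (data frame: parameter, H, p_raw, p_adj,
#'   epsilon2), `posthoc` (data frame of pairwise Mann-Whitney results),
#'   `candidates`.
#' @export
discriminative_features <- function(pca, profiles, assignments,
                                    alpha = 0.05, top_n = 5) {
  cand <- unique(unlist(lapply(seq_len(ncol(pca$loadings)), function(j) {
    ld <- abs(pca$loadings[, j])
    names(sort(ld, decreasing = TRUE))[seq_len(min(top_n, length(ld)))]
  })))
  tests <- lapply(cand, function(p) {
    kw <- kruskal_epsilon2(profiles[, p], assignments)
    data.frame(parameter = p, H = kw$H, p_raw = kw$p,
               epsilon2 = kw$epsilon2)
  })
  tab <- do.call(rbind, tests)
  tab$p_adj <- holm_bonferroni(tab$p_raw)
  sel <- tab[tab$p_adj < alpha, , drop = FALSE]
  posthoc <- NULL
  if (nrow(sel) > 0) {
    cl <- sort(unique(assignments))
    pairs <- utils::combn(cl, 2, simplify = FALSE)
    posthoc <- do.call(rbind, lapply(sel$parameter, function(p) {
      do.call(rbind, lapply(pairs, function(pr) {
        mw <- mann_whitney_r(profiles[assignments == pr[1], p],
                             profiles[assignments == pr[2], p])
        data.frame(parameter = p, cluster_a = pr[1], cluster_b = pr[2],
                   U = mw$U, p = mw$p, r = mw$r)
      }))
    }))
  }
  list(selected = sel, posthoc = posthoc, candidates = tab)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to label permutation), ~0 for independent ones. Used to
#' validate planted-cluster recovery on synthetic cohorts.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}
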