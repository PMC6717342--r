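#' Ward agglomeration of variants in principal-coordinate space
#'
#' Euclidean distances in the full retained principal-coordinate space
#' (not the 2-D display projection) with Ward's minimum-variance linkage.
#'
#' @param coords numeric matrix (points x dims) with rownames.
#' @return an [stats::hclust] tree (`ward.D2` on Euclidean distance).
#' @export
ward_tree <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 points to build a tree", call. = FALSE)
  stats::hclust(stats::dist(coords), method = "ward.D2")
}

#' Choose the number of clusters from the within-inertia profile
#'
#' For each candidate `k`, the tree is cut and the within-cluster sum of
#' squares `W(k)` computed directly from the coordinates.  With
#' `delta(k) = W(k-1) - W(k)` (the inertia gain of allowing a k-th
#' cluster), the chosen `K` maximizes the relative-loss ratio
#' `delta(k) / delta(k+1)` over `k_min..k_max`: a large ratio marks the
#' last split that buys substantially more separation than the next one.
#'
#' @param tree an [stats::hclust] tree from [ward_tree()].
#' @param coords the coordinates the tree was built on.
#' @param k_min,k_max search range (defaults 2 and `min(10, n - 1)`).
#' @return integer `K`.  A degenerate tree (all merge heights 0, i.e. all
#'   points identical) returns `k_min` with a warning.
#' @export
choose_k <- function(tree, coords, k_min = 2, k_max = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  k_max <- max(k_min, min(k_max, n - 1L))
  if (all(tree$height <= 1e-12)) {
    warning("degenerate tree (all points identical); returning k_min")
    return(as.integer(k_min))
  }
  ks <- seq(k_min - 1L, k_max + 1L)
  W <- vapply(ks, function(k) {
    if (k <= 1) return(total_ss(coords))
    within_ss(coords, stats::cutree(tree, k = k))
  }, numeric(1))
  delta <- -diff(W)                      # delta[i] = gain of (k_min-1+i)-th cluster
  delta <- pmax(delta, 0)
  num <- delta[seq_len(k_max - k_min + 1L)]
  den <- delta[seq_len(k_max - k_min + 1L) + 1L]
  ratio <- ifelse(den > 1e-12, num / den, ifelse(num > 1e-12, Inf, 0))
  as.integer(k_min + which.max(ratio) - 1L)
}

total_ss <- function(coords) {
  ctr <- colMeans(coords)
  sum(sweep(coords, 2, ctr)^2)
}

within_ss <- function(coords, cluster) {
  sum(vapply(split(seq_len(nrow(coords)), cluster), function(idx) {
    total_ss(coords[idx, , drop = FALSE])
  }, numeric(1)))
}

#' Consolidate a tree-cut partition by k-means
#'
#' Lloyd iterations started from the centroids of the tree-cut clusters:
#' assign each point to its nearest centroid, recompute centroids, repeat
#' until no reassignment or `max_iter`.  Within-cluster inertia never
#' increases across iterations.  A cluster emptied mid-iteration keeps
#' its previous centroid.  Initialization is deterministic, so runs are
#' reproducible without a seed.
#'
#' @param coords numeric matrix (points x dims).
#' @param cluster integer vector: initial assignment covering all points.
#' @param max_iter iteration cap (default 100).
#' @return list with `cluster` (final assignment), `moves` (points whose
#'   cluster changed relative to the initial assignment), `iterations`,
#'   and `inertia_trace` (within-SS after each assignment step).
#' @export
kmeans_consolidate <- function(coords, cluster, max_iter = 100) {
  coords <- as.matrix(coords)
  cluster <- as.integer(cluster)
  stopifnot(length(cluster) == nrow(coords))
  ids <- sort(unique(cluster))
  centroids <- t(vapply(ids, function(cl) {
    colMeans(coords[cluster == cl, , drop = FALSE])
  }, numeric(ncol(coords))))
  initial <- cluster
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(coords^2), rep(1, length(ids))) -
      2 * coords %*% t(centroids) +
      outer(rep(1, nrow(coords)), rowSums(centroids^2))
    new_cluster <- ids[max.col(-d2, ties.method = "first")]
    trace <- c(trace, within_ss(coords, new_cluster))
    changed <- any(new_cluster != cluster)
    cluster <- new_cluster
    for (i in seq_along(ids)) {
      pts <- coords[cluster == ids[i], , drop = FALSE]
      if (nrow(pts) > 0) centroids[i, ] <- colMeans(pts)
      # empty cluster: keep previous centroid
    }
    if (!changed || iter >= max_iter) break
  }
  list(cluster = cluster, moves = sum(cluster != initial),
       iterations = iter, inertia_trace = trace)
}

#' Label clusters by their enrichment direction
#'
#' Per cluster, the means of the three contingency-table columns are
#' compared: a cluster is `resistant_enriched` when the mean resistant
#' VAF is strictly the largest of the three, `sensitive_enriched` when
#' the mean sensitive VAF is, otherwise `neutral` (ties give `neutral`
#' with a warning).
#'
#' @param cluster integer assignment named by (or ordered as) the table keys.
#' @param tab the [contingency_table()] the coordinates came from.
#' @return data.frame with one row per cluster: `cluster`, `n`, the three
#'   column means and `label`.
#' @export
label_clusters <- function(cluster, tab) {
  stopifnot(length(cluster) == nrow(tab))
  ids <- sort(unique(cluster))
  out <- do.call(rbind, lapply(ids, function(cl) {
    rows <- tab[cluster == cl, , drop = FALSE]
    data.frame(cluster = cl, n = nrow(rows),
               mean_vaf_sensitive = mean(rows$vaf_sensitive),
               mean_vaf_resistant = mean(rows$vaf_resistant),
               mean_maf_population = mean(rows$maf_population))
  }))
  means <- as.matrix(out[, c("mean_vaf_sensitive", "mean_vaf_resistant",
                             "mean_maf_population")])
  out$label <- apply(means, 1, function(m) {
    top <- which(m == max(m))
    if (length(top) > 1) {
      warning("tie across group means; labelling cluster 'neutral'")
      return("neutral")
    }
    c("sensitive_enriched", "resistant_enriched", "neutral")[top]
  })
  out
}

#' Hierarchical clustering on principal components
#'
#' The complete HCPC stage: Ward tree on the CA row coordinates, cluster
#' count chosen automatically (or forced), k-means consolidation of the
#' tree cut, enrichment labelling, and renumbering of clusters by
#' ascending mean resistant-group VAF (so the resistant-enriched cluster
#' always carries the highest id).
#'
#' @param tab a [contingency_table()].
#' @param k `"auto"` (default) or a fixed integer cluster count.
#' @param solution optionally a precomputed `ca_solution` for `tab`.
#' @param k_max upper bound of the automatic search (default
#'   `min(10, n - 1)`).
#' @return list of class `hcpc_result`: `assignment` (data.frame `key`,
#'   `cluster`), `clusters` (per-cluster summary with labels), `K`,
#'   `consolidation_moves`, `tree`, `solution`.
#' @export
hcpc <- function(tab, k = "auto", solution = NULL, k_max = NULL) {
  tab <- validate_contingency_table(tab)
  if (is.null(solution)) solution <- correspondence_analysis(tab)
  coords <- solution$row_coords
  tree <- ward_tree(coords)
  K <- if (identical(k, "auto")) {
    choose_k(tree, coords, k_max = k_max)
  } else {
    as.integer(k)
  }
  if (K < 1 || K > nrow(coords)) stop("invalid cluster count K", call. = FALSE)
  cut <- if (K == 1) rep(1L, nrow(coords)) else stats::cutree(tree, k = K)
  cons <- kmeans_consolidate(coords, cut)
  cluster <- cons$cluster
  # renumber by ascending mean resistant VAF
  means_r <- vapply(sort(unique(cluster)), function(cl) {
    mean(tab$vaf_resistant[cluster == cl])
  }, numeric(1))
  remap <- stats::setNames(rank(means_r, ties.method = "first"),
                           sort(unique(cluster)))
  cluster <- as.integer(remap[as.character(cluster)])
  summary <- label_clusters(cluster, tab)
  structure(list(
    assignment = data.frame(key = tab$key, cluster = cluster,
                            stringsAsFactors = FALSE),
    clusters = summary,
    K = length(unique(cluster)),
    consolidation_moves = cons$moves,
    tree = tree,
    solution = solution
  ), class = "hcpc_result")
}

#' @export
print.hcpc_result <- function(x, ...) {
  cat(sprintf("hcpc_result: %d clusters over %d variants (%d consolidation moves)\n",
              x$K, nrow(x$assignment), x$consolidation_moves))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
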