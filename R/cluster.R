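#' Variance-targeted principal component reduction
#'
#' Projects the enrichment-ratio matrix onto the smallest number of leading
#' principal components whose cumulative explained-variance ratio reaches
#' the target (default 95%).
#'
#' @param x Numeric matrix, chemicals in rows.
#' @param target_variance Cumulative explained-variance target in (0, 1].
#' @return Score matrix (same rownames) with an attribute
#'   `explained_variance` holding the cumulative ratio at the retained
#'   dimensionality.
#' @export
reduce_pca <- function(x, target_variance = 0.95) {
  if (nrow(x) < 2 || ncol(x) < 2) abort("need at least a 2x2 matrix for PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) abort("matrix has zero variance; PCA is undefined")
  cum <- cumsum(v) / sum(v)
  d <- which(cum >= target_variance - 1e-12)[1]
  out <- pc$x[, seq_len(d), drop = FALSE]
  attr(out, "explained_variance") <- cum[d]
  out
}

#' Nonlinear embedding of the reduced matrix (UMAP)
#'
#' Thin, seed-deterministic wrapper around the published UMAP procedure
#' (via uwot), treated as a pluggable embedding stage: fixed inputs and
#' seed give an identical embedding.
#'
#' @param x Numeric matrix (rows = chemicals).
#' @param n_neighbors,min_dist,n_components UMAP parameters.
#' @param seed Integer random seed.
#' @return Embedding matrix with `n_components` columns and the rownames
#'   of `x`.
#' @export
embed_umap <- function(x, n_neighbors, min_dist, n_components = 2, seed = 0) {
  if (nrow(x) < n_neighbors + 1) {
    abort(sprintf("need at least n_neighbors + 1 = %d rows, got %d",
                  n_neighbors + 1, nrow(x)))
  }
  # spectral initialization is undefined when the input has fewer columns
  # than the embedding; fall back to seeded random init
  init <- if (ncol(x) <= n_components) "random" else "spectral"
  emb <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_components = n_components, seed = seed, init = init,
                    n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  rownames(emb) <- rownames(x)
  emb
}

#' Mean silhouette score of a clustering
#'
#' For each point, a is its mean Euclidean distance to the other members of
#' its cluster and b the smallest mean distance to any other cluster; the
#' point's silhouette is (b - a) / max(a, b) (0 for singleton clusters) and
#' the score is the mean over points. Scores near 1 indicate cohesive,
#' well-separated clusters; near 0, overlapping clusters; below 0,
#' misassigned points.
#'
#' @param points Numeric matrix of coordinates (rows = points).
#' @param labels Cluster assignment vector, length `nrow(points)`, with at
#'   least two distinct clusters.
#' @return The mean silhouette, in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  if (length(labels) != nrow(points)) abort("one label per point required")
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) abort("silhouette requires at least two clusters")
  d <- as.matrix(dist(points))
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster (including its own)
  cluster_sums <- sapply(seq_len(k), function(cl) rowSums(d[, labels == cl, drop = FALSE]))
  s <- vapply(seq_len(nrow(points)), function(i) {
    own <- labels[i]
    if (sizes[own] == 1) return(0)
    a <- cluster_sums[i, own] / (sizes[own] - 1)
    b <- min(cluster_sums[i, -own] / sizes[-own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Clustering grid specification
#'
#' The default grid mirrors the screening protocol: UMAP `n_neighbors` at
#' every integer from 2 to 20, `min_dist` in {0, 0.1, 0.25, 0.5, 0.8,
#' 0.99}, k-means k from 3 to 10, five random seeds (applied in lockstep to
#' UMAP and k-means), and a minimum acceptable silhouette of 0.70.
#'
#' @param n_neighbors,min_dist,k_range,seeds Grid axes.
#' @param n_components Embedding dimensionality (fixed during the grid).
#' @param min_silhouette Acceptance floor for the best solution.
#' @return A list of class `cluster_grid`.
#' @export
cluster_grid <- function(n_neighbors = 2:20,
                         min_dist = c(0, 0.1, 0.25, 0.5, 0.8, 0.99),
                         k_range = 3:10,
                         seeds = 0:4,
                         n_components = 2,
                         min_silhouette = 0.70) {
  if (!length(n_neighbors) || !length(min_dist) || !length(k_range) || !length(seeds)) {
    abort("all grid axes must be nonempty")
  }
  if (min_silhouette <= -1 || min_silhouette >= 1) {
    abort("min_silhouette must lie in (-1, 1)")
  }
  structure(list(n_neighbors = sort(n_neighbors), min_dist = sort(min_dist),
                 k_range = sort(k_range), seeds = sort(seeds),
                 n_components = n_components, min_silhouette = min_silhouette),
            class = "cluster_grid")
}

#' Silhouette-gated grid search over UMAP + k-means
#'
#' Applies PCA to the target explained variance, then walks the full
#' Cartesian grid in deterministic order (n_neighbors ascending, min_dist
#' ascending, seeds ascending, k ascending), embedding with UMAP and
#' clustering with k-means (10 restarts per seed, best inertia kept). The
#' solution with the highest silhouette — computed on the embedding the
#' clustering ran in — wins; ties go to the smaller k, then the earlier
#' grid position. If the best silhouette is below the grid's floor the
#' solution is returned flagged `accepted = FALSE` (a failure report).
#' Grid points infeasible for the matrix size (too few rows for the
#' neighborhood or for k) are skipped.
#'
#' @param x Enrichment-ratio matrix (chemicals in rows).
#' @param grid A [cluster_grid()].
#' @param target_variance Passed to [reduce_pca()].
#' @return Object of class `cluster_solution`: `labels` (named by
#'   chemical), `k`, `silhouette`, `params`, `embedding`, `accepted`,
#'   `history` (silhouette of every grid point evaluated).
#' @export
grid_search_clustering <- function(x, grid = cluster_grid(), target_variance = 0.95) {
  if (is.null(nrow(x)) || nrow(x) == 0) abort("empty matrix")
  scores <- reduce_pca(x, target_variance)
  best <- NULL
  hist_rows <- list()
  for (nn in grid$n_neighbors) {
    if (nrow(scores) < nn + 1) next
    for (md in grid$min_dist) {
      for (seed in grid$seeds) {
        emb <- embed_umap(scores, n_neighbors = nn, min_dist = md,
                          n_components = grid$n_components, seed = seed)
        for (k in grid$k_range) {
          if (nrow(emb) <= k) next
          km <- withr::with_seed(seed, kmeans(emb, centers = k, nstart = 10,
                                              iter.max = 50))
          sil <- silhouette_score(emb, km$cluster)
          hist_rows[[length(hist_rows) + 1]] <-
            tibble(n_neighbors = nn, min_dist = md, seed = seed, k = k,
                   silhouette = sil)
          if (is.null(best) || sil > best$silhouette ||
              (sil == best$silhouette && k < best$k)) {
            best <- list(labels = setNames(km$cluster, rownames(emb)),
                         k = k, silhouette = sil,
                         params = list(n_neighbors = nn, min_dist = md,
                                       n_components = grid$n_components,
                                       umap_seed = seed, kmeans_seed = seed),
                         embedding = emb)
          }
        }
      }
    }
  }
  if (is.null(best)) abort("no feasible grid point for this matrix size")
  best$accepted <- best$silhouette >= grid$min_silhouette
  best$min_silhouette <- grid$min_silhouette
  best$history <- bind_rows(hist_rows)
  class(best) <- "cluster_solution"
  best
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "%s clustering: k = %d, silhouette = %.3f (floor %.2f)\n",
    if (x$accepted) "Accepted" else "BELOW-THRESHOLD", x$k, x$silhouette,
    x$min_silhouette))
  cat(sprintf("  UMAP n_neighbors = %d, min_dist = %.2f, seed = %d; %d chemicals\n",
              x$params$n_neighbors, x$params$min_dist, x$params$umap_seed,
              length(x$labels)))
  invisible(x)
}

#' Restrict an ER matrix to cancer-keyword pathways
#'
#' Keeps the columns whose pathway names contain any of the cancer
#' keywords (case-insensitive substring), then the rows (additives) with at
#' least one nonzero enrichment among the kept columns.
#'
#' @param x ER matrix with `set_id` colnames.
#' @param set_names Tibble `set_id`, `name` giving pathway display names.
#' @param keywords Substrings identifying cancer-related pathway names.
#' @return The submatrix (possibly with zero rows/columns, with a warning
#'   when no column matches).
#' @export
subset_cancer_keywords <- function(x, set_names,
                                   keywords = c("cancer", "carcin", "metasta", "tumor")) {
  stopifnot_cols(set_names, c("set_id", "name"), "pathway name table")
  nm <- set_names$name[match(colnames(x), set_names$set_id)]
  nm[is.na(nm)] <- ""
  keep_col <- purrr::map_lgl(tolower(nm), function(s) {
    any(stringr::str_detect(s, stringr::fixed(tolower(keywords))))
  })
  if (!any(keep_col)) {
    warn("no pathway name matches a cancer keyword; returning empty submatrix")
    return(x[integer(), integer(), drop = FALSE])
  }
  sub <- x[, keep_col, drop = FALSE]
  keep_row <- rowSums(sub != 0) > 0
  sub[keep_row, , drop = FALSE]
}
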