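#' Select pathways differentially enriched across a cluster
#'
#' A candidate pathway is selected when the standard deviation of its raw
#' enrichment ratios across the cluster's additives exceeds the threshold
#' (sample SD, n-1 denominator). The cluster-profiling protocol then keeps
#' only additives enriching at least one selected pathway; see
#' [cluster_profile()].
#'
#' @param x ER matrix restricted to one cluster's additives (rows).
#' @param candidates Column set_ids to consider (default: all columns),
#'   e.g. the cancer-focused collection.
#' @param sd_threshold Strict lower bound on the SD.
#' @return Character vector of selected set_ids (order of appearance).
#' @export
select_differential_pathways <- function(x, sd_threshold, candidates = colnames(x)) {
  candidates <- intersect(candidates, colnames(x))
  if (length(candidates) == 0 || nrow(x) < 2) return(character())
  sds <- apply(x[, candidates, drop = FALSE], 2, sd)
  sel <- candidates[sds > sd_threshold]
  if (length(sel) == 0) warn("no pathway exceeds the SD threshold")
  sel
}

#' Column standardization (z-scores)
#'
#' Centers each column to mean 0 and divides by its sample standard
#' deviation (n-1), the `scale()` convention. Constant columns cannot be
#' standardized and become all-zero with a warning.
#'
#' @param x Numeric matrix with at least two rows.
#' @return The standardized matrix (dimnames preserved).
#' @export
scale_columns <- function(x) {
  if (nrow(x) < 2) abort("standardization needs at least two rows")
  sds <- apply(x, 2, sd)
  constant <- sds == 0
  if (any(constant)) {
    warn(sprintf("%d constant column(s) set to zero", sum(constant)))
    sds[constant] <- 1
  }
  out <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  out[, constant] <- 0
  out
}

#' Deterministic leaf order from hierarchical clustering
#'
#' Agglomerative clustering of the rows (`axis = "rows"`) or columns
#' (`axis = "columns"`) with the configured distance and linkage
#' (Euclidean / complete by default, the common heatmap defaults),
#' returning the dendrogram leaf order.
#'
#' @param x Numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param method Linkage method for [stats::hclust()].
#' @param distance Distance measure for [stats::dist()].
#' @return Integer vector: the leaf order as indices into the chosen axis.
#' @export
hierarchical_order <- function(x, axis = c("rows", "columns"),
                               method = "complete", distance = "euclidean") {
  axis <- match.arg(axis)
  m <- if (axis == "rows") x else t(x)
  n <- nrow(m)
  if (n < 2) return(seq_len(n))
  hclust(dist(m, method = distance), method = method)$order
}

#' Central pathways of a cluster
#'
#' Ranks pathways by the number of the cluster's additives that enrich
#' them (nonzero ER / significant call) and returns the top `top_n`
#' (default 50); ties are broken by set_id so the ranking is
#' deterministic.
#'
#' @param x ER (or binary enrichment) matrix for the cluster's additives.
#' @param top_n Number of pathways to keep.
#' @return Tibble `set_id`, `n_additives`, ranked.
#' @export
central_pathways <- function(x, top_n = 50) {
  counts <- colSums(x != 0)
  tibble(set_id = colnames(x), n_additives = as.integer(counts)) |>
    arrange(desc(.data$n_additives), .data$set_id) |>
    head(top_n)
}

#' Uniquely enriched pathways per cluster
#'
#' A cluster's uniquely enriched pathways are its central (top-50)
#' pathways that appear in no other cluster's central list.
#'
#' @param central_lists Named list of character vectors (or
#'   [central_pathways()] tibbles) of central set_ids per cluster.
#' @return Named list of character vectors, same names.
#' @export
uniquely_enriched <- function(central_lists) {
  ids <- lapply(central_lists, function(x) if (is.data.frame(x)) x$set_id else x)
  purrr::imap(ids, function(own, nm) {
    others <- unlist(ids[setdiff(names(ids), nm)])
    setdiff(own, others)
  })
}

#' Highly enriched pathways of a cluster
#'
#' Pathways whose maximum enrichment ratio over the cluster's additives
#' reaches the floor (default ER >= 100).
#'
#' @param x ER matrix for the cluster's additives.
#' @param er_floor Inclusive floor on the maximum ER.
#' @return Character vector of set_ids.
#' @export
highly_enriched <- function(x, er_floor = 100) {
  mx <- apply(x, 2, max)
  colnames(x)[mx >= er_floor]
}

#' Characterize each cluster by its differential cancer pathways
#'
#' For every cluster: selects the cancer-collection pathways whose raw ER
#' standard deviation across the cluster exceeds that cluster's threshold,
#' drops additives enriching none of them, column-standardizes the
#' remaining submatrix, and hierarchically orders both additives and
#' pathways for heatmap display. Pathway cancer-relation categories
#' (cancer type, cell cycle/proliferation, cell death/survival, DNA
#' damage, immune, metabolism) are a user-supplied lookup — they are
#' curated manually, never invented here.
#'
#' @param x Full ER matrix (all clustered additives).
#' @param labels Named cluster assignment (names = rownames of `x`).
#' @param candidates set_ids of the cancer-focused collection (default all
#'   columns).
#' @param sd_thresholds Numeric vector of per-cluster SD thresholds,
#'   recycled across clusters in sorted label order.
#' @param categories Optional tibble `set_id`, `category`; validated to
#'   cover every selected pathway.
#' @return Named list (one element per cluster) of `cluster_profile`
#'   lists: `cluster_id`, `selected_pathways`, `scaled_matrix`,
#'   `additive_order`, `pathway_order`, `category_of`.
#' @export
cluster_profile <- function(x, labels, sd_thresholds, candidates = colnames(x),
                            categories = NULL) {
  labels <- labels[rownames(x)]
  if (anyNA(labels)) abort("every row of `x` needs a cluster label")
  ids <- sort(unique(labels))
  thr <- rep_len(sd_thresholds, length(ids))
  out <- purrr::map2(ids, thr, function(cl, th) {
    rows <- x[labels == cl, , drop = FALSE]
    sel <- select_differential_pathways(rows, sd_threshold = th, candidates = candidates)
    if (length(sel) == 0) {
      return(structure(list(cluster_id = cl, selected_pathways = character(),
                            scaled_matrix = NULL, additive_order = integer(),
                            pathway_order = integer(), category_of = NULL),
                       class = "cluster_profile"))
    }
    sub <- rows[, sel, drop = FALSE]
    sub <- sub[rowSums(sub != 0) > 0, , drop = FALSE]
    scaled <- if (nrow(sub) >= 2) scale_columns(sub) else sub
    cat_of <- NULL
    if (!is.null(categories)) {
      stopifnot_cols(categories, c("set_id", "category"), "category lookup")
      cat_of <- setNames(categories$category[match(sel, categories$set_id)], sel)
      if (anyNA(cat_of)) {
        abort(sprintf("category lookup does not cover pathway(s): %s",
                      paste(sel[is.na(cat_of)], collapse = ", ")))
      }
    }
    structure(list(
      cluster_id = cl,
      selected_pathways = sel,
      scaled_matrix = scaled,
      additive_order = hierarchical_order(scaled, "rows"),
      pathway_order = hierarchical_order(scaled, "columns"),
      category_of = cat_of
    ), class = "cluster_profile")
  })
  names(out) <- paste0("cluster_", ids)
  out
}
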