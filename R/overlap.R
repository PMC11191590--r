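chem_gene_sets <- function(records, cas) {
  rows <- records[records$cas == cas, ]
  list(up = unique(rows$gene_id[rows$direction == "up"]),
       down = unique(rows$gene_id[rows$direction == "down"]))
}

chem_pathways <- function(results, cas) {
  unique(results$set_id[results$cas == cas])
}

#' Shared gene and pathway alterations between two chemicals
#'
#' Counts the upregulated genes, downregulated genes, and significantly
#' enriched pathways that a pair of chemicals has in common. A gene
#' reported both up- and downregulated for a chemical contributes to both
#' direction overlaps.
#'
#' @param records All-human interaction tibble (`cas`, `gene_id`,
#'   `direction`).
#' @param results Significant ORA results (`cas`, `set_id`).
#' @param cas_a,cas_b The two chemicals; both must appear in `records`
#'   and/or `results`.
#' @return One-row tibble `cas_a`, `cas_b`, `shared_up`, `shared_down`,
#'   `shared_pathways`.
#' @export
pairwise_overlap <- function(records, results, cas_a, cas_b) {
  known <- unique(c(records$cas, results$cas))
  missing <- setdiff(c(cas_a, cas_b), known)
  if (length(missing)) {
    abort(sprintf("unknown CAS: %s", paste(missing, collapse = ", ")))
  }
  a <- chem_gene_sets(records, cas_a)
  b <- chem_gene_sets(records, cas_b)
  tibble(
    cas_a = cas_a, cas_b = cas_b,
    shared_up = length(intersect(a$up, b$up)),
    shared_down = length(intersect(a$down, b$down)),
    shared_pathways = length(intersect(chem_pathways(results, cas_a),
                                       chem_pathways(results, cas_b)))
  )
}

#' All query-reference pairwise overlaps
#'
#' @inheritParams pairwise_overlap
#' @param query_cas,reference_cas Chemical groups to compare (every query
#'   is paired with every reference).
#' @return Tibble of [pairwise_overlap()] rows, query as `cas_a`.
#' @export
group_overlap <- function(records, results, query_cas, reference_cas) {
  grid <- tidyr::expand_grid(cas_a = unique(query_cas), cas_b = unique(reference_cas))
  purrr::map2(grid$cas_a, grid$cas_b, function(a, b) {
    pairwise_overlap(records, results, a, b)
  }) |> bind_rows()
}

#' Rank query chemicals by overlap with a reference group
#'
#' Each query chemical's overlaps with the reference chemicals are
#' aggregated (sum by default, or the best single pairing with
#' `aggregate = "max"`) on the chosen metric, and the top k queries are
#' returned (ties broken by CAS ascending). This identifies, e.g., the
#' Group 3 or unclassified additives sharing the most upregulated genes,
#' downregulated genes, or enriched pathways with Group 1 carcinogens.
#'
#' @inheritParams group_overlap
#' @param metric One of `"up"`, `"down"`, `"pathways"`.
#' @param k Number of query chemicals to return.
#' @param aggregate `"sum"` (default) or `"max"` over reference chemicals.
#' @return Tibble `cas`, `overlap` (aggregated), `best_match` (reference
#'   chemical with the largest single overlap), ranked descending.
#' @export
top_overlapping <- function(records, results, query_cas, reference_cas,
                            metric = c("up", "down", "pathways"), k = 10,
                            aggregate = c("sum", "max")) {
  metric <- match.arg(metric)
  aggregate <- match.arg(aggregate)
  if (length(query_cas) == 0 || length(reference_cas) == 0) {
    abort("query and reference groups must be nonempty")
  }
  col <- switch(metric, up = "shared_up", down = "shared_down",
                pathways = "shared_pathways")
  pairs <- group_overlap(records, results, query_cas, reference_cas)
  pairs |>
    group_by(cas = .data$cas_a) |>
    summarise(
      overlap = if (aggregate == "sum") sum(.data[[col]]) else max(.data[[col]]),
      best_match = .data$cas_b[order(-.data[[col]], .data$cas_b)][1],
      .groups = "drop"
    ) |>
    arrange(desc(.data$overlap), .data$cas) |>
    head(k)
}

#' Enrichment profile of query chemicals over a reference pathway union
#'
#' Collects the union U of pathways significantly enriched by the
#' reference group (e.g. all pathways enriched by Group 1 carcinogens) and
#' reports, per query chemical, the percentage of U it enriches. Queries
#' enriching none of U are flagged.
#'
#' @inheritParams group_overlap
#' @return Tibble `cas`, `n_union` (|U|), `n_enriched`, `pct` in
#'   \[0, 100\], `nonzero`.
#' @export
pathway_union_profile <- function(records, results, query_cas, reference_cas) {
  u <- sort(unique(results$set_id[results$cas %in% reference_cas]))
  if (length(u) == 0) abort("reference group enriches no pathways")
  purrr::map(unique(query_cas), function(q) {
    n <- length(intersect(chem_pathways(results, q), u))
    tibble(cas = q, n_union = length(u), n_enriched = n,
           pct = 100 * n / length(u), nonzero = n > 0)
  }) |> bind_rows() |> arrange(desc(.data$pct), .data$cas)
}
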