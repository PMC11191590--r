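#' End-to-end enrichment stage: interactions to ER matrix
#'
#' Chains ortholog remapping, gene-set filtering against the background,
#' per-chemical over-representation analysis, and ER-matrix assembly. The
#' matrix rows are the chemicals that produced at least one significant
#' result (the additives that enter clustering); columns are all filtered
#' sets.
#'
#' @param records Interaction tibble (may contain nonhuman records).
#' @param ortholog_map Ortholog tibble for [remap_orthologs()]; `NULL` if
#'   records are already all-human.
#' @param sets Gene-set tibble.
#' @param background Background gene universe.
#' @param fdr_threshold,min_size,max_size Gates for
#'   [enrich_chemical()]/[filter_gene_sets()].
#' @return List: `remapped`, `unmapped`, `sets` (filtered), `results`
#'   (significant ORA rows), `eligible_cas`, `er` (the ER matrix).
#' @export
enrichment_pipeline <- function(records, ortholog_map = NULL, sets, background,
                                fdr_threshold = 0.25, min_size = 10,
                                max_size = 2000) {
  if (!is.null(ortholog_map)) {
    mapped <- remap_orthologs(records, ortholog_map)
  } else {
    mapped <- list(remapped = validate_interactions(records),
                   unmapped = validate_interactions(records)[0, ])
  }
  filtered <- filter_gene_sets(sets, background, min_size = min_size,
                               max_size = max_size)
  enr <- enrich_all(mapped$remapped, filtered, background,
                    fdr_threshold = fdr_threshold)
  with_results <- sort(unique(enr$results$cas))
  er <- build_er_matrix(enr$results, with_results, filtered$set_id)
  list(remapped = mapped$remapped, unmapped = mapped$unmapped,
       sets = filtered, results = enr$results,
       eligible_cas = enr$eligible_cas, er = er)
}
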