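#' Read a chemical-gene interaction table
#'
#' One row per regulation event, in the dialect of Comparative
#' Toxicogenomics Database exports: `cas,gene_id,gene_symbol,organism,
#' direction` with `direction` in `up`/`down`. A gene may legitimately
#' appear both up- and downregulated for one chemical (separate rows).
#'
#' @param path CSV path.
#' @return Tibble with the five columns above, `gene_id` integer.
#' @export
read_interactions <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    cas = readr::col_character(),
    gene_id = readr::col_integer(),
    gene_symbol = readr::col_character(),
    organism = readr::col_character(),
    direction = readr::col_character()
  ))
  validate_interactions(df)
}

validate_interactions <- function(df) {
  stopifnot_cols(df, c("cas", "gene_id", "direction"), "interaction table")
  bad <- !df$direction %in% c("up", "down")
  if (any(bad)) abort("interaction `direction` must be 'up' or 'down'")
  if (!"organism" %in% names(df)) df$organism <- "human"
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
  df
}

#' Read an ortholog mapping table
#'
#' @param path TSV with columns `source_gene_id` and `human_entrez_id`,
#'   one (source, human) pair per row; a source gene with several human
#'   orthologs occupies several rows.
#' @return Tibble with the two integer columns, deduplicated.
#' @export
read_ortholog_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    source_gene_id = readr::col_integer(),
    human_entrez_id = readr::col_integer()
  ))
  stopifnot_cols(df, c("source_gene_id", "human_entrez_id"), "ortholog map")
  distinct(df)
}

#' Remap nonhuman interaction records to human Entrez IDs
#'
#' Records labeled human pass through unchanged. A nonhuman record whose
#' gene has k human orthologs in the map expands to k human records with
#' the direction preserved (all human matches are substituted for the
#' homologue); a nonhuman record absent from the map goes to the unmapped
#' bucket and is excluded from downstream enrichment. Expansion duplicates
#' are collapsed on (cas, gene_id, direction).
#'
#' @param records Interaction tibble (see [read_interactions()]).
#' @param map Ortholog tibble (see [read_ortholog_map()]).
#' @return List with `remapped` (all-human interaction tibble, deduplicated
#'   on cas/gene_id/direction) and `unmapped` (the input rows that could
#'   not be remapped).
#' @export
remap_orthologs <- function(records, map) {
  records <- validate_interactions(records)
  stopifnot_cols(map, c("source_gene_id", "human_entrez_id"), "ortholog map")
  is_human <- records$organism %in% "human"
  human <- records[is_human, ]
  nonhuman <- records[!is_human, ]
  if (nrow(nonhuman) > 0) {
    expanded <- nonhuman |>
      dplyr::inner_join(map, by = c(gene_id = "source_gene_id"),
                        relationship = "many-to-many") |>
      mutate(gene_id = .data$human_entrez_id, organism = "human") |>
      select(-"human_entrez_id")
    unmapped <- nonhuman |> dplyr::anti_join(map, by = c(gene_id = "source_gene_id"))
    if (nrow(unmapped) > 0) {
      warn(sprintf("%d nonhuman interaction record(s) had no human ortholog and were excluded",
                   nrow(unmapped)))
    }
  } else {
    expanded <- nonhuman
    unmapped <- nonhuman
  }
  remapped <- bind_rows(human, expanded) |>
    distinct(.data$cas, .data$gene_id, .data$direction, .keep_all = TRUE) |>
    arrange(.data$cas, .data$gene_id, .data$direction)
  list(remapped = remapped, unmapped = unmapped)
}

#' Assemble the ORA input gene list for one chemical
#'
#' The over-representation input for a chemical is a single list combining
#' all of its up- and downregulated genes (deduplicated union; a gene
#' reported in both directions appears once).
#'
#' @param records All-human interaction tibble.
#' @param cas One CAS number.
#' @return Sorted integer vector of gene IDs (possibly empty).
#' @export
build_ora_input <- function(records, cas) {
  stopifnot_cols(records, c("cas", "gene_id"), "interaction table")
  sort(unique(records$gene_id[records$cas == cas]))
}

#' Interaction coverage of the registry by carcinogenicity class
#'
#' Counts the chemicals with at least one recorded gene interaction,
#' overall and split into classified vs unclassified, as exact tallies
#' plus percentages of the registry total.
#'
#' @param registry Tibble with `cas` and `is_classified` (see
#'   [derive_class()]), one row per CAS.
#' @param records Interaction tibble (or any tibble with a `cas` column).
#' @return Tibble `group`, `n_chemicals`, `n_with_interactions`,
#'   `pct_of_registry`.
#' @export
interaction_coverage <- function(registry, records) {
  stopifnot_cols(registry, c("cas", "is_classified"), "registry")
  has <- registry$cas %in% unique(records$cas)
  n <- nrow(registry)
  tibble(
    group = c("all", "classified", "unclassified"),
    n_chemicals = c(n, sum(registry$is_classified), sum(!registry$is_classified)),
    n_with_interactions = c(sum(has), sum(has & registry$is_classified),
                            sum(has & !registry$is_classified))
  ) |>
    mutate(pct_of_registry = 100 * .data$n_with_interactions / n)
}

#' Yield of ORA results among chemicals with interaction data
#'
#' Of the chemicals that have gene-interaction records, reports how many
#' produced at least one significant over-representation result, split by
#' classification, with percentages over the with-interactions subset of
#' each class.
#'
#' @param registry Tibble with `cas` and `is_classified`.
#' @param records Interaction tibble.
#' @param result_cas Character vector of CAS numbers that produced ORA
#'   results.
#' @return Tibble `group`, `n_with_interactions`, `n_with_results`,
#'   `pct_of_with_interactions`.
#' @export
ora_yield <- function(registry, records, result_cas) {
  stopifnot_cols(registry, c("cas", "is_classified"), "registry")
  has <- registry$cas %in% unique(records$cas)
  res <- registry$cas %in% unique(result_cas)
  row_for <- function(keep, group) {
    tibble(
      group = group,
      n_with_interactions = sum(has & keep),
      n_with_results = sum(res & has & keep),
      pct_of_with_interactions =
        100 * sum(res & has & keep) / sum(has & keep)
    )
  }
  bind_rows(
    row_for(rep(TRUE, nrow(registry)), "all"),
    row_for(registry$is_classified, "classified"),
    row_for(!registry$is_classified, "unclassified")
  )
}
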