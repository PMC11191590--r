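#' Read gene sets from a GMT file
#'
#' Standard GMT: one gene set per tab-separated line — set identifier,
#' description, then member genes. Duplicate members within a line are
#' collapsed; empty lines are skipped.
#'
#' @param path GMT file path.
#' @param source Collection label attached to every set (e.g. "KEGG",
#'   "WikipathwaysCancer").
#' @return Gene-set tibble: `set_id`, `name`, `source`, `genes`
#'   (list-column of integer/character gene IDs), `size`.
#' @export
read_gmt <- function(path, source = "other") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1]),
          class = "plastitox_gmt_parse")
  }
  tibble(
    set_id = vapply(fields, `[[`, character(1), 1),
    name = vapply(fields, `[[`, character(1), 2),
    source = source,
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  ) |>
    mutate(size = lengths(.data$genes))
}

#' Filter gene sets against a background universe
#'
#' Each set is first intersected with the background; sets whose effective
#' (intersected) size falls outside `[min_size, max_size]` are removed.
#' Defaults follow common over-representation practice: minimum 10,
#' maximum 2,000 genes.
#'
#' @param sets Gene-set tibble (see [read_gmt()]).
#' @param background Vector of background gene IDs (nonempty).
#' @param min_size,max_size Inclusive bounds on the effective set size.
#' @return The filtered tibble with `genes` replaced by the
#'   background-intersected members and `size` updated.
#' @export
filter_gene_sets <- function(sets, background, min_size = 10, max_size = 2000) {
  if (length(background) == 0) abort("background universe is empty")
  stopifnot_cols(sets, c("set_id", "genes"), "gene-set collection")
  sets$genes <- lapply(sets$genes, intersect, background)
  sets$size <- lengths(sets$genes)
  filter(sets, .data$size >= min_size, .data$size <= max_size)
}

#' Hypergeometric over-representation test with enrichment ratio
#'
#' Tests whether `input_genes` overlaps `set_genes` more than expected when
#' drawing `|input|` genes at random from the background. The p-value is
#' the upper tail P(X >= overlap) of the hypergeometric distribution; the
#' enrichment ratio is
#' \deqn{ER = overlap / expect, \quad expect = input\_size \times set\_size / background\_size,}
#' the ratio of observed to expected overlap.
#'
#' @param input_genes Genes submitted for the chemical (intersected with
#'   the background by the caller or here; genes outside the background are
#'   dropped).
#' @param set_genes Members of one gene set (assumed already intersected
#'   with the background, as [filter_gene_sets()] leaves them).
#' @param background Background universe of gene IDs.
#' @return One-row tibble: `overlap`, `input_size`, `set_size`,
#'   `background_size`, `expect`, `er`, `p`.
#' @examples
#' ora_test(1:5, 3:12, 1:100)  # overlap 3 of expected 0.5
#' @export
ora_test <- function(input_genes, set_genes, background) {
  bg_n <- length(unique(background))
  if (bg_n == 0) abort("background universe is empty")
  input <- intersect(unique(input_genes), background)
  if (length(input) == 0) abort("no input genes remain after background intersection")
  set <- unique(set_genes)
  overlap <- length(intersect(input, set))
  k <- length(input)
  m <- length(set)
  expect <- k * m / bg_n
  tibble(
    overlap = overlap,
    input_size = k,
    set_size = m,
    background_size = bg_n,
    expect = expect,
    er = if (expect > 0) overlap / expect else 0,
    p = phyper(overlap - 1, m, bg_n - m, k, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted values q(i) = min over j >= i of p(j) * m / j (on the
#' sorted p-values), capped at 1 and returned in input order. Rejecting
#' all tests with q <= alpha reproduces the classic BH step-up rule at
#' level alpha.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Over-representation analysis for one chemical across a collection
#'
#' Runs [ora_test()] for every filtered gene set, adjusts p-values with
#' Benjamini-Hochberg across all sets tested for this chemical (all source
#' collections pooled into one family — one submission, one family; set
#' `by_source = TRUE` for per-collection adjustment), and keeps results
#' with FDR at or below the threshold, sorted by FDR, then descending ER,
#' then set ID.
#'
#' @param cas The chemical's CAS number (carried into the results).
#' @param input_genes The chemical's combined up+down gene list.
#' @param sets Filtered gene-set tibble.
#' @param background Background universe.
#' @param fdr_threshold Significance gate on the adjusted value
#'   (default 0.25).
#' @param by_source Adjust within each `source` collection separately.
#' @param keep_all Return all tested sets, not only those passing the
#'   gate (the gate is still recorded in `significant`).
#' @return Tibble of ORA results: `cas`, `set_id`, `source`, the
#'   [ora_test()] columns, `fdr`, and `significant`.
#' @export
enrich_chemical <- function(cas, input_genes, sets, background,
                            fdr_threshold = 0.25, by_source = FALSE,
                            keep_all = FALSE) {
  if (nrow(sets) == 0) {
    warn("no eligible gene sets; returning empty result")
    return(empty_ora_result())
  }
  bg <- unique(background)
  input <- intersect(unique(input_genes), bg)
  if (length(input) == 0) abort("no input genes remain after background intersection")
  res <- purrr::map(sets$genes, ora_test, input_genes = input, background = bg) |>
    bind_rows() |>
    mutate(cas = cas, set_id = sets$set_id,
           source = sets$source %||% "other", .before = 1)
  if (by_source) {
    res <- res |> group_by(.data$source) |>
      mutate(fdr = adjust_fdr(.data$p)) |> ungroup()
  } else {
    res$fdr <- adjust_fdr(res$p)
  }
  res <- res |>
    mutate(significant = .data$fdr <= fdr_threshold) |>
    arrange(.data$fdr, desc(.data$er), .data$set_id)
  if (!keep_all) res <- filter(res, .data$significant)
  res
}

empty_ora_result <- function() {
  tibble(
    cas = character(), set_id = character(), source = character(),
    overlap = integer(), input_size = integer(), set_size = integer(),
    background_size = integer(), expect = double(), er = double(),
    p = double(), fdr = double(), significant = logical()
  )
}

#' Batch over-representation analysis for all chemicals
#'
#' Builds each chemical's combined up+down gene list from the interaction
#' table and runs [enrich_chemical()] for every chemical with at least one
#' input gene inside the background (the ORA-eligible chemicals).
#'
#' @inheritParams enrich_chemical
#' @param records All-human interaction tibble.
#' @return List: `results` — row-bound significant ORA results for all
#'   chemicals; `eligible_cas` — chemicals whose input intersected the
#'   background; `tested_sets` — the `set_id`s tested.
#' @export
enrich_all <- function(records, sets, background, fdr_threshold = 0.25,
                       by_source = FALSE) {
  stopifnot_cols(records, c("cas", "gene_id"), "interaction table")
  bg <- unique(background)
  inputs <- records |>
    filter(.data$gene_id %in% bg) |>
    group_by(.data$cas) |>
    summarise(genes = list(sort(unique(.data$gene_id))), .groups = "drop")
  results <- purrr::map2(inputs$cas, inputs$genes, function(chem, genes) {
    enrich_chemical(chem, genes, sets, bg, fdr_threshold = fdr_threshold,
                    by_source = by_source)
  }) |> bind_rows()
  list(results = results, eligible_cas = inputs$cas, tested_sets = sets$set_id)
}

#' Assemble the chemical-by-pathway enrichment-ratio matrix
#'
#' Rows are chemicals, columns gene sets; a cell holds the enrichment
#' ratio where that chemical-pathway pair passed the significance gate and
#' 0 otherwise.
#'
#' @param results Significant ORA results (rows define the nonzero cells).
#' @param chemicals Row universe (CAS numbers).
#' @param set_ids Column universe.
#' @return Numeric matrix with `chemicals` as rownames and `set_ids` as
#'   colnames.
#' @export
build_er_matrix <- function(results, chemicals, set_ids) {
  m <- matrix(0, nrow = length(chemicals), ncol = length(set_ids),
              dimnames = list(chemicals, set_ids))
  if (nrow(results) > 0) {
    keep <- results$cas %in% chemicals & results$set_id %in% set_ids
    r <- results[keep, ]
    m[cbind(match(r$cas, chemicals), match(r$set_id, set_ids))] <- r$er
  }
  m
}
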