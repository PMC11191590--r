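confidence_levels <- c("unknown", "low", "medium", "high")

#' Read an additive registry CSV
#'
#' Expected columns: `cas,name,confidence,functions,polymers,products`.
#' Multi-valued cells (`functions`, `polymers`, `products`) are
#' pipe-delimited. Rows whose CAS fails the format or check-digit rule are
#' quarantined: they are dropped from the returned registry and, when
#' `rejects` is a path, written there for audit.
#'
#' @param path Path to the registry CSV (UTF-8, header required).
#' @param rejects Optional path; invalid-CAS rows are written to this CSV.
#' @return A registry tibble with list-columns `functions`, `polymers`,
#'   `products`, an empty `aliases` list-column, and `confidence` as an
#'   ordered factor (`unknown < low < medium < high`). One row per source
#'   record; call [merge_registry()] to collapse to one row per CAS.
#' @seealso [merge_registry()], [categorize_products()]
#' @export
read_registry <- function(path, rejects = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot_cols(raw, c("cas", "name"), "registry CSV")
  for (col in c("confidence", "functions", "polymers", "products")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  canon <- normalize_cas(raw$cas, strict = FALSE)
  bad <- is.na(canon)
  if (any(bad)) {
    warn(sprintf("%d registry row(s) failed CAS validation and were quarantined", sum(bad)))
    if (!is.null(rejects)) readr::write_csv(raw[bad, ], rejects)
  }
  out <- raw[!bad, ]
  out$cas <- canon[!bad]
  tibble(
    cas = out$cas,
    name = out$name,
    aliases = replicate(nrow(out), character(), simplify = FALSE),
    confidence = parse_confidence(out$confidence),
    functions = split_multi(out$functions),
    polymers = split_multi(out$polymers),
    products = split_multi(out$products)
  )
}

parse_confidence <- function(x) {
  x <- tolower(ifelse(is.na(x) | !nzchar(x), "unknown", x))
  unknown <- !x %in% confidence_levels
  if (any(unknown)) {
    warn(sprintf("unrecognized confidence value(s) treated as 'unknown': %s",
                 paste(unique(x[unknown]), collapse = ", ")))
    x[unknown] <- "unknown"
  }
  factor(x, levels = confidence_levels, ordered = TRUE)
}

#' Merge registry records that share a CAS number
#'
#' Source reviews often report the same additive; records are collapsed to
#' one row per CAS assuming a one-to-one mapping of CAS number to substance.
#' The merged record keeps the highest confidence seen (high > medium > low
#' > unknown), the union of functions/polymers/products, and the name of the
#' highest-confidence record (ties broken lexicographically); all other
#' names are retained as aliases.
#'
#' @param registry A registry tibble from [read_registry()] (or built in
#'   code with the same columns).
#' @return A registry tibble with one row per CAS, sorted by CAS.
#' @export
merge_registry <- function(registry) {
  stopifnot_cols(registry, c("cas", "name", "confidence"), "registry")
  registry |>
    dplyr::group_split(.data$cas) |>
    purrr::map(merge_source_records) |>
    bind_rows() |>
    arrange(.data$cas)
}

#' @rdname merge_registry
#' @param records A registry tibble whose rows all share one CAS number.
#' @export
merge_source_records <- function(records) {
  if (nrow(records) == 0) abort("cannot merge an empty record set")
  if (dplyr::n_distinct(records$cas) != 1) {
    abort("merge_source_records() requires all records to share one CAS")
  }
  conf <- max(records$confidence)
  top <- records$name[records$confidence == conf]
  name <- sort(top)[1]
  aliases <- sort(unique(c(
    unlist(records$aliases %||% list(character())),
    setdiff(records$name, name)
  )))
  tibble(
    cas = records$cas[1],
    name = name,
    aliases = list(aliases),
    confidence = conf,
    functions = list(sort(unique(unlist(records$functions)))),
    polymers = list(sort(unique(unlist(records$polymers)))),
    products = list(sort(unique(unlist(records$products))))
  )
}

#' Read product-category search-string rules
#'
#' Product strings are grouped into interpretable categories (food,
#' packaging, clothing, ...) by substring search. Each category has one or
#' more positive search strings and optionally negative search strings that
#' veto a match (e.g. "tablecloth" would match the clothing category via
#' "cloth", so "tablecloth" is listed as a negative string).
#'
#' @param path CSV with columns `category,kind,string`, `kind` being
#'   `positive` or `negative`.
#' @return A rules tibble: `category`, `positive` (list-column), `negative`
#'   (list-column). Every category has at least one positive string.
#' @export
read_category_rules <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot_cols(raw, c("category", "kind", "string"), "category rule CSV")
  bad <- !raw$kind %in% c("positive", "negative")
  if (any(bad)) abort("rule `kind` must be 'positive' or 'negative'")
  rules <- raw |>
    group_by(.data$category) |>
    summarise(
      positive = list(.data$string[.data$kind == "positive"]),
      negative = list(.data$string[.data$kind == "negative"]),
      .groups = "drop"
    )
  validate_category_rules(rules)
}

validate_category_rules <- function(rules) {
  stopifnot_cols(rules, c("category", "positive", "negative"), "category rules")
  empty <- lengths(rules$positive) == 0
  if (any(empty)) {
    abort(sprintf("category rule(s) without positive strings: %s",
                  paste(rules$category[empty], collapse = ", ")))
  }
  rules
}

#' Categorize product strings by positive/negative substring rules
#'
#' A product string matches a category iff it contains (case-insensitive,
#' whitespace-normalized substring) at least one of the category's positive
#' strings and none of its negative strings. The result is the union of
#' categories over all product strings.
#'
#' @param products Character vector of product strings (may be empty).
#' @param rules Rules tibble as returned by [read_category_rules()].
#' @return Sorted character vector of matching category labels.
#' @export
categorize_products <- function(products, rules) {
  rules <- validate_category_rules(rules)
  if (length(products) == 0) return(character())
  prod <- squash_ws(products)
  hit <- purrr::pmap_lgl(rules, function(category, positive, negative) {
    pos <- squash_ws(positive)
    neg <- squash_ws(negative)
    any(vapply(prod, function(p) {
      any(stringr::str_detect(p, stringr::fixed(pos))) &&
        (length(neg) == 0 || !any(stringr::str_detect(p, stringr::fixed(neg))))
    }, logical(1)))
  })
  sort(rules$category[hit])
}

#' @describeIn categorize_products Apply the rules to a whole registry,
#'   adding a `product_categories` list-column.
#' @param registry A registry tibble with a `products` list-column.
#' @export
assign_product_categories <- function(registry, rules) {
  stopifnot_cols(registry, "products", "registry")
  registry$product_categories <-
    purrr::map(registry$products, categorize_products, rules = rules)
  registry
}

#' Summarize additive usage annotations
#'
#' Produces the per-additive association counts (polymers, functions,
#' products per additive) and the per-item additive counts (additives per
#' polymer / function / product category). Additives with zero associations
#' in a usage dimension are excluded from that dimension's per-additive
#' distribution, so the distributions describe annotated additives only.
#'
#' @param registry A merged registry tibble; `product_categories` is used
#'   when present.
#' @return A list of class `usage_summary`:
#'   `per_additive` — tibble `cas`, `n_polymers`, `n_functions`,
#'   `n_products`, `n_categories`; `distributions` — long tibble
#'   `dimension`, `n` (associations per additive, zeros removed), and
#'   `top_items` — tibble `dimension`, `item`, `n_additives` sorted
#'   descending within dimension.
#' @export
summarize_usage <- function(registry) {
  stopifnot_cols(registry, c("cas", "functions", "polymers", "products"), "registry")
  has_cat <- "product_categories" %in% names(registry)
  per_additive <- tibble(
    cas = registry$cas,
    n_polymers = lengths(registry$polymers),
    n_functions = lengths(registry$functions),
    n_products = lengths(registry$products),
    n_categories = if (has_cat) lengths(registry$product_categories) else NA_integer_
  )
  dims <- c(polymers = "n_polymers", functions = "n_functions", products = "n_products")
  distributions <- purrr::imap(dims, function(col, dim) {
    n <- per_additive[[col]]
    tibble(dimension = dim, n = n[n > 0])
  }) |> bind_rows()
  count_items <- function(col, dim) {
    x <- unlist(registry[[col]])
    if (length(x) == 0) {
      return(tibble(dimension = character(), item = character(), n_additives = integer()))
    }
    tibble(dimension = dim, item = x) |>
      dplyr::count(.data$dimension, .data$item, name = "n_additives") |>
      arrange(desc(.data$n_additives), .data$item)
  }
  top_items <- bind_rows(
    count_items("polymers", "polymers"),
    count_items("functions", "functions"),
    count_items("products", "products"),
    if (has_cat) count_items("product_categories", "product_categories")
  )
  structure(
    list(per_additive = per_additive, distributions = distributions, top_items = top_items),
    class = "usage_summary"
  )
}

#' @export
print.usage_summary <- function(x, ...) {
  cat("Usage summary over", nrow(x$per_additive), "additives\n")
  for (dim in unique(x$distributions$dimension)) {
    n <- x$distributions$n[x$distributions$dimension == dim]
    cat(sprintf("  %s/additive: mean %.2f +/- %.2f over %d annotated additives\n",
                sub("s$", "", dim), mean(n), stats::sd(n), length(n)))
  }
  invisible(x)
}
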