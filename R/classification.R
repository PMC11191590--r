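#' Carcinogenicity label vocabularies
#'
#' IARC monograph groups and EPA IRIS cancer descriptors as used throughout
#' the package. `present_unassigned` marks chemicals listed in IARC without
#' a group; `absent` marks chemicals not found in the database at all.
#'
#' @format Character vectors of level names, most severe first where the
#'   order matters (`iris_levels`).
#' @name label_levels
NULL

#' @rdname label_levels
#' @export
iarc_levels <- c("G1", "G2A", "G2B", "G3", "present_unassigned", "absent")

#' @rdname label_levels
#' @export
iris_levels <- c("carcinogen", "likely_carcinogen", "probable_carcinogen",
                 "possible_carcinogen", "suggestive", "noncancer", "absent")

iris_cancer_levels <- setdiff(iris_levels, c("noncancer", "absent"))

#' Derive the carcinogen / classified / unclassified partition from IARC
#'
#' IARC Groups 1, 2A and 2B are treated as carcinogens; carcinogens
#' together with Group 3 form the classified additives (their carcinogenic
#' potential has been evaluated); anything lacking an IARC group —
#' including chemicals present in IARC with no classification — is
#' unclassified.
#'
#' @param iarc_group Character or factor vector over [iarc_levels].
#' @return A tibble with columns `iarc_group`, `is_carcinogen`,
#'   `is_classified` (one row per input element).
#' @examples
#' derive_class(c("G2B", "G3", "absent"))
#' @export
derive_class <- function(iarc_group) {
  g <- as.character(iarc_group)
  bad <- !g %in% iarc_levels
  if (any(bad)) {
    abort(sprintf("unknown IARC group(s): %s", paste(unique(g[bad]), collapse = ", ")))
  }
  tibble(
    iarc_group = g,
    is_carcinogen = g %in% c("G1", "G2A", "G2B"),
    is_classified = g %in% c("G1", "G2A", "G2B", "G3")
  )
}

#' Resolve multi-route IRIS entries to one status per chemical
#'
#' IRIS can list one chemical with different carcinogenicity descriptors
#' for different exposure routes; a chemical listed as carcinogenic for any
#' route is treated as carcinogenic. Generally, the most severe descriptor
#' present wins, using the order carcinogen > likely > probable > possible
#' > suggestive > noncancer.
#'
#' @param status Character vector of IRIS descriptors for one chemical
#'   (one element per route).
#' @return A single descriptor string.
#' @examples
#' resolve_iris_multiroute(c("noncancer", "carcinogen"))
#' @export
resolve_iris_multiroute <- function(status) {
  s <- as.character(status)
  if (length(s) == 0) abort("no IRIS entries to resolve")
  bad <- !s %in% iris_levels
  if (any(bad)) {
    abort(sprintf("unknown IRIS status(es): %s", paste(unique(s[bad]), collapse = ", ")))
  }
  iris_levels[min(match(s, iris_levels))]
}

#' @describeIn resolve_iris_multiroute Resolve a whole per-route label
#'   table (`cas`, `iris_status`) to one row per CAS.
#' @param labels Tibble with columns `cas` and `iris_status`.
#' @export
resolve_iris <- function(labels) {
  stopifnot_cols(labels, c("cas", "iris_status"), "IRIS label table")
  labels |>
    group_by(.data$cas) |>
    summarise(iris_status = resolve_iris_multiroute(.data$iris_status), .groups = "drop")
}

default_correspondence <- function() {
  tidyr::expand_grid(iarc_group = iarc_levels, iris_status = iris_levels) |>
    mutate(verdict = dplyr::case_when(
      .data$iarc_group %in% c("present_unassigned", "absent") ~ "not_comparable",
      .data$iris_status == "absent" ~ "not_comparable",
      .data$iarc_group %in% c("G1", "G2A", "G2B") &
        .data$iris_status %in% iris_cancer_levels ~ "consistent",
      .data$iarc_group == "G3" & .data$iris_status == "noncancer" ~ "consistent",
      TRUE ~ "inconsistent"
    ))
}

#' Cross-database consistency of IARC and IRIS verdicts
#'
#' Compares the binary carcinogenicity verdicts of the two databases for
#' chemicals present in both. Under the default correspondence table, IARC
#' Groups 1/2A/2B agree with any IRIS cancer descriptor (carcinogen,
#' likely, probable, possible, or suggestive evidence) and IARC Group 3
#' agrees with IRIS noncancer; chemicals absent or unassigned in either
#' database are `not_comparable`. The table can be replaced to encode a
#' different correspondence (e.g. treating suggestive evidence as
#' noncancer).
#'
#' @param iarc_group,iris_status Equal-length vectors of labels.
#' @param correspondence Optional tibble `iarc_group,iris_status,verdict`
#'   overriding the default; verdicts must be `consistent`, `inconsistent`
#'   or `not_comparable`.
#' @return Character vector over `{consistent, inconsistent,
#'   not_comparable}`.
#' @export
consistency_check <- function(iarc_group, iris_status, correspondence = NULL) {
  if (length(iarc_group) != length(iris_status)) {
    abort("`iarc_group` and `iris_status` must have equal length")
  }
  tab <- correspondence %||% default_correspondence()
  stopifnot_cols(tab, c("iarc_group", "iris_status", "verdict"), "correspondence table")
  key <- paste(as.character(iarc_group), as.character(iris_status), sep = "\r")
  verdict <- tab$verdict[match(key, paste(tab$iarc_group, tab$iris_status, sep = "\r"))]
  if (anyNA(verdict)) abort("label combination missing from the correspondence table")
  verdict
}

#' Database coverage summary over a classified registry
#'
#' Tallies each IARC group and IRIS status, as counts and percentages, over
#' two explicit denominators: the whole registry and the subset present in
#' the respective database. This reproduces coverage statements such as
#' "89.27% of additives are absent from IARC" (registry denominator) and
#' "37.1% of IARC-present additives are Group 2B" (present denominator).
#'
#' @param registry Tibble with one row per CAS and columns `iarc_group`
#'   and/or `iris_status`.
#' @return Tibble `database`, `level`, `count`, `n_registry`,
#'   `pct_registry`, `n_present`, `pct_present` (percentages unrounded;
#'   `pct_present` is `NA` for the `absent` level).
#' @export
coverage_summary <- function(registry) {
  if (nrow(registry) == 0) abort("cannot summarize an empty registry")
  one_db <- function(labels, levels, database) {
    x <- factor(as.character(labels), levels = levels)
    if (anyNA(x)) abort(sprintf("unknown %s label(s)", database))
    n_total <- length(x)
    n_present <- sum(x != "absent")
    counts <- table(x)
    tibble(
      database = database,
      level = names(counts),
      count = as.integer(counts),
      n_registry = n_total,
      pct_registry = 100 * as.integer(counts) / n_total,
      n_present = n_present,
      pct_present = ifelse(names(counts) == "absent", NA_real_,
                           100 * as.integer(counts) / n_present)
    )
  }
  out <- list()
  if ("iarc_group" %in% names(registry)) {
    out <- c(out, list(one_db(registry$iarc_group, iarc_levels, "IARC")))
  }
  if ("iris_status" %in% names(registry)) {
    out <- c(out, list(one_db(registry$iris_status, iris_levels, "IRIS")))
  }
  if (length(out) == 0) abort("registry has neither `iarc_group` nor `iris_status`")
  bind_rows(out)
}
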