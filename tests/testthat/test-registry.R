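make_records <- function(...) {
  rows <- list(...)
  tibble::tibble(
    cas = vapply(rows, `[[`, character(1), "cas"),
    name = vapply(rows, `[[`, character(1), "name"),
    aliases = lapply(rows, function(r) r$aliases %||% character()),
    confidence = factor(vapply(rows, `[[`, character(1), "confidence"),
                        levels = c("unknown", "low", "medium", "high"),
                        ordered = TRUE),
    functions = lapply(rows, function(r) r$functions %||% character()),
    polymers = lapply(rows, function(r) r$polymers %||% character()),
    products = lapply(rows, function(r) r$products %||% character())
  )
}
`%||%` <- rlang::`%||%`

test_that("merging keeps the highest confidence and unions annotations", {
  recs <- make_records(
    list(cas = "50-00-0", name = "formaldehyde", confidence = "medium",
         functions = c("preservative"), polymers = c("PUR")),
    list(cas = "50-00-0", name = "methanal", confidence = "high",
         functions = c("biocide"), polymers = c("PVC"))
  )
  m <- merge_source_records(recs)
  expect_equal(nrow(m), 1)
  expect_equal(as.character(m$confidence), "high")
  expect_equal(m$name, "methanal")
  expect_setequal(m$aliases[[1]], "formaldehyde")
  expect_setequal(m$functions[[1]], c("preservative", "biocide"))
  expect_setequal(m$polymers[[1]], c("PUR", "PVC"))
})

test_that("name ties between equal-confidence records break lexicographically", {
  recs <- make_records(
    list(cas = "80-05-7", name = "bisphenol A", confidence = "high"),
    list(cas = "80-05-7", name = "BPA", confidence = "high")
  )
  m <- merge_source_records(recs)
  expect_equal(m$name, "BPA")
  expect_true("bisphenol A" %in% m$aliases[[1]])
})

test_that("merge is idempotent and order-invariant; errors are raised", {
  recs <- make_records(
    list(cas = "900-95-8", name = "phentin acetate", confidence = "low",
         products = "sealants"),
    list(cas = "900-95-8", name = "fentin acetate", confidence = "medium",
         products = "paints"),
    list(cas = "900-95-8", name = "acetoxytriphenylstannane", confidence = "unknown")
  )
  once <- merge_source_records(recs)
  expect_equal(merge_source_records(once), once)
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(merge_source_records(recs[perm, ]), once)
  }
  single <- recs[1, ]
  merged_single <- merge_source_records(single)
  expect_equal(merged_single$name, single$name)
  expect_equal(merged_single$confidence, single$confidence)
  expect_error(merge_source_records(recs[0, ]), "empty")
  mixed <- make_records(
    list(cas = "50-00-0", name = "a", confidence = "high"),
    list(cas = "80-05-7", name = "b", confidence = "high")
  )
  expect_error(merge_source_records(mixed), "share one CAS")
  expect_equal(nrow(merge_registry(mixed)), 2)
})

rules_fixture <- tibble::tibble(
  category = c("clothing", "bathroom"),
  positive = list(c("cloth", "coat"), c("shower", "sanitary")),
  negative = list("tablecloth", character())
)

test_that("negative search strings veto product category matches", {
  expect_equal(categorize_products("tablecloth", rules_fixture), character())
  expect_setequal(categorize_products(c("shower curtain", "raincoat"), rules_fixture),
                  c("bathroom", "clothing"))
  expect_equal(categorize_products(character(), rules_fixture), character())
  expect_equal(categorize_products("Lab COAT", rules_fixture), "clothing")
})

test_that("adding a positive string never removes a category", {
  set.seed(11)
  vocab <- c("cloth", "coat", "shower", "toy", "film", "pipe", "bag")
  for (i in 1:20) {
    prods <- sample(vocab, 3, replace = TRUE)
    rules <- tibble::tibble(
      category = "c1",
      positive = list(sample(vocab, 2)),
      negative = list(character())
    )
    before <- categorize_products(prods, rules)
    rules$positive[[1]] <- c(rules$positive[[1]], sample(vocab, 1))
    after <- categorize_products(prods, rules)
    expect_true(all(before %in% after))
  }
})

test_that("registry CSV round-trips and invalid CAS rows are quarantined", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "cas,name,confidence,functions,polymers,products",
    "50-00-0,formaldehyde,high,biocide|preservative,PUR,car seats",
    "0900-95-8,phentin acetate,medium,,PVC,paints|sealants",
    "50-00-1,badchem,low,,,"
  ), csv)
  rej <- tempfile(fileext = ".csv")
  expect_warning(reg <- read_registry(csv, rejects = rej), "quarantined")
  expect_equal(reg$cas, c("50-00-0", "900-95-8"))  # leading zero stripped
  expect_equal(reg$functions[[1]], c("biocide", "preservative"))
  expect_equal(reg$products[[2]], c("paints", "sealants"))
  rejected <- readr::read_csv(rej, show_col_types = FALSE)
  expect_equal(rejected$cas, "50-00-1")
  expect_true(all(cas_is_valid(merge_registry(reg)$cas)))
})

test_that("rule CSV parsing requires positives and tolerates empty negatives", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "category,kind,string",
    "clothing,positive,cloth",
    "clothing,negative,tablecloth",
    "bathroom,positive,shower"
  ), csv)
  rules <- read_category_rules(csv)
  expect_setequal(rules$category, c("clothing", "bathroom"))
  writeLines(c("category,kind,string", "food,negative,drink"), csv)
  expect_error(read_category_rules(csv), "positive")
})

test_that("usage summaries exclude zero-association additives from distributions", {
  reg <- make_records(
    list(cas = "50-00-0", name = "a", confidence = "high",
         polymers = c("PVC"), functions = c("f1", "f2"), products = "toys"),
    list(cas = "80-05-7", name = "b", confidence = "high",
         polymers = c("PVC", "PET"), functions = "f1", products = character()),
    list(cas = "900-95-8", name = "c", confidence = "high",
         polymers = c("PS", "PP", "PUR"), functions = character(), products = "bags")
  )
  s <- summarize_usage(reg)
  pol <- s$distributions$n[s$distributions$dimension == "polymers"]
  expect_equal(mean(pol), 2)          # 1, 2, 3 polymers/additive
  prod <- s$distributions$n[s$distributions$dimension == "products"]
  expect_equal(length(prod), 2)       # additive b has none and is excluded
  top_pol <- s$top_items[s$top_items$dimension == "polymers", ]
  expect_equal(top_pol$item[1], "PVC")
  expect_equal(top_pol$n_additives[1], 2)
})

test_that("usage counts agree with the generator's ground-truth tallies", {
  cfg <- simulate_config(n_chemicals = 150, seed = 3)
  gen <- generate_registry(cfg)
  s <- summarize_usage(gen$registry)
  expect_equal(s$per_additive$n_polymers, unname(gen$tallies$usage$polymers))
  expect_equal(s$per_additive$n_functions, unname(gen$tallies$usage$functions))
  expect_equal(sum(s$distributions$dimension == "products"),
               sum(gen$tallies$usage$products > 0))
})
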