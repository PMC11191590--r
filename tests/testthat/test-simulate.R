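test_that("generator output is reproducible and label draws follow proportions", {
  cfg <- simulate_config(n_chemicals = 400, seed = 8)
  g1 <- generate_registry(cfg)
  g2 <- generate_registry(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$registry), 400)
  expect_true(all(cas_is_valid(g1$registry$cas)))
  expect_equal(anyDuplicated(g1$registry$cas), 0L)
  # absent count within binomial tolerance of the configured proportion
  p_abs <- cfg$class_proportions[["absent"]]
  n_abs <- sum(g1$registry$iarc_group == "absent")
  expect_lt(abs(n_abs - 400 * p_abs), 4 * sqrt(400 * p_abs * (1 - p_abs)))
  # degenerate proportions: everything absent
  cfg0 <- simulate_config(
    n_chemicals = 50,
    class_proportions = c(G1 = 0, G2A = 0, G2B = 0, G3 = 0,
                          present_unassigned = 0, absent = 1),
    seed = 8)
  expect_true(all(generate_registry(cfg0)$registry$iarc_group == "absent"))
  expect_error(simulate_config(class_proportions = c(absent = 0.5)), "sum to 1")
})

test_that("gene sets honor sizes, disjointness and keyword naming", {
  cfg <- simulate_config(n_chemicals = 30, n_genes = 3000, n_pathways = 30,
                         pathway_size_range = c(10, 10), overlap = "disjoint",
                         keyword_fraction = 0.5, seed = 21)
  gs <- generate_gene_sets(cfg)
  expect_true(all(gs$sets$size == 10))
  all_genes <- unlist(gs$sets$genes)
  expect_equal(anyDuplicated(all_genes), 0L)  # pairwise disjoint
  # signatures: 3 clusters x 3 sets, cancer-keyword names, cancer source
  sig_ids <- unlist(gs$signature_sets)
  expect_length(sig_ids, 9)
  sig <- gs$sets[gs$sets$set_id %in% sig_ids, ]
  expect_true(all(sig$source == "WikipathwaysCancer"))
  kw <- c("cancer", "carcin", "metasta", "tumor")
  has_kw <- function(nm) any(vapply(kw, grepl, logical(1), x = tolower(nm), fixed = TRUE))
  expect_true(all(vapply(sig$name, has_kw, logical(1))))
  # about half the decoys carry a keyword
  decoys <- gs$sets[!gs$sets$set_id %in% sig_ids, ]
  frac <- mean(vapply(decoys$name, has_kw, logical(1)))
  expect_gt(frac, 0.2); expect_lt(frac, 0.8)
  expect_error(
    generate_gene_sets(simulate_config(n_genes = 50, n_pathways = 20,
                                       pathway_size_range = c(10, 10),
                                       overlap = "disjoint", seed = 1)),
    "infeasible")
})

test_that("planted chemicals draw their genes from their cluster signatures", {
  cfg <- simulate_config(n_chemicals = 30, interacting_fraction = 1,
                         n_genes = 3000, n_pathways = 12,
                         pathway_size_range = c(30, 60),
                         signal_fraction = 1, nonhuman_fraction = 0,
                         genes_per_chemical_range = c(20, 40),
                         overlap = "disjoint", seed = 13)
  sim <- simulate_screen(cfg)
  sig_genes <- lapply(sim$truth$signature_sets, function(ids) {
    sort(unique(unlist(sim$sets$genes[match(ids, sim$sets$set_id)])))
  })
  for (i in seq_len(nrow(sim$truth$cluster_of))) {
    chem <- sim$truth$cluster_of$cas[i]
    cl <- sim$truth$cluster_of$cluster[i]
    genes <- unique(sim$interactions$gene_id[sim$interactions$cas == chem])
    expect_true(all(genes %in% sig_genes[[cl]]))
  }
  # per-chemical gene counts match the generator's tally
  counts <- table(sim$interactions$cas)
  expect_equal(as.integer(counts[names(sim$truth$genes_per_chemical)]),
               unname(sim$truth$genes_per_chemical))
})

test_that("nonhuman relabeling is reversible through the ortholog map", {
  cfg <- simulate_config(n_chemicals = 40, interacting_fraction = 1,
                         n_genes = 2000, n_pathways = 12,
                         pathway_size_range = c(20, 40),
                         nonhuman_fraction = 0.3,
                         ortholog_multiplicity = c(0, 1),  # always 2 matches
                         genes_per_chemical_range = c(20, 40), seed = 5)
  sim <- simulate_screen(cfg)
  nonhuman <- sim$interactions$organism != "human"
  expect_gt(sum(nonhuman), 0)
  expect_true(all(sim$interactions$gene_id[nonhuman] > 1e8))
  expect_true(all(sim$interactions$gene_id[nonhuman] %in% sim$ortholog_map$source_gene_id))
  # every surrogate maps to exactly 2 human genes
  mult <- table(sim$ortholog_map$source_gene_id)
  expect_true(all(mult == 2))
  out <- remap_orthologs(sim$interactions, sim$ortholog_map)
  expect_equal(nrow(out$unmapped), 0)
  expect_true(all(out$remapped$gene_id <= cfg$n_genes))
  # with multiplicity 2 the remapped table grows (pre-dedup ~ 1.3x)
  expect_gt(nrow(out$remapped), nrow(sim$interactions))
})

test_that("simulated files round-trip through the package readers", {
  cfg <- simulate_config(n_chemicals = 25, interacting_fraction = 0.8,
                         n_genes = 1000, n_pathways = 10,
                         pathway_size_range = c(10, 20),
                         genes_per_chemical_range = c(10, 20), seed = 33)
  sim <- simulate_screen(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  reg <- read_registry(file.path(dir, "registry.csv"))
  expect_equal(sort(reg$cas), sort(sim$registry$cas))
  ints <- read_interactions(file.path(dir, "interactions.csv"))
  expect_equal(nrow(ints), nrow(sim$interactions))
  gmt <- read_gmt(file.path(dir, "sets.gmt"))
  expect_equal(gmt$set_id, sim$sets$set_id)
  expect_equal(lapply(gmt$genes, as.integer), sim$sets$genes)
  if (nrow(sim$ortholog_map) > 0) {
    om <- read_ortholog_map(file.path(dir, "orthologs.tsv"))
    expect_equal(om, sim$ortholog_map)
  }
})
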