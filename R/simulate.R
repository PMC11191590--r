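#' Configuration for the synthetic toxicogenomic screen generator
#'
#' Defaults emulate the composition of the real screen: 2,712 additives
#' with the IARC tallies 23 (Group 1) / 36 (2A) / 108 (2B) / 112 (3) / 12
#' (present, unassigned) and the rest absent; an IRIS breakdown of
#' 9/11/22/3/2 cancer descriptors plus 122 noncancer of 169 present; 428
#' of 2,712 chemicals carrying gene-interaction records; a 13,049-gene
#' background; gene sets of 10-2,000 members (log-uniform sizes);
#' 10-500 genes per interacting chemical (log-uniform); up/down assigned
#' 0.5/0.5 independently per record; 5% of records relabeled with
#' surrogate nonhuman gene IDs (ortholog multiplicity 1/2/3 with
#' probability 0.80/0.15/0.05). Planted structure: chemicals with
#' interactions are split evenly among `n_planted_clusters` clusters, and
#' a fraction `signal_fraction` of each chemical's genes is drawn from its
#' cluster's signature gene sets (disjoint across clusters), the rest
#' uniformly from the universe; `signal_fraction = 0` is the pure-noise
#' null.
#'
#' @param n_chemicals Registry size.
#' @param class_proportions Named probabilities over [iarc_levels]
#'   (must sum to 1).
#' @param iris_proportions Named probabilities over [iris_levels].
#' @param interacting_fraction Fraction of chemicals with >= 1 interaction
#'   record.
#' @param n_genes Human gene universe size (IDs 1..n_genes).
#' @param n_pathways Number of gene sets, including signatures.
#' @param pathway_size_range Inclusive set-size range.
#' @param n_planted_clusters Number of planted chemical clusters (0 for
#'   none).
#' @param signatures_per_cluster Signature gene sets per cluster.
#' @param signal_fraction f in \[0, 1\]: fraction of an interacting
#'   chemical's genes drawn from its cluster's signatures.
#' @param genes_per_chemical_range Inclusive range of genes per
#'   interacting chemical.
#' @param direction_prob_up Probability a record is upregulation.
#' @param nonhuman_fraction Fraction of records relabeled with surrogate
#'   nonhuman IDs (exercises ortholog remapping).
#' @param ortholog_multiplicity Probability vector: element i is the
#'   probability a surrogate maps to i human genes.
#' @param keyword_fraction Fraction of decoy pathway names seeded with a
#'   cancer keyword (signature names always carry one).
#' @param overlap `"random"` (decoy sets sampled independently) or
#'   `"disjoint"` (all sets pairwise disjoint).
#' @param seed Integer seed; every generator draw flows from it.
#' @return A list of class `sim_config`.
#' @export
simulate_config <- function(
    n_chemicals = 2712,
    class_proportions = c(G1 = 23, G2A = 36, G2B = 108, G3 = 112,
                          present_unassigned = 12, absent = 2421) / 2712,
    iris_proportions = c(carcinogen = 9, likely_carcinogen = 11,
                         probable_carcinogen = 22, possible_carcinogen = 3,
                         suggestive = 2, noncancer = 122, absent = 2543) / 2712,
    interacting_fraction = 428 / 2712,
    n_genes = 13049,
    n_pathways = 500,
    pathway_size_range = c(10, 2000),
    n_planted_clusters = 3,
    signatures_per_cluster = 3,
    signal_fraction = 0.9,
    genes_per_chemical_range = c(10, 500),
    direction_prob_up = 0.5,
    nonhuman_fraction = 0.05,
    ortholog_multiplicity = c(0.80, 0.15, 0.05),
    keyword_fraction = 0.3,
    overlap = c("random", "disjoint"),
    seed = 1L) {
  overlap <- match.arg(overlap)
  if (abs(sum(class_proportions) - 1) > 1e-8) abort("class_proportions must sum to 1")
  if (abs(sum(iris_proportions) - 1) > 1e-8) abort("iris_proportions must sum to 1")
  if (!setequal(names(class_proportions), iarc_levels)) {
    abort("class_proportions must be named over the IARC levels")
  }
  if (signal_fraction < 0 || signal_fraction > 1) abort("signal_fraction must be in [0, 1]")
  if (pathway_size_range[1] < 1 || diff(pathway_size_range) < 0) {
    abort("invalid pathway_size_range")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Scaled generator presets for pipeline validation
#'
#' `strong_signal_config()` is the desk-scale strong-signal condition used
#' to validate cluster recovery: 3 planted clusters of 32 chemicals each
#' (96 chemicals, all with interactions), disjoint signatures, signal
#' fraction 0.9, a 2,000-gene universe, 45 gene sets of 20-60 members and
#' 40-120 genes per chemical. `null_config()` is the matching no-signal
#' null (f = 0) over 240 chemicals, used to check false-discovery
#' behavior.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
strong_signal_config <- function(seed = 1L) {
  simulate_config(
    n_chemicals = 96, interacting_fraction = 1,
    n_genes = 2000, n_pathways = 45, pathway_size_range = c(20, 60),
    n_planted_clusters = 3, signatures_per_cluster = 3,
    signal_fraction = 0.9, genes_per_chemical_range = c(40, 120),
    overlap = "disjoint", seed = seed
  )
}

#' @rdname strong_signal_config
#' @export
null_config <- function(seed = 1L) {
  cfg <- strong_signal_config(seed)
  cfg$n_chemicals <- 240
  cfg$signal_fraction <- 0
  cfg
}

cancer_keywords_pool <- c("Cancer", "Carcinoma", "Metastasis", "Tumor")

rint_loguniform <- function(n, range) {
  lo <- log(range[1])
  hi <- log(range[2] + 1)
  pmin(range[2], floor(exp(runif(n, lo, hi))))
}

#' Generate a synthetic additive registry
#'
#' Draws `n_chemicals` check-digit-valid CAS numbers with IARC and IRIS
#' labels sampled independently per chemical from the configured
#' proportions, and usage annotations (functions, polymers, products)
#' sampled from small vocabularies with some chemicals left unannotated.
#' Deterministic for a fixed config seed.
#'
#' @param config A [simulate_config()].
#' @return List: `registry` (tibble `cas`, `name`, `confidence`, usage
#'   list-columns, `iarc_group`, `iris_status`, plus `is_carcinogen` /
#'   `is_classified`) and `tallies` (ground-truth label counts).
#' @export
generate_registry <- function(config) {
  withr::with_seed(config$seed, {
    n <- config$n_chemicals
    body <- sample(1000:9999999, n)
    cas <- cas_from_body(as.character(body))
    iarc <- sample(names(config$class_proportions), n, replace = TRUE,
                   prob = config$class_proportions)
    iris <- sample(names(config$iris_proportions), n, replace = TRUE,
                   prob = config$iris_proportions)
    vocab_fun <- c("plasticizer", "flame retardant", "colorant", "stabilizer",
                   "filler", "lubricant", "antioxidant", "processing aid")
    vocab_pol <- c("PVC", "PET", "PP", "PS", "PUR", "LDPE", "HDPE", "latex")
    vocab_prod <- c("food packaging", "toys", "raincoat", "shower curtain",
                    "flooring", "medical tubing", "electronics", "furniture")
    draw <- function(vocab, lambda) {
      k <- stats::rpois(n, lambda)
      lapply(k, function(m) sort(sample(vocab, min(m, length(vocab)))))
    }
    registry <- tibble(
      cas = cas,
      name = sprintf("additive-%05d", seq_len(n)),
      aliases = replicate(n, character(), simplify = FALSE),
      confidence = factor(sample(confidence_levels, n, replace = TRUE,
                                 prob = c(0.05, 0.1, 0.25, 0.6)),
                          levels = confidence_levels, ordered = TRUE),
      functions = draw(vocab_fun, 2),
      polymers = draw(vocab_pol, 2.4),
      products = draw(vocab_prod, 1.5),
      iarc_group = iarc,
      iris_status = iris
    ) |> bind_cols(derive_class(iarc)[, c("is_carcinogen", "is_classified")])
    tallies <- list(
      iarc = table(factor(iarc, levels = iarc_levels)),
      iris = table(factor(iris, levels = iris_levels)),
      usage = list(polymers = lengths(registry$polymers),
                   functions = lengths(registry$functions),
                   products = lengths(registry$products))
    )
    list(registry = registry, tallies = tallies)
  })
}

#' Generate a synthetic gene-set collection with planted signatures
#'
#' The first `n_planted_clusters * signatures_per_cluster` sets are the
#' cluster signatures, carved from disjoint blocks of the universe and
#' named with cancer keywords (source "WikipathwaysCancer"); the remaining
#' decoy sets are sampled from the universe (independently, or from
#' disjoint blocks under `overlap = "disjoint"`), with a configurable
#' fraction of keyword-bearing decoy names.
#'
#' @param config A [simulate_config()].
#' @return List: `sets` (gene-set tibble as from [read_gmt()]),
#'   `signature_sets` (list: cluster -> set_ids), `background`
#'   (the gene universe `1:n_genes`).
#' @export
generate_gene_sets <- function(config) {
  withr::with_seed(config$seed + 1L, {
    universe <- seq_len(config$n_genes)
    n_sig <- config$n_planted_clusters * config$signatures_per_cluster
    if (n_sig > config$n_pathways) abort("more signature sets than pathways")
    sizes <- rint_loguniform(config$n_pathways, config$pathway_size_range)
    sig_total <- sum(sizes[seq_len(n_sig)])
    disjoint_total <- if (config$overlap == "disjoint") sum(sizes) else sig_total
    if (disjoint_total > config$n_genes) {
      abort("pathway size range infeasible for the universe (disjoint sets)")
    }
    pool <- sample(universe)  # shuffled once; blocks are disjoint by construction
    offset <- 0
    genes <- vector("list", config$n_pathways)
    for (i in seq_len(config$n_pathways)) {
      if (i <= n_sig || config$overlap == "disjoint") {
        genes[[i]] <- sort(pool[offset + seq_len(sizes[i])])
        offset <- offset + sizes[i]
      } else {
        genes[[i]] <- sort(sample(universe, sizes[i]))
      }
    }
    is_sig <- seq_len(config$n_pathways) <= n_sig
    kw <- sample(cancer_keywords_pool, config$n_pathways, replace = TRUE)
    decoy_kw <- runif(config$n_pathways) < config$keyword_fraction
    name <- ifelse(is_sig, sprintf("%s Signaling Pathway S%02d", kw, seq_len(config$n_pathways)),
            ifelse(decoy_kw, sprintf("%s Related Process P%03d", kw, seq_len(config$n_pathways)),
                   sprintf("Housekeeping Process P%03d", seq_len(config$n_pathways))))
    sources <- c("PANTHER", "Reactome", "KEGG", "Wikipathways")
    sets <- tibble(
      set_id = sprintf("SET%04d", seq_len(config$n_pathways)),
      name = name,
      source = ifelse(is_sig, "WikipathwaysCancer",
                      sources[(seq_len(config$n_pathways) %% 4) + 1]),
      genes = genes,
      size = lengths(genes)
    )
    signature_sets <- NULL
    if (config$n_planted_clusters > 0) {
      signature_sets <- split(sets$set_id[is_sig],
                              rep(seq_len(config$n_planted_clusters),
                                  each = config$signatures_per_cluster))
    }
    list(sets = sets, signature_sets = signature_sets, background = universe)
  })
}

#' Generate chemical-gene interaction records with planted cluster signal
#'
#' Chemicals with interactions are assigned round-robin to the planted
#' clusters. Each draws its gene count from the configured range; a
#' fraction `signal_fraction` of those genes comes from the union of its
#' cluster's signature sets and the rest uniformly from the remaining
#' universe. Directions are assigned independently; a configured fraction
#' of records is relabeled with surrogate nonhuman gene IDs (offset by
#' 10^8) and entered in the ortholog map with the configured multiplicity,
#' to exercise remapping.
#'
#' @param registry Registry tibble from [generate_registry()].
#' @param gene_sets Output of [generate_gene_sets()].
#' @param config The same [simulate_config()].
#' @return List: `interactions` (tibble `cas,gene_id,gene_symbol,organism,
#'   direction`), `ortholog_map` (tibble `source_gene_id,human_entrez_id`),
#'   `cluster_of` (tibble `cas`, `cluster`; `NA` cluster for chemicals
#'   without planted membership), `genes_per_chemical` (named counts, the
#'   generator's tally before nonhuman relabeling).
#' @export
generate_interactions <- function(registry, gene_sets, config) {
  withr::with_seed(config$seed + 2L, {
    n_int <- round(config$interacting_fraction * nrow(registry))
    chems <- sort(sample(registry$cas, n_int))
    k_cl <- config$n_planted_clusters
    cluster <- if (k_cl > 0) rep_len(seq_len(k_cl), n_int) else rep(NA_integer_, n_int)
    universe <- gene_sets$background
    sig_union <- lapply(seq_len(max(k_cl, 1)), function(cl) {
      if (k_cl == 0) return(integer())
      ids <- gene_sets$signature_sets[[cl]]
      sort(unique(unlist(gene_sets$sets$genes[match(ids, gene_sets$sets$set_id)])))
    })
    m <- rint_loguniform(n_int, config$genes_per_chemical_range)
    rows <- purrr::map(seq_len(n_int), function(i) {
      pool <- if (!is.na(cluster[i])) sig_union[[cluster[i]]] else integer()
      k_sig <- min(ceiling(config$signal_fraction * m[i]), length(pool))
      sig_genes <- if (k_sig > 0) sample(pool, k_sig) else integer()
      noise_pool <- setdiff(universe, sig_genes)
      noise_genes <- sample(noise_pool, m[i] - k_sig)
      genes <- c(sig_genes, noise_genes)
      tibble(
        cas = chems[i],
        gene_id = as.integer(genes),
        direction = ifelse(runif(m[i]) < config$direction_prob_up, "up", "down")
      )
    })
    interactions <- bind_rows(rows) |>
      mutate(gene_symbol = sprintf("GENE%d", .data$gene_id), organism = "human",
             .after = "gene_id")
    # relabel a fraction as nonhuman surrogates and build the ortholog map
    offset <- 100000000L
    flip <- runif(nrow(interactions)) < config$nonhuman_fraction
    surrogates <- unique(interactions$gene_id[flip])
    map <- tibble(source_gene_id = integer(), human_entrez_id = integer())
    if (length(surrogates) > 0) {
      mult <- sample(seq_along(config$ortholog_multiplicity), length(surrogates),
                     replace = TRUE, prob = config$ortholog_multiplicity)
      map <- purrr::map2(surrogates, mult, function(g, k) {
        extra <- if (k > 1) sample(setdiff(universe, g), k - 1) else integer()
        tibble(source_gene_id = g + offset,
               human_entrez_id = as.integer(c(g, extra)))
      }) |> bind_rows()
      interactions <- interactions |>
        mutate(
          organism = ifelse(flip, "mouse", .data$organism),
          gene_id = ifelse(flip, .data$gene_id + offset, .data$gene_id)
        )
    }
    list(
      interactions = interactions,
      ortholog_map = map,
      cluster_of = tibble(cas = chems, cluster = cluster),
      genes_per_chemical = setNames(m, chems)
    )
  })
}

#' Run the whole generator
#'
#' Convenience wrapper producing every input the pipeline consumes plus
#' the ground truth, all deterministic under `config$seed`.
#'
#' @param config A [simulate_config()].
#' @return List: `registry`, `sets`, `interactions`, `ortholog_map`,
#'   `background`, `truth` (list: `cluster_of`, `signature_sets`,
#'   `tallies`, `genes_per_chemical`).
#' @export
simulate_screen <- function(config) {
  reg <- generate_registry(config)
  gs <- generate_gene_sets(config)
  int <- generate_interactions(reg$registry, gs, config)
  list(
    registry = reg$registry,
    sets = gs$sets,
    interactions = int$interactions,
    ortholog_map = int$ortholog_map,
    background = gs$background,
    truth = list(cluster_of = int$cluster_of,
                 signature_sets = gs$signature_sets,
                 tallies = reg$tallies,
                 genes_per_chemical = int$genes_per_chemical)
  )
}

#' Write a simulated screen to the pipeline's file dialects
#'
#' Emits registry.csv (multi-valued cells pipe-delimited),
#' interactions.csv, sets.gmt, orthologs.tsv, labels.csv and
#' cluster_of.csv under `dir`.
#'
#' @param sim Output of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- sim$registry |>
    mutate(functions = collapse_multi(.data$functions),
           polymers = collapse_multi(.data$polymers),
           products = collapse_multi(.data$products)) |>
    select("cas", "name", "confidence", "functions", "polymers", "products")
  readr::write_csv(reg, file.path(dir, "registry.csv"))
  readr::write_csv(sim$interactions, file.path(dir, "interactions.csv"))
  readr::write_csv(select(sim$registry, "cas", "iarc_group", "iris_status"),
                   file.path(dir, "labels.csv"))
  readr::write_tsv(sim$ortholog_map, file.path(dir, "orthologs.tsv"))
  readr::write_csv(sim$truth$cluster_of, file.path(dir, "cluster_of.csv"))
  gmt <- vapply(seq_len(nrow(sim$sets)), function(i) {
    paste(c(sim$sets$set_id[i], sim$sets$name[i], sim$sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(gmt, file.path(dir, "sets.gmt"))
  invisible(dir)
}
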