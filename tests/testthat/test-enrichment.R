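test_that("GMT parsing dedups members and reports malformed lines", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c(
    "WP530\tcytokines and inflammatory response\tIL6\tCXCL8",
    "",
    "WP143\tfatty acid beta-oxidation\tACADM\tACADM\tHADHA"
  ), gmt)
  sets <- read_gmt(gmt, source = "Wikipathways")
  expect_equal(sets$set_id, c("WP530", "WP143"))
  expect_equal(sets$size, c(2L, 2L))  # duplicate ACADM collapsed
  writeLines(c("ok\tdesc\tG1", "short\tonlydesc"), gmt)
  expect_error(read_gmt(gmt), "line 2", class = "plastitox_gmt_parse")
})

test_that("gene-set filtering intersects with the background first", {
  sets <- tibble::tibble(
    set_id = c("A", "B", "C"),
    name = c("a", "b", "c"),
    source = "KEGG",
    genes = list(1:9, 1:15, 101:110),
    size = c(9L, 15L, 10L)
  )
  bg <- c(1:8, 101:200)
  out <- filter_gene_sets(sets, bg, min_size = 10, max_size = 2000)
  # A has 9 genes (< 10); B intersects to 8 (< 10); C keeps its 10
  expect_equal(out$set_id, "C")
  expect_equal(out$size, 10L)
  out2 <- filter_gene_sets(sets, 1:1000, min_size = 10, max_size = 14)
  expect_equal(out2$set_id, "C")  # B (15) now exceeds the max
})

test_that("ora_test matches the printed ER formula and degenerate tails", {
  r <- ora_test(1:5, 3:12, 1:100)
  expect_equal(r$expect, 5 * 10 / 100)
  expect_equal(r$er, r$overlap / r$expect)
  expect_equal(r$overlap, 3)
  # zero overlap: p = P(X >= 0) = 1, ER = 0
  r0 <- ora_test(1:5, 50:59, 1:100)
  expect_equal(r0$p, 1)
  expect_equal(r0$er, 0)
  expect_error(ora_test(integer(), 1:5, 1:10), "no input genes")
})

test_that("hypergeometric p equals exhaustive enumeration for small backgrounds", {
  # spec-style case: background 10, set 5, input 4, full overlap
  r <- ora_test(1:4, 1:5, 1:10)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  expect_equal(r$p, hyper_p_enum(4, m = 5, k = 4, N = 10), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    m <- sample(1:(N - 1), 1)
    k <- sample(1:(N - 1), 1)
    input <- sample(N, k)
    r <- ora_test(input, seq_len(m), seq_len(N))
    expect_equal(r$p, hyper_p_enum(r$overlap, m, k, N), tolerance = 1e-12)
  }
})

test_that("p decreases in overlap and ER is scale-invariant", {
  ps <- vapply(1:5, function(ov) {
    set_genes <- c(seq_len(ov), 100 + seq_len(10 - ov))  # overlap = ov, size 10
    ora_test(1:20, set_genes, 1:200)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  r1 <- ora_test(1:10, 6:25, 1:200)
  r2 <- ora_test(1:20, c(11:50), 1:400)  # everything doubled
  expect_equal(r2$er, r1$er)
})

test_that("BH adjustment reproduces the step-up oracle and rejection sets", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.5), 0.5)
  expect_error(adjust_fdr(c(0.5, 0)), "0, 1")
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    q <- adjust_fdr(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # the q <= alpha set equals the classic step-up rejection set
    for (alpha in c(0.05, 0.25)) {
      m <- length(p)
      ord <- order(p)
      passes <- which(p[ord] <= alpha * seq_len(m) / m)
      rejected <- if (length(passes)) ord[seq_len(max(passes))] else integer()
      expect_setequal(which(q <= alpha), rejected)
    }
  }
})

test_that("per-chemical enrichment gates on FDR and sorts deterministically", {
  set.seed(23)
  bg <- 1:1000
  signal <- 1:10
  decoys <- lapply(1:200, function(i) sample(11:1000, 10))
  sets <- tibble::tibble(
    set_id = sprintf("S%03d", 0:200),
    name = sprintf("set %d", 0:200),
    source = "KEGG",
    genes = c(list(signal), decoys),
    size = 10L
  )
  res <- enrich_chemical("50-00-0", signal, sets, bg)
  expect_true("S000" %in% res$set_id)
  expect_equal(res$set_id[1], "S000")  # minimal p sorts first
  expect_true(all(res$fdr <= 0.25))
  expect_true(all(res$fdr >= res$p))
  # permuting the collection order leaves the result unchanged
  perm <- sample(nrow(sets))
  res_perm <- enrich_chemical("50-00-0", signal, sets[perm, ], bg)
  expect_equal(res_perm, res)
  # input disjoint from every set
  res_none <- enrich_chemical("50-00-0", 900:950, sets[1:5, ], bg)
  expect_equal(nrow(res_none), 0)
})

test_that("a planted prostate-style fixture yields exactly its six pathways", {
  # five input genes; six planted sets each fully contained in the input;
  # decoys disjoint from it (mirrors an additive enriching 6 pathways)
  bg <- 1:1000
  input <- 1:5
  planted <- lapply(1:6, function(i) c(1:5, 100 + (1:10) + 10 * i))
  decoys <- lapply(1:50, function(i) 500 + (1:12) + 9 * i)
  sets <- tibble::tibble(
    set_id = sprintf("P%02d", seq_along(c(planted, decoys))),
    name = c(rep("prostate signaling", 6), rep("decoy", 50)),
    source = "Wikipathways",
    genes = c(planted, decoys),
    size = lengths(c(planted, decoys))
  )
  res <- enrich_chemical("900-95-8", input, sets, bg)
  expect_equal(nrow(res), 6)
  expect_setequal(res$set_id, sprintf("P%02d", 1:6))
})

test_that("the ER matrix places significant ratios and zero-fills the rest", {
  res <- tibble::tibble(
    cas = c("a", "b"), set_id = c("S1", "S3"), er = c(4, 2.5)
  )
  m <- build_er_matrix(res, c("a", "b"), c("S1", "S2", "S3"))
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["a", "S1"], 4)
  expect_equal(m["b", "S3"], 2.5)
  expect_equal(sum(m != 0), 2)
  expect_equal(rowSums(m), c(a = 4, b = 2.5))
  empty <- build_er_matrix(res[0, ], c("a", "b"), c("S1", "S2"))
  expect_true(all(empty == 0) && all(dim(empty) == c(2, 2)))
})
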