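# Independent oracles used to cross-check the package's statistics.

# Upper-tail hypergeometric P(X >= overlap) by exhaustive enumeration of all
# C(N, k) draws of the input from a background of size N containing the set
# {1..m}. Feasible for N <= 15.
hyper_p_enum <- function(overlap, m, k, N) {
  draws <- utils::combn(N, k)
  hits <- colSums(draws <= m)  # set members are 1..m
  mean(hits >= overlap)
}

# Literal Benjamini-Hochberg step-up: sort, q_(i) = min_{j >= i} p_(j) m / j,
# cap at 1, undo the sort.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    q[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# A minimal registry tibble with the given number of chemicals per IARC
# group (and optionally IRIS status), using synthetic valid CAS numbers.
make_label_registry <- function(iarc_counts, iris_counts = NULL) {
  n <- sum(iarc_counts)
  cas <- plastitox:::cas_from_body(as.character(seq(1000, length.out = n)))
  reg <- tibble::tibble(
    cas = cas,
    iarc_group = rep(names(iarc_counts), iarc_counts)
  )
  if (!is.null(iris_counts)) {
    stopifnot(sum(iris_counts) == n)
    reg$iris_status <- rep(names(iris_counts), iris_counts)
  }
  reg
}

reduced_grid <- function() {
  cluster_grid(n_neighbors = c(5, 10, 15), min_dist = c(0, 0.5),
               k_range = 3:10, seeds = 0:4)
}
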