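# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ranks are computed by pairwise counting, exact
# test probabilities from binomial coefficients.

# brute-force directed mean-rank score: fractional ranks by pairwise
# comparison counting, decreasing rank as G + 1 - increasing rank
oracle_directed_score <- function(x, weights) {
  G <- length(x)
  rank_of <- function(g) sum(x < x[g]) + (sum(x == x[g]) + 1) / 2
  present <- intersect(names(weights), names(x))
  dr <- vapply(present, function(g) {
    r <- rank_of(g)
    if (weights[[g]] > 0) r else G + 1 - r
  }, numeric(1))
  list(score = mean(dr), n_used = length(present))
}

# brute-force two-sided Fisher 2x2: enumerate the first cell over its
# support, table probability from binomial coefficients
oracle_fisher_2x2 <- function(tab, tol = 1e-7) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(tab[1, 1])
  min(1, sum(probs[probs <= p_obs * (1 + tol)]))
}

# random 2x2 table with no zero margins and a bounded total
random_2x2 <- function(max_total = 30) {
  repeat {
    tab <- matrix(sample.int(max_total %/% 2, 4, replace = TRUE) - 1L, 2)
    if (sum(tab) >= 1 && sum(tab) <= max_total &&
        all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      return(tab)
  }
}

# random segmented-cell table over two regions with a couple of markers
random_cell_table <- function() {
  n <- sample(0:200, 1)
  areas <- c(intratumor = runif(1, 0.5, 3), peritumor = runif(1, 0.5, 3))
  markers <- c("CD3", "CD8", "FOXP3", "ICOS", "CD39", "PD1", "GZMB", "SOX10")
  cells <- data.frame(
    x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
    region = sample(names(areas), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (mk in markers) cells[[mk]] <- sample(0:1, n, replace = TRUE)
  cell_table(cells, areas)
}

# shared small synthetic cohort for expensive tests, built once per run
planted_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulation_config(n_per_group = 24, n_genes = 2000,
                               n_signature_genes = 100, log2_effect = 1.5,
                               seed = 7)
      co <- generate_expression_cohort(sim)
      nrm <- median_of_ratios_normalize(filter_low_counts(co$matrix))
      cls <- co$truth$class_labels
      de <- differential_expression(nrm, names(cls)[cls == "PD"],
                                    names(cls)[cls == "CR"])
      cache <<- list(sim = sim, truth = co$truth, norm = nrm, de = de,
                     classes = cls)
    }
    cache
  }
})
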