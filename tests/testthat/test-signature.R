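test_that("directed gene sets validate their sign structure", {
  expect_error(directed_gene_set("s", up = "A", down = "A"), "both signs")
  expect_error(directed_gene_set("s"), "at least one gene")
  s <- directed_gene_set("s", up = c("A", "B"), down = "C")
  expect_equal(unname(s$weights[c("A", "B", "C")]), c(1, 1, -1))
})

test_that("signature construction signs genes by fold change at the padj threshold", {
  de <- data.frame(gene = c("up", "down", "ns", "weak"),
                   log2fc = c(2, -2, 3, 0.5),
                   pvalue = c(1e-4, 1e-4, 0.1, 1e-3),
                   padj = c(0.01, 0.01, 0.2, 0.04))
  sig <- build_directed_signature(de)
  expect_equal(sig$weights[["up"]], 1)
  expect_equal(sig$weights[["down"]], -1)
  expect_false("ns" %in% names(sig$weights))
  expect_true("weak" %in% names(sig$weights))
  expect_error(build_directed_signature(de, alpha = 1e-6), "empty signature")
})

test_that("directed rank score matches the stated small examples", {
  x <- c(A = 1, B = 2, C = 3)
  expect_equal(directed_rank_score(x, directed_gene_set("s", up = "C"))$score, 3)
  expect_equal(directed_rank_score(x, directed_gene_set("s", down = "A"))$score, 3)
  r <- directed_rank_score(x, directed_gene_set("s", up = c("C", "D"), down = "A"))
  expect_equal(r$score, 3)       # D absent: excluded from numerator and N
  expect_equal(r$n_used, 2L)
  expect_error(
    directed_rank_score(x, directed_gene_set("s", up = "Z")), "undefined score")
})

test_that("directed rank score equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    G <- sample(5:50, 1)
    x <- setNames(round(rnorm(G), sample(0:2, 1)), sprintf("g%d", 1:G))
    k <- sample(1:min(G, 12), 1)
    genes <- sample(names(x), k)
    n_up <- sample(0:k, 1)
    w <- setNames(c(rep(1, n_up), rep(-1, k - n_up)), genes)
    if (n_up == 0) gs <- directed_gene_set("r", down = genes)
    else if (n_up == k) gs <- directed_gene_set("r", up = genes)
    else gs <- directed_gene_set("r", up = genes[seq_len(n_up)],
                                 down = genes[-seq_len(n_up)])
    got <- directed_rank_score(x, gs)
    want <- oracle_directed_score(x, as.list(w))
    expect_equal(got$score, want$score)
    expect_equal(got$n_used, want$n_used)
  }
})

test_that("all-genes +1 set scores exactly (G+1)/2 and sign flip maps s to G+1-s", {
  set.seed(55)
  for (i in 1:25) {
    G <- sample(10:50, 1)
    x <- setNames(sample(seq_len(1000), G), sprintf("g%d", 1:G))  # tie-free
    all_up <- directed_gene_set("all", up = names(x))
    expect_equal(directed_rank_score(x, all_up)$score, (G + 1) / 2)
    k <- sample(1:G, 1)
    genes <- sample(names(x), k)
    fwd <- directed_gene_set("f", up = genes)
    rev <- directed_gene_set("r", down = genes)
    s <- directed_rank_score(x, fwd)$score
    expect_equal(directed_rank_score(x, rev)$score, G + 1 - s)
  }
})

test_that("scores are invariant under strictly increasing transforms and sample order", {
  set.seed(77)
  m <- matrix(rlnorm(100 * 6), 100, 6,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  gs <- directed_gene_set("s", up = sprintf("g%d", 1:5),
                          down = sprintf("g%d", 6:10))
  sc <- score_cohort(m, gs)
  m_cubed <- m; m_cubed[, 2] <- m_cubed[, 2]^3
  expect_equal(score_cohort(m_cubed, gs)$score, sc$score)
  perm <- sample(6)
  sc_perm <- score_cohort(m[, perm], gs)
  expect_equal(sc_perm$score[match(sc$sample, sc_perm$sample)], sc$score)
  # per-sample calls agree with the vectorized cohort path
  v <- m[, 3]; names(v) <- rownames(m)
  expect_equal(sc$score[3], directed_rank_score(v, gs)$score)
})

test_that("raising a +1 gene's expression never decreases the score", {
  set.seed(13)
  x <- setNames(runif(40), sprintf("g%d", 1:40))
  gs <- directed_gene_set("s", up = c("g1", "g2"), down = c("g3", "g4"))
  base <- directed_rank_score(x, gs)$score
  for (bump in c(0.1, 1, 10)) {
    x2 <- x; x2[["g1"]] <- x2[["g1"]] + bump
    expect_gte(directed_rank_score(x2, gs)$score, base)
  }
})

test_that("normalized and two-block scoring variants behave as documented", {
  x <- setNames(1:10, letters[1:10])
  gs <- directed_gene_set("s", up = c("i", "j"), down = c("a", "b"))
  raw <- directed_rank_score(x, gs)
  norm <- directed_rank_score(x, gs, normalize = TRUE)
  expect_equal(norm$score, (raw$score - 1) / (10 - 1))
  two <- directed_rank_score(x, gs, method = "two_block")
  expect_equal(two$score, mean(c(9, 10)) + mean(c(10, 9)))
  # monotone relation: both variants rank these two samples the same way
  y <- setNames(10:1, letters[1:10])
  expect_lt(directed_rank_score(y, gs)$score, raw$score)
  expect_lt(directed_rank_score(y, gs, method = "two_block")$score, two$score)
})

test_that("IMMU composite equals scoring the merged signed set", {
  set.seed(19)
  m <- matrix(rlnorm(60 * 4), 60, 4,
              dimnames = list(sprintf("g%d", 1:60), sprintf("s%d", 1:4)))
  eff <- list(chemokine = c("g1", "g2"), interferon_gamma = c("g3"),
              t_effector = c("g4", "g5"), t_cell_inflamed = c("g2", "g6"))
  sup <- list(b_catenin = c("g10", "g11"), tgf_beta = c("g12"),
              immunosuppression = c("g13", "g14"))
  sets <- c(lapply(eff, function(g) directed_gene_set("c", up = g)),
            lapply(sup, function(g) directed_gene_set("c", up = g)))
  composite <- immu_composite(sets)
  manual <- directed_gene_set("manual",
                              up = unique(unlist(eff)),
                              down = unique(unlist(sup)))
  expect_equal(score_cohort(m, composite)$score, score_cohort(m, manual)$score)
})

test_that("immunophenogram z-scores match hand computation and conventions", {
  m <- rbind(g1 = c(0, 2), g2 = c(5, 5), g3 = c(1, 3))
  colnames(m) <- c("s1", "s2")
  prof <- immunophenogram_scores(m, list(cat1 = "g1", flat = "g2",
                                         pair = c("g1", "g3"),
                                         absent = "g99"))
  expect_equal(prof$cat1, c(-1, 1) / sqrt(2))   # n-1 SD
  expect_equal(prof$flat, c(0, 0))              # zero-variance convention
  expect_equal(prof$pair, (prof$cat1 + c(-1, 1) / sqrt(2)) / 2)
  expect_true(all(is.na(prof$absent)))
  expect_identical(attr(prof, "missing_categories"), "absent")
  expect_error(immunophenogram_scores(m[, 1, drop = FALSE], list(a = "g1")),
               "2 samples")
})

test_that("immunophenogram stratification thresholds the chosen category", {
  prof <- data.frame(sample = c("a", "b", "c"),
                     suppressor_cells = c(-1, 0, 2))
  g <- immunophenogram_stratify(prof)
  expect_identical(unname(g), c("SIL_low", "SIL_high", "SIL_high"))
})

test_that("signature overlap reports directed-blind fraction and Jaccard", {
  a <- directed_gene_set("a", up = c("A", "B"), down = c("C", "D"))
  b <- directed_gene_set("b", up = "D", down = "E")
  ov <- signature_overlap(a, b)
  expect_equal(ov$fraction, 0.25)
  expect_equal(ov$jaccard, 0.2)
  expect_equal(signature_overlap(a, a)$fraction, 1.0)
  disj <- directed_gene_set("d", up = c("X", "Y"))
  expect_equal(signature_overlap(a, disj)$fraction, 0.0)
})

test_that("signed GMT round-trips directed sets and accepts plain GMT", {
  sets <- list(directed_gene_set("one", up = c("A", "B"), down = "C"),
               directed_gene_set("two", up = "D"))
  tf <- tempfile(fileext = ".gmt")
  write_signed_gmt(sets, tf)
  back <- read_signed_gmt(tf)
  expect_equal(back$one$weights, sets[[1]]$weights)
  expect_equal(back$two$weights, sets[[2]]$weights)
  plain <- tempfile(fileext = ".gmt")
  writeLines("plainset\tdesc\tA\tB\tC", plain)
  ps <- read_signed_gmt(plain)
  expect_equal(unname(ps$plainset$weights), c(1, 1, 1))
})
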