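test_that("Nei Fst reproduces hand-evaluated cases", {
  # fixed for different alleles, n = 4 vs 1: Hs = 0, Ht = 0.5, Fst = 1
  r <- nei_fst_pair(c(4, 0), c(0, 1))
  expect_equal(r$hs, 0)
  expect_equal(r$ht, 0.5)
  expect_equal(r$fst, 1)

  # identical polymorphic groups p = (0.5, 0.5), n = 10 each:
  # corrected Hs = 5/9, Ht = 0.5 + Hs/20, Fst = -1/19
  r2 <- nei_fst_pair(c(5, 5), c(5, 5))
  expect_equal(r2$hs, 5 / 9, tolerance = 1e-12)
  expect_equal(r2$ht, 0.5 + (5 / 9) / 20, tolerance = 1e-12)
  expect_equal(r2$fst, -0.0526, tolerance = 1e-3)

  # (3N,1S) vs (1N): singleton triggers plug-in diversities for both groups
  # h1 = 0.375, h2 = 0, Hs = 0.1875, Ht = 0.21875 + 0.1875/3.2, Fst ~ 0.324
  r3 <- nei_fst_pair(c(3, 1), c(1, 0))
  expect_equal(r3$hs, 0.1875)
  expect_equal(r3$ht, 0.21875 + 0.1875 / 3.2, tolerance = 1e-12)
  expect_equal(r3$fst, 0.324, tolerance = 1e-3)

  # both groups fixed for the same allele: Ht = 0, Fst defined as 0
  expect_equal(nei_fst_pair(c(3, 0), c(2, 0))$fst, 0)
  expect_error(nei_fst_pair(numeric(0), c(1)), "empty|allele")
})

test_that("Fst is invariant to allele relabeling and group swap, bounded by 1", {
  set.seed(81)
  for (k in 1:20) {
    a <- sample(5:30, 1); A <- sample(2:6, 1)
    c1 <- as.numeric(stats::rmultinom(1, a, rep(1, A)))
    c2 <- as.numeric(stats::rmultinom(1, sample(5:30, 1), rep(1, A)))
    f <- nei_fst_pair(c1, c2)$fst
    perm <- sample(A)
    expect_equal(nei_fst_pair(c1[perm], c2[perm])$fst, f, tolerance = 1e-12)
    expect_equal(nei_fst_pair(c2, c1)$fst, f, tolerance = 1e-12)
    expect_lte(f, 1)
    # internal fast path agrees with the estimator object
    expect_equal(haplohab:::fst_counts(c1, c2), f, tolerance = 1e-12)
  }
  # fst = 1 iff within-group diversity is zero with divergence present
  expect_equal(nei_fst_pair(c(7, 0), c(0, 9))$fst, 1)
  expect_lt(nei_fst_pair(c(7, 1), c(0, 9))$fst, 1)
})

test_that("exhaustive permutation p-values match brute-force enumeration", {
  # NNNN vs S: 5 assignments, only the observed one isolates S: p = 1/5
  r <- permutation_test_pair(c("N", "N", "N", "N", "S"), 4, 1)
  expect_true(r$exhaustive)
  expect_equal(r$p, 0.2)

  # degenerate pool
  r0 <- permutation_test_pair(rep("N", 6), 3, 3)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)

  # independent multiset enumeration oracle for pooled n <= 8
  brute_p <- function(alleles, n1) {
    obs <- haplohab:::fst_from_alleles(alleles, seq_len(n1))
    combos <- utils::combn(length(alleles), n1)
    stats <- apply(combos, 2, function(ix)
      haplohab:::fst_from_alleles(alleles, ix))
    mean(stats >= obs - 1e-12)
  }
  set.seed(82)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    n1 <- sample(seq_len(n - 1), 1)
    alleles <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(alleles)) == 1) next
    r <- permutation_test_pair(alleles, n1, n - n1)
    expect_equal(r$p, brute_p(alleles, n1))
  }
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  alleles <- c("a", "a", "b", "b", "b", "c")
  exact <- permutation_test_pair(alleles, 3, 3)$p
  set.seed(83)
  mc <- permutation_test_pair(alleles, 3, 3, n_perm = 10000,
                              exhaustive_cap = 1)$p
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 10000) + 2e-4)
})

test_that("allele counts are conserved and zero-padded across groups", {
  sim <- simulate_dataset(two_site_config(n1 = 6, n2 = 4, seed = 84))
  ac <- allele_counts(sim$dataset, grouping = "habitat")
  expect_equal(unname(rowSums(ac$counts)), unname(lengths(ac$groups)))
  expect_equal(sum(ac$counts), 10)

  # lineage mode on a truth-anchored assignment gives two allele classes
  dm <- distance_matrix(sim$dataset$alignment, "p")
  asg <- assign_lineages(upgma(dm))
  ac2 <- allele_counts(sim$dataset, "habitat", "lineage", assignment = asg)
  expect_equal(ncol(ac2$counts), 2L)

  # explicit grouping lists are honored and validated
  ids <- sim$dataset$metadata$sample_id
  acl <- allele_counts(sim$dataset, list(g1 = ids[1:3], g2 = ids[4:6]))
  expect_equal(unname(rowSums(acl$counts)), c(3, 3))
  expect_error(allele_counts(sim$dataset, list(g1 = "nope", g2 = ids[1:2])),
               "not in dataset")
})

test_that("pairwise analysis covers all pairs and respects the seed", {
  sim <- simulate_dataset(sim_config(seed = 85))
  set.seed(1)
  res <- pairwise_fst(sim$dataset, "habitat", n_perm = 199)
  expect_equal(nrow(res$table), 3L)  # 3 habitat classes -> 3 pairs
  expect_true(all(res$table$p > 0 & res$table$p <= 1))
  expect_true(all(res$table$fst <= 1))
  set.seed(1)
  res2 <- pairwise_fst(sim$dataset, "habitat", n_perm = 199)
  expect_identical(res$table, res2$table)
  # site-level analysis includes the singleton site rather than failing
  set.seed(2)
  res_site <- pairwise_fst(sim$dataset, "site", n_perm = 99)
  expect_equal(nrow(res_site$table), choose(8, 2))
  expect_true("kml_grass" %in% c(res_site$table$group1, res_site$table$group2))
})

test_that("permutation p-values are conservative under exchangeability", {
  # alpha = 0: one-sided KS-style check that p-values are stochastically
  # >= uniform, pooling the three habitat pairs over replicates
  set.seed(86)
  ps <- c()
  for (k in 1:25) {
    sim <- simulate_dataset(sim_config(alpha = 0, seed = 860 + k))
    res <- pairwise_fst(sim$dataset, "habitat", n_perm = 199,
                        exhaustive_cap = 3000)
    ps <- c(ps, res$table$p)
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  emp <- vapply(grid, function(q) mean(ps <= q), 0)
  # allow one-sided binomial slack at each grid point
  expect_true(all(emp <= grid + 3 * sqrt(grid * (1 - grid) / length(ps))))
})

test_that("lineage frequency tables sum to one per group", {
  sim <- simulate_dataset(sim_config(seed = 87))
  truth <- stats::setNames(sim$dataset$metadata$lineage_truth,
                           sim$dataset$metadata$sample_id)
  dm <- distance_matrix(sim$dataset$alignment, "p")
  asg <- assign_lineages(upgma(dm),
                         anchors = list(northern = names(truth)[truth == "northern"][1]))
  ft <- frequency_table(sim$dataset, asg, "site")
  expect_equal(nrow(ft), 8L)
  expect_equal(ft$prop_northern + ft$prop_southern, rep(1, nrow(ft)))
  expect_equal(sum(ft$n), 78)
  expect_equal(ft$n_northern + ft$n_southern, ft$n)
  # per-group counts match the truth labels given a truth anchor
  for (i in seq_len(nrow(ft))) {
    m <- sim$dataset$metadata$sample_id[sim$dataset$metadata$site == ft$group[i]]
    expect_equal(ft$n_northern[i], sum(truth[m] == "northern"))
  }
})
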