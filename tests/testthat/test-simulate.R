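test_that("config validation rejects impossible designs", {
  expect_error(two_site_config(tau = -1), "tau")
  expect_error(two_site_config(theta = 0), "theta")
  expect_error(two_site_config(alpha = 1.5), "alpha")
  expect_error(sim_config(sites = data.frame(name = "a", habitat = "other",
                                             n = 1)), "total sample size")
  expect_error(estimate_error_rates(two_site_config(seed = 1), replicates = 0),
               "replicates")
})

test_that("lineage draws follow the assortment probabilities", {
  # alpha = 1: complete segregation by habitat
  cfg <- two_site_config(n1 = 20, n2 = 20, alpha = 1, seed = 4)
  lab <- draw_lineages(cfg)
  sf <- haplohab:::sample_frame(cfg)
  expect_true(all(lab[sf$habitat == "offshore_reef"] == "southern"))
  expect_true(all(lab[sf$habitat == "inshore_reef"] == "northern"))

  # alpha = 0: lineage independent of habitat, ~half northern per habitat
  big <- sim_config(sites = data.frame(
    name = c("o", "i", "g"),
    habitat = c("offshore_reef", "inshore_reef", "grass_bed"),
    n = c(4000, 3000, 3000)), alpha = 0, seed = 5)
  lab0 <- draw_lineages(big)
  sf0 <- haplohab:::sample_frame(big)
  for (hab in unique(sf0$habitat)) {
    n_h <- sum(sf0$habitat == hab)
    frac <- mean(lab0[sf0$habitat == hab] == "northern")
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_h))
  }
})

test_that("identical config and seed reproduce the simulation bit-for-bit", {
  cfg <- two_site_config(n1 = 5, n2 = 5, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(unclass(s1$dataset$alignment), unclass(s2$dataset$alignment))
  expect_identical(ape::write.tree(s1$genealogy), ape::write.tree(s2$genealogy))
  expect_identical(s1$dataset$metadata$lineage_truth,
                   s2$dataset$metadata$lineage_truth)
})

test_that("coalescent pairwise distances match closed-form expectations", {
  set.seed(101)
  theta <- 0.005; tau <- 0.0225
  cfg_same <- sim_config(sites = data.frame(name = "p", habitat = "other",
                                            n = 2), tau = tau, theta = theta)
  # same lineage: E[pairwise tree distance] = theta
  d_same <- replicate(2000, {
    lab <- c(a = "northern", b = "northern")
    g <- simulate_genealogy(lab, cfg_same)
    sum(g$edge.length)
  })
  se <- stats::sd(d_same) / sqrt(length(d_same))
  expect_lt(abs(mean(d_same) - theta), 3 * se)

  # different lineages: E = 2*tau + theta_anc
  d_diff <- replicate(2000, {
    lab <- c(a = "northern", b = "southern")
    g <- simulate_genealogy(lab, cfg_same)
    sum(g$edge.length)
  })
  se <- stats::sd(d_diff) / sqrt(length(d_diff))
  expect_lt(abs(mean(d_diff) - (2 * tau + theta)), 3 * se)
})

test_that("single-population root height matches the coalescent E[T_MRCA]", {
  set.seed(202)
  n <- 10; theta <- 0.005
  cfg <- one_pop_config(n = n, theta = theta)
  hts <- replicate(800, {
    lab <- stats::setNames(rep("northern", n), paste0("s", seq_len(n)))
    g <- simulate_genealogy(lab, cfg)
    max(node_heights(g))
  })
  # E[T_MRCA] = theta * (1 - 1/n) in substitutions/site time units
  se <- stats::sd(hts) / sqrt(length(hts))
  expect_lt(abs(mean(hts) - theta * (1 - 1 / n)), 3 * se)
})

test_that("JC69 mutation sprinkling matches the finite-sites closed form", {
  cfg <- one_pop_config(n = 2, theta = 0.005)
  h <- 0.02
  tree <- ape::read.tree(text = sprintf("(a:%g,b:%g);", h, h))
  set.seed(303)
  p_exp <- 0.75 * (1 - exp(-(4 / 3) * 2 * h))
  ps <- replicate(500, {
    aln <- sprinkle_mutations(tree, cfg)
    p_distance(unclass(aln)[1, ], unclass(aln)[2, ])$p
  })
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - p_exp), 3 * se)

  # zero-length tree: all sequences identical; seeded runs identical
  tree0 <- ape::read.tree(text = "(a:0,b:0);")
  aln0 <- sprinkle_mutations(tree0, cfg)
  expect_identical(unclass(aln0)[1, ], unclass(aln0)[2, ])
  set.seed(9); a1 <- sprinkle_mutations(tree, cfg)
  set.seed(9); a2 <- sprinkle_mutations(tree, cfg)
  expect_identical(unclass(a1), unclass(a2))
})

test_that("default design yields 78 samples x 723 sites with truth labels", {
  sim <- simulate_dataset(sim_config(seed = 11))
  expect_equal(nrow(sim$dataset$alignment), 78L)
  expect_equal(ncol(sim$dataset$alignment), 723L)
  expect_false(anyNA(sim$dataset$metadata$lineage_truth))
  expect_setequal(sim$genealogy$tip.label, sim$dataset$metadata$sample_id)
  expect_equal(length(unique(sim$dataset$metadata$site)), 8L)
})

test_that("within-lineage diversity does not depend on assortment strength", {
  # alpha moves labels, not the genealogy law: compare mean within-lineage
  # pairwise tree distance across alpha = 0 and alpha = 1
  mean_within <- function(alpha, seed) {
    vals <- numeric(0)
    for (k in seq_len(12)) {
      cfg <- two_site_config(n1 = 8, n2 = 8, alpha = alpha,
                             seed = seed + k)
      sim <- simulate_dataset(cfg)
      lab <- stats::setNames(sim$dataset$metadata$lineage_truth,
                             sim$dataset$metadata$sample_id)
      d <- ape::cophenetic.phylo(sim$genealogy)
      for (side in c("northern", "southern")) {
        m <- names(lab)[lab == side]
        if (length(m) >= 2) vals <- c(vals, mean(d[m, m][lower.tri(d[m, m])]))
      }
    }
    vals
  }
  v0 <- mean_within(0, 400)
  v1 <- mean_within(1, 500)
  se <- sqrt(stats::var(v0) / length(v0) + stats::var(v1) / length(v1))
  expect_lt(abs(mean(v0) - mean(v1)), 3 * se)
})
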