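test_that("UPGMA reproduces hand-computed merge heights", {
  # 2 taxa: single cherry at half the distance
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  tr2 <- upgma(d2)
  expect_equal(max(node_heights(tr2)), 0.1)

  # 3 taxa: (A,B) join at 0.1, C at 0.3
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma(d3)
  h <- sort(node_heights(tr3)[4:5])
  expect_equal(unname(h), c(0.1, 0.3))
  expect_true(ape::is.ultrametric(tr3, tol = 1e-9))
  expect_error(upgma(matrix(c(0, Inf, Inf, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "non-finite")
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  set.seed(71)
  for (k in 1:4) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- as.matrix(dist(x))
    tr <- upgma(d)
    hc <- stats::hclust(as.dist(d), method = "average")
    # merge heights: UPGMA node heights are half the hclust heights
    expect_equal(sort(node_heights(tr)[(n + 1):(2 * n - 1)]),
                 sort(hc$height / 2), tolerance = 1e-12)
    # cophenetic distances agree fully
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), rownames(d)],
                 as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-12)
  }
})

test_that("UPGMA recovers a tree from its own ultrametric distances", {
  sim <- simulate_dataset(two_site_config(n1 = 6, n2 = 6, seed = 72))
  g <- sim$genealogy
  d <- ape::cophenetic.phylo(g)
  tr <- upgma(d)
  expect_true(ape::all.equal.phylo(tr, g, use.edge.length = FALSE))
  expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] - d)),
            1e-9)
})

test_that("root-split lineage assignment recovers simulated truth", {
  set.seed(73)
  hits <- 0; total <- 0
  for (k in 1:15) {
    sim <- simulate_dataset(two_site_config(n1 = 8, n2 = 8, alpha = 0.5,
                                            seed = 730 + k))
    truth <- stats::setNames(sim$dataset$metadata$lineage_truth,
                             sim$dataset$metadata$sample_id)
    if (length(unique(truth)) < 2) next
    dm <- distance_matrix(sim$dataset$alignment, "p")
    asg <- assign_lineages(upgma(dm),
                           anchors = list(northern = names(truth)[truth == "northern"][1]))
    hits <- hits + sum(asg$labels[names(truth)] == truth)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.99)
})

test_that("assignment orients by anchors and validates them", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  asg <- assign_lineages(tr, anchors = list(southern = "a"))
  expect_equal(unname(asg$labels[c("a", "c")]), c("southern", "northern"))
  expect_equal(asg$split_depth, 2)
  expect_error(assign_lineages(tr, anchors = list(northern = c("a", "c"))),
               "inconsistent anchors")
  expect_error(assign_lineages(tr, anchors = list(northern = "a",
                                                  southern = "b")),
               "inconsistent anchors")
  # 2-leaf tree: each leaf its own group
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  asg2 <- assign_lineages(tr2)
  expect_setequal(unname(asg2$labels), c("northern", "southern"))
  # relabeling samples permutes but does not change the partition
  tr_swap <- tr; tr_swap$tip.label <- c("d", "c", "b", "a")
  asg_swap <- assign_lineages(tr_swap)
  expect_equal(sort(table(asg_swap$labels)), sort(table(asg$labels)),
               ignore_attr = TRUE)
})

test_that("haplotype collapsing preserves counts and identity", {
  aln <- aln_from_strings(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  haps <- collapse_haplotypes(aln)
  expect_equal(nrow(haps), 2L)
  expect_equal(sort(haps$count), c(1L, 2L))
  expect_equal(sum(haps$count), 3L)
  expect_setequal(haps$members[[which(haps$count == 2)]], c("a", "b"))

  # all distinct
  aln2 <- aln_from_strings(c(a = "ACGT", b = "ACGA", c = "ACCA"))
  expect_equal(nrow(collapse_haplotypes(aln2)), 3L)

  # ambiguity codes distinguish haplotypes
  aln3 <- aln_from_strings(c(a = "ACGT", b = "ACGN"))
  expect_equal(nrow(collapse_haplotypes(aln3)), 2L)

  # conservation on simulated data
  sim <- simulate_dataset(two_site_config(n1 = 10, n2 = 10, seed = 74))
  h <- collapse_haplotypes(sim$dataset$alignment)
  expect_equal(sum(h$count), 20L)
})

test_that("network is a minimum spanning tree (brute-force oracle)", {
  # forced MST on 3 haplotypes
  aln <- aln_from_strings(c(a = "AAAA", b = "AAAT", c = "AATT"))
  net <- build_network(collapse_haplotypes(aln))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sum(net$edges$steps), 2L)
  expect_false(any(net$edges$steps == 2))  # the AC edge (2 steps) is excluded

  # exhaustive comparison over all spanning trees for <= 6 haplotypes
  brute_mst_weight <- function(w) {
    k <- nrow(w)
    pairs <- utils::combn(k, 2)
    best <- Inf
    for (sel in utils::combn(ncol(pairs), k - 1, simplify = FALSE)) {
      g <- pairs[, sel, drop = FALSE]
      # spanning check via union-find
      parent <- seq_len(k)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      ok <- TRUE
      for (e in seq_len(ncol(g))) {
        a <- find(g[1, e]); b <- find(g[2, e])
        if (a == b) { ok <- FALSE; break }
        parent[a] <- b
      }
      if (ok) best <- min(best, sum(w[t(g)]))
    }
    best
  }
  set.seed(75)
  for (k in 1:3) {
    sim <- simulate_dataset(one_pop_config(n = 8, theta = 0.02,
                                           seed = 750 + k))
    haps <- collapse_haplotypes(sim$dataset$alignment)
    if (nrow(haps) < 3 || nrow(haps) > 6) next
    net <- build_network(haps)
    reps <- attr(haps, "sequences")
    w <- matrix(0, nrow(haps), nrow(haps))
    for (i in seq_len(nrow(haps) - 1)) for (j in (i + 1):nrow(haps))
      w[i, j] <- w[j, i] <- haplohab:::mismatch_count(reps[i, ], reps[j, ])
    expect_equal(sum(net$edges$steps), brute_mst_weight(w))
    expect_equal(nrow(net$edges), nrow(haps) - 1L)
  }

  # single haplotype: one node, no edges
  net1 <- build_network(collapse_haplotypes(aln_from_strings(c(x = "AAAA"))))
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)
})
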