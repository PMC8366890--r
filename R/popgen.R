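# Pairwise Nei Fst between groups of haploid mitochondrial samples, with a
# fixed-sample-size permutation null (exhaustive enumeration when feasible),
# plus allele-count and lineage-frequency tables.
#
# Estimator (variant "nei-chesser-haploid, singleton-plugin"):
#   h_k = (n_k/(n_k-1)) (1 - sum p_ki^2)    for n_k >= 2
#   Hs  = (h_1 + h_2)/2,  pbar_i = (p_1i + p_2i)/2
#   Ht  = 1 - sum pbar_i^2 + Hs/(2*ntilde), ntilde = harmonic mean(n1, n2)
#   Fst = 1 - Hs/Ht   (0 when Ht = 0)
# When either group is a singleton the n/(n-1) correction is undefined, so
# BOTH groups fall back to plug-in diversities h_k = 1 - sum p_ki^2; this
# keeps the 4-vs-1 site comparison (the smallest the design produces)
# well defined.

FST_VARIANT <- "nei-chesser-haploid, singleton-plugin"

#' Per-group allele counts
#'
#' Alleles are either exact haplotypes or the two lineage classes.
#'
#' @param dataset An \code{hb_dataset}.
#' @param grouping Either the string \code{"habitat"} or \code{"site"}
#'   (grouping columns of the metadata), or a named list of sample-id
#'   vectors. Samples with habitat \code{other} are excluded from the
#'   habitat grouping.
#' @param allele_mode \code{"haplotype"} (exact sequence classes) or
#'   \code{"lineage"} (northern/southern from \code{assignment}).
#' @param assignment A \code{\link{assign_lineages}} result; required for
#'   \code{allele_mode = "lineage"}.
#' @return A list with \code{counts} (matrix: groups x alleles) and
#'   \code{alleles_of} (named allele label per sample).
#' @export
allele_counts <- function(dataset, grouping = "habitat",
                          allele_mode = c("haplotype", "lineage"),
                          assignment = NULL) {
  allele_mode <- match.arg(allele_mode)
  groups <- resolve_grouping(dataset, grouping)
  if (allele_mode == "haplotype") {
    haps <- collapse_haplotypes(dataset$alignment)
    alleles_of <- character(0)
    for (i in seq_len(nrow(haps)))
      alleles_of[haps$members[[i]]] <- haps$haplotype[i]
  } else {
    if (is.null(assignment))
      stop("allele_mode = 'lineage' requires an assignment")
    alleles_of <- assignment$labels
  }
  lev <- unique(unname(alleles_of))
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    groups <- groups[lengths(groups) > 0L]
  }
  counts <- t(vapply(groups, function(m)
    table(factor(alleles_of[m], levels = lev)),
    numeric(length(lev))))
  if (length(lev) == 1L) {
    counts <- matrix(counts, ncol = 1L, dimnames = list(names(groups), lev))
  } else {
    colnames(counts) <- lev
  }
  list(counts = counts, alleles_of = alleles_of, groups = groups)
}

resolve_grouping <- function(dataset, grouping) {
  md <- dataset$metadata
  if (is.character(grouping) && length(grouping) == 1L) {
    if (!grouping %in% c("habitat", "site", "region"))
      stop("grouping must be 'habitat', 'site', 'region', or a named list")
    keep <- if (grouping == "habitat") md$habitat != "other" else TRUE
    split(md$sample_id[keep], md[[grouping]][keep])
  } else {
    if (is.null(names(grouping))) stop("grouping list must be named")
    all_ids <- unlist(grouping)
    if (anyDuplicated(all_ids)) stop("grouping lists must be disjoint")
    miss <- setdiff(all_ids, md$sample_id)
    if (length(miss)) stop("grouping ids not in dataset: ",
                           paste(miss, collapse = ", "))
    grouping
  }
}

gene_diversity <- function(counts, corrected = TRUE) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts / n
  h <- 1 - sum(p^2)
  if (corrected && n >= 2) h * n / (n - 1) else h
}

#' Pairwise Nei Fst between two groups from allele counts
#'
#' Bias-corrected Nei/Chesser estimator for haploid data; see the package
#' vignette for the exact variant and the singleton fallback.
#'
#' @param counts1,counts2 Nonnegative allele-count vectors over the same
#'   allele set.
#' @return List of class \code{fst_pair}: \code{fst}, \code{hs}, \code{ht},
#'   \code{n1}, \code{n2}, \code{variant}.
#' @export
nei_fst_pair <- function(counts1, counts2) {
  if (!length(counts1) || !length(counts2))
    stop("empty allele count vector")
  if (length(counts1) != length(counts2))
    stop("count vectors must cover the same allele set")
  n1 <- sum(counts1); n2 <- sum(counts2)
  if (n1 < 1 || n2 < 1) stop("both groups need n >= 1")
  corrected <- n1 >= 2 && n2 >= 2
  h1 <- gene_diversity(counts1, corrected)
  h2 <- gene_diversity(counts2, corrected)
  hs <- (h1 + h2) / 2
  pbar <- (counts1 / n1 + counts2 / n2) / 2
  ntilde <- 2 / (1 / n1 + 1 / n2)
  ht <- 1 - sum(pbar^2) + hs / (2 * ntilde)
  fst <- if (ht > 0) 1 - hs / ht else 0
  structure(list(fst = fst, hs = hs, ht = ht, n1 = n1, n2 = n2,
                 variant = FST_VARIANT),
            class = "fst_pair")
}

#' @export
print.fst_pair <- function(x, ...) {
  cat(sprintf("<Fst = %.4f (Hs = %.4f, Ht = %.4f; n = %d, %d)>\n",
              x$fst, x$hs, x$ht, x$n1, x$n2))
  invisible(x)
}

# numeric-only core of the estimator, used in permutation loops
fst_counts <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- c1 / n1; p2 <- c2 / n2
  h1 <- 1 - sum(p1^2); h2 <- 1 - sum(p2^2)
  if (n1 >= 2 && n2 >= 2) {
    h1 <- h1 * n1 / (n1 - 1)
    h2 <- h2 * n2 / (n2 - 1)
  }
  hs <- (h1 + h2) / 2
  pbar <- (p1 + p2) / 2
  ht <- 1 - sum(pbar^2) + hs * (1 / n1 + 1 / n2) / 4
  if (ht > 0) 1 - hs / ht else 0
}

fst_from_alleles <- function(alleles, idx1) {
  lev <- unique(alleles)
  code <- match(alleles, lev)
  c1 <- tabulate(code[idx1], length(lev))
  fst_counts(c1, tabulate(code, length(lev)) - c1)
}

#' Permutation test for differentiation between two groups
#'
#' Reshuffles allele labels into groups of the observed sizes (the
#' fixed-sample-size null). When the number of distinct assignments
#' \code{choose(n1+n2, n1)} is at most \code{exhaustive_cap}, all are
#' enumerated and p is the exact fraction with Fst >= observed; otherwise
#' add-one Monte Carlo: p = (1 + #\{perm >= obs\}) / (1 + n_perm). The test
#' is one-sided (large Fst = differentiation).
#'
#' @param alleles Character vector of allele labels for the pooled samples.
#' @param n1,n2 Group sizes (must sum to \code{length(alleles)}).
#' @param n_perm Monte-Carlo permutations.
#' @param exhaustive_cap Maximum number of assignments to enumerate.
#' @param observed Optional observed Fst; defaults to the first \code{n1}
#'   entries of \code{alleles} forming group 1.
#' @return List: \code{p}, \code{observed}, \code{n_perm}, \code{exhaustive},
#'   \code{degenerate}.
#' @export
permutation_test_pair <- function(alleles, n1, n2, n_perm = 9999,
                                  exhaustive_cap = 1e5, observed = NULL) {
  n <- length(alleles)
  if (n1 + n2 != n) stop("n1 + n2 must equal the pooled sample count")
  if (length(unique(alleles)) == 1L)
    return(list(p = 1, observed = 0, n_perm = 0L, exhaustive = TRUE,
                degenerate = TRUE))
  if (is.null(observed)) observed <- fst_from_alleles(alleles, seq_len(n1))
  lev <- unique(alleles)
  code <- match(alleles, lev)
  tot <- tabulate(code, length(lev))
  stat_of <- function(ix) {
    c1 <- tabulate(code[ix], length(lev))
    fst_counts(c1, tot - c1)
  }
  n_assign <- choose(n, n1)
  if (n_assign <= exhaustive_cap) {
    combos <- utils::combn(n, n1)
    stats <- apply(combos, 2L, stat_of)
    p <- sum(stats >= observed - 1e-12) / ncol(combos)
    list(p = p, observed = observed, n_perm = as.integer(ncol(combos)),
         exhaustive = TRUE, degenerate = FALSE)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (stat_of(sample.int(n, n1)) >= observed - 1e-12) hits <- hits + 1L
    }
    list(p = (1 + hits) / (1 + n_perm), observed = observed,
         n_perm = as.integer(n_perm), exhaustive = FALSE, degenerate = FALSE)
  }
}

#' Pairwise Fst with permutation p-values over all group pairs
#'
#' @param dataset An \code{hb_dataset}.
#' @param grouping See \code{\link{allele_counts}}.
#' @param allele_mode \code{"haplotype"} or \code{"lineage"}.
#' @param assignment Required for lineage mode.
#' @param n_perm Monte-Carlo permutations per pair.
#' @param exhaustive_cap See \code{\link{permutation_test_pair}}.
#' @param holm If TRUE add a Holm-adjusted p column.
#' @return A list of class \code{fst_table} with \code{table} (one row per
#'   unordered pair: group1, group2, n1, n2, fst, hs, ht, p, n_perm,
#'   exhaustive) and \code{variant}.
#' @export
pairwise_fst <- function(dataset, grouping = "habitat",
                         allele_mode = c("haplotype", "lineage"),
                         assignment = NULL, n_perm = 9999,
                         exhaustive_cap = 1e5, holm = FALSE) {
  allele_mode <- match.arg(allele_mode)
  ac <- allele_counts(dataset, grouping, allele_mode, assignment)
  groups <- ac$groups
  g <- length(groups)
  if (g < 2L) stop("need at least 2 nonempty groups")
  gnames <- names(groups)
  rows <- list()
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      m1 <- groups[[i]]; m2 <- groups[[j]]
      alleles <- unname(ac$alleles_of[c(m1, m2)])
      est <- nei_fst_pair(
        tabulate(match(ac$alleles_of[m1], unique(alleles)), length(unique(alleles))),
        tabulate(match(ac$alleles_of[m2], unique(alleles)), length(unique(alleles))))
      pt <- permutation_test_pair(alleles, length(m1), length(m2),
                                  n_perm = n_perm,
                                  exhaustive_cap = exhaustive_cap,
                                  observed = est$fst)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = gnames[i], group2 = gnames[j],
        n1 = length(m1), n2 = length(m2),
        fst = est$fst, hs = est$hs, ht = est$ht,
        p = pt$p, n_perm = pt$n_perm, exhaustive = pt$exhaustive,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (holm) tab$p_holm <- stats::p.adjust(tab$p, "holm")
  structure(list(table = tab, variant = FST_VARIANT,
                 allele_mode = allele_mode),
            class = "fst_table")
}

#' @export
print.fst_table <- function(x, ...) {
  cat(sprintf("Pairwise Nei Fst (%s alleles; %s)\n", x$allele_mode, x$variant))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Lineage frequencies per group
#'
#' @param dataset An \code{hb_dataset}.
#' @param assignment A \code{\link{assign_lineages}} result.
#' @param grouping See \code{\link{allele_counts}}.
#' @return Data frame: group, n, n_northern, n_southern, prop_northern,
#'   prop_southern.
#' @export
frequency_table <- function(dataset, assignment, grouping = "site") {
  groups <- resolve_grouping(dataset, grouping)
  lab <- assignment$labels
  rows <- lapply(names(groups), function(gn) {
    m <- groups[[gn]]
    nn <- sum(lab[m] == "northern")
    data.frame(group = gn, n = length(m), n_northern = nn,
               n_southern = length(m) - nn,
               prop_northern = nn / length(m),
               prop_southern = 1 - nn / length(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
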