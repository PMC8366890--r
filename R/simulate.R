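# Coalescent synthetic-data generator: two diverged mitochondrial lineages,
# finite-sites JC69 mutation, and habitat assignment with tunable assortment.
# All time units are expected substitutions/site, so divergence time tau and
# diversity theta compose additively into expected pairwise distances.

#' Default Keys-like sampling design
#'
#' Eight sites in three habitat classes plus three out-of-Keys context sites
#' are available; the default is the 8-site Keys design summing to n = 78,
#' including a singleton grass-bed site. Per-site sizes are package defaults
#' chosen to be realistic for this kind of survey, not published counts.
#'
#' @return Data frame with columns \code{name}, \code{habitat}, \code{n}.
#' @export
default_sites <- function() {
  data.frame(
    name = c("sombrero", "eleven_foot", "xmuta", "tennessee",
             "washerwoman", "turtle_shoal", "long_key_grass", "kml_grass"),
    habitat = c(rep("offshore_reef", 4), rep("inshore_reef", 2),
                rep("grass_bed", 2)),
    n = c(18L, 14L, 4L, 17L, 12L, 8L, 4L, 1L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param sites Data frame with columns \code{name}, \code{habitat},
#'   \code{n} (one row per sampling site, n >= 1).
#' @param tau Lineage divergence time in expected substitutions/site. The
#'   default 0.0225, with \code{theta} 0.005, targets a deep ~5\% net
#'   between-lineage divergence (2*tau + theta = 0.05).
#' @param theta Expected within-lineage pairwise diversity, substitutions/site.
#' @param theta_anc Ancestral-population diversity (defaults to \code{theta}).
#' @param alpha Lineage-habitat assortment strength in [0, 1]: 0 places
#'   lineages independently of habitat, 1 segregates them completely
#'   (inshore reef and grass bed northern, offshore reef southern).
#' @param L Fragment length in bp.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(sites = default_sites(), tau = 0.0225, theta = 0.005,
                       theta_anc = theta, alpha = 0, L = 723L, seed = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("name", "habitat", "n") %in% names(sites)))
  sites$habitat <- normalize_habitat(as.character(sites$habitat))
  if (any(sites$n < 1L)) stop("each site needs n >= 1")
  if (sum(sites$n) < 2L) stop("total sample size must be >= 2")
  if (tau < 0) stop("tau must be >= 0")
  if (theta <= 0 || theta_anc <= 0) stop("theta must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (L < 1L) stop("L must be >= 1")
  structure(list(sites = sites, tau = tau, theta = theta,
                 theta_anc = theta_anc, alpha = alpha, L = as.integer(L),
                 seed = seed),
            class = "sim_config")
}

sample_frame <- function(config) {
  s <- config$sites
  data.frame(
    sample_id = unlist(lapply(seq_len(nrow(s)), function(i)
      sprintf("%s_%02d", s$name[i], seq_len(s$n[i])))),
    site = rep(s$name, s$n),
    habitat = rep(s$habitat, s$n),
    stringsAsFactors = FALSE)
}

#' Draw per-sample lineage labels given habitat
#'
#' P(northern | inshore reef or grass bed) = (1 + alpha)/2,
#' P(northern | offshore reef) = (1 - alpha)/2, and 1/2 for \code{other}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Character vector of \code{"northern"}/\code{"southern"} labels,
#'   one per sample, named by sample id.
#' @export
draw_lineages <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sf <- sample_frame(config)
  p_north <- ifelse(sf$habitat %in% c("inshore_reef", "grass_bed"),
                    (1 + config$alpha) / 2,
                    ifelse(sf$habitat == "offshore_reef",
                           (1 - config$alpha) / 2, 0.5))
  lab <- ifelse(stats::runif(nrow(sf)) < p_north, "northern", "southern")
  names(lab) <- sf$sample_id
  lab
}

# Kingman coalescent within a set of lineages: pairwise coalescence rate
# 2/theta so that E[pairwise distance] = theta. Runs until one lineage
# remains or `until` is reached. `nodes` is an environment accumulating the
# growing tree.
coalesce_pool <- function(active, t0, theta, until, nodes) {
  t <- t0
  while (length(active) > 1L) {
    k <- length(active)
    rate <- k * (k - 1) / 2 * (2 / theta)
    t_next <- t + stats::rexp(1L, rate)
    if (!is.null(until) && t_next > until) return(list(active = active, t = until))
    t <- t_next
    pair <- sample.int(k, 2L)
    new_id <- nodes$next_id
    nodes$next_id <- nodes$next_id + 1L
    nodes$parent[active[pair]] <- new_id
    nodes$height[new_id] <- t
    active <- c(active[-pair], new_id)
  }
  list(active = active, t = t)
}

#' Simulate a two-lineage coalescent genealogy
#'
#' Within each lineage, samples coalesce under a Kingman coalescent with
#' pairwise rate 2/theta (time in substitutions/site). At time \code{tau}
#' the survivors of both lineages merge into one ancestral pool that
#' coalesces at pairwise rate 2/theta_anc. The expected pairwise tree
#' distance is theta within a lineage and 2*tau + theta_anc between
#' lineages.
#'
#' @param lineage_labels Named character vector (\code{"northern"} /
#'   \code{"southern"}) as from \code{\link{draw_lineages}}; names are the
#'   sample ids and become tip labels.
#' @param config A \code{\link{sim_config}} (\code{tau}, \code{theta},
#'   \code{theta_anc} are used; the seed is NOT reset here so the genealogy
#'   can be drawn inside a larger seeded simulation).
#' @return A binary ultrametric \code{phylo} tree with heights in
#'   substitutions/site.
#' @export
simulate_genealogy <- function(lineage_labels, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- names(lineage_labels)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 samples")
  n_nodes_max <- 2L * n
  nodes <- new.env()
  nodes$parent <- rep(NA_integer_, n_nodes_max)
  nodes$height <- numeric(n_nodes_max)
  nodes$next_id <- n + 1L
  north <- which(lineage_labels == "northern")
  south <- which(lineage_labels == "southern")
  rn <- coalesce_pool(north, 0, config$theta, config$tau, nodes)
  rs <- coalesce_pool(south, 0, config$theta, config$tau, nodes)
  pool <- c(rn$active, rs$active)
  if (length(pool) > 1L)
    coalesce_pool(pool, config$tau, config$theta_anc, NULL, nodes)
  build_phylo(nodes, ids)
}

# Assemble an ape phylo from the parent/height tables. Internal node ids in
# `nodes` are in coalescence order; remap to ape convention (tips 1..n,
# root n+1, then the rest).
build_phylo <- function(nodes, tip_ids) {
  n <- length(tip_ids)
  n_int <- nodes$next_id - 1L - n
  used <- seq_len(n + n_int)
  parent <- nodes$parent[used]
  height <- nodes$height[used]
  root_old <- which(is.na(parent))
  stopifnot(length(root_old) == 1L)
  int_old <- (n + 1L):(n + n_int)
  # ape wants root = n+1; order other internals arbitrarily (keep height order)
  ord <- c(root_old, setdiff(int_old, root_old))
  new_of <- integer(n + n_int)
  new_of[seq_len(n)] <- seq_len(n)
  new_of[ord] <- n + seq_len(n_int)
  child <- which(!is.na(parent))
  edge <- cbind(new_of[parent[child]], new_of[child])
  edge_len <- height[parent[child]] - height[child]
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = tip_ids, Nnode = n_int),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Drop finite-sites JC69 mutations on a genealogy
#'
#' Per branch, the mutation count is Poisson(L x branch length); each
#' mutation hits a uniformly chosen site and substitutes a uniformly chosen
#' different base. The root sequence is uniform over \{A,C,G,T\}. Output is
#' gap-free.
#'
#' @param tree A \code{phylo} with branch lengths in substitutions/site.
#' @param config A \code{\link{sim_config}} (\code{L} is used; the seed is
#'   NOT reset here).
#' @return An \code{\link{hb_alignment}} with one row per tip.
#' @export
sprinkle_mutations <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$L
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  seqs <- vector("list", n_all)
  root <- n_tip + 1L
  seqs[[root]] <- sample(bases, L, replace = TRUE)
  ord <- rev(ape::postorder(tree))  # parent before child
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    s <- seqs[[p]]
    n_mut <- stats::rpois(1L, L * tree$edge.length[e])
    if (n_mut > 0L) {
      pos <- sample.int(L, n_mut, replace = TRUE)
      for (m in seq_len(n_mut)) {
        s[pos[m]] <- sample(setdiff(bases, s[pos[m]]), 1L)
      }
    }
    seqs[[ch]] <- s
  }
  mat <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(mat) <- tree$tip.label
  hb_alignment(mat)
}

#' Simulate a complete dataset
#'
#' Composes \code{\link{draw_lineages}}, \code{\link{simulate_genealogy}} and
#' \code{\link{sprinkle_mutations}} under one seeded generator, and packages
#' the result with metadata carrying the true lineage of every sample.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{sim_result} with elements \code{dataset}
#'   (an \code{hb_dataset} whose metadata includes \code{lineage_truth}) and
#'   \code{genealogy} (the true \code{phylo} tree, substitutions/site).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL
  labels <- draw_lineages(inner)
  tree <- simulate_genealogy(labels, inner)
  aln <- sprinkle_mutations(tree, inner)
  sf <- sample_frame(config)
  sf$region <- "keys"
  sf$lineage_truth <- unname(labels[sf$sample_id])
  md <- hb_metadata(sf)
  structure(list(dataset = make_dataset(aln, md), genealogy = tree,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n <- nrow(x$dataset$alignment)
  cat(sprintf("<sim_result: %d samples, %d bp, tau=%g theta=%g alpha=%g>\n",
              n, ncol(x$dataset$alignment), x$config$tau, x$config$theta,
              x$config$alpha))
  invisible(x)
}

#' Monte-Carlo error rates of the habitat permutation test and GMYC LRT
#'
#' Repeatedly simulates datasets under \code{config}, runs the habitat-pooled
#' pairwise Fst permutation tests (and optionally the GMYC LRT on the UPGMA
#' tree), and reports rejection fractions at the nominal level. The habitat
#' test rejects a replicate when any habitat pair has raw p <= level; a
#' Holm-adjusted family-wise rate is reported alongside.
#'
#' @param config A \code{\link{sim_config}}; its seed seeds the whole run.
#' @param replicates Number of simulated datasets (>= 50).
#' @param nominal_level Nominal significance level.
#' @param n_perm Permutations per test (Monte-Carlo branch).
#' @param gmyc If TRUE also fit GMYC per replicate (slower).
#' @return A list with rejection rates, binomial standard errors, and the
#'   per-replicate minimum p-values.
#' @export
estimate_error_rates <- function(config, replicates, nominal_level = 0.05,
                                 n_perm = 199, gmyc = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (replicates < 50) stop("replicates must be >= 50")
  if (!is.null(config$seed)) set.seed(config$seed)
  any_raw <- logical(replicates)
  any_holm <- logical(replicates)
  pair_p <- vector("list", replicates)
  gmyc_rej <- rep(NA, replicates)
  for (r in seq_len(replicates)) {
    inner <- config
    inner$seed <- NULL
    sim <- simulate_dataset(inner)
    res <- pairwise_fst(sim$dataset, grouping = "habitat",
                        allele_mode = "haplotype", n_perm = n_perm)
    p <- res$table$p
    pair_p[[r]] <- p
    any_raw[r] <- any(p <= nominal_level)
    any_holm[r] <- any(stats::p.adjust(p, "holm") <= nominal_level)
    if (gmyc) {
      dm <- distance_matrix(sim$dataset$alignment, model = "p")
      fit <- fit_gmyc(upgma(dm))
      gmyc_rej[r] <- fit$p_value <= nominal_level
    }
  }
  se <- function(x) sqrt(mean(x) * (1 - mean(x)) / length(x))
  out <- list(replicates = replicates, nominal_level = nominal_level,
              habitat_reject_raw = mean(any_raw),
              habitat_reject_raw_se = se(any_raw),
              habitat_reject_holm = mean(any_holm),
              habitat_reject_holm_se = se(any_holm),
              pair_p = pair_p)
  if (gmyc) {
    out$gmyc_reject <- mean(gmyc_rej)
    out$gmyc_reject_se <- se(gmyc_rej)
  }
  out
}
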