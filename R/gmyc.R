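# Single-threshold generalized mixed Yule-coalescent (GMYC) species
# delimitation on an ultrametric tree.
#
# The tree's n-1 internal nodes define n-1 inter-event intervals running
# from the present to the root; each interval is terminated by the node at
# its upper (older) end. A threshold height T classifies nodes: nodes older
# than T are diversification (Yule) events; lineages crossing T root
# coalescent clusters, and every node at or below T is a coalescence inside
# one cluster. Interval i with duration x_i carries a total hazard
#   b_i = lambda1 * n_i^p1 + lambda2 * sum_j [n_ij (n_ij - 1)]^p2
# where n_i is the diversification-process lineage count (all lineages
# above T; the number of clusters below T) and n_ij the lineage count of
# cluster j. Each interval contributes the waiting-time density of the
# superposed process, b_i * exp(-b_i x_i), so the log-likelihood is
# sum_i [ -b_i x_i + log b_i ]. The final present-day interval does not
# exist in this parameterization: events end at the nodes, and the interval
# from the most recent node to the present carries no event (it is the
# first interval, terminated by that node).

#' Event series of an ultrametric tree at a given threshold
#'
#' @param tree Binary ultrametric \code{phylo} with >= 3 leaves.
#' @param threshold_height Height in (0, root height]; nodes strictly above
#'   it are diversification events.
#' @return List of class \code{gmyc_series}: \code{duration} (per
#'   interval, present to root), \code{n_div} (diversification lineage
#'   count), \code{coal_pairs} (matrix interval x cluster of
#'   n_ij*(n_ij-1)), \code{event_type} ("div"/"coal"),
#'   \code{event_pair} (the terminating cluster's n_ij*(n_ij-1), coalescent
#'   events only), \code{clusters} (list of tip labels per cluster, with
#'   singleton lineages as their own cluster).
#' @export
event_series <- function(tree, threshold_height) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("GMYC needs at least 3 leaves")
  h <- node_heights(tree)
  root <- n_tip + 1L
  root_h <- h[root]
  if (threshold_height <= 0 || threshold_height > root_h + 1e-12)
    stop("threshold must be in (0, root height]")
  T <- min(threshold_height, root_h)
  # cluster roots: edges crossing T (parent above, child at/below), or the
  # whole tree when T is the root height
  if (T >= root_h - 1e-15) {
    cluster_root <- root
  } else {
    cross <- which(h[tree$edge[, 1L]] > T + 1e-15 &
                     h[tree$edge[, 2L]] <= T + 1e-15)
    cluster_root <- tree$edge[cross, 2L]
  }
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    # iterative stack to avoid recursion limits
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (v <= n_tip) out <- c(out, v)
      else stack <- c(stack, kids[[as.character(v)]])
    }
    out
  }
  clusters <- lapply(cluster_root, tips_under)
  k_c <- length(clusters)
  # cluster id per internal node (NA = diversification event)
  node_cluster <- rep(NA_integer_, n_tip + tree$Nnode)
  for (j in seq_len(k_c)) {
    cr <- cluster_root[j]
    if (cr > n_tip) {
      stack <- cr
      while (length(stack)) {
        v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (v > n_tip) {
          node_cluster[v] <- j
          stack <- c(stack, kids[[as.character(v)]])
        }
      }
    }
  }
  int_nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  ord <- int_nodes[order(h[int_nodes])]  # present -> root
  heights <- h[ord]
  n_int <- length(ord)
  duration <- diff(c(0, heights))
  # lineage bookkeeping, walking from the present upward
  cl_sizes <- vapply(clusters, length, 1L)
  n_div_total <- k_c  # below threshold the species count equals cluster count
  coal_pairs <- matrix(0, n_int, k_c)
  n_div <- numeric(n_int)
  event_type <- character(n_int)
  event_pair <- rep(NA_real_, n_int)
  cur_cl <- cl_sizes              # lineages per cluster in current interval
  total_lineages <- n_tip
  n_above <- 0                    # diversification lineages (above T region)
  for (i in seq_len(n_int)) {
    below_T <- heights[i] <= T + 1e-15
    if (below_T) {
      n_div[i] <- k_c
      coal_pairs[i, ] <- cur_cl * (cur_cl - 1)
    } else {
      n_div[i] <- total_lineages
      # all clusters fully coalesced above threshold
    }
    v <- ord[i]
    if (!is.na(node_cluster[v])) {
      j <- node_cluster[v]
      event_type[i] <- "coal"
      event_pair[i] <- cur_cl[j] * (cur_cl[j] - 1)
      cur_cl[j] <- cur_cl[j] - 1L
    } else {
      event_type[i] <- "div"
    }
    total_lineages <- total_lineages - 1L
  }
  structure(list(duration = duration, heights = heights, n_div = n_div,
                 coal_pairs = coal_pairs, event_type = event_type,
                 event_pair = event_pair,
                 clusters = lapply(clusters, function(ix) tree$tip.label[ix]),
                 threshold = T, root_height = root_h, n_tip = n_tip),
            class = "gmyc_series")
}

#' GMYC mixed-model log-likelihood
#'
#' Each inter-event interval contributes the waiting-time density of the
#' superposed branching process, b_i * exp(-b_i * x_i); zero-duration
#' intervals (tied node heights) contribute only the rate factor.
#'
#' @param series An \code{\link{event_series}}.
#' @param lambda1,p1 Diversification rate and scaling exponent.
#' @param lambda2,p2 Coalescent rate and scaling exponent.
#' @return Log-likelihood (scalar).
#' @export
mixed_loglik <- function(series, lambda1, p1, lambda2, p2) {
  if (lambda1 < 0 || lambda2 <= 0) stop("rates must be positive")
  coal_term <- rowSums(series$coal_pairs^p2 * (series$coal_pairs > 0))
  b <- lambda1 * series$n_div^p1 + lambda2 * coal_term
  if (any(b <= 0)) return(-Inf)
  ll <- sum(-b * series$duration + log(b))
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

# series for the null model: one coalescent over the whole tree
null_series <- function(tree) {
  n_tip <- length(tree$tip.label)
  h <- node_heights(tree)
  event_series(tree, h[n_tip + 1L])
}

optimize_rates <- function(obj, k_par, starts) {
  # obj takes a parameter vector on the optimization scale
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                            lower = rep(c(log(1e-4), 0), k_par / 2),
                            upper = rep(c(log(1e4), 3), k_par / 2),
                            control = list(fnscale = -1, factr = 1e7)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed for all starts")
  best
}

null_starts <- function() {
  cbind(log_lambda = log(c(0.5, 5, 50, 500, 0.01)),
        p = c(1, 1, 0.5, 1.5, 1))
}

mixed_starts <- function() {
  l <- log(c(0.5, 5, 50, 500, 0.01))
  cbind(l1 = l, p1 = c(1, 1, 0.5, 1.5, 1),
        l2 = l, p2 = c(1, 1, 0.5, 1.5, 1))
}

# Trees are normalized to unit root height before optimization: rates then
# live on a scale-free axis (the bounds apply to the normalized rates), and
# rescaling all branch lengths by c provably shifts both logliks by
# -E log c without touching the LRT, threshold rank, or cluster count.
normalize_tree <- function(tree) {
  H <- max(node_heights(tree))
  if (H <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / H
  list(tree = tree, H = H)
}

#' Fit the one-species (single coalescent) null model
#'
#' Maximizes the likelihood of a single coalescent process spanning the
#' whole tree, b_i = lambda0 * [n_i (n_i - 1)]^p0, by bounded quasi-Newton
#' with deterministic multi-starts. The tree is normalized to unit root
#' height internally; reported rate and log-likelihood are in the input
#' time units.
#'
#' @param tree Binary ultrametric \code{phylo} with >= 3 leaves.
#' @return List: \code{lambda0}, \code{p0}, \code{loglik},
#'   \code{convergence}.
#' @export
fit_null <- function(tree) {
  nt <- normalize_tree(tree)
  series <- null_series(nt$tree)
  obj <- function(par) mixed_loglik(series, lambda1 = 0, p1 = 1,
                                    lambda2 = exp(par[1]), p2 = par[2])
  best <- optimize_rates(obj, 2L, null_starts())
  E <- length(series$duration)
  list(lambda0 = exp(best$par[1]) / nt$H, p0 = best$par[2],
       loglik = best$value - E * log(nt$H),
       convergence = best$convergence)
}

fit_threshold <- function(series) {
  obj <- function(par) mixed_loglik(series, lambda1 = exp(par[1]),
                                    p1 = par[2], lambda2 = exp(par[3]),
                                    p2 = par[4])
  best <- optimize_rates(obj, 4L, mixed_starts())
  list(lambda1 = exp(best$par[1]), p1 = best$par[2],
       lambda2 = exp(best$par[3]), p2 = best$par[4],
       loglik = best$value, convergence = best$convergence)
}

#' Upper-tail chi-squared p-value for the GMYC likelihood-ratio test
#'
#' @param lrt_stat Nonnegative LR statistic 2*(loglik - null loglik).
#' @param df Degrees of freedom (3 by default: threshold plus the extra
#'   rate and exponent; 2 is a common alternative).
#' @return Upper-tail probability.
#' @export
lrt_pvalue <- function(lrt_stat, df = 3) {
  if (lrt_stat < 0) stop("lrt_stat must be >= 0")
  stats::pchisq(lrt_stat, df = df, lower.tail = FALSE)
}

#' Fit the single-threshold GMYC model
#'
#' Candidate thresholds are the interior node heights strictly below the
#' root (deduplicated within 1e-12). For each candidate the four mixed-model
#' parameters are optimized; the best-scoring threshold is selected (ties
#' broken toward the root, i.e. fewer clusters). The likelihood-ratio test
#' compares the best mixed fit against the single-coalescent null; if no
#' candidate beats the null the fit degrades to the null configuration with
#' one cluster.
#'
#' @param tree Binary ultrametric \code{phylo} with >= 3 leaves.
#' @param df Chi-squared degrees of freedom for the LRT (3 or 2).
#' @return Object of class \code{gmyc} with threshold, parameter estimates,
#'   log-likelihoods, LRT statistic and p-value, and the delimited entities.
#' @export
fit_gmyc <- function(tree, df = 3) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("GMYC needs at least 3 leaves")
  validate_ultrametric(tree, tol = 1e-6)
  nt <- normalize_tree(tree)
  ntree <- nt$tree
  E <- n_tip - 1L
  shift <- E * log(nt$H)  # loglik offset between normalized and input units
  null_fit <- fit_null(tree)
  h <- node_heights(ntree)
  root_h <- h[n_tip + 1L]
  cand <- sort(unique(h[(n_tip + 1L):(n_tip + ntree$Nnode)]))
  # zero-height nodes (identical sequences) cannot host a threshold
  cand <- cand[cand > root_h * 1e-12 & cand < root_h - 1e-12]
  cand <- cand[!duplicated(round(cand / max(root_h, 1e-300), 12))]
  best <- NULL
  for (T in rev(cand)) {  # root-ward first so ties keep the deeper threshold
    series <- event_series(ntree, T)
    fit <- try(fit_threshold(series), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fit$loglik <- fit$loglik - shift
    if (is.null(best) || fit$loglik > best$fit$loglik + 1e-9) {
      best <- list(T = T, fit = fit, series = series)
    }
  }
  if (is.null(best) || best$fit$loglik <= null_fit$loglik) {
    out <- list(threshold_height = max(node_heights(tree)),
                lambda1 = NA_real_, p1 = NA_real_,
                lambda2 = null_fit$lambda0, p2 = null_fit$p0,
                loglik = null_fit$loglik,
                null_loglik = null_fit$loglik,
                lambda0 = null_fit$lambda0, p0 = null_fit$p0,
                lrt_stat = 0, df = df, p_value = 1,
                entities = list(tree$tip.label), n_clusters = 1L,
                degenerate = TRUE, tree = tree)
    class(out) <- "gmyc"
    return(out)
  }
  lrt <- 2 * (best$fit$loglik - null_fit$loglik)
  out <- list(threshold_height = best$T * nt$H,
              lambda1 = best$fit$lambda1 / nt$H, p1 = best$fit$p1,
              lambda2 = best$fit$lambda2 / nt$H, p2 = best$fit$p2,
              loglik = best$fit$loglik,
              null_loglik = null_fit$loglik,
              lambda0 = null_fit$lambda0, p0 = null_fit$p0,
              lrt_stat = lrt, df = df, p_value = lrt_pvalue(lrt, df),
              entities = best$series$clusters,
              n_clusters = length(best$series$clusters),
              degenerate = FALSE, tree = tree)
  class(out) <- "gmyc"
  out
}

#' @export
print.gmyc <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat(sprintf("  entities: %d (threshold height %.5g)\n",
              x$n_clusters, x$threshold_height))
  cat(sprintf("  loglik: %.4f  null: %.4f  LRT: %.4f (df = %d), p = %.4g\n",
              x$loglik, x$null_loglik, x$lrt_stat, x$df, x$p_value))
  invisible(x)
}

#' @export
summary.gmyc <- function(object, ...) {
  print(object)
  cat(sprintf("  mixed:  lambda1 = %.4g (p1 = %.3g), lambda2 = %.4g (p2 = %.3g)\n",
              object$lambda1, object$p1, object$lambda2, object$p2))
  cat(sprintf("  null:   lambda0 = %.4g (p0 = %.3g)\n",
              object$lambda0, object$p0))
  sizes <- vapply(object$entities, length, 1L)
  cat(sprintf("  entity sizes: %s\n", paste(sizes, collapse = ", ")))
  invisible(object)
}

#' @export
logLik.gmyc <- function(object, ...) {
  structure(object$loglik, df = 4L + 1L, class = "logLik")
}

#' Lineages-through-time plot with the fitted GMYC threshold
#'
#' @param x A \code{\link{fit_gmyc}} object.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.gmyc <- function(x, ...) {
  h <- node_heights(x$tree)
  n_tip <- length(x$tree$tip.label)
  bh <- sort(h[(n_tip + 1L):(n_tip + x$tree$Nnode)], decreasing = TRUE)
  times <- c(max(h), bh, 0)
  lineages <- c(1L, seq_len(length(bh)) + 1L, n_tip)
  plot(-times, lineages, type = "s", log = "y",
       xlab = "height before present (subst/site)",
       ylab = "lineages", ...)
  abline(v = -x$threshold_height, col = "firebrick", lty = 2)
  invisible(x)
}
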