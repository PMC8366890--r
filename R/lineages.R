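# Lineage assignment and haplotype structures. The clock tree is a UPGMA
# tree built from the chosen distance model; the two subtrees of its root
# define the northern/southern partition. Haplotypes are exact sequence
# classes; the network is a minimum spanning tree over mismatch counts.

#' UPGMA ultrametric tree from a distance matrix
#'
#' Average-linkage agglomeration; the height of each internal node is half
#' the average distance between the two merged clusters, so leaf-to-leaf
#' path lengths reproduce cluster-average distances. Ties are broken by the
#' lexicographically smallest (cluster-representative) id pair, making the
#' result fully deterministic.
#'
#' @param dm A symmetric distance matrix with sample ids as dimnames
#'   (e.g. from \code{\link{distance_matrix}}).
#' @return A binary ultrametric \code{phylo}.
#' @export
upgma <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples")
  if (any(!is.finite(d))) stop("non-finite distances; cannot build UPGMA tree")
  ids <- rownames(d)
  # cluster state: representative id (lexicographic min) and member count
  reps <- ids
  sizes <- rep(1L, n)
  alive <- rep(TRUE, n)
  D <- d
  # collect merges first, then number internal nodes so the root is n+1
  merge_rec <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    av <- which(alive)
    best <- NULL
    for (ii in seq_along(av)[-length(av)]) {
      for (jj in (ii + 1L):length(av)) {
        i <- av[ii]; j <- av[jj]
        cand <- D[i, j]
        key <- sort(c(reps[i], reps[j]))
        if (is.null(best) || cand < best$d - 1e-15 ||
            (abs(cand - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = cand, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    merge_rec[[step]] <- list(i = i, j = j, h = h)
    # update distances: weighted average over member counts
    for (k in av) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (sizes[i] * D[i, k] + sizes[j] * D[j, k]) /
        (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    reps[i] <- min(reps[i], reps[j])
    alive[j] <- FALSE
    merge_rec[[step]]$new <- i
  }
  # ape numbering: the final merge is the root and must be node n+1;
  # earlier merges get larger numbers (step s -> n + 1 + (n-1-s))
  n_int <- n - 1L
  int_num <- n + 1L + (n_int - seq_len(n_int))
  cluster_node <- seq_len(n)
  cluster_height <- rep(0, n)
  edges <- matrix(0L, 2L * n_int, 2L)
  edge_len <- numeric(2L * n_int)
  e <- 0L
  for (step in seq_len(n_int)) {
    m <- merge_rec[[step]]
    parent <- int_num[step]
    for (childslot in c(m$i, m$j)) {
      e <- e + 1L
      edges[e, ] <- c(parent, cluster_node[childslot])
      edge_len[e] <- m$h - cluster_height[childslot]
    }
    cluster_node[m$new] <- parent
    cluster_height[m$new] <- m$h
  }
  tree <- structure(list(edge = edges, edge.length = pmax(edge_len, 0),
                         tip.label = ids, Nnode = n_int),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Assign samples to the northern or southern lineage
#'
#' The partition is the deepest split of the clock tree: the two subtrees of
#' the root. Labels are oriented by anchor ids when given (any anchor fixes
#' its group's label); otherwise the group containing the lexicographically
#' smallest sample id is called northern and the policy is recorded.
#'
#' @param tree Binary rooted ultrametric \code{phylo} with >= 2 leaves.
#' @param anchors Optional list with elements \code{northern} and/or
#'   \code{southern}, each a character vector of reference sample ids.
#' @return A list of class \code{lineage_assignment}: \code{labels} (named
#'   character vector over all tips), \code{split_depth} (root height),
#'   \code{anchor_policy}.
#' @export
assign_lineages <- function(tree, anchors = NULL) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("need at least 2 leaves")
  root <- n_tip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (length(kids) != 2L) stop("tree root must be binary")
  tips_under <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  g1 <- tips_under(kids[1L]); g2 <- tips_under(kids[2L])
  h <- node_heights(tree)
  split_depth <- h[root]
  pick <- NULL
  if (!is.null(anchors)) {
    side_of <- function(idset) {
      in1 <- any(idset %in% g1); in2 <- any(idset %in% g2)
      if (in1 && in2) stop("inconsistent anchors: ids span both root subtrees")
      if (in1) 1L else if (in2) 2L else NA_integer_
    }
    s_n <- if (!is.null(anchors$northern)) side_of(anchors$northern) else NA
    s_s <- if (!is.null(anchors$southern)) side_of(anchors$southern) else NA
    if (!is.na(s_n) && !is.na(s_s) && s_n == s_s)
      stop("inconsistent anchors: northern and southern anchors fall in the same root subtree")
    if (!is.na(s_n)) pick <- s_n
    else if (!is.na(s_s)) pick <- 3L - s_s
  }
  policy <- "anchored"
  if (is.null(pick)) {
    pick <- if (min(g1) <= min(g2)) 1L else 2L
    policy <- "lexicographic-smallest-id-is-northern"
  }
  north <- if (pick == 1L) g1 else g2
  labels <- stats::setNames(
    ifelse(tree$tip.label %in% north, "northern", "southern"),
    tree$tip.label)
  structure(list(labels = labels, split_depth = split_depth,
                 anchor_policy = policy),
            class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat(sprintf("<lineage assignment: %d northern, %d southern; split depth %.4g (%s)>\n",
              sum(x$labels == "northern"), sum(x$labels == "southern"),
              x$split_depth, x$anchor_policy))
  invisible(x)
}

#' Collapse identical sequences into haplotypes
#'
#' Strict row equality after case normalization; ambiguity codes are treated
#' as distinct symbols. Haplotype ids are assigned in first-occurrence order
#' (H1, H2, ...).
#'
#' @param alignment An \code{\link{hb_alignment}}.
#' @return A data frame of class \code{haplotype_table} with columns
#'   \code{haplotype}, \code{count}, \code{members} (list column), and
#'   attribute \code{sequences} (representative row per haplotype).
#' @export
collapse_haplotypes <- function(alignment) {
  mat <- unclass(alignment)
  key <- apply(mat, 1L, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  hap_of <- match(key, uniq)
  ids <- paste0("H", seq_along(uniq))
  members <- split(rownames(mat), factor(hap_of, seq_along(uniq)))
  out <- data.frame(haplotype = ids,
                    count = as.integer(lengths(members)),
                    stringsAsFactors = FALSE)
  out$members <- unname(members)
  reps <- mat[first, , drop = FALSE]
  rownames(reps) <- ids
  structure(out, sequences = reps,
            class = c("haplotype_table", "data.frame"))
}

# integer mismatch count over columns where both symbols are unambiguous
mismatch_count <- function(a, b) {
  ok <- a %in% UNAMBIG & b %in% UNAMBIG
  sum(a[ok] != b[ok])
}

#' Haplotype network as a minimum spanning tree
#'
#' Kruskal's algorithm over all haplotype pairs with integer mismatch-count
#' weights; ties are broken by (weight, lexicographically smaller id pair),
#' so the network is deterministic.
#'
#' @param haps A \code{\link{collapse_haplotypes}} table.
#' @return A list of class \code{haplotype_network} with \code{nodes} (the
#'   haplotype table without sequences) and \code{edges} (data frame
#'   \code{from}, \code{to}, \code{steps}).
#' @export
build_network <- function(haps) {
  reps <- attr(haps, "sequences")
  k <- nrow(haps)
  if (k < 1L) stop("need at least one haplotype")
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (k > 1L) {
    pairs <- utils::combn(k, 2L)
    w <- apply(pairs, 2L, function(ij)
      mismatch_count(reps[ij[1L], ], reps[ij[2L], ]))
    ord <- order(w, haps$haplotype[pairs[1L, ]], haps$haplotype[pairs[2L, ]])
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    taken <- 0L
    from <- character(k - 1L); to <- character(k - 1L); steps <- integer(k - 1L)
    for (e in ord) {
      i <- pairs[1L, e]; j <- pairs[2L, e]
      ri <- find(i); rj <- find(j)
      if (ri != rj) {
        parent[ri] <- rj
        taken <- taken + 1L
        from[taken] <- haps$haplotype[i]
        to[taken] <- haps$haplotype[j]
        steps[taken] <- w[e]
        if (taken == k - 1L) break
      }
    }
    edges <- data.frame(from = from, to = to, steps = steps,
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = haps[, c("haplotype", "count")], edges = edges),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype network: %d haplotypes, %d edges, total %d steps>\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$steps)))
  invisible(x)
}

#' Plot a haplotype network
#'
#' Simple force-free layout: nodes placed on a circle, circle area
#' proportional to haplotype count, edges annotated with step counts.
#'
#' @param x A \code{\link{build_network}} result.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.haplotype_network <- function(x, ...) {
  k <- nrow(x$nodes)
  th <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  xy <- cbind(cos(th), sin(th))
  rownames(xy) <- x$nodes$haplotype
  plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
       xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, ...)
  if (nrow(x$edges)) {
    segments(xy[x$edges$from, 1], xy[x$edges$from, 2],
             xy[x$edges$to, 1], xy[x$edges$to, 2], col = "grey50")
    mx <- (xy[x$edges$from, 1] + xy[x$edges$to, 1]) / 2
    my <- (xy[x$edges$from, 2] + xy[x$edges$to, 2]) / 2
    text(mx, my, x$edges$steps, cex = 0.7, col = "grey30")
  }
  r <- 0.08 * sqrt(x$nodes$count / max(x$nodes$count))
  symbols(xy[, 1], xy[, 2], circles = r, inches = FALSE, add = TRUE,
          bg = "steelblue")
  text(xy[, 1], xy[, 2] + r + 0.06, x$nodes$haplotype, cex = 0.8)
  invisible(x)
}
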