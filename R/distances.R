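# Pairwise genetic distances: uncorrected p, JC69, TN93, with pairwise
# deletion of gapped/ambiguous columns throughout. Sites where either symbol
# is '-', 'N' or any other ambiguity code are excluded pair by pair, which
# keeps partial GenBank fragments informative.

UNAMBIG <- c("A", "C", "G", "T")

#' Uncorrected p-distance between two aligned sequences
#'
#' Mismatches divided by the number of compared sites, with pairwise
#' deletion: columns where either symbol is a gap, \code{N}, or another
#' ambiguity code are excluded.
#'
#' @param a,b Character vectors of single symbols, equal length (rows of an
#'   \code{\link{hb_alignment}}).
#' @return A list with \code{p} (proportion in [0,1]) and \code{n_sites}
#'   (compared sites).
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% UNAMBIG & b %in% UNAMBIG
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  list(p = sum(a[ok] != b[ok]) / n, n_sites = n)
}

#' Jukes-Cantor correction of a p-distance
#'
#' d = -(3/4) log(1 - 4p/3). Saturated inputs (p >= 0.75) return \code{Inf}
#' with attribute \code{saturated = TRUE} rather than NaN.
#'
#' @param p Proportion of differing sites, in [0, 1].
#' @return Corrected distance (possibly \code{Inf} with a saturation flag).
#' @export
jc69_correct <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), Inf)
  attr(out, "saturated") <- p >= 0.75
  out
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Uses observed A<->G and C<->T transition proportions, the transversion
#' proportion, and base frequencies averaged over the two sequences.
#' Pairwise deletion as in \code{\link{p_distance}}. When a frequency class
#' is empty or a logarithm argument is non-positive the distance is
#' undefined; the function falls back to the JC69 correction of the
#' p-distance with a warning, flagged via attribute \code{fallback}.
#'
#' @param a,b Character vectors of single symbols, equal length.
#' @return Numeric distance with attributes \code{n_sites},
#'   \code{fallback}, \code{saturated}.
#' @export
tn93_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% UNAMBIG & b %in% UNAMBIG
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  a <- a[ok]; b <- b[ok]
  freq <- (table(factor(a, UNAMBIG)) + table(factor(b, UNAMBIG))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  pur <- a %in% c("A", "G") & b %in% c("A", "G")
  pyr <- a %in% c("C", "T") & b %in% c("C", "T")
  P1 <- sum(diff & pur) / n   # A<->G transitions
  P2 <- sum(diff & pyr) / n   # C<->T transitions
  Q <- sum(diff & !pur & !pyr) / n
  fallback <- function(msg) {
    warning("TN93 undefined (", msg, "); falling back to JC69")
    p <- sum(diff) / n
    d <- jc69_correct(p)
    structure(as.numeric(d), n_sites = n, fallback = TRUE,
              saturated = attr(d, "saturated"))
  }
  if (gA * gG == 0 || gC * gT == 0 || gR == 0 || gY == 0)
    return(fallback("empty frequency class"))
  w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    return(fallback("log argument <= 0"))
  d <- -2 * gA * gG / gR * log(w1) -
    2 * gC * gT / gY * log(w2) -
    2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
  structure(d, n_sites = n, fallback = FALSE, saturated = FALSE)
}

#' Pairwise distance matrix over an alignment
#'
#' @param alignment An \code{\link{hb_alignment}} with at least 2 samples.
#' @param model One of \code{"p"}, \code{"jc69"}, \code{"tn93"}.
#' @return A symmetric matrix of class \code{hb_distmat} with zero diagonal,
#'   sample ids as dimnames, and attributes \code{model} and
#'   \code{saturated} (logical matrix).
#' @export
distance_matrix <- function(alignment, model = c("p", "jc69", "tn93")) {
  model <- match.arg(model)
  mat <- unclass(alignment)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (model == "tn93") {
        v <- suppressWarnings(tn93_distance(mat[i, ], mat[j, ]))
        s <- isTRUE(attr(v, "saturated"))
      } else {
        p <- p_distance(mat[i, ], mat[j, ])$p
        if (model == "p") {
          v <- p; s <- FALSE
        } else {
          v <- jc69_correct(p)
          s <- attr(v, "saturated")
        }
      }
      d[i, j] <- d[j, i] <- as.numeric(v)
      sat[i, j] <- sat[j, i] <- s
    }
  }
  structure(d, model = model, saturated = sat,
            class = c("hb_distmat", "matrix"))
}

#' Mean genetic divergence between two groups of samples
#'
#' Arithmetic mean (plus min/max) of all between-group pairwise distances.
#'
#' @param dm An \code{\link{distance_matrix}} result.
#' @param group1,group2 Disjoint, nonempty character vectors of sample ids
#'   present in \code{dm}.
#' @return List with \code{mean}, \code{min}, \code{max}, \code{n_pairs},
#'   \code{model}.
#' @export
between_group_divergence <- function(dm, group1, group2) {
  if (!length(group1) || !length(group2)) stop("both groups must be nonempty")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  miss <- setdiff(c(group1, group2), rownames(dm))
  if (length(miss)) stop("ids not in distance matrix: ",
                         paste(miss, collapse = ", "))
  vals <- dm[group1, group2, drop = FALSE]
  list(mean = mean(vals), min = min(vals), max = max(vals),
       n_pairs = length(vals), model = attr(dm, "model"))
}
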