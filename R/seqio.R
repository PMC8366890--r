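# IO for the three formats the pipeline touches: aligned FASTA, tab-separated
# per-sample metadata, and Newick clock trees.

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")
HABITAT_LEVELS <- c("offshore_reef", "inshore_reef", "grass_bed", "other")

#' Construct an aligned sequence matrix
#'
#' An alignment is stored as a character matrix with one row per sample
#' (rownames are the sample ids) and one column per aligned site, symbols
#' uppercase and restricted to the IUPAC nucleotide alphabet plus \code{-}.
#'
#' @param mat Character matrix of single-character symbols with unique,
#'   non-empty rownames.
#' @return An object of class \code{hb_alignment} (a validated character
#'   matrix).
#' @export
hb_alignment <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat))
    stop("alignment must be a character matrix")
  ids <- rownames(mat)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("alignment rows must be named by sample id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample id in alignment: ", dup[1])
  if (ncol(mat) < 1L)
    stop("alignment must have at least one column")
  mat[] <- toupper(mat)
  bad <- which(!(mat %in% IUPAC_SYMBOLS))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf("non-IUPAC symbol '%s' in sample '%s' at position %d",
                 mat[bad[1]], ids[i], j))
  }
  structure(mat, class = c("hb_alignment", "matrix"))
}

#' @export
print.hb_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d samples x %d sites>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Accepts relaxed FASTA (wrapped or single-line records). All records must
#' have identical length; symbols are uppercased and validated against the
#' IUPAC nucleotide alphabet.
#'
#' @param path Path to a FASTA text file.
#' @return An \code{\link{hb_alignment}}; record order is preserved.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("not FASTA text: ", path)
  id_of <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], id_of[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), "")
  if (length(seqs) != length(ids)) stop("FASTA record with no sequence lines")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1])[1]
    stop(sprintf("ragged alignment: '%s' has length %d, expected %d",
                 ids[off], lens[off], lens[1]))
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(ids), byrow = TRUE)
  rownames(mat) <- ids
  hb_alignment(mat)
}

#' Write an alignment to FASTA
#'
#' @param alignment An \code{\link{hb_alignment}}.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(alignment, path, width = 70L) {
  seqs <- apply(unclass(alignment), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

normalize_habitat <- function(x) {
  key <- gsub("[ _]+", "_", tolower(trimws(x)))
  map <- c(offshore_reef = "offshore_reef",
           fore_reef = "offshore_reef",
           inshore_reef = "inshore_reef",
           inshore_patch_reef = "inshore_reef",
           patch_reef = "inshore_reef",
           grass_bed = "grass_bed",
           inshore_grass_bed = "grass_bed",
           grassbed = "grass_bed",
           other = "other")
  out <- unname(map[key])
  unknown <- unique(x[is.na(out) & !is.na(x)])
  if (length(unknown)) {
    warning("unrecognized habitat label(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
    out[is.na(out) & !is.na(x)] <- "other"
  }
  out
}

#' Construct a per-sample metadata table
#'
#' @param df Data frame with columns \code{sample_id}, \code{site},
#'   \code{habitat}, and optionally \code{region} and \code{lineage_truth}.
#'   Habitat labels are normalized case-insensitively (spaces and underscores
#'   equivalent); labels outside \{offshore reef, inshore reef, grass bed\}
#'   map to \code{other} with a warning.
#' @return A validated data frame of class \code{hb_metadata}.
#' @export
hb_metadata <- function(df) {
  req <- c("sample_id", "site", "habitat")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id in metadata: ", dup[1])
  df$site <- as.character(df$site)
  df$habitat <- normalize_habitat(as.character(df$habitat))
  if (is.null(df$region)) df$region <- NA_character_
  df$region <- as.character(df$region)
  if (!is.null(df$lineage_truth)) {
    lt <- as.character(df$lineage_truth)
    if (!all(lt %in% c("northern", "southern", NA)))
      stop("lineage_truth must be 'northern' or 'southern'")
    df$lineage_truth <- lt
  }
  keep <- intersect(c("sample_id", "site", "habitat", "region", "lineage_truth"),
                    names(df))
  out <- df[, keep, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hb_metadata", "data.frame")
  out
}

#' Read a tab-separated metadata table
#'
#' Expects a header with at least \code{sample_id}, \code{site},
#' \code{habitat}; \code{region} and \code{lineage_truth} are optional.
#'
#' @param path Path to a TSV file.
#' @return An \code{\link{hb_metadata}} data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  hb_metadata(df)
}

#' Write a metadata table as TSV
#'
#' @param metadata An \code{\link{hb_metadata}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Join an alignment and metadata into one validated dataset
#'
#' Keeps the intersection of the two id sets; ids present on one side only
#' are dropped with a warning (mixed GenBank/new-collection inputs routinely
#' disagree on coverage).
#'
#' @param alignment An \code{\link{hb_alignment}}.
#' @param metadata An \code{\link{hb_metadata}}.
#' @return A list of class \code{hb_dataset} with elements \code{alignment}
#'   and \code{metadata}, restricted to the shared sample ids.
#' @export
make_dataset <- function(alignment, metadata) {
  a_ids <- rownames(alignment)
  m_ids <- metadata$sample_id
  keep <- intersect(a_ids, m_ids)
  if (!length(keep))
    stop("empty dataset: alignment and metadata share no sample ids")
  drop_a <- setdiff(a_ids, keep)
  drop_m <- setdiff(m_ids, keep)
  if (length(drop_a) || length(drop_m))
    warning(sprintf("dropped %d alignment-only and %d metadata-only sample(s)",
                    length(drop_a), length(drop_m)))
  md <- metadata[match(keep, m_ids), , drop = FALSE]
  rownames(md) <- NULL
  class(md) <- c("hb_metadata", "data.frame")
  structure(list(alignment = hb_alignment(unclass(alignment)[keep, , drop = FALSE]),
                 metadata = md),
            class = "hb_dataset")
}

#' @export
print.hb_dataset <- function(x, ...) {
  cat(sprintf("<dataset: %d samples, %d sites, %d site label(s), habitats: %s>\n",
              nrow(x$alignment), ncol(x$alignment),
              length(unique(x$metadata$site)),
              paste(sort(unique(x$metadata$habitat)), collapse = ", ")))
  invisible(x)
}

#' Heights of all nodes above the leaves of an ultrametric tree
#'
#' @param tree An \code{ape} \code{phylo} object with branch lengths.
#' @return Numeric vector of node heights (distance above the leaf level),
#'   indexed by ape node number (tips first, then internal nodes).
#' @export
node_heights <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- numeric(n_all)  # distance from root
  root <- n_tip + 1L
  ord <- rev(ape::postorder(tree))  # edges parent-first
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    depth[ch] <- depth[p] + tree$edge.length[e]
  }
  max(depth[seq_len(n_tip)]) - depth
}

validate_ultrametric <- function(tree, tol = 1e-6) {
  h <- node_heights(tree)
  tip_h <- h[seq_len(length(tree$tip.label))]
  height <- max(h)
  spread <- max(tip_h) - min(tip_h)
  if (spread > tol * max(height, .Machine$double.eps))
    stop(sprintf("tree is not ultrametric: leaf-height spread %.3g exceeds tolerance %.3g",
                 spread, tol * height))
  invisible(tree)
}

resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  # deterministic resolution: order children by sorted labels, zero-length splits
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::multi2di(tree, random = FALSE)
}

#' Read a rooted ultrametric tree from Newick
#'
#' Strips comments, resolves polytomies deterministically with zero-length
#' branches, and validates ultrametricity (maximum leaf-depth spread at most
#' \code{tol} times the tree height).
#'
#' @param path Path to a Newick file containing a single rooted tree with
#'   branch lengths.
#' @param tol Relative ultrametricity tolerance.
#' @return An \code{ape} \code{phylo} object, binary and ultrametric.
#' @export
read_newick <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths: ", path)
  tree <- resolve_polytomies(tree)
  validate_ultrametric(tree, tol = tol)
  tree
}

#' Write a tree to Newick
#'
#' @param tree An \code{ape} \code{phylo} object.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
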