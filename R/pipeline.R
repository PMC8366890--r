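# End-to-end orchestration: distances -> clock tree -> lineage assignment ->
# haplotypes/network -> frequency tables -> pairwise Fst (pooled by habitat
# and per site) -> GMYC, gathered into one machine-readable report.

#' Analysis configuration
#'
#' @param allele_mode Allele definition for Fst: \code{"haplotype"} or
#'   \code{"lineage"}.
#' @param model Distance model: \code{"p"}, \code{"jc69"} or \code{"tn93"}.
#' @param n_perm Monte-Carlo permutations per Fst pair (>= 99).
#' @param seed Integer seed for the permutation draws.
#' @param gmyc_df Chi-squared df for the GMYC LRT (3 or 2).
#' @param pool_habitats Run the habitat-pooled analysis.
#' @param by_site Also run the unpooled site-level analysis.
#' @param anchors Optional anchors for \code{\link{assign_lineages}}.
#' @param tree Optional user-supplied ultrametric \code{phylo} (e.g. an
#'   externally inferred clock tree) used in place of the UPGMA tree.
#' @param holm Add Holm-adjusted p-values to Fst tables.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(allele_mode = c("haplotype", "lineage"),
                            model = c("p", "jc69", "tn93"),
                            n_perm = 9999, seed = NULL, gmyc_df = 3,
                            pool_habitats = TRUE, by_site = TRUE,
                            anchors = NULL, tree = NULL, holm = FALSE) {
  allele_mode <- match.arg(allele_mode)
  model <- match.arg(model)
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!gmyc_df %in% c(2, 3)) stop("gmyc_df must be 2 or 3")
  structure(list(allele_mode = allele_mode, model = model,
                 n_perm = as.integer(n_perm), seed = seed,
                 gmyc_df = gmyc_df, pool_habitats = pool_habitats,
                 by_site = by_site, anchors = anchors, tree = tree,
                 holm = holm),
            class = "analysis_config")
}

#' Run the full analysis
#'
#' Computes the distance matrix, the UPGMA clock tree (unless a tree is
#' supplied), the northern/southern lineage assignment, haplotype table and
#' network, lineage-frequency tables per site/habitat/region, pairwise Nei
#' Fst with permutation p-values (habitat-pooled and site-level), the
#' between-lineage divergence summary under both p and TN93, and the GMYC
#' fit. Stages needing >= 3 samples (Fst, GMYC) are skipped with a notice
#' on smaller inputs; independent stage failures are recorded rather than
#' aborting the run.
#'
#' @param dataset An \code{hb_dataset}.
#' @param config An \code{\link{analysis_config}}.
#' @return A list of class \code{hb_report}.
#' @export
analyze <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "hb_dataset"))
  if (!is.null(config$seed)) set.seed(config$seed)
  notices <- character(0)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  n <- nrow(dataset$alignment)
  dm <- stage("distances", distance_matrix(dataset$alignment, config$model))
  tree <- config$tree
  if (is.null(tree) && !is.null(dm) && n >= 2L)
    tree <- stage("upgma", upgma(dm))
  assignment <- if (!is.null(tree))
    stage("lineages", assign_lineages(tree, config$anchors)) else NULL
  haps <- stage("haplotypes", collapse_haplotypes(dataset$alignment))
  network <- if (!is.null(haps)) stage("network", build_network(haps)) else NULL
  freq <- list()
  if (!is.null(assignment)) {
    for (g in c("site", "habitat", "region"))
      freq[[g]] <- stage(paste0("freq_", g),
                         frequency_table(dataset, assignment, g))
  }
  fst_habitat <- NULL
  fst_site <- NULL
  if (n >= 3L) {
    if (config$pool_habitats)
      fst_habitat <- stage("fst_habitat",
        pairwise_fst(dataset, "habitat", config$allele_mode,
                     assignment = assignment, n_perm = config$n_perm,
                     holm = config$holm))
    if (config$by_site)
      fst_site <- stage("fst_site",
        pairwise_fst(dataset, "site", config$allele_mode,
                     assignment = assignment, n_perm = config$n_perm,
                     holm = config$holm))
  } else {
    notices <- c(notices, "fewer than 3 samples: Fst stage skipped")
  }
  divergence <- NULL
  if (!is.null(assignment) &&
      length(unique(assignment$labels)) == 2L) {
    north <- names(assignment$labels)[assignment$labels == "northern"]
    south <- names(assignment$labels)[assignment$labels == "southern"]
    dm_p <- if (identical(config$model, "p")) dm
            else stage("divergence_p", distance_matrix(dataset$alignment, "p"))
    dm_tn <- if (identical(config$model, "tn93")) dm
             else stage("divergence_tn93",
                        suppressWarnings(distance_matrix(dataset$alignment, "tn93")))
    divergence <- list(
      p = if (!is.null(dm_p)) between_group_divergence(dm_p, north, south),
      tn93 = if (!is.null(dm_tn)) between_group_divergence(dm_tn, north, south))
  }
  # GMYC runs on one tip per haplotype: identical sequences produce
  # zero-length branches whose tied, zero-duration intervals degenerate the
  # threshold likelihood (standard GMYC practice removes duplicates).
  # Entities are expanded back to samples afterwards. A user-supplied tree
  # is used as given.
  gmyc_fit <- NULL
  if (n >= 3L && !is.null(haps)) {
    if (!is.null(config$tree)) {
      gmyc_fit <- stage("gmyc", fit_gmyc(config$tree, df = config$gmyc_df))
    } else if (nrow(haps) >= 3L) {
      gmyc_fit <- stage("gmyc", {
        hap_aln <- attr(haps, "sequences")
        hdm <- distance_matrix(hb_alignment(hap_aln), config$model)
        fit <- fit_gmyc(upgma(hdm), df = config$gmyc_df)
        members <- stats::setNames(haps$members, haps$haplotype)
        fit$entities <- lapply(fit$entities, function(hs)
          unlist(members[hs], use.names = FALSE))
        fit
      })
    } else {
      notices <- c(notices, "fewer than 3 haplotypes: GMYC stage skipped")
    }
  } else if (n < 3L) {
    notices <- c(notices, "fewer than 3 samples: GMYC stage skipped")
  }
  structure(list(
    n_samples = n, n_sites = ncol(dataset$alignment),
    tree = tree, assignment = assignment, haplotypes = haps,
    network = network, frequencies = freq,
    fst_habitat = fst_habitat, fst_site = fst_site,
    divergence = divergence, gmyc = gmyc_fit,
    notices = notices, errors = errors,
    provenance = list(config = config[setdiff(names(config), "tree")],
                      fst_variant = FST_VARIANT,
                      network_method = "minimum-spanning-tree (Kruskal)",
                      package_version = as.character(utils::packageVersion("haplohab")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "hb_report")
}

#' @export
print.hb_report <- function(x, ...) {
  cat(sprintf("Analysis report: %d samples, %d sites\n", x$n_samples, x$n_sites))
  if (!is.null(x$assignment))
    cat(sprintf("  lineages: %d northern / %d southern\n",
                sum(x$assignment$labels == "northern"),
                sum(x$assignment$labels == "southern")))
  if (!is.null(x$divergence) && !is.null(x$divergence$p))
    cat(sprintf("  between-lineage divergence: %.2f%% (p), %.2f%% (TN93)\n",
                100 * x$divergence$p$mean,
                if (!is.null(x$divergence$tn93)) 100 * x$divergence$tn93$mean else NA))
  if (!is.null(x$haplotypes))
    cat(sprintf("  haplotypes: %d\n", nrow(x$haplotypes)))
  if (!is.null(x$fst_habitat)) {
    cat("  habitat-pooled Fst:\n")
    print(x$fst_habitat$table[, c("group1", "group2", "n1", "n2", "fst", "p")],
          row.names = FALSE)
  }
  if (!is.null(x$gmyc))
    cat(sprintf("  GMYC: %d entities, LRT p = %.4g\n",
                x$gmyc$n_clusters, x$gmyc$p_value))
  for (nt in x$notices) cat("  note: ", nt, "\n", sep = "")
  for (en in names(x$errors))
    cat("  stage error [", en, "]: ", x$errors[[en]], "\n", sep = "")
  invisible(x)
}

report_json <- function(report) {
  keep <- list(
    n_samples = report$n_samples,
    n_sites = report$n_sites,
    lineage_counts = if (!is.null(report$assignment))
      as.list(table(report$assignment$labels)),
    split_depth = if (!is.null(report$assignment)) report$assignment$split_depth,
    divergence = report$divergence,
    n_haplotypes = if (!is.null(report$haplotypes)) nrow(report$haplotypes),
    network_edges = if (!is.null(report$network)) report$network$edges,
    frequencies = report$frequencies,
    fst_habitat = if (!is.null(report$fst_habitat)) report$fst_habitat$table,
    fst_site = if (!is.null(report$fst_site)) report$fst_site$table,
    gmyc = if (!is.null(report$gmyc))
      report$gmyc[c("threshold_height", "lambda1", "p1", "lambda2", "p2",
                    "loglik", "null_loglik", "lrt_stat", "df", "p_value",
                    "n_clusters")],
    notices = report$notices,
    errors = report$errors,
    provenance = report$provenance)
  jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Write a report to disk
#'
#' Emits \code{report.json} plus TSV tables \code{fst_pairs.tsv} (pooled and
#' site-level stacked, with a \code{level} column) and
#' \code{frequencies.tsv}.
#'
#' @param report An \code{\link{analyze}} result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  fst <- list()
  if (!is.null(report$fst_habitat))
    fst$habitat <- cbind(level = "habitat", report$fst_habitat$table)
  if (!is.null(report$fst_site))
    fst$site <- cbind(level = "site", report$fst_site$table)
  if (length(fst))
    utils::write.table(do.call(rbind, fst), file.path(dir, "fst_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report$frequencies)) {
    tabs <- lapply(names(report$frequencies), function(g)
      cbind(level = g, report$frequencies[[g]]))
    utils::write.table(do.call(rbind, tabs),
                       file.path(dir, "frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write a simulated FASTA + metadata TSV),
#' \code{analyze} (FASTA + TSV to a report directory), \code{power}
#' (error-rate calibration), \code{benchmark} (analyze a local copy of a
#' deposited alignment). Returns an exit status instead of calling
#' \code{quit()} so it is testable in-process.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit status (0 success, 2 usage/validation error).
#' @export
cli_main <- function(argv) {
  usage <- paste(
    "usage: haplohab <simulate|analyze|power|benchmark> [options]",
    "  simulate  --out DIR [--seed N] [--alpha X] [--tau X] [--theta X]",
    "  analyze   --fasta FILE --metadata FILE --out DIR [--seed N]",
    "            [--n-perm N] [--model p|jc69|tn93]",
    "            [--allele-mode haplotype|lineage] [--gmyc-df 2|3]",
    "            [--no-pooling] [--tree FILE]",
    "  power     --replicates N [--seed N] [--alpha X] [--level X]",
    "  benchmark --fasta FILE --metadata FILE --out DIR [--seed N]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  if (inherits(opts, "cli-error")) { message(opts); message(usage); return(2L) }
  get <- function(key, default = NULL) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  ok <- tryCatch({
    if (cmd == "simulate") {
      out <- get("out"); if (is.null(out)) stop("--out is required")
      cfg <- sim_config(alpha = as.numeric(get("alpha", 0)),
                        tau = as.numeric(get("tau", 0.0225)),
                        theta = as.numeric(get("theta", 0.005)),
                        seed = as.integer(get("seed", 1)))
      sim <- simulate_dataset(cfg)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_alignment(sim$dataset$alignment, file.path(out, "alignment.fasta"))
      write_metadata(sim$dataset$metadata, file.path(out, "metadata.tsv"))
      write_newick(sim$genealogy, file.path(out, "genealogy.nwk"))
      message("wrote simulated dataset to ", out)
    } else if (cmd %in% c("analyze", "benchmark")) {
      fasta <- get("fasta"); meta <- get("metadata"); out <- get("out")
      if (is.null(fasta) || is.null(meta) || is.null(out))
        stop("--fasta, --metadata and --out are required")
      if (!file.exists(fasta)) stop("input file not found: ", fasta)
      if (!file.exists(meta)) stop("input file not found: ", meta)
      ds <- make_dataset(read_alignment(fasta), read_metadata(meta))
      tree <- if (!is.null(get("tree"))) read_newick(get("tree"))
      cfg <- analysis_config(
        allele_mode = get("allele-mode", "haplotype"),
        model = get("model", "p"),
        n_perm = as.integer(get("n-perm", 9999)),
        seed = as.integer(get("seed", 1)),
        gmyc_df = as.numeric(get("gmyc-df", 3)),
        pool_habitats = is.null(opts[["no-pooling"]]),
        tree = tree)
      rep <- analyze(ds, cfg)
      write_report(rep, out)
      message("wrote report to ", out)
    } else if (cmd == "power") {
      reps <- get("replicates")
      if (is.null(reps)) stop("--replicates is required")
      cfg <- sim_config(alpha = as.numeric(get("alpha", 0)),
                        seed = as.integer(get("seed", 1)))
      res <- estimate_error_rates(cfg, as.integer(reps),
                                  nominal_level = as.numeric(get("level", 0.05)))
      cat(sprintf("habitat_reject_raw\t%.4f\t(se %.4f)\n",
                  res$habitat_reject_raw, res$habitat_reject_raw_se))
      cat(sprintf("habitat_reject_holm\t%.4f\t(se %.4f)\n",
                  res$habitat_reject_holm, res$habitat_reject_holm_se))
    } else {
      stop("unknown subcommand: ", cmd)
    }
    TRUE
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    FALSE
  })
  if (ok) 0L else 2L
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  flags <- c("no-pooling")
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      return(structure(paste("unexpected argument:", a), class = "cli-error"))
    key <- substring(a, 3)
    if (key %in% flags) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args))
        return(structure(paste("missing value for --", key), class = "cli-error"))
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
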