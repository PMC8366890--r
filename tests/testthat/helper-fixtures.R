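# Small in-code fixtures shared across test files.

aln_from_strings <- function(seqs) {
  mat <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(seqs)
  hb_alignment(mat)
}

tiny_metadata <- function(ids, habitat = "offshore reef", site = "s1") {
  hb_metadata(data.frame(sample_id = ids, site = site, habitat = habitat,
                         stringsAsFactors = FALSE))
}

two_site_config <- function(n1 = 10, n2 = 10, tau = 0.0225, theta = 0.005,
                            alpha = 1, seed = NULL) {
  sim_config(sites = data.frame(name = c("off", "in"),
                                habitat = c("offshore_reef", "inshore_reef"),
                                n = c(n1, n2), stringsAsFactors = FALSE),
             tau = tau, theta = theta, alpha = alpha, seed = seed)
}

one_pop_config <- function(n = 20, theta = 0.005, seed = NULL) {
  sim_config(sites = data.frame(name = "pop", habitat = "other", n = n,
                                stringsAsFactors = FALSE),
             tau = 0, theta = theta, alpha = 0, seed = seed)
}
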