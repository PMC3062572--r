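# In-code fixtures: tiny code sets and count matrices used across tests.

tiny_codeset <- function() {
  codeset(data.frame(
    gene_id = c("g1", "g2", "g3", "POS_A", "POS_B", "NEG_A", "NEG_B"),
    probe_class = c("target", "target", "target",
                    "positive", "positive", "negative", "negative"),
    spike_fmol = c(NA, NA, NA, 0.5, 2, NA, NA),
    stringsAsFactors = FALSE))
}

# build a count_matrix from a probes x samples matrix (rownames = gene ids)
tiny_counts <- function(mat, cs = tiny_codeset(), state = "raw",
                        meta = NULL) {
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
  }
  count_matrix(mat, cs, meta, state)
}

# a random count matrix with a random class partition, for oracle tests
random_count_matrix <- function(n_probes, n_samples, state = "raw") {
  classes <- sample(c("target", "positive", "negative"), n_probes,
                    replace = TRUE)
  # guarantee at least one probe per class
  classes[sample(n_probes, 3)] <- c("target", "positive", "negative")
  cs <- codeset(data.frame(
    gene_id = sprintf("p%03d", seq_len(n_probes)),
    probe_class = classes,
    spike_fmol = ifelse(classes == "positive",
                        2^(seq_len(n_probes) %% 5), NA),
    stringsAsFactors = FALSE))
  mat <- matrix(rpois(n_probes * n_samples, 200), n_probes, n_samples,
                dimnames = list(cs$gene_id,
                                sprintf("s%02d", seq_len(n_samples))))
  tiny_counts(mat, cs, state)
}

# a noise-free expression profile from a plain means matrix
profile_from_means <- function(means, n = 3) {
  expression_profile(means, means * 0,
                     stats::setNames(rep(n, ncol(means)), colnames(means)))
}

# Fig-3-style deletion summaries (printed residual means +/- SD)
deletion_panel <- function() {
  data.frame(gene_id = c("ins-4", "ins-5", "ins-6"),
             wildtype_mean = c(1500, 1500, 2000),
             deletion_mean = c(31, 124, 137),
             deletion_sd = c(2, 55, 53),
             n_replicates = 3,
             stringsAsFactors = FALSE)
}
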