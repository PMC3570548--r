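# Shared fixtures, built in code.  Expensive objects are memoized per test
# run so several test files can reuse the same trained ensemble.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# reference-like training cohort (240 samples, 73/115/52) and its features
wright_features <- function() memo("wright_features", {
  co <- simulate_cohort(cohort_spec(seed = 0))
  z <- gene_zscores(merge_probes(quantile_normalize(co$expression),
                                 co$probe_map))
  list(features = assemble_features(z, dac_classifier_genes()$gene),
       labels = co$labels)
})

# default four-learner ensemble trained on the reference-like cohort
wright_fit <- function() memo("wright_fit", {
  w <- wright_features()
  dac(w$features, w$labels, seed = 0L)
})

# gene-level features for any simulated probe-level cohort
cohort_features <- function(cohort,
                            genes = dac_classifier_genes()$gene) {
  z <- gene_zscores(merge_probes(quantile_normalize(cohort$expression),
                                 cohort$probe_map))
  assemble_features(z, genes)
}

# linearly separable two-gene toy: ABC high on gene1, GCB high on gene2
toy_separable <- function(n = 20L, seed = 1L) {
  set.seed(seed)
  y <- rep(c("ABC", "GCB"), each = n / 2)
  x <- cbind(gene1 = ifelse(y == "ABC", 3, -3) + rnorm(n, 0, 0.3),
             gene2 = ifelse(y == "GCB", 3, -3) + rnorm(n, 0, 0.3))
  rownames(x) <- paste0("S", seq_len(n))
  list(features = x, labels = y)
}

calls_df <- function(sample_id, predicted,
                     confidence = rep(1, length(sample_id))) {
  data.frame(sample_id = sample_id, predicted = predicted,
             P_ABC = NA_real_, P_GCB = NA_real_, P_TYPE_III = NA_real_,
             confidence = confidence, stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
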