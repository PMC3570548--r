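#' Hypergeometric enrichment/depletion test
#'
#' For a draw of `n` genes from a population of `N` containing `K`
#' signature genes, with `k` observed hits:
#' `p_enriched = P(X >= k)` and `p_depleted = P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  The draw is the differentially expressed
#' gene list, the successes the signature genes, the population the genes
#' on the platform.
#'
#' @param k observed overlap.
#' @param K signature genes in the population.
#' @param n draw size.
#' @param N population size.
#' @return `list(p_enriched=, p_depleted=, enriched=)`; `enriched` is
#'   `TRUE` iff `p_enriched < p_depleted`.
#' @export
hypergeometric_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || min(n, K) > N || n > N ||
      K > N)
    stop("inconsistent hypergeometric counts")
  p_enr <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_dep <- phyper(k, K, N - K, n)
  list(p_enriched = p_enr, p_depleted = p_dep, enriched = p_enr < p_dep)
}

#' Monte-Carlo null moments of the overlap count
#'
#' Empirical mean and sd of the overlap between a random draw of `n` genes
#' (without replacement from a population of `N` containing `K` signature
#' genes) and the signature, over `n_samplings` repetitions.  Each
#' repetition's hit count is a hypergeometric draw, sampled directly.
#'
#' @param K signature genes in the population.
#' @param n draw size.
#' @param N population size.
#' @param n_samplings number of random draws (>= 1000; the published
#'   analyses use 1e6 for signatures and 1e7 for pairwise comparisons).
#' @param seed integer seed.
#' @return `list(mu_rand=, sd_rand=)`.
#' @export
mc_null_moments <- function(K, n, N, n_samplings = 1e6, seed = 0L) {
  if (n > N) stop("draw larger than population")
  if (n_samplings < 1000) stop("use >= 1000 samplings")
  if (K == 0) return(list(mu_rand = 0, sd_rand = 0))
  set.seed(seed)
  hits <- rhyper(n_samplings, K, N - K, n)
  list(mu_rand = mean(hits), sd_rand = sd(hits))
}

# one reporter row from overlap counts; the %Overlap / Z / p conventions
# shared by the signature screen and the acceptance checks
enrichment_row <- function(name, source, k, K, n, N, n_samplings, seed,
                           genes = character(0), excluded = character(0)) {
  ht <- hypergeometric_test(k, K, n, N)
  mc <- mc_null_moments(K, n, N, n_samplings, seed)
  z <- if (mc$sd_rand > 0) (k - mc$mu_rand) / mc$sd_rand else 0
  data.frame(signature = name, source = source, overlapping = k,
             sig_size = K, draw_size = n, population_size = N,
             random_avg = mc$mu_rand, random_sd = mc$sd_rand,
             pct_overlap = 100 * k / K, zscore = z,
             p_enriched = ht$p_enriched, p_depleted = ht$p_depleted,
             enriched = ht$enriched,
             genes = paste(genes, collapse = "|"),
             excluded_genes = paste(excluded, collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Signature enrichment screen for a gene profile
#'
#' Tests a profile (e.g. a class meta-profile or one data set's
#' class-associated list) against a signature collection with the
#' hypergeometric test plus a Monte-Carlo empirical-null Z-score.  The
#' classifier genes are removed from every signature and from the draw
#' before testing, to avoid the trivial enrichment of the genes the
#' classifier was trained on; removed genes are reported per signature in
#' `excluded_genes`.  FDR is Benjamini-Hochberg over the hypergeometric
#' enrichment p across all signatures tested.
#'
#' @param profile_genes character vector (the draw, before exclusion).
#' @param signatures list of `list(name, source, genes)` ([read_gmt()]).
#' @param population character vector: genes on the platform.
#' @param classifier_genes genes to exclude (default the shipped panel).
#' @param alpha FDR cut-off for the `significant` flag.
#' @param n_samplings Monte-Carlo draws per signature (default 1e6).
#' @param seed integer seed.
#' @return `dac_enrichment` data.frame, one row per testable signature,
#'   with the reporter columns `signature`, `source`, `overlapping`,
#'   `sig_size`, `random_avg`, `random_sd`, `pct_overlap`, `zscore`,
#'   `p_enriched`, `fdr`, `enriched`, `significant`, `genes`,
#'   `excluded_genes`.  Signatures empty after exclusion are skipped and
#'   listed in the `skipped` attribute.
#' @export
signature_enrichment <- function(profile_genes, signatures, population,
                                 classifier_genes = dac_classifier_genes()$gene,
                                 alpha = 0.05, n_samplings = 1e6, seed = 0L) {
  population <- unique(population)
  draw <- setdiff(intersect(profile_genes, population), classifier_genes)
  pop <- setdiff(population, classifier_genes)
  n <- length(draw)
  N <- length(pop)
  rows <- vector("list", length(signatures))
  skipped <- character(0)
  for (i in seq_along(signatures)) {
    s <- signatures[[i]]
    excluded <- intersect(s$genes, classifier_genes)
    sig <- setdiff(intersect(s$genes, population), classifier_genes)
    if (!length(sig)) {
      skipped <- c(skipped, s$name)
      next
    }
    k <- length(intersect(draw, sig))
    rows[[i]] <- enrichment_row(s$name, s$source %||% "", k, length(sig),
                                n, N, n_samplings, seed + i,
                                genes = intersect(draw, sig),
                                excluded = excluded)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no testable signatures")
  out$fdr <- p.adjust(out$p_enriched, method = "BH")
  out$significant <- out$fdr < alpha
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("dac_enrichment", "data.frame")
  out
}

#' Build a reporter row directly from overlap counts
#'
#' Recomputes the full enrichment reporter row (percentage overlap,
#' hypergeometric p, Monte-Carlo null moments and Z) from already-counted
#' `(overlapping, signature size, draw size, population size)` values --
#' useful to audit published enrichment tables without the underlying gene
#' lists.
#'
#' @param k observed overlap (`Overlapping`).
#' @param sig_size signature size after classifier-gene removal
#'   (`GeneSigSize`).
#' @param draw_size profile size.
#' @param population_size platform gene count.
#' @param name,source labels for the row.
#' @param n_samplings,seed Monte-Carlo settings.
#' @return One-row data.frame with the reporter columns (see
#'   [signature_enrichment()]).
#' @export
enrichment_from_counts <- function(k, sig_size, draw_size, population_size,
                                   name = "signature", source = "",
                                   n_samplings = 1e5, seed = 0L) {
  enrichment_row(name, source, k, sig_size, draw_size,
                 population_size, n_samplings, seed)
}

#' Write an enrichment table in the published column layout
#'
#' TSV with columns `Gene Signature`, `Overlapping`, `GeneSigSize`,
#' `randomAvg`, `randomSD`, `%Overlap`, `Zscore`, `FDR`, `Source`,
#' `EnrichedGenes` (pipe-separated, with excluded classifier genes after an
#' `EXCLUDED_GENES:` tag).  Percentages and Z to two decimals.
#'
#' @param x `dac_enrichment` table.
#' @param path output file.
#' @export
write_enrichment <- function(x, path) {
  genes <- ifelse(nzchar(x$excluded_genes),
                  paste0(x$genes, "|EXCLUDED_GENES:", x$excluded_genes),
                  x$genes)
  out <- data.frame(`Gene Signature` = x$signature,
                    Overlapping = x$overlapping, GeneSigSize = x$sig_size,
                    randomAvg = round(x$random_avg, 2),
                    randomSD = round(x$random_sd, 2),
                    `%Overlap` = round(x$pct_overlap, 2),
                    Zscore = round(x$zscore, 2),
                    FDR = signif(x$fdr, 3), Source = x$source,
                    EnrichedGenes = genes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
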