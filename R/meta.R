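#' Pairwise dataset concordance of class-associated gene lists
#'
#' For every ordered pair of data sets and each class, the second data
#' set's class-associated list is treated as the signature, the first's as
#' the draw, and the first's platform gene set as the population; the
#' overlap is standardized against the Monte-Carlo null
#' ([mc_null_moments()]).  The four Z-scores per unordered pair (two
#' directions x ABC/GCB) are averaged into one symmetric matrix.
#'
#' @param class_lists named list per data set of `list(ABC=, GCB=)`
#'   character vectors (see [class_associated_lists()]).
#' @param populations named list per data set of platform gene vectors.
#' @param n_samplings Monte-Carlo draws (published analyses use 1e7).
#' @param seed integer seed.
#' @return Symmetric numeric matrix of averaged Z-scores, `NA` diagonal;
#'   cells involving a data set with an empty class list are `NA`.
#' @export
pairwise_dataset_concordance <- function(class_lists, populations,
                                         n_samplings = 1e7, seed = 0L) {
  ds <- names(class_lists)
  z_dir <- function(i, j, cls, offset) {
    draw <- intersect(class_lists[[i]][[cls]], populations[[i]])
    sig <- intersect(class_lists[[j]][[cls]], populations[[i]])
    if (!length(draw) || !length(sig)) return(NA_real_)
    N <- length(unique(populations[[i]]))
    k <- length(intersect(draw, sig))
    mc <- mc_null_moments(length(sig), length(draw), N, n_samplings,
                          seed + offset)
    if (mc$sd_rand == 0) return(0)
    (k - mc$mu_rand) / mc$sd_rand
  }
  out <- matrix(NA_real_, length(ds), length(ds), dimnames = list(ds, ds))
  off <- 0L
  for (a in seq_along(ds)) for (b in seq_along(ds)) if (a < b) {
    zs <- c(z_dir(ds[a], ds[b], "ABC", off + 1L),
            z_dir(ds[b], ds[a], "ABC", off + 2L),
            z_dir(ds[a], ds[b], "GCB", off + 3L),
            z_dir(ds[b], ds[a], "GCB", off + 4L))
    off <- off + 4L
    out[a, b] <- out[b, a] <- if (anyNA(zs)) NA_real_ else mean(zs)
  }
  out
}

#' Build a class meta-profile across data sets
#'
#' Ranks genes by the consistency of their class association across data
#' sets: `num_files` = number of data sets in which the gene was
#' class-associated, `median_nfc` = median of its normalized fold change
#' over those data sets, `pct_present` = percentage of the data sets whose
#' platform carries the gene in which it was associated.  Genes associated
#' in at least `min_datasets` data sets are kept, sorted by
#' (`num_files` desc, `median_nfc` desc).
#'
#' @param class_lists list per data set: character vector of the
#'   class-associated genes for the class being profiled.
#' @param nfc list per data set: named numeric NFC vectors
#'   ([normalized_fold_change()], the component for this class).
#' @param min_datasets inclusion threshold (default 6, i.e. at least half
#'   of 11 data sets).
#' @param platforms optional list per data set of platform gene vectors;
#'   when omitted every platform is assumed to carry every gene.
#' @return data.frame `gene`, `median_nfc`, `num_files`, `pct_present`,
#'   sorted as above.
#' @export
build_meta_profile <- function(class_lists, nfc, min_datasets = 6L,
                               platforms = NULL) {
  genes <- sort(unique(unlist(class_lists)))
  if (!length(genes))
    return(data.frame(gene = character(0), median_nfc = numeric(0),
                      num_files = integer(0), pct_present = numeric(0)))
  num_files <- vapply(genes, function(g)
    sum(vapply(class_lists, function(l) g %in% l, TRUE)), 0L)
  med_nfc <- vapply(genes, function(g) {
    v <- unlist(lapply(nfc, function(x) unname(x[g])))
    median(v, na.rm = TRUE)
  }, 0)
  carrying <- if (is.null(platforms)) rep(length(class_lists), length(genes))
    else vapply(genes, function(g)
      sum(vapply(platforms, function(p) g %in% p, TRUE)), 0L)
  pct_present <- 100 * num_files / pmax(carrying, 1L)
  out <- data.frame(gene = genes, median_nfc = med_nfc,
                    num_files = num_files, pct_present = pct_present,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$num_files >= min_datasets, , drop = FALSE]
  out <- out[order(-out$num_files, -out$median_nfc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-dataset consistency of signature enrichment
#'
#' Summarizes one signature collection tested per data set: in how many
#' data sets each signature was significant, mean and sd of its Z-score,
#' whether all Z-scores share a sign, and a per-dataset annotation string
#' using `+` (significantly enriched), `-` (significantly depleted) and `*`
#' (neither).
#'
#' @param enrichments named list per data set of `dac_enrichment` tables
#'   over the same signature collection.
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame `signature`, `n_significant`, `mean_z`, `sd_z`,
#'   `all_same_sign`, `annotation`.
#' @export
per_dataset_consistency <- function(enrichments, alpha = 0.05) {
  sigs <- enrichments[[1L]]$signature
  rows <- lapply(sigs, function(s) {
    z <- vapply(enrichments, function(e) e$zscore[match(s, e$signature)], 0)
    fdr <- vapply(enrichments, function(e) e$fdr[match(s, e$signature)], 0)
    sym <- ifelse(fdr < alpha & z > 0, "+",
                  ifelse(fdr < alpha & z < 0, "-", "*"))
    data.frame(signature = s, n_significant = sum(fdr < alpha),
               mean_z = mean(z), sd_z = sd(z),
               all_same_sign = all(z > 0) || all(z < 0),
               annotation = paste(sym, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consistent cytoband enrichment across data sets
#'
#' Reports chromosomal-region (cytoband) signatures significantly enriched
#' in at least `min_datasets` data sets, with their average Z-score and a
#' two-tier flag from the meta-profile enrichment FDR (`tier1` below 0.05,
#' `tier2` below 0.1, `none` otherwise).
#'
#' @param cytoband_enrichments named list per data set of `dac_enrichment`
#'   tables over the cytoband collection.
#' @param meta_profile_enrichment `dac_enrichment` table of the same
#'   collection against the meta-profile.
#' @param min_datasets inclusion threshold (default 6, i.e. more than 5 of
#'   11 data sets).
#' @param alpha per-dataset FDR significance threshold.
#' @return data.frame `signature`, `n_enriched`, `avg_z`, `meta_fdr`,
#'   `tier`.
#' @export
cytoband_consistency <- function(cytoband_enrichments,
                                 meta_profile_enrichment,
                                 min_datasets = 6L, alpha = 0.05) {
  sigs <- cytoband_enrichments[[1L]]$signature
  n_enr <- vapply(sigs, function(s)
    sum(vapply(cytoband_enrichments, function(e) {
      i <- match(s, e$signature)
      !is.na(i) && e$fdr[i] < alpha && e$zscore[i] > 0
    }, TRUE)), 0L)
  avg_z <- vapply(sigs, function(s)
    mean(vapply(cytoband_enrichments, function(e)
      e$zscore[match(s, e$signature)], 0), na.rm = TRUE), 0)
  meta_fdr <- meta_profile_enrichment$fdr[
    match(sigs, meta_profile_enrichment$signature)]
  keep <- n_enr >= min_datasets
  tier <- ifelse(is.na(meta_fdr), "none",
                 ifelse(meta_fdr < 0.05, "tier1",
                        ifelse(meta_fdr < 0.1, "tier2", "none")))
  data.frame(signature = sigs, n_enriched = n_enr, avg_z = avg_z,
             meta_fdr = meta_fdr, tier = tier,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
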