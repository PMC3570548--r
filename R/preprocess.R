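#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' vector of row-rank means.  Each column is sorted, values at the same sort
#' position are averaged across columns to give the reference distribution,
#' and each column's values are replaced by the reference value at their
#' within-column rank.  Tied values within a column receive the mean of the
#' reference values their rank span covers, so the map is deterministic and
#' idempotent.
#'
#' @param x an [expression_matrix()] or numeric matrix (rows = features,
#'   columns = samples) with at least two columns.
#' @return Matrix of the same shape and dimnames; an `expr_matrix` input
#'   keeps its class and metadata.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L)
    stop("quantile normalization needs >= 2 samples; ",
         "use classify_single_samples() with a background cohort ",
         "for single-sample input")
  ref <- rowMeans(apply(unclass(x), 2L, sort))
  out <- apply(unclass(x), 2L, function(col) {
    o <- order(col)
    grp <- cumsum(c(TRUE, diff(col[o]) != 0))  # runs of tied values
    gmeans <- vapply(split(ref, grp), mean, 0)
    res <- numeric(length(col))
    res[o] <- gmeans[grp]
    res
  })
  dimnames(out) <- dimnames(x)
  if (inherits(x, "expr_matrix")) out <- as_expr(out, x)
  out
}

#' Collapse probe-level rows to gene level
#'
#' Two collapse rules are supported.  `median` takes the per-sample median
#' across a gene's probes.  `maxavg` follows the correlation-gated rule:
#' probes whose mean pairwise Pearson correlation across samples exceeds 0.2
#' are averaged per sample, otherwise the per-sample element-wise maximum is
#' taken.  With more than two probes the gate is a single decision per gene
#' on the mean over all probe pairs.  Probes without a map entry are dropped
#' (count reported via the `dropped_probes` attribute).
#'
#' @param x probe-level [expression_matrix()] (or numeric matrix).
#' @param probe_map named character vector or list: probe id -> gene symbol.
#' @param method `"median"` or `"maxavg"`.
#' @param cor_threshold correlation gate for `maxavg` (default 0.2).
#' @return Gene-level `expr_matrix`, one row per mapped gene, with an
#'   attribute `dropped_probes` giving the number of unmapped probes.
#' @export
merge_probes <- function(x, probe_map, method = c("median", "maxavg"),
                         cor_threshold = 0.2) {
  method <- match.arg(method)
  map <- unlist(probe_map)
  if (any(!nzchar(map))) stop("probe map contains empty gene symbols")
  probes <- rownames(x)
  mapped <- probes[probes %in% names(map)]
  dropped <- length(probes) - length(mapped)
  if (!length(mapped)) stop("no probes covered by the probe map")
  genes <- split(mapped, map[mapped])
  vals <- unclass(x)
  out <- matrix(NA_real_, length(genes), ncol(x),
                dimnames = list(names(genes), colnames(x)))
  for (g in names(genes)) {
    block <- vals[genes[[g]], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[g, ] <- block
    } else if (method == "median") {
      out[g, ] <- apply(block, 2L, median)
    } else {
      cc <- cor(t(block))
      mean_r <- mean(cc[upper.tri(cc)])
      if (is.na(mean_r)) mean_r <- 0  # constant probe rows
      out[g, ] <- if (mean_r > cor_threshold) colMeans(block)
                  else apply(block, 2L, max)
    }
  }
  res <- expression_matrix(out, level = "GENE",
                           platform = attr(x, "platform") %||% "")
  attr(res, "dropped_probes") <- dropped
  res
}

#' Per-gene Z-scores across samples
#'
#' Standardizes each gene to mean 0, sd 1 across samples (sample sd,
#' denominator n-1).  Constant genes become all-zero rows and are flagged.
#'
#' @param x gene-level [expression_matrix()] or numeric matrix with at least
#'   two columns.
#' @return Matrix of Z-scores with attribute `constant_genes` (character
#'   vector of flagged genes); a warning is raised if any gene is constant.
#' @export
gene_zscores <- function(x) {
  if (ncol(x) < 2L) stop("Z-scores need >= 2 samples")
  vals <- unclass(x)
  mu <- rowMeans(vals)
  sdev <- apply(vals, 1L, sd)
  flat <- sdev == 0 | is.na(sdev)
  sdev[flat] <- 1
  z <- (vals - mu) / sdev
  z[flat, ] <- 0
  if (any(flat))
    warning(sum(flat), " constant gene(s) set to all-zero Z-scores")
  attr(z, "constant_genes") <- rownames(vals)[flat]
  z
}

#' Assemble the classifier feature table
#'
#' Transposes gene-level Z-scores into a samples x genes feature table
#' restricted to the requested classifier genes, in the requested order.
#' Genes absent from the matrix are omitted and reported, mirroring
#' platforms that carry only part of the classifier panel.
#'
#' @param z Z-score matrix from [gene_zscores()] (genes x samples).
#' @param classifier_genes character vector of genes wanted, in order.
#' @return Numeric matrix samples x genes with attribute `missing_genes`.
#' @export
assemble_features <- function(z, classifier_genes) {
  if (!length(classifier_genes)) stop("no classifier genes requested")
  present <- classifier_genes[classifier_genes %in% rownames(z)]
  missing <- setdiff(classifier_genes, present)
  if (!length(present))
    stop("none of the requested classifier genes are present")
  feats <- t(unclass(z)[present, , drop = FALSE])
  attr(feats, "missing_genes") <- missing
  feats
}
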