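#' Rank genes by information gain
#'
#' Information gain of each gene about the class label after equal-frequency
#' discretization of the gene into `n_bins` bins:
#' `IG = H(class) - H(class | bin)`, entropies in bits.  Equal-frequency
#' binning makes the score invariant to strictly monotone transforms of the
#' gene; a constant gene scores zero.
#'
#' @param features samples x genes numeric matrix.
#' @param labels categorical class labels.
#' @param n_bins number of bins (>= 2, default 10).
#' @return data.frame `gene`, `score` sorted by descending score, with
#'   attribute `method = "info_gain"`.
#' @export
info_gain_rank <- function(features, labels, n_bins = 10L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  features <- as.matrix(features)
  y <- factor(labels)
  h_class <- entropy_bits(table(y))
  ig <- vapply(seq_len(ncol(features)), function(j) {
    b <- ef_bin(features[, j], n_bins)
    tab <- table(b, y)
    h_cond <- sum(rowSums(tab) / length(y) *
                    apply(tab, 1L, entropy_bits))
    h_class - h_cond
  }, 0)
  out <- data.frame(gene = colnames(features), score = ig,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "info_gain"
  out
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# equal-frequency bins; duplicate quantile breaks collapse, so few-valued
# genes get one bin per distinct value
ef_bin <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Greedy correlation-based feature subset selection (CFS)
#'
#' Greedy stepwise forward selection maximizing the CFS merit
#' `M_S = k * r_cf / sqrt(k + k (k - 1) * r_ff)` where `r_cf` is the mean
#' absolute gene-class correlation over the subset and `r_ff` the mean
#' absolute gene-gene correlation.  The gene-class correlation of one gene
#' is the mean over classes of the absolute point-biserial correlation with
#' the one-vs-rest class indicator.  Selection stops when no candidate
#' improves the merit or `max_genes` is reached.
#'
#' @param features samples x genes numeric matrix (>= 2 genes).
#' @param labels class labels.
#' @param max_genes cap on selected genes (default all).
#' @return data.frame `gene`, `merit` in order of inclusion (merit at the
#'   step the gene entered), with attribute `method = "cfs"`.
#' @export
cfs_select <- function(features, labels, max_genes = ncol(features)) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("need >= 2 genes")
  y <- factor(labels)
  ind <- vapply(levels(y), function(l) as.numeric(y == l),
                numeric(length(y)))
  r_cf <- vapply(seq_len(ncol(features)), function(j) {
    r <- suppressWarnings(cor(features[, j], ind))
    mean(abs(ifelse(is.na(r), 0, r)))
  }, 0)
  r_ff <- suppressWarnings(abs(cor(features)))
  r_ff[is.na(r_ff)] <- 0
  selected <- integer(0)
  merits <- numeric(0)
  current <- -Inf
  repeat {
    cand <- setdiff(seq_len(ncol(features)), selected)
    if (!length(cand) || length(selected) >= max_genes) break
    trial <- vapply(cand, function(j) cfs_merit(c(selected, j), r_cf, r_ff), 0)
    best <- which.max(trial)
    if (trial[best] <= current) break
    current <- trial[best]
    selected <- c(selected, cand[best])
    merits <- c(merits, current)
  }
  out <- data.frame(gene = colnames(features)[selected], merit = merits,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "cfs"
  out
}

cfs_merit <- function(idx, r_cf, r_ff) {
  k <- length(idx)
  rcf <- mean(r_cf[idx])
  rff <- if (k > 1L) {
    sub <- r_ff[idx, idx]
    mean(sub[upper.tri(sub)])
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Consensus gene rank across data sets
#'
#' Averages each gene's rank across several rankings; a gene absent from a
#' ranking is imputed rank `length(that ranking) + 1`.  Output is ordered by
#' ascending mean rank, ties broken alphabetically.
#'
#' @param rankings list (>= 2 useful, >= 1 required) of rankings: either
#'   data.frames with a `gene` column (as the other ranking functions
#'   return) or plain character vectors in rank order.
#' @return data.frame `gene`, `mean_rank`.
#' @export
consensus_rank <- function(rankings) {
  if (!length(rankings)) stop("no rankings supplied")
  lists <- lapply(rankings, function(r)
    if (is.data.frame(r)) as.character(r$gene) else as.character(r))
  universe <- sort(unique(unlist(lists)))
  ranks <- vapply(lists, function(l) {
    r <- match(universe, l)
    r[is.na(r)] <- length(l) + 1L
    as.numeric(r)
  }, numeric(length(universe)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = length(universe))
  mean_rank <- rowMeans(ranks)
  out <- data.frame(gene = universe, mean_rank = mean_rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-stage gene ranking: information gain then CFS
#'
#' Whole-platform screening: rank all genes by [info_gain_rank()], keep the
#' top `top_n` (1000 by default, all genes if fewer), then re-rank the
#' survivors with the more expensive [cfs_select()].
#'
#' @param features samples x genes numeric matrix.
#' @param labels class labels.
#' @param top_n stage-1 truncation (default 1000).
#' @param n_bins bins for the information-gain stage.
#' @return data.frame from [cfs_select()] on the stage-1 survivors.
#' @export
two_stage_rank <- function(features, labels, top_n = 1000L, n_bins = 10L) {
  ig <- info_gain_rank(features, labels, n_bins = n_bins)
  keep <- head(ig$gene, top_n)
  cfs_select(as.matrix(features)[, keep, drop = FALSE], labels)
}
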