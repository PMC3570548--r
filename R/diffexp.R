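#' Moderated t-test between assigned ABC and GCB cases
#'
#' Fits a per-gene two-group linear model (ABC vs GCB; Type-III cases
#' excluded) with empirical-Bayes variance moderation: residual variances
#' are shrunk toward a common prior fitted to the variance distribution,
#' giving a moderated t with `d0 + d_residual` degrees of freedom, and
#' p-values are Benjamini-Hochberg adjusted.  The fit is delegated to
#' limma's `lmFit`/`eBayes`; the prior df `d0` and prior variance `s0^2`
#' are reported in the result's attributes.  Expression values are assumed
#' to be on a log2-like scale so the group-mean difference is a log2 fold
#' change (ABC minus GCB).
#'
#' @param x gene-level expression matrix (genes x samples), normalized,
#'   log2 scale.
#' @param calls `dac_calls` data.frame (or data.frame with `sample_id`,
#'   `predicted`) covering the columns of `x`.
#' @param alpha BH-adjusted significance cut-off for class association
#'   (default 0.05).
#' @return data.frame `gene`, `log2_fc`, `moderated_t`, `p_value`, `adj_p`,
#'   `class_association` (`ABC`/`GCB`/`none`), `constant` flag; attributes
#'   `d0`, `s0sq`, `alpha`.
#' @export
moderated_t_test <- function(x, calls, alpha = 0.05) {
  keep <- calls$sample_id[calls$predicted %in% c("ABC", "GCB")]
  keep <- intersect(colnames(x), keep)
  cls <- calls$predicted[match(keep, calls$sample_id)]
  if (sum(cls == "ABC") < 2L || sum(cls == "GCB") < 2L)
    stop("need >= 2 ABC and >= 2 GCB samples")
  vals <- unclass(x)[, keep, drop = FALSE]
  design <- cbind(GCB = 1, ABCvsGCB = as.numeric(cls == "ABC"))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  lfc <- fit$coefficients[, "ABCvsGCB"]
  tmod <- fit$t[, "ABCvsGCB"]
  p <- fit$p.value[, "ABCvsGCB"]
  scale <- max(abs(vals), 1)
  constant <- fit$sigma < 1e-10 * scale & abs(lfc) < 1e-10 * scale
  p[constant] <- 1
  tmod[constant] <- 0
  adj <- p.adjust(p, method = "BH")
  assoc <- ifelse(adj < alpha & lfc > 0, "ABC",
                  ifelse(adj < alpha & lfc < 0, "GCB", "none"))
  out <- data.frame(gene = rownames(vals), log2_fc = lfc, moderated_t = tmod,
                    p_value = p, adj_p = adj, class_association = assoc,
                    constant = constant,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- fit$df.prior
  attr(out, "s0sq") <- fit$s2.prior
  attr(out, "alpha") <- alpha
  out
}

#' Split a differential-expression table into class-associated gene lists
#'
#' ABC list: BH-adjusted p below the table's alpha and positive log2 fold
#' change (up in ABC); GCB list: significant and negative.  Lists are
#' disjoint by construction.
#'
#' @param table result of [moderated_t_test()].
#' @param alpha override of the table's alpha.
#' @return `list(ABC=, GCB=)` character vectors of gene symbols.
#' @export
class_associated_lists <- function(table, alpha = attr(table, "alpha") %||% 0.05) {
  sig <- table$adj_p < alpha
  list(ABC = table$gene[sig & table$log2_fc > 0],
       GCB = table$gene[sig & table$log2_fc < 0])
}

#' Normalized fold change among significant genes
#'
#' Maps each class-associated gene's absolute log2 fold change onto (0, 1]
#' by dividing by the maximum absolute fold change among the significant
#' genes of the same class in the same data set; the top gene of each class
#' therefore has NFC 1.  Scale choice (max-scaling) is recorded in the
#' `nfc_scaling` attribute.
#'
#' @param table result of [moderated_t_test()].
#' @return named list `ABC`, `GCB` of named numeric vectors (gene -> NFC);
#'   empty vectors when a class has no significant genes.
#' @export
normalized_fold_change <- function(table) {
  lists <- class_associated_lists(table)
  out <- lapply(lists, function(genes) {
    if (!length(genes)) return(setNames(numeric(0), character(0)))
    fc <- abs(table$log2_fc[match(genes, table$gene)])
    setNames(fc / max(fc), genes)
  })
  attr(out, "nfc_scaling") <- "max"
  out
}
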