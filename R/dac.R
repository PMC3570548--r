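#' Train the balanced-voting ensemble classifier
#'
#' Fits one probabilistic learner per requested kind (default: the four-tool
#' combination LMT + J48 + RF100 + SMO) on classifier-gene Z-scores and
#' combines them by the average-of-probabilities vote at prediction time.
#' Cases are assigned to the class with the highest averaged probability;
#' exact ties break in the canonical order ABC < GCB < TYPE_III.
#'
#' @param features numeric matrix, samples x classifier genes (Z-scores),
#'   e.g. from [assemble_features()].
#' @param labels class labels (`ABC`/`GCB`/`TYPE_III`) aligned with rows.
#' @param kinds character vector of learner kinds, see
#'   [train_base_learner()].
#' @param seed integer; seeds every stochastic learner and is recorded.
#' @return Object of class `dac`: list with `learners`, `gene_list`,
#'   `kinds`, `seed` and a `training_fingerprint` hash of the training data.
#' @seealso [predict.dac()], [apply_confidence_threshold()],
#'   [classify_single_samples()]
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_samples = 60, seed = 1))
#' z <- gene_zscores(merge_probes(quantile_normalize(cohort$expression),
#'                                cohort$probe_map))
#' feats <- assemble_features(z, dac_classifier_genes()$gene)
#' fit <- dac(feats, cohort$labels, kinds = "RF100")
#' head(predict(fit, feats))
#' @export
dac <- function(features, labels, kinds = c("LMT", "J48", "RF100", "SMO"),
                seed = 0L) {
  features <- as.matrix(features)
  learners <- lapply(kinds, train_base_learner, features = features,
                     labels = labels, seed = seed)
  structure(list(learners = learners, kinds = kinds,
                 gene_list = colnames(features), seed = seed,
                 n_train = nrow(features),
                 training_fingerprint = data_fingerprint(features, labels)),
            class = "dac")
}

data_fingerprint <- function(features, labels) {
  raw <- as.integer(serialize(list(round(unname(as.matrix(features)), 10),
                                   as.character(labels)), NULL))
  sprintf("%08x", sum(raw * (seq_along(raw) %% 97 + 1)) %% 2147483647)
}

#' @export
print.dac <- function(x, ...) {
  cat("DLBCL cell-of-origin ensemble classifier\n")
  cat("  learners:", paste(x$kinds, collapse = " + "), "\n")
  cat("  genes:   ", length(x$gene_list), "classifier genes\n")
  cat("  trained: ", x$n_train, "samples  (seed", x$seed,
      " fingerprint", x$training_fingerprint, ")\n")
  invisible(x)
}

#' @export
summary.dac <- function(object, ...) {
  print(object)
  cat("  gene list:", paste(object$gene_list, collapse = ", "), "\n")
  invisible(object)
}

#' Classify samples with a trained ensemble
#'
#' Averages the class-probability vectors of all learners (balanced voting)
#' and assigns each sample to the class with the largest averaged
#' probability (canonical tie-break ABC < GCB < TYPE_III).
#'
#' @param object a fitted [dac()] ensemble.
#' @param features samples x genes matrix; columns must cover the
#'   ensemble's gene list (genes missing on a platform are handled upstream
#'   by [assemble_features()] and by retraining on the shared panel).
#' @param ... unused.
#' @return A `dac_calls` data.frame: `sample_id`, `P_ABC`, `P_GCB`,
#'   `P_TYPE_III`, `predicted`, `confidence` (the winning probability).
#' @export
predict.dac <- function(object, features, ...) {
  features <- as.matrix(features)
  if (!nrow(features)) stop("empty feature table")
  missing <- setdiff(object$gene_list, colnames(features))
  if (length(missing))
    stop("features lack ensemble genes: ", paste(missing, collapse = ", "))
  features <- features[, object$gene_list, drop = FALSE]
  probs <- Reduce(`+`, lapply(object$learners, predict_proba, features))
  probs <- probs / length(object$learners)
  make_calls(rownames(features) %||% paste0("S", seq_len(nrow(features))),
             probs)
}

make_calls <- function(sample_ids, probs) {
  idx <- apply(probs, 1L, which.max)  # first max = canonical tie-break
  out <- data.frame(sample_id = sample_ids,
                    P_ABC = probs[, "ABC"], P_GCB = probs[, "GCB"],
                    P_TYPE_III = probs[, "TYPE_III"],
                    predicted = DAC_CLASSES[idx],
                    confidence = probs[cbind(seq_len(nrow(probs)), idx)],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dac_calls", "data.frame")
  out
}

#' Apply a hard confidence threshold to class calls
#'
#' Calls predicted as ABC or GCB whose confidence does not exceed `tau` are
#' reassigned to TYPE_III; the probability vectors are left untouched.
#' Monotone in `tau`: the TYPE_III set can only grow as `tau` rises.
#'
#' @param calls a `dac_calls` data.frame from [predict.dac()].
#' @param tau threshold in `[0, 1]`; a call survives only with
#'   `confidence > tau`.
#' @return The calls with `predicted` updated.
#' @export
apply_confidence_threshold <- function(calls, tau) {
  stopifnot(tau >= 0, tau <= 1)
  hit <- calls$predicted %in% c("ABC", "GCB") & calls$confidence <= tau
  calls$predicted[hit] <- "TYPE_III"
  calls
}

#' Classify samples one at a time against a background cohort
#'
#' Single-sample mode: each input sample is appended on its own to a
#' background cohort (>30 samples of random class from the equivalent
#' platform), the combined matrix is quantile normalized, probe-collapsed if
#' needed, Z-scored, and only that sample's Z-score row is classified.  The
#' gene set used is the intersection of the two files' genes with the
#' ensemble panel.
#'
#' @param samples [expression_matrix()] of the samples to classify.
#' @param background [expression_matrix()] of background samples on the
#'   equivalent platform; 30 or fewer samples raises a warning.
#' @param ensemble a fitted [dac()] object; it is refitted on the shared
#'   gene panel when genes are missing, using `train_features`/`train_labels`.
#' @param train_features,train_labels the ensemble's training data, needed
#'   only when the shared panel is smaller than the ensemble's gene list.
#' @param probe_map optional probe -> gene map if inputs are probe-level.
#' @param merge_method probe collapse rule, see [merge_probes()].
#' @return `dac_calls` data.frame in input sample order.
#' @export
classify_single_samples <- function(samples, background, ensemble,
                                    train_features = NULL,
                                    train_labels = NULL,
                                    probe_map = NULL,
                                    merge_method = "median") {
  if (ncol(background) <= 30L)
    warning("background has ", ncol(background),
            " samples; more than 30 are recommended")
  shared <- intersect(rownames(samples), rownames(background))
  if (!length(shared)) stop("samples and background share no genes/probes")
  calls <- vector("list", ncol(samples))
  for (i in seq_len(ncol(samples))) {
    combined <- cbind(unclass(background)[shared, , drop = FALSE],
                      unclass(samples)[shared, i, drop = FALSE])
    combined <- expression_matrix(combined, level = expr_level(samples),
                                  platform = attr(samples, "platform") %||% "")
    qn <- quantile_normalize(combined)
    if (!is.null(probe_map) && expr_level(samples) == "PROBE")
      qn <- merge_probes(qn, probe_map, method = merge_method)
    z <- suppressWarnings(gene_zscores(qn))
    feats <- assemble_features(z, ensemble$gene_list)
    ens <- ensemble
    if (length(attr(feats, "missing_genes"))) {
      if (is.null(train_features))
        stop("genes missing from the shared panel; supply train_features/",
             "train_labels so the ensemble can be refitted")
      keep <- colnames(feats)
      ens <- dac(train_features[, keep, drop = FALSE], train_labels,
                 kinds = ensemble$kinds, seed = ensemble$seed)
    }
    calls[[i]] <- predict(ens, feats[ncol(combined), , drop = FALSE])
  }
  out <- do.call(rbind, calls)
  out$sample_id <- colnames(samples)
  class(out) <- c("dac_calls", "data.frame")
  out
}

#' @export
print.dac_calls <- function(x, ...) {
  cat(sprintf("<dac_calls> %d samples: %s\n", nrow(x),
              paste(sprintf("%s=%d", DAC_CLASSES,
                            tabulate(factor(x$predicted, DAC_CLASSES),
                                     3L)), collapse = " ")))
  print.data.frame(head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, "more )\n")
  invisible(x)
}

#' Write class calls as TSV
#'
#' @param calls `dac_calls` data.frame.
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
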