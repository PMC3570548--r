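# The four base learners of the voting ensemble.  Each is wrapped behind a
# common contract: fit on (features, labels), then emit a samples x 3
# probability matrix over the canonical classes that sums to one per row.
# Classes absent from training get probability zero.

#' Train one probabilistic base learner
#'
#' Kinds: `"RF100"` (100-tree random forest), `"J48"` (pruned CART-style
#' decision tree with Laplace-smoothed leaf class frequencies), `"SMO"`
#' (linear-kernel maximum-margin classifier with pairwise-coupled Platt
#' probability calibration) and `"LMT"` (multinomial logistic model, the
#' logistic-model component of a logistic model tree with a trivial root --
#' a documented substitute meeting the same recovery contract).
#'
#' @param kind one of `"LMT"`, `"J48"`, `"RF100"`, `"SMO"`.
#' @param features numeric matrix, samples x genes (classifier Z-scores).
#' @param labels factor/character of class labels covering >= 2 classes.
#' @param seed integer seed for the stochastic learners.
#' @return object of class `dac_learner` with a `predict_proba(features)`
#'   contract via [predict_proba()].
#' @export
train_base_learner <- function(kind = c("LMT", "J48", "RF100", "SMO"),
                               features, labels, seed = 0L) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  y <- factor(as.character(labels),
              levels = intersect(DAC_CLASSES, unique(as.character(labels))))
  if (nlevels(y) < 2L) stop("training labels cover a single class")
  if (nrow(features) != length(y)) stop("features/labels length mismatch")
  df <- data.frame(features, check.names = FALSE)
  fit <- switch(kind,
    RF100 = {
      set.seed(seed)
      randomForest::randomForest(x = df, y = y, ntree = 100L)
    },
    J48 = {
      set.seed(seed)
      rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class",
                   control = rpart::rpart.control(xval = 10L))
    },
    SMO = {
      set.seed(seed)
      e1071::svm(x = features, y = y, kernel = "linear", probability = TRUE)
    },
    LMT = {
      # deterministic; multinomial logistic fit
      capture_multinom(y, df)
    })
  structure(list(kind = kind, fit = fit, genes = colnames(features),
                 levels = levels(y), seed = seed),
            class = "dac_learner")
}

capture_multinom <- function(y, df) {
  dat <- cbind(df, .class = y)
  nnet::multinom(.class ~ ., data = dat, trace = FALSE, maxit = 500L,
                 decay = 1e-3)
}

#' Class-probability predictions from a base learner
#'
#' @param learner a `dac_learner`.
#' @param features samples x genes matrix with the learner's gene columns.
#' @return samples x 3 matrix over `ABC`, `GCB`, `TYPE_III`; rows sum to 1.
#' @export
predict_proba <- function(learner, features) {
  features <- as.matrix(features)[, learner$genes, drop = FALSE]
  df <- data.frame(features, check.names = FALSE)
  p <- switch(learner$kind,
    RF100 = predict(learner$fit, df, type = "prob"),
    J48 = predict_rpart_laplace(learner$fit, df),
    SMO = {
      pr <- predict(learner$fit, features, probability = TRUE)
      attr(pr, "probabilities")
    },
    LMT = {
      pr <- predict(learner$fit, df, type = "probs")
      if (is.null(dim(pr))) {
        # single row and/or two-class fit both drop to a vector
        pr <- if (length(learner$levels) == 2L && nrow(df) > 1L)
          cbind(1 - pr, pr, deparse.level = 0)
        else if (length(pr) == length(learner$levels))
          matrix(pr, nrow = 1L)
        else matrix(c(1 - pr, pr), nrow = 1L)
      }
      colnames(pr) <- learner$levels
      pr
    })
  out <- matrix(0, nrow(features), length(DAC_CLASSES),
                dimnames = list(rownames(features), DAC_CLASSES))
  out[, colnames(p)] <- as.matrix(p)
  out / rowSums(out)
}

# rpart leaf class counts with add-one (Laplace) smoothing
predict_rpart_laplace <- function(fit, df) {
  one <- nrow(df) == 1L
  if (one) df <- df[c(1L, 1L), , drop = FALSE]  # rpart quirk on 1-row input
  m <- predict(fit, df, type = "matrix")
  if (one) m <- m[1L, , drop = FALSE]
  k <- (ncol(m) - 2L) / 2L  # columns: class, k counts, k probs, node weight
  counts <- m[, 1L + seq_len(k), drop = FALSE]
  sm <- counts + 1
  p <- sm / rowSums(sm)
  colnames(p) <- attr(fit, "ylevels")
  p
}
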