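test_that("every base learner separates an easy toy and emits proper probabilities", {
  toy <- toy_separable()
  for (kind in c("LMT", "J48", "RF100", "SMO")) {
    l <- train_base_learner(kind, toy$features, toy$labels, seed = 0L)
    p <- predict_proba(l, toy$features)
    expect_equal(dim(p), c(20L, 3L))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9), info = kind)
    pred <- colnames(p)[apply(p, 1, which.max)]
    expect_equal(pred, toy$labels, info = kind)  # 100% training accuracy
  }
  expect_error(train_base_learner("RF100", toy$features,
                                  rep("ABC", 20), seed = 0L), "single class")
})

test_that("stochastic learners are deterministic given the seed", {
  toy <- toy_separable(n = 30)
  for (kind in c("RF100", "SMO")) {
    a <- predict_proba(train_base_learner(kind, toy$features, toy$labels,
                                          seed = 7L), toy$features)
    b <- predict_proba(train_base_learner(kind, toy$features, toy$labels,
                                          seed = 7L), toy$features)
    expect_identical(a, b, info = kind)
  }
})

test_that("the ensemble averages learner probabilities and tie-breaks canonically", {
  toy <- toy_separable(n = 40, seed = 2)
  ens <- dac(toy$features, toy$labels, kinds = c("LMT", "RF100"), seed = 0L)
  expect_length(ens$learners, 2L)
  calls <- predict(ens, toy$features)
  # independently computed average of the two learners' probabilities
  p1 <- predict_proba(ens$learners[[1]], toy$features)
  p2 <- predict_proba(ens$learners[[2]], toy$features)
  avg <- (p1 + p2) / 2
  expect_equal(as.matrix(calls[, c("P_ABC", "P_GCB", "P_TYPE_III")]),
               avg, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(abs(rowSums(avg) - 1) < 1e-9))
  expect_equal(calls$predicted,
               c("ABC", "GCB", "TYPE_III")[apply(avg, 1, which.max)])
  expect_equal(calls$confidence, unname(apply(avg, 1, max)),
               tolerance = 1e-12)

  # degenerate single-learner ensemble equals that learner
  solo <- dac(toy$features, toy$labels, kinds = "RF100", seed = 0L)
  ps <- predict_proba(solo$learners[[1]], toy$features)
  cs <- predict(solo, toy$features)
  expect_equal(as.matrix(cs[, c("P_ABC", "P_GCB", "P_TYPE_III")]), ps,
               ignore_attr = TRUE)
  expect_error(predict(solo, toy$features[0, , drop = FALSE]), "empty")
})

test_that("default four-tool ensemble re-classifies its training cohort", {
  fit <- wright_fit()
  expect_length(fit$learners, 4L)
  expect_equal(fit$kinds, c("LMT", "J48", "RF100", "SMO"))
  w <- wright_features()
  calls <- predict(fit, w$features)
  expect_gte(mean(calls$predicted == w$labels), 0.9)
  expect_true(all(abs(rowSums(
    calls[, c("P_ABC", "P_GCB", "P_TYPE_III")]) - 1) < 1e-9))
})

test_that("confidence thresholding reassigns low-confidence calls monotonically", {
  calls <- calls_df(paste0("S", 1:4),
                    c("ABC", "GCB", "TYPE_III", "ABC"),
                    confidence = c(0.55, 0.55, 0.40, 0.95))
  out6 <- apply_confidence_threshold(calls, 0.6)
  expect_equal(out6$predicted, c("TYPE_III", "TYPE_III", "TYPE_III", "ABC"))
  out5 <- apply_confidence_threshold(calls, 0.5)
  expect_equal(out5$predicted, calls$predicted)  # 0.55 strictly above 0.5
  expect_equal(apply_confidence_threshold(calls, 0)$predicted,
               calls$predicted)

  # TYPE_III set grows with tau over random calls
  set.seed(4)
  p <- matrix(runif(300), 100, 3)
  p <- p / rowSums(p)
  rc <- calls_df(paste0("S", 1:100),
                 c("ABC", "GCB", "TYPE_III")[apply(p, 1, which.max)],
                 confidence = apply(p, 1, max))
  taus <- seq(0, 1, by = 0.1)
  sets <- lapply(taus, function(t)
    which(apply_confidence_threshold(rc, t)$predicted == "TYPE_III"))
  for (i in seq_along(taus)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("single-sample classification matches batch calls and flags small backgrounds", {
  co <- simulate_cohort(cohort_spec(n_samples = 60, n_noise_genes = 60,
                                    seed = 11))
  vals <- unclass(co$expression)
  bg <- expression_matrix(vals[, 1:40], level = "PROBE")
  sm <- expression_matrix(vals[, 41:46], level = "PROBE")
  fit <- wright_fit()
  ss <- classify_single_samples(sm, bg, fit, probe_map = co$probe_map)
  expect_equal(ss$sample_id, colnames(sm))
  batch <- predict(fit, cohort_features(co))
  agree <- mean(ss$predicted == batch$predicted[41:46])
  expect_gte(agree, 0.8)

  bg31 <- expression_matrix(vals[, 1:31], level = "PROBE")
  bg30 <- expression_matrix(vals[, 1:30], level = "PROBE")
  one <- expression_matrix(vals[, 47, drop = FALSE], level = "PROBE")
  expect_warning(classify_single_samples(one, bg30, fit,
                                         probe_map = co$probe_map), "30")
  expect_no_warning(classify_single_samples(one, bg31, fit,
                                            probe_map = co$probe_map))

  other <- expression_matrix(matrix(1:4, 2, 2,
                                    dimnames = list(c("X1", "X2"),
                                                    c("A", "B"))),
                             level = "PROBE")
  expect_error(classify_single_samples(other, bg, fit,
                                       probe_map = co$probe_map), "share")
})
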