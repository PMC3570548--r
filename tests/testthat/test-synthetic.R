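test_that("cohort generation reproduces the reference class counts deterministically", {
  co <- simulate_cohort(cohort_spec(seed = 0))
  counts <- table(factor(co$labels, c("ABC", "GCB", "TYPE_III")))
  expect_equal(unname(c(counts)), c(73L, 115L, 52L))
  expect_equal(ncol(co$expression), 240L)
  expect_true(all(co$probe_map[rownames(co$expression)] != ""))

  # same seed twice: bit-identical
  co2 <- simulate_cohort(cohort_spec(seed = 0))
  expect_identical(unclass(co$expression), unclass(co2$expression))
  expect_identical(co$labels, co2$labels)
  co3 <- simulate_cohort(cohort_spec(seed = 1))
  expect_false(identical(unclass(co$expression), unclass(co3$expression)))

  expect_error(cohort_spec(class_proportions = c(ABC = 0.5, GCB = 0.5,
                                                 TYPE_III = 0.5)), "sum to 1")
})

test_that("zero class shift removes the signal", {
  spec0 <- cohort_spec(n_samples = 120, shift = 0, type3_shift = 0,
                       n_noise_genes = 40, seed = 5)
  tr <- simulate_cohort(spec0)
  te <- simulate_cohort(cohort_spec(n_samples = 120, shift = 0,
                                    type3_shift = 0, n_noise_genes = 40,
                                    seed = 6))
  fit <- dac(cohort_features(tr), tr$labels, kinds = "RF100", seed = 0)
  acc <- mean(predict(fit, cohort_features(te))$predicted == te$labels)
  # chance level = largest class proportion (115/240), binomial slack
  p0 <- 115 / 240
  expect_lt(acc, p0 + 3 * sqrt(p0 * (1 - p0) / 120))
})

test_that("simulated survival honours censoring and planted hazard structure", {
  labels <- setNames(rep(c("ABC", "GCB", "TYPE_III"), each = 50),
                     paste0("S", 1:150))
  sv0 <- simulate_survival(labels, censor_rate = 0, seed = 0)
  expect_true(all(sv0$event == 1))
  expect_true(all(sv0$time >= 0))

  # hr = 1: no separation in the vast majority of replicate cohorts
  l2 <- setNames(rep(c("ABC", "GCB"), each = 100), paste0("S", 1:200))
  pv <- vapply(1:100, function(i) {
    sv <- simulate_survival(l2, hr_gcb_vs_abc = 1, censor_rate = 0.2,
                            seed = i)
    survival_separation(calls_df(names(l2), unname(l2)), sv)$p_value
  }, 0)
  expect_gte(mean(pv > 0.05), 0.9)

  # hr = 0.4 recovered without bias across replicates
  l3 <- setNames(rep(c("ABC", "GCB"), each = 150), paste0("S", 1:300))
  hrs <- vapply(1:100, function(i) {
    sv <- simulate_survival(l3, hr_gcb_vs_abc = 0.4, censor_rate = 0.2,
                            seed = 100 + i)
    survival_separation(calls_df(names(l3), unname(l3)), sv)$hazard_ratio
  }, 0)
  expect_gt(mean(hrs), 0.36)
  expect_lt(mean(hrs), 0.44)
  expect_error(simulate_survival(labels, hr_gcb_vs_abc = -1), "hr")
})

test_that("signature database generator plants positives and honest nulls", {
  pop <- sprintf("G%04d", 1:5000)
  profile <- pop[1:400]
  db <- simulate_signature_db(pop, planted_from_profile = profile,
                              n_planted = 3, n_random_sigs = 100,
                              size_range = c(40, 60), seed = 0)
  res <- signature_enrichment(profile, db, pop,
                              classifier_genes = character(0),
                              n_samplings = 1e4, seed = 0)
  planted <- res[grepl("^PLANTED", res$signature), ]
  expect_true(all(planted$fdr < 0.05))
  random <- res[grepl("^RANDOM", res$signature), ]
  expect_lte(mean(random$p_enriched < 0.05), 0.10)

  fixed <- simulate_signature_db(pop, n_random_sigs = 20,
                                 size_range = c(5, 5), seed = 1)
  expect_true(all(lengths(lapply(fixed, `[[`, "genes")) == 5L))
})

test_that("multi-dataset bundles share a recoverable class-gene core", {
  md <- simulate_multidataset(n_datasets = 4, n_core_abc = 20,
                              n_core_gcb = 20, dropout = 0.1, seed = 0)
  expect_length(md$datasets, 4L)
  cls <- lapply(md$datasets, function(d) {
    tab <- moderated_t_test(d$expression,
                            calls_df(names(d$labels), unname(d$labels)))
    class_associated_lists(tab)
  })
  nfc_abc <- lapply(md$datasets, function(d) {
    tab <- moderated_t_test(d$expression,
                            calls_df(names(d$labels), unname(d$labels)))
    normalized_fold_change(tab)$ABC
  })
  prof <- build_meta_profile(lapply(cls, `[[`, "ABC"), nfc_abc,
                             min_datasets = 2,
                             platforms = lapply(md$datasets, `[[`,
                                                "platform"))
  expect_gte(mean(md$truth$abc_core %in% prof$gene), 0.9)

  # a dropped gene still shows 100% presence where its platform carries it
  plat_counts <- rowSums(vapply(md$datasets, function(d)
    md$truth$abc_core %in% d$platform, logical(20)))
  expect_true(any(plat_counts < 4))  # dropout actually happened

  two <- simulate_multidataset(n_datasets = 2, n_samples = 60, seed = 1)
  cls2 <- lapply(two$datasets, function(d) {
    tab <- moderated_t_test(d$expression,
                            calls_df(names(d$labels), unname(d$labels)))
    class_associated_lists(tab)
  })
  z <- pairwise_dataset_concordance(cls2,
                                    lapply(two$datasets, `[[`, "platform"),
                                    n_samplings = 2000, seed = 0)
  expect_equal(dim(z), c(2L, 2L))
  expect_false(is.na(z[1, 2]))
  expect_error(simulate_multidataset(n_datasets = 1), ">= 2")
})
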