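test_that("quantile normalization equalizes distributions and preserves ranks", {
  # worked example: columns (5,3) and (4,8) -> (6.5,3.5) and (3.5,6.5)
  m <- matrix(c(5, 3, 4, 8), 2, 2)
  expect_equal(unname(quantile_normalize(m)),
               matrix(c(6.5, 3.5, 3.5, 6.5), 2, 2))

  # already-identical columns come back unchanged
  same <- matrix(rep(c(1, 4, 2), 3), 3, 3)
  expect_equal(unname(quantile_normalize(same)), same)

  set.seed(0)
  x <- matrix(rnorm(200), 40, 5)
  q <- quantile_normalize(x)
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)  # idempotent
  sorted <- apply(q, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))  # equal distributions
  for (j in 1:5) expect_equal(rank(q[, j]), rank(x[, j]))  # rank-preserving

  # agrees with the standard implementation on tie-free data
  expect_equal(unname(q), unname(limma::normalizeQuantiles(x)),
               tolerance = 1e-9)

  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "single-sample|>= 2")
})

test_that("probe collapse follows the median and correlation-gated rules", {
  samples <- paste0("S", 1:6)
  single <- expression_matrix(
    matrix(1:6, 1, 6, dimnames = list("P1", samples)), level = "PROBE")
  map <- c(P1 = "G1")
  for (meth in c("median", "maxavg"))
    expect_equal(unname(unclass(merge_probes(single, map, meth))),
                 matrix(1:6, 1, 6), ignore_attr = TRUE)

  # median over probes (1,2,9) is 2 in every sample
  m <- expression_matrix(
    matrix(rep(c(1, 2, 9), 6), 3, 6, dimnames = list(paste0("P", 1:3),
                                                     samples)),
    level = "PROBE")
  med <- merge_probes(m, c(P1 = "G1", P2 = "G1", P3 = "G1"), "median")
  expect_equal(unname(unclass(med)), matrix(2, 1, 6), ignore_attr = TRUE)

  # perfectly correlated probes are averaged, anti-correlated take the max
  base <- c(1, 2, 3, 4, 5, 6)
  cor1 <- expression_matrix(rbind(P1 = base, P2 = 2 * base),
                            sample_ids = samples, level = "PROBE")
  avg <- merge_probes(cor1, c(P1 = "G1", P2 = "G1"), "maxavg")
  expect_equal(unname(unclass(avg)), rbind((base + 2 * base) / 2),
               ignore_attr = TRUE)
  anti <- expression_matrix(rbind(P1 = base, P2 = rev(base)),
                            sample_ids = samples, level = "PROBE")
  mx <- merge_probes(anti, c(P1 = "G1", P2 = "G1"), "maxavg")
  expect_equal(unname(unclass(mx)), rbind(pmax(base, rev(base))),
               ignore_attr = TRUE)

  # probe order does not matter for the median rule; unmapped probes drop
  set.seed(2)
  big <- matrix(rnorm(30), 5, 6,
                dimnames = list(paste0("P", 1:5), samples))
  map5 <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")  # P5 unmapped
  a <- merge_probes(expression_matrix(big, level = "PROBE"), map5, "median")
  b <- merge_probes(expression_matrix(big[5:1, ], level = "PROBE"),
                    map5, "median")
  expect_equal(unclass(a), unclass(b)[rownames(a), ], ignore_attr = TRUE)
  expect_equal(attr(a, "dropped_probes"), 1L)
  expect_setequal(rownames(a), c("G1", "G2"))
})

test_that("gene Z-scores standardize rows and flag constant genes", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("G1", paste0("S", 1:3)))
  expect_equal(unname(gene_zscores(m)), rbind(c(-1, 0, 1)),
               ignore_attr = TRUE)

  const <- rbind(G1 = c(1, 2, 3), G2 = c(5, 5, 5))
  colnames(const) <- paste0("S", 1:3)
  expect_warning(z <- gene_zscores(const), "constant")
  expect_equal(unname(z["G2", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_genes"), "G2")

  set.seed(3)
  x <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("G", 1:5),
                                                paste0("S", 1:10)))
  z <- gene_zscores(x)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
  # affine invariance: a*x + b with a > 0 gives identical Z-scores
  expect_equal(gene_zscores(3.7 * x + 11), z, ignore_attr = TRUE)

  expect_error(gene_zscores(matrix(1, 2, 1)), ">= 2")
})

test_that("feature assembly keeps requested order and reports missing genes", {
  z <- matrix(rnorm(20), 4, 5,
              dimnames = list(c("MME", "CCND2", "LMO2", "BCL6"),
                              paste0("S", 1:5)))
  f <- assemble_features(z, c("CCND2", "MME", "LMO2", "BCL6"))
  expect_equal(colnames(f), c("CCND2", "MME", "LMO2", "BCL6"))
  expect_equal(attr(f, "missing_genes"), character(0))

  f2 <- assemble_features(z, c("CCND2", "IRF4", "PIM1", "MME"))
  expect_equal(colnames(f2), c("CCND2", "MME"))
  expect_equal(attr(f2, "missing_genes"), c("IRF4", "PIM1"))

  f1 <- assemble_features(z, "BCL6")
  expect_equal(ncol(f1), 1L)
  expect_error(assemble_features(z, c("NOPE1", "NOPE2")), "none")
  expect_error(assemble_features(z, character(0)))
})
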