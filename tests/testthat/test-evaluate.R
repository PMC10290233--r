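test_that("CLR normalization matches direct evaluation of the formula", {
  m <- rbind(c1 = c(1, 4), c2 = c(2, 2))
  colnames(m) <- c("abA", "abB")
  out <- clr_normalize(m)
  g1 <- exp((log(2) + log(5)) / 2)                 # sqrt(10)
  expect_equal(g1, sqrt(10), tolerance = 1e-15)
  expect_equal(out["c1", ], log1p(c(abA = 1, abB = 4) / sqrt(10)),
               tolerance = 1e-12)
  # identical inputs within a cell give identical outputs
  expect_equal(out["c2", "abA"], out["c2", "abB"])
})

test_that("CLR margins, re-normalization and zero units are policed", {
  m <- rbind(c1 = c(0, 0), c2 = c(1, 2))
  expect_error(clr_normalize(m), "all-zero cell")
  m2 <- rbind(c1 = c(0, 3), c2 = c(0, 2))
  expect_error(clr_normalize(m2, margin = "feature"), "all-zero antibody")
  ok <- clr_normalize(rbind(c1 = c(1, 2), c2 = c(3, 4)))
  expect_error(clr_normalize(ok), "already")

  # per-feature margin: geometric mean taken down columns
  m3 <- rbind(c1 = c(1, 8), c2 = c(3, 2))
  f <- clr_normalize(m3, margin = "feature")
  g <- exp(colMeans(log1p(m3)))
  expect_equal(unclass(f), log1p(sweep(m3, 2, g, "/")), ignore_attr = TRUE)
})

test_that("per-receptor correlations hit textbook values", {
  est <- cbind(CD4 = c(1, 2, 3, 4), CD8A = c(4, 3, 2, 1))
  rownames(est) <- paste0("c", 1:4)
  adt <- cbind(`anti-CD4` = c(1, 3, 2, 4), `anti-CD8A` = c(1, 3, 2, 4))
  rownames(adt) <- paste0("c", 1:4)
  map <- feature_map(c("anti-CD4", "anti-CD8A"), c("CD4", "CD8A"))

  sp <- receptor_correlations(est, adt, map, method = "spearman")
  expect_equal(sp$correlation[sp$receptor == "CD4"], 0.8)  # 1 - 12/60

  # identical columns correlate at 1, reversed at -1, for all methods
  for (meth in c("spearman", "pearson", "kendall")) {
    r <- receptor_correlations(est, adt, map, method = meth)
    expect_equal(r$correlation[r$receptor == "CD4"],
                 cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = meth))
  }
  est2 <- cbind(CD4 = c(1, 3, 2, 4), CD8A = -c(1, 3, 2, 4))
  rownames(est2) <- paste0("c", 1:4)
  for (meth in c("spearman", "pearson", "kendall")) {
    r <- receptor_correlations(est2, adt, map, method = meth)
    expect_equal(r$correlation, c(1, -1))
  }
})

test_that("rank correlations are invariant under monotone transforms", {
  set.seed(12)
  est <- cbind(CD4 = rnorm(50))
  rownames(est) <- paste0("c", 1:50)
  adt <- cbind(`anti-CD4` = rgamma(50, 2))
  rownames(adt) <- paste0("c", 1:50)
  map <- feature_map("anti-CD4", "CD4")
  for (meth in c("spearman", "kendall")) {
    r0 <- receptor_correlations(est, adt, map, meth)$correlation
    r1 <- receptor_correlations(exp(3 * est), adt^2 + 1, map,
                                meth)$correlation
    expect_equal(r1, r0, tolerance = 1e-12)
  }
})

test_that("constant estimate columns yield NA, and misalignments error", {
  est <- cbind(CD4 = rep(1, 4), CD8A = 1:4)
  rownames(est) <- paste0("c", 1:4)
  adt <- cbind(`anti-CD4` = c(1, 2, 3, 4), `anti-CD8A` = c(2, 1, 4, 3))
  rownames(adt) <- paste0("c", 1:4)
  map <- feature_map(colnames(adt), c("CD4", "CD8A"))
  r <- receptor_correlations(est, adt, map)
  expect_true(is.na(r$correlation[r$receptor == "CD4"]))
  expect_false(is.na(r$correlation[r$receptor == "CD8A"]))

  rownames(adt) <- paste0("x", 1:4)
  expect_error(receptor_correlations(est, adt, map), "no overlapping")
  expect_error(receptor_correlations(est, adt, map[0, ]), "empty")
})

test_that("ambiguous antibodies are excluded from the feature map", {
  expect_message(fm <- feature_map(c("a1", "a1", "a2"),
                                   c("CD4", "CD8A", "CD19")),
                 "multiple")
  expect_identical(fm$antibody, "a2")
  # duplicated identical rows collapse without exclusion
  fm2 <- feature_map(c("a1", "a1"), c("CD4", "CD4"))
  expect_identical(fm2$symbol, "CD4")
})

test_that("proportion-best splits wins, handles ties, sums to one", {
  a <- c(r1 = 0.9, r2 = 0.8, r3 = 0.7, r4 = 0.1)
  b <- c(r1 = 0.5, r2 = 0.4, r3 = 0.3, r4 = 0.6)
  p <- proportion_best(list(A = a, B = b))
  expect_equal(p, c(A = 0.75, B = 0.25))

  # exact tie: fractional split keeps the total at one
  p2 <- proportion_best(list(A = c(r1 = 0.5, r2 = 0.9),
                             B = c(r1 = 0.5, r2 = 0.1)))
  expect_equal(p2, c(A = 0.75, B = 0.25))
  expect_equal(sum(p2), 1)

  # single receptor, three methods
  p3 <- proportion_best(list(A = c(r1 = 0.2), B = c(r1 = 0.9),
                             C = c(r1 = 0.5)))
  expect_equal(p3, c(A = 0, B = 1, C = 0))

  expect_error(proportion_best(list(A = a)), "at least 2")
  expect_message(
    p4 <- proportion_best(list(A = c(r1 = 0.1, r2 = NA),
                               B = c(r1 = 0.6, r2 = 0.2))),
    "dropping")
  expect_equal(p4, c(A = 0, B = 1))
})

test_that("proportion-best accepts correlation report data frames", {
  ra <- data.frame(receptor = c("CD4", "CD8A"), antibody = c("x", "y"),
                   correlation = c(0.9, 0.2), method = "spearman")
  rb <- data.frame(receptor = c("CD4", "CD8A"), antibody = c("x", "y"),
                   correlation = c(0.3, 0.6), method = "spearman")
  expect_equal(proportion_best(list(A = ra, B = rb)),
               c(A = 0.5, B = 0.5))
})
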