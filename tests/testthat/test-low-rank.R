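test_that("randomized SVD recovers an embedded diagonal spectrum", {
  x <- matrix(0, 5, 5)
  diag(x)[1:3] <- c(3, 2, 1)
  f <- randomized_svd(x, max_rank = 3, seed = 1)
  expect_equal(f$d, c(3, 2, 1), tolerance = 1e-10)
  expect_equal(f$r, 3L)
})

test_that("randomized SVD matches an exact dense SVD on random matrices", {
  for (s in 1:5) {
    set.seed(100 + s)
    m <- sample(10:50, 1); n <- sample(10:40, 1)
    x <- matrix(rnorm(m * n), m, n)
    f <- randomized_svd(x, max_rank = 100, seed = s)
    ex <- svd(x)
    expect_equal(f$d, ex$d[seq_len(f$r)], tolerance = 1e-6)
    # orthonormal factors
    expect_lt(max(abs(crossprod(f$u) - diag(f$r))), 1e-8)
    expect_lt(max(abs(crossprod(f$v) - diag(f$r))), 1e-8)
  }
})

test_that("an exactly rank-2 matrix has a vanishing third singular value", {
  set.seed(9)
  x <- tcrossprod(matrix(rnorm(40), 20, 2), matrix(rnorm(30), 15, 2))
  f <- randomized_svd(x, max_rank = 5, seed = 2)
  expect_lt(f$d[3], 1e-8 * f$d[1])
})

test_that("randomized SVD is reproducible for a fixed seed", {
  set.seed(77); x <- matrix(rnorm(600), 30, 20)
  f1 <- randomized_svd(x, seed = 5)
  f2 <- randomized_svd(x, seed = 5)
  expect_identical(f1, f2)
  expect_error(randomized_svd(x, max_rank = 1), "max_rank")
  expect_error(randomized_svd(matrix(0, 4, 4)), "all-zero")
})

test_that("rank selection reproduces the worked run-length example", {
  s <- c(10, 8, 6, 4, 3.99, 3.98, 3.98, 3.98)
  rs <- select_rank(s)
  expect_equal(rs$k, 5L)
  expect_equal(rs$rounded_roc, c(2, 2, 2, 0.01, 0.01, 0, 0))
  expect_equal(rs$runs$value, c(2, 0.01, 0))
  expect_equal(rs$runs$length, c(3L, 2L, 2L))
  expect_false(rs$fallback)
})

test_that("rank selection falls back to full rank without a qualifying run", {
  s <- rep(2, 10)                       # constant stdevs: all drops zero
  expect_warning(rs <- select_rank(s), "falling back")
  expect_equal(rs$k, 10L)
  expect_true(rs$fallback)
})

test_that("a single qualifying run starting at the first pair gives k = 2", {
  s <- 5 - 0.5 * (0:9)                  # every drop is 0.5: one long run
  rs <- select_rank(s)
  expect_equal(rs$k, 2L)
})

test_that("rank selection needs at least three components", {
  expect_error(select_rank(c(2, 1)), "at least 3")
})

test_that("rank selection works straight from SVD factors", {
  sim <- simulate_joint(n_cells = 300, n_genes = 80, n_receptors = 4,
                        seed = 21)
  f <- randomized_svd(log_normalize(sim$counts), max_rank = 40, seed = 21)
  rs <- select_rank(f)
  expect_equal(rs$stdevs, f$d / sqrt(f$m - 1))
  expect_gte(rs$k, 2L)
  expect_lte(rs$k, f$r)
})

test_that("reconstruction satisfies Eckart-Young on small matrices", {
  set.seed(42)
  x <- matrix(rnorm(35 * 25), 35, 25)
  f <- randomized_svd(x, max_rank = 100, seed = 3)
  ex <- svd(x)
  errs <- vapply(1:10, function(k) {
    norm(x - reconstruct(f, k), "F")
  }, numeric(1))
  expected <- vapply(1:10, function(k) sqrt(sum(ex$d[-seq_len(k)]^2)),
                     numeric(1))
  expect_equal(errs, expected, tolerance = 1e-6)
  expect_true(all(diff(errs) <= 1e-10))          # non-increasing in k
})

test_that("full-rank reconstruction returns the input; k is validated", {
  set.seed(8)
  x <- tcrossprod(matrix(rnorm(24), 12, 2), matrix(rnorm(16), 8, 2))
  f <- randomized_svd(x, max_rank = 11, seed = 1)
  expect_equal(reconstruct(f, f$r), x, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(reconstruct(f, 0), "k must be")
  expect_error(reconstruct(f, f$r + 1), "k must be")
})

test_that("best rank-1 approximation of a padded diagonal drops sqrt(5)", {
  x <- matrix(0, 5, 5); diag(x)[1:3] <- c(3, 2, 1)
  f <- randomized_svd(x, max_rank = 4, seed = 6)
  expect_equal(norm(x - reconstruct(f, 1), "F"), sqrt(2^2 + 1^2),
               tolerance = 1e-8)
})

test_that("planted spectral elbows are recovered across seeds and ranks", {
  hits <- 0L
  for (s in 1:20) {
    p <- 2L + (s %% 7L)
    rs <- select_rank(simulate_spectrum(p, seed = 1000L + s))
    if (rs$k == p) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
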