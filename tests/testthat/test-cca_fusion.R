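# brute-force oracle: maximize |cor(wx'X, wy'Y)| over random unit directions
grid_search_cca <- function(X, Y, n_dir = 4000L, seed = 99L) {
  withr::with_seed(seed, {
    best <- 0
    for (i in seq_len(n_dir)) {
      wx <- rnorm(nrow(X)); wy <- rnorm(nrow(Y))
      r <- suppressWarnings(abs(cor(as.vector(wx %*% X),
                                    as.vector(wy %*% Y))))
      if (is.finite(r) && r > best) best <- r
    }
    best
  })
}

test_that("one-dimensional fusion reproduces the absolute Pearson r", {
  m <- cca_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m$correlations, 1.0, tolerance = 1e-8)
  z <- cca_transform(m, c(1, 2, 3), c(2, 4, 6))
  expect_equal(abs(cor(z[1, ], z[2, ])), 1.0, tolerance = 1e-8)

  x <- c(1, 2, 3); y <- c(3, 1, 2)
  expect_equal(cca_fit(x, y)$correlations, abs(cor(x, y)),
               tolerance = 1e-10)
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(40); y <- rnorm(40)
    expect_equal(cca_fit(x, y)$correlations, abs(cor(x, y)),
                 tolerance = 1e-8)
  }
  expect_error(cca_fit(c(1, 2), c(1, 2)), "3 samples")
})

test_that("low-dimensional correlations match grid search and cancor", {
  set.seed(31)
  X <- matrix(rnorm(100), 2)
  Y <- 0.6 * X + matrix(rnorm(100), 2)
  m <- cca_fit(X, Y)
  expect_lt(abs(m$correlations[1] - grid_search_cca(X, Y)), 1e-2)
  # independent library oracle for the full spectrum
  cc <- stats::cancor(t(X), t(Y))
  expect_equal(m$correlations, cc$cor, tolerance = 1e-6)
  expect_true(all(diff(m$correlations) <= 1e-12))
  expect_true(all(m$correlations >= -1e-8 & m$correlations <= 1 + 1e-8))
})

test_that("training-set fused covariance has the canonical block structure", {
  set.seed(32)
  X <- matrix(rnorm(120), 2)
  Y <- matrix(rnorm(120), 2) + 0.5 * X
  m <- cca_fit(X, Y)
  Z <- cca_transform(m, X, Y)
  d <- m$d
  S_star <- rbind(cbind(diag(d), diag(m$correlations, d)),
                  cbind(diag(m$correlations, d), diag(d)))
  expect_lt(max(abs(cov(t(Z)) - S_star)), 1e-5)
})

test_that("canonical correlations are affine-invariant and symmetric", {
  set.seed(33)
  for (rep in 1:5) {
    X <- matrix(rnorm(2 * 50), 2)
    Y <- matrix(rnorm(2 * 50), 2) + 0.3 * X
    m0 <- cca_fit(X, Y)
    A <- matrix(rnorm(4), 2); while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
    m1 <- cca_fit(A %*% X + c(3, -7), Y)
    expect_equal(m1$correlations, m0$correlations, tolerance = 1e-8)
    m2 <- cca_fit(Y, X)
    expect_equal(m2$correlations, m0$correlations, tolerance = 1e-8)
  }
})

test_that("transforms replay exactly on training data, sanely on held-out", {
  set.seed(34)
  X <- matrix(rnorm(2 * 200), 2)
  Y <- matrix(rnorm(2 * 200), 2) + 0.4 * X
  tr <- 1:120; te <- 121:200
  m <- cca_fit(X[, tr], Y[, tr])
  Ztr <- cca_transform(m, X[, tr], Y[, tr])
  expect_equal(unname(apply(Ztr, 1, var)), rep(1, 2 * m$d),
               tolerance = 1e-6)
  Zte <- cca_transform(m, X[, te], Y[, te])
  expect_true(all(apply(Zte, 1, var) > 0.5 & apply(Zte, 1, var) < 2))
  # degenerate injected model maps everything to zero
  m0 <- m
  m0$Wx[] <- 0; m0$Wy[] <- 0
  expect_true(all(cca_transform(m0, X, Y) == 0))
  expect_error(cca_transform(m, X[1, , drop = FALSE], Y), "dimensions")
})

test_that("the sequential chain fuses five features into two rows", {
  set.seed(35)
  # self-fusion: five identical copies -> perfect correlation at every step
  v <- rnorm(50)
  # collinear inputs make the within-set covariance singular by design
  ch <- suppressWarnings(sequential_fuse(replicate(5, v, simplify = FALSE)))
  for (m in ch$models) expect_equal(m$correlations[1], 1, tolerance = 1e-6)
  expect_identical(nrow(ch$Z), 2L)

  # independent features: canonical correlations near zero at n = 200
  cols <- replicate(5, rnorm(200), simplify = FALSE)
  ch2 <- sequential_fuse(cols)
  expect_identical(nrow(ch2$Z), 2L)
  expect_lt(max(abs(cor(t(ch2$Z))[1, 2])), 0.3)

  # planted common factor: strong correlation at every step
  g <- rnorm(200)
  cols3 <- lapply(1:5, function(k) 0.9 * g + 0.3 * rnorm(200))
  ch3 <- sequential_fuse(cols3)
  for (m in ch3$models) expect_gt(m$correlations[1], 0.8)

  expect_error(sequential_fuse(replicate(5, rnorm(5), simplify = FALSE)),
               "at least 6")
})

test_that("fitted chains replay identically after JSON serialization", {
  set.seed(36)
  cols <- replicate(5, rnorm(40), simplify = FALSE)
  ch <- sequential_fuse(cols)
  path <- withr::local_tempfile(fileext = ".json")
  write_cca_chain(ch, path)
  back <- read_cca_chain(path)
  cols_new <- replicate(5, rnorm(15), simplify = FALSE)
  expect_equal(sequential_transform(back, cols_new),
               sequential_transform(ch, cols_new), tolerance = 1e-12)
  expect_identical(back$order, ch$order)
})
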