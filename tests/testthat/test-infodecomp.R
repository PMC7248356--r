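test_that("entropies of simple marginals are exact", {
  uni <- binary_pmf(function(x, z, u, y) 1)           # all independent
  expect_equal(entropy(uni, "Y"), 1)
  point <- binary_pmf(function(x, z, u, y)
    as.numeric(x == 0 & z == 0 & u == 0 & y == 0))
  expect_equal(entropy(point, "Y"), 0)
  skew <- binary_pmf(function(x, z, u, y) if (y == 0) 0.25 else 0.75)
  expect_equal(entropy(skew, "Y"), 0.811278, tolerance = 1e-6)
  expect_error(entropy(uni, character()), "empty")
  # marginalisation agrees with brute-force summation
  p <- random_pmf(4)
  for (ax in list("X", c("X", "Y"), c("Z", "U", "Y")))
    expect_equal(entropy(p, ax), brute_entropy(p, ax), tolerance = 1e-12)
})

test_that("conditional entropy captures determinism and independence", {
  copy <- binary_pmf(function(x, z, u, y) as.numeric(y == x))
  expect_equal(conditional_entropy(copy, "Y", "X"), 0)
  uni <- binary_pmf(function(x, z, u, y) 1)
  expect_equal(conditional_entropy(uni, "Y", "X"), entropy(uni, "Y"))
  bsc <- binary_pmf(function(x, z, u, y) if (y == x) 0.9 else 0.1)
  expect_equal(conditional_entropy(bsc, "Y", "X"), binary_entropy(0.1),
               tolerance = 1e-12)
  expect_equal(conditional_entropy(bsc, "Y", "X"), 0.468996,
               tolerance = 1e-6)
  expect_error(conditional_entropy(bsc, "Y", c("Y", "X")), "overlapping")
})

test_that("mutual information is symmetric and exact on a noisy channel", {
  uni <- binary_pmf(function(x, z, u, y) 1)
  expect_equal(mutual_information(uni, "X", "Y"), 0)
  copy <- binary_pmf(function(x, z, u, y) as.numeric(y == x))
  expect_equal(mutual_information(copy, "X", "Y"), 1)
  bsc <- binary_pmf(function(x, z, u, y) if (y == x) 0.9 else 0.1)
  expect_equal(mutual_information(bsc, "X", "Y"), 1 - binary_entropy(0.1),
               tolerance = 1e-12)
  expect_equal(mutual_information(bsc, "X", "Y"), 0.531004,
               tolerance = 1e-6)
  for (seed in 1:5) {
    p <- random_pmf(seed)
    expect_equal(mutual_information(p, "X", "Y"),
                 mutual_information(p, "Y", "X"), tolerance = 1e-12)
  }
})

test_that("conditional MI reveals parity structure and stays non-negative", {
  uni <- binary_pmf(function(x, z, u, y) 1)
  expect_equal(conditional_mutual_information(uni, "X", "Y", "Z"), 0)
  xor <- binary_pmf(function(x, z, u, y) as.numeric(y == xor(x, z)))
  expect_equal(conditional_mutual_information(xor, "X", "Y", "Z"), 1)
  # direct triple-sum oracle on a random table
  p <- random_pmf(11)
  d <- dim(p$table)
  acc <- 0
  for (x in 1:d[1]) for (y in 1:d[4]) for (z in 1:d[2]) {
    pxyz <- sum(p$table[x, z, , y])
    pz <- sum(p$table[, z, , ])
    pxz <- sum(p$table[x, z, , ])
    pyz <- sum(p$table[, z, , y])
    if (pxyz > 0)
      acc <- acc + pxyz * log2(pz * pxyz / (pxz * pyz))
  }
  expect_equal(conditional_mutual_information(p, "X", "Y", "Z"), acc,
               tolerance = 1e-12)
  for (seed in 6:10) {
    p <- random_pmf(seed)
    expect_gte(conditional_mutual_information(p, "X", "Y", c("Z", "U")),
               -1e-12)
  }
})

test_that("the four-way interaction term signs redundancy and synergy", {
  uni <- binary_pmf(function(x, z, u, y) 1)
  f0 <- four_way_interaction(uni)
  expect_equal(f0$value, 0)
  expect_lt(f0$max_discrepancy, 1e-12)
  redundant <- binary_pmf(function(x, z, u, y)
    as.numeric(y == x & z == x))          # Y = X = Z, U independent
  expect_equal(four_way_interaction(redundant)$value, 1)
  synergy <- binary_pmf(function(x, z, u, y) as.numeric(y == xor(x, z)))
  expect_equal(four_way_interaction(synergy)$value, -1)
})

test_that("the output-entropy decomposition and its residual are exact", {
  uni <- binary_pmf(function(x, z, u, y) 1)
  rep0 <- decompose_output_entropy(uni)
  expect_equal(rep0$I4, 0)
  expect_equal(rep0$H_y_given_xzu, rep0$H_y)
  expect_equal(rep0$residual, 0)

  # Y = Z xor U with X independent: the decomposition under-counts H(Y)
  zu <- binary_pmf(function(x, z, u, y) as.numeric(y == xor(z, u)))
  repz <- decompose_output_entropy(zu)
  expect_equal(repz$I4, 0)
  expect_equal(repz$I_yz_given_xu, 1)
  expect_equal(repz$I_yu_given_xz, 1)
  expect_equal(repz$H_y_given_xzu, 0)
  expect_equal(repz$H_y, 1)
  expect_equal(repz$residual, -1)

  # residual identity: residual = I(Y;Z|X) - I(Y;Z|X,U) on random pmfs
  for (seed in 21:26) {
    p <- random_pmf(seed)
    r <- decompose_output_entropy(p)
    expect_equal(r$residual,
                 conditional_mutual_information(p, "Z", "Y", "X") -
                   conditional_mutual_information(p, "Z", "Y", c("X", "U")),
                 tolerance = 1e-10)
  }
})

test_that("single-field weight settings reduce F to plain MI", {
  for (seed in 31:33) {
    p <- random_pmf(seed)
    # the RF case is an exact identity because the four-way term is
    # anchored on (Y, X): F = I4 + I(Y;X|Z,U) = I(Y;X)
    f1 <- decompose_output_entropy(
      p, objective_weights(1, 1, 0, 0, 0))$F
    expect_equal(f1, mutual_information(p, "Y", "X"), tolerance = 1e-12)
    # the LCF/UCF cases hold only up to the discrepancy between the
    # pair-anchored four-way expressions, which the diagnostic reports
    fwi <- four_way_interaction(p)
    f2 <- decompose_output_entropy(
      p, objective_weights(1, 0, 1, 0, 0))$F
    expect_equal(f2 - mutual_information(p, "Y", "Z"),
                 fwi$expressions[["X;Y"]] - fwi$expressions[["Y;Z"]],
                 tolerance = 1e-12)
    expect_lte(abs(f2 - mutual_information(p, "Y", "Z")),
               fwi$max_discrepancy + 1e-12)
    f3 <- decompose_output_entropy(
      p, objective_weights(1, 0, 0, 1, 0))$F
    expect_equal(f3 - mutual_information(p, "Y", "U"),
                 fwi$expressions[["X;Y"]] - fwi$expressions[["Y;U"]],
                 tolerance = 1e-12)
  }
  expect_error(objective_weights(2, 0, 0, 0, 0), "\\[-1, 1\\]")
})

test_that("the chain rule holds exactly on pmfs", {
  for (seed in 41:46) {
    p <- random_pmf(seed, dims = c(3, 2, 2, 3))
    lhs <- mutual_information(p, "Y", "X") +
      conditional_mutual_information(p, "Z", "Y", "X") +
      conditional_mutual_information(p, "U", "Y", c("X", "Z"))
    rhs <- mutual_information(p, "Y", c("X", "Z", "U"))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("the plug-in estimator recovers analytic Gaussian MI", {
  set.seed(1234)
  n <- 1e5
  rho <- 0.9
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  samples <- data.frame(X = x, Z = stats::rnorm(n), U = stats::rnorm(n),
                        Y = y)
  pmf <- estimate_pmf(samples, n_bins = 24)
  analytic <- -0.5 * log2(1 - rho^2)
  expect_lt(abs(mutual_information(pmf, "X", "Y") - analytic), 0.1)
})

test_that("estimator handles degenerate and small inputs", {
  const <- data.frame(X = rep(1, 5), Z = rep(2, 5), U = rep(3, 5),
                      Y = rep(4, 5))
  pmf <- estimate_pmf(const)
  expect_equal(dim(pmf$table), c(1, 1, 1, 1))
  expect_equal(entropy(pmf, "Y"), 0)
  set.seed(2)
  anyp <- estimate_pmf(matrix(stats::runif(40), 10, 4))
  expect_equal(sum(anyp$table), 1, tolerance = 1e-12)
  expect_error(estimate_pmf(data.frame(X = 1, Z = 1, U = 1, Y = 1)[0, ]),
               "zero samples")
})

test_that("coarser binning does not inflate estimated dependence", {
  set.seed(55)
  n <- 2e4
  x <- stats::rnorm(n)
  y <- 0.8 * x + 0.6 * stats::rnorm(n)
  samples <- data.frame(X = x, Z = 0 * x, U = 0 * x, Y = y)
  mi <- vapply(c(4, 8, 16), function(b)
    mutual_information(estimate_pmf(samples, n_bins = b), "X", "Y"),
    numeric(1))
  expect_true(all(diff(mi) > -0.02))   # finer bins only add information
})

test_that("pmf CSV round trip preserves the table", {
  p <- random_pmf(77, dims = c(3, 2, 2, 4))
  path <- tempfile(fileext = ".csv")
  write_pmf(p, path)
  back <- read_pmf(path)
  expect_equal(back$table, p$table, tolerance = 1e-12)
  unlink(path)
})
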