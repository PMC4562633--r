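test_that("path starts all-zero at s_max and the single-predictor closed form holds", {
  set.seed(11)
  T <- 10
  y <- as.numeric(scale(rnorm(T)))
  X <- matrix(y, dimnames = list(NULL, "twin"))
  cfg <- enet_config()
  path <- fit_enet_path(y, X, cfg)

  expect_equal(path$coefficients[, 1], c(twin = 0))
  expect_equal(path$variance_explained[1], 0)
  expect_true(all(diff(path$penalties) < 0))

  # univariate closed-form oracle at every penalty:
  # beta(s) = S(x'(y-ybar)/T, s*mix) / (x'x/T + s*(1-mix))
  g <- sum(X[, 1] * (y - mean(y))) / T
  xn <- sum(X[, 1]^2) / T
  oracle <- soft_threshold(g, path$penalties * cfg$mixing) /
    (xn + path$penalties * (1 - cfg$mixing))
  expect_equal(unname(path$coefficients[1, ]), oracle, tolerance = 1e-10)

  last <- length(path$penalties)
  expect_equal(unname(path$coefficients[1, last]), 0.99800, tolerance = 1e-4)
  expect_gt(path$variance_explained[last], 0.99)
})

test_that("orthonormal designs match the soft-threshold/shrinkage closed form", {
  for (seed in 1:5) {
    set.seed(seed)
    T <- 8; P <- 4
    X <- orthonormal_design(T, P)
    y <- rnorm(T)
    cfg <- enet_config()
    path <- fit_enet_path(y, X, cfg)
    g <- as.numeric(crossprod(X, y - mean(y))) / T
    for (l in seq_along(path$penalties)) {
      s <- path$penalties[l]
      oracle <- soft_threshold(g, s * cfg$mixing) / (1 + s * (1 - cfg$mixing))
      expect_equal(unname(path$coefficients[, l]), oracle, tolerance = 1e-6)
    }
  }
})

test_that("path points satisfy the objective's stationarity conditions", {
  for (seed in 1:5) {
    set.seed(seed)
    T <- 10; P <- 30
    X <- scale(matrix(rnorm(T * P), T, P))
    y <- rnorm(T)
    for (mix in c(0.3, 0.5, 1)) {
      cfg <- enet_config(mixing = mix)
      path <- fit_enet_path(y, X, cfg)
      expect_lt(path_kkt_violation(path, X, y, mix), 1e-6)
      # variance explained nondecreasing along decreasing penalty
      expect_gte(min(diff(path$variance_explained)), -1e-9)
    }
  }
})

test_that("identical predictors receive equal coefficients (grouping effect)", {
  set.seed(5)
  T <- 12
  x <- as.numeric(scale(rnorm(T)))
  X <- cbind(a = x, b = x, c = as.numeric(scale(rnorm(T))))
  y <- 0.9 * x + rnorm(T, sd = 0.2)
  path <- fit_enet_path(y, X, enet_config(mixing = 0.5))
  for (l in seq_along(path$penalties)) {
    expect_lt(abs(path$coefficients["a", l] - path$coefficients["b", l]), 1e-6)
  }
})

test_that("select_coefficients picks the sparsest qualifying model", {
  mock_path <- structure(list(
    target_gene = "g", penalties = c(4, 3, 2, 1),
    coefficients = matrix(1:8, 2, 4, dimnames = list(c("p1", "p2"), NULL)),
    intercepts = rep(0, 4),
    variance_explained = c(0.1, 0.5, 0.8, 0.9)), class = "regression_path")
  sel <- select_coefficients(mock_path, 0.75)
  expect_equal(sel$penalty, 2)
  expect_equal(unname(sel$coefficients), c(5, 6))
  expect_true(sel$met_target)
  expect_equal(sel$achieved_variance, 0.8)

  sel2 <- select_coefficients(mock_path, 0.95)   # unreachable target
  expect_false(sel2$met_target)
  expect_equal(sel2$penalty, 1)

  sel3 <- select_coefficients(mock_path, 0)      # boundary: first model
  expect_equal(sel3$penalty, 4)
})

test_that("neighbor calling respects the zero tolerance", {
  co <- c(g1 = 0.3, g2 = 0, g3 = -0.2)
  expect_equal(neighbors_of_gene(co), c("g1", "g3"))
  expect_equal(neighbors_of_gene(c(g1 = 0, g2 = 0)), character())
  expect_equal(neighbors_of_gene(c(g1 = 1e-12), zero_tol = 1e-10), character())
})

test_that("degenerate inputs are rejected with clear errors", {
  y <- rnorm(10)
  X <- matrix(rnorm(50), 10, 5)
  expect_error(fit_enet_path(y[1:2], X[1:2, ]), "3 samples")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fit_enet_path(y, Xb), "non-finite")
  expect_error(fit_enet_path(rep(1, 10), X), "zero variance")
})
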