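test_that("local quadratic WLS reproduces exact polynomials", {
  set.seed(1)
  a <- runif(30, -1, 1)
  w <- runif(30, 0.2, 1)
  y <- 1 + 2 * (a - 0.2) + 3 * (a - 0.2)^2
  expect_equal(localQuadraticFit(y, a, 0.2, w), c(1, 2, 3), tolerance = 1e-9)
  expect_equal(localQuadraticFit(rep(4, 30), a, 0, w), c(4, 0, 0),
               tolerance = 1e-9)
})

test_that("local quadratic WLS matches the lm() oracle on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    a <- rnorm(n)
    at <- rnorm(1)
    w <- runif(n, 0.05, 2)
    y <- rnorm(n)
    ours <- localQuadraticFit(y, a, at, w)
    d <- a - at
    oracle <- unname(coef(lm(y ~ d + I(d^2), weights = w)))
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("singular designs degrade gracefully to lower degree", {
  # all observations at the focal point: intercept only (the mean)
  y <- c(1, 2, 3)
  expect_equal(localQuadraticFit(y, c(5, 5, 5), 5, rep(1, 3)), c(2, 0, 0))
  # two distinct points: linear fit, no curvature
  cf <- localQuadraticFit(c(0, 0, 2), c(0, 0, 1), 0, rep(1, 3))
  expect_equal(cf[3], 0)
  expect_equal(cf[1] + cf[2], 2, tolerance = 1e-10)
})

test_that("residuals and conditional covariance match brute force", {
  set.seed(5)
  N <- 120
  a <- runif(N, 0, 10)
  x <- cbind(V1 = rnorm(N), V2 = rnorm(N), V3 = rnorm(N))
  w <- computeWeights(a, c(3, 7), kernel = "gaussian", bw = 2)
  mom <- localMoments(x, a, w, residualize = TRUE, mode = "weighted",
                      pd = FALSE)
  # brute force at focal point 1
  t <- 1
  wt <- weightMatrix(w)[, t]
  E <- sapply(1:3, function(i) {
    cf <- localQuadraticFit(x[, i], a, focalGrid(w)[t], wt)
    d <- a - focalGrid(w)[t]
    x[, i] - (cf[1] + cf[2] * d + cf[3] * d^2)
  })
  Sref <- t(E * wt) %*% E / sum(wt)
  expect_equal(unname(conditionalCov(mom)[, , t]), unname(Sref),
               tolerance = 1e-8)
  expect_equal(mom@means[, t],
               setNames(sapply(1:3, function(i) {
                 localQuadraticFit(x[, i], a, focalGrid(w)[t], wt)[1]
               }), colnames(x)), tolerance = 1e-8)
})

test_that("all-ones weights at one focal point give the plain (/N) moment matrix", {
  set.seed(6)
  N <- 60
  x <- matrix(rnorm(N * 2), N, 2, dimnames = list(NULL, c("A", "B")))
  a <- rnorm(N)
  w <- new("LsemWeights", weights = matrix(1, N, 1), grid = 0,
           Wt = N, density = 1, kernel = "uniform", bw = 1, h = NA_real_,
           dropped = integer(0))
  mom <- localMoments(x, a, w, residualize = FALSE, pd = FALSE)
  xc <- scale(x, scale = FALSE)
  expect_equal(unname(conditionalCov(mom)[, , 1]),
               unname(crossprod(xc) / N), tolerance = 1e-10)
})

test_that("local-regression covariance mode returns product-curve intercepts", {
  set.seed(8)
  N <- 200
  a <- runif(N, -1, 1)
  x <- matrix(rnorm(2 * N), N, 2, dimnames = list(NULL, c("A", "B")))
  w <- computeWeights(a, 0, kernel = "gaussian", bw = 0.8)
  # constant products: both modes agree with the constant
  x2 <- cbind(A = rep(1, N), B = rep(1, N)) * sqrt(0.5)
  # build residual products directly through the estimator on centered data
  momw <- localMoments(x, a, w, mode = "weighted", pd = FALSE)
  moml <- localMoments(x, a, w, mode = "local_regression", pd = FALSE)
  # no moderator trend in the products: the two estimators agree closely
  expect_equal(conditionalCov(moml)[, , 1], conditionalCov(momw)[, , 1],
               tolerance = 0.15)
  # exact check: quadratic product trend is picked up by the intercept
  e <- sqrt(pmax(0.2, 1 + 0.5 * a)) * rnorm(N)
  xq <- cbind(A = e, B = e)
  momq <- localMoments(xq, a, w, residualize = FALSE,
                       mode = "local_regression", pd = FALSE)
  d <- a - 0
  E <- sweep(xq, 2, colSums(xq * weightMatrix(w)[, 1]) / sum(weightMatrix(w)[, 1]))
  oracle <- coef(lm(I(E[, 1] * E[, 2]) ~ d + I(d^2),
                    weights = weightMatrix(w)[, 1]))[1]
  expect_equal(unname(conditionalCov(momq)[1, 2, 1]), unname(oracle),
               tolerance = 1e-8)
})

test_that("positive definite repair clips eigenvalues and keeps the diagonal", {
  S <- rand_pd(4, seed = 9)
  expect_equal(repairPositiveDefinite(S), S)   # idempotent on PD input

  B <- matrix(c(1, 1.2, 1.2, 1), 2)
  Br <- repairPositiveDefinite(B, floor = 1e-4)
  ev <- eigen(Br, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(Br), c(1, 1))

  Z <- matrix(0, 3, 3)
  Zr <- repairPositiveDefinite(Z, floor = 1e-4)
  expect_equal(Zr, diag(1e-4, 3))
  expect_error(repairPositiveDefinite(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("weighted conditional covariance is scale equivariant", {
  set.seed(10)
  N <- 80
  a <- runif(N)
  x <- matrix(rnorm(3 * N), N, 3, dimnames = list(NULL, c("A", "B", "C")))
  w <- computeWeights(a, 0.5, kernel = "gaussian", bw = 0.5)
  m1 <- localMoments(x, a, w, pd = FALSE)
  x2 <- x; x2[, 2] <- 3 * x[, 2]
  m2 <- localMoments(x2, a, w, pd = FALSE)
  S1 <- conditionalCov(m1)[, , 1]; S2 <- conditionalCov(m2)[, , 1]
  expect_equal(S2[2, 2], 9 * S1[2, 2], tolerance = 1e-10)
  expect_equal(S2[1, 2], 3 * S1[1, 2], tolerance = 1e-10)
  expect_equal(S2[1, 3], S1[1, 3], tolerance = 1e-10)
})

test_that("grid data with uniform half-spacing kernel give per-group ML covariances", {
  pop <- dgm3_pop()
  x <- as.matrix(pop[, 1:3])
  a <- pop$age
  w <- computeWeights(a, 6:18, kernel = "uniform", bw = 0.5)
  mom <- localMoments(x, a, w)
  dgm <- lsemDGM("dgm3", n_factors = 1)
  for (t in c(1, 7, 13)) {
    grp <- a == (6:18)[t]
    Sg <- crossprod(scale(x[grp, ], scale = FALSE)) / sum(grp)
    expect_equal(unname(conditionalCov(mom)[, , t]), unname(Sg),
                 tolerance = 1e-10)
    # and the population covariance is matched exactly (exact-moment data)
    expect_equal(unname(Sg), unname(dgm$sigma((6:18)[t])), tolerance = 1e-10)
  }
})

test_that("missing data fall back to pairwise deletion with renormalized weights", {
  set.seed(12)
  N <- 150
  a <- runif(N, 0, 1)
  x <- matrix(rnorm(2 * N), N, 2, dimnames = list(NULL, c("A", "B")))
  x[sample(N, 20), 1] <- NA
  w <- computeWeights(a, 0.5, kernel = "gaussian", bw = 0.4)
  mom <- localMoments(x, a, w, residualize = FALSE, pd = FALSE)
  wt <- weightMatrix(w)[, 1]
  keep <- !is.na(x[, 1])
  muA <- weighted.mean(x[keep, 1], wt[keep])
  muB <- weighted.mean(x[, 2], wt)
  eA <- x[, 1] - muA; eB <- x[, 2] - muB
  both <- keep
  expect_equal(mom@cov["A", "B", 1],
               sum(wt[both] * eA[both] * eB[both]) / sum(wt[both]),
               tolerance = 1e-10)
})
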