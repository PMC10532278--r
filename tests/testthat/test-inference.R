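test_that("curve mean/SD summaries match hand evaluation", {
  expect_equal(curveMeanSd(rep(3.2, 5), rep(0.2, 5)),
               c(M = 3.2, SD = 0))
  expect_equal(curveMeanSd(c(0, 1), c(0.5, 0.5)), c(M = 0.5, SD = 0.5))
  f <- c(0.7, 0.3)
  th <- c(2, 4)
  M <- 0.7 * 2 + 0.3 * 4
  expect_equal(unname(curveMeanSd(th, f)["SD"]),
               sqrt(0.7 * (2 - M)^2 + 0.3 * (4 - M)^2))
  expect_error(curveMeanSd(c(1, 2), c(0.5, 0.4)), "sum to 1")
})

test_that("bootstrap bias correction follows the clamped formula", {
  # zero estimated bias: replicate SDs match the sample SD on average
  r <- sdBiasCorrected(0.5, c(0.4, 0.6) * sqrt(0.25 / 0.26))
  expect_equal(r$sd_bc, 0.5, tolerance = 1e-10)
  # bias exceeding the estimate: clamp at zero
  r2 <- sdBiasCorrected(0.1, c(0.5, 0.6, 0.7))
  expect_equal(r2$sd_bc, 0)
  # generic identity: sd_bc = sqrt(max(0, 2 sd^2 - mean(sd*^2)))
  reps <- c(0.2, 0.3, 0.25)
  r3 <- sdBiasCorrected(0.28, reps)
  expect_equal(r3$sd_bc, sqrt(max(0, 2 * 0.28^2 - mean(reps^2))))
  expect_equal(r3$se, sd(reps))
})

test_that("SD test uses the one-sided normal convention", {
  expect_equal(sdTest(0, 1), list(t = 0, p = 0.5))
  r <- sdTest(2.326, 1)
  expect_equal(r$p, 0.01, tolerance = 1e-3)
  expect_warning(r0 <- sdTest(0.2, 0), "undefined")
  expect_true(is.na(r0$t) && is.na(r0$p))
})

test_that("Wald equality test matches the dense hand computation", {
  w0 <- waldEqualityTest(rep(2, 6), diag(6))
  expect_equal(w0$chisq, 0)
  expect_equal(w0$p, 1)
  expect_equal(w0$df, 5)

  w <- waldEqualityTest(c(0, 1, 0), diag(3))
  H <- rbind(c(-1, 1, 0), c(0, -1, 1))
  hv <- H %*% diag(3) %*% t(H)
  hand <- drop(t(H %*% c(0, 1, 0)) %*% solve(hv) %*% (H %*% c(0, 1, 0)))
  expect_equal(w$chisq, hand)
  expect_equal(w$chisq, 2 / 3, tolerance = 1e-12)
  expect_equal(w$df, 2)
})

test_that("Wald statistic is invariant to the contrast basis", {
  set.seed(51)
  Tn <- 7
  xi <- rnorm(Tn)
  V <- rand_pd(Tn)
  H1 <- diff(diag(Tn))
  # deviations from the mean, first T-1 rows: same contrast space
  H2 <- (diag(Tn) - 1 / Tn)[1:(Tn - 1), ]
  w1 <- waldEqualityTest(xi, V, H = H1)
  w2 <- waldEqualityTest(xi, V, H = H2)
  expect_equal(w1$chisq, w2$chisq, tolerance = 1e-8)
  expect_equal(w1$df, w2$df)
})

test_that("functional Wald test recovers exact polynomial coefficients", {
  grid <- seq(6, 18, length.out = 13)
  xi <- 2 + 3 * grid
  w <- waldFunctionalTest(xi, grid, diag(13), hypothesis = ~ m)
  expect_equal(unname(w$coef["m"]), 3, tolerance = 1e-10)
  expect_equal(w$df, 1)

  wc <- waldFunctionalTest(rep(5, 13), grid, diag(13))
  expect_equal(wc$chisq, 0, tolerance = 1e-10)
  expect_equal(wc$df, 2)   # linear plus quadratic hypothesis
  expect_equal(wc$p, 1)
})

test_that("bootstrap draws are reproducible and summaries are coherent", {
  dat <- drawSample(dgm1_pop(), 700, seed = 52)
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                      par_invariant = c("FX=~X2", "FX=~X3"), est_dif = TRUE,
                      wt_min = 0)
  b1 <- lsemBootstrap(fit, dat, R = 12, seed = 99)
  b2 <- lsemBootstrap(fit, dat, R = 12, seed = 99)
  expect_identical(b1@curves, b2@curves)
  b3 <- lsemBootstrap(fit, dat, R = 12, seed = 100)
  expect_false(identical(b1@curves, b3@curves))

  s <- lsemSummary(fit, b1)
  expect_true(all(c("parameter", "M", "SD", "SD_bc", "SE", "t", "p",
                    "wald_chisq", "wald_df", "wald_p") %in% names(s)))
  expect_true(all(s$SD >= 0))
  # invariant parameters: exactly zero SD, undefined tests
  inv <- s[s$parameter %in% c("FX=~X2", "FX=~X3"), ]
  expect_equal(inv$SD, c(0, 0))
  expect_equal(inv$SD_bc, c(0, 0))
  expect_true(all(is.na(inv$p)))
  # free parameters: bias correction shrinks the raw SD estimate or not,
  # but never goes negative, and SD_bc <= SD when the bias estimate is >= 0
  free <- s[s$parameter == "FX~~FX", ]
  expect_gte(free$SD_bc, 0)
  expect_true(is.finite(free$p))
  # replicate curves for a fast-path replicate equal a fresh refit
  set.seed(99)
  idx <- sample.int(nrow(dat), nrow(dat), replace = TRUE)
  direct <- lsemEstimate(dat[idx, ], "age", "FX =~ X1 + X2 + X3",
                         grid = 6:18, bw = fit@weights@bw,
                         par_invariant = c("FX=~X2", "FX=~X3"),
                         est_dif = TRUE, wt_min = 0)
  md <- localsem:::.curveMatrices(direct)
  expect_equal(b1@curves[, , 1], md$est[rownames(b1@curves), ],
               tolerance = 1e-5)
})

test_that("cluster bootstrap resamples whole clusters", {
  dat <- drawSample(dgm3_pop(), 400, seed = 53)
  dat$school <- rep(1:40, each = 10)
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                      wt_min = 0, est_joint = TRUE)
  b <- lsemBootstrap(fit, dat, R = 5, cluster = "school", seed = 3)
  expect_equal(b@design, "cluster")
  expect_equal(dim(b@curves)[3], 5 - b@dropped)
  # the resampling indices partition into original clusters by construction:
  # replaying the draw must give row blocks of size 10
  set.seed(3)
  ids <- unique(dat$school)
  pick <- sample(ids, length(ids), replace = TRUE)
  idx <- unlist(lapply(pick, function(g) which(dat$school == g)))
  expect_equal(length(idx) %% 10, 0)
  expect_true(all(table(dat$school[idx]) %% 10 == 0))
})

test_that("replication designs scale the curve covariance by repl_factor", {
  dat <- drawSample(dgm3_pop(), 300, seed = 54)
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                      wt_min = 0, est_joint = TRUE)
  # half-sampling replicate weights
  set.seed(8)
  R <- 6
  rd <- matrix(rbinom(nrow(dat) * R, 1, 0.5) * 2, nrow(dat), R)
  expect_error(lsemBootstrap(fit, dat, repl_design = rd), "repl_factor")
  b <- lsemBootstrap(fit, dat, repl_design = rd, repl_factor = 1 / R, seed = 1)
  expect_equal(b@design, "repl_design")
  V <- curveCov(b, "FX~~FX")
  b2 <- b; b2@repl_factor <- 2 / R
  expect_equal(curveCov(b2, "FX~~FX"), 2 * V)
  # pointwise SEs are the square roots of the diagonal of V
  se <- pointwiseSE(b)
  expect_equal(unname(se["FX~~FX", ]), unname(sqrt(diag(V))), tolerance = 1e-10)
})

test_that("permutation test preserves the moderator multiset and detects variation", {
  dat <- drawSample(dgm1_pop(), 4000, seed = 55)
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                      wt_min = 0, est_joint = TRUE)
  pt <- lsemPermutationTest(fit, dat, B = 9, seed = 4)
  expect_true(all(pt$p >= 1 / 10 & pt$p <= 1))
  reps <- attr(pt, "replicates")
  expect_equal(dim(reps), c(nrow(pt), 9))
  # add-one p-value convention reproduced from the stored replicates
  for (k in seq_len(nrow(pt))) {
    expect_equal(pt$p[k], (1 + sum(reps[k, ] >= pt$SD_obs[k])) / 10)
  }
  # true variation in the factor variance curve: smallest possible p
  expect_equal(pt$p[pt$parameter == "FX~~FX"], 1 / 10)
  # the shuffle itself preserves the multiset
  set.seed(4)
  perm <- sample(dat$age)
  expect_equal(sort(perm), sort(dat$age))
})
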