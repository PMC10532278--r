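test_that("implied covariance matches hand-evaluated structures", {
  m <- lsemModel("F =~ 1*X1 + 1*X2 + 1*X3")
  th <- c("F~~F" = 1, "X1~~X1" = 1, "X2~~X2" = 1, "X3~~X3" = 1)
  S <- impliedCovariance(m, th)
  expect_equal(unname(diag(S)), rep(2, 3))
  expect_equal(unname(S[lower.tri(S)]), rep(1, 3))

  # zero loadings: Sigma reduces to the residual covariance
  m0 <- lsemModel("F =~ 0*X1 + 0*X2\nF ~~ 1*F")
  th0 <- c("X1~~X1" = 2, "X2~~X2" = 3)
  expect_equal(unname(impliedCovariance(m0, th0)), diag(c(2, 3)))
})

test_that("a zero structural path reduces to the path-free covariance", {
  mb <- lsemModel("FX =~ 1*X1 + X2\nFY =~ 1*Y1 + Y2\nFY ~ FX")
  thb <- c("FX=~X2" = 0.8, "FY=~Y2" = 0.7, "FY~FX" = 0,
           "FX~~FX" = 1.2, "FY~~FY" = 0.9,
           "X1~~X1" = 0.5, "X2~~X2" = 0.5, "Y1~~Y1" = 0.5, "Y2~~Y2" = 0.5)
  mp <- lsemModel("FX =~ 1*X1 + X2\nFY =~ 1*Y1 + Y2\nFX ~~ 0*FY")
  thp <- thb[setdiff(names(thb), "FY~FX")]
  expect_equal(impliedCovariance(mb, thb), impliedCovariance(mp, thp),
               tolerance = 1e-12)
  # nonzero path flows through (I - B)^{-1}
  thb["FY~FX"] <- 0.5
  S <- impliedCovariance(mb, thb)
  expect_equal(S["X1", "Y1"], 0.5 * 1.2, tolerance = 1e-12)
})

test_that("ML discrepancy matches closed forms and is a true discrepancy", {
  expect_equal(mlDiscrepancy(diag(2), diag(2)), 0)
  expect_equal(mlDiscrepancy(diag(2), 2 * diag(2)), 2 * log(2) - 1,
               tolerance = 1e-12)
  expect_equal(mlDiscrepancy(diag(c(2, 1)), diag(2)), 1 - log(2),
               tolerance = 1e-12)
  expect_error(mlDiscrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")

  set.seed(42)
  for (i in 1:20) {
    S <- rand_pd(4)
    Sig <- rand_pd(4)
    expect_gte(mlDiscrepancy(S, Sig), 0)
    expect_equal(mlDiscrepancy(S, S), 0, tolerance = 1e-10)
    # invariance under simultaneous congruence transforms
    A <- matrix(rnorm(16), 4) + 2 * diag(4)
    expect_equal(mlDiscrepancy(A %*% S %*% t(A), A %*% Sig %*% t(A)),
                 mlDiscrepancy(S, Sig), tolerance = 1e-8)
  }
})

test_that("just-identified one-factor fit matches the algebraic solution", {
  set.seed(7)
  lam <- c(1, 0.8, 1.2); phi <- 0.9; psi <- c(0.4, 0.6, 0.5)
  S <- tcrossprod(lam) * phi + diag(psi)
  S <- S + 0  # exact moments: model reproduces S, F = 0
  dimnames(S) <- list(paste0("X", 1:3), paste0("X", 1:3))
  fit <- fitGroups(one_factor_model(), S, ng = 500)
  expect_true(fit$convergence)
  expect_lt(fit$objective, 1e-8)
  v <- setNames(fit$values$value, fit$values$label)
  expect_equal(unname(v["FX~~FX"]), S[1, 2] * S[1, 3] / S[2, 3],
               tolerance = 1e-5)
  expect_equal(unname(v["FX=~X2"]), S[2, 3] / S[1, 3], tolerance = 1e-5)
  expect_equal(unname(v["FX=~X3"]), S[2, 3] / S[1, 2], tolerance = 1e-5)
  # implied covariance reproduces S elementwise
  expect_equal(unname(fit$implied[, , 1]), unname(S), tolerance = 1e-6)
})

test_that("identical groups with shared parameters equal the pooled fit", {
  S <- rand_pd(3, seed = 3)
  dimnames(S) <- list(paste0("X", 1:3), paste0("X", 1:3))
  m <- one_factor_model()
  labs <- m@partable$label[m@partable$free]
  f1 <- fitGroups(m, S, 100)
  f2 <- fitGroups(m, list(S, S), c(50, 50), par_invariant = labs)
  v1 <- setNames(f1$values$value, f1$values$label)
  v2 <- setNames(f2$values$value[f2$values$group == 1],
                 f2$values$label[f2$values$group == 1])
  expect_equal(v1[labs], v2[labs], tolerance = 1e-6)
})

test_that("analytic gradient and expected Hessian agree with finite differences", {
  m <- lsemModel("FX =~ X1 + X2 + X3\nFY =~ Y1 + Y2 + Y3\nFY ~ FX")
  S <- rand_pd(6, seed = 8)
  dimnames(S) <- list(c(paste0("X", 1:3), paste0("Y", 1:3)),
                      c(paste0("X", 1:3), paste0("Y", 1:3)))
  fit <- fitGroups(m, S, 50)
  eng <- fit$engine
  set.seed(9)
  th <- fit$theta_work + rnorm(length(fit$theta_work), sd = 0.05)
  g <- drop(localsem:::.eng_gradient(th, eng))
  gn <- vapply(seq_along(th), function(k) {
    e <- 1e-6; tp <- th; tm <- th
    tp[k] <- tp[k] + e; tm[k] <- tm[k] - e
    (localsem:::.eng_objective(tp, eng) -
       localsem:::.eng_objective(tm, eng)) / (2 * e)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-5)
  H <- localsem:::.eng_hessian(th, eng)
  expect_equal(H, t(H))
  # the expected information is positive definite at the solution
  Hs <- localsem:::.eng_hessian(fit$theta_work, eng)
  expect_gt(min(eigen(Hs, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("objective at the solution never exceeds the start value", {
  S <- rand_pd(3, seed = 5)
  dimnames(S) <- list(paste0("X", 1:3), paste0("X", 1:3))
  fit <- fitGroups(one_factor_model(), S, 80)
  f_start <- localsem:::.eng_objective(fit$engine$theta0, fit$engine)
  expect_lte(fit$objective, f_start + 1e-12)
})

test_that("reordering indicators permutes but does not change estimates", {
  S <- rand_pd(3, seed = 21)
  nm <- paste0("X", 1:3)
  dimnames(S) <- list(nm, nm)
  m1 <- lsemModel("FX =~ 1*X1 + X2 + X3")
  m2 <- lsemModel("FX =~ X3 + X2 + 1*X1")  # X3 listed first but X1 anchors
  f1 <- fitGroups(m1, S, 100)
  perm <- c("X3", "X2", "X1")
  f2 <- fitGroups(m2, S[perm, perm], 100)
  v1 <- setNames(f1$values$value, f1$values$label)
  v2 <- setNames(f2$values$value, f2$values$label)
  expect_equal(v1[names(v2)], v2, tolerance = 1e-5)
})

test_that("fit statistics behave at the perfect-fit boundary and match a hand case", {
  # saturated: one factor, three indicators is just-identified, F ~ 0
  S <- rand_pd(3, seed = 6)
  dimnames(S) <- list(paste0("X", 1:3), paste0("X", 1:3))
  fit <- fitGroups(one_factor_model(), S, 120)
  st <- fitStatistics(fit)
  expect_equal(st$srmr, 0, tolerance = 1e-5)
  expect_equal(st$rmsea, 0)
  expect_equal(st$cfi, 1)
  expect_equal(st$df, 0)

  # 2x2 worked SRMR: residual 0.2 on the off-diagonal, unit variances
  m2 <- lsemModel("F =~ 1*X1 + 0.3*X2\nF ~~ 1*F\nX1 ~~ 0*X1\nX2 ~~ 0.91*X2")
  S2 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("X1", "X2"), c("X1", "X2")))
  Sig2 <- matrix(c(1, .3, .3, 1), 2)
  res <- (S2 - Sig2) / sqrt(tcrossprod(diag(S2)))
  srmr_hand <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  expect_equal(srmr_hand, 0.2 / sqrt(3), tolerance = 1e-12)
  fake <- list(engine = localsem:::.buildEngine(m2, list(S2), 100),
               implied = array(Sig2, c(2, 2, 1)), objective = 0, npar = 0,
               ng = 100)
  st2 <- fitStatistics(fake, effective_n = 100)
  expect_equal(st2$srmr, srmr_hand, tolerance = 1e-10)
})

test_that("standardized solution lands in the correlation metric", {
  m <- two_factor_model()
  th <- c("FX=~X2" = 0.8, "FX=~X3" = 1.1, "FY=~Y2" = 0.9, "FY=~Y3" = 1.2,
          "FX~~FX" = 4, "FY~~FY" = 4, "FX~~FY" = 2,
          "X1~~X1" = 1, "X2~~X2" = 1, "X3~~X3" = 1,
          "Y1~~Y1" = 1, "Y2~~Y2" = 1, "Y3~~Y3" = 1)
  std <- standardizeSolution(m, th)
  expect_equal(unname(std["FX~~FY"]), 2 / sqrt(4 * 4))
  expect_equal(unname(std["FX~~FX"]), 1)
  # unit factor variances: factor correlation unchanged
  th2 <- th; th2["FX~~FX"] <- 1; th2["FY~~FY"] <- 1; th2["FX~~FY"] <- 0.37
  expect_equal(unname(standardizeSolution(m, th2)["FX~~FY"]), 0.37)
  # residual signs are preserved
  expect_true(all(std[grep("X.~~X.", names(std))] > 0))
  # standardized loadings: lambda * sd(F) / sd(X)
  sdX2 <- sqrt(0.8^2 * 4 + 1)
  expect_equal(unname(std["FX=~X2"]), 0.8 * 2 / sdX2, tolerance = 1e-12)
})
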