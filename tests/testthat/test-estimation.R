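test_that("a single focal point with unit weights reduces to a single-group SEM", {
  set.seed(31)
  pop <- dgm3_pop()
  dat <- drawSample(pop, 600, seed = 31)
  # one focal point in the middle with a huge uniform bandwidth: every
  # subject enters with weight one
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 12,
                      kernel = "uniform", bw = 100, residualize = FALSE)
  x <- as.matrix(dat[, 1:3])
  S <- crossprod(scale(x, scale = FALSE)) / nrow(x)
  dimnames(S) <- list(colnames(x), colnames(x))
  ref <- fitGroups(one_factor_model(), S, nrow(x))
  v <- setNames(ref$values$value, ref$values$label)
  cv <- lsemCurves(fit)
  expect_equal(setNames(cv$estimate, cv$parameter), v[cv$parameter],
               tolerance = 1e-6)
})

test_that("uniform-kernel local estimation equals the multiple-group model on grid data", {
  dat <- drawSample(dgm1_pop(), 1200, seed = 32)
  fit_lsem <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18,
                           kernel = "uniform", bw = 0.5, wt_min = 0)
  fit_mgm <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", type = "mgm",
                          grid = 13)
  c1 <- lsemCurves(fit_lsem); c2 <- lsemCurves(fit_mgm)
  key <- function(d) paste(d$parameter, d$focal_index)
  expect_equal(setNames(c1$estimate, key(c1)),
               setNames(c2$estimate, key(c2))[key(c1)], tolerance = 1e-5)
})

test_that("joint estimation with no constraints equals pointwise estimation", {
  dat <- drawSample(dgm1_pop(), 900, seed = 33)
  fp <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                     est_joint = FALSE, wt_min = 0)
  fj <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                     est_joint = TRUE, wt_min = 0)
  key <- function(d) paste(d$parameter, d$focal_index)
  cp <- lsemCurves(fp); cj <- lsemCurves(fj)
  expect_equal(setNames(cj$estimate, key(cj)),
               setNames(cp$estimate, key(cp))[key(cj)], tolerance = 1e-5)
})

test_that("exact-moment populations are recovered without estimation noise", {
  # pointwise on dgm1 (everything varies): just-identified per focal point
  pop1 <- dgm1_pop()
  dgm1 <- lsemDGM("dgm1", n_factors = 1)
  fit1 <- lsemEstimate(pop1, "age", "FX =~ X1 + X2 + X3", grid = 6:18,
                       kernel = "uniform", bw = 0.5, est_joint = FALSE)
  truth1 <- dgmTrueCurves(dgm1)
  m1 <- localsem:::.curveMatrices(fit1)
  for (lab in c("FX=~X2", "FX=~X3", "FX~~FX", "X1~~X1")) {
    expect_equal(unname(m1$est[lab, ]), unname(truth1[lab, ]),
                 tolerance = 1e-5)
  }
  # joint with invariant loadings on dgm3 (all constant)
  pop3 <- dgm3_pop()
  dgm3 <- lsemDGM("dgm3", n_factors = 1)
  fit3 <- lsemEstimate(pop3, "age", "FX =~ X1 + X2 + X3", grid = 6:18,
                       kernel = "uniform", bw = 0.5,
                       par_invariant = c("FX=~X2", "FX=~X3"))
  truth3 <- dgmTrueCurves(dgm3)
  m3 <- localsem:::.curveMatrices(fit3)
  for (lab in rownames(truth3)) {
    expect_equal(unname(m3$est[lab, ]), unname(truth3[lab, ]),
                 tolerance = 1e-4)
  }
})

test_that("fully invariant fit on identical matrices equals the single-group fit", {
  S <- rand_pd(3, seed = 35)
  dimnames(S) <- list(paste0("X", 1:3), paste0("X", 1:3))
  m <- one_factor_model()
  labs <- m@partable$label[m@partable$free]
  joint <- fitGroups(m, rep(list(S), 5), rep(30, 5), par_invariant = labs)
  single <- fitGroups(m, S, 150)
  vj <- setNames(joint$values$value[joint$values$group == 1],
                 joint$values$label[joint$values$group == 1])
  vs <- setNames(single$values$value, single$values$label)
  expect_equal(vj[labs], vs[labs], tolerance = 1e-6)
})

test_that("quadratic parameter constraints recover an exactly quadratic curve", {
  # population factor-variance curve is linear in the moderator (a special
  # quadratic), loadings constant: the constrained fit must reproduce it
  dgm2 <- lsemDGM("dgm2", n_factors = 1)
  pop2 <- makePopulation(dgm2, group_size = 400, seed = 14)
  fitq <- lsemEstimate(pop2, "age", "FX =~ X1 + X2 + X3", grid = 6:18,
                       kernel = "uniform", bw = 0.5,
                       par_invariant = c("FX=~X2", "FX=~X3"),
                       par_quadratic = "FX~~FX")
  truth2 <- dgmTrueCurves(dgm2)
  mq <- localsem:::.curveMatrices(fitq)
  expect_equal(unname(mq$est["FX~~FX", ]), unname(truth2["FX~~FX", ]),
               tolerance = 1e-4)
  # second differences of the fitted curve are constant
  d2 <- diff(mq$est["FX~~FX", ], differences = 2)
  expect_lt(max(abs(d2 - mean(d2))), 1e-6)
})

test_that("DIF effects free invariant parameters pointwise", {
  dat <- drawSample(dgm1_pop(), 1500, seed = 36)
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                      par_invariant = c("FX=~X2", "FX=~X3"), est_dif = TRUE,
                      wt_min = 0)
  cv <- fit@curves
  expect_true(any(cv$is_dif))
  dif <- cv[cv$is_dif & cv$parameter == "FX=~X2", ]
  expect_equal(nrow(dif), 13)
  # DIF curves move while the constrained parameter is flat
  inv <- cv[!cv$is_dif & cv$parameter == "FX=~X2", ]
  expect_lt(diff(range(inv$estimate)), 1e-8)
  expect_gt(diff(range(dif$estimate)), 0.01)

  # single focal point: the DIF effect equals the pointwise free estimate
  fit1 <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 12,
                       kernel = "uniform", bw = 100, residualize = FALSE,
                       par_invariant = c("FX=~X2", "FX=~X3"), est_dif = TRUE)
  free1 <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 12,
                        kernel = "uniform", bw = 100, residualize = FALSE)
  d1 <- fit1@curves
  f1 <- lsemCurves(free1)
  expect_equal(d1$estimate[d1$is_dif & d1$parameter == "FX=~X2"],
               f1$estimate[f1$parameter == "FX=~X2"], tolerance = 1e-4)

  # DIF of a truly invariant loading stays near the invariant estimate
  dat3 <- drawSample(dgm3_pop(), 3000, seed = 37)
  fit3 <- lsemEstimate(dat3, "age", "FX =~ X1 + X2 + X3", grid = 6:18, h = 2,
                       par_invariant = c("FX=~X2", "FX=~X3"), est_dif = TRUE,
                       wt_min = 0)
  cv3 <- fit3@curves
  inv_val <- cv3$estimate[!cv3$is_dif & cv3$parameter == "FX=~X2"][1]
  dif3 <- cv3$estimate[cv3$is_dif & cv3$parameter == "FX=~X2"]
  expect_lt(max(abs(dif3 - inv_val)), 0.15)
})

test_that("DIF estimation requires invariant parameters", {
  dat <- drawSample(dgm3_pop(), 400, seed = 38)
  expect_error(
    lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", est_dif = TRUE),
    "invariant")
})

test_that("constrained joint objective dominates the unconstrained one", {
  dat <- drawSample(dgm1_pop(), 800, seed = 39)
  f_free <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18,
                         h = 2, est_joint = TRUE, wt_min = 0)
  f_inv <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", grid = 6:18,
                        h = 2, par_invariant = c("FX=~X2", "FX=~X3"),
                        wt_min = 0)
  expect_gte(f_inv@fit$objective, f_free@fit$objective - 1e-8)
})

test_that("standardized factor correlations stay within [-1, 1]", {
  dat <- drawSample(dgm1_pop2f(), 1200, seed = 40)
  fit <- lsemEstimate(dat, "age", lsemDGM("dgm1")$model_syntax, grid = 6:18,
                      h = 2, wt_min = 0)
  cv <- lsemCurves(fit)
  rho <- cv$standardized[cv$parameter == "FX~~FY"]
  expect_true(all(abs(rho) <= 1))
  expect_true(all(is.finite(cv$standardized)))
})

test_that("MGM with a single group is the single-group fit", {
  dat <- drawSample(dgm3_pop(), 500, seed = 41)
  fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3", type = "mgm",
                      grid = 1)
  expect_length(focalGrid(fit), 1)
  x <- as.matrix(dat[, 1:3])
  S <- crossprod(scale(x, scale = FALSE)) / nrow(x)
  dimnames(S) <- list(colnames(x), colnames(x))
  ref <- fitGroups(one_factor_model(), S, nrow(x))
  v <- setNames(ref$values$value, ref$values$label)
  cv <- lsemCurves(fit)
  expect_equal(setNames(cv$estimate, cv$parameter), v[cv$parameter],
               tolerance = 1e-6)
})
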