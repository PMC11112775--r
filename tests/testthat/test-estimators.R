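# regression estimators, quantile transform, FDR adjustment

test_that("quantile transform matches the Blom closed form and handles ties", {
  z <- quantileTransform(c(1, 2, 3))
  expect_equal(z, qnorm((1:3 - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(round(z, 4), c(-0.8694, 0, 0.8694))

  # strictly increasing input stays strictly increasing
  x <- sort(rnorm(50))
  expect_true(all(diff(quantileTransform(x)) > 0))

  # ties get identical transformed values; NAs propagate
  zt <- quantileTransform(c(5, 1, 5, NA, 2))
  expect_equal(zt[1], zt[3])
  expect_true(is.na(zt[4]))

  expect_error(quantileTransform(c(1, 2)), "at least 3")
  expect_error(quantileTransform(rep(7, 10)), "identical")
})

test_that("FDR adjustment implements the step-up rule", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdrAdjust(0.33), 0.33)
  # idempotent and order-preserving in the sorted sequence
  p <- c(0.001, 0.2, 0.03, 0.8, 0.04)
  q1 <- fdrAdjust(p)
  expect_equal(fdrAdjust(q1) >= q1, rep(TRUE, 5))
  expect_false(is.unsorted(q1[order(p)]))
  expect_true(all(q1 >= p))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("models 1a and 1b match an independent normal-equations oracle", {
  # oracle coded from scratch: beta = (X'X)^-1 X'y, SE from sigma^2 (X'X)^-1
  oracle <- function(X, y) {
    XtXi <- solve(t(X) %*% X)
    beta <- XtXi %*% t(X) %*% y
    res <- y - X %*% beta
    s2 <- sum(res^2) / (nrow(X) - ncol(X))
    list(beta = drop(beta), se = sqrt(diag(s2 * XtXi)))
  }
  set.seed(7)
  for (r in 1:50) {
    n <- 30
    d <- data.frame(id = paste0("i", 1:n), q = runif(n),
                    age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
    d$y <- rnorm(n, 2 * d$q + 0.01 * d$age, 1)
    fit <- fitModel1a(d)
    orc <- oracle(cbind(1, d$q, d$age, d$sex), d$y)
    expect_equal(fit$estimate, orc$beta[2], tolerance = 1e-10)
    expect_equal(fit$se, orc$se[2], tolerance = 1e-10)
  }
  for (r in 1:50) {
    m <- 25
    diffs <- data.frame(id1 = paste0("a", 1:m), id2 = paste0("b", 1:m),
                        fid = paste0("f", 1:m), dY = rnorm(m),
                        dQ = rnorm(m, 0, 0.02), dAge = rnorm(m, 0, 5),
                        age1 = runif(m, 18, 80), dSex = sample(-1:1, m, TRUE),
                        sex1 = rbinom(m, 1, 0.5))
    fit <- fitModel1b(diffs)
    orc <- oracle(cbind(1, diffs$dQ, diffs$dAge, diffs$age1, diffs$dSex,
                        diffs$sex1), diffs$dY)
    expect_equal(fit$estimate, orc$beta[2], tolerance = 1e-10)
    expect_equal(fit$se, orc$se[2], tolerance = 1e-10)
  }
})

test_that("noiseless generative models are recovered exactly", {
  pop <- mediumPop()
  ph <- simulatePhenotypes(pop, phenotypeConfig(deltaG = 2.5, sigma = 0))
  # the "essentially perfect fit" warning is the expected situation here
  fit <- suppressWarnings(fitModel1a(ph))
  expect_equal(fit$estimate, 2.5, tolerance = 1e-8)
  expect_equal(fit$estimatePerPct, 0.025, tolerance = 1e-10)

  sibs <- sibPairTable(pop)
  diffs <- sibPairDiffs(sibs[, c("id1", "id2")], ph)
  fitb <- suppressWarnings(fitModel1b(diffs))
  expect_equal(fitb$estimate, 2.5, tolerance = 1e-8)

  # model 2, noiseless: both slopes equal deltaG (singular fit fallback)
  suppressWarnings(fit2 <- fitModel2(ph))
  expect_equal(fit2$estimate[fit2$term == "deltaG_within"], 2.5,
               tolerance = 1e-6)
  expect_equal(fit2$estimate[fit2$term == "deltaY_between"], 2.5,
               tolerance = 1e-6)
})

test_that("model 1b is invariant to globally swapping sibling order", {
  pop <- mediumPop()
  ph <- simulatePhenotypes(pop, phenotypeConfig(deltaG = 1, sigma = 0.5),
                           seed = 8)
  sibs <- sibPairTable(pop)
  d1 <- sibPairDiffs(sibs[, c("id1", "id2")], ph)
  swapped <- data.frame(id1 = sibs$id2, id2 = sibs$id1)
  d2 <- sibPairDiffs(swapped, ph)
  # deterministic lexicographic ordering makes the tables identical
  expect_equal(d1$dQ, d2$dQ)
  expect_equal(fitModel1b(d1)$estimate, fitModel1b(d2)$estimate)
})

test_that("degenerate designs raise informative errors", {
  n <- 20
  d <- data.frame(id = paste0("i", 1:n), q = runif(n), age = rep(40, n),
                  sex = rbinom(n, 1, 0.5))
  d$y <- rnorm(n)
  # constant age is collinear with the intercept
  expect_error(fitModel1a(d), "age")
  diffs <- data.frame(id1 = "a", id2 = "b", fid = "f",
                      dY = rnorm(10), dQ = 0, dAge = rnorm(10),
                      age1 = runif(10, 20, 60), dSex = rbinom(10, 1, 0.5),
                      sex1 = rbinom(10, 1, 0.5))
  expect_error(fitModel1b(diffs), "ancestry differences")
})

test_that("model 2 within-slope tracks model 1b in two-sibling families", {
  pop <- simulatePopulation(250, sibsPerFamily = function(n) rep(2L, n),
                            seed = 9)
  sibs <- sibPairTable(pop)
  ph <- simulatePhenotypes(pop, phenotypeConfig(deltaG = 1, sigma = 1),
                           seed = 10)
  phSib <- ph[ph$id %in% c(sibs$id1, sibs$id2), ]
  b1b <- fitModel1b(sibPairDiffs(sibs[, c("id1", "id2")], ph))
  suppressWarnings(f2 <- fitModel2(phSib))
  bW <- f2$estimate[f2$term == "deltaG_within"]
  # same within-family contrast: estimates agree within a fraction of SE
  expect_lt(abs(bW - b1b$estimate), b1b$se)
})

test_that("model 1b confidence intervals cover the true effect", {
  # two-sibling families: pairs are independent, so the OLS interval is
  # exact; multi-pair families induce correlation that model 2 handles
  pop <- simulatePopulation(200, sibsPerFamily = function(n) rep(2L, n),
                            seed = 11)
  sibs <- sibPairTable(pop)
  cfg <- phenotypeConfig(deltaG = 1, sigma = 1, sigmaFam = 0.5)
  set.seed(12)
  nRep <- 400
  covered <- logical(nRep)
  for (r in seq_len(nRep)) {
    ph <- simulatePhenotypes(pop, cfg)
    fit <- fitModel1b(sibPairDiffs(sibs[, c("id1", "id2")], ph))
    ci <- fit$estimate + c(-1, 1) * qt(0.975, fit$n - 6) * fit$se
    covered[r] <- ci[1] <= 1 && 1 <= ci[2]
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("estimateEffects reports dual-scale results with FDR across phenotypes", {
  pop <- mediumPop()
  sibs <- sibPairTable(pop)
  set.seed(13)
  ph <- simulatePhenotypes(pop, phenotypeConfig(deltaG = 1, sigma = 1))
  ph$y2 <- rnorm(nrow(ph)) # null phenotype
  suppressWarnings(
    res <- estimateEffects(ph, sibs[, c("id1", "id2")], c("y", "y2")))
  s <- res$summary
  expect_setequal(unique(s$phenotype), c("y", "y2"))
  expect_setequal(unique(s$model), c("1a", "1b", "2"))
  expect_true(all(s$fdrP >= s$p))
  # per-percentage convention: raw effect = 100 x per-pct effect
  raw <- res$full[res$full$scale == "raw", ]
  expect_equal(raw$estimate, 100 * raw$estimatePerPct)

  # declarative inclusion mask: excluded individuals drop from that
  # phenotype's fits only
  mask <- rep(TRUE, nrow(ph))
  mask[1:30] <- FALSE
  suppressWarnings(
    res2 <- estimateEffects(ph, sibs[, c("id1", "id2")], c("y", "y2"),
                            models = "1a", include = list(y = mask)))
  s2 <- res2$summary
  expect_equal(s2$n[s2$phenotype == "y"], sum(mask))
  expect_equal(s2$n[s2$phenotype == "y2"], nrow(ph))
})
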