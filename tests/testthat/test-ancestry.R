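# variant QC and admixture proportion estimation

test_that("variant QC removes low-MAF, high-missingness and LD-duplicated loci", {
  set.seed(1)
  n <- 100
  g1 <- rbinom(n, 2, 0.04)          # MAF 0.04 -> removed
  g2 <- rbinom(n, 2, 0.5)           # kept
  g3 <- g2                          # r2 = 1 duplicate -> one of pair removed
  g4 <- rbinom(n, 2, 0.3)
  g4[1:7] <- NA                     # 7% missing -> removed
  G <- cbind(g1, g2, g3, g4)
  qc <- variantQC(G)
  expect_false(qc$keep[1])
  expect_false(qc$keep[4])
  expect_equal(sum(qc$keep[2:3]), 1L) # exactly one of the duplicates
  expect_equal(qc$report$count[qc$report$rule == "kept"], sum(qc$keep))
  expect_error(variantQC(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("supervised estimator matches boundary cases and a grid oracle", {
  map <- smallMap()
  af <- simulateAncestralFreqs(200, fst = 0.3, map = map, seed = 2)
  # fully informative loci, all genotypes 2 -> boundary MLE exactly 1
  afb <- af
  afb@f1 <- rep(1, 200); afb@f2 <- rep(0, 200)
  G <- matrix(2L, 1, 200)
  expect_equal(unname(ancestryQ(estimateAdmixtureSupervised(G, afb))), 1)
  # all heterozygous -> pi maximized at 1/2 -> q = 1/2
  Gh <- matrix(1L, 1, 200)
  expect_equal(unname(ancestryQ(estimateAdmixtureSupervised(Gh, afb))), 0.5,
               tolerance = 1e-6)

  # random instances vs brute-force grid search of the same likelihood
  set.seed(3)
  gridQ <- function(g, f1, f2) {
    qs <- seq(0, 1, by = 1e-4)
    ll <- vapply(qs, function(q) {
      pi <- pmin(pmax(q * f1 + (1 - q) * f2, 1e-6), 1 - 1e-6)
      sum(g * log(pi) + (2 - g) * log(1 - pi))
    }, numeric(1))
    qs[which.max(ll)]
  }
  for (r in 1:5) {
    qtrue <- runif(1)
    pi <- qtrue * af@f1 + (1 - qtrue) * af@f2
    g <- rbinom(200, 2, pi)
    qhat <- unname(ancestryQ(estimateAdmixtureSupervised(rbind(g), af)))
    expect_lt(abs(qhat - gridQ(g, af@f1, af@f2)), 1e-4)
  }
  expect_error(estimateAdmixtureSupervised(matrix(0L, 1, 3), af),
               "locus count mismatch")
})

test_that("unsupervised EM is monotone, label-symmetric and consistent", {
  # two unadmixed groups plus admixed individuals, fst 0.2
  makeData <- function(L, seed) {
    set.seed(seed)
    p <- runif(L, 0.1, 0.9)
    f1 <- rbeta(L, p * 4, (1 - p) * 4) # fst = 0.2
    f2 <- rbeta(L, p * 4, (1 - p) * 4)
    q <- c(rep(1, 10), rep(0, 10), runif(20))
    G <- t(vapply(q, function(qi) rbinom(L, 2, qi * f1 + (1 - qi) * f2),
                  numeric(L)))
    rownames(G) <- paste0("i", seq_along(q))
    list(G = G, q = q)
  }
  d <- makeData(1000, 4)
  est <- estimateAdmixtureUnsupervised(d$G, anchors = paste0("i", 1:10),
                                       seed = 5)
  tr <- est@logLik
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-1]))) # non-decreasing
  rmse1k <- sqrt(mean((ancestryQ(est) - d$q)^2))
  expect_lt(rmse1k, 0.1)

  # label-swap symmetry of the likelihood itself
  ll <- function(q, f1, f2, G) {
    PI <- pmin(pmax(q %o% f1 + (1 - q) %o% f2, 1e-6), 1 - 1e-6)
    sum(G * log(PI) + (2 - G) * log(1 - PI))
  }
  f1 <- est@P[, "f1"]; f2 <- est@P[, "f2"]; qv <- unname(ancestryQ(est))
  expect_equal(ll(qv, f1, f2, d$G), ll(1 - qv, f2, f1, d$G))

  # consistency: more loci -> smaller RMSE
  d4 <- makeData(4000, 4)
  est4 <- estimateAdmixtureUnsupervised(d4$G, anchors = paste0("i", 1:10),
                                        seed = 5)
  expect_lt(sqrt(mean((ancestryQ(est4) - d4$q)^2)), rmse1k)

  # semi-supervised mode: reference individuals stay at their fixed values
  fixed <- setNames(c(rep(1, 10), rep(0, 10)), paste0("i", 1:20))
  estF <- estimateAdmixtureUnsupervised(d$G, anchors = paste0("i", 1:10),
                                        fixedQ = fixed, seed = 5)
  expect_equal(unname(ancestryQ(estF)[1:20]), unname(fixed))
  expect_lt(sqrt(mean((ancestryQ(estF) - d$q)^2)), rmse1k)
  expect_error(estimateAdmixtureUnsupervised(d$G, fixedQ = c(zz = 1)),
               "fixedQ")

  # degenerate input and missing anchors
  expect_error(estimateAdmixtureUnsupervised(matrix(0L, 5, 10)),
               "monomorphic")
  expect_warning(estimateAdmixtureUnsupervised(d$G, seed = 5), "anchors")
})
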