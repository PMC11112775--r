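# IBD coefficient estimation, sibling classification, pair filtering, and
# the F1-based error estimator

test_that("IBD estimates recover identity, parent-offspring and sibling pairs", {
  pop <- mediumPop()
  G <- mediumGeno()
  af <- mediumFreqs()
  ped <- pedigree(pop)
  q <- qTrue(pop)
  off <- ped[ped$role == "offspring", ]

  # duplicate individual -> k2 ~ 1
  id <- off$id[1]
  dup <- estimateK(G[id, ], G[id, ], q[id], q[id], af)
  expect_gt(dup$k["k2"], 0.95)
  expect_equal(sum(dup$k), 1)

  # parent-offspring -> k1 ~ 1, k0 ~ 0
  dad <- off$father[1]
  po <- estimateK(G[id, ], G[dad, ], q[id], q[dad], af)
  expect_gt(po$k["k1"], 0.9)
  expect_lt(po$k["k0"], 0.05)

  # full siblings average near (0.25, 0.5, 0.25)
  sibs <- sibPairTable(pop, filter = FALSE)
  rel <- pairwiseRelatedness(G, q, af, sibs[, c("id1", "id2")])
  expect_lt(abs(mean(rel$k0) - 0.25), 0.05)
  expect_lt(abs(mean(rel$k1) - 0.50), 0.05)
  expect_lt(abs(mean(rel$k2) - 0.25), 0.05)

  # unrelated pairs -> k0 ~ 1
  o2 <- off$id[off$fid != off$fid[1]][1]
  un <- estimateK(G[id, ], G[o2, ], q[id], q[o2], af)
  expect_gt(un$k["k0"], 0.9)

  # too few informative loci is an error
  expect_error(estimateK(G[id, 1:100], G[o2, 1:100], q[id], q[o2],
                         new("AncestralFreqs", chrom = af@chrom[1:100],
                             posM = af@posM[1:100], f1 = af@f1[1:100],
                             f2 = af@f2[1:100], fst = af@fst, map = af@map)),
               "informative loci")
})

test_that("EM for IBD coefficients increases the likelihood monotonically", {
  # re-run the EM by hand on a sibling pair and track the trace
  pop <- mediumPop()
  G <- mediumGeno()
  af <- mediumFreqs()
  q <- qTrue(pop)
  sibs <- sibPairTable(pop, filter = FALSE)
  i <- sibs$id1[1]; j <- sibs$id2[1]
  pi1 <- pmin(pmax(q[i] * af@f1 + (1 - q[i]) * af@f2, 1e-6), 1 - 1e-6)
  pi2 <- pmin(pmax(q[j] * af@f1 + (1 - q[j]) * af@f2, 1e-6), 1 - 1e-6)
  P <- admixsib:::.pairGenoProbs(G[i, ], G[j, ], pi1, pi2)
  P <- pmax(P, 1e-300)
  k <- c(1, 1, 1) / 3
  lls <- numeric(40)
  for (it in 1:40) {
    D <- as.vector(P %*% k)
    lls[it] <- sum(log(D))
    k <- colMeans(P * rep(k, each = nrow(P)) / D)
    k <- k / sum(k)
    expect_equal(sum(k), 1)
  }
  expect_true(all(diff(lls) > -1e-9))
})

test_that("full-sibling classification applies the box and rescue rules", {
  rel <- data.frame(
    id1 = c("a", "b", "a", "x", "u"),
    id2 = c("b", "c", "c", "y", "v"),
    k1 = c(0.50, 0.52, 0.45, 0.50, 0.45),
    k2 = c(0.25, 0.30, 0.13, 0.10, 0.14))
  # a-b, b-c primary; a-c rescued (k1 in (0.4,0.6), k2 > 0.125, both members
  # primary-siblings of someone else); x-y fails both rules; u-v fails
  # rescue because u and v have no primary links
  out <- classifyFullSiblings(rel)
  expect_setequal(paste(out$id1, out$id2),
                  c("a b", "b c", "a c"))
  expect_equal(out$class[out$id1 == "a" & out$id2 == "c"], "rescued")
  # one sibship: connected component a-b-c shares a family id
  expect_equal(length(unique(out$sibship)), 1L)
  # empty input -> empty output
  expect_equal(nrow(classifyFullSiblings(rel[0, ])), 0L)
})

test_that("admixed-pair filter applies the 95% and F1 rules", {
  q <- c(a1 = 0.97, a2 = 0.98, b1 = 0.50, b2 = 0.50, c1 = 0.70, c2 = 0.72,
         d1 = 0.45, d2 = 0.55, e1 = 0.02, e2 = 0.01)
  pairs <- data.frame(id1 = c("a1", "b1", "c1", "d1", "e1"),
                      id2 = c("a2", "b2", "c2", "d2", "e2"))
  parentQ <- data.frame(id = c("b1", "d1"),
                        fatherQ = c(0.99, 0.60),
                        motherQ = c(0.01, 0.40))
  flt <- filterAdmixedPairs(pairs, q, parentQ)
  st <- setNames(flt$pairs$status, flt$pairs$id1)
  expect_equal(unname(st["a1"]), "excluded_same_ancestry") # both > 0.95
  expect_equal(unname(st["b1"]), "excluded_F1")            # parents 0.99/0.01
  expect_equal(unname(st["c1"]), "retained")               # admixed range
  expect_equal(unname(st["d1"]), "retained")               # admixed parents
  expect_equal(unname(st["e1"]), "excluded_same_ancestry") # both < 0.05

  # central-band pair without parental ancestry: dropped by default,
  # kept on request
  flt2 <- filterAdmixedPairs(pairs, q, parentQ = NULL)
  expect_equal(flt2$pairs$status[flt2$pairs$id1 == "b1"], "unresolved")
  expect_false("b1" %in% flt2$retained$id1)
  flt3 <- filterAdmixedPairs(pairs, q, parentQ = NULL, unresolved = "keep")
  expect_true("b1" %in% flt3$retained$id1)

  # idempotent and order-independent
  again <- filterAdmixedPairs(flt$retained[, c("id1", "id2")], q, parentQ)
  expect_equal(nrow(again$retained), nrow(flt$retained))
  perm <- sample(nrow(pairs))
  fltP <- filterAdmixedPairs(pairs[perm, ], q, parentQ)
  expect_equal(sort(fltP$retained$id1), sort(flt$retained$id1))
})

test_that("F1 error estimator matches its closed form under normal noise", {
  # true Q of F1 siblings is exactly 0.5, so injected noise is the only
  # source of estimated differences; E|Q1 - Q2| = 2 sigma / sqrt(pi)
  set.seed(6)
  nPairs <- 20000
  sigma <- 0.002
  q <- c(0.5 + rnorm(nPairs, 0, sigma), 0.5 + rnorm(nPairs, 0, sigma))
  names(q) <- c(paste0("s1_", 1:nPairs), paste0("s2_", 1:nPairs))
  f1pairs <- data.frame(id1 = paste0("s1_", 1:nPairs),
                        id2 = paste0("s2_", 1:nPairs))
  est <- estimateDqErrorFromF1(f1pairs, q)
  expect_equal(est, 2 * sigma / sqrt(pi), tolerance = 0.03)
  # exact estimates -> zero error
  qPerfect <- setNames(rep(0.5, 4), c("x1", "x2", "y1", "y2"))
  expect_equal(estimateDqErrorFromF1(
    data.frame(id1 = c("x1", "y1"), id2 = c("x2", "y2")), qPerfect), 0)
  expect_error(estimateDqErrorFromF1(f1pairs[0, ], q), "no F1 pairs")
})
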