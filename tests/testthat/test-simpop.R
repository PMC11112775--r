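# population, genotype and phenotype generators

test_that("Balding-Nichols frequencies have the right limits and spread", {
  map <- smallMap()
  # zero divergence: both populations equal the base frequency
  af0 <- simulateAncestralFreqs(50, fst = 0, map = map, seed = 1)
  expect_identical(af0@f1, af0@f2)

  # fst 0.1 at p = 0.5: Var(f) = fst * p(1-p) = 0.025
  af <- simulateAncestralFreqs(50000, fst = 0.1, map = map,
                               baseFreq = rep(0.5, 50000), seed = 2)
  expect_lt(abs(var(af@f1) - 0.025) / 0.025, 0.05)
  expect_true(all(af@f1 >= 0 & af@f1 <= 1))
  # sorted within chromosome (validity also enforces this)
  for (ch in unique(af@chrom))
    expect_false(is.unsorted(af@posM[af@chrom == ch]))

  expect_error(simulateAncestralFreqs(10, fst = 1), "fst")
  expect_error(simulateAncestralFreqs(0), "nLoci")
})

test_that("simulated pedigrees have consistent tracts and ancestry", {
  pop <- mediumPop()
  ped <- pedigree(pop)
  expect_true(all(ped$qTrue >= 0 & ped$qTrue <= 1))
  # stored qTrue equals the Morgan-weighted tract fraction (recomputed)
  for (id in ped$id[1:10]) {
    expect_equal(ancestryFraction(tracts(pop, id), pop@map),
                 ped$qTrue[ped$id == id])
    expectTiles(tracts(pop, id)$h1, pop@map)
  }
  # offspring of two unadmixed discordant parents are exactly 0.5
  pq <- setNames(ped$qTrue, ped$id)
  off <- ped[ped$role == "offspring", ]
  f1 <- off[pq[off$father] + pq[off$mother] == 1 &
              abs(pq[off$father] - pq[off$mother]) == 1, ]
  if (nrow(f1) > 0) expect_true(all(f1$qTrue == 0.5))
  # both parents unadmixed-1 -> offspring exactly 1, dQ exactly 0
  u1 <- off[pq[off$father] == 1 & pq[off$mother] == 1, ]
  if (nrow(u1) > 0) expect_true(all(u1$qTrue == 1))
  expect_error(simulatePopulation(3, sibsPerFamily = 1), "at least 2")
})

test_that("most admixed sibling pairs differ by under 5 ancestry points", {
  pop <- simulatePopulation(300, seed = 99)
  sibs <- sibPairTable(pop) # truth-filtered admixed pairs
  adq <- abs(sibs$q1 - sibs$q2)
  expect_gt(mean(adq < 0.05), 0.8)
  expect_lt(max(adq), 0.2)
})

test_that("genotypes reflect local ancestry and transmit alleles IBD", {
  map <- smallMap()
  pop <- simulatePopulation(12, founderComp = c(1, 0, 0), map = map,
                            seed = 11)
  # fully informative loci: unadmixed population-1 individuals are all hom
  af <- simulateAncestralFreqs(60, fst = 0.3, map = map, seed = 12)
  af@f1 <- rep(1, 60); af@f2 <- rep(0, 60)
  G <- simulateGenotypes(pop, af, seed = 13)
  expect_true(all(G == 2L))

  # unadmixed population-1 founder sample frequency tracks f1 (founders are
  # independent draws; offspring duplicate founder alleles by descent)
  af2 <- simulateAncestralFreqs(400, fst = 0.2, map = map, seed = 14)
  G2 <- simulateGenotypes(pop, af2, seed = 15)
  founders <- pedigree(pop)$id[pedigree(pop)$role == "founder"]
  n2 <- 2 * length(founders)
  z <- (colMeans(G2[founders, ]) / 2 - af2@f1) /
    sqrt(pmax(af2@f1 * (1 - af2@f1), 1e-4) / n2)
  expect_lt(mean(abs(z) > 3), 0.03)

  # siblings share transmitted alleles: after centering each locus at its
  # expected frequency, sibling genotype correlation ~ k1/2 + k2 = 0.5,
  # while unrelated individuals are uncorrelated
  Gc <- sweep(G2, 2, 2 * af2@f1)
  offs <- pedigree(pop)[pedigree(pop)$role == "offspring", ]
  fams <- split(offs$id, offs$fid)
  sibCor <- mean(sapply(fams[lengths(fams) >= 2], function(ids)
    cor(Gc[ids[1], ], Gc[ids[2], ])))
  crossCors <- sapply(seq_along(fams)[-1], function(k)
    cor(Gc[fams[[1]][1], ], Gc[fams[[k]][1], ]))
  expect_gt(sibCor, 0.35)
  expect_lt(abs(mean(crossCors)), 0.1)

  # mismatched map is an error
  expect_error(simulateGenotypes(pop, mediumFreqs()), "same genetic map")
})

test_that("phenotype generator follows the configured model exactly", {
  pop <- mediumPop()
  # deterministic: y = deltaG * Q
  cfg0 <- phenotypeConfig(deltaG = 3, sigma = 0, sigmaFam = 0)
  ph <- simulatePhenotypes(pop, cfg0, seed = 21)
  expect_equal(ph$y, 3 * ph$q)

  # individual-mode, sigma 0: within-pair difference is (deltaG + eAnc) dQ
  cfgI <- phenotypeConfig(deltaG = 1, sigma = 0, eAnc = 0.5,
                          eAncMode = "individual")
  phI <- simulatePhenotypes(pop, cfgI, seed = 22)
  sibs <- sibPairTable(pop, filter = FALSE)
  dY <- phI$y[match(sibs$id1, phI$id)] - phI$y[match(sibs$id2, phI$id)]
  expect_equal(dY, 1.5 * (sibs$q1 - sibs$q2))

  # config validation
  expect_error(phenotypeConfig(eAnc = 1, eAncMode = "none"), "eAnc")
  expect_error(phenotypeConfig(sigma = -1), "sigma")
})

test_that("environmental terms are independent of sibling ancestry splits", {
  # family-mode environment depends only on the family mean, so it cannot
  # correlate with the within-pair ancestry difference
  pop <- simulatePopulation(400, seed = 31)
  sibs <- sibPairTable(pop)
  cfg <- phenotypeConfig(deltaG = 0, sigma = 0, eAnc = 2,
                         eAncMode = "family")
  ph <- simulatePhenotypes(pop, cfg)
  env1 <- ph$y[match(sibs$id1, ph$id)] # = eAnc * family mean ancestry
  dq <- sibs$q1 - sibs$q2
  expect_lt(abs(cor(env1, dq)), 3 / sqrt(nrow(sibs)))
})
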