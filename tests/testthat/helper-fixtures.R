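# shared fixtures, built once per test run

# small 3-chromosome map for fast tract tests
smallMap <- function() geneticMap(c(1.2, 1.0, 0.8))

# check that a haplotype tiles its map exactly
expectTiles <- function(hap, map) {
  for (k in seq_along(map@chrom)) {
    seg <- hap[[k]]
    expect_false(is.unsorted(seg$end, strictly = TRUE))
    expect_equal(seg$end[length(seg$end)], map@lengthM[k])
    expect_true(all(seg$anc %in% c(1L, 2L)))
  }
}

# memoized medium population + genotypes for reuse across test files
.fixtureEnv <- new.env()
mediumPop <- function() {
  if (is.null(.fixtureEnv$pop))
    .fixtureEnv$pop <- simulatePopulation(40, seed = 424242)
  .fixtureEnv$pop
}
mediumFreqs <- function() {
  if (is.null(.fixtureEnv$freqs))
    .fixtureEnv$freqs <- simulateAncestralFreqs(4000, fst = 0.12,
                                                seed = 424243)
  .fixtureEnv$freqs
}
mediumGeno <- function() {
  if (is.null(.fixtureEnv$geno))
    .fixtureEnv$geno <- simulateGenotypes(mediumPop(), mediumFreqs(),
                                          seed = 424244)
  .fixtureEnv$geno
}
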