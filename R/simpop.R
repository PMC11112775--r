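## Synthetic two-way admixed population generator: ancestral allele
## frequencies, pedigrees with local-ancestry haplotypes, genotypes at
## ancestry-informative loci, and phenotypes under configurable generative
## models.

#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' Draws, at each locus, the two ancestral populations' allele frequencies
#' independently from a Beta distribution around a shared base frequency
#' `p`: `Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`, so that the expected
#' squared divergence matches the target FST. `fst = 0` returns the base
#' frequencies unchanged for both populations. Loci are placed uniformly on
#' the genetic map and sorted by position.
#'
#' @param nLoci number of loci.
#' @param fst divergence parameter in `[0, 1)`; default 0.12.
#' @param map a [GeneticMap-class].
#' @param baseFreq function of `n` returning base frequencies, or a numeric
#'   vector of length `nLoci`. Default: uniform on `[0.05, 0.95]`.
#' @param seed optional integer seed.
#' @return An [AncestralFreqs-class] object.
#' @examples
#' af <- simulateAncestralFreqs(100, fst = 0.12, seed = 1)
#' @export
simulateAncestralFreqs <- function(nLoci, fst = 0.12, map = geneticMap(),
                                   baseFreq = NULL, seed = NULL) {
  if (!.isCount(nLoci)) stop("nLoci must be a positive integer")
  if (!is.numeric(fst) || length(fst) != 1L || is.na(fst) ||
      fst < 0 || fst >= 1)
    stop("fst must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(baseFreq)) runif(nLoci, 0.05, 0.95)
       else if (is.function(baseFreq)) baseFreq(nLoci)
       else rep_len(as.numeric(baseFreq), nLoci)
  if (!.isProb(p)) stop("base frequencies must lie in [0, 1]")
  if (fst == 0) {
    f1 <- f2 <- p
  } else {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    f1 <- rbeta(nLoci, a, b)
    f2 <- rbeta(nLoci, a, b)
  }
  # uniform placement over the genome, proportional to genetic length
  chromIdx <- sample.int(nChromosomes(map), nLoci, replace = TRUE,
                         prob = map@lengthM / sum(map@lengthM))
  pos <- runif(nLoci, 0, map@lengthM[chromIdx])
  ord <- order(chromIdx, pos)
  new("AncestralFreqs", chrom = map@chrom[chromIdx][ord], posM = pos[ord],
      f1 = f1[ord], f2 = f2[ord], fst = fst, map = map)
}

# default number-of-siblings sampler: most families contribute one pair
.defaultSibsSampler <- function(n) sample(2:4, n, TRUE, c(0.80, 0.15, 0.05))

#' Simulate an admixed population of full-sibling families
#'
#' Each family has two founder parents and two or more offspring produced by
#' meiosis. Founders are, independently of each other, unadmixed from
#' population 1, unadmixed from population 2, or admixed with an
#' ancestry-proportion target drawn from a Beta distribution (default mean
#' 0.71), so the output contains unadmixed-unadmixed families, F1-producing
#' families and admixed-admixed families, exercising all downstream filters.
#' With the defaults, most admixed sibling pairs differ by less than 5
#' percentage points in true ancestry proportion.
#'
#' @param nFamilies number of families.
#' @param sibsPerFamily function of `n` returning integer sibship sizes
#'   (all must be >= 2), or an integer vector to recycle.
#' @param founderComp named fractions `c(unadmixed1, unadmixed2, admixed)`
#'   summing to 1; default `c(0.55, 0.05, 0.40)`.
#' @param admixedQBeta `c(shape1, shape2)` of the Beta distribution for
#'   admixed founders' ancestry target; default `c(5.68, 2.32)` (mean 0.71).
#' @param admixGenerations generations since admixture for founder tracts.
#' @param map a [GeneticMap-class].
#' @param seed optional integer seed.
#' @return An [AdmixPedigree-class] with founders and offspring.
#' @examples
#' pop <- simulatePopulation(5, seed = 1)
#' pedigree(pop)[1:4, ]
#' @export
simulatePopulation <- function(nFamilies,
                               sibsPerFamily = .defaultSibsSampler,
                               founderComp = c(unadmixed1 = 0.55,
                                               unadmixed2 = 0.05,
                                               admixed = 0.40),
                               admixedQBeta = c(5.68, 2.32),
                               admixGenerations = 5,
                               map = geneticMap(), seed = NULL) {
  if (!.isCount(nFamilies)) stop("nFamilies must be a positive integer")
  if (abs(sum(founderComp) - 1) > 1e-8)
    stop("founderComp fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  nSibs <- if (is.function(sibsPerFamily)) sibsPerFamily(nFamilies)
           else rep_len(as.integer(sibsPerFamily), nFamilies)
  if (any(nSibs < 2L))
    stop("sibsPerFamily must give at least 2 siblings per family")

  fmt <- function(i) sprintf("F%04d", i)
  rows <- vector("list", nFamilies)
  allTracts <- list()
  allOrigins <- list()
  for (j in seq_len(nFamilies)) {
    fid <- fmt(j)
    founderQ <- function() {
      type <- sample(3L, 1L, prob = founderComp)
      switch(type, 1, 0, rbeta(1L, admixedQBeta[1], admixedQBeta[2]))
    }
    pat <- makeFounder(founderQ(), admixGenerations, map)
    mat <- makeFounder(founderQ(), admixGenerations, map)
    pid <- paste0(fid, "_P1")
    mid <- paste0(fid, "_P2")
    allTracts[[pid]] <- pat
    allTracts[[mid]] <- mat
    kidIds <- sprintf("%s_S%d", fid, seq_len(nSibs[j]))
    for (kid in kidIds) {
      gp <- meiosis(pat, map, withOrigin = TRUE)
      gm <- meiosis(mat, map, withOrigin = TRUE)
      allTracts[[kid]] <- list(h1 = gp$tract, h2 = gm$tract)
      allOrigins[[kid]] <- list(pat = gp$origin, mat = gm$origin)
    }
    ids <- c(pid, mid, kidIds)
    rows[[j]] <- data.frame(
      id = ids, fid = fid,
      father = c(NA, NA, rep(pid, nSibs[j])),
      mother = c(NA, NA, rep(mid, nSibs[j])),
      sex = c(0L, 1L, rbinom(nSibs[j], 1L, 0.5)),
      age = round(runif(2L + nSibs[j], 18, 80), 1),
      qTrue = NA_real_,
      role = c("founder", "founder", rep("offspring", nSibs[j])),
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  ped$qTrue <- vapply(ped$id, function(i) ancestryFraction(allTracts[[i]], map),
                      numeric(1))
  new("AdmixPedigree", ped = ped, tracts = allTracts, origins = allOrigins,
      map = map)
}

#' Simulate genotypes from local-ancestry tracts
#'
#' Founder haplotype alleles are drawn per locus as Bernoulli with the allele
#' frequency of the ancestral population carrying the haplotype at that
#' position. Offspring haplotypes copy the parental alleles along the
#' transmitted-gamete origin tracts recorded at meiosis, so siblings share
#' alleles identical by descent exactly where their transmitted gametes
#' coincide. Genotypes are 0/1/2 reference-allele dosages.
#'
#' @param pop an [AdmixPedigree-class].
#' @param freqs an [AncestralFreqs-class] on the same map.
#' @param missingRate fraction of entries set missing at random (default 0).
#' @param seed optional integer seed.
#' @return integer matrix, individuals x loci, with `NA` for missing calls.
#' @export
simulateGenotypes <- function(pop, freqs, missingRate = 0, seed = NULL) {
  if (!identical(pop@map@chrom, freqs@map@chrom) ||
      !identical(pop@map@lengthM, freqs@map@lengthM))
    stop("pop and freqs must use the same genetic map")
  if (!.isProb(missingRate)) stop("missingRate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ped <- pop@ped
  ids <- ped$id
  L <- nLoci(freqs)
  chromOf <- split(seq_len(L), factor(freqs@chrom, levels = pop@map@chrom))

  # per-haplotype allele vectors, founders first, then transmission
  hapAlleles <- vector("list", length(ids))
  names(hapAlleles) <- ids
  drawFounderHap <- function(hap) {
    a <- integer(L)
    for (k in seq_along(pop@map@chrom)) {
      idx <- chromOf[[k]]
      if (!length(idx)) next
      anc <- .segAt(hap[[k]], freqs@posM[idx])
      f <- ifelse(anc == 1L, freqs@f1[idx], freqs@f2[idx])
      a[idx] <- rbinom(length(idx), 1L, f)
    }
    a
  }
  copyGamete <- function(parentHaps, origin) {
    a <- integer(L)
    for (k in seq_along(pop@map@chrom)) {
      idx <- chromOf[[k]]
      if (!length(idx)) next
      src <- .segAt(origin[[k]], freqs@posM[idx])
      a[idx] <- ifelse(src == 1L, parentHaps$h1[idx], parentHaps$h2[idx])
    }
    a
  }
  for (i in which(ped$role == "founder")) {
    ind <- pop@tracts[[ids[i]]]
    hapAlleles[[ids[i]]] <- list(h1 = drawFounderHap(ind$h1),
                                 h2 = drawFounderHap(ind$h2))
  }
  for (i in which(ped$role == "offspring")) {
    org <- pop@origins[[ids[i]]]
    if (is.null(org))
      stop("offspring ", ids[i], " has no recorded gamete origins")
    hapAlleles[[ids[i]]] <- list(
      h1 = copyGamete(hapAlleles[[ped$father[i]]], org$pat),
      h2 = copyGamete(hapAlleles[[ped$mother[i]]], org$mat))
  }

  G <- matrix(NA_integer_, length(ids), L,
              dimnames = list(ids, paste0(freqs@chrom, ":",
                                          signif(freqs@posM, 6))))
  for (i in seq_along(ids))
    G[i, ] <- hapAlleles[[ids[i]]]$h1 + hapAlleles[[ids[i]]]$h2
  if (missingRate > 0) {
    drop <- runif(length(G)) < missingRate
    G[drop] <- NA_integer_
  }
  G
}

#' Phenotype generative-model configuration
#'
#' Parameters of the phenotype model
#' `y_ij = alpha + Q_ij * deltaG + env_ij + gamma_j + betaAge*Age +
#' betaSex*Sex + eps_ij` with `gamma_j ~ N(0, sigmaFam^2)` and
#' `eps_ij ~ N(0, sigma^2)`. The ancestry-by-environment term `env_ij` is
#' `eAnc * mean(Q of family's siblings)` in `"family"` mode,
#' `eAnc * Q_ij` in `"individual"` mode, and absent in `"none"` mode.
#'
#' @param deltaG difference in mean genotypic value per unit ancestry.
#' @param alpha intercept.
#' @param sigma residual standard deviation (>= 0).
#' @param sigmaFam family random-effect standard deviation (>= 0).
#' @param eAnc ancestry-by-environment interaction coefficient.
#' @param eAncMode one of `"none"`, `"family"`, `"individual"`.
#' @param betaAge,betaSex covariate effect sizes (default 0: nuisance).
#' @return A list of class `"PhenotypeGenConfig"`.
#' @export
phenotypeConfig <- function(deltaG = 1, alpha = 0, sigma = 1, sigmaFam = 0,
                            eAnc = 0, eAncMode = c("none", "family",
                                                   "individual"),
                            betaAge = 0, betaSex = 0) {
  eAncMode <- match.arg(eAncMode)
  if (sigma < 0 || sigmaFam < 0) stop("sigma and sigmaFam must be >= 0")
  if (eAnc != 0 && eAncMode == "none")
    stop("eAnc is nonzero but eAncMode is 'none'")
  structure(list(deltaG = deltaG, alpha = alpha, sigma = sigma,
                 sigmaFam = sigmaFam, eAnc = eAnc, eAncMode = eAncMode,
                 betaAge = betaAge, betaSex = betaSex),
            class = "PhenotypeGenConfig")
}

#' Simulate phenotypes for the offspring of a pedigree
#'
#' @param pop an [AdmixPedigree-class].
#' @param cfg a [phenotypeConfig()].
#' @param q optional named vector of ancestry proportions to use instead of
#'   the simulation truth (e.g. estimated Q).
#' @param seed optional integer seed.
#' @return data.frame with columns `id`, `fid`, `age`, `sex`, `q`, `y`
#'   (offspring only).
#' @export
simulatePhenotypes <- function(pop, cfg = phenotypeConfig(), q = NULL,
                               seed = NULL) {
  stopifnot(inherits(cfg, "PhenotypeGenConfig"))
  if (!is.null(seed)) set.seed(seed)
  off <- pop@ped[pop@ped$role == "offspring", ]
  Q <- if (is.null(q)) off$qTrue else unname(q[off$id])
  if (anyNA(Q)) stop("missing ancestry proportion for some offspring")
  fam <- factor(off$fid)
  env <- switch(cfg$eAncMode,
    none = 0,
    family = cfg$eAnc * ave(Q, fam),
    individual = cfg$eAnc * Q)
  gamma <- rnorm(nlevels(fam), 0, cfg$sigmaFam)[as.integer(fam)]
  y <- cfg$alpha + Q * cfg$deltaG + env + gamma +
    cfg$betaAge * off$age + cfg$betaSex * off$sex +
    rnorm(nrow(off), 0, cfg$sigma)
  data.frame(id = off$id, fid = off$fid, age = off$age, sex = off$sex,
             q = Q, y = y, stringsAsFactors = FALSE)
}
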