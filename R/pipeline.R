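## End-to-end pipeline: simulate -> QC -> ancestry -> relatedness ->
## sibling identification -> filtering -> effect estimation, with every
## stage's outputs written alongside the seed and a configuration hash.

.defaultConfig <- function() {
  list(
    seed = 1L,
    outDir = NULL,
    simulate = list(nFamilies = 100L, nLoci = 2000L, fst = 0.12,
                    missingRate = 0, deltaG = 1, sigma = 1, sigmaFam = 0,
                    eAnc = 0, eAncMode = "none"),
    qc = list(mafMin = 0.05, missMax = 0.05, ldR2Max = 0.8, window = 50L,
              step = 5L),
    ancestry = list(mode = "supervised", tol = 1e-6, maxIter = 2000L),
    relatedness = list(minLoci = 200L, candidatePairs = "within-family",
                       nCrossFamily = 200L),
    sibpairs = list(threshold = 0.95, centralBand = c(0.40, 0.60),
                    unresolved = "drop"),
    estimate = list(models = c("1a", "1b", "2"), phenotypes = "y")
  )
}

# strict merge of a user config into the defaults: unknown keys are an error
.mergeConfig <- function(user, defaults = .defaultConfig(), path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .mergeConfig(user[[k]], defaults[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config `NULL` (defaults), a named list overriding defaults, or the
#'   path to a YAML file with the same structure. Unknown keys are rejected.
#' @return the complete configuration list.
#' @export
pipelineConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .mergeConfig(config)
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates an admixed sibling population, applies variant QC, estimates
#' ancestry proportions, estimates pairwise IBD coefficients on candidate
#' pairs, classifies full siblings, filters to informative admixed pairs,
#' and fits the effect estimators. Re-running with the same seed and
#' configuration reproduces identical numeric outputs. If `outDir` is set,
#' each stage's tables are written as TSV plus a JSON summary including the
#' seed and a hash of the configuration.
#'
#' @param config see [pipelineConfig()].
#' @return list with elements `config`, `pop`, `freqs`, `qc`, `ancestry`,
#'   `relatedness`, `siblings`, `filter`, `phenotypes`, `effects`.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- pipelineConfig(config)
  if (!is.null(cfg$outDir))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  ## simulate
  sc <- cfg$simulate
  map <- geneticMap()
  freqs <- simulateAncestralFreqs(sc$nLoci, fst = sc$fst, map = map)
  pop <- simulatePopulation(sc$nFamilies, map = map)
  geno <- simulateGenotypes(pop, freqs, missingRate = sc$missingRate)
  phen <- simulatePhenotypes(pop, phenotypeConfig(
    deltaG = sc$deltaG, sigma = sc$sigma, sigmaFam = sc$sigmaFam,
    eAnc = sc$eAnc, eAncMode = sc$eAncMode))

  ## qc
  qc <- variantQC(geno, cfg$qc$mafMin, cfg$qc$missMax, cfg$qc$ldR2Max,
                  cfg$qc$window, cfg$qc$step)
  freqsKept <- new("AncestralFreqs", chrom = freqs@chrom[qc$keep],
                   posM = freqs@posM[qc$keep], f1 = freqs@f1[qc$keep],
                   f2 = freqs@f2[qc$keep], fst = freqs@fst, map = freqs@map)

  ## ancestry
  anc <- if (cfg$ancestry$mode == "supervised") {
    estimateAdmixtureSupervised(qc$genotypes, freqsKept)
  } else {
    anchors <- pop@ped$id[pop@ped$role == "founder" & pop@ped$qTrue == 1]
    estimateAdmixtureUnsupervised(qc$genotypes, tol = cfg$ancestry$tol,
                                  maxIter = cfg$ancestry$maxIter,
                                  anchors = anchors)
  }
  qhat <- ancestryQ(anc)

  ## relatedness on candidate pairs
  ped <- pedigree(pop)
  off <- ped[ped$role == "offspring", ]
  candidates <- do.call(rbind, lapply(split(off$id, off$fid), function(ids) {
    if (length(ids) < 2L) return(NULL)
    cmb <- utils::combn(sort(ids), 2L)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  }))
  if (cfg$relatedness$candidatePairs == "all") {
    cmb <- utils::combn(off$id, 2L)
    candidates <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  } else if (cfg$relatedness$nCrossFamily > 0L && nrow(off) > 3L) {
    i <- sample(off$id, cfg$relatedness$nCrossFamily, replace = TRUE)
    j <- sample(off$id, cfg$relatedness$nCrossFamily, replace = TRUE)
    keep <- off$fid[match(i, off$id)] != off$fid[match(j, off$id)]
    if (any(keep))
      candidates <- unique(rbind(candidates,
                                 data.frame(id1 = pmin(i, j)[keep],
                                            id2 = pmax(i, j)[keep])))
  }
  rel <- pairwiseRelatedness(qc$genotypes, qhat, freqsKept, candidates,
                             minLoci = cfg$relatedness$minLoci)

  ## sibling classification + filtering
  sibs <- classifyFullSiblings(rel)
  parentQhat <- parentAncestry(pop, q = qhat)
  flt <- filterAdmixedPairs(sibs, qhat, parentQ = parentQhat,
                            threshold = cfg$sibpairs$threshold,
                            centralBand = cfg$sibpairs$centralBand,
                            unresolved = cfg$sibpairs$unresolved)

  ## effect estimation
  phen$q <- unname(qhat[phen$id])
  effects <- if (nrow(flt$retained) >= 7L)
    estimateEffects(phen, flt$retained, cfg$estimate$phenotypes,
                    cfg$estimate$models)
  else list(summary = NULL, full = NULL)

  bundle <- list(config = cfg, pop = pop, freqs = freqsKept, qc = qc,
                 ancestry = anc, relatedness = rel, siblings = sibs,
                 filter = flt, phenotypes = phen, effects = effects)

  if (!is.null(cfg$outDir)) {
    od <- cfg$outDir
    cfgPath <- file.path(od, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    meta <- list(seed = cfg$seed,
                 configHash = unname(tools::md5sum(cfgPath)),
                 version = as.character(utils::packageVersion("admixsib")))
    jsonlite::write_json(meta, file.path(od, "run.json"), auto_unbox = TRUE)
    writeTSV(ped, file.path(od, "pedigree.tsv"))
    writeTSV(rel, file.path(od, "relatedness.tsv"))
    writeTSV(flt$pairs, file.path(od, "sibpairs.tsv"))
    writeTSV(phen, file.path(od, "phenotypes.tsv"))
    writeQ(qhat, file.path(od, "ancestry.Q"))
    if (!is.null(effects$summary))
      writeTSV(effects$summary, file.path(od, "effects.tsv"))
  }
  bundle
}
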