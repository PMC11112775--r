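## S4 containers for the simulator and the ancestry estimator.

#' Genetic map of autosomes
#'
#' Chromosome labels and genetic lengths in Morgans. The default map has 22
#' autosomes with sex-averaged lengths summing to about 35.4 Morgans, enough
#' to give realistic between-sibling variance in ancestry proportion without
#' external map files.
#'
#' @slot chrom character vector of chromosome labels.
#' @slot lengthM numeric vector of genetic lengths in Morgans, parallel to
#'   `chrom`.
#' @export
setClass("GeneticMap",
  representation(chrom = "character", lengthM = "numeric"))

setValidity("GeneticMap", function(object) {
  if (length(object@chrom) != length(object@lengthM))
    return("chrom and lengthM must have the same length")
  if (length(object@chrom) < 1L) return("map must have at least 1 chromosome")
  if (anyDuplicated(object@chrom)) return("duplicated chromosome labels")
  if (any(!is.finite(object@lengthM)) || any(object@lengthM <= 0))
    return("all chromosome lengths must be positive and finite")
  TRUE
})

#' Construct a genetic map
#'
#' @param lengthM genetic lengths in Morgans, one per chromosome. Defaults to
#'   sex-averaged human-like autosome lengths (total ~35.4 Morgans).
#' @param chrom chromosome labels; defaults to `"1".."22"` (or as many as
#'   `lengthM` has entries).
#' @return A [GeneticMap-class] object.
#' @examples
#' map <- geneticMap()
#' totalLength(map)
#' @export
geneticMap <- function(lengthM = NULL, chrom = NULL) {
  if (is.null(lengthM))
    lengthM <- c(2.84, 2.69, 2.23, 2.14, 2.04, 1.92, 1.87, 1.70, 1.68, 1.81,
                 1.58, 1.75, 1.26, 1.19, 1.41, 1.34, 1.29, 1.18, 1.08, 1.08,
                 0.62, 0.74)
  if (is.null(chrom)) chrom <- as.character(seq_along(lengthM))
  new("GeneticMap", chrom = as.character(chrom), lengthM = as.numeric(lengthM))
}

#' @describeIn geneticMap total genetic length of the map in Morgans.
#' @param map a [GeneticMap-class].
#' @export
totalLength <- function(map) sum(map@lengthM)

#' @describeIn geneticMap number of chromosomes.
#' @export
nChromosomes <- function(map) length(map@chrom)

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@chrom), "chromosomes,",
      format(sum(object@lengthM), digits = 4), "Morgans total\n")
})

#' Ancestral allele frequencies at mapped loci
#'
#' Per-locus reference-allele frequencies in the two ancestral populations,
#' with locus positions on a genetic map. These play the role of the
#' ancestry-specific allele frequencies a supervised admixture analysis
#' conditions on.
#'
#' @slot chrom character, chromosome label per locus.
#' @slot posM numeric, position in Morgans per locus (sorted within
#'   chromosome).
#' @slot f1 numeric, frequency in ancestral population 1.
#' @slot f2 numeric, frequency in ancestral population 2.
#' @slot fst numeric(1), divergence parameter used to generate the
#'   frequencies (NA when unknown).
#' @slot map the [GeneticMap-class] the positions refer to.
#' @export
setClass("AncestralFreqs",
  representation(chrom = "character", posM = "numeric", f1 = "numeric",
                 f2 = "numeric", fst = "numeric", map = "GeneticMap"))

setValidity("AncestralFreqs", function(object) {
  n <- length(object@posM)
  if (length(object@chrom) != n || length(object@f1) != n ||
      length(object@f2) != n)
    return("chrom, posM, f1, f2 must be parallel vectors")
  if (!.isProb(object@f1) || !.isProb(object@f2))
    return("allele frequencies must lie in [0, 1]")
  if (!all(object@chrom %in% object@map@chrom))
    return("locus chromosome not present in map")
  lenOf <- setNames(object@map@lengthM, object@map@chrom)
  if (any(object@posM < 0) || any(object@posM > lenOf[object@chrom]))
    return("locus positions must lie within chromosome bounds")
  for (ch in unique(object@chrom)) {
    p <- object@posM[object@chrom == ch]
    if (is.unsorted(p)) return("loci must be sorted by position in chromosome")
  }
  TRUE
})

setMethod("show", "AncestralFreqs", function(object) {
  cat("AncestralFreqs:", length(object@posM), "loci on",
      length(unique(object@chrom)), "chromosomes")
  if (!is.na(object@fst)) cat(", FST =", object@fst)
  cat("\n")
})

#' @rdname AncestralFreqs-class
#' @param x an `AncestralFreqs` object.
#' @return `nLoci()` the locus count; `freqTable()` a data.frame with columns
#'   `chrom`, `posM`, `f1`, `f2`.
#' @export
nLoci <- function(x) length(x@posM)

#' @rdname AncestralFreqs-class
#' @export
freqTable <- function(x)
  data.frame(chrom = x@chrom, posM = x@posM, f1 = x@f1, f2 = x@f2)

#' Simulated admixed pedigree with local-ancestry haplotypes
#'
#' Holds the pedigree table and, for each individual, the two haplotypes'
#' local-ancestry tracts (the simulator's ground truth). Tracts are stored
#' per chromosome as segment end positions (Morgans, tiling the chromosome)
#' and per-segment ancestry labels in `{1, 2}`.
#'
#' @slot ped data.frame with columns `id`, `fid`, `father`, `mother`, `sex`
#'   (0/1), `age` (years), `qTrue` (genome fraction of ancestry 1), `role`
#'   (`"founder"` or `"offspring"`).
#' @slot tracts named list (by id); each element is `list(h1, h2)`, each
#'   haplotype a list over chromosomes of `list(end, anc)`.
#' @slot origins named list (offspring only): `list(pat, mat)` origin tracts
#'   recording which parental haplotype each transmitted gamete segment was
#'   copied from; used to transmit founder alleles and as IBD ground truth.
#' @slot map the [GeneticMap-class] used.
#' @export
setClass("AdmixPedigree",
  representation(ped = "data.frame", tracts = "list", origins = "list",
                 map = "GeneticMap"))

setValidity("AdmixPedigree", function(object) {
  need <- c("id", "fid", "father", "mother", "sex", "age", "qTrue", "role")
  if (!all(need %in% names(object@ped)))
    return(paste("ped must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@ped$id)) return("duplicated individual ids")
  if (!all(object@ped$id %in% names(object@tracts)))
    return("every individual needs tracts")
  if (!.isProb(object@ped$qTrue)) return("qTrue must lie in [0, 1]")
  TRUE
})

setMethod("show", "AdmixPedigree", function(object) {
  p <- object@ped
  cat("AdmixPedigree:", nrow(p), "individuals (",
      sum(p$role == "founder"), "founders,",
      sum(p$role == "offspring"), "offspring ) in",
      length(unique(p$fid)), "families\n")
  cat("  mean ancestry-1 proportion:",
      format(mean(p$qTrue), digits = 3), "\n")
})

#' @rdname AdmixPedigree-class
#' @param object an `AdmixPedigree`.
#' @return `pedigree()` the pedigree data.frame; `qTrue()` a named vector of
#'   true ancestry proportions; `tracts()` the tract list for one individual.
#' @export
pedigree <- function(object) object@ped

#' @rdname AdmixPedigree-class
#' @export
qTrue <- function(object) setNames(object@ped$qTrue, object@ped$id)

#' @rdname AdmixPedigree-class
#' @param id individual id.
#' @export
tracts <- function(object, id) object@tracts[[id]]

#' Admixture proportion estimate
#'
#' Result of supervised or unsupervised two-way admixture estimation.
#'
#' @slot Q named numeric, estimated proportion of ancestry 1 per individual.
#' @slot P numeric matrix with columns `f1`, `f2`: allele frequencies used
#'   (supervised) or estimated (unsupervised).
#' @slot logLik numeric vector: the log-likelihood trace across EM iterations
#'   (unsupervised) or the total log-likelihood at the optimum (supervised).
#' @slot converged logical(1).
#' @slot method character(1), `"supervised"` or `"unsupervised"`.
#' @export
setClass("AdmixtureEstimate",
  representation(Q = "numeric", P = "matrix", logLik = "numeric",
                 converged = "logical", method = "character"))

setValidity("AdmixtureEstimate", function(object) {
  if (!.isProb(object@Q)) return("Q must lie in [0, 1]")
  if (length(object@logLik) > 1L &&
      any(diff(object@logLik) < -1e-6 * abs(object@logLik[-1])))
    return("log-likelihood trace must be non-decreasing")
  TRUE
})

setMethod("show", "AdmixtureEstimate", function(object) {
  cat("AdmixtureEstimate (", object@method, "): ", length(object@Q),
      " individuals, mean Q = ", format(mean(object@Q), digits = 3),
      if (length(object@logLik)) paste0(", logLik = ",
        format(object@logLik[length(object@logLik)], digits = 8)), "\n",
      sep = "")
})

#' @rdname AdmixtureEstimate-class
#' @param object an `AdmixtureEstimate`.
#' @return `ancestryQ()` the named vector of estimated proportions.
#' @export
ancestryQ <- function(object) object@Q
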