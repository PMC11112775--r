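## Local-ancestry tract machinery: founders, meiosis, IBD truth.
##
## A haplotype is a list over chromosomes; each chromosome is
## list(end, anc): `end` strictly increasing segment end positions in
## Morgans with end[length(end)] == chromosome length, `anc` parallel
## integer labels. Segments tile the chromosome exactly.

# merge adjacent segments with equal labels
.simplifySeg <- function(end, anc) {
  if (length(end) <= 1L) return(list(end = end, anc = anc))
  keep <- c(anc[-length(anc)] != anc[-1L], TRUE)
  list(end = end[keep], anc = anc[keep])
}

# label at positions pos (0 <= pos < L); positions exactly on a boundary
# take the following segment
.segAt <- function(seg, pos) {
  seg$anc[findInterval(pos, seg$end, left.open = FALSE) + 1L]
}

# portion of a segment list within (a, b], re-expressed with absolute ends
.sliceSeg <- function(seg, a, b) {
  ends <- seg$end
  i0 <- findInterval(a, ends, left.open = FALSE) + 1L # segment containing a
  i1 <- findInterval(b, ends, left.open = TRUE) + 1L  # segment containing b
  i1 <- min(i1, length(ends))
  e <- pmin(ends[i0:i1], b)
  list(end = e, anc = seg$anc[i0:i1])
}

.chromTract <- function(L, anc) list(end = L, anc = as.integer(anc))

# Morgan-weighted fraction of a haplotype carrying ancestry label 1
.hapAncestry1 <- function(hap, map) {
  tot <- 0
  for (k in seq_along(map@chrom)) {
    seg <- hap[[k]]
    len <- diff(c(0, seg$end))
    tot <- tot + sum(len[seg$anc == 1L])
  }
  tot
}

#' True ancestry proportion from tracts
#'
#' Morgan-weighted genome fraction of ancestry 1 across an individual's two
#' haplotypes.
#'
#' @param ind `list(h1, h2)` of haplotype tract lists.
#' @param map a [GeneticMap-class].
#' @return numeric(1) in `[0, 1]`.
#' @export
ancestryFraction <- function(ind, map) {
  (.hapAncestry1(ind$h1, map) + .hapAncestry1(ind$h2, map)) /
    (2 * sum(map@lengthM))
}

#' Simulate a founder individual's haplotypes
#'
#' Founder haplotypes follow a stationary approximation of admixture
#' `admixGenerations` generations ago: tract boundaries are a Poisson process
#' with rate `admixGenerations` per Morgan, and each segment's ancestry is 1
#' with probability `qTarget`, independently. `qTarget` 0 or 1 yields
#' single-ancestry chromosomes.
#'
#' @param qTarget expected proportion of ancestry 1.
#' @param admixGenerations generations since admixture (Poisson rate per
#'   Morgan); default 5.
#' @param map a [GeneticMap-class].
#' @return `list(h1, h2)` of haplotype tract lists.
#' @export
makeFounder <- function(qTarget, admixGenerations = 5, map = geneticMap()) {
  if (!.isProb(qTarget) || length(qTarget) != 1L)
    stop("qTarget must be a single probability in [0, 1]")
  if (!.isCount(admixGenerations))
    stop("admixGenerations must be a positive integer")
  oneHap <- function() {
    lapply(map@lengthM, function(L) {
      if (qTarget == 0) return(.chromTract(L, 2L))
      if (qTarget == 1) return(.chromTract(L, 1L))
      nb <- rpois(1L, admixGenerations * L)
      end <- c(sort(runif(nb, 0, L)), L)
      anc <- ifelse(runif(nb + 1L) < qTarget, 1L, 2L)
      .simplifySeg(end, anc)
    })
  }
  list(h1 = oneHap(), h2 = oneHap())
}

# core of meiosis for one chromosome: returns the gamete ancestry segments
# and the parental-origin segments (labels 1/2 = parent haplotype copied)
.meiosisChrom <- function(h1seg, h2seg, L) {
  nco <- rpois(1L, L)
  cross <- if (nco > 0L) sort(runif(nco, 0, L)) else numeric(0)
  start <- if (runif(1L) < 0.5) 1L else 2L
  bounds <- c(0, cross, L)
  nSegs <- length(bounds) - 1L
  haps <- rep_len(c(start, 3L - start), nSegs)
  endOut <- vector("list", nSegs)
  ancOut <- vector("list", nSegs)
  for (s in seq_len(nSegs)) {
    src <- if (haps[s] == 1L) h1seg else h2seg
    piece <- .sliceSeg(src, bounds[s], bounds[s + 1L])
    endOut[[s]] <- piece$end
    ancOut[[s]] <- piece$anc
  }
  gam <- .simplifySeg(unlist(endOut), unlist(ancOut))
  origin <- .simplifySeg(c(cross, L), haps)
  list(tract = gam, origin = origin)
}

#' Simulate a meiosis
#'
#' Produces one gamete from a parent under the Haldane model: per chromosome
#' the crossover count is Poisson with mean equal to the genetic length in
#' Morgans, crossover positions are uniform, there is no interference, and
#' the starting haplotype is chosen with probability 1/2.
#'
#' @param parent `list(h1, h2)` of haplotype tract lists.
#' @param map a [GeneticMap-class].
#' @param withOrigin if `TRUE`, also return which parental haplotype each
#'   gamete segment was copied from (used for IBD ground truth).
#' @return A haplotype tract list, or if `withOrigin`,
#'   `list(tract, origin)` where both are haplotype-style tract lists.
#' @export
meiosis <- function(parent, map = geneticMap(), withOrigin = FALSE) {
  res <- lapply(seq_along(map@chrom), function(k)
    .meiosisChrom(parent$h1[[k]], parent$h2[[k]], map@lengthM[k]))
  tract <- lapply(res, `[[`, "tract")
  if (!withOrigin) return(tract)
  list(tract = tract, origin = lapply(res, `[[`, "origin"))
}

# genome fractions of IBD state 0/1/2 for a sibling pair given the four
# transmitted-gamete origin tract lists
.ibdFractions <- function(pat1, pat2, mat1, mat2, map) {
  len2 <- len1 <- len0 <- 0
  for (k in seq_along(map@chrom)) {
    b <- sort(unique(c(pat1[[k]]$end, pat2[[k]]$end,
                       mat1[[k]]$end, mat2[[k]]$end)))
    w <- diff(c(0, b))
    mid <- b - w / 2
    ibd <- (.segAt(pat1[[k]], mid) == .segAt(pat2[[k]], mid)) +
           (.segAt(mat1[[k]], mid) == .segAt(mat2[[k]], mid))
    len0 <- len0 + sum(w[ibd == 0L])
    len1 <- len1 + sum(w[ibd == 1L])
    len2 <- len2 + sum(w[ibd == 2L])
  }
  c(k0 = len0, k1 = len1, k2 = len2) / sum(map@lengthM)
}

#' Genome-wide IBD sharing of simulated sibling pairs
#'
#' Simulates full-sibling pairs by two independent meioses per parent and
#' returns, for each pair, the exact Morgan-weighted genome fractions in IBD
#' state 0, 1 and 2, computed from transmitted-gamete identity (the
#' simulator's ground truth, no genotypes involved). For full siblings these
#' fractions average (0.25, 0.50, 0.25).
#'
#' @param nPairs number of sibling pairs to simulate.
#' @param map a [GeneticMap-class].
#' @param seed optional integer seed.
#' @return data.frame with columns `k0`, `k1`, `k2`, one row per pair.
#' @export
sibIBDTruth <- function(nPairs, map = geneticMap(), seed = NULL) {
  if (!.isCount(nPairs)) stop("nPairs must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  # parental ancestry is irrelevant to IBD; use unadmixed dummies
  dummy <- list(h1 = lapply(map@lengthM, .chromTract, anc = 1L),
                h2 = lapply(map@lengthM, .chromTract, anc = 1L))
  out <- matrix(0, nPairs, 3L, dimnames = list(NULL, c("k0", "k1", "k2")))
  for (i in seq_len(nPairs)) {
    p1 <- meiosis(dummy, map, withOrigin = TRUE)$origin
    p2 <- meiosis(dummy, map, withOrigin = TRUE)$origin
    m1 <- meiosis(dummy, map, withOrigin = TRUE)$origin
    m2 <- meiosis(dummy, map, withOrigin = TRUE)$origin
    out[i, ] <- .ibdFractions(p1, p2, m1, m2, map)
  }
  as.data.frame(out)
}
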