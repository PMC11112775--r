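## Admixture-aware IBD coefficient estimation, full-sibling classification,
## admixed-pair filtering, and the F1-based ancestry-difference error
## estimator.

# P(genotype | one allele is the shared allele, other drawn from pi)
.hShared <- function(g, pi, sharedRef) {
  if (sharedRef)
    ifelse(g == 2L, pi, ifelse(g == 1L, 1 - pi, 0))
  else
    ifelse(g == 0L, 1 - pi, ifelse(g == 1L, pi, 0))
}

.hwe <- function(g, pi)
  ifelse(g == 2L, pi^2, ifelse(g == 1L, 2 * pi * (1 - pi), (1 - pi)^2))

# per-locus genotype-pair probabilities conditional on IBD state 0/1/2,
# with individual-specific allele frequencies pi1, pi2 (admixture-aware);
# shared alleles use the pair-average frequency
.pairGenoProbs <- function(g1, g2, pi1, pi2) {
  pbar <- (pi1 + pi2) / 2
  P0 <- .hwe(g1, pi1) * .hwe(g2, pi2)
  P1 <- pbar * .hShared(g1, pi1, TRUE) * .hShared(g2, pi2, TRUE) +
    (1 - pbar) * .hShared(g1, pi1, FALSE) * .hShared(g2, pi2, FALSE)
  P2 <- (g1 == g2) * .hwe(g1, pbar)
  cbind(P0, P1, P2)
}

#' Estimate pairwise IBD coefficients for admixed individuals
#'
#' Maximum-likelihood estimate of the genome fractions `(k0, k1, k2)` at
#' which a pair of individuals shares 0, 1 or 2 alleles identical by
#' descent, taking admixture into account by substituting individual-specific
#' allele frequencies `pi_il = q_i f1_l + (1 - q_i) f2_l` into the standard
#' IBD-conditional genotype-pair probabilities (shared alleles use the
#' pair-average frequency). The mixture weights are maximized by EM on the
#' simplex; the log-likelihood is non-decreasing per iteration.
#'
#' @param g1,g2 genotype vectors (0/1/2, `NA` missing) at the same loci.
#' @param q1,q2 the two individuals' ancestry-1 proportions.
#' @param freqs an [AncestralFreqs-class] with matching loci.
#' @param minLoci minimum number of informative (non-missing in both) loci;
#'   below this the estimate is unstable and an error is raised. Default 200.
#' @param tol EM convergence tolerance (default 1e-7 log-likelihood units).
#' @param maxIter maximum EM iterations.
#' @return list with `k` (named numeric `k0, k1, k2` summing to 1),
#'   `logLik`, `nLoci`, `iterations`.
#' @export
estimateK <- function(g1, g2, q1, q2, freqs, minLoci = 200L, tol = 1e-7,
                      maxIter = 1000L) {
  if (length(g1) != length(g2) || length(g1) != nLoci(freqs))
    stop("g1, g2 and freqs must cover the same loci")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < minLoci)
    stop("only ", sum(ok), " informative loci; at least ", minLoci,
         " required for a stable IBD estimate")
  pi1 <- .clampProb(q1 * freqs@f1[ok] + (1 - q1) * freqs@f2[ok])
  pi2 <- .clampProb(q2 * freqs@f1[ok] + (1 - q2) * freqs@f2[ok])
  P <- .pairGenoProbs(g1[ok], g2[ok], pi1, pi2)
  P <- pmax(P, 1e-300)
  P0 <- P[, 1L]; P1 <- P[, 2L]; P2 <- P[, 3L]

  k0 <- k1 <- k2 <- 1 / 3
  llOld <- -Inf
  for (it in seq_len(maxIter)) {
    D <- k0 * P0 + k1 * P1 + k2 * P2
    ll <- sum(log(D))
    if (ll - llOld < tol && is.finite(llOld)) break
    llOld <- ll
    invD <- 1 / D
    k0 <- k0 * mean(P0 * invD)
    k1 <- k1 * mean(P1 * invD)
    k2 <- k2 * mean(P2 * invD)
    s <- k0 + k1 + k2
    k0 <- k0 / s; k1 <- k1 / s; k2 <- k2 / s
  }
  list(k = setNames(c(k0, k1, k2), c("k0", "k1", "k2")), logLik = ll,
       nLoci = sum(ok), iterations = it)
}

#' Pairwise relatedness over a set of candidate pairs
#'
#' Convenience wrapper running [estimateK()] for each row of a pair table.
#'
#' @param geno genotype matrix (individuals x loci) with rownames.
#' @param q named vector of estimated ancestry proportions.
#' @param freqs an [AncestralFreqs-class].
#' @param pairs two-column matrix or data.frame of individual ids; default:
#'   all unordered pairs (quadratic - supply a candidate list for large n).
#' @param ... passed to [estimateK()].
#' @return data.frame `id1, id2, k0, k1, k2, logLik, nLoci`.
#' @export
pairwiseRelatedness <- function(geno, q, freqs, pairs = NULL, ...) {
  ids <- rownames(geno)
  if (is.null(pairs)) {
    cmb <- utils::combn(ids, 2L)
    pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("id1", "id2")
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$id1[r]; j <- pairs$id2[r]
    est <- estimateK(geno[i, ], geno[j, ], q[[i]], q[[j]], freqs, ...)
    data.frame(id1 = i, id2 = j, k0 = est$k["k0"], k1 = est$k["k1"],
               k2 = est$k["k2"], logLik = est$logLik, nLoci = est$nLoci,
               row.names = NULL)
  })
  do.call(rbind, res)
}

# union-find for sibship components
.components <- function(id1, id2) {
  ids <- sort(unique(c(id1, id2)))
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_along(id1)) {
    a <- find(match(id1[r], ids)); b <- find(match(id2[r], ids))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  setNames(match(roots, sort(unique(roots))), ids)
}

#' Classify full-sibling pairs from IBD estimates
#'
#' Pairs with `0.25 < k1 < 0.75` and `0.15 < k2 < 0.5` form the primary
#' full-sibling set. A boundary rescue rule then adds pairs with
#' `0.4 < k1 < 0.6` and `k2 > 0.125` when both members already appear in a
#' primary-set pair with some other individual. Sibships are the connected
#' components of the resulting sibling graph and receive a shared family id.
#'
#' @param rel data.frame with columns `id1`, `id2`, `k1`, `k2` (e.g. from
#'   [pairwiseRelatedness()]).
#' @return data.frame of full-sibling pairs with columns `id1`, `id2`,
#'   `k1`, `k2`, `class` (`"primary"`/`"rescued"`), `sibship`. Empty input
#'   gives an empty output.
#' @export
classifyFullSiblings <- function(rel) {
  cols <- c("id1", "id2", "k1", "k2", "class", "sibship")
  empty <- data.frame(id1 = character(), id2 = character(), k1 = numeric(),
                      k2 = numeric(), class = character(),
                      sibship = character(), stringsAsFactors = FALSE)
  if (is.null(rel) || nrow(rel) == 0L) return(empty)
  primary <- rel$k1 > 0.25 & rel$k1 < 0.75 & rel$k2 > 0.15 & rel$k2 < 0.5
  primIds <- unique(c(rel$id1[primary], rel$id2[primary]))
  # rescue: both members already sibling to someone else in the primary set
  inPrimaryWithOther <- function(id, other)
    any(primary & ((rel$id1 == id & rel$id2 != other) |
                   (rel$id2 == id & rel$id1 != other)))
  rescue <- !primary & rel$k1 > 0.4 & rel$k1 < 0.6 & rel$k2 > 0.125
  if (any(rescue)) {
    chk <- vapply(which(rescue), function(r)
      inPrimaryWithOther(rel$id1[r], rel$id2[r]) &&
      inPrimaryWithOther(rel$id2[r], rel$id1[r]), logical(1))
    rescue[rescue] <- chk
  }
  sel <- primary | rescue
  if (!any(sel)) return(empty)
  out <- rel[sel, c("id1", "id2", "k1", "k2")]
  out$class <- ifelse(primary[sel], "primary", "rescued")
  comp <- .components(out$id1, out$id2)
  out$sibship <- sprintf("SIB%03d", comp[out$id1])
  rownames(out) <- NULL
  out[, cols]
}

#' Filter sibling pairs to those informative about ancestry differences
#'
#' Applies the two exclusion rules of the design: (i) pairs where both
#' siblings have more than `threshold` of the same genetic ancestry are
#' excluded (their parents were unadmixed with the same ancestry, so the
#' true ancestry difference is 0); (ii) pairs where both siblings' estimated
#' proportions fall in a central band around 0.5 are candidate F1 pairs, and
#' are excluded when one parent has more than `threshold` ancestry 1 and the
#' other less than `1 - threshold` (unadmixed parents of different
#' ancestries, so again the true difference is exactly 0). The filter is
#' idempotent and order-independent.
#'
#' @param pairs data.frame with columns `id1`, `id2` (e.g. from
#'   [classifyFullSiblings()]).
#' @param q named vector of estimated ancestry-1 proportions.
#' @param parentQ parental ancestry proportions for central-band pairs: a
#'   data.frame with columns `id`, `fatherQ`, `motherQ` keyed by offspring
#'   id (see [parentAncestry()]), or `NULL` if unavailable.
#' @param threshold same-ancestry / unadmixed-parent cutoff (default 0.95).
#' @param centralBand candidate-F1 band for estimated proportions
#'   (default `c(0.40, 0.60)`).
#' @param unresolved what to do with central-band pairs lacking parental
#'   ancestry: `"drop"` (conservative default) or `"keep"`.
#' @return list with `pairs` (input plus `status` and `dQ` columns),
#'   `retained` (the retained subset) and `report` (status counts).
#' @export
filterAdmixedPairs <- function(pairs, q, parentQ = NULL, threshold = 0.95,
                               centralBand = c(0.40, 0.60),
                               unresolved = c("drop", "keep")) {
  unresolved <- match.arg(unresolved)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  q1 <- unname(q[pairs$id1])
  q2 <- unname(q[pairs$id2])
  if (anyNA(q1) || anyNA(q2))
    stop("missing ancestry proportion for some pair members")
  lookupParents <- function(id) {
    if (is.null(parentQ)) return(c(NA_real_, NA_real_))
    r <- match(id, parentQ$id)
    if (is.na(r)) c(NA_real_, NA_real_)
    else c(parentQ$fatherQ[r], parentQ$motherQ[r])
  }
  status <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- q1[r]; b <- q2[r]
    if ((a > threshold && b > threshold) ||
        (a < 1 - threshold && b < 1 - threshold)) {
      status[r] <- "excluded_same_ancestry"
    } else if (a >= centralBand[1] && a <= centralBand[2] &&
               b >= centralBand[1] && b <= centralBand[2]) {
      pq <- lookupParents(pairs$id1[r])
      if (anyNA(pq)) pq <- lookupParents(pairs$id2[r])
      if (anyNA(pq)) {
        status[r] <- "unresolved"
      } else if (max(pq) > threshold && min(pq) < 1 - threshold) {
        status[r] <- "excluded_F1"
      } else {
        status[r] <- "retained"
      }
    } else {
      status[r] <- "retained"
    }
  }
  pairs$status <- status
  pairs$dQ <- q1 - q2
  keepStatus <- c("retained", if (unresolved == "keep") "unresolved")
  list(pairs = pairs,
       retained = pairs[pairs$status %in% keepStatus, , drop = FALSE],
       report = as.data.frame(table(status = status),
                              stringsAsFactors = FALSE))
}

#' Parental ancestry table from a simulated pedigree
#'
#' Builds the per-offspring table of parental ancestry-1 proportions used by
#' the F1 filter, either from the simulation truth or from a supplied vector
#' of (estimated) proportions. In a real analysis this table would come from
#' an external parental-ancestry method or from genotyped parents.
#'
#' @param pop an [AdmixPedigree-class].
#' @param q optional named vector of proportions to use for the parents
#'   (defaults to the simulation truth).
#' @return data.frame with columns `id`, `fatherQ`, `motherQ`.
#' @export
parentAncestry <- function(pop, q = NULL) {
  ped <- pop@ped
  if (is.null(q)) q <- setNames(ped$qTrue, ped$id)
  off <- ped[ped$role == "offspring", ]
  data.frame(id = off$id,
             fatherQ = unname(q[off$father]),
             motherQ = unname(q[off$mother]),
             stringsAsFactors = FALSE)
}

#' Average ancestry-difference error from F1 sibling pairs
#'
#' Each sibling in an F1 pair (offspring of two unadmixed parents of
#' different ancestries) has exactly 50% of each ancestry, so the true
#' within-pair ancestry difference is zero and any estimated difference is
#' pure estimation error. The average absolute estimated difference across
#' F1 pairs therefore estimates the average error in the within-pair
#' ancestry difference. If the per-individual estimation error is
#' `N(0, sigma^2)`, the statistic's expectation is `2 sigma / sqrt(pi)`.
#'
#' @param f1pairs data.frame with columns `id1`, `id2` (the F1 pairs).
#' @param q named vector of estimated ancestry proportions.
#' @return numeric(1): mean absolute estimated ancestry difference.
#' @export
estimateDqErrorFromF1 <- function(f1pairs, q) {
  if (is.null(f1pairs) || nrow(f1pairs) == 0L)
    stop("no F1 pairs supplied; the error estimator is undefined")
  d <- q[f1pairs$id1] - q[f1pairs$id2]
  if (anyNA(d)) stop("missing ancestry estimate for some F1 pair members")
  mean(abs(d))
}
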