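## Variant QC and two-way admixture proportion estimation.

#' Variant quality control
#'
#' Removes loci with minor-allele frequency below `mafMin` or missing-call
#' fraction above `missMax`, then greedily prunes one locus of any pair with
#' squared Pearson correlation above `ldR2Max` within a sliding window
#' (PLINK-style `indep-pairwise` convention: window of `window` loci advanced
#' by `step`; the later locus of an offending pair is dropped).
#'
#' @param geno genotype matrix (individuals x loci, 0/1/2, `NA` missing).
#' @param mafMin minimum minor-allele frequency (loci with MAF strictly below
#'   are removed); default 0.05.
#' @param missMax maximum missing-call fraction (loci strictly above are
#'   removed); default 0.05.
#' @param ldR2Max squared-correlation threshold for pruning; default 0.8.
#' @param window,step sliding-window size and step in loci (defaults 50, 5).
#' @return `list(genotypes, keep, report)`: the filtered matrix, a logical
#'   vector over input loci, and a data.frame counting removals per rule.
#' @export
variantQC <- function(geno, mafMin = 0.05, missMax = 0.05, ldR2Max = 0.8,
                      window = 50L, step = 5L) {
  if (!is.matrix(geno) || nrow(geno) < 1L || ncol(geno) < 1L)
    stop("geno must be a non-empty matrix")
  L <- ncol(geno)
  missFrac <- colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0 # all-missing locus
  badMaf <- maf < mafMin
  badMiss <- missFrac > missMax
  keep <- !(badMaf | badMiss)

  # greedy LD pruning on the surviving loci
  prunedLD <- 0L
  idxKeep <- which(keep)
  if (length(idxKeep) > 1L && ldR2Max < 1) {
    i <- 1L
    while (i <= length(idxKeep)) {
      win <- idxKeep[seq(i, min(i + window - 1L, length(idxKeep)))]
      win <- win[keep[win]]
      if (length(win) > 1L) {
        sub <- geno[, win, drop = FALSE]
        use <- if (anyNA(sub)) "pairwise.complete.obs" else "everything"
        r2 <- suppressWarnings(cor(sub, use = use))^2
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          hits <- which(keep[win] & r2[a, ] > ldR2Max & !is.na(r2[a, ]))
          hits <- hits[hits > a]
          if (length(hits)) {
            keep[win[hits]] <- FALSE
            prunedLD <- prunedLD + length(hits)
          }
        }
      }
      i <- i + step
    }
  }
  report <- data.frame(
    rule = c("maf", "missingness", "ld_prune", "kept"),
    count = c(sum(badMaf), sum(badMiss & !badMaf), prunedLD, sum(keep)))
  list(genotypes = geno[, keep, drop = FALSE], keep = keep, report = report)
}

# per-individual binomial log-likelihood of q given fixed frequencies;
# 0 * log(0) terms are zero so boundary maxima evaluate exactly
.qLogLik <- function(g, f1, f2, q) {
  ok <- !is.na(g)
  g <- g[ok]
  pi <- q * f1[ok] + (1 - q) * f2[ok]
  t1 <- g * log(pi)
  t1[g == 0L] <- 0
  t2 <- (2 - g) * log1p(-pi)
  t2[g == 2L] <- 0
  sum(t1) + sum(t2)
}

#' Supervised two-way admixture estimation
#'
#' With the ancestral allele frequencies known, the ancestry proportion of
#' each individual is the one-dimensional maximizer over `q` in `[0, 1]` of
#' the binomial likelihood with per-locus reference-allele probability
#' `pi_l = q f1_l + (1 - q) f2_l`. Missing genotypes are skipped. Boundary
#' maxima are returned exactly.
#'
#' @param geno genotype matrix (individuals x loci, 0/1/2, `NA` missing).
#' @param freqs an [AncestralFreqs-class] with the same loci (column count
#'   must match).
#' @return An [AdmixtureEstimate-class] with `method = "supervised"`.
#' @export
estimateAdmixtureSupervised <- function(geno, freqs) {
  if (ncol(geno) != nLoci(freqs))
    stop("locus count mismatch between genotypes (", ncol(geno),
         ") and frequencies (", nLoci(freqs), ")")
  f1 <- freqs@f1
  f2 <- freqs@f2
  qhat <- numeric(nrow(geno))
  llTot <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    opt <- optimize(function(q) .qLogLik(g, f1, f2, q),
                    interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    ll <- vapply(cand, function(q) .qLogLik(g, f1, f2, q), numeric(1))
    best <- which.max(ll)
    qhat[i] <- cand[best]
    llTot <- llTot + ll[best]
  }
  new("AdmixtureEstimate", Q = setNames(qhat, rownames(geno)),
      P = cbind(f1 = f1, f2 = f2), logLik = llTot, converged = TRUE,
      method = "supervised")
}

#' Unsupervised two-way admixture estimation by EM
#'
#' Block EM for the K = 2 admixture model: alternating closed-form updates of
#' the individual ancestry proportions and the two populations' allele
#' frequencies for the binomial likelihood with
#' `pi_il = q_i f1_l + (1 - q_i) f2_l`, accelerated by guarded squared
#' extrapolation (SQUAREM): an extrapolated parameter candidate is accepted
#' only when it improves the log-likelihood, otherwise the plain EM step is
#' taken, so the reported log-likelihood trace is non-decreasing.
#' Convergence is declared when the gain per EM step drops below `tol`.
#' Component labels are aligned so that the anchor individuals (known
#' members of population 1) have mean estimated proportion above one half;
#' without anchors the labelling is ambiguous and a deterministic convention
#' (population 1 = majority component) is used with a warning.
#'
#' @param geno genotype matrix (individuals x loci, 0/1/2, `NA` missing).
#' @param K number of ancestral populations; only 2 is supported.
#' @param tol convergence tolerance in log-likelihood units (default 1e-6).
#' @param maxIter maximum EM iterations (default 2000).
#' @param anchors ids (rownames) or indices of individuals known to belong
#'   to population 1, used to resolve label swapping.
#' @param fixedQ optional named numeric vector of ancestry proportions held
#'   fixed during EM (reference-panel individuals, e.g. 0 or 1), as in the
#'   supervised mode of standard admixture software; names must match
#'   rownames of `geno`. Fixed individuals contribute hard allele counts to
#'   the frequency updates, anchoring the components.
#' @param seed optional integer seed for the random initialisation.
#' @return An [AdmixtureEstimate-class] with the estimated `Q`, estimated
#'   frequency matrix `P`, and the log-likelihood trace.
#' @export
estimateAdmixtureUnsupervised <- function(geno, K = 2, tol = 1e-6,
                                          maxIter = 2000L, anchors = NULL,
                                          fixedQ = NULL, seed = NULL) {
  if (K != 2) stop("only K = 2 is supported")
  if (!is.matrix(geno) || nrow(geno) < 2L || ncol(geno) < 2L)
    stop("need at least 2 individuals and 2 loci")
  obs <- !is.na(geno)
  pbar <- colMeans(geno, na.rm = TRUE) / 2
  if (all(pbar %in% c(0, 1) | !is.finite(pbar)))
    stop("all loci are monomorphic; admixture proportions are unidentifiable")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(geno)
  L <- ncol(geno)
  G <- geno
  G[!obs] <- 0L
  E2 <- ifelse(obs, 2L - geno, 0L)
  denomQ <- 2 * rowSums(obs)
  cG <- colSums(G)   # observed reference alleles per locus
  cE <- colSums(E2)  # observed alternate alleles per locus
  const <- sum(lchoose(2, geno[obs]))

  logLik <- function(par) {
    PI <- .clampProb(par$q %o% par$f1 + (1 - par$q) %o% par$f2)
    sum(G * log(PI)) + sum(E2 * log(1 - PI)) + const
  }
  # one block-EM step; also returns the log-likelihood at the input
  emStep <- function(par) {
    PI <- .clampProb(par$q %o% par$f1 + (1 - par$q) %o% par$f2)
    ll <- sum(G * log(PI)) + sum(E2 * log(1 - PI)) + const
    A1 <- G * ((par$q %o% par$f1) / PI)              # E[pop-1 ref alleles]
    B1 <- E2 * ((par$q %o% (1 - par$f1)) / (1 - PI)) # E[pop-1 alt alleles]
    sA <- colSums(A1)
    sB <- colSums(B1)
    list(par = list(
           q = applyFixed((rowSums(A1) + rowSums(B1)) / denomQ),
           f1 = .clampProb(sA / (sA + sB)),
           f2 = .clampProb((cG - sA) / ((cG - sA) + (cE - sB)))),
         ll = ll)
  }
  flatten <- function(p) c(p$q, p$f1, p$f2)
  unflatten <- function(v)
    list(q = applyFixed(pmin(pmax(v[seq_len(n)], 0), 1)),
         f1 = .clampProb(v[n + seq_len(L)]),
         f2 = .clampProb(v[n + L + seq_len(L)]))

  fixedIdx <- integer(0)
  fixedVal <- numeric(0)
  if (!is.null(fixedQ)) {
    fixedIdx <- match(names(fixedQ), rownames(geno))
    if (anyNA(fixedIdx)) stop("fixedQ names not found among individuals")
    if (!.isProb(fixedQ)) stop("fixedQ values must lie in [0, 1]")
    fixedVal <- as.numeric(fixedQ)
  }
  applyFixed <- function(q) {
    if (length(fixedIdx)) q[fixedIdx] <- fixedVal
    q
  }

  par <- list(q = applyFixed(runif(n, 0.2, 0.8)),
              f1 = .clampProb(pbar + runif(L, 0, 0.1)),
              f2 = .clampProb(pbar - runif(L, 0, 0.1)))

  # guarded SQUAREM cycles over pairs of EM steps
  llTrace <- numeric(0)
  converged <- FALSE
  evals <- 0L
  while (evals < maxIter) {
    s1 <- emStep(par)
    s2 <- emStep(s1$par)
    evals <- evals + 2L
    llTrace <- c(llTrace, s1$ll, s2$ll)
    if (s2$ll - s1$ll < tol) { par <- s1$par; converged <- TRUE; break }
    t0 <- flatten(par)
    t1 <- flatten(s1$par)
    t2 <- flatten(s2$par)
    r <- t1 - t0
    v <- (t2 - t1) - r
    vv <- sum(v * v)
    par <- s2$par
    if (vv > 0 && is.finite(vv)) {
      alpha <- min(-1, -sqrt(sum(r * r) / vv))
      cand <- unflatten(t0 - 2 * alpha * r + alpha^2 * v)
      if (logLik(cand) > s2$ll) par <- cand
      evals <- evals + 1L
    }
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations")

  # label alignment
  q <- par$q
  f1 <- par$f1
  f2 <- par$f2
  if (!is.null(anchors)) {
    idx <- if (is.character(anchors)) match(anchors, rownames(geno))
           else as.integer(anchors)
    if (anyNA(idx)) stop("unknown anchor individuals")
    flip <- mean(q[idx]) < 0.5
  } else {
    warning("no anchors supplied; component labels are ambiguous - ",
            "labelling population 1 as the majority component")
    flip <- mean(q) < 0.5
  }
  if (flip) {
    q <- 1 - q
    tmp <- f1; f1 <- f2; f2 <- tmp
  }
  new("AdmixtureEstimate", Q = setNames(pmin(pmax(q, 0), 1), rownames(geno)),
      P = cbind(f1 = f1, f2 = f2), logLik = llTrace, converged = converged,
      method = "unsupervised")
}
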