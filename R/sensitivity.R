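## Simulation-based sensitivity analyses: ancestry-by-environment
## interaction, participation bias, and ancestry-estimation error.
## All three draw replicate phenotypes over a fixed sibling-pair population
## (its ancestry proportions, ages, sexes and family structure), estimate
## deltaY (model 1a) and/or deltaG (model 1b) per replicate, and summarise
## bias against the simulated truth.

#' Sibling-pair table for sensitivity simulations
#'
#' Enumerates all within-family offspring pairs of a simulated pedigree and
#' (by default) applies the admixed-pair filter with the simulation-truth
#' ancestry proportions, returning the per-pair quantities the sensitivity
#' simulations condition on.
#'
#' @param pop an [AdmixPedigree-class].
#' @param q optional named ancestry proportions (defaults to truth).
#' @param filter apply [filterAdmixedPairs()] and keep retained pairs only.
#' @param ... passed to [filterAdmixedPairs()].
#' @return data.frame with columns `id1`, `id2`, `fid`, `q1`, `q2`, `age1`,
#'   `age2`, `sex1`, `sex2`, `motherQ`.
#' @export
sibPairTable <- function(pop, q = NULL, filter = TRUE, ...) {
  ped <- pop@ped
  if (is.null(q)) q <- setNames(ped$qTrue, ped$id)
  off <- ped[ped$role == "offspring", ]
  pairs <- do.call(rbind, lapply(split(off$id, off$fid), function(ids) {
    if (length(ids) < 2L) return(NULL)
    cmb <- utils::combn(sort(ids), 2L)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  if (filter) {
    flt <- filterAdmixedPairs(pairs, q, parentQ = parentAncestry(pop, q), ...)
    pairs <- flt$retained[, c("id1", "id2")]
  }
  i1 <- match(pairs$id1, ped$id)
  i2 <- match(pairs$id2, ped$id)
  data.frame(id1 = pairs$id1, id2 = pairs$id2, fid = ped$fid[i1],
             q1 = unname(q[pairs$id1]), q2 = unname(q[pairs$id2]),
             age1 = ped$age[i1], age2 = ped$age[i2],
             sex1 = ped$sex[i1], sex2 = ped$sex[i2],
             motherQ = unname(q[ped$mother[i1]]),
             stringsAsFactors = FALSE)
}

# individual-level frame + fixed design matrices and projection rows for the
# deltaY (model 1a) and deltaG (model 1b) slopes
.sensPrep <- function(sibs) {
  ids <- unique(c(sibs$id1, sibs$id2))
  pick <- function(col1, col2) {
    v <- setNames(rep(NA_real_, length(ids)), ids)
    v[sibs$id1] <- sibs[[col1]]
    v[sibs$id2] <- sibs[[col2]]
    unname(v)
  }
  fid <- setNames(rep(NA_character_, length(ids)), ids)
  fid[sibs$id1] <- sibs$fid
  fid[sibs$id2] <- sibs$fid
  ind <- data.frame(id = ids, fid = unname(fid), q = pick("q1", "q2"),
                    age = pick("age1", "age2"), sex = pick("sex1", "sex2"),
                    stringsAsFactors = FALSE)
  ind$qbar <- ave(ind$q, ind$fid)
  i1 <- match(sibs$id1, ind$id)
  i2 <- match(sibs$id2, ind$id)
  X1a <- cbind(1, ind$q, ind$age, ind$sex)
  X1b <- cbind(1, ind$q[i1] - ind$q[i2], ind$age[i1] - ind$age[i2],
               ind$age[i1], ind$sex[i1] - ind$sex[i2], ind$sex[i1])
  proj <- function(X, row) solve(crossprod(X), t(X))[row, ]
  list(ind = ind, i1 = i1, i2 = i2, X1a = X1a, X1b = X1b,
       v1a = proj(X1a, 2L), v1b = proj(X1b, 2L))
}

.gridSummary <- function(param, value, mode, estimator, est, truth) {
  data.frame(param = param, value = value, mode = mode,
             estimator = estimator, mean = mean(est), sd = sd(est),
             bias = mean(est) - truth, mcse = sd(est) / sqrt(length(est)),
             truth = truth, nReps = length(est), stringsAsFactors = FALSE)
}

#' Ancestry-by-environment interaction simulation
#'
#' Per replicate, sibling phenotypes are drawn as
#' `y ~ N(Q*deltaG + eAnc*Qbar, sigma^2)` (family mode, environment tied to
#' the family's mean sibling ancestry) or `y ~ N(Q*deltaG + eAnc*Q, sigma^2)`
#' (individual mode), deltaY is estimated by model 1a and deltaG by model 1b,
#' and the grid of `eAnc` values is summarised as mean, sd and bias against
#' the true deltaG. Family-level interactions cancel in the within-pair
#' differencing, so the deltaG estimator stays centred on deltaG while the
#' deltaY estimator is pulled by `eAnc`; an individual-level interaction
#' shifts the deltaG estimator by exactly `eAnc`.
#'
#' @param sibs sibling-pair table from [sibPairTable()].
#' @param mode `"family"` or `"individual"`.
#' @param eAncGrid interaction coefficients to simulate (default
#'   `c(-2, -1, -0.5, 0, 0.5, 1, 2)`).
#' @param nReps replicates per grid value (default 10000).
#' @param deltaG,sigma generative parameters (defaults 1, 1).
#' @param seed optional integer seed.
#' @return data.frame, one row per grid value x estimator: `param`, `value`,
#'   `mode`, `estimator`, `mean`, `sd`, `bias`, `mcse`, `truth`, `nReps`.
#' @export
simEnvInteraction <- function(sibs, mode = c("family", "individual"),
                              eAncGrid = c(-2, -1, -0.5, 0, 0.5, 1, 2),
                              nReps = 10000L, deltaG = 1, sigma = 1,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pr <- .sensPrep(sibs)
  n <- nrow(pr$ind)
  out <- list()
  for (e in eAncGrid) {
    env <- if (mode == "family") e * pr$ind$qbar else e * pr$ind$q
    mu <- pr$ind$q * deltaG + env
    bY <- bG <- numeric(nReps)
    for (r in seq_len(nReps)) {
      y <- mu + rnorm(n, 0, sigma)
      bY[r] <- sum(pr$v1a * y)
      bG[r] <- sum(pr$v1b * (y[pr$i1] - y[pr$i2]))
    }
    out[[length(out) + 1L]] <-
      rbind(.gridSummary("eAnc", e, mode, "deltaY_1a", bY, deltaG),
            .gridSummary("eAnc", e, mode, "deltaG_1b", bG, deltaG))
  }
  do.call(rbind, out)
}

#' Participation-bias simulation
#'
#' Phenotypes are drawn as `y ~ N(Q*deltaG, sigma^2)`. In `"self"` mode an
#' individual whose phenotype exceeds the threshold (a quantile of the
#' replicate's simulated phenotypes) fails to participate with probability
#' `dropoutProb`; to keep the sample size fixed, each non-participant's
#' phenotype is redrawn from its ancestry-based distribution until it falls
#' below the threshold (rejection sampling), and both estimators are then
#' computed on the full sample. This truncates the upper phenotype tail, so
#' the absolute deltaY estimate shrinks while the within-pair deltaG
#' estimator is largely unaffected. In `"mother"` mode a phenotype is
#' simulated for each family's mother from her ancestry proportion; families
#' whose mother is flagged as a non-participant are excluded from that
#' replicate's estimation (no replacement), probing ancestry-dependent
#' selection of whole sibships.
#'
#' @param sibs sibling-pair table from [sibPairTable()] (`motherQ` required
#'   for mother mode).
#' @param thresholdQuantiles phenotype quantiles in (0, 1) defining "high"
#'   (default `c(0.5, 0.7, 0.9)`).
#' @param dropoutProb non-participation probability above threshold
#'   (default 0.2).
#' @param mode `"self"` or `"mother"`.
#' @param nReps replicates per threshold (default 1000).
#' @param deltaG,sigma generative parameters.
#' @param seed optional integer seed.
#' @return data.frame as in [simEnvInteraction()] with
#'   `param = "thresholdQuantile"`.
#' @export
simParticipationBias <- function(sibs, thresholdQuantiles = c(0.5, 0.7, 0.9),
                                 dropoutProb = 0.2,
                                 mode = c("self", "mother"), nReps = 1000L,
                                 deltaG = 1, sigma = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (any(thresholdQuantiles <= 0) || any(thresholdQuantiles >= 1))
    stop("threshold quantiles must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  pr <- .sensPrep(sibs)
  n <- nrow(pr$ind)
  mu <- pr$ind$q * deltaG
  fams <- unique(sibs$fid)
  famQm <- sibs$motherQ[match(fams, sibs$fid)]
  out <- list()
  for (tq in thresholdQuantiles) {
    bY <- bG <- numeric(nReps)
    for (r in seq_len(nReps)) {
      y <- mu + rnorm(n, 0, sigma)
      if (mode == "self") {
        thr <- quantile(y, tq)
        redo <- y > thr & runif(n) < dropoutProb
        while (any(redo)) {
          y[redo] <- mu[redo] + rnorm(sum(redo), 0, sigma)
          redo <- redo & y > thr
        }
        bY[r] <- sum(pr$v1a * y)
        bG[r] <- sum(pr$v1b * (y[pr$i1] - y[pr$i2]))
      } else {
        if (anyNA(famQm)) stop("motherQ required for mother mode")
        ym <- famQm * deltaG + rnorm(length(fams), 0, sigma)
        thr <- quantile(ym, tq)
        dropFam <- fams[ym > thr & runif(length(fams)) < dropoutProb]
        keepPair <- !(sibs$fid %in% dropFam)
        keepInd <- !(pr$ind$fid %in% dropFam)
        if (sum(keepPair) < 7L || sum(keepInd) < 4L) {
          bY[r] <- NA; bG[r] <- NA; next
        }
        bY[r] <- .lm.fit(pr$X1a[keepInd, , drop = FALSE],
                         y[keepInd])$coefficients[2L]
        dY <- y[pr$i1] - y[pr$i2]
        bG[r] <- .lm.fit(pr$X1b[keepPair, , drop = FALSE],
                         dY[keepPair])$coefficients[2L]
      }
    }
    bY <- bY[!is.na(bY)]; bG <- bG[!is.na(bG)]
    out[[length(out) + 1L]] <-
      rbind(.gridSummary("thresholdQuantile", tq, mode, "deltaY_1a", bY,
                         deltaG),
            .gridSummary("thresholdQuantile", tq, mode, "deltaG_1b", bG,
                         deltaG))
  }
  do.call(rbind, out)
}

#' Ancestry-estimation-error simulation
#'
#' Phenotypes are drawn from the true ancestry proportions as
#' `y ~ N(Q*deltaG, sigma^2)`, but independent errors
#' `eps ~ N(0, sigmaQerror^2)` are added to each individual's Q (or directly
#' to each pair's ancestry difference, with variance `2*sigmaQerror^2`, in
#' `"pair"` mode) before estimating deltaG with model 1b. Measurement error in the predictor attenuates the
#' slope towards zero by the classical errors-in-variables factor
#' `Var(dQ) / (Var(dQ) + 2*sigmaQerror^2)`; the larger the error, the larger
#' the downward bias. The induced mean absolute error of the pair ancestry
#' difference is reported per grid point for comparison with the F1-based
#' error estimator.
#'
#' @param sibs sibling-pair table from [sibPairTable()].
#' @param sigmaGrid standard deviations of the Q error; default 100 values
#'   drawn uniformly in `[0, 0.05]`.
#' @param nReps replicates per grid value (default 10000, i.e. one million
#'   total at the default grid; scalable).
#' @param deltaG,sigma generative parameters.
#' @param errorLevel `"individual"` (independent error per individual) or
#'   `"pair"` (one error on the pair difference, variance `2*sigma^2`).
#' @param seed optional integer seed.
#' @return data.frame, one row per grid value: `sigmaQerror`, `mean`, `sd`,
#'   `bias`, `mcse`, `attenuationEmp`, `attenuationPred`, `meanAbsDqError`,
#'   `nReps`.
#' @export
simQError <- function(sibs, sigmaGrid = NULL, nReps = 10000L, deltaG = 1,
                      sigma = 1, errorLevel = c("individual", "pair"),
                      seed = NULL) {
  errorLevel <- match.arg(errorLevel)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigmaGrid)) sigmaGrid <- sort(runif(100L, 0, 0.05))
  if (any(sigmaGrid < 0)) stop("sigmaGrid values must be >= 0")
  pr <- .sensPrep(sibs)
  n <- nrow(pr$ind)
  nPairs <- nrow(sibs)
  mu <- pr$ind$q * deltaG
  dQtrue <- pr$ind$q[pr$i1] - pr$ind$q[pr$i2]
  vDQ <- var(dQtrue)
  X <- pr$X1b
  out <- vector("list", length(sigmaGrid))
  for (gi in seq_along(sigmaGrid)) {
    s <- sigmaGrid[gi]
    b <- numeric(nReps)
    absErr <- numeric(nReps)
    for (r in seq_len(nReps)) {
      y <- mu + rnorm(n, 0, sigma)
      dY <- y[pr$i1] - y[pr$i2]
      dEps <- if (errorLevel == "individual") {
        eps <- rnorm(n, 0, s)
        eps[pr$i1] - eps[pr$i2]
      } else rnorm(nPairs, 0, s * sqrt(2))
      X[, 2L] <- dQtrue + dEps
      b[r] <- .lm.fit(X, dY)$coefficients[2L]
      absErr[r] <- mean(abs(dEps))
    }
    out[[gi]] <- data.frame(sigmaQerror = s, mean = mean(b), sd = sd(b),
                            bias = mean(b) - deltaG,
                            mcse = sd(b) / sqrt(nReps),
                            attenuationEmp = mean(b) / deltaG,
                            attenuationPred = vDQ / (vDQ + 2 * s^2),
                            meanAbsDqError = mean(absErr), nReps = nReps)
  }
  do.call(rbind, out)
}
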