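## The three regression estimators of the design, the rank-based
## inverse-normal transform, and FDR correction.
##
## Model 1a (individual level):  Y_i  = a + bY*Q_i + bA*Age_i + bS*Sex_i + e
## Model 1b (pair differences):  dy_j = a + bG*dQ_j + b*dAge_j + b*Age_j1
##                                        + b*dSex_j + b*Sex_j1 + e
## Model 2  (mixed):  y_ij = a + bW*(Q_ij - Qbar_j) + bB*Qbar_j
##                             + b*Age_ij + b*Sex_ij + gamma_j + e_ij
## bY and bB estimate the difference in mean phenotype value (deltaY);
## bG and bW estimate the difference in mean genotypic value (deltaG).
## Effects are reported per percentage point of ancestry (estimate / 100
## when Q is a proportion).

#' Rank-based inverse-normal (quantile) transform
#'
#' Maps values to normal quantiles via `qnorm((r - c) / (n - 2c + 1))` with
#' ranks `r` (average rank for ties, so tied values map to equal z-scores)
#' and the Blom offset `c = 3/8`. Missing values propagate.
#'
#' @param x numeric vector (at least 3 non-missing, not all identical).
#' @param offset rank offset `c`; default `3/8` (Blom).
#' @return numeric vector of transformed values.
#' @examples
#' quantileTransform(c(1, 2, 3)) # approx -0.8694, 0, 0.8694
#' @export
quantileTransform <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 non-missing values")
  if (length(unique(x[ok])) == 1L)
    stop("all values identical; quantile transform undefined")
  r <- rank(x[ok], ties.method = "average")
  z <- x
  z[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  z
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of p-values, returned in input order. Thin, validated
#' wrapper around `p.adjust(..., method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone in the sorted p, idempotent).
#' @export
fdrAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# rank check with named collinear columns
.checkFullRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

.effectRow <- function(model, term, fit, coefName, n, scale) {
  sm <- summary(fit)$coefficients
  est <- sm[coefName, 1]
  se <- sm[coefName, 2]
  data.frame(model = model, term = term, estimate = est,
             estimatePerPct = est / 100, se = se, sePerPct = se / 100,
             p = sm[coefName, ncol(sm)], n = n, scale = scale,
             stringsAsFactors = FALSE)
}

#' Fit model 1a: phenotype difference between ancestries
#'
#' Ordinary least squares of the phenotype on the ancestry proportion with
#' age and sex as covariates. The ancestry slope estimates the difference in
#' mean phenotype value between the two ancestral populations (deltaY),
#' including any environmental component correlated with ancestry.
#'
#' @param data data.frame with the columns named by `pheno`, `qCol`,
#'   `ageCol`, `sexCol`.
#' @param pheno,qCol,ageCol,sexCol column names (defaults `"y"`, `"q"`,
#'   `"age"`, `"sex"`).
#' @param scale tag recorded in the output (`"raw"` or `"transformed"`);
#'   purely descriptive, no transformation is applied here.
#' @return one-row data.frame: `model`, `term`, `estimate` (per unit
#'   ancestry), `estimatePerPct` (per percentage point), `se`, `sePerPct`,
#'   `p`, `n`, `scale`.
#' @export
fitModel1a <- function(data, pheno = "y", qCol = "q", ageCol = "age",
                       sexCol = "sex", scale = "raw") {
  d <- data.frame(y = data[[pheno]], q = data[[qCol]],
                  age = data[[ageCol]], sex = data[[sexCol]])
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3L) stop("need at least 3 complete cases")
  X <- cbind(`(Intercept)` = 1, q = d$q, age = d$age, sex = d$sex)
  .checkFullRank(X)
  fit <- lm(y ~ q + age + sex, data = d)
  .effectRow("1a", "deltaY", fit, "q", nrow(d), scale)
}

#' Build the sibling-pair difference table
#'
#' For each sibling pair, computes the phenotype and ancestry differences
#' and the covariates of model 1b. The sign convention is fixed by ordering
#' each pair lexicographically by individual id (sibling 1 = smaller id);
#' the model-1b slope is invariant to this choice.
#'
#' @param pairs data.frame with columns `id1`, `id2` (retained admixed
#'   pairs); an optional `fid`/`sibship` column is carried through.
#' @param data per-individual data.frame with columns `id`, `q`, `age`,
#'   `sex` and the phenotype column `pheno`.
#' @param pheno phenotype column name (default `"y"`).
#' @param transform if `TRUE`, apply [quantileTransform()] to the phenotype
#'   across individuals before differencing.
#' @return data.frame with `id1`, `id2`, `fid`, `dY`, `dQ`, `dAge`, `age1`,
#'   `dSex`, `sex1`.
#' @export
sibPairDiffs <- function(pairs, data, pheno = "y", transform = FALSE) {
  stopifnot(all(c("id1", "id2") %in% names(pairs)))
  y <- data[[pheno]]
  if (transform) y <- quantileTransform(y)
  rowOf <- match
  famCol <- intersect(c("fid", "sibship"), names(pairs))[1]
  swap <- pairs$id1 > pairs$id2
  a <- ifelse(swap, pairs$id2, pairs$id1)
  b <- ifelse(swap, pairs$id1, pairs$id2)
  i1 <- rowOf(a, data$id)
  i2 <- rowOf(b, data$id)
  if (anyNA(i1) || anyNA(i2)) stop("pair member missing from data")
  data.frame(id1 = a, id2 = b,
             fid = if (!is.na(famCol)) pairs[[famCol]] else NA_character_,
             dY = y[i1] - y[i2],
             dQ = data$q[i1] - data$q[i2],
             dAge = data$age[i1] - data$age[i2],
             age1 = data$age[i1],
             dSex = data$sex[i1] - data$sex[i2],
             sex1 = data$sex[i1],
             stringsAsFactors = FALSE)
}

#' Fit model 1b: genotypic-value difference from sibling-pair differences
#'
#' Ordinary least squares of the within-pair phenotype difference on the
#' within-pair ancestry difference, with the age difference, first sibling's
#' age, sex difference and first sibling's sex as covariates. Because family
#' environment is shared within a pair, the ancestry-difference slope
#' estimates the difference in mean genotypic value (deltaG) free of
#' family-level environmental confounding.
#'
#' @param diffs pair-difference table from [sibPairDiffs()].
#' @param scale descriptive tag (`"raw"` or `"transformed"`).
#' @return one-row data.frame as in [fitModel1a()], `term = "deltaG"`.
#' @export
fitModel1b <- function(diffs, scale = "raw") {
  d <- diffs[complete.cases(diffs[, c("dY", "dQ", "dAge", "age1", "dSex",
                                      "sex1")]), ]
  if (nrow(d) < 7L) stop("need at least 7 complete pairs")
  if (all(d$dQ == 0))
    stop("all ancestry differences are zero; deltaG is unidentifiable")
  X <- cbind(`(Intercept)` = 1, dQ = d$dQ, dAge = d$dAge, age1 = d$age1,
             dSex = d$dSex, sex1 = d$sex1)
  .checkFullRank(X)
  fit <- lm(dY ~ dQ + dAge + age1 + dSex + sex1, data = d)
  .effectRow("1b", "deltaG", fit, "dQ", nrow(d), scale)
}

#' Fit model 2: within/between-family mixed model
#'
#' Linear mixed model with a family random intercept, decomposing the
#' ancestry effect into a within-family contrast `Q_ij - Qbar_j` (slope
#' estimates deltaG) and the family mean `Qbar_j` (slope estimates deltaY),
#' with age and sex as covariates. Fitted by REML via `lmerTest::lmer`
#' (Satterthwaite p-values); a singular random-effect variance triggers a
#' warning and a fall back to the fixed-effects fit with `sigma_gamma = 0`.
#'
#' @param data per-individual data.frame with columns `id`, `fid`, `q`,
#'   `age`, `sex` and the phenotype column `pheno`.
#' @param pheno phenotype column name (default `"y"`).
#' @param scale descriptive tag (`"raw"` or `"transformed"`).
#' @return two-row data.frame: terms `"deltaG_within"` and
#'   `"deltaY_between"`.
#' @export
fitModel2 <- function(data, pheno = "y", scale = "raw") {
  d <- data.frame(y = data[[pheno]], q = data$q, age = data$age,
                  sex = data$sex, fid = data$fid)
  d <- d[complete.cases(d), ]
  sizes <- table(d$fid)
  if (sum(sizes >= 2L) < 2L)
    stop("need at least 2 families with at least 2 siblings each")
  d$qbar <- ave(d$q, d$fid)
  d$qc <- d$q - d$qbar
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(y ~ qc + qbar + age + sex + (1 | fid),
                                    data = d, REML = TRUE)),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  if (lme4::isSingular(fit)) {
    warning("singular family random-effect variance; refitting with ",
            "sigma_gamma = 0")
    flm <- lm(y ~ qc + qbar + age + sex, data = d)
    out <- rbind(.effectRow("2", "deltaG_within", flm, "qc", nrow(d), scale),
                 .effectRow("2", "deltaY_between", flm, "qbar", nrow(d),
                            scale))
    return(out)
  }
  rbind(.effectRow("2", "deltaG_within", fit, "qc", nrow(d), scale),
        .effectRow("2", "deltaY_between", fit, "qbar", nrow(d), scale))
}

#' Estimate ancestry differences across phenotypes
#'
#' Runs models 1a, 1b and 2 for each phenotype column, on the raw scale (for
#' effect sizes) and on the quantile-transformed scale (for p-values,
#' transforming individual values before pair differencing), and applies FDR
#' correction across phenotypes within each model. This reproduces the
#' dual-scale reporting convention of admixture-cohort tables: effect and SE
#' per percentage point of ancestry on the raw scale, p-value from the
#' transformed scale.
#'
#' @param data per-individual data.frame with columns `id`, `fid`, `q`,
#'   `age`, `sex` and one column per phenotype.
#' @param pairs retained sibling-pair table with columns `id1`, `id2`.
#' @param phenotypes character vector of phenotype column names.
#' @param models subset of `c("1a", "1b", "2")`.
#' @param include optional named list of per-phenotype inclusion masks
#'   (logical vectors over rows of `data`); excluded individuals' values are
#'   treated as missing for that phenotype. This is how cohort-specific
#'   exclusions (e.g. treated individuals for metabolic measures) are
#'   declared rather than hard-coded.
#' @return list with `summary` (one row per phenotype x model: effect and SE
#'   per percentage point from the raw scale, p and FDR-adjusted p from the
#'   transformed scale) and `full` (all fitted rows, both scales).
#' @export
estimateEffects <- function(data, pairs, phenotypes,
                            models = c("1a", "1b", "2"), include = NULL) {
  full <- list()
  for (ph in phenotypes) {
    for (sc in c("raw", "transformed")) {
      dat <- data
      if (!is.null(include[[ph]])) dat[[ph]][!include[[ph]]] <- NA
      if (sc == "transformed") dat[[ph]] <- quantileTransform(dat[[ph]])
      if ("1a" %in% models) {
        r <- fitModel1a(dat, pheno = ph, scale = sc)
        r$phenotype <- ph
        full[[length(full) + 1L]] <- r
      }
      if ("1b" %in% models) {
        diffs <- sibPairDiffs(pairs, dat, pheno = ph)
        r <- fitModel1b(diffs, scale = sc)
        r$phenotype <- ph
        full[[length(full) + 1L]] <- r
      }
      if ("2" %in% models) {
        r <- fitModel2(dat, pheno = ph, scale = sc)
        r$phenotype <- ph
        full[[length(full) + 1L]] <- r
      }
    }
  }
  full <- do.call(rbind, full)
  raw <- full[full$scale == "raw", ]
  trn <- full[full$scale == "transformed", ]
  key <- paste(raw$phenotype, raw$model, raw$term)
  stopifnot(identical(key, paste(trn$phenotype, trn$model, trn$term)))
  summary <- data.frame(phenotype = raw$phenotype, model = raw$model,
                        term = raw$term, n = raw$n,
                        effectPerPct = raw$estimatePerPct,
                        sePerPct = raw$sePerPct, p = trn$p,
                        stringsAsFactors = FALSE)
  summary$fdrP <- NA_real_
  for (grp in split(seq_len(nrow(summary)),
                    paste(summary$model, summary$term)))
    summary$fdrP[grp] <- fdrAdjust(summary$p[grp])
  list(summary = summary, full = full)
}
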