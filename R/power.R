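# Hanley-McNeil sample-size calculation for a single ROC AUC.

#' Hanley-McNeil variance of an estimated AUC
#'
#' `V = [A(1-A) + (nPos-1)(Q1 - A^2) + (nNeg-1)(Q2 - A^2)] / (nPos * nNeg)`
#' with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc the AUC `A` (in `(0, 1)`)
#' @param nPos,nNeg group sizes (each >= 1)
#' @return the variance of the AUC estimate
#' @examples
#' hanleyMcneilVariance(0.9, 15, 285)
#' @export
hanleyMcneilVariance <- function(auc, nPos, nNeg) {
  if (!is.finite(auc) || auc <= 0 || auc >= 1) stop("auc must lie in (0, 1)")
  if (nPos < 1 || nNeg < 1) stop("group sizes must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) + (nNeg - 1) * (q2 - auc^2)) /
    (nPos * nNeg)
}

.achievedPower <- function(aucAlt, aucNull, nPos, nNeg, alpha) {
  v0 <- hanleyMcneilVariance(aucNull, nPos, nNeg)
  v1 <- hanleyMcneilVariance(aucAlt, nPos, nNeg)
  stats::pnorm((aucAlt - aucNull - stats::qnorm(1 - alpha / 2) * sqrt(v0)) / sqrt(v1))
}

#' Sample size to detect an AUC against a null value
#'
#' Finds the smallest number of positive cases such that a two-sided level
#' `alpha` test of `H0: AUC = aucNull` reaches the target power at
#' `AUC = aucAlt`, with the negative group size tied to the positive one by
#' the prevalence of the rarer (positive) class:
#' `nNeg = round(nPos * (1 - prevalence) / prevalence)`. Power is the normal
#' approximation `pnorm((A1 - A0 - z * sqrt(V0)) / sqrt(V1))` with
#' Hanley-McNeil variances at the respective AUCs.
#'
#' With the defaults (detect 0.9 against 0.7, alpha 0.05, power 0.8,
#' prevalence 5%), the minimum design is 15 positives + 285 negatives = 300
#' cases.
#'
#' @param aucAlt AUC under the alternative
#' @param aucNull AUC under the null (must be below `aucAlt`)
#' @param alpha two-sided type-I error rate
#' @param power target power (1 - beta)
#' @param prevalence fraction of positive (rarer-class) cases, in `(0, 0.5)`
#' @param maxNPos search bound on the positive group size
#' @return list with `nPos`, `nNeg`, `nTotal` and the `achievedPower` at the
#'   returned sizes
#' @examples
#' aucSampleSize(0.9, 0.7, prevalence = 0.05)$nTotal  # 300
#' @export
aucSampleSize <- function(aucAlt, aucNull, alpha = 0.05, power = 0.8,
                          prevalence = 0.05, maxNPos = 10000L) {
  if (aucAlt <= aucNull)
    stop("aucAlt must exceed aucNull: no finite sample size otherwise")
  if (aucNull < 0.5 || aucAlt >= 1) stop("need 0.5 <= aucNull < aucAlt < 1")
  if (prevalence <= 0 || prevalence >= 0.5)
    stop("prevalence must lie in (0, 0.5): the positive class is the rarer one")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  ratio <- (1 - prevalence) / prevalence
  for (nPos in seq_len(maxNPos)) {
    nNeg <- round(nPos * ratio)
    if (nNeg < 1L) next
    p <- .achievedPower(aucAlt, aucNull, nPos, nNeg, alpha)
    if (p >= power) {
      return(list(nPos = nPos, nNeg = as.integer(nNeg),
                  nTotal = as.integer(nPos + nNeg), achievedPower = p))
    }
  }
  stop("no sample size up to maxNPos reaches the target power; ",
       "the alternative may be too close to the null")
}
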