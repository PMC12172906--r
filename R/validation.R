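# Validation statistics: transitivity (one-step vs multi-step TLVC),
# accuracy against manual lesion volume change, ICC for absolute
# agreement, atrophy compounding, and Spearman factor correlations.

#' Sum yearly TLVC measurements into a multi-step TLVC
#'
#' The indirect multi-step TLVC over an interval is the arithmetic sum of
#' the consecutive one-year TLVCs.
#'
#' @param yearly numeric vector of yearly TLVCs (mL).
#' @return the multi-step TLVC (mL).
#' @export
multiStepTLVC <- function(yearly) {
  if (!length(yearly)) stop("empty list of yearly TLVCs")
  sum(yearly)
}

#' Compound yearly percentage volume changes over a longer interval
#'
#' Percentage brain or ventricular volume change (PBVC/PVVC) over
#' multi-year intervals compounds multiplicatively:
#' `((1 + p1/100) * ... * (1 + pN/100) - 1) * 100`.
#'
#' @param yearlyPct numeric vector of yearly percentage changes (each
#'   > -100).
#' @return the compounded percentage change.
#' @export
compoundVolumeChange <- function(yearlyPct) {
  if (any(yearlyPct <= -100))
    stop("percentage changes must be > -100")
  (prod(1 + yearlyPct / 100) - 1) * 100
}

#' Expected yearly lesion volume change for a given lesion volume
#'
#' The yearly change in T2 lesion volume in untreated early MS is about
#' 10% of the lesion volume; this helper scales a (median) lesion volume
#' by that annual rate to give the change the method must be able to
#' resolve.
#'
#' @param lesionVolume lesion volume in mL (e.g. a cohort median).
#' @param annualRate relative yearly change (default 0.10).
#' @return expected yearly lesion volume change (mL).
#' @export
yearlyLesionVolumeChangeEstimate <- function(lesionVolume,
                                             annualRate = 0.10) {
  lesionVolume * annualRate
}

#' Intraclass correlation for absolute agreement, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (McGraw and Wong's ICC(A,1)) between two measurement methods, with an
#' F-distribution-based 95% confidence interval.  Absolute agreement
#' penalizes systematic offsets between the methods, unlike the
#' consistency ICC.
#'
#' @param x,y paired measurements (equal length, no missing values,
#'   n >= 3).
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`, `n` and the ANOVA mean
#'   squares (`msr`, `msc`, `mse`).
#' @export
iccAbsoluteAgreement <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs required")
  k <- 2
  X <- cbind(x, y)
  grand <- mean(X)
  rowM <- rowMeans(X); colM <- colMeans(X)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((X - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0 || (msr <= mse && msc <= mse && msr == 0))
    stop("degenerate-data error: no between-subject variance")
  est <- (msr - mse) / denom
  alpha <- 1 - conf
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) v <- (n - 1) * (k - 1)
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(estimate = est, lower = max(-1, lower), upper = min(1, upper),
       n = n, msr = msr, msc = msc, mse = mse)
}

.spearmanTable <- function(diffs, factors) {
  if (is.null(factors) || !ncol(factors)) return(NULL)
  do.call(rbind, lapply(names(factors), function(nm) {
    f <- factors[[nm]]
    ct <- suppressWarnings(
      cor.test(diffs, f, method = "spearman",
               exact = length(diffs) < 20 && !anyDuplicated(diffs) &&
                 !anyDuplicated(f)))
    data.frame(factor = nm, rs = unname(ct$estimate), p = ct$p.value)
  }))
}

#' Transitivity (reproducibility) report
#'
#' Compares the direct one-step TLVC of an interval with the indirect
#' multi-step TLVC (sum of the consecutive yearly TLVCs): ICC for absolute
#' agreement, mean and SD of the transitivity error
#' (multi-step minus one-step), and Spearman correlations of the
#' *absolute* transitivity error against supplied factors (atrophy, lesion
#' volume, lesion volume change).
#'
#' @param measurements data.frame with numeric columns `tlvcOneStep` and
#'   `tlvcMultiStep` (mL), one row per subject-interval.
#' @param factors optional data.frame of factor columns (same rows).
#' @param alpha significance cut-off recorded in the report (default 0.05).
#' @return list with `icc`, `meanDifference`, `sdOfDifference`, `n`,
#'   `spearman` (data.frame or NULL) and `alpha`.
#' @export
transitivityReport <- function(measurements, factors = NULL, alpha = 0.05) {
  one <- measurements$tlvcOneStep
  multi <- measurements$tlvcMultiStep
  if (is.null(one) || is.null(multi))
    stop("measurements must have tlvcOneStep and tlvcMultiStep columns")
  d <- multi - one
  list(icc = iccAbsoluteAgreement(one, multi),
       meanDifference = mean(d),
       sdOfDifference = sd(d),
       n = length(d),
       spearman = .spearmanTable(abs(d), factors),
       alpha = alpha)
}

#' Accuracy report against manual lesion volume change
#'
#' Compares the one-step semi-automated TLVC with the manually measured
#' lesion volume change (LVC): ICC for absolute agreement, mean difference
#' with a two-sided paired t-test, and Spearman correlations of the
#' (signed) difference against supplied factors.  With a degenerate
#' (zero-variance) difference the t-test p-value is NA and
#' `degenerateVariance` is TRUE.
#'
#' @param measurements data.frame with numeric columns `tlvcOneStep` and
#'   `manualLvc` (mL).
#' @inheritParams transitivityReport
#' @return list with `icc`, `meanDifference`, `sdOfDifference`,
#'   `pairedTP`, `degenerateVariance`, `n`, `spearman` and `alpha`.
#' @export
accuracyReport <- function(measurements, factors = NULL, alpha = 0.05) {
  one <- measurements$tlvcOneStep
  man <- measurements$manualLvc
  if (is.null(one) || is.null(man))
    stop("measurements must have tlvcOneStep and manualLvc columns")
  d <- one - man
  degenerate <- sd(d) < 1e-10 * max(1, abs(mean(d)))
  p <- if (degenerate) NA_real_ else t.test(one, man, paired = TRUE)$p.value
  list(icc = iccAbsoluteAgreement(one, man),
       meanDifference = mean(d),
       sdOfDifference = sd(d),
       pairedTP = p,
       degenerateVariance = degenerate,
       n = length(d),
       spearman = .spearmanTable(d, factors),
       alpha = alpha)
}
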