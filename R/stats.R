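# VOI summaries and paired comparisons between ADC calculation variants.

#' Summarise voxelwise ADC within a volume of interest
#'
#' Pools the ADC values of the mask voxels (intersected with the map's
#' valid-fit mask) and reports mean, median, sample standard deviation
#' (n - 1) and the nonparametric skew `(mean - median) / sd` -- a bounded,
#' dimensionless asymmetry measure (0 when sd = 0).
#'
#' @param adc an [ADCMap-class], or a numeric vector of values.
#' @param mask logical 3D array (ignored when `adc` is a vector).
#' @return a [VOISummary-class].
#' @examples
#' as.data.frame(voiSummary(c(1, 2, 3, 4, 10)))
#' @export
voiSummary <- function(adc, mask = NULL) {
  if (is(adc, "ADCMap")) {
    stopifnot(!is.null(mask), identical(dim(mask), dim(adcValues(adc))))
    sel <- mask & validMask(adc)
    if (!any(sel)) stop("mask and valid-fit mask have empty intersection")
    v <- adcValues(adc)[sel]
  } else {
    v <- as.numeric(adc)
    if (length(v) == 0L) stop("no values to summarise")
  }
  m <- mean(v)
  md <- stats::median(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  skew <- if (s > 0) (m - md) / s else 0
  new("VOISummary", mean = m, median = md, sd = s, npSkew = skew,
      n = length(v))
}

#' Relative difference between two ADC values
#'
#' `(adc1 - adc2) / adcReference`; the standard way to express agreement
#' between two ADC estimates against a calibrated or reference value.
#'
#' @param adc1,adc2 numeric values (um^2/s).
#' @param adcReference nonzero reference value (um^2/s).
#' @return signed fraction (multiply by 100 for percent).
#' @export
relativeDifference <- function(adc1, adc2, adcReference) {
  if (any(adcReference == 0)) stop("reference ADC must be nonzero")
  (adc1 - adc2) / adcReference
}

#' Two-tailed paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (the signed-rank convention). For n <= 25
#' remaining pairs without ties among the absolute differences the exact
#' two-sided p-value is computed from the signed-rank null distribution;
#' otherwise the normal approximation with tie correction is used. When
#' all differences are zero the test is undefined and `p` is `NA`.
#'
#' @param x,y numeric vectors of per-subject values (equal length).
#' @return list with `p` (two-sided p-value or NA), `statistic` (V, the
#'   positive-rank sum), `n` (pairs after dropping zeros), `method`.
#' @examples
#' pairedWilcoxon(2:8, 1:7)$p  # n = 7 all-positive differences: 2/2^7
#' @export
pairedWilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = NA_real_, statistic = NA_real_, n = 0L,
                method = "undefined (all differences zero)"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact signed-rank"
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(p = p, statistic = V, n = n, method = method)
}

#' Pairwise comparison of ADC calculation methods across subjects
#'
#' For each VOI and each statistic (mean and/or median), compares every
#' pair of methods with a two-tailed paired Wilcoxon signed-rank test over
#' subjects, flagging p < alpha. No multiplicity correction is applied;
#' the flags are descriptive.
#'
#' @param summaries data.frame with columns `subject`, `method`, `voi` and
#'   the statistic columns (`mean`, `median`), e.g. stacked rows of
#'   [voiSummary()] results.
#' @param statistic character, which statistics to compare.
#' @param alpha significance threshold.
#' @return data.frame: voi, statistic, method_a, method_b, n, p,
#'   significant.
#' @export
compareMethods <- function(summaries, statistic = c("mean", "median"),
                           alpha = 0.05) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  need <- c("subject", "method", "voi", statistic)
  stopifnot(all(need %in% names(summaries)))
  methods_ <- unique(summaries$method)
  if (length(methods_) < 2L) stop("need at least two methods")
  subjects <- unique(summaries$subject)
  if (length(subjects) < 5L) stop("need at least five subjects")
  out <- list()
  for (voi_ in unique(summaries$voi)) {
    for (st in statistic) {
      for (a in seq_len(length(methods_) - 1L)) {
        for (b in (a + 1L):length(methods_)) {
          xa <- xb <- numeric(length(subjects))
          for (s in seq_along(subjects)) {
            ra <- summaries$voi == voi_ & summaries$method == methods_[a] &
              summaries$subject == subjects[s]
            rb <- summaries$voi == voi_ & summaries$method == methods_[b] &
              summaries$subject == subjects[s]
            if (sum(ra) != 1L || sum(rb) != 1L)
              stop(sprintf("missing or duplicated cell: voi %s, subject %s",
                           voi_, subjects[s]))
            xa[s] <- summaries[[st]][ra]
            xb[s] <- summaries[[st]][rb]
          }
          w <- pairedWilcoxon(xa, xb)
          out[[length(out) + 1L]] <- data.frame(
            voi = voi_, statistic = st,
            method_a = methods_[a], method_b = methods_[b],
            n = w$n, p = w$p,
            significant = !is.na(w$p) & w$p < alpha,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
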