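## Case-control association of adjusted local PCs, with genomic-control,
## quantile-quantile and GC-bias diagnostics.

## Median of the chi-squared distribution with 1 df, fixed to 12 significant
## digits so the inflation factor is bit-stable across platforms.
CHISQ1_MEDIAN <- 0.454936423120

#' Logistic regression of phenotype on one predictor
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 x` by iteratively
#' reweighted least squares, with a two-sided Wald p-value for `b1`.
#' Zero-variance predictors and complete separation (diverging `|b1| > 15`)
#' are flagged non-estimable rather than returned with a nominal p-value.
#'
#' @param x length-N numeric predictor.
#' @param y length-N phenotype vector in `{0, 1}`, both classes present.
#' @param max_iter IRLS iteration cap (default 25).
#' @param tol convergence tolerance on the deviance; tight by default so
#'   the Wald standard error is evaluated at the maximum, not one Newton
#'   step short of it.
#' @return list with `beta`, `se`, `wald_chi2`, `p_value`, `estimable`,
#'   `converged`. Non-estimable fits carry `NA` statistics.
#' @export
fit_logistic <- function(x, y, max_iter = 25L, tol = 1e-12) {
  stopifnot(length(x) == length(y))
  if (!all(y %in% c(0, 1))) stop("phenotype must be coded 0/1")
  if (length(unique(y)) < 2L) stop("phenotype has a single class")
  not_ok <- list(beta = NA_real_, se = NA_real_, wald_chi2 = NA_real_,
                 p_value = NA_real_, estimable = FALSE, converged = FALSE)
  if (any(!is.finite(x)) || var(x) == 0) return(not_ok)

  ## fit on the standardized predictor: the Wald statistic is invariant,
  ## the IRLS is better conditioned, and the separation rule below is a
  ## per-standard-deviation log-odds, meaningful whatever the raw scale
  sdx <- stats::sd(x)
  xs <- (x - mean(x)) / sdx
  X <- cbind(1, xs)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = tol, maxit = max_iter)))
  beta_s <- unname(fit$coefficients[2L])
  if (is.na(beta_s)) return(not_ok)
  ## complete or quasi-separation: log-odds per sd of x diverging
  if (abs(beta_s) > 15) return(not_ok)
  p_rank <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE])
  se_s <- sqrt(covmat[2L, 2L])
  if (!is.finite(se_s) || se_s <= 0) return(not_ok)
  beta <- beta_s / sdx
  se <- se_s / sdx
  z <- beta_s / se_s
  list(beta = beta, se = se, wald_chi2 = z^2,
       p_value = 2 * pnorm(-abs(z)),
       estimable = TRUE, converged = fit$converged)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.454936423120`, the ratio of the observed
#' median association statistic to the chi-squared(1 df) median. Values
#' near 1 indicate calibrated tests; values above 1, inflation.
#'
#' @param wald_chi2 numeric vector of at least 10 finite 1-df statistics.
#' @return positive scalar lambda.
#' @export
compute_lambda <- function(wald_chi2) {
  wald_chi2 <- wald_chi2[is.finite(wald_chi2)]
  if (length(wald_chi2) < 10L) {
    stop("need at least 10 finite statistics for a stable median")
  }
  median(wald_chi2) / CHISQ1_MEDIAN
}

#' Association scan of adjusted local PCs against phenotype
#'
#' Fits [fit_logistic()] for every region, ranks regions by ascending
#' p-value (ties broken by region id, making the scan independent of input
#' order), and summarizes inflation with [compute_lambda()]. Non-estimable
#' regions are excluded from both ranking and lambda.
#'
#' @param adjusted R x N matrix of adjusted local PCs with region ids as row
#'   names.
#' @param phenotypes length-N vector in `{0, 1}`, in the matrix's sample
#'   order.
#' @param H the adjustment level, recorded in the output.
#' @param gc_fraction optional per-region GC fractions named by region id.
#' @return list with `results` (data.frame: region_id, H, beta, se,
#'   wald_chi2, p_value, rank, gc_fraction) and `inflation` (list: H,
#'   lambda, n_regions).
#' @export
assoc_scan <- function(adjusted, phenotypes, H = 0L, gc_fraction = NULL) {
  if (nrow(adjusted) == 0L) stop("empty region set")
  ids <- rownames(adjusted)
  if (is.null(ids)) stop("adjusted matrix must carry region ids as rownames")
  fits <- apply(adjusted, 1L, fit_logistic, y = phenotypes, simplify = FALSE)
  res <- data.frame(
    region_id = ids,
    H = as.integer(H),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    wald_chi2 = vapply(fits, `[[`, numeric(1), "wald_chi2"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  estimable <- vapply(fits, `[[`, logical(1), "estimable")
  if (!any(estimable)) stop("no estimable region in scan")
  res$rank <- NA_integer_
  ord <- order(res$p_value[estimable], res$region_id[estimable])
  res$rank[which(estimable)[ord]] <- seq_len(sum(estimable))
  res$gc_fraction <- if (is.null(gc_fraction)) NA_real_ else
    unname(gc_fraction[res$region_id])
  lambda <- if (sum(estimable) >= 10L) {
    compute_lambda(res$wald_chi2[estimable])
  } else {
    warning("fewer than 10 estimable regions; lambda not reported")
    NA_real_
  }
  list(results = res,
       inflation = list(H = as.integer(H), lambda = lambda,
                        n_regions = sum(estimable)))
}

#' Quantile-quantile table of scan p-values
#'
#' Observed quantiles are the sorted `-log10(p)`; expected quantiles are
#' `-log10((rank - 0.5) / n)` under the uniform null. Zero p-values are
#' clamped to the smallest positive double.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return data.frame with columns `expected` and `observed` (both
#'   `-log10` scale), sorted by `expected` ascending.
#' @export
qq_table <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (any(p <= 0)) {
    message(sum(p <= 0), " p-value(s) at or below 0 clamped")
    p[p <= 0] <- .Machine$double.xmin
  }
  n <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  exp <- -log10((seq_len(n) - 0.5) / n)
  out <- data.frame(expected = exp, observed = obs)
  out[order(out$expected), , drop = FALSE]
}

#' GC-content versus significance diagnostic
#'
#' Returns a per-region scatter table of GC fraction against `-log10(p)`
#' and, per GC bin, the fraction of regions with p below a threshold --
#' quantifying over-representation of significant signals at particular GC
#' contents before correction.
#'
#' @param results scan results data.frame (from [assoc_scan()]) carrying
#'   `gc_fraction` and `p_value`.
#' @param p_threshold significance threshold for the per-bin enrichment
#'   fraction (default 1e-4).
#' @param bin_width GC bin width (default 0.05).
#' @return list with `points` (gc_fraction, neg_log10_p) and `bins`
#'   (gc_lo, gc_hi, n_regions, frac_significant).
#' @export
gc_significance_table <- function(results, p_threshold = 1e-4,
                                  bin_width = 0.05) {
  keep <- is.finite(results$gc_fraction) & is.finite(results$p_value)
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " region(s) without GC or p dropped")
  r <- results[keep, , drop = FALSE]
  points <- data.frame(gc_fraction = r$gc_fraction,
                       neg_log10_p = -log10(pmax(r$p_value,
                                                 .Machine$double.xmin)))
  if (nrow(r) == 0L) {
    return(list(points = points,
                bins = data.frame(gc_lo = numeric(0), gc_hi = numeric(0),
                                  n_regions = integer(0),
                                  frac_significant = numeric(0))))
  }
  lo <- seq(0, 1 - bin_width, by = bin_width)
  bin <- pmin(floor(r$gc_fraction / bin_width) + 1L, length(lo))
  n_regions <- tabulate(bin, nbins = length(lo))
  signif <- tabulate(bin[r$p_value < p_threshold], nbins = length(lo))
  bins <- data.frame(gc_lo = lo, gc_hi = lo + bin_width,
                     n_regions = n_regions,
                     frac_significant = ifelse(n_regions > 0,
                                               signif / n_regions, NA_real_))
  list(points = points, bins = bins)
}
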