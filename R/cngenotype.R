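## Absolute copy-number genotyping at a target locus.
##
## Normalized depths in non-overlapping 100-bp windows are cleaned of the
## leading global PCs, then modelled with a population hidden Markov model:
## one Gaussian emission cluster per copy-number state CN = 0..4, shared
## across all samples, with a sticky transition matrix along windows.
## Cluster means and variances are updated by expectation maximization on
## posteriors pooled over the whole cohort, so every sample informs every
## cluster. Each sample's genotype is the state maximizing its mean
## posterior across windows; the maximum is the call's certainty, and calls
## below a certainty threshold are set missing.

#' Construct a copy-number emission model
#'
#' @param states copy-number states (fixed at 0..4).
#' @param means initial cluster means on the normalized-depth axis; the
#'   default CN/2 places a diploid sample at 1.
#' @param variances initial cluster variances (all 0.01 by default: compact
#'   clusters at exome coverage).
#' @param stay_prob probability of staying in the same state between
#'   adjacent windows (default 0.99 per 100-bp step; common CNVs span many
#'   windows, so state changes are rare within a locus).
#' @param em_iterations number of EM iterations (default 20).
#' @return a `cn_model` list.
#' @export
cn_model <- function(states = 0:4, means = states / 2,
                     variances = rep(0.01, length(states)),
                     stay_prob = 0.99, em_iterations = 20L) {
  stopifnot(length(means) == length(states),
            length(variances) == length(states),
            all(diff(means) > 0), all(variances > 0),
            stay_prob > 0, stay_prob < 1)
  structure(list(states = as.integer(states), means = as.numeric(means),
                 variances = as.numeric(variances),
                 stay_prob = stay_prob,
                 em_iterations = as.integer(em_iterations)),
            class = "cn_model")
}

#' Window-averaged normalized depth matrix for a locus
#'
#' Splits the interval into non-overlapping windows anchored at its start
#' (trailing partial window dropped) and records, per window and sample,
#' the mean raw depth divided by the sample's mean depth.
#'
#' @param depth M x N matrix of raw per-base depths over the interval.
#' @param interval single-row region (BED semantics) the depths cover.
#' @param mean_depths per-sample mean depths, in column order.
#' @param window_size window width in bp (default 100).
#' @return list with `values` (W x N), `window_starts`, `window_size`,
#'   `interval`, `sample_order`.
#' @export
build_window_matrix <- function(depth, interval, mean_depths,
                                window_size = 100L) {
  m <- nrow(depth)
  w <- m %/% window_size
  if (w < 1L) stop("interval shorter than one window")
  idx <- rep(seq_len(w), each = window_size)
  used <- seq_len(w * window_size)
  sums <- rowsum(depth[used, , drop = FALSE], idx)
  values <- sweep(sums / window_size, 2L, mean_depths, "/")
  rownames(values) <- NULL
  list(values = values,
       window_starts = interval$start + (seq_len(w) - 1L) * window_size,
       window_size = as.integer(window_size),
       interval = interval,
       sample_order = colnames(depth) %||% names(mean_depths))
}

#' Project global PCs out of each window row
#'
#' Every window row is a length-N vector across samples; the first H global
#' PCs are removed from each row with the same projection operator used for
#' local PCs. `H = 0` is the identity.
#'
#' @param wm window matrix from [build_window_matrix()].
#' @param gpcs global PC set (sample order must match).
#' @param H number of components to remove.
#' @return the window matrix with adjusted `values`.
#' @export
adjust_window_matrix <- function(wm, gpcs, H) {
  wm$values <- project_out_rows(wm$values, gpcs, H)
  wm
}

## Scaled forward-backward across all samples at once. values: W x N;
## returns per-(window, sample, state) posteriors and per-sample loglik.
forward_backward <- function(values, means, vars, stay_prob) {
  w <- nrow(values)
  n <- ncol(values)
  s <- length(means)
  A <- matrix((1 - stay_prob) / (s - 1), s, s)
  diag(A) <- stay_prob
  sds <- sqrt(vars)
  ## emissions as W-list of N x S matrices
  emis <- array(0, dim = c(w, n, s))
  for (j in seq_len(s)) {
    emis[, , j] <- dnorm(values, mean = means[j], sd = sds[j])
  }
  ## guard against all-zero emission rows (far outliers)
  tiny <- .Machine$double.xmin
  alpha <- array(0, dim = c(w, n, s))
  scale <- matrix(0, w, n)
  a <- matrix(emis[1L, , ], n, s) / s
  sc <- pmax(rowSums(a), tiny)
  alpha[1L, , ] <- a / sc
  scale[1L, ] <- sc
  if (w > 1L) {
    for (t in 2:w) {
      a <- (matrix(alpha[t - 1L, , ], n, s) %*% A) * matrix(emis[t, , ], n, s)
      sc <- pmax(rowSums(a), tiny)
      alpha[t, , ] <- a / sc
      scale[t, ] <- sc
    }
  }
  beta <- array(0, dim = c(w, n, s))
  beta[w, , ] <- 1
  if (w > 1L) {
    for (t in (w - 1L):1L) {
      b <- (matrix(beta[t + 1L, , ], n, s) *
              matrix(emis[t + 1L, , ], n, s)) %*% t(A)
      beta[t, , ] <- b / scale[t + 1L, ]
    }
  }
  post <- alpha * beta
  norm <- apply(post, c(1L, 2L), sum)
  post <- post / pmax(array(norm, dim = dim(post)), tiny)
  list(posteriors = post, loglik = sum(log(scale)))
}

#' Fit the population copy-number HMM by expectation maximization
#'
#' E-step: scaled forward-backward per sample with uniform initial state
#' distribution and a sticky transition matrix. M-step: each state's
#' Gaussian mean and variance re-estimated from posterior-weighted window
#' values pooled over all samples; means are re-sorted so the
#' state-to-copy-number mapping keeps strictly increasing means. Runs
#' `model$em_iterations` iterations (default 20) or stops early when the
#' total log-likelihood improves by less than `loglik_tol`.
#'
#' A state whose posterior occupancy falls below `min_state_weight` keeps
#' its current parameters: a copy-number state with no samples otherwise
#' accumulates tail mass from the occupied clusters and drifts into them
#' over the iterations, splitting a real cluster between two states and
#' shifting every label above it. Freezing is a partial (generalized) EM
#' update, so the log-likelihood stays non-decreasing.
#'
#' @param wm (adjusted) window matrix.
#' @param model initial [cn_model()].
#' @param loglik_tol early-stop tolerance on log-likelihood improvement.
#' @param min_variance variance floor preventing cluster collapse.
#' @param min_state_weight minimum fraction of total posterior mass for a
#'   state's parameters to be updated (default 0.01).
#' @return list with `model` (fitted), `posteriors` (W x N x 5 array),
#'   `logliks` (per iteration), `trace` (data.frame of per-iteration state
#'   means, variances and weights), `converged`.
#' @export
fit_population_hmm <- function(wm, model = cn_model(), loglik_tol = 1e-6,
                               min_variance = 1e-6,
                               min_state_weight = 0.01) {
  values <- wm$values
  w <- nrow(values)
  n <- ncol(values)
  if (w < 1L) stop("window matrix has no windows")
  if (n < 2L) stop("population model needs at least 2 samples")
  means <- model$means
  vars <- model$variances
  s <- length(means)
  logliks <- numeric(0)
  trace <- list()
  fb <- NULL
  frozen_reported <- logical(s)
  for (it in seq_len(model$em_iterations)) {
    fb <- forward_backward(values, means, vars, model$stay_prob)
    logliks <- c(logliks, fb$loglik)
    ## M-step: pooled weighted moments per state
    wsum <- numeric(s)
    new_means <- means
    new_vars <- vars
    for (j in seq_len(s)) {
      g <- matrix(fb$posteriors[, , j], w, n)
      wj <- sum(g)
      wsum[j] <- wj
      if (wj < min_state_weight * w * n) {
        if (!frozen_reported[j]) {
          message("state CN=", model$states[j], " occupancy ",
                  signif(wj / (w * n), 2), " below ", min_state_weight,
                  "; parameters frozen")
          frozen_reported[j] <- TRUE
        }
        next
      }
      mu <- sum(g * values) / wj
      new_means[j] <- mu
      new_vars[j] <- max(sum(g * (values - mu)^2) / wj, min_variance)
    }
    ## keep the state -> copy-number mapping ordered by mean
    ord <- order(new_means)
    new_means <- new_means[ord]
    new_vars <- new_vars[ord]
    wsum <- wsum[ord]
    bump <- which(diff(new_means) <= 0)
    for (b in bump) new_means[b + 1L] <- new_means[b] + 1e-8
    means <- new_means
    vars <- new_vars
    trace[[it]] <- data.frame(iteration = it, state = model$states,
                              mean = means, variance = vars,
                              weight = wsum / (w * n))
    if (it > 1L &&
        logliks[it] - logliks[it - 1L] < loglik_tol) break
  }
  ## final E-step under the last parameters so posteriors match the model
  fb <- forward_backward(values, means, vars, model$stay_prob)
  fitted <- model
  fitted$means <- means
  fitted$variances <- vars
  list(model = fitted, posteriors = fb$posteriors,
       logliks = c(logliks, fb$loglik),
       trace = do.call(rbind, trace),
       converged = length(logliks) < model$em_iterations)
}

#' Call per-sample copy numbers from HMM posteriors
#'
#' Summarizes each sample's posterior as the mean across windows; the call
#' is the state maximizing that mean, its value is the certainty, and
#' samples whose certainty falls below the threshold are set missing.
#'
#' @param posteriors W x N x S posterior array from [fit_population_hmm()].
#' @param threshold certainty cutoff below which a call is missing
#'   (default 0.9).
#' @param states copy-number labels (default 0..4).
#' @param sample_ids optional sample names.
#' @return data.frame with `sample_id`, `copy_number` (NA when missing) and
#'   `certainty`; the missing rate is attached as attribute
#'   `missing_rate`.
#' @export
call_genotypes <- function(posteriors, threshold = 0.9, states = 0:4,
                           sample_ids = NULL) {
  mp <- apply(posteriors, c(2L, 3L), mean)  # N x S mean posterior
  best <- max.col(mp, ties.method = "first")
  certainty <- mp[cbind(seq_len(nrow(mp)), best)]
  cn <- states[best]
  missing <- certainty < threshold
  cn[missing] <- NA_integer_
  out <- data.frame(
    sample_id = sample_ids %||% paste0("S", seq_len(nrow(mp))),
    copy_number = cn, certainty = certainty, stringsAsFactors = FALSE)
  attr(out, "missing_rate") <- mean(missing)
  out
}

#' Concordance of genotype calls with truth
#'
#' Accuracy is computed over non-missing calls only; missing calls enter
#' the missing rate but neither the numerator nor denominator of accuracy.
#'
#' @param calls data.frame from [call_genotypes()].
#' @param truth per-sample true copy numbers, in the same sample order.
#' @return list with `accuracy` (NA when every call is missing),
#'   `missing_rate`, `n_called`.
#' @export
concordance <- function(calls, truth) {
  stopifnot(nrow(calls) == length(truth))
  called <- !is.na(calls$copy_number)
  acc <- if (any(called)) {
    mean(calls$copy_number[called] == truth[called])
  } else {
    NA_real_
  }
  list(accuracy = acc, missing_rate = mean(!called), n_called = sum(called))
}

#' Most likely state path per sample (Viterbi)
#'
#' Exposed for segmentation audits; the single-CNV genotype call uses the
#' mean posterior, not this path.
#'
#' @inheritParams fit_population_hmm
#' @return W x N integer matrix of copy-number states.
#' @export
viterbi_paths <- function(wm, model) {
  values <- wm$values
  w <- nrow(values)
  n <- ncol(values)
  s <- length(model$means)
  logA <- matrix(log((1 - model$stay_prob) / (s - 1)), s, s)
  diag(logA) <- log(model$stay_prob)
  sds <- sqrt(model$variances)
  paths <- matrix(0L, w, n)
  for (k in seq_len(n)) {
    le <- vapply(seq_len(s), function(j)
      dnorm(values[, k], model$means[j], sds[j], log = TRUE),
      numeric(w))
    le <- matrix(le, w, s)
    delta <- le[1L, ] - log(s)
    back <- matrix(0L, w, s)
    if (w > 1L) {
      for (t in 2:w) {
        cand <- delta + logA  # entry (i, j): from i to j
        back[t, ] <- max.col(t(cand), ties.method = "first")
        delta <- cand[cbind(back[t, ], seq_len(s))] + le[t, ]
      }
    }
    path <- integer(w)
    path[w] <- which.max(delta)
    if (w > 1L) for (t in (w - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
    paths[, k] <- model$states[path]
  }
  paths
}
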