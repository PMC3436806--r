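# Independent single-window oracle: EM for a 5-component Gaussian mixture
# with fixed uniform weights, the same variance floor and the same
# occupancy freeze, written without any HMM machinery.
mixture_em_oracle <- function(x, means, vars, iters, min_var = 1e-6,
                              min_weight = 0.01) {
  n <- length(x)
  s <- length(means)
  post <- NULL
  for (it in seq_len(iters)) {
    dens <- vapply(seq_len(s), function(j)
      dnorm(x, means[j], sqrt(vars[j])), numeric(n))
    post <- dens / pmax(rowSums(dens), .Machine$double.xmin)
    for (j in seq_len(s)) {
      wj <- sum(post[, j])
      if (wj < min_weight * n) next
      mu <- sum(post[, j] * x) / wj
      means[j] <- mu
      vars[j] <- max(sum(post[, j] * (x - mu)^2) / wj, min_var)
    }
    ord <- order(means)
    means <- means[ord]
    vars <- vars[ord]
  }
  dens <- vapply(seq_len(s), function(j)
    dnorm(x, means[j], sqrt(vars[j])), numeric(n))
  list(posteriors = dens / rowSums(dens), means = means, vars = vars)
}

make_wm <- function(values, window_size = 100L) {
  list(values = values,
       window_starts = (seq_len(nrow(values)) - 1L) * window_size,
       window_size = window_size,
       interval = region_row("chr1", 0L, nrow(values) * window_size),
       sample_order = colnames(values))
}

test_that("window matrix anchors at the interval start and drops the tail", {
  interval <- region_row("chr1", 1000L, 1350L)
  depth <- matrix(rep(c(10L, 20L), each = 350), 350, 2)
  wm <- build_window_matrix(depth, interval, c(10, 10), window_size = 100L)
  expect_equal(nrow(wm$values), 3L)
  expect_equal(wm$window_starts, c(1000L, 1100L, 1200L))
  expect_equal(wm$values[, 1], rep(1, 3))
  expect_equal(wm$values[, 2], rep(2, 3))
  expect_equal(build_window_matrix(matrix(0L, 120, 2), interval,
                                   c(5, 5))$values,
               matrix(0, 1, 2), ignore_attr = TRUE)
  expect_error(build_window_matrix(matrix(1L, 80, 2), interval, c(5, 5)),
               "shorter than one window")
})

test_that("window adjustment is the row projection operator", {
  set.seed(21)
  gp <- compute_global_pcs(matrix(rnorm(600), 30, 20), K = 8)
  wm <- make_wm(matrix(rnorm(5 * 20), 5, 20))
  expect_identical(adjust_window_matrix(wm, gp, 0L)$values, wm$values)
  wm1 <- make_wm(matrix(rep(gp$components[, 1], each = 4), 4, 20,
                        byrow = FALSE))
  wm1$values <- matrix(gp$components[, 1], 4, 20, byrow = TRUE)
  adj1 <- adjust_window_matrix(wm1, gp, 1L)
  expect_lt(max(abs(adj1$values)), 1e-10)
  adj <- adjust_window_matrix(wm, gp, 5L)
  expect_lt(max(abs(adj$values %*% gp$components[, 1:5])), 1e-8)
})

test_that("a constant diploid matrix decodes as CN 2 with full certainty", {
  wm <- make_wm(matrix(1, 8, 6))
  fit <- suppressMessages(fit_population_hmm(wm))
  calls <- call_genotypes(fit$posteriors)
  expect_true(all(calls$copy_number == 2L))
  expect_true(all(calls$certainty > 0.999))
})

test_that("a single window reduces to the uniform-weight mixture oracle", {
  set.seed(31)
  x <- c(rnorm(20, 0, 0.02), rnorm(25, 0.5, 0.04), rnorm(20, 1, 0.05),
         rnorm(18, 1.5, 0.04), rnorm(15, 2, 0.05))
  wm <- make_wm(matrix(x, 1, length(x)))
  model <- cn_model(em_iterations = 6L)
  fit <- suppressMessages(fit_population_hmm(wm, model, loglik_tol = -1))
  oracle <- mixture_em_oracle(x, model$means, model$variances, iters = 6L)
  expect_equal(fit$model$means, oracle$means, tolerance = 1e-6)
  expect_equal(fit$model$variances, oracle$vars, tolerance = 1e-6)
  expect_equal(matrix(fit$posteriors[1, , ], length(x), 5),
               oracle$posteriors, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("EM recovers well-separated clusters and keeps invariants", {
  set.seed(41)
  n <- 90
  cn <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  w <- 30
  values <- matrix(rnorm(w * n, mean = rep(cn / 2, each = w), sd = 0.03),
                   w, n)
  fit <- suppressMessages(fit_population_hmm(make_wm(values)))
  expect_lt(max(abs(fit$model$means[1:3] - c(0, 0.5, 1))), 0.02)
  # posteriors normalized per sample per window
  sums <- apply(fit$posteriors, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # log-likelihood non-decreasing
  expect_true(all(diff(fit$logliks) > -1e-6))
  # means strictly increasing after every M-step
  for (it in unique(fit$trace$iteration)) {
    expect_true(all(diff(fit$trace$mean[fit$trace$iteration == it]) > 0))
  }
  calls <- call_genotypes(fit$posteriors)
  expect_equal(concordance(calls, cn)$accuracy, 1)
})

test_that("calls respect the certainty threshold", {
  post <- array(0, dim = c(1, 3, 5))
  post[1, 1, ] <- c(0.95, 0.05, 0, 0, 0)
  post[1, 2, ] <- c(0.85, 0.15, 0, 0, 0)
  post[1, 3, ] <- c(0, 0, 0.5, 0.5, 0)
  calls <- call_genotypes(post, threshold = 0.9)
  expect_equal(calls$copy_number, c(0L, NA, NA))
  expect_equal(attr(calls, "missing_rate"), 2 / 3)
  calls0 <- call_genotypes(post, threshold = 0)
  expect_equal(attr(calls0, "missing_rate"), 0)
})

test_that("concordance separates accuracy from missingness", {
  calls <- data.frame(sample_id = sprintf("S%02d", 1:12),
                      copy_number = c(rep(1L, 9), 2L, NA, NA),
                      certainty = c(rep(0.99, 10), 0.5, 0.5))
  truth <- rep(1L, 12)
  m <- concordance(calls, truth)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$missing_rate, 2 / 12)
  all_missing <- data.frame(sample_id = "a", copy_number = NA_integer_,
                            certainty = 0.2)
  expect_true(is.na(concordance(all_missing, 2L)$accuracy))
  perfect <- data.frame(sample_id = c("a", "b"), copy_number = c(1L, 2L),
                        certainty = c(1, 1))
  expect_equal(concordance(perfect, c(1L, 2L)),
               list(accuracy = 1, missing_rate = 0, n_called = 2L))
})

test_that("viterbi decodes a clean piecewise-constant path", {
  w <- 40
  values <- matrix(c(rep(1, 20), rep(0.5, 20)), w, 4)
  paths <- viterbi_paths(make_wm(values), cn_model())
  expect_true(all(paths[1:20, ] == 2L))
  expect_true(all(paths[21:40, ] == 1L))
})
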