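# Closed-form oracle for logistic regression on a binary predictor:
# the MLE slope is the log odds ratio of the 2x2 table and its standard
# error is Woolf's formula.
oracle_2x2 <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  list(beta = log((case_exp * ctrl_unexp) / (case_unexp * ctrl_exp)),
       se = sqrt(1 / case_exp + 1 / case_unexp + 1 / ctrl_exp +
                   1 / ctrl_unexp))
}

expand_2x2 <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  list(x = c(rep(1, case_exp), rep(0, case_unexp),
             rep(1, ctrl_exp), rep(0, ctrl_unexp)),
       y = c(rep(1, case_exp + case_unexp),
             rep(0, ctrl_exp + ctrl_unexp)))
}

test_that("logistic fit matches the 2x2 closed form", {
  tab <- expand_2x2(60, 40, 40, 60)
  fit <- fit_logistic(tab$x, tab$y)
  oracle <- oracle_2x2(60, 40, 40, 60)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-6)
  expect_equal(fit$beta, log(2.25), tolerance = 1e-6)
  expect_equal(fit$se, oracle$se, tolerance = 1e-6)
  expect_equal(fit$wald_chi2, (fit$beta / fit$se)^2, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    cells <- sample(8:80, 4, replace = TRUE)
    tab <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(tab$x, tab$y)
    oracle <- do.call(oracle_2x2, as.list(cells))
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-6)
    expect_equal(fit$se, oracle$se, tolerance = 1e-6)
  }
})

test_that("degenerate predictors and responses are handled explicitly", {
  expect_error(fit_logistic(rnorm(10), rep(1, 10)), "single class")
  flat <- fit_logistic(rep(2, 20), rep(c(0, 1), 10))
  expect_false(flat$estimable)
  expect_true(is.na(flat$p_value))
  # complete separation
  sep <- fit_logistic(c(rep(0, 15), rep(1, 15)),
                      c(rep(0, 15), rep(1, 15)))
  expect_false(sep$estimable)
})

test_that("lambda is the chi-squared median ratio", {
  expect_equal(compute_lambda(rep(0.454936423120, 25)), 1, tolerance = 1e-9)
  stats <- rchisq(1000, df = 1) * 1.7
  expect_equal(compute_lambda(stats * 2), 2 * compute_lambda(stats),
               tolerance = 1e-12)
  expect_error(compute_lambda(rep(1, 9)), "at least 10")
})

test_that("qq table pairs sorted observed with uniform-null expected", {
  qq <- qq_table(0.5)
  expect_equal(qq$expected, -log10(0.5), tolerance = 1e-12)
  expect_equal(qq$observed, -log10(0.5), tolerance = 1e-12)
  qq1 <- qq_table(rep(1, 5))
  expect_true(all(qq1$observed == 0))
  expect_message(qq0 <- qq_table(c(0, 0.5)), "clamped")
  expect_true(all(is.finite(qq0$observed)))
  expect_true(!is.unsorted(qq_table(runif(50))$expected))
})

test_that("scan ranks by p-value with deterministic ties and drops
           non-estimable regions from lambda", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  x_strong <- y + rnorm(n, sd = 0.4)
  x_null <- rnorm(n)
  adjusted <- rbind(B_strong = x_strong, A_null = x_null,
                    C_flat = rep(1, n))
  for (i in 1:12) adjusted <- rbind(adjusted, rnorm(n))
  rownames(adjusted)[4:15] <- sprintf("N%02d", 1:12)
  scan <- assoc_scan(adjusted, y, H = 0L)
  res <- scan$results
  expect_equal(res$rank[res$region_id == "B_strong"], 1L)
  expect_true(is.na(res$rank[res$region_id == "C_flat"]))
  expect_equal(sort(res$rank[!is.na(res$rank)]), 1:14)
  expect_equal(scan$inflation$n_regions, 14L)
  # region order must not affect ranks
  perm <- sample(nrow(adjusted))
  scan2 <- assoc_scan(adjusted[perm, ], y, H = 0L)
  m <- match(scan$results$region_id, scan2$results$region_id)
  expect_equal(scan2$results$rank[m], scan$results$rank)
  expect_equal(scan2$inflation$lambda, scan$inflation$lambda)
})

test_that("ties in p-value break lexicographically by region id", {
  y <- rep(c(0, 1), 20)
  x <- rnorm(40)
  adjusted <- rbind(Zed = x, Abc = x, Mid = x)
  res <- suppressWarnings(assoc_scan(adjusted, y, H = 0L)$results)
  # identical p-values: Abc < Mid < Zed lexicographically
  expect_equal(res$rank[match(c("Abc", "Mid", "Zed"), res$region_id)],
               c(1L, 2L, 3L))
})

test_that("GC table bins regions and flags enrichment", {
  res <- data.frame(region_id = sprintf("R%02d", 1:40),
                    gc_fraction = seq(0.025, 1, by = 0.025),
                    p_value = rep(0.5, 40))
  gt <- gc_significance_table(res, p_threshold = 1e-3)
  expect_equal(nrow(gt$points), 40L)
  fracs <- gt$bins$frac_significant[gt$bins$n_regions > 0]
  expect_true(all(fracs == 0))
  # identical p below threshold: all populated bins equally enriched
  res$p_value <- 1e-5
  gt2 <- gc_significance_table(res, p_threshold = 1e-3)
  expect_true(all(gt2$bins$frac_significant[gt2$bins$n_regions > 0] == 1))
  # missing GC dropped with a note
  res$gc_fraction[1:5] <- NA
  expect_message(gt3 <- gc_significance_table(res), "dropped")
  expect_equal(nrow(gt3$points), 35L)
  empty <- gc_significance_table(res[0, ])
  expect_equal(nrow(empty$points), 0L)
})
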