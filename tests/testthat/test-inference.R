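test_that("insertion-rate MLE reproduces published rates from counts", {
  tr <- erv_tree()
  counts <- erv_reference_counts()
  rates <- erv_reference_rates()
  for (fam in colnames(counts)) {
    est <- fit_insertion_rates(setNames(counts[, fam], rownames(counts)), tr)
    # printed rates carry two decimals; the derived lengths reproduce them
    # to within half a unit in the last printed digit
    expect_lt(max(abs(est - rates[, fam])), 0.006)
  }
  # the printed examples
  expect_equal(round(fit_insertion_rates(
    setNames(counts[, "HERV-K"], rownames(counts)), tr)[["h"]], 2), 1.36)
  expect_equal(round(fit_insertion_rates(
    setNames(counts[, "ERV9"], rownames(counts)), tr)[["o"]], 2), 2.02)
  # zero counts give zero rates
  zero <- setNames(rep(0L, 9), rownames(counts))
  expect_true(all(fit_insertion_rates(zero, tr) == 0))
})

test_that("closed-form rate MLE agrees with numeric maximization", {
  tr <- erv_tree()
  counts <- setNames(c(3L, 0L, 2L, 7L, 20L, 1L, 4L, 9L, 6L), tr$branches)
  closed <- fit_insertion_rates(counts, tr)
  for (b in tr$branches) {
    if (counts[[b]] == 0) next
    num <- optimize(function(r) {
      rates <- closed; rates[[b]] <- r
      insertion_log_likelihood(counts, rates, tr)
    }, c(1e-8, 10), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(num, closed[[b]], tolerance = 1e-6)
  }
})

test_that("deletion MLE recovers generating parameters", {
  tr <- erv_tree()
  rates <- setNames(erv_reference_rates()[, "HERV-H"],
                    rownames(erv_reference_rates()))
  pats <- simulate_patterns(400, NULL, rates = rates, tree = tr,
                            params = deletion_params("weibull",
                                                     inv_psi = 0.09,
                                                     omega = 0.18),
                            family = "HERV-H", seed = 11)
  fw <- fit_deletion(pats, tr, "weibull", n_starts = 6, seed = 2)
  expect_true(fw$converged)
  expect_gt(fw$params$omega, 0.1)
  expect_lt(fw$params$omega, 0.3)
  expect_gt(1 / fw$params$psi, 0.03)
  expect_lt(1 / fw$params$psi, 0.25)
  fe <- fit_deletion(pats, tr, "exponential", n_starts = 4, seed = 2)
  # Table-2-like exponential rate for these study conditions
  expect_gt(fe$params$psi, 0.02)
  expect_lt(fe$params$psi, 0.1)
})

test_that("omega near 1 is recovered when data are exponential", {
  tr <- erv_tree()
  pats <- simulate_patterns(500, "hcgom", tree = tr,
                            params = deletion_params("exponential",
                                                     psi = 0.1),
                            seed = 31)
  fw <- fit_deletion(pats, tr, "weibull", n_starts = 6, seed = 3)
  expect_gt(fw$params$omega, 0.6)
  expect_lt(fw$params$omega, 1.6)
})

test_that("a fully retained single pattern drives the rate to the bound", {
  tr <- erv_tree()
  one <- erv_patterns(rbind(c("1", "0", "0", "0", "0")))
  fe <- fit_deletion(one, tr, "exponential", n_starts = 2, seed = 1)
  expect_true(fe$at_bound[["psi"]])
  expect_equal(fe$params$psi, 1e-6, tolerance = 1e-3)
})

test_that("erv_fit assembles rates, deletion MLE and log likelihood", {
  tr <- erv_tree()
  pats <- simulate_patterns(120, "hcgom", tree = tr,
                            params = deletion_params("exponential",
                                                     psi = 0.15),
                            family = "HERV-K", seed = 8)
  fit <- erv_fit(pats, tr, "exponential", n_starts = 2)
  expect_s3_class(fit, "erv_fit")
  expect_equal(unname(fit$rates[["hcgom"]]),
               unname(120 / tr$lengths[["hcgom"]]))
  expect_equal(fit$loglik$total, fit$loglik$insertion + fit$loglik$deletion)
  cf <- coef(fit)
  expect_true(all(c("Phi_hcgom", "psi_e") %in% names(cf)))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 10)
  expect_output(print(fit), "exponential")
  expect_output(print(summary(fit)), "Per-branch")
})

test_that("Weibull always attains at least the exponential likelihood", {
  tr <- erv_tree()
  for (seed in c(2, 12)) {
    pats <- simulate_patterns(150, "hcgom", tree = tr,
                              params = random_params("weibull", seed),
                              seed = seed)
    fe <- fit_deletion(pats, tr, "exponential", n_starts = 3, seed = 1)
    fw <- fit_deletion(pats, tr, "weibull", n_starts = 6, seed = 1)
    expect_gte(fw$loglik, fe$loglik - 1e-4)
  }
})

test_that("likelihood-ratio statistic and decision follow the chi-square", {
  lrt <- likelihood_ratio_test(-140.88, -121.79)
  expect_equal(lrt$statistic, 38.18)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$cutoff, qchisq(0.999, 1))
  expect_true(lrt$reject_exponential)
  same <- likelihood_ratio_test(-100, -100)
  expect_equal(same$statistic, 0)
  expect_false(same$reject_exponential)
  expect_warning(likelihood_ratio_test(-100, -101), "negative")
})

test_that("anova on two fits performs the model comparison", {
  tr <- erv_tree()
  pats <- simulate_patterns(200, "hcgom", tree = tr,
                            params = deletion_params("weibull", psi = 20,
                                                     omega = 0.3),
                            seed = 77)
  fe <- erv_fit(pats, tr, "exponential", n_starts = 2)
  fw <- erv_fit(pats, tr, "weibull", n_starts = 4)
  cmp <- anova(fe, fw)
  expect_s3_class(cmp, "erv_lrt")
  expect_equal(cmp$statistic,
               2 * (fw$loglik$deletion - fe$loglik$deletion))
  expect_error(anova(fe, fe), "Weibull")
})

test_that("null calibration: LRT rejects rarely under the exponential", {
  # data simulated under the null; the statistic follows (at most) a
  # half-half mix of 0 and chi-square(1), so rejections at the 0.001
  # cutoff should be very rare across replicates
  tr <- erv_tree()
  rejections <- 0
  for (r in 1:12) {
    pats <- simulate_patterns(80, "hcgom", tree = tr,
                              params = deletion_params("exponential",
                                                       psi = 0.12),
                              seed = 500 + r)
    fe <- fit_deletion(pats, tr, "exponential", n_starts = 2, seed = r)
    fw <- fit_deletion(pats, tr, "weibull", n_starts = 4, seed = r)
    lrt <- likelihood_ratio_test(fe$loglik, fw$loglik)
    rejections <- rejections + lrt$reject_exponential
  }
  expect_lte(rejections, 1)
})

test_that("bootstrap is reproducible, warm-started and collapses at n=1", {
  tr <- erv_tree()
  pats <- simulate_patterns(100, "hcgom", tree = tr,
                            params = deletion_params("exponential",
                                                     psi = 0.1),
                            seed = 15)
  fit <- erv_fit(pats, tr, "exponential", n_starts = 2)
  b1 <- erv_bootstrap(fit, n_reps = 5, seed = 9)
  b2 <- erv_bootstrap(fit, n_reps = 5, seed = 9)
  expect_equal(b1$estimates, b2$estimates)
  expect_equal(dim(b1$estimates), c(5L, 10L))
  expect_true(all(b1$ci[1, ] <= b1$ci[2, ]))
  ci <- confint(fit, parm = "psi_e", n_reps = 5, seed = 9)
  expect_equal(unname(ci[1, ]), unname(b1$ci[, "psi_e"]))
})

test_that("bootstrap CI covers the generating deletion rate", {
  # small calibration run: nominal 95% intervals from case resampling
  # should cover the truth in most replications
  tr <- erv_tree()
  truth <- 0.12
  covered <- 0
  for (r in 1:5) {
    pats <- simulate_patterns(120, "hcgom", tree = tr,
                              params = deletion_params("exponential",
                                                       psi = truth),
                              seed = 700 + r)
    fit <- erv_fit(pats, tr, "exponential", n_starts = 2, seed = r)
    bt <- erv_bootstrap(fit, n_reps = 40, seed = r)
    ci <- bt$ci[, "psi_e"]
    covered <- covered + (truth >= ci[1] && truth <= ci[2])
  }
  expect_gte(covered, 4)
})
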