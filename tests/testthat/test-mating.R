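# Expected values below were computed with independent oracles: direct
# arithmetic for the log-likelihood examples and the dense-grid profile
# scan in helper-fixtures.R for support limits.

test_that("multinomial log-likelihood matches direct evaluation", {
  expect_equal(multinomial_loglik(c(13, 0, 0), c(1, 0, 0)), 0)
  expect_equal(multinomial_loglik(c(13, 10, 0), rep(1 / 3, 3)), 23 * log(1 / 3))
  expect_equal(multinomial_loglik(c(13, 10, 0), c(13 / 23, 10 / 23, 0)),
               13 * log(13 / 23) + 10 * log(10 / 23))
  expect_identical(multinomial_loglik(c(1, 1), c(1, 0)), -Inf)
  expect_error(multinomial_loglik(c(-1, 1), c(0.5, 0.5)), "non-negative")
  expect_error(multinomial_loglik(c(1, 1), c(0.8, 0.8)), "sum")
})

test_that("MLE is closed-form y/n and zero-count support limit is exact", {
  fit <- fit_mating_mle(c(13, 10, 0))
  expect_equal(unname(fit$estimate), c(13 / 23, 10 / 23, 0))
  expect_equal(fit$n, 23)
  fit2 <- fit_mating_mle(c(13, 0, 0))
  expect_equal(unname(fit2$estimate), c(1, 0, 0))
  # closed form: 13 log p = -2  =>  p = exp(-2/13)
  expect_equal(unname(fit2$support[1, "lower"]), exp(-2 / 13), tolerance = 1e-5)
  expect_equal(unname(fit2$support[1, "upper"]), 1)
  # zero-count coordinate: upper limit solves (n) log(1-p) = -2
  expect_equal(unname(fit2$support[2, "upper"]), 1 - exp(-2 / 13), tolerance = 1e-5)
  expect_error(fit_mating_mle(c(0, 0, 0)), "no matings")
})

test_that("support limits agree with the dense-grid profile oracle", {
  # sampled (y, n) pairs; the acceptance suite covers all n <= 50
  set.seed(7)
  cases <- unique(rbind(data.frame(y = c(0, 1, 5, 13, 25, 49, 50),
                                   n = c(13, 10, 5, 23, 50, 50, 50)),
                        data.frame(y = sample(0:30, 10), n = 0)))
  cases$n <- pmax(cases$y, ifelse(cases$n == 0, cases$y + sample(0:20, nrow(cases), TRUE), cases$n))
  cases <- cases[cases$n >= 1 & cases$y <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    y <- cases$y[i]; n <- cases$n[i]
    rest <- c(n - y, 0)
    got <- ribarriers:::support_limits_one(y, n, rest)
    want <- grid_support_oracle(y, n, rest)
    expect_equal(unname(got), unname(want), tolerance = 1e-3,
                 info = sprintf("y=%d n=%d", y, n))
  }
})

test_that("profile reduction matches the full 2-simplex brute force", {
  for (y in list(c(13, 10, 0), c(5, 3, 1), c(2, 2, 2), c(10, 0, 0))) {
    got <- ribarriers:::support_limits_one(y[1], sum(y), y[-1])
    want <- simplex_support_oracle(y)
    expect_equal(unname(got), unname(want), tolerance = 2e-3,
                 info = paste(y, collapse = ","))
  }
})

test_that("support interval contains the MLE and shrinks with n", {
  widths <- vapply(c(1, 2, 4, 8), function(mult) {
    fit <- fit_mating_mle(c(13, 10, 2) * mult)
    expect_true(all(fit$support[, 1] <= fit$estimate + 1e-9))
    expect_true(all(fit$support[, 2] >= fit$estimate - 1e-9))
    # endpoints sit on the drop contour (tolerance of the bisection)
    for (i in 1:3) {
      y <- c(13, 10, 2) * mult
      for (end in fit$support[i, ]) {
        if (end %in% c(0, 1)) next
        ll <- ribarriers:::profile_loglik(end, y[i], sum(y),
          sum(y[-i] * log(y[-i] / sum(y[-i]))))
        expect_equal(ll, fit$loglik - 2, tolerance = 1e-4)
      }
    }
    mean(fit$support[, 2] - fit$support[, 1])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("pooling LRT: zero for identical proportions, df = k - 1", {
  out <- pooling_lrt(c(13, 10, 0), c(26, 20, 0))
  expect_equal(out$chi2, 0, tolerance = 1e-10)
  expect_equal(out$df, 2L)
  expect_equal(out$p, 1)
  expect_warning(res <- pooling_lrt(c(1, 0, 0), c(0, 0, 0)), "skipped")
  expect_true(is.na(res$chi2))
})

test_that("mating_x restricts to the pair's 2x2 sub-table", {
  mc <- paper_mating_counts()
  expect_equal(mating_x(mc, c("Pb", "Ps")), 15 / 31)
  expect_equal(mating_x(mc, c("Ps", "Pb")), 15 / 31)  # symmetric
  expect_equal(mating_x(mc, c("E", "Pb")), 0)
  m <- matrix(c(5, 5, 5, 5), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(mating_x(m, c("A", "B")), 0.5)
  m0 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(x0 <- mating_x(m0, c("A", "B")), "undefined")
  expect_true(is.na(x0))
})

test_that("fitting generator output recovers configured probabilities", {
  cfg <- sim_config(seed = 202, n_trials = c(E = 1500, Pb = 1500, Ps = 1500),
                    p_mating = c(E = 0.8, Pb = 0.8, Ps = 0.8))
  trials <- gen_mating_trials(cfg)
  mc <- mating_counts_from_trials(trials, taxa3)
  for (f in taxa3) {
    fit <- fit_mating_mle(mc, f)
    p_true <- cfg$mating_probabilities[f, ]
    se <- sqrt(p_true * (1 - p_true) / fit$n)
    expect_true(all(abs(fit$estimate - p_true) <= 3 * se + 1e-12), info = f)
  }
})
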