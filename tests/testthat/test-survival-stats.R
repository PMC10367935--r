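test_that("KM estimate matches the hand-computed product limit", {
  # records {2E, 3E, 4C, 6E, 9E}: S = .8, .6, (censor), .3, 0
  km <- km_estimate(c(2, 3, 4, 6, 9), c(1, 1, 0, 1, 1))
  expect_equal(km$curve$surv[km$curve$time %in% c(2, 3, 6, 9)],
               c(0.8, 0.6, 0.3, 0.0), tolerance = 1e-12)
  expect_equal(km$median, 6)   # first time S <= 0.5
  expect_equal(km$n_events, 4)

  # point mass: all events at t = 5
  expect_equal(km_estimate(rep(5, 4), rep(1, 4))$median, 5)

  # all censored: median not reached, no error
  expect_true(is.na(km_estimate(c(3, 4), c(0, 0))$median))

  # duplication invariance of the curve
  km2 <- km_estimate(rep(c(2, 3, 4, 6, 9), 2), rep(c(1, 1, 0, 1, 1), 2))
  expect_equal(km2$curve$surv, km$curve$surv)
  expect_equal(km2$median, km$median)

  expect_error(km_estimate(numeric(), logical()), "no survival")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM median approaches the closed form for exponential data", {
  set.seed(41)
  lambda <- 0.2
  t <- rexp(4000, lambda)
  km <- km_estimate(t, rep(1, 4000))
  expect_equal(km$median, log(2) / lambda, tolerance = 0.08)
})

test_that("Cox fit equals the Efron partial-likelihood oracle", {
  # fixed 6-record dataset: coefficient equals the argmax of the
  # hand-coded partial likelihood
  d <- data.frame(time = c(1, 2, 2, 3, 4, 5), event = c(1, 1, 1, 0, 1, 1),
                  x = c(1, 0, 1, 1, 0, 0))
  cx <- fit_cox(d, Surv(time, event) ~ x, term = "x")
  opt <- optimize(function(b) efron_partial_loglik(b, d$time, d$event, d$x),
                  c(-10, 10), maximum = TRUE, tol = 1e-9)
  expect_equal(log(cx$aHR), opt$maximum, tolerance = 1e-3)
  expect_equal(cx$log_likelihood, opt$objective, tolerance = 1e-6)

  # exchangeable groups give aHR 1
  d2 <- data.frame(time = rep(c(2, 4, 6, 8), 2), event = 1,
                   x = rep(0:1, each = 4))
  expect_equal(fit_cox(d2, Surv(time, event) ~ x)$aHR, 1, tolerance = 1e-8)

  suppressWarnings(
    expect_error(fit_cox(data.frame(time = c(1, 2), event = c(1, 0),
                                    x = c(0, 1)),
                         Surv(time, event) ~ x), "2 events"))
})

test_that("Cox fit matches the oracle on random tiny datasets", {
  set.seed(42)
  for (i in 1:250) {
    d <- random_tiny_cox_data()
    cx <- suppressWarnings(fit_cox(d, Surv(time, event) ~ x, term = "x"))
    if (cx$separation) next
    opt <- optimize(function(b)
      efron_partial_loglik(b, d$time, d$event, d$x),
      c(-12, 12), maximum = TRUE, tol = 1e-9)
    expect_equal(log(cx$aHR), opt$maximum, tolerance = 1e-3)
  }
})

test_that("time rescaling leaves the hazard ratio unchanged and scales medians", {
  set.seed(43)
  d <- data.frame(time = rexp(120, 0.3), event = rbinom(120, 1, 0.8),
                  x = rbinom(120, 1, 0.5))
  cx1 <- fit_cox(d, Surv(time, event) ~ x)
  km1 <- km_estimate(d$time, d$event)
  d2 <- transform(d, time = time * 7)
  cx2 <- fit_cox(d2, Surv(time, event) ~ x)
  km2 <- km_estimate(d2$time, d2$event)
  expect_equal(cx1$aHR, cx2$aHR, tolerance = 1e-8)
  expect_equal(km2$median, 7 * km1$median, tolerance = 1e-8)
})

test_that("nested-model LRT uses the chi-squared reference", {
  set.seed(44)
  d <- data.frame(time = rexp(80), event = rbinom(80, 1, 0.8),
                  x = rbinom(80, 1, 0.5), z = rnorm(80))
  full <- fit_cox(d, Surv(time, event) ~ x + z)
  reduced <- fit_cox(d, Surv(time, event) ~ x)
  out <- lrt_nested(full, reduced)
  expect_equal(out$df, 1)
  expect_equal(out$p_value,
               pchisq(2 * (full$log_likelihood - reduced$log_likelihood),
                      1, lower.tail = FALSE))
  # identical models: statistic 0, p 1
  same <- lrt_nested(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # chi-squared anchor: 2*dll = 3.841 at df 1 is p ~ 0.05
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  d2 <- d[1:40, ]
  other <- fit_cox(d2, Surv(time, event) ~ x)
  expect_error(lrt_nested(full, other), "different records")
})

test_that("RMST: rectangle case, closed form, and symmetric difference", {
  # all events at 5, tau 10: area is exactly 5
  g <- rep(c("a", "b"), each = 4)
  r <- rmst_compare(rep(5, 8), rep(1, 8), g, tau = NULL)
  expect_equal(r$rmst$rmst, c(5, 5))
  expect_equal(r$difference$estimate, 0)

  # exponential closed form (1 - exp(-l*tau)) / l
  set.seed(45)
  lam <- 0.25; tau <- 8
  t1 <- rexp(3000, lam); t2 <- rexp(3000, lam)
  rr <- rmst_compare(c(t1, t2), rep(1, 6000),
                     rep(c("a", "b"), each = 3000), tau = tau)
  expect_equal(rr$rmst$rmst, rep((1 - exp(-lam * tau)) / lam, 2),
               tolerance = 0.05)
  expect_lt(abs(rr$difference$estimate), 0.3)

  expect_error(rmst_compare(c(1, 2, 3, 4), c(1, 1, 1, 1),
                            c("a", "a", "b", "b"), tau = 3.5), "tau")
})

test_that("Schoenfeld PH check rejects strong time-varying effects", {
  set.seed(46)
  # crossing hazards: the index group has a burst of very early events and
  # a late plateau, so its hazard ratio versus the reference reverses sign
  n <- 200
  x <- rbinom(n, 1, 0.5)
  t <- ifelse(x == 1,
              ifelse(runif(n) < 0.5, runif(n, 0.05, 0.3), runif(n, 20, 30)),
              runif(n, 1, 10))
  d <- data.frame(time = t, event = 1, x = x)
  fit <- fit_cox(d, Surv(time, event) ~ x)
  ph <- schoenfeld_ph_check(fit)
  expect_lt(ph$p_value[ph$term == "x"], 0.01)
  expect_true("GLOBAL" %in% ph$term)

  expect_error(
    schoenfeld_ph_check(structure(list(n_events = 1), class = "cox_fit")),
    "2 events")
})

test_that("Schoenfeld power formula reproduces the design anchors", {
  # the published design: 180 patients, HR 0.5, 50% events, 1:1, alpha .05
  expect_equal(power_two_group_cox(180, 0.5, 0.5), 0.90, tolerance = 0.02)
  # null HR: power collapses to one-sided alpha/2
  expect_equal(power_two_group_cox(500, 1.0, 0.5), 0.025, tolerance = 1e-10)
  # monotone in n, effect size and event rate
  grid_n <- sapply(c(100, 200, 400, 800), power_two_group_cox,
                   hr_alt = 0.6, event_rate = 0.5)
  expect_true(all(diff(grid_n) > 0))
  grid_hr <- sapply(c(0.8, 0.6, 0.4, 0.2), power_two_group_cox,
                    n_total = 200, event_rate = 0.5)
  expect_true(all(diff(grid_hr) > 0))
  grid_ev <- sapply(c(0.2, 0.4, 0.8), function(e)
    power_two_group_cox(200, 0.5, e))
  expect_true(all(diff(grid_ev) > 0))
  expect_error(power_two_group_cox(100, -1, 0.5), "hr_alt")
})

test_that("single-stratum MH odds ratio equals the plain cross-product", {
  # the case cross-over classification counts: 13/18 vs 14/59
  tab <- matrix(c(13, 14, 5, 45), 2, 2)
  out <- cmh_ratio_test(tab)
  expect_equal(out$or, (13 * 45) / (5 * 14), tolerance = 1e-12)
  expect_equal(out$or, 8.357143, tolerance = 1e-6)
  expect_lt(out$p_value, 0.001)

  # null table: OR 1, p 1
  null_tab <- matrix(c(10, 10, 10, 10), 2, 2)
  out0 <- cmh_ratio_test(null_tab)
  expect_equal(out0$or, 1)
  expect_equal(out0$p_value, 1)
})

test_that("multi-stratum MH agrees with the stats reference implementation", {
  set.seed(47)
  arr <- array(rpois(2 * 2 * 3, 12) + 1, dim = c(2, 2, 3))
  mine <- cmh_ratio_test(arr)
  ref <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(mine$or, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # degenerate stratum dropped with warning
  arr2 <- array(c(arr, 0, 0, 0, 0), dim = c(2, 2, 4))
  expect_warning(out2 <- cmh_ratio_test(arr2), "degenerate")
  expect_equal(out2$or, mine$or)
})

test_that("Fisher comparisons match hypergeometric enumeration", {
  # full enumeration oracle for a 2x2 table
  enum_fisher <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(
    fisher_frequency_compare(c(g = 1, ref = 11), c(g = 10, ref = 14),
                             "ref")$p_value,
    enum_fisher(1, 9, 11, 3), tolerance = 1e-10)

  # identical proportions at large n: p near 1
  out <- fisher_frequency_compare(c(a = 50, ref = 50),
                                  c(a = 100, ref = 100), "ref")
  expect_gt(out$p_value, 0.9)
  expect_equal(out$proportion, out$ref_proportion)

  expect_warning(
    fisher_frequency_compare(c(a = 0, b = 5, ref = 4),
                             c(a = 0, b = 10, ref = 10), "ref"),
    "zero-total")
})

test_that("overlap weights balance covariate means exactly", {
  set.seed(48)
  n <- 300
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  z <- rbinom(n, 1, plogis(-0.3 + 0.9 * x1 - 0.7 * x2))  # confounded
  d <- data.frame(x1 = x1, x2 = x2,
                  tr = factor(ifelse(z == 1, "B", "A")),
                  rwpfs_months = rexp(n, 0.2 * exp(0.5 * x1)),
                  rwpfs_event = TRUE)
  ow <- overlap_weight_analysis(d, "tr", c("x1", "x2"))
  expect_lt(max(abs(ow$balance$difference)), 1e-8)

  # randomized treatment: weighted HR tracks the unweighted marginal HR
  d2 <- d
  d2$tr <- factor(sample(c("A", "B"), n, TRUE))
  ow2 <- overlap_weight_analysis(d2, "tr", c("x1", "x2"))
  un2 <- fit_cox(d2, Surv(rwpfs_months, rwpfs_event) ~ tr, term = "trB")
  expect_equal(log(ow2$cox$aHR), log(un2$aHR), tolerance = 0.15)
})

test_that("overlap weighting moves confounded estimates toward the truth", {
  set.seed(49)
  devs <- replicate(30, {
    n <- 400
    x <- rnorm(n)
    z <- rbinom(n, 1, plogis(1.2 * x))
    # true treatment effect null; x raises the hazard, so naive HR is biased
    t <- rexp(n, 0.2 * exp(0.9 * x))
    d <- data.frame(x = x, tr = factor(ifelse(z == 1, "B", "A")),
                    rwpfs_months = t, rwpfs_event = TRUE)
    naive <- fit_cox(d, Surv(rwpfs_months, rwpfs_event) ~ tr, term = "trB")
    ow <- overlap_weight_analysis(d, "tr", "x")
    c(naive = abs(log(naive$aHR)), weighted = abs(log(ow$cox$aHR)))
  })
  expect_lt(mean(devs["weighted", ]), mean(devs["naive", ]))
})
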