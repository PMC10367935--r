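# Statistical machinery for the validation analyses. Cox fitting, KM
# estimation, log-rank and Schoenfeld checks are delegated to the survival
# package; the Schoenfeld power formula, Mantel-Haenszel common odds ratio
# (with the Robins-Breslow-Greenland interval) and overlap weighting are
# implemented here.

#' Kaplan-Meier summary of a set of survival records
#'
#' Product-limit estimator with the log-log median confidence interval.
#' The median is the first time at which survival drops to 0.5 or below;
#' with all records censored it is reported as not reached (NA), which is
#' not an error.
#'
#' @param time positive durations (months)
#' @param event logical/0-1 event indicators
#' @param conf.level confidence level for the median CI
#' @return object of class `km_summary`: `median`, `ci95`, `curve`
#'   (data.frame time / surv / n.risk / n.event), `n`, `n_events` and the
#'   underlying `survfit` object
#' @export
km_estimate <- function(time, event, conf.level = 0.95) {
  if (length(time) == 0) stop_input("no survival records")
  if (any(time <= 0)) stop_input("durations must be positive")
  event <- as.integer(event)
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "log-log",
                 conf.int = conf.level)
  tab <- summary(fit)$table
  structure(list(
    median = unname(tab["median"]),
    ci95 = c(low = unname(tab["0.95LCL"]), high = unname(tab["0.95UCL"])),
    curve = data.frame(time = fit$time, surv = fit$surv,
                       n.risk = fit$n.risk, n.event = fit$n.event),
    n = length(time), n_events = sum(event), fit = fit),
    class = "km_summary")
}

#' @export
print.km_summary <- function(x, ...) {
  cat(sprintf("KM: n=%d, events=%d, median %s (95%% CI %s-%s)\n",
              x$n, x$n_events, format(x$median),
              format(x$ci95[["low"]]), format(x$ci95[["high"]])))
  invisible(x)
}

#' Covariate-adjusted Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (the accurate
#' default for heavily tied month-scale data). Reports the adjusted hazard
#' ratio, confidence interval and p-value for the designated term of
#' interest together with the full model log-likelihood, so that fits can
#' feed [lrt_nested()]. An optional `strata_var` preserves proportional
#' hazards by stratification; `cluster_var` requests robust (grouped
#' jackknife) variance; `weights` supports weighted (e.g. overlap-weighted)
#' fits.
#'
#' Non-convergence raises an error carrying the fitter diagnostics. A
#' monotone (separated) likelihood is reported with a warning and
#' `separation = TRUE` in the result.
#'
#' @param data data.frame with the time/event columns and covariates
#' @param formula model formula, e.g.
#'   `Surv(rwpfs_months, rwpfs_event) ~ irs_group2 + age + sex`
#' @param term name (or prefix) of the coefficient of interest; default the
#'   first coefficient
#' @param strata_var optional name of a stratification column
#' @param cluster_var optional name of a grouping column for robust variance
#' @param weights optional observation weights
#' @param conf.level confidence level
#' @return object of class `cox_fit`: `aHR`, `ci95`, `p_value`, `term`,
#'   `coefficients`, `log_likelihood`, `n`, `n_events`, `separation` and
#'   the underlying `coxph` fit
#' @export
fit_cox <- function(data, formula, term = NULL, strata_var = NULL,
                    cluster_var = NULL, weights = NULL, conf.level = 0.95) {
  if (!is.null(strata_var))
    formula <- stats::update(formula,
      as.formula(sprintf(". ~ . + strata(%s)", strata_var)))
  args <- list(formula = formula, data = data, ties = "efron",
               control = coxph.control(eps = 1e-10, iter.max = 50))
  if (!is.null(weights)) { data$.w <- weights; args$weights <- data$.w
                           args$data <- data }
  if (!is.null(cluster_var)) args$cluster <- data[[cluster_var]]
  fit <- tryCatch(do.call(coxph, args),
                  error = function(e)
                    stop_input("Cox model failed to converge: %s",
                               conditionMessage(e)))
  if (fit$nevent < 2)
    stop_input("Cox model needs at least 2 events, got %d", fit$nevent)
  separation <- any(abs(coef(fit)) > 15)
  if (separation)
    warning("possible separation: a coefficient exceeds 15 on the log scale")
  cf <- coef(fit)
  if (is.null(term)) term <- names(cf)[1]
  idx <- which(names(cf) == term)
  if (length(idx) == 0) idx <- grep(term, names(cf), fixed = TRUE)
  if (length(idx) != 1)
    stop_input("term '%s' does not identify a unique coefficient", term)
  se <- sqrt(diag(vcov(fit)))[idx]   # robust vcov when cluster was given
  z <- qnorm(1 - (1 - conf.level) / 2)
  structure(list(
    aHR = unname(exp(cf[idx])),
    ci95 = c(low = unname(exp(cf[idx] - z * se)),
             high = unname(exp(cf[idx] + z * se))),
    p_value = unname(2 * pnorm(-abs(cf[idx] / se))),
    term = names(cf)[idx],
    coefficients = cf,
    log_likelihood = fit$loglik[length(fit$loglik)],
    n = fit$n, n_events = fit$nevent,
    separation = separation,
    fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%d records, %d events): %s aHR %.3f (95%% CI %.3f-%.3f), p=%.4g\n",
              x$n, x$n_events, x$term, x$aHR, x$ci95[["low"]],
              x$ci95[["high"]], x$p_value))
  invisible(x)
}

#' Likelihood-ratio test between nested Cox models
#'
#' Compares a full and a reduced [fit_cox()] fit on the same records:
#' statistic 2 * (loglik_full - loglik_reduced) referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in
#' parameter count.
#'
#' @param full,reduced `cox_fit` objects on the same data, reduced nested
#'   in full
#' @return list with `statistic`, `df`, `p_value`
#' @export
lrt_nested <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  if (full$n != reduced$n || full$n_events != reduced$n_events)
    stop_input("full and reduced models were fitted on different records")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop_input("'full' has fewer parameters than 'reduced'")
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  list(statistic = stat, df = df,
       p_value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Restricted mean survival time comparison
#'
#' Area under the Kaplan-Meier curve up to `tau` per group, with the
#' Greenwood-based standard error, and the between-group difference with a
#' normal-approximation confidence interval. RMST does not require the
#' proportional-hazards assumption.
#'
#' @param time,event survival records
#' @param group two-level grouping vector
#' @param tau restriction time; default the minimum over groups of the
#'   largest observed time, the largest tau at which both curves are
#'   identified
#' @param conf.level confidence level
#' @return list with `tau`, per-group `rmst` table (estimate, se), and
#'   `difference` (second level minus first, with CI and p)
#' @export
rmst_compare <- function(time, event, group, tau = NULL, conf.level = 0.95) {
  group <- factor(group)
  if (nlevels(group) != 2) stop_input("'group' must have exactly two levels")
  maxt <- tapply(time, group, max)
  if (is.null(tau)) tau <- min(maxt)
  if (tau > min(maxt))
    stop_input("tau = %g exceeds the follow-up of group '%s' (%g)",
               tau, names(which.min(maxt)), min(maxt))
  one <- function(lv) {
    sel <- group == lv
    fit <- survfit(Surv(time[sel], as.integer(event[sel])) ~ 1)
    tab <- summary(fit, rmean = tau)$table
    c(rmst = unname(tab["rmean"]), se = unname(tab["se(rmean)"]))
  }
  est <- t(vapply(levels(group), one, c(rmst = 0, se = 0)))
  diff <- est[2, "rmst"] - est[1, "rmst"]
  se <- sqrt(sum(est[, "se"]^2))
  z <- qnorm(1 - (1 - conf.level) / 2)
  list(tau = tau,
       rmst = data.frame(group = levels(group), rmst = est[, "rmst"],
                         se = est[, "se"], row.names = NULL),
       difference = list(estimate = diff,
                         ci95 = c(low = diff - z * se, high = diff + z * se),
                         p_value = 2 * pnorm(-abs(diff / se))))
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Correlation-with-time test of the scaled Schoenfeld residuals for each
#' model term plus the global test, as implemented by
#' [survival::cox.zph()].
#'
#' @param fit a `cox_fit` from [fit_cox()]
#' @param transform time transform passed to `cox.zph`
#' @return data.frame with one row per term (and GLOBAL): `chisq`, `df`,
#'   `p_value`
#' @export
schoenfeld_ph_check <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2)
    stop_input("proportional-hazards check needs at least 2 events")
  z <- cox.zph(fit$fit, transform = transform)
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p_value = z$table[, "p"],
             row.names = NULL)
}

#' Power of a two-group Cox comparison (Schoenfeld formula)
#'
#' Expected number of events D = n_total * event_rate; with allocation
#' fraction p, the power against hazard ratio `hr_alt` at two-sided level
#' `alpha` is
#' \deqn{\Phi(|\log hr| \sqrt{D p (1-p)} - z_{1-\alpha/2}).}
#'
#' @param n_total total sample size
#' @param hr_alt alternative hazard ratio (> 0)
#' @param event_rate expected event fraction in (0, 1]
#' @param allocation fraction allocated to the index group (default 0.5,
#'   i.e. 1:1)
#' @param alpha two-sided type-I error
#' @return power (probability of rejecting in the direction of the
#'   alternative)
#' @examples
#' power_two_group_cox(180, hr_alt = 0.5, event_rate = 0.5)
#' @export
power_two_group_cox <- function(n_total, hr_alt, event_rate,
                                allocation = 0.5, alpha = 0.05) {
  if (hr_alt <= 0) stop_input("'hr_alt' must be positive")
  if (event_rate <= 0 || event_rate > 1)
    stop_input("'event_rate' must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop_input("'alpha' must be in (0, 1)")
  d <- n_total * event_rate
  pnorm(abs(log(hr_alt)) * sqrt(d * allocation * (1 - allocation)) -
          qnorm(1 - alpha / 2))
}

#' Mantel-Haenszel common odds ratio and Cochran-Mantel-Haenszel test
#'
#' For a set of 2x2 strata (exposed/unexposed x success/failure) computes
#' the Mantel-Haenszel common odds-ratio estimate, its
#' Robins-Breslow-Greenland confidence interval, and the CMH chi-squared
#' test (no continuity correction). With a single stratum the estimate is
#' exactly the plain cross-product odds ratio. Strata with an all-zero
#' margin contribute nothing and are dropped with a warning.
#'
#' @param strata either a 2x2 matrix, a list of 2x2 matrices, or a 2x2xK
#'   array; rows = exposure, columns = outcome, counts
#'   `matrix(c(a, c, b, d), 2, 2)` with `a` = exposed successes
#' @param conf.level confidence level
#' @return list with `or`, `ci95`, `p_value`, `statistic`, `n_strata`
#' @examples
#' cmh_ratio_test(matrix(c(13, 14, 5, 45), 2, 2))
#' @export
cmh_ratio_test <- function(strata, conf.level = 0.95) {
  if (is.matrix(strata)) strata <- list(strata)
  if (is.array(strata) && length(dim(strata)) == 3)
    strata <- lapply(seq_len(dim(strata)[3]), function(k) strata[, , k])
  if (length(strata) < 1) stop_input("need at least one stratum")
  ok <- vapply(strata, function(m) {
    all(dim(m) == c(2, 2)) && all(m >= 0) && sum(m) > 0 &&
      all(rowSums(m) + colSums(m) > 0)
  }, logical(1))
  degenerate <- vapply(strata, function(m) {
    any(rowSums(m) == 0) || any(colSums(m) == 0)
  }, logical(1))
  if (any(degenerate)) {
    warning(sprintf("dropping %d degenerate strata (all-zero margin)",
                    sum(degenerate)))
    strata <- strata[!degenerate]
  }
  if (!length(strata)) stop_input("no informative strata remain")
  a <- vapply(strata, function(m) m[1, 1], 0)
  b <- vapply(strata, function(m) m[1, 2], 0)
  c_ <- vapply(strata, function(m) m[2, 1], 0)
  d <- vapply(strata, function(m) m[2, 2], 0)
  n <- a + b + c_ + d

  r <- a * d / n; s <- b * c_ / n
  or <- sum(r) / sum(s)
  # Robins-Breslow-Greenland variance of log OR_MH
  p <- (a + d) / n; q <- (b + c_) / n
  v <- sum(p * r) / (2 * sum(r)^2) +
       sum(p * s + q * r) / (2 * sum(r) * sum(s)) +
       sum(q * s) / (2 * sum(s)^2)
  z <- qnorm(1 - (1 - conf.level) / 2)
  # CMH statistic, no continuity correction
  e <- (a + b) * (a + c_) / n
  vh <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  stat <- sum(a - e)^2 / sum(vh)
  list(or = or,
       ci95 = c(low = exp(log(or) - z * sqrt(v)),
                high = exp(log(or) + z * sqrt(v))),
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat,
       n_strata = length(strata))
}

#' Fisher exact comparison of group frequencies against a reference
#'
#' For each non-reference group, builds the 2x2 table of hits/misses versus
#' the reference group and reports the two-sided Fisher exact p-value.
#' Groups with zero total are skipped with a warning.
#'
#' @param hits named integer vector of successes per group
#' @param totals named integer vector of group sizes (same names)
#' @param reference name of the reference group
#' @return data.frame with `group`, `proportion`, `ref_proportion`,
#'   `p_value`
#' @export
fisher_frequency_compare <- function(hits, totals, reference) {
  if (is.null(names(hits)) || !identical(names(hits), names(totals)))
    stop_input("'hits' and 'totals' must share the same names")
  if (!reference %in% names(hits))
    stop_input("reference group '%s' not found", reference)
  if (any(hits < 0) || any(totals < hits))
    stop_input("counts must satisfy 0 <= hits <= totals")
  zero <- totals == 0
  if (any(zero & names(totals) != reference)) {
    warning(sprintf("skipping zero-total groups: %s",
                    paste(names(totals)[zero], collapse = ", ")))
  }
  others <- setdiff(names(hits)[!zero], reference)
  res <- lapply(others, function(g) {
    tab <- matrix(c(hits[[g]], totals[[g]] - hits[[g]],
                    hits[[reference]], totals[[reference]] - hits[[reference]]),
                  nrow = 2, byrow = TRUE)
    data.frame(group = g,
               proportion = hits[[g]] / totals[[g]],
               ref_proportion = hits[[reference]] / totals[[reference]],
               p_value = fisher.test(tab)$p.value)
  })
  do.call(rbind, res)
}

#' Overlap-weighting propensity analysis of a two-arm comparison
#'
#' Fits a logistic propensity model for treatment assignment, forms overlap
#' weights (1 - e(x) for the treated arm, e(x) for the control arm) and
#' reruns the survival comparison with those weights: a weighted
#' Kaplan-Meier per arm and a weighted Cox model with robust variance.
#' Overlap weights with a logistic propensity model balance the weighted
#' covariate means between arms exactly, which is reported as a balance
#' check.
#'
#' @param data data.frame
#' @param treatment name of a two-level treatment column (second level =
#'   treated)
#' @param covariates character vector of confounder column names
#' @param time,event names of the survival columns
#' @return list with `weights`, `balance` (per-covariate weighted means by
#'   arm and their difference), `cox` (weighted `cox_fit` for the treatment
#'   term) and `km` (weighted survfit)
#' @export
overlap_weight_analysis <- function(data, treatment, covariates,
                                    time = "rwpfs_months",
                                    event = "rwpfs_event") {
  tr <- factor(data[[treatment]])
  if (nlevels(tr) != 2) stop_input("'%s' must have two levels", treatment)
  z <- as.integer(tr) - 1L
  ps_formula <- as.formula(paste(".z ~", paste(covariates, collapse = " + ")))
  df <- data
  df$.z <- z
  ps_fit <- glm(ps_formula, data = df, family = binomial(),
                control = list(epsilon = 1e-14, maxit = 100))
  if (!ps_fit$converged) stop_input("propensity model did not converge")
  e <- predict(ps_fit, type = "response")
  w <- ifelse(z == 1, 1 - e, e)

  bal <- t(vapply(covariates, function(cv) {
    x <- df[[cv]]
    m1 <- weighted.mean(x[z == 1], w[z == 1])
    m0 <- weighted.mean(x[z == 0], w[z == 0])
    c(treated = m1, control = m0, difference = m1 - m0)
  }, c(treated = 0, control = 0, difference = 0)))

  df$.t <- df[[time]]; df$.e <- as.integer(df[[event]]); df$.tr <- tr
  cox <- fit_cox(df, Surv(.t, .e) ~ .tr, term = ".tr",
                 cluster_var = NULL, weights = w)
  km <- survfit(Surv(.t, .e) ~ .tr, data = df, weights = w)
  list(weights = w,
       balance = data.frame(covariate = covariates, bal, row.names = NULL),
       cox = cox, km = km, propensity = e)
}
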