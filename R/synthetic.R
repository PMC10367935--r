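# Synthetic cohort generator. Emulates the statistical structure the
# validation analyses assume -- tumor-type composition, IRS-H and MSI/TMB-H
# prevalence, Weibull proportional-hazards outcomes with IRS-dependent,
# treatment-specific hazard ratios, uniform-accrual censoring calibrated to
# the study's event rates, and independent drug action for combination
# lines -- so that every pipeline stage can be exercised end to end without
# external data. All fraction targets are calibrated deterministically
# (quadrature + root finding), not by trial sampling, so a config fully
# determines the generative law and the seed fully determines the draw.

IRS_WEIGHTS <- c(tmb = 0.273758, pd1 = 0.112641, pdl1 = 0.061904,
                 top2a = -0.077011, adam12 = -0.057991)

default_tumor_freqs <- function() {
  # six frequent types, NSCLC leading at 31.2%, plus 25 rare types that all
  # fall under the >15-line grouping threshold at the default cohort size
  frequent <- c(NSCLC = 0.312, CUP = 0.085, Bladder = 0.068,
                Melanoma = 0.060, "H&N" = 0.051, EGC = 0.048)
  rare <- setNames(rep((1 - sum(frequent)) / 25, 25),
                   paste0("RareType", sprintf("%02d", 1:25)))
  c(frequent, rare)
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults are the study conditions of the monotherapy validation
#' setting: 352 patients, NSCLC the most frequent tumor type (31.2%),
#' 45.5% IRS-H, 28.4% MSI/TMB-H, an 81.8% pembrolizumab fraction, a true
#' IRS-H vs IRS-L rwPFS hazard ratio of 0.41 (OS 0.47), a Weibull baseline
#' whose IRS-L median rwPFS is 3.8 months, and uniform-accrual censoring
#' calibrated to about 48.6% progression events and 37.5% deaths. Two
#' derived quantities are solved at construction time: the gamma scale of
#' the TMB distribution (so the MSI/TMB-H fraction hits its target) and a
#' location shift of the PD-1 expression mean (so the IRS-H fraction hits
#' its target under the locked score).
#'
#' @param n_patients cohort size
#' @param seed integer seed; fully determines [generate_cohort()] output
#' @param tumor_type_freqs named probability vector over tumor types
#' @param irs_h_target_frac target IRS-H prevalence
#' @param msi_tmb_h_frac target combined MSI/TMB-H prevalence
#' @param p_msi MSI-H prevalence (within the combined target)
#' @param treatment_mix named fractions over
#'   `c("PD-(L)1 mono", "chemo", "PD-(L)1+chemo")`
#' @param pembro_frac fraction of PD-(L)1 monotherapy lines that are
#'   pembrolizumab
#' @param prior_line_frac fraction of patients with a systemic line
#'   immediately preceding the index line (case cross-over feed)
#' @param hr_rwpfs_h,hr_os_h true IRS-H vs IRS-L hazard ratios (two-group
#'   effect model)
#' @param irs_effect `"two-group"` (H vs L on the index endpoint; the
#'   monotherapy validation conditions) or `"three-group"`
#'   (treatment-specific hazards by UL/IL/H; the treatment-comparison
#'   conditions)
#' @param pd1_hr_group3 hazard multipliers of the anti-PD-(L)1 latent time
#'   by three-group status, relative to the chemotherapy baseline
#'   (three-group effect model only)
#' @param combo_model `"independent-action"` (a combination line's time is
#'   the maximum of independently drawn anti-PD-(L)1 and chemotherapy
#'   latent times; the default) or `"proportional"` (a single Weibull
#'   proportional-hazards draw on the chemotherapy baseline with the
#'   anti-PD-(L)1 group hazard multiplier; for sensitivity analyses)
#' @param age_effect log-hazard per year of age (centered at 65), shared by
#'   all endpoints; recovered by the adjusted models
#' @param weibull_shape,rwpfs_scale_l baseline Weibull shape and IRS-L scale
#'   (months) of the rwPFS endpoint; the defaults place the IRS-L median at
#'   3.8 months and, at hazard ratio 0.41, the IRS-H median near 15.1
#' @param chemo_scale Weibull scale of the chemotherapy latent time
#'   (independent-drug-action component and prior lines)
#' @param cens_min,cens_max log-uniform accrual-censoring window (months):
#'   most patients have short follow-up with a long tail of early
#'   enrollees, as under ongoing accrual; calibrated to the target event
#'   rates
#' @param p_death_at_prog probability that an index-line progression event
#'   is a death rather than a next-line start
#' @param gap_shape,gap_scale_l,gap_hr_h Weibull post-progression survival
#'   gap (IRS-L scale, months) and its IRS-H hazard multiplier; these place
#'   the OS medians and death rate near the study's
#' @param expr_mean,expr_sd,expr_cor means, SDs and correlation matrix of
#'   the log2 nRPM expression covariates (pd1, pdl1, top2a, adam12)
#' @param tmb_shape gamma shape of the Muts/Mb TMB distribution
#' @param msi_tmb_mult TMB scale inflation for MSI-H samples
#' @param panel_mb panel footprint (Mb) attached to every sample
#' @param ihc_r_target Pearson correlation target of [generate_ihc_scores()]
#' @param germline_rate_per_mb,gnomad_coverage,vaf_conc variant-generation
#'   parameters, see [generate_variant_set()]
#' @return object of class `sim_config` (the arguments plus the solved
#'   `tmb_scale` and `pd1_shift`)
#' @export
sim_config <- function(n_patients = 352,
                       seed = 1L,
                       tumor_type_freqs = default_tumor_freqs(),
                       irs_h_target_frac = 0.455,
                       msi_tmb_h_frac = 0.284,
                       p_msi = 0.03,
                       treatment_mix = c("PD-(L)1 mono" = 1, "chemo" = 0,
                                         "PD-(L)1+chemo" = 0),
                       pembro_frac = 288 / 352,
                       prior_line_frac = 0.304,
                       hr_rwpfs_h = 0.41,
                       hr_os_h = 0.47,
                       irs_effect = c("two-group", "three-group"),
                       pd1_hr_group3 = c(UL = 1.05, IL = 0.75, H = 0.41),
                       combo_model = c("independent-action", "proportional"),
                       age_effect = 0.01,
                       weibull_shape = 0.65,
                       rwpfs_scale_l = 6.70,
                       chemo_scale = 8.0,
                       cens_min = 0.75,
                       cens_max = 48,
                       p_death_at_prog = 0.58,
                       gap_shape = 0.75,
                       gap_scale_l = 18,
                       gap_hr_h = 0.35,
                       expr_mean = c(pd1 = 2, pdl1 = 3, top2a = 5, adam12 = 4),
                       expr_sd = c(pd1 = 2, pdl1 = 2, top2a = 2, adam12 = 2),
                       expr_cor = NULL,
                       tmb_shape = 0.8,
                       msi_tmb_mult = 3,
                       panel_mb = 1.1,
                       ihc_r_target = 0.64,
                       germline_rate_per_mb = 2,
                       gnomad_coverage = 0.95,
                       vaf_conc = 25) {
  irs_effect <- match.arg(irs_effect)
  combo_model <- match.arg(combo_model)
  fr <- tumor_type_freqs
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop_input("tumor_type_freqs must be nonnegative and sum to 1")
  if (any(treatment_mix < 0) || sum(treatment_mix) <= 0 ||
      abs(sum(treatment_mix) - 1) > 0.01)
    stop_input("treatment_mix must be nonnegative fractions summing to 1")
  treatment_mix <- treatment_mix / sum(treatment_mix)
  for (fx in c(irs_h_target_frac, msi_tmb_h_frac, p_msi, pembro_frac,
               prior_line_frac, p_death_at_prog))
    if (fx < 0 || fx > 1) stop_input("fraction targets must lie in [0, 1]")
  if (msi_tmb_h_frac <= p_msi)
    stop_input("msi_tmb_h_frac must exceed p_msi")
  if (is.null(expr_cor)) {
    expr_cor <- diag(4) * 0.9 + 0.1
    expr_cor[1, 2] <- expr_cor[2, 1] <- 0.4   # PD-1 / PD-L1 co-expression
  }
  dimnames(expr_cor) <- list(names(expr_mean), names(expr_mean))

  cfg <- as.list(environment())
  cfg$expr_sigma <- diag(expr_sd) %*% expr_cor %*% diag(expr_sd)

  # TMB gamma scale: P(TMB >= 10 | MSS) solving the combined target under
  # independence of MSI status and the MSS TMB draw
  p_tmb_mss <- 1 - (1 - msi_tmb_h_frac) / (1 - p_msi)
  cfg$tmb_scale <- uniroot(function(s)
    pgamma(10, shape = tmb_shape, scale = s, lower.tail = FALSE) - p_tmb_mss,
    c(1e-3, 1e3), tol = 1e-10)$root

  # PD-1 mean shift so that P(score >= 0.873569) equals the IRS-H target.
  # score = w_tmb * T + G with G gaussian; integrate the gaussian tail over
  # the gamma mixture of T.
  w <- IRS_WEIGHTS
  g_mean0 <- sum(w[-1] * expr_mean)
  g_sd <- sqrt(drop(t(w[-1]) %*% cfg$expr_sigma %*% w[-1]))
  p_high <- function(shift, scale) {
    integrate(function(t)
      dgamma(t, shape = tmb_shape, scale = scale) *
        pnorm((0.873569 - w[["tmb"]] * t - g_mean0 - w[["pd1"]] * shift) /
                g_sd, lower.tail = FALSE),
      0, Inf, rel.tol = 1e-9)$value
  }
  cfg$pd1_shift <- uniroot(function(s) {
    (1 - p_msi) * p_high(s, cfg$tmb_scale) +
      p_msi * p_high(s, cfg$tmb_scale * msi_tmb_mult) - irs_h_target_frac
  }, c(-60, 60), tol = 1e-9)$root

  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: n=%d, seed=%d, %s IRS effect\n", x$n_patients,
              x$seed, x$irs_effect))
  cat(sprintf("  targets: IRS-H %.3f, MSI/TMB-H %.3f; true rwPFS HR %.2f, OS HR %.2f\n",
              x$irs_h_target_frac, x$msi_tmb_h_frac, x$hr_rwpfs_h, x$hr_os_h))
  cat(sprintf("  solved : tmb_scale %.4f, pd1_shift %.4f\n",
              x$tmb_scale, x$pd1_shift))
  invisible(x)
}

rweibull_ph <- function(n, shape, scale, log_hr) {
  # Weibull proportional hazards: multiplying the hazard by exp(log_hr)
  # divides (-log U) by it before the inverse-cdf transform
  scale * (-log(runif(n)) / exp(log_hr))^(1 / shape)
}

#' Generate a synthetic validation cohort
#'
#' Draws patients (demographics, tumor type, MSI status, TMB, expression,
#' derived IRS), therapy lines (optional preceding systemic line, the index
#' line, and post-progression lines implied by the outcome draw) and
#' outcomes from the generative model described in [sim_config()]. The
#' index-line rwPFS time is Weibull proportional-hazards with the
#' configured IRS (and age) log-hazards; overall survival is the rwPFS time
#' plus a post-progression gap (or the progression event itself, for the
#' death-at-progression fraction), so rwPFS never exceeds OS by
#' construction. Combination lines follow independent drug action: the
#' observed time is the maximum of independently drawn anti-PD-(L)1 and
#' chemotherapy latent times.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_cohort` with `patients`, `lines` and `truth`
#'   (all generating parameters, including the true log hazard contrasts)
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  id <- sprintf("P%05d", seq_len(n))

  age <- pmin(90, pmax(25, round(rnorm(n, 67, 10))))
  sex <- sample(c("F", "M"), n, TRUE, c(0.45, 0.55))
  race <- sample(c("White or Caucasian", "Black or African American",
                   "Asian", "Other", "Unknown"),
                 n, TRUE, c(0.40, 0.08, 0.05, 0.044, 0.426))
  tumor_type <- sample(names(config$tumor_type_freqs), n, TRUE,
                       config$tumor_type_freqs)
  msi_high <- runif(n) < config$p_msi
  tmb <- rgamma(n, shape = config$tmb_shape,
                scale = config$tmb_scale *
                  ifelse(msi_high, config$msi_tmb_mult, 1))
  mu <- config$expr_mean
  mu[["pd1"]] <- mu[["pd1"]] + config$pd1_shift
  expr <- mvrnorm(n, mu = mu, Sigma = config$expr_sigma)
  colnames(expr) <- names(config$expr_mean)
  mtc <- runif(n, 0.20, 1.00)

  score <- irs_score(tmb, expr[, "pd1"], expr[, "pdl1"], expr[, "top2a"],
                     expr[, "adam12"])
  cls <- irs_classify(score)

  treatment <- sample(names(config$treatment_mix), n, TRUE,
                      config$treatment_mix)
  pembro <- treatment == "PD-(L)1 mono" & runif(n) < config$pembro_frac

  is_h <- cls$irs_group2 == "H"
  eta_age <- config$age_effect * (age - 65)

  # latent event times (months); index endpoint is rwPFS
  draw_pd1 <- function() {
    if (config$irs_effect == "two-group")
      rweibull_ph(n, config$weibull_shape, config$rwpfs_scale_l,
                  log(config$hr_rwpfs_h) * is_h + eta_age)
    else
      rweibull_ph(n, config$weibull_shape, config$rwpfs_scale_l,
                  log(config$pd1_hr_group3[as.character(cls$irs_group3)]) +
                    eta_age)
  }
  t_chemo <- rweibull_ph(n, config$weibull_shape, config$chemo_scale, eta_age)
  t_pd1 <- draw_pd1()
  t_combo <- if (config$combo_model == "independent-action") {
    pmax(t_chemo, t_pd1)
  } else {
    eta_pd1_group <- if (config$irs_effect == "two-group")
      log(config$hr_rwpfs_h) * is_h
    else
      log(config$pd1_hr_group3[as.character(cls$irs_group3)])
    rweibull_ph(n, config$weibull_shape, config$chemo_scale,
                eta_pd1_group + eta_age)
  }
  t_event <- ifelse(treatment == "chemo", t_chemo,
                    ifelse(treatment == "PD-(L)1 mono", t_pd1, t_combo))

  # log-uniform accrual censoring: most patients enrolled recently (short
  # follow-up) with a long tail of early enrollees, as in ongoing accrual
  cens <- exp(runif(n, log(config$cens_min), log(config$cens_max)))
  prog_event <- t_event <= cens
  death_at_prog <- runif(n) < config$p_death_at_prog
  gap <- rweibull_ph(n, config$gap_shape, config$gap_scale_l,
                     log(config$gap_hr_h) * is_h)
  t_death <- ifelse(death_at_prog, t_event, t_event + gap)
  death_obs <- t_death <= cens

  # therapy-line layout on the per-patient day clock (collection at day 0)
  has_prior <- runif(n) < config$prior_line_frac
  prior_start <- rep(NA_real_, n)
  prior_dur <- rweibull_ph(n, 1.1, 6.2, 0)      # prior-line PFS, IRS-free
  index_start <- ifelse(has_prior,
                        30 + pmax(1, round(prior_dur * DAYS_PER_MONTH)),
                        round(runif(n, 14, 60)))
  prior_start[has_prior] <- 30

  day <- function(m) round(m * DAYS_PER_MONTH)
  death_day <- ifelse(death_obs, index_start + day(t_death), NA_real_)
  last_fu <- ifelse(death_obs, death_day, index_start + day(cens))

  patients <- data.frame(
    patient_id = id, age = age, sex = sex, race = race,
    tumor_type = tumor_type, msi_high = msi_high,
    mtc = mtc, panel_mb = config$panel_mb,
    tmb = tmb, pd1 = expr[, "pd1"], pdl1 = expr[, "pdl1"],
    top2a = expr[, "top2a"], adam12 = expr[, "adam12"],
    score = score, irs_group2 = cls$irs_group2, irs_group3 = cls$irs_group3,
    collection_day = 0, death_day = death_day, last_followup_day = last_fu,
    prior_io = FALSE, in_discovery = FALSE, in_prior_validation = FALSE,
    stringsAsFactors = FALSE)

  agents_for <- function(tr, pem) {
    switch(tr,
           "PD-(L)1 mono" = if (pem) "pembrolizumab" else "atezolizumab",
           "chemo" = "carboplatin+paclitaxel",
           "PD-(L)1+chemo" = paste0(if (pem) "pembrolizumab"
                                    else "atezolizumab",
                                    "+carboplatin+paclitaxel"))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- 0L
    out <- list()
    if (has_prior[i]) {
      ln <- ln + 1L
      out[[length(out) + 1]] <- data.frame(
        patient_id = id[i], line_number = ln, start_day = prior_start[i],
        stop_day = index_start[i], agents = "carboplatin+paclitaxel",
        stringsAsFactors = FALSE)
    }
    ln <- ln + 1L
    out[[length(out) + 1]] <- data.frame(
      patient_id = id[i], line_number = ln, start_day = index_start[i],
      stop_day = NA_real_, agents = agents_for(treatment[i], pembro[i]),
      stringsAsFactors = FALSE)
    if (prog_event[i] && !death_at_prog[i]) {
      ln <- ln + 1L
      out[[length(out) + 1]] <- data.frame(
        patient_id = id[i], line_number = ln,
        start_day = index_start[i] + max(1, day(t_event[i])),
        stop_day = NA_real_, agents = "investigational",
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, out)
  }
  lines <- classify_therapy_lines(do.call(rbind, rows))
  rownames(lines) <- NULL

  truth <- list(
    config = config,
    log_hr_rwpfs_h = log(config$hr_rwpfs_h),
    log_hr_os_gap_h = log(config$gap_hr_h),
    age_effect = config$age_effect,
    treatment = setNames(treatment, id),
    irs_h_frac = mean(is_h),
    latent = data.frame(patient_id = id, t_event = t_event,
                        t_death = t_death, cens = cens,
                        prog_event = prog_event, death_obs = death_obs))
  structure(list(patients = patients, lines = lines, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d therapy lines; IRS-H %.1f%%\n",
              nrow(x$patients), nrow(x$lines), 100 * x$truth$irs_h_frac))
  invisible(x)
}

#' Generate a per-sample variant call set
#'
#' Somatic variants are drawn at the configured rate with allele
#' frequencies from a beta distribution centered near half the molecularly
#' informed tumor content (MTC), restricted to the clonal, filter-passing
#' region so that the configured somatic rate is the post-filter truth.
#' Germline contaminants are added at allele frequencies near 0.5 and
#' carry a gnomAD-membership flag with the configured coverage probability;
#' the uncovered remainder is what the allele-frequency-window rule of
#' [filter_candidate_mutations()] must catch.
#'
#' @param mtc molecularly informed tumor content in (0, 1]
#' @param panel_mb panel footprint in megabases
#' @param somatic_rate_per_mb true somatic mutation rate (Muts/Mb)
#' @param germline_rate_per_mb germline contaminant rate (per Mb)
#' @param gnomad_coverage probability a germline contaminant is flagged as
#'   present in gnomAD
#' @param vaf_conc beta concentration of the somatic VAF distribution
#' @return data.frame of variant calls: `variant_id`, `vaf`, `in_gnomad`,
#'   `eligible`, plus the generating truth `is_somatic`
#' @export
generate_variant_set <- function(mtc, panel_mb, somatic_rate_per_mb,
                                 germline_rate_per_mb = 2,
                                 gnomad_coverage = 0.95,
                                 vaf_conc = 25) {
  if (mtc <= 0 || mtc > 1) stop_input("'mtc' must be in (0, 1]")
  n_som <- rpois(1, somatic_rate_per_mb * panel_mb)
  m <- mtc / 2
  passes <- function(v)
    v > mtc / 4 & !(mtc < 0.80 & v >= 0.45 & v <= 0.55)
  vaf_som <- numeric(0)
  while (length(vaf_som) < n_som) {
    cand <- rbeta(2 * (n_som - length(vaf_som)) + 10,
                  m * vaf_conc, (1 - m) * vaf_conc)
    vaf_som <- c(vaf_som, cand[passes(cand)])
  }
  vaf_som <- vaf_som[seq_len(n_som)]
  n_germ <- rpois(1, germline_rate_per_mb * panel_mb)
  vaf_germ <- pmin(0.65, pmax(0.35, rnorm(n_germ, 0.5, 0.03)))
  out <- data.frame(
    vaf = c(vaf_som, vaf_germ),
    in_gnomad = c(rep(FALSE, n_som),
                  runif(n_germ) < gnomad_coverage),
    eligible = TRUE,
    is_somatic = rep(c(TRUE, FALSE), c(n_som, n_germ)))
  if (nrow(out)) out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$variant_id <- sprintf("var%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("variant_id", "vaf", "in_gnomad", "eligible", "is_somatic")]
}

#' Generate PD-L1 immunohistochemistry-like scores coupled to expression
#'
#' Monotone noisy mapping from log2 PD-L1 expression to a tumor proportion
#' score (TPS/CPS-like, 0-100) such that the Pearson correlation between
#' log2(score + 1) and expression approaches `r_target` at large n. The
#' noise standard deviation is solved in closed form from the sample
#' spread of the expression values.
#'
#' @param pdl1 log2 nRPM PD-L1 expression vector
#' @param r_target target Pearson correlation on the log scale, in (0, 1)
#' @param intercept,slope location and gain of the latent log2(score + 1)
#'   mapping
#' @return numeric IHC-like scores in \[0, 100\]
#' @export
generate_ihc_scores <- function(pdl1, r_target = 0.64,
                                intercept = 3, slope = 0.5) {
  if (r_target <= 0 || r_target >= 1)
    stop_input("'r_target' must be in (0, 1)")
  sdx <- sd(pdl1)
  noise_sd <- slope * sdx * sqrt(1 / r_target^2 - 1)
  latent <- intercept + slope * (pdl1 - mean(pdl1)) +
    rnorm(length(pdl1), 0, noise_sd)
  latent <- pmin(log2(101), pmax(0, latent))
  2^latent - 1
}
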