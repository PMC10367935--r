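# Orchestration of the four named validation analyses. Each run_* function
# consumes validated patient/line tables (real or synthetic), assembles the
# relevant cohort, and returns a machine-readable report list; run_analysis()
# drives them from a YAML/list config and writes JSON + CSV artifacts.

ensure_scored <- function(patients, model = irs_model()) {
  if (!is.null(patients$score) && !is.null(patients$irs_group2)) {
    # re-level after round-trips through flat files (L is the reference)
    patients$irs_group2 <- factor(patients$irs_group2, levels = c("L", "H"))
    patients$irs_group3 <- factor(patients$irs_group3,
                                  levels = c("UL", "IL", "H"))
    return(patients)
  }
  sc <- irs_score(patients$tmb, patients$pd1, patients$pdl1,
                  patients$top2a, patients$adam12, model)
  cls <- irs_classify(sc, model)
  patients$score <- cls$score
  patients$irs_group2 <- cls$irs_group2
  patients$irs_group3 <- cls$irs_group3
  patients
}

# standard covariate set; factors collapsing to a single level in the
# cohort at hand are dropped from the model
build_adjusted_formula <- function(d, time, event, primary,
                                   extra = character(0)) {
  covs <- c(primary, "age", "sex", "tumor_f", "line_number",
            "pembrolizumab", extra)
  keep <- vapply(covs, function(cv) {
    v <- d[[cv]]
    !is.null(v) && length(unique(v)) > 1
  }, logical(1))
  as.formula(paste0("Surv(", time, ", ", event, ") ~ ",
                    paste(covs[keep], collapse = " + ")))
}

km_brief <- function(km) {
  list(n = km$n, events = km$n_events, median = km$median,
       ci95 = as.list(km$ci95))
}

cox_brief <- function(cx) {
  list(term = cx$term, aHR = cx$aHR, ci95 = as.list(cx$ci95),
       p_value = cx$p_value, n = cx$n, events = cx$n_events,
       log_likelihood = cx$log_likelihood)
}

#' Monotherapy validation analysis
#'
#' Assembles the anti-PD-(L)1 monotherapy cohort, computes unadjusted
#' Kaplan-Meier summaries by IRS group and covariate-adjusted Cox models
#' (age, sex assigned at birth, tumor type with small types grouped, line
#' of systemic therapy, pembrolizumab versus other anti-PD-(L)1) for both
#' rwPFS and OS, checks proportional hazards via Schoenfeld residuals, and
#' reports key subgroup fits (pembrolizumab, MSI/TMB status).
#'
#' @param patients,lines clinical input tables (see [select_cohort()])
#' @param model an [irs_model()]
#' @param spec optional [cohort_spec()] override
#' @return report list: cohort sizes and audit, per-group KM, adjusted Cox
#'   per endpoint, PH checks, subgroup fits
#' @export
run_monotherapy_validation <- function(patients, lines, model = irs_model(),
                                       spec = NULL) {
  patients <- ensure_scored(patients, model)
  if (is.null(spec)) spec <- cohort_spec("monotherapy")
  cohort <- select_cohort(patients, lines, spec)
  d <- cohort$data
  if (nrow(d) == 0)
    return(list(status = "empty cohort", audit = as.list(cohort$audit)))
  d$tumor_f <- assign_tumor_type_covariate(d$tumor_type)

  endpoint <- function(time, event, label) {
    km <- lapply(split(seq_len(nrow(d)), d$irs_group2), function(ii)
      km_brief(km_estimate(d[[time]][ii], d[[event]][ii])))
    f <- build_adjusted_formula(d, time, event, "irs_group2")
    cx <- fit_cox(d, f, term = "irs_group2H")
    ph <- schoenfeld_ph_check(cx)
    subgroups <- list()
    for (sg in list(c("pembrolizumab", "TRUE"),
                    c("pembrolizumab", "FALSE"))) {
      sel <- as.character(d[[sg[1]]]) == sg[2]
      if (sum(sel) >= 20 && length(unique(d$irs_group2[sel])) == 2) {
        ds <- d[sel, ]
        ds$tumor_f <- assign_tumor_type_covariate(ds$tumor_type)
        fs <- build_adjusted_formula(ds, time, event, "irs_group2")
        subgroups[[paste(sg, collapse = "=")]] <-
          cox_brief(fit_cox(ds, fs, term = "irs_group2H"))
      }
    }
    # MSI/TMB strata
    d$msi_tmb_h <- d$msi_high | d$tmb >= 10
    for (v in c(TRUE, FALSE)) {
      sel <- d$msi_tmb_h == v
      if (sum(sel) >= 20 && length(unique(d$irs_group2[sel])) == 2 &&
          sum(d[[event]][sel]) >= 5) {
        ds <- d[sel, ]
        ds$tumor_f <- assign_tumor_type_covariate(ds$tumor_type)
        fs <- build_adjusted_formula(ds, time, event, "irs_group2")
        subgroups[[paste0("msi_tmb_h=", v)]] <-
          cox_brief(fit_cox(ds, fs, term = "irs_group2H"))
      }
    }
    list(endpoint = label, km_by_group = km, adjusted_cox = cox_brief(cx),
         ph_check = ph, subgroups = subgroups)
  }

  list(status = "ok",
       cohort = list(n_lines = nrow(d),
                     n_patients = length(unique(d$patient_id)),
                     n_irs_h = sum(d$irs_group2 == "H"),
                     n_irs_l = sum(d$irs_group2 == "L"),
                     audit = as.list(cohort$audit)),
       rwpfs = endpoint("rwpfs_months", "rwpfs_event", "rwPFS"),
       os = endpoint("os_months", "os_event", "OS"))
}

#' Case cross-over analysis
#'
#' Builds within-patient pairs of the index anti-PD-(L)1 line versus the
#' immediately preceding systemic line, tests the treatment-by-IRS
#' interaction, and classifies rwPFS2/rwPFS1 ratios at the benefit cutoff,
#' feeding the IRS-H vs IRS-L comparison of above-cutoff rates into the
#' Mantel-Haenszel machinery.
#'
#' @inheritParams run_monotherapy_validation
#' @param cutoff PFS-ratio benefit cutoff, inclusive (default 1.3)
#' @return report list: pair counts, interaction LRT, per-group log-rank
#'   and medians, ratio table with MH odds ratio
#' @export
run_crossover_analysis <- function(patients, lines, model = irs_model(),
                                   spec = NULL, cutoff = 1.3) {
  patients <- ensure_scored(patients, model)
  if (is.null(spec)) spec <- cohort_spec("crossover")
  cohort <- select_cohort(patients, lines, spec)
  pairs <- build_crossover_pairs(cohort, patients, lines)
  if (nrow(pairs) == 0)
    return(list(status = "empty cohort", n_pairs = 0))
  inter <- tryCatch(interaction_lrt(pairs), error = function(e) NULL)
  ratio <- pfs_ratio_classify(pairs, cutoff = cutoff)
  mh <- if (all(ratio$counts$evaluable > 0))
    cmh_ratio_test(ratio$table) else NULL
  list(status = "ok",
       n_pairs = nrow(pairs),
       n_by_group = as.list(table(pairs$irs_group)),
       interaction = if (!is.null(inter))
         list(lrt_p = inter$lrt$p_value, statistic = inter$lrt$statistic,
              interaction_coef = as.list(inter$interaction_coef),
              by_group = inter$by_group),
       ratio = list(cutoff = cutoff,
                    counts = ratio$counts,
                    mh = if (!is.null(mh))
                      list(or = mh$or, ci95 = as.list(mh$ci95),
                           p_value = mh$p_value)),
       pairs = ratio$pairs)
}

#' Three-group treatment comparison
#'
#' Within each three-group IRS stratum, compares rwPFS across anti-PD-(L)1
#' monotherapy, chemotherapy and the combination by a Cox model with
#' treatment as a three-level factor (adjusting for age, sex, line of
#' therapy, tumor type and PD-L1 RNA expression); the three pairwise
#' contrasts are read off the factor fits. An overlap-weighting propensity
#' analysis is run for each pairwise contrast as a sensitivity check.
#'
#' @inheritParams run_monotherapy_validation
#' @param overlap_weighting also run the pairwise overlap-weighted fits
#' @return report list keyed by IRS group: line counts, KM by treatment,
#'   pairwise adjusted contrasts, overlap-weighted contrasts
#' @export
run_treatment_comparison <- function(patients, lines, model = irs_model(),
                                     spec = NULL, overlap_weighting = TRUE) {
  patients <- ensure_scored(patients, model)
  if (is.null(spec))
    spec <- cohort_spec("treatment-comparison",
                        classes = c("PD-(L)1 mono", "chemo", "PD-(L)1+chemo"),
                        one_line_per_patient = FALSE)
  cohort <- select_cohort(patients, lines, spec)
  d <- cohort$data
  if (nrow(d) == 0)
    return(list(status = "empty cohort", audit = as.list(cohort$audit)))
  d$treatment <- factor(d$therapy_class,
                        levels = c("chemo", "PD-(L)1 mono", "PD-(L)1+chemo"))
  out <- list(status = "ok",
              cohort = list(n_lines = nrow(d),
                            n_patients = length(unique(d$patient_id)),
                            by_irs = as.list(table(d$irs_group3)),
                            by_treatment = as.list(table(d$treatment)),
                            audit = as.list(cohort$audit)))
  contrasts <- list(c("PD-(L)1 mono", "chemo"),
                    c("PD-(L)1+chemo", "chemo"),
                    c("PD-(L)1+chemo", "PD-(L)1 mono"))
  for (g in levels(d$irs_group3)) {
    dg <- d[d$irs_group3 == g, ]
    if (nrow(dg) < 30 || length(unique(dg$treatment)) < 2) next
    dg$tumor_f <- assign_tumor_type_covariate(dg$tumor_type)
    km <- lapply(split(seq_len(nrow(dg)), dg$treatment), function(ii)
      if (length(ii)) km_brief(km_estimate(dg$rwpfs_months[ii],
                                           dg$rwpfs_event[ii])))
    pair_fits <- list()
    for (ct in contrasts) {
      sel <- dg$treatment %in% ct
      ds <- dg[sel, ]
      if (length(unique(as.character(ds$treatment))) < 2 ||
          nrow(ds) < 20 || sum(ds$rwpfs_event) < 5) next
      ds$trt <- factor(as.character(ds$treatment), levels = rev(ct))
      ds$tumor_f <- assign_tumor_type_covariate(ds$tumor_type)
      f <- build_adjusted_formula(ds, "rwpfs_months", "rwpfs_event", "trt",
                                  extra = "pdl1")
      key <- paste(ct[1], "vs", ct[2])
      pair_fits[[key]] <- cox_brief(fit_cox(ds, f, term = "trt"))
      if (overlap_weighting) {
        ow <- tryCatch(
          overlap_weight_analysis(ds, "trt",
                                  covariates = c("age", "line_number", "pdl1")),
          error = function(e) NULL)
        if (!is.null(ow))
          pair_fits[[key]]$overlap_weighted <-
            list(aHR = ow$cox$aHR, ci95 = as.list(ow$cox$ci95),
                 p_value = ow$cox$p_value,
                 max_balance_gap = max(abs(ow$balance$difference)))
      }
    }
    out[[paste0("irs_", g)]] <- list(n = nrow(dg), km_by_treatment = km,
                                     contrasts = pair_fits)
  }
  out
}

#' PD-L1 IHC model comparison
#'
#' Nested Cox model comparison on a cohort with clinical PD-L1 IHC scores:
#' the baseline model carries continuous log2(IHC + 1) with the standard
#' clinical covariates; TMB status, IRS status, and both are added in turn
#' and each extension is tested against the baseline by likelihood-ratio
#' test.
#'
#' @inheritParams run_monotherapy_validation
#' @param ihc_col name of the IHC score column on `patients` (0-100 scale;
#'   entered into models as log2(score + 1))
#' @return report list with the four model fits and LRT p-values
#' @export
run_ihc_model_comparison <- function(patients, lines, ihc_col = "ihc_score",
                                     model = irs_model(), spec = NULL) {
  patients <- ensure_scored(patients, model)
  if (is.null(patients[[ihc_col]]))
    stop_input("patients table has no IHC column '%s'", ihc_col)
  if (is.null(spec))
    spec <- cohort_spec("pdl1-ihc",
                        classes = c("PD-(L)1 mono", "PD-(L)1+chemo"),
                        exclude_discovery = FALSE)
  cohort <- select_cohort(patients, lines, spec)
  d <- cohort$data
  if (nrow(d) == 0)
    return(list(status = "empty cohort", audit = as.list(cohort$audit)))
  d$tumor_f <- assign_tumor_type_covariate(d$tumor_type)
  d$log_ihc <- log2(d[[ihc_col]] + 1)   # +1 offset admits score 0
  d$tmb_h <- factor(ifelse(d$tmb >= 10, "H", "L"), levels = c("L", "H"))

  base_f <- build_adjusted_formula(d, "rwpfs_months", "rwpfs_event",
                                   "log_ihc")
  m1 <- fit_cox(d, base_f, term = "log_ihc")
  m2 <- fit_cox(d, stats::update(base_f, . ~ . + tmb_h), term = "tmb_hH")
  m3 <- fit_cox(d, stats::update(base_f, . ~ . + irs_group2),
                term = "irs_group2H")
  m4 <- fit_cox(d, stats::update(base_f, . ~ . + tmb_h + irs_group2),
                term = "irs_group2H")
  list(status = "ok",
       n = nrow(d), events = sum(d$rwpfs_event),
       model1_ihc = cox_brief(m1),
       model2_tmb = c(cox_brief(m2), lrt_vs_base = lrt_nested(m2, m1)$p_value),
       model3_irs = c(cox_brief(m3), lrt_vs_base = lrt_nested(m3, m1)$p_value),
       model4_all = c(cox_brief(m4), lrt_vs_base = lrt_nested(m4, m1)$p_value))
}

#' Run a configured analysis and write its report bundle
#'
#' `config` is a list (or path to a YAML file) with fields:
#' \describe{
#'   \item{analysis}{one of `"monotherapy"`, `"crossover"`,
#'     `"treatment-comparison"`, `"ihc-models"`, `"simulate"`}
#'   \item{patients,lines}{input CSV paths (omit when `simulate` is given)}
#'   \item{simulate}{optional list of [sim_config()] overrides; when
#'     present the cohort is generated rather than read}
#'   \item{seed}{integer seed for any simulation}
#'   \item{out}{output directory (created); JSON report plus CSV artifacts}
#' }
#' Identical config and inputs produce an identical report (no timestamps).
#'
#' @param config list or YAML path
#' @return the report list, invisibly; written to `<out>/report.json` when
#'   `out` is set
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  analysis <- config$analysis
  if (is.null(analysis))
    stop_input("config must name an 'analysis'")
  if (!is.null(config$simulate) || analysis == "simulate") {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- as.integer(config$seed)
    cohort <- generate_cohort(do.call(sim_config, sim_args))
    patients <- cohort$patients
    lines <- cohort$lines
  } else {
    for (fld in c("patients", "lines"))
      if (is.null(config[[fld]]) || !file.exists(config[[fld]]))
        stop_input("config field '%s' must point to an existing file", fld)
    patients <- read_table_auto(config$patients)
    lines <- read_table_auto(config$lines)
  }
  report <- switch(analysis,
    "monotherapy" = run_monotherapy_validation(patients, lines),
    "crossover" = run_crossover_analysis(patients, lines),
    "treatment-comparison" = run_treatment_comparison(patients, lines),
    "ihc-models" = run_ihc_model_comparison(patients, lines,
                                            ihc_col = config$ihc_col %||% "ihc_score"),
    "simulate" = list(status = "ok",
                      n_patients = nrow(patients), n_lines = nrow(lines)),
    stop_input("unknown analysis '%s'", analysis))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(strip_unserializable(report),
                         file.path(config$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write.csv(patients, file.path(config$out, "patients.csv"),
              row.names = FALSE)
    write.csv(lines, file.path(config$out, "lines.csv"), row.names = FALSE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop fitted model objects and other non-JSON payloads from a report
strip_unserializable <- function(x) {
  if (inherits(x, c("coxph", "survfit", "cox_fit", "km_summary")))
    return(NULL)
  if (is.list(x)) {
    x <- lapply(x, strip_unserializable)
    x[!vapply(x, is.null, logical(1))]
  } else x
}
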