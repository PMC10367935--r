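# Case cross-over analysis: each patient's rwPFS on the index anti-PD-(L)1
# monotherapy line is compared with rwPFS on the immediately preceding
# systemic therapy line within the same patient.

#' Build case cross-over pairs
#'
#' One pair per eligible patient: those whose index PD-(L)1 line was
#' preceded by at least one systemic therapy line. The preceding line is
#' the line with the largest start day strictly before the index line's
#' start. Patients whose index line is first-line contribute no pair.
#' Construction is order-independent and idempotent.
#'
#' @param cohort an `analysis_cohort` from [select_cohort()] (the index
#'   lines) whose underlying line history is supplied as `lines`
#' @param patients full patient table
#' @param lines full therapy-line table (for preceding-line lookup)
#' @return data.frame with one row per pair: `patient_id`, `irs_group`,
#'   `pfs1_months`/`pfs1_event` (preceding line), `pfs2_months`/`pfs2_event`
#'   (index line)
#' @export
build_crossover_pairs <- function(cohort, patients, lines) {
  stopifnot(inherits(cohort, "analysis_cohort"))
  idx <- cohort$data
  if (is.null(idx$irs_group2)) idx <- ensure_scored(idx)
  if (is.null(lines$therapy_class)) lines <- classify_therapy_lines(lines)
  out <- lapply(seq_len(nrow(idx)), function(i) {
    row <- idx[i, ]
    prev <- lines[lines$patient_id == row$patient_id &
                    lines$start_day < row$start_day, , drop = FALSE]
    if (nrow(prev) == 0) return(NULL)
    prev <- prev[which.max(prev$start_day), ]
    if (prev$start_day >= row$start_day)
      stop_input("preceding line does not precede index for patient %s",
                 row$patient_id)
    p <- patients[patients$patient_id == row$patient_id, ]
    pfs1 <- derive_rwpfs(p, prev, lines)
    data.frame(patient_id = row$patient_id,
               irs_group = as.character(row$irs_group2),
               prior_class = prev$therapy_class,
               pfs1_months = pfs1$duration_months,
               pfs1_event = pfs1$event,
               pfs2_months = row$rwpfs_months,
               pfs2_event = row$rwpfs_event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient_id = character(), irs_group = character(),
                      prior_class = character(), pfs1_months = numeric(),
                      pfs1_event = logical(), pfs2_months = numeric(),
                      pfs2_event = logical())
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Stack cross-over pairs into a long per-line table
#'
#' Two rows per patient: the preceding line (`treatment = "prior"`) and the
#' index PD-(L)1 line (`treatment = "PD-(L)1"`).
#'
#' @param pairs output of [build_crossover_pairs()]
#' @return long data.frame with `patient_id`, `treatment`, `irs_group`,
#'   `months`, `event`
#' @export
stack_crossover <- function(pairs) {
  long <- rbind(
    data.frame(patient_id = pairs$patient_id, treatment = "prior",
               irs_group = pairs$irs_group, months = pairs$pfs1_months,
               event = pairs$pfs1_event, stringsAsFactors = FALSE),
    data.frame(patient_id = pairs$patient_id, treatment = "PD-(L)1",
               irs_group = pairs$irs_group, months = pairs$pfs2_months,
               event = pairs$pfs2_event, stringsAsFactors = FALSE))
  long$treatment <- factor(long$treatment, levels = c("prior", "PD-(L)1"))
  long$irs_group <- factor(long$irs_group, levels = c("L", "H"))
  long
}

#' Treatment-by-IRS interaction test for the cross-over cohort
#'
#' Stacks both rwPFS records of every pair, fits a Cox model with
#' treatment, IRS group and their interaction, and tests the interaction by
#' a likelihood-ratio test against the no-interaction model (chi-squared,
#' df = 1, on the partial likelihood). The paired dependence is
#' acknowledged through cluster-robust (by patient) variance for the
#' reported Wald intervals. Per-IRS-group log-rank comparisons of PD-(L)1
#' versus the preceding line are reported alongside.
#'
#' @param pairs output of [build_crossover_pairs()]
#' @return list with `lrt` (statistic, df, p_value), `full`/`reduced`
#'   `cox_fit`s, `interaction_coef`, and `by_group` (per-IRS-group log-rank
#'   p and medians)
#' @export
interaction_lrt <- function(pairs) {
  if (any(table(pairs$irs_group) < 2))
    stop_input("need at least 2 pairs in each IRS group")
  long <- stack_crossover(pairs)
  full <- fit_cox(long, Surv(months, event) ~ treatment * irs_group,
                  term = "treatmentPD-(L)1", cluster_var = "patient_id")
  reduced <- fit_cox(long, Surv(months, event) ~ treatment + irs_group,
                     term = "treatmentPD-(L)1", cluster_var = "patient_id")
  lrt <- lrt_nested(full, reduced)
  by_group <- lapply(levels(long$irs_group), function(g) {
    sub <- long[long$irs_group == g, ]
    sd_ <- survdiff(Surv(months, event) ~ treatment, data = sub)
    meds <- tapply(seq_len(nrow(sub)), sub$treatment, function(ii)
      km_estimate(sub$months[ii], sub$event[ii])$median)
    list(irs_group = g, n_pairs = nrow(sub) / 2,
         logrank_p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
         median_prior = meds[["prior"]], median_pdl1 = meds[["PD-(L)1"]])
  })
  names(by_group) <- levels(long$irs_group)
  ic <- full$coefficients[grep(":", names(full$coefficients))]
  list(lrt = lrt, full = full, reduced = reduced,
       interaction_coef = ic, by_group = by_group)
}

#' Classify rwPFS2/rwPFS1 ratios against a benefit cutoff
#'
#' The PFS ratio of the index PD-(L)1 line over the immediately preceding
#' line; a ratio at or above the cutoff (default 1.3, inclusive) indicates
#' clinical benefit of the index therapy. A pair is evaluable when the
#' denominator PFS is a completed (event) record and the classification is
#' determinate: the numerator either ended in an event or was censored at
#' or above cutoff times the denominator (a censored numerator already
#' beyond the cutoff can only classify above). Classification is
#' scale-invariant.
#'
#' @param pairs output of [build_crossover_pairs()]
#' @param cutoff benefit threshold on the ratio (inclusive)
#' @return list with the annotated `pairs` (adds `evaluable`, `ratio`,
#'   `above_cutoff`), `counts` (per-IRS-group evaluable/above), and `table`
#'   (2x2 matrix IRS-H/IRS-L x above/below for [cmh_ratio_test()])
#' @export
pfs_ratio_classify <- function(pairs, cutoff = 1.3) {
  p <- pairs
  denom_ok <- p$pfs1_event & p$pfs1_months > 0
  ratio <- ifelse(denom_ok, p$pfs2_months / p$pfs1_months, NA_real_)
  determinate <- denom_ok & (p$pfs2_event | ratio >= cutoff)
  p$evaluable <- determinate
  p$ratio <- ifelse(p$evaluable, ratio, NA_real_)
  p$above_cutoff <- ifelse(p$evaluable, ratio >= cutoff, NA)

  ev <- p[p$evaluable & !is.na(p$evaluable), ]
  counts <- do.call(rbind, lapply(c("H", "L"), function(g) {
    sub <- ev[ev$irs_group == g, ]
    data.frame(irs_group = g, evaluable = nrow(sub),
               above = sum(sub$above_cutoff),
               proportion = if (nrow(sub)) sum(sub$above_cutoff) / nrow(sub)
                            else NA_real_)
  }))
  tab <- matrix(c(counts$above[1], counts$evaluable[1] - counts$above[1],
                  counts$above[2], counts$evaluable[2] - counts$above[2]),
                nrow = 2, byrow = TRUE,
                dimnames = list(irs = c("H", "L"),
                                ratio = c("above", "below")))
  list(pairs = p, counts = counts, table = tab, cutoff = cutoff)
}
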