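#' The locked IRS scoring model
#'
#' Returns the Immunotherapy Response Score model object: the five fixed
#' linear weights (TMB, PD-1, PD-L1, TOP2A, ADAM12) and the two
#' classification thresholds. The defaults are the locked constants of the
#' published model and should not normally be changed; they are exposed as
#' arguments so that sensitivity analyses can perturb them explicitly.
#'
#' The score is
#' \deqn{IRS = 0.273758\,TMB + 0.112641\,PD1 + 0.061904\,PDL1
#'       - 0.077011\,TOP2A - 0.057991\,ADAM12}
#' with TMB in mutations per megabase (model scale, see `tmb_transform`) and
#' the four expression covariates in log2 normalized-reads-per-million.
#' Two-group status is High (H) when the score is >= `threshold_high`
#' (inclusive), otherwise Low (L). The three-group classification further
#' splits Low into Ultra-Low (UL, score < `threshold_ul`) and
#' Intermediate-Low (IL, `threshold_ul` <= score < `threshold_high`).
#'
#' @param coef_tmb,coef_pd1,coef_pdl1,coef_top2a,coef_adam12 model weights
#' @param threshold_high score threshold at and above which a sample is IRS-H
#' @param threshold_ul score threshold strictly below which a sample is IRS-UL
#' @param tmb_transform function applied to the raw Muts/Mb TMB before it
#'   enters the linear model. The default is the identity (TMB enters on the
#'   raw Muts/Mb scale); any upstream transform is configuration here, not a
#'   property of the score.
#' @return an object of class `irs_model`
#' @examples
#' m <- irs_model()
#' irs_score(tmb = 1, pd1 = 0, pdl1 = 0, top2a = 0, adam12 = 0, model = m)
#' @export
irs_model <- function(coef_tmb = 0.273758,
                      coef_pd1 = 0.112641,
                      coef_pdl1 = 0.061904,
                      coef_top2a = -0.077011,
                      coef_adam12 = -0.057991,
                      threshold_high = 0.873569,
                      threshold_ul = 0.41,
                      tmb_transform = identity) {
  check_finite(c(coef_tmb, coef_pd1, coef_pdl1, coef_top2a, coef_adam12,
                 threshold_high, threshold_ul), "irs_model coefficients")
  if (threshold_ul >= threshold_high)
    stop_input("threshold_ul (%g) must be below threshold_high (%g)",
               threshold_ul, threshold_high)
  stopifnot(is.function(tmb_transform))
  structure(
    list(coef = c(tmb = coef_tmb, pd1 = coef_pd1, pdl1 = coef_pdl1,
                  top2a = coef_top2a, adam12 = coef_adam12),
         threshold_high = threshold_high,
         threshold_ul = threshold_ul,
         tmb_transform = tmb_transform),
    class = "irs_model")
}

#' @export
print.irs_model <- function(x, ...) {
  cat("IRS scoring model\n")
  cat("  weights:", paste(names(x$coef), format(x$coef), sep = "=",
                          collapse = ", "), "\n")
  cat(sprintf("  groups : H >= %g; UL < %g; IL otherwise\n",
              x$threshold_high, x$threshold_ul))
  invisible(x)
}

#' Compute the IRS linear score
#'
#' Exact linear combination of the five molecular covariates with the model
#' weights; no clipping or rounding. All arguments are vectorized and
#' recycled to a common length.
#'
#' @param tmb model-scale tumor mutation burden (Muts/Mb under the default
#'   model; `model$tmb_transform` is applied first)
#' @param pd1,pdl1,top2a,adam12 log2 normalized-reads-per-million expression;
#'   negative values are permitted (log scale)
#' @param model an [irs_model()]
#' @return numeric score vector, full float precision
#' @export
irs_score <- function(tmb, pd1, pdl1, top2a, adam12, model = irs_model()) {
  for (nm in c("tmb", "pd1", "pdl1", "top2a", "adam12"))
    check_finite(get(nm), nm)
  tmb <- model$tmb_transform(tmb)
  check_finite(tmb, "tmb (after model transform)")
  w <- model$coef
  w[["tmb"]] * tmb + w[["pd1"]] * pd1 + w[["pdl1"]] * pdl1 +
    w[["top2a"]] * top2a + w[["adam12"]] * adam12
}

#' Classify an IRS score into two- and three-group status
#'
#' Classification happens on the unrounded score. Boundaries follow the
#' locked model exactly: H is inclusive at the high threshold
#' (score >= 0.873569), IL is inclusive at its lower bound (score >= 0.41),
#' UL is strictly below it.
#'
#' @param score numeric score vector (finite)
#' @param model an [irs_model()]
#' @return data.frame with columns `score`, `irs_group2` (factor L/H) and
#'   `irs_group3` (factor UL/IL/H)
#' @export
irs_classify <- function(score, model = irs_model()) {
  check_finite(score, "score")
  g2 <- factor(ifelse(score >= model$threshold_high, "H", "L"),
               levels = c("L", "H"))
  g3 <- factor(ifelse(score >= model$threshold_high, "H",
                      ifelse(score >= model$threshold_ul, "IL", "UL")),
               levels = c("UL", "IL", "H"))
  data.frame(score = score, irs_group2 = g2, irs_group3 = g3)
}

#' Score a table of per-sample molecular covariates
#'
#' Takes a data.frame (or a path to a CSV/TSV file) with columns
#' `sample_id`, `tmb`, `pd1`, `pdl1`, `top2a`, `adam12` and returns it with
#' `score`, `irs_group2` and `irs_group3` appended.
#'
#' @param x data.frame or file path (delimiter sniffed from the extension:
#'   `.tsv`/`.txt` tab, otherwise comma)
#' @param model an [irs_model()]
#' @return the input table with scoring columns appended
#' @export
irs_score_table <- function(x, model = irs_model()) {
  if (is.character(x)) x <- read_table_auto(x)
  need <- c("sample_id", "tmb", "pd1", "pdl1", "top2a", "adam12")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_input("covariate table is missing columns: %s",
               paste(miss, collapse = ", "))
  bad <- !complete.cases(x[, c("tmb", "pd1", "pdl1", "top2a", "adam12")])
  if (any(bad))
    stop_input("non-finite covariates for samples: %s",
               paste(head(x$sample_id[bad], 5), collapse = ", "))
  sc <- irs_score(x$tmb, x$pd1, x$pdl1, x$top2a, x$adam12, model)
  cls <- irs_classify(sc, model)
  x$score <- cls$score
  x$irs_group2 <- cls$irs_group2
  x$irs_group3 <- cls$irs_group3
  x
}

read_table_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    read.delim(path, stringsAsFactors = FALSE)
  else
    read.csv(path, stringsAsFactors = FALSE)
}
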