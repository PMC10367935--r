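# Cohort construction: therapy-line classification, real-world endpoint
# derivation and eligibility filtering.
#
# Clinical inputs are two flat tables joined on patient_id:
#   patients: patient_id, age, sex, tumor_type, race, collection_day,
#             death_day (NA if alive), last_followup_day, prior_io,
#             msi_high, in_discovery, in_prior_validation, and the molecular
#             covariates tmb, pd1, pdl1, top2a, adam12
#   lines:    patient_id, line_number, start_day, stop_day (NA allowed),
#             agents ("+"-separated), plus derived therapy_class and
#             pembrolizumab
# All dates are integer day offsets on a per-patient clock.

#' Default drug dictionary for therapy-line classification
#'
#' Three agent categories: anti-PD-(L)1 antibodies, cytotoxic chemotherapy,
#' and permitted non-chemotherapy partners (ramucirumab, bevacizumab,
#' cetuximab) that are compatible with inclusion but do not define a class
#' by themselves. Extend or replace any component for site-specific
#' formularies.
#'
#' @return named list of character vectors `anti_pdl1`, `cytotoxic`,
#'   `compatible`
#' @export
default_drug_dictionary <- function() {
  list(
    anti_pdl1 = c("pembrolizumab", "nivolumab", "atezolizumab",
                  "durvalumab", "avelumab", "cemiplimab", "dostarlimab"),
    cytotoxic = c("carboplatin", "cisplatin", "oxaliplatin", "paclitaxel",
                  "nab-paclitaxel", "docetaxel", "pemetrexed", "gemcitabine",
                  "fluorouracil", "5-fluorouracil", "capecitabine",
                  "etoposide", "irinotecan", "topotecan", "vinorelbine",
                  "doxorubicin", "eribulin", "cyclophosphamide"),
    compatible = c("ramucirumab", "bevacizumab", "cetuximab"))
}

#' Classify a therapy line from its agent set
#'
#' Deterministic mapping from the set of drug names to one of
#' `"PD-(L)1 mono"`, `"chemo"`, `"PD-(L)1+chemo"` or `"other"`. Permitted
#' partner agents (see [default_drug_dictionary()]) are ignored for
#' classification; a line containing any agent outside the dictionary is
#' classed `"other"`.
#'
#' @param agents character vector of agents, or a single `"+"`-separated
#'   string
#' @param dictionary a drug dictionary, see [default_drug_dictionary()]
#' @return list with `therapy_class` and logical `pembrolizumab`
#' @examples
#' classify_therapy_line("carboplatin+pemetrexed+pembrolizumab")
#' @export
classify_therapy_line <- function(agents, dictionary = default_drug_dictionary()) {
  if (length(agents) == 1 && grepl("+", agents, fixed = TRUE))
    agents <- strsplit(agents, "+", fixed = TRUE)[[1]]
  agents <- tolower(trimws(agents))
  agents <- agents[nzchar(agents)]
  if (length(agents) == 0)
    stop_input("therapy line has an empty agent set")
  has_pd <- any(agents %in% dictionary$anti_pdl1)
  has_chemo <- any(agents %in% dictionary$cytotoxic)
  known <- agents %in% unlist(dictionary)
  cls <- if (any(!known)) "other"
         else if (has_pd && has_chemo) "PD-(L)1+chemo"
         else if (has_pd) "PD-(L)1 mono"
         else if (has_chemo) "chemo"
         else "other"
  list(therapy_class = cls, pembrolizumab = "pembrolizumab" %in% agents)
}

#' Classify every line in a therapy-line table
#'
#' @param lines data.frame with an `agents` column
#' @param dictionary see [default_drug_dictionary()]
#' @return `lines` with `therapy_class` and `pembrolizumab` columns added
#' @export
classify_therapy_lines <- function(lines, dictionary = default_drug_dictionary()) {
  cl <- lapply(lines$agents, classify_therapy_line, dictionary = dictionary)
  lines$therapy_class <- vapply(cl, `[[`, character(1), "therapy_class")
  lines$pembrolizumab <- vapply(cl, `[[`, logical(1), "pembrolizumab")
  lines
}

# minimum positive duration (days): a next line starting the day therapy
# started would otherwise yield a zero-length record, which survival fitters
# reject
MIN_DURATION_DAYS <- 0.5

next_line_start <- function(line, lines) {
  cand <- lines$start_day[lines$patient_id == line$patient_id &
                            lines$start_day > line$start_day]
  if (length(cand)) min(cand) else NA_real_
}

#' Derive real-world progression-free survival for a therapy line
#'
#' rwPFS is the time from starting the line to starting a new therapy line
#' or death, whichever comes first; patients with neither event are censored
#' at last follow-up. Durations are converted to months at 30.4375 days per
#' month; a same-day event is recorded at 0.5 day to keep durations
#' positive.
#'
#' @param patient one-row data.frame (or list) with `death_day` and
#'   `last_followup_day`
#' @param line one-row data.frame (or list) with `patient_id` and
#'   `start_day`
#' @param lines full therapy-line table for next-line lookup
#' @return list with `duration_months`, `event`, `endpoint = "rwPFS"`
#' @export
derive_rwpfs <- function(patient, line, lines) {
  own <- lines[lines$patient_id == line$patient_id, , drop = FALSE]
  if (!is.null(own$line_number) &&
      any(own$line_number > line$line_number &
            own$start_day <= line$start_day))
    stop_input("a later line starts on or before line %s of patient %s",
               line$line_number, line$patient_id)
  nxt <- next_line_start(line, lines)
  death <- patient$death_day
  cand <- c(nxt, if (!is.na(death) && !is.null(death)) death)
  cand <- cand[!is.na(cand)]
  if (length(cand)) {
    t_days <- min(cand) - line$start_day
    if (t_days < 0)
      stop_input("event before line start for patient %s", line$patient_id)
    event <- TRUE
  } else {
    t_days <- patient$last_followup_day - line$start_day
    if (t_days < 0)
      stop_input("last follow-up before line start for patient %s",
                 line$patient_id)
    event <- FALSE
  }
  list(duration_months = days_to_months(max(t_days, MIN_DURATION_DAYS)),
       event = event, endpoint = "rwPFS")
}

#' Derive overall survival for a therapy line
#'
#' OS is the time from line start to death; patients alive at data cutoff
#' are censored at last follow-up.
#'
#' @inheritParams derive_rwpfs
#' @return list with `duration_months`, `event`, `endpoint = "OS"`
#' @export
derive_os <- function(patient, line, lines = NULL) {
  death <- patient$death_day
  if (!is.null(death) && !is.na(death)) {
    t_days <- death - line$start_day
    event <- TRUE
  } else {
    t_days <- patient$last_followup_day - line$start_day
    event <- FALSE
  }
  if (t_days < 0)
    stop_input("negative OS duration for patient %s", line$patient_id)
  list(duration_months = days_to_months(max(t_days, MIN_DURATION_DAYS)),
       event = event, endpoint = "OS")
}

#' Specify an analysis cohort
#'
#' Encodes the eligibility rules used to assemble an analysis cohort from
#' validated patient and line tables: eligible therapy classes, the
#' molecular-data requirement, the specimen-before-treatment rule, prior
#' checkpoint-blockade exclusion, discovery/validation reuse exclusions,
#' optional MSI-H exclusion (used for the self-reported race cohort) and an
#' optional tumor-type whitelist.
#'
#' @param name cohort label
#' @param classes eligible therapy classes
#' @param require_molecular require finite TMB and expression covariates
#' @param require_collection_before_start specimen collected strictly before
#'   line start
#' @param exclude_prior_io exclude lines with prior anti-PD-(L)1/CTLA4
#'   exposure (patient flag or an earlier PD-(L)1-containing line)
#' @param exclude_discovery,exclude_prior_validation drop patients reused
#'   from earlier discovery / validation cohorts
#' @param exclude_msi_high drop MSI-H patients
#' @param tumor_whitelist optional character vector of tumor types
#' @param one_line_per_patient keep only the earliest eligible line per
#'   patient (monotherapy-style cohorts); multi-line cohorts set FALSE
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(name,
                        classes = "PD-(L)1 mono",
                        require_molecular = TRUE,
                        require_collection_before_start = TRUE,
                        exclude_prior_io = TRUE,
                        exclude_discovery = TRUE,
                        exclude_prior_validation = TRUE,
                        exclude_msi_high = FALSE,
                        tumor_whitelist = NULL,
                        one_line_per_patient = TRUE) {
  if (!is.null(tumor_whitelist) && length(tumor_whitelist) == 0)
    stop_input("tumor_whitelist must be NULL or nonempty")
  structure(as.list(environment()), class = "cohort_spec")
}

MOLECULAR_COLS <- c("tmb", "pd1", "pdl1", "top2a", "adam12")
PDL1_CLASSES <- c("PD-(L)1 mono", "PD-(L)1+chemo")

#' Assemble an analysis cohort
#'
#' Applies the criteria of a [cohort_spec()] to the candidate lines in
#' order, recording how many lines each criterion removes (the audit
#' counts sum to the total number excluded). Eligible lines are joined with
#' their patient covariates and annotated with derived rwPFS and OS records.
#' The result is order-independent: permuting the input patients or lines
#' yields the same cohort.
#'
#' @param patients patient table (see the file header of this module)
#' @param lines therapy-line table; classified first if `therapy_class` is
#'   absent
#' @param spec a [cohort_spec()]
#' @return object of class `analysis_cohort`: list with `data` (one row per
#'   eligible line, patient covariates and endpoint columns `rwpfs_months`,
#'   `rwpfs_event`, `os_months`, `os_event` attached), `audit` (named
#'   exclusion counts) and `spec`
#' @export
select_cohort <- function(patients, lines, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(lines$therapy_class)) lines <- classify_therapy_lines(lines)
  lines <- lines[order(lines$patient_id, lines$start_day), , drop = FALSE]
  patients <- patients[order(patients$patient_id), , drop = FALSE]

  cand <- lines
  audit <- c(candidates = nrow(cand))
  drop_step <- function(cand, keep, label) {
    audit[[label]] <<- sum(!keep)
    cand[keep, , drop = FALSE]
  }
  pat <- function(col) patients[[col]][match(cand$patient_id, patients$patient_id)]

  cand <- drop_step(cand, cand$therapy_class %in% spec$classes,
                    "ineligible_therapy_class")
  if (spec$require_molecular) {
    ok <- Reduce(`&`, lapply(MOLECULAR_COLS, function(cl) {
      v <- pat(cl); !is.na(v) & is.finite(v)
    }))
    cand <- drop_step(cand, ok, "missing_molecular_data")
  }
  if (spec$require_collection_before_start)
    cand <- drop_step(cand, pat("collection_day") < cand$start_day,
                      "specimen_after_line_start")
  if (spec$exclude_prior_io) {
    flag <- isTRUE_vec(pat("prior_io"))
    earlier_io <- vapply(seq_len(nrow(cand)), function(i) {
      sel <- lines$patient_id == cand$patient_id[i] &
        lines$start_day < cand$start_day[i] &
        lines$therapy_class %in% PDL1_CLASSES
      any(sel)
    }, logical(1))
    cand <- drop_step(cand, !(flag | earlier_io), "prior_checkpoint_blockade")
  }
  if (spec$exclude_discovery)
    cand <- drop_step(cand, !isTRUE_vec(pat("in_discovery")), "in_discovery")
  if (spec$exclude_prior_validation)
    cand <- drop_step(cand, !isTRUE_vec(pat("in_prior_validation")),
                      "in_prior_validation")
  if (spec$exclude_msi_high)
    cand <- drop_step(cand, !isTRUE_vec(pat("msi_high")), "msi_high")
  if (!is.null(spec$tumor_whitelist))
    cand <- drop_step(cand, pat("tumor_type") %in% spec$tumor_whitelist,
                      "tumor_type_not_whitelisted")
  if (spec$one_line_per_patient && nrow(cand)) {
    first <- !duplicated(cand$patient_id)   # cand is start_day-ordered
    cand <- drop_step(cand, first, "later_lines_collapsed")
  }

  data <- merge(cand, patients, by = "patient_id", sort = TRUE)
  data <- data[order(data$patient_id, data$start_day), , drop = FALSE]
  if (nrow(data)) {
    ep <- lapply(seq_len(nrow(data)), function(i) {
      p <- data[i, ]
      rw <- derive_rwpfs(p, p, lines)
      os <- derive_os(p, p)
      c(rw$duration_months, rw$event, os$duration_months, os$event)
    })
    ep <- do.call(rbind, ep)
    data$rwpfs_months <- ep[, 1]
    data$rwpfs_event <- as.logical(ep[, 2])
    data$os_months <- ep[, 3]
    data$os_event <- as.logical(ep[, 4])
  }
  rownames(data) <- NULL
  structure(list(data = data, audit = audit, spec = spec),
            class = "analysis_cohort")
}

#' @export
print.analysis_cohort <- function(x, ...) {
  cat(sprintf("Analysis cohort '%s': %d lines from %d patients\n",
              x$spec$name, nrow(x$data), length(unique(x$data$patient_id))))
  cat("Exclusion audit:\n")
  for (nm in names(x$audit)[-1])
    cat(sprintf("  %-28s %d\n", nm, x$audit[[nm]]))
  invisible(x)
}

#' Recode the tumor-type covariate for adjusted models
#'
#' Tumor types with more than `min_count` lines in the cohort keep their
#' own level; the rest are grouped into a single `"other"` level. The
#' reference level is the most frequent type. The count is of lines (rows),
#' the unit entering the models.
#'
#' @param tumor_type character vector of tumor-type labels
#' @param min_count strict threshold; a type is kept separate when its
#'   count exceeds this (default 15)
#' @return factor with the recoded, reference-ordered levels
#' @export
assign_tumor_type_covariate <- function(tumor_type, min_count = 15) {
  if (length(tumor_type) == 0) stop_input("empty cohort")
  tab <- sort(table(tumor_type), decreasing = TRUE)
  keep <- names(tab)[tab > min_count]
  out <- ifelse(tumor_type %in% keep, tumor_type, "other")
  lev <- c(keep, if (any(out == "other")) "other")
  factor(out, levels = lev)
}

#' Group self-reported race into analysis categories
#'
#' American Indian/Alaskan Native, Native Hawaiian/Pacific Islander and
#' Other are combined as `"Other"`; Other, Asian and Black or African
#' American together form `"non-European"`; White or Caucasian is
#' `"European"`; missing values are `"unknown"`.
#'
#' @param race character vector of self-reported race labels
#' @return data.frame with `race_group` (fine grouping: European, Asian,
#'   Black, Other, unknown) and `race_binary` (European / non-European /
#'   unknown)
#' @export
group_race <- function(race) {
  race <- tolower(trimws(as.character(race)))
  fine <- rep("unknown", length(race))
  fine[race %in% c("white", "caucasian", "white or caucasian",
                   "european")] <- "European"
  fine[race %in% c("asian")] <- "Asian"
  fine[race %in% c("black", "black or african american",
                   "african american")] <- "Black"
  fine[race %in% c("american indian or alaskan native",
                   "native hawaiian or other pacific islander",
                   "other")] <- "Other"
  bin <- ifelse(fine == "European", "European",
                ifelse(fine == "unknown", "unknown", "non-European"))
  data.frame(race_group = fine, race_binary = bin,
             stringsAsFactors = FALSE)
}

#' Check the line-count targets for including a tumor type
#'
#' Reusable predicate for the treatment-comparison cohort: a tumor type is
#' targeted for inclusion when it reaches a minimum total number of lines
#' with per-class minima (defaults: 80 total with at least 40 chemotherapy,
#' 20 combination and 20 monotherapy lines).
#'
#' @param therapy_class character vector of classes for one tumor type
#' @param min_total,min_chemo,min_combo,min_mono the targets
#' @return logical
#' @export
tumor_type_meets_targets <- function(therapy_class, min_total = 80,
                                     min_chemo = 40, min_combo = 20,
                                     min_mono = 20) {
  length(therapy_class) >= min_total &&
    sum(therapy_class == "chemo") >= min_chemo &&
    sum(therapy_class == "PD-(L)1+chemo") >= min_combo &&
    sum(therapy_class == "PD-(L)1 mono") >= min_mono
}
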