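test_that("rwPFS derives from next-line start, death, or censoring", {
  p <- make_patient(death_day = 300, last_fu = 300)
  l <- rbind(make_line(line_number = 1, start_day = 0),
             make_line(line_number = 2, start_day = 120,
                       agents = "carboplatin"))
  # next line (day 120) precedes death (day 300)
  r <- derive_rwpfs(p, l[1, ], l)
  expect_true(r$event)
  expect_equal(r$duration_months, 120 / 30.4375, tolerance = 1e-12)
  expect_equal(r$duration_months, 3.94, tolerance = 0.01)

  # no next line: death is the event
  r2 <- derive_rwpfs(make_patient(death_day = 250, last_fu = 250),
                     make_line(), make_line())
  expect_true(r2$event)
  expect_equal(r2$duration_months, 250 / 30.4375)

  # alive, no next line: censored at last follow-up
  r3 <- derive_rwpfs(make_patient(last_fu = 400), make_line(), make_line())
  expect_false(r3$event)
  expect_equal(r3$duration_months, 400 / 30.4375)

  # same-day next line keeps a positive duration
  l0 <- rbind(make_line(line_number = 1, start_day = 100),
              make_line(line_number = 2, start_day = 100.5))
  r4 <- derive_rwpfs(make_patient(), l0[1, ], l0)
  expect_gt(r4$duration_months, 0)

  # inconsistent ordering errors
  lbad <- rbind(make_line(line_number = 1, start_day = 100),
                make_line(line_number = 2, start_day = 50))
  expect_error(derive_rwpfs(make_patient(), lbad[1, ], lbad), "before")
})

test_that("OS derivation and the rwPFS <= OS invariant", {
  p <- make_patient(death_day = 300, last_fu = 300)
  expect_equal(derive_os(p, make_line())$duration_months, 300 / 30.4375)
  expect_false(derive_os(make_patient(last_fu = 400), make_line())$event)

  # property: for any record layout, rwPFS duration <= OS duration
  set.seed(31)
  for (i in 1:40) {
    death <- if (runif(1) < 0.5) sample(50:500, 1) else NA
    fu <- if (is.na(death)) sample(50:500, 1) else death
    nxt <- if (runif(1) < 0.5) sample(10:fu, 1) else NA
    p <- make_patient(death_day = death, last_fu = fu)
    l <- make_line(line_number = 1, start_day = 0)
    if (!is.na(nxt))
      l <- rbind(l, make_line(line_number = 2, start_day = nxt))
    rw <- derive_rwpfs(p, l[1, ], l)
    os <- derive_os(p, l[1, ])
    expect_lte(rw$duration_months, os$duration_months + 1e-12)
    if (os$event) expect_false(is.na(death))
  }
})

test_that("therapy-line classification maps agent sets deterministically", {
  expect_equal(classify_therapy_line("pembrolizumab"),
               list(therapy_class = "PD-(L)1 mono", pembrolizumab = TRUE))
  expect_equal(classify_therapy_line(c("carboplatin", "pemetrexed",
                                       "pembrolizumab"))$therapy_class,
               "PD-(L)1+chemo")
  # permitted partners are chemo-compatible, not class-defining
  expect_equal(classify_therapy_line(c("carboplatin",
                                       "bevacizumab"))$therapy_class,
               "chemo")
  expect_equal(classify_therapy_line("atezolizumab")$pembrolizumab, FALSE)
  expect_equal(classify_therapy_line("osimertinib")$therapy_class, "other")
  expect_equal(classify_therapy_line("bevacizumab")$therapy_class, "other")
  expect_error(classify_therapy_line(character()), "empty")
})

test_that("cohort selection matches hand enumeration on a known fixture", {
  # 20 patients, each with one pembrolizumab line; flags chosen so that
  # eligibility is decidable by hand
  pats <- do.call(rbind, lapply(1:20, function(i)
    make_patient(patient_id = sprintf("P%02d", i))))
  lns <- do.call(rbind, lapply(1:20, function(i)
    make_line(patient_id = sprintf("P%02d", i), start_day = 30)))
  pats$tmb[2] <- NA                       # P02: no molecular data
  pats$collection_day[3] <- 30            # P03: specimen not before start
  pats$collection_day[4] <- 31            # P04: specimen after start
  pats$prior_io[5] <- TRUE                # P05: prior checkpoint blockade
  pats$in_discovery[6] <- TRUE            # P06: reused from discovery
  pats$in_prior_validation[7] <- TRUE     # P07: reused from validation
  pats$msi_high[8] <- TRUE                # excluded only when flag set
  lns$agents[9] <- "carboplatin"          # P09: not monotherapy
  # P10: earlier PD-(L)1 line (itself ineligible: starts before specimen
  # collection) implies prior blockade for the index line
  lns <- rbind(lns, make_line(patient_id = "P10", line_number = 0,
                              start_day = -5, agents = "nivolumab"))
  expected <- sprintf("P%02d", c(1, 8, 11:20))

  co <- select_cohort(pats, lns, cohort_spec("test"))
  expect_setequal(co$data$patient_id, expected)
  # audit counts: each criterion logs its exclusions and they sum
  expect_equal(unname(co$audit[["candidates"]] - sum(co$audit[-1])),
               nrow(co$data))
  expect_equal(unname(co$audit[["missing_molecular_data"]]), 1)
  expect_equal(unname(co$audit[["specimen_after_line_start"]]), 3)
  expect_equal(unname(co$audit[["prior_checkpoint_blockade"]]), 2)

  # MSI-H exclusion flag (race-cohort variant) removes P08
  co2 <- select_cohort(pats, lns,
                       cohort_spec("race", exclude_msi_high = TRUE))
  expect_false("P08" %in% co2$data$patient_id)

  # order independence
  perm <- sample(nrow(pats))
  co3 <- select_cohort(pats[perm, ], lns[sample(nrow(lns)), ],
                       cohort_spec("test"))
  expect_equal(co3$data$patient_id, co$data$patient_id)

  # empty result is allowed
  co4 <- select_cohort(pats, lns,
                       cohort_spec("none", classes = "PD-(L)1+chemo"))
  expect_equal(nrow(co4$data), 0)
})

test_that("tumor-type recoding groups at the strict >15 threshold", {
  tt <- rep(c("A", "B", "C", "D"), c(20, 16, 15, 2))
  f <- assign_tumor_type_covariate(tt)
  expect_equal(levels(f), c("A", "B", "other"))
  expect_equal(levels(f)[1], "A")          # reference = most frequent
  expect_equal(sum(f == "other"), 17)
  # 16 > 15: kept separate even alone
  expect_equal(levels(assign_tumor_type_covariate(rep("A", 16))), "A")
  # single level degenerates to one level
  expect_equal(nlevels(assign_tumor_type_covariate(rep("X", 5))), 1)
  expect_error(assign_tumor_type_covariate(character()), "empty")
})

test_that("race grouping follows the published collapse", {
  g <- group_race(c("White or Caucasian", "Asian",
                    "Black or African American", "Other",
                    "American Indian or Alaskan Native", NA))
  expect_equal(g$race_group,
               c("European", "Asian", "Black", "Other", "Other", "unknown"))
  expect_equal(g$race_binary,
               c("European", "non-European", "non-European", "non-European",
                 "non-European", "unknown"))
})

test_that("tumor-type targeting predicate applies the line-count minima", {
  cls <- rep(c("chemo", "PD-(L)1+chemo", "PD-(L)1 mono"), c(40, 20, 20))
  expect_true(tumor_type_meets_targets(cls))
  expect_false(tumor_type_meets_targets(cls[-1]))
  expect_false(tumor_type_meets_targets(rep("chemo", 100)))
})
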