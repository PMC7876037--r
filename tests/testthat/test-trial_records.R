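test_that("parse_trial_record populates fields and maps absence to missing", {
  r <- parse_trial_record(fixture_xml())
  expect_s3_class(r, "trial_record")
  expect_equal(r$status, "Completed")
  expect_equal(r$start_year, 2005L)
  expect_equal(r$sponsor_class, "Industry")
  expect_equal(r$collaborator_classes, "Other")
  expect_equal(r$n_officials, 1L)
  expect_equal(r$has_dmc, "yes")
  expect_equal(r$phase, "Phase 2")
  expect_equal(r$n_arms, 2L)
  expect_equal(r$has_placebo, "yes")
  expect_equal(r$randomized, "yes")
  expect_equal(r$site_countries, c("United States", "United States", "France"))
  expect_equal(r$keywords_field, "Ankle Joint; Osteoarthritis")

  r2 <- parse_trial_record(fixture_xml(include_description = FALSE))
  expect_true(is.na(r2$detailed_description))
  # fields absent from the document are missing, not defaulted
  minimal <- parse_trial_record("<clinical_study><overall_status>Terminated</overall_status></clinical_study>")
  expect_true(is.na(minimal$sponsor_class))
  expect_true(is.na(minimal$eligibility_text))
  expect_true(is.na(minimal$is_fda_regulated))
  expect_equal(minimal$n_sites, 0L)
})

test_that("parse_trial_record rejects malformed XML and unknown statuses", {
  expect_error(parse_trial_record("<clinical_study><overall_status>Completed"),
               "malformed")
  expect_error(parse_trial_record(fixture_xml(status = "Cancelled")),
               "unknown trial status.*Cancelled")
  expect_error(parse_trial_record("<clinical_study></clinical_study>"),
               "overall_status")
})

test_that("main country is the modal country with first-listed tie-break", {
  expect_equal(resolve_main_country(c("United States", "United States", "France")),
               "United States")
  expect_equal(resolve_main_country(c("France", "United States")), "France")
  expect_equal(resolve_main_country("Canada"), "Canada")
  expect_error(resolve_main_country(character(0)), "no location data")
})

test_that("select_cohort applies the inclusion rules in order", {
  recs <- list(
    make_record(id = "keep_completed"),
    make_record(id = "keep_terminated", status = "Terminated"),
    make_record(id = "bad_status", status = "Withdrawn"),
    make_record(id = "too_early", start_year = 1999),
    make_record(id = "no_sites", site_countries = character(0), n_sites = 0L),
    make_record(id = "rare_country", site_countries = "Narnia"),
    make_record(id = "no_kw", keywords_field = NA_character_),
    make_record(id = "blank_kw", keywords_field = "   "),
    make_record(id = "no_desc", detailed_description = NA_character_)
  )
  sel <- select_cohort(recs, min_country_count = 2)
  ids <- vapply(sel$records, `[[`, character(1), "id")
  expect_setequal(ids, c("keep_completed", "keep_terminated"))
  expect_equal(sel$label[match("keep_terminated", ids)], 1L)
  expect_equal(sel$label[match("keep_completed", ids)], 0L)
  log <- sel$exclusion_log
  expect_equal(log$reason[log$id == "bad_status"], "status not Completed/Terminated")
  expect_equal(log$reason[log$id == "too_early"], "start year before 2000")
  expect_equal(log$reason[log$id == "no_sites"], "no location data")
  expect_equal(log$reason[log$id == "rare_country"],
               "main country below trial-count threshold")
  expect_equal(log$reason[log$id == "blank_kw"], "missing keyword field")
  expect_equal(log$reason[log$id == "no_desc"], "missing detailed description")
})

test_that("cohort selection conserves records, is order-independent and idempotent", {
  co <- generate_cohort(cohort_spec(n_trials = 60, seed = 3))
  recs <- co$records
  # make some records fail different rules
  recs[[1]]$start_year <- 1995L
  recs[[2]]$keywords_field <- NA_character_
  sel <- select_cohort(recs, min_country_count = 2)
  expect_equal(length(sel$records) + nrow(sel$exclusion_log), length(recs))

  perm <- withr::with_seed(9, sample(length(recs)))
  sel_p <- select_cohort(recs[perm], min_country_count = 2)
  ids <- function(s) sort(vapply(s$records, `[[`, character(1), "id"))
  expect_equal(ids(sel_p), ids(sel))
  expect_equal(sum(sel_p$label), sum(sel$label))

  sel2 <- select_cohort(sel$records, min_country_count = 2)
  expect_equal(ids(sel2), ids(sel))
  expect_equal(sel2$label, sel$label)
  expect_equal(nrow(sel2$exclusion_log), 0)
})

test_that("empty input yields an empty cohort", {
  sel <- select_cohort(list())
  expect_length(sel$records, 0)
  expect_length(sel$label, 0)
  expect_length(sel$top_countries, 0)
})

test_that("cohort_table flattens records with labels aligned", {
  co <- generate_cohort(cohort_spec(n_trials = 20, seed = 5))
  sel <- select_cohort(co$records, min_country_count = 1)
  tab <- cohort_table(sel)
  expect_equal(nrow(tab), length(sel$records))
  expect_true(all(c("id", "status", "label") %in% names(tab)))
  expect_equal(tab$label, sel$label)
})

test_that("XML round-trip through a directory preserves every field", {
  co <- generate_cohort(cohort_spec(n_trials = 8, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort_xml(co, dir)
  back <- read_trial_xml_dir(dir)
  expect_length(back, 8)
  ids <- vapply(back, `[[`, character(1), "id")
  for (r in co$records) {
    expect_equal(unclass(back[[match(r$id, ids)]]), unclass(r))
  }
})
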