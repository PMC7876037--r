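test_that("missing eligibility text flags no_eligibility with zero counts", {
  es <- parse_eligibility(NA_character_)
  expect_true(es$no_eligibility)
  expect_equal(unname(es$total), c(0, 0, 0, 0))
  expect_true(parse_eligibility("   \n  ")$no_eligibility)
})

test_that("parse_eligibility matches hand-counted sections", {
  txt <- paste(
    "Inclusion Criteria:",
    "",
    "  -  adults with confirmed diagnosis",
    "  -  age 18 to 65 years",
    "",
    "Exclusion Criteria:",
    "",
    "  -  pregnant women",
    sep = "\n")
  es <- parse_eligibility(txt)
  expect_equal(unname(es$inclusion[["lines"]]), 2)
  expect_equal(unname(es$inclusion[["words"]]), 9)   # 4 + 5 tokens
  expect_equal(unname(es$inclusion[["numerics"]]), 2) # "18" and "65"
  expect_equal(unname(es$exclusion[["lines"]]), 1)
  expect_equal(unname(es$exclusion[["words"]]), 2)
  expect_equal(unname(es$total[["lines"]]), 3)
  expect_equal(unname(es$total[["words"]]), 11)
  expect_equal(unname(es$inclusion[["avg_words"]]), 4.5)

  # exclusion-only block: inclusion scope stays empty, total covers the block
  es2 <- parse_eligibility("Exclusion Criteria:\n- severe cardiac disease\n")
  expect_equal(unname(es2$inclusion[["lines"]]), 0)
  expect_gt(es2$exclusion[["words"]], 0)
  expect_gte(es2$total[["words"]], es2$exclusion[["words"]])

  # lines before any header count only toward the total scope
  es3 <- parse_eligibility("all comers accepted\nInclusion Criteria:\n- adults")
  expect_equal(unname(es3$total[["lines"]]), 2)
  expect_equal(unname(es3$inclusion[["lines"]]), 1)
})

test_that("parse_eligibility ignores trailing whitespace and blank padding", {
  a <- "Inclusion Criteria:\n- adults over 18\n- signed consent"
  b <- "Inclusion Criteria:   \n\n-  adults over 18   \n\n\n- signed consent  \n\n"
  expect_equal(parse_eligibility(a), parse_eligibility(b))
})

test_that("parse_eligibility reproduces generator ground truth", {
  withr::with_seed(77, {
    for (i in 1:50) {
      blk <- generate_eligibility_block(sample(0:6, 1), sample(0:5, 1),
                                        sample(3:10, 1), sample(0:2, 1))
      got <- parse_eligibility(if (nzchar(blk$text)) blk$text else NA)
      expect_equal(got, blk$expected)
    }
  })
})

test_that("the catalog holds exactly 40 features including the published names", {
  nm <- stat_feature_names()
  expect_length(nm, 40)
  expect_equal(anyDuplicated(nm), 0)
  published <- c("Eligibility Words", "No Eligibility Requirement",
                 "Inclusion Words", "Number Countries", "Phase 1",
                 "Eligibility Lines", "Number Arms", "Industry Sponsor",
                 "Average Inclusion Words", "Average Eligibility Words",
                 "Exclusion Words", "Number Officials", "Average Exclusion Words",
                 "Random Groups", "Eligibility Numbers", "Inclusion Lines",
                 "Exclusion Lines", "Healthy Volunteer", "Exclusion Numbers",
                 "Responsible Party: Sponsor")
  expect_true(all(published %in% nm))
})

test_that("feature extraction follows the documented encodings", {
  r <- make_record(collaborator_classes = character(0), n_officials = 0L,
                   phase = "Phase 1")
  v <- extract_statistics_features(r)
  expect_length(v, 40)
  expect_named(v, stat_feature_names())
  expect_equal(unname(v["Number Collaborators"]), 0)
  expect_equal(unname(v["Number Officials"]), 0)
  # phase one-hot exclusivity
  phase_cols <- c("No Phase", "Early Phase 1", "Phase 1", "Phase 1/2",
                  "Phase 2", "Phase 2/3", "Phase 3", "Phase 4")
  expect_equal(unname(v["Phase 1"]), 1)
  expect_equal(sum(v[phase_cols]), 1)

  # collaborator majority tie resolves to the first class listed
  r2 <- make_record(collaborator_classes = c("Other", "Industry"))
  expect_equal(unname(extract_statistics_features(r2)["Industry Collaborator"]), 0)
  r3 <- make_record(collaborator_classes = c("Industry", "Other", "Industry"))
  expect_equal(unname(extract_statistics_features(r3)["Industry Collaborator"]), 1)

  # USA flag follows the main country
  r4 <- make_record(site_countries = c("France", "France", "United States"),
                    n_sites = 3L)
  expect_equal(unname(extract_statistics_features(r4)["USA Study"]), 0)
  expect_equal(unname(extract_statistics_features(r4, "United States")["USA Study"]), 1)
})

test_that("phase one-hot sums to one over a generated cohort", {
  co <- generate_cohort(cohort_spec(n_trials = 300, seed = 8))
  X <- co$truth$stat_features
  phase_cols <- c("No Phase", "Early Phase 1", "Phase 1", "Phase 1/2",
                  "Phase 2", "Phase 2/3", "Phase 3", "Phase 4")
  expect_equal(unname(rowSums(X[, phase_cols])), rep(1, 300))
  expect_true(all(X[, c("Number Arms", "Number Sites", "Number Officials")] >= 0))
})

test_that("extraction is row-independent", {
  co <- generate_cohort(cohort_spec(n_trials = 50, seed = 12))
  full <- extract_statistics_matrix(co$records)
  sub <- extract_statistics_matrix(co$records[10:20])
  expect_equal(sub, full[10:20, ])
})
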