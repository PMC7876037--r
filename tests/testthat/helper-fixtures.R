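# Shared fixtures: a registry-style XML study document and tiny cohorts.

fixture_xml <- function(status = "Completed", start_date = "March 2005",
                        countries = c("United States", "United States", "France"),
                        keywords = c("Ankle Joint", "Osteoarthritis"),
                        description = "A study of ankle osteoarthritis.",
                        eligibility = "Inclusion Criteria:\n\n  -  adults with confirmed diagnosis\n",
                        include_description = TRUE) {
  loc <- paste(vapply(countries, function(cc) {
    paste0("<location><facility><address><country>", cc,
           "</country></address></facility></location>")
  }, character(1)), collapse = "\n")
  kw <- paste(vapply(keywords, function(k) paste0("<keyword>", k, "</keyword>"),
                     character(1)), collapse = "\n")
  desc <- if (include_description) {
    paste0("<detailed_description><textblock>", description,
           "</textblock></detailed_description>")
  } else ""
  paste0(
    "<clinical_study>",
    "<id_info><nct_id>NCT00000001</nct_id></id_info>",
    "<overall_status>", status, "</overall_status>",
    "<start_date>", start_date, "</start_date>",
    "<sponsors><lead_sponsor><agency_class>Industry</agency_class></lead_sponsor>",
    "<collaborator><agency_class>Other</agency_class></collaborator></sponsors>",
    "<oversight_info><has_dmc>Yes</has_dmc></oversight_info>",
    "<study_type>Interventional</study_type>",
    "<phase>Phase 2</phase>",
    "<number_of_arms>2</number_of_arms>",
    "<study_design_info><allocation>Randomized</allocation>",
    "<masking>Double</masking></study_design_info>",
    "<arm_group><arm_group_type>Placebo Comparator</arm_group_type></arm_group>",
    "<overall_official><role>Principal Investigator</role></overall_official>",
    "<responsible_party><responsible_party_type>Sponsor</responsible_party_type></responsible_party>",
    "<eligibility><criteria><textblock>", eligibility, "</textblock></criteria>",
    "<gender>All</gender><minimum_age>18 Years</minimum_age>",
    "<healthy_volunteers>No</healthy_volunteers></eligibility>",
    loc, kw, desc,
    "</clinical_study>"
  )
}

# minimal valid record with overridable fields
make_record <- function(...) {
  args <- list(...)
  defaults <- list(
    id = "NCT1", status = "Completed", start_year = 2010,
    sponsor_class = "Other", site_countries = c("United States"),
    n_sites = 1L, keywords_field = "pain; knee",
    detailed_description = "some description text"
  )
  do.call(trial_record, utils::modifyList(defaults, args))
}

# balanced toy classification matrix with a clean signal
toy_matrix <- function(n = 120, p = 4, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- as.integer(X[, 1] + rnorm(n, sd = 0.5) > 0)
    list(X = X, y = y)
  })
}
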