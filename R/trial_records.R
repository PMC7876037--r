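# Parsing of registry study records and cohort selection.
#
# The input format is the public per-study XML schema of ClinicalTrials.gov
# (one <clinical_study> document per trial). Only the fields consumed by the
# feature-engineering stages are retained.

#' Recruitment statuses recognised in registry records
#'
#' The recruitment status vocabulary of the trial registry. "Completed" and
#' "Terminated" are the two classes analysed; "Withdrawn" trials stopped
#' before enrolling their first participant and are excluded.
#'
#' @export
TRIAL_STATUSES <- c(
  "Not yet recruiting", "Recruiting", "Enrolling by invitation",
  "Active, not recruiting", "Completed", "Suspended", "Terminated",
  "Withdrawn", "Unknown", "Available", "No longer available",
  "Temporarily not available", "Approved for Marketing"
)

AGENCY_CLASSES <- c("Industry", "NIH", "U.S. Fed", "Other")

PHASES <- c(
  "No Phase", "Early Phase 1", "Phase 1", "Phase 1/2",
  "Phase 2", "Phase 2/3", "Phase 3", "Phase 4"
)

tristate <- function(x) {
  if (is_missing_text(x)) return(NA_character_)
  x <- tolower(trimws(x))
  if (x %in% c("yes", "true", "accepts healthy volunteers")) return("yes")
  if (x %in% c("no", "false")) return("no")
  NA_character_
}

#' Construct a trial record
#'
#' Low-level constructor for a single parsed registry study. All fields
#' default to missing; [parse_trial_record()] is the usual entry point.
#'
#' @param id registry identifier (e.g. an NCT number).
#' @param status recruitment status, one of [TRIAL_STATUSES].
#' @param start_year integer start year, or `NA`.
#' @param sponsor_class agency class of the lead sponsor.
#' @param collaborator_classes character vector of collaborator agency
#'   classes, in document order.
#' @param n_officials number of study officials.
#' @param responsible_party responsible-party type, or `NA`.
#' @param has_expanded_access,has_dmc,is_fda_regulated tristates
#'   (`"yes"`/`"no"`/`NA`).
#' @param study_type `"Interventional"` or `"Observational"`.
#' @param phase one of the eight registry phase labels (see `extract`
#'   documentation), or `NA`.
#' @param n_arms,n_sites non-negative counts.
#' @param site_countries character vector of site countries in document order.
#' @param randomized tristate: does the design allocate groups at random.
#' @param masking masking description, or `NA`.
#' @param has_placebo tristate: does any arm use a placebo comparator.
#' @param eligibility_text free-text eligibility criteria block, or `NA`.
#' @param gender eligibility gender field, or `NA`.
#' @param min_age,max_age age limit strings as recorded (e.g. "18 Years").
#' @param healthy_volunteers tristate.
#' @param keywords_field keyword list collapsed to one string with `"; "`.
#' @param detailed_description free-text detailed description, or `NA`.
#'
#' @return An object of class `trial_record` (a named list).
#' @export
trial_record <- function(id = NA_character_, status = "Completed",
                         start_year = NA_integer_,
                         sponsor_class = NA_character_,
                         collaborator_classes = character(0),
                         n_officials = 0L, responsible_party = NA_character_,
                         has_expanded_access = NA_character_,
                         has_dmc = NA_character_,
                         is_fda_regulated = NA_character_,
                         study_type = NA_character_, phase = NA_character_,
                         n_arms = NA_integer_, n_sites = 0L,
                         site_countries = character(0),
                         randomized = NA_character_, masking = NA_character_,
                         has_placebo = NA_character_,
                         eligibility_text = NA_character_,
                         gender = NA_character_, min_age = NA_character_,
                         max_age = NA_character_,
                         healthy_volunteers = NA_character_,
                         keywords_field = NA_character_,
                         detailed_description = NA_character_) {
  if (!status %in% TRIAL_STATUSES) {
    stop("unknown trial status: '", status, "'", call. = FALSE)
  }
  stopifnot(n_officials >= 0, n_sites >= 0, is.na(n_arms) || n_arms >= 0)
  structure(list(
    id = id, status = status, start_year = as.integer(start_year),
    sponsor_class = sponsor_class,
    collaborator_classes = as.character(collaborator_classes),
    n_officials = as.integer(n_officials),
    responsible_party = responsible_party,
    has_expanded_access = has_expanded_access, has_dmc = has_dmc,
    is_fda_regulated = is_fda_regulated, study_type = study_type,
    phase = phase, n_arms = as.integer(n_arms), n_sites = as.integer(n_sites),
    site_countries = as.character(site_countries), randomized = randomized,
    masking = masking, has_placebo = has_placebo,
    eligibility_text = eligibility_text, gender = gender,
    min_age = min_age, max_age = max_age,
    healthy_volunteers = healthy_volunteers,
    keywords_field = keywords_field,
    detailed_description = detailed_description
  ), class = "trial_record")
}

xml_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NA_character_)
  txt <- xml2::xml_text(node)
  if (!nzchar(trimws(txt))) NA_character_ else txt
}

start_year_from_date <- function(x) {
  if (is_missing_text(x)) return(NA_integer_)
  m <- regmatches(x, regexpr("[0-9]{4}", x))
  if (length(m) == 0) NA_integer_ else as.integer(m)
}

#' Parse one registry XML study record
#'
#' Reads a single `<clinical_study>` document in the registry's public XML
#' schema and populates a [trial_record()]. Absent elements map to explicit
#' missing values; nothing is silently defaulted.
#'
#' @param xml_text XML document as a string, a file path, or an `xml2`
#'   document.
#' @return A `trial_record`.
#' @export
parse_trial_record <- function(xml_text) {
  doc <- tryCatch(
    if (inherits(xml_text, "xml_document")) xml_text else xml2::read_xml(xml_text),
    error = function(e) {
      stop("malformed trial XML: ", conditionMessage(e), call. = FALSE)
    }
  )
  status <- xml_text1(doc, ".//overall_status")
  if (is.na(status)) stop("trial record has no overall_status element", call. = FALSE)
  status <- trimws(status)
  if (identical(status, "Unknown status")) status <- "Unknown"
  if (!status %in% TRIAL_STATUSES) {
    stop("unknown trial status: '", status, "'", call. = FALSE)
  }

  phase <- xml_text1(doc, ".//phase")
  if (!is.na(phase) && phase %in% c("N/A", "n/a")) phase <- "No Phase"

  countries <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//location/facility/address/country")
  )
  n_sites <- length(xml2::xml_find_all(doc, ".//location"))

  arm_types <- xml2::xml_text(xml2::xml_find_all(doc, ".//arm_group/arm_group_type"))
  has_placebo <- if (length(arm_types) == 0) {
    NA_character_
  } else if (any(grepl("placebo", arm_types, ignore.case = TRUE))) "yes" else "no"

  allocation <- xml_text1(doc, ".//study_design_info/allocation")
  randomized <- if (is_missing_text(allocation) || allocation == "N/A") {
    NA_character_
  } else if (grepl("^non", allocation, ignore.case = TRUE)) "no" else "yes"

  keywords <- xml2::xml_text(xml2::xml_find_all(doc, ".//keyword"))
  keywords <- keywords[nzchar(trimws(keywords))]
  keywords_field <- if (length(keywords) == 0) NA_character_ else {
    paste(keywords, collapse = "; ")
  }

  masking <- xml_text1(doc, ".//study_design_info/masking")

  trial_record(
    id = xml_text1(doc, ".//id_info/nct_id"),
    status = status,
    start_year = start_year_from_date(xml_text1(doc, ".//start_date")),
    sponsor_class = xml_text1(doc, ".//sponsors/lead_sponsor/agency_class"),
    collaborator_classes =
      xml2::xml_text(xml2::xml_find_all(doc, ".//sponsors/collaborator/agency_class")),
    n_officials = length(xml2::xml_find_all(doc, ".//overall_official")),
    responsible_party = xml_text1(doc, ".//responsible_party/responsible_party_type"),
    has_expanded_access = tristate(xml_text1(doc, ".//has_expanded_access")),
    has_dmc = tristate(xml_text1(doc, ".//oversight_info/has_dmc")),
    is_fda_regulated = tristate(xml_text1(doc, ".//oversight_info/is_fda_regulated")),
    study_type = xml_text1(doc, ".//study_type"),
    phase = phase,
    n_arms = {
      a <- xml_text1(doc, ".//number_of_arms")
      if (is.na(a)) NA_integer_ else as.integer(a)
    },
    n_sites = n_sites,
    site_countries = countries,
    randomized = randomized,
    masking = masking,
    has_placebo = has_placebo,
    eligibility_text = xml_text1(doc, ".//eligibility/criteria/textblock"),
    gender = xml_text1(doc, ".//eligibility/gender"),
    min_age = xml_text1(doc, ".//eligibility/minimum_age"),
    max_age = xml_text1(doc, ".//eligibility/maximum_age"),
    healthy_volunteers = tristate(xml_text1(doc, ".//eligibility/healthy_volunteers")),
    keywords_field = keywords_field,
    detailed_description = xml_text1(doc, ".//detailed_description/textblock")
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

tristate_out <- function(x) {
  if (is.na(x)) NULL else if (x == "yes") "Yes" else "No"
}

#' Serialize a trial record back to registry XML
#'
#' Writes the same schema that [parse_trial_record()] reads, so that
#' `parse_trial_record(serialize_trial_record(r))` reproduces every field.
#' Used by the synthetic-cohort generator to exercise the full I/O layer.
#'
#' @param record a `trial_record`.
#' @return A single XML string.
#' @export
serialize_trial_record <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  out <- character(0)
  add <- function(tag, value, indent = "  ") {
    if (is.null(value) || (length(value) == 1 && is.na(value))) return()
    out[[length(out) + 1]] <<- paste0(indent, "<", tag, ">", xml_escape(as.character(value)),
                                      "</", tag, ">")
  }
  out <- c(out, "<clinical_study>")
  if (!is.na(record$id)) {
    out <- c(out, "  <id_info>")
    add("nct_id", record$id, "    ")
    out <- c(out, "  </id_info>")
  }
  add("overall_status", record$status)
  add("start_date", if (is.na(record$start_year)) NA else paste("January", record$start_year))
  out <- c(out, "  <sponsors>")
  if (!is.na(record$sponsor_class)) {
    out <- c(out, "    <lead_sponsor>")
    add("agency_class", record$sponsor_class, "      ")
    out <- c(out, "    </lead_sponsor>")
  }
  for (cc in record$collaborator_classes) {
    out <- c(out, "    <collaborator>")
    add("agency_class", cc, "      ")
    out <- c(out, "    </collaborator>")
  }
  out <- c(out, "  </sponsors>")
  if (!is.na(record$has_expanded_access)) {
    add("has_expanded_access", tristate_out(record$has_expanded_access))
  }
  if (!is.na(record$has_dmc) || !is.na(record$is_fda_regulated)) {
    out <- c(out, "  <oversight_info>")
    add("has_dmc", tristate_out(record$has_dmc), "    ")
    add("is_fda_regulated", tristate_out(record$is_fda_regulated), "    ")
    out <- c(out, "  </oversight_info>")
  }
  add("study_type", record$study_type)
  add("phase", record$phase)
  add("number_of_arms", record$n_arms)
  if (!is.na(record$randomized) || !is.na(record$masking)) {
    out <- c(out, "  <study_design_info>")
    add("allocation",
        if (is.na(record$randomized)) NA else
          if (record$randomized == "yes") "Randomized" else "Non-Randomized", "    ")
    add("masking", record$masking, "    ")
    out <- c(out, "  </study_design_info>")
  }
  if (!is.na(record$has_placebo)) {
    out <- c(out, "  <arm_group>")
    add("arm_group_type",
        if (record$has_placebo == "yes") "Placebo Comparator" else "Experimental", "    ")
    out <- c(out, "  </arm_group>")
  }
  for (i in seq_len(record$n_officials)) {
    out <- c(out, "  <overall_official>", "    <role>Principal Investigator</role>",
             "  </overall_official>")
  }
  if (!is.na(record$responsible_party)) {
    out <- c(out, "  <responsible_party>")
    add("responsible_party_type", record$responsible_party, "    ")
    out <- c(out, "  </responsible_party>")
  }
  elig <- !is.na(record$eligibility_text) || !is.na(record$gender) ||
    !is.na(record$min_age) || !is.na(record$max_age) ||
    !is.na(record$healthy_volunteers)
  if (elig) {
    out <- c(out, "  <eligibility>")
    if (!is.na(record$eligibility_text)) {
      out <- c(out, "    <criteria>",
               paste0("      <textblock>", xml_escape(record$eligibility_text),
                      "</textblock>"),
               "    </criteria>")
    }
    add("gender", record$gender, "    ")
    add("minimum_age", record$min_age, "    ")
    add("maximum_age", record$max_age, "    ")
    add("healthy_volunteers",
        if (is.na(record$healthy_volunteers)) NA else
          if (record$healthy_volunteers == "yes") "Accepts Healthy Volunteers" else "No",
        "    ")
    out <- c(out, "  </eligibility>")
  }
  # one <location> per site; countries are assigned to the first sites in
  # order, remaining sites carry no country element
  for (i in seq_len(record$n_sites)) {
    out <- c(out, "  <location>", "    <facility>", "      <address>")
    if (i <= length(record$site_countries)) {
      add("country", record$site_countries[i], "        ")
    }
    out <- c(out, "      </address>", "    </facility>", "  </location>")
  }
  if (!is.na(record$keywords_field)) {
    for (kw in strsplit(record$keywords_field, "; ", fixed = TRUE)[[1]]) {
      add("keyword", kw)
    }
  }
  if (!is.na(record$detailed_description)) {
    out <- c(out, "  <detailed_description>",
             paste0("    <textblock>", xml_escape(record$detailed_description),
                    "</textblock>"),
             "  </detailed_description>")
  }
  out <- c(out, "</clinical_study>")
  paste(out, collapse = "\n")
}

#' Resolve the main country of a multi-site trial
#'
#' The main country is the country with the most sites; ties are broken by
#' the first country listed among the trial's sites.
#'
#' @param site_countries character vector of per-site countries, in document
#'   order.
#' @return A single country name.
#' @export
resolve_main_country <- function(site_countries) {
  if (length(site_countries) == 0) {
    stop("trial has no location data: cannot resolve a main country", call. = FALSE)
  }
  u <- unique(site_countries)            # ordered by first appearance
  u[which.max(tabulate(match(site_countries, u)))]
}

# same modal/first-tie rule for collaborator agency classes
resolve_main_collaborator <- function(classes) {
  if (length(classes) == 0) return(NA_character_)
  u <- unique(classes)
  u[which.max(tabulate(match(classes, u)))]
}

norm_country <- function(x) tolower(trimws(x))

#' Select the analysis cohort from parsed trial records
#'
#' Applies the inclusion filter used throughout the analysis: keep trials
#' whose status is Completed or Terminated, starting in or after
#' `min_start_year`, whose main country (most sites, first-listed on ties)
#' belongs to the set of countries contributing at least `min_country_count`
#' trials in the full input, and whose keyword and detailed-description
#' fields are non-missing. Terminated trials are labelled 1, completed 0.
#'
#' @param records list of `trial_record` objects.
#' @param min_country_count minimum number of trials (over the full input)
#'   for a country to qualify as a top country. Default 1000.
#' @param min_start_year earliest admissible start year. Default 2000.
#' @return A `cohort_selection` list with elements `records` (included
#'   trials), `label` (integer vector, 1 = terminated), `main_country`
#'   (per included trial), `exclusion_log` (data frame of id and the first
#'   failing rule) and `top_countries`.
#' @export
select_cohort <- function(records, min_country_count = 1000,
                          min_start_year = 2000) {
  main <- vapply(records, function(r) {
    if (length(r$site_countries) == 0) NA_character_ else
      resolve_main_country(r$site_countries)
  }, character(1))
  cc <- table(norm_country(main[!is.na(main)]))
  top <- names(cc)[cc >= min_country_count]

  reason <- vapply(records, function(r) {
    if (!r$status %in% c("Completed", "Terminated")) return("status not Completed/Terminated")
    if (is.na(r$start_year)) return("missing or unparseable start date")
    if (r$start_year < min_start_year) {
      return(sprintf("start year before %d", min_start_year))
    }
    if (length(r$site_countries) == 0) return("no location data")
    NA_character_
  }, character(1))
  idx_country <- which(is.na(reason))
  bad_country <- idx_country[!(norm_country(main[idx_country]) %in% top)]
  reason[bad_country] <- "main country below trial-count threshold"
  miss_kw <- which(is.na(reason) &
                     vapply(records, function(r) is_missing_text(r$keywords_field), logical(1)))
  reason[miss_kw] <- "missing keyword field"
  miss_dd <- which(is.na(reason) &
                     vapply(records, function(r) is_missing_text(r$detailed_description),
                            logical(1)))
  reason[miss_dd] <- "missing detailed description"

  keep <- is.na(reason)
  ids <- vapply(records, function(r) r$id %||% NA_character_, character(1))
  structure(list(
    records = records[keep],
    label = as.integer(vapply(records[keep], function(r) r$status == "Terminated",
                              logical(1))),
    main_country = main[keep],
    exclusion_log = data.frame(id = ids[!keep], reason = reason[!keep],
                               stringsAsFactors = FALSE),
    top_countries = sort(top)
  ), class = "cohort_selection")
}

#' Flatten a cohort selection to a data frame
#'
#' One row per included trial; list-valued fields (collaborator classes,
#' site countries) are collapsed with `"|"`. Suitable for writing with
#' [utils::write.csv()].
#'
#' @param cohort a `cohort_selection`.
#' @return A data frame with one column per record field plus `label`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_selection"))
  rows <- lapply(cohort$records, function(r) {
    r$collaborator_classes <- paste(r$collaborator_classes, collapse = "|")
    r$site_countries <- paste(r$site_countries, collapse = "|")
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$label <- cohort$label
  out
}

#' Read a directory of registry XML files
#'
#' @param dir directory containing one `.xml` file per study.
#' @return List of `trial_record` objects, in lexicographic file order.
#' @export
read_trial_xml_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  lapply(files, parse_trial_record)
}
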