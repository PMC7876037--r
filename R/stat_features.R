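# The 40 statistics features: administrative, study information, study
# design, and eligibility-text counts. The canonical feature names live in
# inst/extdata/stat_feature_catalog.csv so they can be corrected without a
# code change.

.catalog_cache <- new.env(parent = emptyenv())

#' The canonical statistics-feature catalog
#'
#' Returns the 40 statistics-feature names (and their group) in canonical
#' column order. Shipped as a plain CSV under `extdata`.
#'
#' @return A data frame with columns `name` and `group`, 40 rows.
#' @export
stat_feature_catalog <- function() {
  if (is.null(.catalog_cache$catalog)) {
    path <- system.file("extdata", "stat_feature_catalog.csv", package = "trialterm")
    .catalog_cache$catalog <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  .catalog_cache$catalog
}

#' @rdname stat_feature_catalog
#' @export
stat_feature_names <- function() stat_feature_catalog()$name

empty_scope <- function() c(lines = 0, words = 0, avg_words = 0, numerics = 0)

#' Parse an eligibility criteria text block into count statistics
#'
#' Splits the block into lines; lines are assigned to the inclusion or
#' exclusion scope by case-insensitive "Inclusion Criteria" / "Exclusion
#' Criteria" header lines (the headers themselves and blank lines are not
#' counted). The total scope counts every non-blank, non-header line of the
#' block, including lines preceding any header. Words are whitespace-
#' delimited tokens after stripping leading bullet markers; a numeric token
#' is any token containing a decimal digit.
#'
#' @param text eligibility block, or `NA` for trials without one.
#' @return An `eligibility_stats` list: per scope (`inclusion`, `exclusion`,
#'   `total`) the counts `lines`, `words`, `avg_words`, `numerics`, plus the
#'   flag `no_eligibility`.
#' @export
parse_eligibility <- function(text) {
  out <- list(inclusion = empty_scope(), exclusion = empty_scope(),
              total = empty_scope(), no_eligibility = FALSE)
  class(out) <- "eligibility_stats"
  if (is_missing_text(text)) {
    out$no_eligibility <- TRUE
    return(out)
  }
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- sub("^[-*•]+\\s*", "", lines)
  scope <- "none"
  acc <- list(inclusion = c(0, 0, 0), exclusion = c(0, 0, 0),
              total = c(0, 0, 0))   # lines, words, numerics
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^inclusion criteria[[:punct:]]?$", ln, ignore.case = TRUE)) {
      scope <- "inclusion"
      next
    }
    if (grepl("^exclusion criteria[[:punct:]]?$", ln, ignore.case = TRUE)) {
      scope <- "exclusion"
      next
    }
    tokens <- strsplit(ln, "\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    counts <- c(1, length(tokens), sum(grepl("[0-9]", tokens)))
    acc$total <- acc$total + counts
    if (scope != "none") acc[[scope]] <- acc[[scope]] + counts
  }
  for (s in c("inclusion", "exclusion", "total")) {
    a <- acc[[s]]
    out[[s]] <- c(lines = a[1], words = a[2],
                  avg_words = if (a[1] > 0) a[2] / a[1] else 0,
                  numerics = a[3])
  }
  if (acc$total[1] == 0) out$no_eligibility <- TRUE
  out
}

#' Extract the 40 statistics features from one trial record
#'
#' Computes the administrative, study-information, study-design and
#' eligibility features of a trial. The main collaborator class is the modal
#' class of the collaborator list, ties broken by the first class listed.
#' The phase indicators one-hot encode the eight registry phase labels (a
#' missing phase maps to "No Phase"). `USA Study` is 1 iff the trial's main
#' country is the United States.
#'
#' @param record a `trial_record`.
#' @param main_country the trial's main country, as from
#'   [resolve_main_country()]; if `NULL` it is resolved from the record's
#'   sites (trials without location data get `USA Study = 0`).
#' @return Named numeric vector of exactly 40 features in catalog order.
#' @export
extract_statistics_features <- function(record, main_country = NULL) {
  stopifnot(inherits(record, "trial_record"))
  if (is.null(main_country)) {
    main_country <- if (length(record$site_countries) == 0) NA_character_ else
      resolve_main_country(record$site_countries)
  }
  es <- parse_eligibility(record$eligibility_text)
  yes <- function(x) as.numeric(!is.na(x) && x == "yes")
  phase <- if (is_missing_text(record$phase)) "No Phase" else record$phase
  phase_onehot <- as.numeric(PHASES == phase)
  names(phase_onehot) <- PHASES
  if (!phase %in% PHASES) phase_onehot["No Phase"] <- 1

  v <- c(
    "Inclusion Lines" = es$inclusion[["lines"]],
    "Inclusion Words" = es$inclusion[["words"]],
    "Average Inclusion Words" = es$inclusion[["avg_words"]],
    "Inclusion Numbers" = es$inclusion[["numerics"]],
    "Exclusion Lines" = es$exclusion[["lines"]],
    "Exclusion Words" = es$exclusion[["words"]],
    "Average Exclusion Words" = es$exclusion[["avg_words"]],
    "Exclusion Numbers" = es$exclusion[["numerics"]],
    "Eligibility Lines" = es$total[["lines"]],
    "Eligibility Words" = es$total[["words"]],
    "Average Eligibility Words" = es$total[["avg_words"]],
    "Eligibility Numbers" = es$total[["numerics"]],
    "No Eligibility Requirement" = as.numeric(es$no_eligibility),
    "Gender Restriction" = as.numeric(!is.na(record$gender) &&
                                        record$gender %in% c("Male", "Female")),
    "Age Restriction" = as.numeric(!is_missing_text(record$min_age) &&
                                     !record$min_age %in% c("N/A", "n/a")),
    "Healthy Volunteer" = yes(record$healthy_volunteers),
    phase_onehot,
    "Expanded Access" = yes(record$has_expanded_access),
    "Data Monitoring Committee" = yes(record$has_dmc),
    "FDA Regulated" = yes(record$is_fda_regulated),
    "Interventional Study" = as.numeric(!is.na(record$study_type) &&
                                          record$study_type == "Interventional"),
    "USA Study" = as.numeric(!is.na(main_country) &&
                               norm_country(main_country) %in%
                                 c("united states", "usa", "united states of america")),
    "Industry Sponsor" = as.numeric(!is.na(record$sponsor_class) &&
                                      record$sponsor_class == "Industry"),
    "Industry Collaborator" = as.numeric(
      identical(resolve_main_collaborator(record$collaborator_classes), "Industry")),
    "Number Collaborators" = length(record$collaborator_classes),
    "Number Officials" = record$n_officials,
    "Responsible Party: Sponsor" = as.numeric(!is.na(record$responsible_party) &&
                                                record$responsible_party == "Sponsor"),
    "Number Arms" = if (is.na(record$n_arms)) 0 else record$n_arms,
    "Number Countries" = length(unique(record$site_countries)),
    "Number Sites" = record$n_sites,
    "Random Groups" = yes(record$randomized),
    "Masked Groups" = as.numeric(!is_missing_text(record$masking) &&
                                   !grepl("^none", record$masking, ignore.case = TRUE)),
    "Placebo Group" = yes(record$has_placebo)
  )
  v[stat_feature_names()]
}

#' Extract statistics features for a whole cohort
#'
#' @param records list of `trial_record` objects.
#' @param main_countries optional character vector of per-trial main
#'   countries (resolved from sites when `NULL`).
#' @return Numeric matrix, one row per trial, 40 named columns.
#' @export
extract_statistics_matrix <- function(records, main_countries = NULL) {
  n <- length(records)
  out <- matrix(0, n, length(stat_feature_names()),
                dimnames = list(NULL, stat_feature_names()))
  for (i in seq_len(n)) {
    out[i, ] <- extract_statistics_features(
      records[[i]], if (is.null(main_countries)) NULL else main_countries[i])
  }
  out
}
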