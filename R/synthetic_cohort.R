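# Synthetic trial-cohort generator with known ground truth.
#
# Records are generated field-first; the termination label is then drawn
# from a logistic model over the record's own statistics features, so that
# parameter-recovery and ranking tests have exact ground truth. Keyword and
# description text are generated conditionally on the label: a rare-disease
# keyword subset is over-represented in terminated trials, and descriptions
# are a two-topic mixture whose mixing weight depends on the label.

RARE_DISEASE_TERMS <- c(
  "mycosis", "fungoides", "sezary", "verrucous", "testicular",
  "neuroblastoma", "nasopharynx", "noncontiguous", "germ", "thyroid",
  "paranasal", "myelomonocytic", "hypopharynx", "uterine", "oropharynx",
  "salivary", "contiguous", "remission", "astrocytoma", "cleaved"
)

default_keyword_vocab <- function() {
  terms <- c(RARE_DISEASE_TERMS, sprintf("cond%03d", seq_len(580)))
  data.frame(
    term = terms,
    base_weight = 1 / seq_along(terms)^0.6,     # heavy-tailed base frequencies
    terminated_multiplier = c(rep(4, length(RARE_DISEASE_TERMS)),
                              rep(1, 580)),
    stringsAsFactors = FALSE
  )
}

default_description_topics <- function(n_words = 150) {
  words <- sprintf("descw%03d", seq_len(n_words))
  zipf <- 1 / seq_len(n_words)
  list(words = words,
       topic_a = zipf / sum(zipf),
       topic_b = rev(zipf) / sum(zipf),
       base_mix = 0.35,          # topic-b share in completed trials
       signal = 0.30,            # added topic-b share in terminated trials
       length_min = 20, length_mean_extra = 40)
}

default_eligibility_spec <- function() {
  list(p_missing = 0.07,
       n_inc = c(1L, 8L), n_exc = c(0L, 6L),
       words_per_line = c(4L, 12L), numerics_per_line = c(0L, 2L))
}

#' Specification of a synthetic trial cohort
#'
#' Bundles every knob of the generator. Defaults reflect the corpus the
#' pipeline targets: an 11.46% termination rate (1:7.75 terminated to
#' completed), a 600-term keyword vocabulary whose rare-disease subset is
#' over-represented among terminated trials, two-topic description text
#' with a label-dependent mixing weight, and eligibility blocks of 1-8
#' inclusion and 0-6 exclusion lines.
#'
#' @param n_trials number of trials to generate.
#' @param termination_rate marginal probability of termination, in (0, 1).
#' @param effect_weights named numeric vector of log-odds weights on
#'   statistics features (names from [stat_feature_names()]); the generator
#'   calibrates the intercept so the marginal rate matches
#'   `termination_rate`.
#' @param keyword_vocab data frame with columns `term`, `base_weight`,
#'   `terminated_multiplier`.
#' @param description_topics list describing the two-topic description
#'   model (see `default_description_topics`).
#' @param eligibility_spec list of ranges for eligibility-block generation
#'   (see `default_eligibility_spec`).
#' @param seed integer seed; identical specs generate byte-identical
#'   corpora.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_trials, termination_rate = 0.1146,
                        effect_weights = c("Industry Sponsor" = 0.3,
                                           "No Eligibility Requirement" = 0.8,
                                           "Eligibility Lines" = 0.04,
                                           "Number Sites" = -0.05,
                                           "Healthy Volunteer" = -0.3,
                                           "Phase 1" = 0.4),
                        keyword_vocab = default_keyword_vocab(),
                        description_topics = default_description_topics(),
                        eligibility_spec = default_eligibility_spec(),
                        seed = 1L) {
  if (n_trials < 1) stop("n_trials must be at least 1", call. = FALSE)
  if (!(termination_rate > 0 && termination_rate < 1)) {
    stop("termination_rate must lie strictly in (0, 1)", call. = FALSE)
  }
  if (nrow(keyword_vocab) == 0) {
    stop("keyword_vocab must contain at least one term", call. = FALSE)
  }
  if (length(effect_weights) > 0) {
    bad <- setdiff(names(effect_weights), stat_feature_names())
    if (length(bad) > 0) {
      stop("effect_weights name unknown statistics features: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_trials = as.integer(n_trials),
                 termination_rate = termination_rate,
                 effect_weights = effect_weights,
                 keyword_vocab = keyword_vocab,
                 description_topics = description_topics,
                 eligibility_spec = eligibility_spec,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

ELIG_LEXICON <- c(
  "patients", "diagnosed", "with", "confirmed", "disease", "stage",
  "prior", "therapy", "adequate", "organ", "function", "written",
  "informed", "consent", "history", "of", "severe", "allergy", "pregnant",
  "or", "nursing", "women", "life", "expectancy", "months", "performance",
  "status", "measurable", "lesion", "able", "to", "comply", "protocol"
)

#' Generate one synthetic eligibility block with exact ground truth
#'
#' Builds an eligibility text block with `n_inc` inclusion and `n_exc`
#' exclusion lines (with their headers present iff the section is
#' non-empty), each line carrying exactly `words_per_line` tokens of which
#' `numerics_per_line` contain a digit. The returned expected counts are
#' exact ground truth for [parse_eligibility()]. Uses the current RNG
#' state.
#'
#' @param n_inc,n_exc number of inclusion / exclusion lines.
#' @param words_per_line tokens per line (numeric tokens included).
#' @param numerics_per_line digit-bearing tokens per line (at most
#'   `words_per_line`).
#' @return List with `text` and `expected` (an `eligibility_stats`).
#' @export
generate_eligibility_block <- function(n_inc, n_exc, words_per_line,
                                       numerics_per_line) {
  stopifnot(n_inc >= 0, n_exc >= 0, numerics_per_line <= words_per_line)
  expected <- list(
    inclusion = c(lines = n_inc, words = n_inc * words_per_line,
                  avg_words = if (n_inc > 0) words_per_line else 0,
                  numerics = n_inc * numerics_per_line),
    exclusion = c(lines = n_exc, words = n_exc * words_per_line,
                  avg_words = if (n_exc > 0) words_per_line else 0,
                  numerics = n_exc * numerics_per_line),
    total = c(lines = n_inc + n_exc,
              words = (n_inc + n_exc) * words_per_line,
              avg_words = if (n_inc + n_exc > 0) words_per_line else 0,
              numerics = (n_inc + n_exc) * numerics_per_line),
    no_eligibility = (n_inc + n_exc) == 0
  )
  class(expected) <- "eligibility_stats"
  if (n_inc + n_exc == 0) {
    return(list(text = "", expected = expected))
  }
  make_lines <- function(n_lines) {
    if (n_lines == 0) return(character(0))
    m <- matrix(sample(ELIG_LEXICON, n_lines * words_per_line, replace = TRUE),
                nrow = n_lines)
    if (numerics_per_line > 0) {
      cols <- sample.int(words_per_line, numerics_per_line)
      m[, cols] <- as.character(matrix(
        sample.int(500, n_lines * numerics_per_line, replace = TRUE),
        nrow = n_lines))
    }
    paste0("  -  ", do.call(paste, c(split(m, col(m)), sep = " ")))
  }
  parts <- character(0)
  if (n_inc > 0) parts <- c(parts, "Inclusion Criteria:", "", make_lines(n_inc))
  if (n_exc > 0) {
    if (length(parts) > 0) parts <- c(parts, "")
    parts <- c(parts, "Exclusion Criteria:", "", make_lines(n_exc))
  }
  list(text = paste(parts, collapse = "\n"), expected = expected)
}

COUNTRY_POOL <- c("United States", "France", "Canada", "China", "Germany",
                  "U.K.", "Korea, Republic of", "Belgium", "Australia",
                  "Italy", "Spain", "Netherlands")

sample_between <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic cohort of trial records
#'
#' Draws `spec$n_trials` records, computes their 40 statistics features,
#' draws the termination label from a logistic model over those features
#' using `spec$effect_weights` (the intercept is calibrated numerically so
#' that the expected termination rate equals `spec$termination_rate`), and
#' then generates keyword and description text conditionally on the label.
#' Every record round-trips through [serialize_trial_record()] /
#' [parse_trial_record()].
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort` list: `records`, `labels`, and `truth`
#'   (spec echo, calibrated intercept, per-trial linear predictor `eta`,
#'   Bayes-oracle scores, and the statistics-feature matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_trials
  es <- spec$eligibility_spec

  start_year <- sample(2000:2018, n, replace = TRUE)
  sponsor_class <- sample(AGENCY_CLASSES, n, replace = TRUE,
                          prob = c(0.20, 0.08, 0.05, 0.67))
  n_collab <- rpois(n, 0.7)
  n_officials <- rpois(n, 1.2)
  responsible_party <- sample(
    c("Sponsor", "Principal Investigator", "Sponsor-Investigator", NA),
    n, replace = TRUE, prob = c(0.45, 0.30, 0.05, 0.20))
  has_expanded_access <- sample(c("no", "yes", NA), n, replace = TRUE,
                                prob = c(0.85, 0.02, 0.13))
  has_dmc <- sample(c("yes", "no", NA), n, replace = TRUE,
                    prob = c(0.35, 0.45, 0.20))
  is_fda_regulated <- sample(c("yes", "no", NA), n, replace = TRUE,
                             prob = c(0.40, 0.40, 0.20))
  study_type <- sample(c("Interventional", "Observational"), n,
                       replace = TRUE, prob = c(0.82, 0.18))
  phase <- sample(PHASES, n, replace = TRUE,
                  prob = c(0.33, 0.02, 0.12, 0.05, 0.20, 0.03, 0.15, 0.10))
  n_arms <- 1L + rpois(n, 1)
  n_sites <- 1L + rpois(n, 2)
  site_countries <- lapply(n_sites, function(k) {
    sample(COUNTRY_POOL, k, replace = TRUE,
           prob = c(0.40, 0.09, 0.08, 0.08, 0.07, 0.06, 0.05, 0.05, 0.04,
                    0.04, 0.02, 0.02))
  })
  randomized <- sample(c("yes", "no", NA), n, replace = TRUE,
                       prob = c(0.55, 0.20, 0.25))
  masking <- sample(c("None (Open Label)", "Single", "Double", "Triple",
                      "Quadruple", NA),
                    n, replace = TRUE,
                    prob = c(0.40, 0.12, 0.18, 0.05, 0.05, 0.20))
  has_placebo <- sample(c("yes", "no", NA), n, replace = TRUE,
                        prob = c(0.25, 0.55, 0.20))
  gender <- sample(c("All", "Female", "Male"), n, replace = TRUE,
                   prob = c(0.82, 0.11, 0.07))
  min_age <- sample(c("18 Years", "N/A", "12 Years", "65 Years"), n,
                    replace = TRUE, prob = c(0.65, 0.20, 0.10, 0.05))
  healthy_volunteers <- sample(c("no", "yes", NA), n, replace = TRUE,
                               prob = c(0.70, 0.25, 0.05))

  elig_missing <- runif(n) < es$p_missing
  n_inc <- sample_between(n, es$n_inc)
  n_exc <- sample_between(n, es$n_exc)
  wpl <- sample_between(n, es$words_per_line)
  npl <- pmin(sample_between(n, es$numerics_per_line), wpl)
  eligibility_text <- rep(NA_character_, n)
  for (i in which(!elig_missing)) {
    eligibility_text[i] <- generate_eligibility_block(n_inc[i], n_exc[i],
                                                      wpl[i], npl[i])$text
  }

  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- trial_record(
      id = sprintf("NCT%08d", i),
      status = "Completed",
      start_year = start_year[i],
      sponsor_class = sponsor_class[i],
      collaborator_classes = if (n_collab[i] > 0) {
        sample(AGENCY_CLASSES, n_collab[i], replace = TRUE,
               prob = c(0.25, 0.10, 0.05, 0.60))
      } else character(0),
      n_officials = n_officials[i],
      responsible_party = responsible_party[i],
      has_expanded_access = has_expanded_access[i],
      has_dmc = has_dmc[i],
      is_fda_regulated = is_fda_regulated[i],
      study_type = study_type[i],
      phase = phase[i],
      n_arms = n_arms[i],
      n_sites = n_sites[i],
      site_countries = site_countries[[i]],
      randomized = randomized[i],
      masking = masking[i],
      has_placebo = has_placebo[i],
      eligibility_text = eligibility_text[i],
      gender = gender[i],
      min_age = min_age[i],
      healthy_volunteers = healthy_volunteers[i]
    )
  }

  X <- extract_statistics_matrix(records)
  w <- spec$effect_weights
  eta <- if (length(w) == 0) rep(0, n) else as.numeric(X[, names(w), drop = FALSE] %*% w)
  intercept <- uniroot(function(b) mean(plogis(b + eta)) - spec$termination_rate,
                       interval = c(-50, 50), tol = 1e-10)$root
  prob <- plogis(intercept + eta)
  labels <- rbinom(n, 1, prob)

  keywords <- generate_keywords(labels, spec$keyword_vocab)
  descriptions <- generate_descriptions(labels, spec$description_topics)
  for (i in seq_len(n)) {
    records[[i]]$status <- if (labels[i] == 1) "Terminated" else "Completed"
    records[[i]]$keywords_field <- keywords[i]
    records[[i]]$detailed_description <- descriptions[i]
  }

  structure(list(
    records = records, labels = labels,
    truth = list(spec = spec, intercept = intercept, eta = eta,
                 oracle_score = prob, stat_features = X)
  ), class = "synthetic_cohort")
}

generate_keywords <- function(labels, vocab) {
  n <- length(labels)
  n_kw <- 2L + rpois(n, 3)
  out <- character(n)
  p0 <- vocab$base_weight
  p1 <- vocab$base_weight * vocab$terminated_multiplier
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) == 0) next
    draws <- sample(vocab$term, sum(n_kw[idx]), replace = TRUE,
                    prob = if (cls == 1) p1 else p0)
    grp <- rep(seq_along(idx), n_kw[idx])
    out[idx] <- unname(vapply(split(draws, grp), paste, character(1),
                              collapse = "; "))
  }
  out
}

generate_descriptions <- function(labels, topics) {
  n <- length(labels)
  len <- topics$length_min + rpois(n, topics$length_mean_extra)
  p_b <- topics$base_mix + topics$signal * labels
  doc_of_token <- rep(seq_len(n), len)
  from_b <- rbinom(sum(len), 1, p_b[doc_of_token]) == 1
  tokens <- character(sum(len))
  if (any(!from_b)) {
    tokens[!from_b] <- sample(topics$words, sum(!from_b), replace = TRUE,
                              prob = topics$topic_a)
  }
  if (any(from_b)) {
    tokens[from_b] <- sample(topics$words, sum(from_b), replace = TRUE,
                             prob = topics$topic_b)
  }
  unname(vapply(split(tokens, doc_of_token), paste, character(1),
                collapse = " "))
}

#' Bayes-oracle AUC of a synthetic cohort
#'
#' AUC of the generator's own oracle scores (the true termination
#' probabilities) against the realised labels: an estimate of the best AUC
#' any model restricted to the statistics features can reach.
#'
#' @param cohort a `synthetic_cohort`.
#' @return AUC on the 0-1 scale.
#' @export
oracle_auc <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  compute_metrics(cohort$labels, cohort$truth$oracle_score)$auc / 100
}

#' Write a synthetic cohort as per-trial XML plus a truth table
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed); one `<id>.xml` per
#'   trial plus `truth.csv` with labels and oracle scores.
#' @return `dir`, invisibly.
#' @export
write_cohort_xml <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort$records) {
    writeLines(serialize_trial_record(r), file.path(dir, paste0(r$id, ".xml")))
  }
  truth <- data.frame(
    id = vapply(cohort$records, `[[`, character(1), "id"),
    label = cohort$labels,
    eta = cohort$truth$eta,
    oracle_score = cohort$truth$oracle_score,
    stringsAsFactors = FALSE
  )
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
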