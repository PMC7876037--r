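# TF-IDF keyword features from the registry keyword field.
#
# A trial's keyword field is a list of MeSH-like terms; multi-word terms
# contribute one token per word ("Ankle Joint" + "Osteoarthritis" gives the
# three keywords ankle, joint, osteoarthritis). TF-IDF uses the classical
# variant: tf = raw in-document count, idf = ln(N / df).

.stopword_cache <- new.env(parent = emptyenv())

#' English stop-word list used for keyword tokenization
#'
#' A fixed, versioned list shipped with the package (`extdata/stopwords_en.txt`).
#'
#' @return Character vector of lower-case stop words.
#' @export
keyword_stopwords <- function() {
  if (is.null(.stopword_cache$words)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "trialterm")
    .stopword_cache$words <- readLines(path)
  }
  .stopword_cache$words
}

#' Tokenize a trial keyword field
#'
#' Splits on any punctuation or whitespace, lower-cases, removes stop words
#' and drops empty tokens.
#'
#' @param keyword_field the raw keyword field (terms joined with `"; "`), or
#'   `NA`.
#' @return Character vector of tokens (empty for a missing field).
#' @export
tokenize_keywords <- function(keyword_field) {
  if (is_missing_text(keyword_field)) return(character(0))
  tokens <- strsplit(tolower(keyword_field), "[^[:alnum:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens[!tokens %in% keyword_stopwords()]
}

#' Fit the keyword vocabulary by corpus TF-IDF score
#'
#' Computes, for every distinct token, idf = ln(N / df) (N documents, df the
#' number of documents containing the token) and the corpus score
#' sum over documents of tf x idf. The vocabulary is the `max_terms` tokens
#' with the highest corpus score; ties are broken lexicographically.
#'
#' @param token_lists list of token vectors, one per trial (from
#'   [tokenize_keywords()]).
#' @param max_terms vocabulary cap, default 500.
#' @return A `keyword_vocabulary` list with `terms` (ordered by descending
#'   score), `idf` (named), `score` and `corpus_size`.
#' @export
fit_keyword_vocabulary <- function(token_lists, max_terms = 500) {
  n_doc <- length(token_lists)
  if (n_doc < 1 || all(lengths(token_lists) == 0)) {
    stop("cannot fit a keyword vocabulary on an all-empty corpus", call. = FALSE)
  }
  tf_total <- table(unlist(token_lists, use.names = FALSE))
  df <- table(unlist(lapply(token_lists, unique), use.names = FALSE))
  terms <- names(tf_total)
  idf <- log(n_doc / as.numeric(df[terms]))
  score <- as.numeric(tf_total) * idf
  ord <- order(-score, terms)
  keep <- ord[seq_len(min(max_terms, length(terms)))]
  structure(list(
    terms = terms[keep],
    idf = stats::setNames(idf[keep], terms[keep]),
    score = stats::setNames(score[keep], terms[keep]),
    corpus_size = n_doc
  ), class = "keyword_vocabulary")
}

#' TF-IDF vector of one trial against a fitted vocabulary
#'
#' Component i is tf(term_i in tokens) x idf(term_i); tokens outside the
#' vocabulary are ignored.
#'
#' @param tokens token vector of one trial.
#' @param vocab a `keyword_vocabulary`.
#' @return Numeric vector of length `length(vocab$terms)`, named by term.
#' @export
keyword_vector <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "keyword_vocabulary"))
  p <- length(vocab$terms)
  m <- match(tokens, vocab$terms)
  tf <- tabulate(m[!is.na(m)], nbins = p)
  stats::setNames(tf * unname(vocab$idf), vocab$terms)
}

#' Keyword feature block for a cohort
#'
#' @param token_lists list of token vectors.
#' @param vocab a `keyword_vocabulary`.
#' @return Numeric matrix, one row per trial, one named column per
#'   vocabulary term.
#' @export
keyword_matrix <- function(token_lists, vocab) {
  out <- t(vapply(token_lists, keyword_vector, numeric(length(vocab$terms)),
                  vocab = vocab))
  colnames(out) <- vocab$terms
  out
}
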