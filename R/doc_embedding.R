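# Dense document embeddings of the detailed-description field.
#
# Paragraph vectors in the distributed-memory formulation: every word owns a
# column of the input matrix W, every document an extra paragraph vector; the
# mean of the paragraph vector and the context word vectors predicts the
# center word through a negative-sampling objective. Training is serial and
# seeded, so models are bit-reproducible.

embed_tokenize <- function(text) {
  if (is_missing_text(text)) return(character(0))
  tokens <- strsplit(gsub("[^a-z0-9 ]", " ", tolower(text)), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Fit a paragraph-vector model on detailed descriptions
#'
#' Trains PV-DM paragraph vectors with negative sampling on the given
#' documents. Text is lower-cased, punctuation-stripped and whitespace
#' tokenized; words seen fewer than `min_count` times are dropped. Training
#' is single-threaded and deterministic under a fixed seed.
#'
#' @param descriptions character vector of documents (at least two
#'   non-empty).
#' @param d embedding dimension, default 100.
#' @param seed integer seed for initialisation and negative sampling.
#' @param window context half-window in tokens, default 5.
#' @param min_count minimum corpus frequency for a word to enter the
#'   vocabulary, default 2.
#' @param epochs training passes over the corpus, default 20.
#' @param negative negative samples per center word, default 5.
#' @param alpha,min_alpha initial and final learning rate (linear decay).
#' @return A `doc_embedding` model holding the word-vector matrix `W`
#'   (vocabulary x d), the output matrix, the trained per-document vectors
#'   and the training metadata.
#' @export
fit_doc_embedding <- function(descriptions, d = 100, seed = 1L, window = 5L,
                              min_count = 2L, epochs = 20L, negative = 5L,
                              alpha = 0.025, min_alpha = 1e-4) {
  stopifnot(d >= 1)
  token_lists <- lapply(descriptions, embed_tokenize)
  if (sum(lengths(token_lists) > 0) < 2) {
    stop("need at least two non-empty documents to fit an embedding", call. = FALSE)
  }
  counts <- table(unlist(token_lists, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) {
    stop("no word reaches min_count; corpus too small", call. = FALSE)
  }
  ord <- order(-as.numeric(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.numeric(counts)[ord]

  docs <- lapply(token_lists, function(tok) {
    idx <- match(tok, vocab)
    as.integer(idx[!is.na(idx)] - 1L)
  })
  unigram <- freq^0.75
  fit <- .d2v_train(docs, length(vocab), as.integer(d), as.integer(window),
                    as.integer(epochs), as.integer(negative), alpha, min_alpha,
                    unigram, as.integer(seed))
  rownames(fit$W) <- vocab
  structure(list(
    d = as.integer(d), vocab = vocab, freq = freq, W = fit$W,
    Wout = fit$Wout, doc_vectors = fit$doc_vectors, unigram = unigram,
    params = list(seed = as.integer(seed), window = as.integer(window),
                  min_count = as.integer(min_count), epochs = as.integer(epochs),
                  negative = as.integer(negative), alpha = alpha,
                  min_alpha = min_alpha)
  ), class = "doc_embedding")
}

#' Infer the embedding vector of a (possibly unseen) document
#'
#' Freezes the word and output matrices and trains a fresh paragraph vector
#' for the document. Deterministic under a fixed seed, so identical
#' documents map to identical vectors.
#'
#' @param model a fitted `doc_embedding`.
#' @param description document text.
#' @param epochs inference passes, default 50.
#' @param seed seed for the inference; defaults to the model's training
#'   seed.
#' @return Numeric vector of length `model$d`. A document with no
#'   in-vocabulary word falls back to the zero vector (with a message).
#' @export
infer_doc_vector <- function(model, description, epochs = 50L, seed = NULL) {
  stopifnot(inherits(model, "doc_embedding"))
  seed <- as.integer(seed %||% model$params$seed)
  idx <- match(embed_tokenize(description), model$vocab)
  idx <- as.integer(idx[!is.na(idx)] - 1L)
  if (length(idx) == 0) {
    message("document has no in-vocabulary words; returning the zero vector")
    return(numeric(model$d))
  }
  .d2v_infer(idx, model$W, model$Wout, model$params$window,
             as.integer(epochs), model$params$negative, model$params$alpha,
             model$params$min_alpha, model$unigram, seed)
}

#' Embedding feature block for a set of documents
#'
#' @param model a fitted `doc_embedding`.
#' @param descriptions character vector of documents.
#' @param epochs,seed passed to [infer_doc_vector()].
#' @return Numeric matrix, one row per document, columns named
#'   `emb_0` ... `emb_{d-1}`.
#' @export
infer_doc_matrix <- function(model, descriptions, epochs = 50L, seed = NULL) {
  out <- t(vapply(descriptions, function(x) {
    infer_doc_vector(model, x, epochs = epochs, seed = seed)
  }, numeric(model$d), USE.NAMES = FALSE))
  colnames(out) <- paste0("emb_", seq_len(model$d) - 1L)
  out
}

#' Nearest words to a query by cosine similarity
#'
#' @param model a fitted `doc_embedding`.
#' @param query a word in the model vocabulary.
#' @param k number of neighbours, default 10.
#' @return Data frame of `word` and `similarity`, non-increasing, query
#'   excluded.
#' @export
nearest_words <- function(model, query, k = 10) {
  stopifnot(inherits(model, "doc_embedding"))
  if (!query %in% model$vocab) {
    stop("word '", query, "' is not in the embedding vocabulary", call. = FALSE)
  }
  W <- model$W
  q <- W[query, ]
  sims <- as.numeric(W %*% q) / (sqrt(rowSums(W^2)) * sqrt(sum(q^2)))
  names(sims) <- model$vocab
  sims <- sims[names(sims) != query]
  ord <- order(-sims, names(sims))[seq_len(min(k, length(sims)))]
  data.frame(word = names(sims)[ord], similarity = unname(sims[ord]),
             stringsAsFactors = FALSE)
}
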