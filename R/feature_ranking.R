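# Filter feature selection and Dowdall rank aggregation.
#
# Five filters rank every feature by its relevance to the binary termination
# label: one-way ANOVA F, plug-in mutual information on equal-frequency
# discretized features, ReliefF, and the two information-theoretic greedy
# selectors CIFE and ICAP (run to exhaustion so they yield complete
# rankings). Ties are always broken lexicographically by feature name, so
# rankings are reproducible.

RANK_METHODS <- c("anova", "mutual_information", "relieff", "cife", "icap")

#' Equal-frequency discretization
#'
#' Bins a numeric vector into (at most) `bins` equal-frequency classes;
#' constant vectors collapse to a single bin.
#'
#' @param x numeric vector.
#' @param bins target number of bins, default 10.
#' @return Integer codes in `1..bins`.
#' @export
discretize_ef <- function(x, bins = 10) {
  if (length(unique(x)) <= bins) {
    return(match(x, sort(unique(x))))
  }
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# plug-in mutual information (nats) between two integer code vectors
mi_disc <- function(a, b) {
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

# conditional mutual information I(a;b | y)
cmi_disc <- function(a, b, y) {
  n <- length(a)
  out <- 0
  for (lev in unique(y)) {
    idx <- y == lev
    out <- out + sum(idx) / n * mi_disc(a[idx], b[idx])
  }
  out
}

anova_f_scores <- function(X, y) {
  n <- nrow(X)
  g1 <- y == 1
  n1 <- sum(g1)
  n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((t(t(X[g1, , drop = FALSE]) - m1))^2) +
    colSums((t(t(X[!g1, , drop = FALSE]) - m0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  # a perfectly separating feature has ssw = 0 and F = Inf (keeps rank 1);
  # a constant feature is 0/0 and scores 0
  f[is.nan(f)] <- 0
  f
}

relieff_scores <- function(X, y, k = 10) {
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(col) {
    r <- diff(range(col))
    if (r == 0) 1 else r
  })
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  prior1 <- mean(y == 1)
  w <- numeric(p)
  for (i in seq_len(n)) {
    diffs <- abs(sweep(Xn, 2, Xn[i, ]))      # n x p
    d <- rowSums(diffs)
    d[i] <- Inf
    same <- y == y[i]
    same[i] <- FALSE
    hits <- which(same)[order(d[same])]
    miss <- which(!same)[order(d[!same])]
    kh <- hits[seq_len(min(k, length(hits)))]
    km <- miss[seq_len(min(k, length(miss)))]
    pm <- if (y[i] == 1) 1 - prior1 else prior1
    pm <- pm / (1 - (if (y[i] == 1) prior1 else 1 - prior1))
    if (length(kh) > 0) w <- w - colMeans(diffs[kh, , drop = FALSE]) / n
    if (length(km) > 0) w <- w + pm * colMeans(diffs[km, , drop = FALSE]) / n
  }
  w
}

# greedy forward selection to exhaustion under the CIFE or ICAP criterion;
# returns the selection order (vector of column indices)
greedy_cmi_order <- function(X, y, criterion = c("cife", "icap"), bins = 10) {
  criterion <- match.arg(criterion)
  p <- ncol(X)
  nm <- colnames(X)
  Xd <- lapply(seq_len(p), function(j) discretize_ef(X[, j], bins))
  rel <- vapply(Xd, function(a) mi_disc(a, y), numeric(1))

  selected <- integer(0)
  remaining <- seq_len(p)
  # running penalty per candidate: sum over selected s of the criterion term
  penalty <- numeric(p)
  for (step in seq_len(p)) {
    score <- rel[remaining] - penalty[remaining]
    best <- remaining[order(-score, nm[remaining])[1]]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    for (f in remaining) {
      red <- mi_disc(Xd[[f]], Xd[[best]])
      cred <- cmi_disc(Xd[[f]], Xd[[best]], y)
      penalty[f] <- penalty[f] + if (criterion == "cife") {
        red - cred
      } else {
        max(0, red - cred)
      }
    }
  }
  selected
}

#' Rank features by one filter method
#'
#' Produces a complete ranking (1 = most relevant) of the columns of `X`
#' with respect to the binary label `y`. `anova` ranks by descending one-way
#' F statistic; `mutual_information` by plug-in MI on equal-frequency
#' discretized features; `relieff` by ReliefF weight with `k` nearest
#' hits/misses over all instances; `cife` and `icap` convert a greedy
#' forward-selection order under their respective criteria (CIFE: relevance
#' minus redundancy plus conditional redundancy; ICAP: relevance minus
#' capped interaction) into ranks. All ties break lexicographically by
#' feature name.
#'
#' @param X numeric feature matrix with column names, no missing values.
#' @param y binary label vector (0/1) with both classes present.
#' @param method one of `"anova"`, `"mutual_information"`, `"relieff"`,
#'   `"cife"`, `"icap"`.
#' @param k ReliefF neighbourhood size, default 10.
#' @param bins discretization bins for the information-theoretic methods,
#'   default 10.
#' @return A `rank_list`: list with `method` and `rank`, a named integer
#'   permutation of `1..ncol(X)`.
#' @export
rank_features <- function(X, y, method = RANK_METHODS, k = 10, bins = 10) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("y must contain both classes", call. = FALSE)
  }
  nm <- colnames(X)
  p <- ncol(X)
  rank <- integer(p)
  if (method %in% c("cife", "icap")) {
    yd <- y
    ord <- greedy_cmi_order(X, yd, method, bins)
    rank[ord] <- seq_len(p)
  } else {
    score <- switch(method,
      anova = anova_f_scores(X, y),
      mutual_information = {
        yd <- y
        vapply(seq_len(p), function(j) mi_disc(discretize_ef(X[, j], bins), yd),
               numeric(1))
      },
      relieff = relieff_scores(X, y, k)
    )
    rank[order(-score, nm)] <- seq_len(p)
  }
  structure(list(method = method, rank = stats::setNames(rank, nm)),
            class = "rank_list")
}

#' Fuse filter rankings with the Dowdall system
#'
#' Each method contributes 1/rank for every feature; features are ordered by
#' descending total score (ties lexicographic). The Dowdall system is a
#' Borda-count variant that favours features with many first preferences: a
#' single bottom rank contributes only a small fraction to the total.
#'
#' @param rank_lists list of `rank_list` objects over the same feature set.
#' @return An `aggregated_ranking`: list with `score` (named, descending)
#'   and `order` (feature names).
#' @export
dowdall_aggregate <- function(rank_lists) {
  stopifnot(length(rank_lists) >= 1)
  feats <- sort(names(rank_lists[[1]]$rank))
  for (rl in rank_lists) {
    other <- sort(names(rl$rank))
    if (!identical(feats, other)) {
      d <- union(setdiff(feats, other), setdiff(other, feats))
      stop("rank lists cover different feature sets; mismatched features: ",
           paste(d, collapse = ", "), call. = FALSE)
    }
  }
  score <- numeric(length(feats))
  names(score) <- feats
  for (rl in rank_lists) score <- score + 1 / rl$rank[feats]
  ord <- order(-score, feats)
  structure(list(score = score[ord], order = feats[ord]),
            class = "aggregated_ranking")
}

#' Full ranking report over all five filters
#'
#' Runs every method in [RANK_METHODS] and fuses them with
#' [dowdall_aggregate()].
#'
#' @inheritParams rank_features
#' @param methods which filters to run (default all five).
#' @return Data frame with one row per feature: per-method ranks,
#'   `dowdall_score` and `aggregate_rank`, sorted by aggregate rank.
#' @export
ranking_report <- function(X, y, methods = RANK_METHODS, k = 10, bins = 10) {
  lists <- lapply(methods, function(m) rank_features(X, y, m, k = k, bins = bins))
  agg <- dowdall_aggregate(lists)
  feats <- agg$order
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (rl in lists) out[[paste0("rank_", rl$method)]] <- unname(rl$rank[feats])
  out$dowdall_score <- unname(agg$score[feats])
  out$aggregate_rank <- seq_along(feats)
  out
}
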