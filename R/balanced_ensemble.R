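# Class-imbalance handling by repeated random undersampling.
#
# The terminated class is the minority (roughly 1:7.75 against completed
# trials). Each ensemble member is trained on all minority samples plus an
# equally sized uniform subsample of the majority class (1:1 after
# undersampling); member scores are combined by averaging the predicted
# termination probabilities (majority vote available as an alternative).

LEARNERS <- c("neural_network", "random_forest", "gradient_boosted_trees",
              "logistic_regression")

#' Balanced random undersample of a binary label vector
#'
#' Keeps every minority-class index and a uniform random subset of the
#' majority class of equal size, giving an exact 1:1 class ratio. When the
#' classes are already balanced both are fully retained.
#'
#' @param y binary label vector (0/1).
#' @param seed integer seed for the majority draw.
#' @return Sorted integer vector of retained row indices.
#' @export
random_undersample <- function(y, seed) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("y must contain both classes", call. = FALSE)
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  keep <- with_seed(seed, sample(maj_idx, length(min_idx)))
  sort(c(min_idx, keep))
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
scale_apply <- function(X, s) sweep(sweep(X, 2, s$center), 2, s$scale, "/")

#' Fit a single base learner
#'
#' Trains one model of the requested family on the given matrix. Settings
#' follow the study configuration: the neural network has one hidden layer
#' of 100 nodes, the random forest 1,000 fully grown trees; the remaining
#' hyperparameters are overridable defaults.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary labels (0/1).
#' @param learner_spec one of [LEARNERS].
#' @param seed integer seed.
#' @param params named list of learner-specific overrides (`size`, `maxit`,
#'   `decay` for the neural network; `num_trees` for the forest; `nrounds`,
#'   `max_depth`, `eta` for boosting).
#' @return A `base_model` usable with [predict_base()].
#' @export
fit_base <- function(X, y, learner_spec = LEARNERS, seed = 1L, params = list()) {
  learner_spec <- match.arg(learner_spec)
  X <- as.matrix(X)
  y <- as.integer(y)
  fit <- switch(learner_spec,
    logistic_regression = {
      with_seed(seed, suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                       family = stats::binomial())))
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE)
      ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                     num.trees = params$num_trees %||% 1000,
                     min.node.size = 1, probability = TRUE,
                     num.threads = 1, seed = seed)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 6,
                      eta = params$eta %||% 0.3,
                      nthread = 1),
        data = dtrain,
        nrounds = params$nrounds %||% 100,
        verbose = 0))
    },
    neural_network = {
      sc <- scale_fit(X)
      fit <- with_seed(seed, nnet::nnet(
        scale_apply(X, sc), y, size = params$size %||% 100,
        decay = params$decay %||% 1e-3, maxit = params$maxit %||% 100,
        entropy = TRUE, MaxNWts = 1e6, trace = FALSE))
      list(net = fit, scaler = sc)
    }
  )
  structure(list(type = learner_spec, fit = fit, seed = seed,
                 feature_names = colnames(X)),
            class = "base_model")
}

#' Predicted termination probability of a base model
#'
#' @param model a `base_model`.
#' @param X feature matrix with the training column names.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict_base <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature-name mismatch between model and prediction data", call. = FALSE)
  }
  switch(model$type,
    logistic_regression = {
      beta <- model$fit$coefficients
      beta[is.na(beta)] <- 0
      as.numeric(plogis(cbind(1, X) %*% beta))
    },
    random_forest = {
      pr <- predict(model$fit, data = data.frame(X, check.names = FALSE),
                    num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    gradient_boosted_trees = as.numeric(predict(model$fit,
                                                xgboost::xgb.DMatrix(X))),
    neural_network = as.numeric(predict(model$fit$net,
                                        scale_apply(X, model$fit$scaler)))
  )
}

#' Fit a random-undersampling ensemble
#'
#' Repeats balanced undersampling `rounds` times (default 10); each round
#' trains one base model on its balanced subsample. Member seeds derive
#' deterministically from the master seed, so the fit is fully
#' reproducible.
#'
#' @inheritParams fit_base
#' @param rounds number of undersampling rounds / members, default 10.
#' @param combination `"mean"` (average member probabilities, default) or
#'   `"vote"` (fraction of members voting class 1 at 0.5).
#' @return An `ensemble_model` with `members`, `learner_spec`,
#'   `member_seeds` and `combination`.
#' @export
fit_ensemble <- function(X, y, learner_spec = LEARNERS, rounds = 10L,
                         seed = 1L, params = list(),
                         combination = c("mean", "vote")) {
  learner_spec <- match.arg(learner_spec)
  combination <- match.arg(combination)
  stopifnot(rounds >= 1)
  X <- as.matrix(X)
  y <- as.integer(y)
  member_seeds <- with_seed(seed, sample.int(2147483646L, rounds))
  members <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    idx <- random_undersample(y, member_seeds[r])
    members[[r]] <- tryCatch(
      fit_base(X[idx, , drop = FALSE], y[idx], learner_spec,
               seed = member_seeds[r], params = params),
      error = function(e) {
        stop("ensemble member ", r, " failed to train: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  structure(list(members = members, learner_spec = learner_spec,
                 member_seeds = member_seeds, combination = combination),
            class = "ensemble_model")
}

#' Combined termination score of an ensemble
#'
#' @param model an `ensemble_model`.
#' @param X feature matrix with the training column names.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
ensemble_score <- function(model, X) {
  stopifnot(inherits(model, "ensemble_model"))
  probs <- vapply(model$members, function(m) predict_base(m, X),
                  numeric(nrow(X)))
  probs <- matrix(probs, nrow = nrow(X))
  if (model$combination == "vote") {
    rowMeans(probs >= 0.5)
  } else {
    rowMeans(probs)
  }
}

#' Threshold scores into class labels
#'
#' A score exactly at the threshold is classified as terminated (label 1).
#'
#' @param scores numeric score vector.
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return Integer labels (0/1).
#' @export
classify <- function(scores, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  as.integer(scores >= threshold)
}
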