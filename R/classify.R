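#' Balanced accuracy
#'
#' Unweighted mean of per-class recalls; robust to class imbalance and
#' equal to ordinary accuracy on balanced data. Chance level is `1/k`
#' for `k` classes.
#'
#' @param truth True class labels (every class non-empty).
#' @param predicted Predicted labels, same length.
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  check_lengths_equal(truth, predicted)
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- unique(truth)
  recalls <- vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Stratified fold assignment for repeated cross-validation
#'
#' Assigns each observation to one of `folds` test folds per repeat,
#' separately within every class, so each fold's class proportions match
#' the global proportions to within one observation.
#'
#' @param y Class labels.
#' @param folds Folds per repeat.
#' @param repeats Number of repeats.
#' @param seed Seed.
#' @return Integer matrix (length(y) x repeats) of fold ids in
#'   `1:folds`.
#' @export
stratified_folds <- function(y, folds = 5L, repeats = 10L, seed = 1L) {
  y <- as.character(y)
  if (min(table(y)) < folds) {
    abort("Every class must have at least `folds` members.")
  }
  out <- matrix(NA_integer_, length(y), repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, r))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      out[idx, r] <- rep_len(seq_len(folds), length(idx))
    }
  }
  out
}

# --- classifier panel -------------------------------------------------
# Each learner is a list(fit = function(x, y, w), predict = function(fit, x))
# where x is a numeric matrix with syntactic column names, y a factor and
# w per-observation weights inverse to class frequency. Learners without
# native weighting use a uniform class-prior adjustment instead.

class_weights_for <- function(y) {
  tb <- table(y)
  w <- (length(y) / (length(tb) * tb))[as.character(y)]
  as.numeric(w)
}

learner_logistic <- function() list(
  fit = function(x, y, w) {
    df <- data.frame(x, .y = y)
    nnet::multinom(.y ~ ., data = df, weights = w, trace = FALSE,
                   maxit = 300, MaxNWts = 10000)
  },
  predict = function(fit, x) as.character(predict(fit, data.frame(x)))
)

learner_lda <- function() list(
  fit = function(x, y, w) {
    k <- nlevels(y)
    MASS::lda(x, grouping = y, prior = rep(1 / k, k))
  },
  predict = function(fit, x) as.character(predict(fit, x)$class)
)

learner_bayes <- function() list(
  fit = function(fit_x, y, w) {
    list(model = e1071::naiveBayes(fit_x, y), prior = prop.table(table(y)))
  },
  predict = function(fit, x) {
    post <- predict(fit$model, x, type = "raw")
    # uniform-prior adjustment in place of per-sample weights
    adj <- sweep(post, 2, as.numeric(fit$prior[colnames(post)]), "/")
    colnames(post)[max.col(adj)]
  }
)

learner_ranger <- function(extratrees = FALSE) list(
  fit = function(x, y, w) {
    tb <- table(y)
    cw <- as.numeric(length(y) / (length(tb) * tb))
    names(cw) <- names(tb)
    args <- list(x = x, y = y, num.trees = 500, class.weights = cw,
                 seed = 1L, num.threads = 1L)
    if (extratrees) {
      args <- c(args, list(splitrule = "extratrees", num.random.splits = 1,
                           replace = FALSE, sample.fraction = 1))
    }
    do.call(ranger::ranger, args)
  },
  predict = function(fit, x) as.character(predict(fit, data.frame(x))$predictions)
)

# SAMME adaptive boosting over shallow rpart trees.
learner_adaboost <- function(n_rounds = 50L, maxdepth = 3L) list(
  fit = function(x, y, w) {
    df <- data.frame(x, .y = y)
    k <- nlevels(y)
    wts <- w / sum(w)
    stumps <- list(); alphas <- numeric(0)
    for (m in seq_len(n_rounds)) {
      tr <- rpart::rpart(.y ~ ., data = df, weights = wts, method = "class",
                         control = rpart::rpart.control(maxdepth = maxdepth,
                                                        cp = 0, xval = 0))
      pred <- as.character(predict(tr, df, type = "class"))
      mis <- pred != as.character(y)
      err <- sum(wts[mis])
      if (err <= 1e-10) { stumps[[m]] <- tr; alphas[m] <- 10; break }
      if (err >= 1 - 1 / k) break
      alpha <- log((1 - err) / err) + log(k - 1)
      stumps[[m]] <- tr; alphas[m] <- alpha
      wts <- wts * exp(alpha * mis)
      wts <- wts / sum(wts)
    }
    if (!length(stumps)) {
      stumps <- list(rpart::rpart(.y ~ ., data = df, method = "class"))
      alphas <- 1
    }
    list(stumps = stumps, alphas = alphas, levels = levels(y))
  },
  predict = function(fit, x) {
    df <- data.frame(x)
    votes <- matrix(0, nrow(df), length(fit$levels),
                    dimnames = list(NULL, fit$levels))
    for (m in seq_along(fit$stumps)) {
      pred <- as.character(predict(fit$stumps[[m]], df, type = "class"))
      votes[cbind(seq_len(nrow(df)), match(pred, fit$levels))] <-
        votes[cbind(seq_len(nrow(df)), match(pred, fit$levels))] + fit$alphas[m]
    }
    fit$levels[max.col(votes)]
  }
)

learner_dummy <- function() list(
  fit = function(x, y, w) list(levels = levels(y), prior = prop.table(table(y))),
  predict = function(fit, x) {
    sample(fit$levels, nrow(x), replace = TRUE,
           prob = as.numeric(fit$prior[fit$levels]))
  }
)

#' Default classifier panel
#'
#' Logistic regression, linear discriminant analysis, naive Bayes,
#' random forest, extremely randomised trees, SAMME adaptive boosting
#' over shallow trees, and a chance-level dummy that samples labels from
#' the class prior. All learners run with default hyperparameters;
#' classes are weighted inversely to frequency where the learner
#' supports it (the discriminant and Bayes learners use a uniform-prior
#' adjustment instead).
#'
#' @return Named list of learners for [run_cv_panel()].
#' @export
default_classifier_panel <- function() {
  list(
    dummy = learner_dummy(),
    lr = learner_logistic(),
    lda = learner_lda(),
    bayes = learner_bayes(),
    rf = learner_ranger(extratrees = FALSE),
    et = learner_ranger(extratrees = TRUE),
    abc = learner_adaboost()
  )
}

#' Repeated stratified cross-validation of a classifier panel
#'
#' Evaluates each classifier's ability to reproduce the cluster labels
#' from the clinical variables under repeated stratified k-fold
#' cross-validation (5 folds x 10 repeats by default), scoring every
#' fold by balanced accuracy.
#'
#' @param data Data frame of predictor variables (coded clinical
#'   variables), one row per patient.
#' @param labels Cluster label per row; every class needs at least
#'   `folds` members.
#' @param classifiers Named learner list (see
#'   [default_classifier_panel()]).
#' @param folds,repeats Cross-validation design.
#' @param seed Master seed (fold assignment and learner randomness).
#' @return A `bcrl_cv` object; `tidy()` gives per-classifier mean and SD
#'   of balanced accuracy in percent across all fold scores, `x$scores`
#'   the per-fold results.
#' @export
run_cv_panel <- function(data, labels, classifiers = default_classifier_panel(),
                         folds = 5L, repeats = 10L, seed = 1L) {
  x <- as.matrix(as.data.frame(lapply(as_tibble(data), as.numeric)))
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  y <- factor(labels)
  fold_ids <- stratified_folds(y, folds = folds, repeats = repeats, seed = seed)
  scores <- purrr::imap_dfr(classifiers, function(learner, name) {
    purrr::map_dfr(seq_len(repeats), function(r) {
      purrr::map_dfr(seq_len(folds), function(f) {
        test <- fold_ids[, r] == f
        ytr <- droplevels(y[!test])
        set.seed(derive_seed(seed, 1000L * r + f))
        fit <- learner$fit(x[!test, , drop = FALSE], ytr,
                           class_weights_for(ytr))
        pred <- learner$predict(fit, x[test, , drop = FALSE])
        tibble(classifier = name, rep = r, fold = f,
               balanced_accuracy = balanced_accuracy(y[test], pred))
      })
    })
  })
  structure(list(scores = scores, folds = folds, repeats = repeats,
                 k = nlevels(y), seed = seed),
            class = "bcrl_cv")
}

#' @rdname run_cv_panel
#' @param x A `bcrl_cv`.
#' @param ... Unused.
#' @method tidy bcrl_cv
#' @export
tidy.bcrl_cv <- function(x, ...) {
  x$scores |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(
      mean_ba_pct = 100 * mean(.data$balanced_accuracy),
      sd_ba_pct = 100 * sd(.data$balanced_accuracy),
      n_folds = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_ba_pct))
}

#' @rdname run_cv_panel
#' @method glance bcrl_cv
#' @export
glance.bcrl_cv <- function(x, ...) {
  tibble(classes = x$k, folds = x$folds, repeats = x$repeats,
         total_fits = x$folds * x$repeats * dplyr::n_distinct(x$scores$classifier))
}

#' @export
print.bcrl_cv <- function(x, ...) {
  cat(sprintf("<bcrl_cv: %d classes, %d-fold x %d repeats>\n",
              x$k, x$folds, x$repeats))
  print(as.data.frame(tidy(x)), digits = 3)
  invisible(x)
}
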