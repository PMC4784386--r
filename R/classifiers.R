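# Classifier panel with embedded feature-subset selection, the >0.6
# validity rule, and the classifier-consensus desirability.

#' Built-in classifiers with embedded feature selection
#'
#' Each classifier is a function `fit(x, y)` (`x` samples x genes, `y`
#' factor with levels `case`/`control`) returning `list(predict =
#' function(newx) character, features = character)` where `features` is
#' the gene subset the classifier itself selected while fitting: nonzero
#' coefficients for the penalized logistic models, split variables for the
#' CART tree, impurity importance above its mean for the random forest,
#' and nonzero gain for gradient boosting.
#'
#' @return Named list of classifier constructors.
#' @export
default_classifiers <- function() {
  list(
    lasso_logistic = glmnet_classifier(alpha = 1),
    elastic_net = glmnet_classifier(alpha = 0.5),
    cart = function(x, y) {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 5, cp = 0.01))
      vars <- as.character(fit$frame$var)
      list(predict = function(newx) {
             as.character(predict(fit, data.frame(newx, check.names = FALSE),
                                  type = "class"))
           },
           features = unique(vars[vars != "<leaf>"]))
    },
    random_forest = function(x, y) {
      fit <- ranger::ranger(x = x, y = y, num.trees = 100,
                            importance = "impurity",
                            num.threads = 1L, verbose = FALSE)
      imp <- fit$variable.importance
      list(predict = function(newx) {
             as.character(stats::predict(fit, data = newx,
                                         num.threads = 1L)$predictions)
           },
           features = names(imp)[imp > mean(imp)])
    },
    gradient_boosting = function(x, y) {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "case"))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 2,
                      eta = 0.3, nthread = 1L),
        data = dtrain, nrounds = 30, verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      list(predict = function(newx) {
             pr <- stats::predict(fit, xgboost::xgb.DMatrix(newx))
             ifelse(pr > 0.5, "case", "control")
           },
           features = imp$Feature)
    })
}

glmnet_classifier <- function(alpha) {
  force(alpha)
  function(x, y) {
    fit <- suppressWarnings(
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                        nfolds = 5))
    coefs <- as.matrix(stats::coef(fit, s = "lambda.min"))
    feats <- rownames(coefs)[coefs[, 1L] != 0]
    feats <- setdiff(feats, "(Intercept)")
    list(predict = function(newx) {
           as.character(stats::predict(fit, newx, s = "lambda.min",
                                       type = "class"))
         },
         features = feats)
  }
}

classification_metrics <- function(pred, truth) {
  acc <- mean(pred == truth)
  se <- mean(pred[truth == "case"] == "case")
  sp <- mean(pred[truth == "control"] == "control")
  c(acc = acc, se = se, sp = sp)
}

stratified_indices <- function(group, fraction) {
  idx <- unlist(lapply(split(seq_along(group), group), function(i) {
    n_test <- max(1L, round(length(i) * fraction))
    sample(i, n_test)
  }), use.names = FALSE)
  sort(idx)
}

stratified_folds <- function(group, k) {
  fold <- integer(length(group))
  for (g in unique(group)) {
    i <- sample(which(group == g))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

#' Evaluate a classifier panel with embedded gene selection
#'
#' Splits the samples into a stratified training/test partition
#' (`test_fraction` held out, reproducible from `seed`), fits every
#' classifier on the training set, and reports accuracy, sensitivity and
#' specificity on the training set, leave-one-out cross-validation,
#' stratified 5-fold cross-validation, and the held-out test set. A
#' classifier is `valid` when all twelve performance numbers exceed 0.6.
#'
#' @param expr Expression tibble (typically the mRMR-selected genes).
#' @param labels Phenotype tibble.
#' @param classifiers Named list of classifier constructors (default
#'   [default_classifiers()]).
#' @param test_fraction Held-out proportion (default 0.25).
#' @param seed Integer seed controlling the split, CV folds and any
#'   stochastic learner.
#' @return Tibble of class `classifier_panel`: one row per classifier with
#'   `n_selected`, a `genes` list-column of the selected subset, the
#'   twelve metrics (`acc`/`se`/`sp` x `train`/`loo`/`cv5`/`test`) and
#'   `valid`.
#' @export
evaluate_classifier_panel <- function(expr, labels = expr_labels(expr),
                                      classifiers = default_classifiers(),
                                      test_fraction = 0.25, seed = 1L) {
  labels <- check_labeled(expr, labels)
  m <- t(expr_matrix(expr))  # samples x genes
  y <- factor(labels$group, levels = c("case", "control"))
  withr::with_seed(seed, {
    test_idx <- stratified_indices(as.character(y), test_fraction)
    train_idx <- setdiff(seq_len(nrow(m)), test_idx)
    y_train <- y[train_idx]
    if (length(unique(y_train)) < 2L || min(table(y_train)) < 2L)
      stop("a class is (nearly) absent from the training split")
    x_train <- m[train_idx, , drop = FALSE]
    x_test <- m[test_idx, , drop = FALSE]
    y_test <- y[test_idx]
    folds <- stratified_folds(as.character(y_train), 5L)

    rows <- purrr::imap(classifiers, function(cls, name) {
      fit <- cls(x_train, y_train)
      train_met <- classification_metrics(fit$predict(x_train),
                                          as.character(y_train))
      loo_pred <- vapply(seq_along(train_idx), function(i) {
        f <- cls(x_train[-i, , drop = FALSE], y_train[-i])
        f$predict(x_train[i, , drop = FALSE])[1L]
      }, character(1L))
      loo_met <- classification_metrics(loo_pred, as.character(y_train))
      cv_pred <- character(length(train_idx))
      for (k in 1:5) {
        hold <- folds == k
        f <- cls(x_train[!hold, , drop = FALSE], y_train[!hold])
        cv_pred[hold] <- f$predict(x_train[hold, , drop = FALSE])
      }
      cv_met <- classification_metrics(cv_pred, as.character(y_train))
      test_met <- classification_metrics(fit$predict(x_test),
                                         as.character(y_test))
      mets <- c(train = train_met, loo = loo_met, cv5 = cv_met,
                test = test_met)
      names(mets) <- sub("^(train|loo|cv5|test)\\.(acc|se|sp)$", "\\2_\\1",
                         names(mets))
      tibble::tibble(classifier = name,
                     n_selected = length(fit$features),
                     genes = list(fit$features),
                     !!!as.list(mets),
                     valid = all(mets > 0.6))
    })
    out <- dplyr::bind_rows(rows)
  })
  attr(out, "seed") <- seed
  attr(out, "test_samples") <- labels$sample_id[test_idx]
  class(out) <- c("classifier_panel", class(out))
  out
}

#' @method glance classifier_panel
#' @export
glance.classifier_panel <- function(x, ...) {
  tibble::tibble(
    n_classifiers = nrow(x),
    n_valid = sum(x$valid),
    mean_acc_test = mean(x$acc_test),
    n_union_valid = length(unique(unlist(x$genes[x$valid]))))
}

#' Classifier-consensus desirability
#'
#' Linear desirability of the number of valid classifiers that selected a
#' gene: `(nrel - 1) / (n_class - 1)`, 0 when only one valid classifier
#' includes the gene and 1 when all of them do.
#'
#' @param nrel Number of valid classifiers including the gene (>= 1).
#' @param n_class Number of valid classifiers (>= 2).
#' @return Desirability in `[0, 1]`.
#' @export
classifier_consensus_score <- function(nrel, n_class) {
  if (any(n_class < 2L)) stop("n_class must be >= 2")
  if (any(nrel < 1L)) stop("nrel must be >= 1 (genes outside every valid classifier are excluded upstream)")
  if (any(nrel > n_class)) stop("nrel cannot exceed n_class")
  (nrel - 1) / (n_class - 1)
}

#' Machine-learning relevance ranking
#'
#' Fuses the ranker-ensemble desirability and the classifier-consensus
#' desirability into the per-gene relevance score `MLrel = (d_rank_mean +
#' d_class) / 2` over the union of the gene subsets selected by the valid
#' classifiers. When exactly one classifier is valid `d_class` is 1 for
#' every gene in its subset (each gene is included by all valid
#' classifiers).
#'
#' @param ens A [consensus_feature_ranking()] result covering at least the
#'   union of valid subsets.
#' @param panel An [evaluate_classifier_panel()] result with at least one
#'   valid classifier.
#' @return Ranked-list tibble (`rank`, `gene_id`, `score = MLrel`),
#'   descending score with ties broken by gene id.
#' @export
ml_relevance_ranking <- function(ens, panel) {
  valid <- panel[panel$valid, , drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid classifiers")
  subsets <- valid$genes
  universe <- sort(unique(unlist(subsets)))
  if (length(universe) == 0L) stop("valid classifiers selected no genes")
  d_rank <- ensemble_scores(ens)
  missing <- setdiff(universe, d_rank$gene_id)
  if (length(missing) > 0L)
    stop("gene(s) in a valid subset but absent from the ranker ensemble: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  nrel <- vapply(universe, function(g)
    sum(vapply(subsets, function(s) g %in% s, logical(1L))), integer(1L))
  n_class <- nrow(valid)
  d_class <- if (n_class >= 2L) classifier_consensus_score(nrel, n_class)
             else rep(1, length(universe))
  mlrel <- (d_rank$d_rank_mean[match(universe, d_rank$gene_id)] + d_class) / 2
  ord <- order(-mlrel, universe)
  new_ranked_list(universe[ord], mlrel[ord])
}
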