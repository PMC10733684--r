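#' Names of the nine classifier families
#'
#' @return character vector of the accepted algorithm names.
#' @export
algorithm_names <- function() {
  c("AdaBoost", "GradientBoosting", "kNN", "LogisticRegression", "NaiveBayes",
    "NeuralNetwork", "RandomForest", "SVM", "Tree")
}

fixed_hyperparameters <- function(name) {
  switch(name,
    AdaBoost = list(n_estimators = 50L, learning_rate = 1, variant = "SAMME.R",
                    base_learner = "depth-1 tree (stump)"),
    GradientBoosting = list(n_trees = 100L, learning_rate = 0.1, max_depth = 3L,
                            min_split = 2L),
    kNN = list(k = 7L, metric = "euclidean", weights = "uniform"),
    LogisticRegression = list(penalty = "ridge", C = 1),
    NaiveBayes = list(distribution = "gaussian"),
    NeuralNetwork = list(hidden_neurons = 100L, activation = "relu",
                         solver = "adam", max_iter = 200L),
    RandomForest = list(n_trees = 10L, min_split = 5L),
    SVM = list(cost = 1, kernel = "rbf", tolerance = 0.001, max_iter = 100L),
    Tree = list(max_depth = 10L, min_split = 5L, majority_stop = 0.95))
}

#' Construct a classifier specification
#'
#' Returns the fixed hyperparameters of one of the nine classifier families
#' used throughout the pipeline. Hyperparameters are immutable; knobs the
#' protocol leaves implicit are pinned to the backend defaults recorded by
#' [algorithms_lock()].
#'
#' @param name one of [algorithm_names()].
#' @param seed integer seed applied before fitting (stochastic learners).
#' @return a list of class `nir_algorithm`.
#' @export
make_algorithm <- function(name, seed = 1L) {
  if (!(name %in% algorithm_names())) {
    abort("unknown algorithm '%s'; valid names: %s", name,
          paste(algorithm_names(), collapse = ", "))
  }
  structure(list(name = name, hyperparameters = fixed_hyperparameters(name),
                 seed = as.integer(seed)),
            class = "nir_algorithm")
}

prep_X <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  colnames(X) <- paste0("ch", seq_len(ncol(X)))
  X
}

# ---- backends ------------------------------------------------------------

fit_adaboost_samme_r <- function(X, y, n_rounds, lr) {
  df <- as.data.frame(X)
  df$.y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y, 1, -1)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = -1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  stumps <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    p <- pmin(pmax(predict(fit, df)[, "pos"], 1e-7), 1 - 1e-7)
    h <- 0.5 * (log(p) - log1p(-p))   # real-valued stump contribution
    w <- w * exp(-lr * yy * h)
    w <- w / sum(w)
    stumps[[m]] <- fit
  }
  stumps
}

score_adaboost <- function(stumps, X, lr) {
  df <- as.data.frame(X)
  s <- numeric(nrow(X))
  for (fit in stumps) {
    p <- pmin(pmax(predict(fit, df)[, "pos"], 1e-7), 1 - 1e-7)
    s <- s + lr * 0.5 * (log(p) - log1p(-p))
  }
  s
}

fit_mlp_adam <- function(X, y, hidden, max_iter, seed) {
  set.seed(seed)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  n <- nrow(X)
  p <- ncol(X)
  par <- list(W1 = matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden),
              b1 = numeric(hidden),
              W2 = matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), hidden, 1),
              b2 = 0)
  mom <- lapply(par, function(z) z * 0)
  vel <- lapply(par, function(z) z * 0)
  lr <- 1e-3; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  yv <- matrix(as.numeric(y), ncol = 1)
  for (t in seq_len(max_iter)) {   # full-batch Adam on the cross-entropy
    Z1 <- sweep(Xs %*% par$W1, 2, par$b1, "+")
    A1 <- pmax(Z1, 0)
    pr <- 1 / (1 + exp(-(A1 %*% par$W2 + par$b2)))
    dl <- (pr - yv) / n
    dA1 <- dl %*% t(par$W2)
    dZ1 <- dA1 * (Z1 > 0)
    gr <- list(W1 = t(Xs) %*% dZ1, b1 = colSums(dZ1),
               W2 = t(A1) %*% dl, b2 = sum(dl))
    for (nm in names(par)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gr[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gr[[nm]]^2
      m_hat <- mom[[nm]] / (1 - beta1^t)
      v_hat <- vel[[nm]] / (1 - beta2^t)
      par[[nm]] <- par[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
  }
  list(par = par, mu = mu, sdv = sdv)
}

score_mlp <- function(fit, X) {
  Xs <- scale(X, center = fit$mu, scale = fit$sdv)
  A1 <- pmax(sweep(Xs %*% fit$par$W1, 2, fit$par$b1, "+"), 0)
  as.vector(1 / (1 + exp(-(A1 %*% fit$par$W2 + fit$par$b2))))
}

fit_tree_majority_stop <- function(X, y, max_depth, min_split, majority_stop) {
  df <- as.data.frame(X)
  df$.y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minsplit = min_split,
                               cp = 0, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
  fr <- fit$frame
  counts <- fr$yval2[, 2:3, drop = FALSE]
  majority <- apply(counts, 1, max) / rowSums(counts)
  toss <- as.integer(rownames(fr))[fr$var != "<leaf>" & majority >= majority_stop]
  if (length(toss) > 0) fit <- rpart::snip.rpart(fit, toss = toss)
  fit
}

svm_orientation <- function(dv) {
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == "pos") 1 else -1
}

# ---- uniform contract ----------------------------------------------------

#' Fit a classifier
#'
#' Trains the classifier described by `spec` on a samples-by-channels
#' matrix with binary labels. Deterministic given `spec$seed`.
#'
#' @param spec an [make_algorithm()] specification.
#' @param X numeric matrix, samples in rows.
#' @param y logical vector (TRUE = positive class), both classes present
#'   with at least 2 samples each.
#' @return a fitted model of class `nir_model`.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "nir_algorithm"))
  X <- prep_X(X)
  y <- as.logical(y)
  if (anyNA(X) || anyNA(y)) abort("missing values in training data")
  if (length(y) != nrow(X)) abort("label length does not match row count")
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  if (min(table(y)) < 2) abort("each class needs at least 2 training samples")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- switch(spec$name,
    AdaBoost = fit_adaboost_samme_r(X, y, hp$n_estimators, hp$learning_rate),
    GradientBoosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$learning_rate,
                    max_depth = hp$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1),
      nrounds = hp$n_trees, verbose = 0),
    kNN = list(X = X, yf = yf, k = hp$k),
    LogisticRegression = glmnet::glmnet(
      X, yf, family = "binomial", alpha = 0, lambda = 1 / (hp$C * nrow(X)),
      standardize = FALSE),
    NaiveBayes = {
      nb <- e1071::naiveBayes(x = X, y = yf)
      floor_sd <- 1e-9 + 1e-6 * stats::sd(X)
      nb$tables <- lapply(nb$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], floor_sd)  # guard zero within-class variance
        tb
      })
      nb
    },
    NeuralNetwork = fit_mlp_adam(X, y, hp$hidden_neurons, hp$max_iter, spec$seed),
    RandomForest = randomForest::randomForest(
      x = X, y = yf, ntree = hp$n_trees, nodesize = hp$min_split),
    SVM = e1071::svm(
      x = X, y = yf, kernel = "radial", cost = hp$cost,
      gamma = 1 / (ncol(X) * max(stats::var(as.vector(X)), .Machine$double.eps)),
      tolerance = hp$tolerance, scale = FALSE, probability = FALSE),
    Tree = fit_tree_majority_stop(X, y, hp$max_depth, hp$min_split,
                                  hp$majority_stop))
  structure(list(spec = spec, fit = fit, n_channels = ncol(X)),
            class = "nir_model")
}

#' Score samples with a fitted classifier
#'
#' Returns one finite real per row, higher meaning more positive-class:
#' the positive-class probability for probabilistic models, the signed
#' margin for SVM and AdaBoost.
#'
#' @param model a fitted `nir_model`.
#' @param X numeric matrix with the training channel count.
#' @return numeric vector of scores.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "nir_model"))
  X <- prep_X(X)
  if (ncol(X) != model$n_channels) {
    abort("channel mismatch: model trained on %d channels, data has %d",
          model$n_channels, ncol(X))
  }
  hp <- model$spec$hyperparameters
  s <- switch(model$spec$name,
    AdaBoost = score_adaboost(model$fit, X, hp$learning_rate),
    GradientBoosting = predict(model$fit, X),
    kNN = {
      pred <- class::knn(model$fit$X, X, model$fit$yf, k = model$fit$k,
                         prob = TRUE, use.all = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "pos", pr, 1 - pr)
    },
    LogisticRegression = as.vector(predict(model$fit, X, type = "response")),
    NaiveBayes = predict(model$fit, X, type = "raw")[, "pos"],
    NeuralNetwork = score_mlp(model$fit, X),
    RandomForest = predict(model$fit, X, type = "prob")[, "pos"],
    SVM = {
      pr <- predict(model$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      svm_orientation(dv) * as.vector(dv)
    },
    Tree = predict(model$fit, as.data.frame(X), type = "prob")[, "pos"])
  s <- as.numeric(s)
  if (any(!is.finite(s))) abort("non-finite classifier scores")
  unname(s)
}

#' Predict class labels
#'
#' Thresholds [predict_scores()] at the model's natural decision point:
#' 0.5 for probabilistic scores, 0 for margins.
#'
#' @inheritParams predict_scores
#' @return logical vector (TRUE = positive class).
#' @export
predict_classes <- function(model, X) {
  threshold <- if (model$spec$name %in% c("SVM", "AdaBoost")) 0 else 0.5
  predict_scores(model, X) > threshold
}

#' Write the algorithm lock report
#'
#' Records, for each algorithm, the fixed hyperparameters together with the
#' backend implementation and the implicit knobs pinned by this package, so
#' a run can be reproduced exactly.
#'
#' @param path output text file.
#' @param algorithms algorithm names to include.
#' @return `path`, invisibly.
#' @export
algorithms_lock <- function(path, algorithms = algorithm_names()) {
  backend <- c(
    AdaBoost = "in-package SAMME.R boosting of rpart stumps (maxdepth=1, minbucket=1, cp=-1); probabilities clipped at 1e-7",
    GradientBoosting = sprintf("xgboost %s: objective=binary:logistic, nthread=1, remaining knobs at xgboost defaults (lambda=1)", utils::packageVersion("xgboost")),
    kNN = sprintf("class %s knn: use.all=TRUE for distance ties", utils::packageVersion("class")),
    LogisticRegression = sprintf("glmnet %s: alpha=0, lambda=1/(C*n), standardize=FALSE, intercept fitted", utils::packageVersion("glmnet")),
    NaiveBayes = sprintf("e1071 %s naiveBayes: gaussian likelihoods, within-class sd floored at 1e-9 + 1e-6*sd(X)", utils::packageVersion("e1071")),
    NeuralNetwork = "in-package single-hidden-layer MLP: column z-scoring, He init, full-batch Adam (lr=1e-3, beta1=0.9, beta2=0.999, eps=1e-8), cross-entropy loss",
    RandomForest = sprintf("randomForest %s: nodesize=5 (min terminal size), mtry=floor(sqrt(p))", utils::packageVersion("randomForest")),
    SVM = sprintf("e1071 %s svm (libsvm): gamma=1/(p*var(X)), scale=FALSE, shrinking on; libsvm exposes no iteration cap so the cap of 100 is recorded but not enforced", utils::packageVersion("e1071")),
    Tree = sprintf("rpart %s: gini splits, cp=0, then internal nodes with majority >= 95%% snipped", utils::packageVersion("rpart")))
  lines <- c("# algorithms.lock: fixed hyperparameters and pinned backend knobs", "")
  for (a in algorithms) {
    hp <- fixed_hyperparameters(a)
    lines <- c(lines, sprintf("[%s]", a),
               sprintf("  %s = %s", names(hp), vapply(hp, format, character(1))),
               sprintf("  backend: %s", backend[[a]]), "")
  }
  writeLines(lines, path)
  invisible(path)
}
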