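# The classifier zoo. Eleven architectures behind one contract:
#   fit(x, y, hp, seed)  -> opaque fit object
#   prob(fit, x)         -> P(active) in [0, 1] for every row
# x is the model-ready matrix from features_matrix() (scaled descriptors +
# fingerprint bits); y is an integer 0/1 vector. Every architecture is
# deterministic given the seed.

# ---- in-package learners ------------------------------------------------

# Full-batch steepest-descent logistic classifier (linear model trained by
# gradient descent on the cross-entropy loss, optional L2 penalty).
fit_sgd_linear <- function(x, y, lr = 0.1, epochs = 200, l2 = 1e-4) {
  x1 <- cbind(1, x)
  w <- numeric(ncol(x1))
  n <- nrow(x1)
  for (i in seq_len(epochs)) {
    p <- plogis(as.vector(x1 %*% w))
    g <- as.vector(crossprod(x1, p - y)) / n + l2 * c(0, w[-1])
    w <- w - lr * g
  }
  list(w = w)
}
predict_sgd_linear <- function(fit, x) plogis(as.vector(cbind(1, x) %*% fit$w))

# Classical AdaBoost (SAMME) over shallow rpart trees. Probability via the
# logistic of the aggregated margin.
fit_adaboost <- function(x, y, n_estimators = 50, maxdepth = 1, learning_rate = 1) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}
predict_adaboost <- function(fit, x) {
  df <- as.data.frame(x)
  if (length(fit$stumps) == 0) return(rep(0.5, nrow(df)))
  f <- numeric(nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- as.integer(as.character(predict(fit$stumps[[m]], df, type = "class")))
    f <- f + fit$alphas[m] * (2 * pred - 1)
  }
  plogis(2 * f)
}

# ---- architecture registry ---------------------------------------------

xgb_fit <- function(x, y, params, nrounds, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = y)
  params <- c(params, list(objective = "binary:logistic", nthread = 1, seed = seed))
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds, verbose = 0)
}
xgb_prob <- function(fit, x) as.numeric(predict(fit, xgboost::xgb.DMatrix(x)))

zoo_registry <- function() {
  list(
    naive_bayes = list(
      default = list(),
      space = list(),
      fit = function(x, y, hp, seed) {
        keep <- apply(x, 2, function(col) stats::var(col) > 0)
        m <- e1071::naiveBayes(x = as.data.frame(x[, keep, drop = FALSE]),
                               y = factor(y, levels = c(0, 1)))
        # guard class-conditional zero variances
        m$tables <- lapply(m$tables, function(tab) {
          tab[, 2] <- pmax(tab[, 2], 1e-3); tab
        })
        list(model = m, keep = keep)
      },
      prob = function(fit, x) {
        p <- predict(fit$model, as.data.frame(x[, fit$keep, drop = FALSE]), type = "raw")
        as.numeric(p[, "1"])
      }
    ),
    sgd_linear = list(
      default = list(lr = 0.1, epochs = 200, l2 = 1e-4),
      space = list(lr = c(0.01, 0.05, 0.1, 0.3), epochs = c(100, 200, 400),
                   l2 = c(0, 1e-4, 1e-3)),
      fit = function(x, y, hp, seed) fit_sgd_linear(x, y, hp$lr, hp$epochs, hp$l2),
      prob = predict_sgd_linear
    ),
    decision_tree = list(
      default = list(maxdepth = 30, cp = 0.001, minsplit = 20),
      space = list(maxdepth = c(1, 2, 4, 8, 16, 30), cp = c(1e-4, 1e-3, 1e-2),
                   minsplit = c(5, 20)),
      fit = function(x, y, hp, seed) {
        df <- as.data.frame(x); df$.y <- factor(y, levels = c(0, 1))
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(maxdepth = hp$maxdepth,
                                                    cp = hp$cp,
                                                    minsplit = hp$minsplit,
                                                    xval = 0))
      },
      prob = function(fit, x) as.numeric(predict(fit, as.data.frame(x), type = "prob")[, "1"])
    ),
    random_forest = list(
      default = list(num.trees = 300, mtry_frac = 0.1, min.node.size = 5),
      space = list(num.trees = c(100, 300, 500), mtry_frac = c(0.05, 0.1, 0.3, 0.6),
                   min.node.size = c(1, 5, 10)),
      fit = function(x, y, hp, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
                       num.trees = hp$num.trees,
                       mtry = max(1, floor(hp$mtry_frac * ncol(x))),
                       min.node.size = hp$min.node.size,
                       seed = seed, num.threads = 1)
      },
      prob = function(fit, x) as.numeric(predict(fit, data = x, num.threads = 1)$predictions[, "1"])
    ),
    extra_trees = list(
      default = list(num.trees = 300, mtry_frac = 0.1, min.node.size = 5),
      space = list(num.trees = c(100, 300, 500), mtry_frac = c(0.05, 0.1, 0.3, 0.6),
                   min.node.size = c(1, 5, 10)),
      fit = function(x, y, hp, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
                       num.trees = hp$num.trees,
                       mtry = max(1, floor(hp$mtry_frac * ncol(x))),
                       min.node.size = hp$min.node.size,
                       splitrule = "extratrees", replace = FALSE,
                       sample.fraction = 1,
                       seed = seed, num.threads = 1)
      },
      prob = function(fit, x) as.numeric(predict(fit, data = x, num.threads = 1)$predictions[, "1"])
    ),
    knn = list(
      default = list(k = 5),
      space = list(k = c(1, 3, 5, 7, 11, 15)),
      fit = function(x, y, hp, seed) list(x = x, y = factor(y, levels = c(0, 1)),
                                          k = hp$k, seed = seed),
      prob = function(fit, x) {
        # tie-breaking in class::knn is randomized; pin it to the fit seed
        withr::with_seed(fit$seed, {
          pred <- class::knn(train = fit$x, test = x, cl = fit$y,
                             k = min(fit$k, nrow(fit$x)), prob = TRUE)
        })
        win <- attr(pred, "prob")
        ifelse(pred == "1", win, 1 - win)
      }
    ),
    mlp = list(
      default = list(size = 16, decay = 1e-3, maxit = 150),
      space = list(size = c(4, 8, 16, 32), decay = c(0, 1e-4, 1e-3, 1e-2),
                   maxit = c(100, 200)),
      fit = function(x, y, hp, seed) {
        args <- list(x = x, y = y, size = hp$size, decay = hp$decay,
                     maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                     MaxNWts = (ncol(x) + 2) * hp$size + hp$size + 50)
        if (!is.null(hp$Wts)) args$Wts <- hp$Wts   # warm-start continuation
        withr::with_seed(seed, do.call(nnet::nnet, args))
      },
      prob = function(fit, x) as.numeric(predict(fit, x))
    ),
    adaboost = list(
      default = list(n_estimators = 50, maxdepth = 1, learning_rate = 1),
      space = list(n_estimators = c(25, 50, 100), maxdepth = c(1, 2, 3),
                   learning_rate = c(0.5, 1)),
      fit = function(x, y, hp, seed) {
        fit_adaboost(x, y, hp$n_estimators, hp$maxdepth, hp$learning_rate)
      },
      prob = predict_adaboost
    ),
    gradient_boosting = list(
      default = list(nrounds = 150, eta = 0.1, max_depth = 3),
      space = list(nrounds = c(50, 150, 300), eta = c(0.05, 0.1, 0.3),
                   max_depth = c(2, 3, 5)),
      fit = function(x, y, hp, seed) {
        xgb_fit(x, y, list(eta = hp$eta, max_depth = hp$max_depth,
                           subsample = 1, colsample_bytree = 1,
                           lambda = 0, tree_method = "exact"),
                hp$nrounds, seed)
      },
      prob = xgb_prob
    ),
    svc = list(
      default = list(cost = 1, gamma = 0.01),
      space = list(cost = c(0.1, 1, 10), gamma = c(0.001, 0.01, 0.1)),
      fit = function(x, y, hp, seed) {
        withr::with_seed(seed, {
          e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = hp$cost, gamma = hp$gamma, probability = TRUE)
        })
      },
      prob = function(fit, x) {
        p <- attr(predict(fit, x, probability = TRUE), "probabilities")
        as.numeric(p[, "1"])
      }
    ),
    xgboost = list(
      default = list(nrounds = 150, eta = 0.1, max_depth = 5,
                     subsample = 0.8, colsample_bytree = 0.8, lambda = 1),
      space = list(nrounds = c(50, 150, 300), eta = c(0.05, 0.1, 0.3),
                   max_depth = c(3, 5, 7), subsample = c(0.7, 1),
                   colsample_bytree = c(0.7, 1), lambda = c(0, 1)),
      fit = function(x, y, hp, seed) {
        xgb_fit(x, y, list(eta = hp$eta, max_depth = hp$max_depth,
                           subsample = hp$subsample,
                           colsample_bytree = hp$colsample_bytree,
                           lambda = hp$lambda),
                hp$nrounds, seed)
      },
      prob = xgb_prob
    )
  )
}

#' Names of the configured classifier architectures
#'
#' The zoo covers naive Bayes, a gradient-descent linear classifier, a
#' decision tree, random forest, extremely randomized trees, k-nearest
#' neighbours, a multilayer perceptron, AdaBoost, gradient boosting, a
#' support-vector classifier, and extreme gradient boosting — all behind
#' one probability-emitting contract.
#'
#' @return Character vector of architecture names.
#' @export
zoo_architectures <- function() names(zoo_registry())

get_architecture <- function(name) {
  reg <- zoo_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("unknown architecture '%s'; available: %s",
                  name, paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

#' Default hyperparameters of an architecture
#' @param architecture Architecture name (see [zoo_architectures()]).
#' @export
default_hyperparameters <- function(architecture) get_architecture(architecture)$default

fit_architecture <- function(architecture, x, y, hyperparameters = NULL, seed = 1) {
  arch <- get_architecture(architecture)
  hp <- modifyList(arch$default, hyperparameters %||% list())
  y <- check_both_classes(y)
  fit <- withr::with_seed(seed, arch$fit(x, y, hp, seed))
  structure(list(architecture = architecture, fit = fit, hyperparameters = hp,
                 seed = seed, n_features = ncol(x)),
            class = "fluid_fit")
}

prob_architecture <- function(fitobj, x) {
  stopifnot(inherits(fitobj, "fluid_fit"))
  if (ncol(x) != fitobj$n_features) {
    abort("feature matrix width does not match the fitted model.")
  }
  p <- get_architecture(fitobj$architecture)$prob(fitobj$fit, x)
  pmin(pmax(as.numeric(p), 0), 1)
}
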