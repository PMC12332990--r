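# Per-side AI classifiers.  The panel mirrors the commonly used model set
# (random forest, logistic regression, linear SVM, k-nearest neighbours,
# gradient boosting, Gaussian naive Bayes); random forest, SVM, boosting
# and naive Bayes are compact native implementations (no heavyweight ML
# stack is assumed), logistic uses stats::glm and kNN uses FNN.

SUPPORTED_MODELS <- c("random_forest", "logistic", "svm", "knn",
                      "gradient_boosting", "naive_bayes")

# ---- CART-style trees (shared by random forest and boosting) ---------------

build_tree <- function(X, y, mtry, max_depth, min_node, criterion = "gini",
                       depth = 0L) {
  n <- nrow(X)
  leaf <- function() list(leaf = TRUE, value = mean(y))
  if (depth >= max_depth || n < 2L * min_node || length(unique(y)) == 1L)
    return(leaf())
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  impurity <- function(v) {
    if (criterion == "gini") { p <- mean(v); length(v) * 2 * p * (1 - p) }
    else sum((v - mean(v))^2)
  }
  best <- list(score = impurity(y) - 1e-10)
  for (j in feats) {
    xs <- X[, j]
    cuts <- unique(stats::quantile(xs, probs = seq(0.1, 0.9, by = 0.1),
                                   type = 7, names = FALSE))
    for (cut in cuts) {
      l <- xs <= cut
      if (sum(l) < min_node || sum(!l) < min_node) next
      sc <- impurity(y[l]) + impurity(y[!l])
      if (sc < best$score) best <- list(score = sc, j = j, cut = cut, l = l)
    }
  }
  if (is.null(best$j)) return(leaf())
  list(leaf = FALSE, j = best$j, cut = best$cut,
       left = build_tree(X[best$l, , drop = FALSE], y[best$l], mtry,
                         max_depth, min_node, criterion, depth + 1L),
       right = build_tree(X[!best$l, , drop = FALSE], y[!best$l], mtry,
                          max_depth, min_node, criterion, depth + 1L))
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    l <- X[idx, node$j] <= node$cut
    rec(node$left, idx[l]); rec(node$right, idx[!l])
  }
  rec(tree, seq_len(n))
  out
}

# ---- individual models ------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

fit_one_model <- function(name, X, y, seed) {
  set.seed(seed)
  switch(
    name,
    random_forest = {
      ntree <- 200L
      mtry <- max(1L, floor(sqrt(ncol(X))))
      trees <- lapply(seq_len(ntree), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        build_tree(X[idx, , drop = FALSE], y[idx], mtry,
                   max_depth = 10L, min_node = 2L, criterion = "gini")
      })
      list(predict = function(Xn) {
        preds <- vapply(trees, function(tr) predict_tree(tr, Xn),
                        numeric(nrow(Xn)))
        rowMeans(matrix(preds, nrow = nrow(Xn)))
      })
    },
    logistic = {
      df <- data.frame(y = y, X)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      list(predict = function(Xn)
        suppressWarnings(as.numeric(stats::predict(
          fit, newdata = data.frame(Xn), type = "response"))))
    },
    svm = {
      # linear SVM via Pegasos stochastic subgradient descent
      mu <- colMeans(X); sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
      Xs <- scale(X, mu, sdv)
      ys <- ifelse(y == 1, 1, -1)
      lambda <- 0.01
      w <- numeric(ncol(X)); b <- 0
      Tit <- 50L * nrow(X)
      order_idx <- sample.int(nrow(X), Tit, replace = TRUE)
      for (t in seq_len(Tit)) {
        i <- order_idx[t]
        eta <- 1 / (lambda * t)
        margin <- ys[i] * (sum(w * Xs[i, ]) + b)
        w <- (1 - eta * lambda) * w
        if (margin < 1) {
          w <- w + eta * ys[i] * Xs[i, ]
          b <- b + eta * ys[i]
        }
      }
      list(predict = function(Xn)
        sigmoid(as.numeric(scale(Xn, mu, sdv) %*% w + b)))
    },
    knn = {
      k <- min(5L, nrow(X) - 1L)
      list(predict = function(Xn) {
        nn <- FNN::knnx.index(X, Xn, k = k)
        rowMeans(matrix(y[nn], nrow = nrow(Xn)))
      })
    },
    gradient_boosting = {
      M <- 100L; shrink <- 0.1
      p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
      F0 <- log(p0 / (1 - p0))
      Fv <- rep(F0, nrow(X))
      trees <- vector("list", M)
      for (m in seq_len(M)) {
        r <- y - sigmoid(Fv)
        tr <- build_tree(X, r, mtry = ncol(X), max_depth = 2L,
                         min_node = 3L, criterion = "sse")
        trees[[m]] <- tr
        Fv <- Fv + shrink * predict_tree(tr, X)
      }
      list(predict = function(Xn) {
        Fn <- rep(F0, nrow(Xn))
        for (tr in trees) Fn <- Fn + shrink * predict_tree(tr, Xn)
        sigmoid(Fn)
      })
    },
    naive_bayes = {
      stats_by <- lapply(c(0, 1), function(cl) {
        Xi <- X[y == cl, , drop = FALSE]
        list(mu = colMeans(Xi),
             var = pmax(apply(Xi, 2, stats::var), 1e-9),
             prior = mean(y == cl))
      })
      list(predict = function(Xn) {
        ll <- vapply(1:2, function(ci) {
          st <- stats_by[[ci]]
          rowSums(t(stats::dnorm(t(Xn), st$mu, sqrt(st$var), log = TRUE))) +
            log(st$prior)
        }, numeric(nrow(Xn)))
        ll <- matrix(ll, ncol = 2)
        1 / (1 + exp(ll[, 1] - ll[, 2]))
      })
    },
    stop("unknown model '", name, "'; supported: ",
         paste(SUPPORTED_MODELS, collapse = ", "))
  )
}

#' Fit and compare per-side AI classifiers
#'
#' Fits every named model on the training split of the feature table
#' (restricted to the selected features), scores the validation split, and
#' flags the model with the highest validation AUC as selected.  Fully
#' seeded; default hyperparameters are fixed, common choices.
#'
#' @param table a `FeatureTable` (see [build_feature_table()]).
#' @param selection a `FeatureSelection` for the same side.
#' @param model_set subset of
#'   `c("random_forest", "logistic", "svm", "knn", "gradient_boosting",
#'   "naive_bayes")`.
#' @param seed integer.
#' @param train_split,valid_split split names used for fitting and scoring.
#' @return A `ClassifierBench`: list(side, models, roc, scores, labels,
#'   selected, selection).
#' @export
fit_classifiers <- function(table, selection, model_set = SUPPORTED_MODELS,
                            seed = 1, train_split = "train",
                            valid_split = "valid") {
  unknown <- setdiff(model_set, SUPPORTED_MODELS)
  if (length(unknown))
    stop("unknown model name(s) ", paste(unknown, collapse = ", "),
         "; supported: ", paste(SUPPORTED_MODELS, collapse = ", "))
  stopifnot(inherits(selection, "FeatureSelection"),
            length(selection$selected) >= 1)
  side <- selection$side
  rows <- table[table$side == side, ]
  tr <- rows[rows$split == train_split, ]
  va <- rows[rows$split == valid_split, ]
  if (length(unique(tr$label)) < 2L)
    stop("training split for side '", side, "' has a single class")
  Xtr <- as.matrix(tr[, selection$selected, drop = FALSE])
  Xva <- as.matrix(va[, selection$selected, drop = FALSE])
  seeds <- derive_seeds(seed, length(model_set), salt = 71L)
  models <- list(); rocs <- list(); scores <- list()
  for (i in seq_along(model_set)) {
    nm <- model_set[i]
    models[[nm]] <- fit_one_model(nm, Xtr, tr$label, seeds[i])
    s <- models[[nm]]$predict(Xva)
    scores[[nm]] <- s
    rocs[[nm]] <- roc_auc(s, va$label)
  }
  aucs <- vapply(rocs, function(r) r$auc, numeric(1))
  structure(list(side = side, models = models, roc = rocs, scores = scores,
                 labels = va$label, ids = va$id,
                 selected = names(which.max(aucs)), selection = selection,
                 features = selection$selected),
            class = "ClassifierBench")
}

#' @export
print.ClassifierBench <- function(x, ...) {
  cat(sprintf("<ClassifierBench> side %s, %d features\n", x$side,
              length(x$features)))
  for (nm in names(x$roc))
    cat(sprintf("  %-18s AUC %.4f%s\n", nm, x$roc[[nm]]$auc,
                if (nm == x$selected) "  <- selected" else ""))
  invisible(x)
}

#' Score a fitted classifier bench on new feature rows
#'
#' @param bench a `ClassifierBench`.
#' @param table a `FeatureTable` containing the bench's side and features.
#' @param model model name; default the selected one.
#' @param split optional split filter.
#' @return data.frame(id, label, score).
#' @export
score_cohort <- function(bench, table, model = bench$selected, split = NULL) {
  rows <- table[table$side == bench$side, ]
  if (!is.null(split)) rows <- rows[rows$split %in% split, ]
  X <- as.matrix(rows[, bench$features, drop = FALSE])
  data.frame(id = rows$id, label = rows$label,
             score = bench$models[[model]]$predict(X))
}

#' Validation-style performance summary at the Youden threshold
#'
#' For one side: selected model, AUC with CI, Youden-optimal threshold and
#' confusion-derived accuracy/sensitivity/specificity -- the per-side rows
#' of the usual performance tables.
#'
#' @param bench a `ClassifierBench`.
#' @param threshold optional fixed threshold; default the Youden optimum
#'   on the bench's validation scores.
#' @return one-row data.frame.
#' @export
summarize_bench <- function(bench, threshold = NULL) {
  roc <- bench$roc[[bench$selected]]
  if (is.null(threshold)) {
    yt <- suppressMessages(youden_threshold(roc))
    threshold <- yt[["threshold"]]
  }
  cm <- confusion_at_threshold(bench$scores[[bench$selected]], bench$labels,
                               threshold)
  data.frame(side = bench$side, model = bench$selected,
             acc = 100 * cm$accuracy, auc = 100 * roc$auc,
             auc_lo = 100 * roc$ci95[1], auc_hi = 100 * roc$ci95[2],
             sens = 100 * cm$sensitivity, spec = 100 * cm$specificity,
             threshold = threshold)
}
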